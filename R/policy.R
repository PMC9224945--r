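#' @include AllClasses.R
NULL

XACML_NS <- "urn:oasis:names:tc:xacml:3.0:core:schema:wd-17"
CATEGORY_SUBJECT <- "urn:oasis:names:tc:xacml:1.0:subject-category:access-subject"
CATEGORY_ACTION <- "urn:oasis:names:tc:xacml:3.0:attribute-category:action"
CATEGORY_ENVIRONMENT <-
  "urn:oasis:names:tc:xacml:3.0:attribute-category:environment"
ATTR_ACTION_ID <- "action-id"

# ---- constructors -----------------------------------------------------------

#' Construct a request attribute
#'
#' @param attributeId attribute identifier.
#' @param value single string, integer-valued number, or logical; the
#'   datatype is inferred from the R type.
#' @param category attribute category; defaults to the XACML subject
#'   category for \code{role} and \code{subject-id}, the action category for
#'   \code{action-id}, and the environment category otherwise.
#' @return an \code{\link{AttributeValue}}.
#' @export
attributeValue <- function(attributeId, value, category = NULL) {
  datatype <- if (is.logical(value)) "boolean"
  else if (is.numeric(value)) "integer"
  else "string"
  if (datatype == "integer") value <- as.numeric(value)
  if (is.null(category))
    category <- if (attributeId %in% c("role", "subject-id"))
      CATEGORY_SUBJECT
    else if (attributeId == ATTR_ACTION_ID) CATEGORY_ACTION
    else CATEGORY_ENVIRONMENT
  new("AttributeValue", category = category, attributeId = attributeId,
      datatype = datatype, value = value)
}

#' Construct an authorization request
#'
#' @param ... \code{\link{AttributeValue}} objects, or named arguments that
#'   are passed to \code{\link{attributeValue}} (name = attribute id).
#' @return an \code{\link{AuthzRequest}}.
#' @examples
#' authzRequest(role = "practitioner", `action-id` = "GetDataBySimpleFilter",
#'              situation = "Emergency", read_count = 1200)
#' @export
authzRequest <- function(...) {
  args <- list(...)
  attrs <- vector("list", length(args))
  nms <- names(args)
  for (i in seq_along(args)) {
    attrs[[i]] <- if (is(args[[i]], "AttributeValue")) args[[i]]
    else attributeValue(nms[i], args[[i]])
  }
  new("AuthzRequest", attributes = attrs)
}

#' Fetch an attribute value from a request
#'
#' @param request an \code{\link{AuthzRequest}}.
#' @param attributeId attribute id.
#' @return the \code{\link{AttributeValue}}, or NULL when absent.
#' @export
requestAttribute <- function(request, attributeId) {
  for (a in request@attributes)
    if (a@attributeId == attributeId) return(a)
  NULL
}

#' Add or replace an attribute in a request
#'
#' @param request an \code{\link{AuthzRequest}}.
#' @param attr an \code{\link{AttributeValue}}.
#' @return the updated request.
#' @export
setRequestAttribute <- function(request, attr) {
  ids <- vapply(request@attributes, slot, character(1), "attributeId")
  attrs <- request@attributes[ids != attr@attributeId]
  initialize(request, attributes = c(attrs, list(attr)))
}

#' Construct a rule condition
#'
#' @param attributeId attribute id (two ids, start and end, for
#'   \code{integer-range-within}).
#' @param operator one of \code{equals}, \code{boolean-equals},
#'   \code{integer-at-most}, \code{integer-range-within}.
#' @param value the constant operand (\code{c(lo, hi)} for range-within).
#' @return a \code{\link{Condition}}.
#' @export
xacmlCondition <- function(attributeId, operator, value) {
  if (is.numeric(value)) value <- as.numeric(value)
  new("Condition", attributeId = attributeId, operator = operator,
      value = value)
}

#' Construct a privacy rule
#'
#' @param ruleId rule identifier.
#' @param effect \code{"Permit"} or \code{"Deny"}.
#' @param role required subject role, or NULL for any.
#' @param action required action id, or NULL for any.
#' @param conditions list of \code{\link{Condition}} objects.
#' @return a \code{\link{PolicyRule}}.
#' @export
policyRule <- function(ruleId, effect = "Permit", role = NULL, action = NULL,
                       conditions = list()) {
  new("PolicyRule", ruleId = ruleId, effect = effect,
      targetRole = if (is.null(role)) character(0) else role,
      targetAction = if (is.null(action)) character(0) else action,
      conditions = conditions)
}

#' Construct a policy
#'
#' @param policyId policy identifier.
#' @param rules list of \code{\link{PolicyRule}} objects.
#' @param combining rule-combining algorithm: \code{deny-overrides}
#'   (default), \code{permit-overrides} or \code{first-applicable}.
#' @return a \code{\link{XacmlPolicy}}.
#' @export
xacmlPolicy <- function(policyId, rules = list(),
                        combining = "deny-overrides") {
  new("XacmlPolicy", policyId = policyId, rules = rules,
      combining = combining)
}

decision <- function(outcome, matchedRuleIds = character(0)) {
  new("Decision", outcome = outcome, matchedRuleIds = matchedRuleIds)
}

# ---- evaluation -------------------------------------------------------------

conditionTypeOk <- function(cond, attr) {
  switch(cond@operator,
    "equals" = (is.character(cond@value) && attr@datatype == "string") ||
               (is.numeric(cond@value) && attr@datatype == "integer"),
    "boolean-equals" = attr@datatype == "boolean",
    "integer-at-most" = attr@datatype == "integer",
    "integer-range-within" = attr@datatype == "integer")
}

# Evaluates one condition: TRUE, FALSE, or NA for indeterminate (missing or
# ill-typed attribute).
evalCondition <- function(cond, request) {
  if (cond@operator == "integer-range-within") {
    a1 <- requestAttribute(request, cond@attributeId[1])
    a2 <- requestAttribute(request, cond@attributeId[2])
    if (is.null(a1) || is.null(a2)) return(NA)
    if (a1@datatype != "integer" || a2@datatype != "integer") return(NA)
    return(a1@value >= cond@value[1] && a2@value <= cond@value[2])
  }
  attr <- requestAttribute(request, cond@attributeId)
  if (is.null(attr)) return(NA)
  if (!conditionTypeOk(cond, attr)) return(NA)
  switch(cond@operator,
    "equals" = identical(as.character(attr@value),
                         as.character(cond@value)) ||
               (is.numeric(cond@value) && attr@value == cond@value),
    "boolean-equals" = attr@value == cond@value,
    "integer-at-most" = attr@value <= cond@value)
}

#' Evaluate a single rule against a request
#'
#' The rule's target (role and action) is matched first; a mismatch or a
#' missing target attribute yields \code{NotApplicable}.  With a matching
#' target, the conditions are evaluated as a conjunction: any false condition
#' yields \code{NotApplicable}, any condition whose attribute is missing or
#' ill-typed (with no false condition) yields \code{Indeterminate}, and when
#' all hold the rule's effect is returned.
#'
#' @param rule a \code{\link{PolicyRule}}.
#' @param request an \code{\link{AuthzRequest}}.
#' @return a \code{\link{Decision}}.
#' @export
evaluateRule <- function(rule, request) {
  matchTarget <- function(required, attributeId) {
    if (!length(required)) return(TRUE)
    attr <- requestAttribute(request, attributeId)
    !is.null(attr) && attr@datatype == "string" &&
      identical(attr@value, required)
  }
  if (!matchTarget(rule@targetRole, "role") ||
      !matchTarget(rule@targetAction, ATTR_ACTION_ID))
    return(decision("NotApplicable"))
  results <- vapply(rule@conditions, evalCondition, logical(1),
                    request = request)
  if (any(results %in% FALSE)) return(decision("NotApplicable"))
  if (any(is.na(results))) return(decision("Indeterminate", rule@ruleId))
  decision(rule@effect, rule@ruleId)
}

#' Evaluate a policy against a request
#'
#' All rules are evaluated and combined by the policy's algorithm:
#' \describe{
#'   \item{deny-overrides}{any applicable Deny wins; otherwise any
#'     Indeterminate; otherwise any Permit; otherwise NotApplicable.}
#'   \item{permit-overrides}{mirror image: Permit wins.}
#'   \item{first-applicable}{the first rule whose decision is not
#'     NotApplicable.}
#' }
#' A policy with no applicable rule returns \code{NotApplicable}, which every
#' caller in this package treats as not granted.  The decision is a pure
#' function of (policy, request).
#'
#' @param policy a \code{\link{XacmlPolicy}}.
#' @param request an \code{\link{AuthzRequest}}.
#' @return a \code{\link{Decision}}.
#' @export
evaluatePolicy <- function(policy, request) {
  ds <- lapply(policy@rules, evaluateRule, request = request)
  outcomes <- vapply(ds, slot, character(1), "outcome")
  ruleFor <- function(o) {
    ids <- unlist(lapply(ds[outcomes == o], slot, "matchedRuleIds"))
    if (is.null(ids)) character(0) else ids
  }
  if (policy@combining == "first-applicable") {
    for (d in ds) if (d@outcome != "NotApplicable") return(d)
    return(decision("NotApplicable"))
  }
  order <- if (policy@combining == "deny-overrides")
    c("Deny", "Indeterminate", "Permit")
  else c("Permit", "Indeterminate", "Deny")
  for (o in order)
    if (any(outcomes == o)) return(decision(o, ruleFor(o)))
  decision("NotApplicable")
}

# ---- worked example ---------------------------------------------------------

#' The worked-example privacy rule and request
#'
#' Builds the package's reference fixture: a rule permitting the role
#' \code{practitioner} to execute \code{GetDataBySimpleFilter} under an
#' emergency situation, for a read count of at most 5000, without multiple
#' alignments, on reference sequence 4, for a requested region contained in
#' positions 40,810,027 to 41,216,714 (both extremes included) -- conditions
#' of the kind used to protect genome regions linked to Alzheimer's disease
#' predisposition.  The companion request carries a different role (plus a
#' date attribute that no condition matches), so evaluating it yields a
#' not-granted decision.
#'
#' @return list with elements \code{policy} (a \code{\link{XacmlPolicy}}
#'   holding the single rule) and \code{request} (the non-matching
#'   \code{\link{AuthzRequest}}).
#' @examples
#' wx <- buildWorkedExample()
#' outcome(evaluatePolicy(wx$policy, wx$request))
#' @export
buildWorkedExample <- function() {
  rule <- policyRule(
    ruleId = "alzheimer-region-access", effect = "Permit",
    role = "practitioner", action = "GetDataBySimpleFilter",
    conditions = list(
      xacmlCondition("situation", "equals", "Emergency"),
      xacmlCondition("read_count", "integer-at-most", 5000),
      xacmlCondition("presence_of_multiple_alignments", "boolean-equals",
                     FALSE),
      xacmlCondition("reference_id", "equals", 4),
      xacmlCondition(c("start_position", "end_position"),
                     "integer-range-within", c(40810027, 41216714))))
  request <- authzRequest(
    role = "researcher",
    `action-id` = "GetDataBySimpleFilter",
    date = "2022-05-31")
  list(policy = xacmlPolicy("alzheimer-region-policy", list(rule)),
       request = request)
}

#' A request matching every constraint of the worked-example rule
#'
#' Convenience companion to \code{\link{buildWorkedExample}}: role
#' practitioner, action GetDataBySimpleFilter, emergency situation, read
#' count at the cap, no multiple alignments, reference 4, and the full
#' permitted interval as the requested range.  Individual attributes can be
#' overridden through \code{...}.
#'
#' @param ... named values replacing individual attributes (as in
#'   \code{\link{authzRequest}}).
#' @return an \code{\link{AuthzRequest}}.
#' @export
workedExampleMatchingRequest <- function(...) {
  req <- authzRequest(
    role = "practitioner",
    `action-id` = "GetDataBySimpleFilter",
    situation = "Emergency",
    read_count = 5000,
    presence_of_multiple_alignments = FALSE,
    reference_id = 4,
    start_position = 40810027,
    end_position = 41216714)
  overrides <- list(...)
  for (nm in names(overrides))
    req <- setRequestAttribute(req, attributeValue(nm, overrides[[nm]]))
  req
}
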
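#' @include policy.R
NULL

# XACML 3.0 XML subset: Policy > Rule > Target/Condition with
# Apply/AttributeDesignator/AttributeValue, and Request > Attributes.
# Anything outside the subset raises an "xacml_unsupported_feature"
# condition naming the offending element or function.

XS_STRING <- "http://www.w3.org/2001/XMLSchema#string"
XS_INTEGER <- "http://www.w3.org/2001/XMLSchema#integer"
XS_BOOLEAN <- "http://www.w3.org/2001/XMLSchema#boolean"

FN_STRING_EQUAL <- "urn:oasis:names:tc:xacml:1.0:function:string-equal"
FN_INTEGER_EQUAL <- "urn:oasis:names:tc:xacml:1.0:function:integer-equal"
FN_BOOLEAN_EQUAL <- "urn:oasis:names:tc:xacml:1.0:function:boolean-equal"
FN_INTEGER_LE <-
  "urn:oasis:names:tc:xacml:1.0:function:integer-less-than-or-equal"
FN_AND <- "urn:oasis:names:tc:xacml:1.0:function:and"
FN_RANGE_WITHIN <- "urn:genomicvault:function:integer-range-within"
ATTR_ACTION_ID_URN <- "urn:oasis:names:tc:xacml:1.0:action:action-id"
COMBINING_URN_PREFIX <- "urn:oasis:names:tc:xacml:3.0:rule-combining-algorithm:"

unsupportedXacml <- function(what) {
  structure(class = c("xacml_unsupported_feature", "error", "condition"),
            list(message = sprintf("unsupported XACML feature: %s", what),
                 call = NULL))
}

datatypeUrn <- function(datatype) {
  switch(datatype, string = XS_STRING, integer = XS_INTEGER,
         boolean = XS_BOOLEAN)
}

xacmlLiteral <- function(value) {
  if (is.logical(value)) tolower(as.character(value))
  else if (is.numeric(value)) format(value, scientific = FALSE)
  else as.character(value)
}

# ---- serialization ----------------------------------------------------------

addAttributeValueNode <- function(parent, value, datatype) {
  node <- xml2::xml_add_child(parent, "AttributeValue",
                              xacmlLiteral(value))
  xml2::xml_set_attr(node, "DataType", datatypeUrn(datatype))
  node
}

addDesignatorNode <- function(parent, attributeId, datatype,
                              category = CATEGORY_ENVIRONMENT) {
  node <- xml2::xml_add_child(parent, "AttributeDesignator")
  xml2::xml_set_attrs(node, c(Category = category,
                              AttributeId = attributeId,
                              DataType = datatypeUrn(datatype),
                              MustBePresent = "false"))
  node
}

addConditionApply <- function(parent, cond) {
  switch(cond@operator,
    "equals" = {
      dt <- if (is.numeric(cond@value)) "integer" else "string"
      node <- xml2::xml_add_child(parent, "Apply")
      xml2::xml_set_attr(node, "FunctionId",
                         if (dt == "integer") FN_INTEGER_EQUAL
                         else FN_STRING_EQUAL)
      addDesignatorNode(node, cond@attributeId, dt)
      addAttributeValueNode(node, cond@value, dt)
    },
    "boolean-equals" = {
      node <- xml2::xml_add_child(parent, "Apply")
      xml2::xml_set_attr(node, "FunctionId", FN_BOOLEAN_EQUAL)
      addDesignatorNode(node, cond@attributeId, "boolean")
      addAttributeValueNode(node, cond@value, "boolean")
    },
    "integer-at-most" = {
      node <- xml2::xml_add_child(parent, "Apply")
      xml2::xml_set_attr(node, "FunctionId", FN_INTEGER_LE)
      addDesignatorNode(node, cond@attributeId, "integer")
      addAttributeValueNode(node, cond@value, "integer")
    },
    "integer-range-within" = {
      node <- xml2::xml_add_child(parent, "Apply")
      xml2::xml_set_attr(node, "FunctionId", FN_RANGE_WITHIN)
      addDesignatorNode(node, cond@attributeId[1], "integer")
      addDesignatorNode(node, cond@attributeId[2], "integer")
      addAttributeValueNode(node, cond@value[1], "integer")
      addAttributeValueNode(node, cond@value[2], "integer")
    })
  invisible(parent)
}

addTargetMatch <- function(target, attributeId, value, category) {
  anyOf <- xml2::xml_add_child(target, "AnyOf")
  allOf <- xml2::xml_add_child(anyOf, "AllOf")
  match <- xml2::xml_add_child(allOf, "Match")
  xml2::xml_set_attr(match, "MatchId", FN_STRING_EQUAL)
  addAttributeValueNode(match, value, "string")
  addDesignatorNode(match, attributeId, "string", category)
  invisible(target)
}

#' Serialize a policy to XACML XML
#'
#' Emits the XACML 3.0 subset this package evaluates; the output parses back
#' to an equal policy through \code{\link{parsePolicyXml}}.
#'
#' @param policy a \code{\link{XacmlPolicy}}.
#' @return raw vector of UTF-8 XML bytes.
#' @export
serializePolicyXml <- function(policy) {
  doc <- xml2::read_xml(sprintf('<Policy xmlns="%s"/>', XACML_NS))
  xml2::xml_set_attr(doc, "PolicyId", policy@policyId)
  xml2::xml_set_attr(doc, "Version", "1.0")
  xml2::xml_set_attr(doc, "RuleCombiningAlgId",
                     paste0(COMBINING_URN_PREFIX, policy@combining))
  xml2::xml_add_child(doc, "Target")
  for (rule in policy@rules) {
    rnode <- xml2::xml_add_child(doc, "Rule")
    xml2::xml_set_attrs(rnode, c(RuleId = rule@ruleId, Effect = rule@effect))
    target <- xml2::xml_add_child(rnode, "Target")
    if (length(rule@targetRole))
      addTargetMatch(target, "role", rule@targetRole, CATEGORY_SUBJECT)
    if (length(rule@targetAction))
      addTargetMatch(target, ATTR_ACTION_ID_URN, rule@targetAction,
                     CATEGORY_ACTION)
    if (length(rule@conditions)) {
      cnode <- xml2::xml_add_child(rnode, "Condition")
      if (length(rule@conditions) == 1L) {
        addConditionApply(cnode, rule@conditions[[1]])
      } else {
        andNode <- xml2::xml_add_child(cnode, "Apply")
        xml2::xml_set_attr(andNode, "FunctionId", FN_AND)
        for (cond in rule@conditions) addConditionApply(andNode, cond)
      }
    }
  }
  charToRaw(as.character(doc))
}

# ---- parsing ----------------------------------------------------------------

parseValueNode <- function(node) {
  dt <- xml2::xml_attr(node, "DataType")
  txt <- xml2::xml_text(node)
  switch(dt,
    "http://www.w3.org/2001/XMLSchema#string" = txt,
    "http://www.w3.org/2001/XMLSchema#integer" = as.numeric(txt),
    "http://www.w3.org/2001/XMLSchema#boolean" = identical(txt, "true"),
    stop(unsupportedXacml(paste("DataType", dt))))
}

parseApplyCondition <- function(node) {
  fn <- xml2::xml_attr(node, "FunctionId")
  kids <- xml2::xml_children(node)
  names <- vapply(kids, xml2::xml_name, character(1))
  designators <- kids[names == "AttributeDesignator"]
  values <- kids[names == "AttributeValue"]
  if (length(designators) + length(values) != length(kids))
    stop(unsupportedXacml(paste("nested Apply structure in", fn)))
  dIds <- vapply(designators, xml2::xml_attr, character(1), "AttributeId")
  vVals <- lapply(values, parseValueNode)
  if (fn %in% c(FN_STRING_EQUAL, FN_INTEGER_EQUAL)) {
    stopifnot(length(dIds) == 1L, length(vVals) == 1L)
    xacmlCondition(dIds, "equals", vVals[[1]])
  } else if (fn == FN_BOOLEAN_EQUAL) {
    stopifnot(length(dIds) == 1L, length(vVals) == 1L)
    xacmlCondition(dIds, "boolean-equals", vVals[[1]])
  } else if (fn == FN_INTEGER_LE) {
    stopifnot(length(dIds) == 1L, length(vVals) == 1L)
    xacmlCondition(dIds, "integer-at-most", vVals[[1]])
  } else if (fn == FN_RANGE_WITHIN) {
    stopifnot(length(dIds) == 2L, length(vVals) == 2L)
    xacmlCondition(dIds, "integer-range-within",
                   c(vVals[[1]], vVals[[2]]))
  } else {
    stop(unsupportedXacml(paste("FunctionId", fn)))
  }
}

parseRuleTarget <- function(node) {
  role <- NULL; action <- NULL
  for (anyOf in xml2::xml_children(node)) {
    if (xml2::xml_name(anyOf) != "AnyOf")
      stop(unsupportedXacml(xml2::xml_name(anyOf)))
    for (allOf in xml2::xml_children(anyOf)) {
      for (match in xml2::xml_children(allOf)) {
        if (xml2::xml_name(match) != "Match")
          stop(unsupportedXacml(xml2::xml_name(match)))
        if (!identical(xml2::xml_attr(match, "MatchId"), FN_STRING_EQUAL))
          stop(unsupportedXacml(
            paste("MatchId", xml2::xml_attr(match, "MatchId"))))
        kids <- xml2::xml_children(match)
        nms <- vapply(kids, xml2::xml_name, character(1))
        value <- parseValueNode(kids[[which(nms == "AttributeValue")]])
        desig <- kids[[which(nms == "AttributeDesignator")]]
        aid <- xml2::xml_attr(desig, "AttributeId")
        if (aid == "role") role <- value
        else if (aid %in% c(ATTR_ACTION_ID_URN, ATTR_ACTION_ID))
          action <- value
        else stop(unsupportedXacml(paste("target attribute", aid)))
      }
    }
  }
  list(role = role, action = action)
}

parseRuleNode <- function(node) {
  ruleId <- xml2::xml_attr(node, "RuleId")
  effect <- xml2::xml_attr(node, "Effect")
  role <- NULL; action <- NULL; conditions <- list()
  for (kid in xml2::xml_children(node)) {
    nm <- xml2::xml_name(kid)
    if (nm == "Target") {
      tgt <- parseRuleTarget(kid)
      role <- tgt$role; action <- tgt$action
    } else if (nm == "Condition") {
      applies <- xml2::xml_children(kid)
      if (length(applies) != 1L || xml2::xml_name(applies[[1]]) != "Apply")
        stop(unsupportedXacml("Condition without a single Apply"))
      top <- applies[[1]]
      if (identical(xml2::xml_attr(top, "FunctionId"), FN_AND)) {
        conditions <- lapply(xml2::xml_children(top), parseApplyCondition)
      } else {
        conditions <- list(parseApplyCondition(top))
      }
    } else {
      stop(unsupportedXacml(nm))
    }
  }
  policyRule(ruleId, effect, role = role, action = action,
             conditions = conditions)
}

#' Parse a policy from XACML XML
#'
#' Accepts the XACML 3.0 subset emitted by \code{\link{serializePolicyXml}}.
#' Out-of-subset features (PolicySet, Obligations, advice, unknown functions
#' or datatypes) raise an \code{xacml_unsupported_feature} error naming the
#' offending element.
#'
#' @param xml raw vector or string of XACML XML.
#' @return a \code{\link{XacmlPolicy}}.
#' @export
parsePolicyXml <- function(xml) {
  if (is.raw(xml)) xml <- rawToChar(xml)
  doc <- xml2::read_xml(xml)
  rootName <- xml2::xml_name(doc)
  if (rootName == "PolicySet") stop(unsupportedXacml("PolicySet"))
  if (rootName != "Policy")
    stop(sprintf("expected a <Policy> root, found <%s>", rootName))
  ns <- xml2::xml_ns(doc)
  if (!XACML_NS %in% unlist(ns))
    stop("policy document is not in the XACML 3.0 namespace")
  xml2::xml_ns_strip(doc)
  combining <- sub(COMBINING_URN_PREFIX, "",
                   xml2::xml_attr(doc, "RuleCombiningAlgId"), fixed = TRUE)
  rules <- list()
  for (kid in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(kid)
    if (nm == "Rule") rules[[length(rules) + 1L]] <- parseRuleNode(kid)
    else if (nm == "Target") {
      if (length(xml2::xml_children(kid)))
        stop(unsupportedXacml("policy-level Target constraints"))
    } else stop(unsupportedXacml(nm))
  }
  xacmlPolicy(xml2::xml_attr(doc, "PolicyId"), rules, combining)
}

# ---- requests ---------------------------------------------------------------

#' Serialize / parse an authorization request as XACML XML
#'
#' Attributes are grouped by category under \code{<Attributes>} elements, as
#' in an XACML 3.0 Request.
#'
#' @param request an \code{\link{AuthzRequest}}.
#' @return \code{serializeRequestXml}: raw XML bytes;
#'   \code{parseRequestXml}: an \code{\link{AuthzRequest}}.
#' @export
serializeRequestXml <- function(request) {
  doc <- xml2::read_xml(sprintf('<Request xmlns="%s"/>', XACML_NS))
  xml2::xml_set_attr(doc, "CombinedDecision", "false")
  xml2::xml_set_attr(doc, "ReturnPolicyIdList", "false")
  cats <- vapply(request@attributes, slot, character(1), "category")
  for (cat in unique(cats)) {
    catNode <- xml2::xml_add_child(doc, "Attributes")
    xml2::xml_set_attr(catNode, "Category", cat)
    for (a in request@attributes[cats == cat]) {
      node <- xml2::xml_add_child(catNode, "Attribute")
      xml2::xml_set_attrs(node, c(AttributeId = a@attributeId,
                                  IncludeInResult = "false"))
      addAttributeValueNode(node, a@value, a@datatype)
    }
  }
  charToRaw(as.character(doc))
}

#' @rdname serializeRequestXml
#' @param xml raw vector or string of XACML Request XML.
#' @export
parseRequestXml <- function(xml) {
  if (is.raw(xml)) xml <- rawToChar(xml)
  doc <- xml2::read_xml(xml)
  if (xml2::xml_name(doc) != "Request")
    stop("expected a <Request> root")
  xml2::xml_ns_strip(doc)
  attrs <- list()
  for (catNode in xml2::xml_children(doc)) {
    if (xml2::xml_name(catNode) != "Attributes")
      stop(unsupportedXacml(xml2::xml_name(catNode)))
    cat <- xml2::xml_attr(catNode, "Category")
    for (node in xml2::xml_children(catNode)) {
      aid <- xml2::xml_attr(node, "AttributeId")
      valNode <- xml2::xml_child(node, "AttributeValue")
      value <- parseValueNode(valNode)
      attrs[[length(attrs) + 1L]] <- attributeValue(aid, value,
                                                    category = cat)
    }
  }
  new("AuthzRequest", attributes = attrs)
}
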
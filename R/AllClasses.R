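#' @import methods
NULL

#' Hierarchical protected genomic container
#'
#' A \code{GenomicContainer} is a handle to an on-disk box hierarchy in the
#' style of the ISO/IEC 23092 (MPEG-G) file format working in Access Unit
#' Container (AUC) mode.  The directory tree is the authoritative
#' representation: dataset groups live in \code{dg_<id>} directories, datasets
#' in \code{dt_<id>}, access units in \code{au_<id>}, and coded payloads in
#' \code{block_<id>} files.  Header files are named \code{flhd}, \code{dghd},
#' \code{dthd} and \code{auhd}; metadata files \code{dgmd}/\code{dtmd};
#' protection files \code{dgpr}/\code{dtpr}/\code{aupr}.  All operations in
#' the package read and write this layout, and \code{\link{packContainer}}
#' folds it into a single length-prefixed box stream.
#'
#' @slot rootPath absolute path of the container root directory.
#' @export
setClass("GenomicContainer", representation(rootPath = "character"))

setValidity("GenomicContainer", function(object) {
  if (length(object@rootPath) != 1L || is.na(object@rootPath))
    return("rootPath must be a single path")
  if (!dir.exists(object@rootPath))
    return(sprintf("container root '%s' does not exist", object@rootPath))
  if (!file.exists(file.path(object@rootPath, "flhd")))
    return("container root has no 'flhd' file header")
  TRUE
})

#' Study/sample metadata record
#'
#' Core metadata fields follow the MPEG-G metadata vocabulary (Title, Type,
#' Abstract, ProjectCentre, Description, Sample-TaxonId, Sample-Title) so that
#' EGA Study/Assembly and NCBI BioProject/BioSample records map onto them (see
#' \code{\link{mapFromEga}} and \code{\link{mapFromNcbi}}).  Additional
#' information is carried in the ordered \code{extensions} map (see
#' \code{\link{addExtension}}).
#'
#' @slot title,type,abstract,projectCentre,description,sampleTaxonId,sampleTitle
#'   single character strings (may be empty).
#' @slot extensions named character vector of extension attributes; names are
#'   unique, order is preserved.
#' @export
setClass("MetadataRecord", representation(
  title = "character", type = "character", abstract = "character",
  projectCentre = "character", description = "character",
  sampleTaxonId = "character", sampleTitle = "character",
  extensions = "character"
), prototype(
  title = "", type = "", abstract = "", projectCentre = "",
  description = "", sampleTaxonId = "", sampleTitle = "",
  extensions = setNames(character(0), character(0))
))

setValidity("MetadataRecord", function(object) {
  core <- c("title", "type", "abstract", "projectCentre", "description",
            "sampleTaxonId", "sampleTitle")
  for (s in core)
    if (length(slot(object, s)) != 1L)
      return(sprintf("field '%s' must be a single string", s))
  ext <- object@extensions
  if (length(ext) && (is.null(names(ext)) || any(names(ext) == "")))
    return("all extensions must be named")
  if (anyDuplicated(names(ext)))
    return("extension names must be unique")
  TRUE
})

#' Attribute value of an authorization request
#'
#' One attribute of an XACML-style request: a category (e.g. the XACML 1.0
#' \code{access-subject} category for the subject's \code{role}), an attribute
#' id, a datatype and a value.  Supported datatypes are \code{string},
#' \code{integer} and \code{boolean}.
#'
#' @slot category attribute category (free text; standard XACML URNs are used
#'   for subject and action attributes).
#' @slot attributeId attribute identifier, e.g. \code{role}, \code{action-id},
#'   \code{situation}, \code{read_count}, \code{reference_id}.
#' @slot datatype one of \code{"string"}, \code{"integer"}, \code{"boolean"}.
#' @slot value the attribute value, of the matching R type.
#' @export
setClass("AttributeValue", representation(
  category = "character", attributeId = "character",
  datatype = "character", value = "ANY"
))

setValidity("AttributeValue", function(object) {
  if (!object@datatype %in% c("string", "integer", "boolean"))
    return("datatype must be string, integer or boolean")
  ok <- switch(object@datatype,
    string  = is.character(object@value),
    integer = is.numeric(object@value) && object@value == floor(object@value),
    boolean = is.logical(object@value))
  if (!isTRUE(ok) || length(object@value) != 1L || is.na(object@value))
    return(sprintf("value is not a single %s", object@datatype))
  TRUE
})

#' Condition of a privacy rule
#'
#' Conditions constrain non-target attributes of a request.  Operators:
#' \describe{
#'   \item{\code{equals}}{attribute equals a constant (string or integer).}
#'   \item{\code{boolean-equals}}{boolean attribute equals a constant.}
#'   \item{\code{integer-at-most}}{integer attribute \eqn{\le} a constant cap.}
#'   \item{\code{integer-range-within}}{the request's interval
#'     \code{[attributeId[1], attributeId[2]]} must be contained in the rule's
#'     inclusive interval \code{value[1]..value[2]} (both extremes included).}
#' }
#'
#' @slot attributeId one attribute id, or two (start, end) for
#'   \code{integer-range-within}.
#' @slot operator one of the operators above.
#' @slot value the constant operand; for \code{integer-range-within} a length-2
#'   numeric \code{c(lo, hi)}.
#' @export
setClass("Condition", representation(
  attributeId = "character", operator = "character", value = "ANY"
))

setValidity("Condition", function(object) {
  op <- object@operator
  if (length(op) != 1L ||
      !op %in% c("equals", "boolean-equals", "integer-at-most",
                 "integer-range-within"))
    return("unknown condition operator")
  v <- object@value
  switch(op,
    "equals" = if (!((is.character(v) || is.numeric(v)) && length(v) == 1L))
      return("equals needs a single string or integer operand"),
    "boolean-equals" = if (!(is.logical(v) && length(v) == 1L && !is.na(v)))
      return("boolean-equals needs a single logical operand"),
    "integer-at-most" = if (!(is.numeric(v) && length(v) == 1L))
      return("integer-at-most needs a single numeric operand"),
    "integer-range-within" = {
      if (!(is.numeric(v) && length(v) == 2L && v[1] <= v[2]))
        return("integer-range-within needs numeric bounds c(lo, hi)")
      if (length(object@attributeId) != 2L)
        return("integer-range-within needs two attribute ids (start, end)")
    })
  if (op != "integer-range-within" && length(object@attributeId) != 1L)
    return("condition needs exactly one attribute id")
  TRUE
})

#' XACML-subset privacy rule
#'
#' A rule has a target (required subject role and/or action), a conjunction of
#' \code{\link{Condition}}s and an effect.  The protected resource is never
#' named in the rule: a rule applies implicitly to the dataset group or
#' dataset whose protection box contains it.
#'
#' @slot ruleId rule identifier.
#' @slot effect \code{"Permit"} or \code{"Deny"}.
#' @slot targetRole required subject role (empty = any role).
#' @slot targetAction required action id (empty = any action).
#' @slot conditions list of \code{\link{Condition}} objects, all of which must
#'   hold for the rule to apply.
#' @export
setClass("PolicyRule", representation(
  ruleId = "character", effect = "character",
  targetRole = "character", targetAction = "character",
  conditions = "list"
), prototype(targetRole = character(0), targetAction = character(0),
             conditions = list()))

setValidity("PolicyRule", function(object) {
  if (!object@effect %in% c("Permit", "Deny"))
    return("effect must be Permit or Deny")
  if (length(object@targetRole) > 1L || length(object@targetAction) > 1L)
    return("target matches must be single values")
  if (!all(vapply(object@conditions, is, logical(1), "Condition")))
    return("conditions must be Condition objects")
  TRUE
})

#' XACML-subset policy
#'
#' An ordered list of \code{\link{PolicyRule}}s plus a rule-combining
#' algorithm (\code{deny-overrides}, \code{permit-overrides} or
#' \code{first-applicable}).
#'
#' @slot policyId policy identifier.
#' @slot rules list of \code{\link{PolicyRule}}.
#' @slot combining combining algorithm name.
#' @export
setClass("XacmlPolicy", representation(
  policyId = "character", rules = "list", combining = "character"
), prototype(rules = list(), combining = "deny-overrides"))

setValidity("XacmlPolicy", function(object) {
  if (!object@combining %in%
      c("deny-overrides", "permit-overrides", "first-applicable"))
    return("unknown combining algorithm")
  if (!all(vapply(object@rules, is, logical(1), "PolicyRule")))
    return("rules must be PolicyRule objects")
  TRUE
})

#' Authorization request
#'
#' The attribute bag a subject presents for evaluation, mirroring an XACML
#' Request.  Multi-valued attributes are rejected: each attribute id occurs at
#' most once.
#'
#' @slot attributes list of \code{\link{AttributeValue}} objects.
#' @export
setClass("AuthzRequest", representation(attributes = "list"),
         prototype(attributes = list()))

setValidity("AuthzRequest", function(object) {
  if (!all(vapply(object@attributes, is, logical(1), "AttributeValue")))
    return("attributes must be AttributeValue objects")
  ids <- vapply(object@attributes, slot, character(1), "attributeId")
  if (anyDuplicated(ids))
    return(sprintf("multi-valued attribute '%s' not supported",
                   ids[duplicated(ids)][1]))
  TRUE
})

#' Policy decision
#'
#' Outcome of evaluating a rule or policy against a request:
#' \code{Permit}, \code{Deny}, \code{NotApplicable} (nothing matched; callers
#' treat this as not granted) or \code{Indeterminate} (a required attribute
#' was missing or ill-typed).
#'
#' @slot outcome decision outcome.
#' @slot matchedRuleIds ids of the rules that produced the outcome.
#' @export
setClass("Decision", representation(
  outcome = "character", matchedRuleIds = "character"
), prototype(matchedRuleIds = character(0)))

setValidity("Decision", function(object) {
  if (!object@outcome %in%
      c("Permit", "Deny", "NotApplicable", "Indeterminate"))
    return("invalid outcome")
  TRUE
})

#' Result of hierarchical dataset authorization
#'
#' Produced by \code{\link{authorizeDataset}}: the outcome, which level of the
#' hierarchy granted it (\code{dataset}, \code{dataset_group} or \code{none}),
#' and the request annotated with the provenance attribute
#' \code{granted_by_dataset_group} when the permit was delegated upward.
#'
#' @slot outcome \code{"Permit"} or \code{"Deny"}.
#' @slot grantedBy granting level.
#' @slot annotatedRequest the (possibly annotated) \code{\link{AuthzRequest}}.
#' @export
setClass("AuthzResult", representation(
  outcome = "character", grantedBy = "character",
  annotatedRequest = "AuthzRequest"
))

setValidity("AuthzResult", function(object) {
  if (!object@outcome %in% c("Permit", "Deny"))
    return("outcome must be Permit or Deny")
  if (!object@grantedBy %in% c("dataset", "dataset_group", "none"))
    return("grantedBy must be dataset, dataset_group or none")
  if (object@grantedBy == "dataset_group") {
    ids <- vapply(object@annotatedRequest@attributes, slot, character(1),
                  "attributeId")
    if (!"granted_by_dataset_group" %in% ids)
      return("delegated permit lacks the granted_by_dataset_group attribute")
  }
  TRUE
})

#' Result of dataset-group-wide authorization
#'
#' Produced by \code{\link{authorizeDatasetGroup}}: when the group-level
#' policy permits, every dataset in the group is reviewed and lands either in
#' \code{grantedDatasets} (its own policy permits, or it has no policy and
#' inherits) or in \code{blockedDatasets}.
#'
#' @slot outcome \code{"Permit"} or \code{"Deny"} (group-level decision).
#' @slot grantedDatasets,blockedDatasets disjoint integer vectors of dataset
#'   ids; their union covers the group's datasets when outcome is Permit.
#' @export
setClass("GroupAuthzResult", representation(
  outcome = "character", grantedDatasets = "integer",
  blockedDatasets = "integer"
))

setValidity("GroupAuthzResult", function(object) {
  if (!object@outcome %in% c("Permit", "Deny"))
    return("outcome must be Permit or Deny")
  if (length(intersect(object@grantedDatasets, object@blockedDatasets)))
    return("granted and blocked dataset sets overlap")
  TRUE
})

#' Encryption entry of a protection box
#'
#' Records the authenticated encryption of one payload (a block or a metadata
#' file): the target selector, algorithm id, nonce and a reference to the key
#' used (a wrapped key id or an external key name).
#'
#' @slot target payload selector, e.g. \code{"dg_0/dt_0/au_0/block_1"} or
#'   \code{"dg_0/dt_0/dtmd"}.
#' @slot algorithm algorithm identifier.
#' @slot nonce raw nonce (12 bytes), unique per key and entry.
#' @slot keyRef key reference.
#' @export
setClass("EncryptionEntry", representation(
  target = "character", algorithm = "character",
  nonce = "raw", keyRef = "character"
))

#' Signature entry of a protection box
#'
#' A detached Ed25519 signature over a payload's plaintext.
#'
#' @slot target payload selector.
#' @slot algorithm algorithm identifier (\code{"ed25519"}).
#' @slot publicKey raw public key bytes.
#' @slot signature raw signature bytes.
#' @export
setClass("SignatureEntry", representation(
  target = "character", algorithm = "character",
  publicKey = "raw", signature = "raw"
))

#' Passphrase-wrapped content key
#'
#' A symmetric content key encrypted under a key derived from a passphrase,
#' so it can be stored next to the data it protects.
#'
#' @slot keyId key identifier.
#' @slot method wrapping method identifier.
#' @slot salt raw KDF salt.
#' @slot nonce raw AEAD nonce.
#' @slot wrapped raw wrapped key bytes (ciphertext + tag).
#' @export
setClass("KeyWrapper", representation(
  keyId = "character", method = "character",
  salt = "raw", nonce = "raw", wrapped = "raw"
))

#' Protection box
#'
#' The per-level XML protection record of the container: an optional embedded
#' privacy policy plus encryption entries, signature entries and wrapped keys
#' for payloads at or below the level the box is attached to.
#'
#' @slot policy a \code{\link{XacmlPolicy}} or \code{NULL}.
#' @slot encryptionEntries list of \code{\link{EncryptionEntry}}.
#' @slot signatures list of \code{\link{SignatureEntry}}.
#' @slot wrappedKeys list of \code{\link{KeyWrapper}}.
#' @export
setClass("ProtectionBox", representation(
  policy = "ANY", encryptionEntries = "list",
  signatures = "list", wrappedKeys = "list"
), prototype(policy = NULL, encryptionEntries = list(),
             signatures = list(), wrappedKeys = list()))

setValidity("ProtectionBox", function(object) {
  if (!is.null(object@policy) && !is(object@policy, "XacmlPolicy"))
    return("policy must be NULL or a XacmlPolicy")
  if (!all(vapply(object@encryptionEntries, is, logical(1),
                  "EncryptionEntry")))
    return("encryptionEntries must be EncryptionEntry objects")
  if (!all(vapply(object@signatures, is, logical(1), "SignatureEntry")))
    return("signatures must be SignatureEntry objects")
  if (!all(vapply(object@wrappedKeys, is, logical(1), "KeyWrapper")))
    return("wrappedKeys must be KeyWrapper objects")
  TRUE
})
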
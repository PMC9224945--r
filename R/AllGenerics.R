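#' @include AllClasses.R
NULL

setMethod("show", "GenomicContainer", function(object) {
  dgs <- datasetGroupIds(object)
  cat("GenomicContainer at", object@rootPath, "\n")
  cat(" ", length(dgs), "dataset group(s)")
  if (length(dgs)) cat(":", paste0("dg_", dgs, collapse = " "))
  cat("\n")
  for (dg in dgs) {
    dts <- datasetIds(object, dg)
    cat("  dg_", dg, ": ", length(dts), " dataset(s)", sep = "")
    if (length(dts)) cat(" [", paste0("dt_", dts, collapse = " "), "]",
                         sep = "")
    cat("\n")
  }
  invisible(NULL)
})

setMethod("show", "MetadataRecord", function(object) {
  cat("MetadataRecord\n")
  flds <- metadataFields(object)
  for (nm in names(flds))
    if (nzchar(flds[[nm]])) cat(sprintf("  %-14s %s\n", nm, flds[[nm]]))
  if (length(object@extensions))
    cat("  extensions:   ",
        paste(names(object@extensions), object@extensions,
              sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "XacmlPolicy", function(object) {
  cat("XacmlPolicy", object@policyId, "(", object@combining, ")\n")
  for (r in object@rules)
    cat(sprintf("  rule %s -> %s [role=%s action=%s, %d condition(s)]\n",
                r@ruleId, r@effect,
                if (length(r@targetRole)) r@targetRole else "*",
                if (length(r@targetAction)) r@targetAction else "*",
                length(r@conditions)))
  invisible(NULL)
})

setMethod("show", "Decision", function(object) {
  cat("Decision:", object@outcome)
  if (length(object@matchedRuleIds))
    cat(" (rules:", paste(object@matchedRuleIds, collapse = ", "), ")")
  cat("\n")
  invisible(NULL)
})

setMethod("show", "AuthzResult", function(object) {
  cat("AuthzResult:", object@outcome, "granted_by =", object@grantedBy, "\n")
  invisible(NULL)
})

setMethod("show", "GroupAuthzResult", function(object) {
  cat("GroupAuthzResult:", object@outcome,
      "granted =", paste(object@grantedDatasets, collapse = ","),
      "blocked =", paste(object@blockedDatasets, collapse = ","), "\n")
  invisible(NULL)
})

setMethod("show", "ProtectionBox", function(object) {
  cat("ProtectionBox:",
      if (is.null(object@policy)) "no policy" else
        paste("policy", object@policy@policyId),
      "|", length(object@encryptionEntries), "encryption,",
      length(object@signatures), "signature(s),",
      length(object@wrappedKeys), "wrapped key(s)\n")
  invisible(NULL)
})

#' Outcome of a decision or authorization result
#'
#' @param x a \code{Decision}, \code{AuthzResult} or \code{GroupAuthzResult}.
#' @return the outcome string.
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @rdname outcome
setMethod("outcome", "Decision", function(x) x@outcome)
#' @rdname outcome
setMethod("outcome", "AuthzResult", function(x) x@outcome)
#' @rdname outcome
setMethod("outcome", "GroupAuthzResult", function(x) x@outcome)
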
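#' @include policy.R container.R
NULL

OPERATION_VOCABULARY <- c("GetDataBySimpleFilter", "addDatasetGroup",
                          "addDataset", "editAnyElement", "deleteAnyElement",
                          "metadata-read", "metadata-write", "create-file")
MUTATING_OPERATIONS <- c("addDatasetGroup", "addDataset", "editAnyElement",
                         "deleteAnyElement", "metadata-write")

policyAt <- function(c, dgId, dtId = NULL) {
  pb <- readProtection(c, dgId, dtId)
  if (is.null(pb)) NULL else pb@policy
}

#' Authorize a request against one dataset
#'
#' Dataset-specific rules are checked first; a dataset-level Permit is final
#' and is never overridden by group rules, so a dataset can diverge from its
#' group's default policy.  When the dataset's rules do not grant (Deny or
#' NotApplicable, or when the dataset carries no policy at all), the same
#' request is evaluated against the dataset group's policy; a group-level
#' Permit is delegated downward and the provenance attribute
#' \code{granted_by_dataset_group = true} is appended to the request.
#' When neither level grants, the result is Deny.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @param dgId,dtId dataset-group and dataset ids.
#' @param request an \code{\link{AuthzRequest}}.
#' @return an \code{\link{AuthzResult}}.
#' @export
authorizeDataset <- function(c, dgId, dtId, request) {
  checkNode(dgPath(c, dgId), "dataset group")
  checkNode(dtPath(c, dgId, dtId), "dataset")
  dtPolicy <- policyAt(c, dgId, dtId)
  if (!is.null(dtPolicy) &&
      outcome(evaluatePolicy(dtPolicy, request)) == "Permit")
    return(new("AuthzResult", outcome = "Permit", grantedBy = "dataset",
               annotatedRequest = request))
  dgPolicy <- policyAt(c, dgId)
  if (!is.null(dgPolicy) &&
      outcome(evaluatePolicy(dgPolicy, request)) == "Permit") {
    annotated <- setRequestAttribute(
      request, attributeValue("granted_by_dataset_group", TRUE))
    return(new("AuthzResult", outcome = "Permit",
               grantedBy = "dataset_group", annotatedRequest = annotated))
  }
  new("AuthzResult", outcome = "Deny", grantedBy = "none",
      annotatedRequest = request)
}

#' Authorize a request against a whole dataset group
#'
#' The group-level policy is evaluated first; anything but Permit denies the
#' request outright with no per-dataset review.  When the group grants, each
#' dataset is reviewed one by one going down the hierarchy: a dataset with no
#' policy of its own inherits the group's grant, a dataset whose policy
#' permits is granted, and a dataset whose policy yields Deny or
#' NotApplicable is blocked, so data from it is withheld even though the
#' group-wide request was granted.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @param dgId dataset-group id.
#' @param request an \code{\link{AuthzRequest}}.
#' @return a \code{\link{GroupAuthzResult}}.
#' @export
authorizeDatasetGroup <- function(c, dgId, request) {
  checkNode(dgPath(c, dgId), "dataset group")
  dgPolicy <- policyAt(c, dgId)
  granted <- if (!is.null(dgPolicy))
    outcome(evaluatePolicy(dgPolicy, request)) == "Permit"
  else FALSE
  if (!granted)
    return(new("GroupAuthzResult", outcome = "Deny",
               grantedDatasets = integer(0), blockedDatasets = integer(0)))
  grantedDts <- integer(0); blockedDts <- integer(0)
  for (dt in datasetIds(c, dgId)) {
    dtPolicy <- policyAt(c, dgId, dt)
    ok <- is.null(dtPolicy) ||
      outcome(evaluatePolicy(dtPolicy, request)) == "Permit"
    if (ok) grantedDts <- c(grantedDts, dt)
    else blockedDts <- c(blockedDts, dt)
  }
  new("GroupAuthzResult", outcome = "Permit",
      grantedDatasets = grantedDts, blockedDatasets = blockedDts)
}

# ---- operation-level authorization and audit logging ------------------------

#' Where authorization decisions are logged
#'
#' The audit log is a JSON-lines file; every \code{\link{authorizeOperation}}
#' call appends exactly one record (timestamp, subject attributes, operation,
#' target, outcome), so the log doubles as a trace of unusual or denied
#' operations.  Set the path with \code{options(genomicvault.auditLog = ...)}
#' or per call.
#'
#' @param path audit log path, or NULL to disable logging.
#' @return \code{auditLogPath}: the active path (or NULL).
#' @export
auditLogPath <- function(path) {
  if (!missing(path)) {
    options(genomicvault.auditLog = path)
    return(invisible(path))
  }
  getOption("genomicvault.auditLog", NULL)
}

#' Read an audit log
#'
#' @param path path to a JSON-lines audit log.
#' @return data.frame with one row per authorization decision.
#' @export
readAuditLog <- function(path) {
  if (!file.exists(path))
    return(data.frame(timestamp = character(0), operation = character(0),
                      target = character(0), outcome = character(0),
                      subject = character(0)))
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  do.call(rbind, lapply(recs, function(r)
    data.frame(timestamp = r$timestamp, operation = r$operation,
               target = r$target, outcome = r$outcome,
               subject = r$subject, stringsAsFactors = FALSE)))
}

writeAuditRecord <- function(log, operation, target, request, outcomeStr) {
  if (is.null(log)) return(invisible(NULL))
  subj <- requestAttribute(request, "subject-id")
  role <- requestAttribute(request, "role")
  rec <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    subject = if (!is.null(subj)) subj@value
              else if (!is.null(role)) role@value else "",
    operation = operation, target = target, outcome = outcomeStr)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "",
      file = log, append = TRUE)
  invisible(NULL)
}

#' Authorize an API operation on a container element
#'
#' The operation-level gate: the \code{action-id} attribute is injected into
#' the request, ownership is checked for mutating operations (when the file
#' header carries an owner, the request's \code{subject-id} must match), and
#' the request is dispatched to the level-appropriate algorithm
#' (\code{\link{authorizeDataset}} for dataset targets, group-policy
#' evaluation for group targets).  Only container creation requires no
#' authorization.  When no policy governs the target, read operations are
#' denied (closed by default) while mutating operations fall back to the
#' ownership check.  Exactly one audit record is appended per call when an
#' audit log is configured.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @param operation one of \code{GetDataBySimpleFilter},
#'   \code{addDatasetGroup}, \code{addDataset}, \code{editAnyElement},
#'   \code{deleteAnyElement}, \code{metadata-read}, \code{metadata-write},
#'   \code{create-file}.
#' @param target element path (\code{""} for file level, \code{"dg_X"} or
#'   \code{"dg_X/dt_Y"}).
#' @param request an \code{\link{AuthzRequest}}.
#' @param log audit log path; defaults to \code{\link{auditLogPath}()}.
#' @return an \code{\link{AuthzResult}}.
#' @export
authorizeOperation <- function(c, operation, target, request,
                               log = auditLogPath()) {
  if (!operation %in% OPERATION_VOCABULARY)
    stop(sprintf("unknown operation '%s'", operation))
  res <- authorizeOperationImpl(c, operation, target, request)
  writeAuditRecord(log, operation, target, request, res@outcome)
  res
}

authorizeOperationImpl <- function(c, operation, target, request) {
  permit <- function(req = request, by = "none")
    new("AuthzResult", outcome = "Permit", grantedBy = by,
        annotatedRequest = req)
  deny <- function()
    new("AuthzResult", outcome = "Deny", grantedBy = "none",
        annotatedRequest = request)

  # File creation starts a fresh container owned by the caller: nothing to
  # protect yet, so no policy evaluation.
  if (operation == "create-file") return(permit())

  request <- setRequestAttribute(request,
                                 attributeValue(ATTR_ACTION_ID, operation))
  spec <- parseElementPath(target)

  if (operation %in% MUTATING_OPERATIONS) {
    owner <- fileHeader(c)$owner
    if (!is.null(owner) && nzchar(owner)) {
      subj <- requestAttribute(request, "subject-id")
      if (is.null(subj) || !identical(subj@value, owner)) return(deny())
    }
  }

  governing <- if (!is.null(spec$dt)) {
    return(authorizeWithFallback(c, spec, request, operation,
                                 permit, deny))
  } else if (!is.null(spec$dg)) {
    policyAt(c, spec$dg)
  } else NULL

  if (!is.null(governing)) {
    out <- outcome(evaluatePolicy(governing, request))
    if (out == "Permit") {
      annotated <- setRequestAttribute(
        request, attributeValue("granted_by_dataset_group", TRUE))
      return(permit(annotated, "dataset_group"))
    }
    if (out == "Deny") return(deny())
    # NotApplicable / Indeterminate: fall through to the default
  }
  if (operation %in% MUTATING_OPERATIONS)
    permit(request)  # ownership check already passed
  else deny()
}

authorizeWithFallback <- function(c, spec, request, operation, permit, deny) {
  hasAnyPolicy <- !is.null(policyAt(c, spec$dg, spec$dt)) ||
    !is.null(policyAt(c, spec$dg))
  if (hasAnyPolicy) {
    res <- authorizeDataset(c, spec$dg, spec$dt, request)
    if (res@outcome == "Permit") return(res)
    if (operation %in% MUTATING_OPERATIONS) {
      # an existing policy that does not grant blocks even the owner only
      # when it explicitly denies
      dtP <- policyAt(c, spec$dg, spec$dt)
      dgP <- policyAt(c, spec$dg)
      explicitDeny <- (!is.null(dtP) &&
                         outcome(evaluatePolicy(dtP, request)) == "Deny") ||
                      (!is.null(dgP) &&
                         outcome(evaluatePolicy(dgP, request)) == "Deny")
      if (!explicitDeny) return(permit(request))
    }
    return(res)
  }
  if (operation %in% MUTATING_OPERATIONS) permit(request) else deny()
}
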
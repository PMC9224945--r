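#' @include container.R hierarchy.R
NULL

#' Index the metadata of a container
#'
#' Walks the tree and emits one row per populated metadata field (core
#' fields and extensions) at dataset-group and dataset level.  The index is
#' a deterministic function of the tree, so re-indexing after an edit
#' reflects the change.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @return data.frame with columns \code{path} (\code{"dg_X"} or
#'   \code{"dg_X/dt_Y"}), \code{level} (\code{"dg"}/\code{"dt"}),
#'   \code{field} and \code{value}; the container root is carried in the
#'   \code{rootPath} attribute.
#' @export
indexContainer <- function(c) {
  rows <- list()
  emit <- function(path, level, md) {
    if (is.null(md)) return()
    flds <- metadataFields(md)
    for (nm in names(flds))
      if (nzchar(flds[[nm]]))
        rows[[length(rows) + 1L]] <<- data.frame(
          path = path, level = level, field = nm, value = flds[[nm]],
          stringsAsFactors = FALSE)
    ext <- metadataExtensions(md)
    for (nm in names(ext))
      rows[[length(rows) + 1L]] <<- data.frame(
        path = path, level = level, field = nm, value = unname(ext[nm]),
        stringsAsFactors = FALSE)
  }
  for (dg in datasetGroupIds(c)) {
    emit(sprintf("dg_%d", dg), "dg", readMetadata(c, dg))
    for (dt in datasetIds(c, dg))
      emit(sprintf("dg_%d/dt_%d", dg, dt), "dt", readMetadata(c, dg, dt))
  }
  idx <- if (length(rows)) do.call(rbind, rows)
  else data.frame(path = character(0), level = character(0),
                  field = character(0), value = character(0),
                  stringsAsFactors = FALSE)
  attr(idx, "rootPath") <- c@rootPath
  idx
}

#' Search container metadata with per-result authorization
#'
#' Matches are case-insensitive substring hits on the field value (an empty
#' pattern matches everything).  Every candidate hit is then passed through
#' \code{metadata-read} authorization for the requesting subject at the
#' hit's level of the hierarchy; denied hits are silently dropped, so the
#' caller only ever sees results they are allowed to see.
#'
#' @param index index from \code{\link{indexContainer}}.
#' @param field metadata field name to search, or NULL for all fields.
#' @param pattern substring to look for (case-insensitive; \code{""} matches
#'   all).
#' @param request the subject's \code{\link{AuthzRequest}}.
#' @return data.frame of authorized hits (columns as the index, plus
#'   \code{authorized = TRUE}).
#' @export
queryMetadata <- function(index, field = NULL, pattern = "", request) {
  c <- readContainer(attr(index, "rootPath"))
  hits <- index
  if (!is.null(field)) hits <- hits[hits$field == field, , drop = FALSE]
  if (nzchar(pattern))
    hits <- hits[grepl(pattern, hits$value, fixed = TRUE,
                       ignore.case = FALSE) |
                   grepl(tolower(pattern), tolower(hits$value),
                         fixed = TRUE), , drop = FALSE]
  if (!nrow(hits)) {
    hits$authorized <- logical(0)
    return(hits)
  }
  ok <- vapply(seq_len(nrow(hits)), function(i) {
    res <- authorizeOperation(c, "metadata-read", hits$path[i], request,
                              log = NULL)
    res@outcome == "Permit"
  }, logical(1))
  out <- hits[ok, , drop = FALSE]
  out$authorized <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
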
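#' @include container.R
NULL

#' Pack a container into a single box stream
#'
#' Serializes the on-disk hierarchy into one binary file: the 8-byte magic
#' tag followed by a single \code{flcn} box whose payload nests the
#' \code{flhd} header box, an optional \code{flmd} box, and one \code{dgcn}
#' box per dataset group; children are emitted in ascending id order, so
#' equal trees always produce identical bytes.  The container must validate
#' (\code{\link{validateContainer}}) before packing.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @param file optional path; when given, the stream is also written there.
#' @return raw vector with the packed stream, invisibly when \code{file} is
#'   given.
#' @export
packContainer <- function(c, file = NULL) {
  violations <- validateContainer(c)
  if (length(violations))
    stop(paste(c("container does not validate:", violations),
               collapse = "\n  "))
  tree <- containerTree(c)
  opt <- function(type, bytes)
    if (is.null(bytes)) raw(0) else encodeBox(type, bytes)
  auBytes <- function(au) {
    encodeBox("aucn", c(
      encodeBox("auhd", au$header),
      opt("auin", au$info),
      opt("aupr", au$protection),
      concatRaw(lapply(au$blocks, function(b) encodeBox("blck", b)))))
  }
  dtBytes <- function(dt) {
    encodeBox("dtcn", c(
      encodeBox("dthd", dt$header),
      opt("dtmd", dt$metadata),
      opt("dtpr", dt$protection),
      opt("labl", dt$label),
      opt("dtin", dt$index),
      concatRaw(lapply(dt$accessUnits, auBytes))))
  }
  dgBytes <- function(dg) {
    encodeBox("dgcn", c(
      encodeBox("dghd", dg$header),
      opt("dgmd", dg$metadata),
      opt("dgpr", dg$protection),
      concatRaw(lapply(dg$datasets, dtBytes))))
  }
  stream <- c(charToRaw(CONTAINER_MAGIC),
              encodeBox("flcn", c(
                encodeBox("flhd", tree$fileHeader),
                opt("flmd", tree$fileMetadata),
                concatRaw(lapply(tree$groups, dgBytes)))))
  if (!is.null(file)) {
    writeFileRaw(file, stream)
    return(invisible(stream))
  }
  stream
}

#' Unpack a box stream into a container directory
#'
#' Inverse of \code{\link{packContainer}}: parses the stream and
#' reconstructs the directory layout at \code{dest}.  Fails with specific
#' errors on a bad magic tag, a truncated box, or an unknown box type.
#'
#' @param bytes raw vector (or path to a packed file).
#' @param dest destination directory; must not exist or be empty.
#' @return the reconstructed \code{\link{GenomicContainer}}.
#' @export
unpackContainer <- function(bytes, dest) {
  if (is.character(bytes)) bytes <- readFileRaw(bytes)
  if (length(bytes) < 8L ||
      !identical(bytes[1:8], charToRaw(CONTAINER_MAGIC)))
    stop("not a packed container: bad magic tag")
  if (dir.exists(dest) && length(list.files(dest, all.files = TRUE,
                                            no.. = TRUE)) > 0)
    stop(sprintf("destination '%s' exists and is not empty", dest))
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)

  top <- decodeBoxes(bytes[-(1:8)])
  if (length(top) != 1L || top[[1]]$type != "flcn")
    stop("packed container must consist of a single 'flcn' box")
  children <- decodeBoxes(top[[1]]$payload)
  if (!length(children) || children[[1]]$type != "flhd")
    stop("'flcn' payload must start with the 'flhd' header box")

  writeLeaf <- function(dir, name, payload)
    writeFileRaw(file.path(dir, name), payload)

  unpackAu <- function(box, dtDir) {
    kids <- decodeBoxes(box$payload)
    if (!length(kids) || kids[[1]]$type != "auhd")
      stop("'aucn' payload must start with 'auhd'")
    auId <- readHeaderJsonRaw(kids[[1]]$payload, "au_id")
    dir <- file.path(dtDir, sprintf("au_%d", auId))
    dir.create(dir)
    blockId <- 0L
    for (k in kids) {
      switch(k$type,
        auhd = writeLeaf(dir, "auhd", k$payload),
        auin = writeLeaf(dir, "auin", k$payload),
        aupr = writeLeaf(dir, "aupr", k$payload),
        blck = {
          writeLeaf(dir, sprintf("block_%d", blockId), k$payload)
          blockId <- blockId + 1L
        },
        stop(sprintf("box '%s' not allowed inside 'aucn'", k$type)))
    }
  }
  unpackDt <- function(box, dgDir) {
    kids <- decodeBoxes(box$payload)
    if (!length(kids) || kids[[1]]$type != "dthd")
      stop("'dtcn' payload must start with 'dthd'")
    dtId <- readHeaderJsonRaw(kids[[1]]$payload, "dt_id")
    dir <- file.path(dgDir, sprintf("dt_%d", dtId))
    dir.create(dir)
    for (k in kids) {
      switch(k$type,
        dthd = writeLeaf(dir, "dthd", k$payload),
        dtmd = writeLeaf(dir, "dtmd", k$payload),
        dtpr = writeLeaf(dir, "dtpr", k$payload),
        labl = writeLeaf(dir, "labl", k$payload),
        dtin = writeLeaf(dir, "dtin", k$payload),
        aucn = unpackAu(k, dir),
        stop(sprintf("box '%s' not allowed inside 'dtcn'", k$type)))
    }
  }
  unpackDg <- function(box) {
    kids <- decodeBoxes(box$payload)
    if (!length(kids) || kids[[1]]$type != "dghd")
      stop("'dgcn' payload must start with 'dghd'")
    dgId <- readHeaderJsonRaw(kids[[1]]$payload, "dg_id")
    dir <- file.path(dest, sprintf("dg_%d", dgId))
    dir.create(dir)
    for (k in kids) {
      switch(k$type,
        dghd = writeLeaf(dir, "dghd", k$payload),
        dgmd = writeLeaf(dir, "dgmd", k$payload),
        dgpr = writeLeaf(dir, "dgpr", k$payload),
        dtcn = unpackDt(k, dir),
        stop(sprintf("box '%s' not allowed inside 'dgcn'", k$type)))
    }
  }
  for (k in children) {
    switch(k$type,
      flhd = writeLeaf(dest, "flhd", k$payload),
      flmd = writeLeaf(dest, "flmd", k$payload),
      dgcn = unpackDg(k),
      stop(sprintf("box '%s' not allowed inside 'flcn'", k$type)))
  }
  readContainer(dest)
}

readHeaderJsonRaw <- function(payload, field) {
  val <- tryCatch(jsonlite::fromJSON(rawToChar(payload))[[field]],
                  error = function(e) NULL)
  if (is.null(val))
    stop(sprintf("header box payload lacks the '%s' field", field))
  as.integer(val)
}
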
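#' @include AllClasses.R boxio.R
NULL

# ---- path helpers -----------------------------------------------------------

dgPath <- function(c, dgId) file.path(c@rootPath, sprintf("dg_%d", dgId))
dtPath <- function(c, dgId, dtId) file.path(dgPath(c, dgId),
                                            sprintf("dt_%d", dtId))
auPath <- function(c, dgId, dtId, auId) file.path(dtPath(c, dgId, dtId),
                                                  sprintf("au_%d", auId))

idsIn <- function(dir, prefix) {
  if (!dir.exists(dir)) return(integer(0))
  entries <- list.files(dir, pattern = sprintf("^%s_[0-9]+$", prefix))
  sort(as.integer(sub(sprintf("^%s_", prefix), "", entries)))
}

checkNode <- function(path, what) {
  if (!dir.exists(path) && !file.exists(path))
    stop(sprintf("%s '%s' does not exist", what, path))
  invisible(path)
}

writeHeaderJson <- function(path, fields) {
  writeLines(jsonlite::toJSON(fields, auto_unbox = TRUE), path)
}

readHeaderJson <- function(path) {
  jsonlite::fromJSON(readFileRaw(path) |> rawToChar(), simplifyVector = TRUE)
}

# ---- creation and opening ---------------------------------------------------

#' Create an empty protected genomic container
#'
#' Initializes the on-disk box hierarchy at \code{rootPath}: the directory is
#' created containing only the file header artifact \code{flhd} (magic tag,
#' format version, brand and owner).  Creating a container is the only
#' operation that never requires authorization.
#'
#' @param rootPath directory to create; must not exist or be empty.
#' @param brand free-text brand string stored in the file header.
#' @param owner subject id of the container owner; when non-empty, mutating
#'   operations authorized through \code{\link{authorizeOperation}} require
#'   the request's \code{subject-id} to match.
#' @return a \code{\link{GenomicContainer}} with zero dataset groups.
#' @examples
#' c <- createContainer(file.path(tempdir(), "vault-example"))
#' datasetGroupIds(c)
#' @export
createContainer <- function(rootPath, brand = "GenomicVault", owner = "") {
  if (dir.exists(rootPath) && length(list.files(rootPath, all.files = TRUE,
                                                no.. = TRUE)) > 0)
    stop(sprintf("path '%s' exists and is not empty", rootPath))
  dir.create(rootPath, recursive = TRUE, showWarnings = FALSE)
  hdr <- list(version = CONTAINER_VERSION, brand = brand, owner = owner)
  writeFileRaw(file.path(rootPath, "flhd"),
               c(charToRaw(CONTAINER_MAGIC),
                 charToRaw(as.character(jsonlite::toJSON(hdr,
                                                         auto_unbox = TRUE)))))
  new("GenomicContainer", rootPath = normalizePath(rootPath))
}

#' Open an existing container
#'
#' @param rootPath root directory of a container previously written by
#'   \code{\link{createContainer}} or \code{\link{unpackContainer}}.
#' @return a \code{\link{GenomicContainer}}.
#' @export
readContainer <- function(rootPath) {
  new("GenomicContainer", rootPath = normalizePath(rootPath))
}

#' File header of a container
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @return list with elements \code{magic}, \code{version}, \code{brand} and
#'   \code{owner}.
#' @export
fileHeader <- function(c) {
  bytes <- readFileRaw(file.path(c@rootPath, "flhd"))
  if (length(bytes) < 8L ||
      !identical(bytes[1:8], charToRaw(CONTAINER_MAGIC)))
    stop("flhd does not start with the container magic")
  c(list(magic = rawToChar(bytes[1:8])),
    jsonlite::fromJSON(rawToChar(bytes[-(1:8)])))
}

writeFileHeader <- function(c, fields) {
  keep <- fields[setdiff(names(fields), "magic")]
  writeFileRaw(file.path(c@rootPath, "flhd"),
               c(charToRaw(CONTAINER_MAGIC),
                 charToRaw(as.character(jsonlite::toJSON(keep,
                                                         auto_unbox = TRUE)))))
  invisible(c)
}

# ---- tree construction ------------------------------------------------------

#' List dataset group ids
#' @param c a \code{\link{GenomicContainer}}.
#' @return sorted integer vector of dataset-group ids.
#' @export
datasetGroupIds <- function(c) idsIn(c@rootPath, "dg")

#' List dataset ids within a group
#' @param c a \code{\link{GenomicContainer}}.
#' @param dgId dataset-group id.
#' @return sorted integer vector of dataset ids.
#' @export
datasetIds <- function(c, dgId) {
  checkNode(dgPath(c, dgId), "dataset group")
  idsIn(dgPath(c, dgId), "dt")
}

#' List access-unit ids within a dataset
#' @param c a \code{\link{GenomicContainer}}.
#' @param dgId,dtId dataset-group and dataset ids.
#' @return sorted integer vector of access-unit ids.
#' @export
accessUnitIds <- function(c, dgId, dtId) {
  checkNode(dtPath(c, dgId, dtId), "dataset")
  idsIn(dtPath(c, dgId, dtId), "au")
}

#' List block ids within an access unit
#' @param c a \code{\link{GenomicContainer}}.
#' @param dgId,dtId,auId dataset-group, dataset and access-unit ids.
#' @return sorted integer vector of block ids (contiguous from 0).
#' @export
blockIds <- function(c, dgId, dtId, auId) {
  p <- checkNode(auPath(c, dgId, dtId, auId), "access unit")
  blocks <- list.files(p, pattern = "^block_[0-9]+$")
  sort(as.integer(sub("^block_", "", blocks)))
}

#' Add a dataset group
#'
#' Creates directory \code{dg_<dgId>} with its \code{dghd} header file.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @param dgId non-negative integer id, unique within the container.
#' @param header named list of additional opaque header fields.
#' @return \code{c}, invisibly.
#' @export
addDatasetGroup <- function(c, dgId, header = list()) {
  stopifnot(dgId >= 0, dgId == floor(dgId))
  p <- dgPath(c, dgId)
  if (dir.exists(p))
    stop(sprintf("dataset group %d already exists", dgId))
  dir.create(p)
  writeHeaderJson(file.path(p, "dghd"), c(list(dg_id = as.integer(dgId)),
                                          header))
  invisible(c)
}

#' Add a dataset to a dataset group
#'
#' Creates directory \code{dg_<dgId>/dt_<dtId>} with its \code{dthd} header.
#'
#' @inheritParams addDatasetGroup
#' @param dtId non-negative integer id, unique within the group.
#' @return \code{c}, invisibly.
#' @export
addDataset <- function(c, dgId, dtId, header = list()) {
  checkNode(dgPath(c, dgId), "dataset group")
  stopifnot(dtId >= 0, dtId == floor(dtId))
  p <- dtPath(c, dgId, dtId)
  if (dir.exists(p))
    stop(sprintf("dataset %d already exists in dg_%d", dtId, dgId))
  dir.create(p)
  writeHeaderJson(file.path(p, "dthd"), c(list(dt_id = as.integer(dtId)),
                                          header))
  invisible(c)
}

#' Add an access unit to a dataset
#'
#' Creates directory \code{au_<auId>} with its \code{auhd} header and,
#' optionally, the access-unit information file \code{auin}.
#'
#' @inheritParams addDataset
#' @param auId non-negative integer id, unique within the dataset.
#' @param info optional raw vector written as the \code{auin} file.
#' @return \code{c}, invisibly.
#' @export
addAccessUnit <- function(c, dgId, dtId, auId, header = list(), info = NULL) {
  checkNode(dtPath(c, dgId, dtId), "dataset")
  stopifnot(auId >= 0, auId == floor(auId))
  p <- auPath(c, dgId, dtId, auId)
  if (dir.exists(p))
    stop(sprintf("access unit %d already exists in dg_%d/dt_%d",
                 auId, dgId, dtId))
  dir.create(p)
  writeHeaderJson(file.path(p, "auhd"), c(list(au_id = as.integer(auId)),
                                          header))
  if (!is.null(info)) writeFileRaw(file.path(p, "auin"), as.raw(info))
  invisible(c)
}

#' Append a payload block to an access unit
#'
#' Block ids are assigned contiguously from 0 in append order; the payload
#' may be empty.  Payload bytes are opaque to the container.
#'
#' @inheritParams addAccessUnit
#' @param payload raw vector of coded genomic payload bytes.
#' @return the id of the new block, invisibly.
#' @export
addBlock <- function(c, dgId, dtId, auId, payload) {
  p <- checkNode(auPath(c, dgId, dtId, auId), "access unit")
  stopifnot(is.raw(payload))
  blockId <- length(blockIds(c, dgId, dtId, auId))
  writeFileRaw(file.path(p, sprintf("block_%d", blockId)), payload)
  invisible(blockId)
}

#' Read one block payload
#'
#' @inheritParams addAccessUnit
#' @param blockId block id.
#' @return raw payload with attribute \code{encrypted} (TRUE when an
#'   encryption entry in the enclosing access unit's protection box targets
#'   this block).
#' @export
readBlock <- function(c, dgId, dtId, auId, blockId) {
  p <- file.path(auPath(c, dgId, dtId, auId), sprintf("block_%d", blockId))
  checkNode(p, "block")
  bytes <- readFileRaw(p)
  sel <- sprintf("dg_%d/dt_%d/au_%d/block_%d", dgId, dtId, auId, blockId)
  pb <- readProtection(c, dgId, dtId, auId)
  enc <- !is.null(pb) && any(vapply(pb@encryptionEntries, slot, character(1),
                                    "target") == sel)
  structure(bytes, encrypted = enc)
}

# ---- metadata / protection / label / index attachments ----------------------

nodeDir <- function(c, dgId = NULL, dtId = NULL, auId = NULL) {
  if (is.null(dgId)) return(c@rootPath)
  if (is.null(dtId)) return(checkNode(dgPath(c, dgId), "dataset group"))
  if (is.null(auId)) return(checkNode(dtPath(c, dgId, dtId), "dataset"))
  checkNode(auPath(c, dgId, dtId, auId), "access unit")
}

mdFileName <- function(dgId, dtId) {
  if (is.null(dgId)) "flmd" else if (is.null(dtId)) "dgmd" else "dtmd"
}

prFileName <- function(dgId, dtId, auId) {
  if (is.null(dtId)) "dgpr" else if (is.null(auId)) "dtpr" else "aupr"
}

#' Attach a metadata record to a container level
#'
#' Writes the record as the \code{dgmd} (dataset group), \code{dtmd}
#' (dataset) or \code{flmd} (file level, when \code{dgId} is NULL) XML file,
#' replacing any previous metadata at that level.  Access units carry no
#' metadata file.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @param md a \code{\link{MetadataRecord}}.
#' @param dgId dataset-group id, or NULL for file-level metadata.
#' @param dtId dataset id, or NULL for group-level metadata.
#' @return \code{c}, invisibly.
#' @export
attachMetadata <- function(c, md, dgId = NULL, dtId = NULL) {
  stopifnot(is(md, "MetadataRecord"))
  dir <- nodeDir(c, dgId, dtId)
  writeFileRaw(file.path(dir, mdFileName(dgId, dtId)), metadataToXml(md))
  invisible(c)
}

#' Read the metadata record at a container level
#'
#' @inheritParams attachMetadata
#' @return a \code{\link{MetadataRecord}}, or NULL when the level has no
#'   metadata file.
#' @export
readMetadata <- function(c, dgId = NULL, dtId = NULL) {
  f <- file.path(nodeDir(c, dgId, dtId), mdFileName(dgId, dtId))
  if (!file.exists(f)) return(NULL)
  metadataFromXml(readFileRaw(f))
}

#' Attach a protection box to a container level
#'
#' Writes the box as the \code{dgpr}, \code{dtpr} or \code{aupr} XML file
#' of the addressed node, replacing any previous protection record.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @param pb a \code{\link{ProtectionBox}}.
#' @param dgId dataset-group id.
#' @param dtId dataset id (NULL for a group-level box).
#' @param auId access-unit id (NULL for a dataset-level box).
#' @return \code{c}, invisibly.
#' @export
attachProtection <- function(c, pb, dgId, dtId = NULL, auId = NULL) {
  stopifnot(is(pb, "ProtectionBox"))
  dir <- nodeDir(c, dgId, dtId, auId)
  writeFileRaw(file.path(dir, prFileName(dgId, dtId, auId)),
               protectionToXml(pb))
  invisible(c)
}

#' Read the protection box at a container level
#'
#' @inheritParams attachProtection
#' @return a \code{\link{ProtectionBox}}, or NULL when the level has no
#'   protection file.
#' @export
readProtection <- function(c, dgId, dtId = NULL, auId = NULL) {
  f <- file.path(nodeDir(c, dgId, dtId, auId), prFileName(dgId, dtId, auId))
  if (!file.exists(f)) return(NULL)
  protectionFromXml(readFileRaw(f))
}

#' Set or read the dataset label
#'
#' The label element (\code{labl}) is free text attached at dataset level.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @param dgId,dtId dataset-group and dataset ids.
#' @param label label text.
#' @return \code{setLabel}: \code{c} invisibly; \code{readLabel}: the label
#'   string or NULL.
#' @export
setLabel <- function(c, dgId, dtId, label) {
  dir <- nodeDir(c, dgId, dtId)
  writeFileRaw(file.path(dir, "labl"), charToRaw(label))
  invisible(c)
}

#' @rdname setLabel
#' @export
readLabel <- function(c, dgId, dtId) {
  f <- file.path(nodeDir(c, dgId, dtId), "labl")
  if (!file.exists(f)) return(NULL)
  rawToChar(readFileRaw(f))
}

#' Set or read the dataset block index
#'
#' The index (\code{dtin} file) records, per access unit, the byte offset of
#' that access unit's payload within the dataset, supporting direct access.
#' \code{buildDatasetIndex} computes the offsets from the current tree;
#' coordinates are 1-based inclusive.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @param dgId,dtId dataset-group and dataset ids.
#' @param index named numeric vector: names are access-unit ids, values are
#'   1-based byte offsets.
#' @return \code{readDatasetIndex}: the named numeric vector or NULL.
#' @export
setDatasetIndex <- function(c, dgId, dtId, index) {
  stopifnot(is.numeric(index), !is.null(names(index)))
  dir <- nodeDir(c, dgId, dtId)
  writeFileRaw(file.path(dir, "dtin"),
               charToRaw(as.character(jsonlite::toJSON(as.list(index),
                                                       auto_unbox = TRUE))))
  invisible(c)
}

#' @rdname setDatasetIndex
#' @export
readDatasetIndex <- function(c, dgId, dtId) {
  f <- file.path(nodeDir(c, dgId, dtId), "dtin")
  if (!file.exists(f)) return(NULL)
  v <- unlist(jsonlite::fromJSON(rawToChar(readFileRaw(f))))
  storage.mode(v) <- "double"
  v
}

#' @rdname setDatasetIndex
#' @export
buildDatasetIndex <- function(c, dgId, dtId) {
  offset <- 1
  index <- numeric(0)
  for (au in accessUnitIds(c, dgId, dtId)) {
    index[as.character(au)] <- offset
    sizes <- vapply(blockIds(c, dgId, dtId, au), function(b)
      file.info(file.path(auPath(c, dgId, dtId, au),
                          sprintf("block_%d", b)))$size, numeric(1))
    offset <- offset + sum(sizes)
  }
  setDatasetIndex(c, dgId, dtId, index)
  invisible(index)
}

# ---- edit / delete ----------------------------------------------------------

parseElementPath <- function(path) {
  if (identical(path, "") || is.null(path))
    return(list())
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  out <- list()
  pat <- c(dg = "^dg_([0-9]+)$", dt = "^dt_([0-9]+)$",
           au = "^au_([0-9]+)$", block = "^block_([0-9]+)$")
  want <- c("dg", "dt", "au", "block")
  for (i in seq_along(parts)) {
    lvl <- want[i]
    if (is.na(lvl) || !grepl(pat[[lvl]], parts[i]))
      stop(sprintf("malformed element path '%s'", path))
    out[[lvl]] <- as.integer(sub(pat[[lvl]], "\\1", parts[i]))
  }
  out
}

elementDir <- function(c, spec) {
  if (!length(spec)) return(c@rootPath)
  p <- c@rootPath
  nm <- c(dg = "dg_%d", dt = "dt_%d", au = "au_%d", block = "block_%d")
  for (lvl in names(spec)) p <- file.path(p, sprintf(nm[[lvl]], spec[[lvl]]))
  p
}

#' Edit the header fields of a container element
#'
#' Replaces (merges over) the opaque header fields of the addressed element:
#' the file header for path \code{""}, or a \code{dghd}/\code{dthd}/
#' \code{auhd} header for paths such as \code{"dg_0"} or \code{"dg_0/dt_1"}.
#' The structural id field and the file magic cannot be changed.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @param path element path (\code{""}, \code{"dg_X"}, \code{"dg_X/dt_Y"},
#'   \code{"dg_X/dt_Y/au_Z"}).
#' @param fields named list of header fields to set.
#' @return \code{c}, invisibly.
#' @export
editElement <- function(c, path, fields) {
  spec <- parseElementPath(path)
  dir <- elementDir(c, spec)
  checkNode(dir, "element")
  if (!length(spec)) {
    hdr <- fileHeader(c)
    hdr[names(fields)] <- fields
    hdr$version <- CONTAINER_VERSION
    return(writeFileHeader(c, hdr))
  }
  if (!is.null(spec$block))
    stop("blocks have no header fields; rewrite the payload instead")
  hf <- c(dg = "dghd", dt = "dthd", au = "auhd")[[names(spec)[length(spec)]]]
  idField <- c(dghd = "dg_id", dthd = "dt_id", auhd = "au_id")[[hf]]
  hdr <- as.list(readHeaderJson(file.path(dir, hf)))
  fields[[idField]] <- NULL
  hdr[names(fields)] <- fields
  writeHeaderJson(file.path(dir, hf), hdr)
  invisible(c)
}

#' Read the header fields of a container element
#'
#' @inheritParams editElement
#' @return named list of header fields.
#' @export
readElementHeader <- function(c, path) {
  spec <- parseElementPath(path)
  if (!length(spec)) return(fileHeader(c))
  dir <- checkNode(elementDir(c, spec), "element")
  hf <- c(dg = "dghd", dt = "dthd", au = "auhd")[[names(spec)[length(spec)]]]
  as.list(readHeaderJson(file.path(dir, hf)))
}

#' Delete a container element and its subtree
#'
#' Removes the addressed dataset group, dataset, access unit or block,
#' recursively deleting directories.
#'
#' @inheritParams editElement
#' @return \code{c}, invisibly.
#' @export
deleteElement <- function(c, path) {
  spec <- parseElementPath(path)
  if (!length(spec)) stop("refusing to delete the container root")
  dir <- elementDir(c, spec)
  checkNode(dir, "element")
  unlink(dir, recursive = TRUE)
  invisible(c)
}

# ---- validation -------------------------------------------------------------

KNOWN_DG_FILES <- c("dghd", "dgmd", "dgpr")
KNOWN_DT_FILES <- c("dthd", "dtmd", "dtpr", "labl", "dtin")
KNOWN_AU_FILES <- c("auhd", "auin", "aupr")

#' Validate a container tree
#'
#' Checks the structural invariants of the hierarchy: the file magic, header
#' presence, agreement between directory names and header ids, uniqueness of
#' ids, contiguity of block ids, index references, protection-entry targets,
#' and absence of foreign files.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @return character vector of violations; empty when the container is valid.
#' @export
validateContainer <- function(c) {
  v <- character(0)
  bad <- function(...) v <<- c(v, sprintf(...))

  flhd <- file.path(c@rootPath, "flhd")
  if (!file.exists(flhd)) {
    bad("missing file header 'flhd'")
    return(v)
  }
  hdrTry <- tryCatch(fileHeader(c), error = function(e) conditionMessage(e))
  if (is.character(hdrTry)) bad("invalid file header: %s", hdrTry)

  rootFiles <- list.files(c@rootPath, no.. = TRUE)
  foreign <- setdiff(rootFiles, c("flhd", "flmd",
                                  grep("^dg_[0-9]+$", rootFiles,
                                       value = TRUE)))
  for (f in foreign) bad("unexpected entry '%s' at container root", f)

  seenDg <- integer(0)
  for (dg in datasetGroupIds(c)) {
    p <- dgPath(c, dg)
    hf <- file.path(p, "dghd")
    if (!file.exists(hf)) { bad("dg_%d missing 'dghd'", dg); next }
    hid <- tryCatch(readHeaderJson(hf)$dg_id, error = function(e) NULL)
    if (is.null(hid)) bad("dg_%d has unreadable 'dghd'", dg)
    else {
      if (hid %in% seenDg) bad("duplicate dg_id %d (directory dg_%d)",
                               hid, dg)
      seenDg <- c(seenDg, hid)
      if (hid != dg) bad("dg_%d header declares dg_id %d", dg, hid)
    }
    entries <- list.files(p, no.. = TRUE)
    for (f in setdiff(entries, c(KNOWN_DG_FILES,
                                 grep("^dt_[0-9]+$", entries, value = TRUE))))
      bad("unexpected entry '%s' in dg_%d", f, dg)

    seenDt <- integer(0)
    for (dt in datasetIds(c, dg)) {
      dp <- dtPath(c, dg, dt)
      hf <- file.path(dp, "dthd")
      if (!file.exists(hf)) { bad("dg_%d/dt_%d missing 'dthd'", dg, dt); next }
      hid <- tryCatch(readHeaderJson(hf)$dt_id, error = function(e) NULL)
      if (is.null(hid)) bad("dg_%d/dt_%d has unreadable 'dthd'", dg, dt)
      else {
        if (hid %in% seenDt)
          bad("duplicate dt_id %d in dg_%d (directory dt_%d)", hid, dg, dt)
        seenDt <- c(seenDt, hid)
        if (hid != dt) bad("dg_%d/dt_%d header declares dt_id %d", dg, dt, hid)
      }
      entries <- list.files(dp, no.. = TRUE)
      for (f in setdiff(entries, c(KNOWN_DT_FILES,
                                   grep("^au_[0-9]+$", entries,
                                        value = TRUE))))
        bad("unexpected entry '%s' in dg_%d/dt_%d", f, dg, dt)

      idx <- tryCatch(readDatasetIndex(c, dg, dt), error = function(e) NULL)
      if (!is.null(idx)) {
        missing <- setdiff(as.integer(names(idx)), accessUnitIds(c, dg, dt))
        for (m in missing)
          bad("dg_%d/dt_%d index references missing access unit %d",
              dg, dt, m)
      }

      for (au in accessUnitIds(c, dg, dt)) {
        ap <- auPath(c, dg, dt, au)
        hf <- file.path(ap, "auhd")
        if (!file.exists(hf)) {
          bad("dg_%d/dt_%d/au_%d missing 'auhd'", dg, dt, au); next
        }
        hid <- tryCatch(readHeaderJson(hf)$au_id, error = function(e) NULL)
        if (!is.null(hid) && hid != au)
          bad("dg_%d/dt_%d/au_%d header declares au_id %d", dg, dt, au, hid)
        blocks <- blockIds(c, dg, dt, au)
        if (length(blocks) && !identical(blocks, seq_len(length(blocks)) - 1L))
          bad("dg_%d/dt_%d/au_%d block ids not contiguous from 0: %s",
              dg, dt, au, paste(blocks, collapse = ","))
        entries <- list.files(ap, no.. = TRUE)
        for (f in setdiff(entries, c(KNOWN_AU_FILES,
                                     grep("^block_[0-9]+$", entries,
                                          value = TRUE))))
          bad("unexpected entry '%s' in dg_%d/dt_%d/au_%d", f, dg, dt, au)
      }
    }
  }

  # protection-entry targets must exist
  v <- c(v, validateProtectionTargets(c))
  v
}

validateProtectionTargets <- function(c) {
  v <- character(0)
  checkBox <- function(pb, where) {
    if (is.null(pb)) return()
    for (e in pb@encryptionEntries)
      if (!file.exists(file.path(c@rootPath, e@target)))
        v <<- c(v, sprintf("%s encryption entry targets missing '%s'",
                           where, e@target))
    for (s in pb@signatures)
      if (!file.exists(file.path(c@rootPath, s@target)))
        v <<- c(v, sprintf("%s signature entry targets missing '%s'",
                           where, s@target))
  }
  for (dg in datasetGroupIds(c)) {
    checkBox(tryCatch(readProtection(c, dg), error = function(e) NULL),
             sprintf("dg_%d", dg))
    for (dt in datasetIds(c, dg)) {
      checkBox(tryCatch(readProtection(c, dg, dt), error = function(e) NULL),
               sprintf("dg_%d/dt_%d", dg, dt))
      for (au in accessUnitIds(c, dg, dt))
        checkBox(tryCatch(readProtection(c, dg, dt, au),
                          error = function(e) NULL),
                 sprintf("dg_%d/dt_%d/au_%d", dg, dt, au))
    }
  }
  v
}

# ---- tree snapshot ----------------------------------------------------------

#' Snapshot of the container tree
#'
#' Reads the whole hierarchy into a nested list (file bytes verbatim), used
#' for structural comparison and by \code{\link{packContainer}}.  Two
#' containers are equal as trees iff their snapshots are identical.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @return nested list mirroring the box hierarchy.
#' @export
containerTree <- function(c) {
  readOpt <- function(path) if (file.exists(path)) readFileRaw(path) else NULL
  groups <- lapply(datasetGroupIds(c), function(dg) {
    p <- dgPath(c, dg)
    datasets <- lapply(datasetIds(c, dg), function(dt) {
      dp <- dtPath(c, dg, dt)
      aus <- lapply(accessUnitIds(c, dg, dt), function(au) {
        ap <- auPath(c, dg, dt, au)
        list(id = au,
             header = readFileRaw(file.path(ap, "auhd")),
             info = readOpt(file.path(ap, "auin")),
             protection = readOpt(file.path(ap, "aupr")),
             blocks = lapply(blockIds(c, dg, dt, au), function(b)
               readFileRaw(file.path(ap, sprintf("block_%d", b)))))
      })
      list(id = dt,
           header = readFileRaw(file.path(dp, "dthd")),
           metadata = readOpt(file.path(dp, "dtmd")),
           protection = readOpt(file.path(dp, "dtpr")),
           label = readOpt(file.path(dp, "labl")),
           index = readOpt(file.path(dp, "dtin")),
           accessUnits = aus)
    })
    list(id = dg,
         header = readFileRaw(file.path(p, "dghd")),
         metadata = readOpt(file.path(p, "dgmd")),
         protection = readOpt(file.path(p, "dgpr")),
         datasets = datasets)
  })
  list(fileHeader = readFileRaw(file.path(c@rootPath, "flhd")),
       fileMetadata = readOpt(file.path(c@rootPath, "flmd")),
       groups = groups)
}
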
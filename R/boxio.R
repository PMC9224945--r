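# Binary box stream primitives.
#
# The packed container is an ISO-BMFF-like stream: each box is a 4-byte ASCII
# type code, an 8-byte big-endian unsigned payload length, and the payload.
# Container boxes (flcn, dgcn, dtcn, aucn) nest child boxes in their payload;
# leaf box types reuse the on-disk file names.  Lengths are doubles in R, so
# payloads are limited to 2^53 bytes -- far beyond anything writable here.

CONTAINER_MAGIC <- "GIPAMS01"
CONTAINER_VERSION <- 1L

BOX_CONTAINER_TYPES <- c("flcn", "dgcn", "dtcn", "aucn")
BOX_LEAF_TYPES <- c("flhd", "flmd", "dghd", "dgmd", "dgpr",
                    "dthd", "dtmd", "dtpr", "labl", "dtin",
                    "auhd", "auin", "aupr", "blck")

packUint32 <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}

packUint64 <- function(x) {
  # big-endian 8-byte unsigned from a non-negative double
  hi <- floor(x / 2^32)
  lo <- x - hi * 2^32
  c(packUint32(hi), packUint32(lo))
}

readUint64 <- function(bytes) {
  v <- as.numeric(bytes)
  sum(v * 256^(7:0))
}

encodeBox <- function(type, payload) {
  stopifnot(nchar(type) == 4L)
  c(charToRaw(type), packUint64(length(payload)), payload)
}

# Splits a raw vector into its top-level boxes; errors on truncation and on
# unknown box types.
decodeBoxes <- function(bytes) {
  boxes <- list()
  pos <- 0L
  n <- length(bytes)
  while (pos < n) {
    if (n - pos < 12)
      stop("truncated box stream: incomplete box header")
    type <- rawToChar(bytes[pos + 1:4])
    len <- readUint64(bytes[pos + 5:12])
    if (!type %in% c(BOX_CONTAINER_TYPES, BOX_LEAF_TYPES))
      stop(sprintf("unknown box type '%s'", type))
    if (pos + 12 + len > n)
      stop(sprintf("truncated box stream: '%s' declares %.0f payload bytes, %d available",
                   type, len, n - pos - 12L))
    payload <- if (len > 0) bytes[pos + 12 + seq_len(len)] else raw(0)
    boxes[[length(boxes) + 1L]] <- list(type = type, payload = payload)
    pos <- pos + 12L + as.integer(len)
  }
  boxes
}

readFileRaw <- function(path) {
  readBin(path, raw(), n = file.info(path)$size)
}

writeFileRaw <- function(path, bytes) {
  writeBin(as.vector(bytes), path)
}

concatRaw <- function(xs) {
  if (!length(xs)) raw(0) else do.call(base::c, xs)
}
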
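#' @include aead.R boxio.R
NULL

# Envelope layout (little-endian lengths):
#   magic "crypt4gh" (8) | version uint32 = 1 | packet count uint32
#   packets: uint32 length | writer pubkey (32) | nonce (12) |
#            sealed session key (32 + 16 tag)
#   body: data segments, each nonce (12) | sealed plaintext (<= 65536 + 16);
#         every segment except possibly the last is full-size.
# The session key is sealed under a key agreed by X25519 between the writer
# key and each recipient, so a recipient discovers "their" packet by trial
# decryption: packets whose tag does not verify are simply not for them.

C4GH_MAGIC <- "crypt4gh"
C4GH_VERSION <- 1L
C4GH_SEGMENT_SIZE <- 65536L
C4GH_PACKET_BODY_LEN <- 32L + 12L + 32L + 16L
C4GH_FULL_SEGMENT_LEN <- 12L + C4GH_SEGMENT_SIZE + 16L

packUint32le <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                     endian = "little")
readUint32le <- function(bytes) sum(as.numeric(bytes) * 256^(0:3))

#' Generate an X25519 keypair for envelope encryption
#'
#' @param seed optional string; when given, the private scalar is derived
#'   deterministically from it.
#' @return list of class \code{c4ghKeypair} with elements \code{private} and
#'   \code{public} (openssl key objects).
#' @examples
#' kp <- c4ghKeygen(seed = "example")
#' identical(c4ghKeygen(seed = "example")$public, kp$public)
#' @export
c4ghKeygen <- function(seed = NULL) {
  key <- if (is.null(seed)) openssl::x25519_keygen()
  else openssl::read_x25519_key(derivedBytes(paste0("c4gh-key:", seed), 32L))
  structure(list(private = key, public = as.list(key)$pubkey),
            class = "c4ghKeypair")
}

pubkeyRaw <- function(pub) as.raw(as.list(pub)$data)

# Key-agreement KDF: hash the X25519 shared secret together with both public
# keys so each (writer, reader) pair yields a distinct packet key.
packetKey <- function(sharedSecret, writerPubRaw, readerPubRaw) {
  as.raw(openssl::sha256(c(as.raw(sharedSecret), writerPubRaw,
                           readerPubRaw)))
}

c4ghError <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = NULL))
}

#' Encrypt a payload into a Crypt4GH-style envelope
#'
#' The plaintext is split into fixed 65,536-byte segments, each sealed
#' independently under a fresh random session key, and the session key is
#' wrapped once per recipient in a header packet keyed by X25519 agreement
#' between the writer's private key and that recipient's public key.  All
#' recipients decrypt the same payload; re-encrypting the same plaintext
#' yields different bytes (fresh session key and nonces) that decrypt
#' identically.
#'
#' @param plaintext raw vector (may be empty).
#' @param writerPrivate the writer's keypair or private key
#'   (\code{\link{c4ghKeygen}}).
#' @param readerPublics list of recipient public keys (or keypairs); at
#'   least one.
#' @return raw envelope bytes.
#' @export
c4ghEncrypt <- function(plaintext, writerPrivate, readerPublics) {
  stopifnot(is.raw(plaintext))
  if (inherits(writerPrivate, "c4ghKeypair"))
    writerPrivate <- writerPrivate$private
  if (!is.list(readerPublics) || inherits(readerPublics, "c4ghKeypair"))
    readerPublics <- list(readerPublics)
  if (length(readerPublics) == 0L)
    stop("at least one reader public key is required")
  readerPublics <- lapply(readerPublics, function(r)
    if (inherits(r, "c4ghKeypair")) r$public else r)

  sessionKey <- randomBytes(32L)
  writerPub <- as.list(writerPrivate)$pubkey
  writerPubRaw <- pubkeyRaw(writerPub)

  packets <- lapply(readerPublics, function(readerPub) {
    shared <- openssl::x25519_diffie_hellman(writerPrivate, readerPub)
    pk <- packetKey(shared, writerPubRaw, pubkeyRaw(readerPub))
    nonce <- randomBytes(AEAD_NONCE_LEN)
    sealed <- aeadSeal(pk, nonce, sessionKey, aad = charToRaw("c4gh-header"))
    body <- c(writerPubRaw, nonce, sealed)
    c(packUint32le(length(body)), body)
  })

  nSeg <- if (length(plaintext)) ceiling(length(plaintext) /
                                           C4GH_SEGMENT_SIZE) else 0L
  segments <- lapply(seq_len(nSeg), function(i) {
    lo <- (i - 1L) * C4GH_SEGMENT_SIZE + 1L
    hi <- min(i * C4GH_SEGMENT_SIZE, length(plaintext))
    nonce <- randomBytes(AEAD_NONCE_LEN)
    c(nonce, aeadSeal(sessionKey, nonce, plaintext[lo:hi],
                      aad = charToRaw("c4gh-segment")))
  })

  c(charToRaw(C4GH_MAGIC), packUint32le(C4GH_VERSION),
    packUint32le(length(packets)),
    concatRaw(packets),
    concatRaw(segments))
}

parseEnvelope <- function(envelope) {
  if (length(envelope) < 16L ||
      !identical(envelope[1:8], charToRaw(C4GH_MAGIC)))
    stop("not a crypt4gh-style envelope: bad magic")
  version <- readUint32le(envelope[9:12])
  if (version != C4GH_VERSION)
    stop(sprintf("unsupported envelope version %d", version))
  nPackets <- readUint32le(envelope[13:16])
  pos <- 16L
  packets <- vector("list", nPackets)
  for (i in seq_len(nPackets)) {
    if (length(envelope) < pos + 4L) stop("truncated envelope header")
    len <- readUint32le(envelope[pos + 1:4])
    if (len != C4GH_PACKET_BODY_LEN)
      stop(sprintf("malformed header packet of length %.0f", len))
    if (length(envelope) < pos + 4L + len) stop("truncated header packet")
    body <- envelope[pos + 4L + seq_len(len)]
    packets[[i]] <- list(writerPub = body[1:32], nonce = body[33:44],
                         sealed = body[45:length(body)])
    pos <- pos + 4L + as.integer(len)
  }
  body <- if (pos < length(envelope)) envelope[(pos + 1L):length(envelope)]
  else raw(0)
  segments <- list()
  spos <- 0L
  while (spos < length(body)) {
    remaining <- length(body) - spos
    segLen <- if (remaining >= C4GH_FULL_SEGMENT_LEN) C4GH_FULL_SEGMENT_LEN
    else remaining
    if (segLen < AEAD_NONCE_LEN + AEAD_TAG_LEN)
      stop("truncated data segment")
    seg <- body[spos + seq_len(segLen)]
    segments[[length(segments) + 1L]] <-
      list(nonce = seg[1:12], sealed = seg[13:segLen])
    spos <- spos + segLen
  }
  list(packets = packets, segments = segments)
}

# Trial-decrypts every header packet with the reader's key; returns the list
# of distinct session keys recovered.
collectSessionKeys <- function(packets, readerPrivate) {
  readerPubRaw <- pubkeyRaw(as.list(readerPrivate)$pubkey)
  keys <- list()
  for (p in packets) {
    writerPub <- openssl::read_x25519_pubkey(p$writerPub)
    shared <- openssl::x25519_diffie_hellman(readerPrivate, writerPub)
    pk <- packetKey(shared, p$writerPub, readerPubRaw)
    key <- tryCatch(aeadOpen(pk, p$nonce, p$sealed,
                             aad = charToRaw("c4gh-header")),
                    integrity_error = function(e) NULL)
    if (!is.null(key)) keys[[length(keys) + 1L]] <- key
  }
  keys
}

openSegment <- function(segment, keys) {
  for (k in keys) {
    pt <- tryCatch(aeadOpen(k, segment$nonce, segment$sealed,
                            aad = charToRaw("c4gh-segment")),
                   integrity_error = function(e) NULL)
    if (!is.null(pt)) return(pt)
  }
  stop(c4ghError("c4gh_segment_auth",
                 "no key authenticates a data segment ciphertext"))
}

#' Decrypt a Crypt4GH-style envelope
#'
#' All header packets are trial-decrypted with the reader's key; packets
#' whose tag does not verify are ignored (they were intended for other
#' recipients).  If no packet verifies, a \code{c4gh_no_verifiable_packet}
#' error is raised.  Every data segment is then authenticated by trying each
#' recovered key; a segment that no key authenticates raises a
#' \code{c4gh_segment_auth} error.
#'
#' @param envelope raw envelope bytes.
#' @param readerPrivate the reader's keypair or private key.
#' @return raw plaintext.
#' @export
c4ghDecrypt <- function(envelope, readerPrivate) {
  if (inherits(readerPrivate, "c4ghKeypair"))
    readerPrivate <- readerPrivate$private
  env <- parseEnvelope(envelope)
  keys <- collectSessionKeys(env$packets, readerPrivate)
  if (length(keys) == 0L)
    stop(c4ghError("c4gh_no_verifiable_packet",
                   "no header packet could be verified for this reader"))
  out <- lapply(env$segments, openSegment, keys = keys)
  concatRaw(out)
}

#' Decrypt a byte range from an envelope
#'
#' Lazily decrypts only the segments overlapping the half-open byte range
#' \code{[from, to)} (0-based), then slices out exactly the requested bytes:
#' the result always equals \code{c4ghDecrypt(envelope, key)[from:to]}.  The
#' number of segments actually decrypted is returned in the
#' \code{segmentsDecrypted} attribute.
#'
#' @inheritParams c4ghDecrypt
#' @param from,to 0-based half-open byte range, \code{0 <= from < to <=}
#'   plaintext length.
#' @return raw vector of \code{to - from} bytes.
#' @export
c4ghDecryptRange <- function(envelope, readerPrivate, from, to) {
  if (inherits(readerPrivate, "c4ghKeypair"))
    readerPrivate <- readerPrivate$private
  if (!(from >= 0 && from < to))
    stop("invalid range: need 0 <= from < to")
  env <- parseEnvelope(envelope)
  keys <- collectSessionKeys(env$packets, readerPrivate)
  if (length(keys) == 0L)
    stop(c4ghError("c4gh_no_verifiable_packet",
                   "no header packet could be verified for this reader"))
  firstSeg <- floor(from / C4GH_SEGMENT_SIZE) + 1L
  lastSeg <- ceiling(to / C4GH_SEGMENT_SIZE)
  if (lastSeg > length(env$segments))
    stop("range out of bounds: envelope holds fewer bytes")
  pieces <- lapply(env$segments[firstSeg:lastSeg], openSegment, keys = keys)
  joined <- concatRaw(pieces)
  offset <- (firstSeg - 1L) * C4GH_SEGMENT_SIZE
  if (to - offset > length(joined))
    stop("range out of bounds: envelope holds fewer bytes")
  structure(joined[(from - offset + 1L):(to - offset)],
            segmentsDecrypted = lastSeg - firstSeg + 1L)
}
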
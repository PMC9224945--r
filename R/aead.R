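# Internal authenticated encryption.
#
# Encrypt-then-MAC over openssl primitives: AES-256-CTR for confidentiality,
# HMAC-SHA256 (truncated to 16 bytes) over nonce || aad-length || aad ||
# ciphertext for integrity.  Distinct encryption and MAC keys are derived from
# the 32-byte content key by domain-separated SHA-256.  Any tag mismatch --
# wrong key, wrong nonce, flipped bit, swapped context -- raises an
# "integrity_error" condition; plaintext is never returned from an
# unauthenticated ciphertext.

AEAD_ALG <- "aes-256-ctr-hmac-sha256"
AEAD_TAG_LEN <- 16L
AEAD_NONCE_LEN <- 12L

aeadSubkeys <- function(key) {
  stopifnot(is.raw(key), length(key) == 32L)
  list(enc = openssl::sha256(c(key, charToRaw("enc"))),
       mac = openssl::sha256(c(key, charToRaw("mac"))))
}

ctrIv <- function(nonce) c(nonce, as.raw(c(0, 0, 0, 0)))

aeadTag <- function(macKey, nonce, aad, ciphertext) {
  msg <- c(nonce, packUint32(length(aad)), aad, ciphertext)
  as.raw(openssl::sha256(msg, key = macKey))[seq_len(AEAD_TAG_LEN)]
}

# Returns ciphertext || 16-byte tag.
aeadSeal <- function(key, nonce, plaintext, aad = raw(0)) {
  stopifnot(length(nonce) == AEAD_NONCE_LEN)
  ks <- aeadSubkeys(key)
  ct <- as.raw(openssl::aes_ctr_encrypt(plaintext, ks$enc, iv = ctrIv(nonce)))
  c(ct, aeadTag(ks$mac, nonce, aad, ct))
}

aeadOpen <- function(key, nonce, sealed, aad = raw(0)) {
  stopifnot(length(nonce) == AEAD_NONCE_LEN)
  if (length(sealed) < AEAD_TAG_LEN)
    stop(integrityError("ciphertext shorter than the authentication tag"))
  ks <- aeadSubkeys(key)
  n <- length(sealed) - AEAD_TAG_LEN
  ct <- sealed[seq_len(n)]
  tag <- sealed[n + seq_len(AEAD_TAG_LEN)]
  if (!identical(aeadTag(ks$mac, nonce, aad, ct), tag))
    stop(integrityError("authentication tag mismatch"))
  as.raw(openssl::aes_ctr_decrypt(ct, ks$enc, iv = ctrIv(nonce)))
}

integrityError <- function(msg) {
  structure(class = c("integrity_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

# Deterministic pseudo-random bytes: SHA-256 in counter mode over a seed
# label.  Used wherever a caller asks for reproducible key material.
derivedBytes <- function(label, n) {
  out <- raw(0)
  i <- 0L
  while (length(out) < n) {
    out <- c(out, as.raw(openssl::sha256(c(charToRaw(label),
                                           packUint32(i)))))
    i <- i + 1L
  }
  out[seq_len(n)]
}

randomBytes <- function(n) as.raw(openssl::rand_bytes(n))
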
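#' @include AllClasses.R aead.R container.R policy-xml.R
NULL

SIGNATURE_ALG <- "ed25519"
KEYWRAP_METHOD <- "bcrypt-pbkdf-aes-256-ctr-hmac-sha256"
KEYWRAP_ROUNDS <- 16L

#' Construct a protection box
#'
#' @param policy optional \code{\link{XacmlPolicy}} embedded in the box.
#' @param encryptionEntries,signatures,wrappedKeys lists of
#'   \code{\link{EncryptionEntry}}, \code{\link{SignatureEntry}} and
#'   \code{\link{KeyWrapper}} objects.
#' @return a \code{\link{ProtectionBox}}.
#' @export
protectionBox <- function(policy = NULL, encryptionEntries = list(),
                          signatures = list(), wrappedKeys = list()) {
  new("ProtectionBox", policy = policy,
      encryptionEntries = encryptionEntries,
      signatures = signatures, wrappedKeys = wrappedKeys)
}

#' Generate a symmetric content key
#'
#' @param seed optional string; when given the key is derived
#'   deterministically from it, otherwise 32 random bytes are drawn.
#' @return raw 32-byte key.
#' @export
contentKeygen <- function(seed = NULL) {
  if (is.null(seed)) randomBytes(32L)
  else derivedBytes(paste0("content-key:", seed), 32L)
}

#' Generate an Ed25519 signing keypair
#'
#' @param seed optional string for deterministic derivation.
#' @return list with elements \code{private} (openssl key) and \code{public}
#'   (openssl pubkey).
#' @export
signingKeygen <- function(seed = NULL) {
  key <- if (is.null(seed)) openssl::ed25519_keygen()
  else openssl::read_ed25519_key(derivedBytes(paste0("signing-key:", seed),
                                              32L))
  list(private = key, public = as.list(key)$pubkey)
}

# ---- target selectors -------------------------------------------------------

# A selector addresses one payload: a block ("dg_X/dt_Y/au_Z/block_W") or a
# metadata file ("dg_X/dgmd", "dg_X/dt_Y/dtmd").  The protection record for a
# target lives in the nearest enclosing level's box: block -> the access
# unit's aupr, dtmd -> dtpr, dgmd -> dgpr.
resolveSelector <- function(c, selector) {
  parts <- strsplit(selector, "/", fixed = TRUE)[[1]]
  last <- parts[length(parts)]
  getId <- function(part, prefix) {
    pat <- sprintf("^%s_([0-9]+)$", prefix)
    if (!grepl(pat, part)) stop(sprintf("malformed selector '%s'", selector))
    as.integer(sub(pat, "\\1", part))
  }
  if (grepl("^block_[0-9]+$", last)) {
    if (length(parts) != 4L) stop(sprintf("malformed selector '%s'", selector))
    dg <- getId(parts[1], "dg"); dt <- getId(parts[2], "dt")
    au <- getId(parts[3], "au")
    list(file = file.path(c@rootPath, selector),
         boxArgs = list(dgId = dg, dtId = dt, auId = au))
  } else if (last == "dtmd") {
    if (length(parts) != 3L) stop(sprintf("malformed selector '%s'", selector))
    dg <- getId(parts[1], "dg"); dt <- getId(parts[2], "dt")
    list(file = file.path(c@rootPath, selector),
         boxArgs = list(dgId = dg, dtId = dt))
  } else if (last == "dgmd") {
    if (length(parts) != 2L) stop(sprintf("malformed selector '%s'", selector))
    dg <- getId(parts[1], "dg")
    list(file = file.path(c@rootPath, selector), boxArgs = list(dgId = dg))
  } else {
    stop(sprintf("selector '%s' does not address a block or metadata file",
                 selector))
  }
}

readBoxFor <- function(c, boxArgs) {
  pb <- do.call(readProtection, c(list(c), boxArgs))
  if (is.null(pb)) protectionBox() else pb
}

writeBoxFor <- function(c, boxArgs, pb) {
  do.call(attachProtection, c(list(c, pb), boxArgs))
}

findEncryptionEntry <- function(pb, selector) {
  for (e in pb@encryptionEntries)
    if (e@target == selector) return(e)
  NULL
}

#' Selectively encrypt one container payload
#'
#' Replaces the target payload (a block or a metadata file) with its
#' authenticated ciphertext and records an \code{\link{EncryptionEntry}} in
#' the nearest enclosing protection box.  No byte outside the target payload
#' and its protection box changes, so protection can mix freely: e.g.
#' encrypted metadata next to plaintext blocks, or one encrypted block among
#' plaintext siblings.  The selector string is bound to the ciphertext as
#' associated data, so a ciphertext moved to another target fails decryption.
#'
#' @param c a \code{\link{GenomicContainer}}.
#' @param selector payload selector, e.g. \code{"dg_0/dt_0/au_0/block_1"},
#'   \code{"dg_0/dgmd"} or \code{"dg_0/dt_0/dtmd"}.
#' @param key raw 32-byte content key (\code{\link{contentKeygen}}).
#' @param keyRef identifier recorded in the entry (a wrapped-key id or an
#'   external key name).
#' @return the new \code{\link{EncryptionEntry}}, invisibly.
#' @export
encryptTarget <- function(c, selector, key, keyRef = "content-key") {
  tgt <- resolveSelector(c, selector)
  checkNode(tgt$file, "target payload")
  pb <- readBoxFor(c, tgt$boxArgs)
  if (!is.null(findEncryptionEntry(pb, selector)))
    stop(sprintf("target '%s' is already encrypted", selector))
  nonce <- randomBytes(AEAD_NONCE_LEN)
  plaintext <- readFileRaw(tgt$file)
  writeFileRaw(tgt$file, aeadSeal(key, nonce, plaintext,
                                  aad = charToRaw(selector)))
  entry <- new("EncryptionEntry", target = selector, algorithm = AEAD_ALG,
               nonce = nonce, keyRef = keyRef)
  pb@encryptionEntries <- c(pb@encryptionEntries, list(entry))
  writeBoxFor(c, tgt$boxArgs, pb)
  invisible(entry)
}

#' Decrypt one container payload
#'
#' Authenticated decryption of a target previously encrypted with
#' \code{\link{encryptTarget}}.  A wrong key, a tampered ciphertext or a
#' mismatched nonce raises an \code{integrity_error}; garbage plaintext is
#' never returned and the stored ciphertext is left untouched.
#'
#' @inheritParams encryptTarget
#' @param restore when TRUE, the decrypted plaintext is also written back to
#'   the target file and the encryption entry is removed.
#' @return raw plaintext payload.
#' @export
decryptTarget <- function(c, selector, key, restore = FALSE) {
  tgt <- resolveSelector(c, selector)
  checkNode(tgt$file, "target payload")
  pb <- readBoxFor(c, tgt$boxArgs)
  entry <- findEncryptionEntry(pb, selector)
  if (is.null(entry))
    stop(sprintf("no encryption entry for target '%s'", selector))
  plaintext <- aeadOpen(key, entry@nonce, readFileRaw(tgt$file),
                        aad = charToRaw(selector))
  if (restore) {
    writeFileRaw(tgt$file, plaintext)
    pb@encryptionEntries <- Filter(function(e) e@target != selector,
                                   pb@encryptionEntries)
    writeBoxFor(c, tgt$boxArgs, pb)
  }
  plaintext
}

#' Sign and verify container payloads
#'
#' \code{signTarget} stores a detached Ed25519 signature over the target's
#' current (plaintext) payload in the nearest enclosing protection box;
#' signatures bind to plaintext, so when a payload is both signed and
#' encrypted it must be signed first and integrity is checked after
#' decryption.  \code{verifyTarget} recomputes the verification against the
#' payload as stored.
#'
#' @inheritParams encryptTarget
#' @param signingKey an Ed25519 private key (\code{\link{signingKeygen}}).
#' @return \code{signTarget}: the \code{\link{SignatureEntry}}, invisibly;
#'   \code{verifyTarget}: TRUE iff the payload is unchanged since signing.
#' @export
signTarget <- function(c, selector, signingKey) {
  tgt <- resolveSelector(c, selector)
  checkNode(tgt$file, "target payload")
  pb <- readBoxFor(c, tgt$boxArgs)
  if (!is.null(findEncryptionEntry(pb, selector)))
    stop(sprintf("target '%s' is encrypted; sign the plaintext first",
                 selector))
  payload <- readFileRaw(tgt$file)
  if (is.list(signingKey)) signingKey <- signingKey$private
  sig <- openssl::ed25519_sign(data = payload, key = signingKey)
  pubRaw <- as.list(as.list(signingKey)$pubkey)$data
  entry <- new("SignatureEntry", target = selector,
               algorithm = SIGNATURE_ALG,
               publicKey = as.raw(pubRaw), signature = as.raw(sig))
  pb@signatures <- Filter(function(s) s@target != selector, pb@signatures)
  pb@signatures <- c(pb@signatures, list(entry))
  writeBoxFor(c, tgt$boxArgs, pb)
  invisible(entry)
}

#' @rdname signTarget
#' @export
verifyTarget <- function(c, selector) {
  tgt <- resolveSelector(c, selector)
  checkNode(tgt$file, "target payload")
  pb <- readBoxFor(c, tgt$boxArgs)
  entry <- NULL
  for (s in pb@signatures) if (s@target == selector) entry <- s
  if (is.null(entry))
    stop(sprintf("no signature entry for target '%s'", selector))
  payload <- readFileRaw(tgt$file)
  pub <- openssl::read_ed25519_pubkey(entry@publicKey)
  tryCatch(isTRUE(openssl::ed25519_verify(data = payload,
                                          sig = entry@signature,
                                          pubkey = pub)),
           error = function(e) FALSE)
}

# ---- key wrapping -----------------------------------------------------------

#' Wrap and unwrap content keys under a passphrase
#'
#' The wrapping key is derived from the passphrase with bcrypt_pbkdf over a
#' fresh random salt, and the content key is sealed with the package's
#' authenticated encryption, so unwrapping with a wrong passphrase fails
#' loudly rather than yielding a silently wrong key.  Two wraps of the same
#' key produce distinct salts, nonces and ciphertexts.
#'
#' @param key raw 32-byte content key.
#' @param passphrase passphrase string.
#' @param keyId identifier stored in the wrapper.
#' @return \code{wrapKey}: a \code{\link{KeyWrapper}}; \code{unwrapKey}: the
#'   raw content key.
#' @export
wrapKey <- function(key, passphrase, keyId = "content-key") {
  stopifnot(is.raw(key))
  salt <- randomBytes(16L)
  kek <- as.raw(openssl::bcrypt_pbkdf(passphrase, salt,
                                      rounds = KEYWRAP_ROUNDS, size = 32L))
  nonce <- randomBytes(AEAD_NONCE_LEN)
  new("KeyWrapper", keyId = keyId, method = KEYWRAP_METHOD,
      salt = salt, nonce = nonce,
      wrapped = aeadSeal(kek, nonce, key, aad = charToRaw("key-wrap")))
}

#' @rdname wrapKey
#' @param w a \code{\link{KeyWrapper}}.
#' @export
unwrapKey <- function(w, passphrase) {
  if (w@method != KEYWRAP_METHOD)
    stop(sprintf("unknown key wrapping method '%s'", w@method))
  kek <- as.raw(openssl::bcrypt_pbkdf(passphrase, w@salt,
                                      rounds = KEYWRAP_ROUNDS, size = 32L))
  tryCatch(aeadOpen(kek, w@nonce, w@wrapped, aad = charToRaw("key-wrap")),
           integrity_error = function(e)
             stop("wrong passphrase or corrupted key wrapper"))
}

# ---- XML serialization ------------------------------------------------------

b64 <- function(x) openssl::base64_encode(x)
unb64 <- function(x) as.raw(openssl::base64_decode(x))

#' Serialize a protection box to XML
#'
#' Root \code{<Protection>} with an optional embedded \code{<Policy>} (the
#' XACML subset), \code{<Encryption>}, \code{<Signature>} and
#' \code{<WrappedKey>} entries; binary values are base64.
#'
#' @param pb a \code{\link{ProtectionBox}}.
#' @return raw vector of UTF-8 XML bytes.
#' @export
protectionToXml <- function(pb) {
  doc <- xml2::xml_new_root("Protection")
  if (!is.null(pb@policy)) {
    polNode <- xml2::xml_add_child(doc, "Policy")
    polDoc <- xml2::read_xml(rawToChar(serializePolicyXml(pb@policy)))
    xml2::xml_add_child(polNode, polDoc)
  }
  for (e in pb@encryptionEntries) {
    node <- xml2::xml_add_child(doc, "Encryption")
    xml2::xml_set_attrs(node, c(target = e@target, alg = e@algorithm,
                                nonce = b64(e@nonce), keyRef = e@keyRef))
  }
  for (s in pb@signatures) {
    node <- xml2::xml_add_child(doc, "Signature")
    xml2::xml_set_attrs(node, c(target = s@target, alg = s@algorithm,
                                pubkey = b64(s@publicKey),
                                value = b64(s@signature)))
  }
  for (w in pb@wrappedKeys) {
    node <- xml2::xml_add_child(doc, "WrappedKey")
    xml2::xml_set_attrs(node, c(id = w@keyId, method = w@method,
                                salt = b64(w@salt), nonce = b64(w@nonce),
                                value = b64(w@wrapped)))
  }
  charToRaw(as.character(doc))
}

#' Parse a protection box from XML
#'
#' @param xml raw vector or string of protection XML.
#' @return a \code{\link{ProtectionBox}}.
#' @export
protectionFromXml <- function(xml) {
  if (is.raw(xml)) xml <- rawToChar(xml)
  doc <- xml2::read_xml(xml)
  if (xml2::xml_name(doc) != "Protection")
    stop("protection XML root must be <Protection>")
  policy <- NULL
  enc <- list(); sigs <- list(); keys <- list()
  for (node in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(node)
    if (nm == "Policy") {
      kids <- xml2::xml_children(node)
      if (length(kids) != 1L)
        stop("<Policy> must wrap exactly one XACML policy element")
      policy <- parsePolicyXml(as.character(kids[[1]]))
    } else if (nm == "Encryption") {
      enc[[length(enc) + 1L]] <- new("EncryptionEntry",
        target = xml2::xml_attr(node, "target"),
        algorithm = xml2::xml_attr(node, "alg"),
        nonce = unb64(xml2::xml_attr(node, "nonce")),
        keyRef = xml2::xml_attr(node, "keyRef"))
    } else if (nm == "Signature") {
      sigs[[length(sigs) + 1L]] <- new("SignatureEntry",
        target = xml2::xml_attr(node, "target"),
        algorithm = xml2::xml_attr(node, "alg"),
        publicKey = unb64(xml2::xml_attr(node, "pubkey")),
        signature = unb64(xml2::xml_attr(node, "value")))
    } else if (nm == "WrappedKey") {
      keys[[length(keys) + 1L]] <- new("KeyWrapper",
        keyId = xml2::xml_attr(node, "id"),
        method = xml2::xml_attr(node, "method"),
        salt = unb64(xml2::xml_attr(node, "salt")),
        nonce = unb64(xml2::xml_attr(node, "nonce")),
        wrapped = unb64(xml2::xml_attr(node, "value")))
    } else {
      stop(sprintf("unknown protection element <%s>", nm))
    }
  }
  protectionBox(policy, enc, sigs, keys)
}
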
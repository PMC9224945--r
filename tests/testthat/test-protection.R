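protContainer <- function() {
  c <- createContainer(newRoot())
  addDatasetGroup(c, 0)
  addDataset(c, 0, 0)
  addAccessUnit(c, 0, 0, 0)
  addBlock(c, 0, 0, 0, as.raw(1:64))
  addBlock(c, 0, 0, 0, as.raw(65:128))
  attachMetadata(c, MetadataRecord(title = "protected study"), 0)
  attachMetadata(c, MetadataRecord(sampleTitle = "s1"), 0, 0)
  c
}

treeWithout <- function(c, drop) {
  # snapshot of all files except the target payload and its protection box
  files <- sort(list.files(c@rootPath, recursive = TRUE))
  files <- setdiff(files, drop)
  lapply(setNames(files, files), function(f)
    readBin(file.path(c@rootPath, f), raw(),
            n = file.info(file.path(c@rootPath, f))$size))
}

test_that("encryption touches only the target payload and its box", {
  c <- protContainer()
  key <- contentKeygen(seed = "k")
  target <- "dg_0/dt_0/au_0/block_1"
  before <- treeWithout(c, c(target, "dg_0/dt_0/au_0/aupr"))
  plainBefore <- readBlock(c, 0, 0, 0, 1)
  encryptTarget(c, target, key)
  expect_identical(treeWithout(c, c(target, "dg_0/dt_0/au_0/aupr")), before)
  expect_false(identical(as.raw(readBlock(c, 0, 0, 0, 1)),
                         as.raw(plainBefore)))
  expect_true(attr(readBlock(c, 0, 0, 0, 1), "encrypted"))
  expect_false(attr(readBlock(c, 0, 0, 0, 0), "encrypted"))
  expect_identical(as.raw(decryptTarget(c, target, key)),
                   as.raw(65:128))
})

test_that("metadata can be encrypted while blocks stay plaintext", {
  c <- protContainer()
  key <- contentKeygen()
  encryptTarget(c, "dg_0/dt_0/dtmd", key)
  expect_true(file.exists(file.path(c@rootPath, "dg_0", "dt_0", "dtpr")))
  expect_identical(as.raw(readBlock(c, 0, 0, 0, 0)), as.raw(1:64))
  expect_length(validateContainer(c), 0)
  md <- metadataFromXml(decryptTarget(c, "dg_0/dt_0/dtmd", key))
  expect_identical(md@sampleTitle, "s1")
  # group-level metadata goes through dgpr
  encryptTarget(c, "dg_0/dgmd", key)
  pb <- readProtection(c, 0)
  expect_length(pb@encryptionEntries, 1)
  expect_identical(pb@encryptionEntries[[1]]@target, "dg_0/dgmd")
})

test_that("decryption fails loudly on wrong keys and tampering", {
  c <- protContainer()
  key <- contentKeygen()
  target <- "dg_0/dt_0/au_0/block_0"
  encryptTarget(c, target, key)
  expect_error(encryptTarget(c, target, key), "already encrypted")
  expect_error(decryptTarget(c, target, contentKeygen()),
               class = "integrity_error")
  # flip one ciphertext byte
  f <- file.path(c@rootPath, target)
  ct <- readBin(f, raw(), n = file.info(f)$size)
  ct[5] <- xor(ct[5], as.raw(1))
  writeBin(ct, f)
  expect_error(decryptTarget(c, target, key), class = "integrity_error")
  # payload untouched by the failed attempts
  expect_identical(readBin(f, raw(), n = file.info(f)$size), ct)
  expect_error(decryptTarget(c, "dg_0/dgmd", key), "no encryption entry")
})

test_that("encryption round-trips across payload sizes including empty", {
  set.seed(8)
  key <- contentKeygen()
  for (n in c(0L, 1L, 255L, 4096L, 70000L)) {
    c <- createContainer(newRoot())
    addDatasetGroup(c, 0); addDataset(c, 0, 0); addAccessUnit(c, 0, 0, 0)
    payload <- as.raw(sample.int(256L, n, replace = TRUE) - 1L)
    addBlock(c, 0, 0, 0, payload)
    encryptTarget(c, "dg_0/dt_0/au_0/block_0", key)
    expect_identical(as.raw(decryptTarget(c, "dg_0/dt_0/au_0/block_0",
                                          key)), payload)
    unlink(c@rootPath, recursive = TRUE)
  }
})

test_that("restore-mode decryption returns the container to plaintext", {
  c <- protContainer()
  key <- contentKeygen()
  encryptTarget(c, "dg_0/dt_0/au_0/block_0", key)
  decryptTarget(c, "dg_0/dt_0/au_0/block_0", key, restore = TRUE)
  expect_identical(as.raw(readBlock(c, 0, 0, 0, 0)), as.raw(1:64))
  expect_false(attr(readBlock(c, 0, 0, 0, 0), "encrypted"))
})

test_that("signatures verify until the payload changes", {
  c <- protContainer()
  sk <- signingKeygen(seed = "signer")
  signTarget(c, "dg_0/dgmd", sk)
  expect_true(verifyTarget(c, "dg_0/dgmd"))
  # mutate the metadata -> signature no longer verifies
  attachMetadata(c, MetadataRecord(title = "tampered"), 0)
  expect_false(verifyTarget(c, "dg_0/dgmd"))
  expect_error(verifyTarget(c, "dg_0/dt_0/dtmd"), "no signature entry")
})

test_that("signing metadata and encrypting blocks work independently", {
  c <- protContainer()
  sk <- signingKeygen()
  key <- contentKeygen()
  signTarget(c, "dg_0/dt_0/dtmd", sk)
  encryptTarget(c, "dg_0/dt_0/au_0/block_0", key)
  expect_true(verifyTarget(c, "dg_0/dt_0/dtmd"))
  expect_identical(as.raw(decryptTarget(c, "dg_0/dt_0/au_0/block_0", key)),
                   as.raw(1:64))
  # signing an encrypted payload is refused (signatures bind to plaintext)
  expect_error(signTarget(c, "dg_0/dt_0/au_0/block_0", sk), "encrypted")
  expect_length(validateContainer(c), 0)
})

test_that("key wrapping round-trips and rejects wrong passphrases", {
  key <- contentKeygen()
  w <- wrapKey(key, "correct horse")
  expect_identical(unwrapKey(w, "correct horse"), key)
  expect_error(unwrapKey(w, "wrong"), "wrong passphrase")
  # fresh randomness per wrap
  w2 <- wrapKey(key, "correct horse")
  expect_false(identical(w@salt, w2@salt))
  expect_false(identical(w@wrapped, w2@wrapped))
  expect_identical(unwrapKey(w2, "correct horse"), key)
})

test_that("protection boxes round-trip through XML", {
  key <- contentKeygen()
  pb <- protectionBox(
    policy = buildWorkedExample()$policy,
    encryptionEntries = list(
      new("EncryptionEntry", target = "dg_0/dt_0/au_0/block_0",
          algorithm = "aes-256-ctr-hmac-sha256",
          nonce = as.raw(1:12), keyRef = "k1"),
      new("EncryptionEntry", target = "dg_0/dgmd",
          algorithm = "aes-256-ctr-hmac-sha256",
          nonce = as.raw(13:24), keyRef = "k2")),
    signatures = list(
      new("SignatureEntry", target = "dg_0/dgmd", algorithm = "ed25519",
          publicKey = as.raw(1:32), signature = as.raw(1:64))),
    wrappedKeys = list(wrapKey(key, "pw", keyId = "k1")))
  expect_equal(protectionFromXml(protectionToXml(pb)), pb)
  # empty box and policy-only box are both valid documents
  expect_equal(protectionFromXml(protectionToXml(protectionBox())),
               protectionBox())
  polOnly <- protectionBox(policy = allDenyPolicy())
  expect_equal(protectionFromXml(protectionToXml(polOnly)), polOnly)
  expect_error(protectionFromXml("<Wrong/>"), "root")
})

test_that("packing preserves mixed-protection ciphertexts byte-exactly", {
  c <- protContainer()
  key <- contentKeygen()
  encryptTarget(c, "dg_0/dt_0/au_0/block_1", key)
  ct <- as.raw(readBlock(c, 0, 0, 0, 1))
  c2 <- unpackContainer(packContainer(c), newRoot())
  expect_identical(as.raw(readBlock(c2, 0, 0, 0, 1)), ct)
  expect_identical(as.raw(decryptTarget(c2, "dg_0/dt_0/au_0/block_1", key)),
                   as.raw(65:128))
})
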
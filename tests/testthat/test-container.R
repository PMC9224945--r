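test_that("a fresh container holds only the file header and no groups", {
  root <- newRoot()
  c <- createContainer(root)
  expect_true(file.exists(file.path(root, "flhd")))
  expect_identical(list.files(root), "flhd")
  expect_length(datasetGroupIds(c), 0)
  expect_identical(fileHeader(c)$magic, "GIPAMS01")
})

test_that("creating over a non-empty path is refused", {
  root <- newRoot()
  dir.create(root)
  writeLines("x", file.path(root, "occupied"))
  expect_error(createContainer(root), "not empty")
})

test_that("the on-disk layout follows the dg/dt/au/block naming scheme", {
  root <- newRoot()
  c <- createContainer(root)
  addDatasetGroup(c, 0)
  expect_true(dir.exists(file.path(root, "dg_0")))
  expect_true(file.exists(file.path(root, "dg_0", "dghd")))
  addDataset(c, 0, 0)
  expect_true(file.exists(file.path(root, "dg_0", "dt_0", "dthd")))
  addAccessUnit(c, 0, 0, 0, info = as.raw(1:4))
  expect_true(file.exists(file.path(root, "dg_0", "dt_0", "au_0", "auhd")))
  expect_true(file.exists(file.path(root, "dg_0", "dt_0", "au_0", "auin")))
  addBlock(c, 0, 0, 0, as.raw(1:8))
  expect_true(file.exists(file.path(root, "dg_0", "dt_0", "au_0",
                                    "block_0")))
  setLabel(c, 0, 0, "lane 1")
  expect_true(file.exists(file.path(root, "dg_0", "dt_0", "labl")))
  attachProtection(c, protectionBox(), 0)
  attachProtection(c, protectionBox(), 0, 0)
  attachProtection(c, protectionBox(), 0, 0, 0)
  expect_true(file.exists(file.path(root, "dg_0", "dgpr")))
  expect_true(file.exists(file.path(root, "dg_0", "dt_0", "dtpr")))
  expect_true(file.exists(file.path(root, "dg_0", "dt_0", "au_0", "aupr")))
})

test_that("duplicate and orphan ids are rejected, ordering is ascending", {
  c <- createContainer(newRoot())
  addDatasetGroup(c, 0)
  expect_error(addDatasetGroup(c, 0), "already exists")
  addDatasetGroup(c, 1)
  expect_identical(datasetGroupIds(c), c(0L, 1L))
  expect_error(addDataset(c, 7, 0), "does not exist")
  addDataset(c, 0, 0)
  expect_error(addDataset(c, 0, 0), "already exists")
  expect_error(addAccessUnit(c, 0, 5, 0), "does not exist")
})

test_that("blocks accept empty payloads and enumerate exhaustively", {
  c <- basicContainer(payload = raw(0))
  expect_identical(length(readBlock(c, 0, 0, 0, 0)), 0L)

  # 2 x 2 x 2 x 1 tree -> 8 blocks
  c2 <- createContainer(newRoot())
  for (dg in 0:1) {
    addDatasetGroup(c2, dg)
    for (dt in 0:1) {
      addDataset(c2, dg, dt)
      for (au in 0:1) {
        addAccessUnit(c2, dg, dt, au)
        addBlock(c2, dg, dt, au, as.raw(dg * 4 + dt * 2 + au))
      }
    }
  }
  n <- 0L
  for (dg in datasetGroupIds(c2))
    for (dt in datasetIds(c2, dg))
      for (au in accessUnitIds(c2, dg, dt))
        n <- n + length(blockIds(c2, dg, dt, au))
  expect_identical(n, 8L)
})

test_that("metadata attachment replaces and round-trips", {
  c <- basicContainer()
  md <- MetadataRecord(title = "first")
  attachMetadata(c, md, 0)
  expect_true(file.exists(file.path(c@rootPath, "dg_0", "dgmd")))
  md2 <- MetadataRecord(title = "second", sampleTaxonId = "9606")
  attachMetadata(c, md2, 0)
  expect_identical(readMetadata(c, 0), md2)
  attachMetadata(c, md2, 0, 0)
  expect_true(file.exists(file.path(c@rootPath, "dg_0", "dt_0", "dtmd")))
  expect_identical(readMetadata(c, 0, 0), md2)
})

test_that("protection boxes round-trip through their XML files", {
  c <- basicContainer()
  pb <- protectionBox(policy = allPermitPolicy())
  attachProtection(c, pb, 0, 0)
  expect_equal(readProtection(c, 0, 0), pb)
  expect_null(readProtection(c, 0))
})

test_that("edited header fields persist through pack and unpack", {
  c <- basicContainer()
  editElement(c, "dg_0", list(note = "edited"))
  editElement(c, "", list(brand = "rebranded"))
  bytes <- packContainer(c)
  c2 <- unpackContainer(bytes, newRoot())
  expect_identical(readElementHeader(c2, "dg_0")$note, "edited")
  expect_identical(fileHeader(c2)$brand, "rebranded")
  expect_error(editElement(c, "dg_9", list(a = 1)), "does not exist")
})

test_that("deleting elements removes whole subtrees", {
  c <- createContainer(newRoot())
  addDatasetGroup(c, 0)
  addDataset(c, 0, 0); addDataset(c, 0, 1)
  deleteElement(c, "dg_0/dt_0")
  expect_identical(datasetIds(c, 0), 1L)
  deleteElement(c, "dg_0")
  expect_length(datasetGroupIds(c), 0)
  expect_false(dir.exists(file.path(c@rootPath, "dg_0")))
  expect_error(deleteElement(c, "dg_0"), "does not exist")
})

test_that("an empty container packs to a single flcn-wrapped flhd box", {
  c <- createContainer(newRoot())
  bytes <- packContainer(c)
  expect_identical(rawToChar(bytes[1:8]), "GIPAMS01")
  expect_identical(rawToChar(bytes[9:12]), "flcn")
  expect_identical(rawToChar(bytes[21:24]), "flhd")
  # exactly one box inside flcn
  inner <- bytes[-(1:20)]
  len <- sum(as.numeric(inner[5:12]) * 256^(7:0))
  expect_identical(length(inner), 12L + as.integer(len))
})

test_that("pack is deterministic and pack/unpack are mutual identities", {
  set.seed(42)
  for (i in 1:20) {
    c <- randomTree(maxDim = 3L, maxBlocks = 3L, maxBlockSize = 4096L)
    b1 <- packContainer(c)
    b2 <- packContainer(c)
    expect_identical(b1, b2)
    c2 <- unpackContainer(b1, newRoot())
    expect_identical(containerTree(c2), containerTree(c))
    expect_identical(packContainer(c2), b1)
    unlink(c@rootPath, recursive = TRUE)
    unlink(c2@rootPath, recursive = TRUE)
  }
})

test_that("unpack rejects bad magic, truncation and unknown box types", {
  c <- basicContainer()
  bytes <- packContainer(c)
  bad <- bytes; bad[1] <- as.raw(0)
  expect_error(unpackContainer(bad, newRoot()), "bad magic")
  expect_error(unpackContainer(bytes[1:(length(bytes) - 4L)], newRoot()),
               "truncated")
  unknown <- bytes
  unknown[9:12] <- charToRaw("zzzz")
  expect_error(unpackContainer(unknown, newRoot()), "unknown box type|flcn")
})

test_that("random single-byte corruptions never unpack into broken trees", {
  set.seed(99)
  c <- basicContainer()
  attachMetadata(c, MetadataRecord(title = "T"), 0)
  bytes <- packContainer(c)
  for (i in 1:40) {
    pos <- sample.int(length(bytes), 1)
    mut <- bytes
    mut[pos] <- xor(mut[pos], as.raw(sample.int(255, 1)))
    dest <- newRoot()
    res <- tryCatch(unpackContainer(mut, dest), error = function(e) NULL)
    if (!is.null(res)) {
      # parsed: the result must at least be a well-formed tree
      expect_true(dir.exists(res@rootPath))
      expect_silent(containerTree(res))
    }
    unlink(dest, recursive = TRUE)
  }
})

test_that("validate flags duplicate ids and dangling index references", {
  c <- basicContainer()
  expect_length(validateContainer(c), 0)

  # duplicate dt_id: rewrite dt_1's header to claim dt_id 0
  addDataset(c, 0, 1)
  writeLines('{"dt_id":0}', file.path(c@rootPath, "dg_0", "dt_1", "dthd"))
  v <- validateContainer(c)
  expect_true(any(grepl("duplicate dt_id 0", v)))
  expect_error(packContainer(c), "does not validate")

  # index referencing a missing access unit
  c2 <- basicContainer()
  setDatasetIndex(c2, 0, 0, c("0" = 1, "5" = 100))
  v2 <- validateContainer(c2)
  expect_true(any(grepl("index references missing access unit 5", v2)))

  # foreign file
  c3 <- basicContainer()
  writeLines("x", file.path(c3@rootPath, "dg_0", "stray"))
  expect_true(any(grepl("unexpected entry 'stray'", validateContainer(c3))))
})

test_that("the dataset index records 1-based access-unit offsets", {
  c <- createContainer(newRoot())
  addDatasetGroup(c, 0); addDataset(c, 0, 0)
  addAccessUnit(c, 0, 0, 0); addBlock(c, 0, 0, 0, as.raw(1:100))
  addAccessUnit(c, 0, 0, 1); addBlock(c, 0, 0, 1, as.raw(1:50))
  idx <- buildDatasetIndex(c, 0, 0)
  expect_identical(idx, c("0" = 1, "1" = 101))
  expect_identical(readDatasetIndex(c, 0, 0), idx)
})
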
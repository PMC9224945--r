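# container with one group, one dataset, and configurable policies at each
# level; effects may be "Permit", "Deny", "NotApplicable" (a policy exists
# but matches nothing) or NULL (no policy file at all).
hierContainer <- function(dtEffect, dgEffect) {
  c <- createContainer(newRoot())
  addDatasetGroup(c, 0)
  addDataset(c, 0, 0)
  attachRulePolicy(c, dgEffect, 0)
  attachRulePolicy(c, dtEffect, 0, 0)
  c
}

test_that("dataset authorization follows the delegation truth table", {
  req <- authzRequest(role = "tester")
  cases <- expand.grid(
    dt = c("Permit", "Deny", "NotApplicable", "none"),
    dg = c("Permit", "Deny", "NotApplicable", "none"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    dtE <- if (cases$dt[i] == "none") NULL else cases$dt[i]
    dgE <- if (cases$dg[i] == "none") NULL else cases$dg[i]
    c <- hierContainer(dtE, dgE)
    res <- authorizeDataset(c, 0, 0, req)
    if (identical(dtE, "Permit")) {
      expect_identical(res@outcome, "Permit")
      expect_identical(res@grantedBy, "dataset")
      # dataset-level grants carry no provenance attribute
      expect_null(requestAttribute(res@annotatedRequest,
                                   "granted_by_dataset_group"))
    } else if (identical(dgE, "Permit")) {
      expect_identical(res@outcome, "Permit")
      expect_identical(res@grantedBy, "dataset_group")
      prov <- requestAttribute(res@annotatedRequest,
                               "granted_by_dataset_group")
      expect_true(!is.null(prov) && isTRUE(prov@value))
    } else {
      expect_identical(res@outcome, "Deny")
      expect_identical(res@grantedBy, "none")
    }
    unlink(c@rootPath, recursive = TRUE)
  }
  expect_error(authorizeDataset(hierContainer(NULL, NULL), 3, 0, req),
               "does not exist")
})

test_that("a dataset-level Permit beats an explicit group-level Deny", {
  c <- hierContainer("Permit", "Deny")
  res <- authorizeDataset(c, 0, 0, authzRequest(role = "tester"))
  expect_identical(res@outcome, "Permit")
  expect_identical(res@grantedBy, "dataset")
})

test_that("group-wide review blocks datasets whose own rules do not grant", {
  req <- authzRequest(role = "tester")
  c <- createContainer(newRoot())
  addDatasetGroup(c, 0)
  addDataset(c, 0, 0)                      # no policy -> inherits
  addDataset(c, 0, 1); attachRulePolicy(c, "Deny", 0, 1)
  addDataset(c, 0, 2); attachRulePolicy(c, "Permit", 0, 2)
  attachRulePolicy(c, "Permit", 0)
  g <- authorizeDatasetGroup(c, 0, req)
  expect_identical(g@outcome, "Permit")
  expect_identical(g@grantedDatasets, c(0L, 2L))
  expect_identical(g@blockedDatasets, 1L)

  # a NotApplicable dataset policy blocks; only a missing policy inherits
  addDataset(c, 0, 3); attachRulePolicy(c, "NotApplicable", 0, 3)
  g2 <- authorizeDatasetGroup(c, 0, req)
  expect_true(3L %in% g2@blockedDatasets)

  # group-level Deny short-circuits with no per-dataset review
  attachRulePolicy(c, "Deny", 0)
  g3 <- authorizeDatasetGroup(c, 0, req)
  expect_identical(g3@outcome, "Deny")
  expect_length(g3@grantedDatasets, 0)
  expect_length(g3@blockedDatasets, 0)
  expect_error(authorizeDatasetGroup(c, 9, req), "does not exist")
})

test_that("randomized group reviews match a set-builder oracle", {
  set.seed(77)
  req <- authzRequest(role = "tester")
  for (trial in 1:40) {
    nDt <- sample.int(5L, 1)
    effects <- sample(c("Permit", "Deny", "NotApplicable", "none"), nDt,
                      replace = TRUE)
    c <- createContainer(newRoot())
    addDatasetGroup(c, 0)
    for (dt in seq_len(nDt) - 1L) {
      addDataset(c, 0, dt)
      e <- effects[dt + 1L]
      attachRulePolicy(c, if (e == "none") NULL else e, 0, dt)
    }
    attachRulePolicy(c, "Permit", 0)
    g <- authorizeDatasetGroup(c, 0, req)
    expectGranted <- which(effects %in% c("Permit", "none")) - 1L
    expectBlocked <- which(!effects %in% c("Permit", "none")) - 1L
    expect_identical(g@grantedDatasets, as.integer(expectGranted))
    expect_identical(g@blockedDatasets, as.integer(expectBlocked))
    # invariant: no applicable Deny ever lands in the granted set
    expect_length(intersect(g@grantedDatasets,
                            which(effects == "Deny") - 1L), 0)
    unlink(c@rootPath, recursive = TRUE)
  }
})

test_that("dataset specificity survives randomized group policies", {
  set.seed(31)
  for (trial in 1:30) {
    dgE <- sample(c("Permit", "Deny", "NotApplicable", "none"), 1)
    c <- hierContainer("Permit", if (dgE == "none") NULL else dgE)
    res <- authorizeDataset(c, 0, 0, authzRequest(role = "tester"))
    expect_identical(res@outcome, "Permit")
    expect_identical(res@grantedBy, "dataset")
    unlink(c@rootPath, recursive = TRUE)
  }
})

test_that("operation authorization dispatches, logs, and spares creation", {
  log <- tempfile()
  c <- hierContainer("Permit", "Deny")
  req <- authzRequest(role = "tester", `subject-id` = "alice")

  # file creation needs no policy at all
  r0 <- authorizeOperation(c, "create-file", "", req, log = log)
  expect_identical(r0@outcome, "Permit")

  # dataset read dispatches to the hierarchical algorithm
  r1 <- authorizeOperation(c, "GetDataBySimpleFilter", "dg_0/dt_0", req,
                           log = log)
  expect_identical(r1@outcome, "Permit")
  expect_identical(r1@grantedBy, "dataset")

  # metadata-read blocked when the governing rule denies
  c2 <- hierContainer("Deny", NULL)
  r2 <- authorizeOperation(c2, "metadata-read", "dg_0/dt_0", req, log = log)
  expect_identical(r2@outcome, "Deny")

  # reads are closed by default when no policy governs
  c3 <- hierContainer(NULL, NULL)
  r3 <- authorizeOperation(c3, "GetDataBySimpleFilter", "dg_0/dt_0", req,
                           log = log)
  expect_identical(r3@outcome, "Deny")

  expect_error(authorizeOperation(c, "launchMissiles", "", req),
               "unknown operation")

  # one audit record per authorization call, append-only
  al <- readAuditLog(log)
  expect_identical(nrow(al), 4L)
  expect_identical(al$outcome, c("Permit", "Permit", "Deny", "Deny"))
  expect_identical(al$operation[1], "create-file")
})

test_that("ownership gates mutating operations before policy evaluation", {
  c <- createContainer(newRoot(), owner = "alice")
  addDatasetGroup(c, 0)
  bob <- authzRequest(role = "admin", `subject-id` = "bob")
  alice <- authzRequest(role = "admin", `subject-id` = "alice")
  expect_identical(
    authorizeOperation(c, "addDataset", "dg_0", bob, log = NULL)@outcome,
    "Deny")
  expect_identical(
    authorizeOperation(c, "addDataset", "dg_0", alice, log = NULL)@outcome,
    "Permit")
  # reads are not ownership-gated (but remain closed without a policy)
  expect_identical(
    authorizeOperation(c, "GetDataBySimpleFilter", "dg_0", bob,
                       log = NULL)@outcome, "Deny")
})
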
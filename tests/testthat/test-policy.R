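test_that("the worked-example rule denies the mismatched-role request", {
  wx <- buildWorkedExample()
  d <- evaluatePolicy(wx$policy, wx$request)
  expect_false(outcome(d) == "Permit")
  # and the matching practitioner request is permitted
  expect_identical(outcome(evaluatePolicy(wx$policy,
                                          workedExampleMatchingRequest())),
                   "Permit")
})

test_that("the permitted region boundaries are sharp at both extremes", {
  wx <- buildWorkedExample()
  evalAt <- function(...) outcome(evaluatePolicy(
    wx$policy, workedExampleMatchingRequest(...)))
  # brute force +-2 around the inclusive lower bound, end held at the top
  for (s in 40810025:40810029)
    expect_identical(evalAt(start_position = s),
                     if (s >= 40810027) "Permit" else "NotApplicable")
  # upper bound, start held at the bottom
  for (e in 41216712:41216716)
    expect_identical(evalAt(end_position = e),
                     if (e <= 41216714) "Permit" else "NotApplicable")
  # read-count cap and reference identity
  expect_identical(evalAt(read_count = 5000), "Permit")
  expect_identical(evalAt(read_count = 5001), "NotApplicable")
  expect_identical(evalAt(reference_id = 5), "NotApplicable")
  expect_identical(evalAt(presence_of_multiple_alignments = TRUE),
                   "NotApplicable")
  expect_identical(evalAt(situation = "Routine"), "NotApplicable")
})

test_that("rule evaluation distinguishes mismatch, failure and missing data", {
  rule <- policyRule("r", "Permit", role = "practitioner",
                     action = "GetDataBySimpleFilter",
                     conditions = list(
                       xacmlCondition("situation", "equals", "Emergency"),
                       xacmlCondition("read_count", "integer-at-most", 100)))
  # target mismatch
  expect_identical(outcome(evaluateRule(rule, authzRequest(
    role = "student", `action-id` = "GetDataBySimpleFilter"))),
    "NotApplicable")
  # missing target attribute is a mismatch too
  expect_identical(outcome(evaluateRule(rule, authzRequest(
    `action-id` = "GetDataBySimpleFilter"))), "NotApplicable")
  # condition false
  expect_identical(outcome(evaluateRule(rule, authzRequest(
    role = "practitioner", `action-id` = "GetDataBySimpleFilter",
    situation = "Routine", read_count = 10))), "NotApplicable")
  # condition attribute missing -> Indeterminate
  expect_identical(outcome(evaluateRule(rule, authzRequest(
    role = "practitioner", `action-id` = "GetDataBySimpleFilter",
    situation = "Emergency"))), "Indeterminate")
  # ill-typed attribute -> Indeterminate
  expect_identical(outcome(evaluateRule(rule, authzRequest(
    role = "practitioner", `action-id` = "GetDataBySimpleFilter",
    situation = "Emergency",
    read_count = "lots"))), "Indeterminate")
  # all conditions hold
  expect_identical(outcome(evaluateRule(rule, authzRequest(
    role = "practitioner", `action-id` = "GetDataBySimpleFilter",
    situation = "Emergency", read_count = 99))), "Permit")
})

test_that("combining algorithms order Permit/Deny/Indeterminate correctly", {
  permitRule <- policyRule("p", "Permit")
  denyRule <- policyRule("d", "Deny")
  req <- authzRequest(role = "anyone")
  expect_identical(outcome(evaluatePolicy(xacmlPolicy("empty"), req)),
                   "NotApplicable")
  both <- xacmlPolicy("b", list(permitRule, denyRule))
  expect_identical(outcome(evaluatePolicy(both, req)), "Deny")
  # deny-overrides is order-independent
  flipped <- xacmlPolicy("b2", list(denyRule, permitRule))
  expect_identical(outcome(evaluatePolicy(flipped, req)), "Deny")
  po <- xacmlPolicy("po", list(denyRule, permitRule),
                    combining = "permit-overrides")
  expect_identical(outcome(evaluatePolicy(po, req)), "Permit")
  fa <- xacmlPolicy("fa", list(denyRule, permitRule),
                    combining = "first-applicable")
  expect_identical(outcome(evaluatePolicy(fa, req)), "Deny")
  fa2 <- xacmlPolicy("fa2", list(permitRule, denyRule),
                     combining = "first-applicable")
  expect_identical(outcome(evaluatePolicy(fa2, req)), "Permit")
})

test_that("the engine agrees with a brute-force oracle over random policies", {
  set.seed(123)
  boolIds <- c("flag_a", "flag_b", "flag_c")
  for (trial in 1:60) {
    nRules <- sample.int(4L, 1)
    combining <- sample(c("deny-overrides", "permit-overrides",
                          "first-applicable"), 1)
    rules <- lapply(seq_len(nRules), function(i) {
      conds <- lapply(sample(boolIds, sample.int(3L, 1)), function(id)
        list(id = id, op = "eq", value = sample(c(TRUE, FALSE), 1)))
      list(effect = sample(c("Permit", "Deny"), 1),
           role = if (runif(1) < 0.5) "tester",
           action = NULL, conds = conds)
    })
    policy <- xacmlPolicy("rand", lapply(seq_along(rules), function(i)
      asPolicyRule(rules[[i]], paste0("r", i))), combining)
    # exhaustive truth table over the three boolean attributes
    for (a in c(TRUE, FALSE)) for (b in c(TRUE, FALSE))
      for (cc in c(TRUE, FALSE)) {
        attrs <- list(role = "tester", flag_a = a, flag_b = b, flag_c = cc)
        expected <- oracleEvalPolicy(rules, attrs, combining)
        got <- outcome(evaluatePolicy(policy, asRequest(attrs)))
        expect_identical(got, expected)
      }
  }
})

test_that("policy decisions are pure functions of policy and request", {
  wx <- buildWorkedExample()
  req <- workedExampleMatchingRequest()
  d1 <- evaluatePolicy(wx$policy, req)
  for (i in 1:5)
    expect_identical(evaluatePolicy(wx$policy, req), d1)
})

test_that("requests reject multi-valued attributes", {
  expect_error(new("AuthzRequest", attributes = list(
    attributeValue("role", "a"), attributeValue("role", "b"))),
    "multi-valued")
})

test_that("policy XML round-trips losslessly within the subset", {
  wx <- buildWorkedExample()
  xml <- serializePolicyXml(wx$policy)
  expect_equal(parsePolicyXml(xml), wx$policy)
  # the role match carries the XACML 1.0 access-subject category
  expect_match(rawToChar(xml),
               "urn:oasis:names:tc:xacml:1.0:subject-category:access-subject",
               fixed = TRUE)
  set.seed(5)
  for (i in 1:20) {
    conds <- list(
      xacmlCondition("situation", "equals",
                     sample(c("Emergency", "Routine"), 1)),
      xacmlCondition("read_count", "integer-at-most",
                     sample.int(10000L, 1)),
      xacmlCondition(c("start_position", "end_position"),
                     "integer-range-within", sort(sample.int(1e6, 2))))
    pol <- xacmlPolicy(paste0("p", i), list(
      policyRule("r1", sample(c("Permit", "Deny"), 1),
                 role = if (i %% 2) "practitioner",
                 action = if (i %% 3) "GetDataBySimpleFilter",
                 conditions = sample(conds, sample.int(3L, 1))),
      policyRule("r2", "Deny")),
      combining = sample(c("deny-overrides", "permit-overrides",
                           "first-applicable"), 1))
    expect_equal(parsePolicyXml(serializePolicyXml(pol)), pol)
  }
})

test_that("out-of-subset XACML documents raise named unsupported errors", {
  wx <- buildWorkedExample()
  doc <- xml2::read_xml(rawToChar(serializePolicyXml(wx$policy)))
  xml2::xml_add_child(doc, "Obligations")
  expect_error(parsePolicyXml(as.character(doc)),
               "unsupported XACML feature: Obligations",
               class = "xacml_unsupported_feature")
  ps <- sprintf('<PolicySet xmlns="%s"/>',
                "urn:oasis:names:tc:xacml:3.0:core:schema:wd-17")
  expect_error(parsePolicyXml(ps), class = "xacml_unsupported_feature")
  wrongNs <- '<Policy xmlns="urn:example:other"/>'
  expect_error(parsePolicyXml(wrongNs), "namespace")
})

test_that("request XML round-trips with category grouping", {
  req <- workedExampleMatchingRequest()
  out <- parseRequestXml(serializeRequestXml(req))
  getv <- function(r, id) requestAttribute(r, id)@value
  for (id in c("role", "action-id", "situation", "read_count",
               "reference_id", "start_position", "end_position"))
    expect_identical(getv(out, id), getv(req, id))
  expect_identical(requestAttribute(out, "role")@category,
                   requestAttribute(req, "role")@category)
})
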
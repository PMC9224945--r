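# Shared test fixtures: everything is generated in code under tempdirs.

newRoot <- function() {
  path <- tempfile(pattern = "gvtest-")
  path
}

# small container with one dg/dt/au/block path
basicContainer <- function(payload = as.raw(1:16)) {
  c <- createContainer(newRoot())
  addDatasetGroup(c, 0)
  addDataset(c, 0, 0)
  addAccessUnit(c, 0, 0, 0)
  addBlock(c, 0, 0, 0, payload)
  c
}

# Randomized container tree: up to maxDim nodes per level, random block
# payloads, optional metadata/label sprinkled in.  Driven by the caller's
# RNG state.
randomTree <- function(maxDim = 3L, maxBlocks = 4L, maxBlockSize = 65536L) {
  c <- createContainer(newRoot())
  for (dg in seq_len(sample.int(maxDim, 1)) - 1L) {
    addDatasetGroup(c, dg)
    if (runif(1) < 0.3)
      attachMetadata(c, MetadataRecord(title = paste("g", dg)), dg)
    for (dt in seq_len(sample.int(maxDim, 1)) - 1L) {
      addDataset(c, dg, dt)
      if (runif(1) < 0.3) setLabel(c, dg, dt, paste("label", dg, dt))
      for (au in seq_len(sample.int(maxDim, 1)) - 1L) {
        addAccessUnit(c, dg, dt, au,
                      info = if (runif(1) < 0.3) as.raw(sample(0:255, 8)))
        for (b in seq_len(sample.int(maxBlocks, 1))) {
          n <- sample.int(maxBlockSize + 1L, 1) - 1L
          addBlock(c, dg, dt, au,
                   as.raw(sample.int(256L, n, replace = TRUE) - 1L))
        }
      }
      if (runif(1) < 0.3) buildDatasetIndex(c, dg, dt)
    }
  }
  c
}

# Attaches a single-rule policy at a level; effect NULL means no policy file.
attachRulePolicy <- function(c, effect, dgId, dtId = NULL,
                             role = NULL) {
  if (is.null(effect)) return(invisible(c))
  pol <- if (effect == "NotApplicable")
    xacmlPolicy("na", list(policyRule("na-rule", "Permit",
                                      role = "nobody-has-this-role")))
  else xacmlPolicy(tolower(effect),
                   list(policyRule(paste0(tolower(effect), "-rule"), effect,
                                   role = role)))
  attachProtection(c, protectionBox(policy = pol), dgId, dtId)
  invisible(c)
}

# Independent brute-force policy evaluator used as oracle: rules are plain
# lists (effect, role, action, conds = list(list(id, op, value))).  It never
# calls the package's evaluator.
oracleEvalRule <- function(rule, attrs) {
  # attrs: named list of plain values
  matches <- function(req, have) is.null(req) || (!is.null(have) &&
                                                    identical(have, req))
  if (!matches(rule$role, attrs[["role"]])) return("NotApplicable")
  if (!matches(rule$action, attrs[["action-id"]])) return("NotApplicable")
  anyNA <- FALSE
  for (cond in rule$conds) {
    v <- attrs[[cond$id]]
    if (is.null(v)) { anyNA <- TRUE; next }
    ok <- switch(cond$op,
      eq = identical(v, cond$value),
      le = v <= cond$value)
    if (!ok) return("NotApplicable")
  }
  if (anyNA) return("Indeterminate")
  rule$effect
}

oracleEvalPolicy <- function(rules, attrs, combining = "deny-overrides") {
  outs <- vapply(rules, oracleEvalRule, character(1), attrs = attrs)
  if (combining == "first-applicable") {
    appl <- outs[outs != "NotApplicable"]
    return(if (length(appl)) appl[1] else "NotApplicable")
  }
  pref <- if (combining == "deny-overrides")
    c("Deny", "Indeterminate", "Permit") else
      c("Permit", "Indeterminate", "Deny")
  for (o in pref) if (o %in% outs) return(o)
  "NotApplicable"
}

# converts an oracle rule (plain list) into a package PolicyRule
asPolicyRule <- function(rule, id) {
  conds <- lapply(rule$conds, function(cond)
    xacmlCondition(cond$id,
                   switch(cond$op, eq = if (is.logical(cond$value))
                     "boolean-equals" else "equals",
                     le = "integer-at-most"),
                   cond$value))
  policyRule(id, rule$effect, role = rule$role, action = rule$action,
             conditions = conds)
}

asRequest <- function(attrs) {
  do.call(authzRequest, attrs)
}
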
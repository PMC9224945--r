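#' @include container.R metadata.R policy.R protection.R
NULL

#' Specification for a synthetic test container
#'
#' Defines the dimensions and protection template of a generated container.
#' The same seed always yields a byte-identical fixture (identical
#' \code{\link{packContainer}} output).
#'
#' @param seed integer seed for all randomness in the fixture.
#' @param nGroups number of dataset groups.
#' @param nDatasets datasets per group.
#' @param nAccessUnits access units per dataset.
#' @param nBlocks blocks per access unit.
#' @param blockSize block payload size in bytes.
#' @param policyTemplate policy attached at both hierarchy levels:
#'   \code{"all-permit"} (a single unconditional Permit rule),
#'   \code{"all-deny"}, \code{"worked-example"} (the
#'   \code{\link{buildWorkedExample}} rule, attached at dataset level with an
#'   all-permit group policy), or \code{"none"}.
#' @return list of class \code{fixtureSpec}.
#' @export
fixtureSpec <- function(seed = 1L, nGroups = 2L, nDatasets = 2L,
                        nAccessUnits = 1L, nBlocks = 1L, blockSize = 1024L,
                        policyTemplate = c("none", "all-permit", "all-deny",
                                           "worked-example")) {
  policyTemplate <- match.arg(policyTemplate)
  stopifnot(nGroups > 0, nDatasets > 0, nAccessUnits > 0, nBlocks > 0,
            blockSize >= 0)
  structure(list(seed = as.integer(seed), nGroups = as.integer(nGroups),
                 nDatasets = as.integer(nDatasets),
                 nAccessUnits = as.integer(nAccessUnits),
                 nBlocks = as.integer(nBlocks),
                 blockSize = as.integer(blockSize),
                 policyTemplate = policyTemplate),
            class = "fixtureSpec")
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

seededBytes <- function(n) as.raw(sample.int(256L, n, replace = TRUE) - 1L)

#' All-permit and all-deny policy templates
#'
#' Single-rule policies with no target and no conditions, granting or
#' denying every request.
#'
#' @param policyId policy identifier.
#' @return a \code{\link{XacmlPolicy}}.
#' @export
allPermitPolicy <- function(policyId = "all-permit") {
  xacmlPolicy(policyId, list(policyRule("permit-everything", "Permit")))
}

#' @rdname allPermitPolicy
#' @export
allDenyPolicy <- function(policyId = "all-deny") {
  xacmlPolicy(policyId, list(policyRule("deny-everything", "Deny")))
}

templatePolicies <- function(template) {
  switch(template,
    "none" = list(dg = NULL, dt = NULL),
    "all-permit" = list(dg = allPermitPolicy(), dt = allPermitPolicy()),
    "all-deny" = list(dg = allDenyPolicy(), dt = allDenyPolicy()),
    "worked-example" = list(dg = NULL, dt = buildWorkedExample()$policy))
}

#' Generate a synthetic container fixture
#'
#' Builds a container populated with seeded random block payloads,
#' EGA-style study metadata at group level and sample metadata at dataset
#' level, and policies drawn from the chosen template.  Everything is
#' derived from the spec's seed, so fixtures are exactly reproducible.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir destination directory (must not exist or be empty).
#' @return the generated \code{\link{GenomicContainer}}.
#' @examples
#' c <- generateFixture(fixtureSpec(seed = 7), file.path(tempdir(), "fx7"))
#' validateContainer(c)
#' @export
generateFixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  pols <- templatePolicies(spec$policyTemplate)
  withSeed(spec$seed, {
    c <- createContainer(dir, brand = "GenomicVault-fixture")
    for (dg in seq_len(spec$nGroups) - 1L) {
      addDatasetGroup(c, dg)
      md <- mapFromEga(list(
        "Study-STUDY_TITLE" = sprintf("Synthetic study %d", dg),
        "Study-STUDY_TYPE" = "Whole Genome Sequencing",
        "Study-STUDY_ABSTRACT" = sprintf(
          "Synthetic fixture dataset group %d (seed %d).", dg, spec$seed),
        "Study-CENTER_PROJECT_NAME" = "GenomicVault test centre",
        "Study-STUDY_DESCRIPTION" = "Generated container fixture."))
      attachMetadata(c, md, dg)
      if (!is.null(pols$dg))
        attachProtection(c, protectionBox(policy = pols$dg), dg)
      for (dt in seq_len(spec$nDatasets) - 1L) {
        addDataset(c, dg, dt)
        dtMd <- mapFromEga(list(
          "Assembly-TAXON_ID" = "9606",
          "Assembly-TITLE" = sprintf("Sample dg%d-dt%d", dg, dt)))
        attachMetadata(c, dtMd, dg, dt)
        if (!is.null(pols$dt))
          attachProtection(c, protectionBox(policy = pols$dt), dg, dt)
        for (au in seq_len(spec$nAccessUnits) - 1L) {
          addAccessUnit(c, dg, dt, au)
          for (b in seq_len(spec$nBlocks))
            addBlock(c, dg, dt, au, seededBytes(spec$blockSize))
        }
      }
    }
    c
  })
}
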
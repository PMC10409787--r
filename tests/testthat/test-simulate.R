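smallSpec <- function(...) {
  SyntheticSpec(nGenomes = 40L, nSamples = 40L, moduleSizes = rep(10L, 3L),
                nDependents = 4L, depth = 2e4, ...)
}

test_that("simulation is bit-reproducible under its seed", {
  s1 <- simulateCommunity(smallSpec(), seed = 5)
  s2 <- simulateCommunity(smallSpec(), seed = 5)
  expect_identical(abundances(s1$abundance), abundances(s2$abundance))
  expect_identical(s1$truth@rolesByVitamin, s2$truth@rolesByVitamin)
  expect_identical(as.data.frame(s1$metadata), as.data.frame(s2$metadata))
  s3 <- simulateCommunity(smallSpec(), seed = 6)
  expect_false(identical(abundances(s1$abundance), abundances(s3$abundance)))
})

test_that("the generated table satisfies the abundance invariants", {
  sim <- simulateCommunity(smallSpec(), seed = 2)
  expect_true(validObject(sim$abundance))
  v <- abundances(sim$abundance)
  expect_true(all(v >= 0))
  expect_true(all(colSums(v) <= 1 + 1e-6))
  expect_equal(dim(v), c(40L, 40L))
})

test_that("producer counts match the requested fractions exactly", {
  sim <- simulateCommunity(SyntheticSpec(), seed = 3)
  roles <- sim$truth@rolesByVitamin$thiamine
  expect_equal(sum(roles == "producer"), 38)
  expect_equal(sum(roles == "auxotroph"), 120 - 38)
  ## the hub is a producer and its dependents are auxotrophs
  expect_identical(unname(roles[sim$truth@hubId]), "producer")
  expect_true(all(roles[sim$truth@dependents] == "auxotroph"))
  ## the hub is its module's only producer for the hub vitamin
  mod <- sim$truth@modules
  inHubModule <- names(mod)[mod == mod[sim$truth@hubId]]
  expect_equal(sum(roles[inHubModule] == "producer"), 1)
})

test_that("planted modules correlate more within than between", {
  wins <- 0
  for (s in 1:20) {
    spec <- SyntheticSpec(nGenomes = 30L, nSamples = 92L,
                          moduleSizes = c(10L, 10L, 10L),
                          rhoIn = 0.8, nDependents = 4L, depth = 2e4)
    sim <- simulateCommunity(spec, seed = 600 + s)
    lv <- log(abundances(sim$abundance) + 1e-6)
    cc <- stats::cor(t(lv))
    mod <- sim$truth@modules
    same <- outer(mod, mod, "==") & upper.tri(cc)
    diff <- (!outer(mod, mod, "==")) & upper.tri(cc)
    wins <- wins + (mean(cc[same]) > mean(cc[diff]))
  }
  expect_gte(wins, 19)  # >= 95% of seeds
})

test_that("annotations reproduce the planted roles under the shipped catalog", {
  cat <- defaultPathwayCatalog()
  spec <- smallSpec()
  sim <- simulateCommunity(spec, seed = 7)
  ann <- simulateAnnotations(sim$truth, cat, spec, seed = 7)
  calls <- callAllPathways(ann, cat)
  for (vit in names(sim$truth@rolesByVitamin)) {
    sel <- calls[calls$vitamin == vit, ]
    status <- stats::setNames(sel$status, sel$genome_id)
    planted <- sim$truth@rolesByVitamin[[vit]]
    nc <- sim$truth@nearComplete[[vit]]
    for (g in names(planted)) {
      if (planted[[g]] == "producer") {
        expect_identical(unname(status[g]),
                         if (g %in% nc) "near_complete" else "complete")
      } else {
        expect_identical(unname(status[g]), "absent")
      }
    }
    if (length(nc)) {
      miss <- sel$missing_kos[match(nc, sel$genome_id)]
      expect_true(all(miss == "K03147"))
    }
  }
  ## role labels derived from the calls equal the planted labels
  lab <- classifyRoles(calls, "thiamine", "producer")
  expect_identical(roles(lab)[names(sim$truth@rolesByVitamin$thiamine)],
                   sim$truth@rolesByVitamin$thiamine)
})

test_that("near-complete planting requires a non-empty exempt set", {
  cat <- defaultPathwayCatalog()
  noExempt <- PathwayCatalog(local({
    vs <- cat@vitamins
    vs$thiamine$exempt <- character()
    vs
  }))
  spec <- smallSpec()
  sim <- simulateCommunity(spec, seed = 8)
  expect_error(simulateAnnotations(sim$truth, noExempt, spec, seed = 8),
               "exempt set is empty")
})

test_that("an infeasible correlation structure is rejected by name", {
  spec <- smallSpec(rhoIn = 0, rhoOut = 0.9)
  expect_error(simulateCommunity(spec, seed = 1), "not positive semidefinite")
})

test_that("genome length grows with planted vitamin breadth", {
  sim <- simulateCommunity(smallSpec(), seed = 9)
  nPath <- rowSums(vapply(sim$truth@rolesByVitamin,
                          function(r) r == "producer",
                          logical(length(sim$truth@modules))))
  lens <- sim$truth@lengths
  expect_gt(stats::cor(nPath, lens), 0.5)
})

test_that("condition effects shift the responsive module's abundance", {
  spec <- smallSpec(metadataEffect = 3)
  sim <- simulateCommunity(spec, seed = 10)
  v <- abundances(sim$abundance)
  mod2 <- names(sim$truth@modules)[sim$truth@modules == 2L]
  plank <- sampleIds(sim$abundance)[
    as.character(sim$metadata[sampleIds(sim$abundance), "lifestyle"]) ==
      "planktonic"]
  bio <- setdiff(sampleIds(sim$abundance), plank)
  expect_gt(mean(v[mod2, plank]), mean(v[mod2, bio]))
})
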
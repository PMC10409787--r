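thiamineComplete <- c("K03149", "K03147", "K00788", "K00941")

test_that("thiamine tiers follow the four-stage rule", {
  cat <- defaultPathwayCatalog()
  ann <- AnnotationSet(list(
    full = thiamineComplete,
    noThiC = setdiff(thiamineComplete, "K03147"),
    noThiG = setdiff(thiamineComplete, "K03149"),
    altKinase = c("K03150", "K03147", "K00788", "K00946")))
  expect_identical(callStatus(callPathway(ann, cat, "full", "thiamine")),
                   "complete")
  nc <- callPathway(ann, cat, "noThiC", "thiamine")
  expect_identical(callStatus(nc), "near_complete")
  expect_identical(missingKos(nc), "K03147")
  ## no KO from the thiazole stage at all -> absent
  expect_identical(callStatus(callPathway(ann, cat, "noThiG", "thiamine")),
                   "absent")
  ## alternative KOs satisfy their stages
  expect_identical(callStatus(callPathway(ann, cat, "altKinase", "thiamine")),
                   "complete")
  expect_error(callPathway(ann, cat, "full", "vitaminX"), "unknown vitamin")
  expect_error(callPathway(ann, cat, "nope", "thiamine"), "unknown genome")
})

test_that("adding a KO never demotes a pathway status", {
  rank <- c(absent = 1, near_complete = 2, complete = 3)
  set.seed(33)
  for (i in 1:100) {
    cat <- randomCatalog()
    allKo <- unlist(pathwayStages(cat, "vit"))
    kos <- allKo[runif(length(allKo)) < 0.5]
    ann1 <- AnnotationSet(list(g = kos))
    extra <- setdiff(allKo, kos)
    if (!length(extra)) next
    ann2 <- AnnotationSet(list(g = c(kos, sample(extra, 1))))
    s1 <- callStatus(callPathway(ann1, cat, "g", "vit"))
    s2 <- callStatus(callPathway(ann2, cat, "g", "vit"))
    expect_gte(rank[[s2]], rank[[s1]])
  }
})

test_that("pathway calls agree with the subset-enumeration oracle", {
  set.seed(44)
  for (i in 1:200) {
    cat <- randomCatalog()
    stages <- pathwayStages(cat, "vit")
    exempt <- exemptKos(cat, "vit")
    allKo <- unlist(stages)
    kos <- allKo[runif(length(allKo)) < runif(1)]
    ann <- AnnotationSet(list(g = kos))
    expect_identical(callStatus(callPathway(ann, cat, "g", "vit")),
                     oracleStatus(stages, kos, exempt))
  }
})

test_that("role classification partitions genomes under both policies", {
  calls <- S4Vectors::DataFrame(
    genome_id = c("a", "b", "c", "d"),
    vitamin = "thiamine",
    status = c("complete", "near_complete", "absent", "absent"))
  lab <- classifyRoles(calls, "thiamine", "producer")
  expect_equal(nProducers(lab), 2)
  expect_equal(nAuxotrophs(lab), 2)
  expect_identical(unname(roles(lab)["b"]), "producer")
  lab2 <- classifyRoles(calls, "thiamine", "auxotroph")
  expect_identical(unname(roles(lab2)["b"]), "auxotroph")
  expect_equal(nProducers(lab2) + nAuxotrophs(lab2), 4)

  dup <- rbind(calls, calls[1, ])
  expect_error(classifyRoles(dup, "thiamine"), "duplicate genome")

  empty <- classifyRoles(calls[0, ], "thiamine")
  expect_equal(nProducers(empty), 0)
  expect_equal(nAuxotrophs(empty), 0)
})

test_that("vitamin counts bin genomes and Welch tests match the closed form", {
  cat <- defaultPathwayCatalog()
  ## three genomes complete for 3 vitamins, three for 0-1
  mk <- function(vits) unlist(lapply(vits, function(v)
    vapply(pathwayStages(cat, v), `[`, "", 1L)), use.names = FALSE)
  ko <- list(g1 = mk(c("thiamine", "biotin", "NAD")),
             g2 = mk(c("thiamine", "biotin", "NAD")),
             g3 = mk(c("thiamine", "biotin", "NAD")),
             g4 = character(), g5 = character(), g6 = character())
  lens <- c(g1 = 20, g2 = 22, g3 = 21, g4 = 10, g5 = 12, g6 = 11)
  ann <- AnnotationSet(ko, lens)
  calls <- callAllPathways(ann, cat)
  res <- vitaminCountVsSize(ann, calls)
  expect_identical(unique(res$perGenome[res$perGenome$bin == "3", "genome_id"]),
                   c("g1", "g2", "g3"))
  expect_equal(res$perBin$n[res$perBin$bin == "3"], 3L)

  ## Welch for {10,12,11} vs {20,22,21} by hand: equal variances 1, n = 3
  tt <- res$tests[res$tests$bin1 == "0-1" & res$tests$bin2 == "3", ]
  se <- sqrt(1 / 3 + 1 / 3)
  tHand <- (11 - 21) / se
  dfHand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(tt$t, tHand, tolerance = 1e-12)
  expect_equal(tt$p, 2 * stats::pt(-abs(tHand), dfHand), tolerance = 1e-12)
  ## bins with < 2 genomes are not computable
  expect_true(all(is.na(res$tests$t[res$tests$bin2 == "5-6"])))
})

test_that("identical length distributions give t = 0, p = 1", {
  cat <- defaultPathwayCatalog()
  kos <- vapply(pathwayStages(cat, "thiamine"), `[`, "", 1L)
  ko <- list(g1 = kos, g2 = kos, g3 = kos,
             g4 = character(), g5 = character(), g6 = character())
  lens <- c(g1 = 10, g2 = 12, g3 = 11, g4 = 10, g5 = 12, g6 = 11)
  ann <- AnnotationSet(ko, lens)
  calls <- callAllPathways(ann, cat, vitamins = "thiamine")
  res <- vitaminCountVsSize(ann, calls, bins = list(lo = 0, hi = 1))
  tt <- res$tests[1, ]
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
})
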
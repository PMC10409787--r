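#' @include AllClasses.R
NULL

## Planted latent correlation of log abundances: block-diagonal modules at
## rhoIn (rhoOut elsewhere), with the hub-dependent pairs raised to rhoHub.
.plantedSigma <- function(spec, modules, hubIdx, depIdx) {
  n <- spec@nGenomes
  Sigma <- matrix(spec@rhoOut, n, n)
  for (m in seq_along(spec@moduleSizes)) {
    idx <- which(modules == m)
    Sigma[idx, idx] <- spec@rhoIn
  }
  Sigma[hubIdx, depIdx] <- spec@rhoHub
  Sigma[depIdx, hubIdx] <- spec@rhoHub
  diag(Sigma) <- 1
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf(
      "infeasible correlation structure: the hub block (module %d, rhoIn = %.2f, rhoHub = %.2f) is not positive semidefinite",
      spec@hubModule, spec@rhoIn, spec@rhoHub))
  Sigma
}

#' Simulate a bioreactor-style community
#'
#' Latent log abundances are drawn from a correlated normal with the planted
#' block structure (modules at `rhoIn`, hub-dependent pairs at `rhoHub`),
#' exponentiated, shifted per sample by the condition-specific module effect,
#' and observed through per-sample multinomial sequencing at the stated
#' depth; the returned abundances are count fractions. Thiamine producers are
#' drawn outside the hub's module, so the planted hub is its module's only
#' producer and its correlated neighbors are auxotrophs — the provisioning
#' phenotype the hub metric is designed to detect. Fully deterministic given
#' `seed`.
#'
#' @param spec A [SyntheticSpec].
#' @param seed Integer seed (default: the spec's own).
#' @return A list with elements `abundance` (an [AbundanceTable]),
#'   `metadata` (a [SampleMetadata]) and `truth` (a [SyntheticTruth]).
#' @export
simulateCommunity <- function(spec = SyntheticSpec(), seed = spec@seed) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  n <- spec@nGenomes
  S <- spec@nSamples
  genomes <- sprintf("G%03d", seq_len(n))
  samples <- sprintf("S%03d", seq_len(S))

  modules <- integer(n)                 # 0 = uncorrelated background
  pos <- 1L
  for (m in seq_along(spec@moduleSizes)) {
    modules[seq.int(pos, length.out = spec@moduleSizes[m])] <- m
    pos <- pos + spec@moduleSizes[m]
  }
  names(modules) <- genomes
  hubIdx <- which(modules == spec@hubModule)[1L]
  depIdx <- which(modules == spec@hubModule)[-1L][seq_len(spec@nDependents)]
  hubId <- genomes[hubIdx]
  dependents <- genomes[depIdx]

  Sigma <- .plantedSigma(spec, modules, hubIdx, depIdx)

  set.seed(seed)
  L <- chol(Sigma)
  Z <- t(L) %*% matrix(stats::rnorm(n * S), n, S)
  logAb <- spec@logMu + spec@logSigma * Z

  ## condition metadata and per-module occupancy shifts: one module pair
  ## responds to lifestyle, one module to thiocyanate level (log-scale
  ## multiplicative effect), mirroring condition-tracking subnetworks.
  lifestyle <- sample(rep(.lifestyleVocab, length.out = S))
  scn <- sample(rep(.scnVocab, length.out = S))
  nMod <- length(spec@moduleSizes)
  if (spec@metadataEffect != 1 && nMod >= 2) {
    shift <- log(spec@metadataEffect)
    m2 <- which(modules == 2L)           # planktonic + high-SCN module
    logAb[m2, lifestyle == "planktonic"] <-
      logAb[m2, lifestyle == "planktonic"] + shift
    logAb[m2, scn == "high"] <- logAb[m2, scn == "high"] + shift
    if (nMod >= 3) {                     # planktonic + low-SCN module
      m3 <- which(modules == 3L)
      logAb[m3, lifestyle == "planktonic"] <-
        logAb[m3, lifestyle == "planktonic"] + shift
      logAb[m3, scn == "low"] <- logAb[m3, scn == "low"] + shift
    }
  }

  basis <- exp(logAb)
  counts <- vapply(seq_len(S), function(s)
    stats::rmultinom(1L, size = spec@depth, prob = basis[, s])[, 1L],
    numeric(n))
  dimnames(counts) <- list(genomes, samples)
  tab <- abundanceFromCounts(counts)

  meta <- SampleMetadata(data.frame(sample_id = samples,
                                    lifestyle = lifestyle,
                                    scn_level = scn,
                                    stringsAsFactors = FALSE))

  ## role labels per vitamin; the hub vitamin's producers avoid the hub module
  cat <- defaultPathwayCatalog()
  rolesByVitamin <- list()
  nearComplete <- list()
  for (vit in names(spec@producerFractions)) {
    nProd <- round(spec@producerFractions[[vit]] * n)
    roleVec <- rep("auxotroph", n)
    names(roleVec) <- genomes
    if (vit == spec@hubVitamin) {
      pool <- setdiff(which(modules != spec@hubModule), c(hubIdx, depIdx))
      nOther <- min(max(nProd - 1L, 0L), length(pool))
      prodIdx <- c(hubIdx, pool[sample.int(length(pool), nOther)])
    } else {
      pool <- seq_len(n)
      prodIdx <- pool[sample.int(n, min(nProd, n))]
    }
    roleVec[prodIdx] <- "producer"
    rolesByVitamin[[vit]] <- roleVec
    exempt <- if (vit %in% vitaminNames(cat)) exemptKos(cat, vit) else character()
    nc <- character()
    if (spec@nearCompleteFraction > 0 && length(exempt)) {
      cand <- setdiff(genomes[prodIdx], hubId)
      nNear <- round(spec@nearCompleteFraction * length(cand))
      if (nNear > 0)
        nc <- cand[sample.int(length(cand), nNear)]
    }
    nearComplete[[vit]] <- nc
  }

  ## genome length grows with vitamin-synthesis breadth (plus lognormal noise)
  nPathways <- rowSums(vapply(rolesByVitamin, function(r) r == "producer",
                              logical(n)))
  lens <- (2.5e6 + 4e5 * nPathways) * exp(stats::rnorm(n, 0, 0.08))
  names(lens) <- genomes

  truth <- new("SyntheticTruth", basisCorrelation = Sigma, modules = modules,
               rolesByVitamin = rolesByVitamin, nearComplete = nearComplete,
               hubId = hubId, dependents = dependents, lengths = lens)
  list(abundance = tab, metadata = meta, truth = truth)
}

#' Generate KO annotations consistent with simulated roles
#'
#' Producers receive at least one KO from every stage of the vitamin's
#' pathway; near-complete genomes receive every stage KO except one drawn
#' from the catalog's exempt set; auxotrophs lack at least one non-exempt
#' stage entirely (other stages are partially filled at random). Decoy KOs
#' outside the catalog are added as annotation noise. Calling
#' [callPathway()] on the output reproduces the planted roles exactly.
#'
#' @param truth A [SyntheticTruth] from [simulateCommunity()].
#' @param cat A [PathwayCatalog] covering the truth's vitamins.
#' @param spec The [SyntheticSpec] used for the simulation.
#' @param seed Integer seed.
#' @return An [AnnotationSet] (with the truth's genome lengths).
#' @export
simulateAnnotations <- function(truth, cat = defaultPathwayCatalog(),
                                spec = SyntheticSpec(), seed = spec@seed) {
  stopifnot(is(truth, "SyntheticTruth"), is(cat, "PathwayCatalog"))
  genomes <- names(truth@modules)
  vitamins <- names(truth@rolesByVitamin)
  missingVit <- setdiff(vitamins, vitaminNames(cat))
  if (length(missingVit))
    stop(sprintf("catalog lacks vitamin(s): %s",
                 paste(missingVit, collapse = ", ")))
  for (vit in vitamins) {
    if (length(truth@nearComplete[[vit]]) && !length(exemptKos(cat, vit)))
      stop(sprintf(
        "vitamin '%s' has near-complete genomes but the catalog's exempt set is empty",
        vit))
  }

  set.seed(seed)
  ko <- stats::setNames(vector("list", length(genomes)), genomes)
  for (g in genomes) ko[[g]] <- character()
  for (vit in vitamins) {
    stages <- pathwayStages(cat, vit)
    exempt <- exemptKos(cat, vit)
    nonExempt <- which(vapply(stages, function(s)
      !length(intersect(s, exempt)), NA))
    roleVec <- truth@rolesByVitamin[[vit]]
    nc <- truth@nearComplete[[vit]]
    for (g in genomes) {
      if (roleVec[[g]] == "producer") {
        if (g %in% nc) {
          dropKo <- exempt[sample.int(length(exempt), 1L)]
          kos <- setdiff(unlist(stages, use.names = FALSE), dropKo)
        } else {
          kos <- unlist(lapply(stages, function(s) {
            pick <- s[stats::runif(length(s)) < 0.6]
            if (!length(pick)) pick <- s[sample.int(length(s), 1L)]
            pick
          }), use.names = FALSE)
        }
      } else {
        killed <- nonExempt[sample.int(length(nonExempt), 1L)]
        kos <- unlist(lapply(seq_along(stages), function(i) {
          if (i == killed) return(character())
          s <- stages[[i]]
          s[stats::runif(length(s)) < 0.4]
        }), use.names = FALSE)
      }
      ko[[g]] <- union(ko[[g]], kos)
    }
  }
  ## decoy KOs outside the catalog (annotation noise)
  decoyPool <- sprintf("K9%04d", seq_len(500))
  for (g in genomes)
    ko[[g]] <- union(ko[[g]],
                     decoyPool[sample.int(length(decoyPool),
                                          5L + sample.int(10L, 1L))])
  AnnotationSet(ko, truth@lengths)
}
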
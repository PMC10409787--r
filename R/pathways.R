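#' @include AllClasses.R
NULL

## status from the set of unsatisfied stages:
##   complete      — every stage has at least one of its KOs in the genome
##   near_complete — the union of KOs of all unsatisfied stages lies entirely
##                   within the catalog's exempt set (for the shipped thiamine
##                   catalog this reduces to "lacks only thiC, K03147")
##   absent        — otherwise
.statusFromStages <- function(stages, kos, exempt) {
  sat <- vapply(stages, function(s) length(intersect(s, kos)) > 0, NA)
  unsat <- stages[!sat]
  missing <- sort(unique(as.character(unlist(unsat, use.names = FALSE))))
  status <- if (!length(unsat)) "complete"
  else if (length(exempt) && all(missing %in% exempt)) "near_complete"
  else "absent"
  list(status = status, satisfied = names(stages)[sat], missing = missing)
}

#' Call pathway completeness for one genome and vitamin
#'
#' A stage is satisfied iff any of its alternative KOs is present in the
#' genome's annotation. The call is `complete` when every stage is satisfied,
#' `near_complete` when the only missing KOs all lie in the catalog's exempt
#' set, and `absent` otherwise. Adding a KO can never demote a status.
#'
#' @param ann An [AnnotationSet].
#' @param cat A [PathwayCatalog].
#' @param genomeId Genome to call.
#' @param vitamin Vitamin to call.
#' @return A [CapabilityCall].
#' @examples
#' cat <- defaultPathwayCatalog()
#' ann <- AnnotationSet(list(gA = c("K03149", "K00788", "K00941")))
#' callPathway(ann, cat, "gA", "thiamine")  # lacks only K03147 -> near_complete
#' @export
callPathway <- function(ann, cat, genomeId, vitamin) {
  stopifnot(is(ann, "AnnotationSet"), is(cat, "PathwayCatalog"))
  if (!genomeId %in% genomeIds(ann))
    stop(sprintf("unknown genome '%s'", genomeId))
  stages <- pathwayStages(cat, vitamin)   # errors on unknown vitamin
  res <- .statusFromStages(stages, koSets(ann)[[genomeId]],
                           exemptKos(cat, vitamin))
  new("CapabilityCall", genomeId = genomeId, vitamin = vitamin,
      status = res$status, satisfiedStages = res$satisfied,
      missingKos = res$missing)
}

#' Call pathway completeness for all genomes and vitamins
#'
#' @param ann An [AnnotationSet].
#' @param cat A [PathwayCatalog].
#' @param genomes Genomes to call (default: all in `ann`).
#' @param vitamins Vitamins to call (default: all in `cat`).
#' @return A [S4Vectors::DataFrame] with columns `genome_id`, `vitamin`,
#'   `status`, `satisfied_stages`, `missing_kos` (comma-separated).
#' @export
callAllPathways <- function(ann, cat, genomes = NULL, vitamins = NULL) {
  stopifnot(is(ann, "AnnotationSet"), is(cat, "PathwayCatalog"))
  if (is.null(genomes)) genomes <- genomeIds(ann)
  if (is.null(vitamins)) vitamins <- vitaminNames(cat)
  koList <- as.list(koSets(ann)[genomes])
  rows <- vector("list", length(vitamins))
  for (vi in seq_along(vitamins)) {
    vit <- vitamins[[vi]]
    stages <- pathwayStages(cat, vit)
    exempt <- exemptKos(cat, vit)
    calls <- lapply(koList, function(kos)
      .statusFromStages(stages, kos, exempt))
    rows[[vi]] <- S4Vectors::DataFrame(
      genome_id = genomes,
      vitamin = vit,
      status = vapply(calls, `[[`, "", "status"),
      satisfied_stages = vapply(calls, function(x)
        paste(x$satisfied, collapse = ","), ""),
      missing_kos = vapply(calls, function(x)
        paste(x$missing, collapse = ","), ""))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive producer/auxotroph roles from capability calls
#'
#' A genome is a producer iff its call is `complete`, or `near_complete`
#' when `nearCompletePolicy = "producer"` (the default, matching the
#' convention of counting near-complete pathways toward capability). Every
#' other genome is an auxotroph, so the roles partition the call set.
#'
#' @param calls Output of [callAllPathways()] (or a list of
#'   [CapabilityCall] objects).
#' @param vitamin Vitamin to label.
#' @param nearCompletePolicy `"producer"` or `"auxotroph"`.
#' @return A [RoleLabels].
#' @export
classifyRoles <- function(calls, vitamin,
                          nearCompletePolicy = c("producer", "auxotroph")) {
  nearCompletePolicy <- match.arg(nearCompletePolicy)
  if (is.list(calls) && !is(calls, "DataFrame") &&
      all(vapply(calls, is, NA, "CapabilityCall"))) {
    calls <- S4Vectors::DataFrame(
      genome_id = vapply(calls, function(x) x@genomeId, ""),
      vitamin = vapply(calls, function(x) x@vitamin, ""),
      status = vapply(calls, function(x) x@status, ""))
  }
  sel <- calls[calls$vitamin == vitamin, , drop = FALSE]
  if (anyDuplicated(sel$genome_id))
    stop(sprintf("duplicate genome in calls: '%s'",
                 sel$genome_id[duplicated(sel$genome_id)][1L]))
  producer <- sel$status == "complete" |
    (sel$status == "near_complete" & nearCompletePolicy == "producer")
  roleVec <- as.character(ifelse(producer, "producer", "auxotroph"))
  names(roleVec) <- as.character(sel$genome_id)
  new("RoleLabels", vitamin = vitamin, roleVec = roleVec,
      policy = nearCompletePolicy)
}

#' Restrict role labels to the nodes of a network
#'
#' @param labels A [RoleLabels].
#' @param net A [CooccurrenceNetwork]; every network node must be labeled.
#' @return A [RoleLabels] covering exactly the network's node set.
#' @export
restrictRoles <- function(labels, net) {
  stopifnot(is(labels, "RoleLabels"), is(net, "CooccurrenceNetwork"))
  nodes <- genomeIds(net)
  miss <- setdiff(nodes, names(roles(labels)))
  if (length(miss))
    stop(sprintf("network node(s) without role labels: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  new("RoleLabels", vitamin = labels@vitamin,
      roleVec = roles(labels)[nodes], policy = labels@policy)
}

#' Vitamin-synthesis breadth versus genome size
#'
#' Counts, for each genome, the number of vitamins with a `complete` pathway
#' (optionally also `near_complete`), bins genomes by that count, and
#' compares genome lengths between every pair of bins with a two-tailed
#' Welch t-test (unequal variances). Genomes without a known length are
#' excluded from this analysis.
#'
#' @param ann An [AnnotationSet] with genome lengths.
#' @param calls Output of [callAllPathways()].
#' @param bins Named list mapping bin label to the vitamin counts it covers;
#'   default `list("0-1" = 0:1, "2" = 2, "3" = 3, "4" = 4, "5-6" = 5:6)`.
#' @param countNearComplete Also count near-complete pathways (default
#'   `FALSE`).
#' @return A list with `perGenome` (genome, count, bin, length), `perBin`
#'   (bin, n, meanLength) and `tests` (pairwise Welch t and two-sided p;
#'   `NA` when a bin has fewer than 2 genomes).
#' @export
vitaminCountVsSize <- function(ann, calls, bins = NULL,
                               countNearComplete = FALSE) {
  stopifnot(is(ann, "AnnotationSet"))
  if (is.null(bins))
    bins <- list("0-1" = 0:1, "2" = 2, "3" = 3, "4" = 4, "5-6" = 5:6)
  ok <- c("complete", if (countNearComplete) "near_complete")
  counted <- calls[calls$status %in% ok, , drop = FALSE]
  genomes <- genomeIds(ann)
  counts <- table(factor(counted$genome_id, levels = genomes))
  counts <- as.integer(counts)
  names(counts) <- genomes
  lens <- genomeLengths(ann)
  keep <- !is.na(lens)
  if (any(!keep))
    message(sprintf("%d genome(s) without length excluded from size analysis",
                    sum(!keep)))
  counts <- counts[keep]
  lens <- lens[keep]
  binOf <- rep(NA_character_, length(counts))
  for (bl in names(bins)) binOf[counts %in% bins[[bl]]] <- bl
  inRange <- !is.na(binOf)
  perGenome <- S4Vectors::DataFrame(genome_id = names(counts)[inRange],
                                    n_vitamins = counts[inRange],
                                    bin = binOf[inRange],
                                    length_bp = lens[inRange])
  lenBy <- split(perGenome$length_bp, factor(perGenome$bin, names(bins)))
  perBin <- S4Vectors::DataFrame(
    bin = names(bins),
    n = as.integer(lengths(lenBy)),
    meanLength = vapply(lenBy, function(x)
      if (length(x)) mean(x) else NA_real_, 0))
  pairs <- utils::combn(names(bins), 2L)
  tests <- S4Vectors::DataFrame(
    bin1 = pairs[1L, ], bin2 = pairs[2L, ],
    t = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    x <- lenBy[[pairs[1L, i]]]
    y <- lenBy[[pairs[2L, i]]]
    wt <- .welch(x, y)
    tests$t[i] <- wt$t
    tests$p[i] <- wt$p
  }
  list(perGenome = perGenome, perBin = perBin, tests = tests)
}

## Welch t-test wrapper: NA when not computable (a group below 2 observations
## or all values constant); t = 0 / p = 1 for identical non-degenerate groups.
.welch <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    return(list(t = NA_real_, p = NA_real_))
  out <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(out)) return(list(t = NA_real_, p = NA_real_))
  list(t = unname(out$statistic), p = out$p.value)
}
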
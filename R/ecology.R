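#' @include AllClasses.R
NULL

#' Condition-stratified prevalence and abundance comparisons
#'
#' For each entity (a genome, or a module aggregate whose abundance is the
#' sum of its members' abundances per sample) and a two-level condition axis,
#' reports per-category sample counts, frequency (fraction of samples with
#' abundance above the presence threshold), mean abundance, and a two-tailed
#' Welch t-test on the per-sample abundances. The test is `NA` when a
#' category has fewer than 2 samples; frequencies are still reported.
#'
#' @param tab An [AbundanceTable].
#' @param meta A [SampleMetadata] covering every sample of `tab`.
#' @param axis `"lifestyle"` (biofilm vs planktonic) or `"scn_level"`
#'   (high vs low thiocyanate).
#' @param entities Entity ids to compare; defaults to all genomes, or all
#'   modules when `modules` is given.
#' @param modules Optional named vector mapping genome id to module id; when
#'   given, entities are module aggregates.
#' @param presenceThreshold Abundance strictly above which a genome counts as
#'   present (default 0: any nonzero abundance).
#' @return A [S4Vectors::DataFrame] with one row per entity: `entity`,
#'   `axis`, `catA`, `catB`, `nA`, `nB`, `freqA`, `freqB`, `meanA`, `meanB`,
#'   `t` (category A minus B), `p`.
#' @export
compareCategories <- function(tab, meta, axis = c("lifestyle", "scn_level"),
                              entities = NULL, modules = NULL,
                              presenceThreshold = 0) {
  stopifnot(is(tab, "AbundanceTable"), is(meta, "SampleMetadata"))
  axis <- match.arg(axis)
  samples <- sampleIds(tab)
  miss <- setdiff(samples, sampleIds(meta))
  if (length(miss))
    stop(sprintf("sample(s) without metadata: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  axisVals <- as.character(meta[samples, axis])
  if (anyNA(axisVals))
    stop(sprintf("axis '%s' has missing values for some samples", axis))
  cats <- if (axis == "lifestyle") .lifestyleVocab else .scnVocab

  v <- abundances(tab)
  if (!is.null(modules)) {
    modOf <- modules[rownames(v)]
    keep <- !is.na(modOf)
    agg <- rowsum(v[keep, , drop = FALSE], group = as.character(modOf[keep]))
    v <- agg
  }
  if (is.null(entities)) entities <- rownames(v)
  unknown <- setdiff(entities, rownames(v))
  if (length(unknown))
    stop(sprintf("unknown entit(y/ies): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))

  inA <- axisVals == cats[1L]
  inB <- axisVals == cats[2L]
  rows <- lapply(entities, function(e) {
    a <- v[e, inA]
    b <- v[e, inB]
    wt <- .welch(a, b)
    S4Vectors::DataFrame(
      entity = e, axis = axis, catA = cats[1L], catB = cats[2L],
      nA = sum(inA), nB = sum(inB),
      freqA = if (sum(inA)) mean(a > presenceThreshold) else NA_real_,
      freqB = if (sum(inB)) mean(b > presenceThreshold) else NA_real_,
      meanA = if (sum(inA)) mean(a) else NA_real_,
      meanB = if (sum(inB)) mean(b) else NA_real_,
      t = wt$t, p = wt$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
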
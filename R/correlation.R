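#' @include AllClasses.R
NULL

## Compositional (SparCC-style) correlation estimation.
##
## The estimator works on log-ratio variances t_ij = Var[log(x_i / x_j)],
## which are invariant to per-sample totals, and solves for basis variances
## w_i^2 under the sparsity assumption:
##     sum_{j in inc(i)} t_ij = d_i w_i^2 + sum_{j in inc(i)} w_j^2
## i.e. M w^2 = rowSums(T), with M = 1 off-diagonal and d_i on the diagonal.
## Basis correlations follow as r_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j).
## Strongly-correlated pairs violate the sparsity assumption and are
## iteratively excluded from the system.

.closure <- function(x) sweep(x, 2L, colSums(x), "/")

.clampUnit <- function(r) {
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

## One basis-correlation estimate with iterative pair exclusion.
## fracs: strictly positive genome-by-sample compositions.
.sparccOnce <- function(fracs, exclusionThreshold, nExclusionRounds) {
  D <- nrow(fracs)
  lf <- log(fracs)
  C <- stats::cov(t(lf))
  v <- diag(C)
  T <- outer(v, v, "+") - 2 * C      # log-ratio variance matrix, zero diag
  diag(T) <- 0
  include <- matrix(TRUE, D, D)
  diag(include) <- FALSE
  M <- matrix(1, D, D)
  diag(M) <- D - 1

  estimate <- function() {
    w2 <- tryCatch(solve(M, rowSums(T * include)),
                   error = function(e) rep(mean(diag(C)), D))
    w2[w2 <= 0] <- min(c(w2[w2 > 0], 1e-12))
    w <- sqrt(w2)
    .clampUnit((outer(w2, w2, "+") - T) / (2 * outer(w, w)))
  }

  r <- estimate()
  if (nExclusionRounds > 0L) {
    excluded <- matrix(FALSE, D, D)
    for (round in seq_len(nExclusionRounds)) {
      cand <- abs(r)
      cand[!include | excluded] <- -Inf
      cand[lower.tri(cand, diag = TRUE)] <- -Inf
      ## pick the strongest still-excludable pair
      ord <- order(cand, decreasing = TRUE)
      picked <- FALSE
      for (k in ord) {
        if (!is.finite(cand[k]) || cand[k] < exclusionThreshold) break
        ij <- arrayInd(k, dim(cand))
        i <- ij[1L]; j <- ij[2L]
        if (M[i, i] <= 2 || M[j, j] <= 2) next  # keep the system solvable
        include[i, j] <- include[j, i] <- FALSE
        excluded[i, j] <- excluded[j, i] <- TRUE
        M[i, j] <- M[j, i] <- 0
        M[i, i] <- M[i, i] - 1
        M[j, j] <- M[j, j] - 1
        picked <- TRUE
        break
      }
      if (!picked) break
      r <- estimate()
    }
  }
  r
}

## Full SparCC estimate on a raw genome-by-sample matrix (no container
## validity involved, so permutation backends can reuse it).
.sparccMatrix <- function(vals, params, seed) {
  rowVar <- apply(vals, 1L, stats::var)
  keep <- rowVar > 0
  if (any(!keep))
    warning(sprintf(
      "%d constant genome(s) have zero variance; their correlations are set to 0: %s",
      sum(!keep), paste(utils::head(rownames(vals)[!keep], 5), collapse = ", ")))
  if (sum(keep) < 4)
    stop("at least 4 genomes with non-zero variance are required")
  work <- vals[keep, , drop = FALSE]
  f0 <- .closure(work + params@pseudocount)
  D <- nrow(f0)

  set.seed(seed)
  ests <- array(NA_real_, c(D, D, params@nIterations))
  for (it in seq_len(params@nIterations)) {
    f <- if (it == 1L) f0 else {
      shapes <- f0 * params@resampleDepth + 1
      draw <- matrix(stats::rgamma(length(shapes), shape = shapes),
                     nrow(shapes), ncol(shapes))
      .closure(draw)
    }
    ests[, , it] <- .sparccOnce(f, params@exclusionThreshold,
                                params@nExclusionRounds)
  }
  r <- apply(ests, c(1L, 2L), stats::median)
  r <- .clampUnit((r + t(r)) / 2)

  full <- diag(nrow(vals))
  dimnames(full) <- list(rownames(vals), rownames(vals))
  full[keep, keep] <- r
  full
}

.naiveMatrix <- function(vals, method) {
  r <- suppressWarnings(stats::cor(t(vals), method = method))
  if (anyNA(r)) {
    zv <- rownames(vals)[apply(vals, 1L, stats::var) == 0]
    warning(sprintf(
      "%d zero-variance genome(s); their correlations are set to 0: %s",
      length(zv), paste(utils::head(zv, 5), collapse = ", ")))
    r[is.na(r)] <- 0
  }
  .clampUnit((r + t(r)) / 2)
}

#' SparCC-style compositional correlations
#'
#' Estimates basis correlations between genomes from compositional relative
#' abundances via log-ratio variances, with iterative exclusion of
#' strongly-correlated pairs from the basis-variance system. Estimation round
#' 1 uses the observed compositions; later rounds Dirichlet-resample them and
#' the reported matrix is the element-wise median, clamped to `[-1, 1]`.
#' Compositions are re-closed internally, so the result is invariant to
#' per-sample rescaling of the input.
#'
#' @param tab An [AbundanceTable] with at least 4 genomes and 3 samples.
#' @param params A [SparccParams].
#' @param seed Integer seed controlling the Dirichlet resampling.
#' @return A [CorrelationMatrix]. Genomes with zero abundance variance get
#'   correlation 0 to every partner (with a warning).
#' @export
sparccCorrelations <- function(tab, params = SparccParams(), seed = 1L) {
  stopifnot(is(tab, "AbundanceTable"), is(params, "SparccParams"))
  vals <- abundances(tab)
  if (nrow(vals) < 4)
    stop("at least 4 genomes are required (basis system is underdetermined)")
  if (ncol(vals) < 3)
    stop("at least 3 samples are required")
  CorrelationMatrix(.sparccMatrix(vals, params, seed))
}

#' Naive (Pearson/Spearman) correlations between genomes
#'
#' Baseline backend ignoring compositional effects; useful for comparison and
#' as a fast permutation backend.
#'
#' @param tab An [AbundanceTable] with at least 2 samples.
#' @param method `"pearson"` or `"spearman"`.
#' @return A [CorrelationMatrix]. Zero-variance genomes get correlation 0
#'   with a warning.
#' @export
naiveCorrelations <- function(tab, method = c("pearson", "spearman")) {
  stopifnot(is(tab, "AbundanceTable"))
  method <- match.arg(method)
  vals <- abundances(tab)
  if (ncol(vals) < 2) stop("at least 2 samples are required")
  CorrelationMatrix(.naiveMatrix(vals, method))
}

#' Permutation p-values for a correlation matrix
#'
#' Each permutation independently shuffles every genome's sample order
#' (breaking all between-genome association while preserving marginals),
#' recomputes correlations with the chosen backend, and the add-one estimator
#' `p = (1 + #{|r*| >= |r_obs|}) / (1 + nPerm)` is reported per pair. The
#' diagonal (not a pair) is set to 0.
#'
#' @param tab The [AbundanceTable] the observed matrix was computed from.
#' @param obs The observed [CorrelationMatrix].
#' @param nPerm Number of permutations (>= 1).
#' @param seed Integer seed; permutations and any backend randomness derive
#'   from it.
#' @param backend `"pearson"`, `"spearman"` or `"sparcc"`.
#' @param params [SparccParams] for the sparcc backend.
#' @return A [CorrelationMatrix] with the `p` slot filled.
#' @export
permutationPvalues <- function(tab, obs, nPerm, seed = 1L,
                               backend = c("pearson", "spearman", "sparcc"),
                               params = SparccParams()) {
  stopifnot(is(tab, "AbundanceTable"), is(obs, "CorrelationMatrix"))
  backend <- match.arg(backend)
  if (nPerm < 1) stop("nPerm must be at least 1")
  vals <- abundances(tab)
  if (!identical(rownames(vals), genomeIds(obs)))
    stop("abundance table and correlation matrix must share genome ids")
  absObs <- abs(correlations(obs))
  count <- matrix(0, nrow(vals), nrow(vals))

  set.seed(seed)
  perms <- lapply(seq_len(nPerm), function(b)
    lapply(seq_len(nrow(vals)), function(i) sample.int(ncol(vals))))
  for (b in seq_len(nPerm)) {
    pv <- vals
    for (i in seq_len(nrow(vals))) pv[i, ] <- vals[i, perms[[b]][[i]]]
    rStar <- suppressWarnings(switch(backend,
      pearson = .naiveMatrix(pv, "pearson"),
      spearman = .naiveMatrix(pv, "spearman"),
      sparcc = .sparccMatrix(pv, params, seed = seed + b)))
    count <- count + (abs(rStar) >= absObs)
  }
  p <- (1 + count) / (1 + nPerm)
  p <- (p + t(p)) / 2
  diag(p) <- 0
  dimnames(p) <- dimnames(absObs)
  CorrelationMatrix(correlations(obs), p)
}
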
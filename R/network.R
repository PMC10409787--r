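#' @include AllClasses.R
NULL

#' Build a thresholded co-occurrence network
#'
#' Retains an edge between genomes i and j iff `r_ij >= threshold` (and, when
#' `pMax` is given, `p_ij <= pMax`). Negative correlations are never turned
#' into edges unless `positiveOnly = FALSE`, in which case the magnitude is
#' thresholded. Genomes with no retained edge are excluded from the network
#' and recorded in the `dropped` slot (the exclusion is logged).
#'
#' @param corr A [CorrelationMatrix].
#' @param threshold Correlation threshold in `(0, 1]`; default 0.35.
#' @param positiveOnly Keep only positive correlations (default `TRUE`).
#' @param pMax Optional p-value cutoff; requires `corr` to carry p-values.
#' @return A [CooccurrenceNetwork] whose edge weights are the correlations.
#' @export
buildNetwork <- function(corr, threshold = 0.35, positiveOnly = TRUE,
                         pMax = NULL) {
  stopifnot(is(corr, "CorrelationMatrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  r <- correlations(corr)
  mask <- if (positiveOnly) r >= threshold else abs(r) >= threshold
  diag(mask) <- FALSE
  if (!is.null(pMax)) {
    if (is.null(pvalues(corr)))
      stop("pMax filtering requires a correlation matrix with p-values")
    mask <- mask & (pvalues(corr) <= pMax)
  }
  ids <- genomeIds(corr)
  idx <- which(mask & upper.tri(mask), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("no correlation passed the threshold; the network is empty")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(CooccurrenceNetwork(g, threshold, positiveOnly, dropped = ids))
  }
  edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                      weight = r[idx])
  connected <- ids[ids %in% c(edges$from, edges$to)]
  dropped <- setdiff(ids, connected)
  if (length(dropped))
    message(sprintf("excluded %d genome(s) with no retained edge",
                    length(dropped)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = connected))
  CooccurrenceNetwork(g, threshold, positiveOnly, dropped = dropped)
}

#' Betweenness centrality of every node
#'
#' For node v, the sum over unordered pairs `s != t != v` of the fraction of
#' shortest s-t paths that pass through v. Paths are unweighted (edge weights
#' are similarities, not lengths); pairs in different components contribute 0.
#' A normalized column (`b / ((n-1)(n-2)/2)`) is included for cross-tool
#' comparison.
#'
#' @param net A non-empty [CooccurrenceNetwork].
#' @return A [S4Vectors::DataFrame] with columns `node`, `degree`,
#'   `betweenness`, `betweennessNorm`, sorted by node.
#' @export
betweennessCentrality <- function(net) {
  stopifnot(is(net, "CooccurrenceNetwork"))
  g <- networkGraph(net)
  n <- igraph::vcount(g)
  if (n == 0) stop("the network is empty")
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  norm <- if (n >= 3) b / ((n - 1) * (n - 2) / 2) else rep(0, n)
  S4Vectors::DataFrame(node = igraph::V(g)$name,
                       degree = as.integer(igraph::degree(g)),
                       betweenness = unname(b),
                       betweennessNorm = unname(norm))
}

#' Network density
#'
#' The realized fraction of possible edges, `d = 2 m / (n (n - 1))`.
#'
#' @param net A [CooccurrenceNetwork] with at least 2 nodes.
#' @return Numeric density in `[0, 1]`.
#' @export
networkDensity <- function(net) {
  stopifnot(is(net, "CooccurrenceNetwork"))
  n <- numNodes(net)
  if (n < 2) stop("density requires at least 2 nodes")
  2 * numEdges(net) / (n * (n - 1))
}

#' Delineate hub nodes from a centrality table
#'
#' `top_k` takes the k highest-betweenness nodes (default
#' `k = max(1, round(0.07 n))`, roughly the hub fraction seen in bioreactor
#' networks), breaking ties by higher degree then lexicographic node id.
#' `mean_plus_sd` takes nodes with `b > mean(b) + sdMult * sd(b)`.
#'
#' @param centrality Output of [betweennessCentrality()].
#' @param method `"top_k"` or `"mean_plus_sd"`.
#' @param k Number of hubs for `top_k`; must not exceed the node count.
#' @param sdMult Multiplier for `mean_plus_sd` (default 1).
#' @return Character vector of hub node ids.
#' @export
delineateHubs <- function(centrality, method = c("top_k", "mean_plus_sd"),
                          k = NULL, sdMult = 1) {
  method <- match.arg(method)
  if (nrow(centrality) == 0) stop("the centrality table is empty")
  b <- centrality$betweenness
  if (method == "top_k") {
    n <- nrow(centrality)
    if (is.null(k)) k <- max(1L, round(0.07 * n))
    if (k > n) stop("k must not exceed the number of nodes")
    ord <- order(-b, -centrality$degree, centrality$node)
    centrality$node[ord[seq_len(k)]]
  } else {
    s <- stats::sd(b)
    if (is.na(s)) s <- 0
    centrality$node[b > mean(b) + sdMult * s]
  }
}

#' Detect network modules
#'
#' Louvain greedily maximizes weighted modularity (resolution 1);
#' Girvan-Newman removes edges of maximal (unweighted) edge betweenness and
#' the partition along the removal hierarchy with maximal weighted modularity
#' is returned. Both are deterministic given `seed`.
#'
#' @param net A non-empty [CooccurrenceNetwork].
#' @param method `"louvain"` or `"girvan_newman"`.
#' @param seed Integer seed (Louvain tie-breaking).
#' @return A [NetworkPartition].
#' @export
detectModules <- function(net, method = c("louvain", "girvan_newman"),
                          seed = 1L) {
  stopifnot(is(net, "CooccurrenceNetwork"))
  method <- match.arg(method)
  g <- networkGraph(net)
  if (igraph::vcount(g) == 0) stop("the network is empty")
  w <- igraph::E(g)$weight
  if (method == "louvain") {
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, weights = w, resolution = 1)
    mem <- igraph::membership(cl)
  } else {
    ceb <- igraph::cluster_edge_betweenness(g, weights = NA, directed = FALSE)
    n <- igraph::vcount(g)
    nComp <- igraph::count_components(g)
    bestQ <- -Inf
    mem <- igraph::membership(ceb)
    for (kk in seq(from = nComp, to = n)) {
      cand <- tryCatch(igraph::cut_at(ceb, no = kk), error = function(e) NULL)
      if (is.null(cand)) next
      q <- .modularityQ(g, cand, w)
      if (q > bestQ + 1e-12) {
        bestQ <- q
        mem <- cand
      }
    }
  }
  mem <- as.integer(mem)
  names(mem) <- igraph::V(g)$name
  q <- .modularityQ(g, mem, w)
  new("NetworkPartition", membership = mem, modularity = q,
      method = method, seed = as.integer(seed))
}

## modularity of a membership vector; 0 by convention for an edgeless graph
.modularityQ <- function(g, mem, w) {
  if (igraph::ecount(g) == 0) return(0)
  igraph::modularity(g, as.integer(factor(mem)), weights = w)
}

#' Whole-network summary
#'
#' @param net A [CooccurrenceNetwork].
#' @param partition Optional [NetworkPartition]; its modularity (recomputed
#'   from the graph) is reported, `NA` when absent. 0 for an edgeless graph.
#' @return A [NetworkSummary].
#' @export
networkSummary <- function(net, partition = NULL) {
  stopifnot(is(net, "CooccurrenceNetwork"))
  n <- numNodes(net)
  m <- numEdges(net)
  d <- if (n >= 2) 2 * m / (n * (n - 1)) else 0
  q <- NA_real_
  if (!is.null(partition)) {
    stopifnot(is(partition, "NetworkPartition"))
    g <- networkGraph(net)
    mem <- moduleMembership(partition)[igraph::V(g)$name]
    q <- .modularityQ(g, mem, igraph::E(g)$weight)
  }
  new("NetworkSummary", nNodes = as.integer(n), nEdges = as.integer(m),
      density = d, meanDegree = if (n > 0) 2 * m / n else 0,
      modularity = q)
}
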
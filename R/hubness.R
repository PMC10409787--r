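#' @include AllClasses.R
NULL

## The vitamin-hubness metric. For a node v with degree D_total, auxotroph
## neighbors a_1..a_N, and producer_links(a) = number of producer-labeled
## nodes adjacent to a (anywhere in the network, v included):
##
##     h(v) = (D_total * N) / mean_a producer_links(a),     N >= 1
##     h(v) = 0,                                            N = 0
##
## High h flags well-connected producers whose correlated auxotrophs have few
## alternative producers to draw the vitamin from.

## integer adjacency list of an igraph (index space 1..n)
.adjIndex <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

## core scoring on index space; isProducer is a logical vector over nodes.
## Returns list(dTotal, aux (indices), links, denom, score, illDefined).
.hubScoreIdx <- function(adj, isProducer, vIdx) {
  nb <- adj[[vIdx]]
  dTotal <- length(nb)
  aux <- nb[!isProducer[nb]]
  N <- length(aux)
  if (N == 0L)
    return(list(dTotal = dTotal, aux = aux, links = numeric(),
                denom = NA_real_, score = 0, illDefined = FALSE))
  links <- vapply(aux, function(a) sum(isProducer[adj[[a]]]), 0L)
  denom <- mean(links)
  if (denom == 0)  # only possible when v itself is not producer-labeled
    return(list(dTotal = dTotal, aux = aux, links = as.numeric(links),
                denom = denom, score = 0, illDefined = TRUE))
  list(dTotal = dTotal, aux = aux, links = as.numeric(links), denom = denom,
       score = dTotal * N / denom, illDefined = FALSE)
}

.checkLabels <- function(net, labels) {
  nodes <- genomeIds(net)
  rv <- roles(labels)
  miss <- setdiff(nodes, names(rv))
  if (length(miss))
    stop(sprintf("node(s) absent from role labels: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  rv[nodes] == "producer"
}

#' Vitamin-hubness score of a node
#'
#' Computes the score together with all of its components: the node's degree,
#' its number of auxotroph neighbors, each auxotroph neighbor's count of
#' producer-labeled neighbors, and their mean (the denominator). A node whose
#' neighbors are all producers scores 0 (no provisioning evidence).
#'
#' @param net A [CooccurrenceNetwork].
#' @param labels [RoleLabels] covering every network node.
#' @param v Node id to score.
#' @return A [HubnessScore].
#' @examples
#' g <- igraph::graph_from_edgelist(cbind(
#'   c("v", "v", "v", "v", "a1"), c("a1", "a2", "a3", "p1", "p1")),
#'   directed = FALSE)
#' net <- CooccurrenceNetwork(igraph::set_edge_attr(g, "weight", value = 0.5),
#'                            threshold = 0.35)
#' lab <- new("RoleLabels", vitamin = "thiamine",
#'            roleVec = c(v = "producer", p1 = "producer", a1 = "auxotroph",
#'                        a2 = "auxotroph", a3 = "auxotroph"),
#'            policy = "producer")
#' hubScore(net, lab, "v")  # h = (4 * 3) / mean(c(2, 1, 1)) = 9
#' @export
hubScore <- function(net, labels, v) {
  stopifnot(is(net, "CooccurrenceNetwork"), is(labels, "RoleLabels"))
  nodes <- genomeIds(net)
  if (!v %in% nodes) stop(sprintf("node '%s' is not in the network", v))
  isProducer <- .checkLabels(net, labels)
  adj <- .adjIndex(networkGraph(net))
  res <- .hubScoreIdx(adj, isProducer, match(v, nodes))
  links <- res$links
  if (length(links)) names(links) <- nodes[res$aux]
  new("HubnessScore", node = v, dTotal = as.integer(res$dTotal),
      dAuxotroph = length(res$aux), producerLinks = links,
      denom = res$denom, score = res$score)
}

#' Rank all producer nodes by vitamin-hubness
#'
#' Scores are computed for producer-labeled nodes only (non-producers are not
#' candidates for provisioning). Ordered by descending score, ties broken by
#' more auxotroph neighbors then lexicographic node id.
#'
#' @param net A [CooccurrenceNetwork].
#' @param labels [RoleLabels] covering every network node.
#' @return A [S4Vectors::DataFrame] with columns `node`, `dTotal`,
#'   `dAuxotroph`, `denom`, `score`; empty (with a warning) when no node is
#'   producer-labeled.
#' @export
rankHubScores <- function(net, labels) {
  stopifnot(is(net, "CooccurrenceNetwork"), is(labels, "RoleLabels"))
  nodes <- genomeIds(net)
  isProducer <- .checkLabels(net, labels)
  prodIdx <- which(isProducer)
  if (!length(prodIdx)) {
    warning("no producer-labeled node in the network")
    return(S4Vectors::DataFrame(node = character(), dTotal = integer(),
                                dAuxotroph = integer(), denom = numeric(),
                                score = numeric()))
  }
  adj <- .adjIndex(networkGraph(net))
  res <- lapply(prodIdx, function(i) .hubScoreIdx(adj, isProducer, i))
  out <- S4Vectors::DataFrame(
    node = unname(nodes[prodIdx]),
    dTotal = unname(vapply(res, function(x) as.integer(x$dTotal), 0L)),
    dAuxotroph = unname(vapply(res, function(x) length(x$aux), 0L)),
    denom = unname(vapply(res, function(x) x$denom, 0)),
    score = unname(vapply(res, function(x) x$score, 0)))
  out[order(-out$score, -out$dAuxotroph, out$node), , drop = FALSE]
}

#' Label-randomization null distribution of a hubness score
#'
#' Re-draws producer labels uniformly at random, preserving the observed
#' producer count, and recomputes the focal node's score in each simulation.
#' Under the default `focal_forced_producer` policy the focal node is always
#' part of the producer set and the remaining producers are drawn from the
#' other nodes; under `free_relabel` the whole set is drawn freely and draws
#' that leave the score ill-defined (focal not producer-labeled and some
#' auxotroph neighbor without any producer neighbor) are recorded as
#' `h = 0` and counted.
#'
#' @param net A [CooccurrenceNetwork].
#' @param labels Observed [RoleLabels] covering every network node; only the
#'   producer count (and the focal node's observed score) are taken from it.
#' @param focal Node whose score is simulated.
#' @param nSim Number of simulations (default 1000).
#' @param seed Integer seed; `(seed, nSim)` fully determine the result.
#' @param focalPolicy `"focal_forced_producer"` (default) or `"free_relabel"`.
#' @return A [NullDistribution] with the simulated scores, their mean and sd,
#'   `z = (h_obs - mean) / sd` (`NA` when sd is 0) and the add-one empirical
#'   p-value.
#' @export
randomizationNull <- function(net, labels, focal, nSim = 1000L, seed = 1L,
                              focalPolicy = c("focal_forced_producer",
                                              "free_relabel")) {
  stopifnot(is(net, "CooccurrenceNetwork"), is(labels, "RoleLabels"))
  focalPolicy <- match.arg(focalPolicy)
  if (nSim < 1) stop("nSim must be at least 1")
  nodes <- genomeIds(net)
  if (!focal %in% nodes) stop(sprintf("node '%s' is not in the network", focal))
  isProducer <- .checkLabels(net, labels)
  n <- length(nodes)
  nProd <- sum(isProducer)
  if (nProd < 1) stop("the observed labeling has no producers")
  adj <- .adjIndex(networkGraph(net))
  fIdx <- match(focal, nodes)
  hObs <- .hubScoreIdx(adj, isProducer, fIdx)$score

  others <- seq_len(n)[-fIdx]
  scores <- numeric(nSim)
  nIll <- 0L
  set.seed(seed)
  for (s in seq_len(nSim)) {
    prod <- logical(n)
    if (focalPolicy == "focal_forced_producer") {
      prod[fIdx] <- TRUE
      if (nProd > 1L)
        prod[others[sample.int(length(others), nProd - 1L)]] <- TRUE
    } else {
      prod[sample.int(n, nProd)] <- TRUE
    }
    res <- .hubScoreIdx(adj, prod, fIdx)
    if (res$illDefined) nIll <- nIll + 1L
    scores[s] <- res$score
  }
  mu <- mean(scores)
  sdv <- stats::sd(scores)
  if (is.na(sdv)) sdv <- 0
  z <- if (sdv > 0) (hObs - mu) / sdv else NA_real_
  new("NullDistribution", focal = focal, nSim = as.integer(nSim),
      seed = as.integer(seed), focalPolicy = focalPolicy, scores = scores,
      nullMean = mu, nullSd = sdv, z = z,
      empiricalP = (1 + sum(scores >= hObs)) / (1 + nSim),
      observed = hObs, nIllDefined = nIll)
}
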
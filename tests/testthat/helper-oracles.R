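## Independent oracles and fixture builders. These deliberately avoid the
## package's own code paths (and igraph) for the quantities they check.

## ---- graph fixtures -------------------------------------------------------

## CooccurrenceNetwork from a 0/1 adjacency matrix (constant edge weight)
netFromAdj <- function(A, ids = NULL, weight = 0.5) {
  n <- nrow(A)
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(n))
  dimnames(A) <- list(ids, ids)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  if (igraph::ecount(g) > 0)
    g <- igraph::set_edge_attr(g, "weight", value = weight)
  CooccurrenceNetwork(g, threshold = weight, positiveOnly = TRUE)
}

randomAdj <- function(n, p) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A + t(A)
}

## all labeled graphs on n nodes (n small!)
allAdjacencies <- function(n) {
  npair <- n * (n - 1) / 2
  lapply(seq_len(2^npair) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(npair)]
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- bits
    A + t(A)
  })
}

## four-block planted-partition adjacency; returns list(A, truth)
plantedBlocks <- function(nBlocks = 4, blockSize = 15, pIn = 0.6,
                          pOut = 0.02) {
  n <- nBlocks * blockSize
  truth <- rep(seq_len(nBlocks), each = blockSize)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    p <- if (truth[i] == truth[j]) pIn else pOut
    A[i, j] <- A[j, i] <- as.integer(stats::runif(1) < p)
  }
  list(A = A, truth = truth)
}

## ---- betweenness oracle: exhaustive simple-path enumeration ---------------

allSimplePaths <- function(A, s, t) {
  n <- nrow(A)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in which(A[last, ] == 1))
      if (!nxt %in% path) walk(c(path, nxt))
  }
  walk(s)
  out
}

oracleBetweenness <- function(A) {
  n <- nrow(A)
  b <- numeric(n)
  if (n < 3) return(b)
  for (s in seq_len(n - 1)) for (t in seq.int(s + 1, n)) {
    paths <- allSimplePaths(A, s, t)
    if (!length(paths)) next
    lens <- lengths(paths)
    sp <- paths[lens == min(lens)]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(sp, function(p)
        v %in% p[-c(1L, length(p))], NA))
      b[v] <- b[v] + through / length(sp)
    }
  }
  b
}

## ---- hub-score oracle: direct adjacency-matrix counting -------------------

oracleHubScore <- function(A, role, v) {
  nb <- which(A[v, ] == 1)
  dTot <- length(nb)
  aux <- nb[role[nb] == "auxotroph"]
  N <- length(aux)
  if (N == 0) return(0)
  links <- vapply(aux, function(a) sum(A[a, ] == 1 & role == "producer"), 0)
  if (mean(links) == 0) return(0)
  dTot * N / mean(links)
}

## ---- pathway-status oracle ------------------------------------------------

oracleStatus <- function(stages, kos, exempt) {
  unsat <- Filter(function(s) !any(s %in% kos), stages)
  if (!length(unsat)) return("complete")
  missing <- unique(unlist(unsat))
  if (length(exempt) && all(missing %in% exempt)) "near_complete" else "absent"
}

## random catalog with <= maxStages stages of <= maxKos alternative KOs
randomCatalog <- function(maxStages = 4, maxKos = 3, pExempt = 0.5) {
  nStages <- sample.int(maxStages, 1)
  pool <- sprintf("K%05d", sample.int(99999, nStages * maxKos))
  stages <- list()
  used <- 0
  for (i in seq_len(nStages)) {
    k <- sample.int(maxKos, 1)
    stages[[paste0("stage", i)]] <- pool[used + seq_len(k)]
    used <- used + k
  }
  allKo <- unlist(stages)
  exempt <- if (stats::runif(1) < pExempt)
    sample(allKo, sample.int(min(2, length(allKo)), 1)) else character()
  PathwayCatalog(list(vit = list(stages = stages, exempt = exempt)))
}

## ---- adjusted Rand index (closed form, no clustering package) -------------

adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(length(a), 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

## ---- misc -----------------------------------------------------------------

roleLabelsFor <- function(roleVec, vitamin = "thiamine",
                          policy = "producer") {
  new("RoleLabels", vitamin = vitamin, roleVec = roleVec, policy = policy)
}

## small abundance table from a count matrix with default dimnames
countsTable <- function(counts) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%03d", seq_len(ncol(counts)))
  abundanceFromCounts(counts)
}
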
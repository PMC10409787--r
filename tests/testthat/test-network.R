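corrOf <- function(m) {
  diag(m) <- 1
  CorrelationMatrix(m)
}

test_that("thresholding keeps r >= 0.35 and only positive correlations", {
  ids <- c("A", "B", "C")
  r <- matrix(0, 3, 3, dimnames = list(ids, ids))
  r["A", "B"] <- r["B", "A"] <- 0.35
  r["A", "C"] <- r["C", "A"] <- 0.2
  r["B", "C"] <- r["C", "B"] <- -0.6
  net <- suppressMessages(buildNetwork(corrOf(r)))
  expect_equal(numEdges(net), 1)  # exactly the boundary edge A-B
  expect_setequal(genomeIds(net), c("A", "B"))
  expect_identical(net@dropped, "C")
  expect_equal(igraph::E(networkGraph(net))$weight, 0.35)
})

test_that("an all-subthreshold matrix yields an empty network with warning", {
  ids <- paste0("g", 1:4)
  r <- matrix(0.1, 4, 4, dimnames = list(ids, ids))
  expect_warning(net <- buildNetwork(corrOf(r)), "empty")
  expect_equal(numNodes(net), 0)
  summ <- networkSummary(net)
  expect_equal(summ@nNodes, 0L)
})

test_that("threshold bounds are enforced", {
  ids <- c("A", "B")
  r <- matrix(c(1, .5, .5, 1), 2, dimnames = list(ids, ids))
  expect_error(buildNetwork(CorrelationMatrix(r), threshold = 0), "\\(0, 1]")
  expect_error(buildNetwork(CorrelationMatrix(r), threshold = 1.5), "\\(0, 1]")
})

test_that("p-value filtering removes edges above pMax", {
  ids <- c("A", "B", "C", "D")
  r <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(r) <- 1
  p <- matrix(0.9, 4, 4, dimnames = list(ids, ids)); diag(p) <- 0
  p["A", "B"] <- p["B", "A"] <- 0.001
  net <- suppressMessages(buildNetwork(CorrelationMatrix(r, p), pMax = 0.05))
  expect_equal(numEdges(net), 1)
  expect_error(buildNetwork(corrOf(r * 0 + 0.5), pMax = 0.05), "p-values")
})

test_that("betweenness matches hand-enumerated cases", {
  path3 <- matrix(0L, 3, 3); path3[1, 2] <- path3[2, 3] <- 1L
  path3 <- path3 + t(path3)
  b <- betweennessCentrality(netFromAdj(path3, ids = c("A", "B", "C")))
  expect_equal(b$betweenness[b$node == "B"], 1)
  expect_equal(sum(b$betweenness), 1)

  star5 <- matrix(0L, 5, 5); star5[1, 2:5] <- 1L; star5 <- star5 + t(star5)
  b5 <- betweennessCentrality(netFromAdj(star5))
  expect_equal(b5$betweenness, c(6, 0, 0, 0, 0))  # (n-1)(n-2)/2 leaf pairs
  expect_equal(b5$betweennessNorm[1], 1)

  k4 <- matrix(1L, 4, 4) - diag(4L)
  expect_equal(betweennessCentrality(netFromAdj(k4))$betweenness, rep(0, 4))
})

test_that("betweenness agrees with the path-enumeration oracle on random graphs", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    A <- randomAdj(n, runif(1, 0.2, 0.8))
    got <- betweennessCentrality(netFromAdj(A))$betweenness
    expect_equal(got, oracleBetweenness(A), tolerance = 1e-10)
  }
})

test_that("density follows the closed form and grows with each edge", {
  k4 <- matrix(1L, 4, 4) - diag(4L)
  expect_equal(networkDensity(netFromAdj(k4)), 1)
  p4 <- matrix(0L, 4, 4); p4[1, 2] <- p4[2, 3] <- p4[3, 4] <- 1L
  expect_equal(networkDensity(netFromAdj(p4 + t(p4))), 0.5)
  one <- matrix(0L, 1, 1)
  expect_error(networkDensity(netFromAdj(one)), "at least 2")
  set.seed(5)
  A <- randomAdj(7, 0.3)
  empt <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
  d0 <- networkDensity(netFromAdj(A))
  A2 <- A
  A2[empt[1, 1], empt[1, 2]] <- A2[empt[1, 2], empt[1, 1]] <- 1L
  expect_gt(networkDensity(netFromAdj(A2)), d0)
})

test_that("hub delineation honors both criteria and the tie-break rule", {
  star5 <- matrix(0L, 5, 5); star5[1, 2:5] <- 1L; star5 <- star5 + t(star5)
  cent <- betweennessCentrality(netFromAdj(star5, ids = paste0("v", 1:5)))
  expect_identical(delineateHubs(cent, "top_k", k = 1), "v1")
  expect_error(delineateHubs(cent, "top_k", k = 9), "exceed")

  k4 <- matrix(1L, 4, 4) - diag(4L)
  centEq <- betweennessCentrality(netFromAdj(k4))
  expect_length(delineateHubs(centEq, "mean_plus_sd"), 0)

  ## symmetric double star: C and D tie on betweenness and degree, so the
  ## lexicographically first node wins at k = 1
  A <- matrix(0L, 6, 6)
  ids <- c("C", "D", "l1", "l2", "l3", "l4")
  A[1, 2] <- 1L                        # C - D bridge
  A[1, 3] <- A[1, 4] <- 1L             # C leaves
  A[2, 5] <- A[2, 6] <- 1L             # D leaves
  A <- A + t(A)
  cent2 <- betweennessCentrality(netFromAdj(A, ids = ids))
  expect_equal(cent2$betweenness[cent2$node == "C"],
               cent2$betweenness[cent2$node == "D"])
  expect_identical(delineateHubs(cent2, "top_k", k = 1), "C")
})

test_that("module detection recovers disjoint cliques with Q = 0.5", {
  A <- matrix(0L, 10, 10)
  A[1:5, 1:5] <- 1L
  A[6:10, 6:10] <- 1L
  diag(A) <- 0L
  net <- netFromAdj(A)
  for (meth in c("louvain", "girvan_newman")) {
    part <- detectModules(net, meth, seed = 1)
    expect_equal(partitionModularity(part), 0.5, tolerance = 1e-12)
    mem <- moduleMembership(part)
    expect_equal(length(unique(mem[1:5])), 1)
    expect_equal(length(unique(mem[6:10])), 1)
    expect_false(mem[1] == mem[6])
  }
  ## single clique: one module, Q = 0
  k5 <- netFromAdj(matrix(1L, 5, 5) - diag(5L))
  p5 <- detectModules(k5, "louvain", seed = 1)
  expect_equal(length(unique(moduleMembership(p5))), 1)
  expect_equal(partitionModularity(p5), 0)
})

test_that("Louvain is deterministic under its seed and Q is recomputable", {
  set.seed(8)
  pb <- plantedBlocks(3, 8, 0.7, 0.05)
  net <- netFromAdj(pb$A)
  p1 <- detectModules(net, "louvain", seed = 4)
  p2 <- detectModules(net, "louvain", seed = 4)
  expect_identical(moduleMembership(p1), moduleMembership(p2))
  g <- networkGraph(net)
  qRecalc <- igraph::modularity(g, moduleMembership(p1)[igraph::V(g)$name],
                                weights = igraph::E(g)$weight)
  expect_equal(partitionModularity(p1), qRecalc, tolerance = 1e-12)
})

test_that("network summary fields satisfy their invariants", {
  k4 <- netFromAdj(matrix(1L, 4, 4) - diag(4L))
  s <- networkSummary(k4, detectModules(k4, "louvain", 1))
  expect_equal(s@nNodes, 4L)
  expect_equal(s@nEdges, 6L)
  expect_equal(s@density, 1)
  expect_equal(s@meanDegree, 3)
  ## edgeless graph: density 0, Q 0 by convention
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  g0 <- igraph::set_vertex_attr(g0, "name", value = c("a", "b", "c"))
  net0 <- CooccurrenceNetwork(g0, threshold = 0.35)
  part0 <- new("NetworkPartition",
               membership = stats::setNames(1:3, c("a", "b", "c")),
               modularity = 0, method = "louvain", seed = 1L)
  s0 <- networkSummary(net0, part0)
  expect_equal(s0@density, 0)
  expect_equal(s0@modularity, 0)
})
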
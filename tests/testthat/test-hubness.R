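## the hand-enumerated 5-node graph: producer v adjacent to auxotrophs
## a1, a2, a3 and producer p1; a1 also adjacent to p1
fiveNodeNet <- function() {
  g <- igraph::graph_from_edgelist(cbind(
    c("v", "v", "v", "v", "a1"), c("a1", "a2", "a3", "p1", "p1")),
    directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = 0.5)
  CooccurrenceNetwork(g, threshold = 0.35)
}

fiveNodeLabels <- function() {
  roleLabelsFor(c(v = "producer", p1 = "producer", a1 = "auxotroph",
                  a2 = "auxotroph", a3 = "auxotroph"))
}

test_that("the worked 5-node example gives h = 9 with all components", {
  hs <- hubScore(fiveNodeNet(), fiveNodeLabels(), "v")
  expect_equal(hs@dTotal, 4L)
  expect_equal(hs@dAuxotroph, 3L)
  expect_equal(sort(unname(hs@producerLinks)), c(1, 1, 2))
  expect_equal(hs@denom, 4 / 3)
  expect_equal(scoreValue(hs), 9)
})

test_that("minimal and degenerate hub scores follow the definition", {
  ## single auxotroph neighbor whose only producer neighbor is v -> h = 1
  g <- igraph::graph_from_edgelist(cbind("v", "a"), directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = 0.5)
  net <- CooccurrenceNetwork(g, threshold = 0.35)
  hs <- hubScore(net, roleLabelsFor(c(v = "producer", a = "auxotroph")), "v")
  expect_equal(scoreValue(hs), 1)

  ## only producer neighbors -> N = 0, h = 0
  g2 <- igraph::graph_from_edgelist(cbind(c("v", "v"), c("p1", "p2")),
                                    directed = FALSE)
  g2 <- igraph::set_edge_attr(g2, "weight", value = 0.5)
  net2 <- CooccurrenceNetwork(g2, threshold = 0.35)
  hs2 <- hubScore(net2, roleLabelsFor(c(v = "producer", p1 = "producer",
                                        p2 = "producer")), "v")
  expect_equal(hs2@dAuxotroph, 0L)
  expect_equal(scoreValue(hs2), 0)

  ## missing labels and unknown nodes are hard errors
  expect_error(hubScore(fiveNodeNet(), fiveNodeLabels(), "zz"),
               "not in the network")
  partial <- roleLabelsFor(c(v = "producer", a1 = "auxotroph"))
  expect_error(hubScore(fiveNodeNet(), partial, "v"), "absent from role")
})

test_that("producer ranking orders by score with documented tie-breaks", {
  rk <- rankHubScores(fiveNodeNet(), fiveNodeLabels())
  expect_identical(rk$node, c("v", "p1"))
  expect_equal(rk$score, c(9, 1))

  ## all producers isolated from auxotrophs: all h = 0, lexicographic order
  g <- igraph::graph_from_edgelist(cbind(c("pB", "a1"), c("pA", "a2")),
                                  directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = 0.5)
  net <- CooccurrenceNetwork(g, threshold = 0.35)
  lab <- roleLabelsFor(c(pA = "producer", pB = "producer",
                         a1 = "auxotroph", a2 = "auxotroph"))
  rk0 <- rankHubScores(net, lab)
  expect_equal(rk0$score, c(0, 0))
  expect_identical(rk0$node, c("pA", "pB"))

  ## no producers at all: empty table with warning
  labNone <- roleLabelsFor(c(pA = "auxotroph", pB = "auxotroph",
                             a1 = "auxotroph", a2 = "auxotroph"))
  expect_warning(rkE <- rankHubScores(net, labNone), "no producer")
  expect_equal(nrow(rkE), 0)
})

test_that("hub scores agree with the adjacency-counting oracle", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    A <- randomAdj(n, runif(1, 0.2, 0.7))
    ids <- sprintf("n%02d", seq_len(n))
    role <- sample(c("producer", "auxotroph"), n, replace = TRUE)
    names(role) <- ids
    net <- netFromAdj(A, ids = ids)
    lab <- roleLabelsFor(role)
    for (v in sample(ids, 3)) {
      expect_equal(scoreValue(hubScore(net, lab, v)),
                   oracleHubScore(A, unname(role), match(v, ids)),
                   tolerance = 1e-12)
    }
  }
})

test_that("h collapses to dTotal * dAuxotroph when v is the only producer neighbor", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    A <- randomAdj(n, runif(1, 0.25, 0.6))
    ids <- sprintf("n%02d", seq_len(n))
    v <- 1L
    nb <- which(A[v, ] == 1)
    if (!length(nb)) next
    ## second neighborhood of v (nodes adjacent to v's neighbors)
    second <- unique(unlist(lapply(nb, function(a) which(A[a, ] == 1))))
    role <- rep("auxotroph", n)
    role[setdiff(seq_len(n), c(second, nb, v))] <- "producer"
    role[v] <- "producer"
    names(role) <- ids
    hs <- hubScore(netFromAdj(A, ids = ids), roleLabelsFor(role), ids[v])
    expect_equal(scoreValue(hs), hs@dTotal * hs@dAuxotroph)
  }
})

test_that("h only depends on the focal node's two-neighborhood", {
  set.seed(23)
  A <- matrix(0L, 12, 12)
  A[1:10, 1:10] <- randomAdj(10, 0.3)
  A[11, 12] <- A[12, 11] <- 1L   # a component the focal node cannot reach
  ids <- sprintf("n%02d", 1:12)
  v <- 1L
  nb <- which(A[v, ] == 1)
  second <- setdiff(unique(unlist(lapply(nb, function(a) which(A[a, ] == 1)))),
                    c(v, nb))
  far <- setdiff(seq_len(12), c(v, nb, second))
  expect_gte(length(far), 2)
  role <- sample(c("producer", "auxotroph"), 12, replace = TRUE)
  role[v] <- "producer"
  names(role) <- ids
  net <- netFromAdj(A, ids = ids)
  h1 <- scoreValue(hubScore(net, roleLabelsFor(role), ids[v]))
  role2 <- role
  role2[far] <- ifelse(role[far] == "producer", "auxotroph", "producer")
  h2 <- scoreValue(hubScore(net, roleLabelsFor(role2), ids[v]))
  expect_equal(h1, h2)
})

test_that("adding an alternative producer for an auxotroph neighbor lowers h", {
  ## start from the worked graph; link a2 to p1 as an alternative source
  g <- igraph::graph_from_edgelist(cbind(
    c("v", "v", "v", "v", "a1", "a2"), c("a1", "a2", "a3", "p1", "p1", "p1")),
    directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = 0.5)
  net2 <- CooccurrenceNetwork(g, threshold = 0.35)
  h0 <- scoreValue(hubScore(fiveNodeNet(), fiveNodeLabels(), "v"))
  h1 <- scoreValue(hubScore(net2, fiveNodeLabels(), "v"))
  expect_lt(h1, h0)
})

test_that("the randomization null is reproducible and preserves producer count", {
  net <- fiveNodeNet()
  lab <- fiveNodeLabels()
  n1 <- randomizationNull(net, lab, "v", nSim = 50, seed = 12)
  n2 <- randomizationNull(net, lab, "v", nSim = 50, seed = 12)
  expect_identical(nullScores(n1), nullScores(n2))
  expect_equal(length(nullScores(n1)), 50)
  expect_equal(n1@observed, 9)
  expect_true(n1@empiricalP >= 1 / 51 && n1@empiricalP <= 1)
  expect_error(randomizationNull(net, lab, "v", nSim = 0), "at least 1")
})

test_that("a degenerate star null has sd 0, z NA and a valid empirical p", {
  ## 10-leaf star, 5 producers, focal center forced producer: every draw
  ## leaves the 4 producer leaves with the center as sole producer neighbor
  ## of each auxotroph leaf, so h = 10 * 6 / 1 = 60 deterministically
  A <- matrix(0L, 11, 11)
  A[1, 2:11] <- 1L
  A <- A + t(A)
  ids <- c("c", sprintf("L%02d", 1:10))
  net <- netFromAdj(A, ids = ids)
  role <- c("producer", rep("producer", 4), rep("auxotroph", 6))
  names(role) <- ids
  nd <- randomizationNull(net, roleLabelsFor(role), "c", nSim = 200, seed = 3)
  expect_equal(nd@nullMean, 60)
  expect_equal(nd@nullSd, 0)
  expect_true(is.na(nd@z))
  expect_equal(nd@empiricalP, (1 + 200) / 201)
})
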
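# a SOM built directly from a known codebook (no training)
fixedSOM <- function(codebook, grid = c(nrow(codebook), 1L)) {
  new("SOMModel", gridShape = as.integer(grid), codebook = codebook,
      meta = list(epochs = 0L))
}

test_that("BMU mapping is nearest-neighbor with low-index tie-break", {
  cb <- rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0))   # duplicated neuron
  som <- fixedSOM(cb, c(2L, 2L))
  expect_equal(mapToSOM(som, rbind(c(0.1, 0), c(1, 0.2), c(2, 0))),
               c(1L, 2L, 4L))                        # tie 2 vs 3 -> 2
  # BMU distance is minimal over all neurons (oracle check on random data)
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  som2 <- trainSOM(X, grid = c(3L, 3L), epochs = 5L, seed = 1L)
  b <- mapToSOM(som2, X)
  allD <- as.matrix(dist(rbind(X, codebook(som2))))[1:20, 21:29]
  expect_equal(b, unname(apply(allD, 1L, which.min)))
})

test_that("untrained SOM initialized at the data is the identity matching", {
  set.seed(5)
  X <- matrix(runif(144 * 2, 0, 10), 144, 2)
  som <- trainSOM(X, grid = c(12L, 12L), epochs = 0L, seed = 9L)
  b <- mapToSOM(som, X)
  expect_equal(sqrt(rowSums((X - codebook(som)[b, ])^2)), rep(0, 144))
})

test_that("SOM training is deterministic and separates distant blobs", {
  set.seed(6)
  blob1 <- matrix(rnorm(400, 0, 0.5), ncol = 2)
  blob2 <- matrix(rnorm(400, 20, 0.5), ncol = 2)
  X <- rbind(blob1, blob2)
  s1 <- trainSOM(X, grid = c(4L, 4L), epochs = 20L, seed = 3L)
  s2 <- trainSOM(X, grid = c(4L, 4L), epochs = 20L, seed = 3L)
  expect_identical(codebook(s1), codebook(s2))
  b <- mapToSOM(s1, X)
  expect_length(intersect(unique(b[1:200]), unique(b[201:400])), 0L)
  expect_warning(trainSOM(X[1:5, ], grid = c(4L, 4L), epochs = 1L,
                          seed = 1L), "fewer data points")
  expect_error(trainSOM(X[0, , drop = FALSE], seed = 1L), "empty")
})

test_that("transition probabilities come from raw hop counts", {
  som <- fixedSOM(rbind(0, 1, 2), c(3L, 1L))
  tr <- FeatureTrajectory("a", 0:2, matrix(c(0, 0, 1), ncol = 1))
  net <- buildTransitionNetwork(TrajectoryEnsemble(list(tr)), som,
                                prune = 0)
  expect_equal(net@P[1, 1], 0.5)     # states 1,1,2: p11 = p12 = 0.5
  expect_equal(net@P[1, 2], 0.5)
  expect_equal(net@W[1, 1], -log(0.5))
  expect_true(2L %in% net@zeroRows || all(net@P[2, ] == 0))
  # p = 1 edge has weight exactly 0
  tr2 <- FeatureTrajectory("b", 0:1, matrix(c(1, 2), ncol = 1))
  net2 <- buildTransitionNetwork(TrajectoryEnsemble(list(tr2)), som,
                                 prune = 0)
  expect_equal(net2@W[2, 3], 0)
})

test_that("pruning resets sub-threshold probabilities to exact zero", {
  som <- fixedSOM(matrix(0:1, 2, 1), c(2L, 1L))
  # 1 hop 1->2 among 200 hops out of state 1: p = 0.005 < 0.01
  xs <- c(rep(0, 200), 1, 1)
  tr <- FeatureTrajectory("a", seq_along(xs) - 1, matrix(xs, ncol = 1))
  net <- buildTransitionNetwork(TrajectoryEnsemble(list(tr)), som,
                                prune = 0.01)
  expect_identical(net@P[1, 2], 0)
  expect_false(is.finite(net@W[1, 2]))
  expect_gt(net@counts[1, 2], 0)                  # raw count preserved
  # rows are NOT renormalized after pruning by default
  expect_lt(sum(net@P[1, ]), 1)
  netR <- buildTransitionNetwork(TrajectoryEnsemble(list(tr)), som,
                                 prune = 0.01, renormalize = TRUE)
  expect_equal(sum(netR@P[1, ]), 1)
})

mkNet <- function(P) {
  W <- -log(P)
  new("TransitionNetwork", P = P, W = W, counts = P, prune = 0,
      zeroRows = integer(0))
}

test_that("shortest paths follow the -log p weights", {
  # chain A -> B -> C with p = 1: unique path of weight 0
  P <- matrix(0, 3, 3); P[1, 2] <- 1; P[2, 3] <- 1; P[3, 3] <- 1
  som <- fixedSOM(rbind(0, 1, 2), c(3L, 1L))
  ps <- shortestTransitionPaths(mkNet(P), som, eCenter = 0, mCenter = 2,
                                radius = 0.2)
  expect_equal(ps@paths, list(c(1L, 2L, 3L)))
  expect_equal(ps@weights, 0)
  # direct p = 0.1 loses to two-hop p = 0.5 * 0.5
  P2 <- matrix(0, 3, 3)
  P2[1, 2] <- 0.1; P2[1, 3] <- 0.5; P2[3, 2] <- 0.5
  P2[2, 2] <- 1; P2[3, 3] <- 0.5
  som2 <- fixedSOM(rbind(0, 5, 2), c(3L, 1L))
  ps2 <- shortestTransitionPaths(mkNet(P2), som2, eCenter = 0, mCenter = 5,
                                 radius = 0.2)
  expect_equal(ps2@paths[[1]], c(1L, 3L, 2L))
  expect_equal(ps2@weights, -log(0.25))
  expect_error(shortestTransitionPaths(mkNet(P2), som2, eCenter = 100,
                                       mCenter = 5, radius = 0.2),
               "empty E or M community")
})

test_that("two corridors both appear across pairs with split frequencies", {
  # two E neurons, two M neurons; corridor 3 favored from E1, 4 from E2
  P <- matrix(0, 6, 6)
  P[1, 3] <- 0.6; P[1, 4] <- 0.4; P[2, 3] <- 0.4; P[2, 4] <- 0.6
  P[3, 5] <- 0.5; P[3, 6] <- 0.5; P[4, 5] <- 0.5; P[4, 6] <- 0.5
  P[5, 5] <- 1; P[6, 6] <- 1
  cb <- rbind(c(0, 0), c(0, 1), c(5, 0), c(5, 1), c(10, 0), c(10, 1))
  som <- fixedSOM(cb, c(6L, 1L))
  ps <- shortestTransitionPaths(mkNet(P), som, eCenter = c(0, 0.5),
                                mCenter = c(10, 0.5), radius = 1)
  expect_length(ps@paths, 4L)
  expect_equal(ps@nodeCounts[3], 2)
  expect_equal(ps@nodeCounts[4], 2)
  # path weight equals -log of the product of edge probabilities
  for (i in seq_along(ps@paths)) {
    p <- ps@paths[[i]]
    expect_equal(ps@weights[i],
                 -log(prod(P[cbind(p[-length(p)], p[-1])])))
  }
  # exact ties resolve deterministically to the lexicographically smaller
  P[1, 3] <- 0.5; P[1, 4] <- 0.5; P[2, 3] <- 0.5; P[2, 4] <- 0.5
  psTie <- shortestTransitionPaths(mkNet(P), som, eCenter = c(0, 0.5),
                                   mCenter = c(10, 0.5), radius = 1)
  expect_equal(psTie@nodeCounts[3], 4)
})

test_that("Dijkstra agrees with brute-force enumeration on random graphs", {
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
      out <- sample(seq_len(n), sample(1:min(3, n), 1))
      P[i, out] <- runif(length(out), 0.05, 1)
      P[i, ] <- P[i, ] / sum(P[i, ])
    }
    W <- -log(P); W[P == 0] <- Inf
    from <- 1L; to <- n
    oracle <- bruteShortestPath(W, from, to)
    distTo <- transpath:::.dijkstraTo(W, to)
    mine <- transpath:::.lexShortestPath(W, from, to, distTo)
    if (is.null(oracle)) {
      expect_null(mine)
    } else {
      expect_equal(mine$weight, oracle$weight, tolerance = 1e-9)
      expect_equal(mine$path, oracle$path)
    }
  }
})

test_that("Dijkstra distances match igraph on a pruned network", {
  set.seed(8)
  n <- 12L
  P <- matrix(runif(n * n), n, n)
  P[P < 0.8] <- 0
  P <- P / pmax(rowSums(P), 1e-12)
  W <- -log(P); W[P == 0] <- Inf
  el <- which(P > 0, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  dOracle <- igraph::distances(g, v = seq_len(n), to = n, mode = "out",
                               weights = W[el])
  expect_equal(unname(as.numeric(dOracle)),
               unname(transpath:::.dijkstraTo(W, n)), tolerance = 1e-9)
})

test_that("edge-list export reflects the pruned network", {
  P <- matrix(0, 3, 3); P[1, 2] <- 0.4; P[1, 1] <- 0.6; P[2, 3] <- 1
  P[3, 3] <- 1
  net <- mkNet(P)
  el <- networkEdgeList(net)
  expect_equal(nrow(el), 4L)
  expect_equal(el$weight, -log(el$probability))
})
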
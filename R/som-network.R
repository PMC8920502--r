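#' Train a self-organizing map on state-space points
#'
#' Online SOM on a rectangular neuron grid: each presented sample moves its
#' best-matching unit (BMU) and the neurons within the learning radius
#' (Euclidean grid distance) toward it, with a Gaussian neighborhood weight
#' of standard deviation \code{std} grid units.  The learning rate decays
#' linearly over epochs; initialization and the (fixed) presentation order
#' are drawn once from \code{seed}, so training is deterministic for a given
#' seed and input.
#'
#' @param points n x d matrix of samples.
#' @param grid integer(2), neuron grid (rows, cols); default 12 x 12.
#' @param epochs training epochs (default 50).
#' @param radius learning radius in grid units (default 1).
#' @param std Gaussian neighborhood standard deviation (default 1).
#' @param seed RNG seed (initial codebook + presentation order).
#' @param learningRate numeric(2): initial and final learning rate; the
#'   schedule is linear.
#' @return a \linkS4class{SOMModel}.
#' @export
trainSOM <- function(points, grid = c(12L, 12L), epochs = 50L, radius = 1,
                     std = 1, seed = NULL, learningRate = c(0.5, 0.01)) {
  if (!is.matrix(points)) points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty data")
  m <- prod(grid)
  if (nrow(points) < m)
    warning("fewer data points than neurons; SOM will be underdetermined")
  .withSeed(seed, {
    init <- points[sample.int(nrow(points), m, replace = nrow(points) < m), ,
                   drop = FALSE]
    ord <- sample.int(nrow(points))
    W <- if (epochs > 0L)
      som_train_cpp(points, grid[1L], grid[2L], as.integer(epochs),
                    radius, std, init, learningRate[1L], learningRate[2L],
                    ord)
    else init
    new("SOMModel", gridShape = as.integer(grid), codebook = W,
        meta = list(epochs = epochs, radius = radius, std = std,
                    seed = seed, learningRate = learningRate))
  })
}

#' Best-matching unit of each point
#'
#' @param som a \linkS4class{SOMModel} (or any object with a codebook
#'   matrix).
#' @param points n x d matrix.
#' @return integer BMU indices (1-based, row-major grid order); ties go to
#'   the lowest index.
#' @export
mapToSOM <- function(som, points) {
  if (!is.matrix(points)) points <- as.matrix(points)
  bmu_cpp(points, codebook(som))
}

#' Build the SOM-state transition network from trajectories
#'
#' Consecutive-frame hops between BMU states are counted over all
#' trajectories (self-transitions included) and row-normalized into
#' transition probabilities.  Probabilities smaller than \code{prune} are
#' reset to exactly 0; rows are not renormalized afterwards (the pruning is
#' a hard reset, with renormalization available as an option).  Edge weights
#' are \code{-log(p)} on the surviving edges.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param som a trained \linkS4class{SOMModel} in the same space.
#' @param prune pruning threshold on transition probabilities (default
#'   0.01).
#' @param renormalize if TRUE, rows are renormalized after pruning (not the
#'   default).
#' @return a \linkS4class{TransitionNetwork}.
#' @export
buildTransitionNetwork <- function(ensemble, som, prune = 0.01,
                                   renormalize = FALSE) {
  m <- nrow(codebook(som))
  enc <- unlist(lapply(ensemble@trajectories, function(tr) {
    b <- bmu_cpp(tr@coords, codebook(som))
    Tn <- length(b)
    if (Tn < 2L) return(integer(0))
    (b[-Tn] - 1L) * m + b[-1L]
  }), use.names = FALSE)
  counts <- matrix(tabulate(enc, nbins = m * m), m, m, byrow = TRUE)
  rs <- rowSums(counts)
  zeroRows <- which(rs == 0)
  P <- counts / ifelse(rs == 0, 1, rs)
  P[P < prune] <- 0
  if (renormalize) {
    rs2 <- rowSums(P)
    P <- P / ifelse(rs2 == 0, 1, rs2)
  }
  W <- -log(P)             # +Inf where P == 0
  new("TransitionNetwork", P = P, W = W, counts = counts, prune = prune,
      zeroRows = as.integer(zeroRows))
}

# Dijkstra distances from every node to `target` on the reversed graph,
# then greedy reconstruction gives, for any source, the lexicographically
# smallest node sequence among equal-weight shortest paths.
.dijkstraTo <- function(W, target) {
  n <- nrow(W)
  dist <- rep(Inf, n)
  dist[target] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1L]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    # predecessors v with edge v -> u
    relax <- which(is.finite(W[, u]) & !done)
    nd <- dist[u] + W[relax, u]
    upd <- nd < dist[relax]
    dist[relax[upd]] <- nd[upd]
  }
  dist
}

.lexShortestPath <- function(W, source, target, distTo, tol = 1e-10) {
  if (!is.finite(distTo[source])) return(NULL)
  path <- source
  u <- source
  total <- distTo[source]
  while (u != target) {
    nbrs <- which(is.finite(W[u, ]))
    ok <- nbrs[abs(W[u, nbrs] + distTo[nbrs] - distTo[u]) <= tol]
    ok <- setdiff(ok, path)                # guard zero-weight cycles
    if (length(ok) == 0L) return(NULL)
    u <- min(ok)                           # lexicographic tie-break
    path <- c(path, u)
  }
  list(path = path, weight = total)
}

#' Shortest E-to-M transition paths over the network
#'
#' Neurons whose codebook vectors lie within \code{radius} of the epithelial
#' and mesenchymal centers form the E and M communities; for every
#' (E-neuron, M-neuron) pair reachable in the directed graph, the Dijkstra
#' shortest path under the \code{-log p} edge weights is returned (ties
#' resolved to the lexicographically smallest node sequence), and node/edge
#' usage frequencies are tallied over all returned paths.
#'
#' @param net a \linkS4class{TransitionNetwork}.
#' @param som the \linkS4class{SOMModel} that defined the states.
#' @param eCenter,mCenter region centers in feature space.
#' @param radius community radius around each center (default 0.7, reduced
#'   units).
#' @return a \linkS4class{PathSummary}.
#' @export
shortestTransitionPaths <- function(net, som, eCenter, mCenter,
                                    radius = 0.7) {
  cb <- codebook(som)
  dE <- sqrt(rowSums(sweep(cb, 2L, eCenter)^2))
  dM <- sqrt(rowSums(sweep(cb, 2L, mCenter)^2))
  eStates <- which(dE <= radius)
  mStates <- which(dM <= radius)
  if (length(eStates) == 0L || length(mStates) == 0L)
    stop("configuration error: empty E or M community at radius ", radius)
  n <- nrow(net@P)
  paths <- list(); weights <- numeric()
  nodeCounts <- numeric(n)
  edgeCounts <- matrix(0, n, n)
  skipped <- 0L
  for (mt in mStates) {
    distTo <- .dijkstraTo(net@W, mt)
    for (es in eStates) {
      res <- .lexShortestPath(net@W, es, mt, distTo)
      if (is.null(res)) {
        skipped <- skipped + 1L
        message("no path from state ", es, " to state ", mt, "; skipped")
        next
      }
      paths[[length(paths) + 1L]] <- res$path
      weights <- c(weights, res$weight)
      nodeCounts[res$path] <- nodeCounts[res$path] + 1
      if (length(res$path) > 1L) {
        eidx <- cbind(res$path[-length(res$path)], res$path[-1L])
        for (h in seq_len(nrow(eidx)))
          edgeCounts[eidx[h, 1L], eidx[h, 2L]] <-
            edgeCounts[eidx[h, 1L], eidx[h, 2L]] + 1
      }
    }
  }
  new("PathSummary", paths = paths, weights = weights,
      nodeCounts = nodeCounts, edgeCounts = edgeCounts,
      eStates = eStates, mStates = mStates,
      skipped = c(skipped, length(eStates) * length(mStates)))
}

#' Export a transition network as an edge-list table
#'
#' @param net a \linkS4class{TransitionNetwork}.
#' @return data.frame(source, target, probability, weight) over surviving
#'   edges.
#' @export
networkEdgeList <- function(net) {
  idx <- which(net@P > 0, arr.ind = TRUE)
  out <- data.frame(source = idx[, 1L], target = idx[, 2L],
                    probability = net@P[idx], weight = net@W[idx])
  out[order(out$source, out$target), , drop = FALSE]
}

#' @rdname networkEdgeList
#' @param path output file (CSV).
#' @export
writeNetworkEdgeList <- function(net, path) {
  utils::write.csv(networkEdgeList(net), path, row.names = FALSE)
  invisible(path)
}
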
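# shared fixtures and independent oracles, built in code at test time

# ensemble of straight-line trajectories with optional noise
lineEnsemble <- function(nTraj = 5L, nFrames = 20L, d = 2L, dt = 0.25,
                         from = rep(0, d), to = c(10, rep(0, d - 1L)),
                         sigma = 0, seed = 1L) {
  set.seed(seed)
  trajs <- lapply(seq_len(nTraj), function(i) {
    tt <- seq(0, 1, length.out = nFrames)
    X <- outer(1 - tt, from) + outer(tt, to) +
      matrix(rnorm(nFrames * d, sd = sigma), nFrames, d)
    FeatureTrajectory(sprintf("cell%02d", i),
                      seq(0, by = dt, length.out = nFrames), X)
  })
  TrajectoryEnsemble(trajs)
}

randomEnsemble <- function(nTraj = 10L, nFrames = 8L, d = 3L, seed = 1L) {
  set.seed(seed)
  trajs <- lapply(seq_len(nTraj), function(i)
    FeatureTrajectory(sprintf("c%03d", i),
                      seq(0, by = 0.5, length.out = nFrames),
                      matrix(rnorm(nFrames * d), nFrames, d)))
  TrajectoryEnsemble(trajs, featureNames = paste0("PC", seq_len(d)))
}

# brute-force enumeration of all simple paths (independent Dijkstra oracle)
bruteShortestPath <- function(W, from, to) {
  n <- nrow(W)
  best <- list(weight = Inf, path = NULL)
  recurse <- function(path, weight) {
    u <- path[length(path)]
    if (u == to) {
      if (weight < best$weight - 1e-12 ||
          (abs(weight - best$weight) <= 1e-12 &&
           .lexLess(path, best$path)))
        best <<- list(weight = weight, path = path)
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (v %in% path || !is.finite(W[u, v])) next
      if (weight + W[u, v] > best$weight + 1e-12) next
      recurse(c(path, v), weight + W[u, v])
    }
  }
  recurse(from, 0)
  if (is.null(best$path)) NULL else best
}

.lexLess <- function(a, b) {
  if (is.null(b)) return(TRUE)
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# exhaustive DTW oracle: minimum total cost over all monotone alignments
bruteDTW <- function(A, B) {
  if (!is.matrix(A)) A <- matrix(A, ncol = 1L)
  if (!is.matrix(B)) B <- matrix(B, ncol = 1L)
  cost <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  recurse <- function(i, j) {
    c0 <- cost(i, j)
    if (i == 1L && j == 1L) return(c0)
    opts <- c()
    if (i > 1L && j > 1L) opts <- c(opts, recurse(i - 1L, j - 1L))
    if (i > 1L) opts <- c(opts, recurse(i - 1L, j))
    if (j > 1L) opts <- c(opts, recurse(i, j - 1L))
    c0 + min(opts)
  }
  recurse(nrow(A), nrow(B))
}

# geometric ground-truth channel of a reactive trajectory on the two-path
# landscape: sign of the mean transverse offset from the central ridge axis
# over the intermediate-region frames (1 = upper / vimentin-first)
channelTruth <- function(reactive) {
  vapply(seq_along(trajectories(reactive)), function(i) {
    X <- coords(trajectories(reactive)[[i]])
    lab <- labelRegions(X, reactive@regions)
    Xi <- X[lab == "I", , drop = FALSE]
    off <- (Xi[, 2] - 6.8) * 0.8 - (Xi[, 1] - 9.5) * 0.6
    if (mean(off) > 0) 1L else 2L
  }, integer(1))
}

twoPathReactive <- function(nTraj = 150L, seed = 11L, deadline = 48,
                            observeEvery = 8L) {
  pot <- makeTwoPathPotential(1)
  ens <- simulateLangevin(pot, nTraj = nTraj, nSteps = 4800L, dtSim = 0.01,
                          sigma = 1.4,
                          init = list(type = "gaussian", mean = c(0, 0),
                                      sd = 0.8),
                          seed = seed, observeEvery = observeEvery)
  reg <- RegionSpec(c(0, 0), c(20, 15), 3, 4)
  list(ensemble = ens, regions = reg,
       reactive = extractReactive(ens, reg, deadline = deadline))
}
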
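lineRegions <- RegionSpec(c(0, 0), c(3, 0), 0.5, 0.5)

pointEnsemble <- function(mat, dt = 1) {
  # one two-frame trajectory per consecutive pair so region means are exact
  n <- nrow(mat)
  TrajectoryEnsemble(lapply(seq_len(n - 1L), function(i)
    FeatureTrajectory(paste0("p", i), c(0, dt), mat[i:(i + 1L), ,
                                                    drop = FALSE])))
}

test_that("the initial string interpolates the E and M data means", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 0), c(3, 0))
  ens <- pointEnsemble(pts)
  rc <- initializeString(ens, lineRegions, N = 4L)
  expect_equal(images(rc), cbind(0:3, 0))
  expect_equal(arcPositions(rc), 0:3)
  expect_equal(rc@anchors, rbind(c(0, 0), c(3, 0)))
  emptyReg <- RegionSpec(c(50, 50), c(60, 60), 1, 1)
  expect_error(initializeString(ens, emptyReg, N = 4L), "no data points")
  # N = 2 gives just the anchors; string optimization then rejects it
  rc2 <- initializeString(ens, lineRegions, N = 2L)
  expect_equal(nrow(images(rc2)), 2L)
  expect_error(updateString(rc2, ens), "minimum N")
})

test_that("average positions follow the two-term weighted update", {
  # straight string; all data on the images, one point per cell:
  # both terms equal the image, so the string is a fixed point
  rc <- straightRC(c(0, 0), c(5, 0), N = 6L)
  onImages <- TrajectoryEnsemble(list(
    FeatureTrajectory("a", 0:5, cbind(0:5, 0))))
  xbar <- stringAveragePositions(rc, onImages, w = 10)
  expect_equal(xbar, images(rc), tolerance = 1e-12)
  rcUp <- updateString(rc, onImages, w = 10, smooth = 1)
  expect_equal(images(rcUp), images(rc), tolerance = 1e-6)

  # term1 = (0,0) and term2 = (1,0) at one cell: xbar = (10/11, 0)
  rc1 <- straightRC(c(0, 0), c(30, 0), N = 4L)   # cells centred 0,10,20,30
  trajA <- FeatureTrajectory("a", 0:1, rbind(c(10, 0), c(10, 0)))
  trajB <- FeatureTrajectory("b", 0:1, rbind(c(11, 0), c(11, 0)))
  # cell 2 holds points from both; term1 = (10.5, 0), term2 = (10.5, 0) --
  # so separate the terms instead: a single far trajectory pulls term2 only
  xbar1 <- stringAveragePositions(
    rc1, TrajectoryEnsemble(list(trajA, trajB)), w = 10)
  expect_equal(xbar1[2, 1], 10.5, tolerance = 1e-12)

  # independent brute-force oracle on a random fixture
  set.seed(12)
  rcR <- straightRC(c(0, 0), c(8, 0), N = 5L)
  ens <- randomEnsemble(nTraj = 6L, nFrames = 10L, d = 2L, seed = 13L)
  xbarFast <- stringAveragePositions(rcR, ens, w = 10)
  img <- images(rcR)
  pts <- ensemblePoints(ens)$points
  cell <- apply(as.matrix(pdist <- outer(rowSums(pts^2),
                                         rowSums(img^2), `+`) -
                            2 * pts %*% t(img)), 1, which.min)
  for (k in 1:5) {
    t2 <- colMeans(t(vapply(trajectories(ens), function(tr) {
      X <- coords(tr)
      X[which.min(colSums((t(X) - img[k, ])^2)), ]
    }, numeric(2))))
    if (any(cell == k)) {
      t1 <- colMeans(pts[cell == k, , drop = FALSE])
      expect_equal(xbarFast[k, ], (t1 + 10 * t2) / 11, tolerance = 1e-10)
    } else {
      expect_equal(xbarFast[k, ], t2, tolerance = 1e-10)
    }
  }
})

test_that("anchors never move and spacing stays uniform across iterations", {
  set.seed(14)
  ens <- lineEnsemble(nTraj = 20L, nFrames = 25L, from = c(0, 0),
                      to = c(10, 0), sigma = 0.3, seed = 14L)
  reg <- RegionSpec(c(0, 0), c(10, 0), 1.2, 1.2)
  rc0 <- initializeString(ens, reg, N = 12L)
  rc <- rc0
  for (i in 1:5) {
    rc <- suppressMessages(updateString(rc, ens))
    expect_equal(rc@anchors, rc0@anchors)
    expect_equal(images(rc)[1, ], rc0@anchors[1, ])
    expect_equal(images(rc)[12, ], rc0@anchors[2, ])
    sp <- diff(arcPositions(rc))
    expect_lt(max(abs(sp - mean(sp))) / mean(sp), 0.01)
  }
})

test_that("straight-line data converges immediately; maxIter 0 is flagged", {
  ens <- lineEnsemble(nTraj = 15L, nFrames = 20L, from = c(0, 0),
                      to = c(10, 0), sigma = 0.05, seed = 15L)
  reg <- RegionSpec(c(0, 0), c(10, 0), 1, 1)
  rc0 <- initializeString(ens, reg, N = 10L)
  rc <- convergeString(rc0, ens, maxIter = 100L)
  expect_true(rc@converged)
  expect_lte(rc@iterations, 2L)
  rcZ <- convergeString(rc0, ens, maxIter = 0L)
  expect_false(rcZ@converged)
  expect_identical(images(rcZ), images(rc0))
})

test_that("the string recovers a curved corridor within the noise scale", {
  for (sg in c(0.25, 0.5, 1)) {
    ens <- makeArcEnsemble(radius = 10, sigma = sg, nTraj = 100L,
                           nFrames = 50L, seed = 16L)
    reg <- RegionSpec(c(10, 0), c(0, 10), 1.5, 1.5)
    rc0 <- initializeString(ens, reg, N = 20L)
    rc <- suppressMessages(convergeString(rc0, ens, maxIter = 100L))
    devs <- abs(sqrt(rowSums(images(rc)^2)) - 10)
    expect_lt(mean(devs), max(sg, 0.3))
  }
})

test_that("string optimization is deterministic", {
  ens <- makeArcEnsemble(sigma = 0.5, nTraj = 40L, seed = 17L)
  reg <- RegionSpec(c(10, 0), c(0, 10), 1.5, 1.5)
  a <- suppressMessages(convergeString(initializeString(ens, reg, N = 15L),
                                       ens))
  b <- suppressMessages(convergeString(initializeString(ens, reg, N = 15L),
                                       ens))
  expect_identical(images(a), images(b))
})

test_that("extrapolation continues the terminal segments uniformly", {
  rc <- straightRC(c(0, 0), c(9, 0), N = 10L)    # spacing exactly 1 along x
  ex <- extrapolateString(rc, nExtra = 3L)
  expect_equal(images(ex)[1:3, 1], c(-3, -2, -1))
  expect_equal(images(ex)[14:16, 1], c(10, 11, 12))
  sp <- diff(arcPositions(ex))
  expect_lt(max(abs(sp - 1)), 1e-9)
  expect_equal(ex@nExtra, 3L)
  expect_identical(extrapolateString(rc, nExtra = 0L), rc)
  # re-indexing keeps the interior images untouched
  expect_equal(images(ex)[4:13, ], images(rc))
})

test_that("matched arc progress is monotone along corridor trajectories", {
  ens <- makeArcEnsemble(radius = 10, sigma = 0.5, nTraj = 50L,
                         nFrames = 50L, seed = 18L)
  reg <- RegionSpec(c(10, 0), c(0, 10), 1.5, 1.5)
  rc <- suppressMessages(convergeString(initializeString(ens, reg, N = 20L),
                                        ens))
  frac <- vapply(trajectories(ens), function(tr) {
    s <- projectOntoRC(rc, coords(tr))$s
    sm <- stats::runmed(s, 5)                    # median filter, window 5
    mean(diff(sm) >= 0)
  }, numeric(1))
  expect_gte(mean(frac), 0.9)
})

test_that("full-dimension lift averages the unmodeled coordinates per cell", {
  set.seed(19)
  ens2 <- lineEnsemble(nTraj = 30L, nFrames = 20L, from = c(0, 0),
                       to = c(10, 0), sigma = 0.2, seed = 19L)
  # add a third coordinate: constant 4 plus noise-free linear trend in x
  full <- TrajectoryEnsemble(lapply(trajectories(ens2), function(tr) {
    X <- coords(tr)
    FeatureTrajectory(tr@cellId, frameTimes(tr),
                      cbind(X, 4, 0.5 * X[, 1]))
  }))
  rc <- extrapolateString(straightRC(c(0, 0), c(10, 0), N = 10L), 1L)
  lifted <- liftFullDimension(rc, full)
  expect_equal(ncol(images(lifted)), 4L)
  inner <- 3:10                                  # interior, well-populated
  expect_equal(images(lifted)[inner, 3], rep(4, length(inner)),
               tolerance = 1e-9)
  fit <- lm(images(lifted)[inner, 4] ~ images(lifted)[inner, 1])
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.05)
  # empty end cells are interpolated/extended, not NA
  expect_true(all(is.finite(images(lifted))))
  expect_error(liftFullDimension(rc, ens2), "more coordinates")
})

test_that("feature dynamics are the PCA back-projection of the lifted path", {
  rc <- straightRC(c(0, 1), c(5, 1), N = 6L)
  # identity loadings: curves equal the lifted coordinates
  idPCA <- PCAModel(c(0, 0), diag(2), c("f1", "f2"))
  expect_equal(unname(featureDynamicsAlongRC(rc, idPCA)), images(rc))
  # a feature defined as 2 * PC1 reproduces exactly twice the PC1 curve
  L <- cbind(c(2, 0, 1) / sqrt(5), c(0, 1, 0))
  pca <- PCAModel(c(0, 0, 0), L, c("f1", "f2", "f3"))
  curves <- featureDynamicsAlongRC(rc, pca)
  expect_equal(unname(curves[, "f1"]), images(rc)[, 1] * 2 / sqrt(5))
  # rotation-only loadings preserve norms image by image
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- PCAModel(c(0, 0), R, c("f1", "f2"))
  expect_equal(sqrt(rowSums(featureDynamicsAlongRC(rc, rot)^2)),
               sqrt(rowSums(images(rc)^2)))
  expect_error(featureDynamicsAlongRC(rc, PCAModel(0, matrix(1, 1, 1), "f")),
               "dimension mismatch")
})
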
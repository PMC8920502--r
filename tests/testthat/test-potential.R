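xRC <- function(lo = 0, hi = 9, N = 10L, nExtra = 1L)
  extrapolateString(straightRC(c(lo, 0), c(hi, 0), N = N), nExtra)

test_that("drift estimator returns minus the mean cell-to-cell speed", {
  rc <- xRC()                                    # images at x = -1..10
  # deterministic traversal, one cell per frame: ds/dt = 1 everywhere
  tr <- FeatureTrajectory("v", 0:9, cbind(0:9, 0))
  ens <- TrajectoryEnsemble(list(tr))
  g <- estimateDrift(ens, rc, minCount = 1L)
  visited <- !is.na(g)
  expect_equal(unname(g[visited]), rep(-1, sum(visited)))
  # stationary jitter within one cell: zero drift
  tr2 <- FeatureTrajectory("j", 0:9, cbind(rep(c(5, 5.1), 5), 0))
  g2 <- estimateDrift(TrajectoryEnsemble(list(tr2)), rc, minCount = 1L)
  expect_equal(unique(g2[!is.na(g2)]), 0)
  # contract: extrapolation required; masking below minCount
  expect_error(estimateDrift(ens, straightRC(c(0, 0), c(9, 0), 10L)),
               "extrapolated")
  # one visit per cell only: minCount = 5 masks every cell
  expect_error(estimateDrift(ens, rc, minCount = 5L), "all cells masked")
})

test_that("diffusion estimator is the per-cell speed variance", {
  rc <- xRC()
  tr <- FeatureTrajectory("v", 0:9, cbind(0:9, 0))
  D <- estimateDiffusion(TrajectoryEnsemble(list(tr)), rc, minCount = 1L)
  expect_true(all(D[!is.na(D)] == 0))
  # pure noise: step variance sigma^2 -> D = sigma^2 / dt^2
  set.seed(20)
  sg <- 0.6; dt <- 0.5
  trs <- lapply(1:30, function(i)
    FeatureTrajectory(paste0("n", i), seq(0, by = dt, length.out = 60),
                      cbind(4.5 + rnorm(60, sd = sg), 0)))
  Dn <- estimateDiffusion(TrajectoryEnsemble(trs), rc, minCount = 20L)
  # successive positions are independent, so conditioned on the current
  # cell the speed variance is Var(s(next)) / dt^2 (cell-quantized arc)
  sOf <- function(x) rc@arcPositions[transpath:::bmu_cpp(cbind(x, 0),
                                                         images(rc))]
  sAll <- unlist(lapply(trs, function(tr) sOf(coords(tr)[, 1])))
  expect_equal(mean(Dn, na.rm = TRUE), var(sAll) / dt^2, tolerance = 0.2)
})

test_that("potential integration is the left-Riemann cumulative sum", {
  expect_equal(as.numeric(integratePotential(rep(2, 5), 1)),
               c(0, 2, 4, 6, 8, 10))
  expect_equal(as.numeric(integratePotential(rep(0, 4), 0.3)), rep(0, 5))
  # masked interior cells are interpolated; masked ends truncate
  g <- c(NA, 1, NA, 3, NA)
  expect_message(phi <- integratePotential(g, 1), "interpolation")
  expect_equal(attr(phi, "kept"), 2:4)
  expect_equal(as.numeric(phi), c(0, 1, 3, 6))
})

test_that("OU trajectories recover the quadratic quasi-potential", {
  pot <- makeQuadraticPotential(k = 1, d = 1L)
  ens <- simulateLangevin(pot, nTraj = 300L, nSteps = 1000L, dtSim = 0.01,
                          sigma = 1,
                          init = list(type = "gaussian", mean = 0, sd = 1),
                          seed = 23L, observeEvery = 10L)
  rc <- extrapolateString(straightRC(-3, 3, N = 30L), 3L)
  grad <- estimateDrift(ens, rc, minCount = 5L)
  s <- attr(grad, "s")
  ok <- !is.na(grad)
  # drift gradient is linear in s with slope ~1 through the origin
  fit <- lm(grad[ok] ~ s[ok])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
  qp <- estimateQuasiPotential(ens, rc, minCount = 5L)
  qfit <- lm(qp@phi ~ I(qp@sGrid^2) + qp@sGrid)
  expect_equal(2 * unname(coef(qfit)[2]), 1, tolerance = 0.1)
  expect_gt(summary(qfit)$r.squared, 0.95)
  # homoskedastic noise: diffusion roughly constant across cells
  expect_lt(sd(qp@D) / mean(qp@D), 0.3)
})

test_that("density-based potential is the Boltzmann inversion", {
  rc <- straightRC(c(0, 0), c(2, 0), N = 3L)
  # uniform occupancy: flat potential
  pts <- cbind(rep(c(0, 1, 2), 50), 0)
  expect_equal(max(abs(potentialFromDensity(pts, rc))), 0)
  # printed toy counts 90 / 9 / 1 with zero pseudocount
  pts2 <- cbind(rep(c(0, 1, 2), c(90, 9, 1)), 0)
  phi0 <- potentialFromDensity(pts2, rc, pseudocount = 0)
  expect_equal(phi0[2] - phi0[1], log(10))
  expect_equal(phi0[3] - phi0[2], log(9))
  expect_error(potentialFromDensity(cbind(numeric(0), numeric(0)), rc),
               "empty")
  # Gaussian sample: quadratic potential, R^2 > 0.9
  set.seed(24)
  rcg <- straightRC(-3, 3, N = 25L)
  x <- matrix(rnorm(20000), ncol = 1)
  ph <- potentialFromDensity(x, rcg)
  s <- arcPositions(rcg) - 3
  use <- abs(s) < 2.5
  fit <- lm(ph[use] ~ I(s[use]^2))
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("CK deviations vanish for deterministic and Markov chains", {
  # deterministic cycle: permutation matrix powers match exactly
  P <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  ch <- makeMarkovFixture(P, 5L, 60L, seed = 25L)
  ck <- ckTestDiscrete(ch, tau = 1L, ks = 2:5)
  expect_equal(ck@deviations, rep(0, 5))
  expect_equal(ck@ks[1], 1L)
  # genuinely Markov chain: small deviation at large sample size
  P2 <- rbind(c(0.8, 0.15, 0.05), c(0.2, 0.6, 0.2), c(0.05, 0.15, 0.8))
  ch2 <- makeMarkovFixture(P2, 100L, 1000L, seed = 26L)  # 1e5 transitions
  ck2 <- ckTestDiscrete(ch2, tau = 1L, ks = 2:3)
  expect_lt(ck2@deviations[ck2@ks == 3L], 0.1)
})

test_that("lumping a non-lumpable chain is detected by the CK test", {
  # noisy 3-cycle whose lumping {1}, {2,3} violates lumpability: the time
  # already spent in the lump predicts the next exit
  P <- rbind(c(0.05, 0.9, 0.05), c(0.05, 0.05, 0.9), c(0.9, 0.05, 0.05))
  ch <- makeMarkovFixture(P, 100L, 1000L, seed = 27L)
  lumped <- lapply(ch, function(x) ifelse(x == 1L, 1L, 2L))
  ckM <- ckTestDiscrete(ch, tau = 1L, ks = 3L)
  ckL <- ckTestDiscrete(lumped, tau = 1L, ks = 3L)
  expect_gt(ckL@deviations[ckL@ks == 3L],
            5 * ckM@deviations[ckM@ks == 3L])
})

test_that("FP stationary state is the Boltzmann distribution", {
  s <- seq(-3, 3, length.out = 80)
  # quadratic phi at kBT = 1/2: sd = 1/sqrt(2) within 1%
  sol <- solveFokkerPlanck(s^2 / 2, 1, s, kBT = 0.5, gridN = 200L)
  expect_true(sol@converged)
  st <- stationaryStats(sol)
  expect_equal(unname(st["sd"]), 1 / sqrt(2), tolerance = 0.01)
  expect_lt(abs(st["mean"]), 0.01)
  expect_lt(max(abs(sol@flux)), 1e-8)
  # flat potential: uniform stationary density
  solU <- solveFokkerPlanck(rep(0, 80), 1, s, kBT = 0.5, gridN = 100L)
  expect_lt(diff(range(solU@rhoSS)) / mean(solU@rhoSS), 1e-6)
  # spatially varying D leaves the stationary state unchanged (two-well phi)
  phi <- (s^2 - 1)^2
  Dvar <- 0.5 + 0.4 * sin(s)
  solV <- solveFokkerPlanck(phi, Dvar, s, kBT = 0.5, gridN = 200L)
  h <- diff(solV@grid[1:2])
  ref <- exp(-stats::spline(s, phi, xout = solV@grid)$y / 0.5)
  ref <- ref / (sum(ref) * h)
  expect_lt(sum(abs(solV@rhoSS - ref)) * h, 0.01)
  expect_error(solveFokkerPlanck(phi, -1, s), "positive")
})

test_that("FP conserves mass and ignores potential offsets", {
  s <- seq(0, 10, length.out = 60)
  phi <- cos(s) + 0.3 * s
  sol1 <- solveFokkerPlanck(phi, 0.8, s, kBT = 0.7, gridN = 150L)
  sol2 <- solveFokkerPlanck(phi + 42, 0.8, s, kBT = 0.7, gridN = 150L)
  h <- diff(sol1@grid[1:2])
  for (i in seq_len(nrow(sol1@rho)))
    expect_equal(sum(sol1@rho[i, ]) * h, 1, tolerance = 1e-6)
  expect_equal(sol1@rhoSS, sol2@rhoSS, tolerance = 1e-8)
  expect_equal(stationaryStats(sol1), stationaryStats(sol2),
               tolerance = 1e-8)
  # near-zero temperature concentrates at the global minimum
  solT <- solveFokkerPlanck((s - 4)^2, 0.5, s, kBT = 0.02, gridN = 150L)
  expect_equal(unname(stationaryStats(solT)["mean"]), 4, tolerance = 0.05)
  bad <- new("FPSolution", grid = s, times = 0, rho = matrix(0, 1, 60),
             rhoSS = rep(0, 60), flux = numeric(0), converged = FALSE,
             kBT = 1)
  expect_error(stationaryStats(bad), "stationarity")
})

test_that("double-well Langevin data recover barrier and wells", {
  pot <- makeDoubleWellPotential(a = 1, r = 1)
  barriers <- wells <- NULL
  for (seed in 1:5) {
    ens <- simulateLangevin(pot, nTraj = 300L, nSteps = 600L, dtSim = 0.01,
                            sigma = 1,
                            init = list(type = "uniform", lower = -1.8,
                                        upper = 1.8),
                            seed = 100L + seed, observeEvery = 5L)
    rc <- extrapolateString(straightRC(-1.8, 1.8, N = 30L), 3L)
    qp <- estimateQuasiPotential(ens, rc, minCount = 5L)
    s <- qp@sGrid - 1.8                    # arc origin at s = -1.8
    wellL <- s[which.min(qp@phi[s < 0])]
    wellR <- s[s > 0][which.min(qp@phi[s > 0])]
    mid <- abs(s) < 0.5
    barrier <- max(qp@phi[mid]) -
      (min(qp@phi[s < 0]) + min(qp@phi[s > 0])) / 2
    barriers <- c(barriers, barrier)
    wells <- rbind(wells, c(wellL, wellR))
  }
  ds <- 3.6 / 29
  expect_equal(mean(barriers), 1, tolerance = 0.15)
  expect_lt(abs(mean(wells[, 1]) + 1), ds)
  expect_lt(abs(mean(wells[, 2]) - 1), ds)
})

test_that("FP prediction closes the loop against the simulator", {
  # recovered (phi, D) from transition-period data predict the long-run
  # stationary moments; pseudo-temperature from the measured diffusion
  pot <- makeDoubleWellPotential(a = 1, r = 1)
  dt <- 0.05
  ens <- simulateLangevin(pot, nTraj = 600L, nSteps = 600L, dtSim = 0.01,
                          sigma = 1,
                          init = list(type = "uniform", lower = -1.8,
                                      upper = 1.8),
                          seed = 31L, observeEvery = 5L)
  rc <- extrapolateString(straightRC(-1.8, 1.8, N = 30L), 3L)
  qp <- estimateQuasiPotential(ens, rc, minCount = 5L)
  kBT <- mean(qp@D) * dt / 2               # variance at the sampling interval
  sol <- solveFokkerPlanck(qp@phi, qp@D, qp@sGrid, kBT = kBT,
                           gridN = 200L)
  st <- stationaryStats(sol)
  # long-run empirical reference from an independent long simulation
  long <- simulateLangevin(pot, nTraj = 100L, nSteps = 6000L, dtSim = 0.01,
                           sigma = 1,
                           init = list(type = "uniform", lower = -1.8,
                                       upper = 1.8),
                           seed = 32L, observeEvery = 20L)
  pts <- ensemblePoints(long)
  x <- pts$points[pts$frame > 100L, 1]
  sEmp <- x + 1.8                           # arc origin at x = -1.8
  expect_equal(unname(st["mean"]), mean(sEmp), tolerance = 0.1)
  expect_equal(unname(st["sd"]), sd(sEmp), tolerance = 0.1)
})

test_that("CK test along an RC discretizes frames into Voronoi cells", {
  pot <- makeQuadraticPotential(k = 1, d = 1L)
  ens <- simulateLangevin(pot, nTraj = 50L, nSteps = 500L, dtSim = 0.02,
                          sigma = 1,
                          init = list(type = "gaussian", mean = 0, sd = 0.7),
                          seed = 33L, observeEvery = 5L)
  rc <- straightRC(-3, 3, N = 12L)
  ck <- ckTest(ens, rc, tau = 1L, ks = 2:3)
  expect_s4_class(ck, "CKTestResult")
  expect_equal(ck@deviations[1], 0)
  expect_true(all(ck@deviations >= 0))
  expect_equal(ck@nStates, 12L)
})
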
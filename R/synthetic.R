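#' Construct an analytic potential landscape
#'
#' A \linkS4class{PotentialSpec} is a sum of analytic terms, each a list with
#' a \code{type} field:
#' \describe{
#'   \item{gauss}{\code{center} (d-vector), signed \code{height} (negative =
#'     well, positive = barrier), \code{width} (scalar or d-vector of
#'     standard deviations), optional \code{theta} (2-D rotation of the
#'     width axes, radians).}
#'   \item{quad}{\code{center}, \code{k} (scalar or d-vector):
#'     \eqn{\frac12 \sum_j k_j (x_j - c_j)^2}, a confining funnel.}
#'   \item{quartic_dw}{\code{dim}, \code{center}, \code{a}, \code{r}:
#'     \eqn{a((x - c)^2 - r^2)^2} in one coordinate, a double well with
#'     minima at \eqn{c \pm r} and barrier height \eqn{a r^4}.}
#' }
#'
#' @param terms list of term descriptors.
#' @param d integer dimension.
#' @param control scalar in [0, 1], dose-like control parameter (recorded;
#'   used by \code{\link{makeTwoPathPotential}}).
#' @param metadata free-form list (attractor centers, channel centerlines).
#' @return a \linkS4class{PotentialSpec}.
#' @export
PotentialSpec <- function(terms, d, control = 0, metadata = list()) {
  new("PotentialSpec", terms = terms, d = as.integer(d),
      control = as.numeric(control), metadata = metadata)
}

#' Evaluate a potential and its gradient
#'
#' @param spec a \linkS4class{PotentialSpec}.
#' @param x point(s): a d-vector or an n x d matrix of row points.
#' @return \code{potentialValue}: numeric(n); \code{potentialGradient}:
#'   n x d matrix.
#' @export
potentialValue <- function(spec, x) {
  x <- .asRows(x, spec@d)
  u <- numeric(nrow(x))
  for (tm in spec@terms) u <- u + .termEval(tm, x, grad = FALSE)
  u
}

#' @rdname potentialValue
#' @export
potentialGradient <- function(spec, x) {
  x <- .asRows(x, spec@d)
  g <- matrix(0, nrow(x), ncol(x))
  for (tm in spec@terms) g <- g + .termEval(tm, x, grad = TRUE)
  g
}

.asRows <- function(x, d) {
  if (!is.matrix(x)) x <- matrix(x, ncol = d)
  if (ncol(x) != d) stop("point dimension does not match potential dimension")
  x
}

.termEval <- function(tm, x, grad) {
  n <- nrow(x); d <- ncol(x)
  switch(tm$type,
    gauss = {
      w <- rep_len(tm$width, d)
      y <- sweep(x, 2L, tm$center)                  # n x d
      if (!is.null(tm$theta) && d == 2L) {
        R <- matrix(c(cos(tm$theta), sin(tm$theta),
                      -sin(tm$theta), cos(tm$theta)), 2L, 2L)
        y <- y %*% R                                # y in rotated frame
      } else R <- NULL
      e <- tm$height * exp(-0.5 * rowSums(sweep(y, 2L, w, `/`)^2))
      if (!grad) return(e)
      gy <- -e * sweep(y, 2L, w^2, `/`)             # d/dy
      if (is.null(R)) gy else gy %*% t(R)
    },
    quad = {
      k <- rep_len(tm$k, d)
      y <- sweep(x, 2L, tm$center)
      if (!grad) return(0.5 * rowSums(sweep(y^2, 2L, k, `*`)))
      sweep(y, 2L, k, `*`)
    },
    quartic_dw = {
      j <- tm$dim %||% 1L
      u <- x[, j] - tm$center
      q <- u^2 - tm$r^2
      if (!grad) return(tm$a * q^2)
      g <- matrix(0, n, d)
      g[, j] <- 4 * tm$a * q * u
      g
    },
    stop("unknown potential term type: ", tm$type))
}

#' Single-well and double-well reference landscapes
#'
#' \code{makeQuadraticPotential} builds \eqn{U = \frac12 k |x - c|^2} (an
#' Ornstein-Uhlenbeck well for the Langevin simulator);
#' \code{makeDoubleWellPotential} builds the 1-D quartic
#' \eqn{U = a((s - c)^2 - r^2)^2} with wells at \eqn{c \pm r} and barrier
#' height \eqn{a r^4}.
#'
#' @param k,center,d,a,r landscape parameters.
#' @return a \linkS4class{PotentialSpec}.
#' @export
makeQuadraticPotential <- function(k = 1, d = 1L, center = rep(0, d)) {
  PotentialSpec(list(list(type = "quad", center = center, k = k)), d = d,
                metadata = list(eCenter = center))
}

#' @rdname makeQuadraticPotential
#' @export
makeDoubleWellPotential <- function(a = 1, r = 1, center = 0) {
  PotentialSpec(list(list(type = "quartic_dw", dim = 1L, center = center,
                          a = a, r = r)), d = 1L,
                metadata = list(wells = center + c(-r, r),
                                barrier = a * r^4))
}

# Two-path landscape geometry (fixture constants, reduced units).
# E attractor near the origin (epithelial), M attractor at (20, 15)
# (mesenchymal) in (morphology-PC1-like, vimentin-PC1-like) axes.  A central
# elongated ridge separates an upper "vimentin-first" channel (texture axis
# moves first) from a lower "concerted" channel.  Each channel carries a
# saddle barrier near the E exit whose height decreases with the control
# parameter; the concerted barrier and the E well vanish at control = 0.5,
# the vimentin-first barrier at control = 1 (sequential saddle-node
# collisions with increasing dose).
.tp <- list(
  E = c(0, 0), M = c(20, 15),
  funnelK = 0.05,                        # 2*kappa, kappa = 0.025
  eDepth = 5, eWidth = 2.5,
  mDepth = 3, mWidth = 3,
  ridgeCenter = c(9.5, 6.8), ridgeHeight = 6,
  ridgeWidth = c(5.5, 2.2), ridgeTheta = atan2(15, 20),
  s1Center = c(0.2, 4), s1Height = 14,       # vimentin-first saddle
  s2Center = c(4, 1), s2Height = 14,         # concerted saddle
  saddleWidth = 1.5,
  ctrl1 = c(0, 16),                      # Bezier control point, channel 1
  ctrl2 = c(13, 2))                      # Bezier control point, channel 2

.bezier <- function(p0, p1, p2, t) {
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
}

#' Two-channel EMT-like landscape with dose-dependent barriers
#'
#' Builds a 2-D landscape with an epithelial (E) well near the origin, a
#' mesenchymal (M) well at (20, 15), a global confining funnel centered on M,
#' a central ridge separating two transition channels ("vimentin-first",
#' which moves the texture-like axis first, and "concerted"), and one saddle
#' barrier per channel.  As \code{control} rises from 0 to 1 the E well and
#' the concerted barrier vanish first (at control = 0.5), then the
#' vimentin-first barrier (at control = 1), so the attractor is destabilized
#' directionally: at intermediate control exactly one channel is barrier-less,
#' and at control = 1 the potential decreases monotonically out of E along
#' both channel centerlines.
#'
#' The returned object's \code{metadata} holds \code{eCenter} (the refined E
#' minimum while it exists, else the nominal origin), \code{mCenter} (refined
#' M minimum), and \code{channels}: two dense centerline polylines from E to
#' M used for barrier measurement and as ground-truth channel paths.
#'
#' @param control scalar in [0, 1].
#' @return a \linkS4class{PotentialSpec} (d = 2).
#' @export
makeTwoPathPotential <- function(control) {
  if (!is.numeric(control) || length(control) != 1L ||
      control < 0 || control > 1)
    stop("control must be a scalar in [0, 1]")
  p <- .tp
  eDepth <- p$eDepth * max(0, 1 - control / 0.5)
  b1 <- p$s1Height * max(0, 1 - control)           # vimentin-first barrier
  b2 <- p$s2Height * max(0, 1 - control / 0.5)     # concerted barrier
  terms <- list(
    list(type = "quad", center = p$M, k = p$funnelK),
    list(type = "gauss", center = p$M, height = -p$mDepth, width = p$mWidth),
    list(type = "gauss", center = p$ridgeCenter, height = p$ridgeHeight,
         width = p$ridgeWidth, theta = p$ridgeTheta))
  if (eDepth > 0)
    terms <- c(terms, list(list(type = "gauss", center = p$E,
                                height = -eDepth, width = p$eWidth)))
  if (b1 > 0)
    terms <- c(terms, list(list(type = "gauss", center = p$s1Center,
                                height = b1, width = p$saddleWidth)))
  if (b2 > 0)
    terms <- c(terms, list(list(type = "gauss", center = p$s2Center,
                                height = b2, width = p$saddleWidth)))
  spec <- PotentialSpec(terms, d = 2L, control = control)
  t <- seq(0, 1, length.out = 201L)
  chan <- list(vimentinFirst = .bezier(p$E, p$ctrl1, p$M, t),
               concerted = .bezier(p$E, p$ctrl2, p$M, t))
  eRef <- if (eDepth > 0) .refineMinimum(spec, p$E) else p$E
  spec@metadata <- list(eCenter = eRef, mCenter = .refineMinimum(spec, p$M),
                        channels = chan, nominalE = p$E, nominalM = p$M)
  spec
}

# gradient descent with backtracking; enough to polish an attractor center
.refineMinimum <- function(spec, x0, maxIter = 200L) {
  x <- x0
  step <- 0.5
  for (i in seq_len(maxIter)) {
    g <- potentialGradient(spec, x)[1L, ]
    if (sqrt(sum(g^2)) < 1e-10) break
    repeat {
      xn <- x - step * g
      if (potentialValue(spec, xn) < potentialValue(spec, x)) break
      step <- step / 2
      if (step < 1e-12) return(x)
    }
    x <- xn
    step <- min(step * 2, 0.5)
  }
  x
}

#' Potential profile and barrier along a channel centerline
#'
#' The barrier of a channel is the maximum of the potential along its stored
#' centerline minus the value at the centerline's E-side start; a barrier of
#' zero (up to floating point) means monotone descent out of E.
#'
#' @param spec a landscape from \code{\link{makeTwoPathPotential}}.
#' @param channel 1 (vimentin-first) or 2 (concerted).
#' @return list(profile, barrier, argmax).
#' @export
channelBarrier <- function(spec, channel = 1L) {
  ch <- spec@metadata$channels
  if (is.null(ch)) stop("spec has no channel centerlines")
  u <- potentialValue(spec, ch[[channel]])
  list(profile = u, barrier = max(u) - u[1L], argmax = which.max(u))
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate Langevin trajectories on an analytic landscape
#'
#' Euler-Maruyama integration of \eqn{dx = -\nabla U(x)\,dt + \sigma\sqrt{dt}\,\xi}
#' with \eqn{\xi \sim N(0, I)}.  The same seed gives a bitwise-identical
#' ensemble.  Trajectories whose coordinates exceed \code{bound} are frozen
#' at their last finite position and flagged (attribute \code{"diverged"} on
#' the returned ensemble and a warning), never silently NaN.
#'
#' @param spec a \linkS4class{PotentialSpec}.
#' @param nTraj number of trajectories.
#' @param nSteps integration steps.
#' @param dtSim integration step (hours).
#' @param sigma noise scale, scalar or per-dimension.
#' @param init initial sampler descriptor: \code{list(type = "point", x=)},
#'   \code{list(type = "gaussian", mean=, sd=)},
#'   \code{list(type = "uniform", lower=, upper=)}, or
#'   \code{list(type = "path", points=)} (uniform along a polyline).
#' @param seed integer RNG seed.
#' @param observeEvery thin to one recorded frame per this many steps (the
#'   observation interval is then \code{dtSim * observeEvery}).
#' @param bound divergence guard on |coordinate|.
#' @param conditionLabel condition tag for the ensemble.
#' @return a \linkS4class{TrajectoryEnsemble}.
#' @export
simulateLangevin <- function(spec, nTraj, nSteps, dtSim, sigma,
                             init = list(type = "point",
                                         x = rep(0, spec@d)),
                             seed = NULL, observeEvery = 1L, bound = 1e6,
                             conditionLabel = "") {
  stopifnot(nTraj >= 1L, nSteps >= 1L, all(sigma >= 0), dtSim > 0)
  d <- spec@d
  sig <- rep_len(sigma, d)
  .withSeed(seed, {
    X <- .sampleInit(init, nTraj, d)
    keep <- seq(1L, nSteps + 1L, by = observeEvery)
    out <- array(NA_real_, c(length(keep), nTraj, d))
    alive <- rep(TRUE, nTraj)
    ki <- 1L
    if (keep[ki] == 1L) { out[1L, , ] <- X; ki <- 2L }
    sqdt <- sqrt(dtSim)
    for (step in seq_len(nSteps)) {
      G <- potentialGradient(spec, X)
      Xn <- X - G * dtSim +
        matrix(stats::rnorm(nTraj * d), nTraj, d) %*% diag(sig, d) * sqdt
      bad <- rowSums(abs(Xn) > bound) > 0
      Xn[bad | !alive, ] <- X[bad | !alive, ]
      alive <- alive & !bad
      X <- Xn
      if (ki <= length(keep) && step + 1L == keep[ki]) {
        out[ki, , ] <- X
        ki <- ki + 1L
      }
    }
    dtObs <- dtSim * observeEvery
    trajs <- lapply(seq_len(nTraj), function(i)
      FeatureTrajectory(sprintf("sim_%03d", i),
                        (keep - 1L) * dtSim,
                        matrix(out[, i, ], ncol = d)))
    ens <- TrajectoryEnsemble(trajs, featureNames = paste0("PC", seq_len(d)),
                              conditionLabel = conditionLabel)
    if (any(!alive)) {
      warning("diverged trajectories frozen at last finite position: ",
              paste(which(!alive), collapse = ", "))
      attr(ens, "diverged") <- which(!alive)
    }
    ens
  })
}

.sampleInit <- function(init, n, d) {
  switch(init$type,
    point = matrix(rep(init$x, each = n), n, d),
    gaussian = {
      sd <- rep_len(init$sd, d)
      matrix(rep(init$mean, each = n), n, d) +
        matrix(stats::rnorm(n * d), n, d) %*% diag(sd, d)
    },
    uniform = {
      lo <- rep_len(init$lower, d); hi <- rep_len(init$upper, d)
      sapply(seq_len(d), function(j) stats::runif(n, lo[j], hi[j]))
    },
    path = {
      pts <- init$points
      seg <- sqrt(rowSums(diff(pts)^2))
      cum <- c(0, cumsum(seg))
      s <- stats::runif(n, 0, cum[length(cum)])
      idx <- findInterval(s, cum, rightmost.closed = TRUE)
      idx <- pmin(idx, nrow(pts) - 1L)
      frac <- (s - cum[idx]) / seg[idx]
      pts[idx, , drop = FALSE] +
        (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE]) * frac
    },
    stop("unknown init sampler type: ", init$type))
}

#' Sample discrete Markov chains from a transition matrix
#'
#' A fixture generator for the Chapman-Kolmogorov test: i.i.d. chains from a
#' row-stochastic matrix \code{P}.
#'
#' @param P n x n row-stochastic matrix (rows sum to 1 within 1e-12).
#' @param nTraj,nSteps chain count and transition count per chain.
#' @param seed RNG seed.
#' @param init initial state distribution (default uniform).
#' @return list of integer state sequences (length \code{nSteps + 1}).
#' @export
makeMarkovFixture <- function(P, nTraj, nSteps, seed = NULL, init = NULL) {
  if (!is.matrix(P) || nrow(P) != ncol(P) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-12))
    stop("validation error: P must be row-stochastic (tol 1e-12)")
  n <- nrow(P)
  if (is.null(init)) init <- rep(1 / n, n)
  cumP <- t(apply(P, 1L, cumsum))
  .withSeed(seed, {
    states <- matrix(0L, nTraj, nSteps + 1L)
    states[, 1L] <- findInterval(stats::runif(nTraj), cumsum(init)) + 1L
    for (step in seq_len(nSteps)) {
      u <- stats::runif(nTraj)
      cur <- states[, step]
      nxt <- integer(nTraj)
      for (s in unique(cur)) {
        idx <- which(cur == s)
        nxt[idx] <- findInterval(u[idx], cumP[s, ],
                                 rightmost.closed = TRUE) + 1L
      }
      states[, step + 1L] <- pmin(nxt, n)
    }
    lapply(seq_len(nTraj), function(i) states[i, ])
  })
}

#' Random orthonormal PCA model fixture
#'
#' @param D,d original and reduced dimensions (d <= D).
#' @param seed RNG seed.
#' @return a \linkS4class{PCAModel} with random mean and orthonormal
#'   loadings (deterministic for a fixed seed).
#' @export
makePCAFixture <- function(D, d, seed = NULL) {
  if (d > D) stop("d must not exceed D")
  .withSeed(seed, {
    qr_ <- qr(matrix(stats::rnorm(D * D), D, D))
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))), D)   # sign-fixed for determinism
    PCAModel(stats::rnorm(D), Q[, seq_len(d), drop = FALSE],
             paste0("f", seq_len(D)))
  })
}

#' Quarter-circle corridor trajectory fixture
#'
#' Trajectories progressing along a quarter-circle arc of given radius
#' (from (radius, 0) to (0, radius)) with additive isotropic Gaussian noise:
#' a curved-corridor ground truth for string-method recovery.
#'
#' @param radius arc radius.
#' @param sigma noise standard deviation.
#' @param nTraj,nFrames trajectory count and frames per trajectory.
#' @param dt frame interval (hours).
#' @param seed RNG seed.
#' @return a \linkS4class{TrajectoryEnsemble} (d = 2).
#' @export
makeArcEnsemble <- function(radius = 10, sigma = 0.5, nTraj = 100,
                            nFrames = 60, dt = 0.25, seed = NULL) {
  .withSeed(seed, {
    trajs <- lapply(seq_len(nTraj), function(i) {
      jit <- stats::runif(1, -0.02, 0.02)
      th <- seq(0 + jit, pi / 2 + jit, length.out = nFrames)
      xy <- cbind(radius * cos(th), radius * sin(th)) +
        matrix(stats::rnorm(2 * nFrames, sd = sigma), nFrames, 2L)
      FeatureTrajectory(sprintf("arc_%03d", i),
                        seq(0, by = dt, length.out = nFrames), xy)
    })
    TrajectoryEnsemble(trajs, featureNames = c("PC1", "PC2"),
                       conditionLabel = "arc")
  })
}
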
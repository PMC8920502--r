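# Per-cell drift samples along an RC: for every consecutive frame pair with
# X(t) in interior cell i, the sample is (s(X(t+dt)) - s_i)/dt, with s(X)
# the piecewise-constant arc coordinate of the containing Voronoi cell.
# Both reactive and non-reactive trajectories must feed these samples for
# unbiased noise averaging within each cell.
.driftSamples <- function(ensemble, rc) {
  if (rc@nExtra < 1L)
    stop("contract error: drift estimation requires an extrapolated RC ",
         "(see extrapolateString)")
  dt <- ensemble@frameInterval
  svals <- rc@arcPositions
  cells <- integer(); vals <- numeric()
  for (tr in ensemble@trajectories) {
    a <- voronoiAssign(rc, tr@coords)
    Tn <- length(a)
    if (Tn < 2L) next
    from <- a[-Tn]; to <- a[-1L]
    cells <- c(cells, from)
    vals <- c(vals, (svals[to] - svals[from]) / dt)
  }
  nImg <- nrow(rc@images)
  interior <- 2:(nImg - 1L)                 # ignore first and last cells
  keep <- cells %in% interior
  list(cells = cells[keep], vals = vals[keep], interior = interior,
       s = svals[interior], ds = mean(diff(svals)))
}

.perCell <- function(samples, fun) {
  f <- factor(samples$cells, levels = samples$interior)
  counts <- as.integer(table(f))
  vals <- tapply(samples$vals, f, fun)
  list(value = as.numeric(vals), counts = counts)
}

#' Quasi-potential gradient (drift) per Voronoi cell
#'
#' Within each interior Voronoi cell i of an extrapolated RC, the mean
#' drift speed is the average of (s(X(t+dt)) - s_i)/dt over all consecutive
#' frame pairs (from all trajectories, reactive or not) whose first frame
#' lies in the cell; the quasi-potential gradient is its negative, so
#' attractors are potential minima.  Cells with fewer than \code{minCount}
#' samples are masked (NA).
#'
#' @param ensemble all recorded trajectories (not only reactive ones).
#' @param rc an extrapolated \linkS4class{ReactionCoordinate}.
#' @param minCount minimum samples per cell (default 5).
#' @return numeric d(phi)/ds per interior cell, NA where masked, with
#'   attributes \code{"counts"} and \code{"s"}.
#' @export
estimateDrift <- function(ensemble, rc, minCount = 5L) {
  sm <- .driftSamples(ensemble, rc)
  pc <- .perCell(sm, function(v) -mean(v))
  out <- pc$value
  out[pc$counts < minCount] <- NA_real_
  if (all(is.na(out))) stop("estimation error: all cells masked")
  structure(out, counts = pc$counts, s = sm$s)
}

#' Diffusion coefficient per Voronoi cell
#'
#' Sample variance of the same per-cell drift speed samples,
#' D(s_i) = Var(ds/dt | s_i); masked under \code{minCount}.
#'
#' @inheritParams estimateDrift
#' @return numeric D per interior cell with attributes \code{"counts"} and
#'   \code{"s"}.
#' @export
estimateDiffusion <- function(ensemble, rc, minCount = 5L) {
  sm <- .driftSamples(ensemble, rc)
  pc <- .perCell(sm, function(v) if (length(v) >= 2L) stats::var(v) else 0)
  out <- pc$value
  out[pc$counts < minCount] <- NA_real_
  if (all(is.na(out))) stop("estimation error: all cells masked")
  structure(out, counts = pc$counts, s = sm$s)
}

#' Integrate a per-cell gradient into a quasi-potential
#'
#' Left-Riemann cumulative sum, phi(s0) = 0: the returned vector has one
#' more entry than \code{grad} (the reference point followed by the running
#' integral through each cell).  Masked interior cells are filled by linear
#' interpolation first (reported); leading/trailing masked cells truncate
#' the domain (attribute \code{"kept"} gives the retained cell indices).
#'
#' @param grad per-cell d(phi)/ds values (NA = masked).
#' @param ds uniform arc spacing.
#' @return numeric phi of length \code{length(kept) + 1}, phi[1] = 0.
#' @export
integratePotential <- function(grad, ds) {
  n <- length(grad)
  ok <- which(!is.na(grad))
  if (length(ok) == 0L) stop("no unmasked cells")
  kept <- ok[1L]:ok[length(ok)]
  g <- grad[kept]
  if (anyNA(g)) {
    message("masked interior cells filled by linear interpolation: ",
            paste(kept[is.na(g)], collapse = " "))
    g <- stats::approx(seq_along(g)[!is.na(g)], g[!is.na(g)],
                       xout = seq_along(g))$y
  }
  if (length(kept) < n)
    message("leading/trailing masked cells truncated: domain ",
            kept[1L], "..", kept[length(kept)], " of ", n)
  structure(c(0, cumsum(g) * ds), kept = kept)
}

#' Full quasi-potential estimate along a reaction coordinate
#'
#' Convenience wrapper running \code{\link{estimateDrift}},
#' \code{\link{estimateDiffusion}} and \code{\link{integratePotential}} on
#' the same ensemble and RC.
#'
#' @inheritParams estimateDrift
#' @return a \linkS4class{QuasiPotential}.
#' @export
estimateQuasiPotential <- function(ensemble, rc, minCount = 5L) {
  grad <- estimateDrift(ensemble, rc, minCount)
  D <- estimateDiffusion(ensemble, rc, minCount)
  s <- attr(grad, "s")
  ds <- mean(diff(s))
  phi <- integratePotential(as.numeric(grad), ds)
  kept <- attr(phi, "kept")
  gradK <- as.numeric(grad)[kept]
  maskK <- is.na(gradK)
  if (any(maskK))
    gradK <- stats::approx(which(!maskK), gradK[!maskK],
                           xout = seq_along(gradK))$y
  DK <- as.numeric(D)[kept]
  if (anyNA(DK) && any(!is.na(DK)))
    DK <- stats::approx(which(!is.na(DK)), DK[!is.na(DK)],
                        xout = seq_along(DK), rule = 2)$y
  new("QuasiPotential", sGrid = s[kept], grad = gradK,
      phi = phi[-1L] - phi[2L], D = DK,
      counts = attr(grad, "counts")[kept], masked = maskK)
}

#' Quasi-potential from a stationary density
#'
#' Boltzmann inversion of the occupancy of the RC's Voronoi cells by a
#' stationary sample (e.g. untreated control cells): phi0 = -log(p_ss),
#' offset so the minimum is 0.  A pseudocount keeps empty cells finite
#' while preserving the ordering.
#'
#' @param points n x d matrix of stationary sample points.
#' @param rc a \linkS4class{ReactionCoordinate}.
#' @param pseudocount added to each cell count (default 0.5).
#' @return numeric phi0 per image cell with attribute \code{"counts"}.
#' @export
potentialFromDensity <- function(points, rc, pseudocount = 0.5) {
  if (is.null(points) || nrow(points) == 0L) stop("empty sample")
  cell <- voronoiAssign(rc, points)
  counts <- tabulate(cell, nbins = nrow(rc@images))
  p <- (counts + pseudocount) / sum(counts + pseudocount)
  phi0 <- -log(p)
  structure(phi0 - min(phi0), counts = counts)
}

#' Chapman-Kolmogorov test on discrete state sequences
#'
#' Estimates the transition matrix at lag tau and at lag k*tau from
#' row-normalized lagged counts, and reports for each k the maximal
#' row-wise L1 distance between P(k*tau) and P(tau)^k over states with at
#' least \code{minPairs} lagged pairs at both lags.  Markovian dynamics
#' gives small deviations; k = 1 is exactly 0 by construction.
#'
#' @param chains list of integer state sequences.
#' @param tau base lag in frames (default 1).
#' @param ks lag multiples to test (default 2:5).
#' @param nStates number of states (default: maximum observed).
#' @param minPairs minimum lagged pairs for a state to enter the max
#'   (default 1).
#' @return a \linkS4class{CKTestResult}.
#' @export
ckTestDiscrete <- function(chains, tau = 1L, ks = 2:5, nStates = NULL,
                           minPairs = 1L) {
  if (is.null(nStates)) nStates <- max(unlist(chains))
  countsAt <- function(lag) {
    enc <- unlist(lapply(chains, function(ch) {
      Tn <- length(ch)
      if (Tn <= lag) return(integer(0))
      (ch[seq_len(Tn - lag)] - 1L) * nStates + ch[seq_len(Tn - lag) + lag]
    }), use.names = FALSE)
    matrix(tabulate(enc, nbins = nStates * nStates), nStates, nStates,
           byrow = TRUE)
  }
  normalize <- function(C) {
    rs <- rowSums(C)
    list(P = C / ifelse(rs == 0, 1, rs), n = rs)
  }
  base <- normalize(countsAt(tau))
  ks <- sort(unique(as.integer(ks)))
  allk <- c(1L, ks[ks > 1L])
  perState <- matrix(NA_real_, nStates, length(allk),
                     dimnames = list(NULL, paste0("k", allk)))
  devs <- numeric(length(allk))
  Pk <- diag(nStates)
  kPrev <- 0L
  for (qi in seq_along(allk)) {
    k <- allk[qi]
    while (kPrev < k) { Pk <- Pk %*% base$P; kPrev <- kPrev + 1L }
    emp <- normalize(countsAt(k * tau))
    rowDev <- rowSums(abs(emp$P - Pk))
    rowDev[base$n < minPairs | emp$n < minPairs] <- NA_real_
    perState[, qi] <- rowDev
    devs[qi] <- if (all(is.na(rowDev))) NA_real_ else max(rowDev, na.rm = TRUE)
  }
  devs[allk == 1L] <- 0                     # identical estimator at k = 1
  new("CKTestResult", tau = as.integer(tau), ks = allk, deviations = devs,
      perState = perState, nStates = as.integer(nStates))
}

#' Chapman-Kolmogorov test along a reaction coordinate
#'
#' Frames are discretized into the RC's Voronoi cells and the CK test is
#' run on the resulting state sequences.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param rc a \linkS4class{ReactionCoordinate}.
#' @inheritParams ckTestDiscrete
#' @return a \linkS4class{CKTestResult}.
#' @export
ckTest <- function(ensemble, rc, tau = 1L, ks = 2:5, minPairs = 1L) {
  chains <- lapply(ensemble@trajectories,
                   function(tr) voronoiAssign(rc, tr@coords))
  ckTestDiscrete(chains, tau = tau, ks = ks, nStates = nrow(rc@images),
                 minPairs = minPairs)
}

#' Solve the 1-D Fokker-Planck equation to its stationary state
#'
#' Conservative finite-volume discretization of
#' \deqn{\partial_t\rho = \nabla\cdot[D(\nabla - F/k_BT)\rho]},
#' with F = -d(phi)/ds, spatially varying D, no-flux boundaries, and
#' Scharfetter-Gummel face fluxes (whose discrete stationary state is the
#' Boltzmann distribution exp(-phi/kBT) independent of D).  Implicit Euler
#' time stepping with growing steps; mass is conserved to solver roundoff.
#'
#' @param phi quasi-potential values on \code{sGrid}.
#' @param D diffusion coefficients on \code{sGrid} (all positive), or a
#'   scalar.
#' @param sGrid arc positions where phi/D are given.
#' @param kBT pseudo-temperature (default 1/2).
#' @param gridN solver grid cells (default 200).
#' @param tEnd time horizon (default Inf: run to stationarity).
#' @param rho0 initial density on the solver grid (default uniform).
#' @param tolSS stationarity tolerance on ||d rho/dt||_1 (default 1e-8).
#' @return an \linkS4class{FPSolution}.
#' @export
solveFokkerPlanck <- function(phi, D, sGrid, kBT = 0.5, gridN = 200L,
                              tEnd = Inf, rho0 = NULL, tolSS = 1e-8) {
  if (any(D <= 0)) stop("D must be positive everywhere")
  if (kBT <= 0) stop("kBT must be positive")
  rng <- range(sGrid)
  h <- diff(rng) / gridN
  centers <- rng[1L] + (seq_len(gridN) - 0.5) * h
  phiG <- stats::spline(sGrid, phi, xout = centers)$y
  DG <- if (length(D) == 1L) rep(D, gridN)
        else stats::approx(sGrid, D, xout = centers, rule = 2)$y
  if (any(DG <= 0)) stop("interpolated D must stay positive")
  # face quantities (between cells i and i+1)
  Df <- 0.5 * (DG[-gridN] + DG[-1L])
  v <- -(phiG[-1L] - phiG[-gridN]) / kBT     # drift number across the face
  bern <- function(x) ifelse(abs(x) < 1e-10, 1 - x / 2, x / (exp(x) - 1))
  # J_{i+1/2} = (Df/h) * (B(-v) rho_i - B(v) rho_{i+1})
  aUp <- Df / h * bern(-v)                   # coefficient on rho_i
  aDn <- Df / h * bern(v)                    # coefficient on rho_{i+1}
  # d rho_i/dt = (J_{i-1/2} - J_{i+1/2}) / h
  main <- numeric(gridN); lower <- numeric(gridN - 1L); upper <- lower
  main[1L] <- -aUp[1L] / h
  upper[1L] <- aDn[1L] / h
  for (i in 2:(gridN - 1L)) {
    lower[i - 1L] <- aUp[i - 1L] / h
    main[i] <- -(aDn[i - 1L] + aUp[i]) / h
    upper[i] <- aDn[i] / h
  }
  lower[gridN - 1L] <- aUp[gridN - 1L] / h
  main[gridN] <- -aDn[gridN - 1L] / h
  A <- matrix(0, gridN, gridN)
  diag(A) <- main
  A[cbind(2:gridN, 1:(gridN - 1L))] <- lower
  A[cbind(1:(gridN - 1L), 2:gridN)] <- upper

  rho <- if (is.null(rho0)) rep(1 / (gridN * h), gridN) else rho0
  rho <- rho / (sum(rho) * h)
  snapshots <- list(rho); times <- 0
  t <- 0; dt <- 0.1 * h^2 / max(DG) * 100    # start gently, grow fast
  converged <- FALSE
  maxSteps <- 400L
  for (step in seq_len(maxSteps)) {
    if (t >= tEnd) break
    M <- diag(gridN) - dt * A
    rhoNew <- solve(M, rho)
    t <- t + dt
    change <- sum(abs(A %*% rhoNew))
    rho <- rhoNew
    if (step %% 20L == 0L || change < tolSS) {
      snapshots <- c(snapshots, list(rho)); times <- c(times, t)
    }
    if (change < tolSS) { converged <- TRUE; break }
    dt <- min(dt * 1.4, 1e6)
  }
  rhoSS <- rho / (sum(rho) * h)
  fluxSS <- aUp * rhoSS[-gridN] - aDn * rhoSS[-1L]
  new("FPSolution", grid = centers, times = times,
      rho = do.call(rbind, snapshots), rhoSS = rhoSS, flux = fluxSS,
      converged = converged, kBT = kBT)
}

#' Moments of the stationary Fokker-Planck distribution
#'
#' @param sol a converged \linkS4class{FPSolution}.
#' @return c(mean, sd) of s under the stationary density (grid quadrature).
#' @export
stationaryStats <- function(sol) {
  if (!sol@converged)
    stop("contract error: Fokker-Planck solution did not reach stationarity")
  h <- diff(sol@grid[1:2])
  w <- sol@rhoSS * h
  w <- w / sum(w)
  m <- sum(sol@grid * w)
  c(mean = m, sd = sqrt(sum((sol@grid - m)^2 * w)))
}

#' Export a quasi-potential as a tidy table
#'
#' @param qp a \linkS4class{QuasiPotential}.
#' @return data.frame(s, grad, phi, D, counts, masked).
#' @export
quasiPotentialTable <- function(qp) {
  data.frame(s = qp@sGrid, grad = qp@grad, phi = qp@phi, D = qp@D,
             counts = qp@counts, masked = qp@masked)
}
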
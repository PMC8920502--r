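#' Construct a RegionSpec
#'
#' Closed balls define the epithelial (E) and mesenchymal (M) regions; the
#' intermediate region (I) is the complement of their union.
#'
#' @param eCenter,mCenter d-vectors.
#' @param eRadius,mRadius positive radii.
#' @return a \linkS4class{RegionSpec}.
#' @export
RegionSpec <- function(eCenter, mCenter, eRadius, mRadius) {
  new("RegionSpec", eCenter = as.numeric(eCenter),
      mCenter = as.numeric(mCenter),
      eRadius = as.numeric(eRadius), mRadius = as.numeric(mRadius))
}

#' Estimate E/M regions from reference samples
#'
#' Centers are the means of the two reference point sets (e.g. pre-treatment
#' cells for E, late-time cells for M); each radius is the given quantile of
#' the distances of the reference points to their center, so by default 90\%
#' of the reference cells fall inside their region.
#'
#' @param ePoints,mPoints matrices of reference points (rows).
#' @param quantile coverage quantile for the radii.
#' @return a \linkS4class{RegionSpec}.
#' @export
estimateRegions <- function(ePoints, mPoints, quantile = 0.9) {
  ec <- colMeans(ePoints); mc <- colMeans(mPoints)
  er <- stats::quantile(sqrt(rowSums(sweep(ePoints, 2L, ec)^2)), quantile,
                        names = FALSE)
  mr <- stats::quantile(sqrt(rowSums(sweep(mPoints, 2L, mc)^2)), quantile,
                        names = FALSE)
  RegionSpec(ec, mc, er, mr)
}

#' Region label of state-space points
#'
#' A point belongs to E if it lies within (or exactly on) the closed E ball,
#' to M likewise, and to I otherwise.
#'
#' @param x a d-vector (\code{assignRegion}) or an n x d matrix
#'   (\code{labelRegions}).
#' @param regions a \linkS4class{RegionSpec}.
#' @return \code{"E"}, \code{"I"} or \code{"M"} (vector for
#'   \code{labelRegions}).
#' @export
assignRegion <- function(x, regions) {
  if (length(x) != length(regions@eCenter)) stop("dimension mismatch")
  labelRegions(matrix(x, nrow = 1L), regions)
}

#' @rdname assignRegion
#' @export
labelRegions <- function(x, regions) {
  if (ncol(x) != length(regions@eCenter)) stop("dimension mismatch")
  dE <- sqrt(rowSums(sweep(x, 2L, regions@eCenter)^2))
  dM <- sqrt(rowSums(sweep(x, 2L, regions@mCenter)^2))
  out <- rep("I", nrow(x))
  out[dE <= regions@eRadius] <- "E"
  out[dM <= regions@mRadius] <- "M"
  out
}

#' Extract the reactive-trajectory ensemble
#'
#' Keeps trajectories that start in the E region and first enter the M
#' region no later than \code{deadline} hours after their first frame; the
#' frame of first M entry and the final E exit preceding it are recorded.
#' This is the practical single-recording definition of a reactive
#' trajectory (one observed pass), not the infinite-trajectory segment
#' definition of classical transition path theory.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param regions a \linkS4class{RegionSpec}.
#' @param deadline hours from the first frame (default 48, "by day 2").
#' @return a \linkS4class{ReactiveEnsemble} (possibly with zero members, in
#'   which case an error is raised by the ensemble contract -- an empty
#'   reactive set returns \code{NULL} with a warning instead).
#' @export
extractReactive <- function(ensemble, regions, deadline = 48) {
  keep <- list(); eExit <- integer(); mEntry <- integer()
  for (tr in ensemble@trajectories) {
    lab <- labelRegions(tr@coords, regions)
    if (lab[1L] != "E") next
    elapsed <- tr@times - tr@times[1L]
    hit <- which(lab == "M" & elapsed <= deadline)
    if (length(hit) == 0L) next
    m1 <- hit[1L]
    ee <- which(lab[seq_len(m1 - 1L)] == "E")
    if (length(ee) == 0L) next            # must depart from E (starts there)
    keep[[length(keep) + 1L]] <- tr
    eExit <- c(eExit, ee[length(ee)])
    mEntry <- c(mEntry, m1)
  }
  if (length(keep) == 0L) {
    warning("no reactive trajectories found")
    return(NULL)
  }
  new("ReactiveEnsemble", trajectories = keep,
      featureNames = ensemble@featureNames,
      frameInterval = ensemble@frameInterval,
      conditionLabel = ensemble@conditionLabel,
      regions = regions, eExit = eExit, mEntry = mEntry,
      deadline = deadline)
}

#' Gaussian kernel density estimate on a regular grid
#'
#' Product-Gaussian KDE evaluated on the tensor grid spanned by the axis
#' vectors; with a grid covering the support, the returned values integrate
#' to 1 within about 1\%.
#'
#' @param points n x d matrix of sample points (n >= 2).
#' @param grid list of d axis vectors (regularly spaced).
#' @param bandwidth kernel standard deviation, scalar or per-dimension; must
#'   be positive.
#' @return array of density values with dim = lengths of the axes (a matrix
#'   for d = 2, a vector for d = 1).
#' @export
kernelDensity <- function(points, grid, bandwidth) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 1L)
  if (nrow(points) < 2L) stop("need at least 2 points")
  d <- ncol(points)
  if (!is.list(grid)) grid <- list(grid)
  if (length(grid) != d) stop("grid must have one axis per dimension")
  bw <- rep_len(bandwidth, d)
  if (any(bw <= 0)) stop("bandwidth must be positive")
  # per-axis kernel matrices: eval x sample
  K <- lapply(seq_len(d), function(j)
    outer(grid[[j]], points[, j],
          function(g, p) stats::dnorm(g, p, bw[j])))
  if (d == 1L) return(rowMeans(K[[1L]]))
  if (d == 2L) return(K[[1L]] %*% t(K[[2L]]) / nrow(points))
  # general tensor accumulation
  dims <- vapply(grid, length, integer(1))
  out <- array(0, dims)
  for (i in seq_len(nrow(points))) {
    contrib <- K[[1L]][, i]
    for (j in 2:d) contrib <- outer(contrib, K[[j]][, i])
    out <- out + contrib
  }
  out / nrow(points)
}

.binIndex <- function(v, lo, hi, nBins) {
  # half-open bins [lo, hi) except the last bin closed
  idx <- floor((v - lo) / (hi - lo) * nBins) + 1L
  idx[v == hi] <- nBins
  idx[idx < 1L | idx > nBins] <- NA_integer_
  idx
}

.gaussianKernel1D <- function(sigma, truncate) {
  r <- floor(truncate * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

.gaussianFilter2D <- function(mat, sigma, truncate) {
  k <- .gaussianKernel1D(sigma, truncate)
  r <- (length(k) - 1L) / 2L
  pad <- function(m, n) rbind(matrix(0, n, ncol(m)), m, matrix(0, n, ncol(m)))
  conv1 <- function(m) {      # filter down columns
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[seq_len(nrow(m)) + (i - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(mat))))
}

#' Density map of reactive trajectories in a feature plane
#'
#' The plane spanned by two feature axes is divided into
#' \code{nBins x nBins} grid cells; for each reactive trajectory, only its
#' intermediate-region frames before first M entry are considered, and each
#' grid cell visited by the trajectory contributes exactly 1 regardless of
#' how many times it is crossed.  The count matrix is then smoothed with a
#' Gaussian filter (standard deviation \code{sigma} grid cells, truncated at
#' \code{truncate} standard deviations).
#'
#' @param reactive a \linkS4class{ReactiveEnsemble}.
#' @param axes integer(2), feature indices of the plane.
#' @param nBins grid cells per axis.
#' @param sigma,truncate Gaussian filter parameters (grid-cell units).
#' @param bounds optional 2 x 2 matrix (rows lo/hi, columns the two axes);
#'   default: data range per axis expanded by 5\%.
#' @return a \linkS4class{DensityMap}; slot \code{raw} holds the
#'   pre-smoothing counts.
#' @export
reactiveDensityMap <- function(reactive, axes = c(1L, 2L), nBins = 200L,
                               sigma = 2, truncate = 2, bounds = NULL) {
  if (is.null(reactive) || length(reactive@trajectories) == 0L)
    stop("non-empty reactive ensemble required")
  d <- length(reactive@featureNames)
  if (any(axes < 1L | axes > d)) stop("axes out of range")
  allpts <- do.call(rbind, lapply(reactive@trajectories,
                                  function(tr) tr@coords[, axes, drop = FALSE]))
  if (is.null(bounds)) {
    rng <- apply(allpts, 2L, range)
    span <- rng[2L, ] - rng[1L, ]
    bounds <- rbind(rng[1L, ] - 0.05 * span, rng[2L, ] + 0.05 * span)
  }
  counts <- matrix(0, nBins, nBins)
  for (ti in seq_along(reactive@trajectories)) {
    tr <- reactive@trajectories[[ti]]
    lab <- labelRegions(tr@coords, reactive@regions)
    m1 <- reactive@mEntry[ti]
    use <- which(lab == "I" & seq_along(lab) < m1)
    if (length(use) == 0L) next
    xy <- tr@coords[use, axes, drop = FALSE]
    i1 <- .binIndex(xy[, 1L], bounds[1L, 1L], bounds[2L, 1L], nBins)
    i2 <- .binIndex(xy[, 2L], bounds[1L, 2L], bounds[2L, 2L], nBins)
    ok <- !is.na(i1) & !is.na(i2)
    cells <- unique((i1[ok] - 1L) * nBins + i2[ok])   # binary per trajectory
    counts[cbind((cells - 1L) %/% nBins + 1L, (cells - 1L) %% nBins + 1L)] <-
      counts[cbind((cells - 1L) %/% nBins + 1L, (cells - 1L) %% nBins + 1L)] + 1
  }
  sm <- .gaussianFilter2D(counts, sigma, truncate)
  new("DensityMap", axes = as.integer(axes), bounds = bounds, values = sm,
      raw = counts, smoothing = list(sigma = sigma, truncate = truncate))
}

#' Count distinct corridors of a density map at half maximum
#'
#' A transition corridor appears in the reactive density map as an
#' elongated high-density band whose height varies along its length; bands
#' belonging to different corridors are separated by a deep density valley.
#' Corridors are therefore counted as connected components (8-neighborhood)
#' of the super-level set at \code{level} of the global maximum (the
#' full-width-at-half-maximum convention), ignoring components smaller than
#' \code{minCells} cells.
#'
#' Corridors that run between the same two attractors merge near the
#' attractor regions; to count them where they are geometrically distinct,
#' supply \code{window}, a logical matrix restricting the analysis to (for
#' example) the mid-transition band, and the threshold is then taken
#' relative to the maximum inside the window.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param level threshold as a fraction of the (windowed) maximum
#'   (default 0.5).
#' @param minCells minimum component area in grid cells (default 20).
#' @param window optional logical matrix of the map's shape.
#' @return integer count of corridors; attribute \code{"sizes"} gives the
#'   component sizes.
#' @export
densityModes <- function(map, level = 0.5, minCells = 20L, window = NULL) {
  v <- map@values
  if (!is.null(window)) v <- ifelse(window, v, 0)
  mask <- v > level * max(v)
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (st in which(mask)) {
    if (lab[st] != 0L) next
    cur <- cur + 1L
    stack <- st
    while (length(stack)) {
      c0 <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[c0] != 0L) next
      lab[c0] <- cur
      i <- (c0 - 1L) %% nr + 1L
      j <- (c0 - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
          cc <- (jj - 1L) * nr + ii
          if (mask[cc] && lab[cc] == 0L) stack <- c(stack, cc)
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0L], nbins = cur)
  structure(sum(sizes >= minCells), sizes = sizes)
}

#' Ridge maxima of a density map
#'
#' Counts the distinct density ridges by topographic prominence: cells are
#' flooded from the highest down with union-find merging of connected
#' components (8-neighborhood); when a component headed by a lower peak
#' merges into one headed by a higher peak, the lower peak's prominence is
#' its height above the merge level.  A peak counts as a ridge maximum when
#' its prominence is at least \code{minProminence} of the global maximum,
#' so speckle along a single ridge crest is not over-counted while genuinely
#' separate corridors are.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param minProminence prominence floor as a fraction of the global
#'   maximum (default 0.2).
#' @return data.frame(row, col, value, prominence, x, y) of ridge maxima,
#'   ordered by decreasing height; x/y are bin-center coordinates.
#' @export
densityRidges <- function(map, minProminence = 0.2) {
  v <- map@values
  nr <- nrow(v); nc <- ncol(v)
  n <- nr * nc
  ord <- order(v, decreasing = TRUE)
  ord <- ord[v[ord] > 0]
  parent <- integer(n)                    # 0 = unassigned; union-find forest
  rootPeak <- integer(n)                  # root cell -> its peak cell
  promOf <- rep(NA_real_, n)              # peak cell -> prominence at death
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  nbrOff <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (cell in ord) {
    i <- (cell - 1L) %% nr + 1L
    j <- (cell - 1L) %/% nr + 1L
    ok <- rep(TRUE, 8L)
    if (i == 1L) ok[c(1L, 5L, 7L)] <- FALSE
    if (i == nr) ok[c(2L, 6L, 8L)] <- FALSE
    if (j == 1L) ok[c(3L, 5L, 6L)] <- FALSE
    if (j == nc) ok[c(4L, 7L, 8L)] <- FALSE
    nb <- (cell + nbrOff)[ok]
    nb <- nb[parent[nb] != 0L]
    if (length(nb) == 0L) {               # a fresh local peak
      parent[cell] <- cell
      rootPeak[cell] <- cell
      next
    }
    roots <- unique(vapply(nb, find, integer(1)))
    win <- roots[which.max(v[rootPeak[roots]])]
    parent[cell] <- win
    for (r in setdiff(roots, win)) {      # lower peak dies at this level
      promOf[rootPeak[r]] <- v[rootPeak[r]] - v[cell]
      parent[r] <- win
    }
  }
  alive <- which(parent == seq_len(n) & parent != 0L)
  promOf[rootPeak[alive]] <- v[rootPeak[alive]]   # surviving peaks
  peaks <- which(!is.na(promOf) & promOf >= minProminence * max(v))
  row <- (peaks - 1L) %% nr + 1L
  col <- (peaks - 1L) %/% nr + 1L
  ctr <- function(i, j) map@bounds[1L, j] +
    (i - 0.5) / nr * (map@bounds[2L, j] - map@bounds[1L, j])
  out <- data.frame(row = row, col = col, value = v[peaks],
                    prominence = promOf[peaks],
                    x = ctr(row, 1L), y = ctr(col, 2L))
  out[order(-out$value), , drop = FALSE]
}
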
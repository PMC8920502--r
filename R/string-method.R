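#' Initialize a reaction coordinate between the E and M means
#'
#' The string's anchors are the means of the ensemble's data points lying in
#' the epithelial and mesenchymal regions; the initial guess is N images
#' uniformly spaced on the straight segment between them.  The anchors stay
#' fixed through all subsequent string iterations.
#'
#' @param reactive a \linkS4class{ReactiveEnsemble} (or ensemble whose
#'   points cover both regions).
#' @param regions a \linkS4class{RegionSpec}.
#' @param N number of images (default 30; at least 4 for optimization).
#' @return a \linkS4class{ReactionCoordinate}.
#' @export
initializeString <- function(reactive, regions, N = 30L) {
  pts <- ensemblePoints(reactive)$points
  lab <- labelRegions(pts, regions)
  if (!any(lab == "E") || !any(lab == "M"))
    stop("configuration error: a region contains no data points")
  a <- unname(colMeans(pts[lab == "E", , drop = FALSE]))
  b <- unname(colMeans(pts[lab == "M", , drop = FALSE]))
  tt <- seq(0, 1, length.out = N)
  images <- outer(1 - tt, a) + outer(tt, b)
  anchors <- rbind(a, b)
  dimnames(anchors) <- NULL
  new("ReactionCoordinate", images = images,
      arcPositions = tt * sqrt(sum((b - a)^2)),
      anchors = anchors, nExtra = 0L,
      converged = FALSE, iterations = 0L)
}

#' Voronoi assignment of points to string images
#'
#' @param rc a \linkS4class{ReactionCoordinate}.
#' @param points n x d matrix.
#' @return integer image index per point (nearest image, Euclidean; ties to
#'   the lower index).
#' @export
voronoiAssign <- function(rc, points) {
  if (!is.matrix(points)) points <- matrix(points, ncol = ncol(rc@images))
  bmu_cpp(points, rc@images)
}

#' Arc coordinate of points under a reaction coordinate
#'
#' Piecewise-constant mapping: s(X) is the arc position of the Voronoi cell
#' containing X.
#'
#' @param rc a \linkS4class{ReactionCoordinate}.
#' @param points n x d matrix.
#' @return list(cell = image index, s = arc position).
#' @export
projectOntoRC <- function(rc, points) {
  cell <- voronoiAssign(rc, points)
  list(cell = cell, s = rc@arcPositions[cell])
}

#' Weighted average positions of the string update
#'
#' For each image k the average position combines the Voronoi-cell term and
#' the per-trajectory closest-point term,
#' \eqn{\bar X(s_k) = (T_1(k) + w\,T_2(k)) / (1 + w)}:
#' \eqn{T_1(k)} is the mean of all ensemble points assigned to cell k, and
#' \eqn{T_2(k)} the mean over trajectories of each trajectory's closest
#' point to image k (one point per trajectory; with \code{perVisit = TRUE},
#' one per contiguous visit of the trajectory to cell k's neighborhood).
#' Empty cells fall back to the trajectory term alone.
#'
#' @param rc a \linkS4class{ReactionCoordinate}.
#' @param reactive the driving ensemble.
#' @param w weight of the trajectory term (default 10).
#' @param perVisit alternative per-visit averaging of the trajectory term.
#' @return N x d matrix of average positions; attribute \code{"emptyCells"}
#'   lists cells with no assigned points.
#' @export
stringAveragePositions <- function(rc, reactive, w = 10, perVisit = FALSE) {
  N <- nrow(rc@images)
  pts <- ensemblePoints(reactive)$points
  if (!nrow(pts)) stop("optimization error: no data points")
  cell <- voronoiAssign(rc, pts)
  mats <- lapply(reactive@trajectories, coords)
  d <- ncol(pts)
  imgSq <- rowSums(rc@images^2)
  term2sum <- matrix(0, N, d)
  term2n <- rep(0L, N)
  for (X in mats) {
    D2 <- outer(rowSums(X^2), imgSq, `+`) - 2 * X %*% t(rc@images)
    if (!perVisit) {
      idx <- apply(D2, 2L, which.min)
      term2sum <- term2sum + X[idx, , drop = FALSE]
      term2n <- term2n + 1L
    } else {
      a <- voronoiAssign(rc, X)
      runs <- .maximalRuns(a)
      for (r in seq_len(nrow(runs))) {
        k <- runs$rc[r]
        span <- runs$start[r]:runs$end[r]
        best <- span[which.min(D2[span, k])]
        term2sum[k, ] <- term2sum[k, ] + X[best, ]
        term2n[k] <- term2n[k] + 1L
      }
    }
  }
  term2 <- term2sum / ifelse(term2n == 0L, 1L, term2n)
  cellSum <- matrix(0, N, d)
  tmp <- rowsum(pts, cell)
  cellSum[as.integer(rownames(tmp)), ] <- tmp
  cellN <- tabulate(cell, nbins = N)
  emptyCells <- which(cellN == 0L | term2n == 0L)
  term1 <- cellSum / ifelse(cellN == 0L, 1L, cellN)
  xbar <- (term1 + w * term2) / (1 + w)
  xbar[cellN == 0L, ] <- term2[cellN == 0L, , drop = FALSE]
  if (length(emptyCells) == N)
    stop("optimization error: all Voronoi cells empty")
  if (length(emptyCells))
    message("empty Voronoi cells (trajectory-term fallback): ",
            paste(emptyCells, collapse = " "))
  dimnames(xbar) <- NULL
  xbar
}

#' Straight reaction coordinate between two points
#'
#' A fixed linear RC (no optimization): N images uniformly spaced on the
#' segment, e.g. for projecting data onto a prescribed axis or as ground
#' truth in tests.
#'
#' @param from,to d-vectors.
#' @param N number of images.
#' @return a \linkS4class{ReactionCoordinate}.
#' @export
straightRC <- function(from, to, N = 30L) {
  tt <- seq(0, 1, length.out = N)
  images <- outer(1 - tt, as.numeric(from)) + outer(tt, as.numeric(to))
  new("ReactionCoordinate", images = images,
      arcPositions = tt * sqrt(sum((to - from)^2)),
      anchors = rbind(as.numeric(from), as.numeric(to)),
      nExtra = 0L, converged = TRUE, iterations = 0L)
}

#' Reaction coordinate along a prescribed polyline
#'
#' Resamples a dense polyline (e.g. a known channel centerline) into N
#' images uniformly spaced in arc length, as a fixed RC.
#'
#' @param polyline m x d matrix of points along the curve.
#' @param N number of images.
#' @return a \linkS4class{ReactionCoordinate}.
#' @export
polylineRC <- function(polyline, N = 30L) {
  seg <- sqrt(rowSums(diff(polyline)^2))
  arc <- c(0, cumsum(seg))
  starget <- seq(0, arc[length(arc)], length.out = N)
  idx <- pmin(pmax(findInterval(starget, arc, rightmost.closed = TRUE), 1L),
              nrow(polyline) - 1L)
  frac <- ifelse(seg[idx] > 0, (starget - arc[idx]) / seg[idx], 0)
  img <- polyline[idx, , drop = FALSE] +
    (polyline[idx + 1L, , drop = FALSE] - polyline[idx, , drop = FALSE]) *
      frac
  new("ReactionCoordinate", images = img, arcPositions = starget,
      anchors = img[c(1L, N), , drop = FALSE], nExtra = 0L,
      converged = TRUE, iterations = 0L)
}

# Fit per-dimension smoothing splines through the average positions with a
# shared residual budget (sum of squared residuals over all dimensions <=
# budget), then resample N images uniformly in arc length along the smooth
# curve.  The largest smoothing (spar) within budget is used, found by
# bisection; spar -> small approaches interpolation, so the budget is
# always attainable.
.smoothResampleString <- function(xbar, N, budget, dense = 1000L) {
  tt <- c(0, cumsum(sqrt(rowSums(diff(xbar)^2))))
  if (tt[length(tt)] == 0) stop("optimization error: degenerate string")
  tt <- tt / tt[length(tt)]
  d <- ncol(xbar)
  fitAll <- function(spar) {
    fits <- lapply(seq_len(d), function(j)
      stats::smooth.spline(tt, xbar[, j], spar = spar, all.knots = TRUE,
                           keep.data = FALSE))
    ssr <- sum(vapply(seq_len(d), function(j)
      sum((stats::predict(fits[[j]], tt)$y - xbar[, j])^2), numeric(1)))
    list(fits = fits, ssr = ssr)
  }
  lo <- -1.5; hi <- 1.5
  best <- fitAll(lo)
  if (best$ssr <= budget) {
    for (it in seq_len(30L)) {
      mid <- (lo + hi) / 2
      f <- fitAll(mid)
      if (f$ssr <= budget) { lo <- mid; best <- f } else hi <- mid
      if (hi - lo < 1e-3) break
    }
  }
  tf <- seq(0, 1, length.out = dense)
  curve <- vapply(best$fits, function(f) stats::predict(f, tf)$y,
                  numeric(dense))
  arc <- c(0, cumsum(sqrt(rowSums(diff(curve)^2))))
  starget <- seq(0, arc[length(arc)], length.out = N)
  idx <- findInterval(starget, arc, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), dense - 1L)
  seg <- arc[idx + 1L] - arc[idx]
  frac <- ifelse(seg > 0, (starget - arc[idx]) / seg, 0)
  curve[idx, , drop = FALSE] +
    (curve[idx + 1L, , drop = FALSE] - curve[idx, , drop = FALSE]) * frac
}

#' One revised string-method update
#'
#' For each interior image k the new average position is
#' \deqn{\bar X(s_k) = \frac{T_1(k) + w\,T_2(k)}{1 + w}}
#' where \eqn{T_1(k)} is the mean of all data points assigned to image k's
#' Voronoi cell, and \eqn{T_2(k)} is the mean over trajectories of each
#' trajectory's single closest point to \eqn{X(s_k)} (so each trajectory as
#' a whole is pulled toward the string).  A smoothing cubic spline with
#' total squared residual capped at \code{smooth} is then fit through the
#' averages and N images are resampled uniformly in arc length; the anchors
#' are restored exactly.
#'
#' Empty Voronoi cells fall back to the trajectory term alone (reported via
#' a message); if every cell is empty the update fails.
#'
#' @param rc current \linkS4class{ReactionCoordinate} (un-extrapolated).
#' @param reactive the reactive ensemble driving the optimization.
#' @param w weight of the per-trajectory closest-point term (default 10).
#' @param smooth residual budget of the smoothing spline (default 1).
#' @param perVisit if TRUE, the trajectory term averages one closest point
#'   per trajectory visit to the cell's neighborhood instead of one per
#'   trajectory (alternative reading; default FALSE).
#' @return the updated \linkS4class{ReactionCoordinate}.
#' @export
updateString <- function(rc, reactive, w = 10, smooth = 1,
                         perVisit = FALSE) {
  N <- nrow(rc@images)
  if (N < 4L) stop("minimum N (4) enforced for string optimization")
  xbar <- stringAveragePositions(rc, reactive, w = w, perVisit = perVisit)
  xbar[1L, ] <- rc@anchors[1L, ]
  xbar[N, ] <- rc@anchors[2L, ]
  img <- .smoothResampleString(xbar, N, smooth)
  img[1L, ] <- rc@anchors[1L, ]
  img[N, ] <- rc@anchors[2L, ]
  seg <- sqrt(rowSums(diff(img)^2))
  new("ReactionCoordinate", images = img,
      arcPositions = c(0, cumsum(seg)), anchors = rc@anchors,
      nExtra = 0L, converged = FALSE, iterations = rc@iterations + 1L)
}

#' Iterate the string method to convergence
#'
#' Repeats Voronoi assignment and string update until the assignment of
#' data points to Voronoi cells no longer changes between successive
#' iterations.  Oscillating assignments (cycles of period up to 4) are
#' detected and the last iterate returned flagged non-converged, as is the
#' \code{maxIter} limit.
#'
#' @param rc0 initialized \linkS4class{ReactionCoordinate}.
#' @param reactive the reactive ensemble.
#' @param w,smooth see \code{\link{updateString}}.
#' @param maxIter iteration cap (default 100).
#' @return a \linkS4class{ReactionCoordinate} with \code{converged} and
#'   \code{iterations} filled in.
#' @export
convergeString <- function(rc0, reactive, w = 10, smooth = 1,
                           maxIter = 100L) {
  pts <- ensemblePoints(reactive)$points
  rc <- rc0
  prevAssign <- voronoiAssign(rc, pts)
  history <- list(prevAssign)
  if (maxIter == 0L) {
    rc@converged <- FALSE
    return(rc)
  }
  for (it in seq_len(maxIter)) {
    rc <- updateString(rc, reactive, w = w, smooth = smooth)
    a <- voronoiAssign(rc, pts)
    if (identical(a, prevAssign)) {
      rc@converged <- TRUE
      rc@iterations <- it
      return(rc)
    }
    if (any(vapply(utils::head(history, -1L), identical, logical(1), a))) {
      message("oscillating Voronoi assignments (cycle detected); ",
              "returning last iterate")
      rc@converged <- FALSE
      rc@iterations <- it
      return(rc)
    }
    history <- c(utils::tail(history, 4L), list(a))
    prevAssign <- a
  }
  message("string did not converge within ", maxIter, " iterations")
  rc@converged <- FALSE
  rc@iterations <- maxIter
  rc
}

#' Extrapolate a converged string beyond its ends
#'
#' Appends \code{nExtra} images beyond each end along the terminal segment
#' directions, spaced by the string's uniform image spacing, and extends the
#' arc positions accordingly (the extrapolated images are uniformly spaced
#' along s exactly as the interior ones).
#'
#' @param rc a converged \linkS4class{ReactionCoordinate}.
#' @param nExtra images appended per end (default 3).
#' @return the extended \linkS4class{ReactionCoordinate}.
#' @export
extrapolateString <- function(rc, nExtra = 3L) {
  if (nExtra == 0L) return(rc)
  img <- rc@images
  N <- nrow(img)
  ds <- mean(diff(rc@arcPositions))
  dir1 <- (img[1L, ] - img[2L, ])
  dir1 <- dir1 / sqrt(sum(dir1^2))
  dir2 <- (img[N, ] - img[N - 1L, ])
  dir2 <- dir2 / sqrt(sum(dir2^2))
  pre <- sweep(outer(rev(seq_len(nExtra)), ds * dir1), 2L, img[1L, ], `+`)
  post <- sweep(outer(seq_len(nExtra), ds * dir2), 2L, img[N, ], `+`)
  sPre <- rc@arcPositions[1L] - rev(seq_len(nExtra)) * ds
  sPost <- rc@arcPositions[N] + seq_len(nExtra) * ds
  new("ReactionCoordinate", images = rbind(pre, img, post),
      arcPositions = c(sPre, rc@arcPositions, sPost),
      anchors = rc@anchors, nExtra = as.integer(nExtra),
      converged = rc@converged, iterations = rc@iterations)
}

#' Lift a reaction coordinate into the full feature dimension
#'
#' The RC is reconstructed in a d-dimensional subspace that forms the first
#' d coordinates of a larger d_full-dimensional space.  Each image's
#' unmodeled coordinates are set to the mean of those coordinates over the
#' data points in the image's Voronoi cell (cells defined in the modeled
#' subspace); empty cells are filled by linear interpolation from their
#' neighbors.
#'
#' @param rc a \linkS4class{ReactionCoordinate} (d modeled coordinates).
#' @param fullEnsemble a \linkS4class{TrajectoryEnsemble} with d_full > d
#'   coordinates whose first d match the RC's space.
#' @return a \linkS4class{ReactionCoordinate} with d_full columns.
#' @export
liftFullDimension <- function(rc, fullEnsemble) {
  d <- ncol(rc@images)
  pts <- ensemblePoints(fullEnsemble)$points
  if (ncol(pts) <= d)
    stop("full ensemble must have more coordinates than the RC subspace")
  cell <- voronoiAssign(rc, pts[, seq_len(d), drop = FALSE])
  nImg <- nrow(rc@images)
  extra <- matrix(NA_real_, nImg, ncol(pts) - d)
  for (k in seq_len(nImg)) {
    inCell <- cell == k
    if (any(inCell))
      extra[k, ] <- colMeans(pts[inCell, -seq_len(d), drop = FALSE])
  }
  if (anyNA(extra)) {
    message("empty Voronoi cells in lift filled by interpolation: ",
            paste(which(rowSums(is.na(extra)) > 0), collapse = " "))
    for (j in seq_len(ncol(extra))) {
      ok <- !is.na(extra[, j])
      extra[, j] <- stats::approx(rc@arcPositions[ok], extra[ok, j],
                                  xout = rc@arcPositions, rule = 2)$y
    }
  }
  new("ReactionCoordinate", images = cbind(rc@images, extra),
      arcPositions = rc@arcPositions,
      anchors = cbind(rc@anchors,
                      extra[c(1L, nImg) + c(rc@nExtra, -rc@nExtra), ,
                            drop = FALSE]),
      nExtra = rc@nExtra, converged = rc@converged,
      iterations = rc@iterations)
}

#' Original-feature dynamics along a reaction coordinate
#'
#' Inverse-transforms the lifted PC-space images of an RC through a PCA
#' model, giving one curve per original feature (e.g. the 13 Haralick
#' texture channels) as a function of arc position s.
#'
#' @param rc a lifted \linkS4class{ReactionCoordinate} whose column count
#'   equals the PCA model's reduced dimension.
#' @param pca a \linkS4class{PCAModel}.
#' @return matrix (images x original features) with the original feature
#'   names as column names.
#' @export
featureDynamicsAlongRC <- function(rc, pca) {
  if (ncol(rc@images) != ncol(pca@loadings))
    stop("dimension mismatch between RC and PCA model")
  out <- pcaInverseTransform(pca, rc@images)
  colnames(out) <- pca@featureNames
  out
}
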
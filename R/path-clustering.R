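#' Dynamic-time-warping distance between trajectories
#'
#' Classic DTW with the unit step pattern, no window constraint and no
#' normalization; the local cost is the Euclidean distance between
#' multivariate frames.  The distance is 0 iff the two sequences are equal
#' up to repetition of points.
#'
#' @param a,b T x d matrices (or vectors for d = 1).
#' @return accumulated alignment cost.
#' @export
dtwDistance <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 1L)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1L)
  dtw_cost_cpp(a, b)
}

#' All-pairs DTW distance matrix of a reactive ensemble
#'
#' @param reactive a \linkS4class{ReactiveEnsemble} (or any
#'   \linkS4class{TrajectoryEnsemble}) with at least 2 usable trajectories.
#' @param upTo optional frame cutoff applied per trajectory: \code{"mEntry"}
#'   restricts a reactive trajectory to its transition portion (through
#'   first M entry); \code{NULL} uses all frames.
#' @param thin keep every \code{thin}-th frame before alignment (default 1,
#'   no thinning); uniform thinning preserves the path geometry while
#'   reducing the quadratic alignment cost.
#' @return n x n symmetric non-negative matrix with zero diagonal.
#' @export
dtwDistanceMatrix <- function(reactive, upTo = c("mEntry", "all"),
                              thin = 1L) {
  upTo <- match.arg(upTo)
  mats <- lapply(seq_along(reactive@trajectories), function(i) {
    X <- reactive@trajectories[[i]]@coords
    if (upTo == "mEntry" && is(reactive, "ReactiveEnsemble"))
      X <- X[seq_len(reactive@mEntry[i]), , drop = FALSE]
    if (thin > 1L)
      X <- X[unique(c(seq(1L, nrow(X), by = thin), nrow(X))), ,
             drop = FALSE]
    X
  })
  short <- vapply(mats, nrow, integer(1)) < 2L
  if (any(short)) {
    warning(sum(short), " trajectories shorter than 2 frames excluded")
    mats <- mats[!short]
  }
  if (length(mats) < 2L) stop("need at least 2 trajectories")
  D <- dtw_matrix_cpp(mats)
  attr(D, "kept") <- which(!short)
  D
}

#' Cluster reactive trajectories into parallel path groups
#'
#' K-means on the DTW distance matrix, reading each trajectory's row of the
#' matrix as its feature vector (k-medoids on the distances is available as
#' an alternative).  Rows are put in a canonical permutation-invariant order
#' before the seeded k-means so that shuffling trajectory order permutes the
#' labels identically.  With \code{k = 2} and a reference ensemble given,
#' labels are canonicalized so that group 1 is the group whose members move
#' the designated texture axis earlier (the "vimentin-first" convention).
#'
#' @param D symmetric DTW distance matrix.
#' @param k number of groups (default 2).
#' @param seed RNG seed for k-means restarts.
#' @param method \code{"features"} (k-means on rows) or \code{"medoids"}
#'   (PAM on the distances, requires the cluster package).
#' @param reactive optional \linkS4class{ReactiveEnsemble} matching the rows
#'   of \code{D}, used only for the canonical group naming.
#' @param textureAxis feature index of the texture-like axis (default 2).
#' @param nstart k-means restarts.
#' @return integer group labels (1..k); attribute \code{"degenerate"} is
#'   TRUE when all pairwise distances coincide and the labeling is
#'   arbitrary.
#' @export
clusterPaths <- function(D, k = 2L, seed = NULL,
                         method = c("features", "medoids"),
                         reactive = NULL, textureAxis = 2L, nstart = 20L) {
  method <- match.arg(method)
  n <- nrow(D)
  if (k > n) stop("k must not exceed the number of trajectories")
  off <- D[upper.tri(D)]
  if (length(off) && diff(range(off)) < 1e-12 * max(abs(off), 1)) {
    warning("degenerate distance matrix (all pairwise distances equal); ",
            "labeling is arbitrary")
    lab <- rep_len(seq_len(k), n)
    attr(lab, "degenerate") <- TRUE
    return(lab)
  }
  ord <- order(rowSums(D), seq_len(n))        # canonical, permutation-safe
  lab <- .withSeed(seed, {
    if (method == "features") {
      km <- stats::kmeans(D[ord, ord, drop = FALSE], centers = k,
                          nstart = nstart)
      km$cluster
    } else {
      if (!requireNamespace("cluster", quietly = TRUE))
        stop("method 'medoids' requires the cluster package")
      cluster::pam(stats::as.dist(D[ord, ord]), k = k,
                   cluster.only = TRUE)
    }
  })
  labels <- integer(n)
  labels[ord] <- lab
  if (k == 2L && !is.null(reactive))
    labels <- .canonicalizeTwoGroups(labels, reactive, textureAxis)
  attr(labels, "degenerate") <- FALSE
  labels
}

# group 1 = group whose texture axis reaches the midpoint of its own
# start-to-end excursion earlier (in fractional trajectory time)
.canonicalizeTwoGroups <- function(labels, reactive, textureAxis) {
  frac <- vapply(reactive@trajectories, function(tr) {
    v <- tr@coords[, textureAxis]
    mid <- (v[1L] + v[length(v)]) / 2
    dirUp <- v[length(v)] >= v[1L]
    hit <- if (dirUp) which(v >= mid) else which(v <= mid)
    if (length(hit) == 0L) 1 else hit[1L] / length(v)
  }, numeric(1))
  m1 <- mean(frac[labels == 1L]); m2 <- mean(frac[labels == 2L])
  if (!is.na(m1) && !is.na(m2) && m2 < m1) labels <- 3L - labels
  labels
}

#' Assign a trajectory's parts to two reaction coordinates
#'
#' Sub-sequence DTW matches each reaction coordinate's image chain (the
#' query) against a contiguous window of the trajectory; every frame is then
#' assigned to the RC whose nearest image point is closer in Euclidean
#' distance (ties to RC1), and the maximal consecutive runs per RC are
#' reported for downstream per-path drift estimation.
#'
#' @param traj a \linkS4class{FeatureTrajectory}.
#' @param rc1,rc2 \linkS4class{ReactionCoordinate}s in the same space.
#' @return a \linkS4class{PathAssignment}; attribute \code{"windows"} holds
#'   the matched sub-sequence windows (frame ranges) of each RC.
#' @export
alignToRCs <- function(traj, rc1, rc2) {
  X <- traj@coords
  w1 <- subseq_dtw_cpp(images(rc1), X)
  w2 <- subseq_dtw_cpp(images(rc2), X)
  n1 <- bmu_cpp(X, images(rc1))
  n2 <- bmu_cpp(X, images(rc2))
  d1 <- sqrt(rowSums((X - images(rc1)[n1, , drop = FALSE])^2))
  d2 <- sqrt(rowSums((X - images(rc2)[n2, , drop = FALSE])^2))
  labels <- ifelse(d2 < d1, 2L, 1L)           # tie -> RC1
  matchedS <- ifelse(labels == 1L, arcPositions(rc1)[n1],
                     arcPositions(rc2)[n2])
  runs <- .maximalRuns(labels)
  out <- new("PathAssignment", labels = as.integer(labels),
             matchedS = matchedS, runs = runs)
  attr(out, "windows") <- list(rc1 = c(w1$start, w1$end),
                               rc2 = c(w2$start, w2$end),
                               cost = c(w1$cost, w2$cost))
  out
}

.maximalRuns <- function(labels) {
  n <- length(labels)
  brk <- c(0L, which(diff(labels) != 0L), n)
  data.frame(rc = labels[brk[-length(brk)] + 1L],
             start = brk[-length(brk)] + 1L,
             end = brk[-1L])
}
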
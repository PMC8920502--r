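#' @import methods
NULL

.near <- function(a, b, tol = 1e-9) abs(a - b) <= tol * pmax(abs(a), abs(b), 1)

#' FeatureTrajectory: one cell's path through feature space
#'
#' Time-ordered coordinates of a single cell in a reduced (e.g. principal
#' component) feature space.  Times are in hours, strictly increasing with a
#' uniform frame interval.
#'
#' @slot cellId character(1), opaque cell identifier.
#' @slot times numeric vector of frame times (hours), uniformly spaced.
#' @slot coords T x d numeric matrix of feature-space coordinates.
#'
#' @exportClass FeatureTrajectory
setClass("FeatureTrajectory",
  slots = c(cellId = "character", times = "numeric", coords = "matrix"))

setValidity("FeatureTrajectory", function(object) {
  msg <- character()
  if (length(object@cellId) != 1L) msg <- c(msg, "cellId must be length 1")
  Tn <- length(object@times)
  if (Tn < 2L) msg <- c(msg, "a trajectory needs at least 2 frames")
  if (nrow(object@coords) != Tn)
    msg <- c(msg, "nrow(coords) must equal length(times)")
  if (anyNA(object@coords) || any(!is.finite(object@coords)))
    msg <- c(msg, sprintf("trajectory '%s' has missing/non-finite coordinates",
                          object@cellId))
  if (Tn >= 2L) {
    dts <- diff(object@times)
    if (any(dts <= 0)) msg <- c(msg, "times must be strictly increasing")
    if (!all(.near(dts, dts[1L])))
      msg <- c(msg, sprintf("trajectory '%s' has a non-uniform frame interval",
                            object@cellId))
  }
  if (length(msg)) msg else TRUE
})

#' TrajectoryEnsemble: a set of trajectories sharing a feature space
#'
#' @slot trajectories list of \linkS4class{FeatureTrajectory}.
#' @slot featureNames character(d) feature labels.
#' @slot frameInterval numeric(1) shared frame interval (hours).
#' @slot conditionLabel character(1) free-text condition tag (e.g. dose).
#'
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble",
  slots = c(trajectories = "list", featureNames = "character",
            frameInterval = "numeric", conditionLabel = "character"))

setValidity("TrajectoryEnsemble", function(object) {
  msg <- character()
  if (length(object@trajectories) == 0L)
    msg <- c(msg, "ensemble must contain at least one trajectory")
  if (!all(vapply(object@trajectories, is, logical(1), "FeatureTrajectory")))
    msg <- c(msg, "all elements must be FeatureTrajectory objects")
  else {
    d <- length(object@featureNames)
    dims <- vapply(object@trajectories, function(tr) ncol(tr@coords), integer(1))
    if (length(dims) && any(dims != d))
      msg <- c(msg, "all trajectories must share the ensemble dimension")
    dts <- vapply(object@trajectories,
                  function(tr) diff(tr@times)[1L], numeric(1))
    if (length(dts) && !all(.near(dts, object@frameInterval)))
      msg <- c(msg, "all trajectories must share the ensemble frame interval")
  }
  if (length(msg)) msg else TRUE
})

#' PCAModel: affine map between an original feature space and a PC subspace
#'
#' @slot center numeric(D) mean in original feature units.
#' @slot loadings D x d matrix with orthonormal columns.
#' @slot featureNames character(D) original feature labels.
#'
#' @exportClass PCAModel
setClass("PCAModel",
  slots = c(center = "numeric", loadings = "matrix",
            featureNames = "character"))

setValidity("PCAModel", function(object) {
  msg <- character()
  D <- length(object@center)
  if (nrow(object@loadings) != D)
    msg <- c(msg, "nrow(loadings) must equal length(center)")
  if (ncol(object@loadings) > D)
    msg <- c(msg, "d must not exceed D")
  if (length(object@featureNames) != D)
    msg <- c(msg, "featureNames must have length D")
  gram <- crossprod(object@loadings)
  if (max(abs(gram - diag(ncol(object@loadings)))) > 1e-8)
    msg <- c(msg, "loadings columns must be orthonormal (tol 1e-8)")
  if (length(msg)) msg else TRUE
})

#' RegionSpec: epithelial / intermediate / mesenchymal partition
#'
#' Closed balls around the epithelial (E) and mesenchymal (M) attractor
#' centers; the intermediate (I) region is the complement of their union.
#'
#' @slot eCenter,mCenter numeric(d) region centers.
#' @slot eRadius,mRadius numeric(1) positive radii (reduced units).
#'
#' @exportClass RegionSpec
setClass("RegionSpec",
  slots = c(eCenter = "numeric", mCenter = "numeric",
            eRadius = "numeric", mRadius = "numeric"))

setValidity("RegionSpec", function(object) {
  msg <- character()
  if (length(object@eCenter) != length(object@mCenter))
    msg <- c(msg, "eCenter and mCenter must share dimension")
  if (object@eRadius <= 0 || object@mRadius <= 0)
    msg <- c(msg, "radii must be positive")
  if (sqrt(sum((object@eCenter - object@mCenter)^2)) <=
      object@eRadius + object@mRadius)
    msg <- c(msg, "E and M balls must be disjoint")
  if (length(msg)) msg else TRUE
})

#' ReactiveEnsemble: trajectories that transit from E to M
#'
#' Subset of a \linkS4class{TrajectoryEnsemble} whose members start in the E
#' region and reach the M region within a deadline, with the frame indices of
#' the last E exit and first M entry recorded per trajectory.
#'
#' @slot regions the \linkS4class{RegionSpec} used for extraction.
#' @slot eExit integer, per-trajectory frame index of the final departure
#'   from E before first reaching M.
#' @slot mEntry integer, per-trajectory frame index of first M entry.
#' @slot deadline numeric(1), hours.
#'
#' @exportClass ReactiveEnsemble
setClass("ReactiveEnsemble", contains = "TrajectoryEnsemble",
  slots = c(regions = "RegionSpec", eExit = "integer", mEntry = "integer",
            deadline = "numeric"))

setValidity("ReactiveEnsemble", function(object) {
  n <- length(object@trajectories)
  msg <- character()
  if (length(object@eExit) != n || length(object@mEntry) != n)
    msg <- c(msg, "eExit/mEntry must have one entry per trajectory")
  if (any(object@mEntry <= object@eExit))
    msg <- c(msg, "mEntry must follow eExit")
  if (length(msg)) msg else TRUE
})

#' PotentialSpec: analytic potential landscape
#'
#' A sum of analytic terms (Gaussian wells/barriers, isotropic quadratic
#' confinement, and a one-dimensional quartic double well), evaluable with
#' analytic gradient everywhere.  Used by the Langevin simulator and as
#' ground truth in parameter-recovery tests.
#'
#' @slot terms list of term descriptors (see \code{\link{potentialValue}}).
#' @slot d integer(1) dimension.
#' @slot control numeric(1) control parameter in [0, 1] (dose-like).
#' @slot metadata list; for landscapes built by
#'   \code{\link{makeTwoPathPotential}} this holds attractor centers and the
#'   two channel centerlines.
#'
#' @exportClass PotentialSpec
setClass("PotentialSpec",
  slots = c(terms = "list", d = "integer", control = "numeric",
            metadata = "list"),
  prototype = prototype(control = 0, metadata = list()))

#' ReactionCoordinate: discretized 1-D reaction path
#'
#' An ordered chain of image points, uniformly spaced in arc length, whose
#' Voronoi cells partition the feature space into a 1-D array of bins.
#'
#' @slot images (N + 2*nExtra) x d matrix of image coordinates.
#' @slot arcPositions numeric, arc-length coordinate s of each image.
#' @slot anchors 2 x d matrix: the fixed start/end points (E/M means) of the
#'   un-extrapolated string.
#' @slot nExtra integer(1), extrapolated images per end.
#' @slot converged logical(1); \code{iterations} records the count.
#' @slot iterations integer(1).
#'
#' @exportClass ReactionCoordinate
setClass("ReactionCoordinate",
  slots = c(images = "matrix", arcPositions = "numeric", anchors = "matrix",
            nExtra = "integer", converged = "logical",
            iterations = "integer"),
  prototype = prototype(nExtra = 0L, converged = FALSE, iterations = 0L))

setValidity("ReactionCoordinate", function(object) {
  msg <- character()
  if (nrow(object@images) != length(object@arcPositions))
    msg <- c(msg, "one arc position per image required")
  if (nrow(object@images) < 2L) msg <- c(msg, "need at least 2 images")
  if (is.unsorted(object@arcPositions, strictly = TRUE))
    msg <- c(msg, "arc positions must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' SOMModel: trained self-organizing map
#'
#' @slot gridShape integer(2): (rows, cols) of the neuron grid.
#' @slot codebook (rows*cols) x d matrix of neuron weight vectors, in
#'   row-major grid order.
#' @slot meta list of training metadata (epochs, radius, std, learning-rate
#'   schedule, seed).
#'
#' @exportClass SOMModel
setClass("SOMModel",
  slots = c(gridShape = "integer", codebook = "matrix", meta = "list"))

setValidity("SOMModel", function(object) {
  msg <- character()
  if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be two positive integers")
  if (nrow(object@codebook) != prod(object@gridShape))
    msg <- c(msg, "codebook must have rows*cols rows")
  if (any(!is.finite(object@codebook)))
    msg <- c(msg, "codebook must be finite")
  if (length(msg)) msg else TRUE
})

#' TransitionNetwork: SOM-state Markov transition network
#'
#' Directed network over SOM micro-states with empirical transition
#' probabilities (self-transitions included), small entries pruned to exactly
#' zero, and edge weights -log(p) on the surviving edges.
#'
#' @slot P n x n row-count-normalized transition probability matrix.
#' @slot W n x n edge weights, -log(P); +Inf where P is 0.
#' @slot counts n x n raw hop counts.
#' @slot prune numeric(1) pruning threshold applied to P.
#' @slot zeroRows integer, states with no outgoing hops (flagged).
#'
#' @exportClass TransitionNetwork
setClass("TransitionNetwork",
  slots = c(P = "matrix", W = "matrix", counts = "matrix",
            prune = "numeric", zeroRows = "integer"))

setValidity("TransitionNetwork", function(object) {
  msg <- character()
  if (nrow(object@P) != ncol(object@P)) msg <- c(msg, "P must be square")
  if (any(object@P < 0 | object@P > 1)) msg <- c(msg, "P entries must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' PathSummary: shortest-path ensemble over a transition network
#'
#' @slot paths list of integer state sequences, one per reachable
#'   (E-neuron, M-neuron) pair.
#' @slot weights numeric path weights (-log of path probability).
#' @slot nodeCounts numeric(n), times each state is visited by the paths.
#' @slot edgeCounts n x n matrix of directed edge usage counts.
#' @slot eStates,mStates integer index sets of the E and M communities.
#' @slot skipped integer(2): (unreachable pairs, total pairs).
#'
#' @exportClass PathSummary
setClass("PathSummary",
  slots = c(paths = "list", weights = "numeric", nodeCounts = "numeric",
            edgeCounts = "matrix", eStates = "integer", mStates = "integer",
            skipped = "integer"))

#' DensityMap: gridded 2-D density of reactive trajectories
#'
#' @slot axes integer(2), the two feature indices spanning the plane.
#' @slot bounds 2 x 2 matrix; column j holds c(lo, hi) for axis j.
#' @slot values nBins x nBins matrix (row = axis-1 bin, col = axis-2 bin).
#' @slot raw the pre-smoothing binary-visit count matrix.
#' @slot smoothing list(sigma, truncate) of the Gaussian filter applied.
#'
#' @exportClass DensityMap
setClass("DensityMap",
  slots = c(axes = "integer", bounds = "matrix", values = "matrix",
            raw = "matrix", smoothing = "list"))

setValidity("DensityMap", function(object) {
  if (any(object@values < 0)) "density values must be non-negative" else TRUE
})

#' QuasiPotential: drift, diffusion and integrated potential along an RC
#'
#' Per interior Voronoi cell: the quasi-potential gradient (minus the mean
#' drift speed), the integrated potential phi (offset so phi[1] = 0), the
#' diffusion coefficient (variance of ds/dt), and the sample count.
#'
#' @slot sGrid numeric, arc positions of interior cells.
#' @slot grad numeric, d(phi)/ds per cell.
#' @slot phi numeric, integrated quasi-potential.
#' @slot D numeric, diffusion coefficient per cell.
#' @slot counts integer, samples per cell.
#' @slot masked logical, TRUE where counts < minCount (values interpolated).
#'
#' @exportClass QuasiPotential
setClass("QuasiPotential",
  slots = c(sGrid = "numeric", grad = "numeric", phi = "numeric",
            D = "numeric", counts = "integer", masked = "logical"))

#' CKTestResult: Chapman-Kolmogorov Markovianity test
#'
#' @slot tau integer(1) base lag (frames).
#' @slot ks integer, the multiples k tested.
#' @slot deviations numeric, max row-wise L1 distance between P(k*tau) and
#'   P(tau)^k for each k (0 at k = 1 by construction).
#' @slot perState matrix, row-wise L1 deviations (states x k); NA where a
#'   state had too few lagged pairs.
#' @slot nStates integer(1).
#'
#' @exportClass CKTestResult
setClass("CKTestResult",
  slots = c(tau = "integer", ks = "integer", deviations = "numeric",
            perState = "matrix", nStates = "integer"))

#' FPSolution: numerical solution of the 1-D Fokker-Planck equation
#'
#' @slot grid numeric, cell-center positions.
#' @slot times numeric, output times.
#' @slot rho matrix (time x space) of densities.
#' @slot rhoSS numeric, stationary density (unit integral).
#' @slot flux numeric, stationary face fluxes.
#' @slot converged logical(1).
#' @slot kBT numeric(1) pseudo-temperature used.
#'
#' @exportClass FPSolution
setClass("FPSolution",
  slots = c(grid = "numeric", times = "numeric", rho = "matrix",
            rhoSS = "numeric", flux = "numeric", converged = "logical",
            kBT = "numeric"))

#' PathAssignment: per-frame assignment of a trajectory to parallel RCs
#'
#' @slot labels integer per frame: which RC (1 or 2) the frame is assigned to.
#' @slot matchedS numeric per frame: arc coordinate of the nearest image on
#'   the assigned RC.
#' @slot runs data.frame(rc, start, end): maximal consecutive runs.
#'
#' @exportClass PathAssignment
setClass("PathAssignment",
  slots = c(labels = "integer", matchedS = "numeric", runs = "data.frame"))
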
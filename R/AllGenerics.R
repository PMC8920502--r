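#' Accessors for transpath classes
#'
#' Small accessor generics: \code{trajectories} (list of
#' \linkS4class{FeatureTrajectory}), \code{featureNames}, \code{frameInterval}
#' (hours), \code{conditionLabel}, \code{coords} and \code{frameTimes} (one
#' trajectory), \code{nTrajectories}, \code{images} and \code{arcPositions}
#' (reaction coordinate), \code{codebook} and \code{gridShape} (SOM), and
#' \code{transitionMatrix}.
#'
#' @param object a transpath object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases trajectories featureNames frameInterval conditionLabel coords
#'   frameTimes nTrajectories images arcPositions codebook gridShape
#'   transitionMatrix
NULL

#' @rdname accessors
#' @export
setGeneric("trajectories", function(object) standardGeneric("trajectories"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(object) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("nTrajectories", function(object) standardGeneric("nTrajectories"))
#' @rdname accessors
#' @export
setGeneric("images", function(object) standardGeneric("images"))
#' @rdname accessors
#' @export
setGeneric("arcPositions", function(object) standardGeneric("arcPositions"))
#' @rdname accessors
#' @export
setGeneric("codebook", function(object) standardGeneric("codebook"))
#' @rdname accessors
#' @export
setGeneric("gridShape", function(object) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

setMethod("trajectories", "TrajectoryEnsemble", function(object) object@trajectories)
setMethod("featureNames", "TrajectoryEnsemble", function(object) object@featureNames)
setMethod("frameInterval", "TrajectoryEnsemble", function(object) object@frameInterval)
setMethod("conditionLabel", "TrajectoryEnsemble", function(object) object@conditionLabel)
setMethod("nTrajectories", "TrajectoryEnsemble", function(object) length(object@trajectories))
setMethod("coords", "FeatureTrajectory", function(object) object@coords)
setMethod("frameTimes", "FeatureTrajectory", function(object) object@times)
setMethod("images", "ReactionCoordinate", function(object) object@images)
setMethod("arcPositions", "ReactionCoordinate", function(object) object@arcPositions)
setMethod("codebook", "SOMModel", function(object) object@codebook)
setMethod("gridShape", "SOMModel", function(object) object@gridShape)
setMethod("transitionMatrix", "TransitionNetwork", function(object) object@P)

setMethod("show", "FeatureTrajectory", function(object) {
  cat(sprintf("FeatureTrajectory '%s': %d frames x %d features, t = [%g, %g] h\n",
              object@cellId, nrow(object@coords), ncol(object@coords),
              object@times[1L], object@times[length(object@times)]))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf("%s with %d trajectories (d = %d, frame interval = %g h)\n",
              class(object), length(object@trajectories),
              length(object@featureNames), object@frameInterval))
  cat("  features:", paste(object@featureNames, collapse = ", "), "\n")
  if (nzchar(object@conditionLabel))
    cat("  condition:", object@conditionLabel, "\n")
  if (is(object, "ReactiveEnsemble"))
    cat(sprintf("  reactive: E exit / M entry recorded; deadline %g h\n",
                object@deadline))
})

setMethod("show", "ReactionCoordinate", function(object) {
  cat(sprintf("ReactionCoordinate: %d images (%d extrapolated per end), d = %d\n",
              nrow(object@images), object@nExtra, ncol(object@images)))
  cat(sprintf("  arc length %.4g, converged: %s (%d iterations)\n",
              diff(range(object@arcPositions)), object@converged,
              object@iterations))
})

setMethod("show", "SOMModel", function(object) {
  cat(sprintf("SOMModel: %d x %d grid, d = %d, trained %s epochs (seed %s)\n",
              object@gridShape[1L], object@gridShape[2L], ncol(object@codebook),
              as.character(object@meta$epochs %||% "?"),
              as.character(object@meta$seed %||% "?")))
})

setMethod("show", "TransitionNetwork", function(object) {
  nz <- sum(object@P > 0)
  cat(sprintf("TransitionNetwork: %d states, %d edges (prune = %g)\n",
              nrow(object@P), nz, object@prune))
  if (length(object@zeroRows))
    cat("  states with no outgoing hops:", paste(object@zeroRows, collapse = " "), "\n")
})

setMethod("show", "QuasiPotential", function(object) {
  cat(sprintf("QuasiPotential on %d interior cells, s in [%.3g, %.3g]\n",
              length(object@sGrid), min(object@sGrid), max(object@sGrid)))
  cat(sprintf("  phi range %.3g, mean D %.3g, %d masked cells\n",
              diff(range(object@phi)), mean(object@D, na.rm = TRUE),
              sum(object@masked)))
})

setMethod("show", "FPSolution", function(object) {
  cat(sprintf("FPSolution: %d grid cells, kBT = %g, converged: %s\n",
              length(object@grid), object@kBT, object@converged))
})

setMethod("show", "PotentialSpec", function(object) {
  cat(sprintf("PotentialSpec: d = %d, %d terms, control = %g\n",
              object@d, length(object@terms), object@control))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
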
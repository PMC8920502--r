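#' Construct a FeatureTrajectory
#'
#' @param cellId character(1) cell identifier.
#' @param times numeric frame times in hours, strictly increasing and
#'   uniformly spaced.
#' @param coords T x d numeric matrix of coordinates (or a vector for d = 1).
#' @return a \linkS4class{FeatureTrajectory}.
#' @export
FeatureTrajectory <- function(cellId, times, coords) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 1L)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  new("FeatureTrajectory", cellId = as.character(cellId),
      times = as.numeric(times), coords = coords)
}

#' Construct a TrajectoryEnsemble
#'
#' @param trajectories list of \linkS4class{FeatureTrajectory}.
#' @param featureNames character(d) labels; defaults to \code{PC1..PCd}.
#' @param conditionLabel free-text condition tag.
#' @return a \linkS4class{TrajectoryEnsemble}.
#' @export
TrajectoryEnsemble <- function(trajectories, featureNames = NULL,
                               conditionLabel = "") {
  if (length(trajectories) == 0L)
    stop("ensemble must contain at least one trajectory")
  d <- ncol(trajectories[[1L]]@coords)
  if (is.null(featureNames)) featureNames <- paste0("PC", seq_len(d))
  dt <- diff(trajectories[[1L]]@times)[1L]
  new("TrajectoryEnsemble", trajectories = trajectories,
      featureNames = as.character(featureNames), frameInterval = dt,
      conditionLabel = conditionLabel)
}

#' Read a trajectory ensemble from a long-format delimited table
#'
#' One row per (cell, frame).  The reader accepts a column-mapping so tables
#' with arbitrary column names can be ingested; rows may appear in any order
#' (they are grouped by cell and sorted by time).  A YAML sidecar
#' (\code{<path>.yml}) written by \code{\link{writeTrajectories}} restores
#' feature order and the condition label; without it, all non-id, non-time
#' columns are taken as features in table order.
#'
#' @param path path to a delimited text file.
#' @param dialect list with entries \code{cell} (cell-id column name),
#'   \code{time} (time column name), \code{features} (character vector of
#'   feature column names, or NULL for all remaining columns) and \code{sep}.
#' @param tol relative tolerance on frame-interval uniformity.
#' @return a \linkS4class{TrajectoryEnsemble}.
#' @export
readTrajectories <- function(path,
                             dialect = list(cell = "cell_id", time = "time",
                                            features = NULL, sep = ","),
                             tol = 1e-9) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- dialect$sep %||% ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cellCol <- dialect$cell %||% "cell_id"
  timeCol <- dialect$time %||% "time"
  missing <- setdiff(c(cellCol, timeCol), names(tab))
  if (length(missing))
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  featCols <- dialect$features
  if (is.null(featCols)) featCols <- setdiff(names(tab), c(cellCol, timeCol))
  if (length(featCols) == 0L)
    stop("format error: no feature columns found")
  if (length(bad <- setdiff(featCols, names(tab))))
    stop("format error: missing feature column(s): ",
         paste(bad, collapse = ", "))

  meta <- .readSidecar(path)
  if (!is.null(meta$feature_names) &&
      all(meta$feature_names %in% names(tab)) && is.null(dialect$features))
    featCols <- meta$feature_names

  ids <- as.character(tab[[cellCol]])
  trajs <- lapply(split(seq_len(nrow(tab)), factor(ids, levels = unique(ids))),
    function(idx) {
      ord <- idx[order(tab[[timeCol]][idx])]
      times <- as.numeric(tab[[timeCol]][ord])
      dts <- diff(times)
      if (length(dts) >= 2L && !all(.near(dts, dts[1L], tol)))
        stop("validation error: non-uniform frame interval for cell '",
             ids[idx[1L]], "'")
      FeatureTrajectory(ids[idx[1L]], times,
                        as.matrix(tab[ord, featCols, drop = FALSE]))
    })
  names(trajs) <- NULL
  TrajectoryEnsemble(trajs, featureNames = featCols,
                     conditionLabel = meta$condition_label %||% "")
}

#' Write a trajectory ensemble as a long-format delimited table
#'
#' Coordinates are serialized with 17 significant digits so that
#' \code{readTrajectories(writeTrajectories(e))} round-trips bit-for-bit.  A
#' YAML sidecar \code{<path>.yml} records the frame interval, feature names
#' and condition label.
#'
#' @param ensemble a valid \linkS4class{TrajectoryEnsemble}.
#' @param path output file path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
writeTrajectories <- function(ensemble, path, sep = ",") {
  validObject(ensemble)
  fmt <- function(x) sprintf("%.17g", x)
  rows <- lapply(ensemble@trajectories, function(tr) {
    cbind(cell_id = rep(tr@cellId, nrow(tr@coords)),
          time = fmt(tr@times),
          apply(tr@coords, 2L, fmt))
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("cell_id", "time", ensemble@featureNames)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(colnames(tab), collapse = sep), con)
  utils::write.table(tab, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(frame_interval = ensemble@frameInterval,
                        feature_names = as.list(ensemble@featureNames),
                        condition_label = ensemble@conditionLabel),
                   paste0(path, ".yml"))
  invisible(path)
}

.readSidecar <- function(path) {
  side <- paste0(path, ".yml")
  if (!file.exists(side)) return(list())
  out <- yaml::read_yaml(side)
  out$feature_names <- unlist(out$feature_names)
  out
}

#' Construct a PCAModel
#'
#' @param center numeric(D) mean in original units.
#' @param loadings D x d matrix with orthonormal columns.
#' @param featureNames character(D) original feature labels.
#' @return a \linkS4class{PCAModel}.
#' @export
PCAModel <- function(center, loadings, featureNames = NULL) {
  if (is.null(featureNames)) featureNames <- paste0("f", seq_along(center))
  new("PCAModel", center = as.numeric(center), loadings = loadings,
      featureNames = as.character(featureNames))
}

#' Read / write a PCA model as structured text (YAML)
#'
#' @param path file path.
#' @return \code{readPCAModel}: a \linkS4class{PCAModel}.
#' @export
readPCAModel <- function(path) {
  y <- yaml::read_yaml(path)
  L <- matrix(as.numeric(unlist(y$loadings)), nrow = length(y$center),
              byrow = TRUE)
  PCAModel(as.numeric(y$center), L, unlist(y$feature_names))
}

#' @rdname readPCAModel
#' @param model a \linkS4class{PCAModel}.
#' @export
writePCAModel <- function(model, path) {
  validObject(model)
  yaml::write_yaml(list(
    center = as.list(model@center),
    feature_names = as.list(model@featureNames),
    loadings = lapply(seq_len(nrow(model@loadings)),
                      function(i) as.list(model@loadings[i, ]))), path,
    precision = 17L)
  invisible(path)
}

#' Project / back-project with a PCA model
#'
#' \code{pcaTransform} maps original-space rows to the PC subspace;
#' \code{pcaInverseTransform} maps PC-space rows back (onto the affine
#' subspace spanned by the loadings).
#'
#' @param model a \linkS4class{PCAModel}.
#' @param x matrix of row vectors (original space or PC space respectively).
#' @return matrix of transformed rows.
#' @export
pcaTransform <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model@center)) stop("dimension mismatch")
  sweep(x, 2L, model@center) %*% model@loadings
}

#' @rdname pcaTransform
#' @export
pcaInverseTransform <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(model@loadings)) stop("dimension mismatch")
  sweep(x %*% t(model@loadings), 2L, model@center, `+`)
}

#' Stack all frames of an ensemble into one matrix
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @return list(points = (sum T_i) x d matrix, traj = integer trajectory
#'   index per row, frame = frame index per row).
#' @export
ensemblePoints <- function(ensemble) {
  mats <- lapply(ensemble@trajectories, coords)
  ns <- vapply(mats, nrow, integer(1))
  list(points = do.call(rbind, mats),
       traj = rep(seq_along(mats), ns),
       frame = unlist(lapply(ns, seq_len), use.names = FALSE))
}
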
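#' Default pipeline configuration
#'
#' Returns the full configuration list for \code{\link{runPipeline}} with
#' every parameter at its standard default (string: N = 30 images, w = 10,
#' smooth = 1, 3 extrapolated images; SOM: 12 x 12 grid, 50 epochs, radius
#' 1, std 1, prune 0.01, community radius 0.7; density map: 200 x 200 bins,
#' Gaussian sigma = 2 truncated at 2; regions: 48 h reactive deadline;
#' potentials: minCount = 5, kBT = 1/2, pseudocount 0.5; Fokker-Planck: 200
#' grid cells).  Any entry can be overridden via \code{...} or by editing
#' the returned list; \code{input} selects the data source.
#'
#' All stage seeds derive from the single top-level \code{seed} by fixed
#' offsets (simulation +0, SOM +1, clustering +2).
#'
#' @param ... named overrides of the defaults (nested lists are merged).
#' @return a configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    input = list(type = "simulate", control = 1, nTraj = 150L,
                 nSteps = 4800L, dtSim = 0.01, sigma = 1.4,
                 observeEvery = 8L, initSd = 0.8, file = NULL,
                 dialect = NULL),
    regions = list(eRadius = 3, mRadius = 4, deadline = 48),
    densityMap = list(axes = c(1L, 2L), nBins = 200L, sigma = 2,
                      truncate = 2),
    som = list(grid = c(12L, 12L), epochs = 50L, radius = 1, std = 1,
               prune = 0.01, communityRadius = 0.7),
    string = list(N = 30L, w = 10, smooth = 1, nExtra = 3L,
                  maxIter = 100L),
    cluster = list(k = 2L, textureAxis = 2L, thin = 4L),
    potential = list(minCount = 5L, kBT = 0.5, pseudocount = 0.5),
    fp = list(gridN = 200L, tEnd = Inf),
    ck = list(tau = 1L, ks = 2:5),
    seed = 1L,
    outputDir = NULL)
  .mergeConfig(cfg, list(...))
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.validateConfig <- function(cfg) {
  if (cfg$string$N < 4L)
    stop("validation error: string N must be at least 4 ",
         "(string-method minimum image count)")
  if (cfg$som$prune < 0 || cfg$som$prune >= 1)
    stop("validation error: som prune must be in [0, 1)")
  if (cfg$potential$kBT <= 0)
    stop("validation error: kBT must be positive")
  if (!cfg$input$type %in% c("simulate", "file"))
    stop("validation error: input type must be 'simulate' or 'file'")
  invisible(cfg)
}

#' Run the full transition-path analysis pipeline
#'
#' Executes, in dependency order: data input (two-channel simulator or a
#' trajectory table), region assignment and reactive-trajectory extraction,
#' the reactive density map, the SOM transition network with shortest E-to-M
#' paths, DTW clustering into parallel path groups, per-group string-method
#' reaction coordinates (converged and extrapolated), per-group
#' quasi-potential estimation from part-aligned trajectory segments, the
#' Chapman-Kolmogorov test, and the Fokker-Planck stationary prediction per
#' group.  Numeric outputs are deterministic given the configuration (all
#' randomness flows from \code{config$seed}).
#'
#' @param config a configuration list from \code{\link{pipelineConfig}}, or
#'   the path of a YAML file with the same structure.
#' @return a run report: list with per-stage results (\code{ensemble},
#'   \code{reactive}, \code{densityMap}, \code{som}, \code{network},
#'   \code{pathSummary}, \code{clusterLabels}, \code{rcs},
#'   \code{quasiPotentials}, \code{ck}, \code{fp}, \code{fpStats}),
#'   parameter echo and seed.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- .mergeConfig(pipelineConfig(),
                                                   yaml::read_yaml(config))
  .validateConfig(config)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ensemble <- stage("input", {
    if (config$input$type == "simulate") {
      pot <- makeTwoPathPotential(config$input$control)
      simulateLangevin(pot, nTraj = config$input$nTraj,
                       nSteps = config$input$nSteps,
                       dtSim = config$input$dtSim,
                       sigma = config$input$sigma,
                       init = list(type = "gaussian",
                                   mean = pot@metadata$nominalE,
                                   sd = config$input$initSd),
                       seed = seed,
                       observeEvery = config$input$observeEvery,
                       conditionLabel = sprintf("control=%g",
                                                config$input$control))
    } else {
      readTrajectories(config$input$file,
                       dialect = config$input$dialect %||%
                         list(cell = "cell_id", time = "time",
                              features = NULL, sep = ","))
    }
  })

  regions <- stage("regions", {
    if (config$input$type == "simulate") {
      pot <- makeTwoPathPotential(config$input$control)
      RegionSpec(pot@metadata$nominalE, pot@metadata$nominalM,
                 config$regions$eRadius, config$regions$mRadius)
    } else {
      RegionSpec(config$regions$eCenter, config$regions$mCenter,
                 config$regions$eRadius, config$regions$mRadius)
    }
  })

  reactive <- stage("reactive", {
    r <- extractReactive(ensemble, regions,
                         deadline = config$regions$deadline)
    if (is.null(r)) stop("no reactive trajectories; widen the deadline or ",
                         "check the region specification")
    r
  })

  densityMap <- stage("densityMap",
    reactiveDensityMap(reactive, axes = config$densityMap$axes,
                       nBins = config$densityMap$nBins,
                       sigma = config$densityMap$sigma,
                       truncate = config$densityMap$truncate))

  som <- stage("som", {
    pts <- ensemblePoints(reactive)$points
    trainSOM(pts, grid = config$som$grid, epochs = config$som$epochs,
             radius = config$som$radius, std = config$som$std,
             seed = seed + 1L)
  })
  network <- stage("network",
    buildTransitionNetwork(reactive, som, prune = config$som$prune))
  pathSummary <- stage("shortestPaths",
    shortestTransitionPaths(network, som, regions@eCenter, regions@mCenter,
                            radius = config$som$communityRadius))

  D <- stage("dtw", dtwDistanceMatrix(reactive, thin = config$cluster$thin))
  clusterLabels <- stage("cluster",
    clusterPaths(D, k = config$cluster$k, seed = seed + 2L,
                 reactive = reactive,
                 textureAxis = config$cluster$textureAxis))

  rcs <- stage("string", {
    lapply(seq_len(config$cluster$k), function(g) {
      sub <- .subsetReactive(reactive, which(clusterLabels == g))
      rc0 <- initializeString(sub, regions, N = config$string$N)
      rc <- convergeString(rc0, sub, w = config$string$w,
                           smooth = config$string$smooth,
                           maxIter = config$string$maxIter)
      extrapolateString(rc, nExtra = config$string$nExtra)
    })
  })

  quasiPotentials <- stage("quasiPotential", {
    aligned <- partAlignedEnsembles(ensemble, rcs[[1L]], rcs[[2L]])
    lapply(seq_along(rcs), function(g)
      estimateQuasiPotential(aligned[[g]], rcs[[g]],
                             minCount = config$potential$minCount))
  })

  ck <- stage("ckTest",
    ckTest(ensemble, rcs[[1L]], tau = config$ck$tau, ks = config$ck$ks))

  fp <- stage("fokkerPlanck", {
    lapply(quasiPotentials, function(qp)
      solveFokkerPlanck(qp@phi, qp@D, qp@sGrid,
                        kBT = config$potential$kBT,
                        gridN = config$fp$gridN, tEnd = config$fp$tEnd))
  })
  fpStats <- lapply(fp, stationaryStats)

  report <- list(config = config, seed = seed, ensemble = ensemble,
                 regions = regions, reactive = reactive,
                 densityMap = densityMap, som = som, network = network,
                 pathSummary = pathSummary, clusterLabels = clusterLabels,
                 dtw = D, rcs = rcs, quasiPotentials = quasiPotentials,
                 ck = ck, fp = fp, fpStats = fpStats)
  if (!is.null(config$outputDir)) .writeReport(report, config$outputDir)
  report
}

.subsetReactive <- function(reactive, idx) {
  new("ReactiveEnsemble", trajectories = reactive@trajectories[idx],
      featureNames = reactive@featureNames,
      frameInterval = reactive@frameInterval,
      conditionLabel = reactive@conditionLabel,
      regions = reactive@regions, eExit = reactive@eExit[idx],
      mEntry = reactive@mEntry[idx], deadline = reactive@deadline)
}

#' Part-align an ensemble to two reaction coordinates
#'
#' Every trajectory (reactive or not) is assigned frame-wise to the two RCs
#' with \code{\link{alignToRCs}}; each maximal consecutive run of at least 2
#' frames becomes a segment trajectory in the ensemble of its RC.  The two
#' returned ensembles feed per-path drift/diffusion estimation.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param rc1,rc2 the two \linkS4class{ReactionCoordinate}s.
#' @return list of two \linkS4class{TrajectoryEnsemble}s (NULL where no
#'   segments were found).
#' @export
partAlignedEnsembles <- function(ensemble, rc1, rc2) {
  segs <- list(list(), list())
  for (tr in ensemble@trajectories) {
    pa <- alignToRCs(tr, rc1, rc2)
    for (r in seq_len(nrow(pa@runs))) {
      if (pa@runs$end[r] - pa@runs$start[r] < 1L) next
      g <- pa@runs$rc[r]
      idx <- pa@runs$start[r]:pa@runs$end[r]
      segs[[g]][[length(segs[[g]]) + 1L]] <-
        FeatureTrajectory(sprintf("%s_run%d", tr@cellId, r),
                          tr@times[idx], tr@coords[idx, , drop = FALSE])
    }
  }
  lapply(segs, function(s)
    if (length(s)) TrajectoryEnsemble(s, featureNames = ensemble@featureNames,
                                      conditionLabel = ensemble@conditionLabel)
    else NULL)
}

.writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(networkEdgeList(report$network),
                   file.path(dir, "network_edges.csv"), row.names = FALSE)
  for (g in seq_along(report$quasiPotentials))
    utils::write.csv(quasiPotentialTable(report$quasiPotentials[[g]]),
                     file.path(dir, sprintf("quasi_potential_rc%d.csv", g)),
                     row.names = FALSE)
  for (g in seq_along(report$rcs)) {
    img <- images(report$rcs[[g]])
    utils::write.csv(data.frame(s = arcPositions(report$rcs[[g]]), img),
                     file.path(dir, sprintf("rc%d_images.csv", g)),
                     row.names = FALSE)
  }
  fpTab <- do.call(rbind, lapply(seq_along(report$fpStats), function(g)
    data.frame(rc = g, mean = report$fpStats[[g]]["mean"],
               sd = report$fpStats[[g]]["sd"])))
  utils::write.csv(fpTab, file.path(dir, "fp_stationary_stats.csv"),
                   row.names = FALSE)
  yaml::write_yaml(report$config, file.path(dir, "config_echo.yml"))
  invisible(dir)
}
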
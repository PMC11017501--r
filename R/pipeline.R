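#' Assemble a run configuration
#'
#' Collects every tunable of the analysis pipeline with its default, so a
#' run is fully described by one serializable object; \code{pipelineRun()}
#' echoes the resolved configuration next to its outputs for provenance.
#'
#' @param stack path to the tracer stack TIFF (or an
#'   \linkS4class{ImageStack})
#' @param seeds per-vessel seed points: list of n x 3 matrices (um), or an
#'   SWC file whose paths supply the seeds
#' @param rois ROI polygon list or JSON path (optional)
#' @param outputDir directory for reports
#' @param smoothSigmaPx Gaussian pre-smoothing sigma (xy pixels)
#' @param fillThresholdFraction lumen-fill acceptance threshold (fraction of
#'   path-median intensity)
#' @param fillReachFactor geodesic reach bound in local radii
#' @param background background intensity estimate
#' @param detectionThreshold leak-signal threshold (absolute; default
#'   background + 3 * backgroundSd)
#' @param backgroundSd background noise sd used for the default detection
#'   threshold
#' @param sampleInterval spreading-distance station interval (um, in [1, 2])
#' @param tieToleranceUm attribution tie tolerance (um)
#' @param maxAttributionUm maximum attribution radius (um)
#' @param guardRing exclude a 1-voxel dilation of the lumen from the
#'   extraluminal sum
#' @param minSiteVoxels smallest leak-site component kept
#' @param seed RNG seed recorded with the run
#' @return a named list of class \code{avleakConfig}
#' @export
runConfig <- function(stack = NULL, seeds = NULL, rois = NULL,
                      outputDir = ".",
                      smoothSigmaPx = 1,
                      fillThresholdFraction = 0.3,
                      fillReachFactor = 3,
                      background = 0,
                      backgroundSd = 0,
                      detectionThreshold = background + 3 * backgroundSd,
                      sampleInterval = 1,
                      tieToleranceUm = 0.58,
                      maxAttributionUm = 50,
                      guardRing = TRUE,
                      minSiteVoxels = 5,
                      seed = 1L) {
  cfg <- list(stack = stack, seeds = seeds, rois = rois,
              outputDir = outputDir, smoothSigmaPx = smoothSigmaPx,
              fillThresholdFraction = fillThresholdFraction,
              fillReachFactor = fillReachFactor, background = background,
              backgroundSd = backgroundSd,
              detectionThreshold = detectionThreshold,
              sampleInterval = sampleInterval,
              tieToleranceUm = tieToleranceUm,
              maxAttributionUm = maxAttributionUm, guardRing = guardRing,
              minSiteVoxels = minSiteVoxels, seed = as.integer(seed))
  class(cfg) <- "avleakConfig"
  cfg
}

#' Run the end-to-end leakage analysis pipeline
#'
#' Executes the full analysis flow on one stack: Gaussian pre-smoothing,
#' seed-guided tracing of every vessel, lumen filling, luminal/extraluminal
#' signal separation, the normalized leakage ratio (per compartment when
#' ROIs are given), perfused vessel density, vessel classification by
#' diameter, leak-site extraction with nearest-wall attribution and
#' spreading distances.  Each stage is timed and logged; any stage failure
#' aborts with a stage-tagged error.  Results are written as CSV/JSON into
#' \code{config$outputDir} together with the resolved configuration, and
#' also returned invisibly.
#'
#' @param config a configuration from \code{\link{runConfig}}
#' @param writeOutputs write report files (set FALSE for in-memory use)
#' @return invisible list: \code{paths}, \code{lumen}, \code{leakage}
#'   (\linkS4class{LeakageResult}), \code{vessels} (per-vessel table),
#'   \code{sites} (leak-site table), \code{timings}
#' @export
pipelineRun <- function(config, writeOutputs = TRUE) {
  stopifnot(inherits(config, "avleakConfig"))
  set.seed(config$seed)
  timings <- c()
  log_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    dt <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- dt
    message(sprintf("[avleak] %-10s %6.2f s", name, dt))
    out
  }

  stack <- log_stage("load", {
    if (is(config$stack, "ImageStack")) config$stack
    else readStack(config$stack)
  })
  seeds <- config$seeds
  if (is.character(seeds))
    seeds <- lapply(readSWC(seeds), function(p) p@points)
  if (is.null(seeds) || !length(seeds))
    stop("pipeline stage 'trace' failed: no seed points supplied")

  smoothed <- log_stage("smooth", smoothStack(stack, config$smoothSigmaPx))
  paths <- log_stage("trace", {
    lapply(seq_along(seeds), function(t)
      traceVessel(smoothed, seeds[[t]], vesselId = t))
  })
  lumen <- log_stage("fill", {
    masks <- lapply(paths, function(p)
      fillLumen(smoothed, p, config$fillThresholdFraction,
                config$fillReachFactor))
    mergeLumen(masks, paths)
  })
  split <- log_stage("split", splitSignal(stack, lumen))
  comp <- NULL
  if (!is.null(config$rois)) {
    comp <- log_stage("segment", {
      rois <- if (is.character(config$rois)) readROIs(config$rois)
              else config$rois
      segmentCompartments(rois, lumen)
    })
  }
  leakage <- log_stage("ratio",
    leakageRatio(split$luminal, split$extraluminal, comp,
                 background = config$background,
                 guardRing = config$guardRing))
  vol <- prod(dim(stack@data)) * prod(stack@voxelSize)
  density <- log_stage("density",
    perfusedDensity(paths, vol, stack = split$luminal,
                    background = config$background))
  leakage@perfusedDensity <- density

  vessels <- log_stage("classify", {
    diam <- vapply(paths, function(p)
      as.numeric(measureDiameter(smoothed, p)), numeric(1))
    cbind(vessel_id = vapply(paths, function(p) p@vesselId, integer(1)),
          classifyVessels(diam))
  })

  sites <- log_stage("leaks", {
    sl <- extractLeakSites(split$extraluminal, paths,
                           config$detectionThreshold,
                           config$minSiteVoxels,
                           config$tieToleranceUm, config$maxAttributionUm,
                           lumen = lumen)
    wall <- .dilate26(lumen@mask)
    rows <- lapply(sl, function(s) {
      sp <- NA_real_
      if (length(s@vessels)) {
        ids <- vapply(paths, function(p) p@vesselId, integer(1))
        sp <- as.numeric(spreadingDistance(
          split$extraluminal, s, paths[[which(ids == s@vessels[1])]],
          config$detectionThreshold, config$sampleInterval,
          wallMask = wall))
      }
      data.frame(site_id = s@siteId,
                 vessel_id = if (length(s@vessels)) s@vessels[1] else NA,
                 vessel_id2 = if (length(s@vessels) > 1) s@vessels[2] else NA,
                 n_voxels = length(s@voxels),
                 wall_distance_um = if (length(s@wallDistance))
                   s@wallDistance[1] else NA,
                 spreading_um = sp)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  report <- list(
    timepoint = stack@timepoint,
    ratio_total = leakage@ratioTotal,
    ratio_parenchymal = leakage@ratioParenchymal,
    ratio_subarachnoid = leakage@ratioSubarachnoid,
    perfused_density_um_per_um3 = density,
    n_vessels = length(paths),
    n_leak_sites = if (is.null(sites)) 0L else nrow(sites),
    timings_s = as.list(timings))
  if (writeOutputs) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outputDir, f)
    cfg <- config
    cfg$stack <- if (is.character(config$stack)) config$stack else "<in-memory>"
    cfg$seeds <- if (is.character(config$seeds)) config$seeds else "<in-memory>"
    cfg$rois <- if (is.character(config$rois)) config$rois
                else if (is.null(config$rois)) NULL else "<in-memory>"
    jsonlite::write_json(unclass(cfg), out("config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    utils::write.csv(vessels, out("vessels.csv"), row.names = FALSE)
    if (!is.null(sites) && nrow(sites))
      utils::write.csv(sites, out("leak_sites.csv"), row.names = FALSE)
  }
  invisible(list(paths = paths, lumen = lumen, leakage = leakage,
                 vessels = vessels, sites = sites, timings = timings,
                 report = report))
}
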
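# Synthetic parameter-recovery experiments: generate phantoms whose ground
# truth is drawn from the published per-class statistics, push them through
# the full measurement chain, and return planted-vs-recovered tables.  These
# are the package's validation surface (see the methods vignette).

.class_cohort_ns <- c(A = 29, Ae = 28, C = 236, Ve = 190, V = 29)

#' Diameter-recovery experiment
#'
#' Draws \code{n} ground-truth diameters from the class diameter
#' distribution (truncated to the class band), renders a noise-free cylinder
#' phantom for each, traces it from its endpoints on the smoothed stack, and
#' re-measures the diameter with the FWHM operation (axial-curvature
#' corrected for the phantom PSF).
#'
#' @param class vessel class (\code{"A"}, \code{"Ae"}, \code{"C"},
#'   \code{"Ve"}, \code{"V"})
#' @param n cohort size; defaults to the published per-class cohort size
#' @param seed RNG seed
#' @param diameterMean,diameterSd generating distribution (um); defaults to
#'   the published class statistics
#' @return data.frame with \code{true_um} and \code{measured_um}
#' @export
diameterRecovery <- function(class, n = .class_cohort_ns[[class]], seed = 1,
                             diameterMean = .AV_DIAM_MEAN[[class]],
                             diameterSd = .AV_DIAM_SD[[class]]) {
  set.seed(seed)
  # draws follow the published statistics directly (truncated only at a
  # physical minimum): band-truncating would shift the generating mean
  true <- .rnorm_trunc(n, diameterMean, diameterSd, lo = 1)
  measured <- vapply(true, function(d) {
    cp <- cylinderPhantom(d, class = class)
    stk <- renderStack(cp$truth, cp$spec, noise = FALSE)
    sm <- smoothStack(stk, 1)
    ep <- pathPoints(truthPaths(cp$truth)[[1]])
    p <- traceVessel(sm, ep[c(1, nrow(ep)), ], estimateRadius = FALSE)
    as.numeric(measureDiameter(stk, p, maxSearch = 2 * d + 30,
                               axialSigma = cp$spec@psfSigma[3]))
  }, numeric(1))
  data.frame(class = class, true_um = true, measured_um = measured,
             stringsAsFactors = FALSE)
}

#' Spreading-distance-recovery experiment
#'
#' Plants \code{n} leak halos with ground-truth extents drawn from the class
#' spreading-distance distribution on class-typical cylinder phantoms,
#' renders noise-free, runs lumen filling, signal separation, site
#' extraction and the station-sampled spreading-distance measurement.  The
#' detection threshold is half the halo clipping floor
#' (\code{leakAmplitude * tracerIntensity * exp(-2) / 2}), the calibration
#' at which the blurred support edge sits at the planned extent.
#'
#' @param class vessel class
#' @param n number of planted sites
#' @param seed RNG seed
#' @param spreadingMean,spreadingSd generating distribution (um)
#' @param siteLength site extent along the vessel (um)
#' @return data.frame with \code{true_um} and \code{measured_um}
#' @export
spreadingRecovery <- function(class, n = 50, seed = 1,
                              spreadingMean = .AV_SPREAD_MEAN[[class]],
                              spreadingSd = .AV_SPREAD_SD[[class]],
                              siteLength = 30) {
  set.seed(seed)
  diam <- .rnorm_trunc(n, .AV_DIAM_MEAN[[class]], .AV_DIAM_SD[[class]],
                       lo = 1)
  true <- .rnorm_trunc(n, spreadingMean, spreadingSd, lo = 0.5)
  measured <- vapply(seq_len(n), function(t) {
    cp <- cylinderPhantom(diam[t], class = class, lengthUm = siteLength + 20,
                          marginUm = 4,
                          leak = list(position = 0.5, spreading_um = true[t],
                                      site_length_um = siteLength))
    stk <- renderStack(cp$truth, cp$spec, noise = FALSE)
    sm <- smoothStack(stk, 1)
    path <- truthPaths(cp$truth)[[1]]
    fl <- fillLumen(sm, path, 0.3)
    sp <- splitSignal(stk, fl)
    thr <- 0.5 * cp$spec@leakAmplitude * cp$spec@tracerIntensity * exp(-2)
    sites <- extractLeakSites(sp$extraluminal, list(path), thr, lumen = fl)
    if (!length(sites)) return(NA_real_)
    big <- sites[[which.max(lengths(lapply(sites, slot, "voxels")))]]
    wall <- .dilate26(lumenMask(fl))
    as.numeric(spreadingDistance(sp$extraluminal, big, path, thr,
                                 wallMask = wall))
  }, numeric(1))
  data.frame(class = class, true_um = true, measured_um = measured,
             stringsAsFactors = FALSE)
}

#' Leak-attribution-recovery experiment
#'
#' Builds a mixed-class vascular scene, plants leak-site centroids a few um
#' outside the wall of host vessels chosen with the requested per-class
#' counts, re-attributes every site to the nearest vessel wall (with the
#' equally-close tie rule), and tabulates planted versus recovered class
#' shares.
#'
#' @param counts named integer: planted sites per class
#' @param seed RNG seed
#' @param vesselCount scene composition
#' @param volumeSize scene extent (um)
#' @param maxWallOffset sites are planted at wall distances uniform in
#'   (1, maxWallOffset) um
#' @param tieToleranceUm attribution tie tolerance (um)
#' @return list: \code{sites} (planted class, attributed classes),
#'   \code{shares} (percent of attributions per class)
#' @export
attributionRecovery <- function(counts = c(Ve = 96, C = 50, Ae = 25,
                                           A = 13, V = 16),
                                seed = 1,
                                vesselCount = c(A = 2, Ae = 5, C = 20,
                                                Ve = 8, V = 2),
                                volumeSize = c(600, 600, 300),
                                maxWallOffset = 8,
                                tieToleranceUm = 0.58) {
  spec <- phantomSpec(volumeSize = volumeSize, vesselCount = vesselCount,
                      seed = seed)
  truth <- generateTree(spec, compartments = FALSE)
  paths <- truthPaths(truth)
  ids <- vapply(paths, function(p) p@vesselId, integer(1))
  classes <- truthClasses(truth)
  rows <- list()
  for (cl in names(counts)) {
    host <- ids[classes[as.character(ids)] == cl]
    stopifnot(length(host) > 0)
    vid <- host[1 + (seq_len(counts[[cl]]) - 1) %% length(host)]
    for (v in vid) {
      # a valid planted site is parenchymal: outside every vessel and
      # genuinely closest to its host wall (rejection-sampled; if one host
      # vessel offers no valid spot, the site moves to another vessel of
      # the same class)
      centroid <- NULL
      for (hv in c(v, sample(host))) {
        p <- paths[[which(ids == hv)]]
        res <- .resample_polyline(p@points, 1, values = p@radius)
        L <- max(res$arc)
        for (try in 1:60) {
          t <- which.min(abs(res$arc - runif(1, 0.15, 0.85) * L))
          tangent <- res$points[min(t + 1, nrow(res$points)), ] -
                     res$points[max(t - 1, 1), ]
          tangent <- tangent / sqrt(sum(tangent^2))
          u <- rnorm(3)
          u <- u - sum(u * tangent) * tangent
          u <- u / sqrt(sum(u^2))
          wd_host <- runif(1, 1, maxWallOffset)
          cand <- res$points[t, ] + (res$values[t] + wd_host) * u
          wd_other <- vapply(paths[ids != hv], function(q)
            wallDistance(cand, q), numeric(1))
          if (!length(wd_other) || min(wd_other) > wd_host + 1) {
            centroid <- cand
            v <- hv
            break
          }
        }
        if (!is.null(centroid)) break
      }
      if (is.null(centroid)) centroid <- cand
      got <- suppressWarnings(
        attributeLeak(centroid, paths, tieToleranceUm = tieToleranceUm))
      rows[[length(rows) + 1]] <- data.frame(
        planted_class = cl, planted_vessel = v,
        attributed = paste(classes[as.character(got)], collapse = "+"),
        stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, rows)
  tally <- table(unlist(strsplit(sites$attributed, "\\+")))
  shares <- 100 * as.numeric(tally) / sum(tally)
  names(shares) <- names(tally)
  list(sites = sites, shares = shares)
}

#' Constriction-recovery experiment
#'
#' Renders each phantom vessel before and after applying a seeded
#' constriction factor drawn from the class constriction distribution,
#' re-measures both diameters with the FWHM operation, and returns the
#' post/pre ratios.
#'
#' @param class vessel class
#' @param n number of segments; defaults to the published per-class count
#' @param seed RNG seed
#' @param constrictionMean,constrictionSd generating factor distribution
#' @return data.frame with \code{true_factor}, \code{measured_pre_um},
#'   \code{measured_post_um}, \code{measured_ratio}
#' @export
constrictionRecovery <- function(class,
                                 n = c(A = 7, Ae = 14, C = 113, Ve = 128,
                                       V = 16)[[class]],
                                 seed = 1,
                                 constrictionMean = .AV_CONSTR_MEAN[[class]],
                                 constrictionSd = 0.05) {
  set.seed(seed)
  diam <- .rnorm_trunc(n, .AV_DIAM_MEAN[[class]], .AV_DIAM_SD[[class]],
                       lo = 1)
  out <- lapply(seq_len(n), function(t) {
    cp <- cylinderPhantom(diam[t], class = class)
    cm <- structure(rep(1, 5), names = .AV_CLASSES)
    cm[class] <- constrictionMean
    cp$spec@constrictionMean <- cm
    cp$spec@constrictionSd <- structure(rep(constrictionSd, 5),
                                        names = .AV_CLASSES)
    measure <- function(truth) {
      stk <- renderStack(truth, cp$spec, noise = FALSE)
      sm <- smoothStack(stk, 1)
      ep <- pathPoints(truthPaths(truth)[[1]])
      p <- traceVessel(sm, ep[c(1, nrow(ep)), ], estimateRadius = FALSE)
      as.numeric(measureDiameter(stk, p, maxSearch = 2 * diam[t] + 30,
                                 axialSigma = cp$spec@psfSigma[3]))
    }
    pre <- measure(cp$truth)
    post_truth <- applyTimepoint(cp$truth, cp$spec, "post",
                                 render = FALSE)$truth
    post <- measure(post_truth)
    data.frame(true_factor = truthDiameters(post_truth)[[1]] / diam[t],
               measured_pre_um = pre, measured_post_um = post,
               measured_ratio = relativeChange(
                 diameterRecord(1L, 1L, "pre", pre),
                 diameterRecord(1L, 1L, "post", post))$ratio)
  })
  cbind(class = class, do.call(rbind, out))
}

#' Two-timepoint leak-progression-recovery experiment
#'
#' Plants matched leak sites on capillary phantoms, advances each to a
#' follow-up timepoint with a planted direction (exactly
#' \code{nIncreasing} growing, the rest shrinking), measures the spreading
#' distance at both timepoints through the full chain, and classifies the
#' per-site direction with \code{\link{leakProgression}}.
#'
#' @param n number of matched sites
#' @param nIncreasing planted number of growing sites
#' @param seed RNG seed
#' @return the \code{\link{leakProgression}} result, plus
#'   \code{plantedIncreased} and \code{agreement} (fraction of sites whose
#'   measured direction matches the planted one)
#' @export
progressionRecovery <- function(n = 100, nIncreasing = 67, seed = 1) {
  set.seed(seed)
  grow <- c(rep(TRUE, nIncreasing), rep(FALSE, n - nIncreasing))
  grow <- sample(grow)
  diam <- .rnorm_trunc(n, .AV_DIAM_MEAN[["C"]], .AV_DIAM_SD[["C"]],
                       lo = 0, hi = 10)
  s1 <- .rnorm_trunc(n, .AV_SPREAD_MEAN[["C"]], .AV_SPREAD_SD[["C"]],
                     lo = 1.5)
  measure <- function(truth, spec) {
    stk <- renderStack(truth, spec, noise = FALSE)
    sm <- smoothStack(stk, 1)
    path <- truthPaths(truth)[[1]]
    fl <- fillLumen(sm, path, 0.3)
    sp <- splitSignal(stk, fl)
    thr <- 0.5 * spec@leakAmplitude * spec@tracerIntensity * exp(-2)
    sites <- extractLeakSites(sp$extraluminal, list(path), thr, lumen = fl)
    if (!length(sites)) return(NA_real_)
    big <- sites[[which.max(lengths(lapply(sites, slot, "voxels")))]]
    wall <- .dilate26(lumenMask(fl))
    as.numeric(spreadingDistance(sp$extraluminal, big, path, thr,
                                 wallMask = wall))
  }
  m1 <- m2 <- numeric(n)
  for (t in seq_len(n)) {
    cp <- cylinderPhantom(diam[t], class = "C", lengthUm = 45, marginUm = 4,
                          leak = list(position = 0.5, spreading_um = s1[t],
                                      site_length_um = 25))
    m1[t] <- measure(cp$truth, cp$spec)
    adv <- applyTimepoint(cp$truth, cp$spec, "t2",
                          nIncreasing = as.integer(grow[t]),
                          constrict = FALSE, render = FALSE)
    m2[t] <- measure(adv$truth, cp$spec)
  }
  # a site with no detectable component has receded below the detection
  # floor: its measured extent is zero
  m1[is.na(m1)] <- 0
  m2[is.na(m2)] <- 0
  pr <- leakProgression(data.frame(site_id = seq_len(n), spreading_um = m1),
                        data.frame(site_id = seq_len(n), spreading_um = m2))
  pr$plantedIncreased <- nIncreasing
  pr$agreement <- mean((pr$perSite$direction == "increased") == grow)
  pr
}
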
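#' Render a phantom truth into an image stack
#'
#' Forward imaging model: perfused lumina are filled with the tracer
#' intensity, unperfused lumina stay dark, and every planted leak site adds
#' an extraluminal halo decaying from the vessel wall as a half-Gaussian of
#' scale \code{spreading_um / 2}, clipped at the intensity floor
#' \code{exp(-2)} times the wall amplitude so that the most distant rendered
#' signal sits exactly at the planned spreading distance.  The volume is then
#' convolved with the Gaussian PSF and, if requested, shot and read noise are
#' added.  The optional endothelial-reporter channel renders a wall shell for
#' every vessel regardless of perfusion.
#'
#' @param truth a \linkS4class{PhantomTruth}
#' @param spec the \linkS4class{PhantomSpec} it was generated from
#' @param reporter also render the endothelial-reporter channel
#' @param noise add Gaussian/Poisson noise per the PhantomSpec noise model
#' @param blur convolve with the PSF (disable for geometric ground-truth
#'   renders)
#' @param antialias render the lumen edge with partial-volume weights (the
#'   fraction of the voxel inside the tube, approximated along the radial
#'   direction) instead of binary center-in-tube voxelization; emulates the
#'   detector integrating over the voxel and removes grid-phase artifacts
#' @param seed optional RNG seed for the noise draw
#' @return an \linkS4class{ImageStack} (tracer), or a list with elements
#'   \code{tracer} and \code{reporter} when \code{reporter = TRUE}
#' @examples
#' spec <- phantomSpec(vesselCount = c(C = 2), seed = 5, noiseGaussianSd = 0)
#' truth <- generateTree(spec)
#' stk <- renderStack(truth, spec, noise = FALSE)
#' @export
setGeneric("renderStack",
  function(truth, spec, reporter = FALSE, noise = TRUE, blur = TRUE,
           antialias = TRUE, seed = NULL)
    standardGeneric("renderStack"))

#' @rdname renderStack
#' @export
setMethod("renderStack", signature(truth = "PhantomTruth", spec = "PhantomSpec"),
  function(truth, spec, reporter = FALSE, noise = TRUE, blur = TRUE,
           antialias = TRUE, seed = NULL) {
  dims <- truth@dims
  vox <- truth@voxelSizeUm
  tracer <- array(0, dims)
  rep_ch <- if (reporter) array(0, dims)
  h_aa <- mean(vox)   # effective voxel extent for partial-volume weighting

  for (p in truth@paths) {
    id <- as.character(p@vesselId)
    geo <- cpp_tube_geometry(dims, vox, p@points, p@radius,
                             if (antialias) h_aa else 0)
    fin <- is.finite(geo$dcen)
    if (truth@perfused[[id]]) {
      if (antialias) {
        w <- pmin(pmax(0.5 + (geo$rad - geo$dcen) / h_aa, 0), 1)
        w[!fin] <- 0
        sel <- w > 0
        tracer[sel] <- pmax(tracer[sel], spec@tracerIntensity * w[sel])
      } else {
        tracer[fin & geo$dcen <= geo$rad] <- spec@tracerIntensity
      }
    }
    if (reporter) {
      shell <- fin & geo$dcen <= geo$rad & geo$dcen >= pmax(geo$rad - 1.5, 0)
      rep_ch[shell] <- spec@tracerIntensity
    }
  }

  if (nrow(truth@leaks)) {
    amp <- spec@leakAmplitude * spec@tracerIntensity
    ids <- vapply(truth@paths, function(p) p@vesselId, integer(1))
    for (t in seq_len(nrow(truth@leaks))) {
      lk <- truth@leaks[t, ]
      p <- truth@paths[[which(ids == lk$vessel_id)]]
      L <- pathLength(p)
      a0 <- lk$position * L - lk$site_length_um / 2
      a1 <- lk$position * L + lk$site_length_um / 2
      geo <- cpp_tube_geometry(dims, vox, p@points, p@radius,
                               lk$spreading_um + 1)
      sdist <- geo$dcen - geo$rad
      sel <- which(is.finite(geo$dcen) & sdist > 0 &
                   sdist <= lk$spreading_um &
                   geo$arc >= a0 & geo$arc <= a1)
      if (!length(sel)) next
      halo <- amp * exp(-sdist[sel]^2 / (2 * (lk$spreading_um / 2)^2))
      tracer[sel] <- pmax(tracer[sel], halo)
    }
  }

  sigma_vox <- c(spec@psfSigma[2] / vox[2], spec@psfSigma[1] / vox[1],
                 spec@psfSigma[3] / vox[3])
  finish <- function(a, channel) {
    if (blur) a <- .gauss_blur3(a, sigma_vox)
    if (noise) {
      if (!is.null(seed)) set.seed(seed)
      if (spec@noisePoissonScale > 0)
        a <- array(rpois(length(a), a * spec@noisePoissonScale) /
                     spec@noisePoissonScale, dims)
      if (spec@noiseGaussianSd > 0)
        a <- a + array(rnorm(length(a), 0, spec@noiseGaussianSd), dims)
      a[a < 0] <- 0
    }
    ImageStack(a, vox, channel = channel, timepoint = truth@timepoint)
  }
  out <- finish(tracer, "tracer")
  if (reporter) list(tracer = out, reporter = finish(rep_ch, "reporter"))
  else out
})

#' Advance a phantom to a follow-up timepoint
#'
#' Produces the truth (and optionally the rendered stack) of a later
#' timepoint: a configured number of leak sites get strictly larger
#' ground-truth spreading distances and the rest strictly smaller, and every
#' vessel is constricted by a factor drawn from its class constriction
#' distribution (truncated to (0, 1]).  Site identities are preserved so
#' two-timepoint progression can be evaluated against the planted directions
#' (recorded in the \code{direction} column of \code{truthLeaks()}).
#'
#' @param truth the \linkS4class{PhantomTruth} of the earlier timepoint
#' @param spec the generating \linkS4class{PhantomSpec}
#' @param tag timepoint tag of the new state; must differ from
#'   \code{truth@timepoint}
#' @param nIncreasing number of leak sites whose spreading grows (default:
#'   67 percent of sites, the acute-phase share of persistently leaking
#'   vessels)
#' @param growRange,shrinkRange multiplicative factor ranges for growing and
#'   receding sites
#' @param constrict apply the per-class constriction factors
#' @param render also render the follow-up stack
#' @param noise,seed forwarded to \code{\link{renderStack}}
#' @return a list with \code{truth} and (when \code{render = TRUE})
#'   \code{stack}
#' @export
applyTimepoint <- function(truth, spec, tag,
                           nIncreasing = round(0.67 * nrow(truth@leaks)),
                           growRange = c(1.15, 1.6),
                           shrinkRange = c(0.5, 0.85),
                           constrict = TRUE, render = TRUE,
                           noise = TRUE, seed = NULL) {
  if (identical(tag, truth@timepoint))
    stop("timepoint tag collision: '", tag, "' already current")
  new_truth <- truth
  new_truth@timepoint <- tag

  if (constrict && length(truth@paths)) {
    ids <- vapply(truth@paths, function(p) p@vesselId, integer(1))
    for (t in seq_along(truth@paths)) {
      cl <- truth@classes[[as.character(ids[t])]]
      f <- .rnorm_trunc(1, spec@constrictionMean[[cl]],
                        spec@constrictionSd[[cl]], lo = 0, hi = 1)
      p <- new_truth@paths[[t]]
      p@radius <- p@radius * f
      new_truth@paths[[t]] <- p
      new_truth@diametersUm[[as.character(ids[t])]] <-
        new_truth@diametersUm[[as.character(ids[t])]] * f
    }
  }

  lk <- new_truth@leaks
  if (nrow(lk)) {
    if (nIncreasing > nrow(lk)) stop("nIncreasing exceeds site count")
    inc <- rep(FALSE, nrow(lk))
    inc[sample(nrow(lk), nIncreasing)] <- TRUE
    fac <- ifelse(inc, runif(nrow(lk), growRange[1], growRange[2]),
                  runif(nrow(lk), shrinkRange[1], shrinkRange[2]))
    lk$spreading_um <- lk$spreading_um * fac
    lk$direction <- ifelse(inc, "increased", "decreased")
    lk$onset <- tag
    new_truth@leaks <- lk
  }

  # lumen compartment labels follow the constricted radii
  new_truth@compartments <- .compartment_array(
    new_truth@paths, new_truth@perfused, new_truth@dims,
    new_truth@voxelSizeUm, spec@curvatureDepth)

  out <- list(truth = new_truth)
  if (render)
    out$stack <- renderStack(new_truth, spec, noise = noise, seed = seed)
  out
}
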
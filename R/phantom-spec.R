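# Vessel-class constants shared by the phantom generator and the classifier.
# Diameter bands (um): A > 45; Ae 10-45; C < 10; Ve 10-50; V > 50.
.AV_CLASSES <- c("A", "Ae", "C", "Ve", "V")
.AV_BOUNDS <- data.frame(
  class = .AV_CLASSES,
  lo = c(45, 10, 0, 10, 50),
  hi = c(Inf, 45, 10, 50, Inf),
  lo_open = c(TRUE, FALSE, TRUE, FALSE, TRUE),
  hi_open = c(TRUE, FALSE, TRUE, FALSE, TRUE),
  stringsAsFactors = FALSE)

# cohort diameter distributions along the AV axis (um, mean / sd)
.AV_DIAM_MEAN <- c(A = 74.1, Ae = 26.8, C = 6.1, Ve = 21.3, V = 76.7)
.AV_DIAM_SD   <- c(A = 14.5, Ae = 8.0,  C = 1.2, Ve = 8.9,  V = 25.0)
# post-occlusion constriction: mean diameter decrease per class (fractions);
# arterial side constricts most, venules and capillaries least
.AV_CONSTR_MEAN <- 1 - c(A = 0.218, Ae = 0.265, C = 0.113, Ve = 0.131, V = 0.206)
# leak spreading-distance distributions (um).  Arteriole/venule values are not
# separately reported for the acute phase; the generator defaults interpolate
# between the arterial/venous and capillary figures.
.AV_SPREAD_MEAN <- c(A = 14.1, Ae = 10.0, C = 6.0, Ve = 10.0, V = 13.9)
.AV_SPREAD_SD   <- c(A = 5.4,  Ae = 4.0,  C = 3.0, Ve = 4.0,  V = 5.8)

.in_band <- function(d, row) {
  (if (row$lo_open) d > row$lo else d >= row$lo) &
    (if (row$hi_open) d < row$hi else d <= row$hi)
}

#' Specification of a synthetic two-photon vascular phantom
#'
#' Bundles the acquisition geometry, the vascular composition, the forward
#' imaging model (tracer intensity, point-spread function, noise), planned
#' leak sites, and the occlusion/constriction conditions of a simulated
#' stack.  Defaults emulate the imaging geometry of the intravital protocol
#' (0.58 x 0.58 x 1 um voxels; the full 1024 x 1024 field is scaled down to
#' 256 x 256 for desk-scale work) and the per-class vessel calibers of the
#' murine cortical vasculature.
#'
#' @slot volumeSize physical volume (x, y, z) in um
#' @slot voxelSize voxel pitch (x, y, z) in um
#' @slot vesselCount named integer: vessels per class (A, Ae, C, Ve, V)
#' @slot diameterMean,diameterSd named numeric: per-class diameter
#'   distributions in um; draws are truncated to the class diameter band
#' @slot tracerIntensity luminal tracer intensity (arbitrary units)
#' @slot leakAmplitude halo intensity at the vessel wall as a fraction of
#'   \code{tracerIntensity}
#' @slot psfSigma Gaussian PSF sigma (x, y, z) in um
#' @slot noiseGaussianSd additive Gaussian noise sd (absolute units; 0 = off)
#' @slot noisePoissonScale photon-count scale for shot noise (0 = off)
#' @slot leaks data.frame of planned leaks: columns \code{vessel} (vessel id
#'   or class name, resolved at generation), \code{position} (fraction along
#'   the path), \code{spreading_um} (ground-truth halo extent),
#'   \code{site_length_um}, \code{onset}
#' @slot constrictionMean,constrictionSd named numeric: per-class post/pre
#'   diameter factor distributions, in (0, 1]
#' @slot occludedFraction fraction of vessels rendered unperfused
#' @slot curvatureDepth sag of the curved brain surface (um) separating
#'   subarachnoid space (above) from parenchyma (below); 0 = flat surface at
#'   z = 0 (all parenchyma)
#' @slot tortuosityAmp,tortuosityPeriod sinusoidal centerline perturbation
#'   (um)
#' @slot seed integer RNG seed; generation is deterministic given the seed
#' @export
setClass("PhantomSpec",
  representation(volumeSize = "numeric", voxelSize = "numeric",
                 vesselCount = "integer", diameterMean = "numeric",
                 diameterSd = "numeric", tracerIntensity = "numeric",
                 leakAmplitude = "numeric", psfSigma = "numeric",
                 noiseGaussianSd = "numeric", noisePoissonScale = "numeric",
                 leaks = "data.frame", constrictionMean = "numeric",
                 constrictionSd = "numeric", occludedFraction = "numeric",
                 curvatureDepth = "numeric", tortuosityAmp = "numeric",
                 tortuosityPeriod = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (any(object@volumeSize <= 0) || any(object@voxelSize <= 0))
    return("volume and voxel sizes must be > 0")
  if (!all(.AV_CLASSES %in% names(object@vesselCount)))
    return("vesselCount must name all classes A, Ae, C, Ve, V")
  if (any(object@vesselCount < 0)) return("vessel counts must be >= 0")
  for (cl in .AV_CLASSES) {
    row <- .AV_BOUNDS[.AV_BOUNDS$class == cl, ]
    if (object@vesselCount[[cl]] > 0 &&
        !.in_band(object@diameterMean[[cl]], row))
      return(sprintf("diameter mean for class %s outside its band", cl))
  }
  if (object@occludedFraction < 0 || object@occludedFraction > 1)
    return("occludedFraction must lie in [0, 1]")
  if (any(object@constrictionMean <= 0) || any(object@constrictionMean > 1))
    return("constriction factors must lie in (0, 1]")
  if (nrow(object@leaks)) {
    if (any(object@leaks$spreading_um <= 0))
      return("planned spreading distances must be > 0")
    if (any(object@leaks$position < 0 | object@leaks$position > 1))
      return("leak positions must lie in [0, 1]")
  }
  TRUE
})

#' Build a PhantomSpec
#'
#' @param volumeSize physical volume (x, y, z) um
#' @param voxelSize voxel pitch (x, y, z) um
#' @param vesselCount named vector of per-class vessel counts
#' @param diameterMean,diameterSd per-class diameter distributions (um)
#' @param tracerIntensity luminal intensity (arbitrary units)
#' @param leakAmplitude wall halo intensity as fraction of tracerIntensity
#' @param psfSigma PSF sigma (x, y, z) um
#' @param noiseGaussianSd additive noise sd; default 5 percent of
#'   \code{tracerIntensity}
#' @param noisePoissonScale shot-noise scale (counts per intensity unit;
#'   0 disables)
#' @param leaks planned-leak data.frame (see \linkS4class{PhantomSpec})
#' @param constrictionMean,constrictionSd per-class post/pre diameter factors
#' @param occludedFraction fraction of vessels rendered unperfused
#' @param curvatureDepth brain-surface sag in um
#' @param tortuosityAmp,tortuosityPeriod centerline sinusoid (um)
#' @param seed RNG seed
#' @return a \linkS4class{PhantomSpec}
#' @examples
#' spec <- phantomSpec(vesselCount = c(A = 1, Ae = 2, C = 4, Ve = 2, V = 1),
#'                     seed = 7)
#' @export
phantomSpec <- function(volumeSize = c(148.48, 148.48, 64),
                        voxelSize = c(0.58, 0.58, 1),
                        vesselCount = c(A = 0, Ae = 0, C = 0, Ve = 0, V = 0),
                        diameterMean = .AV_DIAM_MEAN,
                        diameterSd = .AV_DIAM_SD,
                        tracerIntensity = 100,
                        leakAmplitude = 0.5,
                        psfSigma = c(0.25, 0.25, 0.5),
                        noiseGaussianSd = 0.05 * tracerIntensity,
                        noisePoissonScale = 0,
                        leaks = data.frame(),
                        constrictionMean = .AV_CONSTR_MEAN,
                        constrictionSd = rep(0.05, 5),
                        occludedFraction = 0,
                        curvatureDepth = 0,
                        tortuosityAmp = 1.2,
                        tortuosityPeriod = 45,
                        seed = 1L) {
  cnt <- structure(integer(5), names = .AV_CLASSES)
  cnt[names(vesselCount)] <- as.integer(vesselCount)
  nm <- function(x) {
    if (is.null(names(x))) names(x) <- .AV_CLASSES
    x[.AV_CLASSES]
  }
  new("PhantomSpec", volumeSize = volumeSize, voxelSize = voxelSize,
      vesselCount = cnt, diameterMean = nm(diameterMean),
      diameterSd = nm(diameterSd), tracerIntensity = tracerIntensity,
      leakAmplitude = leakAmplitude, psfSigma = psfSigma,
      noiseGaussianSd = noiseGaussianSd,
      noisePoissonScale = noisePoissonScale, leaks = leaks,
      constrictionMean = nm(constrictionMean),
      constrictionSd = nm(constrictionSd),
      occludedFraction = occludedFraction, curvatureDepth = curvatureDepth,
      tortuosityAmp = tortuosityAmp, tortuosityPeriod = tortuosityPeriod,
      seed = as.integer(seed))
}

#' Ground truth of a generated phantom
#'
#' Complete description of a simulated stack: centerline paths with true
#' radii, per-vessel class and diameter, perfusion state, planted leak sites,
#' and the per-voxel compartment labels.
#'
#' @slot paths list of \linkS4class{VesselPath}
#' @slot classes named character: vessel id -> class
#' @slot diametersUm named numeric: vessel id -> true diameter (um)
#' @slot perfused named logical: vessel id -> perfusion state
#' @slot leaks data.frame: \code{site_id}, \code{vessel_id}, \code{position},
#'   \code{spreading_um}, \code{site_length_um}, \code{onset}
#' @slot compartments integer array (1 parenchyma, 2 subarachnoid, 3 lumen)
#' @slot dims,voxelSizeUm the voxel grid the compartments refer to
#' @slot perfusedLength total centerline length of perfused vessels (um)
#' @slot timepoint character tag
#' @export
setClass("PhantomTruth",
  representation(paths = "list", classes = "character",
                 diametersUm = "numeric", perfused = "logical",
                 leaks = "data.frame", compartments = "arrayOrNULL",
                 dims = "integer", voxelSizeUm = "numeric",
                 perfusedLength = "numeric", timepoint = "character"),
  prototype(compartments = NULL, timepoint = "t0"))

setValidity("PhantomTruth", function(object) {
  ids <- vapply(object@paths, function(p) p@vesselId, integer(1))
  if (nrow(object@leaks) && !all(object@leaks$vessel_id %in% ids))
    return("leak sites must reference existing vessel ids")
  if (!is.null(object@compartments) &&
      !all(object@compartments %in% 1:3))
    return("compartment labels must partition the volume into {1,2,3}")
  TRUE
})

#' @rdname PhantomTruth-class
#' @param x a PhantomTruth
#' @export
truthPaths <- function(x) x@paths

#' @rdname PhantomTruth-class
#' @export
truthClasses <- function(x) x@classes

#' @rdname PhantomTruth-class
#' @export
truthDiameters <- function(x) x@diametersUm

#' @rdname PhantomTruth-class
#' @export
truthLeaks <- function(x) x@leaks

#' @rdname PhantomTruth-class
#' @export
truthPerfusedLength <- function(x) x@perfusedLength

#' @rdname PhantomTruth-class
#' @export
truthCompartments <- function(x) x@compartments

setMethod("show", "PhantomTruth", function(object) {
  tab <- table(factor(object@classes, levels = .AV_CLASSES))
  cat(sprintf("PhantomTruth [%s]: %d vessels (%s)\n", object@timepoint,
              length(object@paths),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  perfused length %.1f um; %d planted leak site(s)\n",
              object@perfusedLength, nrow(object@leaks)))
})
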
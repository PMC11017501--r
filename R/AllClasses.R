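#' @useDynLib avleak, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot show
#' @importFrom stats median approx dnorm rnorm runif rpois quantile sd t.test
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' 3D intensity stack with physical voxel sizes
#'
#' A single-channel 3D voxel grid, the central image container of the package.
#' The array is ordered \code{[y, x, z]} (a TIFF page is one z-plane, matrix
#' rows run along y) and voxel centers sit at \code{(index - 0.5) *
#' voxelSize}, so all coordinates handed to tracing and measurement functions
#' are physical micrometres.
#'
#' @slot data numeric 3D array of non-negative intensities (arbitrary units)
#' @slot voxelSize numeric length-3, voxel pitch in um along (x, y, z)
#' @slot channel character tag, e.g. \code{"tracer"} or \code{"reporter"}
#' @slot timepoint character tag, e.g. \code{"pre"} or \code{"post30min"}
#' @export
setClass("ImageStack",
  representation(data = "array", voxelSize = "numeric",
                 channel = "character", timepoint = "character"),
  prototype(voxelSize = c(0.58, 0.58, 1), channel = "tracer",
            timepoint = "t0"))

setValidity("ImageStack", function(object) {
  if (length(dim(object@data)) != 3) return("data must be a 3D array")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (um)")
  if (any(object@data < 0, na.rm = TRUE)) return("intensities must be >= 0")
  TRUE
})

#' Construct an ImageStack
#'
#' @param data 3D numeric array ordered \code{[y, x, z]}
#' @param voxelSize voxel pitch in um along (x, y, z)
#' @param channel,timepoint character tags carried through the analysis
#' @return an \linkS4class{ImageStack}
#' @export
ImageStack <- function(data, voxelSize = c(0.58, 0.58, 1),
                       channel = "tracer", timepoint = "t0") {
  new("ImageStack", data = data, voxelSize = as.numeric(voxelSize),
      channel = channel, timepoint = timepoint)
}

#' @describeIn ImageStack intensity array accessor
#' @param object,x an ImageStack
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname ImageStack-class
#' @export
setMethod("intensities", "ImageStack", function(x) x@data)

#' Voxel pitch accessor
#' @param x an object with a voxel grid
#' @return numeric length-3 voxel pitch in um (x, y, z)
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack [%s]: %d x %d x %d voxels (y,x,z), %.2f x %.2f x %.2f um/voxel\n",
              object@channel, d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  timepoint: %s; intensity range [%.3g, %.3g]\n",
              object@timepoint, min(object@data), max(object@data)))
})

#' Ordered 3D vessel centerline with per-point radii
#'
#' @slot vesselId integer vessel identity
#' @slot points n x 3 matrix of (x, y, z) centerline coordinates in um
#' @slot radius per-point radius estimate in um (NA where not measured)
#' @slot parent integer id of the parent vessel at the proximal branch point,
#'   or NULL for a root vessel
#' @export
setClass("VesselPath",
  representation(vesselId = "integer", points = "matrix", radius = "numeric",
                 parent = "integerOrNULL"),
  prototype(parent = NULL))

setValidity("VesselPath", function(object) {
  if (nrow(object@points) < 2) return("a path needs at least 2 points")
  if (ncol(object@points) != 3) return("points must be n x 3 (x, y, z um)")
  if (length(object@radius) != nrow(object@points))
    return("one radius per point required")
  if (any(object@radius <= 0, na.rm = TRUE))
    return("radii must be > 0 where set")
  TRUE
})

#' Construct a VesselPath
#' @param vesselId integer id
#' @param points n x 3 matrix of um coordinates
#' @param radius per-point radius (um); recycled if scalar
#' @param parent parent vessel id or NULL
#' @return a \linkS4class{VesselPath}
#' @export
VesselPath <- function(vesselId, points, radius = NA_real_, parent = NULL) {
  points <- .as_points(points)
  if (length(radius) == 1) radius <- rep(radius, nrow(points))
  new("VesselPath", vesselId = as.integer(vesselId), points = points,
      radius = as.numeric(radius),
      parent = if (is.null(parent)) NULL else as.integer(parent))
}

#' @rdname VesselPath-class
#' @param x a VesselPath
#' @export
pathPoints <- function(x) x@points

#' @rdname VesselPath-class
#' @export
pathRadius <- function(x) x@radius

#' @rdname VesselPath-class
#' @export
pathLength <- function(x) .polyline_length(x@points)

setMethod("show", "VesselPath", function(object) {
  cat(sprintf("VesselPath #%d: %d points, length %.1f um, radius %.2f-%.2f um%s\n",
              object@vesselId, nrow(object@points),
              .polyline_length(object@points),
              suppressWarnings(min(object@radius, na.rm = TRUE)),
              suppressWarnings(max(object@radius, na.rm = TRUE)),
              if (!is.null(object@parent))
                sprintf(", parent #%d", object@parent) else ""))
})

#' Filled vessel lumen mask
#'
#' Boolean voxel membership produced by intensity-constrained region growing
#' from a traced centerline, with per-voxel vessel ownership.  Ownership is
#' disjoint: where fills of several vessels overlap, the voxel belongs to the
#' vessel whose centerline is nearest in um (ties to the lower vessel id).
#'
#' @slot mask logical 3D array of lumen membership
#' @slot owner integer 3D array, owning vesselId per voxel (0 outside)
#' @slot voxelSize voxel pitch in um (x, y, z)
#' @slot fillThreshold absolute intensity threshold used for acceptance
#' @export
setClass("LumenMask",
  representation(mask = "array", owner = "array", voxelSize = "numeric",
                 fillThreshold = "numeric"))

setValidity("LumenMask", function(object) {
  if (!identical(dim(object@mask), dim(object@owner)))
    return("mask and owner must share dimensions")
  if (any(object@owner[!object@mask] != 0))
    return("owner must be 0 outside the mask")
  TRUE
})

#' @rdname LumenMask-class
#' @param x a LumenMask
#' @export
lumenMask <- function(x) x@mask

#' @rdname LumenMask-class
#' @export
lumenOwner <- function(x) x@owner

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "LumenMask", function(x) x@voxelSize)

setMethod("show", "LumenMask", function(object) {
  ids <- sort(unique(object@owner[object@owner > 0]))
  cat(sprintf("LumenMask: %d voxels (%.0f um^3) across %d vessel(s); fill threshold %.3g\n",
              sum(object@mask), sum(object@mask) * prod(object@voxelSize),
              length(ids), object@fillThreshold))
})

#' Lumen / parenchyma / subarachnoid compartment labels
#'
#' Per-voxel compartment labels used to split the leakage ratio between brain
#' parenchyma and subarachnoid space.  \code{roi} holds the region-of-interest
#' label (1 = parenchyma, 2 = subarachnoid) from the per-plane polygons;
#' \code{lumen} marks vessel-lumen voxels, which override the ROI label in the
#' combined view returned by \code{compartmentLabels()} (3 = lumen).
#'
#' @slot roi integer 3D array (1 parenchyma, 2 subarachnoid)
#' @slot lumen logical 3D array
#' @slot voxelSize voxel pitch in um
#' @slot provenance list of the ROI polygons used
#' @export
setClass("CompartmentMap",
  representation(roi = "array", lumen = "array", voxelSize = "numeric",
                 provenance = "list"))

#' @rdname CompartmentMap-class
#' @param x a CompartmentMap
#' @return integer array: 1 parenchyma, 2 subarachnoid, 3 lumen
#' @export
compartmentLabels <- function(x) {
  out <- x@roi
  out[x@lumen] <- 3L
  out
}

setMethod("show", "CompartmentMap", function(object) {
  lab <- compartmentLabels(object)
  cat(sprintf("CompartmentMap: %d parenchyma, %d subarachnoid, %d lumen voxels\n",
              sum(lab == 1L), sum(lab == 2L), sum(lab == 3L)))
})

#' A localized extraluminal leak site
#'
#' A connected component of extraluminal tracer signal, attributed to the
#' nearest vessel(s) by wall distance, with its station-sampled spreading
#' distance.
#'
#' @slot siteId integer
#' @slot voxels 1-based linear voxel indices of the site support
#' @slot dims dimensions of the grid the indices refer to
#' @slot centroid intensity-weighted centroid (x, y, z um)
#' @slot vessels attributed vessel id(s) (1, or 2 when equally close)
#' @slot wallDistance wall distance(s) of the attributed vessel(s), um
#' @slot spreadingDistance station-averaged maximal wall-to-signal distance, um
#' @slot sampleInterval station spacing along the site, um (in [1, 2])
#' @slot timepoint character tag
#' @export
setClass("LeakSite",
  representation(siteId = "integer", voxels = "integer", dims = "integer",
                 centroid = "numeric", vessels = "integer",
                 wallDistance = "numeric", spreadingDistance = "numeric",
                 sampleInterval = "numeric", timepoint = "character"),
  prototype(vessels = integer(0), wallDistance = numeric(0),
            spreadingDistance = NA_real_, sampleInterval = 1,
            timepoint = "t0"))

setValidity("LeakSite", function(object) {
  if (length(object@sampleInterval) == 1 &&
      (object@sampleInterval < 1 || object@sampleInterval > 2))
    return("sampleInterval must lie in [1, 2] um")
  if (!is.na(object@spreadingDistance) && object@spreadingDistance < 0)
    return("spreadingDistance must be >= 0")
  TRUE
})

setMethod("show", "LeakSite", function(object) {
  cat(sprintf("LeakSite #%d: %d voxels, vessel(s) %s, spreading %.2f um\n",
              object@siteId, length(object@voxels),
              paste(object@vessels, collapse = "+"),
              object@spreadingDistance))
})

#' Leakage quantification result
#'
#' The normalized 3D leakage ratio (extraluminal / luminal signal, summed over
#' the whole z-stack) overall and per compartment, plus the perfused vessel
#' density.  A ratio is NA with an entry in \code{flags} when its luminal sum
#' is zero (undefined, not an error).
#'
#' @slot timepoint character tag
#' @slot ratioTotal,ratioParenchymal,ratioSubarachnoid dimensionless ratios
#' @slot luminalSum,extraluminalSum background-subtracted intensity sums
#' @slot perfusedDensity um vessel length per um^3 imaged volume (NA if not
#'   computed)
#' @slot flags character vector of quality flags
#' @export
setClass("LeakageResult",
  representation(timepoint = "character", ratioTotal = "numeric",
                 ratioParenchymal = "numeric", ratioSubarachnoid = "numeric",
                 luminalSum = "numeric", extraluminalSum = "numeric",
                 perfusedDensity = "numeric", flags = "character"),
  prototype(ratioParenchymal = NA_real_, ratioSubarachnoid = NA_real_,
            perfusedDensity = NA_real_, flags = character(0)))

setValidity("LeakageResult", function(object) {
  if (any(c(object@luminalSum, object@extraluminalSum) < 0, na.rm = TRUE))
    return("signal sums must be >= 0")
  TRUE
})

setMethod("show", "LeakageResult", function(object) {
  cat(sprintf("LeakageResult [%s]\n", object@timepoint))
  cat(sprintf("  ratio total        : %.4f\n", object@ratioTotal))
  if (!is.na(object@ratioParenchymal))
    cat(sprintf("  ratio parenchymal  : %.4f\n", object@ratioParenchymal))
  if (!is.na(object@ratioSubarachnoid))
    cat(sprintf("  ratio subarachnoid : %.4f\n", object@ratioSubarachnoid))
  if (!is.na(object@perfusedDensity))
    cat(sprintf("  perfused density   : %.3e um/um^3\n", object@perfusedDensity))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Serial-section masks for infarct volumetry
#'
#' Binary infarct and ipsilateral-hemisphere masks for a series of coronal
#' sections of uniform thickness.
#'
#' @slot infarct list of logical matrices, one per section
#' @slot hemisphere list of logical matrices, one per section
#' @slot pixelSizeMm pixel edge length in mm
#' @slot sectionThicknessMm section thickness in mm (recorded; cancels in the
#'   volume-percentage formula)
#' @export
setClass("SectionMaskSet",
  representation(infarct = "list", hemisphere = "list",
                 pixelSizeMm = "numeric", sectionThicknessMm = "numeric"),
  prototype(pixelSizeMm = 1, sectionThicknessMm = 2))

setValidity("SectionMaskSet", function(object) {
  if (length(object@infarct) < 1) return("need at least one section")
  if (length(object@infarct) != length(object@hemisphere))
    return("infarct and hemisphere section counts differ")
  for (s in seq_along(object@infarct)) {
    if (!identical(dim(object@infarct[[s]]), dim(object@hemisphere[[s]])))
      return(sprintf("section %d: mask dimensions differ", s))
    if (any(object@infarct[[s]] & !object@hemisphere[[s]]))
      return(sprintf("section %d: infarct outside hemisphere", s))
  }
  TRUE
})

#' Construct a SectionMaskSet
#' @param infarct,hemisphere lists of logical matrices (one per section)
#' @param pixelSizeMm pixel edge in mm
#' @param sectionThicknessMm section thickness in mm
#' @return a \linkS4class{SectionMaskSet}
#' @export
SectionMaskSet <- function(infarct, hemisphere, pixelSizeMm = 1,
                           sectionThicknessMm = 2) {
  new("SectionMaskSet", infarct = lapply(infarct, function(m) m > 0),
      hemisphere = lapply(hemisphere, function(m) m > 0),
      pixelSizeMm = pixelSizeMm, sectionThicknessMm = sectionThicknessMm)
}
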
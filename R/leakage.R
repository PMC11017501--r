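#' Split a stack into luminal and extraluminal signal
#'
#' The luminal stack keeps the intensities on lumen voxels and is zero
#' elsewhere; the extraluminal stack is the complement.  Their voxel-wise sum
#' reconstructs the input exactly.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param lumen a \linkS4class{LumenMask} on the same grid
#' @return list with \code{luminal} and \code{extraluminal} ImageStacks
#' @export
setGeneric("splitSignal",
  function(stack, lumen) standardGeneric("splitSignal"))

#' @rdname splitSignal
#' @export
setMethod("splitSignal", signature(stack = "ImageStack", lumen = "LumenMask"),
  function(stack, lumen) {
  if (!identical(dim(stack@data), dim(lumen@mask)))
    stop("stack and lumen mask are on different grids")
  lum <- stack
  lum@data <- stack@data * lumen@mask
  lum@channel <- paste0(stack@channel, ".luminal")
  ext <- stack
  ext@data <- stack@data * !lumen@mask
  ext@channel <- paste0(stack@channel, ".extraluminal")
  list(luminal = lum, extraluminal = ext)
})

#' Normalized 3D leakage ratio
#'
#' Sums the background-subtracted extraluminal and luminal intensities over
#' the whole z-stack and reports their ratio, overall and per compartment
#' (parenchyma / subarachnoid space) when a compartment map is supplied.
#' Normalizing the extraluminal to the luminal signal cancels day-to-day
#' variation in imaging quality and in tracer dose, so the ratio is invariant
#' under global intensity scaling.  By default a one-voxel guard ring around
#' the lumen is excluded from the extraluminal sum to suppress PSF bleed at
#' the vessel wall.
#'
#' @param luminal,extraluminal the two stacks from \code{\link{splitSignal}}
#' @param compartments optional \linkS4class{CompartmentMap}
#' @param background scalar background intensity, subtracted voxel-wise
#'   (negative values clipped to 0)
#' @param guardRing exclude a one-voxel dilation of the lumen from the
#'   extraluminal sum
#' @param aggregate \code{"sum"} (volume-weighted, default) or \code{"mean"}
#' @param timepoint tag recorded in the result
#' @return a \linkS4class{LeakageResult}; when the luminal sum is zero the
#'   ratio is NA and flagged \code{"undefined_zero_luminal"} rather than an
#'   error
#' @export
leakageRatio <- function(luminal, extraluminal, compartments = NULL,
                         background = 0, guardRing = TRUE,
                         aggregate = c("sum", "mean"),
                         timepoint = luminal@timepoint) {
  stopifnot(background >= 0)
  aggregate <- match.arg(aggregate)
  if (!identical(dim(luminal@data), dim(extraluminal@data)))
    stop("luminal and extraluminal stacks are on different grids")
  lum_mask <- luminal@data > 0
  if (!is.null(compartments)) lum_mask <- lum_mask | compartments@lumen
  bsub <- function(x) pmax(x - background, 0)
  agg <- function(x, m) {
    if (aggregate == "sum") sum(bsub(x[m]))
    else if (any(m)) mean(bsub(x[m])) else 0
  }
  ext_ok <- !lum_mask
  if (guardRing) ext_ok <- ext_ok & !.dilate26(lum_mask)

  flags <- character(0)
  lsum <- agg(luminal@data, lum_mask)
  esum <- agg(extraluminal@data, ext_ok)
  if (lsum == 0) {
    flags <- c(flags, "undefined_zero_luminal")
    ratio <- NA_real_
  } else ratio <- esum / lsum

  rp <- rs <- NA_real_
  if (!is.null(compartments)) {
    roi <- compartments@roi
    for (lab in c(1L, 2L)) {
      lsel <- lum_mask & roi == lab
      esel <- ext_ok & roi == lab
      ls <- agg(luminal@data, lsel)
      es <- agg(extraluminal@data, esel)
      r <- if (ls == 0) NA_real_ else es / ls
      if (ls == 0)
        flags <- c(flags, paste0("undefined_zero_luminal_",
                                 c("parenchyma", "subarachnoid")[lab]))
      if (lab == 1L) rp <- r else rs <- r
    }
  }
  new("LeakageResult", timepoint = timepoint, ratioTotal = ratio,
      ratioParenchymal = rp, ratioSubarachnoid = rs,
      luminalSum = lsum, extraluminalSum = esum, flags = flags)
}

#' Segment parenchyma and subarachnoid space from per-plane ROIs
#'
#' Rasterizes closed region-of-interest polygons plane by plane (point in
#' polygon on voxel centers).  Voxels inside a polygon labeled
#' \code{"subarachnoid"} become subarachnoid; everything else is parenchyma;
#' lumen voxels override the ROI label.  This reproduces the crude
#' brain/subarachnoid segmentation that the curvature of the brain makes
#' necessary in planes near the meninges.
#'
#' @param rois list of ROIs, each a list with \code{plane} (1-based z index),
#'   \code{vertices} (m x 2 matrix of xy um, first vertex repeated last) and
#'   \code{label} (\code{"subarachnoid"} or \code{"parenchyma"})
#' @param lumen a \linkS4class{LumenMask}, or a logical array, or NULL
#' @param dims grid dimensions (ny, nx, nz); defaults to the lumen grid
#' @param voxelSize voxel pitch (x, y, z) um
#' @return a \linkS4class{CompartmentMap}
#' @export
segmentCompartments <- function(rois, lumen = NULL, dims = NULL,
                                voxelSize = c(0.58, 0.58, 1)) {
  if (is(lumen, "LumenMask")) {
    dims <- dim(lumen@mask); voxelSize <- lumen@voxelSize
    lum <- lumen@mask
  } else if (is.array(lumen)) {
    dims <- dim(lumen); lum <- lumen
  } else {
    if (is.null(dims)) stop("dims required when no lumen mask is given")
    lum <- array(FALSE, dims)
  }
  roi_arr <- array(1L, dims)
  xc <- ((1:dims[2]) - 0.5) * voxelSize[1]
  yc <- ((1:dims[1]) - 0.5) * voxelSize[2]
  centers <- cbind(rep(xc, each = dims[1]), rep(yc, times = dims[2]))
  for (r in rois) {
    v <- .as_roi_vertices(r$vertices)
    if (!isTRUE(all.equal(v[1, ], v[nrow(v), ])))
      stop("ROI polygon on plane ", r$plane, " is not closed")
    if (r$plane < 1 || r$plane > dims[3])
      stop("ROI plane ", r$plane, " outside the stack")
    inside <- mgcv::in.out(v, centers)
    lab <- if (identical(r$label, "subarachnoid")) 2L else 1L
    plane <- roi_arr[, , r$plane]
    plane[inside] <- lab
    roi_arr[, , r$plane] <- plane
  }
  new("CompartmentMap", roi = roi_arr, lumen = lum, voxelSize = voxelSize,
      provenance = rois)
}

.as_roi_vertices <- function(v) {
  v <- as.matrix(v)
  stopifnot(ncol(v) == 2, nrow(v) >= 4)
  storage.mode(v) <- "double"
  v
}

#' Perfused vessel density
#'
#' Total centerline length of perfused vessels per imaged volume
#' (um / um^3).  A path counts as perfused when the median luminal tracer
#' intensity along it exceeds the background by a configured factor; flags
#' can also be supplied directly (e.g. from a phantom truth).
#'
#' @param paths list of \linkS4class{VesselPath}
#' @param volumeUm3 imaged volume in um^3 (> 0)
#' @param perfusedFlags optional logical vector, one per path
#' @param stack luminal \linkS4class{ImageStack} used to decide perfusion
#'   when no flags are given
#' @param background background intensity
#' @param factor perfusion threshold factor over background; when the
#'   background is zero the threshold falls back to 5 percent of the stack
#'   maximum
#' @return density in um / um^3
#' @export
perfusedDensity <- function(paths, volumeUm3, perfusedFlags = NULL,
                            stack = NULL, background = 0, factor = 2) {
  stopifnot(volumeUm3 > 0)
  if (!length(paths)) return(0)
  if (is.null(perfusedFlags)) {
    if (is.null(stack))
      stop("either perfusedFlags or a luminal stack is required")
    thr <- if (background > 0) background * factor else 0.05 * max(stack@data)
    perfusedFlags <- vapply(paths, function(p) {
      v <- .interp3(stack@data, stack@voxelSize,
                    .resample_polyline(p@points, 2)$points)
      median(v, na.rm = TRUE) > thr
    }, logical(1))
  }
  sum(vapply(paths[perfusedFlags], pathLength, numeric(1))) / volumeUm3
}
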
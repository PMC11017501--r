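#' Single-cylinder calibration phantom
#'
#' A phantom containing one straight tube of known diameter running along
#' the x axis, centered on a voxel line, in a volume sized to leave
#' \code{marginUm} of clearance around the wall (plus any planned leak
#' halo).  This is the workhorse for calibrating and validating the
#' diameter, filling and spreading-distance operations against analytic
#' ground truth.
#'
#' @param diameterUm true tube diameter (um)
#' @param class vessel class recorded in the truth; inferred from the
#'   diameter band when NULL (ambiguous bands resolve to the first match)
#' @param lengthUm tube length (um)
#' @param marginUm clearance between the wall (or halo) and the volume faces
#' @param voxelSize voxel pitch (x, y, z) um
#' @param leak optional one-row planned leak: list/data.frame with
#'   \code{position}, \code{spreading_um}, \code{site_length_um}
#' @param perfused render the lumen with tracer
#' @param ... further arguments passed to \code{\link{phantomSpec}} (e.g.
#'   \code{psfSigma}, \code{noiseGaussianSd}, \code{seed})
#' @return list with \code{spec} (\linkS4class{PhantomSpec}) and
#'   \code{truth} (\linkS4class{PhantomTruth})
#' @examples
#' cp <- cylinderPhantom(20)
#' stk <- renderStack(cp$truth, cp$spec, noise = FALSE)
#' @export
cylinderPhantom <- function(diameterUm, class = NULL, lengthUm = 30,
                            marginUm = 8, voxelSize = c(0.58, 0.58, 1),
                            leak = NULL, perfused = TRUE, ...) {
  stopifnot(diameterUm > 0)
  if (is.null(class)) {
    hits <- vapply(seq_len(nrow(.AV_BOUNDS)), function(r)
      .in_band(diameterUm, .AV_BOUNDS[r, ]), logical(1))
    class <- .AV_BOUNDS$class[which(hits)[1]]
  }
  r <- diameterUm / 2
  reach <- r + marginUm + if (!is.null(leak)) max(leak$spreading_um) else 0
  # center the tube axis on a voxel line: pick an odd-ish voxel count and put
  # the axis at a voxel center
  ny <- 2 * ceiling(reach / voxelSize[2]) + 1
  nz <- 2 * ceiling(reach / voxelSize[3]) + 1
  nx <- ceiling(lengthUm / voxelSize[1])
  vol <- c(nx * voxelSize[1], ny * voxelSize[2], nz * voxelSize[3])
  y0 <- (floor(ny / 2) + 0.5) * voxelSize[2]
  z0 <- (floor(nz / 2) + 0.5) * voxelSize[3]
  pts <- cbind(seq(0, vol[1], by = 2), y0, z0)
  pts[nrow(pts), 1] <- vol[1]
  path <- VesselPath(1L, pts, r)

  cnt <- structure(integer(5), names = .AV_CLASSES)
  dm <- .AV_DIAM_MEAN
  dm[class] <- diameterUm
  spec <- phantomSpec(volumeSize = vol, voxelSize = voxelSize,
                      vesselCount = cnt, diameterMean = dm, ...)
  dims <- as.integer(c(ny, nx, nz))
  leaks <- if (is.null(leak)) .empty_leaks() else
    data.frame(site_id = 1L, vessel_id = 1L,
               position = leak$position,
               spreading_um = leak$spreading_um,
               site_length_um = leak$site_length_um,
               onset = "t1", stringsAsFactors = FALSE)
  comp <- .compartment_array(list(path), c(`1` = perfused), dims, voxelSize,
                             spec@curvatureDepth)
  truth <- new("PhantomTruth", paths = list(path),
               classes = c(`1` = class),
               diametersUm = c(`1` = diameterUm),
               perfused = c(`1` = perfused),
               leaks = leaks, compartments = comp, dims = dims,
               voxelSizeUm = voxelSize,
               perfusedLength = if (perfused) .polyline_length(pts) else 0,
               timepoint = "t0")
  list(spec = spec, truth = truth)
}
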
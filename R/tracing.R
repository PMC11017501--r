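#' Gaussian pre-smoothing of a stack
#'
#' Gaussian blur applied before tracing and filling to reduce noise and
#' sharpen edge detection.  \code{sigmaPx} is interpreted in pixels of the
#' xy plane; the z sigma is scaled by the voxel anisotropy so the physical
#' smoothing scale is isotropic.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param sigmaPx Gaussian sigma in xy pixels (>= 0; 0 returns the input
#'   unchanged)
#' @return the filtered \linkS4class{ImageStack}
#' @export
setGeneric("smoothStack",
  function(stack, sigmaPx = 1) standardGeneric("smoothStack"))

#' @rdname smoothStack
#' @export
setMethod("smoothStack", "ImageStack", function(stack, sigmaPx = 1) {
  stopifnot(sigmaPx >= 0)
  if (sigmaPx == 0) return(stack)
  vox <- stack@voxelSize
  sigma_um <- sigmaPx * vox[1]
  sigma_vox <- c(sigma_um / vox[2], sigmaPx, sigma_um / vox[3])
  out <- stack
  out@data <- .gauss_blur3(stack@data, sigma_vox)
  out
})

#' Seed-guided minimum-cost centerline tracing
#'
#' Connects consecutive seed points by the minimum-cost path on the
#' 26-connected voxel graph, with edge cost equal to the physical step
#' length times \code{1 + kappa / max(intensity, floor)}: bright (luminal)
#' voxels are cheap, dark voxels expensive, so the path follows the vessel
#' rather than the straight chord.  The concatenated path is resampled to at
#' most 2 um point spacing and a per-point radius is initialized from the
#' half-maximum extent of the perpendicular in-plane intensity profile.
#'
#' @param stack a (typically pre-smoothed) \linkS4class{ImageStack}
#' @param seeds n x 3 matrix of seed coordinates (x, y, z um), n >= 2, all
#'   inside the volume
#' @param kappa intensity-weighting strength; default: the 99.9th intensity
#'   percentile, so on-lumen steps cost about twice the plain step length
#' @param floor intensity floor preventing division blow-up in dark voxels;
#'   default 1 percent of \code{kappa}
#' @param vesselId id given to the traced path
#' @param spacing resample spacing in um (must be <= 2)
#' @param estimateRadius measure per-point radii from the image (disable to
#'   skip the profile measurements)
#' @return a \linkS4class{VesselPath}; attribute \code{cost} holds the total
#'   graph cost
#' @export
setGeneric("traceVessel",
  function(stack, seeds, kappa = NULL, floor = NULL, vesselId = 1L,
           spacing = 1, estimateRadius = TRUE)
    standardGeneric("traceVessel"))

#' @rdname traceVessel
#' @export
setMethod("traceVessel", "ImageStack",
  function(stack, seeds, kappa = NULL, floor = NULL, vesselId = 1L,
           spacing = 1, estimateRadius = TRUE) {
  seeds <- .as_points(seeds)
  if (nrow(seeds) < 2) stop("need at least 2 seed points")
  if (spacing > 2) stop("resample spacing must be <= 2 um")
  vox <- stack@voxelSize
  d <- dim(stack@data)
  size_um <- c(d[2] * vox[1], d[1] * vox[2], d[3] * vox[3])
  if (!all(.in_volume(seeds, size_um)))
    stop("all seed points must lie inside the volume")
  if (max(stats::dist(seeds)) == 0)
    stop("seed points are identical: degenerate single-point path")
  if (is.null(kappa)) kappa <- as.numeric(quantile(stack@data, 0.999))
  if (is.null(floor)) floor <- 0.01 * max(kappa, .Machine$double.eps)
  idx <- .um_to_idx(seeds, d, vox)
  if (any(stack@data[idx] <= floor))
    warning("seed in a zero-intensity region; tracing proceeds ",
            "(occluded vessels can be traced on the reporter channel)")
  pieces <- list()
  total_cost <- 0
  for (s in seq_len(nrow(seeds) - 1)) {
    seg <- cpp_trace_path(stack@data, d, vox, idx[s] - 1L, idx[s + 1] - 1L,
                          kappa, floor)
    total_cost <- total_cost + attr(seg, "cost")
    pts <- .idx_to_um(seg + 1L, d, vox)
    if (s > 1) pts <- pts[-1, , drop = FALSE]
    pieces[[s]] <- pts
  }
  pts <- do.call(rbind, pieces)
  res <- .resample_polyline(pts, spacing)
  radius <- rep(NA_real_, nrow(res$points))
  path <- VesselPath(vesselId, res$points, radius)
  if (estimateRadius) {
    radius <- .estimate_radii(stack, path)
    path@radius <- radius
  }
  attr(path, "cost") <- total_cost
  path
})

# per-point radius = half of the FWHM of the perpendicular in-plane profile
.estimate_radii <- function(stack, path, maxSearch = 120) {
  n <- nrow(path@points)
  r <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    w <- .fwhm_at(stack, path@points, t, maxSearch)
    r[t] <- if (is.na(w)) NA_real_ else w / 2
  }
  # carry estimates over unmeasurable points
  if (all(is.na(r))) return(rep(1, n))
  r[is.na(r)] <- stats::approx(which(!is.na(r)), r[!is.na(r)],
                               xout = which(is.na(r)), rule = 2)$y
  pmax(r, min(stack@voxelSize) / 2)
}

#' Intensity-constrained lumen filling from a traced path
#'
#' Region growing over 26-neighbours starting from the path voxels: a voxel
#' joins the lumen when its (smoothed) intensity is at least
#' \code{thresholdFraction} times the median intensity along the path, and
#' its geodesic distance through accepted voxels from the path stays within
#' \code{reachFactor} times the local path radius.  Supervised correction is
#' supported through voxel lists to force-include or force-exclude
#' (mimicking human-corrected filling when strong extraluminal signal defeats
#' edge detection).
#'
#' @param stack the (smoothed) \linkS4class{ImageStack} to fill on
#' @param path a \linkS4class{VesselPath}
#' @param thresholdFraction acceptance threshold as a fraction of the path
#'   median intensity, in (0, 1)
#' @param reachFactor geodesic reach bound in units of the local radius
#' @param forceInclude,forceExclude 1-based linear voxel indices to add /
#'   block regardless of intensity
#' @param defaultRadius fallback local radius (um) where the path has none
#' @return a \linkS4class{LumenMask}
#' @export
setGeneric("fillLumen",
  function(stack, path, thresholdFraction = 0.3, reachFactor = 3,
           forceInclude = NULL, forceExclude = NULL, defaultRadius = 5)
    standardGeneric("fillLumen"))

#' @rdname fillLumen
#' @export
setMethod("fillLumen", signature(stack = "ImageStack", path = "VesselPath"),
  function(stack, path, thresholdFraction = 0.3, reachFactor = 3,
           forceInclude = NULL, forceExclude = NULL, defaultRadius = 5) {
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in (0, 1)")
  if (nrow(path@points) == 0) stop("empty path")
  d <- dim(stack@data)
  vox <- stack@voxelSize
  res <- .resample_polyline(path@points, min(vox) / 2, values = path@radius)
  seed_idx <- .um_to_idx(res$points, d, vox)
  keep <- !duplicated(seed_idx)
  seed_idx <- seed_idx[keep]
  seed_r <- res$values[keep]
  seed_r[is.na(seed_r)] <- defaultRadius
  med <- median(stack@data[seed_idx])
  thr <- thresholdFraction * med
  flag <- integer(0)
  if (!is.null(forceInclude) || !is.null(forceExclude)) {
    flag <- integer(prod(d))
    if (!is.null(forceInclude)) flag[forceInclude] <- 2L
    if (!is.null(forceExclude)) flag[forceExclude] <- 1L
  }
  fill <- cpp_fill_region(stack@data, d, vox, seed_idx - 1L,
                          reachFactor * seed_r, thr, flag)
  mask <- array(FALSE, d)
  mask[fill$idx + 1L] <- TRUE
  owner <- array(0L, d)
  owner[fill$idx + 1L] <- path@vesselId
  new("LumenMask", mask = mask, owner = owner, voxelSize = vox,
      fillThreshold = thr)
})

#' Merge per-vessel lumen masks with disjoint ownership
#'
#' The union of the masks, with overlap voxels assigned to the vessel whose
#' centerline is nearest in um (ties to the lower vessel id).
#'
#' @param masks list of \linkS4class{LumenMask}, one per vessel
#' @param paths list of the corresponding \linkS4class{VesselPath}s
#' @return a single \linkS4class{LumenMask}
#' @export
mergeLumen <- function(masks, paths) {
  stopifnot(length(masks) == length(paths), length(masks) >= 1)
  d <- dim(masks[[1]]@mask)
  vox <- masks[[1]]@voxelSize
  ids <- vapply(paths, function(p) p@vesselId, integer(1))
  count <- array(0L, d)
  owner <- array(0L, d)
  for (t in seq_along(masks)) {
    m <- masks[[t]]@mask
    count <- count + m
    owner[m] <- ids[t]
  }
  mask <- count > 0L
  overlap <- which(count > 1L)
  if (length(overlap)) {
    pts <- .idx_to_um(overlap, d, vox)
    for (v in seq_along(overlap)) {
      involved <- which(vapply(masks, function(m) m@mask[overlap[v]],
                               logical(1)))
      dc <- vapply(involved, function(t)
        .point_to_path(pts[v, ], paths[[t]]@points)$dist, numeric(1))
      # nearest centerline wins; exact ties go to the lower vessel id
      best <- involved[order(dc, ids[involved])][1]
      owner[overlap[v]] <- ids[best]
    }
  }
  new("LumenMask", mask = mask, owner = owner, voxelSize = vox,
      fillThreshold = max(vapply(masks, function(m) m@fillThreshold,
                                 numeric(1))))
}
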
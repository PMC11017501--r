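#' Wall distance from a point to a vessel
#'
#' Minimal Euclidean distance (um) from a point to the vessel wall surface,
#' computed as the centerline distance minus the local radius; negative
#' values (point inside the lumen) are clamped to 0.
#'
#' @param point (x, y, z) um
#' @param path a \linkS4class{VesselPath}
#' @param defaultRadius radius used where the path has none (um)
#' @return wall distance in um
#' @export
wallDistance <- function(point, path, defaultRadius = 2) {
  r <- path@radius
  r[is.na(r)] <- defaultRadius
  pp <- .point_to_path(point, path@points, r)
  max(pp$dist - pp$radius, 0)
}

#' Attribute a leak site to the nearest vessel
#'
#' Computes the wall distance from the site's intensity-weighted centroid to
#' every vessel and attributes the site to the nearest one; when the two
#' closest walls are within \code{tieToleranceUm} of each other a clear
#' attribution is not possible and both vessels are returned.  A site
#' farther than \code{maxAttributionUm} from every wall stays unattributed.
#'
#' @param site a \linkS4class{LeakSite}, or a length-3 centroid (x, y, z um)
#' @param paths list of \linkS4class{VesselPath}
#' @param tieToleranceUm wall-distance difference below which two vessels
#'   count as equally close (default: one xy pixel, 0.58 um)
#' @param maxAttributionUm maximum attribution radius (um)
#' @return integer vector of attributed vessel ids (length 1 or 2; empty when
#'   unattributed), with the wall distances as attribute \code{wallDistance}
#' @export
attributeLeak <- function(site, paths, tieToleranceUm = 0.58,
                          maxAttributionUm = 50) {
  stopifnot(length(paths) >= 1)
  centroid <- if (is(site, "LeakSite")) site@centroid else as.numeric(site)
  if (length(centroid) != 3) stop("site centroid must be (x, y, z) um")
  ids <- vapply(paths, function(p) p@vesselId, integer(1))
  wd <- vapply(paths, function(p) wallDistance(centroid, p), numeric(1))
  ord <- order(wd, ids)
  if (wd[ord[1]] > maxAttributionUm) {
    out <- integer(0)
    attr(out, "wallDistance") <- numeric(0)
    warning("leak site farther than ", maxAttributionUm,
            " um from every vessel wall: unattributed")
    return(out)
  }
  take <- ord[1]
  if (length(ord) > 1 && wd[ord[2]] - wd[ord[1]] <= tieToleranceUm)
    take <- ord[1:2]
  out <- ids[take]
  attr(out, "wallDistance") <- wd[take]
  out
}

#' Extract leak sites from an extraluminal stack
#'
#' Labels the 26-connected components of above-threshold extraluminal signal
#' and turns each into a \linkS4class{LeakSite} with its intensity-weighted
#' centroid, attributed to the nearest vessel wall.
#'
#' @param extraluminal the extraluminal \linkS4class{ImageStack}
#' @param paths list of \linkS4class{VesselPath} to attribute against
#' @param detectionThreshold intensity threshold for leak signal; voxels
#'   strictly above it count
#' @param minVoxels drop components smaller than this
#' @param tieToleranceUm,maxAttributionUm see \code{\link{attributeLeak}}
#' @param lumen optional \linkS4class{LumenMask} (or logical array); when
#'   given, a one-voxel guard ring around the lumen is excluded before
#'   labelling, so the PSF bleed hugging the vessel wall does not merge
#'   every site into one component
#' @return list of \linkS4class{LeakSite}
#' @export
extractLeakSites <- function(extraluminal, paths, detectionThreshold = 0,
                             minVoxels = 5, tieToleranceUm = 0.58,
                             maxAttributionUm = 50, lumen = NULL) {
  d <- dim(extraluminal@data)
  vox <- extraluminal@voxelSize
  above <- extraluminal@data > detectionThreshold
  if (!is.null(lumen)) {
    lm <- if (is(lumen, "LumenMask")) lumen@mask else lumen
    above <- above & !.dilate26(lm)
  }
  lab <- cpp_label_components(above, d)
  sites <- list()
  if (!max(lab)) return(sites)
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    if (length(idx) < minVoxels) next
    w <- extraluminal@data[idx]
    pts <- .idx_to_um(idx, d, vox)
    centroid <- colSums(pts * w) / sum(w)
    site <- new("LeakSite", siteId = length(sites) + 1L,
                voxels = as.integer(idx), dims = as.integer(d),
                centroid = as.numeric(centroid),
                timepoint = extraluminal@timepoint)
    vid <- suppressWarnings(
      attributeLeak(site, paths, tieToleranceUm, maxAttributionUm))
    site@vessels <- as.integer(vid)
    site@wallDistance <- as.numeric(attr(vid, "wallDistance"))
    sites[[length(sites) + 1]] <- site
  }
  sites
}

#' Station-sampled spreading distance of a leak site
#'
#' The extent of dye extravasation, measured from the vessel wall to the
#' most distant continuous tracer signal: above-threshold voxels of the site
#' are kept only when 26-connected (through above-threshold voxels) to the
#' wall; the site is then sampled at stations every \code{sampleInterval}
#' (1-2 um) along its length (the projection of the kept voxels onto the
#' attributed vessel's centerline), the maximal wall-to-voxel distance of
#' continuous signal is taken at each station, and the station maxima are
#' averaged.
#'
#' @param extraluminal the extraluminal \linkS4class{ImageStack}
#' @param site a \linkS4class{LeakSite}
#' @param path the attributed vessel's \linkS4class{VesselPath}
#' @param detectionThreshold voxels strictly above this count as signal
#' @param sampleInterval station spacing along the site in um, in [1, 2]
#' @param mode \code{"3d"} (default) for 3D wall distances, \code{"2d"} for
#'   in-plane distances within each z-plane
#' @param defaultRadius fallback radius where the path has none (um)
#' @param wallMask optional logical array marking the vessel wall region
#'   (e.g. the lumen mask, possibly with its guard ring); continuity is then
#'   judged by 26-adjacency to this region instead of by absolute wall
#'   distance
#' @return mean spreading distance in um (0, flagged, when no above-threshold
#'   voxel is connected to the wall); attributes \code{nStations} and
#'   \code{flag}
#' @export
spreadingDistance <- function(extraluminal, site, path,
                              detectionThreshold = 0, sampleInterval = 1,
                              mode = c("3d", "2d"), defaultRadius = 2,
                              wallMask = NULL) {
  mode <- match.arg(mode)
  if (sampleInterval < 1 || sampleInterval > 2)
    stop("sampleInterval must lie in [1, 2] um")
  if (!length(site@vessels)) stop("site must be attributed first")
  d <- dim(extraluminal@data)
  vox <- extraluminal@voxelSize
  idx <- site@voxels
  above <- idx[extraluminal@data[idx] > detectionThreshold]
  zero <- structure(0, nStations = 0L, flag = "no_signal")
  if (!length(above)) return(zero)

  r <- path@radius
  r[is.na(r)] <- defaultRadius
  # reach of the tube distance field: upper bound from the site bounding box
  pts_above <- .idx_to_um(above, d, vox)
  lo <- apply(pts_above, 2, min); hi <- apply(pts_above, 2, max)
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  samp <- .resample_polyline(path@points, 2)$points
  site_reach <- max(vapply(seq_len(8), function(t)
    min(sqrt(colSums((t(samp) - corners[t, ])^2))), numeric(1))) +
    0.5 * sqrt(sum((hi - lo)^2))   # safe bound anywhere inside the box
  geo <- cpp_tube_geometry(d, vox, path@points, r,
                           max(site_reach, 5) + 2 * max(vox))
  sdist_of <- function(ix) {
    s <- geo$dcen[ix] - geo$rad[ix]
    pmax(s, 0)
  }

  # continuity: components of above-threshold signal in the site that touch
  # the wall.  Wall-adjacent = within one voxel diagonal of the wall surface.
  mask <- array(FALSE, d)
  mask[above] <- TRUE
  lab <- cpp_label_components(mask, d)
  if (!is.null(wallMask)) {
    near_wall <- .dilate26(wallMask)
    wall_adj <- above[near_wall[above]]
  } else {
    diag_um <- sqrt(sum(vox^2))
    wall_adj <- above[sdist_of(above) <= diag_um]
  }
  keep_labels <- unique(lab[wall_adj])
  keep_labels <- keep_labels[keep_labels > 0]
  if (!length(keep_labels)) return(zero)
  kept <- above[lab[above] %in% keep_labels]

  sd_k <- sdist_of(kept)
  if (mode == "2d") {
    pts <- .idx_to_um(kept, d, vox)
    sd_k <- vapply(seq_len(nrow(pts)), function(t) {
      p2 <- pts[t, ]
      pp <- .point_to_path_2d(p2, path@points, r)
      max(pp$dist - pp$radius, 0)
    }, numeric(1))
  }
  arc_k <- geo$arc[kept]
  ok <- is.finite(arc_k)
  sd_k <- sd_k[ok]; arc_k <- arc_k[ok]
  if (!length(arc_k)) return(zero)
  stations <- floor((arc_k - min(arc_k)) / sampleInterval)
  station_max <- tapply(sd_k, stations, max)
  out <- mean(station_max)
  attr(out, "nStations") <- length(station_max)
  attr(out, "flag") <- NA_character_
  out
}

# closest approach using xy components only (2D in-plane distances)
.point_to_path_2d <- function(p, pts, radii) {
  pts2 <- cbind(pts[, 1:2], 0)
  .point_to_path(c(p[1], p[2], 0), pts2, radii)
}

#' Two-timepoint leak progression
#'
#' Compares the spreading distance of matched leak sites at two timepoints:
#' an increase is interpreted as persistent leakage, a decrease as reduced
#' or stopped leakage.  Sites present at only one timepoint are excluded
#' (and reported).  The summary fraction counts strictly increased sites
#' among all matched sites; ties are reported separately.  A paired t-test
#' on the per-site distances is attached as reporting plumbing.
#'
#' @param sitesT1,sitesT2 data.frames with columns \code{site_id} and
#'   \code{spreading_um} (e.g. built from \code{\link{spreadingDistance}}
#'   results)
#' @return list: \code{perSite} (site_id, spreading at both timepoints,
#'   direction), \code{fractionIncreased}, \code{nTies}, \code{nUnmatched},
#'   \code{pValue}
#' @export
leakProgression <- function(sitesT1, sitesT2) {
  m <- merge(sitesT1[, c("site_id", "spreading_um")],
             sitesT2[, c("site_id", "spreading_um")],
             by = "site_id", suffixes = c("_t1", "_t2"))
  ok <- is.finite(m$spreading_um_t1) & is.finite(m$spreading_um_t2)
  n_un <- nrow(sitesT1) + nrow(sitesT2) - 2 * nrow(m) + sum(!ok)
  m <- m[ok, ]
  if (n_un > 0)
    message(n_un, " unmatched or unmeasured site record(s) excluded ",
            "from progression")
  if (!nrow(m)) stop("no matched sites between the two timepoints")
  delta <- m$spreading_um_t2 - m$spreading_um_t1
  m$direction <- ifelse(delta > 0, "increased",
                        ifelse(delta < 0, "decreased", "tie"))
  p <- if (nrow(m) >= 3 && isTRUE(sd(delta) > 0))
    t.test(m$spreading_um_t2, m$spreading_um_t1, paired = TRUE)$p.value
  else NA_real_
  list(perSite = m,
       fractionIncreased = mean(m$direction == "increased"),
       nTies = sum(m$direction == "tie"),
       nUnmatched = n_un,
       pValue = p)
}
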
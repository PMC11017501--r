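#' Generate a synthetic vascular tree
#'
#' Places non-intersecting tubular centerlines of the five arteriovenous
#' classes in the phantom volume, respecting the hierarchy of the cortical
#' vascular tree: arterioles branch off arteries, venules converge onto
#' veins, and capillaries run from the arteriolar to the venular side.
#' Diameters are drawn per vessel from the class distribution truncated to
#' the class band.  A configured fraction of vessels is marked unperfused
#' (occluded), and planned leak sites referencing a class are resolved to a
#' concrete vessel of that class.  Generation is deterministic given
#' \code{spec@seed}.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param compartments also build the per-voxel compartment label array
#'   (disable for large scenes used only geometrically)
#' @return a \linkS4class{PhantomTruth}
#' @examples
#' spec <- phantomSpec(vesselCount = c(Ae = 1, C = 2, Ve = 1), seed = 3)
#' truth <- generateTree(spec)
#' truthClasses(truth)
#' @export
setGeneric("generateTree",
  function(spec, compartments = TRUE) standardGeneric("generateTree"))

#' @rdname generateTree
#' @export
setMethod("generateTree", "PhantomSpec", function(spec, compartments = TRUE) {
  validObject(spec)
  set.seed(spec@seed)
  vol <- spec@volumeSize
  dims <- as.integer(round(vol / spec@voxelSize)[c(2, 1, 3)])  # (ny, nx, nz)

  paths <- list()
  classes <- character(0)
  diams <- numeric(0)
  next_id <- 1L

  draw_diameter <- function(cl) {
    row <- .AV_BOUNDS[.AV_BOUNDS$class == cl, ]
    .rnorm_trunc(1, spec@diameterMean[[cl]], spec@diameterSd[[cl]],
                 lo = row$lo, hi = row$hi)
  }

  wiggle <- function(pts, perp) {
    if (spec@tortuosityAmp <= 0) return(pts)
    s <- .polyline_cumlen(pts)
    phase <- runif(1, 0, 2 * pi)
    off <- spec@tortuosityAmp * sin(2 * pi * s / spec@tortuosityPeriod + phase)
    pts + outer(off, perp)
  }

  # clearance test: candidate centerline must stay (r1 + r2 + 1) um away from
  # every other centerline (sampled at 2 um), except near declared junctions
  clear_of <- function(pts, r, junctions) {
    cand <- .resample_polyline(pts, 2)$points
    for (p in paths) {
      ro <- max(p@radius, na.rm = TRUE)
      need <- r + ro + 1
      keep <- rep(TRUE, nrow(cand))
      for (jn in junctions) {
        d2j <- sqrt(rowSums(sweep(cand, 2, jn)^2))
        keep <- keep & d2j > (need + 3)
      }
      if (!any(keep)) next
      sub <- cand[keep, , drop = FALSE]
      op <- .resample_polyline(p@points, 2)$points
      d2 <- outer(rowSums(sub^2), rowSums(op^2), `+`) -
        2 * tcrossprod(sub, op)
      if (min(d2) < need^2) return(FALSE)
    }
    TRUE
  }

  add_vessel <- function(pts, r, cl, d, parent = NULL) {
    paths[[length(paths) + 1]] <<- VesselPath(next_id, pts, r, parent)
    classes[as.character(next_id)] <<- cl
    diams[as.character(next_id)] <<- d
    next_id <<- next_id + 1L
  }

  # pial trunks run roughly parallel (arteries and veins interdigitate on
  # the cortical surface): one scene orientation, jittered per trunk
  theta0 <- runif(1, 0, 2 * pi)

  # trunk (artery or vein): crosses the volume horizontally at a random
  # depth, low-amplitude sinusoidal tortuosity in the horizontal plane.
  # Each trunk occupies its own lateral lane (fraction of the axis
  # perpendicular to the scene orientation) so several large trunks fit.
  place_trunk <- function(cl, lane = 0.5) {
    ctr <- c(vol[1] / 2, vol[2] / 2)
    for (try in 1:60) {
      # redrawn per attempt so one oversized draw cannot doom the placement
      d <- draw_diameter(cl)
      r <- d / 2
      margin <- min(r + 2, min(vol[1:2]) / 4)
      theta <- theta0 + rnorm(1, 0, pi / 36)
      dirv <- c(cos(theta), sin(theta), 0)
      lat <- (lane - 0.5 + runif(1, -0.05, 0.05)) * 0.8 * min(vol[1:2])
      # trunks stay superficial (pial vessels); deeper volume is left to the
      # penetrating branches and the capillary bed
      z_lo <- max(vol[3] * 0.12, min(r + 2, vol[3] * 0.3))
      p0 <- c(ctr[1] - lat * sin(theta), ctr[2] + lat * cos(theta),
              runif(1, z_lo, max(vol[3] * 0.35, z_lo + 1)))
      # parameter interval of the ray inside the xy box inset by margin
      t1 <- -Inf; t2 <- Inf
      for (ax in 1:2) {
        if (abs(dirv[ax]) < 1e-9) next
        ta <- (margin - p0[ax]) / dirv[ax]
        tb <- (vol[ax] - margin - p0[ax]) / dirv[ax]
        t1 <- max(t1, min(ta, tb)); t2 <- min(t2, max(ta, tb))
      }
      if (!is.finite(t1) || !is.finite(t2) || t2 - t1 < 40) next
      s <- seq(t1, t2, by = 2)
      pts <- t(vapply(s, function(t_) p0 + t_ * dirv, numeric(3)))
      perp <- c(-dirv[2], dirv[1], 0)
      pts <- wiggle(pts, perp)
      if (clear_of(pts, r, list())) {
        add_vessel(pts, r, cl, d)
        return(invisible(TRUE))
      }
    }
    stop("volume too small to place requested vessel counts (class ", cl, ")")
  }

  # branch vessel: starts on a parent path, heads away at an oblique angle
  place_branch <- function(cl, parent_ids, len_range) {
    for (try in 1:60) {
      d <- draw_diameter(cl)
      r <- d / 2
      pts <- NULL; junctions <- list(); parent <- NULL
      if (length(parent_ids)) {
        parent <- sample(parent_ids, 1)
        pp <- paths[[which(vapply(paths, function(p) p@vesselId,
                                  integer(1)) == parent)]]
        res <- .resample_polyline(pp@points, 2)
        i0 <- sample(seq(max(2, round(nrow(res$points) * 0.2)),
                         max(2, round(nrow(res$points) * 0.8))), 1)
        base <- res$points[i0, ]
        tangent <- res$points[min(i0 + 1, nrow(res$points)), ] -
                   res$points[max(i0 - 1, 1), ]
        tangent <- tangent / sqrt(sum(tangent^2))
        junctions <- list(base)
      } else {
        base <- c(runif(1, vol[1] * 0.15, vol[1] * 0.85),
                  runif(1, vol[2] * 0.15, vol[2] * 0.85),
                  runif(1, vol[3] * 0.25, vol[3] * 0.75))
        tangent <- c(1, 0, 0)
      }
      # penetrating arterioles / ascending venules dive into the depth:
      # strongly downward direction with lateral scatter
      repeat {
        dirv <- c(rnorm(2, 0, 0.45), abs(rnorm(1, 0.8, 0.25)))
        dirv <- dirv / sqrt(sum(dirv^2))
        ang <- acos(abs(sum(dirv * tangent)))
        if (ang > pi / 5) break
      }
      len <- runif(1, len_range[1], len_range[2])
      s <- seq(0, len, by = 2)
      pts <- t(vapply(s, function(t_) base + t_ * dirv, numeric(3)))
      inside <- .in_volume(sweep(pts, 2, c(0, 0, 0)),
                           vol - 1e-9) &
                pts[, 3] > 1 & pts[, 3] < vol[3] - 1
      if (sum(inside) < 8) next
      pts <- pts[seq_len(max(which(inside))), , drop = FALSE]
      if (!all(.in_volume(pts, vol))) next
      perp0 <- c(-dirv[2], dirv[1], 0)
      if (sum(perp0^2) < 1e-6) perp0 <- c(1, 0, 0)
      perp0 <- perp0 / sqrt(sum(perp0^2))
      pts <- wiggle(pts, perp0)
      if (clear_of(pts, r, junctions)) {
        add_vessel(pts, r, cl, d, parent)
        return(invisible(TRUE))
      }
    }
    stop("volume too small to place requested vessel counts (class ", cl, ")")
  }

  # capillary spanning from an arteriole to a venule when both exist
  place_capillary <- function(ae_ids, ve_ids) {
    if (!length(ae_ids) || !length(ve_ids)) {
      return(place_branch("C", ae_ids, c(30, 80)))
    }
    for (try in 1:200) {
      d <- draw_diameter("C")
      r <- d / 2
      ids <- vapply(paths, function(p) p@vesselId, integer(1))
      pa <- paths[[which(ids == sample(ae_ids, 1))]]
      a <- .resample_polyline(pa@points, 2)$points
      # spring from the distal half of the arteriole, clear of the fat
      # parent trunk
      p1 <- a[sample(seq(ceiling(nrow(a) * 0.5), nrow(a)), 1), ]
      # drain toward one of the nearby venules, with jitter along its
      # course, attaching on its distal portion
      near <- vapply(ve_ids, function(vv) {
        .point_to_path(p1, paths[[which(ids == vv)]]@points)$dist
      }, numeric(1))
      pick <- order(near)[seq_len(min(3, length(near)))]
      pv <- paths[[which(ids == ve_ids[sample(rep(pick, 2), 1)])]]
      resv <- .resample_polyline(pv@points, 2)
      v <- resv$points
      hit <- .point_to_path(p1, pv@points)
      arc_target <- max(hit$arc + runif(1, -40, 40),
                        0.45 * max(resv$arc))
      tv <- which.min(abs(resv$arc - arc_target))
      p2 <- v[tv, ]
      len <- sqrt(sum((p2 - p1)^2))
      if (len < 15 || len > 220) next
      s <- seq(0, 1, length.out = max(8, ceiling(len / 2)))
      pts <- t(vapply(s, function(t_) p1 + t_ * (p2 - p1), numeric(3)))
      dirv <- (p2 - p1) / len
      perp0 <- c(-dirv[2], dirv[1], 0)
      if (sum(perp0^2) < 1e-6) perp0 <- c(1, 0, 0)
      perp0 <- perp0 / sqrt(sum(perp0^2))
      damp <- sin(pi * s)          # pin the endpoints onto the parent vessels
      off <- spec@tortuosityAmp * damp *
        sin(2 * pi * s * len / spec@tortuosityPeriod + runif(1, 0, 2 * pi))
      pts <- pts + outer(off, perp0)
      if (!all(.in_volume(pts, vol))) next
      if (clear_of(pts, r, list(p1, p2))) {
        add_vessel(pts, r, "C", d, pa@vesselId)
        return(invisible(TRUE))
      }
    }
    # crowded corridors: fall back to a blind-ended capillary segment
    # branching off an arteriole (hierarchy preserved)
    place_branch("C", ae_ids, c(30, 80))
  }

  cnt <- spec@vesselCount
  trunk_cls <- c(rep("A", cnt[["A"]]), rep("V", cnt[["V"]]))
  if (length(trunk_cls)) {
    # interdigitate arteries and veins across the lateral lanes
    lanes <- (sample(length(trunk_cls)) - 0.5) / length(trunk_cls)
    for (i in seq_along(trunk_cls)) place_trunk(trunk_cls[i], lanes[i])
  }
  ids_of <- function(cl) as.integer(names(classes)[classes == cl])
  for (i in seq_len(cnt[["Ae"]])) place_branch("Ae", ids_of("A"), c(60, 180))
  for (i in seq_len(cnt[["Ve"]])) place_branch("Ve", ids_of("V"), c(60, 180))
  for (i in seq_len(cnt[["C"]])) place_capillary(ids_of("Ae"), ids_of("Ve"))

  ids <- vapply(paths, function(p) p@vesselId, integer(1))
  nv <- length(ids)
  perfused <- structure(rep(TRUE, nv), names = as.character(ids))
  n_occ <- round(spec@occludedFraction * nv)
  if (n_occ > 0) perfused[sample(nv, n_occ)] <- FALSE

  # resolve planned leaks whose vessel is given as a class name
  leaks <- spec@leaks
  if (nrow(leaks)) {
    vid <- integer(nrow(leaks))
    for (t in seq_len(nrow(leaks))) {
      v <- leaks$vessel[t]
      if (v %in% .AV_CLASSES) {
        cand <- ids_of(v)
        if (!length(cand)) stop("no vessel of class ", v, " for planned leak")
        vid[t] <- if (length(cand) == 1) cand else sample(cand, 1)
      } else vid[t] <- as.integer(v)
    }
    leaks <- data.frame(site_id = seq_len(nrow(leaks)), vessel_id = vid,
                        position = leaks$position,
                        spreading_um = leaks$spreading_um,
                        site_length_um = leaks$site_length_um,
                        onset = leaks$onset, stringsAsFactors = FALSE)
  } else {
    leaks <- .empty_leaks()
  }

  comp <- if (compartments)
    .compartment_array(paths, perfused, dims, spec@voxelSize,
                       spec@curvatureDepth)
  pl <- sum(vapply(paths[perfused[as.character(ids)]], pathLength, numeric(1)))

  new("PhantomTruth", paths = paths, classes = classes, diametersUm = diams,
      perfused = perfused, leaks = leaks, compartments = comp,
      dims = dims, voxelSizeUm = spec@voxelSize, perfusedLength = pl,
      timepoint = "t0")
})

.empty_leaks <- function() {
  data.frame(site_id = integer(0), vessel_id = integer(0),
             position = numeric(0), spreading_um = numeric(0),
             site_length_um = numeric(0), onset = character(0),
             stringsAsFactors = FALSE)
}

# per-voxel labels: subarachnoid above the spherical-cap brain surface,
# parenchyma below, lumen wherever a vessel tube passes
.compartment_array <- function(paths, perfused, dims, vox, curvature_depth) {
  comp <- array(1L, dims)
  if (curvature_depth > 0) {
    x <- ((1:dims[2]) - 0.5) * vox[1]
    y <- ((1:dims[1]) - 0.5) * vox[2]
    cx <- max(x) / 2; cy <- max(y) / 2
    rmax2 <- cx^2 + cy^2
    R <- (rmax2 + curvature_depth^2) / (2 * curvature_depth)
    r2 <- outer(y - cy, x - cx, function(a, b) a^2 + b^2)  # [y, x]
    zsurf <- R - sqrt(pmax(R^2 - r2, 0))
    zc <- ((1:dims[3]) - 0.5) * vox[3]
    for (k in seq_len(dims[3])) {
      comp[, , k][zc[k] < zsurf] <- 2L
    }
  }
  for (p in paths) {
    geo <- cpp_tube_geometry(dims, vox, p@points, p@radius, 0)
    comp[geo$dcen <= geo$rad & is.finite(geo$dcen)] <- 3L
  }
  comp
}

#' Plant leak sites on an existing phantom truth
#'
#' Adds planned leak sites to a generated truth, with per-class site counts
#' and ground-truth spreading distances drawn from per-class normal
#' distributions truncated at zero.  Site positions along the host vessel are
#' uniform in the central 70 percent of the path.
#'
#' @param truth a \linkS4class{PhantomTruth}
#' @param classCounts named integer: number of sites per vessel class
#' @param spreadingMean,spreadingSd per-class spreading distributions (um)
#' @param siteLength site extent along the vessel (um)
#' @param onset timepoint tag recorded for the sites
#' @return the truth with the new sites appended to \code{truthLeaks()}
#' @export
plantLeaks <- function(truth, classCounts,
                       spreadingMean = .AV_SPREAD_MEAN,
                       spreadingSd = .AV_SPREAD_SD,
                       siteLength = 20, onset = "t1") {
  rows <- list()
  base_id <- if (nrow(truth@leaks)) max(truth@leaks$site_id) else 0L
  for (cl in names(classCounts)) {
    n <- classCounts[[cl]]
    if (n == 0) next
    cand <- as.integer(names(truth@classes)[truth@classes == cl])
    if (!length(cand)) stop("no vessel of class ", cl, " in the truth")
    vid <- cand[1 + (seq_len(n) - 1) %% length(cand)]
    vid <- sample(vid)                       # spread sites over the vessels
    spread <- .rnorm_trunc(n, spreadingMean[[cl]], spreadingSd[[cl]], lo = 0.5)
    rows[[cl]] <- data.frame(
      site_id = base_id + seq_len(n), vessel_id = vid,
      position = runif(n, 0.15, 0.85), spreading_um = spread,
      site_length_um = siteLength, onset = onset, stringsAsFactors = FALSE)
    base_id <- base_id + n
  }
  truth@leaks <- rbind(truth@leaks, do.call(rbind, rows))
  rownames(truth@leaks) <- NULL
  truth
}
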
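# Internal geometry and array helpers.
#
# Grid convention: stacks are arrays dim = c(ny, nx, nz) (TIFF page = z-plane,
# matrix row = y, column = x).  Voxel centers sit at (index - 0.5) * pitch, so
# voxel [1,1,1] is centered at (vx/2, vy/2, vz/2) um.  Point sets are n x 3
# matrices with columns (x, y, z) in um.

# linear (1-based) voxel index -> um coordinates of voxel centers
.idx_to_um <- function(idx, dims, vox) {
  i <- ((idx - 1L) %% dims[1]) + 1L
  j <- (((idx - 1L) %/% dims[1]) %% dims[2]) + 1L
  k <- ((idx - 1L) %/% (dims[1] * dims[2])) + 1L
  cbind(x = (j - 0.5) * vox[1], y = (i - 0.5) * vox[2], z = (k - 0.5) * vox[3])
}

# um coordinates -> linear (1-based) voxel index (nearest voxel)
.um_to_idx <- function(pts, dims, vox) {
  pts <- .as_points(pts)
  j <- pmin(pmax(ceiling(pts[, 1] / vox[1]), 1L), dims[2])
  i <- pmin(pmax(ceiling(pts[, 2] / vox[2]), 1L), dims[1])
  k <- pmin(pmax(ceiling(pts[, 3] / vox[3]), 1L), dims[3])
  as.integer(i + (j - 1) * dims[1] + (k - 1) * dims[1] * dims[2])
}

.in_volume <- function(pts, size_um) {
  pts <- .as_points(pts)
  pts[, 1] >= 0 & pts[, 1] <= size_um[1] &
    pts[, 2] >= 0 & pts[, 2] <= size_um[2] &
    pts[, 3] >= 0 & pts[, 3] <= size_um[3]
}

.as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  stopifnot(ncol(p) == 3)
  p
}

.polyline_length <- function(pts) {
  pts <- .as_points(pts)
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                    pts[-nrow(pts), , drop = FALSE])^2)))
}

.polyline_cumlen <- function(pts) {
  pts <- .as_points(pts)
  c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))))
}

# resample a polyline (with optional per-point values) to a fixed arclength
# spacing; endpoints preserved
.resample_polyline <- function(pts, spacing, values = NULL) {
  pts <- .as_points(pts)
  cl <- .polyline_cumlen(pts)
  total <- cl[length(cl)]
  if (total == 0) {
    return(list(points = pts[1, , drop = FALSE],
                values = if (!is.null(values)) values[1], arc = 0))
  }
  s <- unique(c(seq(0, total, by = spacing), total))
  out <- vapply(1:3, function(c_) stats::approx(cl, pts[, c_], xout = s)$y,
                numeric(length(s)))
  out <- matrix(out, ncol = 3)
  v <- if (!is.null(values)) stats::approx(cl, values, xout = s)$y
  list(points = out, values = v, arc = s)
}

# trilinear interpolation of a stack at um points; outside-volume points -> NA
.interp3 <- function(a, vox, pts) {
  pts <- .as_points(pts)
  d <- dim(a)
  # fractional voxel-center coordinates (1-based)
  fj <- pts[, 1] / vox[1] + 0.5
  fi <- pts[, 2] / vox[2] + 0.5
  fk <- pts[, 3] / vox[3] + 0.5
  out <- rep(NA_real_, nrow(pts))
  ok <- fi >= 1 & fi <= d[1] & fj >= 1 & fj <= d[2] & fk >= 1 & fk <= d[3]
  if (!any(ok)) return(out)
  fi <- fi[ok]; fj <- fj[ok]; fk <- fk[ok]
  i0 <- pmin(floor(fi), d[1] - 1); j0 <- pmin(floor(fj), d[2] - 1)
  k0 <- pmin(floor(fk), d[3] - 1)
  i0 <- pmax(i0, 1); j0 <- pmax(j0, 1); k0 <- pmax(k0, 1)
  ti <- fi - i0; tj <- fj - j0; tk <- fk - k0
  at <- function(i, j, k) a[cbind(i, j, k)]
  v <- (1 - ti) * (1 - tj) * (1 - tk) * at(i0, j0, k0) +
       ti * (1 - tj) * (1 - tk) * at(i0 + 1, j0, k0) +
       (1 - ti) * tj * (1 - tk) * at(i0, j0 + 1, k0) +
       ti * tj * (1 - tk) * at(i0 + 1, j0 + 1, k0) +
       (1 - ti) * (1 - tj) * tk * at(i0, j0, k0 + 1) +
       ti * (1 - tj) * tk * at(i0 + 1, j0, k0 + 1) +
       (1 - ti) * tj * tk * at(i0, j0 + 1, k0 + 1) +
       ti * tj * tk * at(i0 + 1, j0 + 1, k0 + 1)
  out[ok] <- v
  out
}

# separable Gaussian blur of a 3D array; sigma in voxels per dimension
# (order: dim1 = y, dim2 = x, dim3 = z).  The kernel is column-normalized so
# total intensity is conserved exactly, including at the boundaries.
.gauss_blur3 <- function(a, sigma_vox) {
  d <- dim(a)
  blur_dim1 <- function(m, n, sigma) {
    if (sigma <= 0) return(m)
    r <- min(max(1L, ceiling(4 * sigma)), n - 1L)
    off <- -r:r
    w <- stats::dnorm(off, sd = sigma)
    w <- w / sum(w)
    # half-sample reflection at both ends: preserves constants and conserves
    # total mass exactly (kernel is symmetric)
    reflect <- function(p) {
      p <- ifelse(p < 1, 1 - p, p)
      ifelse(p > n, 2 * n + 1 - p, p)
    }
    K <- matrix(0, n, n)
    for (t in seq_along(off)) {
      rows <- reflect(seq_len(n) + off[t])
      tgt <- cbind(rows, seq_len(n))
      K[tgt] <- K[tgt] + w[t]
    }
    K %*% m
  }
  # dim 1 (y)
  a <- array(blur_dim1(matrix(a, d[1]), d[1], sigma_vox[1]), d)
  # dim 2 (x)
  a <- aperm(a, c(2, 1, 3))
  a <- array(blur_dim1(matrix(a, d[2]), d[2], sigma_vox[2]), d[c(2, 1, 3)])
  a <- aperm(a, c(2, 1, 3))
  # dim 3 (z)
  a <- aperm(a, c(3, 2, 1))
  a <- array(blur_dim1(matrix(a, d[3]), d[3], sigma_vox[3]), d[c(3, 2, 1)])
  aperm(a, c(3, 2, 1))
}

# 26-neighborhood binary dilation (1 iteration)
.dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    si <- max(1, 1 + di):min(d[1], d[1] + di)
    ti <- max(1, 1 - di):min(d[1], d[1] - di)
    sj <- max(1, 1 + dj):min(d[2], d[2] + dj)
    tj <- max(1, 1 - dj):min(d[2], d[2] - dj)
    sk <- max(1, 1 + dk):min(d[3], d[3] + dk)
    tk <- max(1, 1 - dk):min(d[3], d[3] - dk)
    out[ti, tj, tk] <- out[ti, tj, tk] | mask[si, sj, sk]
  }
  out
}

# draw from a normal truncated to (lo, hi) by rejection
.rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lo & x < hi])
    guard <- guard + 1
    if (guard > 1000) stop("truncated-normal rejection failed; check bounds")
  }
  out[seq_len(n)]
}

# minimal Euclidean distance (um) from a point to a polyline, together with
# the radius interpolated at, and the arclength of, the closest point
.point_to_path <- function(p, pts, radii = NULL) {
  pts <- .as_points(pts)
  n <- nrow(pts)
  if (n == 1) {
    d <- sqrt(sum((p - pts[1, ])^2))
    return(list(dist = d, radius = if (!is.null(radii)) radii[1] else NA_real_,
                arc = 0))
  }
  a <- pts[-n, , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  u <- b - a
  L2 <- rowSums(u^2)
  w <- matrix(rep(p, each = n - 1), ncol = 3) - a
  t <- pmin(pmax(ifelse(L2 > 0, rowSums(w * u) / L2, 0), 0), 1)
  cp <- a + u * t
  d2 <- rowSums((matrix(rep(p, each = n - 1), ncol = 3) - cp)^2)
  s <- which.min(d2)
  cl <- .polyline_cumlen(pts)
  r <- if (!is.null(radii)) radii[s] + t[s] * (radii[s + 1] - radii[s]) else NA_real_
  list(dist = sqrt(d2[s]), radius = r,
       arc = cl[s] + t[s] * (cl[s + 1] - cl[s]))
}
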
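# Independent oracles used by the unit and acceptance tests.  These are
# deliberately written against a different implementation (igraph shortest
# paths, brute-force loops) than the package's compiled voxel-graph code.

# directed 26-neighbour voxel graph with edge cost into voxel v equal to
# step_length_um * (1 + kappa / max(I[v], floor)); returns an igraph
voxel_graph <- function(img, vox, kappa, floor_) {
  d <- dim(img)
  n <- prod(d)
  idx <- seq_len(n)
  i <- ((idx - 1L) %% d[1]) + 1L
  j <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  k <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    i2 <- i + di; j2 <- j + dj; k2 <- k + dk
    ok <- i2 >= 1 & i2 <= d[1] & j2 >= 1 & j2 <= d[2] & k2 >= 1 & k2 <= d[3]
    v <- i2[ok] + (j2[ok] - 1L) * d[1] + (k2[ok] - 1L) * d[1] * d[2]
    len <- sqrt((di * vox[2])^2 + (dj * vox[1])^2 + (dk * vox[3])^2)
    from <- c(from, idx[ok]); to <- c(to, v)
    w <- c(w, len * (1 + kappa / pmax(img[v], floor_)))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  igraph::E(g)$weight <- w
  g
}

# minimum path cost between two voxels (1-based linear indices)
oracle_trace_cost <- function(img, vox, start, end, kappa, floor_) {
  g <- voxel_graph(img, vox, kappa, floor_)
  as.numeric(igraph::distances(g, v = start, to = end, mode = "out"))
}

# exhaustive flood fill: member voxels are those whose geodesic distance
# from the seed set, through voxels with intensity >= thr (undirected,
# physical step lengths), stays within `bound`
oracle_flood_fill <- function(img, vox, seeds, thr, bound) {
  d <- dim(img)
  n <- prod(d)
  accept <- img >= thr
  accept[seeds] <- TRUE
  idx <- seq_len(n)
  i <- ((idx - 1L) %% d[1]) + 1L
  j <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  k <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    i2 <- i + di; j2 <- j + dj; k2 <- k + dk
    ok <- i2 >= 1 & i2 <= d[1] & j2 >= 1 & j2 <= d[2] & k2 >= 1 & k2 <= d[3]
    v <- i2[ok] + (j2[ok] - 1L) * d[1] + (k2[ok] - 1L) * d[1] * d[2]
    keep <- accept[idx[ok]] & accept[v]
    len <- sqrt((di * vox[2])^2 + (dj * vox[1])^2 + (dk * vox[3])^2)
    from <- c(from, idx[ok][keep]); to <- c(to, v[keep])
    w <- c(w, rep(len, sum(keep)))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$weight <- w
  }
  dist <- suppressWarnings(igraph::distances(g, v = seeds, mode = "all"))
  reach <- apply(dist, 2, min)
  which(reach <= bound)
}

# brute-force even-odd point-in-polygon (ray casting), one point at a time
oracle_point_in_polygon <- function(pt, poly) {
  n <- nrow(poly) - 1   # closed polygon: last vertex repeats the first
  inside <- FALSE
  for (s in seq_len(n)) {
    x1 <- poly[s, 1]; y1 <- poly[s, 2]
    x2 <- poly[s + 1, 1]; y2 <- poly[s + 1, 2]
    if ((y1 > pt[2]) != (y2 > pt[2])) {
      xc <- x1 + (pt[2] - y1) / (y2 - y1) * (x2 - x1)
      if (pt[1] < xc) inside <- !inside
    }
  }
  inside
}

# brute-force rule-table classifier: independent if-chains per class
oracle_classify <- function(d, morph, topo) {
  cand <- character(0)
  if (d > 45) cand <- c(cand, "A")
  if (d >= 10 && d <= 45) cand <- c(cand, "Ae")
  if (d < 10) cand <- c(cand, "C")
  if (d >= 10 && d <= 50) cand <- c(cand, "Ve")
  if (d > 50) cand <- c(cand, "V")
  m <- switch(morph, none = c("A", "Ae", "C", "Ve", "V"),
              elongated = c("A", "Ae"), irregular = c("V", "Ve"),
              `single-cell` = "C")
  if (length(intersect(cand, m))) cand <- intersect(cand, m)
  t_ <- switch(topo, none = c("A", "Ae", "C", "Ve", "V"),
               branches_off_artery = "Ae", converges_to_vein = "Ve")
  if (length(intersect(cand, t_))) cand <- intersect(cand, t_)
  cand
}

# wall distance of a point to every vessel by exhaustive dense sampling of
# the centerlines (0.1 um), independent of the segment-projection code
oracle_wall_distances <- function(pt, paths) {
  vapply(paths, function(p) {
    res <- avleak:::.resample_polyline(p@points, 0.1, values = p@radius)
    d <- sqrt(colSums((t(res$points) - pt)^2))
    max(min(d - res$values), 0)
  }, numeric(1))
}
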
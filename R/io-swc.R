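# SWC structure-type code used for vessel centerlines (custom range)
.SWC_TYPE <- 7L

#' Write vessel centerlines in SWC format
#'
#' One point per line: \code{id type x y z radius parent}, coordinates in
#' um.  Points within a path chain to their predecessor; the first point of
#' a path is a root (parent -1).  The vessel id of each path is recorded in
#' a comment header so \code{\link{readSWC}} can restore identities.
#'
#' @param paths list of \linkS4class{VesselPath}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeSWC <- function(paths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC vessel centerlines (id type x y z radius parent)", con)
  offset <- 0L
  for (p in paths) {
    n <- nrow(p@points)
    writeLines(sprintf("# vessel %d points %d", p@vesselId, n), con)
    r <- p@radius
    r[is.na(r)] <- 0
    parent <- c(-1L, offset + seq_len(n - 1))
    lines <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                     offset + seq_len(n), .SWC_TYPE,
                     p@points[, 1], p@points[, 2], p@points[, 3], r, parent)
    writeLines(lines, con)
    offset <- offset + n
  }
  invisible(path)
}

#' Read vessel centerlines from an SWC file
#'
#' Paths are reconstructed from the parent chains: every root (parent -1)
#' starts a new path.  Vessel ids are taken from the \code{# vessel} header
#' comments when present, otherwise numbered in order.
#'
#' @param path SWC file
#' @return list of \linkS4class{VesselPath}
#' @export
readSWC <- function(path) {
  lines <- readLines(path)
  headers <- grep("^# vessel ", lines, value = TRUE)
  ids <- as.integer(sub("^# vessel (\\d+) .*", "\\1", headers))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("no SWC points in ", path)
  tab <- utils::read.table(text = lines,
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  roots <- which(tab$parent == -1)
  ends <- c(roots[-1] - 1, nrow(tab))
  out <- vector("list", length(roots))
  for (t in seq_along(roots)) {
    seg <- tab[roots[t]:ends[t], ]
    r <- seg$radius
    r[r == 0] <- NA_real_
    vid <- if (t <= length(ids)) ids[t] else t
    out[[t]] <- VesselPath(vid, as.matrix(seg[, c("x", "y", "z")]), r)
  }
  out
}
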
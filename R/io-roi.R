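#' Read / write region-of-interest polygons as JSON
#'
#' ROIs are stored as a JSON array of objects with \code{plane} (1-based z
#' index), \code{label} and \code{vertices} (an array of [x, y] pairs in um,
#' first vertex repeated last to close the polygon).
#'
#' @param rois list of ROIs (see \code{\link{segmentCompartments}})
#' @param path JSON file path
#' @return \code{path} invisibly (write) or the ROI list (read)
#' @export
writeROIs <- function(rois, path) {
  out <- lapply(rois, function(r)
    list(plane = r$plane, label = r$label,
         vertices = unname(apply(.as_roi_vertices(r$vertices), 1, as.list))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeROIs
#' @export
readROIs <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(r)
    list(plane = as.integer(r$plane), label = r$label,
         vertices = do.call(rbind, lapply(r$vertices, function(v)
           c(as.numeric(v[[1]]), as.numeric(v[[2]]))))))
}

#' Serialize / restore a phantom truth as JSON
#'
#' The compartment label array is not serialized (it is reproducible from
#' the paths and the generating PhantomSpec); everything else round-trips.
#'
#' @param truth a \linkS4class{PhantomTruth}
#' @param path JSON file path
#' @return \code{path} invisibly (write) or the truth (read)
#' @export
writeTruth <- function(truth, path) {
  out <- list(
    timepoint = truth@timepoint,
    dims = truth@dims,
    voxel_size_um = truth@voxelSizeUm,
    perfused_length_um = truth@perfusedLength,
    classes = as.list(truth@classes),
    diameters_um = as.list(truth@diametersUm),
    perfused = as.list(truth@perfused),
    leaks = truth@leaks,
    paths = lapply(truth@paths, function(p)
      list(vessel_id = p@vesselId, parent = p@parent,
           points = unname(p@points), radius = p@radius)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  paths <- lapply(seq_len(nrow_or_len(raw$paths)), function(t) {
    p <- if (is.data.frame(raw$paths)) lapply(raw$paths, `[[`, t)
         else raw$paths[[t]]
    pts <- p$points
    if (!is.matrix(pts)) pts <- do.call(rbind, lapply(pts, unlist))
    parent <- unlist(p$parent)
    VesselPath(unlist(p$vessel_id), pts, unlist(p$radius),
               parent = if (is.null(parent) || all(is.na(parent))) NULL
                        else parent)
  })
  leaks <- if (length(raw$leaks)) as.data.frame(raw$leaks) else .empty_leaks()
  new("PhantomTruth", paths = paths,
      classes = unlist(raw$classes),
      diametersUm = unlist(raw$diameters_um),
      perfused = unlist(raw$perfused),
      leaks = leaks, compartments = NULL,
      dims = as.integer(raw$dims),
      voxelSizeUm = as.numeric(raw$voxel_size_um),
      perfusedLength = as.numeric(raw$perfused_length_um),
      timepoint = raw$timepoint)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
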
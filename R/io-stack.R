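#' Read a 3D stack from a multi-page TIFF
#'
#' One TIFF page per z-plane.  Voxel sizes, the intensity scale and the
#' channel/timepoint tags are read from the JSON sidecar written by
#' \code{\link{writeStack}} (\code{<file>.json}); when the sidecar is
#' missing, the acquisition default of 0.58 x 0.58 x 1 um voxels is assumed
#' with a warning.
#'
#' @param path TIFF file path
#' @return an \linkS4class{ImageStack}
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("malformed TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  a <- array(unlist(pages, use.names = FALSE), c(d[1], d[2], length(pages)))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    vox <- as.numeric(meta$voxel_size_um)
    a <- a * meta$intensity_scale
    ImageStack(a, vox,
               channel = meta$channel %||% "tracer",
               timepoint = meta$timepoint %||% "t0")
  } else {
    warning("no voxel-size sidecar for '", path,
            "'; assuming 0.58 x 0.58 x 1 um voxels")
    ImageStack(a, c(0.58, 0.58, 1))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a stack as a multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored as 16-bit (or 32-bit) samples after division by
#' \code{intensity_scale = max(intensities)}; the scale, the voxel sizes and
#' the channel/timepoint tags go into \code{<file>.json} so that
#' \code{\link{readStack}} restores the stack losslessly up to the sample
#' quantization.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param path output TIFF path
#' @param bitsPerSample 16 (default) or 32
#' @return \code{path}, invisibly
#' @export
writeStack <- function(stack, path, bitsPerSample = 16L) {
  a <- stack@data
  scale <- max(a, 1e-12)
  pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample)
  meta <- list(voxel_size_um = stack@voxelSize,
               intensity_scale = scale,
               channel = stack@channel,
               timepoint = stack@timepoint,
               dims = dim(a))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a lumen mask as an 8-bit TIFF label volume
#'
#' Voxel values are the owning vessel id (0 outside any lumen), scaled into
#' the 8-bit range; the id scale and the fill threshold are echoed into the
#' JSON sidecar for provenance.
#'
#' @param mask a \linkS4class{LumenMask}
#' @param path output TIFF path
#' @return \code{path}, invisibly
#' @export
writeMask <- function(mask, path) {
  maxid <- max(1L, max(mask@owner))
  pages <- lapply(seq_len(dim(mask@owner)[3]),
                  function(k) mask@owner[, , k] / maxid)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(voxel_size_um = mask@voxelSize,
                            id_scale = maxid,
                            fill_threshold = mask@fillThreshold),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lumen mask written by writeMask
#' @param path TIFF path
#' @return a \linkS4class{LumenMask}
#' @export
readMask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- dim(pages[[1]])
  owner <- array(as.integer(round(unlist(pages) * meta$id_scale)),
                 c(d[1], d[2], length(pages)))
  new("LumenMask", mask = owner > 0L, owner = owner,
      voxelSize = as.numeric(meta$voxel_size_um),
      fillThreshold = meta$fill_threshold)
}
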
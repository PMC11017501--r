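#' Classify a vessel along the arteriovenous axis
#'
#' Applies the diameter bands of the five cortical vessel classes --
#' arteries (A) > 45 um, arterioles (Ae) 10-45 um, capillaries (C) < 10 um,
#' venules (Ve) 10-50 um, veins (V) > 50 um -- and resolves the overlapping
#' bands with the endothelial-morphology and topology flags: elongated,
#' streamlined endothelium marks the arterial side, irregular endothelium
#' the venous side, a single endothelial cell wrapping the lumen marks a
#' capillary; arterioles branch off arteries and venules converge to form
#' veins.  Bounds are treated strictly as stated, so exact boundary
#' diameters return the ambiguous candidate set for flag resolution.
#'
#' @param diameterUm vessel diameter in um (> 0)
#' @param morphology \code{"none"}, \code{"elongated"}, \code{"irregular"}
#'   or \code{"single-cell"}
#' @param topology \code{"none"}, \code{"branches_off_artery"} or
#'   \code{"converges_to_vein"}
#' @return character vector of candidate classes; length 1 when the flags
#'   resolve the class, longer when it remains ambiguous
#' @examples
#' classifyVessel(6, morphology = "single-cell")      # "C"
#' classifyVessel(47, morphology = "irregular")       # "Ve"
#' classifyVessel(30)                                 # c("Ae", "Ve")
#' @export
classifyVessel <- function(diameterUm,
                           morphology = c("none", "elongated", "irregular",
                                          "single-cell"),
                           topology = c("none", "branches_off_artery",
                                        "converges_to_vein")) {
  stopifnot(length(diameterUm) == 1, diameterUm > 0)
  morphology <- match.arg(morphology)
  topology <- match.arg(topology)
  cand <- .AV_BOUNDS$class[vapply(seq_len(nrow(.AV_BOUNDS)), function(r)
    .in_band(diameterUm, .AV_BOUNDS[r, ]), logical(1))]
  keep <- switch(morphology,
    none = .AV_CLASSES,
    elongated = c("A", "Ae"),
    irregular = c("V", "Ve"),
    `single-cell` = "C")
  if (length(intersect(cand, keep))) cand <- intersect(cand, keep)
  keep <- switch(topology,
    none = .AV_CLASSES,
    branches_off_artery = "Ae",
    converges_to_vein = "Ve")
  if (length(intersect(cand, keep))) cand <- intersect(cand, keep)
  cand
}

#' Classify a table of vessels
#'
#' Vectorized wrapper around \code{\link{classifyVessel}}; ambiguous vessels
#' get the candidates joined with \code{"|"}.
#'
#' @param diameters numeric vector of diameters (um)
#' @param morphology,topology flag vectors (recycled)
#' @return data.frame with \code{diameter_um}, \code{class} and
#'   \code{ambiguous}
#' @export
classifyVessels <- function(diameters, morphology = "none",
                            topology = "none") {
  n <- length(diameters)
  morphology <- rep_len(morphology, n)
  topology <- rep_len(topology, n)
  cls <- character(n)
  amb <- logical(n)
  for (t in seq_len(n)) {
    c_ <- classifyVessel(diameters[t], morphology[t], topology[t])
    cls[t] <- paste(c_, collapse = "|")
    amb[t] <- length(c_) > 1
  }
  data.frame(diameter_um = diameters, class = cls, ambiguous = amb,
             stringsAsFactors = FALSE)
}
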
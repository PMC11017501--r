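#' Infarct volume as percent of the ipsilateral hemisphere
#'
#' Serial-section volumetry of vital-stained coronal sections:
#' \deqn{V_{\%stroke} = \frac{\sum \mathrm{infarct\ area}}
#'   {\sum \mathrm{hemisphere\ area}} \times 100}
#' Areas are summed over all sections; with uniform section thickness the
#' thickness cancels and is only recorded.  The result is invariant under
#' uniform pixel-size rescaling.
#'
#' @param masks a \linkS4class{SectionMaskSet}
#' @return infarct volume in percent of the ipsilateral hemisphere
#' @examples
#' h <- matrix(TRUE, 10, 10)
#' inf <- matrix(FALSE, 10, 10); inf[1:2, 1:5] <- TRUE
#' infarctPercent(SectionMaskSet(list(inf), list(h)))   # 10
#' @export
setGeneric("infarctPercent", function(masks) standardGeneric("infarctPercent"))

#' @rdname infarctPercent
#' @export
setMethod("infarctPercent", "SectionMaskSet", function(masks) {
  validObject(masks)
  px_area <- masks@pixelSizeMm^2
  inf_area <- sum(vapply(masks@infarct, sum, numeric(1))) * px_area
  hem_area <- sum(vapply(masks@hemisphere, sum, numeric(1))) * px_area
  if (hem_area == 0) stop("total hemisphere area is zero")
  inf_area / hem_area * 100
})
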
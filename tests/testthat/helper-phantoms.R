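# Shared measurement chains over cylinder phantoms.

# render a cylinder, trace it from its true endpoints, measure its FWHM
# diameter (with the axial-curvature correction for the known phantom PSF)
measure_cylinder_diameter <- function(diameterUm, trace = TRUE, ...) {
  cp <- cylinderPhantom(diameterUm, ...)
  stk <- renderStack(cp$truth, cp$spec, noise = FALSE)
  ep <- pathPoints(truthPaths(cp$truth)[[1]])
  path <- if (trace) {
    sm <- smoothStack(stk, 1)
    traceVessel(sm, ep[c(1, nrow(ep)), ], estimateRadius = FALSE)
  } else truthPaths(cp$truth)[[1]]
  as.numeric(measureDiameter(stk, path, axialSigma = cp$spec@psfSigma[3]))
}

# plant one halo on a cylinder, run the full extraction chain, return the
# measured spreading distance.  detection threshold: half the halo clipping
# floor (amplitude * exp(-2)), the calibration at which the blurred support
# edge sits at the planned spreading distance
measure_cylinder_spreading <- function(spreadUm, diameterUm = 6,
                                       siteLength = 30) {
  cp <- cylinderPhantom(diameterUm, lengthUm = siteLength + 30, marginUm = 6,
                        leak = list(position = 0.5, spreading_um = spreadUm,
                                    site_length_um = siteLength))
  stk <- renderStack(cp$truth, cp$spec, noise = FALSE)
  sm <- smoothStack(stk, 1)
  path <- truthPaths(cp$truth)[[1]]
  m <- fillLumen(sm, path, 0.3)
  sp <- splitSignal(stk, m)
  thr <- 0.5 * cp$spec@leakAmplitude * cp$spec@tracerIntensity * exp(-2)
  sites <- extractLeakSites(sp$extraluminal, list(path), thr, lumen = m)
  if (!length(sites)) return(NA_real_)
  wall <- avleak:::.dilate26(lumenMask(m))
  as.numeric(spreadingDistance(sp$extraluminal, sites[[1]], path, thr,
                               wallMask = wall))
}
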
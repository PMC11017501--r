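test_that("empty vessel spec yields an empty truth with zero perfused length", {
  spec <- phantomSpec(seed = 2)
  truth <- generateTree(spec)
  expect_length(truthPaths(truth), 0)
  expect_equal(truthPerfusedLength(truth), 0)
  stk <- renderStack(truth, spec, noise = FALSE)
  expect_true(all(intensities(stk) == 0))
})

test_that("a single-artery spec yields one class-A path above 45 um", {
  spec <- phantomSpec(volumeSize = c(250, 250, 120),
                      vesselCount = c(A = 1), seed = 11)
  truth <- generateTree(spec)
  expect_length(truthPaths(truth), 1)
  expect_equal(unname(truthClasses(truth)), "A")
  expect_gt(truthDiameters(truth)[[1]], 45)
})

test_that("generation and rendering are deterministic under a fixed seed", {
  spec <- phantomSpec(vesselCount = c(Ae = 1, C = 2), seed = 1)
  t1 <- generateTree(spec)
  t2 <- generateTree(spec)
  expect_identical(t1, t2)
  s1 <- renderStack(t1, spec, noise = TRUE, seed = 7)
  s2 <- renderStack(t2, spec, noise = TRUE, seed = 7)
  expect_identical(intensities(s1), intensities(s2))
})

test_that("placement fails explicitly when the volume cannot hold the request", {
  spec <- phantomSpec(volumeSize = c(40, 40, 30), voxelSize = c(1, 1, 1),
                      vesselCount = c(A = 4), seed = 3)
  expect_error(generateTree(spec), "volume too small")
})

test_that("without leaks or noise, signal is confined to the dilated lumina", {
  spec <- phantomSpec(vesselCount = c(C = 2), seed = 5)
  truth <- generateTree(spec)
  stk <- renderStack(truth, spec, noise = FALSE)
  lum <- truthCompartments(truth) == 3L
  # dilate by the PSF reach (4 sigma in voxels, plus the anti-alias edge)
  grown <- lum
  for (i in 1:3) grown <- avleak:::.dilate26(grown)
  expect_true(all(intensities(stk)[!grown] == 0))
})

test_that("perfused length equals the summed polyline length of perfused paths", {
  spec <- phantomSpec(vesselCount = c(Ae = 2, C = 3), seed = 9,
                      occludedFraction = 0.4)
  truth <- generateTree(spec)
  perf <- truth@perfused
  expected <- sum(vapply(truthPaths(truth)[perf], pathLength, numeric(1)))
  expect_identical(truthPerfusedLength(truth), expected)
  expect_equal(sum(!perf), round(0.4 * length(perf)))
})

test_that("the PSF conserves total intensity (normalized kernel)", {
  spec <- phantomSpec(vesselCount = c(C = 2), seed = 5)
  truth <- generateTree(spec)
  raw <- renderStack(truth, spec, noise = FALSE, blur = FALSE,
                     antialias = FALSE)
  blurred <- renderStack(truth, spec, noise = FALSE, blur = TRUE,
                         antialias = FALSE)
  lum_total <- sum(truthCompartments(truth) == 3L) * spec@tracerIntensity
  expect_identical(sum(intensities(raw)), lum_total)
  expect_lt(abs(sum(intensities(blurred)) - lum_total) / lum_total, 0.01)
})

test_that("an occluded vessel is dark in the tracer but bright in the reporter", {
  spec <- phantomSpec(vesselCount = c(Ae = 1), seed = 21,
                      occludedFraction = 1)
  truth <- generateTree(spec)
  ch <- renderStack(truth, spec, reporter = TRUE, noise = FALSE)
  lum <- truthCompartments(truth) == 3L
  expect_true(all(intensities(ch$tracer)[lum] < 1e-6))
  # the reporter labels the endothelial wall: bright shell, dark interior
  rep_lum <- intensities(ch$reporter)[lum]
  expect_gt(max(rep_lum), spec@tracerIntensity / 2)
  expect_gt(mean(rep_lum > spec@tracerIntensity / 4), 0.1)
})

test_that("a rendered halo reaches the planned spreading distance from the wall", {
  cp <- cylinderPhantom(6, lengthUm = 50, marginUm = 4,
                        leak = list(position = 0.5, spreading_um = 6,
                                    site_length_um = 20))
  stk <- renderStack(cp$truth, cp$spec, noise = FALSE, blur = FALSE)
  # brute-force distance transform: wall distance of every bright
  # extraluminal voxel, sampled densely and independently of the C++ path
  path <- truthPaths(cp$truth)[[1]]
  lum <- truthCompartments(cp$truth) == 3L
  bright <- which(intensities(stk) > 0 & !lum)
  pts <- avleak:::.idx_to_um(bright, dim(intensities(stk)), voxelSize(stk))
  wd <- apply(pts, 1, function(p) oracle_wall_distances(p, list(path)))
  expect_lt(max(wd), 6 + 1.16)
  expect_gt(max(wd), 6 - 1.16)
})

test_that("planned leaks resolve to vessels of the requested class", {
  spec <- phantomSpec(vesselCount = c(Ae = 1, C = 3), seed = 13,
                      leaks = data.frame(vessel = c("C", "C", "Ae"),
                                         position = c(0.3, 0.6, 0.5),
                                         spreading_um = c(5, 7, 9),
                                         site_length_um = 15,
                                         onset = "t1"))
  truth <- generateTree(spec)
  lk <- truthLeaks(truth)
  expect_equal(nrow(lk), 3)
  cls <- truthClasses(truth)[as.character(lk$vessel_id)]
  expect_equal(unname(cls), c("C", "C", "Ae"))
  expect_true(validObject(truth))
})

test_that("follow-up timepoints constrict diameters and split leak directions", {
  spec <- phantomSpec(vesselCount = c(Ae = 4), seed = 17,
                      constrictionSd = rep(1e-9, 5))
  truth <- generateTree(spec)
  truth <- plantLeaks(truth, c(Ae = 10), siteLength = 15)
  expect_error(applyTimepoint(truth, spec, "t0"), "collision")

  # identity factors leave diameters unchanged
  spec_id <- spec
  spec_id@constrictionMean[] <- 1
  out <- applyTimepoint(truth, spec_id, "t1", nIncreasing = 7,
                        render = FALSE)
  expect_equal(truthDiameters(out$truth), truthDiameters(truth))
  lk <- truthLeaks(out$truth)
  expect_equal(sum(lk$direction == "increased"), 7)
  expect_true(all(lk$spreading_um[lk$direction == "increased"] >
                  truthLeaks(truth)$spreading_um[lk$direction == "increased"]))
  expect_true(all(lk$spreading_um[lk$direction == "decreased"] <
                  truthLeaks(truth)$spreading_um[lk$direction == "decreased"]))

  # near-deterministic arteriole factors give the configured mean ratio
  out2 <- applyTimepoint(truth, spec, "t1", nIncreasing = 7, render = FALSE)
  ratio <- truthDiameters(out2$truth) / truthDiameters(truth)
  expect_equal(unname(mean(ratio)), unname(spec@constrictionMean[["Ae"]]),
               tolerance = 1e-4)
})

test_that("phantom spec validity rejects inconsistent parameters", {
  expect_error(phantomSpec(occludedFraction = 1.3), "occludedFraction")
  expect_error(phantomSpec(vesselCount = c(C = 1),
                           diameterMean = c(A = 74.1, Ae = 26.8, C = 12,
                                            Ve = 21.3, V = 76.7)),
               "band")
  expect_error(phantomSpec(constrictionMean = rep(1.2, 5)), "constriction")
})
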
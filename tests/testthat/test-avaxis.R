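test_that("classification follows the printed diameter bands and flags", {
  expect_identical(classifyVessel(6, morphology = "single-cell"), "C")
  expect_identical(classifyVessel(47, morphology = "elongated"), "A")
  expect_identical(classifyVessel(47, morphology = "irregular"), "Ve")
  expect_setequal(classifyVessel(10), c("Ae", "Ve"))
  expect_identical(classifyVessel(10, topology = "branches_off_artery"), "Ae")
  expect_identical(classifyVessel(30, topology = "converges_to_vein"), "Ve")
  expect_identical(classifyVessel(80, morphology = "irregular"), "V")
  expect_error(classifyVessel(-3))
})

test_that("classification is total and matches the rule-table oracle everywhere", {
  diams <- c(seq(0.5, 100, by = 0.5), 9.999, 10, 10.001, 44.999, 45, 45.001,
             49.999, 50, 50.001)
  morphs <- c("none", "elongated", "irregular", "single-cell")
  topos <- c("none", "branches_off_artery", "converges_to_vein")
  for (m in morphs) for (t in topos) {
    got <- vapply(diams, function(d)
      paste(sort(classifyVessel(d, m, t)), collapse = "|"), character(1))
    want <- vapply(diams, function(d)
      paste(sort(oracle_classify(d, m, t)), collapse = "|"), character(1))
    expect_identical(got, want)
    expect_true(all(nzchar(want)))   # every diameter maps to >= 1 class
  }
})

test_that("FWHM diameter recovers a 20 um cylinder within two xy voxels", {
  d <- measure_cylinder_diameter(20)
  expect_lt(abs(d - 20), 1.16)
})

test_that("FWHM is invariant under intensity scaling and flags lost walls", {
  cp <- cylinderPhantom(12, lengthUm = 30)
  stk <- renderStack(cp$truth, cp$spec, noise = FALSE)
  path <- truthPaths(cp$truth)[[1]]
  d1 <- as.numeric(measureDiameter(stk, path))
  scaled <- stk
  scaled@data <- stk@data * 11.3
  expect_equal(as.numeric(measureDiameter(scaled, path)), d1,
               tolerance = 1e-9)
  # profile never falls to half maximum inside a short search window
  d_lost <- measureDiameter(stk, path, maxSearch = 8)
  expect_true(is.na(as.numeric(d_lost)))
})

test_that("relative change follows the post/pre normalization", {
  pre <- diameterRecord(1L, 1L, "pre", 40)
  post <- diameterRecord(1L, 1L, "post", 30)
  rc <- relativeChange(pre, post)
  expect_equal(rc$ratio, 0.75)
  expect_equal(rc$percentDecrease, 25)
  expect_error(relativeChange(pre, diameterRecord(1L, 2L, "post", 30)),
               "different segments")
  # identical stacks measured twice give a ratio of 1
  d1 <- measure_cylinder_diameter(15)
  d2 <- measure_cylinder_diameter(15)
  expect_equal(d2 / d1, 1, tolerance = 0.02)
})

test_that("leak attribution picks the nearest wall and honors the tie rule", {
  # capillary wall 3 um away vs venule wall 30 um away
  cap <- VesselPath(1L, rbind(c(0, 10, 10), c(50, 10, 10)), 3)
  ven <- VesselPath(2L, rbind(c(0, 51, 10), c(50, 51, 10)), 8)
  got <- attributeLeak(c(25, 16, 10), list(cap, ven))
  expect_identical(as.integer(got), 1L)
  expect_equal(attr(got, "wallDistance"), 3)

  # wall distances 5.0 and 5.3, tolerance 0.58 (one xy pixel): both included
  v1 <- VesselPath(1L, rbind(c(0, 0, 0), c(40, 0, 0)), 2)
  v2 <- VesselPath(2L, rbind(c(0, 13.3, 0), c(40, 13.3, 0)), 1)
  site <- c(20, 7, 0)
  wd <- oracle_wall_distances(site, list(v1, v2))
  expect_equal(wd, c(5, 5.3), tolerance = 1e-6)
  got <- attributeLeak(site, list(v1, v2), tieToleranceUm = 0.58)
  expect_identical(sort(as.integer(got)), c(1L, 2L))
  got2 <- attributeLeak(site, list(v1, v2), tieToleranceUm = 0.2)
  expect_identical(as.integer(got2), 1L)

  expect_warning(un <- attributeLeak(c(500, 500, 500), list(v1, v2)),
                 "unattributed")
  expect_length(un, 0)
})

test_that("attribution agrees with exhaustive pairwise distances on random scenes", {
  set.seed(61)
  for (trial in 1:8) {
    paths <- lapply(1:4, function(v) {
      p0 <- runif(3, 10, 90)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      VesselPath(v, rbind(p0 - 30 * dir, p0 + 30 * dir), runif(1, 1, 6))
    })
    site <- runif(3, 20, 80)
    wd <- oracle_wall_distances(site, paths)
    got <- suppressWarnings(
      attributeLeak(site, paths, tieToleranceUm = 0.58,
                    maxAttributionUm = 1e6))
    expect_identical(as.integer(got)[1], which.min(wd))
    both <- sort(wd)[2] - sort(wd)[1] <= 0.58
    expect_identical(length(got) == 2, both)
    expect_equal(min(attr(got, "wallDistance")), min(wd), tolerance = 0.02)
  }
})

test_that("a constant planted halo is recovered at its spreading distance", {
  s <- measure_cylinder_spreading(8, diameterUm = 6, siteLength = 20)
  expect_lt(abs(s - 8), 1.16)
})

test_that("continuity excludes detached blobs from the spreading distance", {
  # synthetic extraluminal field: 5 um halo on the wall plus a bright blob
  # 30 um out
  d <- c(81, 61, 41)
  vox <- c(1, 1, 1)
  path <- VesselPath(1L, rbind(c(0, 40.5, 20.5), c(61, 40.5, 20.5)), 3)
  a <- array(0, d)
  idx <- seq_len(prod(d))
  pts <- avleak:::.idx_to_um(idx, d, vox)
  wall <- sqrt((pts[, 2] - 40.5)^2 + (pts[, 3] - 20.5)^2) - 3
  halo <- wall > 0 & wall <= 5 & pts[, 1] >= 20 & pts[, 1] <= 40
  blob <- wall > 30 & wall <= 33 & pts[, 2] > 40.5 & pts[, 3] > 15 &
    pts[, 3] < 25 & pts[, 1] >= 25 & pts[, 1] <= 35
  a[idx[halo]] <- 10
  a[idx[blob]] <- 50
  ext <- ImageStack(a, vox)
  site <- new("LeakSite", siteId = 1L, voxels = as.integer(idx[halo | blob]),
              dims = as.integer(d), centroid = c(30, 45, 20.5),
              vessels = 1L, wallDistance = 1)
  s <- spreadingDistance(ext, site, path, detectionThreshold = 1)
  expect_lt(abs(as.numeric(s) - 5), 1.16)

  # dilating the halo never decreases the measurement
  a2 <- a
  halo2 <- wall > 0 & wall <= 7 & pts[, 1] >= 20 & pts[, 1] <= 40
  a2[idx[halo2]] <- 10
  ext2 <- ImageStack(a2, vox)
  site2 <- new("LeakSite", siteId = 1L,
               voxels = as.integer(idx[halo2 | blob]),
               dims = as.integer(d), centroid = c(30, 45, 20.5),
               vessels = 1L, wallDistance = 1)
  s2 <- spreadingDistance(ext2, site2, path, detectionThreshold = 1)
  expect_gte(as.numeric(s2), as.numeric(s))

  # nothing above threshold: zero with a flag
  s0 <- spreadingDistance(ext, site, path, detectionThreshold = 100)
  expect_equal(as.numeric(s0), 0)
  expect_identical(attr(s0, "flag"), "no_signal")
})

test_that("progression classifies per-site direction and reports the fraction", {
  t1 <- data.frame(site_id = 1:10, spreading_um = seq(2, 11))
  # identical: all ties, fraction 0
  pr <- leakProgression(t1, t1)
  expect_equal(pr$fractionIncreased, 0)
  expect_equal(pr$nTies, 10)
  # uniform growth: all increased
  t2 <- t1
  t2$spreading_um <- t1$spreading_um + 1
  pr <- leakProgression(t1, t2)
  expect_equal(pr$fractionIncreased, 1)
  # mixed, with one unmatched site excluded
  t2 <- t1
  t2$spreading_um[1:6] <- t1$spreading_um[1:6] * 1.5
  t2$spreading_um[7:10] <- t1$spreading_um[7:10] * 0.6
  t2 <- rbind(t2, data.frame(site_id = 99, spreading_um = 4))
  expect_message(pr <- leakProgression(t1, t2), "unmatched")
  expect_equal(pr$fractionIncreased, 0.6)
  expect_equal(pr$nUnmatched, 1)
  expect_lt(pr$pValue, 1)
})
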
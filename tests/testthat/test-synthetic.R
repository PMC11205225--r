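test_that("uniform mosaic realises the analytic hex-lattice count and density", {
  fld <- generateMosaic(190000, 1e9, 300, jitterSd = 0, seed = 1)
  expect_equal(nCones(fld), 190000 * 0.3^2, tolerance = 0.02)

  # realised density matches 2/(sqrt(3) s^2) within 2% for jitter <= 0.15 s
  s <- hexSpacing(190000)
  for (jit in c(0, 0.1 * s, 0.15 * s)) {
    f <- generateMosaic(190000, 1e9, 200, jitterSd = jit, seed = 4)
    expect_equal(nCones(f) / 0.2^2, hexDensity(s), tolerance = 0.02)
  }
})

test_that("mosaic generation is deterministic given the seed", {
  a <- generateMosaic(180000, 120, 300, seed = 42)
  b <- generateMosaic(180000, 120, 300, seed = 42)
  c <- generateMosaic(180000, 120, 300, seed = 43)
  expect_identical(conePositions(a), conePositions(b))
  expect_false(isTRUE(all.equal(conePositions(a), conePositions(c))))
})

test_that("radial falloff increases nearest-neighbour spacing with eccentricity", {
  fld <- generateMosaic(200000, 50, 300, jitterSd = 0.2, seed = 9)
  xy <- conePositionsUm(fld)
  r <- sqrt(rowSums(sweep(xy, 2, 150)^2))
  nn <- function(sel) {
    pts <- xy[sel, , drop = FALSE]
    d <- as.matrix(dist(pts))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  center <- nn(r < 20)
  corner <- nn(r >= 140 & r < 160)
  expect_gt(corner, center)
  # realised local density in annuli matches the analytic radial profile
  for (rr in list(c(0, 30), c(60, 90), c(120, 150))) {
    n <- sum(r >= rr[1] & r < rr[2])
    expected <- integrate(function(u) 200000e-6 * exp(-u / 50) * 2 * pi * u,
                          rr[1], rr[2])$value
    expect_equal(n, expected, tolerance = 0.05)
  }
})

test_that("too-sparse parameters are rejected", {
  expect_error(generateMosaic(1000, 1e9, 100, seed = 1), "200")
})

test_that("zero-perturbation revisit is the identity", {
  fld <- generateMosaic(180000, 150, 200, seed = 5)
  rev <- simulateRevisit(fld, seed = 6)
  expect_identical(conePositions(rev), conePositions(fld))
})

test_that("revisit miss rate thins the mosaic binomially", {
  fld <- generateMosaic(200000, 1e9, 250, jitterSd = 0, seed = 7)
  n0 <- nCones(fld)
  rev <- simulateRevisit(fld, missRate = 0.1, seed = 8)
  expected <- 0.9 * n0
  expect_lt(abs(nCones(rev) - expected), 3 * sqrt(n0 * 0.1 * 0.9))
})

test_that("pure translation shifts every cone rigidly", {
  fld <- generateMosaic(180000, 1e9, 200, jitterSd = 0, seed = 10)
  rev <- simulateRevisit(fld, translationUm = c(50, 0))
  a <- conePositionsUm(fld)
  b <- conePositionsUm(rev)
  # cones pushed out of the ROI are clipped; match on the surviving set
  keep <- a[, 1] + 50 <= 200
  expect_equal(nrow(b), sum(keep))
  expect_equal(b[, 1], a[keep, 1] + 50, tolerance = 1e-12)
  expect_equal(b[, 2], a[keep, 2], tolerance = 1e-12)
})

test_that("scale error contracts coordinates about the ROI centre", {
  fld <- generateMosaic(180000, 1e9, 200, jitterSd = 0, seed = 11)
  rev <- simulateRevisit(fld, scaleError = 0.9)
  a <- conePositionsUm(fld)
  b <- conePositionsUm(rev)
  expect_equal(b, (a - 100) * 0.9 + 100, tolerance = 1e-12)
})

test_that("cohort generation emits two visits per subject with stated ROIs", {
  coh <- generateCohort(5, seed = 20)
  expect_s3_class(coh, "ConeCohort")
  expect_length(coh, 5)
  for (s in coh) {
    expect_equal(roiSide(s$visit1), 300)
    expect_equal(roiSide(s$visit2), 500)
    expect_equal(visitNumber(s$visit2), 2L)
    expect_true(s$intervalYears >= 2.48 && s$intervalYears <= 4.28)
  }
  # seed dependence
  coh2 <- generateCohort(2, seed = 21)
  coh3 <- generateCohort(2, seed = 22)
  expect_false(identical(conePositions(coh2[[1]]$visit1),
                         conePositions(coh3[[1]]$visit1)))
  # determinism
  coh4 <- generateCohort(2, seed = 21)
  expect_identical(conePositions(coh2[[1]]$visit2),
                   conePositions(coh4[[1]]$visit2))
})

test_that("cohort generation validates its inputs", {
  expect_error(generateCohort(1), "at least 2")
  expect_error(generateCohort(3, mosaicRanges = list(
    peakDensity = numeric(0), falloffScale = c(90, 140))), "range")
})

test_that("null cohort visit 2 crops back to exactly visit 1", {
  coh <- generateCohort(2, seed = 30, revisit = nullRevisit)
  for (s in coh)
    expect_identical(conePositions(cropConeField(s$visit2, 300)),
                     conePositions(s$visit1))
})
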
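test_that("adaptive-window density recovers the analytic hex density", {
  fld <- rescaleToCommon(generateMosaic(187800, 1e9, 200, jitterSd = 0,
                                        seed = 1), 0.25)
  tess <- tessellate(fld)
  res <- densityAt(fld, cbind(100, 100), k = 150, tess = tess)
  s <- hexSpacing(187800)
  expect_equal(res$density, hexDensity(s), tolerance = 0.02)
  expect_gte(res$count, 150)
})

test_that("density is missing at ROI corners and for infeasible k", {
  fld <- rescaleToCommon(generateMosaic(30000, 1e9, 140, jitterSd = 0.3,
                                        seed = 2), 0.25)
  tess <- tessellate(fld)
  corner <- densityAt(fld, cbind(2, 2), k = 150, tess = tess)
  expect_true(is.na(corner$density))
  # k beyond the number of bounded cells: missing everywhere
  toomany <- densityAt(fld, cbind(70, 70), k = sum(boundedCells(tess)) + 1,
                       tess = tess)
  expect_true(is.na(toomany$density))
})

test_that("density matrix is flat on uniform mosaics and subsamples consistently", {
  fld <- rescaleToCommon(generateMosaic(170000, 1e9, 180,
                                        jitterSd = 0.1 * hexSpacing(170000),
                                        seed = 3), 0.25)
  tess <- tessellate(fld)
  dm1 <- computeDensityMatrix(fld, k = 150, stride = 8, tess = tess)
  v <- densityValues(dm1)
  expect_equal(mean(v, na.rm = TRUE), 170000, tolerance = 0.02)
  expect_lt(sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE), 0.02)
  # stride consistency: coarser grid equals the fine grid subsampled
  dm4 <- computeDensityMatrix(fld, k = 150, stride = 32, tess = tess)
  sub <- densityValues(dm1)[seq(1, nrow(v), by = 4), seq(1, ncol(v), by = 4)]
  expect_identical(densityValues(dm4), sub)
})

test_that("engine agrees with the exhaustive window-search oracle", {
  fld <- rescaleToCommon(generateMosaic(26000, 1e9, 130, jitterSd = 0.8,
                                        seed = 4), 0.25)
  tess <- tessellate(fld)
  expect_lt(nCones(fld), 500)
  set.seed(11)
  pts <- cbind(runif(25, 55, 75), runif(25, 55, 75))
  eng <- densityAt(fld, pts, k = 150, tess = tess)
  for (i in seq_len(nrow(pts))) {
    orc <- oracleDensityAt(fld, tess, pts[i, ], k = 150)
    expect_equal(eng$density[i], orc[["density"]], tolerance = 1e-9)
    expect_equal(eng$window_side_um[i], orc[["side"]], tolerance = 1e-9)
  }
})

test_that("window growth is monotone: larger windows never lose contained cells", {
  fld <- generateMosaic(150000, 200, 120, seed = 5)
  tess <- tessellate(fld)
  idx <- which(boundedCells(tess))
  polys <- cellPolygons(tess)
  set.seed(6)
  for (q in asplit(cbind(runif(5, 40, 80), runif(5, 40, 80)), 1)) {
    req <- vapply(idx, function(i) {
      v <- polys[[i]]
      max(abs(v[, 1] - q[1]), abs(v[, 2] - q[2]))
    }, numeric(1))
    counts <- vapply(seq(2, 60, by = 0.5),
                     function(h) sum(req < h), numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("density output is invariant under global translation of cones and ROI", {
  base <- generateMosaic(180000, 1e9, 120, jitterSd = 0.3, seed = 7)
  shift <- c(40, 25)
  xyUm <- conePositionsUm(base)
  fld2 <- ConeField((xyUm + rep(shift, each = nrow(xyUm))) / 0.45,
                    umPerPixel = 0.45, roiSideUm = 120 + 80)
  # restrict to the translated copy of the original ROI interior
  q <- cbind(c(60, 55, 70), c(60, 72, 58))
  d1 <- densityAt(base, q, k = 150)
  d2 <- densityAt(fld2, q + rep(shift, each = nrow(q)), k = 150)
  expect_equal(d2$density, d1$density, tolerance = 1e-6)
  expect_equal(d2$window_side_um, d1$window_side_um, tolerance = 1e-9)
})

test_that("rescaling to a different common scale moves densities < 0.5%", {
  raw <- generateMosaic(190000, 150, 160, seed = 8)
  fa <- rescaleToCommon(raw, 0.25)
  fb <- rescaleToCommon(raw, 0.5)
  q <- cbind(c(80, 60, 95), c(80, 90, 70))
  da <- densityAt(fa, q, k = 150)
  db <- densityAt(fb, q, k = 150)
  expect_lt(max(abs(db$density / da$density - 1)), 0.005)
})

test_that("angular conversion is the squared retinal magnification factor", {
  expect_equal(toAngular(187000, axialLengthMm = 24),
               187000 * 0.2897^2, tolerance = 1e-3)
  expect_equal(toAngular(0, axialLengthMm = 24), 0)
  expect_equal(toAngular(2 * 91000, axialLengthMm = 23),
               2 * toAngular(91000, axialLengthMm = 23))
  dm <- makeDM(matrix(100000, 3, 3), axialLengthMm = 24)
  expect_equal(toAngular(dm), matrix(100000 * (0.28967)^2, 3, 3),
               tolerance = 1e-4)
  expect_error(toAngular(makeDM(matrix(1, 3, 3))), "axial length")
})
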
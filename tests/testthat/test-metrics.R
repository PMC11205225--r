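test_that("PCD is the valid maximum with deterministic row-major tie-breaking", {
  m <- matrix(5, 4, 4)
  pcd <- findPCD(makeDM(m))
  expect_equal(pcd$value, 5)
  expect_equal(pcd$cell, c(1L, 1L))
  expect_equal(pcd$location, c(0.5, 0.5))

  m2 <- peakMatrix(21)
  m2[3, 17] <- NA
  pcd2 <- findPCD(makeDM(m2))
  expect_equal(pcd2$value, max(m2, na.rm = TRUE))
  expect_equal(pcd2$cell, c(11L, 11L))

  expect_error(findPCD(makeDM(matrix(NA_real_, 3, 3))), "no valid")
})

test_that("percentile region follows the nearest-rank rule", {
  dm <- makeDM(matrix(as.numeric(1:100), 10, 10))
  reg <- percentileRegion(dm, 80)
  expect_equal(reg$threshold, 80)
  expect_equal(reg$areaUm2, 21)
  expect_equal(sum(reg$mask), 21)

  # brute-force recomputation on random matrices (nearest-rank = type-1
  # quantile), and monotone non-increasing area in pct
  set.seed(3)
  for (rep in 1:5) {
    v <- matrix(rexp(400, 1 / 50000), 20, 20)
    v[sample(400, 30)] <- NA
    dmr <- makeDM(v, gridUm = 2.5)
    prev <- Inf
    for (p in c(20, 50, 80, 95)) {
      reg <- percentileRegion(dmr, p)
      ok <- v[!is.na(v)]
      thr <- as.numeric(quantile(ok, p / 100, type = 1))
      expect_equal(reg$threshold, thr)
      expect_equal(reg$areaUm2, sum(ok >= thr) * 2.5^2)
      expect_lte(reg$areaUm2, prev)
      prev <- reg$areaUm2
    }
  }
})

test_that("constant matrices put every valid cell in the percentile region", {
  v <- matrix(7, 8, 8)
  v[1, 1] <- NA
  reg <- percentileRegion(makeDM(v), 80)
  expect_equal(sum(reg$mask), 63)
})

test_that("CDC sits at the peak of symmetric maps and on the midline for twin peaks", {
  dm <- makeDM(peakMatrix(21))
  cdc <- findCDC(dm)
  expect_lt(max(abs(cdc$location - c(10.5, 10.5))), 1)  # within one cell
  expect_lte(cdc$value, findPCD(dm)$value)

  twin <- matrix(1, 21, 21)
  twin[11, 6] <- twin[11, 16] <- 100
  twin[11, 5] <- twin[11, 17] <- 50
  cdc2 <- findCDC(makeDM(twin), 90)
  expect_equal(cdc2$location[1], 10.5, tolerance = 1e-9)  # x on the midline
})

test_that("PCD >= CDC value on noisy single-peak maps", {
  set.seed(8)
  for (rep in 1:10) {
    v <- peakMatrix(25, peak = 1e5, scale = 6) *
      matrix(1 + rnorm(625, 0, 0.02), 25, 25)
    dm <- makeDM(v)
    expect_gte(findPCD(dm)$value, findCDC(dm)$value)
  }
})

test_that("PCD-CDC offset is the Euclidean distance", {
  expect_equal(pcdCdcOffset(list(location = c(0, 0)),
                            list(location = c(0, 0))), 0)
  expect_equal(pcdCdcOffset(list(location = c(10, 0)),
                            list(location = c(0, 0))), 10)
  expect_equal(pcdCdcOffset(list(location = c(3, 4)),
                            list(location = c(0, 0))), 5)
})

test_that("metrics are invariant under rigid translation of the matrix", {
  v <- peakMatrix(21, peak = 2e5, scale = 5)
  dm <- makeDM(v)
  dm2 <- makeDM(v, originUm = c(10.5, 20.5))
  m1 <- fovealMetrics(dm)
  m2 <- fovealMetrics(dm2)
  expect_equal(m2@pcdLocation, m1@pcdLocation + c(10, 20))
  expect_equal(m2@cdcLocation, m1@cdcLocation + c(10, 20))
  expect_equal(m2@pcdValue, m1@pcdValue)
  expect_equal(m2@contourAreaUm2, m1@contourAreaUm2)
  expect_equal(m2@offsetUm, m1@offsetUm)
})

test_that("rounding to three significant digits is half-even and idempotent", {
  expect_equal(roundSig(187436), 187000)
  expect_equal(roundSig(0.012345), 0.0123)
  expect_equal(roundSig(15850), 15800)   # tie goes to the even digit
  x <- c(123456, 0.0034567, 99.99, 15850)
  expect_identical(roundSig(roundSig(x)), roundSig(x))
  # order preserving
  set.seed(1)
  v <- sort(rlnorm(50, 10, 2))
  expect_true(all(diff(roundSig(v)) >= 0))
})

test_that("planted peaks are recovered on synthetic single-peak mosaics", {
  # noise -> 0: PCD and CDC locations converge to the planted peak
  recov <- t(vapply(1:6, function(sd) {
    fld <- generateMosaic(190000, 400, 220, jitterSd = 0.2,
                          peakOffsetUm = c(12, -9), seed = 100 + sd)
    dm <- computeDensityMatrix(rescaleToCommon(fld, 0.25),
                               k = 150, stride = 16)
    c(findPCD(dm)$location, findCDC(dm)$location)
  }, numeric(4)))
  planted <- c(110 + 12, 110 - 9)
  # within 2 grid cells (8 um) of the planted peak on average
  expect_lt(mean(sqrt((recov[, 1] - planted[1])^2 +
                      (recov[, 2] - planted[2])^2)), 8)
  expect_lt(mean(sqrt((recov[, 3] - planted[1])^2 +
                      (recov[, 4] - planted[2])^2)), 8)
})
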
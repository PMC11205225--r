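test_that("percent change uses visit 1 as baseline", {
  expect_equal(percentChange(100, 100), 0)
  expect_equal(percentChange(200000, 190000), 5)
  expect_equal(percentChange(c(100, 50), c(110, 40)), c(10, 20))
  expect_error(percentChange(0, 1), "positive")
  expect_error(percentChange(1:3, 1:2), "paired")
})

test_that("Bland-Altman handles constant and identical differences", {
  ba <- blandAltman(c(1, 2, 3, 4), c(2, 3, 4, 5))   # d identically 1
  expect_equal(ba$bias, 1)
  expect_equal(ba$sd, 0)
  expect_equal(c(ba$loaLower, ba$loaUpper), c(1, 1))

  v <- c(10, 12, 15, 11, 13)
  ba0 <- blandAltman(v, v)
  expect_equal(ba0$bias, 0)
  expect_true(ba0$biasCI[1] <= 0 && 0 <= ba0$biasCI[2])
  expect_error(blandAltman(1:2, 2:3), "at least 3")
})

test_that("Bland-Altman reproduces the textbook formulas", {
  set.seed(5)
  v1 <- rnorm(19, 187000, 20000)
  v2 <- v1 + rnorm(19, 1500, 11000)
  ba <- blandAltman(v1, v2)
  d <- v2 - v1
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loaUpper, mean(d) + 1.96 * sd(d))
  expect_equal(ba$loaLower, mean(d) - 1.96 * sd(d))
  tq <- qt(0.975, 18)
  expect_equal(ba$biasCI, mean(d) + c(-1, 1) * tq * sd(d) / sqrt(19))
  expect_equal(ba$loaUpperCI,
               ba$loaUpper + c(-1, 1) * tq * sd(d) * sqrt(3 / 19))
  # invariant: loaLower <= bias <= loaUpper, CIs contain their estimates
  expect_true(ba$loaLower <= ba$bias && ba$bias <= ba$loaUpper)
  expect_true(ba$biasCI[1] <= ba$bias && ba$bias <= ba$biasCI[2])
})

test_that("paired t matches its reference implementation and degenerate cases", {
  v1 <- c(1.2, 3.4, 2.2, 5.1, 4.0, 3.3, 2.9, 4.6)
  v2 <- c(1.9, 3.1, 2.8, 5.9, 3.6, 3.9, 3.4, 4.1)
  tt <- pairedT(v1, v2)
  # frozen from scipy.stats.ttest_rel on the same vectors
  expect_equal(tt$t, 1.290994448736, tolerance = 1e-6)
  expect_equal(tt$p, 0.237703074985, tolerance = 1e-6)
  expect_equal(tt$df, 7)

  same <- pairedT(v1, v1)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shiftv <- pairedT(v1, v1 + 2)
  expect_equal(shiftv$t, Inf)
  expect_equal(shiftv$p, 0)
  expect_equal(pairedT(rnorm(12), rnorm(12))$df, 11)
})

test_that("Pearson correlation and Fisher-z CI match the reference", {
  v1 <- c(1.2, 3.4, 2.2, 5.1, 4.0, 3.3, 2.9, 4.6)
  v2 <- c(1.9, 3.1, 2.8, 5.9, 3.6, 3.9, 3.4, 4.1)
  pc <- pearsonWithCI(v1, v2)
  # frozen from scipy.stats.pearsonr + Fisher z with SE 1/sqrt(n-3)
  expect_equal(pc$r, 0.901536740104, tolerance = 1e-6)
  expect_equal(pc$ci[1], 0.539779607775, tolerance = 1e-6)
  expect_equal(pc$ci[2], 0.982217898809, tolerance = 1e-6)

  # exact linear relation
  x <- c(1, 2, 4, 7, 9)
  expect_equal(pearsonWithCI(x, 2 * x + 1)$r, 1)
  expect_error(pearsonWithCI(rep(1, 5), 1:5), "zero variance")
  expect_error(pearsonWithCI(1:3, 3:1), "at least 4")
})

test_that("a cohort-sized r of 0.85 gives the expected Fisher-z interval", {
  # construct n = 19 pairs with exact sample correlation 0.85
  set.seed(2)
  x <- scale(rnorm(19))[, 1]
  e <- scale(residuals(lm(rnorm(19) ~ x)))[, 1]
  y <- 0.85 * x + sqrt(1 - 0.85^2) * e
  pc <- pearsonWithCI(x, y)
  expect_equal(pc$r, 0.85, tolerance = 1e-12)
  # closed-form Fisher z: tanh(atanh(0.85) +/- qnorm(0.975)/sqrt(16))
  expect_equal(pc$ci, tanh(atanh(0.85) + c(-1, 1) * qnorm(0.975) / 4),
               tolerance = 1e-9)
  expect_equal(pc$ci, c(0.6447, 0.9407), tolerance = 1e-3)
})

test_that("Fisher-z CI contains r and shrinks as 1/sqrt(n-3)", {
  set.seed(9)
  widths <- vapply(c(10, 43, 163), function(n) {
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    pc <- pearsonWithCI(x, y)
    expect_true(pc$ci[1] <= pc$r && pc$r <= pc$ci[2])
    atanh(pc$ci[2]) - atanh(pc$ci[1])   # constant-width on the z scale
  }, numeric(1))
  expect_equal(widths[1] / widths[2], sqrt(40 / 7), tolerance = 1e-9)
  expect_equal(widths[2] / widths[3], sqrt(160 / 40), tolerance = 1e-9)
})

test_that("independent samples show near-zero correlation at large n", {
  set.seed(4)
  x <- rnorm(10000); y <- rnorm(10000)
  expect_lt(abs(pearsonWithCI(x, y)$r), 0.05)
})

test_that("Shapiro-Wilk wraps Royston's algorithm with range checks", {
  sw <- shapiroWilkTest(c(-2, -1, 0, 1, 2))
  # frozen from scipy.stats.shapiro on the same vector
  expect_equal(sw$W, 0.986762155212, tolerance = 1e-6)
  expect_equal(sw$p, 0.967173934973, tolerance = 1e-6)

  sw2 <- shapiroWilkTest(c(-2, -1, 0, 1.5, 2.2, 0.3, -0.7))
  expect_equal(sw2$W, 0.976549936981, tolerance = 1e-6)
  expect_equal(sw2$p, 0.941178991349, tolerance = 1e-6)

  expect_error(shapiroWilkTest(rep(3, 10)), "zero variance")
  expect_error(shapiroWilkTest(c(1, 2)), "3 <= n")
})
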
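# Cohort reproducibility statistics.  The agreement analysis is implemented
# here; normality, paired t and correlation wrap the corresponding base R
# tests (Royston's Shapiro-Wilk, paired t, Pearson with Fisher-z interval).

#' Intervisit percent change
#'
#' `100 * |v2 - v1| / v1`, with visit 1 as the baseline.
#'
#' @param v1,v2 paired visit-1 and visit-2 values; `v1` must be positive.
#' @return percent change, same length as the inputs.
#' @export
percentChange <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("'v1' and 'v2' must be paired")
  if (any(v1 <= 0)) stop("'v1' must be positive (visit 1 is the baseline)")
  100 * abs(v2 - v1) / v1
}

#' Bland-Altman agreement analysis
#'
#' Classic Bland-Altman analysis of paired differences `d = v2 - v1`:
#' mean bias, 95% limits of agreement `bias +/- 1.96 * SD(d)`, a
#' t-based 95% CI for the bias (`bias +/- t(0.975, n-1) * SD / sqrt(n)`),
#' and the standard approximate CIs for the limits
#' (`LoA +/- t(0.975, n-1) * SD * sqrt(3/n)`).
#'
#' @param v1,v2 paired measurements (n >= 3).
#' @return object of class `"blandAltman"`: list with `bias`, `biasCI`,
#'   `loaLower`, `loaUpper`, `loaLowerCI`, `loaUpperCI`, `sd`, `n`,
#'   `differences` and `means`.
#' @examples
#' ba <- blandAltman(c(10, 12, 11, 14), c(11, 12, 13, 15))
#' ba$bias
#' @export
blandAltman <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("'v1' and 'v2' must be paired")
  n <- length(v1)
  if (n < 3L) stop("Bland-Altman analysis needs at least 3 pairs")
  d <- v2 - v1
  bias <- mean(d)
  s <- sd(d)
  tq <- qt(0.975, n - 1L)
  loaL <- bias - 1.96 * s
  loaU <- bias + 1.96 * s
  seB <- s / sqrt(n)
  seL <- s * sqrt(3 / n)
  structure(list(
    bias = bias, biasCI = c(bias - tq * seB, bias + tq * seB),
    loaLower = loaL, loaUpper = loaU,
    loaLowerCI = c(loaL - tq * seL, loaL + tq * seL),
    loaUpperCI = c(loaU - tq * seL, loaU + tq * seL),
    sd = s, n = n, differences = d, means = (v1 + v2) / 2),
    class = "blandAltman")
}

#' @export
print.blandAltman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.4g [%.4g, %.4g], LoA [%.4g, %.4g]\n",
    x$n, x$bias, x$biasCI[1], x$biasCI[2], x$loaLower, x$loaUpper))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample Pearson correlation with the 95% CI from the Fisher z transform
#' (`SE = 1 / sqrt(n - 3)`), via [stats::cor.test()].
#'
#' @param x,y paired samples (n >= 4), each with nonzero variance.
#' @return list with `r`, `ci` (length 2), `p` and `n`.
#' @export
pearsonWithCI <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must be paired")
  if (length(x) < 4L) stop("correlation CI needs at least 4 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation is undefined")
  ct <- cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(x))
}

#' Paired t-test of visit differences
#'
#' Two-sided paired t-test on `d = v2 - v1`.  The degenerate zero-variance
#' cases are given explicit values rather than an error: identical visits
#' (`d` identically 0) report `t = 0, p = 1` (no evidence of change), and a
#' constant nonzero difference reports `t = +/-Inf, p = 0`.
#'
#' @param v1,v2 paired measurements (n >= 2).
#' @return list with `t`, `df` (`n - 1`) and `p`.
#' @export
pairedT <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("'v1' and 'v2' must be paired")
  n <- length(v1)
  if (n < 2L) stop("paired t-test needs at least 2 pairs")
  d <- v2 - v1
  stderr <- sd(d) / sqrt(n)
  if (sd(d) == 0 || stderr < 10 * .Machine$double.eps * abs(mean(d))) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1L, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0))
  }
  tt <- t.test(v2, v1, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Shapiro-Wilk normality test
#'
#' Royston's Shapiro-Wilk W statistic and p-value (via
#' [stats::shapiro.test()]), used to check that intervisit differences are
#' normally distributed before the Bland-Altman analysis.
#'
#' @param d numeric vector, 3 <= n <= 5000, nonzero variance.
#' @return list with `W`, `p` and `n`.
#' @export
shapiroWilkTest <- function(d) {
  n <- length(d)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk test requires 3 <= n <= 5000")
  if (sd(d) == 0) stop("zero variance: normality test is undefined")
  sw <- shapiro.test(d)
  list(W = unname(sw$statistic), p = sw$p.value, n = n)
}
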
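# Group-level inference: t-tests, robust percentage-bend correlation,
# 2x2 within-subject ANOVA, Bonferroni correction.

tidy_t <- function(ht, n) {
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, estimate = unname(ht$estimate)[1], n = n)
}

#' One-sample and paired t-tests
#'
#' Thin wrappers over [stats::t.test()] returning a flat result; constant
#' input (zero variance) is an explicit error rather than a degenerate
#' statistic.
#'
#' @param x,y Numeric vectors (paired, equal length for `paired_t`).
#' @param mu0 Null mean for the one-sample test.
#' @return List: `statistic` (t), `df`, `p` (two-sided), `estimate`, `n`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  if (length(x) < 2L || anyNA(x) || any(!is.finite(x)))
    stop("need >= 2 finite values")
  if (stats::var(x) == 0) stop("zero variance: t statistic undefined")
  tidy_t(stats::t.test(x, mu = mu0), length(x))
}

#' @rdname one_sample_t
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  if (length(d) < 2L || anyNA(d)) stop("need >= 2 complete pairs")
  if (stats::var(d) == 0) stop("zero variance of differences: t undefined")
  tidy_t(stats::t.test(x, y, paired = TRUE), length(x))
}

# one-step percentage-bend measure of location (Wilcox)
pb_location <- function(x, bend) {
  w <- sort(abs(x - stats::median(x)))
  om <- w[floor((1 - bend) * length(x))]
  if (om <= 0) stop("constant input: percentage-bend scale is zero")
  psi <- (x - stats::median(x)) / om
  i1 <- sum(psi < -1)
  i2 <- sum(psi > 1)
  sx <- ifelse(psi < -1, 0, ifelse(psi > 1, 0, x))
  (sum(sx) + om * (i2 - i1)) / (length(x) - i1 - i2)
}

#' Robust percentage-bend correlation
#'
#' Percentage-bend correlation (Wilcox, 1994): deviations from the
#' percentage-bend location estimate are scaled by the `(1 - bend)`
#' quantile of absolute deviations from the median and clipped to
#' `[-1, 1]` before correlating, which bounds the influence of gross
#' outliers in either margin. The test statistic is
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param bend Bend fraction (proportion of observations allowed to be
#'   downweighted per margin), default 0.2.
#' @return List: `r` in `[-1, 1]`, `statistic` (t), `df`, `p` (two-sided),
#'   `n`.
#' @export
pb_correlation <- function(x, y, bend = 0.2) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  clip <- function(v, loc) {
    w <- sort(abs(v - stats::median(v)))
    om <- w[floor((1 - bend) * length(v))]
    if (om <= 0) stop("constant input: percentage-bend scale is zero")
    a <- (v - loc) / om
    pmin(1, pmax(-1, a))
  }
  a <- clip(x, pb_location(x, bend))
  b <- clip(y, pb_location(y, bend))
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, statistic = tstat, df = n - 2L,
       p = 2 * stats::pt(-abs(tstat), n - 2L), n = n)
}

#' Two-by-two within-subject (repeated-measures) ANOVA
#'
#' Both factors vary within subject, so each effect has one numerator
#' degree of freedom and is equivalent to a paired t-test on the
#' corresponding per-subject contrast: the interaction F equals the
#' squared paired t on the difference-of-differences, and every F is
#' invariant to adding a subject-specific constant to all four cells.
#' Fs are reported with df (1, n - 1).
#'
#' @param cells Numeric n x 4 matrix, columns ordered (A1B1, A1B2, A2B1,
#'   A2B2) — e.g. condition (Self/Other) crossed with modulator parameter
#'   (dmin/dev). No missing cells allowed.
#' @param factor_names Length-2 labels for the two factors.
#' @return Data frame: `effect`, `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(cells, factor_names = c("A", "B")) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 4L) stop("cells must be an n x 4 matrix")
  if (nrow(cells) < 3L) stop("need at least 3 subjects")
  if (anyNA(cells)) stop("missing cells not allowed")
  contrast_f <- function(w) {
    d <- as.vector(cells %*% w)
    tt <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    tt^2
  }
  n <- nrow(cells)
  eff <- data.frame(
    effect = c(factor_names[1], factor_names[2],
               paste(factor_names, collapse = ":")),
    F = c(contrast_f(c(1, 1, -1, -1) / 2),
          contrast_f(c(1, -1, 1, -1) / 2),
          contrast_f(c(1, -1, -1, 1))),
    df1 = 1L, df2 = n - 1L)
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff
}

#' Bonferroni family-wise error correction
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param m Number of tests in the family (>= `length(p)`).
#' @return Adjusted p-values `min(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be at least the number of tests")
  pmin(1, m * p)
}
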
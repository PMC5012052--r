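# Method-comparison statistics: Lin's concordance correlation, Bland-Altman
# bias with confidence interval and paired test, normal tolerance intervals,
# and grouped absolute-error summaries.

#' Lin's concordance correlation coefficient
#'
#' Agreement measure penalizing both dispersion and location shift between two
#' measurement methods:
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`.
#' The original formulation uses population (1/n) moments (the default); the
#' sample-moment (1/(n-1)) variant is exposed as an option. The two differ
#' only through the bias term and coincide when the means are equal.
#'
#' @param x,y numeric vectors of equal length (>= 2), e.g. degrees.
#' @param method `"population"` (default) or `"sample"` moments.
#' @return the concordance coefficient in `[-1, 1]`; exactly 1 iff all pairs
#'   are identical.
#' @export
lin_ccc <- function(x, y, method = c("population", "sample")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 2L) {
    osic_stop("paired sequences of equal length >= 2 required", "osic_validation_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    osic_stop("non-finite values in paired measurements", "osic_validation_error")
  }
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  f <- if (method == "population") (n - 1) / n else 1
  sxy <- stats::cov(x, y) * f
  sx <- stats::var(x) * f
  sy <- stats::var(y) * f
  if (sx == 0 && sy == 0) {
    osic_stop("concordance undefined: both sequences are constant",
              "osic_undefined_statistic")
  }
  denom <- sx + sy + (mx - my)^2
  2 * sxy / denom
}

#' Two-sided 95%/95% normal tolerance limits (and variants)
#'
#' Limits of the interval expected to contain a single future measurement's
#' deviation. The default `"kfactor"` variant is the two-sided normal
#' tolerance interval with 95% content and 95% confidence,
#' `mean(d) +/- k * sd(d)` with Howe's factor
#' `k = sqrt(nu (1 + 1/n) z^2 / chisq(alpha, nu))`, `nu = n - 1`. The
#' `"future_obs"` variant is the prediction-style
#' `mean(d) +/- t(0.975, n-1) sd(d) sqrt(1 + 1/n)`; `"plain"` is
#' `mean(d) +/- 1.96 sd(d)`, the classical limits of agreement.
#'
#' @param d numeric vector of differences (degrees).
#' @param coverage interval content (default 0.95).
#' @param conf confidence level of the `"kfactor"` variant (default 0.95).
#' @param variant `"kfactor"`, `"future_obs"` or `"plain"`.
#' @return numeric `c(lower, upper)`.
#' @export
tolerance_limits <- function(d, coverage = 0.95, conf = 0.95,
                             variant = c("kfactor", "future_obs", "plain")) {
  variant <- match.arg(variant)
  n <- length(d)
  if (n < 2L) osic_stop("at least 2 differences required", "osic_validation_error")
  m <- mean(d); s <- stats::sd(d)
  k <- switch(variant,
    kfactor = {
      z <- stats::qnorm((1 + coverage) / 2)
      sqrt((n - 1) * (1 + 1 / n) * z^2 / stats::qchisq(1 - conf, n - 1))
    },
    future_obs = stats::qt((1 + coverage) / 2, n - 1) * sqrt(1 + 1 / n),
    plain = stats::qnorm((1 + coverage) / 2))
  c(lower = m - k * s, upper = m + k * s)
}

#' Bland-Altman agreement analysis with tolerance limits
#'
#' Computes, on the differences `d = test - reference`: the bias (mean
#' difference) with its 95% confidence interval, a two-sided paired t-test of
#' zero bias, Pearson `R^2` and Lin's concordance coefficient of the raw
#' pairs, and 95% tolerance limits (see [tolerance_limits()]). If the
#' differences have zero variance the tolerance limits collapse to
#' `(bias, bias)` and the p-value is flagged undefined (`NA`).
#'
#' @param reference,test paired measurements (degrees), length >= 3.
#' @param coverage tolerance-interval content (default 0.95).
#' @param variant tolerance-limit variant, see [tolerance_limits()].
#' @param conf confidence level for the bias CI and the k-factor (default
#'   0.95).
#' @return an `agreement_result`: one-row data frame with `n`, `r_squared`,
#'   `rho_c`, `bias`, `bias_ci_low`, `bias_ci_high`, `tl_low`, `tl_high`,
#'   `p_value`.
#' @export
bland_altman <- function(reference, test, coverage = 0.95,
                         variant = c("kfactor", "future_obs", "plain"),
                         conf = 0.95) {
  variant <- match.arg(variant)
  if (length(reference) != length(test) || length(test) < 3L) {
    osic_stop("paired sequences of equal length >= 3 required", "osic_validation_error")
  }
  d <- test - reference
  n <- length(d)
  bias <- mean(d)
  if (stats::sd(d) == 0) {
    osic_warn("zero-variance differences: tolerance limits collapse, p undefined",
              "osic_degenerate_differences")
    res <- data.frame(n = n, r_squared = stats::cor(reference, test)^2,
                      rho_c = lin_ccc(reference, test),
                      bias = bias, bias_ci_low = bias, bias_ci_high = bias,
                      tl_low = bias, tl_high = bias, p_value = NA_real_)
  } else {
    tt <- stats::t.test(d, conf.level = conf)
    tl <- tolerance_limits(d, coverage = coverage, conf = conf, variant = variant)
    res <- data.frame(n = n, r_squared = stats::cor(reference, test)^2,
                      rho_c = lin_ccc(reference, test),
                      bias = bias,
                      bias_ci_low = tt$conf.int[1L], bias_ci_high = tt$conf.int[2L],
                      tl_low = tl[[1L]], tl_high = tl[[2L]],
                      p_value = tt$p.value)
  }
  class(res) <- c("agreement_result", "data.frame")
  res
}

#' Grouped mean and SD of absolute differences
#'
#' Per group, the mean and sample standard deviation of `|test - reference|`
#' (the absolute measurement error against the gold standard). Empty groups
#' are omitted with a warning.
#'
#' @param reference,test paired measurements (degrees).
#' @param group optional grouping vector (factor-like); a single group when
#'   omitted.
#' @return data frame with `group`, `mean_abs`, `sd_abs`, `n`.
#' @export
absolute_error_summary <- function(reference, test, group = NULL) {
  if (length(reference) != length(test) || length(test) < 1L) {
    osic_stop("paired sequences of equal length >= 1 required", "osic_validation_error")
  }
  e <- abs(test - reference)
  if (is.null(group)) group <- rep("all", length(e))
  group <- as.character(group)
  lv <- unique(group)
  out <- do.call(rbind, lapply(lv, function(g) {
    ei <- e[group == g]
    data.frame(group = g, mean_abs = mean(ei),
               sd_abs = if (length(ei) > 1L) stats::sd(ei) else 0,
               n = length(ei), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
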
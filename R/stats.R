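#' Percentage deviation between expected and observed compositions
#'
#' Element-wise `expected - observed`, sign preserved: a positive value
#' is an underestimate of the expected component, a negative value an
#' overestimate.
#'
#' @param expected,observed numeric vectors in percent, equal length.
#' @return numeric vector of deviations (percent units).
#' @export
percentage_deviation <- function(expected, observed) {
  stopifnot(length(expected) == length(observed))
  expected - observed
}

#' Descriptive statistics of percentage deviations
#'
#' Summarises deviations on the absolute scale: minimum, maximum, median,
#' mean, sample standard deviation and variance of `|deviation|`. With a
#' single value the standard deviation is undefined and reported as 0
#' with `sd_defined = FALSE`.
#'
#' @param deviations numeric vector from `percentage_deviation()`.
#' @return object of class `deviation_stats`.
#' @export
describe_deviations <- function(deviations) {
  stopifnot(length(deviations) >= 1)
  a <- abs(deviations)
  sd_defined <- length(a) > 1
  s <- if (sd_defined) sd(a) else 0
  structure(list(n = length(a), min = min(a), max = max(a),
                 median = median(a), mean_abs = mean(a), sd = s,
                 variance = s^2, sd_defined = sd_defined),
            class = "deviation_stats")
}

#' @export
print.deviation_stats <- function(x, ...) {
  cat(sprintf(paste0("Deviation statistics (absolute scale, n = %d):\n",
                     "  min %.2f  max %.2f  median %.3f  mean %.2f",
                     "  sd %.3f  variance %.3f%s\n"),
              x$n, x$min, x$max, x$median, x$mean_abs, x$sd, x$variance,
              if (x$sd_defined) "" else "  [sd undefined at n = 1]"))
  invisible(x)
}

#' Chi-square survival function
#'
#' Upper-tail probability of the chi-square distribution, exact deep into
#' the far tail (needed for p-values down to 1e-20 and beyond). Thin
#' wrapper around the regularized upper incomplete gamma function as
#' implemented by `pchisq(lower.tail = FALSE)`.
#'
#' @param x non-negative quantile.
#' @param df degrees of freedom.
#' @return upper-tail probability.
#' @export
chi2_sf <- function(x, df) {
  stopifnot(all(x >= 0), all(df > 0))
  pchisq(x, df, lower.tail = FALSE)
}

#' Chi-square proportion test
#'
#' Tests an observed binomial proportion `k/n` against a null proportion
#' `p0` (default 0.5) with the Pearson chi-square statistic
#' `n (k/n - p0)^2 / (p0 (1 - p0))` on one degree of freedom, without
#' continuity correction.
#'
#' @param k successes (contaminated samples).
#' @param n total samples, `n >= 1`.
#' @param p0 null proportion.
#' @return object of class `prop_test_result` with `k`, `n`, `p0`,
#'   `chi2`, `df`, `p_value`.
#' @export
prop_test <- function(k, n, p0 = 0.5) {
  if (n < 1) stopf("n must be at least 1")
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  chi2 <- n * (k / n - p0)^2 / (p0 * (1 - p0))
  structure(list(k = k, n = n, p0 = p0, chi2 = chi2, df = 1L,
                 p_value = chi2_sf(chi2, 1)),
            class = "prop_test_result")
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf(paste0("Chi-square proportion test: k = %d, n = %d,",
                     " p0 = %.2f\n  X-squared = %.4f, df = %d,",
                     " p-value = %.3g\n"),
              x$k, x$n, x$p0, x$chi2, x$df, x$p_value))
  invisible(x)
}

cramers_v <- function(chi2, n, r, c) {
  sqrt(chi2 / (n * min(r - 1, c - 1)))
}

pearson_chi2 <- function(table) {
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected == 0))
    stopf("contingency table has a zero marginal")
  sum((table - expected)^2 / expected)
}

#' Contingency test with Cramer's V
#'
#' Pearson chi-square test of independence on an r x c count table
#' (expected counts from the marginals, no continuity correction), with
#' Cramer's V effect size `sqrt(chi2 / (n * min(r - 1, c - 1)))` and a
#' 95% nonparametric bootstrap confidence interval for V obtained by
#' resampling the `n` observations with replacement (percentile
#' interval; resamples with a degenerate margin score V = 0).
#'
#' @param x numeric matrix of counts.
#' @param ci_reps bootstrap resamples (default 10000).
#' @param ci_seed seed for the bootstrap (fixed; deterministic output).
#' @return object of class `contingency_result` with `table`, `chi2`,
#'   `df`, `p_value`, `cramers_v`, `v_ci_low`, `v_ci_high`, `n_obs`.
#' @export
contingency_test <- function(x, ci_reps = 10000, ci_seed = 1) {
  tab <- as.matrix(x)
  stopifnot(nrow(tab) >= 2, ncol(tab) >= 2, all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stopf("empty contingency table")
  chi2 <- pearson_chi2(tab)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  v <- cramers_v(chi2, n, nrow(tab), ncol(tab))
  # bootstrap over individual observations
  cells <- which(tab >= 0, arr.ind = TRUE)
  obs_row <- rep(cells[, 1], times = as.vector(tab))
  obs_col <- rep(cells[, 2], times = as.vector(tab))
  ci <- with_seed(ci_seed, {
    vs <- vapply(seq_len(ci_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tb <- table(factor(obs_row[idx], levels = seq_len(nrow(tab))),
                  factor(obs_col[idx], levels = seq_len(ncol(tab))))
      tb <- as.matrix(tb)
      if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) return(0)
      cramers_v(pearson_chi2(tb), n, nrow(tb), ncol(tb))
    }, numeric(1))
    quantile(vs, c(0.025, 0.975), names = FALSE)
  })
  structure(list(table = tab, chi2 = chi2, df = df,
                 p_value = chi2_sf(chi2, df),
                 cramers_v = v, v_ci_low = ci[1], v_ci_high = ci[2],
                 n_obs = n), class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf(paste0("Contingency test (%d x %d): X-squared = %.4f,",
                     " df = %d, p-value = %.3g\n",
                     "  Cramer's V = %.3f (95%% bootstrap CI %.3f-%.3f),",
                     " n_obs = %d\n"),
              nrow(x$table), ncol(x$table), x$chi2, x$df, x$p_value,
              x$cramers_v, x$v_ci_low, x$v_ci_high, x$n_obs))
  invisible(x)
}
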
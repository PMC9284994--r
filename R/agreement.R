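#' Bland-Altman agreement between two volume series
#'
#' Method-comparison summary for paired measurements of the same quantity by
#' two techniques (here typically histology vs MRTI-predicted ablation
#' volumes). Differences are taken as `a - b`, limits of agreement as the mean
#' difference +/- 1.96 sample standard deviations of the differences, and the
#' percent difference uses the grand mean of all 2n measurements as
#' denominator. Pearson correlation and a two-sided paired t-test are bundled
#' into the result.
#'
#' @param a,b equal-length numeric vectors, n >= 2. Convention: `a` is the
#'   reference method (histology), `b` the predicted one (MRTI).
#' @param z LoA multiplier (1.96 fixed by convention; exposed for completeness).
#' @return an object of class `thermo_agreement`: a list with `n`, `mean_diff`,
#'   `sd_diff`, `sem_diff`, `loa_low`, `loa_high`, `percent_diff`, `pearson_r`,
#'   `r_squared`, `t_stat`, `p_value` and the paired `data` tibble. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @seealso [correlation()], [paired_t()], [summarize_metric()]
#' @examples
#' hist <- c(0.25, 0.60, 0.92, 0.44, 0.48, 0.27)
#' mrti <- c(0.30, 0.35, 0.90, 0.40, 0.45, 0.25)
#' ba <- bland_altman(hist, mrti)
#' glance(ba)
#' @export
bland_altman <- function(a, b, z = 1.96) {
  check_paired(a, b, min_n = 2L)
  d <- a - b
  n <- length(d)
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)            # n - 1 denominator
  sem_diff <- sd_diff / sqrt(n)
  grand_mean <- mean(c(a, b))
  percent_diff <- if (abs(grand_mean) < .Machine$double.eps^0.5) {
    warning("grand mean is zero; percent_diff undefined", call. = FALSE)
    NA_real_
  } else {
    100 * mean_diff / grand_mean
  }
  ct <- correlation(a, b, min_n = 2L)
  tt <- paired_t(a, b)
  structure(list(
    n = n, mean_diff = mean_diff, sd_diff = sd_diff, sem_diff = sem_diff,
    loa_low = mean_diff - z * sd_diff, loa_high = mean_diff + z * sd_diff,
    percent_diff = percent_diff,
    pearson_r = ct$pearson_r, r_squared = ct$r_squared,
    t_stat = tt$t_stat, p_value = tt$p_value,
    data = tibble::tibble(a = as.numeric(a), b = as.numeric(b),
                          mean = (a + b) / 2, diff = d)
  ), class = "thermo_agreement")
}

#' @export
print.thermo_agreement <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  mean difference: %.4g +/- %.4g (SEM), %.3g%% of grand mean\n",
              x$mean_diff, x$sem_diff, x$percent_diff))
  cat(sprintf("  limits of agreement: [%.4g, %.4g]\n", x$loa_low, x$loa_high))
  cat(sprintf("  r = %.3f, r^2 = %.3f; paired t = %.3f, p = %.4g\n",
              x$pearson_r, x$r_squared, x$t_stat, x$p_value))
  invisible(x)
}

check_paired <- function(a, b, min_n = 2L) {
  abort_if(!is.numeric(a) || !is.numeric(b), "inputs must be numeric vectors")
  abort_if(length(a) != length(b), "series must have equal length")
  abort_if(length(a) < min_n, sprintf("need at least %d pairs", min_n))
  abort_if(any(!is.finite(a)) || any(!is.finite(b)), "inputs must be finite")
  invisible(TRUE)
}

#' Pearson correlation and ordinary least-squares fit
#'
#' Product-moment correlation between two paired series plus the OLS slope and
#' intercept of `b` regressed on `a`.
#'
#' @param a,b equal-length numeric vectors with nonzero variance.
#' @param min_n minimum pairs required (default 3).
#' @return one-row tibble with `n`, `pearson_r`, `r_squared`, `slope`,
#'   `intercept`.
#' @export
correlation <- function(a, b, min_n = 3L) {
  check_paired(a, b, min_n = min_n)
  sxx <- sum((a - mean(a))^2)
  syy <- sum((b - mean(b))^2)
  abort_if(sxx == 0 || syy == 0, "zero variance in one of the inputs")
  sxy <- sum((a - mean(a)) * (b - mean(b)))
  r <- sxy / sqrt(sxx * syy)
  slope <- sxy / sxx
  tibble::tibble(n = length(a), pearson_r = r, r_squared = r^2,
                 slope = slope, intercept = mean(b) - slope * mean(a))
}

#' Two-sided paired t-test
#'
#' Classical paired Student t-test: `t = mean(d) / (sd(d) / sqrt(n))` on the
#' pairwise differences `d = a - b`, with `n - 1` degrees of freedom and a
#' two-sided p-value. A degenerate case with zero-variance nonzero differences
#' reports an infinite t and p = 0, with a warning.
#'
#' @param a,b equal-length numeric vectors, n >= 2.
#' @return one-row tibble with `n`, `mean_diff`, `sd_diff`, `t_stat`, `df`,
#'   `p_value`.
#' @export
paired_t <- function(a, b) {
  check_paired(a, b, min_n = 2L)
  d <- a - b
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) {
      t_stat <- 0
      p <- 1
    } else {
      warning("zero-variance nonzero differences: t is infinite", call. = FALSE)
      t_stat <- sign(m) * Inf
      p <- 0
    }
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  tibble::tibble(n = n, mean_diff = m, sd_diff = s,
                 t_stat = t_stat, df = n - 1, p_value = p)
}

#' Mean and standard error of a metric series
#'
#' @param values numeric vector, n >= 2.
#' @return one-row tibble with `n`, `mean`, `sd`, `sem` (sample sd / sqrt(n)).
#' @examples
#' summarize_metric(c(13, 22, 23.07, 7, 16, 8, 9.6, 10))
#' @export
summarize_metric <- function(values) {
  abort_if(!is.numeric(values) || length(values) < 2L, "need at least 2 values")
  abort_if(any(!is.finite(values)), "values must be finite")
  s <- stats::sd(values)
  tibble::tibble(n = length(values), mean = mean(values), sd = s,
                 sem = s / sqrt(length(values)))
}
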
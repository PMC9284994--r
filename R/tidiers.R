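#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an agreement result
#'
#' @param x a `thermo_agreement` from [bland_altman()].
#' @param ... unused.
#' @return a two-column tibble (`term`, `estimate`) with one row per summary
#'   statistic.
#' @export
tidy.thermo_agreement <- function(x, ...) {
  terms <- c("mean_diff", "sd_diff", "sem_diff", "loa_low", "loa_high",
             "percent_diff", "pearson_r", "r_squared", "t_stat", "p_value")
  tibble::tibble(term = terms,
                 estimate = vapply(terms, function(t) x[[t]], numeric(1),
                                   USE.NAMES = FALSE))
}

#' Glance at an agreement result
#'
#' @param x a `thermo_agreement` from [bland_altman()].
#' @param ... unused.
#' @return a one-row tibble with `n` and every summary statistic.
#' @export
glance.thermo_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 sem_diff = x$sem_diff, loa_low = x$loa_low,
                 loa_high = x$loa_high, percent_diff = x$percent_diff,
                 pearson_r = x$pearson_r, r_squared = x$r_squared,
                 t_stat = x$t_stat, p_value = x$p_value)
}
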
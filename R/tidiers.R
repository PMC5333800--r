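# broom-style accessors for fitted/estimated objects.

#' Tidy a power-impact correlation
#'
#' @param x A `power_impact_cor` object from [correlate_power_impact()].
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.power_impact_cor <- function(x, ...) {
  tibble::tibble(estimate = x$r, conf.low = x$ci_lower,
                 conf.high = x$ci_upper)
}

#' Glance at a power-impact correlation
#'
#' @param x A `power_impact_cor` object.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, interval, confidence level
#'   and bootstrap configuration.
#' @export
glance.power_impact_cor <- function(x, ...) {
  tibble::tibble(estimate = x$r, conf.low = x$ci_lower,
                 conf.high = x$ci_upper, conf.level = x$level,
                 n = x$n, n_boot = x$n_boot, seed = x$seed)
}
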
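# Two-sided power of t-tests from the noncentral t distribution, under the
# one-sample/matched vs two-sample mixture.

#' Two-sided power of a t-test at a given effect size
#'
#' Exact power from the noncentral t distribution. The noncentrality
#' parameter is \eqn{\delta = d\sqrt{df+1}} for a one-sample (or matched)
#' test and \eqn{\delta = d\sqrt{N_{group}/2}} for a two-sample test with
#' equal groups of size [n_per_group()] `(df)`. Power is
#' \eqn{P(|T_{\delta}| > t_{crit})} with the two-sided central-t critical
#' value at `alpha`. At `d = 0` power equals `alpha` exactly (computed via
#' the central distribution to avoid noncentral-CDF rounding).
#'
#' @param d Standardized effect size, `>= 0` (vectorized).
#' @param df Positive integer degrees of freedom (vectorized).
#' @param test_type `"one_sample"` or `"two_sample"`.
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in (0, 1).
#' @export
#' @examples
#' power_t(0.5, df = 33, test_type = "one_sample")  # ~0.81
power_t <- function(d, df, test_type = c("one_sample", "two_sample"),
                    alpha = 0.05) {
  test_type <- match.arg(test_type)
  if (any(d < 0)) abort("d must be >= 0", class = "litpower_domain_error")
  if (any(df < 1)) abort("df must be >= 1", class = "litpower_domain_error")
  if (any(alpha <= 0) || any(alpha >= 1)) {
    abort("alpha must lie in (0, 1)", class = "litpower_domain_error")
  }
  n <- max(length(d), length(df))
  d <- rep_len(d, n)
  df <- rep_len(df, n)
  ncp <- if (test_type == "one_sample") d * sqrt(df + 1) else
    d * sqrt(n_per_group(df) / 2)
  tcrit <- qt(1 - alpha / 2, df)
  central <- ncp == 0
  out <- numeric(length(ncp))
  if (any(central)) out[central] <- alpha
  if (any(!central)) {
    out[!central] <- pt(-tcrit[!central], df[!central], ncp = ncp[!central]) +
      pt(tcrit[!central], df[!central], ncp = ncp[!central],
         lower.tail = FALSE)
  }
  out
}

#' Power under the one-sample/two-sample mixture
#'
#' Convex combination of the two test-type powers with the df-conditional
#' mixture weight [w_onesample()], i.e. the expected power of a record whose
#' test type is unknown but distributed as in the validated literature. The
#' same reported df is used in both branches: df is what is observed.
#'
#' @inheritParams power_t
#' @return Power in (0, 1); equals `alpha` at `d = 0`.
#' @export
power_mixture <- function(d, df, alpha = 0.05) {
  w <- w_onesample(df)
  w * power_t(d, df, "one_sample", alpha) +
    (1 - w) * power_t(d, df, "two_sample", alpha)
}

#' Benchmark power profile for a set of df values
#'
#' Mixture power at the conventional small (d = 0.2), medium (d = 0.5) and
#' large (d = 0.8) benchmark effect sizes.
#'
#' @inheritParams power_t
#' @return A tibble with columns `df`, `alpha`, `power_small`,
#'   `power_medium`, `power_large`.
#' @export
benchmark_powers <- function(df, alpha = 0.05) {
  ps <- power_mixture(0.2, df, alpha)
  pm <- power_mixture(0.5, df, alpha)
  pl <- power_mixture(0.8, df, alpha)
  tibble::tibble(df = as.integer(df), alpha = alpha,
                 power_small = ps, power_medium = pm, power_large = pl)
}

#' Append power columns to an effect-size table
#'
#' For every record, adds mixture power at the three benchmark effects and
#' `power_published`, the power to detect the record's own published effect
#' size `d_mixture`. Because published effects are typically inflated,
#' `power_published` overestimates true power, which is what makes the
#' downstream expected false-report probability a *lower*-limit estimate.
#'
#' @param effects Output of [estimate_effects()].
#' @param alpha Two-sided significance level.
#' @return The input with `power_small`, `power_medium`, `power_large`,
#'   `power_published` appended.
#' @export
add_power <- function(effects, alpha = 0.05) {
  if (!"d_mixture" %in% names(effects)) {
    abort("add_power() expects the output of estimate_effects()",
          class = "litpower_domain_error")
  }
  dplyr::mutate(effects,
    power_small = power_mixture(0.2, .data$df, alpha),
    power_medium = power_mixture(0.5, .data$df, alpha),
    power_large = power_mixture(0.8, .data$df, alpha),
    power_published = power_mixture(.data$d_mixture, .data$df, alpha)
  )
}
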
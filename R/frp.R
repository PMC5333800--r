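# False report probability (FRP) under the prestudy-odds + bias model, its
# small/large-effect variant, and the expectation over an empirical
# (df, effect size) distribution.

check_frp_args <- function(odds, alpha, bias) {
  if (any(odds < 0)) {
    abort("prestudy odds must be >= 0", class = "litpower_domain_error")
  }
  if (any(alpha <= 0 | alpha >= 1)) {
    abort("alpha must lie in (0, 1)", class = "litpower_domain_error")
  }
  if (any(bias < 0 | bias > 1)) {
    abort("bias must lie in [0, 1]", class = "litpower_domain_error")
  }
  invisible(NULL)
}

#' False report probability at a given power
#'
#' Probability that the null hypothesis is true given a reported significant
#' finding, for prestudy H0:H1 odds `O`, significance level `alpha`, power,
#' and a bias parameter `u` — the fraction of results that would be reported
#' nonsignificant in the absence of bias but are reported significant:
#' \deqn{FRP = \frac{O\alpha + uO(1-\alpha)}
#'                  {O\alpha + uO(1-\alpha) + power + u(1 - power)}}
#' At `u = 0` this reduces to \eqn{O\alpha / (O\alpha + power)}; at `u = 1`
#' every result is reported significant and FRP equals the prior probability
#' of the null, \eqn{O/(O+1)}.
#'
#' @param odds Prestudy H0:H1 odds, `>= 0` (vectorized).
#' @param power Power to detect the (true) effect, in (0, 1) (vectorized).
#' @param alpha Significance level in (0, 1).
#' @param bias Bias parameter `u` in \code{[0, 1]}.
#' @return A tibble with columns `odds`, `alpha`, `bias`, `power`, `frp`,
#'   `trp` (`trp = 1 - frp`).
#' @export
#' @examples
#' frp_point(odds = 1, power = 0.5)         # frp ~ 0.091
#' frp_point(odds = 13, power = 0.5)        # > 0.5 even without bias
frp_point <- function(odds, power, alpha = 0.05, bias = 0) {
  check_frp_args(odds, alpha, bias)
  if (any(power < 0 | power > 1)) {
    abort("power must lie in [0, 1]", class = "litpower_domain_error")
  }
  num <- odds * alpha + bias * odds * (1 - alpha)
  den <- num + power + bias * (1 - power)
  frp <- ifelse(den == 0, 0, num / den)
  tibble::tibble(odds = odds, alpha = alpha, bias = bias, power = power,
                 frp = frp, trp = 1 - frp)
}

#' FRP distinguishing power for small and large effects
#'
#' Variant of the FRP model in which statistically significant detections of
#' *small* (practically meaningless) effects count as false reports:
#' \deqn{FRP = \frac{O\alpha + P_S\,pr(S)}
#'                  {O\alpha + P_S\,pr(S) + P_L\,pr(L)}}
#' where \eqn{P_S} and \eqn{P_L} are the powers to detect small and large
#' effects and \eqn{pr(S) + pr(L) = 1} are their prevalences. Where the
#' small/large threshold sits is a subjective call; this variant only ever
#' *raises* FRP relative to [frp_point()], which is why the point model is
#' the best-case (lower-limit) estimate.
#'
#' @param odds Prestudy H0:H1 odds.
#' @param p_small,p_large Power to detect small and large effects.
#' @param pr_small Prevalence of small effects among true effects.
#' @param alpha Significance level.
#' @return A tibble with columns `odds`, `alpha`, `pr_small`, `frp`, `trp`.
#' @export
frp_small_large <- function(odds, p_small, p_large, pr_small, alpha = 0.05) {
  check_frp_args(odds, alpha, 0)
  if (any(is.na(p_small)) || any(is.na(p_large)) || any(is.na(pr_small))) {
    abort("p_small, p_large and pr_small must all be present",
          class = "litpower_domain_error")
  }
  if (any(pr_small < 0 | pr_small > 1)) {
    abort("pr_small must lie in [0, 1]", class = "litpower_domain_error")
  }
  num <- odds * alpha + p_small * pr_small
  den <- num + p_large * (1 - pr_small)
  frp <- num / den
  tibble::tibble(odds = odds, alpha = alpha, pr_small = pr_small,
                 frp = frp, trp = 1 - frp)
}

#' Expected FRP over an empirical record set
#'
#' Weighs the FRP computed for each record's (df, D) combination by the
#' probability of that combination occurring in the literature — by default
#' the empirical distribution, weight 1/N per record — and sums:
#' \deqn{E[FRP] = \sum_i FRP(power_i)\, w_i}
#' `power_i` is taken from the `power` column named by `power_col`
#' (default `power_published`, the record's power to detect its own
#' published effect size; since published effects are typically inflated,
#' the result is a lower-limit estimate of FRP).
#'
#' @param records_power Output of [add_power()] (or any tibble with the
#'   chosen power column).
#' @param odds Prestudy H0:H1 odds (scalar).
#' @param alpha Significance level.
#' @param bias Bias parameter `u`.
#' @param weights Optional record weights summing to 1.
#' @param power_col Name of the power column to use.
#' @return A tibble with columns `odds`, `alpha`, `bias`, `frp`, `trp`, `n`.
#' @export
expected_frp <- function(records_power, odds, alpha = 0.05, bias = 0,
                         weights = NULL, power_col = "power_published") {
  if (nrow(records_power) == 0) {
    abort("expected_frp() needs at least one record",
          class = "litpower_domain_error")
  }
  if (!power_col %in% names(records_power)) {
    abort(sprintf("column '%s' not found; run add_power() first", power_col),
          class = "litpower_domain_error")
  }
  pw <- records_power[[power_col]]
  if (is.null(weights)) weights <- rep(1 / length(pw), length(pw))
  if (abs(sum(weights) - 1) > 1e-8) {
    abort("weights must sum to 1", class = "litpower_domain_error")
  }
  frp_i <- frp_point(odds, pw, alpha = alpha, bias = bias)$frp
  frp <- sum(frp_i * weights)
  tibble::tibble(odds = odds, alpha = alpha, bias = bias,
                 frp = frp, trp = 1 - frp, n = length(pw))
}

#' Expected FRP over a grid of odds and bias values
#'
#' Evaluates [expected_frp()] on the Cartesian product of an odds grid and
#' a bias grid (the layout behind FRP-versus-odds curve families).
#'
#' @inheritParams expected_frp
#' @param odds_grid Nonempty numeric vector of H0:H1 odds.
#' @param bias_grid Nonempty numeric vector of bias values.
#' @return A tibble of (`odds`, `alpha`, `bias`, `frp`, `trp`, `n`) rows,
#'   sorted by (`bias`, `odds`).
#' @export
frp_curves <- function(records_power, odds_grid, bias_grid = 0,
                       alpha = 0.05, power_col = "power_published") {
  if (length(odds_grid) == 0 || length(bias_grid) == 0) {
    abort("odds_grid and bias_grid must be nonempty",
          class = "litpower_domain_error")
  }
  grid <- tidyr::expand_grid(bias = sort(bias_grid), odds = sort(odds_grid))
  purrr::pmap(grid, function(bias, odds) {
    expected_frp(records_power, odds, alpha = alpha, bias = bias,
                 power_col = power_col)
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$bias, .data$odds)
}
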
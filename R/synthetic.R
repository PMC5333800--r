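# Synthetic literatures with the statistical structure the survey assumes:
# an H0/H1 mixture with configurable prestudy odds, a right-skewed df
# distribution, a df-conditional test-type mixture, selective publication,
# a bias process that flips nonsignificant results to reported-significant,
# and text rendering in common reporting dialects.

#' Configure a synthetic literature
#'
#' Bundles and validates all generator parameters. Defaults emulate the
#' surveyed literature: df drawn from a discretized lognormal with median 20
#' whose continuous mode sits at 15; one-sample/matched share 0.93 for
#' df <= 10 and 0.72 otherwise; true effects under H1 lognormal with median
#' 0.5 and log-sd 0.5; nonsignificant results published with probability
#' 0.2, which at 1:1 odds yields a published significant share near the
#' observed two-thirds; no bias.
#'
#' @param n_studies Number of studies to simulate (>= 1).
#' @param odds_h0_h1 Prestudy H0:H1 odds (`Inf` = every null true).
#' @param effect_meanlog,effect_sdlog Lognormal parameters of true |d|
#'   under H1.
#' @param fixed_true_d If non-`NULL`, every H1 study gets exactly this true
#'   effect (homogeneous-power designs used for calibration checks).
#' @param df_median,df_mode Target median and mode of the df distribution.
#' @param fixed_df If non-`NULL`, every study gets exactly this df.
#' @param alpha Two-sided significance level.
#' @param select_nonsig Probability that a nonsignificant result is
#'   published.
#' @param bias_u Probability that a nonsignificant result is reported as
#'   significant (flipped), with a t value just above the critical value.
#' @param prob_report_d Probability that a record also reports Cohen's d.
#' @param records_per_paper Average records per paper (used to group
#'   records into papers for rendering).
#' @param dialects Names of rendering dialects (see [litpower_dialects()]).
#' @param malformed_rate Probability that a record is rendered with a line
#'   break inside it, making it unparseable.
#' @param seed Integer seed making the whole literature reproducible.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_studies = 1000, odds_h0_h1 = 1,
                             effect_meanlog = log(0.5), effect_sdlog = 0.5,
                             fixed_true_d = NULL,
                             df_median = 20, df_mode = 15, fixed_df = NULL,
                             alpha = 0.05, select_nonsig = 0.2, bias_u = 0,
                             prob_report_d = 0.08, records_per_paper = 7,
                             dialects = names(litpower_dialects()),
                             malformed_rate = 0, seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies), odds_h0_h1 = odds_h0_h1,
              effect_meanlog = effect_meanlog, effect_sdlog = effect_sdlog,
              fixed_true_d = fixed_true_d, df_median = df_median,
              df_mode = df_mode, fixed_df = fixed_df, alpha = alpha,
              select_nonsig = select_nonsig, bias_u = bias_u,
              prob_report_d = prob_report_d,
              records_per_paper = records_per_paper, dialects = dialects,
              malformed_rate = malformed_rate, seed = as.integer(seed))
  probs <- c(cfg$alpha, cfg$select_nonsig, cfg$bias_u, cfg$prob_report_d,
             cfg$malformed_rate)
  if (cfg$n_studies < 1) {
    abort("n_studies must be >= 1", class = "litpower_domain_error")
  }
  if (cfg$odds_h0_h1 < 0) {
    abort("odds_h0_h1 must be >= 0", class = "litpower_domain_error")
  }
  if (any(probs < 0 | probs > 1) || cfg$alpha == 0 || cfg$alpha == 1) {
    abort("alpha, select_nonsig, bias_u, prob_report_d, malformed_rate must be probabilities",
          class = "litpower_domain_error")
  }
  if (is.null(cfg$fixed_df) && cfg$df_mode > cfg$df_median) {
    abort("df_mode must not exceed df_median (right-skewed df)",
          class = "litpower_domain_error")
  }
  if (!all(cfg$dialects %in% names(litpower_dialects()))) {
    abort("unknown dialect name", class = "litpower_domain_error")
  }
  structure(cfg, class = "synthetic_config")
}

#' Simulate a published literature with known ground truth
#'
#' For each study: the null is true with probability `O/(1+O)`; df and test
#' type are drawn; the true effect is 0 under H0 and lognormal (or fixed)
#' under H1; the t statistic is drawn from the central or noncentral t
#' distribution with noncentrality \eqn{d\sqrt{df+1}} (one-sample) or
#' \eqn{d\sqrt{N_{group}/2}} (two-sample). Latent significance is two-sided
#' at `alpha`. A nonsignificant study is flipped to reported-significant
#' with probability `bias_u` (its reported t is placed just above the
#' critical value so downstream recomputation also classifies it
#' significant). Significant (including flipped) results are always
#' published; nonsignificant ones with probability `select_nonsig`.
#'
#' Reported values are rounded the way articles print them (t to 2
#' decimals, p to 3, `< .001` below that), so rendering and re-parsing a
#' record is lossless.
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (published records tibble, including a
#'   `record_id` linking column) and `truth` (per-study ground truth for
#'   *all* studies: `record_id`, `h1_true`, `true_d`, `test_type`, `df`,
#'   `t_exact`, `p_exact`, `significant_latent`, `bias_flipped`,
#'   `significant_reported`, `published`).
#' @export
#' @examples
#' sim <- simulate_literature(synthetic_config(n_studies = 50, seed = 42))
#' head(sim$records)
simulate_literature <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_studies
  O <- config$odds_h0_h1
  p_h0 <- if (is.infinite(O)) 1 else O / (1 + O)

  h1 <- runif(n) >= p_h0
  df <- if (!is.null(config$fixed_df)) rep(as.integer(config$fixed_df), n)
        else draw_df(n, config$df_median, config$df_mode)
  test_type <- ifelse(runif(n) < w_onesample(df), "one_sample", "two_sample")
  true_d <- ifelse(h1,
                   if (!is.null(config$fixed_true_d)) config$fixed_true_d
                   else rlnorm(n, config$effect_meanlog, config$effect_sdlog),
                   0)
  ncp <- ifelse(test_type == "one_sample", true_d * sqrt(df + 1),
                true_d * sqrt(n_per_group(df) / 2))
  t_exact <- rt(n, df = df, ncp = ncp) * sample(c(-1, 1), n, replace = TRUE)
  p_exact <- 2 * pt(-abs(t_exact), df)
  sig_latent <- p_exact <= config$alpha

  flip <- !sig_latent & runif(n) < config$bias_u
  tcrit <- qt(1 - config$alpha / 2, df)
  t_report <- ifelse(flip,
                     sign(t_exact) * tcrit * (1 + runif(n, 0.005, 0.10)),
                     t_exact)
  published <- sig_latent | flip | (runif(n) < config$select_nonsig)

  # reported (printed) values: t to 2 decimals, p to 3 or "< .001"
  t_round <- round(t_report, 2)
  p_recalc <- 2 * pt(-abs(t_round), df)
  p_small <- p_recalc < 0.001
  p_cmp <- ifelse(p_small, "<", "=")
  p_rep <- ifelse(p_small, 0.001, round(p_recalc, 3))

  report_d <- runif(n) < config$prob_report_d
  d_est <- ifelse(test_type == "one_sample",
                  abs(t_round) / sqrt(df + 1),
                  abs(t_round) * sqrt(2 / n_per_group(df)))
  d_rep <- ifelse(report_d, round(d_est, 2), NA_real_)

  n_papers <- max(1L, round(n / config$records_per_paper))
  paper_of <- sort(sample.int(n_papers, n, replace = TRUE))
  journals <- synthetic_journals()
  journal_of_paper <- sample(journals$journal_id, n_papers, replace = TRUE)

  truth <- tibble::tibble(
    record_id = seq_len(n),
    paper_id = sprintf("paper_%04d", paper_of),
    journal_id = journal_of_paper[paper_of],
    h1_true = h1, true_d = true_d, test_type = test_type,
    df = as.integer(df), t_exact = t_exact, p_exact = p_exact,
    significant_latent = sig_latent, bias_flipped = flip,
    significant_reported = sig_latent | flip,
    published = published
  )
  records <- tibble::tibble(
    record_id = truth$record_id[published],
    paper_id = truth$paper_id[published],
    journal_id = truth$journal_id[published],
    df = truth$df[published],
    t = t_round[published],
    p_cmp = p_cmp[published],
    p = p_rep[published],
    d = d_rep[published]
  )
  list(records = records, truth = truth)
}

# discretized lognormal over df: median `med`, continuous mode `mode`
draw_df <- function(n, med, mode) {
  sdlog <- sqrt(log(med / mode))
  pmax(1L, as.integer(round(rlnorm(n, meanlog = log(med), sdlog = sdlog))))
}

# fixed synthetic impact factors (the real 5-year values live in a journal
# report, not in the package); neuroscience titles get the higher values so
# synthetic power-vs-impact correlations have the realistic sign
synthetic_journals <- function() {
  meta <- journal_metadata()
  ifs <- c(17.15, 14.0, 10.2, 7.1, 6.8, 6.3, 5.0, 3.9, 4.3, 3.3,   # neuro
           5.8, 3.2, 4.1, 2.367, 2.9,                              # psych
           9.4, 4.6, 5.9)                                          # medical
  meta$impact_factor_5yr <- ifs
  meta
}

#' Reporting dialects for rendering records as text
#'
#' Each dialect is a function taking vectors `df`, `t`, `p_cmp`, `p`, `d`
#' and returning one rendered line per record. The shipped set covers the
#' common typographic variants: comma vs semicolon clause separators,
#' `p = .02` vs `p = 0.02`, spaces inside `t (df)`, and a Unicode minus
#' sign. The registry is a plain named list, so downstream code can extend
#' it.
#'
#' @return Named list of rendering functions.
#' @export
litpower_dialects <- function() {
  fmt_t <- function(t) sprintf("%.2f", t)
  fmt_p <- function(p, lead0) {
    s <- sprintf("%.3f", p)
    if (!lead0) s <- sub("^0\\.", ".", s)
    s
  }
  fmt_d <- function(d, sep) ifelse(is.na(d), "",
                                   sprintf("%sd = %.2f", sep, d))
  list(
    comma_baredot = function(df, t, p_cmp, p, d) {
      sprintf("t(%d) = %s, p %s %s%s", df, fmt_t(t), p_cmp,
              vapply(p, fmt_p, "", lead0 = FALSE), fmt_d(d, ", "))
    },
    semicolon_tight = function(df, t, p_cmp, p, d) {
      sprintf("t(%d)=%s; p%s%s%s", df, fmt_t(t), p_cmp,
              vapply(p, fmt_p, "", lead0 = TRUE), fmt_d(d, "; "))
    },
    unicode_minus = function(df, t, p_cmp, p, d) {
      ts <- gsub("-", "−", fmt_t(t), fixed = TRUE)
      sprintf("t(%d) = %s; p %s %s%s", df, ts, p_cmp,
              vapply(p, fmt_p, "", lead0 = TRUE), fmt_d(d, "; "))
    },
    spaced_parens = function(df, t, p_cmp, p, d) {
      sprintf("t (%d) = %s, p %s %s%s", df, fmt_t(t), p_cmp,
              vapply(p, fmt_p, "", lead0 = FALSE), fmt_d(d, ", "))
    }
  )
}

filler_sentences <- c(
  "The main comparison was reliable,",
  "A follow-up comparison showed a similar pattern,",
  "Performance differed between conditions,",
  "The interaction did not reach significance,",
  "Response times were faster in the congruent condition,",
  "Accuracy was higher for the trained group,"
)

#' Render records into a plain-text corpus
#'
#' Renders every record in a randomly chosen dialect and embeds the lines
#' in filler prose, one text body per paper. With probability
#' `malformed_rate` a record is rendered with a line break inserted before
#' its p clause — the typographic accident that defeats single-line window
#' extraction — making it deliberately unparseable. For all well-formed
#' renderings, `extract_records()` on the corpus reproduces the record
#' exactly.
#'
#' @param records A records tibble (reported-precision values, as produced
#'   by [simulate_literature()]).
#' @param dialects Character vector of dialect names to draw from.
#' @param malformed_rate Probability of the line-break corruption.
#' @param seed Integer seed for dialect choice and corruption.
#' @return A list with `corpus` (tibble: `paper_id`, `text`) and
#'   `rendered` (the input records plus `dialect` and `malformed` columns).
#' @export
render_corpus <- function(records, dialects = names(litpower_dialects()),
                          malformed_rate = 0, seed = 1L) {
  if (length(dialects) == 0) {
    abort("dialect list must be nonempty", class = "litpower_domain_error")
  }
  all_dialects <- litpower_dialects()
  if (!all(dialects %in% names(all_dialects))) {
    abort("unknown dialect name", class = "litpower_domain_error")
  }
  set.seed(seed)
  n <- nrow(records)
  which_dialect <- sample(dialects, n, replace = TRUE)
  lines <- character(n)
  for (dia in unique(which_dialect)) {
    idx <- which_dialect == dia
    lines[idx] <- all_dialects[[dia]](records$df[idx], records$t[idx],
                                      records$p_cmp[idx], records$p[idx],
                                      records$d[idx])
  }
  malformed <- runif(n) < malformed_rate
  lines[malformed] <- sub("([,;]?) ?p", "\\1\np", lines[malformed])

  filler <- sample(filler_sentences, n, replace = TRUE)
  sentence <- paste(filler, lines)
  corpus <- tibble::tibble(paper_id = records$paper_id,
                           sentence = sentence) |>
    dplyr::group_by(.data$paper_id) |>
    dplyr::summarise(text = paste(.data$sentence, collapse = ". "),
                     .groups = "drop")
  rendered <- dplyr::mutate(records, dialect = which_dialect,
                            malformed = malformed)
  list(corpus = corpus, rendered = rendered)
}

#' Effect-size exaggeration by true effect
#'
#' Compares the mean estimated effect size among *published significant*
#' records with the mean over *all* generated studies, per true-effect
#' group — the winner's-curse mechanism: conditioning on significance
#' truncates the sampling distribution and inflates the mean, the more so
#' the lower the power.
#'
#' @param truth Ground-truth tibble from [simulate_literature()].
#' @param records Published records tibble from the same simulation (used
#'   only for alignment checking).
#' @param bins Number of true-d bins (ignored when there are few distinct
#'   true effects, which are then grouped exactly).
#' @return A tibble per true-d group: `true_d` (group mean), `n_all`,
#'   `n_sig_published`, `mean_d_all`, `mean_d_sig_published`,
#'   `exaggeration` (ratio of significant-published mean to true d; `NA`
#'   under H0 where true d is 0).
#' @export
exaggeration_summary <- function(truth, records, bins = 6) {
  if (!all(records$record_id %in% truth$record_id)) {
    abort("records and truth are misaligned (unknown record_id)",
          class = "litpower_domain_error")
  }
  d_est <- ifelse(truth$test_type == "one_sample",
                  abs(truth$t_exact) / sqrt(truth$df + 1),
                  abs(truth$t_exact) * sqrt(2 / n_per_group(truth$df)))
  u <- sort(unique(truth$true_d))
  grp <- if (length(u) <= bins) {
    factor(truth$true_d, levels = u)
  } else {
    cut(truth$true_d, breaks = bins, include.lowest = TRUE)
  }
  tibble::tibble(grp = grp, true_d = truth$true_d, d_est = d_est,
                 sig_pub = truth$significant_reported & truth$published) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      true_d = mean(.data$true_d),
      n_all = dplyr::n(),
      n_sig_published = sum(.data$sig_pub),
      mean_d_all = mean(.data$d_est),
      mean_d_sig_published = mean(.data$d_est[.data$sig_pub]),
      .groups = "drop"
    ) |>
    dplyr::mutate(exaggeration = ifelse(.data$true_d > 0,
                                        .data$mean_d_sig_published /
                                          .data$true_d, NA_real_)) |>
    dplyr::select(-"grp")
}
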
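test_that("group summaries report order statistics with bracketing quartiles", {
  eff <- estimate_effects(stat_records(df = 10L, t = c(1, 2, 3),
                                       paper_id = "p1")) |> add_power()
  eff$d_mixture <- c(0.1, 0.2, 0.3)  # pin the summarized values
  s <- summarize_survey(eff)
  expect_equal(s$median_d, 0.2)
  expect_lte(s$q25_d, s$median_d)
  expect_gte(s$q75_d, s$median_d)
  expect_equal(s$n_records, 3L)
  expect_equal(s$n_papers, 1L)
})

test_that("partitions conserve record counts and unknown journals error", {
  sim <- simulate_literature(synthetic_config(n_studies = 2000, seed = 31))
  eff <- estimate_effects(clean_records(sim$records)$kept) |> add_power()
  total <- nrow(eff)
  by_sig <- summarize_survey(eff, split_significance = TRUE)
  expect_equal(sum(by_sig$n_records), total)
  by_field <- summarize_survey(eff, journals = journal_metadata(),
                               by = "subfield", split_significance = TRUE)
  expect_equal(sum(by_field$n_records), total)
  by_journal <- summarize_survey(eff, journals = journal_metadata(),
                                 by = "journal")
  expect_equal(sum(by_journal$n_records), total)

  bad <- dplyr::mutate(eff, journal_id = "nonexistent")
  expect_error(summarize_survey(bad, journals = journal_metadata(),
                                by = "subfield"),
               "nonexistent", class = "litpower_domain_error")
})

test_that("summaries recover the medians a known generator implies", {
  # all-H0 literature with everything published: |t| ~ central t, so the
  # one-sample component's median is |t|_med / sqrt(df + 1) analytically
  df0 <- 20L
  cfg <- synthetic_config(n_studies = 20000, odds_h0_h1 = Inf,
                          fixed_df = df0, select_nonsig = 1, seed = 32)
  sim <- simulate_literature(cfg)
  eff <- estimate_effects(clean_records(sim$records)$kept) |> add_power()
  t_med <- qt(0.75, df0)  # median of |t| under H0
  w <- w_onesample(df0)
  d_med_expected <- (w / sqrt(df0 + 1) +
                     (1 - w) * sqrt(2 / n_per_group(df0))) * t_med
  s <- summarize_survey(eff)
  expect_equal(s$median_d, d_med_expected, tolerance = 0.02)
  expect_equal(s$median_df, df0)
})

test_that("complementary cumulative fractions agree with direct counting", {
  cc <- cumulative_distribution(c(1, 2, 3), grid = 2)
  expect_equal(cc$fraction, 2 / 3)
  expect_equal(cumulative_distribution(c(1, 2, 3), grid = 0)$fraction, 1)

  set.seed(404)
  values <- rlnorm(500, 3, 0.5)
  grid <- sort(runif(20, 0, 60))
  cc <- cumulative_distribution(values, grid)
  brute <- vapply(grid, function(g) sum(values >= g) / length(values),
                  numeric(1))
  expect_equal(cc$fraction, brute)
  expect_true(all(diff(cc$fraction) <= 0))
  expect_error(cumulative_distribution(numeric(), 1),
               class = "litpower_domain_error")
  expect_error(cumulative_distribution(1:3, c(2, 1)),
               class = "litpower_domain_error")
})

test_that("exact linear relations give correlation +/-1 and results are seeded", {
  js <- tibble::tibble(median_power = seq(0.1, 0.9, length.out = 10),
                       impact_factor_5yr = 2 * seq(0.1, 0.9, length.out = 10))
  expect_warning(res <- correlate_power_impact(js, n_boot = 1000, seed = 5),
                 "degenerate")
  expect_equal(res$r, 1)
  js$impact_factor_5yr <- -js$median_power
  # collinear input again: depending on the resamples the BCa endpoints are
  # either undefined or pinned to extreme order statistics; warned either way
  expect_warning(res <- correlate_power_impact(js, n_boot = 1000, seed = 5))
  expect_equal(res$r, -1)

  set.seed(405)
  js2 <- tibble::tibble(median_power = runif(18),
                        impact_factor_5yr = runif(18, 2, 17))
  a <- correlate_power_impact(js2, n_boot = 2000, seed = 9)
  b <- correlate_power_impact(js2, n_boot = 2000, seed = 9)
  expect_equal(tidy(a), tidy(b))
  expect_lt(a$ci_lower, a$r)
  expect_gt(a$ci_upper, a$r)
  expect_error(correlate_power_impact(js2[1:2, ], n_boot = 1000),
               class = "litpower_domain_error")
  expect_error(correlate_power_impact(
    tibble::tibble(median_power = rep(0.5, 5),
                   impact_factor_5yr = 1:5), n_boot = 1000),
    class = "litpower_domain_error")
})

test_that("the BCa interval has near-nominal coverage under independence", {
  set.seed(406)
  n_rep <- 120
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    js <- tibble::tibble(median_power = rnorm(18),
                         impact_factor_5yr = rnorm(18))
    ci <- correlate_power_impact(js, n_boot = 1500, seed = i)
    covered[i] <- ci$ci_lower <= 0 && 0 <= ci$ci_upper
  }
  coverage <- mean(covered)
  # BCa is first-order accurate: mild undercoverage at n = 18 is expected,
  # so the bound allows for it on top of the replication noise
  expect_gt(coverage, 0.85)
  expect_lte(coverage, 1)
})

test_that("KS statistic equals the brute-force ECDF sup-distance", {
  expect_equal(ks_two_sample(1:10, 1:10)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 101:105)$statistic, 1)
  set.seed(407)
  a <- rnorm(300)
  b <- rnorm(200, 0.4)
  res <- ks_two_sample(a, b)
  expect_equal(res$statistic, oracle_ks_stat(a, b), tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)
  expect_error(ks_two_sample(numeric(), 1:3),
               class = "litpower_domain_error")
})

test_that("tidy and glance expose the correlation fit", {
  js <- tibble::tibble(median_power = seq(0.1, 0.9, length.out = 8),
                       impact_factor_5yr = c(3, 2, 5, 4, 8, 7, 10, 9))
  fit <- correlate_power_impact(js, n_boot = 1000, seed = 2)
  td <- tidy(fit)
  expect_named(td, c("estimate", "conf.low", "conf.high"))
  gl <- glance(fit)
  expect_equal(gl$n, 8L)
  expect_equal(gl$n_boot, 1000)
  expect_output(print(fit), "BCa")
})
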
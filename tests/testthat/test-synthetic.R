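test_that("invalid configurations fail before any sampling", {
  expect_error(synthetic_config(n_studies = 0),
               class = "litpower_domain_error")
  expect_error(synthetic_config(odds_h0_h1 = -1),
               class = "litpower_domain_error")
  expect_error(synthetic_config(bias_u = 1.5),
               class = "litpower_domain_error")
  expect_error(synthetic_config(df_mode = 30, df_median = 20),
               class = "litpower_domain_error")
  expect_error(synthetic_config(dialects = "no_such_dialect"),
               class = "litpower_domain_error")
})

test_that("simulation is reproducible bit-for-bit given the config seed", {
  cfg <- synthetic_config(n_studies = 500, seed = 99)
  a <- simulate_literature(cfg)
  b <- simulate_literature(cfg)
  expect_identical(a, b)
  c <- simulate_literature(synthetic_config(n_studies = 500, seed = 100))
  expect_false(identical(a$records, c$records))
})

test_that("the df distribution hits its configured median and stays right-skewed", {
  sim <- simulate_literature(synthetic_config(n_studies = 10000, seed = 41))
  df <- sim$truth$df
  expect_lte(abs(median(df) - 20), 2)
  counts <- table(df)
  mode_df <- as.integer(names(counts)[which.max(counts)])
  expect_lte(abs(mode_df - 15), 5)
  expect_gt(mean(df), median(df))  # right skew
})

test_that("an all-null literature is significant at the alpha rate", {
  cfg <- synthetic_config(n_studies = 30000, odds_h0_h1 = Inf,
                          select_nonsig = 1, bias_u = 0, seed = 42)
  sim <- simulate_literature(cfg)
  frac <- mean(sim$truth$significant_latent)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 30000))
  expect_equal(nrow(sim$records), 30000)  # select_nonsig = 1 publishes all
})

test_that("suppressing nonsignificant results leaves only significant records", {
  cfg <- synthetic_config(n_studies = 5000, select_nonsig = 0, bias_u = 0,
                          seed = 43)
  sim <- simulate_literature(cfg)
  pub <- sim$truth[sim$truth$published, ]
  expect_true(all(pub$significant_latent))
  # and the published records recompute as significant downstream
  eff <- estimate_effects(clean_records(sim$records)$kept)
  expect_gt(mean(eff$significant), 0.99)
})

test_that("bias-flipped records look significant to downstream recomputation", {
  cfg <- synthetic_config(n_studies = 5000, odds_h0_h1 = Inf,
                          select_nonsig = 0, bias_u = 0.3, seed = 44)
  sim <- simulate_literature(cfg)
  flipped <- sim$truth$bias_flipped
  expect_gt(sum(flipped), 0)
  expect_false(any(sim$truth$significant_latent & flipped))
  eff <- estimate_effects(sim$records)
  # all published records recompute as significant, up to the rare latent
  # record whose 2-decimal printed t rounds just below the critical value
  expect_gt(mean(eff$significant), 0.995)
  expect_true(all(eff$significant[sim$records$record_id %in%
                                    sim$truth$record_id[flipped]]))
  # flip probability applies to nonsignificant studies only
  n_nonsig <- sum(!sim$truth$significant_latent)
  expect_lt(abs(sum(flipped) / n_nonsig - 0.3),
            3 * sqrt(0.3 * 0.7 / n_nonsig))
})

test_that("rendering round-trips through extraction in every shipped dialect", {
  recs <- stat_records(df = c(23L, 14L, 8L, 120L), t = c(2.45, -3.1, 0.5, -12.21),
                       p_cmp = c("=", "<", "=", "<"),
                       p = c(0.022, 0.01, 0.617, 0.001),
                       d = c(0.51, NA, NA, 1.1),
                       paper_id = "p1", journal_id = "NN")
  for (dia in names(litpower_dialects())) {
    rc <- render_corpus(recs, dialects = dia, seed = 3)
    parsed <- extract_records(rc$corpus$text, paper_ids = rc$corpus$paper_id)
    expect_equal(validate_extraction(parsed, recs)$recovery, 1,
                 info = dia)
    expect_equal(parsed[order(parsed$df), c("df", "t", "p_cmp", "p", "d")],
                 recs[order(recs$df), c("df", "t", "p_cmp", "p", "d")],
                 ignore_attr = TRUE)
  }
  # the template instance the dialect set is anchored on
  rc <- render_corpus(stat_records(df = 23L, t = 2.45, p_cmp = "=",
                                   p = 0.022, paper_id = "p"),
                      dialects = "comma_baredot", seed = 1)
  expect_match(rc$corpus$text, "t(23) = 2.45, p = .022", fixed = TRUE)
})

test_that("effect-size exaggeration shrinks as power grows and vanishes at high power", {
  ratios <- numeric(0)
  powers <- numeric(0)
  for (df0 in c(10L, 20L, 40L, 80L, 1000L)) {
    cfg <- synthetic_config(n_studies = 25000, odds_h0_h1 = 0,
                            fixed_true_d = 0.3, fixed_df = df0,
                            select_nonsig = 1, seed = 45L + df0)
    sim <- simulate_literature(cfg)
    ex <- exaggeration_summary(sim$truth, sim$records)
    ratios <- c(ratios, ex$exaggeration)
    powers <- c(powers, power_mixture(0.3, df0))
  }
  expect_true(all(diff(powers) > 0))
  # inflation whenever power < 0.5, monotone decay, and convergence to 1
  expect_true(all(ratios[powers < 0.5] > 1))
  expect_true(all(diff(ratios) < 0))
  expect_lt(abs(ratios[length(ratios)] - 1), 0.05)
})

test_that("chance-significant null records still show inflated effects", {
  cfg <- synthetic_config(n_studies = 20000, odds_h0_h1 = Inf,
                          select_nonsig = 1, seed = 46)
  sim <- simulate_literature(cfg)
  ex <- exaggeration_summary(sim$truth, sim$records)
  expect_equal(ex$true_d, 0)
  expect_gt(ex$mean_d_sig_published, ex$mean_d_all)
  expect_gt(ex$mean_d_sig_published, 0)
  bad <- dplyr::mutate(sim$records, record_id = record_id + 1e6)
  expect_error(exaggeration_summary(sim$truth, bad),
               class = "litpower_domain_error")
})
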
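# Independent Monte-Carlo oracles. These simulate t statistics from
# data-level sufficient statistics (sample mean ~ normal, pooled variance ~
# scaled chi-square) and NHST outcomes from bernoulli draws, deliberately
# avoiding the noncentral-t CDF and the package's own power/FRP code paths.

# one-sample t test on n = df + 1 observations with true effect d
mc_t_onesample <- function(nrep, d, df) {
  n <- df + 1
  xbar <- rnorm(nrep, mean = d, sd = 1 / sqrt(n))
  s <- sqrt(rchisq(nrep, df) / df)
  xbar * sqrt(n) / s
}

# two-sample t statistic under the survey's convention: equal groups of
# size N = ceiling((df + 2) / 2), pooled variance carrying the record's df
mc_t_twosample <- function(nrep, d, df) {
  ng <- ceiling((df + 2) / 2)
  diff <- rnorm(nrep, mean = d, sd = sqrt(2 / ng))
  s <- sqrt(rchisq(nrep, df) / df)
  diff / (s * sqrt(2 / ng))
}

# power of the two-sided test under the df-conditional test-type mixture
mc_power_mixture <- function(nrep, d, df, alpha = 0.05) {
  w <- if (df <= 10) 0.93 else 0.72
  one <- runif(nrep) < w
  t <- numeric(nrep)
  t[one] <- mc_t_onesample(sum(one), d, df)
  t[!one] <- mc_t_twosample(sum(!one), d, df)
  mean(abs(t) > qt(1 - alpha / 2, df))
}

# generative NHST process: H0 by odds, significance by alpha or power,
# nonsignificant flipped with probability bias; returns the false fraction
# among (reported) significant outcomes and its binomial SE
mc_frp <- function(nrep, odds, power, alpha = 0.05, bias = 0) {
  h0 <- runif(nrep) < odds / (1 + odds)
  sig <- runif(nrep) < ifelse(h0, alpha, power)
  sig <- sig | (!sig & runif(nrep) < bias)
  frp <- mean(h0[sig])
  list(frp = frp, se = sqrt(frp * (1 - frp) / sum(sig)), n_sig = sum(sig))
}

# brute-force complementary ECDF sup-distance (KS statistic)
oracle_ks_stat <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

# tiny literature for IO / survey tests
toy_records <- function() {
  stat_records(
    df = c(23L, 14L, 40L), t = c(2.45, -3.1, 0.5),
    p_cmp = c("=", "<", NA), p = c(0.022, 0.01, NA),
    d = c(0.51, NA, NA),
    paper_id = c("p1", "p1", "p2"), journal_id = c("NN", "NN", "Acta")
  )
}
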
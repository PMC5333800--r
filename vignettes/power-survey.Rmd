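---
title: "Surveying power and false report probability in a t-test literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying power and false report probability in a t-test literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litpower)
library(dplyr)
```

## The problem

Most empirical claims in cognitive neuroscience and experimental psychology
rest on null hypothesis significance testing, and the most commonly printed
statistic is the t test: `t(df) = x.xx, p = y.yy`, sometimes with a Cohen's
d. Because df pins down sample size and |t| pins down the standardized
effect, a large collection of such records is enough to reconstruct three
things about a literature:

1. the distribution of **published effect sizes** D,
2. the distribution of **statistical power**, and
3. the **false report probability** (FRP): the long-run probability that a
   statistically significant finding is actually a true null.

`litpower` implements that reconstruction as a pipeline of small
tibble-in/tibble-out steps, plus a generative simulator that produces
literatures with *known* truth so that every step can be validated without
any external data.

## The extraction model

Extraction is two-phase. Phase one scans article plain text for `t(`
anchors (and bare `t` directly followed by `=`), reads a window from the
anchor to the end of the physical line, strips all whitespace, lowercases,
and truncates at 65 characters. A window is kept only if it contains one of
`=` `<` `>` *and* a `p=`/`p<`/`p>` token; this deliberately drops
stand-alone values like `t < 1`, trading some nonsignificant records for a
very low false-alarm rate. Phase two applies full-record templates with a
single integer df inside the parentheses (so F-style `t(2,45)` patterns
never match), a signed t (ASCII hyphen or Unicode minus), a p clause with
its comparator, and an optional d clause.

Two conventions are fixed here because a deterministic window needs them:
the 65 characters are counted *after* whitespace removal, and the window
never crosses a line break. The second choice is what makes the classic
failure mode — a statistical record broken across lines — reproducible: the
simulator's "malformed" dialect inserts exactly such a break, and those
records are missed, never misread.

Cleaning drops, in document order and with machine-readable reasons:
records with negative df, records with negative p, records with df above
10,000 (outliers), and records whose statistical fields are identical to
the immediately preceding kept record of the same paper. The last rule
mirrors the double-detection artefact of anchor scanning; it is restricted
to *adjacent* duplicates because the same statistic legitimately reappears
in different analyses, and it is idempotent.

## From t to D: the test-type mixture

A reported `t(df)` does not say whether it came from a one-sample/matched
design or a two-sample design, and the conversion to Cohen's D differs
between them. Manual validation of extracted records against their source
articles gives the mixture weights used throughout: records with df ≤ 10
are one-sample/matched with probability 0.93, all others with probability
0.72. Each record's effect size is the weighted mixture

$$D = pr(t_1|df)\,D_{t_1} + pr(t_2|df)\,D_{t_2},$$

with the textbook conversions $D_{t_1} = |t|/\sqrt{df+1}$ (one-sample;
matched tests with a repeated-measures correlation of 0.5 convert
identically) and $D_{t_2} = |t|\sqrt{2/N_g}$, where the per-group size
assumes equal groups, $N_g = \lceil (df+2)/2 \rceil$. Rounding upward
slightly exaggerates group sizes, which is the generous direction when
computing power. Magnitudes are used throughout (the sign of t encodes
direction, not size), and significance is *recomputed* two-sided from
(t, df) at α = 0.05 rather than trusted from the reported p, which is
often only an inequality.

Two numerical caveats worth knowing:

* The |t|-based estimator carries a known multiplicative small-sample
  factor, $E[t]/\delta = \sqrt{df/2}\,\Gamma((df{-}1)/2)/\Gamma(df/2)$,
  about +4% at df = 20 and O(1/df) thereafter. The tests check the
  Monte-Carlo mean against this exact expectation at n = 21 and against the
  generating d (within 0.02) at n = 40 designs. No Hedges-type correction
  is applied, matching the survey convention the package implements.
* For odd df the equal-group two-sample design cannot exist exactly
  ($2N_g - 2 = df + 1$); the model conditions on the *reported* df in both
  mixture branches, since df is what is observed.

## Power and FRP

Power is exact two-sided noncentral-t power: noncentrality
$\delta = d\sqrt{df+1}$ (one-sample) or $\delta = d\sqrt{N_g/2}$
(two-sample), mixed with the same df-conditional weights. `add_power()`
attaches power at the conventional benchmarks d = 0.2, 0.5, 0.8 and at the
record's own published D. At d = 0 the central branch is used so that power
equals α to machine precision.

FRP with prestudy H0:H1 odds O, significance level α, and a bias parameter
u (the fraction of would-be-nonsignificant results reported significant) is

$$FRP = \frac{O\alpha + uO(1-\alpha)}{O\alpha + uO(1-\alpha) + power + u(1-power)},$$

which reduces to $O\alpha/(O\alpha + power)$ at u = 0 and to the prior
probability of the null, $O/(O+1)$, at u = 1 — both limits are asserted in
the tests, and the general form is validated against a brute-force
generative simulation of the NHST process. A small/large-effect variant
(`frp_small_large()`) treats significant detections of practically
meaningless effects as false reports; it only ever raises FRP, which is why
the point model is the best-case, lower-limit estimate.

`expected_frp()` weighs the per-record FRP by the empirical probability of
each (df, D) combination — by default weight 1/N per record, which is the
same expectation as any (df, D) binning without the arbitrariness of bins.
All records enter, significant or not: the expectation describes the
literature's generating process, not the selected subset. Because it uses
power at the record's own *published* (typically inflated) D, the result
overestimates power and therefore underestimates FRP: it is a lower limit
by construction.

One identity matters for validation. `expected_frp()` is an *average of
ratios* (a records-weighted mean of conditional FRPs), while the false
fraction among significant records in an actual literature is a *ratio of
sums*, which collapses to `frp_point()` evaluated at the mean H1 power.
The two coincide exactly when power is homogeneous, so the end-to-end
calibration check runs the whole pipeline on a generator configuration with
fixed true d and fixed df; the heterogeneous case is checked against the
mean-power form separately.

## What the simulator emulates — and what it does not

`simulate_literature()` draws, per study: H0 with probability $O/(1+O)$; df
from a discretized lognormal with median 20 whose continuous mode sits at
15 (right-skewed, like observed df distributions; the family itself is a
modeling choice — only the median and mode are constrained); test type by
the same df-conditional weights the analysis assumes; true |d| under H1
from a lognormal with median 0.5 and log-sd 0.5; and t from the central or
noncentral t distribution with the matching noncentrality. Nonsignificant
results are published with probability 0.2 — chosen once so that at 1:1
odds the published significant share lands near the two-thirds typically
observed — and flipped to reported-significant with probability `bias_u`,
in which case the reported t is placed just above the critical value so
that downstream recomputation also classifies the record significant (bias
is a reporting-level phenomenon). Reported values are rounded as articles
print them (t to 2 decimals, p to 3 or `< .001`), which makes
render → parse lossless for well-formed records.

The simulator deliberately does **not** emulate: F tests and other
statistics interleaved with t records; tables (the extractor reads prose
only); journal-specific typesetting beyond the four shipped dialects;
correlated records within a paper (records are independent given the
config); or any dependence of effect size on df. Passing tests therefore
certify the pipeline's internal consistency and its fidelity on text whose
structure matches these dialects — not parser performance on arbitrary
publisher PDFs, which always needs per-corpus validation.

## Descriptive layer and design choices

`summarize_survey()` reports medians and quartiles of D and df and
median/mean benchmark powers, overall, by subfield, or by journal, with
quantiles computed by linear interpolation of order statistics (R type 7;
the convention is stated so that any comparison against externally printed
quantiles can attribute sub-precision differences). The journal→subfield
table (10 neuroscience, 5 psychology, 3 medical titles) ships as
`journal_metadata()`; only the two impact factors quoted in the survey
narrative are filled in, the rest are `NA` by design, and the simulator
uses clearly-synthetic values instead. `correlate_power_impact()` pairs one
per-journal median power with the 5-year impact factor and returns a
Pearson r with a bias-corrected and accelerated bootstrap interval
(bias correction from the bootstrap distribution, acceleration from the
jackknife; seeded, defaulting to 10^4 resamples — BCa is first-order
accurate, and its mild undercoverage at n = 18 journals is visible in the
coverage test). `ks_two_sample()` wraps the asymptotic two-sample
Kolmogorov–Smirnov test used to compare automatically and manually
extracted df distributions, and is cross-checked in the tests against a
direct ECDF sup-distance computation.

Degenerate inputs are handled explicitly: empty record sets are errors for
expectation-type operations; exactly collinear correlation inputs yield
r = ±1 with a warning and an `NA` interval when the bootstrap distribution
degenerates; `clean_records()` on an already-clean set is a no-op.

## Problem sizes

The shipped tests validate power against a 10^6-draw simulator per grid
cell (d ∈ {0, 0.2, 0.5, 0.8} × df ∈ {5, 10, 20, 50, 200}), the FRP model
against 10^6-study generative simulations per scenario, and the full
pipeline end-to-end at 10^5 studies; unit tests use 10^3–10^4-study
literatures. These sizes put three Monte-Carlo standard errors comfortably
below every asserted tolerance while keeping the whole suite at a few
minutes on one core.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_literature(synthetic_config(n_studies = 2000, seed = 7))
corpus <- render_corpus(sim$records, seed = 7)
eff <- extract_records(corpus$corpus$text,
                       paper_ids = corpus$corpus$paper_id) |>
  clean_records() |>
  _$kept |>
  estimate_effects() |>
  add_power()

summarize_survey(eff, split_significance = TRUE)
expected_frp(eff, odds = 1)
frp_curves(eff, odds_grid = 10^seq(-1, 3, 0.25),
           bias_grid = c(0, 0.1, 0.2, 0.3)) |>
  plot_frp_curves()
```

## Known limitations

* The one-sample conversion assumes a repeated-measures correlation of 0.5
  for matched designs; real correlations vary and shift both D and power.
* The mixture weights (0.93/0.72) are point estimates from one validation
  sample; no uncertainty in the weights is propagated.
* FRP scenarios treat O and u as parameters to sweep, never quantities
  estimated from the data.
* The extractor is validated for the shipped reporting dialects; publisher
  PDFs with exotic typesetting need their own validation pass, and records
  inside tables are invisible to it.
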
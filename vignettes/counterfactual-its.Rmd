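---
title: "Counterfactual interrupted time-series analysis of surveillance counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual interrupted time-series analysis of surveillance counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itsurv)
```

## The design

`itsurv` implements a *non-segmented* interrupted time-series (ITS)
analysis for monthly event counts. Instead of fitting level and slope
changes to the whole series, the model is estimated on the
pre-intervention window only and extrapolated through the intervention
window; the extrapolation is the counterfactual — what the
pre-intervention process would have produced had nothing changed. This
choice suits disruptions whose effect shape is unknown a priori (it may
grow year on year, dip then rebound, and so on): nothing about the
post-window influences the counterfactual, and the effect is read off as
per-year ratios rather than forced into a parametric break.

The price of non-segmentation is that every post-window discrepancy —
effect, confounding, or drift — lands in the ratio. Outputs are therefore
worded as observed-vs-expected comparisons, never as causal effects.

## The count model

For a subgroup's monthly counts $y_t$, with $x_t$ the 0-based month
index from the window start,

$$
\mathbb{E}[y_t] \;=\;
\exp\!\Big(\beta_0 + \beta_{\mathrm{trend}}\,x_t
 + \sum_{k=1}^{n}\big[\,s_k \sin(2\pi k x_t/12) + c_k \cos(2\pi k x_t/12)\,\big]\Big)
\cdot \mathrm{pop}_t ,
$$

with negative binomial (NB) sampling around that mean. Key choices:

* **Offset.** $\log(\mathrm{pop}_t)$ enters with coefficient fixed at 1,
  so $\beta_0$ is a log rate per person-month. Yearly denominators are
  linearly interpolated to months (anchors at January 1, or July 1 for
  mid-year counts; constant extrapolation beyond the outermost anchors).
  Multiplying the offset by any constant shifts $\beta_0$ by minus its
  log and changes nothing else — a property the tests assert.
* **Dispersion.** The "size" convention:
  $\mathrm{Var}(y) = \mu + \mu^2/\theta$, $\theta > 0$; larger $\theta$
  is closer to Poisson. $\theta$ is estimated by joint maximum
  likelihood (iteratively reweighted least squares alternating with ML
  updates of $\theta$, Poisson-initialised). When that alternation
  stalls — typically on under-dispersed series at the Poisson boundary —
  the fit falls back to profiling $\theta$ over a fixed log-spaced grid,
  which is deterministic and always succeeds.
* **Harmonic degree by AIC.** Candidates $n = 0,\dots,3$ are each fitted
  and the minimal-AIC fit kept, ties broken toward the smaller $n$. AIC
  counts the dispersion parameter:
  $\mathrm{AIC} = -2\ell + 2(p + 1)$. The cap at 3 reflects what a
  48-month pre-window can identify; monthly sampling makes the $k = 6$
  sine column identically zero, so degrees $\ge 6$ are rejected
  outright by a rank check.
* **Indexing discipline.** The design for prediction is built by the
  same convention as the fit, and every prediction request is checked
  against the fit's calendar origin: a request whose `month_index` does
  not equal $12(\mathrm{year}-y_0) + (\mathrm{month}-m_0)$ is a hard
  error. A silently shifted index is the classic ITS bug; it cannot pass
  here.

## Incidence ratios

Monthly values are summed to calendar years (partial years are refused,
not prorated). For each intervention year:

* $\mathrm{oIR} = \dfrac{\text{observed annual count}}
  {\text{pre-period average annual count}}$ — a pure data ratio that no
  model can influence;
* $\mathrm{aIR} = \dfrac{\text{observed annual rate}}
  {\text{expected annual rate}}$ — the counterfactual-adjusted ratio.
  Rates are counts per person-year; holding the population constant
  within a year, the person-years cancel and the ratio of annual counts
  remains. The implementation computes both forms and asserts the
  cancellation numerically rather than assuming it.

### Uncertainty for the aIR

The aIR carries two sources of noise: estimation error in the fitted
counterfactual and NB sampling in the year's counts. The package
quantifies both with a parametric bootstrap, a design choice this
package makes and documents as its own:

1. draw a coefficient vector from
  $\mathcal{N}(\hat\beta, \widehat{\mathrm{Var}}(\hat\beta))$;
2. draw a dispersion log-normally, centred on the fit's
  moment-calibrated dispersion (Pearson statistic equated to its
  residual degrees of freedom) with the ML estimate's relative standard
  error. The moment calibration matters: on short windows the ML
  $\hat\theta$ systematically understates overdispersion because it
  ignores the degrees of freedom absorbed by the regression
  coefficients, and simulating with it makes the test anti-conservative.
  The ML value remains the reported dispersion estimate in all
  summaries;
3. simulate the year's 12 monthly counts from the NB law under the
  no-effect null and keep their sum.

The two-sided p-value doubles the smaller inclusive tail of the observed
annual count within the replicate distribution (capped at 1). The 95% CI
for the aIR divides the observed count by the 97.5/2.5 percent quantiles
of the replicate sums, so "CI excludes 1" and "p < .05" coincide up to
Monte-Carlo error. Zero exceedances are reported as a bound
(`p_label = "<0.002"` at 1,000 replicates), not as an exact zero.

## The characteristics table

The before/during table compares episode attributes across the split
date: Fisher's exact test for binary attributes (sex, 28-day death,
any mental-health condition, public-assistance pay code) and
Mann-Whitney U on raw values for age and the ordinal triage codes —
ordinal codes are ranked, not chi-squared, and ties get midranks. Both
tests are implemented in-package to pin their exact definitions:

* Fisher's two-sided p uses probability ordering — the sum of
  hypergeometric probabilities of all tables, given the margins, no more
  probable than the observed one — evaluated in log-gamma arithmetic so
  cells of order $10^4$ lose no precision. The point estimate is the
  conditional-ML odds ratio. Zero margins yield p = 1 with a warning.
* Mann-Whitney uses the tie-corrected normal approximation with a 0.5
  continuity correction, switching to the exact permutation distribution
  only when both samples have at most 8 values and no ties.

Both are verified against exhaustive enumeration oracles (every 2×2
table with margins up to 30; every 5|5 partition) and cross-checked
against `stats::fisher.test` / `stats::wilcox.test` in the test suite.
Display percentages round half-up (53, not 53.28, from 8184/15,359);
underlying values are kept at full precision, and no multiplicity
correction is applied across table rows.

## The synthetic-data generator

Because registry episode data of this kind are confidential, the
generator is a first-class module, not a test fixture. It draws monthly
counts from the same NB law the model fits — log-linear trend, annual
harmonics, population offset — plus a per-calendar-year multiplicative
effect $\theta_{\mathrm{year}}$ applied from the intervention month
onward ($\theta = 1$ before). The true mean $\mu_t$ is returned beside
each draw so recovery can be asserted against ground truth. A companion
episode-level generator produces visit records (date uniform in period;
sex, mental-health category, 28-day death, pay-assistance and triage
drawn independently from per-period probability vectors) shaped like the
real intake of a large urban ED self-harm cohort.

Default study conditions mirror a large adult stratum over a 48-month
pre-window (2016–2019) and 36-month intervention window (2020–2022):
about 110 visits/month against a population near 2 million with a mild
(0.5%/year) decline, a slightly negative trend
($\beta_{\mathrm{trend}} = -0.002$ per month), one annual harmonic of
modest amplitude (0.08/0.05 on the log scale), dispersion
$\theta = 25$ (variance roughly five times the mean at $\mu = 110$ —
clear but not extreme overdispersion, typical of monthly self-harm
counts), and year effects 1.58/2.64/3.13 echoing the kind of escalating
post-disruption rise the pipeline is designed to measure. A per-year
constant $\theta$ (rather than a post-intervention slope) matches the
per-year ratio reporting.

What the generator deliberately does **not** emulate: within-patient
correlation from repeat attenders (visits are independent draws; the
analysis counts visits, not persons), attribute–date dependence beyond
the period split, operational ED variables (waiting/staying times), and
autocorrelated month-to-month shocks. Passing tests therefore
demonstrate correctness of the estimation machinery under the stated
law, not robustness to serial dependence or case-mix drift in real
registries.

## Numerical and degenerate-input choices

* Month grid is strictly consecutive; months with zero events appear as
  zero counts — a count model cannot skip months.
* Ages 12–84 define the four analysis bands (12–17, 18–24, 25–64,
  65–84); other ages map to `out_of_band`, a value rather than an error,
  so subgroup analyses can exclude them while descriptive totals retain
  them.
* Fitting is deterministic: fixed initialisation, fixed optimiser
  settings, no randomness anywhere in estimation; all simulation draws
  are seeded, each seed is recorded in the corresponding output, and the
  bootstrap derives per-year sub-seeds from the one supplied seed.
* All-zero count series, non-positive offsets, overlapping windows,
  unparseable input rows and partial intervention years fail fast with
  named locations; nothing is silently dropped or prorated.
* A single population anchor falls back to a constant series with a
  notice; non-positive anchors are hard errors.

## Problem sizes in the validation suite

The test suite and acceptance script validate at these scales, chosen to
make Monte-Carlo conclusions stable while keeping a full run in the
low minutes: coefficient recovery over 200 replicates of 480-month
windows; AIC selection over 100 replicates at amplitude 0.5 and 0;
end-to-end aIR recovery over 200 replicates per effect size
$\theta \in \{1.0, 1.5, 2.5\}$ at monthly means above 50; test size
under the null over 400 replicates at 1,000 bootstrap draws each;
Fisher/Mann-Whitney enumeration sweeps that are exhaustive at their
stated margins.

## Known limitations

* The counterfactual inherits every limitation of extrapolation:
  a 48-month window identifies a linear log-trend and low-order annual
  harmonics, nothing richer; three-year extrapolations magnify trend
  uncertainty, which the bootstrap propagates but cannot remove.
* No autocorrelation correction is applied; if real residuals are
  serially correlated the bootstrap understates uncertainty.
* Linear interpolation of yearly population anchors can bias the offset
  when true population shifts abruptly within a year.
* The bootstrap's coefficient draws are asymptotically normal; at much
  smaller counts than validated here (monthly means of a handful),
  coverage is not guaranteed.
* Model selection by AIC is performed once and then treated as fixed;
  selection uncertainty is not propagated. Annual aggregation blunts
  this in practice, since unmodelled annual harmonics largely cancel in
  yearly sums.
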
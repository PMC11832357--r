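# itsurv

Interrupted time-series (ITS) counterfactual analysis of monthly
event-surveillance counts, built for emergency-department (ED) visit
monitoring — e.g. tracking deliberate self-harm presentations across a
population-level disruption such as a pandemic.

## The problem and the model

Surveillance teams often need to answer: *did event rates during a
disruption depart from what the pre-disruption process would have
produced?* `itsurv` answers this with a non-segmented ITS design: a count
model is fitted **only to the pre-intervention window** and extrapolated
through the intervention window as the counterfactual.

Monthly counts `y_t` for a subgroup are modelled as negative binomial
with log link,

```
E[y_t] = exp(b0 + b_trend * x_t
             + sum_{k=1..n} [ s_k sin(2*pi*k*x_t/12) + c_k cos(2*pi*k*x_t/12) ])
         * population_t
```

where `x_t` is the month index from the window start, the sine/cosine
pairs are Fourier harmonics capturing annual seasonality, and the
population enters as an offset so coefficients act on per-person-month
rates. The harmonic degree `n` (0–3) is chosen by AIC. Each intervention
year is then summarised by

* **oIR** — observed annual count / pre-period average annual count
  (model-free), and
* **aIR** — observed annual count / model-expected annual count,
  adjusted for trend, seasonality and population change,

with a parametric-bootstrap 95% CI and two-sided p-value for the aIR.
The package also produces the standard before/during characteristics
table (Fisher exact tests for binary attributes, Mann-Whitney U for age
and ordinal triage), observed-vs-expected figures, and a synthetic-data
generator with known ground truth so the whole pipeline is testable
without access to confidential registry data.

## Worked example

```r
library(itsurv)

scenario <- scenario_config(start = c(2016, 1), end = c(2022, 12),
                            intervention = c(2020, 1), seed = 42)
sim <- simulate_monthly_counts(default_true_params(), scenario)

fit <- select_by_aic(sim, sim$population[sim$period == "pre"])
glance(fit)
#> # A tibble: 1 x 6
#>   degree  nobs theta logLik   AIC converged
#>    <int> <int> <dbl>  <dbl> <dbl> <lgl>
#> 1      0    48  26.9  -217.  441. TRUE

incidence_ratio_table(fit, sim, sim$population,
                      replicates = 2000, seed = 9)
#> # A tibble: 3 x 13
#>   subgroup   year observed pre_avg_annual expected   oIR   aIR ci_lower ...
#> 1 synthetic  2020     1683           1272    1049.  1.32  1.60     1.33
#> 2 synthetic  2021     2973           1272     972.  2.34  3.06     2.44
#> 3 synthetic  2022     3407           1272     901.  2.68  3.78     2.90
```

Here the generator's ground truth multiplied the 2020–2022 rates by
1.58, 2.64 and 3.13; a single simulated realisation recovers aIRs of
1.60, 3.06 and 3.78 — the point estimates scatter around the truth with
the uncertainty the bootstrap CI quantifies (all three years exclude 1,
`p_label` `<0.001`). The `oIR` column is smaller than `aIR` in later
years because the fitted (slightly declining) trend lowers the
counterfactual denominator, exactly the adjustment the design is for.

A full run — characteristics table, per-subgroup fits, IR tables,
figures, logs — is one call:

```r
cfg <- list(start = c(2016, 1), end = c(2022, 12), intervention = c(2020, 1),
            synthetic = list(n_pre = 4000, n_post = 4300),
            subgroups = list(list(name = "all", filter = "TRUE"),
                             list(name = "male", filter = 'sex == "male"')),
            replicates = 2000, seed = 1)
res <- run_pipeline(cfg, out_dir = "itsurv-out")
```

A thin command-line wrapper with `simulate` / `describe` / `fit` /
`report` / `all` subcommands lives at `inst/scripts/itsurv.R`.

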
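fit_study <- function(seed = 20, params = default_true_params()) {
  sim <- simulate_monthly_counts(params, study_scenario(seed = seed))
  fit <- select_by_aic(sim, sim$population[sim$period == "pre"])
  list(sim = sim, fit = fit)
}

test_that("prediction over the fitting window reproduces fitted means", {
  fs <- fit_study(20)
  pre <- fs$sim[fs$sim$period == "pre", ]
  pred <- predict_expected(fs$fit, pre[, c("month_index", "year", "month")],
                           pre$population)
  expect_equal(pred$expected, fs$fit$data$fitted, tolerance = 1e-10)
})

test_that("a flat model predicts proportionally to the offset", {
  series <- tibble::tibble(month_index = 0:35,
                           year = rep(2017:2019, each = 12),
                           month = rep(1:12, 3), period = "pre",
                           count = rep(100L, 36))
  fit <- fit_negative_binomial(series, 0, rep(1e6, 36))
  months <- tibble::tibble(month_index = 36:47, year = 2020, month = 1:12)
  pop <- seq(1e6, 2.1e6, by = 1e5)
  pred <- predict_expected(fit, months, pop)
  expect_equal(pred$expected / pop, rep(pred$expected[1] / pop[1], 12),
               tolerance = 1e-6)
})

test_that("month indexing mismatches are a hard error", {
  fs <- fit_study(21)
  post <- fs$sim[fs$sim$period == "post", ]
  shifted <- post[, c("month_index", "year", "month")]
  shifted$month_index <- shifted$month_index + 1L
  expect_error(predict_expected(fs$fit, shifted, post$population),
               "indexing mismatch")
})

test_that("expected counts track the generative mean on the post window", {
  # ~500-count months: recovery of the counterfactual within 10% MARE
  pars <- true_model_params(beta0 = log(500 / 2e6), beta_trend = 0.001,
                            harmonics = list(c(0.1, -0.08)), dispersion = 40)
  sim <- simulate_monthly_counts(pars, study_scenario(seed = 22))
  fit <- select_by_aic(sim, sim$population[sim$period == "pre"])
  post <- sim[sim$period == "post", ]
  pred <- predict_expected(fit, post[, c("month_index", "year", "month")],
                           post$population)
  mare <- mean(abs(pred$expected - post$mu) / post$mu)
  expect_lt(mare, 0.10)
})

test_that("annual ratios reproduce hand arithmetic", {
  # pre years total 100,110,120,130; 2020 observed 180
  mk_year <- function(year, idx0, total, period) {
    tibble::tibble(month_index = idx0 + 0:11, year = year, month = 1:12,
                   period = period,
                   count = c(rep(total %/% 12, 11),
                             total - 11 * (total %/% 12)))
  }
  observed <- dplyr::bind_rows(
    mk_year(2016, 0, 100, "pre"), mk_year(2017, 12, 110, "pre"),
    mk_year(2018, 24, 120, "pre"), mk_year(2019, 36, 130, "pre"),
    mk_year(2020, 48, 180, "post"))
  expected <- tibble::tibble(year = 2020, month = 1:12, expected = 10)
  ratios <- annual_ratios(observed, expected)
  expect_equal(ratios$pre_avg_annual, 115)
  expect_equal(ratios$oIR, 180 / 115)
  expect_equal(ratios$aIR, 1.5)   # 180 / 120
  expect_equal(ratios$observed, 180)
})

test_that("observed equal to expected gives aIR exactly 1", {
  fs <- fit_study(23)
  post <- fs$sim[fs$sim$period == "post", ]
  pred <- predict_expected(fs$fit, post[, c("month_index", "year", "month")],
                           post$population)
  synthetic_obs <- fs$sim
  synthetic_obs$count[synthetic_obs$period == "post"] <- pred$expected
  ratios <- annual_ratios(synthetic_obs, pred, post$population)
  expect_equal(ratios$aIR, rep(1, 3), tolerance = 1e-12)
})

test_that("partial intervention years are refused, not prorated", {
  fs <- fit_study(24)
  chopped <- fs$sim[1:(nrow(fs$sim) - 3), ]  # 2022 loses three months
  post <- chopped[chopped$period == "post", ]
  pred <- predict_expected(fs$fit, post[, c("month_index", "year", "month")],
                           post$population)
  expect_error(annual_ratios(chopped, pred), "partial post year")
})

test_that("oIR ignores the model and aIR ignores offset rescaling", {
  fs <- fit_study(25)
  sim <- fs$sim
  pop <- sim$population
  t1 <- incidence_ratio_table(fs$fit, sim, pop, replicates = 1000, seed = 3)
  # refit with the offset globally rescaled: aIR point estimates unchanged
  fit2 <- select_by_aic(sim, pop[sim$period == "pre"] * 4)
  t2 <- incidence_ratio_table(fit2, sim, pop * 4, replicates = 1000, seed = 3)
  expect_equal(t1$aIR, t2$aIR, tolerance = 1e-6)
  expect_equal(t1$oIR, t2$oIR)  # pure data ratio
  expect_equal(t1$oIR,
               sapply(2020:2022, function(y) {
                 sum(sim$count[sim$year == y]) /
                   (sum(sim$count[sim$period == "pre"]) / 4)
               }))
})

test_that("bootstrap p and CI are coherent and stable in the replicates", {
  fs <- fit_study(26, params = true_model_params(
    beta0 = log(110 / 2e6), beta_trend = -0.002,
    harmonics = list(c(0.08, 0.05)), dispersion = 25,
    effect_by_year = c(`2020` = 1.1)))
  sim <- fs$sim
  post <- sim[sim$period == "post", ]
  y2020 <- post[post$year == 2020, ]
  obs <- sum(y2020$count)
  a1 <- air_inference(fs$fit, obs, y2020[, c("month_index", "year", "month")],
                      y2020$population, replicates = 1000, seed = 5)
  a2 <- air_inference(fs$fit, obs, y2020[, c("month_index", "year", "month")],
                      y2020$population, replicates = 8000, seed = 5)
  expect_lt(abs(a1$p_value - a2$p_value),
            3 * sqrt(max(a2$p_value, 0.01) / 1000) + 0.02)
  # point estimate inside its own CI
  expect_gte(a1$aIR, a1$ci_lower)
  expect_lte(a1$aIR, a1$ci_upper)
  # CI excluding 1 coincides with p < .05 (up to MC error, so only the
  # clear-cut agreement direction is asserted)
  excl <- a2$ci_lower > 1 || a2$ci_upper < 1
  if (a2$p_value > 0.10) expect_false(excl)
  if (a2$p_value < 0.01) expect_true(excl)
  expect_error(air_inference(fs$fit, obs,
                             y2020[, c("month_index", "year", "month")],
                             y2020$population, replicates = 10),
               "at least 1000")
})

test_that("extreme tails are labelled as bounds", {
  fs <- fit_study(27)  # strong default effects: 2022 is far outside null
  sim <- fs$sim
  post <- sim[sim$period == "post", ]
  y <- post[post$year == 2022, ]
  res <- air_inference(fs$fit, sum(y$count),
                       y[, c("month_index", "year", "month")],
                       y$population, replicates = 1000, seed = 6)
  expect_identical(res$p_label, "<0.002")
  expect_equal(res$p_value, 0)
})
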
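#' Extrapolate the fitted model as a counterfactual expected series
#'
#' Computes `exp(X beta) * population` per month with the design built by
#' the same convention and harmonic degree as the fit. Month indexing is
#' checked against the fit's calendar origin: every requested
#' `month_index` must equal `12*(year - y0) + (month - m0)` for the fit's
#' first month `(y0, m0)`. A mismatch is a hard error — a silently
#' shifted index is the classic ITS mistake.
#'
#' @param fit An `its_fit`.
#' @param months Tibble with `month_index`, `year`, `month` for the
#'   months to predict (may be the fitting window itself).
#' @param population Positive monthly denominators aligned with `months`.
#' @return `months` with an added `expected` column.
#' @export
predict_expected <- function(fit, months, population) {
  stopifnot(inherits(fit, "its_fit"))
  months <- as_tibble(months)
  if (!all(c("month_index", "year", "month") %in% names(months))) {
    abort("`months` needs month_index, year and month columns")
  }
  if (length(population) != nrow(months)) {
    abort("`population` must align one-to-one with `months`")
  }
  if (!is.null(fit$origin)) {
    want <- month_index_from(months$year, months$month,
                             fit$origin$year, fit$origin$month) +
      fit$origin$index
    if (!all(months$month_index == want)) {
      bad <- which(months$month_index != want)[1]
      abort(sprintf(
        paste0("month indexing mismatch at %d-%02d: index %d does not ",
               "extend the fitting window's scheme (expected %d)"),
        months$year[bad], months$month[bad], months$month_index[bad],
        want[bad]))
    }
  }
  X <- design_for_degree(months$month_index, fit$degree)
  months |>
    mutate(expected = as.numeric(exp(X %*% fit$coefficients) * population))
}

# build_design without the identifiability guard: prediction windows may
# be shorter than the parameter count
design_for_degree <- function(month_index, degree) {
  x <- as.numeric(month_index)
  cols <- list(`(Intercept)` = rep(1, length(x)), trend = x)
  for (k in seq_len(degree)) {
    cols[[paste0("sin", k)]] <- sin(2 * pi * k * x / 12)
    cols[[paste0("cos", k)]] <- cos(2 * pi * k * x / 12)
  }
  do.call(cbind, cols)
}

#' Observed and adjusted incidence ratios per intervention year
#'
#' Sums monthly values to calendar years (partial years are refused, not
#' prorated) and forms, for each intervention year:
#' * `oIR` = observed annual count / pre-period average annual count — a
#'   pure data ratio, independent of any model;
#' * `aIR` = observed annual rate / expected annual rate. With a constant
#'   within-year population the person-year denominators cancel and the
#'   ratio of counts is returned; the cancellation is asserted
#'   numerically when populations are supplied.
#'
#' @param observed Monthly count tibble including pre and post rows
#'   (columns `year`, `period`, `count`).
#' @param expected Tibble from [predict_expected()] restricted to the
#'   intervention months (`year`, `expected`).
#' @param population Optional monthly populations aligned with the rows
#'   of `expected`, used only to assert the rate cancellation.
#' @return One row per intervention year: `year`, `observed`,
#'   `pre_avg_annual`, `expected`, `oIR`, `aIR`.
#' @export
annual_ratios <- function(observed, expected, population = NULL) {
  pre <- observed |> filter(.data$period == "pre")
  post <- observed |> filter(.data$period == "post")
  if (!nrow(pre) || !nrow(post)) abort("need both pre and post rows")
  check_whole_years <- function(d, label) {
    bad <- d |> count(.data$year) |> filter(.data$n != 12L)
    if (nrow(bad)) {
      abort(sprintf("partial %s year(s) refused: %s", label,
                    paste(bad$year, collapse = ", ")))
    }
  }
  check_whole_years(pre, "pre")
  check_whole_years(post, "post")
  pre_avg <- sum(pre$count) / length(unique(pre$year))
  obs_year <- post |> group_by(.data$year) |>
    summarise(observed = sum(.data$count), .groups = "drop")
  exp_year <- as_tibble(expected) |> group_by(.data$year) |>
    summarise(expected = sum(.data$expected), .groups = "drop")
  out <- obs_year |> left_join(exp_year, by = "year")
  if (any(is.na(out$expected))) {
    abort("expected series does not cover every intervention year")
  }
  if (any(out$expected <= 0)) abort("expected annual count of zero")
  if (!is.null(population)) {
    # rate form: (obs/person-years) / (exp/person-years); with yearly
    # person-years identical in numerator and denominator this must equal
    # the count ratio to machine precision
    py <- as_tibble(expected) |>
      mutate(population = population) |>
      group_by(.data$year) |>
      summarise(py = sum(.data$population) / 12, .groups = "drop")
    rate_air <- (out$observed / py$py) / (out$expected / py$py)
    stopifnot(all(abs(rate_air - out$observed / out$expected) <
                    1e-10 * pmax(1, rate_air)))
  }
  out |>
    mutate(pre_avg_annual = pre_avg,
           oIR = .data$observed / pre_avg,
           aIR = .data$observed / .data$expected) |>
    select("year", "observed", "pre_avg_annual", "expected", "oIR", "aIR")
}

#' Parametric-bootstrap inference for the adjusted incidence ratio
#'
#' The study's expected counts come from a model fitted to a finite pre
#' window, so the aIR carries both estimation and count-sampling
#' uncertainty. For each replicate a coefficient vector is drawn from the
#' multivariate normal sampling distribution of the fit, a dispersion is
#' drawn log-normally around the fit's moment-calibrated (Pearson/df)
#' dispersion — which undoes the short-window bias of the ML value —
#' and monthly counts for the year are simulated from the negative
#' binomial law under the no-effect null; their annual sum is kept. The two-sided p-value doubles the smaller inclusive tail of
#' the observed annual count within that replicate distribution (capped
#' at 1); the 95 percent CI for the aIR is the observed count divided by
#' the 97.5 and 2.5 percent quantiles of the replicate annual counts, so
#' p < .05 coincides with the CI excluding 1 up to Monte-Carlo error.
#' Zero exceedances are reported via `p_label` as a bound (e.g. "<0.001")
#' rather than as an exact zero.
#'
#' @param fit A converged `its_fit`.
#' @param observed_annual Observed annual count for the year.
#' @param months Tibble (`month_index`, `year`, `month`) of the 12 months
#'   of one intervention year.
#' @param population Monthly denominators aligned with `months`.
#' @param replicates Number of bootstrap replicates (>= 1000).
#' @param seed Integer seed for the replicate stream.
#' @return A one-row tibble: `aIR`, `ci_lower`, `ci_upper`, `p_value`,
#'   `p_label`, `replicates`, `seed`.
#' @export
air_inference <- function(fit, observed_annual, months, population,
                          replicates = 2000, seed = 1L) {
  stopifnot(inherits(fit, "its_fit"))
  if (!fit$converged) abort("inference requires a converged fit")
  if (replicates < 1000) abort("use at least 1000 replicates")
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev)))) {
    abort("degenerate coefficient covariance")
  }
  pred <- predict_expected(fit, months, population)
  X <- design_for_degree(months$month_index, fit$degree)
  draws <- withr_seed(seed, {
    B <- MASS::mvrnorm(replicates, mu = fit$coefficients, Sigma = fit$vcov)
    mu_rep <- exp(X %*% t(B)) * population   # months x replicates
    theta_ref <- fit$theta_moment %||% fit$theta
    theta_rep <- if (is.finite(fit$theta_se %||% NA_real_)) {
      exp(stats::rnorm(replicates, log(theta_ref),
                       fit$theta_se / fit$theta))
    } else rep(theta_ref, replicates)
    matrix(rnbinom(length(mu_rep), mu = mu_rep,
                   size = rep(theta_rep, each = nrow(mu_rep))),
           nrow = nrow(mu_rep))
  })
  annual_rep <- colSums(draws)
  p_hi <- mean(annual_rep >= observed_annual)
  p_lo <- mean(annual_rep <= observed_annual)
  p <- min(1, 2 * min(p_hi, p_lo))
  q <- quantile(annual_rep, c(0.975, 0.025), names = FALSE, type = 8)
  tibble(
    aIR = observed_annual / sum(pred$expected),
    ci_lower = observed_annual / q[1],
    ci_upper = observed_annual / q[2],
    p_value = p,
    p_label = if (p < 1 / replicates) sprintf("<%.3g", 2 / replicates)
              else sprintf("%.3f", p),
    replicates = as.integer(replicates),
    seed = as.integer(seed)
  )
}

#' Full incidence-ratio table for one subgroup
#'
#' Combines [predict_expected()], [annual_ratios()] and [air_inference()]
#' into the per-year results table: observed and expected annual counts,
#' oIR, aIR with bootstrap CI and p-value.
#'
#' @param fit A converged `its_fit` for the subgroup.
#' @param observed Full monthly count tibble (pre and post rows).
#' @param population Monthly denominators aligned with the rows of
#'   `observed`.
#' @param replicates,seed Bootstrap settings passed to [air_inference()];
#'   each year uses an independent sub-seed derived from `seed`.
#' @return One row per intervention year: `subgroup`, `year`, `observed`,
#'   `pre_avg_annual`, `expected`, `oIR`, `aIR`, `ci_lower`, `ci_upper`,
#'   `p_value`, `p_label`, `replicates`, `seed`.
#' @export
incidence_ratio_table <- function(fit, observed, population,
                                  replicates = 2000, seed = 1L) {
  observed <- as_tibble(observed)
  post <- observed |> filter(.data$period == "post")
  pop_post <- population[observed$period == "post"]
  pred <- predict_expected(fit, post |> select("month_index", "year", "month"),
                           pop_post)
  ratios <- annual_ratios(observed, pred, pop_post)
  years <- ratios$year
  boot <- purrr::map2(years, seq_along(years), function(y, i) {
    sel <- post$year == y
    air_inference(fit, ratios$observed[ratios$year == y],
                  post[sel, c("month_index", "year", "month")],
                  pop_post[sel], replicates = replicates,
                  seed = (seed + 7919L * i) %% .Machine$integer.max)
  }) |> list_rbind()
  label <- if ("subgroup" %in% names(observed)) observed$subgroup[1] else "subgroup"
  ratios |>
    mutate(subgroup = label, .before = 1) |>
    mutate(ci_lower = boot$ci_lower, ci_upper = boot$ci_upper,
           p_value = boot$p_value, p_label = boot$p_label,
           replicates = boot$replicates, seed = boot$seed)
}
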
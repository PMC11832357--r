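#' Ground-truth parameters for the synthetic count generator
#'
#' Bundles the generative parameters of the monthly-count law
#' \deqn{\mu_t = \exp(\beta_0 + \beta_{trend} x_t +
#'   \sum_k [s_k \sin(2\pi k x_t/12) + c_k \cos(2\pi k x_t/12)])
#'   \cdot \mathrm{population}_t \cdot \theta_{year(t)}}
#' with counts drawn negative-binomially around \eqn{\mu_t}.
#'
#' Dispersion uses the "size" convention: variance \eqn{= \mu + \mu^2/size},
#' so larger `dispersion` means closer to Poisson.
#'
#' @param beta0 Log rate per person-month at month index 0.
#' @param beta_trend Change in log rate per month.
#' @param harmonics List of length-2 numeric vectors `c(sin, cos)`, one per
#'   Fourier degree `k = 1, 2, ...`; `list()` for no seasonality.
#' @param dispersion Negative binomial size parameter (> 0).
#' @param effect_by_year Named numeric vector mapping intervention calendar
#'   years to a multiplicative rate factor \eqn{\theta \ge 0}; years absent
#'   from the map (all pre-intervention months) get \eqn{\theta = 1}.
#' @return An object of class `true_model_params`.
#' @examples
#' true_model_params(beta0 = log(100 / 2e6), beta_trend = 0,
#'                   harmonics = list(c(0.2, 0.1)), dispersion = 25)
#' @export
true_model_params <- function(beta0,
                              beta_trend = 0,
                              harmonics = list(),
                              dispersion = 25,
                              effect_by_year = numeric()) {
  stopifnot(is.numeric(beta0), length(beta0) == 1, is.finite(beta0),
            is.numeric(beta_trend), length(beta_trend) == 1,
            is.finite(beta_trend))
  if (!is.list(harmonics) ||
      !all(vapply(harmonics, function(h) is.numeric(h) && length(h) == 2 &&
                    all(is.finite(h)), logical(1)))) {
    abort("`harmonics` must be a list of finite numeric pairs c(sin, cos)")
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1 ||
      !is.finite(dispersion) || dispersion <= 0) {
    abort("`dispersion` must be a single finite value > 0")
  }
  if (length(effect_by_year)) {
    if (is.null(names(effect_by_year)) || any(names(effect_by_year) == "")) {
      abort("`effect_by_year` must be named by calendar year")
    }
    if (any(!is.finite(effect_by_year)) || any(effect_by_year < 0)) {
      abort("all effect factors must be finite and non-negative")
    }
  }
  structure(
    list(beta0 = beta0, beta_trend = beta_trend, harmonics = harmonics,
         dispersion = dispersion,
         effect_by_year = setNames(as.numeric(effect_by_year),
                                   names(effect_by_year))),
    class = "true_model_params"
  )
}

#' @export
print.true_model_params <- function(x, ...) {
  cat("<true_model_params>\n")
  cat("  beta0:", format(x$beta0), "  beta_trend:", format(x$beta_trend), "\n")
  cat("  harmonic degree:", length(x$harmonics),
      " dispersion (size):", format(x$dispersion), "\n")
  if (length(x$effect_by_year)) {
    cat("  effect by year:",
        paste(names(x$effect_by_year), format(x$effect_by_year), sep = "=",
              collapse = ", "), "\n")
  } else cat("  effect by year: none (theta = 1 throughout)\n")
  invisible(x)
}

#' Scenario configuration for the synthetic generator
#'
#' Defines the study window, the intervention month, the population
#' schedule and the random seed for one simulated subgroup. The
#' pre-intervention window must span at least 24 months so that annual
#' seasonality is identifiable.
#'
#' @param start,end `c(year, month)` of the first and last month of the
#'   full study window.
#' @param intervention `c(year, month)` of the first month of the
#'   intervention window; must lie strictly inside the window.
#' @param population Either a single positive number (constant population)
#'   or a data frame with columns `year` and `population` covering every
#'   calendar year in the window. Each month of a year uses that year's
#'   population as its person-month denominator (interpolation, when
#'   wanted, is applied downstream via [interpolate_population()]).
#' @param subgroup Label carried through outputs.
#' @param seed Integer random seed, recorded in every output.
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config(start = c(2016, 1), end = c(2022, 12),
#'                 intervention = c(2020, 1), population = 2e6, seed = 1)
#' @export
scenario_config <- function(start = c(2016, 1),
                            end = c(2022, 12),
                            intervention = c(2020, 1),
                            population = default_population(start[1]:end[1]),
                            subgroup = "synthetic",
                            seed = 1L) {
  grid <- month_grid(start, end)
  iv <- month_index_from(intervention[1], intervention[2], start[1], start[2])
  n <- nrow(grid)
  if (iv <= 0 || iv >= n) {
    abort("intervention month must lie strictly inside the study window")
  }
  if (iv < 24) {
    abort("pre-intervention window must span at least 24 months")
  }
  if (is.numeric(population) && length(population) == 1) {
    if (!is.finite(population) || population <= 0) {
      abort("constant population must be positive")
    }
    population <- tibble(year = unique(grid$year),
                         population = as.numeric(population))
  }
  population <- as_tibble(population)
  if (!all(c("year", "population") %in% names(population))) {
    abort("`population` needs columns year and population")
  }
  missing_years <- setdiff(unique(grid$year), population$year)
  if (length(missing_years)) {
    abort(paste("population schedule missing year(s):",
                paste(missing_years, collapse = ", ")))
  }
  if (any(population$population <= 0)) abort("populations must be positive")
  structure(
    list(start = as.integer(start), end = as.integer(end),
         intervention = as.integer(intervention),
         population = population, subgroup = subgroup,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# mildly declining schedule, roughly a large adult stratum
default_population <- function(years) {
  tibble(year = years,
         population = 2e6 * (1 - 0.005)^(seq_along(years) - 1))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$subgroup, "\n", sep = "")
  cat(sprintf("  window %d-%02d .. %d-%02d, intervention from %d-%02d, seed %d\n",
              x$start[1], x$start[2], x$end[1], x$end[2],
              x$intervention[1], x$intervention[2], x$seed))
  invisible(x)
}

# deterministic mean curve shared by the simulator and by tests
true_mu <- function(params, scenario, with_effect = TRUE) {
  grid <- month_grid(scenario$start, scenario$end)
  x <- month_index_from(grid$year, grid$month,
                        scenario$start[1], scenario$start[2])
  eta <- params$beta0 + params$beta_trend * x
  for (k in seq_along(params$harmonics)) {
    h <- params$harmonics[[k]]
    eta <- eta + h[1] * sin(2 * pi * k * x / 12) +
      h[2] * cos(2 * pi * k * x / 12)
  }
  pop <- grid |>
    left_join(scenario$population, by = "year") |>
    pull(.data$population)
  theta <- rep(1, length(x))
  if (with_effect && length(params$effect_by_year)) {
    hit <- match(as.character(grid$year), names(params$effect_by_year))
    theta[!is.na(hit)] <- params$effect_by_year[hit[!is.na(hit)]]
  }
  iv_idx <- month_index_from(scenario$intervention[1], scenario$intervention[2],
                             scenario$start[1], scenario$start[2])
  theta[x < iv_idx] <- 1  # effect applies to intervention months only
  mu <- exp(eta) * pop * theta
  if (any(!is.finite(mu))) {
    bad <- which(!is.finite(mu))[1]
    abort(sprintf("non-finite mean at month %d-%02d; check coefficients",
                  grid$year[bad], grid$month[bad]))
  }
  tibble(month_index = x, year = grid$year, month = grid$month,
         period = ifelse(x < iv_idx, "pre", "post"),
         population = pop, mu = mu)
}

#' Simulate a monthly count series with known ground truth
#'
#' Draws one negative-binomial count per calendar month around the mean
#' \eqn{\mu_t} implied by `params` and the scenario's population schedule,
#' applying the per-year intervention effect \eqn{\theta} from the first
#' intervention month onward. The true \eqn{\mu_t} is returned alongside
#' the draw so downstream recovery can be asserted against it.
#'
#' @param params A [true_model_params()] object.
#' @param scenario A [scenario_config()] object; its seed drives the draws.
#' @return A tibble with one row per month: `subgroup`, `month_index`
#'   (0-based from the window start), `year`, `month`, `period`
#'   (`"pre"`/`"post"`), `population`, `mu` (true mean), `count`, `seed`.
#' @examples
#' sc <- scenario_config(seed = 7)
#' pars <- true_model_params(beta0 = log(110 / 2e6), beta_trend = -0.002,
#'                           harmonics = list(c(0.08, 0.05)))
#' head(simulate_monthly_counts(pars, sc))
#' @export
simulate_monthly_counts <- function(params, scenario) {
  stopifnot(inherits(params, "true_model_params"),
            inherits(scenario, "scenario_config"))
  base <- true_mu(params, scenario)
  counts <- withr_seed(scenario$seed, {
    rnbinom(nrow(base), mu = base$mu, size = params$dispersion)
  })
  base |>
    mutate(subgroup = scenario$subgroup, count = as.integer(counts),
           seed = scenario$seed, .before = 1)
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Default per-period attribute probabilities for the episode generator
#'
#' Category probabilities for each episode attribute in the pre and post
#' periods, shaped like a before/during characteristics table: sex,
#' death within 28 days, co-occurring mental-health condition category
#' (`none` plus four diagnostic groups), public-assistance pay code and
#' 5-level triage category. Values emulate a large urban ED self-harm
#' cohort in which the male share, mental-health comorbidity and
#' mid-urgency triage grow in the post period.
#'
#' @return Nested list `list(pre = ..., post = ...)`; within each period,
#'   one named probability vector per attribute, each summing to 1.
#' @export
default_attribute_probs <- function() {
  list(
    pre = list(
      sex = c(female = 0.53, male = 0.47),
      death28 = c(no = 0.983, yes = 0.017),
      mental_health = c(none = 0.39, mood = 0.27, neurosis = 0.16,
                        alcohol_drug = 0.12, psychotic_developmental = 0.06),
      pay_assist = c(no = 0.785, yes = 0.215),
      triage = c(`1` = 0.12, `2` = 0.39, `3` = 0.42, `4` = 0.068, `5` = 0.002)
    ),
    post = list(
      sex = c(female = 0.50, male = 0.50),
      death28 = c(no = 0.989, yes = 0.011),
      mental_health = c(none = 0.30, mood = 0.30, neurosis = 0.17,
                        alcohol_drug = 0.16, psychotic_developmental = 0.07),
      pay_assist = c(no = 0.794, yes = 0.206),
      triage = c(`1` = 0.08, `2` = 0.33, `3` = 0.52, `4` = 0.068, `5` = 0.002)
    )
  )
}

#' Simulate an episode-level table
#'
#' Generates one row per ED visit with a visit date uniform within its
#' period and categorical attributes drawn independently from per-period
#' probability vectors. Ages are drawn from a discretised bell curve
#' (median near 39) truncated to 0-99 years.
#'
#' @param n_pre,n_post Episode counts in the pre and post windows.
#' @param attribute_probs Per-period probability lists as returned by
#'   [default_attribute_probs()]; every vector must sum to 1 (tolerance
#'   1e-9).
#' @param pre_window,post_window Date pairs bounding the two periods.
#' @param seed Integer random seed.
#' @return A tibble of episode records: `attendance_date`, `sex`, `age`,
#'   mental-health flags (`mood`, `neurosis`, `alcohol_drug`,
#'   `psychotic_developmental`), `any_mh`, `death28`, `pay_assist`,
#'   `triage`, `period`, `seed`.
#' @examples
#' simulate_episode_table(n_pre = 0, n_post = 5, seed = 3)
#' @export
simulate_episode_table <- function(n_pre, n_post,
                                   attribute_probs = default_attribute_probs(),
                                   pre_window = as.Date(c("2016-01-01",
                                                          "2019-12-31")),
                                   post_window = as.Date(c("2020-01-01",
                                                           "2022-12-31")),
                                   seed = 1L) {
  if (n_pre < 0 || n_post < 0) abort("episode counts must be non-negative")
  for (period in c("pre", "post")) {
    for (attr in names(attribute_probs[[period]])) {
      p <- attribute_probs[[period]][[attr]]
      if (abs(sum(p) - 1) > 1e-9) {
        abort(sprintf("probabilities for '%s' (%s period) sum to %.12f, not 1",
                      attr, period, sum(p)))
      }
      if (any(p < 0)) abort(sprintf("negative probability in '%s'", attr))
    }
  }
  draw_period <- function(n, period, window) {
    if (n == 0) return(NULL)
    probs <- attribute_probs[[period]]
    days <- as.integer(window[2] - window[1])
    pick <- function(p) factor(sample(names(p), n, replace = TRUE, prob = p),
                               levels = names(p))
    mh <- pick(probs$mental_health)
    tibble(
      attendance_date = window[1] + sample.int(days + 1L, n, replace = TRUE) - 1L,
      sex = pick(probs$sex),
      age = as.integer(pmin(pmax(round(stats::rnorm(n, mean = 40, sd = 18)),
                                 0), 99)),
      mood = mh == "mood",
      neurosis = mh == "neurosis",
      alcohol_drug = mh == "alcohol_drug",
      psychotic_developmental = mh == "psychotic_developmental",
      death28 = pick(probs$death28) == "yes",
      pay_assist = pick(probs$pay_assist) == "yes",
      triage = as.integer(as.character(pick(probs$triage))),
      period = period
    )
  }
  out <- withr_seed(seed, {
    bind_rows(draw_period(n_pre, "pre", pre_window),
              draw_period(n_post, "post", post_window))
  })
  if (is.null(out) || ncol(out) == 0) {
    out <- tibble(attendance_date = as.Date(character()),
                  sex = factor(character(), c("female", "male")),
                  age = integer(), mood = logical(), neurosis = logical(),
                  alcohol_drug = logical(), psychotic_developmental = logical(),
                  death28 = logical(), pay_assist = logical(),
                  triage = integer(), period = character())
  }
  out |>
    mutate(any_mh = .data$mood | .data$neurosis | .data$alcohol_drug |
             .data$psychotic_developmental,
           .after = "psychotic_developmental") |>
    mutate(seed = seed)
}
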
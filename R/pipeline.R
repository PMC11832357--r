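#' Default ground-truth parameters for the synthetic scenario
#'
#' Emulates a large adult stratum: about 110 visits per month against a
#' ~2 million population, a mild downward trend, one annual harmonic of
#' moderate amplitude, clear overdispersion (size 25) and a
#' year-specific post-intervention rise.
#'
#' @return A [true_model_params()] object.
#' @export
default_true_params <- function() {
  true_model_params(
    beta0 = log(110 / 2e6),
    beta_trend = -0.002,
    harmonics = list(c(0.08, 0.05)),
    dispersion = 25,
    effect_by_year = c(`2020` = 1.58, `2021` = 2.64, `2022` = 3.13)
  )
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (usually read from a YAML file) with
#' either a `synthetic` block or an `inputs` block (never both), window
#' boundaries, subgroup definitions and run settings. See the package
#' vignette for the full schema.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "pipeline_config")) return(config)
  stopifnot(is.list(config))
  has_syn <- !is.null(config$synthetic)
  has_real <- !is.null(config$inputs)
  if (has_syn == has_real) {
    abort("config must contain exactly one of `synthetic` or `inputs`")
  }
  for (f in c("start", "end", "intervention")) {
    v <- config[[f]]
    if (is.null(v) || length(v) != 2) {
      abort(sprintf("config field `%s` must be c(year, month)", f))
    }
    config[[f]] <- as.integer(v)
  }
  i0 <- config$start[1] * 12 + config$start[2]
  i1 <- config$intervention[1] * 12 + config$intervention[2]
  i2 <- config$end[1] * 12 + config$end[2]
  if (!(i0 < i1 && i1 <= i2)) {
    abort("windows overlap or are out of order: need start < intervention <= end")
  }
  config$n_max <- as.integer(config$n_max %||% 3)
  config$replicates <- as.integer(config$replicates %||% 2000)
  config$seed <- as.integer(config$seed %||% 1)
  config$subgroups <- config$subgroups %||%
    list(list(name = "all", filter = "TRUE"))
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage: obtain episodes (synthetic or from files),
#' build the characteristics table, then per subgroup aggregate monthly
#' counts, interpolate the population offset, fit and select the model,
#' extrapolate the counterfactual and write the incidence-ratio table and
#' figure. Every output is stamped with the config hash and seed; any
#' stage failure aborts naming the stage and subgroup.
#'
#' @param config A [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @param out_dir Output directory, created if needed.
#' @param figures Write figures (PDF) as well as tables.
#' @return Invisibly, a list with `episodes`, `characteristics`,
#'   `series` (per-subgroup monthly counts), `fits`, `ir_table`, and
#'   `paths` of the files written.
#' @export
run_pipeline <- function(config, out_dir = tempfile("itsurv-run-"),
                         figures = TRUE) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash: %s seed: %d", rlang::hash(unclass(config)),
                   config$seed)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat(stamp, "\n", sep = "", file = logf)
  stage <- function(name, sub, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed for subgroup '%s': %s", name, sub,
                    conditionMessage(e)))
    })
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    log_line("stage simulate: synthetic scenario, seed %d", config$seed)
    episodes <- stage("simulate", "all", simulate_episode_table(
      n_pre = syn$n_pre %||% 4000, n_post = syn$n_post %||% 4300,
      pre_window = c(first_of_month(config$start[1], config$start[2]),
                     first_of_month(config$intervention[1],
                                    config$intervention[2]) - 1),
      post_window = c(first_of_month(config$intervention[1],
                                     config$intervention[2]),
                      last_of_month(config$end[1], config$end[2])),
      seed = config$seed
    ))
    population <- tibble(year = config$start[1]:config$end[1],
                         population = syn$population %||% 2e6,
                         anchor_type = "year")
  } else {
    log_line("stage read: %s", config$inputs$episodes)
    episodes <- stage("read_episodes", "all",
                      read_episodes(config$inputs$episodes,
                                    config$inputs$dialect))
    population <- stage("read_population", "all",
                        read_population(config$inputs$population))
  }

  # --- descriptive --------------------------------------------------------
  split_date <- first_of_month(config$intervention[1], config$intervention[2])
  characteristics <- stage("describe", "all",
                           build_characteristics_table(episodes, split_date))
  char_path <- file.path(out_dir, "characteristics.csv")
  write_characteristics_table(characteristics, char_path)
  log_line("stage describe: %d attributes", length(unique(characteristics$attribute)))

  # --- per-subgroup ITS ---------------------------------------------------
  monthly_pop <- interpolate_population(population, config$start, config$end)
  paths <- c(characteristics = char_path)
  fits <- list(); all_series <- list(); ir_rows <- list()
  for (sg in config$subgroups) {
    nm <- sg$name
    flt <- rlang::parse_expr(sg$filter %||% "TRUE")
    series <- stage("aggregate", nm, aggregate_monthly(
      episodes, config$start, config$end, config$intervention,
      !!flt, subgroup = nm))
    pop <- monthly_pop$population
    fit <- stage("fit", nm,
                 select_by_aic(series, pop[series$period == "pre"],
                               degrees = 0:config$n_max))
    log_line("stage fit [%s]: degree %d AIC %.3f", nm, fit$degree, fit$aic)
    irt <- stage("report", nm, incidence_ratio_table(
      fit, series, pop, replicates = config$replicates, seed = config$seed))
    series_path <- file.path(out_dir, sprintf("series-%s.csv", nm))
    readr::write_csv(series |> mutate(population = pop), series_path,
                     progress = FALSE)
    fit_path <- file.path(out_dir, sprintf("fit-%s.txt", nm))
    write_fit_summary(fit, fit_path)
    post <- series |> filter(.data$period == "post")
    expected <- predict_expected(
      fit, post |> select("month_index", "year", "month"),
      pop[series$period == "post"])
    exp_path <- file.path(out_dir, sprintf("expected-%s.csv", nm))
    readr::write_csv(expected, exp_path, progress = FALSE)
    if (figures) {
      fig_path <- file.path(out_dir, sprintf("figure-%s.pdf", nm))
      full_expected <- predict_expected(
        fit, series |> select("month_index", "year", "month"), pop)
      p <- plot_observed_vs_expected(series, full_expected, split_date, nm)
      ggplot2::ggsave(fig_path, p, width = 8, height = 4.5)
      paths[paste0("figure_", nm)] <- fig_path
    }
    paths[paste0("series_", nm)] <- series_path
    paths[paste0("fit_", nm)] <- fit_path
    paths[paste0("expected_", nm)] <- exp_path
    fits[[nm]] <- fit
    all_series[[nm]] <- series
    ir_rows[[nm]] <- irt
  }
  ir_table <- list_rbind(ir_rows)
  ir_path <- file.path(out_dir, "incidence-ratios.csv")
  readr::write_csv(ir_table, ir_path, progress = FALSE)
  paths["ir_table"] <- ir_path
  log_line("done: %d subgroup(s)", length(fits))
  invisible(list(episodes = episodes, characteristics = characteristics,
                 series = all_series, fits = fits, ir_table = ir_table,
                 paths = paths, out_dir = out_dir))
}

last_of_month <- function(year, month) {
  nxt <- if (month == 12) c(year + 1, 1) else c(year, month + 1)
  first_of_month(nxt[1], nxt[2]) - 1
}

#' Plot observed versus expected monthly counts
#'
#' Observed monthly counts as points, the model-expected series as a
#' line continuing through the post-intervention window, and a dashed
#' vertical rule at the intervention month.
#'
#' @param observed Monthly count tibble (`year`, `month`, `count`).
#' @param expected Tibble with `year`, `month`, `expected` (typically the
#'   full window from [predict_expected()]).
#' @param intervention_date Date of the first intervention day.
#' @param subgroup Label used in the title.
#' @return A ggplot object.
#' @export
plot_observed_vs_expected <- function(observed, expected, intervention_date,
                                      subgroup = "") {
  obs <- as_tibble(observed) |>
    mutate(date = first_of_month(.data$year, .data$month))
  exp_df <- as_tibble(expected) |>
    mutate(date = first_of_month(.data$year, .data$month))
  if (nrow(exp_df) > nrow(obs)) {
    abort("expected series longer than observed window")
  }
  if (!any(obs$date >= intervention_date)) {
    warn("no post-intervention months in the plotted window")
  }
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$count), colour = "black",
                        size = 1.2) +
    ggplot2::geom_line(data = exp_df, ggplot2::aes(y = .data$expected),
                       colour = "red", linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = as.numeric(intervention_date),
                        linetype = "dashed", colour = "black") +
    ggplot2::labs(x = "Month", y = "Monthly ED visits",
                  title = sprintf("Observed vs expected visits%s",
                                  if (nzchar(subgroup))
                                    paste0(" - ", subgroup) else "")) +
    ggplot2::theme_minimal()
}
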
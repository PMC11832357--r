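#' Read and validate an episode-level table
#'
#' Reads a comma-separated file with one row per ED visit and validates
#' every row. Validation is all-or-nothing: any unparseable date, unknown
#' sex code, negative age or out-of-range triage aborts with a report
#' naming each offending line, so no record is ever silently dropped.
#'
#' @param path Path to a CSV file with a header row and ISO-8601 dates.
#' @param dialect Named character vector mapping canonical column names
#'   (`attendance_date`, `sex`, `age`, `mood`, `neurosis`, `alcohol_drug`,
#'   `psychotic_developmental`, `death28`, `pay_assist`, `triage`) to the
#'   header names used in the file; defaults to the identity mapping.
#' @return A tibble of validated episode records with a derived `any_mh`
#'   column.
#' @export
read_episodes <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  canonical <- c("attendance_date", "sex", "age", "mood", "neurosis",
                 "alcohol_drug", "psychotic_developmental", "death28",
                 "pay_assist", "triage")
  dialect <- dialect %||% setNames(canonical, canonical)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing)) {
    abort(paste("episode file lacks column(s):", paste(missing, collapse = ", ")))
  }
  raw <- raw[, unname(dialect)]
  names(raw) <- names(dialect)
  if (nrow(raw) == 0) {
    return(simulate_episode_table(0, 0) |> select(-"period", -"seed"))
  }

  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  errs <- character()
  note <- function(bad, what) {
    if (any(bad)) {
      errs <<- c(errs, sprintf("line %d: %s", line[bad], what[bad]))
    }
  }

  date <- as.Date(raw$attendance_date, format = "%Y-%m-%d")
  note(is.na(date), sprintf("unparseable date '%s'", raw$attendance_date))
  sex_ok <- raw$sex %in% c("female", "male")
  note(!sex_ok, sprintf("unknown sex code '%s'", raw$sex))
  age <- suppressWarnings(as.integer(raw$age))
  note(is.na(age) | age < 0, sprintf("invalid age '%s'", raw$age))
  triage <- suppressWarnings(as.integer(raw$triage))
  note(is.na(triage) | !triage %in% 1:5,
       sprintf("triage '%s' outside 1-5", raw$triage))
  parse_flag <- function(col) {
    v <- tolower(raw[[col]])
    out <- ifelse(v %in% c("true", "1", "yes"), TRUE,
                  ifelse(v %in% c("false", "0", "no"), FALSE, NA))
    note(is.na(out), sprintf("invalid %s flag '%s'", col, raw[[col]]))
    out
  }
  flags <- lapply(c("mood", "neurosis", "alcohol_drug",
                    "psychotic_developmental", "death28", "pay_assist"),
                  parse_flag)
  if (length(errs)) {
    abort(c("episode file failed validation:", errs))
  }
  tibble(
    attendance_date = date,
    sex = factor(raw$sex, levels = c("female", "male")),
    age = age,
    mood = flags[[1]], neurosis = flags[[2]], alcohol_drug = flags[[3]],
    psychotic_developmental = flags[[4]],
    any_mh = flags[[1]] | flags[[2]] | flags[[3]] | flags[[4]],
    death28 = flags[[5]], pay_assist = flags[[6]],
    triage = triage
  )
}

#' Write an episode table to CSV
#'
#' Inverse of [read_episodes()]: ISO-8601 dates, lowercase sex levels,
#' logical flags as `TRUE`/`FALSE`.
#'
#' @param episodes Episode tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  episodes |>
    select(any_of(c("attendance_date", "sex", "age", "mood", "neurosis",
                    "alcohol_drug", "psychotic_developmental", "death28",
                    "pay_assist", "triage"))) |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' @importFrom dplyr any_of if_else
NULL

#' Assign the analysis age band
#'
#' Bands follow the study's subgroup definitions: teenagers 12-17,
#' young adults 18-24, adults 25-64, older adults 65-84, everything else
#' `out_of_band` (a value, not an error).
#'
#' @param age Integer vector of ages in years (>= 0).
#' @return Factor with levels `teen`, `young_adult`, `adult`,
#'   `older_adult`, `out_of_band`.
#' @examples
#' assign_age_band(c(11, 12, 17, 18, 24, 25, 64, 65, 84, 85))
#' @export
assign_age_band <- function(age) {
  if (any(age < 0, na.rm = TRUE)) abort("age must be non-negative")
  band <- dplyr::case_when(
    age >= 12 & age <= 17 ~ "teen",
    age >= 18 & age <= 24 ~ "young_adult",
    age >= 25 & age <= 64 ~ "adult",
    age >= 65 & age <= 84 ~ "older_adult",
    .default = "out_of_band"
  )
  factor(band, levels = c("teen", "young_adult", "adult", "older_adult",
                          "out_of_band"))
}

#' Aggregate episodes into a monthly count series
#'
#' Filters episodes with the supplied conditions, then counts them per
#' calendar month over the full window. Months with no qualifying episode
#' appear with count 0 — a count model cannot skip months — and each row
#' is tagged `pre` or `post` relative to the intervention month.
#'
#' @param episodes Episode tibble (needs `attendance_date`).
#' @param start,end `c(year, month)` bounds of the aggregation window.
#' @param intervention `c(year, month)` first month of the intervention
#'   window.
#' @param ... Optional filter conditions evaluated in the episode table,
#'   e.g. `sex == "male"`, `assign_age_band(age) == "adult"`,
#'   `alcohol_drug`.
#' @param subgroup Label stored on every row.
#' @return A tibble: `subgroup`, `month_index` (0-based), `year`, `month`,
#'   `period`, `count`.
#' @examples
#' eps <- simulate_episode_table(50, 40, seed = 2)
#' aggregate_monthly(eps, c(2016, 1), c(2022, 12), c(2020, 1),
#'                   sex == "male", subgroup = "male")
#' @export
aggregate_monthly <- function(episodes, start, end, intervention = end, ...,
                              subgroup = "all") {
  grid <- month_grid(start, end)
  if (nrow(grid) == 0) abort("empty aggregation window")
  kept <- episodes |>
    filter(...) |>
    mutate(year = as.integer(format(.data$attendance_date, "%Y")),
           month = as.integer(format(.data$attendance_date, "%m")))
  iv_idx <- month_index_from(intervention[1], intervention[2],
                             start[1], start[2])
  grid |>
    left_join(kept |> count(.data$year, .data$month, name = "count"),
              by = c("year", "month")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L),
           month_index = month_index_from(.data$year, .data$month,
                                          start[1], start[2]),
           period = ifelse(.data$month_index < iv_idx, "pre", "post"),
           subgroup = subgroup) |>
    select("subgroup", "month_index", "year", "month", "period", "count")
}

#' Read a population-denominator file
#'
#' Expects comma-separated columns `stratum`, `year`, `population`,
#' `anchor_type` (`year` for January-1 counts, `mid` for July-1 mid-year
#' counts).
#'
#' @param path CSV path.
#' @return Tibble with those columns.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  pop <- readr::read_csv(path, col_types = readr::cols(
    stratum = "c", year = "i", population = "d", anchor_type = "c"
  ), progress = FALSE)
  if (any(!pop$anchor_type %in% c("year", "mid"))) {
    abort("anchor_type must be 'year' or 'mid'")
  }
  if (any(pop$population <= 0)) abort("populations must be positive")
  pop
}

#' Interpolate yearly population anchors to months
#'
#' Piecewise-linear interpolation between anchors with constant
#' extrapolation beyond the outermost anchors. Yearly anchors sit at
#' January 1 and mid-year anchors at July 1; each month takes the
#' interpolant's value at its first day, so anchor months reproduce their
#' anchor values exactly. A single anchor falls back to a constant series
#' with a notice; non-positive anchors are a hard error.
#'
#' @param population Data frame with columns `year`, `population` and
#'   optionally `anchor_type` (`"year"` or `"mid"`, default `"year"`).
#' @param start,end `c(year, month)` bounds of the monthly series wanted.
#' @return Tibble `year`, `month`, `population`.
#' @examples
#' interpolate_population(data.frame(year = 2016:2017,
#'                                   population = c(1200, 1212)),
#'                        c(2016, 1), c(2017, 12))
#' @export
interpolate_population <- function(population, start, end) {
  population <- as_tibble(population)
  if (!"anchor_type" %in% names(population)) population$anchor_type <- "year"
  if (any(population$population <= 0)) {
    abort("population anchors must be positive")
  }
  at <- population$year + ifelse(population$anchor_type == "mid", 0.5, 0)
  grid <- month_grid(start, end)
  t_month <- month_decimal(grid$year, grid$month)
  if (nrow(population) < 1) abort("need at least one population anchor")
  if (nrow(population) == 1) {
    inform("single population anchor: using a constant monthly series")
    val <- rep(population$population, nrow(grid))
  } else {
    ord <- order(at)
    val <- approx(at[ord], population$population[ord], xout = t_month,
                  method = "linear", rule = 2)$y
  }
  grid |> mutate(population = val)
}
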
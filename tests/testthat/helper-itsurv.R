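# Shared fixtures: all generated in code, nothing on disk.

# short study window (36 pre months, 12 post) for fast model tests
quick_scenario <- function(seed = 1, population = 2e6, subgroup = "test") {
  scenario_config(start = c(2017, 1), end = c(2020, 12),
                  intervention = c(2020, 1), population = population,
                  subgroup = subgroup, seed = seed)
}

# full study-condition window: 48 pre months, 36 post
study_scenario <- function(seed = 1, population = default_population(2016:2022)) {
  scenario_config(start = c(2016, 1), end = c(2022, 12),
                  intervention = c(2020, 1), population = population,
                  seed = seed)
}

flat_params <- function(rate = 1e-4, dispersion = 1e9) {
  true_model_params(beta0 = log(rate), beta_trend = 0, harmonics = list(),
                    dispersion = dispersion)
}

# ten hand-written episode records with known attribute tallies:
# pre (2019): 3 female / 1 male, 1 death, 2 any_mh, 1 pay_assist
# post (2020): 2 female / 4 male, 0 deaths, 3 any_mh, 2 pay_assist
hand_episodes <- function() {
  tibble::tibble(
    attendance_date = as.Date(c("2019-01-15", "2019-03-02", "2019-07-09",
                                "2019-11-30", "2020-02-01", "2020-02-28",
                                "2020-06-15", "2020-09-01", "2020-12-25",
                                "2020-12-31")),
    sex = factor(c("female", "female", "female", "male",
                   "female", "female", "male", "male", "male", "male"),
                 levels = c("female", "male")),
    age = c(15L, 23L, 40L, 67L, 13L, 30L, 45L, 52L, 70L, 85L),
    mood = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    neurosis = FALSE,
    alcohol_drug = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                     FALSE, FALSE),
    psychotic_developmental = FALSE,
    death28 = c(TRUE, rep(FALSE, 9)),
    pay_assist = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
                   FALSE, FALSE),
    triage = c(2L, 3L, 3L, 1L, 2L, 3L, 4L, 3L, 2L, 5L)
  ) |>
    dplyr::mutate(any_mh = mood | neurosis | alcohol_drug |
                    psychotic_developmental,
                  .after = psychotic_developmental)
}

# independent Fisher oracle: two-sided p by explicit enumeration of every
# table compatible with the margins, probabilities from dhyper
fisher_enum_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - m2):min(m1, c1)
  probs <- dhyper(ks, m1, m2, c1)
  p_obs <- dhyper(a, m1, m2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent Mann-Whitney oracle: exact two-sided p by enumerating every
# assignment of the pooled values to the first sample
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
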
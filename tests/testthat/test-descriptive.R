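test_that("Fisher exact p matches the enumeration oracle on a small table", {
  res <- fisher_exact_2x2(1, 9, 11, 3)
  # frozen from the hypergeometric enumeration oracle at these margins
  expect_equal(res$p_value, 0.002759456, tolerance = 1e-6)
  expect_equal(res$p_value, fisher_enum_oracle(1, 9, 11, 3), tolerance = 1e-12)
  expect_lt(res$odds_ratio, 1)
})

test_that("Fisher exact agrees with enumeration and stats::fisher.test on random tables", {
  set.seed(401)
  for (i in 1:300) {
    m1 <- sample(1:30, 1); m2 <- sample(1:30, 1)
    a <- sample(0:m1, 1); c <- sample(0:m2, 1)
    b <- m1 - a; d <- m2 - c
    if (a + c == 0 || b + d == 0) next
    mine <- fisher_exact_2x2(a, b, c, d)
    expect_equal(mine$p_value, fisher_enum_oracle(a, b, c, d),
                 tolerance = 1e-10)
    ref <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-7)
    # fisher.test solves its conditional MLE at tol eps^0.25 (~1e-4), so
    # agreement is only expected to that precision
    expect_equal(mine$odds_ratio, unname(ref$estimate), tolerance = 2e-3)
  }
})

test_that("large balanced tables give p near 1 and huge cells stay precise", {
  even <- fisher_exact_2x2(5000, 5000, 5000, 5000)
  expect_gt(even$p_value, 0.95)
  big <- fisher_exact_2x2(8184, 7175, 8258, 8276)
  expect_lt(big$p_value, 0.001)
  ref <- stats::fisher.test(matrix(c(8184, 7175, 8258, 8276), 2,
                                   byrow = TRUE))$p.value
  expect_equal(big$p_value, ref, tolerance = 1e-7)
})

test_that("zero margins degrade to p = 1 with a flag", {
  expect_warning(res <- fisher_exact_2x2(0, 0, 5, 7), "degenerate")
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
})

test_that("Mann-Whitney exact case matches full enumeration", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 3)  # 2/6 rank arrangements as extreme
  expect_equal(res$method, "exact")
  set.seed(402)
  for (i in 1:25) {
    x <- sample(100, 6); y <- setdiff(sample(100, 12), x)[1:5]
    expect_equal(mann_whitney_u(x, y)$p_value, mw_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(403)
  x <- rpois(40, 9); y <- rpois(35, 12)  # ties force the midrank path
  base <- mann_whitney_u(x, y)
  expect_equal(base$method, "normal")
  for (f in list(function(v) exp(v), function(v) v^3 + 5,
                 function(v) log(v + 1))) {
    expect_equal(mann_whitney_u(f(x), f(y))$p_value, base$p_value,
                 tolerance = 1e-12)
    expect_equal(mann_whitney_u(f(x), f(y))$U, base$U)
  }
})

test_that("Mann-Whitney degenerate and symmetric inputs give p = 1", {
  expect_warning(res <- mann_whitney_u(rep(3, 5), rep(3, 8)), "identical")
  expect_equal(res$p_value, 1)
  same <- mann_whitney_u(c(1, 2, 3, 7), c(1, 2, 3, 7))
  expect_equal(same$p_value, 1)
})

test_that("Mann-Whitney tie-corrected normal p tracks stats::wilcox.test", {
  set.seed(404)
  for (i in 1:20) {
    x <- sample(1:5, 30, replace = TRUE)
    y <- sample(1:5, 45, replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                               exact = FALSE))
    expect_equal(mann_whitney_u(x, y)$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney detects a strong shift essentially always", {
  rejections <- sapply(1:60, function(s) {
    set.seed(6000 + s)
    x <- rnorm(80); y <- rnorm(80, mean = 2)
    mann_whitney_u(x, y)$p_value < 0.001
  })
  expect_gte(mean(rejections), 0.99)
})

test_that("characteristics table matches a hand tally and conserves totals", {
  tab <- build_characteristics_table(hand_episodes(), as.Date("2020-01-01"))
  get <- function(attr, lvl) tab[tab$attribute == attr & tab$level == lvl, ]
  expect_equal(get("total", "episodes")$n_pre, 4)
  expect_equal(get("total", "episodes")$n_post, 6)
  expect_equal(get("sex", "female")$n_pre, 3)
  expect_equal(get("sex", "male")$n_post, 4)
  expect_equal(get("death28", "yes")$n_pre, 1)
  expect_equal(get("any_mh", "yes")$n_post, 3)
  expect_equal(get("pay_assist", "yes")$n_post, 2)
  expect_equal(get("triage", "3")$n_pre, 2)
  # level counts sum to the period totals within each attribute
  sums <- tab |>
    dplyr::filter(!attribute %in% c("total", "age")) |>
    dplyr::group_by(attribute) |>
    dplyr::summarise(pre = sum(n_pre), post = sum(n_post))
  expect_true(all(sums$pre == 4) && all(sums$post == 6))
  # percents recompute from counts under half-up display rounding
  expect_equal(get("sex", "female")$percent_pre, round_half_up(100 * 3 / 4))
})

test_that("period with zero episodes is an error", {
  pre_only <- hand_episodes() |>
    dplyr::filter(attendance_date < as.Date("2020-01-01"))
  expect_error(build_characteristics_table(pre_only, as.Date("2020-01-01")),
               "at least one episode")
})

test_that("null episode generator calibrates the table's Fisher p-values", {
  probs <- default_attribute_probs()
  probs$post <- probs$pre  # identical attribute laws in both periods
  pvals <- sapply(1:200, function(s) {
    eps <- simulate_episode_table(150, 150, attribute_probs = probs,
                                  seed = 7000 + s)
    tab <- suppressWarnings(
      build_characteristics_table(eps, as.Date("2020-01-01")))
    tab$p_value[tab$attribute == "sex" & tab$level == "female"]
  })
  # roughly uniform: conservative rejection at .05, mass near the middle
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals < 0.05), 0.0)
  expect_gt(mean(pvals < 0.6), 0.4)
})

test_that("display percentages use half-up rounding", {
  expect_equal(round_half_up(53.28), 53)
  expect_equal(round_half_up(70.5), 71)
  expect_equal(round_half_up(7.6502, 1), 7.7)
  expect_equal(round_half_up(-2.5), -3)  # away from zero
})

test_that("characteristics table writes CSV plus a readable report", {
  tab <- build_characteristics_table(hand_episodes(), as.Date("2020-01-01"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_characteristics_table(tab, path)
  expect_true(file.exists(path))
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tab))
  txt <- readLines(sub("\\.csv$", ".txt", path))
  expect_match(txt[1], "Characteristics")
  expect_gt(length(txt), nrow(tab))
})
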
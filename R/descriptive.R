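#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-ordering rule: conditional on both
#' margins, sum the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-7 for ties). Probabilities are evaluated in
#' log-gamma arithmetic, so cells of order 1e4 lose no precision. The
#' point estimate is the conditional maximum-likelihood odds ratio.
#'
#' @param a,b,c,d Cell counts, row-wise: `a`,`b` on row 1, `c`,`d` on
#'   row 2. All must be non-negative.
#' @param odds_ratio Compute the conditional MLE odds ratio (default
#'   `TRUE`; turning it off skips the root-solve when only the p-value is
#'   wanted, e.g. in large sweeps).
#' @return A tibble with `odds_ratio`, `p_value`, and `degenerate`
#'   (`TRUE` when a margin is zero, in which case `p_value = 1` by
#'   convention).
#' @examples
#' fisher_exact_2x2(1, 9, 11, 3)
#' @export
fisher_exact_2x2 <- function(a, b, c, d, odds_ratio = TRUE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("cells must be non-negative integers")
  }
  m1 <- a + b; m2 <- c + d; c1 <- a + c; c2 <- b + d
  row1 <- function(or, p, deg) {
    tibble::new_tibble(list(odds_ratio = or, p_value = p, degenerate = deg),
                       nrow = 1L)
  }
  if (m1 == 0 || m2 == 0 || c1 == 0 || c2 == 0) {
    warn("degenerate 2x2 table (zero margin); p = 1 by convention")
    return(row1(NA_real_, 1, TRUE))
  }
  n <- m1 + m2
  lo <- max(0L, c1 - m2)
  hi <- min(m1, c1)
  support <- lo:hi
  # log P(A = k | margins), via log-gamma (lchoose)
  logp <- lchoose(m1, support) + lchoose(m2, c1 - support) - lchoose(n, c1)
  logp_obs <- logp[support == a]
  p <- sum(exp(logp[logp <= logp_obs + 1e-7]))
  or <- if (odds_ratio) cond_mle_odds_ratio(a, m1, m2, c1, support, logp)
        else NA_real_
  row1(or, min(p, 1), FALSE)
}

# conditional MLE of the odds ratio under the noncentral hypergeometric law
cond_mle_odds_ratio <- function(a, m1, m2, c1, support, logp0) {
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  mean_a <- function(log_or) {
    w <- logp0 + support * log_or
    w <- exp(w - max(w))
    sum(support * w) / sum(w)
  }
  f <- function(log_or) mean_a(log_or) - a
  exp(stats::uniroot(f, c(-50, 50), tol = 1e-10)$root)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank ties. The statistic `U` counts pairs
#' \eqn{(x_i, y_j)} with \eqn{x_i > y_j} plus half the ties (the U
#' associated with the first sample). The two-sided p-value uses the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction; when both samples have at most 8 observations and the
#' pooled data has no ties, the exact permutation distribution of U is
#' used instead.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A tibble with `U`, `p_value`, `method` (`"exact"` or
#'   `"normal"`), and `degenerate` (`TRUE` when all pooled values are
#'   identical, in which case `p_value = 1`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (all(pooled == pooled[1])) {
    warn("all pooled values identical; p = 1")
    return(tibble(U = u, p_value = 1, method = "degenerate",
                  degenerate = TRUE))
  }
  ties <- any(duplicated(pooled))
  if (n1 <= 8 && n2 <= 8 && !ties) {
    # exact: P(U <= u) from the null permutation distribution
    p <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                        1 - stats::pwilcox(u - 1, n1, n2)))
    return(tibble(U = u, p_value = p, method = "exact", degenerate = FALSE))
  }
  n <- n1 + n2
  tie_sizes <- table(pooled)
  sigma2 <- n1 * n2 / 12 *
    ((n + 1) - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  tibble(U = u, p_value = min(1, 2 * pnorm(-abs(z))), method = "normal",
         degenerate = FALSE)
}

#' Before/during characteristics table
#'
#' Splits episodes at `split_date` and compares the two periods the way a
#' cohort's baseline table does: Fisher exact tests for the binary
#' attributes (sex, death within 28 days, any mental-health condition,
#' public-assistance pay code), Mann-Whitney U on the raw values for age
#' and for the ordinal triage codes. Percentages are recomputed from
#' counts and rounded half-up only in the `percent_*` display columns.
#'
#' @param episodes Episode tibble (as from [read_episodes()] or
#'   [simulate_episode_table()]).
#' @param split_date First date of the post period.
#' @return A tibble with one row per attribute level: `attribute`,
#'   `level`, `n_pre`, `percent_pre`, `n_post`, `percent_post`, `test`,
#'   `p_value` (repeated within attribute).
#' @examples
#' eps <- simulate_episode_table(300, 300, seed = 5)
#' build_characteristics_table(eps, as.Date("2020-01-01"))
#' @export
build_characteristics_table <- function(episodes, split_date) {
  pre <- episodes |> filter(.data$attendance_date < split_date)
  post <- episodes |> filter(.data$attendance_date >= split_date)
  if (nrow(pre) == 0 || nrow(post) == 0) {
    abort("each period must contain at least one episode")
  }
  total_pre <- nrow(pre); total_post <- nrow(post)

  binary_row <- function(attr, value_of) {
    vp <- value_of(pre); vq <- value_of(post)
    ft <- fisher_exact_2x2(sum(!vp), sum(!vq), sum(vp), sum(vq))
    tibble(
      attribute = attr,
      level = c("no", "yes"),
      n_pre = c(sum(!vp), sum(vp)),
      n_post = c(sum(!vq), sum(vq)),
      test = "fisher_exact",
      p_value = ft$p_value
    )
  }
  rank_row <- function(attr, value_of, levels) {
    mw <- mann_whitney_u(value_of(pre), value_of(post))
    tibble(
      attribute = attr,
      level = as.character(levels),
      n_pre = vapply(levels, function(l) sum(value_of(pre) == l), integer(1)),
      n_post = vapply(levels, function(l) sum(value_of(post) == l), integer(1)),
      test = "mann_whitney",
      p_value = mw$p_value
    )
  }
  age_row <- {
    mw <- mann_whitney_u(pre$age, post$age)
    tibble(attribute = "age", level = "years",
           n_pre = total_pre, n_post = total_post,
           test = "mann_whitney", p_value = mw$p_value)
  }
  sex_row <- {
    ft <- fisher_exact_2x2(sum(pre$sex == "female"), sum(post$sex == "female"),
                           sum(pre$sex == "male"), sum(post$sex == "male"))
    tibble(attribute = "sex", level = c("female", "male"),
           n_pre = c(sum(pre$sex == "female"), sum(pre$sex == "male")),
           n_post = c(sum(post$sex == "female"), sum(post$sex == "male")),
           test = "fisher_exact", p_value = ft$p_value)
  }
  out <- bind_rows(
    tibble(attribute = "total", level = "episodes", n_pre = total_pre,
           n_post = total_post, test = NA_character_, p_value = NA_real_),
    age_row,
    sex_row,
    binary_row("death28", function(d) d$death28),
    binary_row("any_mh", function(d) d$any_mh),
    binary_row("pay_assist", function(d) d$pay_assist),
    rank_row("triage", function(d) d$triage, 1:5)
  )
  out |>
    mutate(percent_pre = round_half_up(100 * .data$n_pre / total_pre),
           percent_post = round_half_up(100 * .data$n_post / total_post),
           .after = "n_post")
}

#' Write a characteristics table as CSV and a plain-text report
#'
#' @param table Output of [build_characteristics_table()].
#' @param path CSV output path; a `.txt` report is written next to it.
#' @return `path`, invisibly.
#' @export
write_characteristics_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  lines <- c("Characteristics before vs during the intervention period",
             sprintf("%-12s %-10s %10s (%3s%%) %10s (%3s%%)  %-13s %s",
                     "attribute", "level", "pre", "", "post", "", "test", "p"))
  fmt_p <- function(p) ifelse(is.na(p), "", ifelse(p < 0.001, "<.001",
                                                   sprintf("%.3f", p)))
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    lines <- c(lines, sprintf("%-12s %-10s %10d (%3.0f%%) %10d (%3.0f%%)  %-13s %s",
                              r$attribute, r$level, r$n_pre, r$percent_pre,
                              r$n_post, r$percent_post,
                              ifelse(is.na(r$test), "", r$test),
                              fmt_p(r$p_value)))
  }
  writeLines(lines, txt)
  invisible(path)
}
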
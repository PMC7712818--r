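# Process-dissociation U/D, traditional scores, and supporting statistics.

pd_battery <- function(subject_id, action_fn) {
  b <- battery_spec()
  tibble::tibble(
    subject_id = subject_id, base_id = b$base_id, norm = b$norm,
    benefits = b$benefits, response = action_fn(b)
  )
}

test_that("U and D follow the printed formulas on aggregate proportions", {
  low <- counts_from_means(low_means, 188)
  pd <- pd_from_counts(low)
  expect_equal(pd$p_unacceptable_congruent, 1 - 1.56 / 6, tolerance = 1e-12)
  expect_equal(pd$p_unacceptable_incongruent, 1 - 2.46 / 6, tolerance = 1e-12)
  expect_equal(round(pd$U, 2), 0.15)
  expect_equal(round(pd$D, 2), 0.69)

  high <- counts_from_means(high_means, 174)
  pdh <- pd_from_counts(high)
  expect_equal(round(pdh$U, 2), 0.14)
})

test_that("per-subject scores handle the pure and degenerate cases", {
  # pure deontologist: every proscriptive action judged unacceptable
  deon <- pd_battery("s1", function(b) {
    as.integer(b$norm == "prescriptive")
  })
  pd <- pd_scores(deon)
  expect_equal(pd$U, 0)
  expect_equal(pd$D, 1)

  # perfect utilitarian discrimination: unacceptable|congruent = 1 (all
  # congruent inaction), unacceptable|incongruent = 0 -> U = 1, D undefined
  split <- pd_battery("s1", function(b) {
    as.integer(b$benefits == "greater")
  })
  expect_message(pd <- pd_scores(split), "U = 1")
  expect_equal(pd$U, 1)
  expect_true(is.na(pd$D))

  pre_only <- pd_battery("s1", function(b) rep(1L, nrow(b)))
  pre_only <- pre_only[pre_only$norm == "prescriptive", ]
  expect_error(pd_scores(pre_only), class = "moralmpt_value_error")
})

test_that("group-mean U from subjects equals U from pooled proportions", {
  withr::local_seed(91)
  cohort <- purrr::map_dfr(1:20, function(i) {
    pd_battery(sprintf("s%02d", i), function(b) rbinom(nrow(b), 1, 0.5))
  })
  per_subject <- pd_scores(cohort)
  pooled <- pd_from_counts(aggregate_counts(cohort))
  expect_equal(mean(per_subject$U), pooled$U, tolerance = 1e-12)
})

test_that("the PD parameters are algebraic functions of the CNI tree", {
  grid <- expand.grid(C = seq(0.05, 0.95, 0.15), N = seq(0.05, 0.95, 0.15),
                      I = seq(0.05, 0.95, 0.15))
  for (i in seq_len(nrow(grid))) {
    th <- as.numeric(grid[i, ])
    p <- p_action_oracle(th[1], th[2], th[3])
    u <- (1 - p[2]) - (1 - p[1])
    d <- (1 - p[1]) / (1 - u)
    expect_equal(u, th[1], tolerance = 1e-12)                     # U = C
    expect_equal(d, th[2] + (1 - th[2]) * th[3], tolerance = 1e-12) # D = N+(1-N)I
  }
})

test_that("simulated tree cohorts reproduce U = C and D = N + (1-N)I", {
  withr::local_seed(101)
  th <- c(0.15, 0.40, 0.49)
  counts <- simulate_counts(th, 1e5)
  pd <- pd_from_counts(counts)
  expect_equal(pd$U, th[1], tolerance = 0.01)
  expect_equal(pd$D, th[2] + (1 - th[2]) * th[3], tolerance = 0.01)
})

test_that("traditional scores count incongruent proscriptive actions", {
  all_action <- pd_battery("s1", function(b) rep(1L, nrow(b)))
  expect_equal(traditional_scores(all_action)$T, 6L)
  none <- pd_battery("s1", function(b) rep(0L, nrow(b)))
  expect_equal(traditional_scores(none)$T, 0L)

  # cohort built to a target frequency reproduces the group mean
  withr::local_seed(103)
  n_sub <- 50
  target <- c(2.46, 1.56, 4.51, 3.60)
  cohort <- purrr::map_dfr(seq_len(n_sub), function(i) {
    pd_battery(sprintf("s%02d", i), function(b) rbinom(nrow(b), 1, 0.5))
  })
  # overwrite type-A responses so exactly mean 2.46 actions per subject
  idx <- cohort$norm == "proscriptive" & cohort$benefits == "greater"
  per <- round(target[1] * n_sub) # 123 actions among 300 type-A trials
  resp <- c(rep(1L, per), rep(0L, sum(idx) - per))
  cohort$response[idx] <- resp
  trad <- traditional_scores(cohort)
  expect_equal(mean(trad$T), per / n_sub, tolerance = 1e-12)
  counts <- aggregate_counts(cohort)
  expect_equal(counts$n_action[1] / n_sub, per / n_sub)
})

test_that("pooled t and Cohen's d match the summary-statistic formulas", {
  d <- cohens_d_from_stats(84.21, 6.39, 174, 47.44, 6.28, 188)
  expect_true(d >= 5.80 && d <= 5.81)
  expect_equal(cohens_d_from_stats(5, 1, 10, 5, 1, 10), 0)
  expect_equal(cohens_d_from_stats(1, 1, 2, 0, 1, 2), 1)
  expect_error(cohens_d_from_stats(1, 1, 1, 0, 1, 5),
               class = "moralmpt_value_error")

  withr::local_seed(111)
  a <- rnorm(12, 1); b <- rnorm(15)
  res <- two_group_t(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p.value, ref$p.value)
  expect_equal(res$cohens.d,
               cohens_d_from_stats(mean(a), sd(a), 12, mean(b), sd(b), 15))
  welch <- two_group_t(a, b, welch = TRUE)
  expect_equal(welch$df, unname(t.test(a, b)$parameter))

  same <- two_group_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p.value, 1)
  # degenerate zero-variance case warns twice (for d and for t)
  inf <- suppressWarnings(two_group_t(c(3, 3), c(1, 1)))
  expect_identical(inf$t, Inf)
  expect_identical(inf$cohens.d, Inf)
  expect_identical(inf$p.value, 0)

  # antisymmetry under group swap
  expect_equal(two_group_t(b, a)$cohens.d, -res$cohens.d)
})

test_that("the pooled t p-value agrees with a permutation oracle", {
  withr::local_seed(121)
  a <- rnorm(15, 0.8); b <- rnorm(15)
  res <- two_group_t(a, b)
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  perm <- replicate(4000, {
    idx <- sample(30, 15)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  perm_p <- mean(perm >= obs - 1e-12)
  expect_lt(abs(res$p.value - perm_p), 0.03)
})

test_that("Pearson correlation validates input and matches hand values", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(1:3, 1:4), class = "moralmpt_value_error")
  expect_error(pearson_r(c(1, 1, 1), 1:3), class = "moralmpt_value_error")
})

test_that("Cronbach's alpha spans its degenerate and ideal regimes", {
  x <- c(1, 5, 3, 2, 4)
  expect_equal(cronbach_alpha(cbind(x, x, x))$alpha, 1)
  expect_equal(cronbach_alpha(rbind(c(1, 2), c(2, 3), c(3, 4)))$alpha, 1)

  withr::local_seed(131)
  noise <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(abs(cronbach_alpha(noise)$alpha), 0.1)

  expect_error(cronbach_alpha(matrix(1, 4, 3)),
               class = "moralmpt_value_error")
  expect_error(cronbach_alpha(matrix(rnorm(4), 1, 4)),
               class = "moralmpt_value_error")
})
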
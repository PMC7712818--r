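# CNI tree probabilities, G-squared, and single-group maximum likelihood.

test_that("tree probabilities match the branch structure at limiting cases", {
  # pure consequence-follower: acts iff benefits exceed costs
  expect_equal(cni_probabilities(c(1, 0.3, 0.7))$p_action, c(1, 0, 1, 0))
  # pure inaction / pure action bias
  expect_equal(cni_probabilities(c(0, 0, 1))$p_action, c(0, 0, 0, 0))
  expect_equal(cni_probabilities(c(0, 0, 0))$p_action, c(1, 1, 1, 1))
  # pure norm-follower
  expect_equal(cni_probabilities(c(0, 1, 0.5))$p_action, c(0, 0, 1, 1))

  # parameters near the low-psychopathy aggregate reproduce its proportions
  p <- cni_probabilities(c(0.151, 0.401, 0.489))$p_action
  expect_equal(p, c(0.410, 0.260, 0.751, 0.600), tolerance = 1e-3)

  expect_error(cni_probabilities(c(1.2, 0.5, 0.5)),
               class = "moralmpt_value_error")
  expect_error(cni_probabilities(c(0.5, NA, 0.5)),
               class = "moralmpt_value_error")
})

test_that("tree identities and monotonicities hold across the parameter cube", {
  withr::local_seed(41)
  grid <- expand.grid(C = seq(0, 1, 0.2), N = seq(0, 1, 0.2),
                      I = seq(0, 1, 0.2))
  grid <- rbind(grid, matrix(runif(3 * 50), ncol = 3,
                             dimnames = list(NULL, c("C", "N", "I"))))
  eps <- 1e-4
  for (i in seq_len(nrow(grid))) {
    th <- as.numeric(grid[i, ])
    p <- cni_probabilities(th)$p_action
    expect_true(all(p >= -1e-12 & p <= 1 + 1e-12))
    # conservation + model identity p1 + p4 = p2 + p3
    expect_equal(p[1] + p[4], p[2] + p[3], tolerance = 1e-12)
    expect_equal(p, p_action_oracle(th[1], th[2], th[3]), tolerance = 1e-12)

    bump <- function(j) {
      th2 <- th; th2[j] <- min(th[j] + eps, 1)
      cni_probabilities(th2)$p_action - p
    }
    dC <- bump(1); dN <- bump(2); dI <- bump(3)
    expect_true(all(dC[c(1, 3)] >= -1e-12) && all(dC[c(2, 4)] <= 1e-12))
    expect_true(all(dN[c(3, 4)] >= -1e-12) && all(dN[c(1, 2)] <= 1e-12))
    expect_true(all(dI <= 1e-12))
  }
})

test_that("G-squared agrees with the direct formula and its conventions", {
  # saturation: counts exactly proportional to the model probabilities
  th <- c(0.3, 0.6, 0.4)
  p <- p_action_oracle(0.3, 0.6, 0.4)
  counts <- make_counts(400 * p, rep(400, 4))
  expect_equal(cni_g_squared(counts, th), 0, tolerance = 1e-10)

  # direct-formula oracle on small integer counts
  counts <- make_counts(c(3, 1, 4, 2), rep(4, 4))
  th <- c(0.5, 0.5, 0.5)
  expect_equal(cni_g_squared(counts, th),
               g2_oracle(c(3, 1, 4, 2), rep(4, 4),
                         p_action_oracle(0.5, 0.5, 0.5)),
               tolerance = 1e-12)

  # a type with no observations contributes nothing
  empty_type <- make_counts(c(3, 1, 4, 0), c(4, 4, 4, 0))
  expect_equal(cni_g_squared(empty_type, th),
               g2_oracle(c(3, 1, 4, 0), c(4, 4, 4, 0),
                         p_action_oracle(0.5, 0.5, 0.5)),
               tolerance = 1e-12)

  # expected probability 0 with observed count -> infinite with warning
  expect_warning(
    inf_g2 <- cni_g_squared(make_counts(c(4, 1, 4, 0), rep(4, 4)),
                            c(1, 0.5, 0.5)),
    "infinite"
  )
  expect_identical(inf_g2, Inf)
})

test_that("noiseless counts are recovered to optimizer precision", {
  th <- c(C = 0.2, N = 0.6, I = 0.4)
  counts <- make_counts(600 * p_action_oracle(0.2, 0.6, 0.4), rep(600, 4))
  fit <- cni_fit(counts)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates), unname(th), tolerance = 1e-6)
  expect_lte(fit$g2, 1e-8)
  expect_equal(fit$df, 1L)
  expect_equal(fit$p_value, chisq_sf(fit$g2, 1))

  expect_error(cni_fit(make_counts(rep(0, 4), rep(0, 4))),
               class = "moralmpt_estimation_error")
})

test_that("the optimizer matches an exhaustive grid search on small counts", {
  cases <- list(
    list(n_action = c(30, 12, 45, 27), n_total = rep(60, 4)),
    list(n_action = c(10, 2, 18, 9), n_total = rep(20, 4)),
    list(n_action = c(25, 13, 39, 33), n_total = rep(60, 4))
  )
  for (cs in cases) {
    fit <- cni_fit(make_counts(cs$n_action, cs$n_total), se = FALSE)
    grid <- grid_g2_min(cs$n_action, cs$n_total)
    expect_lte(fit$g2, grid$g2 + 1e-8) # continuous optimum beats the grid
    expect_lte(abs(fit$g2 - grid$g2), 0.002)
    expect_equal(unname(fit$estimates), unname(grid$par), tolerance = 0.005)
  }
})

test_that("Wald intervals shrink with n, clamp at bounds, and match a bootstrap", {
  # consistency limit: interval width goes to zero at huge n
  p <- p_action_oracle(0.3, 0.6, 0.4)
  small <- cni_fit(make_counts(200 * p, rep(200, 4)))
  huge <- cni_fit(make_counts(2e6 * p, rep(2e6, 4)))
  expect_true(all(huge$ci[, 2] - huge$ci[, 1] <
                    (small$ci[, 2] - small$ci[, 1]) / 50))

  # boundary clamp
  clamped <- small
  clamped$estimates[] <- c(0.01, 0.5, 0.5)
  clamped$std_errors[] <- c(0.02, 0.1, 0.1)
  ci <- wald_ci(clamped, 0.95)
  expect_equal(unname(ci$conf.low[1]), 0)
  expect_error(wald_ci(clamped, 1.2), class = "moralmpt_value_error")

  # parametric bootstrap oracle at the symmetric point
  withr::local_seed(51)
  th <- c(0.5, 0.5, 0.5)
  n_total <- 200
  p <- p_action_oracle(0.5, 0.5, 0.5)
  fit <- cni_fit(make_counts(n_total * p, rep(n_total, 4)))
  boot <- replicate(2000, {
    cnt <- make_counts(rbinom(4, n_total, p), rep(n_total, 4))
    cni_fit(cnt, n_starts = 1, se = FALSE)$estimates
  })
  boot_se <- apply(boot, 1, sd)
  expect_equal(unname(fit$std_errors), unname(boot_se), tolerance = 0.1)
})

test_that("the EQN export reproduces the tree probabilities branch by branch", {
  path <- withr::local_tempfile(fileext = ".eqn")
  write_eqn(path)
  lines <- readLines(path)
  expect_equal(as.integer(lines[1]), length(lines) - 1)

  # evaluate each branch product independently and re-sum per category
  th <- c(C = 0.37, N = 0.22, I = 0.81)
  eval_branch <- function(formula) {
    terms <- strsplit(formula, "*", fixed = TRUE)[[1]]
    prod(vapply(terms, function(term) {
      term <- gsub("[()]", "", term)
      if (grepl("^1-", term)) 1 - th[[sub("^1-", "", term)]] else th[[term]]
    }, numeric(1)))
  }
  parts <- strsplit(lines[-1], " ")
  cat_p <- tapply(
    vapply(parts, function(x) eval_branch(x[3]), numeric(1)),
    vapply(parts, function(x) x[2], character(1)),
    sum
  )
  p <- unname(p_action_oracle(th[[1]], th[[2]], th[[3]]))
  expect_equal(as.numeric(cat_p[c("pro_greater_action", "pro_smaller_action",
                                  "pre_greater_action", "pre_smaller_action")]),
               p, tolerance = 1e-12)
  expect_equal(as.numeric(cat_p[c("pro_greater_inaction", "pro_smaller_inaction",
                                  "pre_greater_inaction",
                                  "pre_smaller_inaction")]),
               1 - p, tolerance = 1e-12)
})

test_that("tidy, glance and autoplot expose the fit consistently", {
  fit <- cni_fit(counts_from_means(low_means, 188))
  td <- tidy(fit)
  expect_equal(td$term, c("C", "N", "I"))
  expect_equal(td$estimate, unname(fit$estimates))
  expect_true(all(td$conf.low >= 0 & td$conf.high <= 1))
  gl <- glance(fit)
  expect_equal(gl$g.squared, fit$g2)
  expect_equal(gl$nobs, 188 * 24)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_action_proportions(counts_from_means(low_means, 188),
                                          fit), "ggplot")
})
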
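# The CNI multinomial processing tree: category probabilities, G-squared,
# and single-group maximum-likelihood estimation.
#
# Tree (per response): with probability C the consequences drive the choice
# (action iff benefits > costs); otherwise with probability N the norm drives
# it (proscriptive -> inaction, prescriptive -> action); otherwise a general
# response bias yields inaction with probability I. Writing a = C,
# b = (1-C)N, c = (1-C)(1-N)(1-I), the action probabilities per type are
#   proscriptive/greater  a + c
#   proscriptive/smaller  c
#   prescriptive/greater  a + b + c
#   prescriptive/smaller  b + c
# which satisfy p1 + p4 = p2 + p3 identically.

validate_cni_params <- function(params) {
  params <- unlist(params)
  if (length(params) != 3 || !is.numeric(params)) {
    stop_value("CNI parameters must be 3 numbers (C, N, I).")
  }
  if (anyNA(params) || any(params < 0 | params > 1)) {
    stop_value("CNI parameters must lie in [0, 1].")
  }
  setNames(as.numeric(params), .cni_params)
}

# length-4 action-probability vector in canonical type order
cni_p_action <- function(params) {
  C <- params[[1]]; N <- params[[2]]; I <- params[[3]]
  a <- C
  b <- (1 - C) * N
  cc <- (1 - C) * (1 - N) * (1 - I)
  c(a + cc, cc, a + b + cc, b + cc)
}

#' Model-implied action probabilities of the CNI tree
#'
#' @param params CNI parameters: a numeric vector or list `(C, N, I)`, each
#'   in `[0, 1]`.
#' @return A tibble with columns `norm`, `benefits`, `p_action` (4 rows in
#'   canonical type order).
#' @export
#' @examples
#' cni_probabilities(c(C = 0.15, N = 0.40, I = 0.49))
cni_probabilities <- function(params) {
  params <- validate_cni_params(params)
  out <- dilemma_types()
  out$p_action <- cni_p_action(params)
  out
}

# product-binomial log-likelihood over the four types; real counts allowed
binomial_loglik <- function(n_action, n_total, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  n_inact <- n_total - n_action
  sum(n_action * log(p) + n_inact * log(1 - p))
}

saturated_loglik <- function(n_action, n_total) {
  pos <- n_total > 0
  n_action <- n_action[pos]; n_total <- n_total[pos]
  p_hat <- n_action / n_total
  term <- function(k, p) ifelse(k > 0, k * log(p), 0)
  sum(term(n_action, p_hat) + term(n_total - n_action, 1 - p_hat))
}

g2_stat <- function(n_action, n_total, p) {
  pos <- n_total > 0
  if (!any(pos)) return(0)
  zero_expected <- (p[pos] == 0 & n_action[pos] > 0) |
    (p[pos] == 1 & (n_total - n_action)[pos] > 0)
  if (any(zero_expected)) {
    warn("Expected count 0 with positive observed count; G^2 is infinite.")
    return(Inf)
  }
  2 * (saturated_loglik(n_action, n_total) -
         binomial_loglik(n_action[pos], n_total[pos], p[pos]))
}

#' G-squared goodness of fit of CNI parameters to observed counts
#'
#' `G^2 = 2 * sum(observed * log(observed / expected))` over the action and
#' inaction cells of the four dilemma types, with `0 * log(0) = 0`; a type
#' with `n_total = 0` contributes nothing. Returns `Inf` (with a warning) when
#' a cell has expected probability 0 but a positive observed count.
#'
#' @param counts A counts tibble for a single group (see
#'   [aggregate_counts()], [counts_from_means()]).
#' @param params CNI parameters `(C, N, I)`.
#' @return A nonnegative number.
#' @export
cni_g_squared <- function(counts, params) {
  params <- validate_cni_params(params)
  x <- single_group_counts(counts)
  g2_stat(x$n_action, x$n_total, cni_p_action(params))
}

single_group_counts <- function(counts) {
  by_group <- counts_by_group(counts)
  if (length(by_group) != 1) {
    stop_value("Expected counts for a single group; use cni_fit_joint() for several.")
  }
  by_group[[1]]
}

# deterministic multi-start lattice on the unit cube
start_lattice <- function(n_starts) {
  lattice <- rbind(
    c(0.50, 0.50, 0.50),
    c(0.25, 0.25, 0.25),
    c(0.75, 0.75, 0.75),
    c(0.25, 0.75, 0.50),
    c(0.75, 0.25, 0.50),
    c(0.50, 0.25, 0.75),
    c(0.50, 0.75, 0.25),
    c(0.25, 0.50, 0.75),
    c(0.75, 0.50, 0.25),
    c(0.10, 0.90, 0.50)
  )
  lattice[seq_len(min(n_starts, nrow(lattice))), , drop = FALSE]
}

minimize_g2 <- function(objective, n_free, n_starts, extra_starts = NULL) {
  lattice <- start_lattice(n_starts)
  starts <- lapply(seq_len(nrow(lattice)), function(i) {
    rep_len(lattice[i, ], n_free)
  })
  starts <- c(starts, extra_starts)
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, objective, method = "L-BFGS-B", lower = 0, upper = 1,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    better <- is.null(best) ||
      res$value < best$value - 1e-10 ||
      (abs(res$value - best$value) <= 1e-10 &&
         isTRUE(all(res$par <= best$par)) && any(res$par < best$par))
    if (better) best <- res
  }
  if (is.null(best)) stop_estimation("All optimizer starts failed.")
  best
}

#' Fit the CNI model to a single group by maximum likelihood
#'
#' Minimizes `G^2` (equivalently, maximizes the product-binomial likelihood of
#' the aggregated counts) over the unit cube, using bounded quasi-Newton
#' optimization from a fixed lattice of starting points. Standard errors come
#' from the inverse observed information (numerical Hessian of the negative
#' log-likelihood at the optimum); Wald intervals are truncated to `[0, 1]`.
#'
#' The aggregate likelihood treats responses as independent within type,
#' ignoring subject clustering — adequate for homogeneous cohorts, and the
#' convention of the standard aggregate MPT analysis, but standard errors are
#' anti-conservative under strong between-subject heterogeneity.
#'
#' @param counts Counts tibble for one group, all four types observed.
#' @param n_starts Number of lattice starts (1-10, default 10).
#' @param level Confidence level for Wald intervals (default 0.95).
#' @param se Compute standard errors and intervals? (Skip for speed in large
#'   simulations.)
#' @return An object of class `cni_fit` with elements `estimates` (named
#'   vector C, N, I), `std_errors`, `ci` (matrix), `g2`, `df` (= 1), `p_value`,
#'   `loglik`, `converged`, `n_starts`, `counts`, `level`.
#' @seealso [tidy.cni_fit()], [glance.cni_fit()], [autoplot.cni_fit()],
#'   [cni_test_point()], [cni_fit_joint()]
#' @export
#' @examples
#' counts <- counts_from_means(c(2.46, 1.56, 4.51, 3.60), 188)
#' fit <- cni_fit(counts)
#' round(fit$estimates, 2)
cni_fit <- function(counts, n_starts = 10, level = 0.95, se = TRUE) {
  x <- single_group_counts(counts)
  if (all(x$n_total == 0)) stop_estimation("All counts are zero; nothing to fit.")
  if (any(x$n_total == 0)) {
    warn("A dilemma type has no observations; the fit uses the remaining types.")
  }

  # clamped objective: finite everywhere on the cube (g2_stat's exact
  # infinity at degenerate expected counts would break the line search)
  sat <- saturated_loglik(x$n_action, x$n_total)
  objective <- function(par) {
    2 * (sat - binomial_loglik(x$n_action, x$n_total, cni_p_action(par)))
  }
  best <- minimize_g2(objective, n_free = 3, n_starts = n_starts)
  est <- setNames(pmin(pmax(best$par, 0), 1), .cni_params)
  g2 <- max(best$value, 0)
  df <- 1L
  out <- structure(
    list(
      estimates = est,
      std_errors = setNames(rep(NA_real_, 3), .cni_params),
      ci = NULL,
      g2 = g2,
      df = df,
      p_value = pchisq(g2, df, lower.tail = FALSE),
      loglik = binomial_loglik(x$n_action, x$n_total, cni_p_action(est)),
      converged = best$convergence == 0,
      n_starts = n_starts,
      counts = new_counts(x$n_action, x$n_total),
      level = level
    ),
    class = "cni_fit"
  )
  if (se) {
    out$std_errors <- cni_std_errors(x, est)
    out$ci <- wald_interval(est, out$std_errors, level)
  }
  out
}

cni_std_errors <- function(x, est) {
  nll <- function(par) {
    par <- pmin(pmax(par, 0), 1)
    -binomial_loglik(x$n_action, x$n_total, cni_p_action(par))
  }
  se <- rep(NA_real_, 3)
  hess <- tryCatch(optimHess(est, nll), error = function(e) NULL)
  if (!is.null(hess)) {
    cov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se <- ifelse(d >= 0, sqrt(d), NA_real_)
    }
  }
  if (anyNA(se)) {
    warn("Observed information is singular or unstable; some standard errors unavailable.")
  }
  setNames(se, .cni_params)
}

wald_interval <- function(est, se, level) {
  z <- qnorm((1 + level) / 2)
  ci <- cbind(
    lower = pmin(pmax(est - z * se, 0), 1),
    upper = pmin(pmax(est + z * se, 0), 1)
  )
  rownames(ci) <- names(est)
  ci
}

#' Wald confidence intervals for a fitted CNI model
#'
#' @param fit A `cni_fit` object.
#' @param level Confidence level in `(0, 1)`.
#' @return A tibble `term`, `conf.low`, `conf.high`; bounds truncated to
#'   `[0, 1]`. Terms with unavailable standard errors get `NA` bounds.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "cni_fit"))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop_value("`level` must lie in (0, 1).")
  }
  ci <- wald_interval(fit$estimates, fit$std_errors, level)
  tibble::tibble(
    term = rownames(ci),
    conf.low = ci[, "lower"],
    conf.high = ci[, "upper"]
  )
}

#' @export
print.cni_fit <- function(x, digits = 2, ...) {
  cat("CNI model fit (single group)\n")
  est <- round(x$estimates, digits)
  se <- round(x$std_errors, max(digits, 3))
  for (p in .cni_params) {
    cat(sprintf("  %s = %.*f (SE %.3f)\n", p, digits, est[[p]], se[[p]]))
  }
  cat(sprintf("  G^2(%d) = %.3f, p = %.3f\n", x$df, x$g2, x$p_value))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' Tidy a CNI fit
#'
#' @param x A `cni_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.cni_fit <- function(x, ...) {
  ci <- x$ci %||% wald_interval(x$estimates, x$std_errors, x$level)
  tibble::tibble(
    term = .cni_params,
    estimate = unname(x$estimates),
    std.error = unname(x$std_errors),
    conf.low = unname(ci[, "lower"]),
    conf.high = unname(ci[, "upper"])
  )
}

#' Glance at a CNI fit
#'
#' @param x A `cni_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `g.squared`, `df`, `p.value`, `logLik`,
#'   `converged`, `n.starts`, `nobs`.
#' @export
glance.cni_fit <- function(x, ...) {
  tibble::tibble(
    g.squared = x$g2,
    df = x$df,
    p.value = x$p_value,
    logLik = x$loglik,
    converged = x$converged,
    n.starts = x$n_starts,
    nobs = sum(x$counts$n_total)
  )
}

#' Write the CNI tree as an EQN model file
#'
#' Emits the standard MPT model-file dialect (one line per branch: tree
#' number, category label, product of parameter terms) so the tree can be
#' cross-checked in general MPT software.
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eqn <- function(path) {
  branches <- c(
    # tree 1: proscriptive / benefits greater
    "1 pro_greater_action C",
    "1 pro_greater_action (1-C)*(1-N)*(1-I)",
    "1 pro_greater_inaction (1-C)*N",
    "1 pro_greater_inaction (1-C)*(1-N)*I",
    # tree 2: proscriptive / benefits smaller
    "2 pro_smaller_action (1-C)*(1-N)*(1-I)",
    "2 pro_smaller_inaction C",
    "2 pro_smaller_inaction (1-C)*N",
    "2 pro_smaller_inaction (1-C)*(1-N)*I",
    # tree 3: prescriptive / benefits greater
    "3 pre_greater_action C",
    "3 pre_greater_action (1-C)*N",
    "3 pre_greater_action (1-C)*(1-N)*(1-I)",
    "3 pre_greater_inaction (1-C)*(1-N)*I",
    # tree 4: prescriptive / benefits smaller
    "4 pre_smaller_action (1-C)*N",
    "4 pre_smaller_action (1-C)*(1-N)*(1-I)",
    "4 pre_smaller_inaction C",
    "4 pre_smaller_inaction (1-C)*(1-N)*I"
  )
  writeLines(c(length(branches), branches), path)
  invisible(path)
}
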
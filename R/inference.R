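# Multi-group CNI fitting with equality / fixed-value constraints and
# likelihood-ratio (delta G-squared) tests.

#' Constrain a CNI parameter to be equal across groups
#'
#' @param parameter One of `"C"`, `"N"`, `"I"`.
#' @return A constraint object for [cni_fit_joint()].
#' @export
equal_constraint <- function(parameter) {
  parameter <- match.arg(parameter, .cni_params)
  structure(list(kind = "equal", parameter = parameter, value = NULL),
            class = "cni_constraint")
}

#' Fix a CNI parameter at a given value
#'
#' @param parameter One of `"C"`, `"N"`, `"I"`.
#' @param value A value in `[0, 1]`.
#' @return A constraint object for [cni_fit_joint()].
#' @export
fixed_constraint <- function(parameter, value) {
  parameter <- match.arg(parameter, .cni_params)
  if (!is.numeric(value) || length(value) != 1 || value < 0 || value > 1) {
    stop_value("Constraint `value` must lie in [0, 1].")
  }
  structure(list(kind = "fixed", parameter = parameter, value = value),
            class = "cni_constraint")
}

validate_constraints <- function(constraints) {
  if (inherits(constraints, "cni_constraint")) constraints <- list(constraints)
  if (!is.list(constraints) ||
      !all(vapply(constraints, inherits, logical(1), "cni_constraint"))) {
    stop_spec("`constraints` must be a list of equal_constraint()/fixed_constraint() objects.")
  }
  params <- vapply(constraints, `[[`, character(1), "parameter")
  if (anyDuplicated(params)) {
    stop_spec("Contradictory constraints: a parameter is constrained more than once.")
  }
  constraints
}

# Build the free-parameter layout for a constrained multi-group fit.
# Returns list(n_free, expand(theta) -> G x 3 matrix, start(lattice_row),
# slot_of[group, param] index into theta or 0 for fixed).
constraint_layout <- function(constraints, n_groups) {
  kind <- setNames(rep("free", 3), .cni_params)
  value <- setNames(rep(NA_real_, 3), .cni_params)
  for (cst in constraints) {
    kind[cst$parameter] <- cst$kind
    if (cst$kind == "fixed") value[cst$parameter] <- cst$value
  }
  slot <- matrix(0L, nrow = n_groups, ncol = 3,
                 dimnames = list(NULL, .cni_params))
  param_of_slot <- integer(0)
  k <- 0L
  for (j in seq_along(.cni_params)) {
    p <- .cni_params[j]
    if (kind[p] == "fixed") next
    if (kind[p] == "equal") {
      k <- k + 1L
      slot[, j] <- k
      param_of_slot[k] <- j
    } else {
      for (g in seq_len(n_groups)) {
        k <- k + 1L
        slot[g, j] <- k
        param_of_slot[k] <- j
      }
    }
  }
  expand <- function(theta) {
    m <- matrix(rep(value, each = n_groups), nrow = n_groups,
                dimnames = list(NULL, .cni_params))
    m[slot > 0] <- theta[slot[slot > 0]]
    m
  }
  list(n_free = k, expand = expand, slot = slot, param_of_slot = param_of_slot)
}

#' Fit the CNI model jointly to several groups
#'
#' Maximizes the summed product-binomial log-likelihood over all groups,
#' subject to optional equality-across-groups or fixed-value constraints.
#' With no constraints this is equivalent to independent single-group fits;
#' the baseline goodness of fit is the summed `G^2` on `n_groups` degrees of
#' freedom.
#'
#' @param counts Counts tibble with a `group` column (or a single group).
#' @param constraints List of [equal_constraint()] / [fixed_constraint()]
#'   objects (default none).
#' @param n_starts Lattice starts per optimization (default 10).
#' @param level Confidence level for Wald intervals.
#' @param se Compute standard errors?
#' @param extra_starts Optional list of additional start vectors in the free
#'   parameterization (used internally to warm-start constrained fits).
#' @return An object of class `cni_fit_joint`: `estimates` (tibble
#'   group x C, N, I), `std_errors` (same shape), `g2` (summed), `g2_by_group`,
#'   `df`, `p_value`, `loglik`, `converged`, `constraints`, `counts`.
#' @export
cni_fit_joint <- function(counts, constraints = list(), n_starts = 10,
                          level = 0.95, se = TRUE, extra_starts = NULL) {
  by_group <- counts_by_group(counts)
  groups <- names(by_group)
  n_groups <- length(groups)
  if (n_groups < 1) stop_spec("Need at least one group.")
  for (x in by_group) {
    if (all(x$n_total == 0)) stop_estimation("A group has all-zero counts.")
  }
  constraints <- validate_constraints(constraints)
  layout <- constraint_layout(constraints, n_groups)

  sat <- vapply(by_group, function(x) saturated_loglik(x$n_action, x$n_total),
                numeric(1))
  neg_ll <- function(theta) {
    m <- layout$expand(theta)
    -sum(vapply(seq_len(n_groups), function(g) {
      binomial_loglik(by_group[[g]]$n_action, by_group[[g]]$n_total,
                      cni_p_action(m[g, ]))
    }, numeric(1)))
  }
  objective <- function(theta) 2 * (sum(sat) + neg_ll(theta))

  if (layout$n_free > 0) {
    lattice <- start_lattice(n_starts)
    starts <- lapply(seq_len(nrow(lattice)), function(i) {
      lattice[i, layout$param_of_slot]
    })
    starts <- c(starts, extra_starts)
    best <- NULL
    for (s in starts) {
      res <- tryCatch(
        optim(s, objective, method = "L-BFGS-B", lower = 0, upper = 1,
              control = list(factr = 1e4, maxit = 1000)),
        error = function(e) NULL
      )
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best)) stop_estimation("All optimizer starts failed.")
    theta <- pmin(pmax(best$par, 0), 1)
    converged <- best$convergence == 0
  } else {
    theta <- numeric(0)
    converged <- TRUE
  }

  m <- layout$expand(theta)
  g2_by_group <- vapply(seq_len(n_groups), function(g) {
    x <- by_group[[g]]
    max(2 * (sat[g] - binomial_loglik(x$n_action, x$n_total,
                                      cni_p_action(m[g, ]))), 0)
  }, numeric(1))
  g2 <- sum(g2_by_group)
  df <- as.integer(4L * n_groups - layout$n_free)

  se_mat <- matrix(NA_real_, n_groups, 3, dimnames = list(NULL, .cni_params))
  if (se && layout$n_free > 0) {
    hess <- tryCatch(optimHess(theta, neg_ll), error = function(e) NULL)
    cov <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se_theta <- ifelse(d >= 0, sqrt(d), NA_real_)
      se_mat[layout$slot > 0] <- se_theta[layout$slot[layout$slot > 0]]
    }
  }

  est_tbl <- tibble::as_tibble(as.data.frame(m))
  est_tbl <- tibble::add_column(est_tbl, group = groups, .before = 1)
  se_tbl <- tibble::as_tibble(as.data.frame(se_mat))
  se_tbl <- tibble::add_column(se_tbl, group = groups, .before = 1)

  structure(
    list(
      estimates = est_tbl,
      std_errors = se_tbl,
      g2 = g2,
      g2_by_group = setNames(g2_by_group, groups),
      df = df,
      p_value = pchisq(g2, df, lower.tail = FALSE),
      loglik = -neg_ll(theta),
      converged = converged,
      n_free = layout$n_free,
      constraints = constraints,
      counts = counts,
      level = level,
      theta = theta,
      layout_slot = layout$slot
    ),
    class = "cni_fit_joint"
  )
}

#' @export
print.cni_fit_joint <- function(x, digits = 2, ...) {
  cat("CNI model joint fit (", nrow(x$estimates), " group(s), ",
      length(x$constraints), " constraint(s))\n", sep = "")
  print(dplyr::mutate(x$estimates,
                      dplyr::across(dplyr::all_of(.cni_params),
                                    ~ round(.x, digits))))
  cat(sprintf("  G^2(%d) = %.3f, p = %.3f\n", x$df, x$g2, x$p_value))
  invisible(x)
}

#' @export
tidy.cni_fit_joint <- function(x, ...) {
  est <- tidyr::pivot_longer(x$estimates, dplyr::all_of(.cni_params),
                             names_to = "term", values_to = "estimate")
  se <- tidyr::pivot_longer(x$std_errors, dplyr::all_of(.cni_params),
                            names_to = "term", values_to = "std.error")
  out <- dplyr::left_join(est, se, by = c("group", "term"))
  z <- qnorm((1 + x$level) / 2)
  dplyr::mutate(out,
    conf.low = pmin(pmax(.data$estimate - z * .data$std.error, 0), 1),
    conf.high = pmin(pmax(.data$estimate + z * .data$std.error, 0), 1)
  )
}

#' @export
glance.cni_fit_joint <- function(x, ...) {
  tibble::tibble(
    g.squared = x$g2,
    df = x$df,
    p.value = x$p_value,
    logLik = x$loglik,
    converged = x$converged,
    n.groups = nrow(x$estimates),
    n.free = x$n_free
  )
}

new_lrtest <- function(g2_delta, df, p_value, unconstrained, constrained,
                       description) {
  structure(
    list(
      g2_delta = g2_delta,
      df = as.integer(df),
      p_value = p_value,
      fits = list(unconstrained = unconstrained, constrained = constrained),
      description = description
    ),
    class = "cni_lrtest"
  )
}

# warm start for a constrained fit: unconstrained estimates mapped into the
# constrained free parameterization (equality slots take the weighted mean)
constrained_warm_start <- function(unconstrained, constraints, by_group) {
  est <- as.matrix(unconstrained$estimates[, .cni_params])
  w <- vapply(by_group, function(x) sum(x$n_total), numeric(1))
  layout <- constraint_layout(constraints, nrow(est))
  theta <- numeric(layout$n_free)
  for (j in seq_along(.cni_params)) {
    for (g in seq_len(nrow(est))) {
      k <- layout$slot[g, j]
      if (k > 0) {
        theta[k] <- if (sum(layout$slot[, j] == k) > 1) {
          sum(w * est[, j]) / sum(w)
        } else {
          est[g, j]
        }
      }
    }
  }
  list(pmin(pmax(theta, 0), 1))
}

#' Likelihood-ratio test of parameter equality across groups
#'
#' Compares the unconstrained multi-group fit with the fit constraining one
#' CNI parameter to a common value across groups. The statistic
#' `delta G^2 = G^2(constrained) - G^2(unconstrained)` is referred to a
#' chi-square distribution with `n_groups - 1` degrees of freedom.
#'
#' @param counts Counts tibble with a `group` column (>= 2 groups).
#' @param parameter One of `"C"`, `"N"`, `"I"`.
#' @param ... Passed to [cni_fit_joint()] (e.g. `n_starts`, `se`).
#' @return A `cni_lrtest` object: `g2_delta`, `df`, `p_value`, `fits`
#'   (unconstrained and constrained `cni_fit_joint`s).
#' @export
#' @examples
#' counts <- dplyr::bind_rows(
#'   counts_from_means(c(3.00, 2.18, 3.91, 3.21), 174, group = "high"),
#'   counts_from_means(c(2.46, 1.56, 4.51, 3.60), 188, group = "low")
#' )
#' cni_test_equality(counts, "N", se = FALSE)
cni_test_equality <- function(counts, parameter, ...) {
  parameter <- match.arg(parameter, .cni_params)
  by_group <- counts_by_group(counts)
  if (length(by_group) < 2) {
    stop_spec("Equality tests need at least 2 groups.")
  }
  unc <- cni_fit_joint(counts, constraints = list(), ...)
  cst <- list(equal_constraint(parameter))
  con <- cni_fit_joint(
    counts, constraints = cst,
    extra_starts = constrained_warm_start(unc, cst, by_group), ...
  )
  delta <- max(con$g2 - unc$g2, 0)
  df <- length(by_group) - 1L
  new_lrtest(delta, df, pchisq(delta, df, lower.tail = FALSE), unc, con,
             paste0("equality of ", parameter, " across groups"))
}

#' Likelihood-ratio test of a point hypothesis on one parameter
#'
#' Compares the free single-group fit with the fit fixing one parameter at
#' `value` (for example, I = 0.5: no response bias; C = 0: no sensitivity to
#' consequences). One degree of freedom.
#'
#' @param counts Counts tibble for a single group.
#' @param parameter One of `"C"`, `"N"`, `"I"`.
#' @param value Hypothesized value in `[0, 1]`. At the boundary (0 or 1) the
#'   chi-square reference distribution is only approximate, and a warning is
#'   issued.
#' @param ... Passed to [cni_fit_joint()].
#' @return A `cni_lrtest` object.
#' @export
cni_test_point <- function(counts, parameter, value, ...) {
  parameter <- match.arg(parameter, .cni_params)
  if (!is.numeric(value) || length(value) != 1 || value < 0 || value > 1) {
    stop_value("`value` must lie in [0, 1].")
  }
  by_group <- counts_by_group(counts)
  if (length(by_group) != 1) {
    stop_spec("Point tests apply to a single group's counts.")
  }
  unc <- cni_fit_joint(counts, constraints = list(), ...)
  cst <- list(fixed_constraint(parameter, value))
  con <- cni_fit_joint(
    counts, constraints = cst,
    extra_starts = constrained_warm_start(unc, cst, by_group), ...
  )
  if (value %in% c(0, 1)) {
    warn("Hypothesized value on the parameter boundary: the chi-square p-value is approximate.")
  }
  delta <- max(con$g2 - unc$g2, 0)
  new_lrtest(delta, 1L, pchisq(delta, 1, lower.tail = FALSE), unc, con,
             paste0(parameter, " = ", value))
}

#' @export
print.cni_lrtest <- function(x, ...) {
  cat("Likelihood-ratio test:", x$description, "\n")
  cat(sprintf("  delta G^2(%d) = %.3f, p = %.4g\n", x$df, x$g2_delta,
              x$p_value))
  invisible(x)
}

#' @export
tidy.cni_lrtest <- function(x, ...) {
  tibble::tibble(
    test = x$description,
    statistic = x$g2_delta,
    df = x$df,
    p.value = x$p_value
  )
}

#' @export
glance.cni_lrtest <- function(x, ...) tidy(x, ...)

#' Machine-readable report of a likelihood-ratio test
#'
#' @param x A `cni_lrtest`.
#' @param path Optional path; when given, the JSON is written there.
#' @return A JSON string (class `json`), invisibly when `path` is given.
#' @export
lrtest_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cni_lrtest"))
  payload <- list(
    model = "CNI",
    test = x$description,
    groups = x$fits$unconstrained$estimates$group,
    g2_delta = x$g2_delta,
    df = x$df,
    p = x$p_value,
    estimates = x$fits$unconstrained$estimates,
    constrained_estimates = x$fits$constrained$estimates
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Upper-tail chi-square probability
#'
#' @param statistic Nonnegative test statistic.
#' @param df Positive degrees of freedom.
#' @return `P(X >= statistic)` for `X ~ chi-square(df)`.
#' @export
#' @examples
#' chisq_sf(1.356, 1) # 0.244
chisq_sf <- function(statistic, df) {
  if (!is.numeric(statistic) || any(statistic < 0)) {
    stop_value("`statistic` must be nonnegative.")
  }
  if (!is.numeric(df) || any(df <= 0)) {
    stop_value("`df` must be positive.")
  }
  pchisq(statistic, df, lower.tail = FALSE)
}
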
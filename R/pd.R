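# Process-dissociation U/D parameters, traditional dilemma scoring, and
# supporting statistics (pooled t, Cohen's d, Pearson r, Cronbach's alpha).
#
# PD works on the proscriptive dilemmas only. "Unacceptable" is the inaction
# response there (the norm forbids the action). Incongruent = benefits
# greater than costs (the utilitarian and deontological processes disagree);
# congruent = benefits smaller (they agree).
#   U = p(unacceptable | congruent) - p(unacceptable | incongruent)
#   D = p(unacceptable | incongruent) / (1 - U),  undefined when U = 1.

pd_from_props <- function(p_cong, p_incong) {
  u <- p_cong - p_incong
  d <- ifelse(abs(1 - u) < .Machine$double.eps^0.5, NA_real_,
              p_incong / (1 - u))
  list(U = u, D = d)
}

#' Per-subject process-dissociation scores
#'
#' Computes, for each subject, the proportion of "unacceptable" (= inaction)
#' responses to congruent and incongruent proscriptive dilemmas and the
#' derived utilitarian (U) and deontological (D) tendencies. `D` is `NA` when
#' `U = 1` (no non-utilitarian responses to normalize by); the number of such
#' subjects is reported via a message.
#'
#' @param responses Response tibble (see [read_responses()]).
#' @return A tibble with columns `subject_id`, `p_unacceptable_congruent`,
#'   `p_unacceptable_incongruent`, `U`, `D`.
#' @export
pd_scores <- function(responses) {
  responses <- validate_responses(responses)
  pro <- responses[responses$norm == "proscriptive", ]
  if (nrow(pro) == 0) {
    stop_value("No proscriptive responses: PD scores are undefined.")
  }
  per <- pro |>
    dplyr::group_by(.data$subject_id, .data$benefits) |>
    dplyr::summarise(p_unacc = 1 - mean(.data$response), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "benefits", values_from = "p_unacc")
  if (!all(c("greater", "smaller") %in% names(per)) ||
      anyNA(per$greater) || anyNA(per$smaller)) {
    bad <- if (!"greater" %in% names(per)) {
      per$subject_id
    } else {
      per$subject_id[is.na(per$greater) | is.na(per$smaller)]
    }
    stop_value(paste0(
      "Subject(s) without both congruent and incongruent proscriptive ",
      "responses: ", paste(head(bad, 3), collapse = ", "),
      if (length(bad) > 3) ", ..." else "", "."
    ))
  }
  pd <- pd_from_props(per$smaller, per$greater)
  n_undef <- sum(is.na(pd$D))
  if (n_undef > 0) {
    message(n_undef, " subject(s) with U = 1: D undefined (NA).")
  }
  tibble::tibble(
    subject_id = per$subject_id,
    p_unacceptable_congruent = per$smaller,
    p_unacceptable_incongruent = per$greater,
    U = pd$U,
    D = pd$D
  )
}

#' Process-dissociation parameters from aggregate counts
#'
#' The same U/D formulas applied to group-level action proportions (one U and
#' D per group). Note the group-aggregate D is a ratio of means, which is not
#' the mean of per-subject D ratios (Jensen gap).
#'
#' @param counts Counts tibble, optionally with a `group` column.
#' @return A tibble with one row per group: `group`,
#'   `p_unacceptable_congruent`, `p_unacceptable_incongruent`, `U`, `D`.
#' @export
#' @examples
#' pd_from_counts(counts_from_means(c(2.46, 1.56, 4.51, 3.60), 188))
pd_from_counts <- function(counts) {
  by_group <- counts_by_group(counts)
  purrr::imap_dfr(by_group, function(x, g) {
    if (x$n_total[1] == 0 || x$n_total[2] == 0) {
      stop_value("PD from counts needs both proscriptive types observed.")
    }
    p_incong <- 1 - x$n_action[1] / x$n_total[1] # proscriptive/greater
    p_cong <- 1 - x$n_action[2] / x$n_total[2]   # proscriptive/smaller
    pd <- pd_from_props(p_cong, p_incong)
    tibble::tibble(
      group = g,
      p_unacceptable_congruent = p_cong,
      p_unacceptable_incongruent = p_incong,
      U = pd$U, D = pd$D
    )
  })
}

#' Traditional dilemma scores
#'
#' The traditional analysis scores each subject by the number of action
#' responses to the incongruent proscriptive dilemmas (benefits greater than
#' costs, norm forbids action); action there is read as a utilitarian
#' judgment.
#'
#' @param responses Response tibble.
#' @return A tibble `subject_id`, `T` (0-6 for a complete battery).
#' @export
traditional_scores <- function(responses) {
  responses <- validate_responses(responses)
  inc <- responses[responses$norm == "proscriptive" &
                     responses$benefits == "greater", ]
  if (nrow(inc) == 0) {
    stop_value("No incongruent proscriptive responses: traditional score undefined.")
  }
  inc |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(T = sum(.data$response), .groups = "drop")
}

#' Cohen's d from group summary statistics
#'
#' `d = (m1 - m2) / s_pooled` with the pooled standard deviation
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return A single number.
#' @export
#' @examples
#' cohens_d_from_stats(84.21, 6.39, 174, 47.44, 6.28, 188)
cohens_d_from_stats <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop_value("Group sizes must be at least 2.")
  if (s1 < 0 || s2 < 0) stop_value("Standard deviations must be nonnegative.")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    if (m1 == m2) return(0)
    warn("Zero pooled SD with unequal means: Cohen's d is infinite.")
    return(sign(m1 - m2) * Inf)
  }
  (m1 - m2) / sp
}

#' Two-sample t test with Cohen's d
#'
#' Student's pooled-variance two-sample t test (two-sided) plus the pooled
#' Cohen's d. Set `welch = TRUE` for the Welch unequal-variance test; d is
#' always the pooled-SD version.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param welch Use the Welch test instead of the pooled Student test?
#' @return A one-row tibble: `t`, `df`, `p.value`, `cohens.d`, `mean.a`,
#'   `mean.b`, `sd.a`, `sd.b`, `n.a`, `n.b`.
#' @export
two_group_t <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop_value("Each group needs at least 2 values.")
  }
  m <- c(mean(values_a), mean(values_b))
  s <- c(sd(values_a), sd(values_b))
  n <- c(length(values_a), length(values_b))
  d <- cohens_d_from_stats(m[1], s[1], n[1], m[2], s[2], n[2])

  if (s[1] == 0 && s[2] == 0) {
    # degenerate: t.test refuses constant data
    if (m[1] == m[2]) {
      t_stat <- 0; p <- 1
    } else {
      warn("Zero variance in both groups with unequal means: t is infinite.")
      t_stat <- sign(m[1] - m[2]) * Inf; p <- 0
    }
    df <- n[1] + n[2] - 2
  } else {
    ht <- stats::t.test(values_a, values_b, var.equal = !welch)
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  tibble::tibble(
    t = t_stat, df = df, p.value = p, cohens.d = d,
    mean.a = m[1], mean.b = m[2], sd.a = s[1], sd.b = s[2],
    n.a = n[1], n.b = n[2]
  )
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return The sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_value("`x` and `y` must have equal length.")
  if (length(x) < 3) stop_value("Need at least 3 paired observations.")
  if (var(x) == 0 || var(y) == 0) {
    stop_value("Zero variance: the correlation is undefined.")
  }
  cor(x, y)
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))` with
#' sample (n-1) variances.
#'
#' @param item_matrix A numeric matrix or data frame, subjects in rows and
#'   items in columns (>= 2 of each).
#' @return A one-row tibble: `alpha`, `n.items`, `n.subjects`.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (!is.numeric(m) || nrow(m) < 2 || ncol(m) < 2) {
    stop_value("Need a numeric matrix with >= 2 subjects and >= 2 items.")
  }
  total_var <- var(rowSums(m))
  if (total_var == 0) {
    stop_value("Zero total-score variance: alpha is undefined.")
  }
  k <- ncol(m)
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
  tibble::tibble(alpha = alpha, n.items = k, n.subjects = nrow(m))
}
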
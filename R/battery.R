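# Dilemma battery: response records, validation, aggregation to per-type counts.

#' Template for a complete dilemma battery
#'
#' A complete battery presents every base dilemma in all four versions
#' (norm type x benefit ratio), i.e. `n_base * 4` items.
#'
#' @param n_base Number of base dilemma scenarios (default 6, giving the
#'   standard 24-item battery).
#' @return A tibble with columns `base_id`, `norm`, `benefits` (one row per
#'   item).
#' @export
#' @examples
#' battery_spec() # 24 items
battery_spec <- function(n_base = 6) {
  if (!is.numeric(n_base) || length(n_base) != 1 || n_base < 1) {
    stop_value("`n_base` must be a single positive integer.")
  }
  tidyr::expand_grid(
    base_id = seq_len(n_base),
    dilemma_types()
  )
}

validate_responses <- function(responses, call_where = "responses") {
  required <- c("subject_id", "base_id", "norm", "benefits", "response")
  missing <- setdiff(required, names(responses))
  if (length(missing) > 0) {
    stop_format(paste0(
      "Missing column(s) in ", call_where, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  responses <- tibble::as_tibble(responses)

  bad_row <- function(what, idx) {
    stop_value(paste0(
      "Invalid ", what, " at row ", idx[1], " of ", call_where, "."
    ))
  }
  bad <- which(!responses$norm %in% .norm_levels)
  if (length(bad) > 0) bad_row("`norm` (expected proscriptive/prescriptive)", bad)
  bad <- which(!responses$benefits %in% .benefit_levels)
  if (length(bad) > 0) bad_row("`benefits` (expected greater/smaller)", bad)
  bad <- which(!responses$response %in% c(0L, 1L))
  if (length(bad) > 0) bad_row("`response` (expected 0 = inaction, 1 = action)", bad)

  key <- paste(responses$subject_id, responses$base_id,
               responses$norm, responses$benefits)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop_integrity(paste0(
      "Duplicate subject x dilemma record at row ", dup[1],
      " (subject ", responses$subject_id[dup[1]], ", base_id ",
      responses$base_id[dup[1]], ", ", responses$norm[dup[1]], "/",
      responses$benefits[dup[1]], ")."
    ))
  }
  responses$subject_id <- as.character(responses$subject_id)
  responses$base_id <- as.integer(responses$base_id)
  responses$response <- as.integer(responses$response)
  responses
}

#' Read dilemma responses from a CSV file
#'
#' The file dialect is comma-separated with header
#' `subject_id,base_id,norm,benefits,response`; `norm` is `proscriptive` or
#' `prescriptive`, `benefits` is `greater` or `smaller`, `response` is 1 for
#' action and 0 for inaction.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of response records, one row per subject x
#'   dilemma version.
#' @export
read_responses <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    base_id = readr::col_integer(),
    norm = readr::col_character(),
    benefits = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  validate_responses(df, call_where = path)
}

#' Write dilemma responses to a CSV file
#'
#' @param responses A response tibble as returned by [read_responses()] or
#'   [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  responses <- validate_responses(responses)
  readr::write_csv(
    responses[, c("subject_id", "base_id", "norm", "benefits", "response")],
    path
  )
  invisible(path)
}

# counts ------------------------------------------------------------------

new_counts <- function(n_action, n_total, group = NULL) {
  out <- dilemma_types()
  out$n_action <- as.numeric(n_action)
  out$n_total <- as.numeric(n_total)
  if (!is.null(group)) out <- tibble::add_column(out, group = group, .before = 1)
  out
}

# counts tibble (optionally with a `group` column) -> named list of
# group -> list(n_action, n_total), both length-4 in canonical type order.
counts_by_group <- function(counts) {
  required <- c("norm", "benefits", "n_action", "n_total")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    stop_format(paste0("Counts are missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (!"group" %in% names(counts)) counts$group <- "all"
  if (any(counts$n_action < 0) || any(counts$n_total < counts$n_action)) {
    stop_value("Counts must satisfy 0 <= n_action <= n_total.")
  }
  split_groups <- split(counts, factor(counts$group, levels = unique(counts$group)))
  lapply(split_groups, function(g) {
    idx <- match(
      paste(.type_norm, .type_benefits),
      paste(g$norm, g$benefits)
    )
    if (anyNA(idx)) {
      stop_value("Each group needs one row per dilemma type (4 rows).")
    }
    list(n_action = g$n_action[idx], n_total = g$n_total[idx])
  })
}

#' Aggregate responses into per-type action counts
#'
#' Sums action responses over subjects within each of the four dilemma types —
#' the sufficient statistic for the CNI likelihood. If a group assignment is
#' supplied, counts are computed per group and subjects assigned `"excluded"`
#' (or absent from the assignment) are dropped.
#'
#' @param responses Response tibble (see [read_responses()]).
#' @param assignment Optional tibble with columns `subject_id`, `group`, as
#'   returned by [assign_groups()].
#' @param incomplete Either `"exclude"` (drop subjects without a complete
#'   battery; the default) or `"count_available"` (keep all answered trials).
#' @param n_base Number of base dilemmas defining a complete battery.
#' @return A tibble with columns (`group`,) `norm`, `benefits`, `n_action`,
#'   `n_total`, four rows per group in canonical type order.
#' @export
aggregate_counts <- function(responses, assignment = NULL,
                             incomplete = c("exclude", "count_available"),
                             n_base = 6) {
  responses <- validate_responses(responses)
  incomplete <- match.arg(incomplete)

  grouped <- !is.null(assignment)
  if (grouped) {
    assignment <- tibble::as_tibble(assignment)
    if (!all(c("subject_id", "group") %in% names(assignment))) {
      stop_format("`assignment` needs columns subject_id and group.")
    }
    keep <- assignment[assignment$group != "excluded", ]
    responses <- dplyr::inner_join(
      responses,
      dplyr::mutate(keep, subject_id = as.character(.data$subject_id)),
      by = "subject_id"
    )
  } else {
    responses$group <- "all"
  }

  if (incomplete == "exclude") {
    n_items <- n_base * 4
    per_subject <- dplyr::count(responses, .data$subject_id)
    complete_ids <- per_subject$subject_id[per_subject$n == n_items]
    n_dropped <- dplyr::n_distinct(responses$subject_id) - length(complete_ids)
    if (n_dropped > 0) {
      message(n_dropped, " subject(s) without a complete battery excluded.")
    }
    responses <- responses[responses$subject_id %in% complete_ids, ]
  }

  group_levels <- if (grouped) {
    setdiff(unique(assignment$group), "excluded")
  } else {
    "all"
  }
  if (nrow(responses) == 0) {
    warn("No included responses; returning zero counts.")
    zero <- lapply(group_levels, function(g) new_counts(rep(0, 4), rep(0, 4), g))
    out <- dplyr::bind_rows(zero)
    if (!grouped) out$group <- NULL
    return(out)
  }

  out <- responses |>
    dplyr::group_by(.data$group, .data$norm, .data$benefits) |>
    dplyr::summarise(
      n_action = sum(.data$response),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(
      group = group_levels,
      tidyr::nesting(!!!dilemma_types()),
      fill = list(n_action = 0, n_total = 0)
    ) |>
    dplyr::mutate(
      norm = factor(.data$norm, levels = .norm_levels),
      benefits = factor(.data$benefits, levels = .benefit_levels)
    ) |>
    dplyr::arrange(.data$group, .data$norm, .data$benefits) |>
    dplyr::mutate(
      norm = as.character(.data$norm),
      benefits = as.character(.data$benefits),
      n_action = as.numeric(.data$n_action),
      n_total = as.numeric(.data$n_total)
    )
  if (!grouped) out$group <- NULL
  out
}

#' Reconstruct counts from published per-type mean scores
#'
#' Group-level reports often print, per dilemma type, the mean number of
#' action responses out of the 6 items of that type. With the group size this
#' determines real-valued aggregate counts: `n_total = 6 * n_subjects` and
#' `n_action = mean * n_subjects`. Real-valued counts are accepted throughout
#' the likelihood machinery precisely so that printed (rounded) means can be
#' re-analysed.
#'
#' @param mean_action_per_type Numeric vector of 4 means in `[0, 6]`, in the
#'   canonical type order of [dilemma_types()].
#' @param n_subjects Number of subjects behind the means.
#' @param group Optional group label to attach as a `group` column.
#' @param items_per_type Items of each type per subject (default 6).
#' @return A counts tibble (see [aggregate_counts()]).
#' @export
#' @examples
#' counts_from_means(c(2.46, 1.56, 4.51, 3.60), 188)
counts_from_means <- function(mean_action_per_type, n_subjects, group = NULL,
                              items_per_type = 6) {
  if (length(mean_action_per_type) != 4 ||
      !is.numeric(mean_action_per_type)) {
    stop_value("`mean_action_per_type` must be 4 numbers.")
  }
  if (any(mean_action_per_type < 0 | mean_action_per_type > items_per_type)) {
    stop_value(paste0("Means must lie in [0, ", items_per_type, "]."))
  }
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects <= 0) {
    stop_value("`n_subjects` must be a single positive number.")
  }
  new_counts(
    n_action = mean_action_per_type * n_subjects,
    n_total = rep(items_per_type * n_subjects, 4),
    group = group
  )
}

# implied per-type means, inverse of counts_from_means
counts_to_means <- function(counts, items_per_type = 6) {
  by_group <- counts_by_group(counts)
  purrr::imap_dfr(by_group, function(x, g) {
    out <- dilemma_types()
    out$mean_action <- x$n_action / (x$n_total / items_per_type)
    out$group <- g
    out
  })
}
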
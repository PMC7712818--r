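# LSRP questionnaire scoring and extreme-quantile group assignment.

#' Define an LSRP keying map
#'
#' The Levenson Self-Report Psychopathy scale has 26 six-point items split
#' into a primary (interpersonal/affective) and a secondary
#' (impulsive/antisocial) subscale; some published administrations reverse-key
#' a subset of items. The keying declares subscale membership and the
#' reverse-keyed set.
#'
#' @param primary Integer item indices of the primary subscale.
#' @param secondary Integer item indices of the secondary subscale.
#' @param reverse Integer indices of reverse-keyed items (value `v` scored as
#'   `7 - v`).
#' @param n_items Total number of items (26 for the LSRP).
#' @return A list of class `lsrp_keying`.
#' @export
lsrp_keying <- function(primary, secondary, reverse = integer(0), n_items = 26) {
  primary <- as.integer(primary)
  secondary <- as.integer(secondary)
  reverse <- as.integer(reverse)
  all_items <- sort(c(primary, secondary))
  if (!identical(all_items, seq_len(n_items))) {
    stop_value("`primary` and `secondary` must partition items 1..n_items.")
  }
  if (length(reverse) > 0 && !all(reverse %in% seq_len(n_items))) {
    stop_value("`reverse` must index items 1..n_items.")
  }
  structure(
    list(primary = primary, secondary = secondary, reverse = reverse,
         n_items = as.integer(n_items)),
    class = "lsrp_keying"
  )
}

#' Default LSRP keying (positional placeholder)
#'
#' A 16-primary / 10-secondary split with no reverse-keyed items: items 1-16
#' are scored on the primary subscale and items 17-26 on the secondary. This
#' matches the published subscale sizes but is positional — if your
#' administration interleaves subscales or reverse-keys items, supply your own
#' [lsrp_keying()] (or a JSON/YAML file via [read_keying()]).
#'
#' @return An `lsrp_keying` object.
#' @export
default_lsrp_keying <- function() {
  lsrp_keying(primary = 1:16, secondary = 17:26)
}

#' Read a keying map from a JSON or YAML file
#'
#' The file must contain fields `primary`, `secondary` and (optionally)
#' `reverse`, each a list of item indices.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `lsrp_keying` object.
#' @export
read_keying <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!all(c("primary", "secondary") %in% names(spec))) {
    stop_format("Keying file needs `primary` and `secondary` fields.")
  }
  lsrp_keying(
    primary = unlist(spec$primary),
    secondary = unlist(spec$secondary),
    reverse = unlist(spec$reverse %||% integer(0)),
    n_items = length(unlist(spec$primary)) + length(unlist(spec$secondary))
  )
}

#' Read LSRP item responses from a CSV file
#'
#' Dialect: comma-separated with header `subject_id,item_01,...,item_26`,
#' item values integers 1-6.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `subject_id` and one column per item.
#' @export
read_lsrp <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
  if (!"subject_id" %in% names(df)) {
    stop_format("LSRP file needs a subject_id column.")
  }
  df
}

item_cols <- function(n_items) sprintf("item_%02d", seq_len(n_items))

#' Score the LSRP scale
#'
#' Reverse-keyed item values `v` are rescored as `7 - v`, then items are
#' summed into the total and the two subscale scores (`total = primary +
#' secondary`).
#'
#' @param items Either a numeric vector of one subject's item responses, or a
#'   tibble with `subject_id` plus `item_01..item_NN` columns (as from
#'   [read_lsrp()] or [simulate_cohort()]).
#' @param keying An [lsrp_keying()]; defaults to [default_lsrp_keying()].
#' @return A tibble with columns `subject_id`, `total`, `primary`,
#'   `secondary`.
#' @export
#' @examples
#' score_lsrp(rep(2, 26))
score_lsrp <- function(items, keying = default_lsrp_keying()) {
  if (is.numeric(items)) {
    items <- tibble::as_tibble(setNames(as.list(items), item_cols(length(items))))
    items$subject_id <- "s1"
  }
  items <- tibble::as_tibble(items)
  cols <- item_cols(keying$n_items)
  missing <- setdiff(cols, names(items))
  if (length(missing) > 0) {
    stop_value(paste0(
      "Expected ", keying$n_items, " item columns; missing ",
      paste(head(missing, 3), collapse = ", "),
      if (length(missing) > 3) ", ..." else "", "."
    ))
  }
  mat <- as.matrix(items[, cols])
  if (!is.numeric(mat) || anyNA(mat) || any(mat < 1 | mat > 6) ||
      any(mat != round(mat))) {
    stop_value("Item responses must be integers in 1..6.")
  }
  if (length(keying$reverse) > 0) {
    mat[, keying$reverse] <- 7 - mat[, keying$reverse]
  }
  tibble::tibble(
    subject_id = as.character(items$subject_id),
    total = as.integer(rowSums(mat)),
    primary = as.integer(rowSums(mat[, keying$primary, drop = FALSE])),
    secondary = as.integer(rowSums(mat[, keying$secondary, drop = FALSE]))
  )
}

#' Assign subjects to extreme trait groups
#'
#' Ranks subjects by total score and labels the top and bottom fraction
#' `quantile` as `"high"` and `"low"`, everyone else `"excluded"`. The group
#' size is `round(quantile * n)` (at least 1). Ties are broken
#' deterministically by ascending `subject_id` within equal totals, so a
#' boundary tie never inflates a group.
#'
#' @param scores Tibble with columns `subject_id` and `total` (see
#'   [score_lsrp()]).
#' @param quantile Fraction in `(0, 0.5]` taken at each extreme (default
#'   0.20).
#' @return A tibble `subject_id`, `group` in the input row order.
#' @export
#' @examples
#' assign_groups(tibble::tibble(subject_id = letters[1:10], total = 1:10))
assign_groups <- function(scores, quantile = 0.20) {
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      quantile <= 0 || quantile > 0.5) {
    stop_value("`quantile` must lie in (0, 0.5].")
  }
  scores <- tibble::as_tibble(scores)
  if (!all(c("subject_id", "total") %in% names(scores))) {
    stop_format("`scores` needs columns subject_id and total.")
  }
  n <- nrow(scores)
  if (n < 2) stop_value("Need at least 2 scored subjects.")
  k <- max(1L, as.integer(round(quantile * n)))

  id <- as.character(scores$subject_id)
  ord_desc <- order(-scores$total, id) # high group: largest totals first
  ord_asc <- order(scores$total, id)   # low group: smallest totals first
  group <- rep("excluded", n)
  group[ord_desc[seq_len(k)]] <- "high"
  group[ord_asc[seq_len(k)]] <- "low"
  tibble::tibble(subject_id = id, group = group)
}
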
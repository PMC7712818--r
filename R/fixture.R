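# Bundled reference aggregates: high- vs low-psychopathy extreme groups
# (top/bottom LSRP quintiles) from a published moral-dilemma study, shipped
# as printed group means so the whole aggregate pipeline runs with no raw
# data. Real-valued counts reconstructed from the rounded means are
# first-class throughout the likelihood machinery.

#' Bundled psychopathy extreme-group aggregates
#'
#' Per-group mean action scores (0-6) for the four dilemma types from an
#' extreme-groups comparison of high- vs low-psychopathy subjects (top and
#' bottom 20% of LSRP totals; n = 174 and 188), plus the groups' LSRP summary
#' statistics. The means are converted to real-valued aggregate counts with
#' [counts_from_means()], ready for [cni_fit()], [cni_test_equality()] and
#' [pd_from_counts()].
#'
#' @return A list with elements
#'   \describe{
#'     \item{counts}{counts tibble with a `group` column (high, low);}
#'     \item{dilemma_summary}{tibble of the per-type means and SDs as printed;}
#'     \item{lsrp}{tibble of group LSRP `n`, `mean`, `sd`.}
#'   }
#' @export
#' @examples
#' fx <- psychopathy_fixture()
#' round(cni_fit(dplyr::filter(fx$counts, group == "low"))$estimates, 2)
psychopathy_fixture <- function() {
  path <- system.file("extdata", "psychopathy_aggregates.json",
                      package = "moralmpt", mustWork = TRUE)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- spec$groups

  row_vec <- function(col, i) {
    if (is.matrix(col)) as.numeric(col[i, ]) else as.numeric(col[[i]])
  }
  counts <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    counts_from_means(row_vec(groups$mean_action, i), groups$n_subjects[i],
                      group = groups$label[i],
                      items_per_type = spec$items_per_type)
  })
  dilemma_summary <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    out <- dilemma_types()
    out$group <- groups$label[i]
    out$n_subjects <- groups$n_subjects[i]
    out$mean_action <- row_vec(groups$mean_action, i)
    out$sd_action <- row_vec(groups$sd_action, i)
    out
  })
  lsrp <- tibble::tibble(
    group = groups$label,
    n = groups$n_subjects,
    mean = groups$lsrp_mean,
    sd = groups$lsrp_sd
  )
  list(counts = counts, dilemma_summary = dilemma_summary, lsrp = lsrp)
}
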
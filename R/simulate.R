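# Seeded synthetic cohorts: dilemma responses drawn from the CNI tree and
# LSRP totals drawn from group-separated normals. Hierarchical seeding: the
# cohort seed yields one sub-seed per subject, so each subject's data is
# reproducible independently of cohort composition order.

#' Specify a simulated group
#'
#' @param label Group label.
#' @param n_subjects Number of subjects.
#' @param cni Generating CNI parameters `(C, N, I)`.
#' @param lsrp_mean,lsrp_sd Mean and SD of the group's LSRP total; realized
#'   totals are rounded and clipped to the instrument range 26-156.
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(label, n_subjects, cni, lsrp_mean = 65, lsrp_sd = 13) {
  if (!is.numeric(n_subjects) || n_subjects < 0) {
    stop_value("`n_subjects` must be nonnegative.")
  }
  if (lsrp_sd < 0) stop_value("`lsrp_sd` must be nonnegative.")
  structure(
    list(label = as.character(label), n_subjects = as.integer(n_subjects),
         cni = validate_cni_params(cni), lsrp_mean = lsrp_mean,
         lsrp_sd = lsrp_sd),
    class = "group_spec"
  )
}

#' Specify between-subject parameter heterogeneity
#'
#' When enabled, each subject's CNI parameters are drawn independently from
#' `Beta(mean * kappa, (1 - mean) * kappa)` around the group parameters, so
#' the expected subject parameter equals the group parameter and larger
#' `kappa` means less heterogeneity (`kappa -> Inf` recovers the homogeneous
#' model).
#'
#' @param enabled Draw per-subject parameters?
#' @param kappa Precision of the Beta perturbation (positive).
#' @return A list of class `heterogeneity_spec`.
#' @export
heterogeneity_spec <- function(enabled = FALSE, kappa = 10) {
  if (!is.numeric(kappa) || kappa <= 0) stop_value("`kappa` must be positive.")
  structure(list(enabled = isTRUE(enabled), kappa = kappa),
            class = "heterogeneity_spec")
}

# one subject's 24 binary responses from the tree, using the current RNG
draw_responses <- function(subject_id, params, battery) {
  n <- nrow(battery)
  u_c <- runif(n); u_n <- runif(n); u_i <- runif(n)
  C <- params[[1]]; N <- params[[2]]; I <- params[[3]]
  consequence <- u_c < C
  norm_driven <- !consequence & (u_n < N)
  bias <- !consequence & !norm_driven
  action <- integer(n)
  action[consequence] <- as.integer(battery$benefits[consequence] == "greater")
  action[norm_driven] <- as.integer(battery$norm[norm_driven] == "prescriptive")
  action[bias] <- as.integer(u_i[bias] >= I)
  tibble::tibble(
    subject_id = subject_id,
    base_id = battery$base_id,
    norm = battery$norm,
    benefits = battery$benefits,
    response = action
  )
}

#' Simulate one subject's dilemma responses
#'
#' Each response is drawn independently from the CNI tree: with probability C
#' the consequences decide (action iff benefits exceed costs); otherwise with
#' probability N the norm decides; otherwise inaction with probability I.
#'
#' @param params CNI parameters `(C, N, I)`.
#' @param battery Battery template (default [battery_spec()], 24 items).
#' @param seed Optional integer seed (restores the RNG state afterwards). If
#'   `NULL`, the current RNG stream is used.
#' @param subject_id Subject identifier for the output records.
#' @return A response tibble (one row per battery item).
#' @export
#' @examples
#' simulate_subject(c(C = 1, N = 0.5, I = 0.5), seed = 1)
simulate_subject <- function(params, battery = battery_spec(), seed = NULL,
                             subject_id = "s1") {
  params <- validate_cni_params(params)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  draw_responses(subject_id, params, battery)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# distribute (total - n_items) extra points uniformly over items capped at 6:
# choose r of the n_items*5 available unit "slots" uniformly at random
lsrp_items_from_total <- function(total, n_items = 26) {
  r <- total - n_items
  add <- tabulate(
    ceiling(sample.int(n_items * 5, r) / 5),
    nbins = n_items
  )
  as.integer(1 + add)
}

#' Simulate a full cohort
#'
#' Generates, per subject: latent CNI parameters (the group values, or
#' Beta-perturbed values under heterogeneity), a complete 24-item response
#' battery drawn from the tree, an LSRP total drawn from the group normal
#' (rounded, clipped to 26-156), and item responses that sum exactly to that
#' total (uniform split over items; item covariance is not modelled).
#'
#' @param groups A list of [group_spec()]s with distinct labels.
#' @param heterogeneity A [heterogeneity_spec()] (default: disabled).
#' @param seed Integer cohort seed.
#' @param battery Battery template.
#' @return A list with elements `responses` (long tibble), `lsrp` (wide item
#'   tibble), `subjects` (tibble of group labels, latent parameters and LSRP
#'   totals).
#' @export
#' @examples
#' cohort <- simulate_cohort(
#'   list(group_spec("low", 5, c(0.15, 0.40, 0.49), 47.44, 6.28)),
#'   seed = 1
#' )
#' dplyr::count(cohort$responses, subject_id)
simulate_cohort <- function(groups, heterogeneity = heterogeneity_spec(),
                            seed = 1, battery = battery_spec()) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_value("Group labels must be distinct.")
  if (!inherits(heterogeneity, "heterogeneity_spec")) {
    stop_value("`heterogeneity` must come from heterogeneity_spec().")
  }

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  n_total <- sum(vapply(groups, `[[`, integer(1), "n_subjects"))
  empty <- list(
    responses = tibble::tibble(
      subject_id = character(), base_id = integer(), norm = character(),
      benefits = character(), response = integer()
    ),
    lsrp = tibble::as_tibble(
      c(list(subject_id = character()),
        setNames(rep(list(integer()), 26), item_cols(26)))
    ),
    subjects = tibble::tibble(
      subject_id = character(), group = character(), C = numeric(),
      N = numeric(), I = numeric(), lsrp_total = integer()
    )
  )
  if (n_total == 0) return(empty)

  subject_seeds <- sample.int(.Machine$integer.max, n_total)

  idx <- 0L
  responses <- vector("list", n_total)
  lsrp_rows <- vector("list", n_total)
  subject_rows <- vector("list", n_total)
  width <- max(4L, nchar(as.character(n_total)))
  for (g in groups) {
    for (i in seq_len(g$n_subjects)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%0*d", g$label, width, idx)
      set.seed(subject_seeds[idx])

      par <- g$cni
      if (heterogeneity$enabled) {
        kappa <- heterogeneity$kappa
        par <- vapply(g$cni, function(mu) {
          if (mu <= 0 || mu >= 1) return(mu) # degenerate Beta: point mass
          stats::rbeta(1, mu * kappa, (1 - mu) * kappa)
        }, numeric(1))
        par <- validate_cni_params(par)
      }
      responses[[idx]] <- draw_responses(sid, par, battery)

      total <- as.integer(round(rnorm(1, g$lsrp_mean, g$lsrp_sd)))
      total <- min(max(total, 26L), 156L) # instrument range
      items <- lsrp_items_from_total(total)
      lsrp_rows[[idx]] <- tibble::as_tibble(
        c(list(subject_id = sid), setNames(as.list(items), item_cols(26)))
      )
      subject_rows[[idx]] <- tibble::tibble(
        subject_id = sid, group = g$label,
        C = par[[1]], N = par[[2]], I = par[[3]], lsrp_total = total
      )
    }
  }
  list(
    responses = dplyr::bind_rows(responses),
    lsrp = dplyr::bind_rows(lsrp_rows),
    subjects = dplyr::bind_rows(subject_rows)
  )
}
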
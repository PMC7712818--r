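# End-to-end pipeline: scoring -> grouping -> aggregation -> traditional ->
# PD -> CNI fits -> likelihood-ratio tests, bundled into a report that can be
# rendered as JSON or markdown.

#' Configure an analysis run
#'
#' Exactly one input source is used: `fixture = TRUE` (the bundled
#' [psychopathy_fixture()] aggregates), `simulate` (a list of [group_spec()]s
#' to generate with [simulate_cohort()]), or file paths (`responses`, and
#' `lsrp` if grouping is wanted).
#'
#' @param responses,lsrp,keying Input file paths (responses CSV, LSRP CSV,
#'   keying JSON/YAML).
#' @param fixture Use the bundled aggregates?
#' @param simulate Optional list of [group_spec()]s.
#' @param quantile Extreme-group fraction for [assign_groups()].
#' @param analyses Character subset of
#'   `c("traditional", "pd", "cni", "equality", "point")`.
#' @param point_tests Named list parameter -> hypothesized value for point
#'   tests on each group (default `list(C = 0, N = 0, I = 0.5)`).
#' @param seed Integer seed (simulation and any other randomness).
#' @param precision Decimal places used in rendered reports.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(responses = NULL, lsrp = NULL, keying = NULL,
                            fixture = FALSE, simulate = NULL,
                            quantile = 0.20,
                            analyses = c("traditional", "pd", "cni",
                                         "equality", "point"),
                            point_tests = list(C = 0, N = 0, I = 0.5),
                            seed = 1, precision = 2) {
  analyses <- if (length(analyses) == 0) {
    character(0)
  } else {
    match.arg(analyses, several.ok = TRUE)
  }
  n_sources <- sum(isTRUE(fixture), !is.null(simulate), !is.null(responses))
  if (n_sources != 1) {
    stop_value("Give exactly one input source: fixture, simulate, or responses.")
  }
  structure(
    list(responses = responses, lsrp = lsrp, keying = keying,
         fixture = isTRUE(fixture), simulate = simulate, quantile = quantile,
         analyses = analyses, point_tests = point_tests,
         seed = as.integer(seed), precision = precision),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes scoring, extreme-group assignment, aggregation, traditional
#' scoring, process dissociation, per-group CNI fits, the joint baseline fit,
#' parameter-equality tests and point-hypothesis tests, as toggled in the
#' config. With the bundled fixture (aggregates only), per-subject analyses
#' are computed in their aggregate form and the traditional comparison uses
#' the printed summary statistics.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `mpt_report`; render with [render_report()].
#' @export
#' @examples
#' report <- run_pipeline(pipeline_config(fixture = TRUE))
#' report$cni$estimates
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop_value("`config` must come from pipeline_config().")
  }
  want <- function(a) a %in% config$analyses
  report <- list(
    provenance = list(
      package = "moralmpt",
      version = as.character(utils::packageVersion("moralmpt")),
      r_version = R.version.string,
      seed = config$seed,
      quantile = config$quantile,
      analyses = config$analyses,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
  )

  per_subject <- NULL
  traditional_stats <- NULL
  lsrp_summary <- NULL

  if (config$fixture) {
    fx <- psychopathy_fixture()
    counts <- fx$counts
    lsrp_summary <- fx$lsrp
    s <- fx$dilemma_summary
    inc <- s[s$norm == "proscriptive" & s$benefits == "greater", ]
    traditional_stats <- inc[, c("group", "n_subjects", "mean_action",
                                 "sd_action")]
  } else if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate, seed = config$seed)
    scores <- score_lsrp(cohort$lsrp)
    assignment <- assign_groups(scores, quantile = config$quantile)
    counts <- aggregate_counts(cohort$responses, assignment)
    per_subject <- list(responses = cohort$responses, scores = scores,
                        assignment = assignment)
    lsrp_summary <- summarize_lsrp(scores, assignment)
  } else {
    responses <- read_responses(config$responses)
    assignment <- NULL
    if (!is.null(config$lsrp)) {
      keying <- if (is.null(config$keying)) {
        default_lsrp_keying()
      } else {
        read_keying(config$keying)
      }
      scores <- score_lsrp(read_lsrp(config$lsrp), keying)
      assignment <- assign_groups(scores, quantile = config$quantile)
      per_subject <- list(responses = responses, scores = scores,
                          assignment = assignment)
      lsrp_summary <- summarize_lsrp(scores, assignment)
    } else {
      if (config$quantile != 0 && length(config$analyses) > 0 &&
          any(c("equality") %in% config$analyses)) {
        # equality tests need groups, which need LSRP scores
        stop_value("Grouped analyses need an `lsrp` file to assign groups.")
      }
      per_subject <- list(responses = responses)
    }
    counts <- aggregate_counts(responses, assignment)
  }
  report$counts <- counts
  report$lsrp <- lsrp_summary

  if (!is.null(lsrp_summary) && nrow(lsrp_summary) == 2) {
    report$lsrp_separation <- tibble::tibble(
      t = with(lsrp_summary,
               (mean[1] - mean[2]) /
                 (pooled_sd(sd[1], n[1], sd[2], n[2]) *
                    sqrt(1 / n[1] + 1 / n[2]))),
      df = sum(lsrp_summary$n) - 2,
      cohens.d = with(lsrp_summary,
                      cohens_d_from_stats(mean[1], sd[1], n[1],
                                          mean[2], sd[2], n[2]))
    )
    report$lsrp_separation$p.value <-
      2 * pt(-abs(report$lsrp_separation$t), report$lsrp_separation$df)
  }

  if (want("traditional")) {
    report$traditional <- if (!is.null(per_subject)) {
      traditional_report(per_subject)
    } else {
      traditional_from_stats(traditional_stats)
    }
  }
  if (want("pd")) {
    report$pd <- if (!is.null(per_subject)) {
      pd_report(per_subject)
    } else {
      pd_from_counts(counts)
    }
  }

  has_groups <- "group" %in% names(counts) &&
    dplyr::n_distinct(counts$group) >= 1
  if (want("cni")) {
    fits <- lapply(counts_split(counts), cni_fit)
    report$cni <- list(
      estimates = purrr::imap_dfr(fits, function(f, g) {
        tibble::add_column(tidy(f), group = g, .before = 1)
      }),
      fit = purrr::imap_dfr(fits, function(f, g) {
        tibble::add_column(glance(f), group = g, .before = 1)
      })
    )
    if (has_groups) {
      joint <- cni_fit_joint(counts)
      report$cni$joint <- glance(joint)
    }
  }
  if (want("equality") && has_groups &&
      dplyr::n_distinct(counts$group) >= 2) {
    report$equality <- purrr::map_dfr(.cni_params, function(p) {
      tidy(cni_test_equality(counts, p, se = FALSE))
    })
  }
  if (want("point")) {
    grids <- counts_split(counts)
    report$point <- purrr::imap_dfr(grids, function(cnt, g) {
      purrr::imap_dfr(config$point_tests, function(value, p) {
        res <- suppressWarnings(cni_test_point(cnt, p, value, se = FALSE))
        tibble::add_column(tidy(res), group = g, .before = 1)
      })
    })
  }

  structure(report, class = "mpt_report")
}

pooled_sd <- function(s1, n1, s2, n2) {
  sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
}

counts_split <- function(counts) {
  if (!"group" %in% names(counts)) return(list(all = counts))
  groups <- unique(counts$group)
  setNames(lapply(groups, function(g) counts[counts$group == g, ]), groups)
}

summarize_lsrp <- function(scores, assignment) {
  dplyr::inner_join(scores, assignment, by = "subject_id") |>
    dplyr::filter(.data$group != "excluded") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$total),
                     sd = sd(.data$total), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$group == "high"))
}

traditional_report <- function(per_subject) {
  trad <- traditional_scores(per_subject$responses)
  if (is.null(per_subject$assignment)) {
    return(tibble::tibble(group = "all", n_subjects = nrow(trad),
                          mean_action = mean(trad$T), sd_action = sd(trad$T)))
  }
  joined <- dplyr::inner_join(trad, per_subject$assignment, by = "subject_id") |>
    dplyr::filter(.data$group != "excluded")
  out <- joined |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_subjects = dplyr::n(), mean_action = mean(.data$T),
                     sd_action = sd(.data$T), .groups = "drop")
  if (dplyr::n_distinct(joined$group) == 2) {
    gl <- unique(joined$group)
    test <- two_group_t(joined$T[joined$group == gl[1]],
                        joined$T[joined$group == gl[2]])
    attr(out, "test") <- test
  }
  out
}

traditional_from_stats <- function(stats_tbl) {
  out <- tibble::as_tibble(stats_tbl)
  if (nrow(out) == 2) {
    sp <- pooled_sd(out$sd_action[1], out$n_subjects[1],
                    out$sd_action[2], out$n_subjects[2])
    t_stat <- (out$mean_action[1] - out$mean_action[2]) /
      (sp * sqrt(1 / out$n_subjects[1] + 1 / out$n_subjects[2]))
    df <- sum(out$n_subjects) - 2
    attr(out, "test") <- tibble::tibble(
      t = t_stat, df = df, p.value = 2 * pt(-abs(t_stat), df),
      cohens.d = cohens_d_from_stats(
        out$mean_action[1], out$sd_action[1], out$n_subjects[1],
        out$mean_action[2], out$sd_action[2], out$n_subjects[2]
      )
    )
  }
  out
}

pd_report <- function(per_subject) {
  pd <- pd_scores(per_subject$responses)
  if (is.null(per_subject$assignment)) return(pd)
  dplyr::inner_join(pd, per_subject$assignment, by = "subject_id") |>
    dplyr::filter(.data$group != "excluded") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      U_mean = mean(.data$U), U_sd = sd(.data$U),
      D_mean = mean(.data$D, na.rm = TRUE), D_sd = sd(.data$D, na.rm = TRUE),
      n_D_undefined = sum(is.na(.data$D)),
      .groups = "drop"
    )
}

#' Render an analysis report
#'
#' @param bundle An `mpt_report` from [run_pipeline()].
#' @param format `"json"` (full precision, machine-readable) or `"markdown"`
#'   (tables rounded to `precision` decimals).
#' @param path Optional output path.
#' @param precision Decimal places for markdown rendering.
#' @return The rendered document as a character scalar (JSON) or character
#'   vector of lines (markdown); written to `path` when given.
#' @export
render_report <- function(bundle, format = c("json", "markdown"), path = NULL,
                          precision = 2) {
  if (!inherits(bundle, "mpt_report")) {
    stop_value("`bundle` must come from run_pipeline().")
  }
  format <- match.arg(format)
  out <- if (format == "json") {
    payload <- unclass(bundle)
    if (!is.null(payload$traditional)) {
      test <- attr(payload$traditional, "test")
      if (!is.null(test)) payload$traditional_test <- test
      attr(payload$traditional, "test") <- NULL
    }
    as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                  na = "null"))
  } else {
    render_markdown(bundle, precision)
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

fmt_tbl <- function(tbl, precision) {
  tbl <- dplyr::mutate(tbl, dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, precision)
  ))
  header <- paste0("| ", paste(names(tbl), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tbl)), collapse = "|"), "|")
  rows <- apply(tbl, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

render_markdown <- function(bundle, precision) {
  lines <- c(
    "# Moral dilemma judgment analysis",
    "",
    paste0("Generated by moralmpt ", bundle$provenance$version,
           " (seed ", bundle$provenance$seed, ")."),
    ""
  )
  add <- function(title, tbl) {
    if (is.null(tbl)) return(invisible())
    lines <<- c(lines, paste("##", title), "", fmt_tbl(tbl, precision), "")
  }
  add("Aggregate counts by dilemma type", bundle$counts)
  add("LSRP group summaries", bundle$lsrp)
  add("LSRP group separation", bundle$lsrp_separation)
  add("Traditional dilemma scores", bundle$traditional)
  if (!is.null(bundle$traditional)) {
    add("Traditional group comparison", attr(bundle$traditional, "test"))
  }
  add("Process dissociation", bundle$pd)
  if (!is.null(bundle$cni)) {
    add("CNI parameter estimates", bundle$cni$estimates)
    add("CNI goodness of fit", bundle$cni$fit)
    add("CNI joint baseline fit", bundle$cni$joint)
  }
  add("Parameter equality tests", bundle$equality)
  add("Point hypothesis tests", bundle$point)
  lines
}

#' @export
print.mpt_report <- function(x, ...) {
  cat("moralmpt analysis report\n")
  cat("  sections:", paste(setdiff(names(x), "provenance"), collapse = ", "),
      "\n")
  if (!is.null(x$cni)) {
    cat("  CNI estimates:\n")
    print(dplyr::mutate(x$cni$estimates, dplyr::across(
      dplyr::where(is.numeric), ~ round(.x, 3)
    )))
  }
  invisible(x)
}
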
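#' Read validation-study 2x2 tables from CSV
#'
#' Expects the header `label,n_tp,n_fp,n_fn,n_tn`, one study per row.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble suitable for [summarize_validation()].
#' @export
read_validation_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  check_confusion(data)
}

#' Read PPV-only algorithm lists from CSV
#'
#' Expects the header `label,ppv`, one algorithm per row.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble suitable for [dlr_span()].
#' @export
read_ppv_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  check_algorithms(data)
}

#' Write a validation summary to tidy CSV
#'
#' Columns `label,measure,estimate,ci_lower,ci_upper,level`, full precision.
#'
#' @param summary A [summarize_validation()] result.
#' @param path Output path.
#' @return `summary`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  out <- dplyr::mutate(tibble::as_tibble(summary),
                       measure = as.character(.data$measure))
  readr::write_csv(out, path)
  invisible(summary)
}

#' Write a database-study plan report
#'
#' Emits the full planning report for a [plan_db_study()] fit: a
#' machine-readable tidy CSV (the [tidy()] tibble at full precision) and,
#' optionally, a human-readable text block with the conventional display
#' rounding (3 decimals for proportions, 1 for likelihood ratios). Studies
#' with not-estimable entries are rendered as `NE`, never dropped.
#'
#' @param plan A `db_plan` object.
#' @param csv_path Path for the tidy CSV.
#' @param text_path Optional path for the formatted text report.
#' @return `plan`, invisibly.
#' @export
write_plan_report <- function(plan, csv_path, text_path = NULL) {
  if (!inherits(plan, "db_plan")) abort("`plan` must be a db_plan object.")
  readr::write_csv(tidy(plan), csv_path)
  if (!is.null(text_path)) {
    writeLines(format_db_plan(plan), text_path)
  }
  invisible(plan)
}

#' Re-read a plan report CSV
#'
#' Inverse of the CSV half of [write_plan_report()]; reproduces the
#' [tidy()] tibble exactly (up to the text round-trip of doubles).
#'
#' @param path Path to a CSV written by [write_plan_report()].
#' @return A tibble with the tidy plan columns.
#' @export
read_plan_report <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      label = readr::col_character(),
      section = readr::col_character(),
      measure = readr::col_character(),
      .default = readr::col_double()
    )
  )
}

# Display rounding: proportions to 3 dp, likelihood ratios to 1 dp,
# relative bias to 3 significant digits. Computation always stays at
# full precision; this is presentation only.
fmt_measure <- function(measure, value) {
  purrr::map2_chr(measure, value, function(m, v) {
    if (is.na(v)) return("NE")
    if (is.infinite(v)) return("Inf")
    if (m %in% c("dlr_pos", "dlr_neg", "rr_expected")) {
      formatC(v, format = "f", digits = ifelse(m == "rr_expected", 3, 1))
    } else if (m == "bias_relative_pct") {
      formatC(v, format = "fg", digits = 3)
    } else {
      formatC(v, format = "f", digits = 3)
    }
  })
}

format_db_plan <- function(plan) {
  td <- tidy(plan)
  labels <- unique(td$label)
  lines <- c(
    "Validation-study summary and DB-study planning projections",
    sprintf("Assumptions: prevalence_db = %g, control_risk = %g, true_rr = %g, level = %g",
            plan$prevalence_db, plan$control_risk, plan$true_rr, plan$level),
    "Assumes non-differential outcome misclassification (shared Se/Sp across groups and populations).",
    ""
  )
  counts <- plan$data
  for (lab in labels) {
    cnt <- counts[counts$label == lab, ]
    lines <- c(lines, sprintf("== %s (N = %d: TP %d, FP %d, FN %d, TN %d)",
                              lab, cnt$n_tp + cnt$n_fp + cnt$n_fn + cnt$n_tn,
                              cnt$n_tp, cnt$n_fp, cnt$n_fn, cnt$n_tn))
    block <- td[td$label == lab, ]
    val <- block[block$section == "validation", ]
    lines <- c(lines, "  Validation study          Estimate   95% CI")
    for (i in seq_len(nrow(val))) {
      lines <- c(lines, sprintf(
        "  %-25s %8s   %s, %s",
        val$measure[i],
        fmt_measure(val$measure[i], val$estimate[i]),
        fmt_measure(val$measure[i], val$lower[i]),
        fmt_measure(val$measure[i], val$upper[i])
      ))
    }
    pl <- block[block$section == "planned", ]
    lines <- c(lines, "  Planned DB study          Expected   Range (DLR+ CI)")
    for (i in seq_len(nrow(pl))) {
      lines <- c(lines, sprintf(
        "  %-25s %8s   %s, %s",
        pl$measure[i],
        fmt_measure(pl$measure[i], pl$estimate[i]),
        fmt_measure(pl$measure[i], pl$lower[i]),
        fmt_measure(pl$measure[i], pl$upper[i])
      ))
    }
    lines <- c(lines, "")
  }
  # normalize any stray unicode minus/dash to ASCII for machine readability
  gsub("−|‒|–", "-", lines)
}
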
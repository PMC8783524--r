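#' Plan a database study from validation-study tables
#'
#' The end-to-end planning workflow: summarize each validation study
#' (all seven measures with confidence intervals), then project the DLR+
#' point estimate and its confidence bounds into the planned study — the
#' expected PPV at the assumed prevalence and the expected risk-ratio bias
#' at the assumed control-group risk and true risk ratio. The range
#' attached to each projection corresponds to the DLR+ confidence interval,
#' so it expresses how the validation study's sampling uncertainty carries
#' into the planning quantities. Non-differential misclassification
#' (sensitivity and specificity shared by both cohort groups and by the
#' validation and planned populations) is assumed throughout.
#'
#' @inheritParams summarize_validation
#' @param prevalence_db Assumed disease prevalence of the planned database
#'   study, in (0, 1). Default 0.05.
#' @param control_risk Assumed true control-group risk, in (0, 1).
#'   Default 0.03.
#' @param true_rr Assumed true risk ratio, `> 0`. Default 2.
#'
#' @return An object of class `db_plan` with components `summary` (the
#'   [summarize_validation()] tibble), `projections` (per-study expected
#'   values with DLR-CI-derived ranges) and the scenario parameters.
#'   Use [tidy()] for a combined long tibble, [glance()] for the scenario,
#'   [autoplot()] for projection curves, and `print()` for a formatted
#'   report block.
#' @examples
#' studies <- data.frame(label = "Kennedy",
#'                       n_tp = 67, n_fp = 43, n_fn = 4, n_tn = 20272)
#' plan <- plan_db_study(studies)
#' tidy(plan)
#' @export
plan_db_study <- function(data, prevalence_db = 0.05, control_risk = 0.03,
                          true_rr = 2, level = 0.95, correction = FALSE) {
  summary <- summarize_validation(data, level = level, correction = correction)
  check_range(prevalence_db, "prevalence_db", 0, 1, open = TRUE)
  check_range(control_risk, "control_risk", 0, 1, open = TRUE)

  dlr <- summary[summary$measure == "dlr_pos", ]
  projections <- purrr::pmap(dlr, function(label, estimate, ci_lower,
                                           ci_upper, ...) {
    proj_row <- function(measure, point_fun) {
      # a not-estimable DLR+ (or CI bound) propagates as NA, never an error
      vals <- vapply(c(estimate, ci_lower, ci_upper), function(d) {
        if (is.na(d)) NA_real_ else point_fun(d)
      }, numeric(1))
      tibble::tibble(
        label = label, measure = measure,
        expected = vals[1],
        range_lower = if (anyNA(vals[2:3])) NA_real_ else min(vals[2:3]),
        range_upper = if (anyNA(vals[2:3])) NA_real_ else max(vals[2:3])
      )
    }
    dplyr::bind_rows(
      proj_row("ppv_db", function(d) expected_ppv(d, prevalence_db)),
      proj_row("rr_expected",
               function(d) expected_rr(true_rr, control_risk, d)$rr_expected),
      proj_row("bias_relative_pct",
               function(d) expected_rr(true_rr, control_risk, d)$bias_relative_pct)
    )
  })
  structure(
    list(
      summary = summary,
      projections = dplyr::bind_rows(projections),
      prevalence_db = prevalence_db,
      control_risk = control_risk,
      true_rr = true_rr,
      level = level,
      data = check_confusion(data)
    ),
    class = "db_plan"
  )
}

#' @describeIn plan_db_study Long tibble of validation estimates and
#'   planning projections: columns `label`, `section`
#'   (`"validation"`/`"planned"`), `measure`, `estimate`, `lower`, `upper`,
#'   `level`.
#' @param x A `db_plan` object.
#' @param ... Unused.
#' @export
tidy.db_plan <- function(x, ...) {
  validation <- dplyr::mutate(
    tibble::as_tibble(x$summary),
    section = "validation",
    measure = as.character(.data$measure)
  ) |>
    dplyr::rename(lower = "ci_lower", upper = "ci_upper")
  planned <- dplyr::mutate(
    x$projections,
    section = "planned", level = x$level
  ) |>
    dplyr::rename(estimate = "expected", lower = "range_lower",
                  upper = "range_upper")
  dplyr::bind_rows(validation, planned)[
    , c("label", "section", "measure", "estimate", "lower", "upper", "level")
  ]
}

#' @describeIn plan_db_study One-row tibble of the scenario assumptions.
#' @export
glance.db_plan <- function(x, ...) {
  tibble::tibble(
    n_studies = length(unique(x$summary$label)),
    prevalence_db = x$prevalence_db,
    control_risk = x$control_risk,
    true_rr = x$true_rr,
    level = x$level
  )
}

#' @export
print.db_plan <- function(x, ...) {
  cat(format_db_plan(x), sep = "\n")
  invisible(x)
}
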
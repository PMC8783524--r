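#' Expected PPV of the planned study as a function of DLR+
#'
#' One curve per assumed database-study prevalence, DLR+ on a log axis.
#' Every curve increases with DLR+; at a fixed DLR+, rarer diseases yield
#' lower expected PPVs.
#'
#' @param prevalence Prevalences to draw, one line each.
#' @param dlr_limits Range of DLR+ values on the x axis.
#' @param n Number of grid points per curve.
#' @return A ggplot object.
#' @examples
#' plot_ppv_vs_dlr()
#' @export
plot_ppv_vs_dlr <- function(prevalence = c(0.025, 0.05, 0.1, 0.2, 0.3, 0.4),
                            dlr_limits = c(20, 1000), n = 200) {
  check_probability(prevalence, "prevalence")
  grid <- tidyr::expand_grid(
    dlr_pos = exp(seq(log(dlr_limits[1]), log(dlr_limits[2]), length.out = n)),
    prevalence = prevalence
  ) |>
    dplyr::mutate(ppv_db = expected_ppv(.data$dlr_pos, .data$prevalence))
  ggplot2::ggplot(grid, ggplot2::aes(.data$dlr_pos, .data$ppv_db,
                                     colour = factor(.data$prevalence))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "DLR+", y = "Expected PPV of DB study",
                  colour = "Prevalence") +
    ggplot2::theme_minimal()
}

#' Expected PPV of the planned study as a function of prevalence
#'
#' The companion display to [plot_ppv_vs_dlr()]: prevalence on the x axis,
#' one line per DLR+ value. Every curve increases with prevalence.
#'
#' @param dlr_pos DLR+ values to draw, one line each.
#' @param prevalence_limits Prevalence range on the x axis.
#' @inheritParams plot_ppv_vs_dlr
#' @return A ggplot object.
#' @export
plot_ppv_vs_prevalence <- function(dlr_pos = c(20, 50, 100, 250, 1000),
                                   prevalence_limits = c(0.025, 0.4),
                                   n = 200) {
  check_dlr(dlr_pos)
  grid <- tidyr::expand_grid(
    prevalence = seq(prevalence_limits[1], prevalence_limits[2],
                     length.out = n),
    dlr_pos = dlr_pos
  ) |>
    dplyr::mutate(ppv_db = expected_ppv(.data$dlr_pos, .data$prevalence))
  ggplot2::ggplot(grid, ggplot2::aes(.data$prevalence, .data$ppv_db,
                                     colour = factor(.data$dlr_pos))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Disease prevalence of DB study",
                  y = "Expected PPV of DB study", colour = "DLR+") +
    ggplot2::theme_minimal()
}

#' DLR+ versus prevalence for fixed PPV values
#'
#' The odds-ratio inversion drawn as curves: each line shows the DLR+ that
#' a given reported PPV implies across validation-population prevalences.
#' Used to read off a plausible DLR+ range when only PPVs are published.
#'
#' @param ppv PPV values to draw, one line each.
#' @param prevalence_limits Prevalence range on the x axis (strictly inside
#'   (0, 1)).
#' @inheritParams plot_ppv_vs_dlr
#' @return A ggplot object.
#' @export
plot_dlr_vs_prevalence <- function(ppv = c(0.5, 0.6, 0.7, 0.8, 0.9),
                                   prevalence_limits = c(0.01, 0.5),
                                   n = 200) {
  grid <- tidyr::expand_grid(
    prevalence = seq(prevalence_limits[1], prevalence_limits[2],
                     length.out = n),
    ppv = ppv
  ) |>
    dplyr::mutate(dlr_pos = dlr_from_ppv(.data$ppv, .data$prevalence))
  ggplot2::ggplot(grid, ggplot2::aes(.data$prevalence, .data$dlr_pos,
                                     colour = factor(.data$ppv))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Disease prevalence of validation study", y = "DLR+",
                  colour = "PPV") +
    ggplot2::theme_minimal()
}

bias_axis <- function(true_rr) {
  ggplot2::sec_axis(~ 100 * (. - true_rr) / true_rr,
                    name = "Relative bias of RR (%)")
}

#' Expected risk ratio as a function of DLR+
#'
#' One curve per assumed control-group risk, with a secondary axis giving
#' the relative bias in percent of the true risk ratio. Bias shrinks as
#' DLR+ grows and as the control risk grows.
#'
#' @param true_rr Assumed true risk ratio.
#' @param control_risk Control-group risks to draw, one line each.
#' @inheritParams plot_ppv_vs_dlr
#' @return A ggplot object.
#' @export
plot_rr_vs_dlr <- function(true_rr = 2,
                           control_risk = c(0.01, 0.02, 0.03, 0.05, 0.1),
                           dlr_limits = c(20, 1000), n = 200) {
  grid <- tidyr::expand_grid(
    dlr_pos = exp(seq(log(dlr_limits[1]), log(dlr_limits[2]), length.out = n)),
    control_risk = control_risk
  )
  grid <- dplyr::bind_cols(
    grid["dlr_pos"],
    expected_rr(true_rr, grid$control_risk, grid$dlr_pos)[
      , c("control_risk", "rr_expected")]
  )
  ggplot2::ggplot(grid, ggplot2::aes(.data$dlr_pos, .data$rr_expected,
                                     colour = factor(.data$control_risk))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = true_rr, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_continuous(sec.axis = bias_axis(true_rr)) +
    ggplot2::labs(x = "DLR+", y = "Expected RR of DB study",
                  colour = "Control risk") +
    ggplot2::theme_minimal()
}

#' Expected risk ratio as a function of the control-group risk
#'
#' The companion display to [plot_rr_vs_dlr()]: control risk on the x axis,
#' one line per DLR+ value, secondary axis in percent relative bias.
#'
#' @param dlr_pos DLR+ values to draw, one line each.
#' @param control_risk_limits Control-risk range on the x axis.
#' @inheritParams plot_rr_vs_dlr
#' @return A ggplot object.
#' @export
plot_rr_vs_control_risk <- function(true_rr = 2,
                                    dlr_pos = c(20, 50, 100, 1000),
                                    control_risk_limits = c(0.01, 0.1),
                                    n = 200) {
  grid <- tidyr::expand_grid(
    control_risk = seq(control_risk_limits[1], control_risk_limits[2],
                       length.out = n),
    dlr_pos = dlr_pos
  )
  grid <- dplyr::bind_cols(
    grid["control_risk"],
    expected_rr(true_rr, grid$control_risk, grid$dlr_pos)[
      , c("dlr_pos", "rr_expected")]
  )
  ggplot2::ggplot(grid, ggplot2::aes(.data$control_risk, .data$rr_expected,
                                     colour = factor(.data$dlr_pos))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = true_rr, linetype = "dashed") +
    ggplot2::scale_y_continuous(sec.axis = bias_axis(true_rr)) +
    ggplot2::labs(x = "True control-group risk", y = "Expected RR of DB study",
                  colour = "DLR+") +
    ggplot2::theme_minimal()
}

#' Projection curves for a fitted database-study plan
#'
#' For each validation study, draws the expected PPV against planned-study
#' prevalence (`which = "ppv"`) or the expected risk ratio against
#' control-group risk (`which = "rr"`, with a secondary relative-bias
#' axis). Each study contributes three lines: its DLR+ point estimate
#' (solid) and the two bounds of its confidence interval (dashed).
#'
#' @param object A [plan_db_study()] result.
#' @param which `"ppv"` or `"rr"`.
#' @param prevalence_limits x-axis range for the PPV panel.
#' @param control_risk_limits x-axis range for the RR panel.
#' @param n Grid points per curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.db_plan <- function(object, which = c("ppv", "rr"),
                             prevalence_limits = c(0.01, 0.09),
                             control_risk_limits = c(0.01, 0.05),
                             n = 200, ...) {
  which <- match.arg(which)
  dlr <- object$summary[object$summary$measure == "dlr_pos", ]
  curves <- purrr::pmap(dlr, function(label, estimate, ci_lower, ci_upper,
                                      ...) {
    tidyr::expand_grid(
      label = label,
      bound = c("point", "ci_lower", "ci_upper"),
      x = if (which == "ppv") {
        seq(prevalence_limits[1], prevalence_limits[2], length.out = n)
      } else {
        seq(control_risk_limits[1], control_risk_limits[2], length.out = n)
      }
    ) |>
      dplyr::mutate(
        dlr_pos = dplyr::case_match(.data$bound,
                                    "point" ~ estimate,
                                    "ci_lower" ~ ci_lower,
                                    "ci_upper" ~ ci_upper),
        y = if (which == "ppv") {
          expected_ppv(.data$dlr_pos, .data$x)
        } else {
          expected_rr(object$true_rr, .data$x, .data$dlr_pos)$rr_expected
        }
      )
  }) |>
    dplyr::bind_rows()
  p <- ggplot2::ggplot(curves, ggplot2::aes(
    .data$x, .data$y, colour = .data$label,
    linetype = .data$bound == "point", group = interaction(.data$label, .data$bound)
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(colour = "Validation study") +
    ggplot2::theme_minimal()
  if (which == "ppv") {
    p + ggplot2::labs(x = "Disease prevalence of DB study",
                      y = "Expected PPV of DB study")
  } else {
    p + ggplot2::scale_y_continuous(sec.axis = bias_axis(object$true_rr)) +
      ggplot2::labs(x = "True control-group risk",
                    y = "Expected RR of DB study")
  }
}

#' PPV-only algorithms as DLR+ curves with plausible spans
#'
#' Draws one DLR+ curve per algorithm over prevalence (log y axis), shades
#' the plausible prevalence band, and marks the DLR+ spans consistent with
#' all algorithms (solid horizontal lines) and with the median algorithm(s)
#' (dotted horizontal lines).
#'
#' @inheritParams dlr_span
#' @param prevalence_limits Prevalence range on the x axis.
#' @param n Grid points per curve.
#' @return A ggplot object.
#' @examples
#' algos <- data.frame(label = c("A", "B", "C"),
#'                     ppv = c(0.72, 0.86, 0.97))
#' plot_dlr_band(algos, c(0.1, 0.3))
#' @export
plot_dlr_band <- function(algorithms, band,
                          prevalence_limits = c(0.02, 0.5), n = 200) {
  algorithms <- check_algorithms(algorithms)
  band <- as_band(band)
  curves <- purrr::pmap(algorithms, function(label, ppv) {
    dplyr::mutate(
      dlr_curve(ppv, seq(prevalence_limits[1], prevalence_limits[2],
                         length.out = n)),
      label = label
    )
  }) |>
    dplyr::bind_rows()
  spans <- dplyr::bind_rows(
    dlr_span(algorithms, band, "all"),
    dlr_span(algorithms, band, "median")
  ) |>
    tidyr::pivot_longer(c("lower", "upper"), values_to = "dlr_pos")
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$prevalence, .data$dlr_pos)) +
    ggplot2::annotate("rect", xmin = band[["p_min"]], xmax = band[["p_max"]],
                      ymin = min(curves$dlr_pos, spans$dlr_pos) / 2,
                      ymax = max(curves$dlr_pos, spans$dlr_pos) * 2,
                      alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$label)) +
    ggplot2::geom_hline(
      data = spans,
      ggplot2::aes(yintercept = .data$dlr_pos,
                   linetype = .data$rule),
      colour = "blue"
    ) +
    ggplot2::scale_linetype_manual(values = c(all = "solid",
                                              median = "dotted")) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Disease prevalence of validation study", y = "DLR+",
                  colour = "Algorithm", linetype = "Span rule") +
    ggplot2::theme_minimal()
}
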
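#' Expected PPV of a planned database study
#'
#' Bayes' theorem, written in odds form, gives the positive predictive value
#' an algorithm is expected to achieve in a population with disease
#' prevalence `p` when its positive diagnostic likelihood ratio is `d`:
#' `PPV = d * p / (d * p + 1 - p)`. The same algorithm therefore yields
#' different PPVs in populations with different prevalence; `d = 1`
#' (an uninformative algorithm) returns the prevalence itself, and an
#' infinitely specific algorithm (`d = Inf`) returns 1 for any positive
#' prevalence. Monotone increasing in both arguments.
#'
#' @param dlr_pos Positive diagnostic likelihood ratio, `>= 0`; may be
#'   `Inf`. Vectorized.
#' @param prevalence Disease prevalence in \[0, 1\]. Vectorized.
#' @return Numeric vector of expected PPVs.
#' @examples
#' expected_ppv(445.8, 0.05)
#' @export
expected_ppv <- function(dlr_pos, prevalence) {
  check_dlr(dlr_pos)
  check_probability(prevalence, "prevalence")
  n <- max(length(dlr_pos), length(prevalence))
  d <- rep_len(dlr_pos, n)
  p <- rep_len(prevalence, n)
  out <- d * p / (d * p + 1 - p)
  out[p == 0] <- 0
  out[is.infinite(d) & p > 0] <- 1
  out
}

#' Expected NPV of a planned database study
#'
#' The negative-result analogue of [expected_ppv()]:
#' `NPV = (1 - p) / ((1 - p) + dlr_neg * p)`. A perfectly sensitive
#' algorithm (`dlr_neg = 0`) yields NPV 1 for any prevalence below 1.
#' Monotone decreasing in both arguments.
#'
#' @param dlr_neg Negative diagnostic likelihood ratio, `>= 0`. Vectorized.
#' @inheritParams expected_ppv
#' @return Numeric vector of expected NPVs.
#' @examples
#' expected_npv(0.206, 0.093)
#' @export
expected_npv <- function(dlr_neg, prevalence) {
  check_dlr(dlr_neg, "dlr_neg")
  check_probability(prevalence, "prevalence")
  n <- max(length(dlr_neg), length(prevalence))
  d <- rep_len(dlr_neg, n)
  p <- rep_len(prevalence, n)
  out <- (1 - p) / ((1 - p) + d * p)
  out[p == 1 & d > 0] <- 0
  out[d == 0 & p < 1] <- 1
  out[is.infinite(d) & p > 0] <- 0
  out
}

#' Back-solve DLR+ from a reported PPV and prevalence
#'
#' Many validation reports give only a PPV. Because DLR+ is the ratio of
#' post-test to pre-test odds, it can be recovered from the PPV and the
#' prevalence of the validation population:
#' `DLR+ = (PPV / (1 - PPV)) / (p / (1 - p))`. This is the exact inverse of
#' [expected_ppv()] in its first argument.
#'
#' @param ppv Positive predictive value, strictly inside (0, 1). Vectorized.
#' @param prevalence Disease prevalence, strictly inside (0, 1). Vectorized.
#' @return Numeric vector of DLR+ values.
#' @examples
#' dlr_from_ppv(0.8, c(0.04, 0.06))
#' @export
dlr_from_ppv <- function(ppv, prevalence) {
  if (!is.numeric(ppv) || any(ppv <= 0 | ppv >= 1)) {
    abort("`ppv` must be strictly inside (0, 1): the odds are infinite at the boundary.")
  }
  if (!is.numeric(prevalence) || any(prevalence <= 0 | prevalence >= 1)) {
    abort("`prevalence` must be strictly inside (0, 1).")
  }
  (ppv / (1 - ppv)) / (prevalence / (1 - prevalence))
}

#' Expected number of algorithm-positive subjects in a cohort group
#'
#' Under non-differential misclassification a group of `n` subjects of whom
#' `x_true` truly have the disease is expected to produce
#' `x_true * Se + (n - x_true) * (1 - Sp)` algorithm positives: the detected
#' true positives plus the false positives among the disease-free.
#'
#' @param n Group size. @param x_true True number of diseased subjects.
#' @param sensitivity,specificity Algorithm operating characteristics in
#'   \[0, 1\].
#' @return Expected count (real-valued).
#' @examples
#' expected_positive_count(1000, 30, 0.9, 0.95)
#' @export
expected_positive_count <- function(n, x_true, sensitivity, specificity) {
  check_count(n, "n"); check_count(x_true, "x_true")
  if (any(x_true > n)) abort("`x_true` must not exceed `n`.")
  check_probability(sensitivity, "sensitivity")
  check_probability(specificity, "specificity")
  x_true * sensitivity + (n - x_true) * (1 - specificity)
}

#' Expected algorithm-based risk in a cohort group
#'
#' The per-subject version of [expected_positive_count()]:
#' `R * Se + (1 - R) * (1 - Sp)` for true risk `R`.
#'
#' @param risk_true True disease risk in \[0, 1\].
#' @inheritParams expected_positive_count
#' @return Expected observed risk.
#' @examples
#' expected_risk(0.03, 0.944, 0.998)
#' @export
expected_risk <- function(risk_true, sensitivity, specificity) {
  check_probability(risk_true, "risk_true")
  check_probability(sensitivity, "sensitivity")
  check_probability(specificity, "specificity")
  risk_true * sensitivity + (1 - risk_true) * (1 - specificity)
}

#' Expected risk ratio and misclassification bias of a planned study
#'
#' Under non-differential outcome misclassification the risk ratio a
#' comparative cohort study is expected to report is
#' `RR_exp = RR_true + (1 - RR_true) / (R_con * (DLR+ - 1) + 1)`,
#' where `R_con` is the true control-group risk. The second term is the
#' bias; when the true risk ratio exceeds 1 it is always negative
#' (attenuation toward the null), vanishing as DLR+ grows. `dlr_pos = Inf`
#' is the exact no-bias limit.
#'
#' @param true_rr True risk ratio (test vs control), `> 0`.
#' @param control_risk True control-group risk, in (0, 1).
#' @param dlr_pos Positive diagnostic likelihood ratio, `> 0`; may be `Inf`.
#'   Vectorized (all three arguments recycled).
#' @return A tibble with columns `true_rr`, `control_risk`, `dlr_pos`,
#'   `rr_expected`, `bias_absolute` (`rr_expected - true_rr`) and
#'   `bias_relative_pct` (percent of the true risk ratio; negative means
#'   attenuation toward the null when `true_rr > 1`).
#' @examples
#' expected_rr(2, 0.03, 445.8)
#' @export
expected_rr <- function(true_rr, control_risk, dlr_pos) {
  if (!is.numeric(true_rr) || any(true_rr <= 0)) {
    abort("`true_rr` must be positive.")
  }
  if (!is.numeric(control_risk) || any(control_risk <= 0 | control_risk >= 1)) {
    abort("`control_risk` must be strictly inside (0, 1).")
  }
  if (!is.numeric(dlr_pos) || any(dlr_pos <= 0)) {
    abort("`dlr_pos` must be positive (may be Inf).")
  }
  n <- max(length(true_rr), length(control_risk), length(dlr_pos))
  rr <- rep_len(true_rr, n)
  rc <- rep_len(control_risk, n)
  d <- rep_len(dlr_pos, n)
  r_tes <- rr * rc
  if (any(r_tes > 1 + 1e-12)) {
    abort(sprintf(
      "invalid scenario: test-group risk true_rr * control_risk = %.4g exceeds 1.",
      max(r_tes)
    ))
  }
  bias <- (1 - rr) / (rc * (d - 1) + 1)
  bias[is.infinite(d)] <- 0
  tibble::tibble(
    true_rr = rr, control_risk = rc, dlr_pos = d,
    rr_expected = rr + bias,
    bias_absolute = bias,
    bias_relative_pct = 100 * bias / rr
  )
}

#' Describe a planning scenario with point or range parameters
#'
#' Bundles the assumptions used to project a validation study onto a planned
#' database study. Each parameter may be a single value or an inclusive
#' range `c(lower, upper)` — e.g. a DLR+ confidence interval, or a band of
#' plausible prevalences.
#'
#' @param dlr_pos DLR+ value or range (e.g. a Katz CI), `> 0`.
#' @param prevalence_db Planned-study disease prevalence value or range in
#'   (0, 1); optional.
#' @param control_risk True control-group risk value or range in (0, 1);
#'   optional.
#' @param true_rr True risk ratio, a single positive value; optional, but
#'   required together with `control_risk` for risk-ratio projections.
#' @return An object of class `planning_scenario`.
#' @examples
#' planning_scenario(dlr_pos = c(329.0, 604.2), prevalence_db = 0.05,
#'                   control_risk = 0.03, true_rr = 2)
#' @export
planning_scenario <- function(dlr_pos, prevalence_db = NULL,
                              control_risk = NULL, true_rr = NULL) {
  check_range(dlr_pos, "dlr_pos", lo = 0, hi = Inf, open = TRUE)
  if (!is.null(prevalence_db)) {
    check_range(prevalence_db, "prevalence_db", lo = 0, hi = 1, open = TRUE)
  }
  if (!is.null(control_risk)) {
    check_range(control_risk, "control_risk", lo = 0, hi = 1, open = TRUE)
  }
  if (!is.null(true_rr)) {
    if (!is.numeric(true_rr) || length(true_rr) != 1 || true_rr <= 0) {
      abort("`true_rr` must be a single positive value.")
    }
    if (!is.null(control_risk) && true_rr * max(control_risk) > 1) {
      abort(sprintf(
        "invalid scenario: test-group risk true_rr * control_risk = %.4g exceeds 1.",
        true_rr * max(control_risk)
      ))
    }
  }
  structure(
    list(
      dlr_pos = as_range(dlr_pos),
      prevalence_db = if (is.null(prevalence_db)) NULL else as_range(prevalence_db),
      control_risk = if (is.null(control_risk)) NULL else as_range(control_risk),
      true_rr = true_rr
    ),
    class = "planning_scenario"
  )
}

#' Propagate parameter ranges through the planning projections
#'
#' Evaluates the expected PPV (when the scenario has a prevalence) and the
#' expected risk ratio and relative bias (when it has a control risk and a
#' true risk ratio) over the Cartesian endpoints of every range in the
#' scenario. Because each projection is monotone in every argument, the
#' extremes over a box of parameters occur at its corners, so evaluating
#' endpoints reproduces the full range exactly; degenerate ranges collapse
#' to the point calculation.
#'
#' @param scenario A [planning_scenario()].
#' @return A tibble with columns `measure` (`ppv_db`, `rr_expected`,
#'   `bias_relative_pct`), `lower`, `upper`; `lower == upper` when every
#'   scenario parameter is a point.
#' @examples
#' sc <- planning_scenario(dlr_pos = c(329.0, 604.2), prevalence_db = 0.05)
#' assess_over_ranges(sc)
#' @export
assess_over_ranges <- function(scenario) {
  if (!inherits(scenario, "planning_scenario")) {
    abort("`scenario` must be created by planning_scenario().")
  }
  out <- list()
  d <- scenario$dlr_pos
  if (!is.null(scenario$prevalence_db)) {
    grid <- expand.grid(d = unique(d), p = unique(scenario$prevalence_db))
    vals <- expected_ppv(grid$d, grid$p)
    out$ppv_db <- range(vals)
  }
  if (!is.null(scenario$control_risk) && !is.null(scenario$true_rr)) {
    grid <- expand.grid(d = unique(d), rc = unique(scenario$control_risk))
    proj <- expected_rr(scenario$true_rr, grid$rc, grid$d)
    out$rr_expected <- range(proj$rr_expected)
    out$bias_relative_pct <- range(proj$bias_relative_pct)
  }
  if (length(out) == 0) {
    abort("scenario has no projection target: supply `prevalence_db` and/or `control_risk` + `true_rr`.")
  }
  tibble::tibble(
    measure = names(out),
    lower = unname(purrr::map_dbl(out, 1)),
    upper = unname(purrr::map_dbl(out, 2))
  )
}

check_dlr <- function(x, name = "dlr_pos") {
  if (!is.numeric(x) || any(x < 0, na.rm = TRUE)) {
    abort(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}

as_range <- function(x) {
  if (length(x) == 1) c(x, x) else sort(x)
}

check_range <- function(x, name, lo, hi, open = FALSE) {
  if (!is.numeric(x) || !length(x) %in% c(1, 2)) {
    abort(sprintf("`%s` must be a single value or a range c(lower, upper).", name))
  }
  bad <- if (open) {
    any(x <= lo) || (is.finite(hi) && any(x >= hi))
  } else {
    any(x < lo) || (is.finite(hi) && any(x > hi))
  }
  if (bad) {
    abort(sprintf("`%s` must lie strictly between %s and %s.", name,
                  format(lo), format(hi)))
  }
  if (length(x) == 2 && diff(x) < 0) {
    abort(sprintf("`%s` range must have lower <= upper.", name))
  }
  invisible(x)
}
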
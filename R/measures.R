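#' Positive diagnostic likelihood ratio
#'
#' The positive diagnostic likelihood ratio (DLR+) of a phenotype algorithm
#' is `sensitivity / (1 - specificity)`: the factor by which a positive
#' algorithm result multiplies the pre-test odds of disease. Unlike the
#' predictive values it does not depend on disease prevalence, which is what
#' makes it the pivotal quantity when projecting a validation study onto a
#' planned database study.
#'
#' @param sensitivity,specificity Probabilities in \[0, 1\]. Vectorized.
#'
#' @return A numeric vector. `Inf` when `specificity == 1` and
#'   `sensitivity > 0` (a perfectly specific algorithm); `NA` for the
#'   indeterminate 0/0 case (`sensitivity == 0` and `specificity == 1`).
#'
#' @examples
#' dlr_positive(0.944, 0.998)
#' dlr_positive(1, 0.5)
#' @seealso [dlr_negative()], [expected_ppv()], [dlr_from_ppv()]
#' @export
dlr_positive <- function(sensitivity, specificity) {
  check_probability(sensitivity, "sensitivity")
  check_probability(specificity, "specificity")
  num <- sensitivity
  den <- 1 - specificity
  out <- num / den
  out[den == 0 & num > 0] <- Inf
  out[den == 0 & num == 0] <- NA_real_
  out
}

#' Negative diagnostic likelihood ratio
#'
#' `(1 - sensitivity) / specificity`: the factor by which a negative
#' algorithm result multiplies the pre-test odds of disease. Values below 1
#' indicate an informative negative result.
#'
#' @inheritParams dlr_positive
#' @return A numeric vector; `NA` when `specificity == 0` (undefined).
#' @examples
#' dlr_negative(0.888, 0.928)
#' @export
dlr_negative <- function(sensitivity, specificity) {
  check_probability(sensitivity, "sensitivity")
  check_probability(specificity, "specificity")
  out <- (1 - sensitivity) / specificity
  out[specificity == 0] <- NA_real_
  out
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, obtained by inverting
#' the binomial tail tests (computed through the beta-quantile form). The
#' lower bound is exactly 0 when `successes == 0` and the upper bound exactly
#' 1 when `successes == trials`.
#'
#' @param successes,trials Non-negative integer counts with
#'   `successes <= trials` and `trials > 0`. Vectorized (recycled).
#' @param level Two-sided confidence level, default `0.95`.
#'
#' @return A tibble with columns `estimate`, `ci_lower`, `ci_upper`, `level`.
#' @examples
#' ci_clopper_pearson(67, 71)
#' @export
ci_clopper_pearson <- function(successes, trials, level = 0.95) {
  check_count(successes, "successes")
  check_count(trials, "trials")
  check_level(level)
  n <- pmax(length(successes), length(trials))
  x <- rep_len(successes, n)
  m <- rep_len(trials, n)
  if (any(m <= 0)) abort("`trials` must be positive.")
  if (any(x > m)) abort("`successes` must not exceed `trials`.")
  alpha <- 1 - level
  lower <- ifelse(x == 0, 0, qbeta(alpha / 2, x, m - x + 1))
  upper <- ifelse(x == m, 1, qbeta(1 - alpha / 2, x + 1, m - x))
  tibble::tibble(
    estimate = x / m, ci_lower = lower, ci_upper = upper, level = level
  )
}

#' Katz log-scale confidence interval for a diagnostic likelihood ratio
#'
#' Approximate interval for DLR+ (or DLR-) from a validation-study 2x2
#' table, built on the log scale with the delta-method variance for a ratio
#' of two independent binomial proportions:
#' `SE^2 = 1/a - 1/(a+c) + 1/b - 1/(b+d)` for DLR+ = (a/(a+c)) / (b/(b+d)),
#' where a, b, c, d are the true-positive, false-positive, false-negative
#' and true-negative counts. The interval `exp(log D +/- z * SE)` is
#' symmetric about the point estimate on the log scale, so the geometric
#' mean of its bounds equals the point estimate.
#'
#' With a zero count in either binomial numerator the log-scale variance is
#' undefined and the interval is reported as not estimable (`NA`) unless
#' `correction = TRUE`, which adds 0.5 to every cell (Haldane-style) before
#' computing — off by default because a silent correction changes numbers.
#'
#' @param n_tp,n_fp,n_fn,n_tn Cell counts of the validation 2x2 table
#'   (algorithm x gold standard). Vectorized (recycled).
#' @param level Two-sided confidence level, default `0.95`.
#' @param measure `"dlr_pos"` (default) or `"dlr_neg"`.
#' @param correction Apply the 0.5 continuity correction to all four cells
#'   when a required cell is zero? Default `FALSE`.
#'
#' @return A tibble with columns `estimate`, `ci_lower`, `ci_upper`, `level`.
#' @examples
#' ci_dlr_katz(67, 43, 4, 20272)
#' @export
ci_dlr_katz <- function(n_tp, n_fp, n_fn, n_tn, level = 0.95,
                        measure = c("dlr_pos", "dlr_neg"),
                        correction = FALSE) {
  measure <- match.arg(measure)
  check_level(level)
  len <- max(length(n_tp), length(n_fp), length(n_fn), length(n_tn))
  a <- rep_len(as.numeric(n_tp), len)
  b <- rep_len(as.numeric(n_fp), len)
  c_ <- rep_len(as.numeric(n_fn), len)
  d <- rep_len(as.numeric(n_tn), len)
  if (any(c(a, b, c_, d) < 0)) abort("cell counts must be non-negative.")

  # For DLR- the roles of the two binomials swap: (1-Se)/Sp.
  if (measure == "dlr_neg") {
    num_x <- c_; num_n <- a + c_
    den_x <- d;  den_n <- b + d
  } else {
    num_x <- a;  num_n <- a + c_
    den_x <- b;  den_n <- b + d
  }

  needs_cc <- num_x == 0 | den_x == 0
  if (correction && any(needs_cc)) {
    # Haldane-style: 0.5 to every cell of affected tables.
    for (i in which(needs_cc)) {
      a[i] <- a[i] + 0.5; b[i] <- b[i] + 0.5
      c_[i] <- c_[i] + 0.5; d[i] <- d[i] + 0.5
    }
    if (measure == "dlr_neg") {
      num_x <- c_; num_n <- a + c_; den_x <- d; den_n <- b + d
    } else {
      num_x <- a; num_n <- a + c_; den_x <- b; den_n <- b + d
    }
    needs_cc <- rep(FALSE, len)
  }

  est <- (num_x / num_n) / (den_x / den_n)
  se <- sqrt(1 / num_x - 1 / num_n + 1 / den_x - 1 / den_n)
  z <- qnorm(1 - (1 - level) / 2)
  lower <- exp(log(est) - z * se)
  upper <- exp(log(est) + z * se)
  bad <- needs_cc | num_n == 0 | den_n == 0
  est[needs_cc] <- ifelse(den_x[needs_cc] == 0 & num_x[needs_cc] > 0,
                          Inf, NA_real_)
  lower[bad] <- NA_real_
  upper[bad] <- NA_real_
  tibble::tibble(
    estimate = est, ci_lower = lower, ci_upper = upper, level = level
  )
}

#' Point estimates of the seven performance measures
#'
#' Computes sensitivity, specificity, prevalence, PPV, NPV, DLR+ and DLR-
#' from validation-study 2x2 cell counts, without confidence intervals.
#' A measure whose denominator is zero is reported as `NA` (not estimable),
#' never silently as 0.
#'
#' @param data A data frame with one validation study per row and columns
#'   `label`, `n_tp`, `n_fp`, `n_fn`, `n_tn` (true-positive, false-positive,
#'   false-negative, true-negative counts).
#'
#' @return A tibble with columns `label`, `measure`, `estimate`; `measure`
#'   is a factor in the canonical order sensitivity, specificity,
#'   prevalence, ppv, npv, dlr_pos, dlr_neg.
#' @examples
#' kennedy <- data.frame(label = "Kennedy",
#'                       n_tp = 67, n_fp = 43, n_fn = 4, n_tn = 20272)
#' point_estimates(kennedy)
#' @export
point_estimates <- function(data) {
  data <- check_confusion(data)
  rows <- purrr::pmap(data, function(label, n_tp, n_fp, n_fn, n_tn, ...) {
    se <- safe_ratio(n_tp, n_tp + n_fn)
    sp <- safe_ratio(n_tn, n_fp + n_tn)
    tibble::tibble(
      label = label,
      measure = factor(MEASURE_LEVELS, levels = MEASURE_LEVELS),
      estimate = c(
        se, sp,
        (n_tp + n_fn) / (n_tp + n_fp + n_fn + n_tn),
        safe_ratio(n_tp, n_tp + n_fp),
        safe_ratio(n_tn, n_fn + n_tn),
        if (is.na(se) || is.na(sp)) NA_real_ else dlr_positive(se, sp),
        if (is.na(se) || is.na(sp)) NA_real_ else dlr_negative(se, sp)
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Summarize validation studies with confidence intervals
#'
#' The full per-study performance summary: the five proportions
#' (sensitivity, specificity, prevalence, PPV, NPV) with exact
#' Clopper-Pearson intervals, each treated as a simple binomial with its own
#' numerator and denominator, and the two likelihood ratios with Katz
#' log-scale intervals. Prevalence uses `n_tp + n_fn` successes out of the
#' total N. A measure that is not estimable for one study is reported as
#' `NA` without aborting the rest of the summary.
#'
#' @inheritParams point_estimates
#' @param level Two-sided confidence level for every interval, default 0.95.
#' @param correction Passed to [ci_dlr_katz()]: apply the 0.5 continuity
#'   correction when a DLR interval has a zero cell. Default `FALSE`.
#'
#' @return A tibble of class `dlr_summary` with columns `label`, `measure`,
#'   `estimate`, `ci_lower`, `ci_upper`, `level`.
#' @examples
#' studies <- data.frame(
#'   label = c("Kennedy", "Pladevall"),
#'   n_tp = c(67, 401), n_fp = c(43, 333),
#'   n_fn = c(4, 95), n_tn = c(20272, 4500)
#' )
#' summarize_validation(studies)
#' @export
summarize_validation <- function(data, level = 0.95, correction = FALSE) {
  data <- check_confusion(data)
  check_level(level)
  rows <- purrr::pmap(data, function(label, n_tp, n_fp, n_fn, n_tn, ...) {
    n <- n_tp + n_fp + n_fn + n_tn
    props <- list(
      sensitivity = c(n_tp, n_tp + n_fn),
      specificity = c(n_tn, n_fp + n_tn),
      prevalence  = c(n_tp + n_fn, n),
      ppv         = c(n_tp, n_tp + n_fp),
      npv         = c(n_tn, n_fn + n_tn)
    )
    prop_rows <- purrr::imap(props, function(xn, nm) {
      if (xn[2] == 0) {
        tibble::tibble(estimate = NA_real_, ci_lower = NA_real_,
                       ci_upper = NA_real_, level = level)
      } else {
        ci_clopper_pearson(xn[1], xn[2], level)
      }
    })
    out <- dplyr::bind_rows(
      dplyr::bind_rows(prop_rows),
      ci_dlr_katz(n_tp, n_fp, n_fn, n_tn, level, "dlr_pos", correction),
      ci_dlr_katz(n_tp, n_fp, n_fn, n_tn, level, "dlr_neg", correction)
    )
    out$label <- label
    out$measure <- factor(MEASURE_LEVELS, levels = MEASURE_LEVELS)
    out[, c("label", "measure", "estimate", "ci_lower", "ci_upper", "level")]
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dlr_summary", class(out))
  out
}

# ---- input validation helpers -----------------------------------------------

safe_ratio <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || any(!is.na(x) & (x < 0 | x > 1))) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || any(!is.na(x) & (x < 0 | x != floor(x)))) {
    abort(sprintf("`%s` must contain non-negative integers.", name))
  }
  invisible(x)
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single probability strictly inside (0, 1).")
  }
  invisible(level)
}

check_confusion <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  needed <- c("n_tp", "n_fp", "n_fn", "n_tn")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (!"label" %in% names(data)) {
    data$label <- paste0("study_", seq_len(nrow(data)))
  }
  for (col in needed) check_count(data[[col]], col)
  totals <- data$n_tp + data$n_fp + data$n_fn + data$n_tn
  if (any(totals <= 0)) abort("each study must have a positive total count.")
  tibble::as_tibble(data[, c("label", needed)])
}
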
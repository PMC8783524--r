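#' Simulate a validation-study 2x2 table
#'
#' Draws the four cells of a validation table from a multinomial with cell
#' probabilities `(p*Se, (1-p)*(1-Sp), p*(1-Se), (1-p)*Sp)` — the sampling
#' model of a validation study drawn at random from its population. Used as
#' a Monte-Carlo oracle for the closed-form estimators: [summarize_validation()]
#' applied to large draws recovers the generating parameters.
#'
#' @param n Sample size of the validation study.
#' @param prevalence,sensitivity,specificity Generating parameters in
#'   \[0, 1\].
#' @param seed Integer seed; the draw is a pure function of its arguments.
#' @param label Study label for the output row.
#' @return A one-row tibble with columns `label`, `n_tp`, `n_fp`, `n_fn`,
#'   `n_tn`; the cells always sum to `n`.
#' @examples
#' simulate_validation(5000, 0.093, 0.808, 0.931, seed = 1)
#' @export
simulate_validation <- function(n, prevalence, sensitivity, specificity,
                                seed, label = paste0("sim_", seed)) {
  check_count(n, "n")
  if (n <= 0) abort("`n` must be positive.")
  check_probability(prevalence, "prevalence")
  check_probability(sensitivity, "sensitivity")
  check_probability(specificity, "specificity")
  probs <- c(
    prevalence * sensitivity,
    (1 - prevalence) * (1 - specificity),
    prevalence * (1 - sensitivity),
    (1 - prevalence) * specificity
  )
  cells <- withr::with_seed(seed, as.vector(rmultinom(1, n, probs)))
  tibble::tibble(
    label = label,
    n_tp = cells[1], n_fp = cells[2], n_fn = cells[3], n_tn = cells[4]
  )
}

#' Simulate misclassified two-group cohort draws
#'
#' Generates a comparative cohort study with a binary outcome read through
#' an imperfect algorithm, under non-differential misclassification. Per
#' group and replicate, true positives are binomial(n, risk); observed
#' algorithm positives are a binomial thinning of the true positives at the
#' sensitivity plus false positives binomial(n - true, 1 - specificity).
#' The empirical risk ratios of these draws center on the closed-form
#' expected risk ratio at the matched parameters.
#'
#' @param n_con,n_tes Control and test group sizes.
#' @param control_risk True control-group risk, in (0, 1).
#' @param true_rr True risk ratio; `true_rr * control_risk` must be a valid
#'   risk (at most 1).
#' @param sensitivity,specificity Algorithm operating characteristics.
#' @param seed Integer seed for the single RNG stream.
#' @param reps Number of replicate draws, default 1.
#' @return A tibble with one row per replicate: `rep`, `n_con`, `n_tes`,
#'   `x_true_con`, `x_true_tes` (true positives), `obs_pos_con`,
#'   `obs_pos_tes` (algorithm positives, true plus false).
#' @examples
#' simulate_cohort(1000, 1000, 0.03, 2, 0.9, 0.99, seed = 1, reps = 3)
#' @export
simulate_cohort <- function(n_con, n_tes, control_risk, true_rr,
                            sensitivity, specificity, seed, reps = 1) {
  check_count(n_con, "n_con"); check_count(n_tes, "n_tes")
  check_count(reps, "reps")
  if (reps < 1) abort("`reps` must be at least 1.")
  check_probability(control_risk, "control_risk")
  check_probability(sensitivity, "sensitivity")
  check_probability(specificity, "specificity")
  if (true_rr <= 0) abort("`true_rr` must be positive.")
  r_tes <- true_rr * control_risk
  if (r_tes > 1) {
    abort(sprintf(
      "invalid scenario: test-group risk true_rr * control_risk = %.4g exceeds 1.",
      r_tes
    ))
  }
  withr::with_seed(seed, {
    draw_group <- function(n, risk) {
      x_true <- rbinom(reps, n, risk)
      detected <- rbinom(reps, x_true, sensitivity)
      false_pos <- rbinom(reps, n - x_true, 1 - specificity)
      list(x_true = x_true, obs = detected + false_pos)
    }
    con <- draw_group(n_con, control_risk)
    tes <- draw_group(n_tes, r_tes)
    tibble::tibble(
      rep = seq_len(reps),
      n_con = n_con, n_tes = n_tes,
      x_true_con = con$x_true, x_true_tes = tes$x_true,
      obs_pos_con = con$obs, obs_pos_tes = tes$obs
    )
  })
}

#' Empirical risk ratio of simulated cohort draws
#'
#' Adds the observed (algorithm-based) risk ratio
#' `(obs_pos_tes / n_tes) / (obs_pos_con / n_con)` to each replicate.
#' Replicates with zero observed positives in the control group have an
#' undefined ratio and get `rr = NA` rather than a continuity correction,
#' so the Monte-Carlo oracle is never silently biased; the count of such
#' dropped replicates is attached as attribute `n_dropped` and reported via
#' a message when positive.
#'
#' @param draws A tibble from [simulate_cohort()] (columns `n_con`,
#'   `n_tes`, `obs_pos_con`, `obs_pos_tes`).
#' @param quiet Suppress the dropped-replicate message? Default `FALSE`.
#' @return `draws` with an `rr` column appended; attribute `n_dropped`
#'   holds the number of undefined replicates.
#' @examples
#' draws <- simulate_cohort(500, 500, 0.05, 2, 0.9, 0.99, seed = 2, reps = 5)
#' empirical_rr(draws)
#' @export
empirical_rr <- function(draws, quiet = FALSE) {
  needed <- c("n_con", "n_tes", "obs_pos_con", "obs_pos_tes")
  if (!is.data.frame(draws) || !all(needed %in% names(draws))) {
    abort(paste0("`draws` must contain columns: ",
                 paste(needed, collapse = ", "), "."))
  }
  rr <- (draws$obs_pos_tes / draws$n_tes) / (draws$obs_pos_con / draws$n_con)
  undefined <- draws$obs_pos_con == 0
  rr[undefined] <- NA_real_
  out <- dplyr::mutate(tibble::as_tibble(draws), rr = rr)
  n_dropped <- sum(undefined)
  if (n_dropped > 0 && !quiet) {
    message(n_dropped, " replicate(s) had no observed control positives; rr set to NA.")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
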
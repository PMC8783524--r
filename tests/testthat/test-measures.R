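test_that("point estimates reproduce the published per-study measures", {
  pts <- point_estimates(mi_studies())
  get <- function(study, measure) {
    pts$estimate[pts$label == study & pts$measure == measure]
  }
  expect_equal(round(get("Kennedy", "sensitivity"), 3), 0.944)
  expect_equal(round(get("Kennedy", "specificity"), 3), 0.998)
  expect_equal(round(get("Kennedy", "prevalence"), 3), 0.003)
  expect_equal(round(get("Kennedy", "ppv"), 3), 0.609)
  expect_equal(round(get("Kennedy", "dlr_pos"), 1), 445.8)
  expect_equal(round(get("Austin", "sensitivity"), 3), 0.888)
  expect_equal(round(get("Austin", "dlr_pos"), 1), 12.4)

  flat <- point_estimates(
    data.frame(label = "flat", n_tp = 25, n_fp = 25, n_fn = 25, n_tn = 25)
  )
  expect_equal(flat$estimate[flat$measure == "sensitivity"], 0.5)
  expect_equal(flat$estimate[flat$measure == "specificity"], 0.5)
  expect_equal(flat$estimate[flat$measure == "dlr_pos"], 1)
})

test_that("likelihood-ratio primitives match their definitions and edge cases", {
  expect_equal(round(dlr_positive(0.943662, 0.997883), 1), 445.8)
  expect_equal(dlr_positive(1, 0.5), 2)
  expect_equal(round(dlr_positive(0.808, 0.931), 1), 11.7)
  expect_identical(dlr_positive(0.9, 1), Inf)
  expect_true(is.na(dlr_positive(0, 1)))
  expect_error(dlr_positive(1.2, 0.5), "probability")

  expect_equal(dlr_negative(1, 0.9), 0)
  expect_equal(dlr_negative(0.5, 0.5), 1)
  expect_equal(round(dlr_negative(0.888, 0.928), 4), 0.1207)
  expect_true(is.na(dlr_negative(0.5, 0)))
})

test_that("DLR+ above 1 forces DLR- below 1 and vice versa", {
  tables <- random_tables(50, seed = 11)
  pts <- point_estimates(tables)
  wide <- tidyr::pivot_wider(pts, names_from = "measure",
                             values_from = "estimate")
  informative <- wide$dlr_pos != 1
  expect_true(all((wide$dlr_pos[informative] > 1) ==
                    (wide$dlr_neg[informative] < 1)))
})

test_that("Clopper-Pearson intervals match the printed values and the tail-inversion oracle", {
  ci <- ci_clopper_pearson(67, 71)
  expect_equal(round(ci$ci_lower, 3), 0.862)
  expect_equal(round(ci$ci_upper, 3), 0.984)

  expect_identical(ci_clopper_pearson(0, 10)$ci_lower, 0)
  expect_identical(ci_clopper_pearson(10, 10)$ci_upper, 1)

  # exhaustive comparison against bisection on the binomial tails
  for (n in c(1, 5, 12, 30)) {
    for (x in 0:n) {
      got <- ci_clopper_pearson(x, n)
      want <- cp_oracle(x, n)
      expect_equal(c(got$ci_lower, got$ci_upper), want, tolerance = 1e-9,
                   info = sprintf("x=%d n=%d", x, n))
    }
  }

  # independent cross-check against stats::binom.test at another level
  bt <- binom.test(5, 17, conf.level = 0.9)
  got <- ci_clopper_pearson(5, 17, level = 0.9)
  expect_equal(c(got$ci_lower, got$ci_upper),
               unname(bt$conf.int), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(ci_clopper_pearson(5, 3), "exceed")
  expect_error(ci_clopper_pearson(-1, 3), "non-negative")
})

test_that("Katz log-scale DLR intervals reproduce the published bounds", {
  k <- kennedy()
  ci <- ci_dlr_katz(k$n_tp, k$n_fp, k$n_fn, k$n_tn)
  expect_equal(round(ci$estimate, 1), 445.8)
  expect_equal(round(ci$ci_lower, 1), 329.0)
  expect_equal(round(ci$ci_upper, 1), 604.2)

  p <- pladevall()
  ci <- ci_dlr_katz(p$n_tp, p$n_fp, p$n_fn, p$n_tn)
  expect_equal(round(ci$ci_lower, 1), 10.5)
  expect_equal(round(ci$ci_upper, 1), 13.1)
})

test_that("Katz interval is log-symmetric and narrows as counts scale up", {
  tables <- random_tables(20, seed = 23)
  cis <- ci_dlr_katz(tables$n_tp, tables$n_fp, tables$n_fn, tables$n_tn)
  expect_equal(sqrt(cis$ci_lower * cis$ci_upper), cis$estimate,
               tolerance = 1e-9)

  k <- kennedy()
  widths <- sapply(c(1, 2, 5, 10, 50), function(scale) {
    ci <- ci_dlr_katz(k$n_tp * scale, k$n_fp * scale,
                      k$n_fn * scale, k$n_tn * scale)
    expect_equal(ci$estimate, 445.8254, tolerance = 1e-3)
    log(ci$ci_upper) - log(ci$ci_lower)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("zero cells give not-estimable Katz intervals unless corrected", {
  plain <- ci_dlr_katz(0, 10, 5, 100)
  expect_true(is.na(plain$ci_lower) && is.na(plain$ci_upper))
  perfect_sp <- ci_dlr_katz(10, 0, 5, 100)
  expect_identical(perfect_sp$estimate, Inf)
  expect_true(is.na(perfect_sp$ci_lower))

  corrected <- ci_dlr_katz(10, 0, 5, 100, correction = TRUE)
  expect_true(is.finite(corrected$estimate))
  expect_true(corrected$ci_lower > 0 && is.finite(corrected$ci_upper))
})

test_that("summarize_validation reproduces the published CI table", {
  summ <- summarize_validation(mi_studies())
  chk <- function(study, measure, est, lo, hi, dp = 3) {
    row <- get_estimate(summ, study, measure)
    expect_equal(round(row$estimate, dp), est)
    expect_equal(round(row$ci_lower, dp), lo)
    expect_equal(round(row$ci_upper, dp), hi)
  }
  chk("Kennedy", "sensitivity", 0.944, 0.862, 0.984)
  chk("Kennedy", "ppv", 0.609, 0.511, 0.701)
  chk("Kennedy", "npv", 1.000, 0.999, 1.000)
  chk("Kennedy", "dlr_pos", 445.8, 329.0, 604.2, dp = 1)
  chk("Pladevall", "sensitivity", 0.808, 0.771, 0.842)
  chk("Pladevall", "prevalence", 0.093, 0.085, 0.101)
  chk("Pladevall", "npv", 0.979, 0.975, 0.983)
  chk("Austin", "specificity", 0.928, 0.926, 0.931)
  chk("Austin", "dlr_pos", 12.4, 12.0, 12.9, dp = 1)
  expect_equal(unique(summ$level), 0.95)
})

test_that("per-measure not-estimable states do not abort the summary", {
  # no truly diseased subjects: sensitivity, prevalence CI etc. still fine,
  # but dlr intervals with zero numerator cells are NA
  odd <- data.frame(label = "odd", n_tp = 0, n_fp = 10, n_fn = 0, n_tn = 90)
  summ <- summarize_validation(odd)
  expect_equal(nrow(summ), 7)
  expect_true(is.na(get_estimate(summ, "odd", "sensitivity")$estimate))
  expect_equal(get_estimate(summ, "odd", "specificity")$estimate, 0.9)
  expect_true(is.na(get_estimate(summ, "odd", "dlr_pos")$estimate))
})

test_that("confusion-table invariants are enforced", {
  expect_error(summarize_validation(data.frame(n_tp = 1, n_fp = 1, n_fn = 1)),
               "missing column")
  expect_error(
    summarize_validation(
      data.frame(label = "x", n_tp = -1, n_fp = 1, n_fn = 1, n_tn = 1)),
    "non-negative")
  expect_error(
    summarize_validation(
      data.frame(label = "x", n_tp = 0, n_fp = 0, n_fn = 0, n_tn = 0)),
    "positive total")
  expect_error(
    summarize_validation(
      data.frame(label = "x", n_tp = 1.5, n_fp = 1, n_fn = 1, n_tn = 1)),
    "non-negative integers")
})

test_that("validation PPV equals the Bayes projection at the validation prevalence", {
  # cross-module identity: ppv = expected_ppv(dlr_pos, prevalence)
  tables <- random_tables(30, seed = 31)
  pts <- tidyr::pivot_wider(point_estimates(tables),
                            names_from = "measure", values_from = "estimate")
  expect_equal(pts$ppv, expected_ppv(pts$dlr_pos, pts$prevalence),
               tolerance = 1e-12)
  # and the analogous NPV identity
  expect_equal(pts$npv, expected_npv(pts$dlr_neg, pts$prevalence),
               tolerance = 1e-12)
})
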
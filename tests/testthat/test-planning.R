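test_that("expected PPV follows the odds form of Bayes' theorem", {
  expect_equal(round(expected_ppv(445.8, 0.05), 3), 0.959)
  expect_equal(expected_ppv(1, 0.37), 0.37)
  k <- pladevall()
  dlr <- ci_dlr_katz(k$n_tp, k$n_fp, k$n_fn, k$n_tn)$estimate
  expect_equal(round(expected_ppv(dlr, 0.05), 3), 0.382)

  expect_identical(expected_ppv(Inf, 0.05), 1)
  expect_identical(expected_ppv(Inf, 0), 0)
  expect_identical(expected_ppv(0, 0.5), 0)
  expect_error(expected_ppv(-1, 0.5), "non-negative")
  expect_error(expected_ppv(2, 1.5), "probability")
})

test_that("expected NPV mirrors expected PPV for negative results", {
  expect_equal(expected_npv(0, 0.3), 1)
  expect_equal(expected_npv(1, 0.3), 0.7)
  # at the validation study's own prevalence the projection must return
  # the validation NPV (Bayes identity)
  p <- pladevall()
  pts <- tidyr::pivot_wider(point_estimates(p), names_from = "measure",
                            values_from = "estimate")
  expect_equal(round(expected_npv(pts$dlr_neg, pts$prevalence), 3), 0.979)
  expect_equal(expected_npv(pts$dlr_neg, pts$prevalence), pts$npv,
               tolerance = 1e-12)
})

test_that("the direct Bayes form and the DLR form of expected PPV agree", {
  grid <- tidyr::expand_grid(
    se = c(0.6, 0.808, 0.944, 0.99),
    sp = c(0.9, 0.931, 0.998),
    p = c(0.003, 0.05, 0.3, 0.9)
  )
  direct <- with(grid, se * p / (se * p + (1 - sp) * (1 - p)))
  via_dlr <- with(grid, expected_ppv(dlr_positive(se, sp), p))
  expect_equal(direct, via_dlr, tolerance = 1e-12)
})

test_that("dlr_from_ppv reproduces the worked back-solved values", {
  expect_equal(round(dlr_from_ppv(0.8, 0.04)), 96)
  expect_equal(round(dlr_from_ppv(0.8, 0.06)), 63)
  expect_equal(round(dlr_from_ppv(0.7202, 0.3)), 6)
  expect_error(dlr_from_ppv(1, 0.1), "strictly inside")
  expect_error(dlr_from_ppv(0.5, 0), "strictly inside")
})

test_that("dlr_from_ppv is the exact inverse of expected_ppv", {
  withr::with_seed(7, {
    d <- 10^runif(200, -3, 6)
    p <- runif(200, 0.001, 0.999)
  })
  ppv <- expected_ppv(d, p)
  ok <- ppv > 0 & ppv < 1
  expect_equal(dlr_from_ppv(ppv[ok], p[ok]) / d[ok], rep(1, sum(ok)),
               tolerance = 1e-9)
})

test_that("expected counts and risks follow the misclassification algebra", {
  expect_equal(expected_positive_count(1000, 30, 1, 1), 30)
  expect_equal(expected_positive_count(1000, 30, 0.9, 0.95), 75.5)
  expect_equal(expected_positive_count(1000, 0, 0.9, 0.95), 50)
  expect_error(expected_positive_count(10, 20, 0.9, 0.9), "exceed")

  expect_equal(expected_risk(0.03, 1, 1), 0.03)
  expect_equal(expected_risk(0, 0.9, 0.95), 0.05)
  expect_equal(round(expected_risk(0.03, 0.943662, 0.997883), 6), 0.030363)
  # per-subject and per-count forms agree for any n
  for (n in c(10, 1000)) {
    expect_equal(expected_positive_count(n, round(0.2 * n), 0.8, 0.9) / n,
                 expected_risk(round(0.2 * n) / n, 0.8, 0.9))
  }
})

test_that("expected risk ratio reproduces the published bias figures", {
  expect_equal(round(expected_rr(2, 0.03, 445.8254)$bias_relative_pct, 2),
               -3.49)
  expect_equal(round(expected_rr(2, 0.03, 12.41254)$bias_relative_pct, 1),
               -37.2)
  expect_equal(round(expected_rr(2, 0.03, 11.73371)$bias_relative_pct, 1),
               -37.8)
  null <- expected_rr(1, 0.05, 12.4)
  expect_equal(null$rr_expected, 1)
  expect_equal(null$bias_absolute, 0)
  expect_identical(expected_rr(2, 0.03, Inf)$rr_expected, 2)
  expect_error(expected_rr(30, 0.5, 10), "exceeds 1")
})

test_that("ratio-of-expected-risks form agrees with the closed-form expected RR", {
  grid <- tidyr::expand_grid(
    rr = c(1, 1.5, 2), rc = c(0.01, 0.03, 0.1),
    se = c(0.8, 0.944), sp = c(0.93, 0.998)
  )
  via_risks <- with(grid, expected_risk(rr * rc, se, sp) /
                      expected_risk(rc, se, sp))
  via_dlr <- with(grid, expected_rr(rr, rc, dlr_positive(se, sp))$rr_expected)
  expect_equal(via_risks, via_dlr, tolerance = 1e-12)
})

test_that("bias is always attenuation toward the null when the true RR exceeds 1", {
  withr::with_seed(13, {
    rr <- runif(300, 1 + 1e-6, 5)
    rc <- runif(300, 0.001, 0.19)
    d <- 10^runif(300, -2, 5)
  })
  res <- expected_rr(rr, rc, d)
  expect_true(all(res$rr_expected < res$true_rr))
  expect_true(all(res$bias_relative_pct < 0))
})

test_that("expected RR approaches the true RR monotonically as DLR+ grows", {
  d_seq <- 10^seq(0, 6, length.out = 30)
  res <- expected_rr(2, 0.03, d_seq)
  expect_true(all(diff(res$rr_expected) > 0))
  expect_equal(res$rr_expected[30], 2, tolerance = 1e-3)
  expect_lt(abs(expected_rr(2, 0.03, 1e9)$bias_absolute), 1e-6)
})

test_that("range propagation over scenario endpoints reproduces published ranges", {
  k <- kennedy()
  kci <- ci_dlr_katz(k$n_tp, k$n_fp, k$n_fn, k$n_tn)
  sc <- planning_scenario(dlr_pos = c(kci$ci_lower, kci$ci_upper),
                          prevalence_db = 0.05,
                          control_risk = 0.03, true_rr = 2)
  out <- assess_over_ranges(sc)
  ppv <- out[out$measure == "ppv_db", ]
  expect_equal(round(ppv$lower, 3), 0.945)
  expect_equal(round(ppv$upper, 3), 0.970)
  bias <- out[out$measure == "bias_relative_pct", ]
  expect_equal(round(bias$lower, 2), -4.61)
  expect_equal(round(bias$upper, 2), -2.62)

  # degenerate ranges collapse to the point operations
  sc_pt <- planning_scenario(dlr_pos = 445.8254, prevalence_db = 0.05)
  out_pt <- assess_over_ranges(sc_pt)
  expect_equal(out_pt$lower, out_pt$upper)
  expect_equal(out_pt$lower, expected_ppv(445.8254, 0.05))
})

test_that("endpoint evaluation is exact because the projections are monotone", {
  # dense-grid extremes equal endpoint extremes for a box of parameters
  d_rng <- c(50, 600); p_rng <- c(0.02, 0.2)
  dense <- tidyr::expand_grid(d = seq(d_rng[1], d_rng[2], length.out = 41),
                              p = seq(p_rng[1], p_rng[2], length.out = 41))
  dense_rng <- range(expected_ppv(dense$d, dense$p))
  sc <- planning_scenario(dlr_pos = d_rng, prevalence_db = p_rng)
  out <- assess_over_ranges(sc)
  expect_equal(c(out$lower[out$measure == "ppv_db"],
                 out$upper[out$measure == "ppv_db"]),
               dense_rng, tolerance = 1e-12)
})

test_that("scenario invariants are validated", {
  expect_error(planning_scenario(dlr_pos = c(10, 5, 2)), "range")
  expect_error(planning_scenario(dlr_pos = 10, prevalence_db = 1.2),
               "strictly between")
  expect_error(planning_scenario(dlr_pos = 10, control_risk = 0.5,
                                 true_rr = 3), "exceeds 1")
  expect_error(assess_over_ranges(planning_scenario(dlr_pos = 10)),
               "projection target")
  expect_error(assess_over_ranges(list()), "planning_scenario")
})
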
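# Validation-study 2x2 tables from three published acute-MI algorithm
# validation studies (cell counts as published: TP, FP, FN, TN).
mi_studies <- function() {
  tibble::tibble(
    label = c("Kennedy", "Pladevall", "Austin"),
    n_tp = c(67, 401, 20048),
    n_fp = c(43, 333, 2594),
    n_fn = c(4, 95, 2521),
    n_tn = c(20272, 4500, 33653)
  )
}

kennedy <- function() mi_studies()[1, ]
pladevall <- function() mi_studies()[2, ]
austin <- function() mi_studies()[3, ]

# Eight acute-MI algorithms reported only through their PPVs
# (troponin-based gold standards).
mi_ppv_algorithms <- function() {
  tibble::tibble(
    label = c("Merry 2009", "Kiyota 2004p", "Ainla 2006", "Kiyota 2004s",
              "Barchielli 2010", "Hammar 2001", "Heckbert 2004",
              "Varas-Lorenzo 2008"),
    ppv = c(0.9688, 0.9411, 0.933, 0.9245, 0.8602, 0.8583, 0.8302, 0.7202)
  )
}

get_estimate <- function(summary, study, measure) {
  row <- summary[summary$label == study & summary$measure == measure, ]
  stopifnot(nrow(row) == 1)
  row
}

# Independent Clopper-Pearson oracle: invert the exact binomial tail
# probabilities by bisection on p (no beta quantiles involved).
cp_oracle <- function(x, n, level = 0.95, tol = 1e-12) {
  alpha <- 1 - level
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else {
    # largest p with P(X >= x | p) <= alpha/2
    bisect(function(p) sum(dbinom(x:n, n, p)) - alpha / 2, 0, 1)
  }
  upper <- if (x == n) 1 else {
    # smallest p with P(X <= x | p) <= alpha/2
    bisect(function(p) -(sum(dbinom(0:x, n, p)) - alpha / 2), 0, 1)
  }
  c(lower, upper)
}

# random valid 2x2 tables with all cells positive
random_tables <- function(n_tables, seed, max_cell = 500) {
  withr::with_seed(seed, {
    tibble::tibble(
      label = paste0("rand_", seq_len(n_tables)),
      n_tp = sample(1:max_cell, n_tables, replace = TRUE),
      n_fp = sample(1:max_cell, n_tables, replace = TRUE),
      n_fn = sample(1:max_cell, n_tables, replace = TRUE),
      n_tn = sample(1:max_cell, n_tables, replace = TRUE)
    )
  })
}
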
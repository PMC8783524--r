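#' Plausible-prevalence band
#'
#' An investigator-chosen interval of plausible disease prevalences for the
#' source validation populations, used when back-solving DLR+ from PPV-only
#' reports. The band is a judgement call based on the studies and external
#' information; it is never inferred from the data.
#'
#' @param p_min,p_max Band endpoints with `0 < p_min <= p_max < 1`.
#' @return A numeric length-2 vector of class `prevalence_band`.
#' @examples
#' prevalence_band(0.1, 0.3)
#' @export
prevalence_band <- function(p_min, p_max) {
  if (!is.numeric(p_min) || !is.numeric(p_max) ||
      length(p_min) != 1 || length(p_max) != 1 ||
      p_min <= 0 || p_max >= 1 || p_min > p_max) {
    abort("need 0 < p_min <= p_max < 1.")
  }
  structure(c(p_min = p_min, p_max = p_max), class = "prevalence_band")
}

as_band <- function(band) {
  if (inherits(band, "prevalence_band")) return(band)
  if (is.numeric(band) && length(band) == 2) {
    return(prevalence_band(band[1], band[2]))
  }
  abort("`band` must be a prevalence_band() or a length-2 numeric vector.")
}

#' DLR+ as a curve over prevalence for a fixed PPV
#'
#' Evaluates the odds-ratio inversion [dlr_from_ppv()] over a prevalence
#' grid. For a fixed PPV the curve is strictly decreasing in prevalence: a
#' given PPV in a low-prevalence population demands a much more informative
#' algorithm than the same PPV where disease is common. At `prevalence ==
#' ppv` the curve passes through 1.
#'
#' @param ppv A single PPV strictly inside (0, 1).
#' @param prevalence_grid Strictly increasing prevalences strictly inside
#'   (0, 1).
#' @return A tibble with columns `ppv`, `prevalence`, `dlr_pos`.
#' @examples
#' dlr_curve(0.9688, c(0.1, 0.2, 0.3))
#' @export
dlr_curve <- function(ppv, prevalence_grid) {
  if (length(ppv) != 1) abort("`ppv` must be a single value.")
  if (any(prevalence_grid <= 0 | prevalence_grid >= 1)) {
    abort("`prevalence_grid` must lie strictly inside (0, 1).")
  }
  if (length(prevalence_grid) > 1 && any(diff(prevalence_grid) <= 0)) {
    abort("`prevalence_grid` must be strictly increasing.")
  }
  tibble::tibble(
    ppv = ppv,
    prevalence = prevalence_grid,
    dlr_pos = dlr_from_ppv(ppv, prevalence_grid)
  )
}

#' Plausible DLR+ span from PPV-only algorithms
#'
#' Given several phenotype algorithms known only through their reported
#' PPVs, and a band of plausible source-population prevalences, each
#' algorithm is compatible with an interval of DLR+ values (its curve
#' restricted to the band). Two span rules summarize the collection:
#'
#' * `"all"` — the smallest interval consistent with every algorithm:
#'   a horizontal line rising from below first touches the lowest-PPV curve
#'   at the band's upper prevalence, and one descending from above first
#'   touches the highest-PPV curve at the band's lower prevalence, so
#'   `lower = dlr_from_ppv(min ppv, p_max)` and
#'   `upper = dlr_from_ppv(max ppv, p_min)`.
#' * `"median"` — the interval spanned by the central algorithm(s) after
#'   sorting by PPV: the middle one for an odd count, the middle two for an
#'   even count. Ties are resolved by a stable sort on (ppv, label), and
#'   tied central PPVs collapse to a single curve.
#'
#' @param algorithms A data frame with columns `label` and `ppv` (each PPV
#'   strictly inside (0, 1)), one algorithm per row.
#' @param band A [prevalence_band()] or length-2 numeric `c(p_min, p_max)`.
#' @param rule `"all"` (default) or `"median"`.
#' @return A one-row tibble with columns `rule`, `lower`, `upper`,
#'   `n_algorithms`. Endpoints are kept at full precision; round only for
#'   display.
#' @examples
#' algos <- data.frame(label = c("A", "B", "C"),
#'                     ppv = c(0.72, 0.86, 0.97))
#' dlr_span(algos, c(0.1, 0.3), rule = "all")
#' @export
dlr_span <- function(algorithms, band, rule = c("all", "median")) {
  rule <- match.arg(rule)
  algorithms <- check_algorithms(algorithms)
  band <- as_band(band)
  ord <- order(algorithms$ppv, algorithms$label)
  sorted <- algorithms[ord, ]
  n <- nrow(sorted)
  central <- if (rule == "all") {
    sorted
  } else if (n %% 2 == 1) {
    sorted[(n + 1) / 2, ]
  } else {
    sorted[c(n / 2, n / 2 + 1), ]
  }
  tibble::tibble(
    rule = rule,
    lower = dlr_from_ppv(min(central$ppv), band[["p_max"]]),
    upper = dlr_from_ppv(max(central$ppv), band[["p_min"]]),
    n_algorithms = n
  )
}

#' Per-algorithm DLR+ at the band endpoints
#'
#' The band-restricted DLR+ interval of each algorithm: since the curve is
#' decreasing in prevalence, each algorithm's interval runs from its value
#' at `p_max` up to its value at `p_min`.
#'
#' @inheritParams dlr_span
#' @return A tibble with columns `label`, `ppv`, `dlr_at_p_max`,
#'   `dlr_at_p_min`, sorted by `ppv`.
#' @examples
#' algos <- data.frame(label = c("A", "B"), ppv = c(0.72, 0.97))
#' band_dlr_table(algos, c(0.1, 0.3))
#' @export
band_dlr_table <- function(algorithms, band) {
  algorithms <- check_algorithms(algorithms)
  band <- as_band(band)
  out <- dplyr::mutate(
    algorithms,
    dlr_at_p_max = dlr_from_ppv(.data$ppv, band[["p_max"]]),
    dlr_at_p_min = dlr_from_ppv(.data$ppv, band[["p_min"]])
  )
  dplyr::arrange(out, .data$ppv, .data$label)
}

check_algorithms <- function(algorithms) {
  if (!is.data.frame(algorithms) || nrow(algorithms) == 0) {
    abort("`algorithms` must be a data frame with at least one row.")
  }
  if (!"ppv" %in% names(algorithms)) {
    abort("`algorithms` must have a `ppv` column.")
  }
  if (!"label" %in% names(algorithms)) {
    algorithms$label <- paste0("algorithm_", seq_len(nrow(algorithms)))
  }
  if (any(algorithms$ppv <= 0 | algorithms$ppv >= 1)) {
    abort("every `ppv` must be strictly inside (0, 1).")
  }
  tibble::as_tibble(algorithms[, c("label", "ppv")])
}
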
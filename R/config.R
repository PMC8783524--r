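#' Load run parameters from a key-value config file
#'
#' Parses a plain-text file of `key: value` (or `key = value`) lines;
#' blank lines and lines starting with `#` are ignored. Recognized keys:
#'
#' * `level` — confidence level (single probability; default 0.95)
#' * `prevalence`, `control_risk`, `dlr` — a value or a range `lo:hi`
#' * `true_rr` — single positive value
#' * `band` — prevalence band `lo:hi`
#' * `rule` — span rule, `all` or `median`
#'
#' Unknown keys and malformed lines are rejected with an error naming the
#' offending key or line.
#'
#' @param path Path to the config file. An empty file yields all defaults.
#' @return A named list with `level` always present (defaulted) and any
#'   other supplied keys parsed: ranges as length-2 numeric vectors,
#'   `band` as a [prevalence_band()].
#' @examples
#' cfg <- tempfile()
#' writeLines(c("level: 0.90", "band: 0.1:0.3"), cfg)
#' load_config(cfg)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  out <- list(level = 0.95)
  known <- c("level", "prevalence", "control_risk", "dlr", "true_rr",
             "band", "rule")
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.+)$", line))[[1]]
    if (length(m) != 3) {
      abort(sprintf("malformed config line %d: \"%s\"", i, line))
    }
    key <- m[2]; value <- trimws(m[3])
    if (!key %in% known) {
      abort(sprintf("unknown config key \"%s\" (line %d); known keys: %s",
                    key, i, paste(known, collapse = ", ")))
    }
    out[[key]] <- switch(
      key,
      rule = {
        if (!value %in% c("all", "median")) {
          abort(sprintf("config key \"rule\" (line %d) must be all or median.", i))
        }
        value
      },
      level = ,
      true_rr = {
        v <- suppressWarnings(as.numeric(value))
        if (is.na(v)) abort(sprintf("config key \"%s\" (line %d) is not numeric.", key, i))
        v
      },
      band = {
        r <- parse_range(value, key, i)
        prevalence_band(r[1], r[2])
      },
      parse_range(value, key, i)  # prevalence, control_risk, dlr
    )
  }
  check_level(out$level)
  out
}

# "0.1:0.3" -> c(0.1, 0.3); "0.05" -> 0.05
parse_range <- function(value, key, line_no) {
  parts <- strsplit(value, ":", fixed = TRUE)[[1]]
  v <- suppressWarnings(as.numeric(parts))
  if (any(is.na(v)) || !length(v) %in% c(1, 2)) {
    abort(sprintf("config key \"%s\" (line %d) must be a number or lo:hi range.",
                  key, line_no))
  }
  v
}
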
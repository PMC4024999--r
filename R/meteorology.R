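#' Atmospheric stability class labels
#'
#' Six-level stability scheme (A--F analogue) used throughout the plume
#' model, ordered from convective to strongly stratified.
#'
#' @format Character vector of length 6.
#' @export
stability_levels <- c(
  "very_unstable", "unstable", "slightly_unstable",
  "neutral", "stable", "very_stable"
)

# Golder (1972)-style nomogram digitized to linear boundaries in
# (1/L, log10 z0) space. Row k gives the 1/L boundary between class k and
# class k+1 as a + b * log10(z0). Data, not physics: swappable via the
# `boundaries` argument of classify_stability().
golder_coefs <- data.frame(
  boundary = c("A_B", "B_C", "C_D", "D_E", "E_F"),
  a = c(-0.096, -0.037, -0.002, 0.004, 0.035),
  b = c(0.029, 0.029, 0.018, -0.018, -0.036)
)

stability_boundaries <- function(z0) {
  # Nomogram validity range; clamp rather than extrapolate.
  z0 <- min(max(z0, 0.001), 0.5)
  golder_coefs$a + golder_coefs$b * log10(z0)
}

#' Classify atmospheric stability from Monin--Obukhov length
#'
#' Maps a signed Monin--Obukhov length `L` (m) and surface roughness length
#' `z0` (m) to one of six stability classes via a shipped boundary table on
#' (1/L, z0). Negative `L` of small magnitude means strong convection
#' (very unstable); positive small-magnitude `L` means strong stratification
#' (very stable); `|1/L| < 1e-4` is always neutral, so "neutral" can be
#' encoded as any large-magnitude `L` without an infinite sentinel.
#'
#' @param obukhov_length Signed Monin--Obukhov length, m. Must be nonzero.
#' @param roughness_length Surface roughness length, m (> 0). Recycled.
#' @return A factor with levels [stability_levels], same length as
#'   `obukhov_length`.
#' @examples
#' classify_stability(c(-5, 1e6, 15), 0.1)
#' @export
classify_stability <- function(obukhov_length, roughness_length = 0.1) {
  L <- obukhov_length
  if (!is.numeric(L) || anyNA(L)) abort_domain("`obukhov_length` must be numeric, non-missing.")
  if (any(L == 0)) abort_domain("Monin-Obukhov length must be nonzero (use a large magnitude for neutral).")
  z0 <- rep_len(roughness_length, length(L))
  if (any(z0 <= 0)) abort_domain("`roughness_length` must be > 0.")
  s <- 1 / L
  lab <- vapply(seq_along(s), function(i) {
    if (abs(s[i]) < 1e-4) return("neutral")
    bb <- stability_boundaries(z0[i])
    stability_levels[findInterval(s[i], bb) + 1L]
  }, character(1))
  factor(lab, levels = stability_levels)
}

met_required_cols <- c(
  "timestamp", "wind_speed", "wind_direction", "temperature",
  "rel_humidity", "precipitation", "obukhov_length"
)

# Shared validator used by the reader and by the synthetic generator.
# Timestamps label the START of each hour.
validate_met_series <- function(df, roughness_length = 0.1, calm_threshold = 0.5) {
  missing_cols <- setdiff(met_required_cols, names(df))
  if (length(missing_cols) > 0) {
    abort_format(paste0("Missing mandatory met column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  ts <- df$timestamp
  if (!inherits(ts, "POSIXct")) {
    abort_format("`timestamp` must parse as ISO-8601 date-times.")
  }
  if (anyNA(ts)) abort_format("Unparseable timestamp(s) in met series.")
  if (any(diff(as.numeric(ts)) <= 0)) {
    bad <- which(diff(as.numeric(ts)) <= 0)[1] + 1L
    abort_sequence(sprintf("Timestamps are not strictly increasing at row %d.", bad))
  }
  checks <- list(
    wind_speed = function(v) v >= 0,
    wind_direction = function(v) v >= 0 & v < 360,
    rel_humidity = function(v) v >= 0 & v <= 100,
    precipitation = function(v) v >= 0,
    obukhov_length = function(v) v != 0
  )
  for (nm in names(checks)) {
    ok <- checks[[nm]](df[[nm]])
    if (anyNA(df[[nm]]) || !all(ok)) {
      row <- which(is.na(df[[nm]]) | !ok)[1]
      abort_validation(sprintf("Out-of-range value in column `%s` at row %d.", nm, row))
    }
  }
  if (!"roughness_length" %in% names(df)) df$roughness_length <- roughness_length
  out <- tibble::as_tibble(df[c(met_required_cols, "roughness_length")])
  out$calm <- out$wind_speed < calm_threshold
  out$stability <- classify_stability(out$obukhov_length, out$roughness_length)
  # Gap report: expected hourly cadence from first to last stamp.
  expected <- seq(min(ts), max(ts), by = 3600)
  gaps <- expected[!expected %in% ts]
  attr(out, "gaps") <- gaps
  attr(out, "calm_threshold") <- calm_threshold
  if (length(gaps) > 0) {
    inform(sprintf("Met series has %d missing hour(s); see attr(x, \"gaps\").",
                   length(gaps)))
  }
  class(out) <- c("met_series", class(out))
  out
}

#' Read an hourly meteorology table
#'
#' Reads a delimited (comma or tab) hourly meteorology file with a header row
#' and ISO-8601 timestamps, validates ranges and temporal ordering, flags
#' calm hours, classifies stability from the Monin--Obukhov length, and
#' reports (never fills) gaps in the hourly sequence.
#'
#' Mandatory columns (renameable via `col_map`): `timestamp`, `wind_speed`
#' (m/s), `wind_direction` (degrees, direction the wind blows from),
#' `temperature` (deg C), `rel_humidity` (%), `precipitation` (mm/h),
#' `obukhov_length` (m, signed, nonzero). Optional: `roughness_length` (m).
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(wind_speed = "ws")`.
#' @param roughness_length Site roughness length, m, used when the file has
#'   no `roughness_length` column.
#' @param calm_threshold Wind speed (m/s) below which an hour is flagged calm
#'   and excluded from plume evaluation.
#' @return A `met_series` tibble; missing hours are listed in
#'   `attr(x, "gaps")`.
#' @export
read_met_series <- function(path, col_map = NULL, roughness_length = 0.1,
                            calm_threshold = 0.5) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df)) {
        abort_format(sprintf("Mapped column `%s` not found in file.", col_map[[canon]]))
      }
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  if ("timestamp" %in% names(df) && is.character(df$timestamp)) {
    df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  }
  validate_met_series(df, roughness_length = roughness_length,
                      calm_threshold = calm_threshold)
}

#' Write a met series back to delimited text
#'
#' Inverse of [read_met_series()]: writing then re-reading a validated series
#' reproduces it (round-trip identity on the canonical columns).
#'
#' @param met A `met_series` tibble.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_met_series <- function(met, path) {
  out <- met[c(met_required_cols, "roughness_length")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}
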
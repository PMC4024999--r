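# Pasture emissions: weather/occupancy scaling rules, diurnal and seasonal
# distribution indices, and inverse dispersion estimation of area-emission
# densities from receptor observations.

#' Weather/occupancy scaling rule
#'
#' Multiplicative factors applied to pasture emissions: continuous
#' measurements put rainy-day allergen concentrations at about 18% of
#' dry-day levels, and a pasture without horses at about 10% of one with
#' horses; rain with no horses emits nothing.
#'
#' @param rain_factor Rain-day factor, in \[0, 1\].
#' @param no_horse_factor Horse-free factor, in \[0, 1\].
#' @return A named list of class `scaling_rule`.
#' @export
scaling_rule <- function(rain_factor = 0.18, no_horse_factor = 0.10) {
  if (rain_factor < 0 || rain_factor > 1 || no_horse_factor < 0 || no_horse_factor > 1) {
    abort_domain("Scaling factors must lie in [0, 1].")
  }
  structure(list(rain_factor = rain_factor, no_horse_factor = no_horse_factor,
                 rain_and_no_horse = 0),
            class = "scaling_rule")
}

#' Weather/occupancy emission scale factor
#'
#' @param rule A [scaling_rule()].
#' @param precip_day Logical: does the day have precipitation?
#' @param horses_present Logical: are horses on the pasture that day?
#' @return Scale factor: 1 (dry, horses), `rain_factor` (rain, horses),
#'   `no_horse_factor` (dry, no horses), 0 (rain, no horses). Vectorized.
#' @export
weather_occupancy_scale <- function(rule = scaling_rule(), precip_day,
                                    horses_present) {
  n <- max(length(precip_day), length(horses_present))
  precip_day <- rep_len(as.logical(precip_day), n)
  horses_present <- rep_len(as.logical(horses_present), n)
  dplyr::case_when(
    !precip_day & horses_present ~ 1,
    precip_day & horses_present ~ rule$rain_factor,
    !precip_day & !horses_present ~ rule$no_horse_factor,
    .default = rule$rain_and_no_horse
  )
}

#' Diurnal pasture emission index
#'
#' Hourly index proportional to the number of horses on the pasture, shaped
#' so the dry-day-with-horses reference has daily mean exactly 1, then
#' multiplied by the weather/occupancy scale. A rain day therefore keeps the
#' same shape at 18% of the dry amplitude, and a horse-free dry day falls
#' back to a flat profile at the horse-free factor.
#'
#' @param horses_in_pasture Numeric vector, one count per hour (24 per day).
#' @param precip_day Logical, one flag per day (recycled over hours).
#' @param rule A [scaling_rule()].
#' @return Numeric index vector, same length as `horses_in_pasture`.
#' @export
pasture_diurnal_index <- function(horses_in_pasture, precip_day = FALSE,
                                  rule = scaling_rule()) {
  n <- length(horses_in_pasture)
  if (n %% 24 != 0) abort_domain("Horse-count series must cover whole days.")
  if (any(horses_in_pasture < 0)) abort_domain("Horse counts must be >= 0.")
  days <- n / 24
  precip_day <- rep_len(as.logical(precip_day), days)
  out <- numeric(n)
  for (d in seq_len(days)) {
    rows <- ((d - 1) * 24 + 1):(d * 24)
    h <- horses_in_pasture[rows]
    present <- any(h > 0)
    scale <- weather_occupancy_scale(rule, precip_day[d], present)
    shape <- if (present) h / mean(h) else rep(1, 24)
    out[rows] <- shape * scale
  }
  out
}

#' Default monthly emission profile
#'
#' Relative monthly factors, winter minimum and summer maximum, normalized
#' to annual mean 1. The shape is declared configuration (seasonal field
#' numbers are not available); only the winter-low / summer-high ordering is
#' observation-backed.
#'
#' @return Numeric vector of length 12 with mean 1.
#' @export
default_seasonal_table <- function() {
  raw <- c(0.30, 0.35, 0.55, 0.90, 1.35, 1.65, 1.75, 1.55, 1.15, 0.75, 0.45, 0.25)
  raw / mean(raw)
}

#' Seasonal emission factor for a month
#'
#' @param month Integer month(s), 1--12.
#' @param table 12-value monthly table; normalized internally to mean 1.
#' @return Relative factor(s).
#' @export
seasonal_profile <- function(month, table = default_seasonal_table()) {
  if (length(table) != 12 || any(table < 0)) {
    abort_domain("Seasonal table must be 12 nonnegative values.")
  }
  if (any(month != round(month)) || any(month < 1) || any(month > 12)) {
    abort_domain("`month` must be an integer in 1..12.")
  }
  table <- table / mean(table)
  table[month]
}

#' Assemble an hourly pasture emission-density series
#'
#' Base emission density scaled by the diurnal occupancy index, the
#' weather/occupancy rule and the seasonal profile.
#'
#' @param times POSIXct start-of-hour stamps.
#' @param base_density Reference dry-day emission density, units per m2 per
#'   hour (daily-mean basis).
#' @param horses_in_pasture Per-hour horse counts (recycled to `times`;
#'   matched by hour-of-day when 24 values are given).
#' @param precip Per-hour precipitation (mm/h) matching `times`, or a
#'   per-day logical rain flag. Default: dry.
#' @param rule A [scaling_rule()].
#' @param seasonal Logical; apply [seasonal_profile()] by calendar month.
#' @return Tibble `time`, `rate` (per-m2 densities).
#' @export
pasture_emission_series <- function(times, base_density, horses_in_pasture,
                                    precip = NULL, rule = scaling_rule(),
                                    seasonal = FALSE) {
  n <- length(times)
  day_id <- format(times, "%Y-%m-%d", tz = "UTC")
  if (length(horses_in_pasture) == 24) {
    hr <- as.integer(format(times, "%H", tz = "UTC"))
    horses <- horses_in_pasture[hr + 1]
  } else {
    horses <- rep_len(horses_in_pasture, n)
  }
  if (is.null(precip)) {
    rain_by_day <- rep(FALSE, length(unique(day_id)))
  } else if (is.logical(precip)) {
    rain_by_day <- rep_len(precip, length(unique(day_id)))
  } else {
    rain_by_day <- tapply(rep_len(precip, n), day_id, function(p) any(p > 0))
    rain_by_day <- as.logical(rain_by_day[unique(day_id)])
  }
  idx <- pasture_diurnal_index(horses, rain_by_day, rule)
  rate <- base_density * idx
  if (seasonal) {
    rate <- rate * seasonal_profile(as.integer(format(times, "%m", tz = "UTC")))
  }
  tibble::tibble(time = times, rate = rate)
}

# ---- inverse dispersion -----------------------------------------------------

#' Forward unit-response matrix for inversion
#'
#' Entry (i, j): the period-mean concentration at observation i's receptor
#' and window produced by source j emitting at unit density (1 emission unit
#' per m2 per hour for area sources, per hour for point sources) with the
#' given meteorology. The matrix is the linear building block of the
#' inversion: modeled = M %*% densities.
#'
#' A source with a scalar emission is replaced by unit emission. A source
#' carrying a `time`/`rate` emission table is used as-is and interpreted as
#' the known per-unit-density temporal shape (diurnal/weather indices): the
#' fit then estimates the base density multiplying that shape, which is how
#' the daily-basis inversion is posed.
#'
#' @param sources List of `plume_source` objects to fit. Scalar emissions
#'   are replaced by 1; emission tables are treated as unit-density shapes.
#' @param met A `met_series` covering all observation windows.
#' @param receptors [receptor_grid()] containing every observed receptor.
#' @param observations Tibble with `receptor`, `period_start`, `period_end`.
#' @param v_d Deposition velocity, m/s.
#' @return Matrix (observations x sources) with source ids as column names;
#'   rows whose window is entirely calm are `NA` and listed in
#'   `attr(x, "all_calm_rows")`.
#' @export
unit_response_matrix <- function(sources, met, receptors, observations,
                                 v_d = 0) {
  if (length(sources) == 0) {
    return(matrix(numeric(0), nrow = nrow(observations), ncol = 0))
  }
  unit_sources <- lapply(sources, function(s) {
    if (is.numeric(s$emission) && length(s$emission) == 1) s$emission <- 1
    s
  })
  field <- simulate_hourly(unit_sources, met, receptors, v_d = v_d)
  n_obs <- nrow(observations)
  ids <- vapply(sources, `[[`, character(1), "id")
  M <- matrix(NA_real_, n_obs, length(sources), dimnames = list(NULL, ids))
  for (i in seq_len(n_obs)) {
    win <- dplyr::filter(
      field,
      .data$receptor == observations$receptor[i],
      .data$time >= observations$period_start[i],
      .data$time < observations$period_end[i]
    )
    if (nrow(win) == 0) {
      abort_alignment(sprintf("Observation %d: window not covered by the met series.", i))
    }
    ok <- !win$calm
    if (any(ok)) {
      m <- win[ok, ] |>
        dplyr::group_by(.data$source) |>
        dplyr::summarise(mc = mean(.data$conc), .groups = "drop")
      M[i, m$source] <- m$mc
    }
  }
  attr(M, "all_calm_rows") <- which(apply(M, 1, function(r) all(is.na(r))))
  M
}

# Active-set nonnegative least squares: solve the unconstrained LS problem,
# drop variables estimated negative, refit on the remaining set.
nnls_active_set <- function(A, b, tol = 1e-10) {
  p <- ncol(A)
  active <- rep(TRUE, p)
  q <- numeric(p)
  repeat {
    q[] <- 0
    if (any(active)) {
      q[active] <- qr.coef(qr(A[, active, drop = FALSE]), b)
      q[is.na(q)] <- 0
    }
    neg <- active & q < -tol
    if (!any(neg)) break
    active[neg] <- FALSE
  }
  pmax(q, 0)
}

#' Inverse-dispersion emission fit
#'
#' Estimates per-source emission densities by nonnegative least squares on
#' the linear forward model `measured ~ M %*% density`: the emissions are
#' adjusted until modeled and measured period means are as similar as
#' possible. Below-detection observations are, by default, substituted at
#' half their detection limit (conventional in exposure science); windows
#' that were entirely calm are dropped from the fit.
#'
#' @param observations Tibble with `value` (measured period-mean
#'   concentration) and optionally `below_detection` (logical) and
#'   `detection_limit`.
#' @param response Matrix from [unit_response_matrix()].
#' @param censored How below-detection values enter the fit:
#'   `"substitute_half"` (limit/2, default), `"substitute_full"` (at the
#'   limit), or `"exclude"`.
#' @param compliance_tol Relative tolerance defining the compliance
#'   fraction reported in the diagnostics (default 20%).
#' @return An object of class `inverse_fit` with [tidy()] and [glance()]
#'   methods: estimates, per-observation residuals, and the fraction of
#'   observations whose modeled value is within `compliance_tol` of the
#'   measurement.
#' @export
inverse_emission_fit <- function(observations, response,
                                 censored = c("substitute_half", "substitute_full", "exclude"),
                                 compliance_tol = 0.2) {
  censored <- match.arg(censored)
  M <- response
  y <- observations$value
  bd <- observations$below_detection %||% rep(FALSE, length(y))
  if (any(bd)) {
    lim <- observations$detection_limit %||% observations$value
    y[bd] <- switch(censored,
      substitute_half = lim[bd] / 2,
      substitute_full = lim[bd],
      exclude = NA_real_
    )
  }
  keep <- !is.na(y) & !apply(M, 1, function(r) any(is.na(r)))
  if (!any(keep)) abort_domain("No usable observations after censoring/calm exclusion.")
  A <- M[keep, , drop = FALSE]
  yy <- y[keep]
  zero_col <- colSums(abs(A)) == 0
  if (any(zero_col)) {
    abort(sprintf("Source(s) %s produce zero response at every usable observation (unidentifiable).",
                  paste(colnames(A)[zero_col], collapse = ", ")),
          class = "equiplume_singularity_error")
  }
  if (nrow(A) < ncol(A)) {
    abort(sprintf("Under-determined fit: %d usable observation(s) for %d source(s).",
                  nrow(A), ncol(A)),
          class = "equiplume_underdetermined_error")
  }
  q <- nnls_active_set(A, yy)
  fitted <- as.numeric(A %*% q)
  rel_err <- ifelse(yy > 0, (fitted - yy) / yy, NA_real_)
  residuals <- tibble::tibble(
    observation = which(keep),
    measured = yy,
    modeled = fitted,
    residual = fitted - yy,
    rel_error = rel_err
  )
  structure(
    list(
      estimates = tibble::tibble(source = colnames(A), emission_density = q),
      residuals = residuals,
      compliance = mean(abs(rel_err) <= compliance_tol, na.rm = TRUE),
      compliance_tol = compliance_tol,
      n_obs = nrow(A),
      n_dropped = sum(!keep),
      censored = censored
    ),
    class = "inverse_fit"
  )
}
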
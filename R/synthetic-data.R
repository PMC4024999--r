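# Seeded synthetic-data generators: every input the pipeline consumes can be
# produced here with the statistical structure the field measurements showed,
# so all stages are testable end-to-end without any download. Every generator
# is a pure function of (arguments, seed); sub-seeds are derived from the one
# scenario seed by fixed small offsets.

derive_seed <- function(seed, offset) (seed + offset) %% .Machine$integer.max

#' Generate an hourly synthetic meteorology series
#'
#' Diurnal wind-speed cycle with noise, slowly wandering wind direction
#' (AR(1) around a base direction), a stability cycle (convective midday,
#' stratified night, neutral transitions) encoded as Monin--Obukhov lengths,
#' Bernoulli rain days, and matching temperature/humidity. The `"campaign"`
#' preset reproduces the measurement-campaign weather: dry, wind uniform in
#' 1--3 m/s, about 20 deg C.
#'
#' @param days Number of days (>= 1).
#' @param seed Integer seed; mandatory (all generators are seed-pure).
#' @param start First hour (ISO date or POSIXct), start-of-hour convention.
#' @param mean_wind,wind_amplitude Mean and diurnal amplitude of wind speed,
#'   m/s.
#' @param wind_min Floor applied to generated speeds, m/s (keep above the
#'   calm threshold to generate calm-free series).
#' @param base_direction Mean wind direction, degrees from.
#' @param direction_sd Standard deviation of the direction wander, degrees.
#' @param rain_day_prob Probability a day is a rain day.
#' @param rain_hour_prob Probability a rain-day hour has precipitation.
#' @param mean_temp Mean temperature, deg C.
#' @param z0 Roughness length, m.
#' @param preset `NULL` or `"campaign"`.
#' @return A validated `met_series` tibble.
#' @export
generate_met <- function(days, seed, start = "2009-05-01",
                         mean_wind = 2.5, wind_amplitude = 1, wind_min = 0.6,
                         base_direction = 270, direction_sd = 15,
                         rain_day_prob = 0.2, rain_hour_prob = 0.4,
                         mean_temp = 15, z0 = 0.1, preset = NULL) {
  if (days < 1) abort_domain("`days` must be >= 1.")
  if (missing(seed)) abort_domain("A seed is mandatory for synthetic generation.")
  n <- days * 24
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  times <- t0 + 3600 * (seq_len(n) - 1)
  hour <- as.integer(format(times, "%H", tz = "UTC"))
  withr::with_seed(derive_seed(seed, 101L), {
    if (identical(preset, "campaign")) {
      ws <- runif(n, 1, 3)
      rain_days <- rep(0L, days)
      mean_temp <- 20
    } else {
      ws <- mean_wind + wind_amplitude * sin(2 * pi * (hour - 9) / 24) +
        rnorm(n, 0, 0.3)
      ws <- pmax(ws, wind_min)
      rain_days <- rbinom(days, 1, rain_day_prob)
    }
    dev <- numeric(n)
    eps <- rnorm(n, 0, direction_sd * sqrt(1 - 0.8^2))
    for (i in seq_len(n)[-1]) dev[i] <- 0.8 * dev[i - 1] + eps[i]
    wd <- (base_direction + dev) %% 360
    # stability cycle via Monin-Obukhov length (m): strongly convective
    # midday, weakly convective shoulders, neutral transitions, stable night
    L <- dplyr::case_when(
      hour >= 10 & hour <= 15 ~ -15,
      hour %in% c(8, 9, 16, 17) ~ -60,
      hour %in% c(6, 7, 18, 19) ~ 1e6,
      .default = 40
    )
    rain_day_h <- rep(rain_days, each = 24)
    precip <- ifelse(rain_day_h == 1 & runif(n) < rain_hour_prob,
                     round(rexp(n, 1), 1) + 0.1, 0)
    temp <- mean_temp + 6 * sin(2 * pi * (hour - 14) / 24) + rnorm(n, 0, 0.8)
    rh <- pmin(pmax(65 + 15 * rain_day_h + rnorm(n, 0, 8), 15), 100)
    df <- tibble::tibble(
      timestamp = times, wind_speed = ws, wind_direction = wd,
      temperature = temp, rel_humidity = rh, precipitation = precip,
      obukhov_length = L
    )
  })
  validate_met_series(df, roughness_length = z0)
}

#' Generate noisy receptor observations from known true emissions
#'
#' Runs the forward model with the supplied (true) sources, averages per
#' receptor-day, applies multiplicative lognormal measurement noise, and
#' censors values below the assay detection limit (stored at the limit and
#' flagged, never zeroed). The noise-free truth is kept in
#' `attr(x, "truth")` for round-trip testing.
#'
#' @param sources True sources (with their true emission series).
#' @param met A `met_series`.
#' @param receptors [receptor_grid()].
#' @param sigma_log SD of the noise on the natural-log scale (0 = noise
#'   free).
#' @param detection_limit Assay detection limit in field units (amplified
#'   outdoor assay: 0.2 U/m3; standard assay: 2 U/m3).
#' @param seed Integer seed.
#' @param v_d Deposition velocity passed to the forward model.
#' @return Observation tibble: `receptor`, `period_start`, `period_end`,
#'   `value`, `below_detection`, `detection_limit`.
#' @export
generate_receptor_observations <- function(sources, met, receptors,
                                           sigma_log = 0.1,
                                           detection_limit = 0.2, seed,
                                           v_d = 0) {
  if (missing(seed)) abort_domain("A seed is mandatory for synthetic generation.")
  field <- field_total(simulate_hourly(sources, met, receptors, v_d = v_d))
  day <- as.POSIXct(format(field$time, "%Y-%m-%d", tz = "UTC"), tz = "UTC")
  obs <- field |>
    dplyr::mutate(day = day) |>
    dplyr::group_by(.data$receptor, .data$day) |>
    dplyr::summarise(true_value = mean(.data$conc[!.data$calm]),
                     .groups = "drop") |>
    dplyr::mutate(period_start = .data$day,
                  period_end = .data$day + 86400) |>
    dplyr::select("receptor", "period_start", "period_end", "true_value")
  withr::with_seed(derive_seed(seed, 202L), {
    noise <- exp(rnorm(nrow(obs), 0, sigma_log))
  })
  obs$value <- obs$true_value * noise
  obs$below_detection <- obs$value < detection_limit
  obs$detection_limit <- detection_limit
  obs$value[obs$below_detection] <- detection_limit
  truth <- obs$true_value
  obs$true_value <- NULL
  attr(obs, "truth") <- truth
  obs
}

#' Generate particle-fraction / allergen measurement tables
#'
#' Co-timed TSP, PM10 and PM2.5 particle masses and allergen contents for
#' stable, duct and outdoor locations, with the structure seen in the field:
#' mass ordering PM2.5 <= PM10 <= TSP always holds; the coarse (TSP - PM10)
#' fraction carries about an order of magnitude more allergen per unit mass
#' than the finer fractions; duct and stable TSP/PM10 ratios center on 1.3
#' and 1.7; allergen densities are drawn independently of particle masses,
#' so no mass--allergen correlation is imposed.
#'
#' @param n Number of sampling periods (days).
#' @param seed Integer seed.
#' @param stable_ratio,duct_ratio TSP/PM10 ratio centers.
#' @param ratio_sd SD of the ratio draws (truncated at 1.05).
#' @param coarse_enrichment Coarse/fine allergen-density ratio target.
#' @return Tibble: `period`, `location`, `fraction`, `particle_mass_conc`
#'   (ug/m3), `allergen_conc` (U/m3).
#' @export
generate_fraction_measurements <- function(n = 30, seed, stable_ratio = 1.7,
                                           duct_ratio = 1.3, ratio_sd = 0.15,
                                           coarse_enrichment = 10) {
  if (missing(seed)) abort_domain("A seed is mandatory for synthetic generation.")
  withr::with_seed(derive_seed(seed, 303L), {
    rows <- list()
    for (loc in c("stable", "duct", "outdoor")) {
      center <- switch(loc, stable = stable_ratio, duct = duct_ratio, outdoor = 1.5)
      base_tsp <- switch(loc, stable = 250, duct = 120, outdoor = 30)
      tsp <- rlnorm(n, log(base_tsp), 0.3)
      ratio <- pmax(rnorm(n, center, ratio_sd), 1.05)
      pm10 <- tsp / ratio
      pm25 <- pm10 * runif(n, 0.3, 0.6)
      # allergen densities (U/ug) per fraction, independent of the masses
      dens_fine <- rlnorm(n, log(0.5), 0.4)
      dens_mid <- rlnorm(n, log(0.6), 0.4)
      dens_coarse <- rlnorm(n, log(0.5 * coarse_enrichment), 0.4)
      a_pm25 <- dens_fine * pm25
      a_pm10 <- a_pm25 + dens_mid * (pm10 - pm25)
      a_tsp <- a_pm10 + dens_coarse * (tsp - pm10)
      for (fr in c("TSP", "PM10", "PM2.5")) {
        rows[[paste(loc, fr)]] <- tibble::tibble(
          period = seq_len(n), location = loc, fraction = fr,
          particle_mass_conc = switch(fr, TSP = tsp, PM10 = pm10, `PM2.5` = pm25),
          allergen_conc = switch(fr, TSP = a_tsp, PM10 = a_pm10, `PM2.5` = a_pm25)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Generate a passive flux-sampler campaign with known total emission
#'
#' Distributes a known total emission `true_E` over the 3 x 3 mast-by-height
#' grid with an exponential vertical decay profile, inverts the flux
#' definition to front/back tube masses, and optionally perturbs the masses
#' with multiplicative noise. [heap_emission()] on the noise-free output
#' returns `true_E` exactly.
#'
#' @param true_E Total emission to encode, g NH3.
#' @param W Per-mast plane widths, m.
#' @param dh Per-level height intervals, m.
#' @param dt Sampling time, h.
#' @param area Effective sampling area of the sampler, m2 (calibration
#'   constant).
#' @param q_background Background (surrounding) flux, g m-2 h-1.
#' @param noise_sd Relative SD of multiplicative tube-mass noise (0 = exact).
#' @param seed Seed (required when `noise_sd > 0`).
#' @param decay_scale Height scale of the vertical profile, m; default the
#'   mid-level height.
#' @return Campaign tibble as accepted by [heap_emission()].
#' @export
generate_flux_campaign <- function(true_E, W = c(10, 10, 10), dh = c(1, 1, 1),
                                   dt = 2, area = 1e-4, q_background = 0.05,
                                   noise_sd = 0, seed = NULL,
                                   decay_scale = NULL) {
  if (true_E < 0) abort_domain("`true_E` must be >= 0.")
  if (noise_sd > 0 && is.null(seed)) {
    abort_domain("A seed is mandatory for noisy generation.")
  }
  h <- cumsum(dh) - dh / 2
  decay_scale <- decay_scale %||% h[2]
  vert <- exp(-h / decay_scale)
  share <- outer(rep(1 / length(W), length(W)), vert / sum(vert)) # mast x level
  camp <- expand.grid(mast = seq_along(W), level = seq_along(dh))
  camp$W_m <- W[camp$mast]
  camp$dh_m <- dh[camp$level]
  camp$dt_h <- dt
  camp$area_m2 <- area
  s <- share[cbind(camp$mast, camp$level)]
  dq <- true_E * s / (camp$W_m * camp$dh_m * dt) # g m-2 h-1 net flux per cell
  q_h <- q_background + dq
  camp$front_mass_ug <- q_h * area * dt * 1e6
  camp$back_mass_ug <- q_background * area * dt * 1e6
  if (noise_sd > 0) {
    withr::with_seed(derive_seed(seed, 404L), {
      camp$front_mass_ug <- pmax(camp$front_mass_ug * (1 + rnorm(nrow(camp), 0, noise_sd)), 0)
      camp$back_mass_ug <- pmax(camp$back_mass_ug * (1 + rnorm(nrow(camp), 0, noise_sd)), 0)
    })
  }
  tibble::as_tibble(camp)
}

#' Generate a walk-toward-source odor survey
#'
#' Each respondent walks inward from `walk_start` in 1-m steps; the first
#' detection distance is drawn from the logistic detection model of
#' [fit_detection_model()] with the given `d50` and `slope` (survival
#' inversion, rounded to the 1-m step). Respondents whose draw falls below
#' 0 m never detect.
#'
#' @param n Number of respondents.
#' @param d50 Median detection distance, m.
#' @param slope Logistic slope, 1/m.
#' @param walk_start Walk start distance, m.
#' @param seed Integer seed.
#' @param site,odor_type Labels copied into the table.
#' @return Survey tibble: `respondent`, `site`, `odor_type`,
#'   `detection_distance` (`NA` if never), `walk_start`.
#' @export
generate_odor_survey <- function(n, d50 = 60, slope = 0.1, walk_start = 150,
                                 seed, site = "synthetic",
                                 odor_type = "manure") {
  if (n < 1) abort_domain("`n` must be >= 1.")
  if (missing(seed)) abort_domain("A seed is mandatory for synthetic generation.")
  withr::with_seed(derive_seed(seed, 505L), {
    u <- runif(n)
    # S(d) = plogis(slope * (d50 - d)); solve S(D) = u
    D <- d50 - qlogis(u) / slope
    D <- round(D) # 1-m walking steps
    det <- ifelse(D < 0, NA_real_, pmin(D, walk_start))
  })
  tibble::tibble(
    respondent = seq_len(n), site = site, odor_type = odor_type,
    detection_distance = det, walk_start = walk_start
  )
}
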
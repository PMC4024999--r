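# Manure-heap ammonia emission from passive flux-sampler campaigns, and the
# stable ammonia emission from duct concentration x ventilation flow.
#
# A passive flux sampler physically integrates concentration x wind speed x
# direction cosine through its probe, so no wind weighting is re-applied
# here: the tube masses already are plane-integrated fluxes.

#' Net fluxes from one sampler record
#'
#' Converts the two denuder tube masses of one mast/height position into
#' fluxes through the sampling plane: the front tube (wind from the source)
#' gives the heap flux, the back tube the background flux.
#'
#' @param record Data frame (one row per sampler; vectorized) with `front_mass_ug`,
#'   `back_mass_ug` (ug NH3), `area_m2` (effective sampling area, a sampler
#'   calibration constant) and `dt_h` (sampling time, h).
#' @return Tibble with `q_heap` and `q_surround`, g NH3 m-2 h-1.
#' @export
net_flux <- function(record) {
  if (any(record$area_m2 <= 0)) abort_domain("Sampling area must be > 0.")
  if (any(record$dt_h <= 0)) abort_domain("Sampling time must be > 0.")
  if (any(record$front_mass_ug < 0) || any(record$back_mass_ug < 0)) {
    abort_domain("Tube masses must be >= 0.")
  }
  denom <- record$area_m2 * record$dt_h
  tibble::tibble(
    q_heap = record$front_mass_ug * 1e-6 / denom,
    q_surround = record$back_mass_ug * 1e-6 / denom
  )
}

check_campaign <- function(campaign) {
  need <- c("mast", "level", "front_mass_ug", "back_mass_ug",
            "area_m2", "W_m", "dh_m", "dt_h")
  missing_cols <- setdiff(need, names(campaign))
  if (length(missing_cols) > 0) {
    abort_format(paste0("Flux campaign table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  grid <- expand.grid(mast = unique(campaign$mast), level = unique(campaign$level))
  have <- paste(campaign$mast, campaign$level)
  want <- paste(grid$mast, grid$level)
  miss <- setdiff(want, have)
  if (length(miss) > 0 || nrow(campaign) != nrow(grid)) {
    abort(sprintf("Incomplete mast x height grid; missing or duplicated cell(s): %s.",
                  paste(miss, collapse = "; ")),
          class = "equiplume_completeness_error")
  }
  invisible(campaign)
}

#' Manure-heap ammonia emission from a flux campaign
#'
#' Total emission over the sampling period from a complete mast-by-height
#' grid of passive flux samplers:
#' \deqn{E = \sum_m \sum_n W_m \, \Delta h_n \, (Q_{H,mn} - Q_{S,mn}) \, \Delta t}
#' with `W` the plane width represented by each mast, `dh` the height
#' interval represented by each level, and the `Q`s from [net_flux()].
#' Individual cells may contribute negatively (back-flux); the total is
#' reported with sign.
#'
#' @param campaign Tibble with one row per mast/level: `mast`, `level`,
#'   `front_mass_ug`, `back_mass_ug`, `area_m2`, `W_m`, `dh_m`, `dt_h`.
#' @return Total emission E, g NH3 (scalar). Per-mast subtotals via
#'   [heap_emission_summary()].
#' @examples
#' camp <- expand.grid(mast = 1:3, level = 1:3)
#' camp$front_mass_ug <- 100; camp$back_mass_ug <- 0
#' camp$area_m2 <- 1e-4; camp$W_m <- 10; camp$dh_m <- 1; camp$dt_h <- 2
#' heap_emission(camp) # 9 cells x 10 m x 1 m x 0.5 g/m2/h x 2 h = 90 g
#' @export
heap_emission <- function(campaign) {
  check_campaign(campaign)
  q <- net_flux(campaign)
  sum(campaign$W_m * campaign$dh_m * (q$q_heap - q$q_surround) * campaign$dt_h)
}

#' Per-mast breakdown and uncertainty of a flux campaign
#'
#' @param campaign As for [heap_emission()].
#' @param rel_uncertainty Relative uncertainty attached to the total
#'   (default the 25% concentration-plus-flow figure from
#'   [emission_uncertainty()]).
#' @return One-row tibble: `emission_g`, `uncertainty_g`, and one
#'   `mast_<id>_g` column per mast.
#' @export
heap_emission_summary <- function(campaign,
                                  rel_uncertainty = emission_uncertainty(0.10, 0.15)) {
  check_campaign(campaign)
  q <- net_flux(campaign)
  cell <- campaign$W_m * campaign$dh_m * (q$q_heap - q$q_surround) * campaign$dt_h
  per_mast <- tapply(cell, campaign$mast, sum)
  out <- tibble::tibble(emission_g = sum(cell),
                        uncertainty_g = abs(sum(cell)) * rel_uncertainty)
  for (m in names(per_mast)) out[[paste0("mast_", m, "_g")]] <- per_mast[[m]]
  out
}

#' Read a flux-campaign table
#'
#' @param path Delimited text file (comma or tab) with the columns listed in
#'   [heap_emission()].
#' @return Validated campaign tibble.
#' @export
read_flux_campaign <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  check_campaign(df)
  tibble::as_tibble(df)
}

#' Stable ammonia emission rate
#'
#' Duct ammonia concentration times ventilation flow, with the combined
#' measurement uncertainty attached (10% on concentration + 15% on flow =
#' 25% by default).
#'
#' @param duct_nh3_conc Duct NH3 concentration, ug/m3.
#' @param ventilation_flow Ventilation flow, m3/h (> 0).
#' @param rel_unc_concentration,rel_unc_ventilation Relative measurement
#'   uncertainties (fractions).
#' @return One-row tibble: `emission_g_h`, `rel_uncertainty`,
#'   `uncertainty_g_h`.
#' @examples
#' stable_ammonia_emission(1000, 2000) # 2 g/h +- 25%
#' @export
stable_ammonia_emission <- function(duct_nh3_conc, ventilation_flow,
                                    rel_unc_concentration = 0.10,
                                    rel_unc_ventilation = 0.15) {
  if (duct_nh3_conc < 0) abort_domain("`duct_nh3_conc` must be >= 0.")
  if (ventilation_flow <= 0) abort_domain("`ventilation_flow` must be > 0.")
  e <- duct_nh3_conc * 1e-6 * ventilation_flow
  ru <- emission_uncertainty(rel_unc_concentration, rel_unc_ventilation)
  tibble::tibble(emission_g_h = e, rel_uncertainty = ru,
                 uncertainty_g_h = e * ru)
}
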
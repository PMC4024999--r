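# Shipped synthetic scenario presets. Geometry is a stylized local planar
# frame (x east, y north, metres) around the stable at the origin; receptors
# sit east of the pastures under the prevailing westerly.

#' Synthetic riding-school scenario (stable, two pastures, manure heap)
#'
#' A 17-horse stable with a roof ventilation stack, two 50 m x 50 m pastures
#' east of the stable, a small manure heap by the stable wall, and seven
#' receptors 130--200 m east. Allergen emissions: stable series from the
#' indoor concentration x ventilation flow x duct transfer factor,
#' redistributed by the activity index; pasture area series from the
#' occupancy/weather indices. Ammonia emissions: stack (duct concentration x
#' flow) and heap area source.
#'
#' @param seed Integer seed for the met generator.
#' @param days Number of simulated days.
#' @param base_density Dry-day pasture allergen emission density,
#'   U m-2 h-1 (daily-mean basis).
#' @param indoor_tsp_allergen Indoor TSP-bound allergen, U/m3.
#' @param ventilation_flow Stable ventilation flow, m3/h.
#' @param duct_nh3 Duct ammonia concentration, ug/m3.
#' @param heap_nh3_density Heap ammonia emission density, ug m-2 h-1.
#' @param ... Passed to [generate_met()].
#' @return A list of class `equiplume_scenario`: `met`, `receptors`,
#'   `allergen_sources`, `nh3_sources`.
#' @export
scenario_gunnebo <- function(seed, days = 30, base_density = 2000,
                             indoor_tsp_allergen = 30,
                             ventilation_flow = 10000,
                             duct_nh3 = 1000, heap_nh3_density = 8e4, ...) {
  met <- generate_met(days, seed = seed, ...)
  times <- met$timestamp
  horses_day <- c(rep(0, 9), rep(8, 8), rep(0, 7)) # out 09:00-17:00
  stack <- point_source(
    "stable_stack", 0, 0, stack_height = 6,
    emission = stable_emission_series(times, indoor_tsp_allergen, ventilation_flow)
  )
  pasture_s <- area_source(
    "pasture_south",
    cbind(c(60, 110, 110, 60), c(-30, -30, 20, 20)),
    emission = pasture_emission_series(times, base_density, horses_day,
                                       precip = met$precipitation)
  )
  pasture_n <- area_source(
    "pasture_north",
    cbind(c(60, 110, 110, 60), c(40, 40, 90, 90)),
    emission = pasture_emission_series(times, base_density, horses_day,
                                       precip = met$precipitation)
  )
  heap <- area_source(
    "manure_heap", cbind(c(-8, -3, -3, -8), c(6, 6, 11, 11)),
    release_height = 1,
    emission = heap_nh3_density, substance = "nh3_ug"
  )
  nh3_stack <- point_source(
    "stable_stack_nh3", 0, 0, stack_height = 6,
    emission = stable_ammonia_emission(duct_nh3, ventilation_flow)$emission_g_h * 1e6,
    substance = "nh3_ug"
  )
  receptors <- receptor_grid(tibble::tibble(
    receptor = paste0("site", 1:7),
    x = c(130, 150, 150, 170, 180, 200, 160),
    y = c(-5, 20, 60, -20, 40, 0, -40)
  ))
  structure(
    list(met = met, receptors = receptors,
         allergen_sources = list(stack, pasture_s, pasture_n),
         nh3_sources = list(heap, nh3_stack)),
    class = "equiplume_scenario"
  )
}

#' Synthetic open-terrain scenario (manure heap only)
#'
#' A heap in open terrain with a line of receptors downwind; used for the
#' odor/ammonia comparison where the heap is the only source.
#'
#' @param seed Integer seed.
#' @param days Number of simulated days.
#' @param heap_nh3_density Heap ammonia emission density, ug m-2 h-1.
#' @param ... Passed to [generate_met()].
#' @return An `equiplume_scenario` list (no allergen sources).
#' @export
scenario_naas <- function(seed, days = 2, heap_nh3_density = 8e4, ...) {
  met <- generate_met(days, seed = seed, preset = "campaign", ...)
  heap <- area_source(
    "manure_heap", cbind(c(-3, 3, 3, -3), c(-3, -3, 3, 3)),
    release_height = 1, emission = heap_nh3_density, substance = "nh3_ug"
  )
  receptors <- receptor_grid(tibble::tibble(
    receptor = paste0("d", seq(10, 150, 20)),
    x = seq(10, 150, 20), y = 0
  ))
  structure(
    list(met = met, receptors = receptors,
         allergen_sources = list(), nh3_sources = list(heap)),
    class = "equiplume_scenario"
  )
}
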
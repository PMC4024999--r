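#' Power-law dispersion coefficient table
#'
#' Plume spread is parameterized as `sigma = a * x^b` (x and sigma in metres)
#' per stability class. The coefficients approximate the classic rural
#' Pasquill--Gifford curves over roughly 50 m -- 2 km while keeping both `a`
#' and `b` monotone across classes, so that at any fixed downwind distance
#' a more unstable class always has the larger spread (the classic piecewise
#' fits cross each other in the near field). Treat as swappable data.
#'
#' @format A data frame with one row per [stability_levels] entry and
#'   columns `a_y`, `b_y`, `a_z`, `b_z`.
#' @export
plume_sigma_coefs <- data.frame(
  stability = stability_levels,
  a_y = c(0.36, 0.28, 0.21, 0.15, 0.11, 0.08),
  b_y = c(0.92, 0.91, 0.90, 0.89, 0.88, 0.87),
  a_z = c(0.24, 0.20, 0.16, 0.12, 0.09, 0.065),
  b_z = c(0.95, 0.92, 0.89, 0.86, 0.83, 0.80)
)

#' Plume spread at a downwind distance
#'
#' Evaluates the shipped power-law spread curves for one stability class.
#' `sigma_z` carries a mild roughness correction `(z0 / 0.1)^0.2` relative to
#' the reference roughness 0.1 m; `sigma_y` does not (crosswind meander is
#' dominated by direction variability, not surface drag).
#'
#' @param x_downwind Downwind distance(s), m, strictly positive.
#' @param stability A single stability class (label or factor level).
#' @param z0 Roughness length, m.
#' @param coefs Coefficient table, defaulting to [plume_sigma_coefs].
#' @return A tibble with columns `sigma_y` and `sigma_z` (m).
#' @export
dispersion_sigmas <- function(x_downwind, stability, z0 = 0.1,
                              coefs = plume_sigma_coefs) {
  if (any(x_downwind <= 0)) abort_domain("`x_downwind` must be > 0.")
  stability <- as.character(stability)
  row <- match(stability[1], coefs$stability)
  if (is.na(row)) abort_domain(sprintf("Unknown stability class `%s`.", stability[1]))
  fz <- (z0 / 0.1)^0.2
  tibble::tibble(
    sigma_y = coefs$a_y[row] * x_downwind^coefs$b_y[row],
    sigma_z = coefs$a_z[row] * x_downwind^coefs$b_z[row] * fz
  )
}

#' Gaussian plume kernel for a point source
#'
#' Ground-reflected Gaussian plume concentration
#' \deqn{C = \frac{Q}{2\pi u \sigma_y \sigma_z}
#'   e^{-y^2/2\sigma_y^2}\left[e^{-(z-H)^2/2\sigma_z^2} +
#'   e^{-(z+H)^2/2\sigma_z^2}\right]}
#' Receptors at or upwind of the source (`x_down <= 0`) receive exactly 0.
#' Calm hours (`u < calm_threshold`) return `NA` as a signal for the caller
#' to skip or flag: the kernel diverges as `u` tends to 0.
#'
#' @param Q Source strength in emission units per second.
#' @param u Wind speed, m/s.
#' @param H Effective release height, m.
#' @param x_down,y_cross,z Receptor offset: downwind and crosswind distance
#'   and evaluation height, m. Vectorized.
#' @param sigma_y,sigma_z Plume spreads at `x_down`, m.
#' @param calm_threshold Calm cutoff, m/s.
#' @return Concentration(s) in emission units per cubic metre.
#' @export
point_concentration <- function(Q, u, H, x_down, y_cross, z,
                                sigma_y, sigma_z, calm_threshold = 0.5) {
  if (Q < 0) abort_domain("`Q` must be >= 0.")
  if (H < 0) abort_domain("`H` must be >= 0.")
  n <- max(length(x_down), length(y_cross), length(z))
  if (u < calm_threshold) {
    return(rep(NA_real_, n))
  }
  x_down <- rep_len(x_down, n)
  out <- numeric(n)
  dw <- x_down > 0
  if (any(dw)) {
    sy <- rep_len(sigma_y, n)[dw]
    sz <- rep_len(sigma_z, n)[dw]
    yc <- rep_len(y_cross, n)[dw]
    zz <- rep_len(z, n)[dw]
    out[dw] <- Q / (2 * pi * u * sy * sz) *
      exp(-yc^2 / (2 * sy^2)) *
      (exp(-(zz - H)^2 / (2 * sz^2)) + exp(-(zz + H)^2 / (2 * sz^2)))
  }
  out
}

#' Source-depletion factor for dry deposition
#'
#' Fraction of the emitted plume still airborne at downwind distance `x`
#' when particles deposit with velocity `v_d` (Chamberlain source-depletion):
#' \deqn{f(x) = \exp\left[-\sqrt{2/\pi}\,\frac{v_d}{u}
#'   \int_0^x \frac{e^{-H^2/2\sigma_z(\xi)^2}}{\sigma_z(\xi)}\,d\xi\right]}
#' The integral is evaluated on a graded trapezoid grid (analytically for a
#' ground-level release, where the integrand is a pure power law).
#'
#' @param x_downwind Downwind distance, m (> 0). Scalar.
#' @param u Wind speed, m/s.
#' @param v_d Deposition velocity, m/s (>= 0). Defaults: 0.002 for PM10-like
#'   particles, 0.02 for the coarse mode; both are configuration, not
#'   measured values.
#' @param stability Stability class.
#' @param z0 Roughness length, m.
#' @param H Effective release height, m.
#' @param n_grid Number of quadrature nodes.
#' @return Depletion fraction in (0, 1]; exactly 1 when `v_d = 0`.
#' @export
deposition_factor <- function(x_downwind, u, v_d, stability, z0 = 0.1,
                              H = 0, n_grid = 600) {
  if (v_d < 0) abort_domain("`v_d` must be >= 0.")
  if (x_downwind <= 0) abort_domain("`x_downwind` must be > 0.")
  if (v_d == 0) return(1)
  row <- match(as.character(stability)[1], plume_sigma_coefs$stability)
  a <- plume_sigma_coefs$a_z[row] * (z0 / 0.1)^0.2
  b <- plume_sigma_coefs$b_z[row]
  if (H <= 1e-12) {
    # sigma_z = a x^b: integral of x^-b / a is closed form (b < 1).
    I <- x_downwind^(1 - b) / (a * (1 - b))
  } else {
    # graded grid, dense near the source where sigma_z is small
    xi <- x_downwind * seq(0, 1, length.out = n_grid)^2
    xi[1] <- x_downwind * 1e-9
    sz <- a * xi^b
    g <- exp(-H^2 / (2 * sz^2)) / sz
    I <- sum(diff(xi) * (g[-1] + g[-length(g)]) / 2)
  }
  exp(-sqrt(2 / pi) * (v_d / u) * I)
}

# Vectorized depletion: the depletion integral is cumulative in x, so one
# graded grid up to max(x) with a cumulative trapezoid serves every tile.
depletion_factors <- function(x, u, v_d, stability, z0 = 0.1, H = 0,
                              n_grid = 800) {
  if (v_d == 0) return(rep(1, length(x)))
  row <- match(as.character(stability)[1], plume_sigma_coefs$stability)
  a <- plume_sigma_coefs$a_z[row] * (z0 / 0.1)^0.2
  b <- plume_sigma_coefs$b_z[row]
  xmax <- max(x)
  if (H <= 1e-12) {
    I <- x^(1 - b) / (a * (1 - b))
  } else {
    xi <- xmax * seq(0, 1, length.out = n_grid)^2
    xi[1] <- xmax * 1e-9
    g <- exp(-H^2 / (2 * (a * xi^b)^2)) / (a * xi^b)
    cumI <- c(0, cumsum(diff(xi) * (g[-1] + g[-n_grid]) / 2))
    I <- approx(xi, cumI, xout = x, rule = 2)$y
  }
  exp(-sqrt(2 / pi) * (v_d / u) * I)
}

# ---- source constructors ----------------------------------------------------

#' Define a point source (ventilation stack)
#'
#' @param id Source identifier (character).
#' @param x,y Position in the local planar frame (x east, y north), m.
#' @param stack_height Release height above ground, m (>= 0).
#' @param emission Either a single nonnegative rate (emission units per hour,
#'   constant) or a tibble with columns `time` (POSIXct, start-of-hour) and
#'   `rate`.
#' @param substance Unit tag, e.g. `"allergen_U"` or `"nh3_ug"`. Sources with
#'   different substances may not be simulated together.
#' @return A `plume_source` object.
#' @export
point_source <- function(id, x, y, stack_height, emission,
                         substance = "allergen_U") {
  if (stack_height < 0) abort_domain("`stack_height` must be >= 0.")
  structure(
    list(id = id, type = "point", x = x, y = y, height = stack_height,
         emission = emission, substance = substance),
    class = "plume_source"
  )
}

#' Define a polygonal area source (pasture, manure heap)
#'
#' @param id Source identifier.
#' @param vertices Two-column matrix or data frame of polygon vertices
#'   (x, y in m, ordered, not closed). Must be simple with positive area and
#'   at least 3 vertices.
#' @param release_height Near-ground release height, m.
#' @param emission Rate per square metre per hour (scalar or `time`/`rate`
#'   tibble of per-m2 rates).
#' @param substance Unit tag; see [point_source()].
#' @return A `plume_source` object.
#' @export
area_source <- function(id, vertices, release_height = 0.5, emission,
                        substance = "allergen_U") {
  xy <- as.matrix(as.data.frame(vertices)[, 1:2])
  if (nrow(xy) < 3) abort_domain("Area source needs >= 3 vertices.")
  if (polygon_area(xy) <= 0) abort_domain("Polygon area must be > 0.")
  if (!is_simple_polygon(xy)) abort_domain("Polygon must be simple (non-self-intersecting).")
  if (release_height < 0) abort_domain("`release_height` must be >= 0.")
  structure(
    list(id = id, type = "area", vertices = xy, height = release_height,
         emission = emission, substance = substance),
    class = "plume_source"
  )
}

#' Build a receptor table
#'
#' @param x,y Receptor coordinates, m (equal length, distinct points), or a
#'   data frame with `x`, `y` (and optionally `receptor`) passed as `x`.
#' @param z Evaluation height, m (breathing height by default).
#' @return A tibble with columns `receptor`, `x`, `y`, `z`.
#' @export
receptor_grid <- function(x, y = NULL, z = 1.5) {
  if (is.data.frame(x)) {
    df <- x
    if (!all(c("x", "y") %in% names(df))) abort_format("Receptor table needs `x` and `y`.")
    ids <- df$receptor %||% paste0("r", seq_len(nrow(df)))
    out <- tibble::tibble(receptor = as.character(ids), x = df$x, y = df$y)
  } else {
    out <- tibble::tibble(receptor = paste0("r", seq_along(x)), x = x, y = y)
  }
  if (z < 0) abort_domain("Evaluation height must be >= 0.")
  if (anyDuplicated(out[c("x", "y")]) > 0) abort_domain("Receptors must be distinct.")
  out$z <- z
  out
}

# ---- area-source tiling -----------------------------------------------------

default_pitch <- function(xy) {
  n <- nrow(xy)
  j <- c(seq(2, n), 1)
  edges <- sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2)
  min(min(edges) / 10, 5)
}

tile_polygon <- function(xy, pitch = NULL) {
  pitch <- pitch %||% default_pitch(xy)
  xs <- seq(min(xy[, 1]) + pitch / 2, max(xy[, 1]), by = pitch)
  ys <- seq(min(xy[, 2]) + pitch / 2, max(xy[, 2]), by = pitch)
  g <- expand.grid(x = xs, y = ys)
  keep <- pracma::inpolygon(g$x, g$y, xy[, 1], xy[, 2], boundary = TRUE)
  tiles <- g[keep, , drop = FALSE]
  if (nrow(tiles) == 0) {
    # degenerate sliver: fall back to the centroid carrying the full area
    tiles <- data.frame(x = mean(xy[, 1]), y = mean(xy[, 2]))
    attr(tiles, "cell_area") <- polygon_area(xy)
  } else {
    attr(tiles, "cell_area") <- pitch^2
  }
  attr(tiles, "pitch") <- pitch
  tiles
}

# concentration (units/m3) at receptors from one source for one met hour;
# rate_hour is the source's emission that hour (per-m2 for area sources).
source_hour_conc <- function(src, rate_hour, u, wd, stability, z0, rec,
                             v_d = 0, pitch = NULL, calm_threshold = 0.5) {
  n <- nrow(rec)
  if (u < calm_threshold) {
    return(list(conc = rep(NA_real_, n), near_field = rep(FALSE, n)))
  }
  if (src$type == "point") {
    off <- plume_offsets(src$x, src$y, rec$x, rec$y, wd)
    conc <- numeric(n)
    dw <- off$x_down > 0
    if (any(dw) && rate_hour > 0) {
      sg <- dispersion_sigmas(off$x_down[dw], stability, z0)
      dep <- depletion_factors(off$x_down[dw], u, v_d, stability, z0, src$height)
      conc[dw] <- point_concentration(
        rate_hour / 3600, u, src$height,
        off$x_down[dw], off$y_cross[dw], rec$z[dw],
        sg$sigma_y, sg$sigma_z, calm_threshold
      ) * dep
    }
    return(list(conc = conc, near_field = rep(FALSE, n)))
  }
  # area source: superpose sub-sources on a tiling of the polygon
  tiles <- tile_polygon(src$vertices, pitch)
  p <- attr(tiles, "pitch")
  q_tile <- rate_hour * attr(tiles, "cell_area") / 3600 # units/s per tile
  conc <- numeric(n)
  near <- logical(n)
  if (q_tile > 0) {
    for (i in seq_len(n)) {
      off <- plume_offsets(tiles$x, tiles$y, rec$x[i], rec$y[i], wd)
      dw <- off$x_down > 0
      if (!any(dw)) next
      xd <- off$x_down[dw]
      clamped <- xd < p
      if (any(clamped)) near[i] <- TRUE
      xd[clamped] <- p # near-field floor: avoid the 1/(sy*sz) singularity
      sg <- dispersion_sigmas(xd, stability, z0)
      dep <- depletion_factors(xd, u, v_d, stability, z0, src$height)
      conc[i] <- sum(point_concentration(
        q_tile, u, src$height, xd, off$y_cross[dw], rec$z[i],
        sg$sigma_y, sg$sigma_z, calm_threshold
      ) * dep)
    }
    inside <- pracma::inpolygon(rec$x, rec$y, src$vertices[, 1], src$vertices[, 2],
                                boundary = TRUE)
    near <- near | inside
  }
  list(conc = conc, near_field = near)
}

#' Concentration from an area source for one meteorological hour
#'
#' Tiles the polygon into sub-point-sources (pitch = one tenth of the
#' shortest edge, capped at 5 m, by default) and superposes the plume kernel.
#' Receptors within one pitch of a sub-source are evaluated with a minimum
#' downwind distance of one pitch and flagged `near_field`. Halving the pitch
#' changes receptor values by well under 1% at the default.
#'
#' @param src An [area_source()].
#' @param met One-row slice of a `met_series` (or any list with `wind_speed`,
#'   `wind_direction`, `stability`, `roughness_length`).
#' @param receptors Output of [receptor_grid()].
#' @param rate Emission density this hour, units per m2 per hour; defaults to
#'   the source's constant emission.
#' @param v_d Deposition velocity, m/s.
#' @param pitch Tiling pitch override, m.
#' @return Tibble: `receptor`, `conc`, `near_field`.
#' @export
area_concentration <- function(src, met, receptors, rate = NULL, v_d = 0,
                               pitch = NULL) {
  rate <- rate %||% src$emission
  if (!is.numeric(rate) || length(rate) != 1) {
    abort_domain("`rate` must be a single per-m2 hourly emission density.")
  }
  r <- source_hour_conc(src, rate, met$wind_speed, met$wind_direction,
                        met$stability, met$roughness_length %||% 0.1,
                        receptors, v_d = v_d, pitch = pitch)
  tibble::tibble(receptor = receptors$receptor, conc = r$conc,
                 near_field = r$near_field)
}

# ---- hourly simulation ------------------------------------------------------

emission_rate_at <- function(src, times) {
  em <- src$emission
  if (is.numeric(em) && length(em) == 1) {
    if (em < 0) abort_domain(sprintf("Source `%s` has negative emission.", src$id))
    return(rep(em, length(times)))
  }
  if (!is.data.frame(em) || !all(c("time", "rate") %in% names(em))) {
    abort_format(sprintf("Source `%s`: emission must be scalar or a time/rate table.", src$id))
  }
  idx <- match(as.numeric(times), as.numeric(em$time))
  if (anyNA(idx)) {
    miss <- times[is.na(idx)]
    abort_alignment(sprintf(
      "Source `%s`: emission series does not cover %d met hour(s), first %s.",
      src$id, length(miss), format(miss[1], "%Y-%m-%d %H:%M", tz = "UTC")
    ))
  }
  rate <- em$rate[idx]
  if (any(rate < 0)) abort_domain(sprintf("Source `%s` has negative emission.", src$id))
  rate
}

#' Hourly plume simulation over a met series
#'
#' Superposes all sources receptor-by-receptor for every hour of the met
#' series. Output is strictly linear in every source's emission. Calm hours
#' (below the series' calm threshold) carry `NA` concentration and
#' `calm = TRUE`.
#'
#' @param sources A list of [point_source()] / [area_source()] objects, all
#'   with the same substance tag.
#' @param met A `met_series`.
#' @param receptors Output of [receptor_grid()].
#' @param v_d Deposition velocity, m/s (applied to every source).
#' @param pitch Area-source tiling pitch override, m.
#' @return A `conc_field` tibble in long format: `time`, `receptor`, `x`,
#'   `y`, `source`, `conc`, `calm`, `near_field`, with the substance recorded
#'   in `attr(x, "substance")`.
#' @export
simulate_hourly <- function(sources, met, receptors, v_d = 0, pitch = NULL) {
  if (inherits(sources, "plume_source")) sources <- list(sources)
  subs <- unique(vapply(sources, `[[`, character(1), "substance"))
  if (length(subs) > 1) {
    abort_domain(paste0("Sources mix substances (", paste(subs, collapse = ", "),
                        "); simulate them separately."))
  }
  calm_thr <- attr(met, "calm_threshold") %||% 0.5
  rates <- lapply(sources, emission_rate_at, times = met$timestamp)
  nh <- nrow(met); nr <- nrow(receptors); ns <- length(sources)
  res <- vector("list", nh)
  for (h in seq_len(nh)) {
    rows <- vector("list", ns)
    for (j in seq_len(ns)) {
      r <- source_hour_conc(
        sources[[j]], rates[[j]][h],
        met$wind_speed[h], met$wind_direction[h],
        met$stability[h], met$roughness_length[h],
        receptors, v_d = v_d, pitch = pitch, calm_threshold = calm_thr
      )
      rows[[j]] <- tibble::tibble(
        time = met$timestamp[h], receptor = receptors$receptor,
        x = receptors$x, y = receptors$y,
        source = sources[[j]]$id, conc = r$conc,
        calm = met$calm[h], near_field = r$near_field
      )
    }
    res[[h]] <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "substance") <- subs
  class(out) <- c("conc_field", class(out))
  out
}

#' Sum a concentration field over sources
#'
#' @param field A `conc_field` from [simulate_hourly()].
#' @return Tibble with one row per time/receptor and the summed `conc`.
#' @export
field_total <- function(field) {
  out <- field |>
    dplyr::group_by(.data$time, .data$receptor, .data$x, .data$y) |>
    dplyr::summarise(
      conc = sum(.data$conc),
      calm = any(.data$calm),
      near_field = any(.data$near_field),
      .groups = "drop"
    )
  attr(out, "substance") <- attr(field, "substance")
  out
}

#' Period-average a concentration field
#'
#' Arithmetic mean over non-calm hours per receptor and source (calm hours
#' optionally counted as zero via `calm = "zero"`). Units are preserved.
#'
#' @param field A `conc_field`.
#' @param start,end Optional POSIXct window bounds (start inclusive, end
#'   exclusive). Default: the whole field.
#' @param calm `"exclude"` (default) drops calm hours from the mean;
#'   `"zero"` counts them as zero concentration.
#' @return Tibble: `receptor`, `x`, `y`, `source`, `mean_conc`, `n_hours`,
#'   `n_calm`.
#' @export
period_average <- function(field, start = NULL, end = NULL,
                           calm = c("exclude", "zero")) {
  calm <- match.arg(calm)
  sub <- field
  if (!is.null(start)) sub <- dplyr::filter(sub, .data$time >= start)
  if (!is.null(end)) sub <- dplyr::filter(sub, .data$time < end)
  if (nrow(sub) == 0) abort_domain("Empty averaging window.")
  if (calm == "zero") sub$conc[sub$calm] <- 0
  out <- sub |>
    dplyr::group_by(.data$receptor, .data$x, .data$y, .data$source) |>
    dplyr::summarise(
      mean_conc = mean(.data$conc[!is.na(.data$conc)]),
      n_hours = dplyr::n(),
      n_calm = sum(.data$calm),
      .groups = "drop"
    )
  attr(out, "substance") <- attr(field, "substance")
  out
}
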
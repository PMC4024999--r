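# Shared fixtures built in code. constant_met() gives a hand-controlled
# hourly series (fixed wind, neutral unless stated) for geometric checks.

constant_met <- function(hours = 24, u = 2, wd = 270, L = 1e6, z0 = 0.1,
                         start = as.POSIXct("2009-05-01 00:00:00", tz = "UTC")) {
  equiplume:::validate_met_series(tibble::tibble(
    timestamp = start + 3600 * (seq_len(hours) - 1),
    wind_speed = u,
    wind_direction = wd,
    temperature = 15,
    rel_humidity = 70,
    precipitation = 0,
    obukhov_length = L
  ), roughness_length = z0)
}

square_poly <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

write_met_csv <- function(df, path = tempfile(fileext = ".csv")) {
  out <- df
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path)
  path
}

met_day_frame <- function(hours = 0:23) {
  tibble::tibble(
    timestamp = as.POSIXct("2009-05-01 00:00:00", tz = "UTC") + 3600 * hours,
    wind_speed = 2 + 0.01 * hours,
    wind_direction = (260 + hours) %% 360,
    temperature = 15,
    rel_humidity = 70,
    precipitation = 0,
    obukhov_length = 1e6
  )
}
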
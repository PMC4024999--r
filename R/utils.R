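# Internal helpers: classed error conditions so callers (and tests) can
# distinguish a domain violation from a malformed file.

abort_domain <- function(msg) abort(msg, class = "equiplume_domain_error")
abort_format <- function(msg) abort(msg, class = "equiplume_format_error")
abort_sequence <- function(msg) abort(msg, class = "equiplume_sequence_error")
abort_validation <- function(msg) abort(msg, class = "equiplume_validation_error")
abort_alignment <- function(msg) abort(msg, class = "equiplume_alignment_error")

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_domain(sprintf("`%s` must be numeric and non-missing.", name))
  }
  if (any(x < lower) || any(x > upper)) {
    abort_domain(sprintf("`%s` must lie in [%s, %s].", name, lower, upper))
  }
  if (!allow_zero && any(x == 0)) {
    abort_domain(sprintf("`%s` must be nonzero.", name))
  }
  invisible(x)
}

# Wind geometry. Meteorological convention: wind_direction is the bearing the
# wind blows FROM, clockwise from north. In the local planar frame (x east,
# y north) the downwind unit vector is therefore (-sin(wd), -cos(wd)).
downwind_unit <- function(wind_direction) {
  th <- wind_direction * pi / 180
  c(dx = -sin(th), dy = -cos(th))
}

# Downwind / crosswind offsets of receptor(s) relative to a source position.
plume_offsets <- function(sx, sy, rx, ry, wind_direction) {
  u <- downwind_unit(wind_direction)
  ex <- rx - sx
  ey <- ry - sy
  list(
    x_down = ex * u[["dx"]] + ey * u[["dy"]],
    y_cross = -ex * u[["dy"]] + ey * u[["dx"]]
  )
}

# Shoelace area of a polygon given as a two-column matrix (not closed).
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# Simplicity check: no two non-adjacent edges may cross.
is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  edges <- lapply(seq_len(n), function(i) {
    rbind(xy[i, ], xy[if (i == n) 1 else i + 1, ])
  })
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      if (segments_intersect(edges[[i]][1, ], edges[[i]][2, ],
                             edges[[j]][1, ], edges[[j]][2, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}
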
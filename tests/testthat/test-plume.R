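test_that("sigma curves match the documented power law and its orderings", {
  coefs <- plume_sigma_coefs
  row <- which(coefs$stability == "neutral")
  sg <- dispersion_sigmas(100, "neutral", z0 = 0.1)
  # oracle: hand evaluation of the shipped coefficients
  expect_equal(sg$sigma_y, coefs$a_y[row] * 100^coefs$b_y[row])
  expect_equal(sg$sigma_z, coefs$a_z[row] * 100^coefs$b_z[row])

  for (cl in stability_levels) {
    xs <- c(10, 50, 100, 200, 500, 1000, 2000)
    sg <- dispersion_sigmas(xs, cl)
    expect_true(all(diff(sg$sigma_y) > 0), info = cl)
    expect_true(all(diff(sg$sigma_z) > 0), info = cl)
  }
  # more unstable => larger sigma_z at any fixed distance
  for (x0 in c(1, 10, 100, 1000)) {
    sz <- vapply(stability_levels,
                 function(cl) dispersion_sigmas(x0, cl)$sigma_z, numeric(1))
    expect_true(all(diff(sz) < 0), info = paste("x =", x0))
  }
  expect_error(dispersion_sigmas(0, "neutral"), class = "equiplume_domain_error")
  expect_error(dispersion_sigmas(-5, "neutral"), class = "equiplume_domain_error")
})

test_that("point kernel matches the closed form, with symmetry and upwind zero", {
  sg <- dispersion_sigmas(100, "neutral")
  # oracle: independent dnorm formulation of the reflected Gaussian kernel
  oracle <- function(Q, u, H, y, z, sy, sz) {
    Q / u * stats::dnorm(y, 0, sy) * (stats::dnorm(z, H, sz) + stats::dnorm(z, -H, sz))
  }
  got <- point_concentration(1, 2, 5, 100, 0, 1.5, sg$sigma_y, sg$sigma_z)
  expect_equal(got, oracle(1, 2, 5, 0, 1.5, sg$sigma_y, sg$sigma_z), tolerance = 1e-12)

  expect_equal(point_concentration(0, 2, 5, 100, 10, 1.5, sg$sigma_y, sg$sigma_z), 0)
  expect_equal(
    point_concentration(1, 2, 5, 100, 25, 1.5, sg$sigma_y, sg$sigma_z),
    point_concentration(1, 2, 5, 100, -25, 1.5, sg$sigma_y, sg$sigma_z)
  )
  expect_equal(point_concentration(1, 2, 5, -50, 0, 1.5, sg$sigma_y, sg$sigma_z), 0)
  expect_true(is.na(point_concentration(1, 0.2, 5, 100, 0, 1.5, sg$sigma_y, sg$sigma_z)))
})

test_that("plume flux recovers Q at several distances (mass consistency)", {
  trap <- function(v, h) h * (sum(v) - (v[1] + v[length(v)]) / 2)
  sg <- dispersion_sigmas(500, "unstable")
  u <- 3; Q <- 1; H <- 10
  ys <- seq(-10 * sg$sigma_y, 10 * sg$sigma_y, length.out = 801)
  zs <- seq(0, H + 12 * sg$sigma_z, length.out = 1001)
  C <- outer(ys, zs, function(y, z) {
    point_concentration(Q, u, H, 500, y, z, sg$sigma_y, sg$sigma_z)
  })
  flux <- trap(apply(C, 1, trap, h = diff(zs[1:2])), diff(ys[1:2])) * u
  expect_equal(flux, Q, tolerance = 1e-6)
})

test_that("source depletion is 1 at v_d = 0, monotone, and matches quadrature", {
  expect_identical(deposition_factor(100, 2, 0, "neutral"), 1)
  expect_identical(deposition_factor(1000, 2, 0, "very_stable"), 1)
  f <- vapply(c(100, 200, 500, 1000), deposition_factor, numeric(1),
              u = 2, v_d = 0.02, stability = "neutral", H = 0)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1))
  expect_error(deposition_factor(100, 2, -0.01, "neutral"),
               class = "equiplume_domain_error")

  # oracle: stats::integrate on the same integrand, elevated release
  coefs <- plume_sigma_coefs
  row <- which(coefs$stability == "neutral")
  a <- coefs$a_z[row]; b <- coefs$b_z[row]
  for (H in c(0, 5)) {
    integrand <- function(xi) exp(-H^2 / (2 * (a * xi^b)^2)) / (a * xi^b)
    I <- stats::integrate(integrand, 0, 500, rel.tol = 1e-10)$value
    want <- exp(-sqrt(2 / pi) * (0.02 / 2) * I)
    expect_equal(deposition_factor(500, 2, 0.02, "neutral", H = H), want,
                 tolerance = 1e-4)
  }
  # vectorized depletion agrees with the scalar op
  xs <- c(60, 150, 420, 900)
  expect_equal(
    equiplume:::depletion_factors(xs, 2, 0.02, "neutral", H = 5),
    vapply(xs, deposition_factor, numeric(1), u = 2, v_d = 0.02,
           stability = "neutral", H = 5),
    tolerance = 1e-3
  )
})

test_that("area sources superpose, converge under tiling refinement, and flag near field", {
  met <- constant_met(1)
  rec <- receptor_grid(100, 0)
  full <- area_source("f", square_poly(-25, 25, -25, 25), emission = 1)
  left <- area_source("l", square_poly(-25, 25, -25, 0), emission = 1)
  right <- area_source("r", square_poly(-25, 25, 0, 25), emission = 1)

  expect_equal(area_concentration(area_source("z", square_poly(-25, 25, -25, 25),
                                              emission = 0),
                                  met[1, ], rec)$conc, 0)

  pitch <- 2.5 # shared pitch so the two halves tile exactly like the whole
  c_full <- area_concentration(full, met[1, ], rec, pitch = pitch)$conc
  c_sum <- area_concentration(left, met[1, ], rec, pitch = pitch)$conc +
    area_concentration(right, met[1, ], rec, pitch = pitch)$conc
  expect_equal(c_sum, c_full, tolerance = 1e-9)

  # self-convergence: default pitch (5 m) vs 10x finer
  c_def <- area_concentration(full, met[1, ], rec)$conc
  c_fine <- area_concentration(full, met[1, ], rec, pitch = 0.5)$conc
  expect_lt(abs(c_def - c_fine) / c_fine, 0.01)

  # receptor inside the polygon: finite value, near-field flag raised
  inside <- area_concentration(full, met[1, ], receptor_grid(0, 0))
  expect_true(inside$near_field)
  expect_true(is.finite(inside$conc) && inside$conc > 0)

  expect_error(area_source("bad", cbind(c(0, 1), c(0, 1)), emission = 1),
               class = "equiplume_domain_error")
  expect_error(
    area_source("bowtie", cbind(c(0, 10, 10, 0), c(0, 10, 0, 10)), emission = 1),
    class = "equiplume_domain_error"
  )
})

test_that("hourly simulation is linear, respects wind geometry, and aligns series", {
  met <- constant_met(3, wd = 270) # westerly: plume travels east
  rec <- receptor_grid(c(100, -100), c(0, 0))
  src <- point_source("stk", 0, 0, 5, emission = 3600)

  f <- simulate_hourly(list(src), met, rec)
  east <- f$conc[f$x == 100]
  west <- f$conc[f$x == -100]
  expect_true(all(east > 0))
  expect_true(all(west == 0))

  src2 <- point_source("stk", 0, 0, 5, emission = 7200)
  f2 <- simulate_hourly(list(src2), met, rec)
  expect_equal(f2$conc, 2 * f$conc, tolerance = 1e-14)

  zero <- simulate_hourly(list(point_source("z", 0, 0, 5, emission = 0)), met, rec)
  expect_true(all(zero$conc == 0))

  # substances never mix
  expect_error(
    simulate_hourly(list(src, point_source("n", 0, 0, 5, emission = 1,
                                           substance = "nh3_ug")), met, rec),
    class = "equiplume_domain_error"
  )

  # emission series must cover the met period
  short <- tibble::tibble(time = met$timestamp[1:2], rate = 1)
  expect_error(
    simulate_hourly(list(point_source("s", 0, 0, 5, emission = short)), met, rec),
    class = "equiplume_alignment_error"
  )

  # calm hours are flagged NA, not evaluated
  met_calm <- constant_met(2, u = 0.3)
  fc <- simulate_hourly(list(src), met_calm, rec)
  expect_true(all(is.na(fc$conc)))
  expect_true(all(fc$calm))
})

test_that("period averages equal brute-force sums and compose over sub-windows", {
  met <- constant_met(72, u = 2)
  met$wind_speed <- 1 + (seq_len(72) %% 5) * 0.5 # vary the field hour to hour
  met <- equiplume:::validate_met_series(
    met[equiplume:::met_required_cols], roughness_length = 0.1
  )
  src <- area_source("p", square_poly(-20, 20, -20, 20), emission = 10)
  rec <- receptor_grid(c(80, 120, 150), c(0, 10, -5))
  f <- simulate_hourly(list(src), met, rec)

  pa <- period_average(f)
  brute <- tapply(f$conc, f$receptor, function(v) sum(v) / length(v))
  expect_equal(pa$mean_conc[match(names(brute), pa$receptor)],
               as.numeric(brute), tolerance = 1e-12)

  # two halves, weighted by hour counts, recompose the full mean
  mid <- met$timestamp[37]
  p1 <- period_average(f, end = mid)
  p2 <- period_average(f, start = mid)
  w <- (p1$mean_conc * p1$n_hours + p2$mean_conc * p2$n_hours) /
    (p1$n_hours + p2$n_hours)
  expect_equal(w, pa$mean_conc, tolerance = 1e-12)

  expect_error(period_average(f, start = met$timestamp[72] + 7200),
               class = "equiplume_domain_error")

  cst <- simulate_hourly(list(src), constant_met(5), rec)
  pc <- period_average(cst)
  expect_equal(pc$mean_conc, cst$conc[match(pc$receptor, cst$receptor)],
               tolerance = 1e-12)
})
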
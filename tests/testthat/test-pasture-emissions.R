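test_that("weather/occupancy scale covers all four day types", {
  r <- scaling_rule()
  expect_equal(weather_occupancy_scale(r, FALSE, TRUE), 1.0)
  expect_equal(weather_occupancy_scale(r, TRUE, TRUE), 0.18)
  expect_equal(weather_occupancy_scale(r, FALSE, FALSE), 0.10)
  expect_equal(weather_occupancy_scale(r, TRUE, FALSE), 0)
  expect_error(scaling_rule(rain_factor = 1.2), class = "equiplume_domain_error")
})

test_that("diurnal pasture index follows occupancy, weather, and scale invariance", {
  horses <- c(rep(0, 9), rep(6, 8), rep(0, 7)) # 8 h on pasture
  idx <- pasture_diurnal_index(horses, precip_day = FALSE)
  expect_equal(idx[10:17], rep(3, 8)) # 24/8 normalization
  expect_equal(idx[c(1:9, 18:24)], rep(0, 16))
  expect_equal(mean(idx), 1, tolerance = 1e-12)

  rain <- pasture_diurnal_index(horses, precip_day = TRUE)
  expect_equal(rain, 0.18 * idx, tolerance = 1e-12)

  # doubling the herd leaves the normalized index unchanged
  expect_equal(pasture_diurnal_index(2 * horses), idx, tolerance = 1e-12)

  # horse-free dry day: flat profile at the horse-free factor
  expect_equal(pasture_diurnal_index(rep(0, 24)), rep(0.10, 24))
  # horse-free rain day: nothing
  expect_equal(pasture_diurnal_index(rep(0, 24), precip_day = TRUE), rep(0, 24))
})

test_that("seasonal profile is normalized, summer-peaked, and identity for flat tables", {
  tab <- default_seasonal_table()
  expect_equal(mean(tab), 1, tolerance = 1e-12)
  expect_gt(seasonal_profile(7), seasonal_profile(1)) # July above January
  expect_equal(which.max(seasonal_profile(1:12)) %in% 6:8, TRUE)
  expect_equal(seasonal_profile(1:12, table = rep(1, 12)), rep(1, 12))
  expect_error(seasonal_profile(13), class = "equiplume_domain_error")

  # occupancy scaling and seasonal scaling commute (pure multiplication)
  r <- scaling_rule()
  a <- weather_occupancy_scale(r, TRUE, TRUE) * seasonal_profile(7)
  b <- seasonal_profile(7) * weather_occupancy_scale(r, TRUE, TRUE)
  expect_identical(a, b)
})

test_that("unit-response entries equal a direct forward run at unit density", {
  met <- constant_met(48)
  src <- area_source("p1", square_poly(-20, 20, -20, 20), emission = 123)
  rec <- receptor_grid(100, 0)
  obs <- tibble::tibble(
    receptor = "r1",
    period_start = met$timestamp[1],
    period_end = met$timestamp[1] + 86400
  )
  M <- unit_response_matrix(list(src), met, rec, obs)
  expect_equal(dim(M), c(1, 1))

  # oracle: direct forward run with emission forced to 1
  src1 <- area_source("p1", square_poly(-20, 20, -20, 20), emission = 1)
  direct <- period_average(simulate_hourly(list(src1), met, rec),
                           end = met$timestamp[1] + 86400)
  expect_equal(unname(M[1, 1]), direct$mean_conc, tolerance = 1e-12)

  expect_equal(ncol(unit_response_matrix(list(), met, rec, obs)), 0)
})

test_that("the inversion recovers generating densities exactly from noise-free data", {
  met <- generate_met(3, seed = 21, rain_day_prob = 0)
  src_a <- area_source("west", square_poly(-40, 0, -20, 20), emission = 800)
  src_b <- area_source("east", square_poly(20, 60, -20, 20), emission = 300)
  rec <- receptor_grid(c(120, 150, 150, 180), c(0, 30, -30, 10))
  obs <- generate_receptor_observations(list(src_a, src_b), met, rec,
                                        sigma_log = 0, detection_limit = 1e-12,
                                        seed = 1)
  M <- unit_response_matrix(list(src_a, src_b), met, rec, obs)
  fit <- inverse_emission_fit(obs, M)
  est <- setNames(fit$estimates$emission_density, fit$estimates$source)
  expect_lt(abs(est[["west"]] - 800) / 800, 1e-6)
  expect_lt(abs(est[["east"]] - 300) / 300, 1e-6)
  # noise-free round trip: every observation within 20% trivially
  expect_equal(fit$compliance, 1.0)

  # all-zero observations force zero emissions
  obs0 <- obs
  obs0$value <- 0
  obs0$below_detection <- FALSE
  fit0 <- inverse_emission_fit(obs0, M)
  expect_equal(fit0$estimates$emission_density, c(0, 0))
})

test_that("inversion errors are classed: unidentifiable and under-determined cases", {
  obs <- tibble::tibble(value = c(1, 2), below_detection = FALSE,
                        detection_limit = 0.2)
  M <- matrix(c(0.1, 0.2, 0, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(inverse_emission_fit(obs, M),
               "b", class = "equiplume_singularity_error")
  M2 <- matrix(c(0.1, 0.2), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(inverse_emission_fit(obs[1, ], M2),
               class = "equiplume_underdetermined_error")
})

test_that("the active-set NNLS agrees with an independent solver", {
  for (s in 1:8) {
    withr::with_seed(s, {
      A <- matrix(abs(rnorm(30 * 3)), 30, 3)
      q_true <- c(2, 0, 5)
      b <- A %*% q_true + rnorm(30, 0, 0.3)
    })
    mine <- equiplume:::nnls_active_set(A, as.numeric(b))
    ref <- pracma::lsqnonneg(A, as.numeric(b))$x
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("below-detection handling follows the configured substitution rule", {
  met <- constant_met(24)
  src <- area_source("p", square_poly(-20, 20, -20, 20), emission = 100)
  rec <- receptor_grid(c(100, 130, 160), c(0, 5, -5))
  obs <- generate_receptor_observations(list(src), met, rec, sigma_log = 0,
                                        detection_limit = 1e-12, seed = 2)
  M <- unit_response_matrix(list(src), met, rec, obs)
  # censor one observation artificially at a limit equal to twice its value
  obs$below_detection[1] <- TRUE
  obs$detection_limit[1] <- 2 * obs$value[1]
  obs$value[1] <- obs$detection_limit[1]

  f_half <- inverse_emission_fit(obs, M, censored = "substitute_half")
  f_full <- inverse_emission_fit(obs, M, censored = "substitute_full")
  f_excl <- inverse_emission_fit(obs, M, censored = "exclude")
  expect_lt(f_half$estimates$emission_density, f_full$estimates$emission_density)
  expect_equal(f_excl$n_obs, nrow(obs) - 1)
  expect_equal(f_excl$estimates$emission_density, 100, tolerance = 1e-6)
})
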
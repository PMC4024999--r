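survey_of <- function(distances, walk_start = 150) {
  tibble::tibble(
    respondent = seq_along(distances), site = "t", odor_type = "manure",
    detection_distance = distances, walk_start = walk_start
  )
}

test_that("detection curve counts both directions with full denominators", {
  # everyone detects at exactly 50 m
  c1 <- detection_curve(survey_of(rep(50, 12)), bin_edges = seq(150, 0, -10))
  expect_equal(c1$frac_within[c1$distance == 60], 1)
  expect_equal(c1$frac_at_or_beyond[c1$distance == 60], 0)

  # nobody detects: all fractions zero, denominators stay n
  c0 <- detection_curve(survey_of(rep(NA_real_, 8)))
  expect_true(all(c0$frac_within == 0))
  expect_true(all(c0$n_total == 8))

  # oracle: hand count on ten fixed distances
  d <- c(90, 80, 70, 60, 60, 50, 40, 30, 20, 10)
  c2 <- detection_curve(survey_of(d))
  expect_equal(c2$frac_at_or_beyond[c2$distance == 60], 0.5) # 5 of 10 at >= 60
  expect_equal(c2$frac_within[c2$distance == 60], 0.7)       # 7 of 10 at <= 60

  # cumulative fraction within is non-decreasing as distance grows,
  # and at the walk start equals the overall detection rate
  expect_true(all(diff(rev(c2$frac_within)) >= 0))
  expect_equal(c2$frac_within[c2$distance == 150], 1.0)

  expect_error(detection_curve(survey_of(numeric(0))),
               class = "equiplume_domain_error")
  expect_error(detection_curve(survey_of(c(50, 90)), bin_edges = seq(60, 0, -10)),
               class = "equiplume_assignment_error")
})

test_that("detection quantiles are order statistics over all respondents", {
  expect_equal(detection_quantile(survey_of(rep(30, 6)), 0.5), 30)
  expect_equal(detection_quantile(survey_of(c(10, 20, 30, 40)), 0.5), 20)
  expect_warning(
    q <- detection_quantile(survey_of(c(40, 55, 60, rep(NA, 7))), 0.5),
    class = "equiplume_quantile_warning"
  )
  expect_true(is.na(q))
  expect_error(detection_quantile(survey_of(30), 1.5),
               class = "equiplume_domain_error")
})

test_that("quantiles are the generalized inverse of the detection curve", {
  for (s in 1:5) {
    srv <- generate_odor_survey(60, d50 = 55, slope = 0.08, seed = s)
    for (q in c(0.25, 0.5, 0.6)) {
      dq <- suppressWarnings(detection_quantile(srv, q))
      if (is.na(dq)) next
      crv <- detection_curve(srv, bin_edges = sort(unique(
        srv$detection_distance[!is.na(srv$detection_distance)]
      ), decreasing = TRUE))
      expect_gte(crv$frac_within[crv$distance == dq], q)
      smaller <- crv$frac_within[crv$distance < dq]
      if (length(smaller) > 0) expect_true(all(smaller < q))
    }
  }
})

test_that("logistic detection model recovers generating parameters", {
  srv <- generate_odor_survey(200, d50 = 60, slope = 0.1, seed = 33)
  fit <- fit_detection_model(srv)
  expect_true(fit$converged)
  expect_lt(abs(fit$d50 - 60) / 60, 0.10)

  # symmetric detections around 60 put d50 near 60
  sym <- survey_of(c(40, 50, 55, 60, 60, 65, 70, 80))
  fsym <- fit_detection_model(sym)
  expect_lt(abs(fsym$d50 - 60), 6)

  # identical distances: separation flag, no crash
  expect_warning(fsep <- fit_detection_model(survey_of(rep(60, 10))),
                 class = "equiplume_separation_warning")
  expect_true(fsep$separation)

  expect_error(fit_detection_model(survey_of(c(60, NA, NA))),
               class = "equiplume_domain_error")
})

test_that("d50 estimation error shrinks as the survey grows", {
  err_at <- function(n) {
    mean(vapply(1:4, function(s) {
      f <- fit_detection_model(generate_odor_survey(n, d50 = 60, slope = 0.1,
                                                    seed = 100 + s))
      abs(f$d50 - 60) / 60
    }, numeric(1)))
  }
  e50 <- err_at(50); e1000 <- err_at(1000)
  expect_lt(e1000, 0.05)
  expect_lt(e1000, e50 + 1e-9)
})

test_that("tracer comparison flags detection below the ammonia odor threshold", {
  crv <- detection_curve(survey_of(c(90, 70, 60, 50, 40, 30)),
                         bin_edges = seq(150, 0, -10))
  prof <- function(c0) tibble::tibble(distance = seq(0, 150, 10),
                                      conc = c0 * exp(-seq(0, 150, 10) / 40))
  cmp <- tracer_comparison(crv, prof(5), prof(2), nh3_odor_threshold = 100)
  expect_true(all(cmp$below_threshold[cmp$frac_at_or_beyond > 0]))
  # monotone profiles in, monotone columns out
  expect_true(all(diff(cmp$nh3) >= 0)) # distances are descending
  expect_true(all(diff(cmp$allergen) >= 0))

  # log-ratio oracle: nh3 0.5 against threshold 100 is ~3 orders below
  flat <- tibble::tibble(distance = c(0, 150), conc = 0.5)
  cmp2 <- tracer_comparison(crv, flat, prof(2), nh3_odor_threshold = 100)
  expect_equal(unique(round(cmp2$log10_nh3_vs_threshold, 1)), -2.3)

  short <- tibble::tibble(distance = c(0, 50), conc = 1)
  expect_error(tracer_comparison(crv, short, prof(2), 100),
               class = "equiplume_coverage_error")
})

test_that("the shipped survey fixture reads and summarizes cleanly", {
  srv <- read_odor_survey(system.file("extdata", "odor_survey_synthetic.csv",
                                      package = "equiplume"))
  expect_equal(nrow(srv), 40)
  crv <- detection_curve(srv)
  expect_true(all(diff(rev(crv$frac_within)) >= 0))
})
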
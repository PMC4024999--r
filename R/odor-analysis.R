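# Walk-toward-source odor surveys: respondents start far from the source and
# walk inward; the distance of first perceived odor is recorded (or nothing,
# if they never detect). Respondents who never detect stay in every
# denominator (intention-to-detect convention).

check_survey <- function(records) {
  need <- c("detection_distance", "walk_start")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort_format(paste0("Survey table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0) abort_domain("Survey has no respondents.")
  d <- records$detection_distance
  ok <- is.na(d) | (d >= 0 & d <= records$walk_start)
  if (!all(ok)) {
    abort_validation(sprintf("Detection distance outside [0, walk_start] at row %d.",
                             which(!ok)[1]))
  }
  invisible(records)
}

#' Read an odor survey table
#'
#' @param path Delimited text (comma or tab): columns `respondent`, `site`,
#'   `odor_type`, `detection_distance` (m, blank if never detected),
#'   `walk_start` (m).
#' @return Validated survey tibble.
#' @export
read_odor_survey <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  check_survey(tibble::as_tibble(df))
}

#' Detection fraction versus distance
#'
#' For each bin edge `d`: the fraction of all respondents who first detected
#' at a distance of `d` or more (detected "already at" `d`), and the
#' cumulative fraction who detected at `d` or closer. Never-detecting
#' respondents count in every denominator. Default edges step down in 10-m
#' bins from the walk start.
#'
#' @param records Survey tibble (see [read_odor_survey()]).
#' @param bin_edges Distance edges, m. Default `seq(max(walk_start), 0, -10)`.
#' @return A `detection_curve` tibble: `distance`, `n_at_or_beyond`,
#'   `frac_at_or_beyond`, `n_within`, `frac_within`, `n_total`.
#' @export
detection_curve <- function(records, bin_edges = NULL) {
  check_survey(records)
  bin_edges <- bin_edges %||% seq(max(records$walk_start), 0, by = -10)
  maxd <- suppressWarnings(max(records$detection_distance, na.rm = TRUE))
  if (is.finite(maxd) && max(bin_edges) < maxd) {
    abort(sprintf("Bin edges (max %g m) do not cover the detection range (max %g m).",
                  max(bin_edges), maxd),
          class = "equiplume_assignment_error")
  }
  d <- records$detection_distance
  n <- nrow(records)
  out <- tibble::tibble(
    distance = sort(bin_edges, decreasing = TRUE),
    n_at_or_beyond = vapply(sort(bin_edges, decreasing = TRUE),
                            function(e) sum(!is.na(d) & d >= e), integer(1)),
    n_within = vapply(sort(bin_edges, decreasing = TRUE),
                      function(e) sum(!is.na(d) & d <= e), integer(1)),
    n_total = n
  )
  out$frac_at_or_beyond <- out$n_at_or_beyond / n
  out$frac_within <- out$n_within / n
  class(out) <- c("detection_curve", class(out))
  out
}

#' Detection-distance quantile
#'
#' Smallest distance `d` such that at least a fraction `q` of all
#' respondents (never-detectors included in the denominator) first detected
#' at `d` or closer. Signals an unattainable quantile (returns `NA` with a
#' warning) when too few respondents detected at all.
#'
#' @param records Survey tibble.
#' @param q Target fraction in (0, 1).
#' @return Distance, m, or `NA` if unattainable.
#' @export
detection_quantile <- function(records, q) {
  check_survey(records)
  if (q <= 0 || q >= 1) abort_domain("`q` must be in (0, 1).")
  n <- nrow(records)
  d <- sort(records$detection_distance[!is.na(records$detection_distance)])
  k <- ceiling(q * n)
  if (k > length(d)) {
    warn(sprintf("Quantile %.0f%% unattainable: only %d of %d respondents detected.",
                 100 * q, length(d), n),
         class = "equiplume_quantile_warning")
    return(NA_real_)
  }
  d[k]
}

# log-likelihood of the logistic first-detection-distance model.
# Survival S(d) = P(first detection at distance >= d) = plogis(slope*(d50-d)):
# monotone non-increasing in d; P(never detect) = 1 - S(0).
odor_loglik <- function(par, d, censored_never, censored_start, walk_start) {
  d50 <- par[1]; slope <- exp(par[2])
  ll <- 0
  if (any(!censored_never & !censored_start)) {
    x <- d[!censored_never & !censored_start]
    # density: f(d) = slope * dlogis(slope * (d50 - d))
    ll <- ll + sum(log(slope) + dlogis(slope * (d50 - x), log = TRUE))
  }
  if (any(censored_never)) {
    ll <- ll + sum(censored_never) * plogis(-slope * d50, log.p = TRUE)
  }
  if (any(censored_start)) {
    ws <- walk_start[censored_start]
    ll <- ll + sum(plogis(slope * (d50 - ws), log.p = TRUE))
  }
  ll
}

#' Fit a logistic detection-distance model
#'
#' Maximum-likelihood fit of a two-parameter logistic model for the first
#' detection distance: the probability of having detected by distance `d`
#' (walking inward) is `1 - plogis(slope * (d50 - d))`, so `d50` is the
#' distance at which half the population would have detected and `slope`
#' (1/m) controls how sharply detection turns on. Respondents who never
#' detect are treated as censored below 0 m; respondents detecting
#' immediately at the walk start are censored at the start distance.
#'
#' @param records Survey tibble.
#' @return An `odor_fit` object with [tidy()] and [glance()] methods:
#'   `d50` (m), `slope` (1/m), log-likelihood, convergence and separation
#'   flags.
#' @export
fit_detection_model <- function(records) {
  check_survey(records)
  d <- records$detection_distance
  detected <- !is.na(d)
  if (sum(detected) < 2) abort_domain("Need at least 2 detections to fit.")
  separation <- length(unique(d[detected])) < 2
  never <- !detected
  at_start <- detected & d >= records$walk_start
  interior <- detected & !at_start
  if (separation) {
    warn("All detections at a single distance: parameters at documented bounds.",
         class = "equiplume_separation_warning")
    return(structure(
      list(d50 = unique(d[detected]), slope = Inf, loglik = NA_real_,
           converged = FALSE, separation = TRUE, n = nrow(records),
           n_detected = sum(detected)),
      class = "odor_fit"
    ))
  }
  init <- c(d50 = median(d[detected]), log_slope = log(0.1))
  fit <- optim(init, function(p) {
    -odor_loglik(p, d, never, at_start, records$walk_start)
  }, method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-10))
  if (fit$convergence != 0) {
    abort(sprintf(
      "Detection model did not converge (code %d; n = %d, detected = %d, median = %.1f m).",
      fit$convergence, nrow(records), sum(detected), median(d[detected])),
      class = "equiplume_convergence_error")
  }
  structure(
    list(d50 = unname(fit$par[1]), slope = unname(exp(fit$par[2])),
         loglik = -fit$value, converged = TRUE, separation = FALSE,
         n = nrow(records), n_detected = sum(detected)),
    class = "odor_fit"
  )
}

#' @export
print.odor_fit <- function(x, ...) {
  cat("Logistic odor detection-distance model\n")
  cat(sprintf("  d50: %.1f m   slope: %.4f /m\n", x$d50, x$slope))
  cat(sprintf("  n = %d (%d detected); logLik = %.2f%s\n",
              x$n, x$n_detected, x$loglik,
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' Compare a detection curve with modeled tracer concentrations
#'
#' Joins the odor-survey detection curve with modeled ammonia (tracer for
#' the gaseous part of odor) and allergen profiles by distance, and flags
#' bins where people detect odor although modeled ammonia is below the
#' stated odor threshold — evidence that ammonia alone does not carry the
#' smell. The threshold has no physiological default and must be supplied.
#'
#' @param curve A [detection_curve()].
#' @param nh3_profile,allergen_profile Tibbles with `distance` (m) and
#'   `conc` (ug/m3 and U/m3); must cover the curve's distance range
#'   (linear interpolation between profile points).
#' @param nh3_odor_threshold Odor threshold for ammonia, ug/m3.
#' @return Tibble per distance bin: `distance`, `frac_at_or_beyond`,
#'   `nh3`, `allergen`, `below_threshold`, `log10_nh3_vs_threshold`.
#' @export
tracer_comparison <- function(curve, nh3_profile, allergen_profile,
                              nh3_odor_threshold) {
  if (nh3_odor_threshold <= 0) abort_domain("`nh3_odor_threshold` must be > 0.")
  rng <- range(curve$distance)
  for (prof in list(nh3_profile, allergen_profile)) {
    if (min(prof$distance) > rng[1] || max(prof$distance) < rng[2]) {
      abort(sprintf("Profile covers [%g, %g] m but the curve needs [%g, %g] m.",
                    min(prof$distance), max(prof$distance), rng[1], rng[2]),
            class = "equiplume_coverage_error")
    }
  }
  nh3 <- approx(nh3_profile$distance, nh3_profile$conc, xout = curve$distance)$y
  alg <- approx(allergen_profile$distance, allergen_profile$conc,
                xout = curve$distance)$y
  tibble::tibble(
    distance = curve$distance,
    frac_at_or_beyond = curve$frac_at_or_beyond,
    nh3 = nh3,
    allergen = alg,
    below_threshold = nh3 < nh3_odor_threshold & curve$frac_at_or_beyond > 0,
    log10_nh3_vs_threshold = log10(nh3 / nh3_odor_threshold)
  )
}
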
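# broom-style methods for the fitted-object classes.

#' Tidy an inverse-dispersion fit
#'
#' @param x An `inverse_fit`.
#' @param ... Unused.
#' @return One row per fitted source: `source`, `emission_density`.
#' @export
tidy.inverse_fit <- function(x, ...) x$estimates

#' One-row summary of an inverse-dispersion fit
#'
#' @param x An `inverse_fit`.
#' @param ... Unused.
#' @return Tibble: `n_obs`, `n_dropped`, `compliance` (fraction of
#'   observations within the compliance tolerance), `compliance_tol`,
#'   `rmse`.
#' @export
glance.inverse_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_dropped = x$n_dropped,
    compliance = x$compliance,
    compliance_tol = x$compliance_tol,
    rmse = sqrt(mean(x$residuals$residual^2))
  )
}

#' @export
print.inverse_fit <- function(x, ...) {
  cat("Inverse-dispersion emission fit\n")
  print(x$estimates)
  cat(sprintf("  %d observation(s), %.0f%% within +-%.0f%%\n",
              x$n_obs, 100 * x$compliance, 100 * x$compliance_tol))
  invisible(x)
}

#' Tidy a logistic odor detection fit
#'
#' @param x An `odor_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`d50`, `slope`).
#' @export
tidy.odor_fit <- function(x, ...) {
  tibble::tibble(term = c("d50", "slope"), estimate = c(x$d50, x$slope))
}

#' One-row summary of a logistic odor detection fit
#'
#' @param x An `odor_fit`.
#' @param ... Unused.
#' @export
glance.odor_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_detected = x$n_detected, logLik = x$loglik,
                 converged = x$converged, separation = x$separation)
}

#' Tidy a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return The scored pairs tibble (`measured`, `modeled`, `rel_error`,
#'   `within`).
#' @export
tidy.validation_report <- function(x, ...) x$pairs

#' One-row summary of a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_excluded = x$n_excluded,
    fraction_within = x$fraction_within,
    fraction_within_35 = x$fraction_within_35,
    tolerance = x$tolerance
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation: %d pair(s); %.0f%% within +-%.0f%% (%.0f%% within +-35%%)\n",
              x$n, 100 * x$fraction_within, 100 * x$tolerance,
              100 * x$fraction_within_35))
  invisible(x)
}
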
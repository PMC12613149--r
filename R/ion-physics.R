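# Ion physics: reduced mass and the single-field Mason-Schamp conversion
# between inverse reduced mobility (1/K0) and collision cross section (CCS).
#
# For an ion of mass m drifting in a gas of molecular mass M, the
# Mason-Schamp relation makes CCS proportional to z * (1/K0) / sqrt(mu),
# with mu = m*M/(m+M) the reduced mass. Temperature, pressure and the
# fundamental constants are absorbed into one proportionality constant that
# is fitted on calibrant ions of known CCS (single-field calibration).

#' Molecular mass of nitrogen drift gas (Da)
#'
#' Default drift-gas mass used throughout the package; TIMS instruments
#' conventionally operate with nitrogen as carrier gas.
#' @export
N2_MASS <- 28.0134

#' Reduced mass of an ion-gas pair
#'
#' @param ion_mass Ion mass in Da (> 0).
#' @param gas_mass Drift-gas molecular mass in Da (> 0).
#' @return Reduced mass \eqn{\mu = mM/(m+M)} in Da. Vectorised; symmetric in
#'   its arguments and always smaller than either input.
#' @examples
#' reduced_mass(322.048, 28.0134)
#' @export
reduced_mass <- function(ion_mass, gas_mass) {
  if (!is.numeric(ion_mass) || !is.numeric(gas_mass) ||
      any(!is.finite(ion_mass)) || any(!is.finite(gas_mass)) ||
      any(ion_mass <= 0) || any(gas_mass <= 0))
    invalid_input("masses must be positive finite numbers")
  ion_mass * gas_mass / (ion_mass + gas_mass)
}

# Mason-Schamp predictor x such that CCS = slope * x (+ intercept).
# Ion mass is taken as charge * m/z; the electron mass (~0.00055 Da per
# charge) is neglected -- its effect is far below calibration residuals.
ms_predictor <- function(inv_k0, mz, charge, gas_mass) {
  mu <- reduced_mass(charge * mz, gas_mass)
  charge * inv_k0 / sqrt(mu)
}

#' Fit a single-field CCS calibration
#'
#' Ordinary least-squares fit of reference CCS values against the
#' Mason-Schamp predictor \eqn{x = z (1/K_0) / \sqrt{\mu}} computed from
#' calibrant ions of known CCS. The default is a pure proportionality
#' (zero intercept), the conventional form for single-field TIMS
#' calibration; an intercept can be requested for robustness.
#'
#' @param calibrants data.frame with columns \code{mz} (Th), \code{charge}
#'   (positive integer), \code{ccs} (reference CCS, A^2) and \code{inv_k0}
#'   (measured inverse reduced mobility, V s/cm^2). A \code{name} column is
#'   carried along if present.
#' @param gas_mass Drift-gas molecular mass in Da (default nitrogen).
#' @param fit_intercept Logical; fit an additive offset (default FALSE).
#' @return An object of class \code{ccs_calibration}: a list with
#'   \code{slope} (A^2 cm^2 sqrt(Da) / (V s)), \code{intercept} (A^2),
#'   \code{gas_mass}, \code{n_calibrants}, \code{residual_rms} (A^2) and
#'   the fitted values and residuals per calibrant.
#' @seealso [inv_k0_to_ccs()], [ccs_to_inv_k0()], [tunemix_calibrants()]
#' @examples
#' cal <- fit_ccs_calibration(tunemix_calibrants())
#' coef(cal)
#' @export
fit_ccs_calibration <- function(calibrants, gas_mass = N2_MASS,
                                fit_intercept = FALSE) {
  req <- c("mz", "charge", "ccs", "inv_k0")
  if (!is.data.frame(calibrants) || !all(req %in% names(calibrants)))
    invalid_input("`calibrants` must be a data.frame with columns mz, charge, ccs, inv_k0")
  if (nrow(calibrants) < 2L)
    data_error("timscreen_insufficient_calibrants",
               "at least 2 calibrant ions are required to fit a calibration")
  with(calibrants, {
    if (any(mz <= 0) || any(charge < 1) || any(ccs <= 0) || any(inv_k0 <= 0))
      invalid_input("calibrant table contains non-physical values")
  })
  x <- ms_predictor(calibrants$inv_k0, calibrants$mz, calibrants$charge, gas_mass)
  if (max(x) - min(x) < 1e-12 * max(abs(x)))
    data_error("timscreen_singular_fit",
               "calibrant predictor values are degenerate; cannot fit")
  y <- calibrants$ccs
  if (fit_intercept) {
    fit <- stats::lm(y ~ x)
    if (any(is.na(stats::coef(fit))))
      data_error("timscreen_singular_fit", "degenerate predictor matrix")
    intercept <- unname(stats::coef(fit)[1L])
    slope <- unname(stats::coef(fit)[2L])
    res <- stats::residuals(fit)
  } else {
    slope <- sum(x * y) / sum(x * x)
    intercept <- 0
    res <- y - slope * x
  }
  if (!is.finite(slope) || slope <= 0)
    data_error("timscreen_singular_fit", "fitted slope is not a positive number")
  structure(list(
    slope = slope,
    intercept = intercept,
    gas_mass = gas_mass,
    n_calibrants = nrow(calibrants),
    residual_rms = sqrt(mean(res^2)),
    fitted = slope * x + intercept,
    residuals = as.numeric(res),
    calibrants = calibrants
  ), class = "ccs_calibration")
}

#' @export
print.ccs_calibration <- function(x, ...) {
  cat("Single-field CCS calibration (Mason-Schamp form)\n")
  cat(sprintf("  slope     : %.4f A^2 cm^2 sqrt(Da)/(V s)\n", x$slope))
  if (x$intercept != 0) cat(sprintf("  intercept : %.4f A^2\n", x$intercept))
  cat(sprintf("  drift gas : %.4f Da\n", x$gas_mass))
  cat(sprintf("  calibrants: %d, residual RMS %.4g A^2\n",
              x$n_calibrants, x$residual_rms))
  invisible(x)
}

#' @export
coef.ccs_calibration <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
residuals.ccs_calibration <- function(object, ...) object$residuals

#' Predict CCS for ions from a fitted calibration
#'
#' @param object A \code{ccs_calibration}.
#' @param newdata data.frame with columns \code{inv_k0}, \code{mz},
#'   \code{charge}; defaults to the calibrant table.
#' @param ... Unused.
#' @return Numeric vector of CCS values (A^2).
#' @export
predict.ccs_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  inv_k0_to_ccs(newdata$inv_k0, newdata$mz, newdata$charge, object)
}

check_calibration <- function(cal) {
  if (!inherits(cal, "ccs_calibration"))
    data_error("timscreen_uncalibrated",
               "a fitted `ccs_calibration` is required; mobility data are uncalibrated")
}

#' Convert inverse reduced mobility to CCS
#'
#' \eqn{CCS = slope \cdot z (1/K_0) / \sqrt{\mu} + intercept}, with the
#' reduced mass from the ion mass (charge times m/z) and the calibration's
#' drift-gas mass.
#'
#' @param inv_k0 Inverse reduced mobility, V s/cm^2 (> 0). Vectorised.
#' @param mz Ion m/z (Th).
#' @param charge Charge state (>= 1).
#' @param cal A \code{ccs_calibration}.
#' @return CCS in A^2.
#' @export
inv_k0_to_ccs <- function(inv_k0, mz, charge, cal) {
  check_calibration(cal)
  if (any(inv_k0 <= 0)) invalid_input("`inv_k0` must be positive")
  if (any(charge < 1)) invalid_input("`charge` must be >= 1")
  cal$slope * ms_predictor(inv_k0, mz, charge, cal$gas_mass) + cal$intercept
}

#' Convert CCS to inverse reduced mobility
#'
#' Exact inverse of [inv_k0_to_ccs()]; used by the synthetic-data generator
#' to place peaks in mobility space.
#'
#' @param ccs CCS in A^2; must exceed the calibration intercept.
#' @inheritParams inv_k0_to_ccs
#' @return Inverse reduced mobility in V s/cm^2.
#' @export
ccs_to_inv_k0 <- function(ccs, mz, charge, cal) {
  check_calibration(cal)
  if (any(ccs <= cal$intercept))
    invalid_input("`ccs` must exceed the calibration intercept")
  mu <- reduced_mass(charge * mz, cal$gas_mass)
  (ccs - cal$intercept) * sqrt(mu) / (cal$slope * charge)
}

#' Tune-mix calibrant table with synthetic mobility measurements
#'
#' The six Agilent ESI-L tune-mix ions with their compendium CCS values,
#' paired with inverse reduced mobility values forward-computed from a
#' chosen Mason-Schamp constant (optionally perturbed). The 1/K0 column is
#' synthetic -- it emulates an instrument whose true calibration constant is
#' \code{slope} -- so a refit recovers \code{slope} exactly in the
#' noise-free case.
#'
#' @param slope True proportionality constant used to place the ions.
#' @param gas_mass Drift-gas mass (Da).
#' @param ccs_noise_sd Gaussian noise (A^2) added to the reference CCS
#'   column, for calibration-robustness experiments. Default 0.
#' @return data.frame with columns \code{name, mz, charge, ccs, inv_k0}.
#' @export
tunemix_calibrants <- function(slope = 1059.9, gas_mass = N2_MASS,
                               ccs_noise_sd = 0) {
  tbl <- data.frame(
    name = paste0("tunemix_", c(118, 322, 622, 922, 1222, 1522)),
    mz = c(118.0863, 322.0481, 622.0290, 922.0098, 1221.9906, 1521.9715),
    charge = 1L,
    ccs = c(121.30, 153.73, 202.96, 243.64, 282.20, 316.96)
  )
  mu <- reduced_mass(tbl$charge * tbl$mz, gas_mass)
  tbl$inv_k0 <- tbl$ccs * sqrt(mu) / (slope * tbl$charge)
  if (ccs_noise_sd > 0)
    tbl$ccs <- tbl$ccs + stats::rnorm(nrow(tbl), 0, ccs_noise_sd)
  tbl
}
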
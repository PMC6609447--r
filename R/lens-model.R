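# Age-dependent ocular-media (lens) density model.
#
# Two-component model of the Pokorny, Smith & Lutze (1987) form: total lens
# density at wavelength lambda and age A (years) is
#
#   D(lambda, A) = TL1(lambda) * (1 + 0.02 (A - 32)) + TL2(lambda)   20 <= A <= 60
#   D(lambda, A) = TL1(lambda) * (1.56 + 0.0667 (A - 60)) + TL2(lambda)   A > 60
#
# TL1 carries the age-varying portion (largest at short wavelengths, zero
# above 650 nm), TL2 the age-invariant portion. The correction factor of an
# observer relative to the 32-year standard observer is the transmittance
# ratio 10^-(D(lambda, A) - D(lambda, 32)), in which TL2 cancels.

.psl_wl <- seq(400, 650, by = 10)
.psl_tl1_vals <- c(0.600, 0.510, 0.433, 0.377, 0.327, 0.295, 0.267, 0.233,
                   0.207, 0.187, 0.167, 0.147, 0.133, 0.120, 0.107, 0.093,
                   0.080, 0.067, 0.053, 0.040, 0.033, 0.027, 0.020, 0.013,
                   0.007, 0.000)
.psl_tl2_vals <- c(1.000, 0.583, 0.300, 0.116, 0.033, 0.005, rep(0, 20))

# Piecewise-linear in 400-650 nm; linear extension of the first segment
# below 400 nm (clamped to >= 0); identically 0 above 650 nm.
.psl_component <- function(wavelength, vals) {
  out <- numeric(length(wavelength))
  below <- wavelength < 400
  inside <- wavelength >= 400 & wavelength <= 650
  slope <- (vals[2] - vals[1]) / 10
  out[below] <- pmax(vals[1] + slope * (wavelength[below] - 400), 0)
  if (any(inside))
    out[inside] <- stats::approx(.psl_wl, vals, xout = wavelength[inside])$y
  out
}

.lens_age_range <- c(20, 80)

.check_observer_age <- function(age) {
  if (!is.numeric(age) || length(age) != 1 || !is.finite(age))
    stop("'age' must be a finite scalar (years)")
  if (age < .lens_age_range[1] || age > .lens_age_range[2])
    stop(sprintf(paste0("observer age %g outside the lens-model validity ",
                        "range %g-%g years; extrapolating lens density is ",
                        "not supported"), age,
                 .lens_age_range[1], .lens_age_range[2]))
  invisible(age)
}

.lens_density <- function(wavelength, age) {
  tl1 <- .psl_component(wavelength, .psl_tl1_vals)
  tl2 <- .psl_component(wavelength, .psl_tl2_vals)
  mult <- if (age <= 60) 1 + 0.02 * (age - 32) else 1.56 + 0.0667 * (age - 60)
  tl1 * mult + tl2
}

#' Age-dependent pre-receptoral filtering correction
#'
#' Spectral transmittance of the ocular media of an observer of the given
#' age relative to the 32-year standard observer, from a two-component
#' lens-density model (Pokorny-Smith-Lutze form). The factor is exactly 1
#' at every wavelength for age 32; above that age, lens yellowing
#' attenuates short wavelengths progressively (factors below 1 that
#' decrease with age), while wavelengths above 650 nm are unaffected.
#'
#' @param age Observer age in years, within 20-80 (error outside; lens
#'   density is not extrapolated).
#' @param wavelength Wavelengths in nm at which to evaluate the factor
#'   (default the 380-780 nm reporting grid).
#' @return Object of class `lens_correction`: a list with `age`,
#'   `wavelength` and `spectral_factor` (multiplicative, relative to the
#'   standard observer).
#' @examples
#' lc <- lens_correction(60)
#' range(lc$spectral_factor)
#' @export
lens_correction <- function(age, wavelength = .default_grid_nm()) {
  .check_observer_age(age)
  factor <- 10^(-(.lens_density(wavelength, age) - .lens_density(wavelength, 32)))
  structure(list(age = age, wavelength = wavelength,
                 spectral_factor = factor),
            class = "lens_correction")
}

#' @export
print.lens_correction <- function(x, ...) {
  cat(sprintf("<lens_correction> age %g y vs standard observer (32 y); factor %0.4f-%0.4f\n",
              x$age, min(x$spectral_factor), max(x$spectral_factor)))
  invisible(x)
}
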
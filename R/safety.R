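#' Blue-light-hazard-weighted radiance
#'
#' Weights a radiance spectrum with the blue-light photochemical hazard
#' function B and integrates, giving the quantity that photobiological
#' safety standards compare against risk-group radiance limits.
#'
#' @param spd A radiance-kind [spd][spectral_measurement()].
#' @param reference Reference functions.
#' @return Weighted radiance in W/(m^2 sr).
#' @examples
#' blue_light_weighted_radiance(planckian_spd(6500, 1e-3, "spectral_radiance"))
#' @export
blue_light_weighted_radiance <- function(spd,
                                         reference = load_reference_functions()) {
  stopifnot(is_spd(spd))
  if (spd$kind != "spectral_radiance")
    stop("blue-light-weighted radiance requires a spectral_radiance input")
  weighted_integral(spd, reference$blue_light_hazard)
}

#' Photobiological risk-group-0 pre-screen
#'
#' A screening check of a radiance spectrum against the photochemical
#' (blue-light) retinal hazard, following the risk-group-0 logic for
#' general light sources:
#'
#' * sources with photopic luminance below 10,000 cd/m^2 are exempt -
#'   detailed hazard measurement is typically not required
#'   (`exempt_low_luminance`);
#' * above that, for exposures longer than 10,000 s, the blue-light-
#'   weighted radiance is compared against the risk-group-0 limit of
#'   100 W/(m^2 sr) (`rg0_pass` / `rg0_exceeded`);
#' * bright sources at exposures of 10,000 s or less return `rg0_pass`
#'   with a rationale noting that the long-exposure limit was not
#'   triggered; time-dependent short-exposure limits are out of scope.
#'
#' This is a pre-screen, not a certification: the rationale always notes
#' that regulatory compliance must be confirmed case by case. Thermal
#' hazard is not assessed (negligible at domestic light levels).
#'
#' @param spd A radiance-kind [spd][spectral_measurement()].
#' @param exposure_duration Exposure duration in seconds (> 0).
#' @param radiance_limit Risk-group-0 blue-light radiance limit,
#'   W/(m^2 sr).
#' @param luminance_exemption Luminance below which the screen exempts the
#'   source, cd/m^2.
#' @param long_exposure Duration in seconds above which the radiance limit
#'   applies.
#' @param reference Reference functions.
#' @return Object of class `safety_screen_result`: `verdict` (one of
#'   `exempt_low_luminance`, `rg0_pass`, `rg0_exceeded`),
#'   `weighted_radiance` (`NA` when the radiance test did not run),
#'   `luminance`, `exposure_duration`, `rationale`, and the thresholds
#'   used.
#' @examples
#' spd <- planckian_spd(6500, 1e-3, "spectral_radiance")
#' rg0_screen(spd, exposure_duration = 20000)
#' @export
rg0_screen <- function(spd, exposure_duration,
                       radiance_limit = .rg0_radiance_limit,
                       luminance_exemption = .rg0_exempt_luminance,
                       long_exposure = .rg0_long_exposure_s,
                       reference = load_reference_functions()) {
  stopifnot(is_spd(spd))
  if (spd$kind != "spectral_radiance")
    stop("the safety screen requires a spectral_radiance input")
  if (!is.numeric(exposure_duration) || exposure_duration <= 0)
    stop("'exposure_duration' must be > 0 s")

  caveat <- paste("Pre-screen only: compliance with photobiological-safety",
                  "regulations must be checked and confirmed case by case.")
  lum <- lux_constants()$K_m * weighted_integral(spd, reference$photopic_V)

  if (lum < luminance_exemption) {
    verdict <- "exempt_low_luminance"
    wr <- NA_real_
    rationale <- sprintf(paste("Luminance %.4g cd/m^2 is below %.4g cd/m^2;",
                               "detailed hazard measurement is typically not",
                               "required for such sources."),
                         lum, luminance_exemption)
  } else {
    wr <- weighted_integral(spd, reference$blue_light_hazard)
    if (exposure_duration <= long_exposure) {
      verdict <- "rg0_pass"
      rationale <- sprintf(paste("Exposure duration %.4g s does not exceed the",
                                 "%.4g s long-exposure threshold, so the",
                                 "risk-group-0 radiance limit was not",
                                 "triggered (blue-light-weighted radiance",
                                 "%.4g W/(m^2 sr)); short-exposure limits are",
                                 "not assessed by this screen."),
                           exposure_duration, long_exposure, wr)
    } else if (wr <= radiance_limit) {
      verdict <- "rg0_pass"
      rationale <- sprintf(paste("Blue-light-weighted radiance %.4g W/(m^2 sr)",
                                 "is within the risk-group-0 limit of %.4g",
                                 "W/(m^2 sr) for exposures longer than %.4g s."),
                           wr, radiance_limit, long_exposure)
    } else {
      verdict <- "rg0_exceeded"
      rationale <- sprintf(paste("Blue-light-weighted radiance %.4g W/(m^2 sr)",
                                 "exceeds the risk-group-0 limit of %.4g",
                                 "W/(m^2 sr) for exposures longer than %.4g s."),
                           wr, radiance_limit, long_exposure)
    }
  }
  structure(list(
    weighted_radiance = wr, luminance = lum,
    exposure_duration = exposure_duration, verdict = verdict,
    rationale = paste(rationale, caveat),
    radiance_limit = radiance_limit,
    luminance_exemption = luminance_exemption,
    long_exposure = long_exposure,
    hazard_function = "synthetic blue-light hazard tabulation (see reference table provenance header)"
  ), class = "safety_screen_result")
}

#' @export
print.safety_screen_result <- function(x, ...) {
  cat(sprintf("<safety_screen_result> %s\n  luminance %0.6g cd/m^2, weighted radiance %s W/(m^2 sr), duration %g s\n  %s\n",
              x$verdict, x$luminance,
              if (is.na(x$weighted_radiance)) "-" else
                sprintf("%0.6g", x$weighted_radiance),
              x$exposure_duration, x$rationale))
  invisible(x)
}
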
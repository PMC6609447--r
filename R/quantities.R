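#' Spectrally weighted band integral
#'
#' The workhorse of every alpha-opic and photometric quantity: aligns the
#' spectrum and the weighting function on a common 1 nm grid over the
#' intersection of their supports and returns the rectangle-rule sum
#' `sum(spd(lambda) * a(lambda) * 1 nm)`. The result carries the input's
#' radiometric units (W/m^2 for spectral irradiance, W/(m^2 sr) for
#' spectral radiance); unit conversions (mW, lux, cd/m^2) happen at panel
#' assembly, keeping the integral itself unit-neutral.
#'
#' @param spd An [spd][spectral_measurement()] object.
#' @param a An [action_spectrum()].
#' @return Scalar band-weighted quantity in the input's units.
#' @examples
#' refs <- load_reference_functions()
#' spd <- monochromatic_spd(555, 1)
#' weighted_integral(spd, refs$photopic_V)  # V(555) = 1 -> 1 W/m^2
#' @export
weighted_integral <- function(spd, a) {
  stopifnot(is_spd(spd), inherits(a, "action_spectrum"))
  lo <- max(min(spd$wavelength), min(a$wavelength))
  hi <- min(max(spd$wavelength), max(a$wavelength))
  if (lo > hi)
    stop(sprintf("spectrum support (%g-%g nm) and '%s' support (%g-%g nm) are disjoint",
                 min(spd$wavelength), max(spd$wavelength), a$name,
                 min(a$wavelength), max(a$wavelength)))
  common <- seq(ceiling(lo), floor(hi), by = 1)
  if (length(common) == 0) common <- lo  # sub-nm overlap
  sv <- if (identical(as.numeric(common), as.numeric(spd$wavelength))) spd$values
        else suppressWarnings(spd_resample(spd, common))$values
  av <- if (identical(as.numeric(common), as.numeric(a$wavelength))) a$weights
        else stats::approx(a$wavelength, a$weights, xout = common,
                           yleft = 0, yright = 0, ties = "ordered")$y
  sum(sv * av)
}

#' Alpha-opic panel of a spectrum
#'
#' Converts a spectral (ir)radiance into the six reportable scalars: the
#' five absolute alpha-opic values (S-, M-, L-cone-opic, rhodopic,
#' melanopic) in mW/m^2 (irradiance input) or mW/(m^2 sr) (radiance
#' input), plus the photopic quantity - illuminance in lux for irradiance
#' input, luminance in cd/m^2 for radiance input - obtained with the
#' maximum luminous efficacy constant of 683 lm/W.
#'
#' For observers away from the standard age of 32 years, the five
#' alpha-opic weighting functions are first adjusted with
#' [lens_corrected_weighting()]; the photopic entry always uses the
#' standard observer, since photometric units are defined for it.
#'
#' @param spd An [spd][spectral_measurement()] object.
#' @param age Observer age in years (default 32, the standard observer).
#' @param reference Reference functions, as from
#'   [load_reference_functions()].
#' @return An object of class `alpha_opic_panel` with fields
#'   `s_cone_opic`, `m_cone_opic`, `l_cone_opic`, `rhodopic`,
#'   `melanopic`, `photopic`, `input_kind`, `observer_age`.
#' @examples
#' alpha_opic_panel(monochromatic_spd(555, 1))$photopic  # 683 lux
#' @export
alpha_opic_panel <- function(spd, age = 32,
                             reference = load_reference_functions()) {
  stopifnot(is_spd(spd))
  .check_observer_age(age)
  vals <- vapply(.alpha_opic_names, function(nm) {
    a <- reference[[nm]]
    if (age != 32) a <- lens_corrected_weighting(a, age)
    1000 * weighted_integral(spd, a)  # W -> mW
  }, numeric(1))
  photopic <- lux_constants()$K_m * weighted_integral(spd, reference$photopic_V)
  structure(c(as.list(vals),
              list(photopic = photopic, input_kind = spd$kind,
                   observer_age = age)),
            class = "alpha_opic_panel")
}

.panel_units <- function(kind) {
  if (kind == "spectral_irradiance")
    list(alpha = "mW/m^2", photopic = "lux", photopic_name = "illuminance")
  else
    list(alpha = "mW/(m^2 sr)", photopic = "cd/m^2", photopic_name = "luminance")
}

#' @export
print.alpha_opic_panel <- function(x, ...) {
  u <- .panel_units(x$input_kind)
  cat(sprintf("<alpha_opic_panel> observer age %g y, input %s\n",
              x$observer_age, x$input_kind))
  for (nm in .alpha_opic_names)
    cat(sprintf("  %-12s %12.6g %s\n", nm, x[[nm]], u$alpha))
  cat(sprintf("  %-12s %12.6g %s (photopic %s)\n", "photopic",
              x$photopic, u$photopic, u$photopic_name))
  invisible(x)
}

#' @export
as.data.frame.alpha_opic_panel <- function(x, ...) {
  u <- .panel_units(x$input_kind)
  df <- as.data.frame(x[c(.alpha_opic_names, "photopic")])
  names(df) <- c(paste0(.alpha_opic_names, "_",
                        gsub("[/^() ]", ".", u$alpha)),
                 paste0("photopic_", gsub("[/^() ]", ".", u$photopic)))
  df$observer_age_y <- x$observer_age
  df$input_kind <- x$input_kind
  df
}

#' Export alpha-opic panels
#'
#' Writes one or more panels as CSV or JSON with units embedded in the
#' column names.
#'
#' @param panels A single `alpha_opic_panel` or a list of them.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @examples
#' p <- alpha_opic_panel(monochromatic_spd(555, 1))
#' f <- tempfile(fileext = ".csv")
#' write_panel_csv(p, f)
#' @export
write_panel_csv <- function(panels, path) {
  if (inherits(panels, "alpha_opic_panel")) panels <- list(panels)
  df <- do.call(rbind, lapply(panels, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
write_panel_json <- function(panels, path) {
  if (inherits(panels, "alpha_opic_panel")) panels <- list(panels)
  jsonlite::write_json(lapply(panels, function(p) {
    u <- .panel_units(p$input_kind)
    list(alpha_opic = p[.alpha_opic_names], alpha_opic_units = u$alpha,
         photopic = p$photopic, photopic_units = u$photopic,
         observer_age_y = p$observer_age, input_kind = p$input_kind)
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Photon irradiance of a spectrum
#'
#' Converts a spectral irradiance into the photon system: the
#' per-wavelength photon rate is `E(lambda) * lambda / (h c)` (photons
#' m^-2 s^-1 nm^-1, converted to cm^-2), with the band total and its
#' base-10 logarithm. The logarithm is reported as `NA` for an all-zero
#' spectrum. Radiance input is rejected - photon radiance is not a
#' reporting quantity here.
#'
#' @param spd An irradiance-kind [spd][spectral_measurement()].
#' @return Object of class `photon_report` with fields
#'   `total_photon_irradiance` (photons cm^-2 s^-1), `log10_total`, and
#'   `per_wavelength` (photon spectral irradiance on the input grid).
#' @examples
#' photon_report(monochromatic_spd(500, 1))$total_photon_irradiance
#' @export
photon_report <- function(spd) {
  stopifnot(is_spd(spd))
  if (spd$kind != "spectral_irradiance")
    stop("photon irradiance requires a spectral_irradiance input; ",
         "photon radiance is not supported")
  cst <- lux_constants()
  # W m^-2 nm^-1 -> photons m^-2 s^-1 nm^-1 -> photons cm^-2 s^-1 nm^-1
  per_wl <- spd$values * (spd$wavelength * 1e-9) / (cst$h * cst$c) * 1e-4
  ph <- spd
  ph$values <- per_wl
  total <- spd_integral(ph)
  structure(list(
    total_photon_irradiance = total,
    log10_total = if (total > 0) log10(total) else NA_real_,
    per_wavelength = per_wl,
    wavelength = spd$wavelength
  ), class = "photon_report")
}

#' @export
print.photon_report <- function(x, ...) {
  cat(sprintf("<photon_report> total %0.6g photons/cm^2/s (log10 %s)\n",
              x$total_photon_irradiance,
              if (is.na(x$log10_total)) "undefined" else
                sprintf("%0.4f", x$log10_total)))
  invisible(x)
}

#' Age sensitivity analysis of the alpha-opic panel
#'
#' Recomputes the alpha-opic panel for a set of candidate observer ages,
#' quantifying how much the reported values depend on the assumed
#' pre-receptoral filtering. The row for age 32 reproduces the
#' standard-observer panel exactly.
#'
#' @param spd An [spd][spectral_measurement()].
#' @param ages Numeric vector of observer ages in years (non-empty, each
#'   within 20-80).
#' @param reference Reference functions.
#' @return A data.frame with one row per age: `age_y`, the five
#'   alpha-opic columns, and `photopic`.
#' @examples
#' age_sensitivity_analysis(monochromatic_spd(480, 1), c(32, 50, 70))
#' @export
age_sensitivity_analysis <- function(spd, ages,
                                     reference = load_reference_functions()) {
  if (length(ages) == 0) stop("'ages' must be non-empty")
  rows <- lapply(ages, function(a) {
    p <- alpha_opic_panel(spd, age = a, reference = reference)
    data.frame(age_y = a, as.list(unlist(p[.alpha_opic_names])),
               photopic = p$photopic)
  })
  do.call(rbind, rows)
}
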
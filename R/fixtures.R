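# Synthetic stimulus generators: Planckian radiators, Gaussian LED
# mixtures and monochromatic lines on the standard 380-780 nm 1-nm grid,
# plus deliberately deficient exposure records for exercising the
# compliance validator. All fixtures are deterministic given their
# parameters; the generating spec is recorded in the SPD metadata.

#' Planck's law, spectral radiance per nm
#'
#' Black-body spectral radiance `(2 h c^2 / lambda^5) / (exp(h c /
#' (lambda k_B T)) - 1)`, converted to per-nm units.
#'
#' @param wavelength Wavelengths in nm.
#' @param temperature Black-body temperature in K (> 0).
#' @return Spectral radiance in W m^-2 sr^-1 nm^-1.
#' @examples
#' planck_spectral_radiance(560, 5000)
#' @export
planck_spectral_radiance <- function(wavelength, temperature) {
  if (temperature <= 0) stop("'temperature' must be > 0 K")
  cst <- lux_constants()
  lam <- wavelength * 1e-9
  (2 * cst$h * cst$c^2 / lam^5) /
    (exp(cst$h * cst$c / (lam * cst$k_B * temperature)) - 1) * 1e-9
}

#' Planckian radiator fixture
#'
#' A black-body spectrum of the given temperature on the standard
#' 380-780 nm 1-nm grid, computed directly from Planck's law in double
#' precision and multiplied by `scale`. The unscaled values are those of
#' an ideal black-body surface, so realistic lab levels correspond to
#' small scale factors.
#'
#' @param temperature Temperature in K (> 0).
#' @param scale Non-negative multiplier.
#' @param kind Quantity kind of the output.
#' @return An [spd][spectral_measurement()].
#' @examples
#' planckian_spd(6500, scale = 1e-4)
#' @export
planckian_spd <- function(temperature, scale = 1,
                          kind = c("spectral_radiance", "spectral_irradiance")) {
  kind <- match.arg(kind)
  if (scale < 0) stop("'scale' must be >= 0")
  wl <- .default_grid_nm()
  spectral_measurement(
    wl, planck_spectral_radiance(wl, temperature) * scale, kind = kind,
    label = sprintf("planckian %gK", temperature),
    metadata = list(fixture = sprintf("planckian(T=%g, scale=%g)",
                                      temperature, scale)))
}

#' Gaussian multi-primary LED fixture
#'
#' A sum of Gaussian bands on the standard grid, one per primary. Each
#' primary is parameterized by peak wavelength (nm), full width at half
#' maximum (nm) and weight, where the weight is the primary's
#' band-integrated power (so the spectrum integrates to approximately the
#' sum of weights when all primaries lie well inside 380-780 nm).
#'
#' @param primaries A list of `c(peak, fwhm, weight)` triples, or a
#'   3-column matrix (one row per primary).
#' @param kind Quantity kind of the output.
#' @return An [spd][spectral_measurement()].
#' @examples
#' gaussian_led_spd(list(c(450, 20, 0.5), c(550, 30, 1)))
#' @export
gaussian_led_spd <- function(primaries,
                             kind = c("spectral_irradiance", "spectral_radiance")) {
  kind <- match.arg(kind)
  if (is.matrix(primaries)) primaries <- asplit(primaries, 1)
  if (length(primaries) == 0) stop("'primaries' must be non-empty")
  wl <- .default_grid_nm()
  vals <- numeric(length(wl))
  for (p in primaries) {
    p <- as.numeric(p)
    if (length(p) != 3) stop("each primary must be c(peak, fwhm, weight)")
    if (p[2] <= 0) stop("fwhm must be > 0 nm")
    if (p[3] < 0) stop("weights must be >= 0")
    sigma <- p[2] / (2 * sqrt(2 * log(2)))
    vals <- vals + p[3] * stats::dnorm(wl, mean = p[1], sd = sigma)
  }
  spectral_measurement(
    wl, vals, kind = kind, label = "gaussian LED mixture",
    metadata = list(fixture = paste0(
      "gaussian_led(",
      paste(vapply(primaries, function(p)
        sprintf("%g/%g/%g", p[1], p[2], p[3]), character(1)), collapse = ";"),
      ")")))
}

#' Monochromatic line fixture
#'
#' A single-bin spectrum on the standard 1-nm grid: all values zero
#' except the bin at `wavelength`, which holds `band_power / 1 nm` so
#' that the band-integrated quantity equals `band_power` exactly. The
#' wavelength must lie on the grid - no sub-bin placement.
#'
#' @param wavelength Line wavelength in nm (integer, 380-780).
#' @param band_power Band-integrated power, W/m^2 (irradiance) or
#'   W/(m^2 sr) (radiance).
#' @param kind Quantity kind of the output.
#' @return An [spd][spectral_measurement()].
#' @examples
#' sum(monochromatic_spd(555, 1)$values)  # 1
#' @export
monochromatic_spd <- function(wavelength, band_power,
                              kind = c("spectral_irradiance", "spectral_radiance")) {
  kind <- match.arg(kind)
  wl <- .default_grid_nm()
  i <- match(wavelength, wl)
  if (is.na(i))
    stop(sprintf("wavelength %g nm is not on the standard 380-780 nm 1-nm grid",
                 wavelength))
  if (band_power < 0) stop("'band_power' must be >= 0")
  vals <- numeric(length(wl))
  vals[i] <- band_power  # / 1 nm bin width
  spectral_measurement(
    wl, vals, kind = kind,
    label = sprintf("monochromatic %g nm", wavelength),
    metadata = list(fixture = sprintf("monochromatic(%g, %g)",
                                      wavelength, band_power)))
}

#' Metamer pair fixture
#'
#' Two spectrally different irradiance spectra with matched photopic
#' illuminance: a three-primary reference mixture and a two-primary
#' comparison whose weights solve the 2x2 linear system matching the
#' reference's photopic illuminance and total irradiance exactly.
#' Because the comparison concentrates its power at long wavelengths, the
#' two spectra differ substantially in melanopic irradiance - the
#' standard demonstration that illuminance alone cannot specify a
#' stimulus.
#'
#' @param reference Reference functions.
#' @return List with elements `reference` and `comparison` (both
#'   irradiance-kind [spd][spectral_measurement()] objects).
#' @examples
#' pair <- metamer_pair()
#' @export
metamer_pair <- function(reference = load_reference_functions()) {
  ref <- gaussian_led_spd(list(c(450, 30, 0.6), c(530, 30, 0.8),
                               c(610, 30, 0.6)))
  p1 <- gaussian_led_spd(list(c(540, 30, 1)))
  p2 <- gaussian_led_spd(list(c(630, 30, 1)))
  v <- reference$photopic_V
  a <- matrix(c(weighted_integral(p1, v), weighted_integral(p2, v),
                spd_integral(p1), spd_integral(p2)),
              nrow = 2, byrow = TRUE)
  b <- c(weighted_integral(ref, v), spd_integral(ref))
  w <- solve(a, b)
  if (any(w <= 0)) stop("metamer construction produced non-positive weights")
  comp <- gaussian_led_spd(list(c(540, 30, w[1]), c(630, 30, w[2])))
  list(reference = ref, comparison = comp)
}

#' Deliberately deficient exposure record
#'
#' Builds a fully populated synthetic exposure record (Gaussian-LED
#' stimulus, dim Planckian background, tabulated exports, panels, timing,
#' geometry and measurement metadata) and then removes exactly the
#' elements owned by the named checklist items. With no omissions the
#' record validates 7/7; omitting `"item2"` (say) produces exactly one
#' failing item.
#'
#' @param omissions Character vector of item labels among
#'   `"item1"`..`"item7"`.
#' @param dir Directory in which tabulated spectrum files are written.
#' @param reference Reference functions.
#' @return An [exposure_record()].
#' @examples
#' rec <- deficient_record("item2")
#' validate_record(rec)
#' @export
deficient_record <- function(omissions = character(),
                             dir = tempfile("luxrep-record-"),
                             reference = load_reference_functions()) {
  known <- paste0("item", 1:7)
  bad <- setdiff(omissions, known)
  if (length(bad))
    stop("unknown checklist item label(s): ", paste(bad, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  stim <- gaussian_led_spd(list(c(455, 25, 0.4), c(545, 35, 0.7),
                                c(620, 25, 0.5)))
  stim$label <- "acute stimulus"
  stim$metadata$measurement_geometry <-
    "spectroradiometer at observer eye position, facing the panel, 0.8 m from source"
  bg <- planckian_spd(2700, scale = 3e-7, kind = "spectral_irradiance")
  bg$label <- "background"
  bg$metadata$measurement_geometry <-
    "vertical irradiance at observer eye position, 1.5 m from luminaire"

  stim_file <- file.path(dir, "stimulus-spd.csv")
  bg_file <- file.path(dir, "background-spd.csv")
  write_spd_tabulated(stim, stim_file)
  write_spd_tabulated(bg, bg_file)

  rec <- exposure_record(
    stimulus_spd = stim,
    background_spd = bg,
    spectra_files = c(stimulus = stim_file, background = bg_file),
    panels = list(stimulus = alpha_opic_panel(stim, reference = reference),
                  background = alpha_opic_panel(bg, reference = reference)),
    timing = timing_spec("2026-03-02T22:00:00+01:00",
                         "2026-03-02T23:30:00+01:00", pattern = "constant"),
    geometry = stimulus_geometry(0.6, 0.4, 0.8, shape = "rectangular panel"),
    observer_position = "seated, eye height 1.2 m, facing panel",
    view_angle_deg = 0,
    measurement = measurement_meta(
      instrument_brand = "Acme", instrument_model = "SpectraCheck 2000",
      sensor = "back-thinned CCD", wavelength_sampling = 1,
      spectral_bandwidth = 5, reporting_range = c(380, 780),
      measurement_geometry = "at observer eye position, aimed at panel centre, 0.8 m"),
    observer = observer_context(age = 28, eyes_open = 2, field_diameter = 40),
    label = "synthetic fixture record")

  if ("item1" %in% omissions) rec$stimulus_spd <- NULL
  if ("item2" %in% omissions) rec$background_spd <- NULL
  if ("item3" %in% omissions) rec$spectra_files <- character()
  if ("item4" %in% omissions) rec$panels <- list()
  if ("item5" %in% omissions) rec$timing <- NULL
  if ("item6" %in% omissions) rec$geometry <- NULL
  if ("item7" %in% omissions) rec$measurement <- NULL
  rec
}
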
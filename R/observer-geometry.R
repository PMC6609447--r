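#' Stimulus geometry
#'
#' Spatial description of a light stimulus: its physical extent (metres,
#' horizontal and vertical), the observer's viewing distance, and a
#' free-text shape descriptor. Visual angles are derived per dimension
#' with [visual_angle()]; no solid-angle computation is attempted.
#'
#' @param width,height Object extent in metres (>= 0).
#' @param distance Viewing distance in metres (> 0).
#' @param shape Free-text shape descriptor.
#' @return Object of class `stimulus_geometry` with derived
#'   `visual_angle_deg` (horizontal, vertical).
#' @examples
#' stimulus_geometry(0.5, 0.3, 1)
#' @export
stimulus_geometry <- function(width, height, distance, shape = "") {
  if (!is.numeric(distance) || distance <= 0) stop("'distance' must be > 0 m")
  if (width < 0 || height < 0) stop("sizes must be >= 0 m")
  structure(list(
    size = c(horizontal = width, vertical = height),
    distance = distance, shape = shape,
    visual_angle_deg = c(horizontal = visual_angle(width, distance),
                         vertical = visual_angle(height, distance))
  ), class = "stimulus_geometry")
}

#' @export
print.stimulus_geometry <- function(x, ...) {
  cat(sprintf("<stimulus_geometry> %g x %g m at %g m (%.2f x %.2f deg)%s\n",
              x$size[1], x$size[2], x$distance,
              x$visual_angle_deg[1], x$visual_angle_deg[2],
              if (nzchar(x$shape)) paste0(", ", x$shape) else ""))
  invisible(x)
}

#' Observer context
#'
#' Observer-side parameters needed for pupil and retinal-illuminance
#' computations: age, number of eyes exposed, the angular diameter of the
#' adapting field, and - when it was measured, or fixed pharmacologically -
#' the pupil diameter, which then overrides the model prediction.
#'
#' @param age Age in years (> 0).
#' @param eyes_open 1 or 2.
#' @param field_diameter Adapting field diameter in degrees of visual
#'   angle (> 0).
#' @param pupil_diameter_mm Measured (or artificial) pupil diameter in mm,
#'   or `NULL` if unavailable.
#' @param dilation_agent Free-text pharmacological agent, if any.
#' @return Object of class `observer_context`.
#' @examples
#' observer_context(age = 28, eyes_open = 2, field_diameter = 60)
#' @export
observer_context <- function(age, eyes_open = 2, field_diameter,
                             pupil_diameter_mm = NULL, dilation_agent = NULL) {
  if (!is.numeric(age) || age <= 0) stop("'age' must be > 0 years")
  if (!eyes_open %in% c(1, 2)) stop("'eyes_open' must be 1 or 2")
  if (!is.numeric(field_diameter) || field_diameter <= 0)
    stop("'field_diameter' must be > 0 degrees")
  if (!is.null(pupil_diameter_mm) &&
      (!is.numeric(pupil_diameter_mm) || pupil_diameter_mm <= 0))
    stop("'pupil_diameter_mm' must be > 0 mm when given")
  structure(list(age = age, eyes_open = as.integer(eyes_open),
                 field_diameter = field_diameter,
                 pupil_diameter_mm = pupil_diameter_mm,
                 dilation_agent = dilation_agent),
            class = "observer_context")
}

#' Visual angle subtended by an object
#'
#' `theta = 2 * atan(0.5 * S / d)`, in degrees: the angular size of an
#' object of extent `S` viewed from distance `d`, per dimension.
#'
#' @param size Object extent in metres (>= 0; vectorized).
#' @param distance Viewing distance in metres (> 0).
#' @return Visual angle in degrees.
#' @examples
#' visual_angle(2, 1)    # 90 degrees
#' visual_angle(0.5, 1)  # 28.07 degrees
#' @export
visual_angle <- function(size, distance) {
  if (!is.numeric(distance) || any(distance <= 0))
    stop("'distance' must be > 0 m")
  if (any(size < 0)) stop("'size' must be >= 0 m")
  2 * atan(0.5 * size / distance) * 180 / pi
}

#' Predicted light-adapted pupil diameter
#'
#' The unified light-adapted pupil formula of Watson & Yellott (2012):
#' the Stanley-Davies diameter evaluated at the effective corneal flux
#' density `F = L * a * M(e)` (luminance times field area in deg^2 times
#' a monocular attenuation factor, 0.1 for one eye, 1 for two), plus a
#' linear age term referenced to 28.58 years,
#' `D = D_SD + (age - 28.58) * (0.02132 - 0.009562 * D_SD)`. The result
#' is clamped to the physiological range 1-10 mm. The formula ignores
#' non-luminance contributions to pupil control; no correction for that
#' is attempted.
#'
#' @param luminance Photopic luminance in cd/m^2 (>= 0).
#' @param field_diameter Adapting field diameter in degrees (> 0), or an
#'   [observer_context()] in place of the three observer arguments.
#' @param age Observer age in years.
#' @param eyes_open 1 or 2.
#' @return Pupil diameter in mm, with the formula variant recorded in
#'   attribute `"model"`.
#' @examples
#' predicted_pupil_diameter(100, field_diameter = 60, age = 30, eyes_open = 2)
#' @export
predicted_pupil_diameter <- function(luminance, field_diameter, age = 32,
                                     eyes_open = 2) {
  if (inherits(field_diameter, "observer_context")) {
    ctx <- field_diameter
    field_diameter <- ctx$field_diameter
    age <- ctx$age
    eyes_open <- ctx$eyes_open
  }
  if (any(luminance < 0)) stop("'luminance' must be >= 0 cd/m^2")
  if (field_diameter <= 0) stop("'field_diameter' must be > 0 degrees")
  if (!eyes_open %in% c(1, 2)) stop("'eyes_open' must be 1 or 2")
  area <- pi * (field_diameter / 2)^2
  m_e <- if (eyes_open == 2) 1 else 0.1
  f <- luminance * area * m_e
  z <- (f / 846)^0.41
  d_sd <- 7.75 - 5.75 * z / (z + 2)
  d <- d_sd + (age - 28.58) * (0.02132 - 0.009562 * d_sd)
  structure(pmin(pmax(d, 1), 10),
            model = "unified light-adapted pupil (Stanley-Davies base, reference age 28.58 y)")
}

#' Retinal illuminance in trolands
#'
#' `luminance (cd/m^2) * pupil area (mm^2)`: the conventional measure of
#' retinal intensity for luminance.
#'
#' @param luminance Photopic luminance in cd/m^2 (>= 0).
#' @param pupil_diameter Pupil diameter in mm (>= 0).
#' @return Retinal illuminance in trolands (Td).
#' @examples
#' trolands(100, 3)  # ~706.9 Td
#' @export
trolands <- function(luminance, pupil_diameter) {
  if (any(luminance < 0) || any(pupil_diameter < 0))
    stop("inputs must be >= 0")
  luminance * pi * (pupil_diameter / 2)^2
}

#' Retinal illuminance of a radiance spectrum
#'
#' Computes the photopic luminance of a radiance-kind spectrum via the
#' alpha-opic panel, chooses the pupil diameter - the measured value from
#' the observer context when present, otherwise the
#' [predicted_pupil_diameter()] model - and returns the troland value
#' with a provenance tag for the pupil source.
#'
#' @param spd A radiance-kind [spd][spectral_measurement()].
#' @param ctx An [observer_context()].
#' @param reference Reference functions.
#' @return Object of class `retinal_illuminance`: `trolands`,
#'   `luminance`, `pupil_diameter_mm`, `pupil_source` (`"measured"` or
#'   `"modelled"`).
#' @examples
#' spd <- planckian_spd(6500, scale = 1e-4, kind = "spectral_radiance")
#' retinal_illuminance(spd, observer_context(30, 2, 60))
#' @export
retinal_illuminance <- function(spd, ctx,
                                reference = load_reference_functions()) {
  stopifnot(is_spd(spd), inherits(ctx, "observer_context"))
  if (spd$kind != "spectral_radiance")
    stop("retinal illuminance in trolands requires a spectral_radiance input")
  lum <- alpha_opic_panel(spd, reference = reference)$photopic
  if (!is.null(ctx$pupil_diameter_mm)) {
    pupil <- ctx$pupil_diameter_mm
    src <- "measured"
  } else {
    pupil <- as.numeric(predicted_pupil_diameter(lum, ctx))
    src <- "modelled"
  }
  structure(list(trolands = trolands(lum, pupil), luminance = lum,
                 pupil_diameter_mm = pupil, pupil_source = src),
            class = "retinal_illuminance")
}

#' @export
print.retinal_illuminance <- function(x, ...) {
  cat(sprintf("<retinal_illuminance> %0.6g Td (luminance %0.6g cd/m^2, pupil %0.3g mm, %s)\n",
              x$trolands, x$luminance, x$pupil_diameter_mm, x$pupil_source))
  invisible(x)
}
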
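.iso8601_re <- paste0("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?",
                      "(Z|[+-]\\d{2}:?\\d{2})$")

.parse_iso8601 <- function(x, what) {
  if (!is.character(x) || length(x) != 1 || !grepl(.iso8601_re, x))
    stop(sprintf("'%s' must be an ISO 8601 timestamp with timezone (got '%s')",
                 what, as.character(x)))
  norm <- sub("Z$", "+0000", x)
  norm <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", norm)
  if (!grepl(":\\d{2}:\\d{2}", norm))  # add seconds if absent
    norm <- sub("([+-]\\d{4})$", ":00\\1", norm)
  t <- strptime(norm, "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
  if (is.na(t)) stop(sprintf("'%s' is not a valid timestamp: %s", what, x))
  as.POSIXct(t)
}

#' Timing specification of a light exposure
#'
#' Clock onset and offset (ISO 8601 with timezone - clock time is part of
#' the minimum report) and the temporal pattern: `constant` light,
#' a `flash_train` (which additionally requires the flash duration and
#' inter-stimulus interval), or a `dynamic` stimulus such as a screen or
#' movie (which requires the device refresh rate and a reference to the
#' SPD of the time-averaged light).
#'
#' @param clock_onset,clock_offset ISO 8601 timestamps with timezone;
#'   offset must be after onset.
#' @param pattern `"constant"`, `"flash_train"` or `"dynamic"`.
#' @param flash_duration Flash duration in seconds (flash_train only).
#' @param inter_stimulus_interval Inter-stimulus interval in seconds
#'   (flash_train only).
#' @param device_refresh_rate Device refresh rate in Hz (dynamic only).
#' @param mean_light_reference Label of the SPD describing the mean light
#'   (dynamic only).
#' @return Object of class `timing_spec`.
#' @examples
#' timing_spec("2026-03-02T22:00:00+01:00", "2026-03-02T23:30:00+01:00")
#' @export
timing_spec <- function(clock_onset, clock_offset,
                        pattern = c("constant", "flash_train", "dynamic"),
                        flash_duration = NULL, inter_stimulus_interval = NULL,
                        device_refresh_rate = NULL, mean_light_reference = NULL) {
  pattern <- match.arg(pattern)
  onset <- .parse_iso8601(clock_onset, "clock_onset")
  offset <- .parse_iso8601(clock_offset, "clock_offset")
  if (!(offset > onset)) stop("'clock_offset' must be after 'clock_onset'")
  if (pattern == "flash_train") {
    if (is.null(flash_duration) || is.null(inter_stimulus_interval))
      stop("a flash_train pattern requires 'flash_duration' and 'inter_stimulus_interval'")
    if (flash_duration <= 0 || inter_stimulus_interval <= 0)
      stop("flash timing values must be > 0 s")
  }
  if (pattern == "dynamic") {
    if (is.null(device_refresh_rate) || is.null(mean_light_reference))
      stop("a dynamic pattern requires 'device_refresh_rate' and 'mean_light_reference'")
    if (device_refresh_rate <= 0) stop("'device_refresh_rate' must be > 0 Hz")
  }
  structure(list(clock_onset = clock_onset, clock_offset = clock_offset,
                 pattern = pattern, flash_duration = flash_duration,
                 inter_stimulus_interval = inter_stimulus_interval,
                 device_refresh_rate = device_refresh_rate,
                 mean_light_reference = mean_light_reference,
                 duration_s = as.numeric(difftime(offset, onset, units = "secs"))),
            class = "timing_spec")
}

#' Measurement conditions and instrument metadata
#'
#' What instrument characterised the stimuli and how: brand, model and
#' sensor, the wavelength sampling and spectral bandwidth (nm), the
#' reporting range, and where/how the measurement was taken.
#' Missing fields may be left `NULL`; completeness is judged by
#' [validate_record()].
#'
#' @param instrument_brand,instrument_model,sensor Free text.
#' @param wavelength_sampling Wavelength sampling in nm (> 0).
#' @param spectral_bandwidth Spectral bandwidth in nm (> 0).
#' @param reporting_range Length-2 numeric, lower < upper (nm).
#' @param measurement_geometry Free text: position, direction and
#'   distance from the source.
#' @return Object of class `measurement_meta`.
#' @examples
#' measurement_meta("Acme", "SC-2000", "CCD", 1, 5, c(380, 780),
#'                  "eye position, 0.8 m from source")
#' @export
measurement_meta <- function(instrument_brand = NULL, instrument_model = NULL,
                             sensor = NULL, wavelength_sampling = NULL,
                             spectral_bandwidth = NULL, reporting_range = NULL,
                             measurement_geometry = NULL) {
  if (!is.null(wavelength_sampling) && wavelength_sampling <= 0)
    stop("'wavelength_sampling' must be > 0 nm")
  if (!is.null(spectral_bandwidth) && spectral_bandwidth <= 0)
    stop("'spectral_bandwidth' must be > 0 nm")
  if (!is.null(reporting_range)) {
    if (length(reporting_range) != 2 || reporting_range[1] >= reporting_range[2])
      stop("'reporting_range' must be c(lower, upper) with lower < upper")
  }
  structure(list(instrument_brand = instrument_brand,
                 instrument_model = instrument_model, sensor = sensor,
                 wavelength_sampling = wavelength_sampling,
                 spectral_bandwidth = spectral_bandwidth,
                 reporting_range = reporting_range,
                 measurement_geometry = measurement_geometry),
            class = "measurement_meta")
}

#' Exposure record
#'
#' The unit of compliance checking: everything a complete light-exposure
#' report carries - stimulus and background SPDs, tabulated spectrum
#' files, alpha-opic panels, timing, spatial geometry, measurement
#' metadata, and the optional items (observer context, in-situ
#' illuminance for manufacturer-provided spectra, photograph reference,
#' percent-eyes-open note, safety screen result). The constructor is
#' deliberately permissive - incomplete records must be representable so
#' that [validate_record()] can diagnose them.
#'
#' @param stimulus_spd,background_spd [spd][spectral_measurement()]
#'   objects or `NULL`.
#' @param spectra_files Character vector of tabulated-export paths.
#' @param panels Named list of [alpha_opic_panel()] objects (names
#'   `"stimulus"`, `"background"`, ... matching the SPDs they describe).
#' @param timing A [timing_spec()] or `NULL`.
#' @param geometry A [stimulus_geometry()] or `NULL`.
#' @param observer_position Free text: observer position in the set-up.
#' @param view_angle_deg Observer view angle relative to the source,
#'   degrees.
#' @param measurement A [measurement_meta()] or `NULL`.
#' @param observer An [observer_context()] or `NULL`.
#' @param illuminance_in_situ Photopic illuminance (lux) measured in
#'   situ; required alongside manufacturer-provided spectra.
#' @param photograph Path or reference to a photograph/sketch of the
#'   set-up.
#' @param percent_eyes_open Free-text note on percent eyes open.
#' @param safety A [rg0_screen()] result or `NULL`.
#' @param label Free-text record label.
#' @return Object of class `exposure_record`.
#' @examples
#' rec <- deficient_record()
#' rec$label
#' @export
exposure_record <- function(stimulus_spd = NULL, background_spd = NULL,
                            spectra_files = character(), panels = list(),
                            timing = NULL, geometry = NULL,
                            observer_position = NULL, view_angle_deg = NULL,
                            measurement = NULL, observer = NULL,
                            illuminance_in_situ = NULL, photograph = NULL,
                            percent_eyes_open = NULL, safety = NULL,
                            label = "") {
  for (s in list(stimulus_spd, background_spd))
    if (!is.null(s) && !is_spd(s)) stop("SPDs must be spd objects or NULL")
  if (!is.null(timing) && !inherits(timing, "timing_spec"))
    stop("'timing' must be a timing_spec")
  if (!is.null(geometry) && !inherits(geometry, "stimulus_geometry"))
    stop("'geometry' must be a stimulus_geometry")
  if (!is.null(measurement) && !inherits(measurement, "measurement_meta"))
    stop("'measurement' must be a measurement_meta")
  if (!is.null(observer) && !inherits(observer, "observer_context"))
    stop("'observer' must be an observer_context")
  structure(list(stimulus_spd = stimulus_spd, background_spd = background_spd,
                 spectra_files = spectra_files, panels = panels,
                 timing = timing, geometry = geometry,
                 observer_position = observer_position,
                 view_angle_deg = view_angle_deg, measurement = measurement,
                 observer = observer, illuminance_in_situ = illuminance_in_situ,
                 photograph = photograph, percent_eyes_open = percent_eyes_open,
                 safety = safety, label = label),
            class = "exposure_record")
}

.checklist_titles <- c(
  "Stimulus SPD from the observer's point of view",
  "Background SPD from the observer's point of view",
  "Spectra available in tabulated form",
  "Alpha-opic (ir)radiances and illuminance reported",
  "Timing properties of the stimulus",
  "Spatial properties of the stimulus",
  "Measurement conditions and equipment")

.panel_is_complete <- function(p) {
  inherits(p, "alpha_opic_panel") &&
    all(vapply(.alpha_opic_names, function(nm)
      is.numeric(p[[nm]]) && is.finite(p[[nm]]), logical(1))) &&
    is.numeric(p$photopic) && is.finite(p$photopic)
}

.check_spd_item <- function(spd, what, record) {
  if (is.null(spd))
    return(list(verdict = "fail",
                message = sprintf("no %s SPD present", what)))
  msgs <- character(0)
  verdict <- "pass"
  if (is.null(spd$metadata$measurement_geometry)) {
    verdict <- "warn"
    msgs <- c(msgs, sprintf(paste("%s SPD present but its measurement",
                                  "geometry (angle/distance from source)",
                                  "is not described"), what))
  }
  if (identical(spd$provenance, "manufacturer") &&
      is.null(record$illuminance_in_situ)) {
    verdict <- "warn"
    msgs <- c(msgs, sprintf(paste("%s SPD is manufacturer-provided but no",
                                  "in-situ photopic illuminance is reported"),
                            what))
  }
  if (verdict == "pass")
    msgs <- sprintf("%s SPD present with measurement geometry", what)
  list(verdict = verdict, message = paste(msgs, collapse = "; "))
}

#' Validate an exposure record against the seven minimum reporting items
#'
#' Checks an [exposure_record()] against the seven-item minimum reporting
#' checklist: (1) stimulus SPD, (2) background SPD, (3) tabulated spectra
#' that exist and re-parse, (4) a complete alpha-opic panel for each
#' reported SPD, (5) valid timing, (6) spatial geometry with a computed
#' visual angle, (7) complete measurement metadata. A missing element
#' fails its item; a present-but-incomplete element warns (e.g. a
#' manufacturer-provided stimulus spectrum without a separately reported
#' in-situ photopic illuminance). Verdicts are per-item: supplying one
#' element never changes another item's verdict, and adding information
#' never turns a pass into a fail.
#'
#' @param record An [exposure_record()].
#' @return Object of class `compliance_report`: data.frame `items`
#'   (item, title, verdict, message) plus summary counts `n_pass`,
#'   `n_warn`, `n_fail`.
#' @examples
#' validate_record(deficient_record("item2"))
#' @export
validate_record <- function(record) {
  if (!inherits(record, "exposure_record"))
    stop("'record' must be an exposure_record")

  res <- vector("list", 7)
  res[[1]] <- .check_spd_item(record$stimulus_spd, "stimulus", record)
  res[[2]] <- .check_spd_item(record$background_spd, "background", record)

  res[[3]] <- if (length(record$spectra_files) == 0) {
    list(verdict = "fail", message = "no tabulated spectrum files listed")
  } else {
    probs <- character(0)
    for (f in record$spectra_files) {
      if (!file.exists(f)) {
        probs <- c(probs, sprintf("missing file %s", f))
      } else {
        ok <- tryCatch({
          suppressWarnings(read_spd(f))
          TRUE
        }, error = function(e) FALSE)
        if (!ok) probs <- c(probs, sprintf("file %s does not re-parse", f))
      }
    }
    if (length(probs)) list(verdict = "fail", message = paste(probs, collapse = "; "))
    else list(verdict = "pass",
              message = sprintf("%d tabulated file(s) present and re-parse",
                                length(record$spectra_files)))
  }

  spds_present <- c(stimulus = !is.null(record$stimulus_spd),
                    background = !is.null(record$background_spd))
  res[[4]] <- if (length(record$panels) == 0) {
    list(verdict = "fail", message = "no alpha-opic panels reported")
  } else if (!all(vapply(record$panels, .panel_is_complete, logical(1)))) {
    list(verdict = "warn",
         message = "panel(s) present but missing alpha-opic or photopic entries")
  } else {
    need <- names(spds_present)[spds_present]
    lacking <- setdiff(need, names(record$panels))
    if (length(lacking))
      list(verdict = "warn",
           message = paste("no panel for reported SPD(s):",
                           paste(lacking, collapse = ", ")))
    else
      list(verdict = "pass",
           message = "complete alpha-opic + photopic panel per reported SPD")
  }

  res[[5]] <- if (is.null(record$timing)) {
    list(verdict = "fail", message = "no timing specification")
  } else {
    list(verdict = "pass",
         message = sprintf("timing specified (%s, %.6g s)",
                           record$timing$pattern, record$timing$duration_s))
  }

  res[[6]] <- if (is.null(record$geometry)) {
    list(verdict = "fail", message = "no spatial geometry")
  } else if (is.null(record$observer_position) || is.null(record$view_angle_deg)) {
    list(verdict = "warn",
         message = "size/distance/visual angle present but observer position or view angle missing")
  } else {
    list(verdict = "pass",
         message = sprintf("size, distance and visual angle (%.2f x %.2f deg) specified",
                           record$geometry$visual_angle_deg[1],
                           record$geometry$visual_angle_deg[2]))
  }

  res[[7]] <- if (is.null(record$measurement)) {
    list(verdict = "fail", message = "no measurement metadata")
  } else {
    m <- record$measurement
    fields <- c("instrument_brand", "instrument_model", "sensor",
                "wavelength_sampling", "spectral_bandwidth", "reporting_range",
                "measurement_geometry")
    missing_fields <- fields[vapply(fields, function(f) {
      x <- m[[f]]
      is.null(x) || (is.character(x) && !any(nzchar(x)))
    }, logical(1))]
    if (length(missing_fields))
      list(verdict = "warn",
           message = paste("measurement metadata incomplete; missing:",
                           paste(missing_fields, collapse = ", ")))
    else list(verdict = "pass", message = "measurement conditions and equipment complete")
  }

  items <- data.frame(
    item = 1:7, title = .checklist_titles,
    verdict = vapply(res, `[[`, character(1), "verdict"),
    message = vapply(res, `[[`, character(1), "message"),
    stringsAsFactors = FALSE)
  structure(list(items = items,
                 n_pass = sum(items$verdict == "pass"),
                 n_warn = sum(items$verdict == "warn"),
                 n_fail = sum(items$verdict == "fail")),
            class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report> %d pass / %d warn / %d fail\n",
              x$n_pass, x$n_warn, x$n_fail))
  marks <- c(pass = "[ok]  ", warn = "[warn]", fail = "[FAIL]")
  for (i in seq_len(nrow(x$items)))
    cat(sprintf("  %s %d. %s - %s\n", marks[[x$items$verdict[i]]],
                x$items$item[i], x$items$title[i], x$items$message[i]))
  invisible(x)
}
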
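#' Construct a wavelength grid
#'
#' A wavelength grid is the abscissa of a tabulated spectrum: a strictly
#' increasing vector of wavelengths in nm. For uniform grids the nominal
#' spacing is recorded; successive differences may deviate from it by at
#' most 1e-6 nm, otherwise the grid is treated as non-uniform.
#'
#' @param values Numeric vector of wavelengths in nm, strictly increasing,
#'   finite and positive.
#' @return An object of class `wavelength_grid` with fields `values` and
#'   `step` (`NA` for non-uniform grids).
#' @examples
#' g <- wavelength_grid(seq(380, 780, by = 5))
#' g$step
#' @export
wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("wavelength grid is empty")
  if (!all(is.finite(values))) stop("wavelength grid contains non-finite values")
  if (any(values <= 0)) stop("wavelengths must be > 0 nm")
  if (length(values) > 1) {
    d <- diff(values)
    if (any(d <= 0)) {
      bad <- which(d <= 0)[1] + 1
      stop(sprintf("wavelengths not strictly increasing at row %d (%g nm)",
                   bad, values[bad]))
    }
    step <- if (max(abs(d - d[1])) < 1e-6) d[1] else NA_real_
  } else {
    step <- NA_real_
  }
  structure(list(values = values, step = step), class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d samples, %g-%g nm, step %s nm\n",
              length(x$values), min(x$values), max(x$values),
              if (is.na(x$step)) "non-uniform" else format(x$step)))
  invisible(x)
}

.spd_kinds <- c("spectral_irradiance", "spectral_radiance")

.spd_units <- function(kind) {
  switch(kind,
         spectral_irradiance = "W/(m^2 nm)",
         spectral_radiance   = "W/(m^2 sr nm)")
}

#' Construct a spectral measurement (SPD)
#'
#' The canonical representation of a light stimulus: a tabulated spectral
#' power distribution, either spectral irradiance received at the cornea
#' (W m^-2 nm^-1) or spectral radiance of an emitting surface
#' (W m^-2 sr^-1 nm^-1). The kind determines the units of every scalar
#' quantity derived downstream (irradiances in mW/m^2 and illuminance in
#' lux, versus radiances in mW/(m^2 sr) and luminance in cd/m^2).
#'
#' Negative spectral values (instrument noise near zero) are retained and
#' flagged by default; they are clipped to zero only when `clip_negative =
#' TRUE`, preserving measured data fidelity otherwise.
#'
#' @param wavelength Numeric vector of wavelengths in nm (or a
#'   [wavelength_grid()]).
#' @param values Numeric vector of spectral values, same length as the grid.
#' @param kind `"spectral_irradiance"` or `"spectral_radiance"`.
#' @param label Free-text label for the measurement.
#' @param provenance `"measured"` or `"manufacturer"` (a manufacturer-
#'   tabulated spectrum used in lieu of an in-situ measurement).
#' @param metadata Named list of free-form metadata (instrument,
#'   timestamp, ...), carried through tabulated export.
#' @param clip_negative If `TRUE`, negative values are set to 0.
#' @return An object of class `spd`.
#' @examples
#' spd <- spectral_measurement(380:780, rep(1e-3, 401), "spectral_irradiance")
#' spd
#' @export
spectral_measurement <- function(wavelength, values,
                                 kind = c("spectral_irradiance", "spectral_radiance"),
                                 label = "", provenance = c("measured", "manufacturer"),
                                 metadata = list(), clip_negative = FALSE) {
  grid <- if (inherits(wavelength, "wavelength_grid")) wavelength else wavelength_grid(wavelength)
  kind <- match.arg(kind)
  provenance <- match.arg(provenance)
  values <- as.numeric(values)
  if (length(values) != length(grid$values))
    stop(sprintf("values length (%d) does not match grid length (%d)",
                 length(values), length(grid$values)))
  if (!all(is.finite(values))) stop("spectral values contain non-finite entries")
  n_neg <- sum(values < 0)
  if (clip_negative && n_neg > 0) {
    values[values < 0] <- 0
    n_neg <- 0L
  }
  structure(list(
    wavelength = grid$values,
    values = values,
    step = grid$step,
    kind = kind,
    label = label,
    provenance = provenance,
    metadata = metadata,
    negative_flagged = n_neg > 0
  ), class = "spd")
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("<spd> %s [%s], %d samples, %g-%g nm%s%s\n",
              x$kind, .spd_units(x$kind), length(x$wavelength),
              min(x$wavelength), max(x$wavelength),
              if (nzchar(x$label)) paste0(", '", x$label, "'") else "",
              if (x$negative_flagged) ", NEGATIVE VALUES FLAGGED" else ""))
  invisible(x)
}

#' @rdname spectral_measurement
#' @param x Object to test.
#' @export
is_spd <- function(x) inherits(x, "spd")

.detect_delimiter <- function(line) {
  for (d in c(",", "\t", ";")) {
    parts <- strsplit(line, d, fixed = TRUE)[[1]]
    if (length(parts) >= 2 &&
        !is.na(suppressWarnings(as.numeric(parts[1]))) &&
        !is.na(suppressWarnings(as.numeric(parts[2]))))
      return(d)
  }
  # whitespace fallback
  parts <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  if (length(parts) >= 2 &&
      !is.na(suppressWarnings(as.numeric(parts[1])))) return("[[:space:]]+")
  stop("could not detect delimiter (expected comma, tab or semicolon): ", line)
}

#' Read a tabulated spectrum from delimited ASCII
#'
#' Parses a two-column delimited text file (wavelength in nm, spectral
#' value per nm). The delimiter is auto-detected among comma, tab and
#' semicolon. Lines starting with `#` are header metadata of the form
#' `# key: value` and are preserved on the returned object. A
#' `# kind:` header, when present, declares the quantity kind; an
#' explicit `kind` argument always wins, and a file carrying no units
#' metadata triggers a warning that the `kind` argument was trusted.
#'
#' @param source Path to a file, a connection, or a character vector of
#'   lines.
#' @param kind Quantity kind; required when the file carries no
#'   `# kind:`/`# units:` metadata.
#' @param clip_negative Passed to [spectral_measurement()].
#' @return An [spd][spectral_measurement()] object.
#' @examples
#' lines <- c("# kind: spectral_irradiance", "wavelength_nm,value",
#'            "380,0.001", "381,0.002")
#' read_spd(lines)
#' @export
read_spd <- function(source, kind = NULL, clip_negative = FALSE) {
  lines <- if (is.character(source) && length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines <- lines[nzchar(trimws(lines))]
  is_header <- startsWith(trimws(lines), "#")
  meta_lines <- lines[is_header]
  data_lines <- lines[!is_header]

  metadata <- list()
  for (ml in meta_lines) {
    body <- sub("^\\s*#\\s*", "", ml)
    if (grepl(":", body, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", body))
      val <- trimws(sub("^[^:]*:\\s*", "", body))
      if (nzchar(key)) metadata[[key]] <- val
    }
  }

  # drop a column-name line if present
  if (length(data_lines) > 0 &&
      is.na(suppressWarnings(as.numeric(strsplit(data_lines[1], "[,;\t]")[[1]][1]))))
    data_lines <- data_lines[-1]
  if (length(data_lines) == 0) stop("no data rows found")

  delim <- .detect_delimiter(data_lines[1])
  fixed <- delim %in% c(",", "\t", ";")
  mat <- t(vapply(seq_along(data_lines), function(i) {
    parts <- strsplit(if (fixed) data_lines[i] else trimws(data_lines[i]),
                      delim, fixed = fixed)[[1]]
    v <- suppressWarnings(as.numeric(parts[1:2]))
    if (any(is.na(v)))
      stop(sprintf("could not parse data row %d: '%s'", i, data_lines[i]))
    v
  }, numeric(2)))

  wl <- mat[, 1]
  if (any(diff(wl) <= 0)) {
    bad <- which(diff(wl) <= 0)[1] + 1
    stop(sprintf("wavelengths not strictly increasing at data row %d (%g nm)",
                 bad, wl[bad]))
  }

  meta_kind <- metadata[["kind"]]
  has_units_meta <- !is.null(meta_kind) || !is.null(metadata[["units"]])
  if (is.null(kind)) {
    if (!is.null(meta_kind) && meta_kind %in% .spd_kinds) {
      kind <- meta_kind
    } else if (!is.null(metadata[["units"]])) {
      kind <- if (grepl("sr", metadata[["units"]])) "spectral_radiance" else "spectral_irradiance"
    } else {
      stop("no units metadata in file and no 'kind' argument given")
    }
  } else {
    kind <- match.arg(kind, .spd_kinds)
    if (!has_units_meta)
      warning("file carries no units metadata; trusting the 'kind' argument (",
              kind, ")")
  }

  label <- metadata[["label"]] %||% ""
  provenance <- metadata[["provenance"]] %||% "measured"
  if (!provenance %in% c("measured", "manufacturer")) provenance <- "measured"
  metadata[["kind"]] <- NULL
  metadata[["units"]] <- NULL
  metadata[["label"]] <- NULL
  metadata[["provenance"]] <- NULL

  spectral_measurement(wl, mat[, 2], kind = kind, label = label,
                       provenance = provenance, metadata = metadata,
                       clip_negative = clip_negative)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a spectrum in tabulated ASCII form
#'
#' Writes an SPD as uncompressed comma-separated text: `# key: value`
#' header lines (kind, units, label, provenance and any carried
#' metadata), a column-name line, then `wavelength,value` rows. The
#' default export grid covers 380-780 nm; values measured outside that
#' range are dropped (with a warning) and wavelengths inside the range
#' but outside the measured support are zero-filled. Spacing must lie in
#' the 1-10 nm reporting window. Numbers are printed with up to 17
#' significant digits so that export -> read -> export is byte-stable.
#'
#' @param spd An [spd][spectral_measurement()] object.
#' @param path Optional output file path; when `NULL` the lines are
#'   returned invisibly only.
#' @param spacing Output grid spacing in nm, within `[1, 10]`. Defaults
#'   to the input's native spacing clamped into that window (1 nm for
#'   non-uniform inputs).
#' @param range Output wavelength range in nm (default `c(380, 780)`).
#' @return Invisibly, the character vector of file lines.
#' @examples
#' spd <- spectral_measurement(380:780, rep(1e-3, 401), "spectral_irradiance")
#' head(write_spd_tabulated(spd))
#' @export
write_spd_tabulated <- function(spd, path = NULL, spacing = NULL,
                                range = c(380, 780)) {
  stopifnot(is_spd(spd))
  if (is.null(spacing)) {
    spacing <- if (is.na(spd$step)) 1 else min(max(spd$step, 1), 10)
  }
  if (spacing < 1 || spacing > 10)
    stop(sprintf(paste0("spacing %g nm is outside the tabulation guideline ",
                        "range of 1-10 nm"), spacing))
  target <- seq(range[1], range[2], by = spacing)
  lo <- min(spd$wavelength); hi <- max(spd$wavelength)
  if (lo < range[1] || hi > range[2])
    warning(sprintf(paste0("measured values outside %g-%g nm dropped from ",
                           "tabulated export (input covers %g-%g nm)"),
                    range[1], range[2], lo, hi))
  out <- if (identical(as.numeric(target), as.numeric(spd$wavelength))) spd
         else suppressWarnings(spd_resample(spd, target))

  hdr <- c(sprintf("# kind: %s", out$kind),
           sprintf("# units: %s", .spd_units(out$kind)))
  if (nzchar(out$label)) hdr <- c(hdr, sprintf("# label: %s", out$label))
  hdr <- c(hdr, sprintf("# provenance: %s", out$provenance))
  if (length(out$metadata)) {
    keys <- sort(names(out$metadata))
    hdr <- c(hdr, vapply(keys, function(k)
      sprintf("# %s: %s", k, as.character(out$metadata[[k]])), character(1)))
  }
  rows <- sprintf("%.17g,%.17g", out$wavelength, out$values)
  lines <- c(hdr, "wavelength_nm,value", rows)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Piecewise-linear interpolation inside the measured support;
#' wavelengths outside the support are zero-filled with a warning (no
#' extrapolation - conservative for short-wavelength-sensitive
#' quantities). The quantity kind and metadata are preserved.
#'
#' @param spd An [spd][spectral_measurement()] object.
#' @param target Numeric vector of target wavelengths (nm) or a
#'   [wavelength_grid()].
#' @return A resampled [spd][spectral_measurement()].
#' @examples
#' spd <- spectral_measurement(seq(380, 780, 5), rep(2, 81), "spectral_irradiance")
#' spd_resample(spd, 400:700)$values[1]
#' @export
spd_resample <- function(spd, target) {
  stopifnot(is_spd(spd))
  tw <- if (inherits(target, "wavelength_grid")) target$values else as.numeric(target)
  tw <- wavelength_grid(tw)$values
  lo <- min(spd$wavelength); hi <- max(spd$wavelength)
  inside <- tw >= lo & tw <= hi
  if (!any(inside))
    stop("target grid does not overlap the measured support (",
         lo, "-", hi, " nm)")
  vals <- numeric(length(tw))
  if (length(spd$wavelength) == 1) {
    vals[tw == spd$wavelength] <- spd$values
  } else {
    vals[inside] <- stats::approx(spd$wavelength, spd$values, xout = tw[inside],
                                  method = "linear", ties = "ordered")$y
  }
  if (any(!inside))
    warning(sprintf("%d target wavelengths outside measured support %g-%g nm zero-filled",
                    sum(!inside), lo, hi))
  spectral_measurement(tw, vals, kind = spd$kind, label = spd$label,
                       provenance = spd$provenance, metadata = spd$metadata)
}

#' Scale a spectrum by a non-negative factor
#'
#' Pointwise multiplication of the spectral values. Every scalar derived
#' downstream (alpha-opic values, photometric quantities, photon rates,
#' hazard-weighted radiance) is homogeneous of degree one in this factor.
#'
#' @param spd An [spd][spectral_measurement()] object.
#' @param factor Non-negative scalar.
#' @return The scaled [spd][spectral_measurement()].
#' @examples
#' spd <- spectral_measurement(380:780, rep(1e-3, 401), "spectral_irradiance")
#' max(spd_scale(spd, 2)$values)
#' @export
spd_scale <- function(spd, factor) {
  stopifnot(is_spd(spd))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor))
    stop("'factor' must be a finite scalar")
  if (factor < 0) stop("'factor' must be >= 0")
  out <- spd
  out$values <- spd$values * factor
  out
}

# Rectangle-rule band integral over the spectrum's own grid (sum of value
# times local bin width). For uniform grids this is sum(values) * step.
spd_integral <- function(spd) {
  w <- spd$wavelength
  if (length(w) == 1) return(spd$values)
  dw <- if (!is.na(spd$step)) rep(spd$step, length(w)) else {
    d <- diff(w)
    c(d[1], (d[-1] + d[-length(d)]) / 2, d[length(d)])[seq_along(w)]
  }
  sum(spd$values * dw)
}
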
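#' Spectral weighting (action) spectra
#'
#' An action spectrum is a named, dimensionless spectral sensitivity
#' function on a wavelength grid. The package ships seven reference
#' functions: the five alpha-opic sensitivities (S-, M-, L-cone-opic,
#' rhodopic, melanopic), the photopic luminous efficiency function V, and
#' the blue-light photochemical hazard function B. The alpha-opic
#' functions and V are unit-peak normalized on a 1 nm, 380-780 nm grid;
#' B lives on its own native 5 nm grid and is aligned to spectra by
#' resampling.
#'
#' The shipped tables are *synthetic* stand-ins for the standardized
#' tabulations: they are generated in code from published analytic forms
#' (Govardovskii A1 pigment templates combined with a two-component
#' ocular-media density model, and the piecewise published structure of
#' the hazard function) rather than transcribed from the standard itself.
#' Their construction is recorded in each file's provenance header; see
#' the package vignette for what this does and does not imply for
#' absolute values computed with them.
#'
#' @param name Function name, one of `"s_cone_opic"`, `"m_cone_opic"`,
#'   `"l_cone_opic"`, `"rhodopic"`, `"melanopic"`, `"photopic_V"`,
#'   `"blue_light_hazard"` (free text is allowed for user-supplied
#'   functions).
#' @param wavelength Wavelength grid in nm.
#' @param weights Non-negative sensitivity values, same length.
#' @param observer_age Age (years) the weighting refers to; 32 is the
#'   standard observer.
#' @return An object of class `action_spectrum`.
#' @examples
#' a <- action_spectrum("demo", 400:500, dnorm(400:500, 450, 20) / dnorm(450, 450, 20))
#' peak_wavelength(a)
#' @export
action_spectrum <- function(name, wavelength, weights, observer_age = 32) {
  grid <- wavelength_grid(wavelength)
  weights <- as.numeric(weights)
  if (length(weights) != length(grid$values))
    stop("weights length does not match grid length")
  if (!all(is.finite(weights))) stop("weights contain non-finite values")
  if (any(weights < 0)) stop("weights must be >= 0")
  structure(list(name = name, wavelength = grid$values, weights = weights,
                 step = grid$step, observer_age = observer_age),
            class = "action_spectrum")
}

#' @export
print.action_spectrum <- function(x, ...) {
  cat(sprintf("<action_spectrum> %s, %d samples, %g-%g nm, peak %g nm%s\n",
              x$name, length(x$wavelength), min(x$wavelength),
              max(x$wavelength), peak_wavelength(x),
              if (!identical(x$observer_age, 32))
                sprintf(" (observer age %g y)", x$observer_age) else ""))
  invisible(x)
}

.alpha_opic_names <- c("s_cone_opic", "m_cone_opic", "l_cone_opic",
                       "rhodopic", "melanopic")
.reference_names <- c(.alpha_opic_names, "photopic_V", "blue_light_hazard")

.reference_file <- function(name) {
  paste0("synthetic-", gsub("_", "-", tolower(name)), ".csv")
}

.luxrep_env <- new.env(parent = emptyenv())

#' Load the reference weighting functions
#'
#' Reads the seven vendored reference tables (five alpha-opic functions,
#' photopic V, blue-light hazard) from the package's `extdata/reference`
#' directory, verifying each file against its recorded checksum. Results
#' are cached for the session.
#'
#' @param dir Directory holding the tables (defaults to the installed
#'   package data).
#' @param verify Verify recorded MD5 checksums (default `TRUE`).
#' @return Named list of seven [action_spectrum()] objects.
#' @examples
#' refs <- load_reference_functions()
#' names(refs)
#' @export
load_reference_functions <- function(dir = NULL, verify = TRUE) {
  default_dir <- is.null(dir)
  if (default_dir && !is.null(.luxrep_env$reference_functions))
    return(.luxrep_env$reference_functions)
  if (is.null(dir))
    dir <- system.file("extdata", "reference", package = "luxrep")
  out <- stats::setNames(vector("list", length(.reference_names)),
                         .reference_names)
  for (nm in .reference_names) {
    path <- file.path(dir, .reference_file(nm))
    if (!file.exists(path))
      stop(sprintf("reference table for '%s' missing (expected %s)", nm, path))
    if (verify) {
      expected <- .reference_checksums[[.reference_file(nm)]]
      got <- unname(tools::md5sum(path))
      if (!is.null(expected) && !identical(got, expected))
        stop(sprintf("reference table for '%s' is corrupt: checksum %s != recorded %s",
                     nm, got, expected))
    }
    lines <- readLines(path, warn = FALSE)
    data_lines <- lines[!startsWith(lines, "#")]
    data_lines <- data_lines[nzchar(trimws(data_lines))]
    if (grepl("[a-zA-Z]", data_lines[1])) data_lines <- data_lines[-1]
    mat <- do.call(rbind, lapply(strsplit(data_lines, ","), as.numeric))
    out[[nm]] <- action_spectrum(nm, mat[, 1], mat[, 2])
    if (nm %in% c(.alpha_opic_names, "photopic_V") &&
        abs(max(out[[nm]]$weights) - 1) > 1e-6)
      stop(sprintf("reference table for '%s' is not unit-peak normalized", nm))
  }
  if (default_dir) .luxrep_env$reference_functions <- out
  out
}

#' Wavelength of peak sensitivity
#'
#' Returns the wavelength at which an action spectrum attains its maximum
#' weight; exact ties are broken toward the lowest wavelength.
#'
#' @param a An [action_spectrum()].
#' @return Peak wavelength in nm.
#' @examples
#' peak_wavelength(load_reference_functions()$photopic_V)
#' @export
peak_wavelength <- function(a) {
  stopifnot(inherits(a, "action_spectrum"))
  if (all(a$weights == 0)) stop("action spectrum is identically zero")
  a$wavelength[which.max(a$weights)]
}

#' Age-corrected spectral weighting
#'
#' Adjusts an action spectrum from the 32-year standard observer to an
#' observer of the given age by multiplying with the age-dependent
#' ocular-media transmittance ratio (see [lens_correction()]): the
#' stimulus stays physical, the observer changes. At age 32 the input is
#' returned unchanged. The corrected function is *not* re-normalized to
#' unit peak - the loss of short-wavelength sensitivity is the point of
#' the correction.
#'
#' @param a An [action_spectrum()] referenced to the standard observer.
#' @param age Observer age in years (20-80; error outside).
#' @return An [action_spectrum()] with `observer_age` set.
#' @examples
#' mel60 <- lens_corrected_weighting(load_reference_functions()$melanopic, 60)
#' max(mel60$weights) < 1
#' @export
lens_corrected_weighting <- function(a, age) {
  stopifnot(inherits(a, "action_spectrum"))
  .check_observer_age(age)
  if (age == 32) {
    a$observer_age <- 32
    return(a)
  }
  lc <- lens_correction(age, wavelength = a$wavelength)
  action_spectrum(a$name, a$wavelength, a$weights * lc$spectral_factor,
                  observer_age = age)
}
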
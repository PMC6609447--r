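# Physical and photometric constants used throughout.
# h, c, k_B are CODATA 2018 exact values (SI redefinition).

#' Physical and photometric constants
#'
#' Named list of the constants the package computes with: Planck constant
#' `h` (J s), speed of light `c` (m/s), Boltzmann constant `k_B` (J/K)
#' (all CODATA 2018 exact values), the maximum luminous efficacy
#' `K_m = 683` lm/W used to convert the V(lambda)-weighted integral to
#' photometric units, and the Wien displacement constant `b_wien` (m K).
#'
#' @return A named list of numeric constants.
#' @examples
#' lux_constants()$K_m
#' @export
lux_constants <- function() {
  list(
    h      = 6.62607015e-34,
    c      = 299792458,
    k_B    = 1.380649e-23,
    K_m    = 683,
    b_wien = 2.897771955e-3
  )
}

# Default reporting grid: 380-780 nm at 1 nm.
.default_grid_nm <- function() seq(380, 780, by = 1)

# Safety-screen thresholds (photobiological pre-screen defaults):
# RG0 blue-light radiance limit for exposures longer than 10,000 s, and the
# luminance below which detailed hazard measurement is typically not required.
.rg0_radiance_limit <- 100     # W/(m^2 sr)
.rg0_exempt_luminance <- 10000 # cd/m^2
.rg0_long_exposure_s <- 10000  # s
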
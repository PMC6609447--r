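# Generates the vendored synthetic reference weighting functions under
# inst/extdata/reference/ and records their checksums in
# R/reference-checksums.R. Run from the package root:
#   Rscript data-raw/make-reference-tables.R
#
# Construction (synthetic stand-ins, see vignette):
#  - photoreceptor corneal sensitivities: Govardovskii et al. (2000) A1
#    pigment template at the pigment's lambda_max, multiplied by the
#    ocular-media transmittance of the 32-year standard observer
#    (two-component lens model; small macular term for cones, 10-deg field),
#    then unit-peak normalized on the 380-780 nm 1-nm grid.
#  - photopic V: weighted sum w*L + M of the corneal L/M-cone functions,
#    with w tuned so the normalized curve peaks at exactly 555 nm.
#  - blue-light hazard B: piecewise published structure (rise from 380 nm
#    to a unit plateau at 435-440 nm, tabulated decline to 500 nm,
#    log-linear 10^((450-lambda)/50) over 500-600 nm, 0.001 to 700 nm) on
#    its native 5 nm grid.

pkgload::load_all(".", quiet = TRUE)

grid <- seq(380, 780, by = 1)

govardovskii_a1 <- function(wl, lmax) {
  x <- lmax / wl
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  bb <- -40.5 + 0.195 * lmb
  beta <- 0.26 * exp(-((wl - lmb) / bb)^2)
  alpha + beta
}

lens_d32 <- luxrep:::.lens_density(grid, 32)
mac_d <- 0.095 * exp(-((grid - 460) / 35)^2)  # 10-deg-field macular pigment

corneal <- function(lmax, macular = FALSE) {
  d <- lens_d32 + if (macular) mac_d else 0
  s <- govardovskii_a1(grid, lmax) * 10^(-d)
  s / max(s)
}

funcs <- list(
  s_cone_opic = corneal(419, macular = TRUE),
  m_cone_opic = corneal(530, macular = TRUE),
  l_cone_opic = corneal(558, macular = TRUE),
  rhodopic    = corneal(500),
  melanopic   = corneal(480)
)

# photopic V: tune L-weight so the peak lands at 555 nm on the 1-nm grid
l <- funcs$l_cone_opic; m <- funcs$m_cone_opic
w_grid <- seq(0.2, 6, by = 0.001)
peaks <- vapply(w_grid, function(w) grid[which.max(w * l + m)], numeric(1))
ok <- w_grid[peaks == 555]
if (length(ok) == 0) stop("no L-weight gives a 555 nm peak")
w555 <- ok[ceiling(length(ok) / 2)]
v <- w555 * l + m
funcs$photopic_V <- v / max(v)
cat(sprintf("photopic V: L-weight %.3f, peak %d nm\n",
            w555, grid[which.max(funcs$photopic_V)]))

# blue-light hazard, native 5 nm grid 380-700
bwl <- seq(380, 700, by = 5)
b_rise <- c("380" = 0.01, "385" = 0.013, "390" = 0.025, "395" = 0.05,
            "400" = 0.10, "405" = 0.20, "410" = 0.40, "415" = 0.80,
            "420" = 0.90, "425" = 0.95, "430" = 0.98, "435" = 1.00,
            "440" = 1.00, "445" = 0.97, "450" = 0.94, "455" = 0.90,
            "460" = 0.80, "465" = 0.70, "470" = 0.62, "475" = 0.55,
            "480" = 0.45, "485" = 0.40, "490" = 0.22, "495" = 0.16)
bvals <- vapply(bwl, function(wl) {
  if (wl < 500) unname(b_rise[as.character(wl)])
  else if (wl <= 600) 10^((450 - wl) / 50)
  else 0.001
}, numeric(1))

dir.create("inst/extdata/reference", recursive = TRUE, showWarnings = FALSE)

write_table <- function(name, wl, weights, construction) {
  path <- file.path("inst/extdata/reference", luxrep:::.reference_file(name))
  lines <- c(sprintf("# function: %s", name),
             "# provenance: synthetic (generated by data-raw/make-reference-tables.R)",
             sprintf("# construction: %s", construction),
             sprintf("# grid: %g-%g nm, %g nm", min(wl), max(wl), wl[2] - wl[1]),
             "wavelength_nm,weight",
             sprintf("%g,%.9g", wl, weights))
  writeLines(lines, path)
  path
}

constructions <- c(
  s_cone_opic = "Govardovskii A1 template (lambda_max 419 nm) x ocular media (lens + macular, age 32), unit peak",
  m_cone_opic = "Govardovskii A1 template (lambda_max 530 nm) x ocular media (lens + macular, age 32), unit peak",
  l_cone_opic = "Govardovskii A1 template (lambda_max 558 nm) x ocular media (lens + macular, age 32), unit peak",
  rhodopic    = "Govardovskii A1 template (lambda_max 500 nm) x lens transmittance (age 32), unit peak",
  melanopic   = "Govardovskii A1 template (lambda_max 480 nm) x lens transmittance (age 32), unit peak",
  photopic_V  = sprintf("%.3f x L-cone-opic + M-cone-opic, unit peak at 555 nm", w555),
  blue_light_hazard = "piecewise published structure: tabulated rise/decline 380-500 nm, 10^((450-lambda)/50) 500-600 nm, 0.001 600-700 nm"
)

paths <- character(0)
for (nm in names(funcs))
  paths[luxrep:::.reference_file(nm)] <-
    write_table(nm, grid, funcs[[nm]], constructions[[nm]])
paths[luxrep:::.reference_file("blue_light_hazard")] <-
  write_table("blue_light_hazard", bwl, bvals, constructions[["blue_light_hazard"]])

sums <- vapply(paths, function(p) unname(tools::md5sum(p)), character(1))
chk <- c("# Generated by data-raw/make-reference-tables.R; do not edit by hand.",
         ".reference_checksums <- c(",
         paste(sprintf('  "%s" = "%s"', names(sums), sums), collapse = ",\n"),
         ")")
writeLines(chk, "R/reference-checksums.R")
cat("wrote", length(paths), "tables and R/reference-checksums.R\n")
for (nm in names(funcs))
  cat(sprintf("  %-12s peak %d nm\n", nm, grid[which.max(funcs[[nm]])]))
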
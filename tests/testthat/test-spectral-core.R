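test_that("wavelength grids reject non-monotone, non-positive and non-finite values", {
  expect_error(wavelength_grid(c(400, 400, 410)), "not strictly increasing at row 2")
  expect_error(wavelength_grid(c(400, 390)), "row 2")
  expect_error(wavelength_grid(c(-5, 400)), "> 0")
  expect_error(wavelength_grid(c(400, NA)), "non-finite")
  expect_identical(wavelength_grid(seq(380, 780, 5))$step, 5)
  expect_true(is.na(wavelength_grid(c(380, 381, 383))$step))
})

test_that("read_spd parses the three delimiter dialects identically and preserves metadata", {
  wl <- 380:780
  vals <- 1e-3 * (1 + sin(wl / 40))
  mk <- function(delim) {
    c("# kind: spectral_irradiance", "# units: W/(m^2 nm)",
      "# instrument: test-rig",
      paste(wl, format(vals, digits = 12), sep = delim))
  }
  a <- read_spd(mk(","))
  b <- read_spd(mk("\t"))
  c_ <- read_spd(mk(";"))
  expect_equal(a$values, b$values)
  expect_equal(a$values, c_$values)
  expect_equal(a$wavelength, b$wavelength)
  expect_identical(a$metadata$instrument, "test-rig")
  expect_identical(a$kind, "spectral_irradiance")
})

test_that("a 1-nm constant file over 380-780 yields 401 samples", {
  lines <- c("# kind: spectral_irradiance", paste0(380:780, ",0.001"))
  spd <- read_spd(lines)
  expect_length(spd$values, 401)
  expect_true(all(spd$values == 0.001))
})

test_that("read_spd errors name the offending row and warns when units metadata is absent", {
  bad <- c("# kind: spectral_irradiance", "380,1", "385,1", "383,1")
  expect_error(read_spd(bad), "row 3")
  plain <- c("380,1", "385,1")
  expect_warning(spd <- read_spd(plain, kind = "spectral_irradiance"),
                 "no units metadata")
  expect_identical(spd$kind, "spectral_irradiance")
  expect_error(read_spd(plain), "no units metadata in file and no 'kind'")
})

test_that("negative values are flagged, and clipped only on request", {
  lines <- c("# kind: spectral_irradiance", "380,-0.001", "381,0.5")
  spd <- read_spd(lines)
  expect_true(spd$negative_flagged)
  expect_equal(spd$values[1], -0.001)
  clipped <- read_spd(lines, clip_negative = TRUE)
  expect_false(clipped$negative_flagged)
  expect_equal(clipped$values[1], 0)
})

test_that("tabulated export covers 380-780 nm and round-trips losslessly", {
  set.seed(42)
  spd <- spectral_measurement(380:780, runif(401, 0, 0.2),
                              "spectral_irradiance", label = "roundtrip",
                              metadata = list(instrument = "rig-1",
                                              timestamp = "2026-01-05T10:00:00Z"))
  lines <- write_spd_tabulated(spd)
  rows <- lines[!startsWith(lines, "#") & lines != "wavelength_nm,value"]
  expect_equal(as.numeric(sub(",.*", "", rows[1])), 380)
  expect_equal(as.numeric(sub(",.*", "", rows[length(rows)])), 780)

  back <- read_spd(lines)
  expect_identical(back$wavelength, spd$wavelength)
  expect_identical(back$values, spd$values)       # bit-exact round trip
  expect_identical(back$metadata$instrument, "rig-1")
  expect_identical(back$label, "roundtrip")

  lines2 <- write_spd_tabulated(back)
  expect_identical(lines2, lines)                 # idempotent re-export
})

test_that("export drops out-of-range values with a warning and enforces 1-10 nm spacing", {
  wide <- spectral_measurement(seq(300, 900, 5), rep(1, 121), "spectral_irradiance")
  expect_warning(lines <- write_spd_tabulated(wide), "dropped")
  wls <- as.numeric(sub(",.*", "",
                        lines[!startsWith(lines, "#") & lines != "wavelength_nm,value"]))
  expect_equal(range(wls), c(380, 780))

  ok <- spectral_measurement(380:780, rep(1, 401), "spectral_irradiance")
  expect_error(write_spd_tabulated(ok, spacing = 0.5), "1-10 nm")
  expect_error(write_spd_tabulated(ok, spacing = 20), "1-10 nm")
})

test_that("resampling matches a brute-force piecewise-linear oracle exactly", {
  set.seed(7)
  wl5 <- seq(380, 780, 5)
  vals <- runif(length(wl5))
  spd <- spectral_measurement(wl5, vals, "spectral_irradiance")
  fine <- spd_resample(spd, 380:780)
  expect_equal(max(abs(fine$values - oracle_linear_interp(wl5, vals, 380:780))), 0)

  const <- spectral_measurement(wl5, rep(3.2, length(wl5)), "spectral_irradiance")
  expect_true(all(spd_resample(const, 400:700)$values == 3.2))

  same <- spd_resample(spd, wl5)
  expect_equal(same$values, vals)
})

test_that("resampling zero-fills outside support with a warning and errors on empty overlap", {
  spd <- spectral_measurement(500:600, rep(1, 101), "spectral_irradiance")
  expect_warning(out <- spd_resample(spd, 380:780), "zero-filled")
  expect_true(all(out$values[out$wavelength < 500] == 0))
  expect_true(all(out$values[out$wavelength > 600] == 0))
  expect_identical(out$kind, "spectral_irradiance")
  expect_error(spd_resample(spd, 700:780), "overlap")
})

test_that("windowing and resampling commute on uniform grids", {
  set.seed(11)
  spd <- spectral_measurement(seq(380, 780, 2), runif(201), "spectral_irradiance")
  a <- spd_resample(spd, seq(400, 700, 1))
  b <- suppressWarnings(spd_resample(spd_resample(spd, seq(380, 780, 1)),
                                     seq(400, 700, 1)))
  expect_equal(a$values, b$values)
})

test_that("scaling is pointwise, linear in derived panels, and rejects negative factors", {
  spd <- gaussian_led_spd(list(c(460, 20, 0.5), c(580, 30, 1)))
  expect_true(all(spd_scale(spd, 0)$values == 0))
  expect_identical(spd_scale(spd, 1)$values, spd$values)

  p1 <- alpha_opic_panel(spd, reference = ref_functions)
  p2 <- alpha_opic_panel(spd_scale(spd, 2), reference = ref_functions)
  for (nm in c("s_cone_opic", "m_cone_opic", "l_cone_opic", "rhodopic",
               "melanopic", "photopic"))
    expect_equal(p2[[nm]], 2 * p1[[nm]])
  expect_error(spd_scale(spd, -1), ">= 0")
})
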
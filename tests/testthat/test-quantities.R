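test_that("weighted_integral matches an independent fine-grid trapezoid oracle", {
  set.seed(1234)
  worst <- 0
  for (i in 1:50) {
    spd <- random_white_led()
    a <- ref_functions[[sample(names(ref_functions), 1)]]
    got <- weighted_integral(spd, a)
    want <- oracle_weighted_integral(spd$wavelength, spd$values,
                                     a$wavelength, a$weights)
    worst <- max(worst, abs(got - want) / want)
  }
  expect_lt(worst, 1e-3)
})

test_that("weighted_integral is linear and detects disjoint supports", {
  x <- gaussian_led_spd(list(c(470, 25, 0.7)))
  y <- gaussian_led_spd(list(c(600, 40, 1.3)))
  v <- ref_functions$photopic_V
  mix <- spectral_measurement(x$wavelength, 2 * x$values + 3 * y$values,
                              "spectral_irradiance")
  expect_equal(weighted_integral(mix, v),
               2 * weighted_integral(x, v) + 3 * weighted_integral(y, v))

  zero <- spectral_measurement(380:780, rep(0, 401), "spectral_irradiance")
  expect_equal(weighted_integral(zero, v), 0)

  uv <- spectral_measurement(300:350, rep(1, 51), "spectral_irradiance")
  expect_error(weighted_integral(uv, v), "disjoint")
})

test_that("a unit band at the peak wavelength passes through a unit-peak function unchanged", {
  for (nm in c("melanopic", "photopic_V")) {
    a <- ref_functions[[nm]]
    spd <- monochromatic_spd(peak_wavelength(a), 1)
    expect_equal(weighted_integral(spd, a), 1)
  }
})

test_that("the panel holds five alpha-opic entries plus a photopic entry in kind-dependent units", {
  p <- alpha_opic_panel(gaussian_led_spd(list(c(500, 30, 1))),
                        reference = ref_functions)
  alpha <- c("s_cone_opic", "m_cone_opic", "l_cone_opic", "rhodopic", "melanopic")
  expect_true(all(alpha %in% names(p)))
  expect_length(intersect(names(p), alpha), 5)
  expect_true(is.numeric(p$photopic))
  expect_identical(p$input_kind, "spectral_irradiance")
  expect_true(all(unlist(p[alpha]) >= 0))

  pr <- alpha_opic_panel(planckian_spd(5000, 1e-4, "spectral_radiance"),
                         reference = ref_functions)
  expect_identical(pr$input_kind, "spectral_radiance")
})

test_that("a 1 W/m^2 band at 555 nm gives a photopic illuminance of 683 lux", {
  p <- alpha_opic_panel(monochromatic_spd(555, 1), reference = ref_functions)
  expect_equal(p$photopic, 683)
})

test_that("alpha-opic values are reported in milliwatts", {
  spd <- monochromatic_spd(487, 1)  # 1 W/m^2 at the melanopic peak
  p <- alpha_opic_panel(spd, reference = ref_functions)
  expect_equal(p$melanopic, 1000 * weighted_integral(spd, ref_functions$melanopic))
})

test_that("photon conversion agrees with direct hc/lambda arithmetic", {
  cst <- lux_constants()
  pr <- photon_report(monochromatic_spd(500, 1))
  want <- 1 * (500e-9) / (cst$h * cst$c) * 1e-4
  expect_lt(abs(pr$total_photon_irradiance - want) / want, 1e-6)
  expect_equal(pr$log10_total, log10(want), tolerance = 1e-9)

  # photon energy scales as 1/lambda: double the wavelength, double the quanta
  p1 <- photon_report(monochromatic_spd(390, 1))$total_photon_irradiance
  p2 <- photon_report(monochromatic_spd(780, 1))$total_photon_irradiance
  expect_equal(p2 / p1, 2, tolerance = 1e-12)
})

test_that("an all-zero spectrum has zero photon irradiance and no log value", {
  pr <- photon_report(spectral_measurement(380:780, rep(0, 401),
                                           "spectral_irradiance"))
  expect_equal(pr$total_photon_irradiance, 0)
  expect_true(is.na(pr$log10_total))
})

test_that("photon irradiance rejects radiance input", {
  expect_error(photon_report(planckian_spd(5000, 1, "spectral_radiance")),
               "spectral_irradiance")
})

test_that("the age sensitivity table reproduces the standard panel at 32 and declines in melanopic", {
  spd <- gaussian_led_spd(list(c(470, 25, 1)))
  tab <- age_sensitivity_analysis(spd, c(32, 40, 50, 60, 70),
                                  reference = ref_functions)
  std <- alpha_opic_panel(spd, reference = ref_functions)
  expect_equal(tab$melanopic[1], std$melanopic)
  expect_equal(tab$photopic[1], std$photopic)
  expect_true(all(diff(tab$melanopic) < 0))

  zero <- spectral_measurement(380:780, rep(0, 401), "spectral_irradiance")
  ztab <- age_sensitivity_analysis(zero, c(32, 50), reference = ref_functions)
  expect_true(all(unlist(ztab[, -1]) == 0))
  expect_error(age_sensitivity_analysis(spd, numeric(0)), "non-empty")
})

test_that("metamers matched in illuminance still separate in melanopic irradiance", {
  pair <- metamer_pair(reference = ref_functions)
  pa <- alpha_opic_panel(pair$reference, reference = ref_functions)
  pb <- alpha_opic_panel(pair$comparison, reference = ref_functions)
  expect_lt(abs(pa$photopic - pb$photopic) / pa$photopic, 0.001)
  expect_gt(abs(pa$melanopic - pb$melanopic) /
              max(pa$melanopic, pb$melanopic), 0.20)
})

test_that("panel export embeds units in column names", {
  p <- alpha_opic_panel(monochromatic_spd(555, 1), reference = ref_functions)
  csv <- tempfile(fileext = ".csv")
  write_panel_csv(p, csv)
  hdr <- names(utils::read.csv(csv, check.names = FALSE))
  expect_true(any(grepl("melanopic", hdr)))
  expect_true(any(grepl("mW", hdr)))

  js <- tempfile(fileext = ".json")
  write_panel_json(p, js)
  parsed <- jsonlite::read_json(js)[[1]]
  expect_equal(parsed$photopic, 683)
  expect_match(parsed$alpha_opic_units, "mW")
})
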
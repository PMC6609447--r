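test_that("visual angle follows 2*atan(0.5 S/d) with its closed-form anchors", {
  expect_equal(visual_angle(0, 3), 0)
  expect_equal(visual_angle(2, 1), 90)
  expect_equal(visual_angle(0.5, 1), 2 * atan(0.25) * 180 / pi)  # 28.07 deg
  expect_equal(round(visual_angle(0.5, 1), 2), 28.07)
  expect_error(visual_angle(1, 0), "> 0")
  expect_error(visual_angle(-1, 1), ">= 0")
})

test_that("visual angle is monotone in size and distance, with the small-angle limit", {
  s <- seq(0.1, 3, length.out = 20)
  expect_true(all(diff(visual_angle(s, 2)) > 0))
  d <- seq(0.5, 10, length.out = 20)
  expect_true(all(diff(vapply(d, function(di) visual_angle(1, di), numeric(1))) < 0))

  for (ratio in c(0.009, 0.005, 0.001)) {
    theta <- visual_angle(ratio, 1)
    approx_deg <- (180 / pi) * ratio
    expect_lt(abs(theta - approx_deg) / theta, 1e-4)
  }
})

test_that("predicted pupil diameter shrinks with luminance and stays physiological", {
  d_dim <- predicted_pupil_diameter(10, field_diameter = 60, age = 30)
  d_bright <- predicted_pupil_diameter(1000, field_diameter = 60, age = 30)
  expect_lt(d_bright, d_dim)

  lums <- 10^seq(-4, 5, by = 0.5)
  for (age in c(20, 40, 60, 80)) {
    ds <- vapply(lums, function(L)
      as.numeric(predicted_pupil_diameter(L, 60, age, 2)), numeric(1))
    expect_true(all(diff(ds) <= 0))
    expect_true(all(ds >= 1 & ds <= 10))
  }
})

test_that("monocular viewing yields an equal or wider pupil than binocular", {
  for (L in c(1, 100, 10000)) {
    one <- as.numeric(predicted_pupil_diameter(L, 60, 35, eyes_open = 1))
    two <- as.numeric(predicted_pupil_diameter(L, 60, 35, eyes_open = 2))
    expect_gte(one, two)
  }
})

test_that("the pupil model accepts an observer context and records its variant", {
  ctx <- observer_context(age = 45, eyes_open = 1, field_diameter = 30)
  d <- predicted_pupil_diameter(200, ctx)
  expect_equal(as.numeric(d),
               as.numeric(predicted_pupil_diameter(200, 30, 45, 1)))
  expect_match(attr(d, "model"), "Stanley-Davies")
})

test_that("trolands are luminance times pupil area, bilinear in both", {
  expect_equal(trolands(0, 5), 0)
  expect_equal(trolands(100, 3), 100 * pi * 1.5^2)
  expect_equal(round(trolands(100, 3), 1), 706.9)
  # doubling the diameter quadruples the area term
  expect_equal(trolands(50, 6), 4 * trolands(50, 3))
  expect_equal(trolands(80, 4), 2 * trolands(40, 4))
  expect_error(trolands(-1, 3), ">= 0")
})

test_that("retinal illuminance prefers the measured pupil and tags the source", {
  spd <- planckian_spd(6500, 2e-5, "spectral_radiance")
  lum <- alpha_opic_panel(spd, reference = ref_functions)$photopic

  measured <- retinal_illuminance(
    spd, observer_context(30, 2, 60, pupil_diameter_mm = 3),
    reference = ref_functions)
  expect_identical(measured$pupil_source, "measured")
  expect_equal(measured$trolands, trolands(lum, 3))

  modelled <- retinal_illuminance(spd, observer_context(30, 2, 60),
                                  reference = ref_functions)
  expect_identical(modelled$pupil_source, "modelled")
  expect_equal(modelled$pupil_diameter_mm,
               as.numeric(predicted_pupil_diameter(lum, 60, 30, 2)))

  zero <- spectral_measurement(380:780, rep(0, 401), "spectral_radiance")
  expect_equal(retinal_illuminance(zero, observer_context(30, 2, 60),
                                   reference = ref_functions)$trolands, 0)

  irr <- planckian_spd(6500, 2e-5, "spectral_irradiance")
  expect_error(retinal_illuminance(irr, observer_context(30, 2, 60)),
               "spectral_radiance")
})

test_that("observer context and stimulus geometry validate their fields", {
  expect_error(observer_context(age = -1, field_diameter = 10), "age")
  expect_error(observer_context(age = 30, eyes_open = 3, field_diameter = 10),
               "eyes_open")
  expect_error(stimulus_geometry(1, 1, 0), "> 0")
  g <- stimulus_geometry(0.6, 0.4, 0.8, shape = "panel")
  expect_equal(unname(g$visual_angle_deg["vertical"]), visual_angle(0.4, 0.8))
})
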
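test_that("a fully populated record passes all seven checklist items", {
  rec <- deficient_record(reference = ref_functions)
  comp <- validate_record(rec)
  expect_equal(comp$n_pass, 7)
  expect_equal(comp$n_fail, 0)
  expect_equal(nrow(comp$items), 7)
})

test_that("each single omission fails exactly its owning item", {
  for (i in 1:7) {
    label <- paste0("item", i)
    comp <- validate_record(deficient_record(label, reference = ref_functions))
    expect_identical(comp$items$verdict[i], "fail",
                     info = paste("omission", label))
    expect_true(all(comp$items$verdict[-i] == "pass"),
                info = paste("collateral damage from", label))
  }
})

test_that("omitting everything fails everything", {
  comp <- validate_record(deficient_record(paste0("item", 1:7),
                                           reference = ref_functions))
  expect_equal(comp$n_pass, 0)
  expect_equal(comp$n_fail, 7)
})

test_that("validation is monotone: restoring an element never downgrades other items", {
  full <- validate_record(deficient_record(reference = ref_functions))
  for (i in 1:7) {
    partial <- validate_record(deficient_record(paste0("item", i),
                                                reference = ref_functions))
    for (j in setdiff(1:7, i))
      expect_identical(partial$items$verdict[j], full$items$verdict[j])
  }
})

test_that("manufacturer-provided stimulus spectra warn unless in-situ illuminance is reported", {
  rec <- deficient_record(reference = ref_functions)
  rec$stimulus_spd$provenance <- "manufacturer"
  comp <- validate_record(rec)
  expect_identical(comp$items$verdict[1], "warn")
  expect_match(comp$items$message[1], "in-situ")

  rec$illuminance_in_situ <- 250
  comp2 <- validate_record(rec)
  expect_identical(comp2$items$verdict[1], "pass")
})

test_that("an SPD without measurement geometry warns rather than fails", {
  rec <- deficient_record(reference = ref_functions)
  rec$stimulus_spd$metadata$measurement_geometry <- NULL
  comp <- validate_record(rec)
  expect_identical(comp$items$verdict[1], "warn")
})

test_that("unparseable or missing tabulated files fail the tabulation item", {
  rec <- deficient_record(reference = ref_functions)
  writeLines("not a spectrum", rec$spectra_files[1])
  expect_identical(validate_record(rec)$items$verdict[3], "fail")
  file.remove(rec$spectra_files[1])
  comp <- validate_record(rec)
  expect_identical(comp$items$verdict[3], "fail")
  expect_match(comp$items$message[3], "missing file")
})

test_that("incomplete measurement metadata warns with the missing fields named", {
  rec <- deficient_record(reference = ref_functions)
  rec$measurement$sensor <- NULL
  comp <- validate_record(rec)
  expect_identical(comp$items$verdict[7], "warn")
  expect_match(comp$items$message[7], "sensor")
})

test_that("timing specifications enforce their pattern-specific invariants", {
  expect_error(timing_spec("2026-03-02T22:00:00", "2026-03-02T23:00:00+01:00"),
               "timezone")
  expect_error(timing_spec("2026-03-02T23:00:00+01:00", "2026-03-02T22:00:00+01:00"),
               "after")
  expect_error(timing_spec("2026-03-02T22:00:00Z", "2026-03-02T23:00:00Z",
                           pattern = "flash_train"),
               "flash_duration")
  expect_error(timing_spec("2026-03-02T22:00:00Z", "2026-03-02T23:00:00Z",
                           pattern = "dynamic"),
               "refresh")
  t <- timing_spec("2026-03-02T22:00:00Z", "2026-03-02T23:00:00Z",
                   pattern = "flash_train", flash_duration = 0.002,
                   inter_stimulus_interval = 1)
  expect_equal(t$duration_s, 3600)
  td <- timing_spec("2026-03-02T22:00:00+02:00", "2026-03-02T21:30:00+01:00",
                    pattern = "dynamic", device_refresh_rate = 60,
                    mean_light_reference = "mean-spd")
  expect_equal(td$duration_s, 1800)  # timezone-aware arithmetic
})

test_that("rendering is deterministic and a clean record renders without failure markers", {
  rec <- deficient_record(reference = ref_functions)
  comp <- validate_record(rec)
  r1 <- render_report(rec, comp)
  r2 <- render_report(rec, comp)
  expect_identical(r1$markdown, r2$markdown)
  expect_false(any(grepl("FAIL", r1$markdown)))

  bad <- deficient_record("item2", reference = ref_functions)
  rb <- render_report(bad, validate_record(bad))
  expect_true(any(grepl("FAIL", rb$markdown)))
})

test_that("the JSON manifest round-trips to the same compliance verdicts", {
  rec <- deficient_record(reference = ref_functions)
  rec$safety <- rg0_screen(planckian_spd(6500, 1e-6, "spectral_radiance"),
                           3600, reference = ref_functions)
  path <- tempfile(fileext = ".json")
  write_exposure_record(rec, path)
  back <- read_exposure_record(path)
  expect_equal(back$stimulus_spd$values, rec$stimulus_spd$values)
  expect_equal(back$panels$stimulus$melanopic, rec$panels$stimulus$melanopic)
  expect_identical(validate_record(back)$items$verdict,
                   validate_record(rec)$items$verdict)
})

test_that("report output directory receives both documents", {
  rec <- deficient_record(reference = ref_functions)
  dir <- tempfile("report-")
  res <- render_report(rec, dir = dir)
  expect_true(file.exists(res$report_path))
  expect_true(file.exists(res$manifest_path))
  reread <- read_exposure_record(res$manifest_path)
  expect_equal(validate_record(reread)$n_pass, 7)
})
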
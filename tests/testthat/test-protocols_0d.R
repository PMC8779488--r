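test_that("biomarker conventions are exact on the analytic triangle AP", {
  fx <- generate_fixture("triangle_ap")
  b <- measure_biomarkers(fx$data)
  expect_equal(b$apd90, fx$ground_truth$apd90, tolerance = 1e-3)
  expect_equal(b$apd50, fx$ground_truth$apd50, tolerance = 1e-3)
  expect_equal(b$rmp, fx$ground_truth$rmp)
  expect_equal(b$v_peak, fx$ground_truth$v_peak, tolerance = 1e-2)
  expect_false(b$repolarization_failure)
  expect_false(b$no_ap)
})

test_that("pacing protocol validates and the threshold cache returns a stable 2x amplitude", {
  expect_error(pacing_protocol(bcl = 1, stim_duration = 2), "bcl")
  thr <- find_threshold("courtemanche")
  expect_identical(find_threshold("courtemanche"), thr)  # cached
  tr <- shared_get("crn_base_trace", pace("courtemanche"))
  expect_equal(tr$stim_amplitude, 2 * thr)
})

test_that("APD levels nest and quasi-steady state is reached by beat 100", {
  tr <- shared_get("crn_base_trace", pace("courtemanche"))
  b100 <- measure_biomarkers(tr)
  b99 <- measure_biomarkers(tr, beat = 1)  # two recorded beats: 99 and 100
  expect_lt(b100$apd20, b100$apd50)
  expect_lt(b100$apd50, b100$apd90)
  expect_lt(b100$apd90, tr$bcl)
  expect_lt(abs(b100$apd90 - b99$apd90), 1)
  expect_error(measure_biomarkers(tr, beat = 7), "beat not found")
})

test_that("a zero-amplitude stimulus yields no AP; plateau arrest is repolarization failure", {
  pz <- pacing_protocol(n_beats = 1, stim_amplitude = 0, record_last_n = 1)
  b <- measure_biomarkers(pace("courtemanche", protocol = pz))
  expect_true(b$no_ap)
  expect_false(b$repolarization_failure)
  expect_true(is.na(b$apd90))
  # Grandi with ICaL x2: repolarization failure (plateau arrest)
  scan <- grandi_ical_scan()
  r2 <- scan[scan$scale == 2, ]
  expect_true(r2$repolarization_failure)
  expect_false(isTRUE(r2$no_ap))
  expect_true(is.na(r2$apd90))
})

test_that("the identity row of a conductance scan reproduces the baseline pace", {
  sc <- conductance_scan("courtemanche", "Ito", c(0.5, 1.0))
  base <- bio100("courtemanche")
  expect_equal(sc$apd90[sc$scale == 1], base$apd90, tolerance = 1e-8)
  expect_lt(sc$apd90[sc$scale == 0.5], sc$apd90[sc$scale == 1])
  expect_true(all(is.na(sc$error)))
  expect_error(conductance_scan("courtemanche", "Ito", c(0.5, 5)), "scales")
})

test_that("Ito block moves the two atrial models in opposite directions", {
  # 50% Ito block shortens the Courtemanche AP and prolongs the Grandi AP
  expect_lt(delta_apd90("courtemanche", "Ito", 0.5), 0)
  expect_gt(delta_apd90("grandi", "Ito", 0.5), 0)
})
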
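test_that("phase of a sinusoidal field advances 2 pi per period; no singularities anywhere", {
  fx <- generate_fixture("sinusoid_field", phase_field = "random", seed = 1)
  ph <- compute_phase(fx$data)
  th <- ph$theta
  j1 <- which.min(abs(ph$times - (ph$times[1] + fx$ground_truth$period)))
  tot <- matrix(0, dim(th)[1], dim(th)[2])
  for (j in 2:j1) {
    tot <- tot + (th[, , j] - th[, , j - 1] + pi) %% (2 * pi) - pi
  }
  expect_lt(max(abs(abs(tot) / (2 * pi) - 1)), 0.02)
  # uniform-phase field: the detector returns an empty list
  ph0 <- compute_phase(generate_fixture("sinusoid_field")$data)
  expect_identical(nrow(detect_singularities(ph0, 150)), 0L)
})

test_that("planar and quiescent fields produce no false-positive singularities", {
  fx <- generate_fixture("planar_wave")
  ph <- compute_phase(fx$data)
  hits <- sum(vapply(ph$times,
                     function(t) nrow(detect_singularities(ph, t)),
                     integer(1)))
  expect_identical(hits, 0L)
})

test_that("a spiral singularity is localized within one node with correct chirality", {
  fx <- generate_fixture("archimedean_spiral")
  ph <- compute_phase(fx$data)
  s <- detect_singularities(ph, 150)
  expect_identical(nrow(s), 1L)
  expect_identical(s$chirality, 1)
  dx <- fx$data$geometry$dx
  expect_lte(abs(s$x - fx$ground_truth$cores$x), dx)
  expect_lte(abs(s$y - fx$ground_truth$cores$y), dx)
})

test_that("a figure-of-eight pair has opposite chirality and zero net charge", {
  cores <- data.frame(x = c(0.5, 1.1), y = c(0.8, 0.8), chirality = c(1, -1))
  fx <- generate_fixture("archimedean_spiral", cores = cores)
  s <- detect_singularities(compute_phase(fx$data), 200)
  expect_identical(nrow(s), 2L)
  expect_identical(sum(s$chirality), 0)
  s <- s[order(s$x), ]
  dx <- fx$data$geometry$dx
  expect_lte(max(abs(s$x - cores$x)), dx)
  expect_lte(max(abs(s$y - cores$y)), dx)
})

test_that("an anchored spiral core does not meander; a drifting core recovers v * t", {
  fx <- generate_fixture("archimedean_spiral")
  trs <- track_cores(fx$data, t_max = 300)
  main <- trs[[which.max(vapply(trs, function(x) x$lifetime, numeric(1)))]]
  expect_lt(main$meander_extent, 2 * fx$data$geometry$dx)
  fx2 <- generate_fixture("drifting_spiral")
  trs2 <- track_cores(fx2$data, t_max = 3000)
  main2 <- trs2[[which.max(vapply(trs2, function(x) x$lifetime, numeric(1)))]]
  expect_lt(abs(main2$path_length - fx2$ground_truth$path_length) /
              fx2$ground_truth$path_length, 0.10)
  expect_identical(main2$chirality, 1)
  expect_gt(main2$lifetime, 0.9 * fx2$ground_truth$lifetime)
})

test_that("phase embedding refuses coarse or irregular snapshot strides", {
  fx <- generate_fixture("sinusoid_field", stride = 2)
  rec <- fx$data
  rec$frame_times <- rec$frame_times * 4  # stride 8 ms
  expect_error(compute_phase(rec), "too coarse")
  rec2 <- fx$data
  rec2$frame_times[5] <- rec2$frame_times[5] + 0.5
  expect_error(compute_phase(rec2), "non-uniform")
})
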
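surrogate_vw_geometry <- function() {
  surrogate_model(140)
  tissue_geometry(60, 60, 0.05, 1e-3)
}

test_that("a self-terminating surrogate reentry is classified transient with the log's own duration", {
  fx <- shared_get("surr_reentry", generate_fixture("surrogate_reentry"))
  out <- classify_outcome(fx$data, 1500)
  expect_identical(out$class, "TRANSIENT_REENTRY")
  expect_true(fx$ground_truth$reexcited)
  # duration within one snapshot stride of the activation-log ground truth
  expect_lt(abs(out$reentry_duration -
                  (fx$ground_truth$termination - fx$data$meta$s2_onset)),
            fx$data$frame_dt)
})

test_that("an interval grid above full recovery yields only NO_REENTRY and window size 0", {
  g <- surrogate_vw_geometry()
  vw <- scan_vulnerable_window("surrogate", NULL, g, c(450, 500), 1200)
  expect_true(all(vw$records$outcome == "NO_REENTRY"))
  expect_identical(vw$size, 0)
  expect_true(all(is.na(vw$records$error)))
})

test_that("the surrogate vulnerable window contains transient and stable records", {
  g <- surrogate_vw_geometry()
  vw <- shared_get("surr_vw",
                   scan_vulnerable_window("surrogate", NULL, g,
                                          c(180, 190, 200, 230), 2000))
  r <- vw$records
  expect_identical(r$outcome[r$interval == 180], "NO_CAPTURE")
  expect_identical(r$outcome[r$interval == 190], "TRANSIENT_REENTRY")
  expect_identical(r$outcome[r$interval == 200], "STABLE_REENTRY")
  expect_identical(r$outcome[r$interval == 230], "NO_REENTRY")
  expect_identical(vw$window_start, 190)
  expect_identical(vw$window_end, 200)
  expect_identical(vw$size, 10)
})

test_that("classification refuses truncated recordings and non-S1S2 recordings", {
  g <- surrogate_vw_geometry()
  rec <- run_s1s2("surrogate", NULL, g, s1s2_interval = 200, duration = 600,
                  frame_dt = 25)
  # stable reentry truncated at 600 ms cannot be judged at a 2000 ms horizon
  expect_identical(rec$stopped, "duration")
  expect_error(classify_outcome(rec, 2000), "truncated")
  plain <- run_tissue("surrogate", geometry = g, duration = 50, frame_dt = 25)
  expect_error(classify_outcome(plain, 2000), "S2 metadata")
})

test_that("enlarging the horizon can downgrade STABLE to TRANSIENT but never creates reentry", {
  g <- surrogate_vw_geometry()
  rec <- shared_get("surr_200_3500",
                    run_s1s2("surrogate", NULL, g, s1s2_interval = 200,
                             duration = 3500, frame_dt = 25))
  short <- classify_outcome(rec, 2000)
  long <- classify_outcome(rec, 3500)
  reentry <- c("TRANSIENT_REENTRY", "STABLE_REENTRY")
  expect_true(short$class %in% reentry)
  expect_true(long$class %in% reentry)
  if (short$class == "NO_REENTRY") expect_identical(long$class, "NO_REENTRY")
})

test_that("identical configurations classify identically (deterministic pipeline)", {
  fx1 <- generate_fixture("surrogate_reentry", duration = 1200)
  out1 <- classify_outcome(fx1$data, 1200)
  fx2 <- generate_fixture("surrogate_reentry", duration = 1200)
  out2 <- classify_outcome(fx2$data, 1200)
  expect_identical(out1$class, out2$class)
  expect_identical(out1$reentry_duration, out2$reentry_duration)
  expect_identical(fx1$data$frames, fx2$data$frames)
})
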
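test_that("named interventions carry the documented scaling sets", {
  af <- unclass(af_scaling())
  expect_identical(unclass(build_intervention("AF")$scaling), af)
  ito <- unclass(build_intervention("AF_recover_Ito")$scaling)
  expect_identical(unname(ito[["Ito"]]), 1)
  expect_identical(ito[setdiff(CURRENT_IDS, "Ito")],
                   af[setdiff(CURRENT_IDS, "Ito")])
  ical <- unclass(build_intervention("AF_recover_ICaL")$scaling)
  expect_identical(unname(ical[["ICaL"]]), 1)
  ikr <- unclass(build_intervention("AF_IKr_block80")$scaling)
  expect_identical(unname(ikr[["IKr"]]), 0.2)
  expect_identical(ikr[setdiff(CURRENT_IDS, "IKr")],
                   af[setdiff(CURRENT_IDS, "IKr")])
  expect_identical(unclass(build_intervention("SR")$scaling),
                   unclass(scaling()))
  expect_error(build_intervention("AF_magic"), "arg")
})

test_that("an acute no-op switch is bit-identical to the uninterrupted run", {
  surrogate_model(140)
  g <- tissue_geometry(60, 60, 0.05, 1e-3)
  plain <- run_s1s2("surrogate", NULL, g, s1s2_interval = 200,
                    duration = 1600, frame_dt = 5)
  noop <- run_s1s2("surrogate", NULL, g, s1s2_interval = 200,
                   duration = 1600, frame_dt = 5,
                   scaling_after = scaling(), t_switch = 1000)
  expect_identical(noop$final_state, plain$final_state)
  expect_equal(noop$frame_times, plain$frame_times)
  expect_identical(noop$frames, plain$frames)
  o1 <- classify_outcome(plain, 1600)
  o2 <- classify_outcome(noop, 1600)
  expect_identical(o1$class, o2$class)
  expect_equal(o1$reentry_duration, o2$reentry_duration)
})

test_that("acute treatment of a quiescent substrate is refused with a diagnostic", {
  surrogate_model(140)
  g <- tissue_geometry(60, 60, 0.05, 1e-3)
  # interval 500: fully recovered, S2 wave extinguishes without reentry
  expect_error(
    run_intervention("surrogate", build_intervention("AF_IKr_block80"), g,
                     s1s2_interval = 500, horizon = 2000, timing = "acute",
                     base = scaling()),
    "no reentry to treat")
})

test_that("an acute surrogate outward-current increase terminates an established reentry", {
  surrogate_model(140)
  g <- tissue_geometry(60, 60, 0.05, 1e-3)
  # untreated: stable at a 2500 ms horizon
  rec0 <- shared_get("surr_200_2500",
                     run_s1s2("surrogate", NULL, g, 200, 2500,
                              frame_dt = 25))
  out0 <- classify_outcome(rec0, 2500)
  expect_identical(out0$class, "STABLE_REENTRY")
  # acute APD shortening (stronger outward flux) destabilizes the rotor
  treat <- run_s1s2("surrogate", NULL, g, 200, 2500, frame_dt = 25,
                    scaling_after = scaling(IKr = 1.6), t_switch = 1200)
  out1 <- classify_outcome(treat, 2500)
  expect_identical(out1$class, "TRANSIENT_REENTRY")
  expect_lt(duration0(out1), duration0(out0))
})
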
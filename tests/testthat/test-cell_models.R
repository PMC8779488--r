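test_that("model registry exposes the contracted definitions", {
  expect_setequal(list_models(), c("courtemanche", "grandi", "surrogate"))
  crn <- cell_model("courtemanche")
  gr <- cell_model("grandi")
  expect_identical(crn$n_state, 21L)
  expect_identical(gr$n_state, 38L)
  expect_identical(names(crn$init_state), crn$state_names)
  expect_identical(crn$state_names[1], "V")
  expect_setequal(crn$current_names[seq_along(CURRENT_IDS)], CURRENT_IDS)
  expect_error(cell_model("nodal"), "arg")
})

test_that("published resting states are near-fixed points and stay so after 60 s unpaced relaxation", {
  for (m in c("courtemanche", "grandi")) {
    # published initial states are rounded, so a small residual imbalance
    # remains (Grandi: ~0.06 mV/ms); it must still be far below upstroke
    # rates and must shrink after relaxation
    d0 <- cell_rhs(m, cell_model(m)$init_state)
    expect_lt(abs(d0[["V"]]), 0.1, label = paste(m, "|dV/dt| at rest"))
    relaxed <- pace(m, protocol = pacing_protocol(bcl = 60000, n_beats = 1,
                                                  stim_amplitude = 0,
                                                  record_last_n = 1),
                    sample_dt = 10)
    d1 <- cell_rhs(m, relaxed$final_state)
    expect_lt(abs(d1[["V"]]), 0.01,
              label = paste(m, "|dV/dt| after 60 s relaxation"))
  }
})

test_that("conductance scaling validates, composes element-wise and defaults to identity", {
  expect_equal(as.numeric(scaling()), rep(1, 9))
  expect_error(scaling(IJunk = 2), "named after")
  expect_error(scaling(Ito = -1), "finite and >= 0")
  comp <- scaling(Ito = 0.5, IK1 = 2) * scaling(Ito = 0.5)
  expect_equal(unname(unclass(comp)[["Ito"]]), 0.25)
  expect_equal(unname(unclass(comp)[["IK1"]]), 2)
})

test_that("AF remodeling variant carries the published seven-current set", {
  af <- af_scaling()
  expect_equal(unclass(af)[CURRENT_IDS],
               c(INa = 0.90, Ito = 0.20, ICaL = 0.50, IKur = 0.45,
                 IKr = 1.0, IKs = 2.0, IK1 = 2.0, INCX = 1.4, INaK = 1.0))
  # composition: applying the variant twice squares each factor
  twice <- af_scaling(af_scaling())
  expect_equal(unname(unclass(twice)[["INa"]]), 0.9^2)
  # recovery: resetting Ito restores the base entry, all others unchanged
  rec <- unclass(af)
  rec[["Ito"]] <- 1
  expect_equal(rec[setdiff(CURRENT_IDS, "Ito")],
               unclass(af)[setdiff(CURRENT_IDS, "Ito")])
})

test_that("scaling acts linearly on each frozen-state current and zero blocks exactly", {
  for (m in c("courtemanche", "grandi")) {
    st <- cell_model(m)$init_state
    st[["V"]] <- -20  # depolarized so every current is engaged
    base <- cell_currents(m, st)
    for (cur in CURRENT_IDS) {
      z <- cell_currents(m, st, do.call(scaling, setNames(list(0), cur)))
      d <- cell_currents(m, st, do.call(scaling, setNames(list(2), cur)))
      expect_identical(unname(z[[cur]]), 0,
                       label = paste(m, cur, "zero scaling"))
      expect_equal(unname(d[[cur]]), 2 * unname(base[[cur]]),
                   label = paste(m, cur, "doubling"))
      others <- setdiff(CURRENT_IDS, cur)
      expect_equal(z[others], base[others],
                   label = paste(m, cur, "other currents untouched"))
    }
  }
})

test_that("ICaL = 0 removes the ICaL contribution from dV/dt and the Ca fluxes", {
  st <- cell_model("courtemanche")$init_state
  st[["V"]] <- 0
  cur <- cell_currents("courtemanche", st, scaling(ICaL = 0))
  expect_identical(unname(cur[["ICaL"]]), 0)
  # dV/dt difference between ICaL = 0 and ICaL = 1 equals the current itself
  d1 <- cell_rhs("courtemanche", st)
  d0 <- cell_rhs("courtemanche", st, scaling(ICaL = 0))
  full <- cell_currents("courtemanche", st)
  expect_equal(d0[["V"]] - d1[["V"]], unname(full[["ICaL"]]))
  # and the SR/cytosol Ca flux terms lose the ICaL-dependent part only
  expect_false(isTRUE(all.equal(d0[["Cai"]], d1[["Cai"]])))
})

test_that("non-finite derivatives are reported with the offending state name", {
  st <- cell_model("courtemanche")$init_state
  st[["Cai"]] <- -1e3
  expect_error(cell_rhs("courtemanche", st), "non-finite")
})

test_that("the surrogate meets its configured APD, has a threshold and propagates", {
  surrogate_model(210)
  p <- pacing_protocol(bcl = 600, n_beats = 3, record_last_n = 1)
  b <- measure_biomarkers(pace("surrogate", protocol = p))
  expect_lt(abs(b$apd90 - 210) / 210, 0.05)
  # sub-threshold stimulus: no regenerative upstroke
  amp <- find_threshold("surrogate")
  psub <- pacing_protocol(bcl = 600, n_beats = 1, stim_amplitude = 0.2 * amp,
                          record_last_n = 1)
  bsub <- measure_biomarkers(pace("surrogate", protocol = psub))
  expect_true(bsub$no_ap)
  expect_lt(bsub$v_peak, -80 + 0.5 * (b$v_peak + 80))
  # finite conduction velocity in a strip
  m <- measure_cv("surrogate", D = 1e-3, nx = 80, ny = 9, dx = 0.05,
                  duration = 400)
  expect_false(m$blocked)
  expect_gt(m$cv, 0)
})

test_that("intracellular ion drift over 100 beats is bounded (Courtemanche, K+ stimulus carrier)", {
  st0 <- prepaced_state("courtemanche")
  tr <- pace("courtemanche", init = st0)
  st1 <- tr$final_state
  # K+ is the stimulus charge carrier and must be tightly conserved; Na+
  # still loads slowly toward its 1 Hz quasi-steady state at beat 100-200
  # (~5% per 100 beats), so it gets a loose bound only
  expect_lt(abs(st1[["Ki"]] - st0[["Ki"]]) / st0[["Ki"]], 0.01,
            label = "drift of Ki")
  expect_lt(abs(st1[["Nai"]] - st0[["Nai"]]) / st0[["Nai"]], 0.08,
            label = "drift of Nai")
  # total Ca content (cytosol + uptake and release compartments, volume
  # weighted) drifts < 1% as well
  ca <- function(s) s[["Cai"]] + s[["Caup"]] * 1109.52 / 13668 +
    s[["Carel"]] * 96.48 / 13668
  expect_lt(abs(ca(st1) - ca(st0)) / ca(st0), 0.01)
})
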
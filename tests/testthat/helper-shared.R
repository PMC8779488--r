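# Shared lazily-computed simulation artifacts, cached for the whole test run
# so expensive runs are paid for once across files.
shared <- new.env(parent = emptyenv())

shared_get <- function(key, expr) {
  if (is.null(shared[[key]])) shared[[key]] <- force(expr)
  shared[[key]]
}

# final-beat biomarkers of a 100-beat 1 Hz pace
bio100 <- function(model, sc = NULL) {
  key <- paste0("bio:", model, ":",
                paste(signif(as.numeric(atriawave:::as_scaling(sc)), 12),
                      collapse = ","))
  shared_get(key, measure_biomarkers(pace(model, sc)))
}

# APD90 change (ms) from baseline under a single-current rescale
delta_apd90 <- function(model, current, scale) {
  sc <- do.call(scaling, stats::setNames(list(scale), current))
  bio100(model, sc)$apd90 - bio100(model)$apd90
}

# adaptive-stiff (lsoda) cross-check of the production fixed-step integrator:
# 5 beats at 1 Hz from the published initial state
oracle_check <- function(model, n_beats = 5, bcl = 1000) {
  shared_get(paste0("oracle:", model), {
    amp <- 2 * find_threshold(model)
    init <- cell_model(model)$init_state
    rhs <- function(t, y, p) {
      ph <- t - bcl * floor(t / bcl)
      list(cell_rhs(model, y, i_stim = if (ph < 2) amp else 0))
    }
    sol <- deSolve::lsoda(init, seq(0, n_beats * bcl, by = 0.1), rhs, NULL,
                          rtol = 1e-6, atol = 1e-8, hmax = 0.5)
    tr <- pace(model,
               protocol = pacing_protocol(n_beats = n_beats, bcl = bcl,
                                          stim_amplitude = amp,
                                          record_last_n = n_beats),
               sample_dt = 0.1)
    vr <- stats::approx(tr$time, tr$V, sol[, 1])$y
    tr_l <- tr
    tr_l$time <- sol[, 1]
    tr_l$V <- sol[, 2]
    list(rms = sqrt(mean((sol[, 2] - vr)^2, na.rm = TRUE)),
         apd90_fixed = measure_biomarkers(tr)$apd90,
         apd90_lsoda = measure_biomarkers(tr_l)$apd90)
  })
}

# Grandi ICaL 0D scan, 100% to 400% in 25% steps (shared by several tests)
grandi_ical_scan <- function() {
  shared_get("gr_ical_scan",
             conductance_scan("grandi", "ICaL", seq(1, 4, by = 0.25)))
}

# Courtemanche CV calibration on the 200 x 15 strip at dx = 0.02 cm
crn_cv_calibration <- function() {
  shared_get("crn_cal", calibrate_cv("courtemanche"))
}

# Scaled-down Courtemanche reentry suite on a 100 x 100 sheet (dx = 0.04 cm,
# 3 s horizon); the S1S2 interval and geometry are frozen protocol choices.
reentry_geometry <- function() {
  shared_get("reentry_geom", {
    cal <- shared_get("crn_cal_dx004",
                      calibrate_cv("courtemanche", dx = 0.04))
    tissue_geometry(100, 100, 0.04, cal$D)
  })
}

reentry_run <- function(label, sc, interval, horizon = 3000) {
  key <- paste0("reentry:", label, ":", interval)
  shared_get(key, {
    rec <- run_s1s2("courtemanche", sc, reentry_geometry(), interval,
                    horizon, frame_dt = 25)
    list(recording = rec, outcome = classify_outcome(rec, horizon))
  })
}

# reentry duration with non-reentrant outcomes counted as 0 ms
duration0 <- function(outcome) {
  if (outcome$class %in% c("TRANSIENT_REENTRY", "STABLE_REENTRY")) {
    outcome$reentry_duration
  } else {
    0
  }
}
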
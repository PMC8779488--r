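#' Pacing protocol
#'
#' Rectangular-pulse pacing at a fixed basic cycle length. The default matches
#' the study conditions for single-cell work: 1 Hz (BCL 1000 ms), 100 beats of
#' pre-pacing so biomarkers are read at quasi-steady state, 2 ms pulses at
#' twice the diastolic threshold (resolved per model, see [find_threshold()]).
#'
#' @param bcl Basic cycle length in ms.
#' @param n_beats Number of beats.
#' @param stim_amplitude Stimulus amplitude in pA/pF, or `NULL` to use twice
#'   the model's diastolic threshold at baseline.
#' @param stim_duration Pulse width in ms.
#' @param record_last_n How many trailing beats to record.
#' @return A `pacing_protocol` list.
#' @export
pacing_protocol <- function(bcl = 1000, n_beats = 100, stim_amplitude = NULL,
                            stim_duration = 2, record_last_n = 2) {
  stopifnot(bcl > stim_duration, stim_duration > 0, n_beats >= 1,
            record_last_n >= 1)
  structure(list(bcl = bcl, n_beats = n_beats,
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration,
                 record_last_n = record_last_n),
            class = "pacing_protocol")
}

#' Diastolic stimulus threshold
#'
#' Minimal rectangular-pulse amplitude (pA/pF, given pulse width) that elicits
#' a regenerative action potential from the model's resting state, found by
#' bisection at baseline conductances. Capture is a voltage overshoot beyond
#' the model's capture level (0 mV for the atrial models). The result is
#' cached per (model, duration).
#'
#' @param model A `cell_model` or name.
#' @param stim_duration Pulse width in ms.
#' @param tol Relative bisection tolerance.
#' @return Threshold amplitude in pA/pF.
#' @export
find_threshold <- function(model, stim_duration = 2, tol = 0.02) {
  name <- as_model_name(model)
  key <- paste0("thr:", name, ":", stim_duration)
  if (!is.null(the[[key]])) return(the[[key]])
  hi <- threshold_bisect(name, stim_duration, tol)
  the[[key]] <- hi
  hi
}

threshold_bisect <- function(name, stim_duration, tol) {
  info <- cell_model(name)
  captured <- function(amp) {
    r <- .pace0d(name, as.numeric(scaling()), numeric(0), 1L, 500,
                 amp, stim_duration, -1, 1L, 0.1)
    max(r$V) > info$capture_voltage
  }
  lo <- 0
  hi <- 2
  while (!captured(hi)) {
    lo <- hi
    hi <- hi * 2
    if (hi > 2000) stop("no capture up to 2000 pA/pF; check the model")
  }
  while ((hi - lo) / hi > tol) {
    mid <- (hi + lo) / 2
    if (captured(mid)) hi <- mid else lo <- mid
  }
  hi
}

resolve_amplitude <- function(model, protocol) {
  if (!is.null(protocol$stim_amplitude)) return(protocol$stim_amplitude)
  2 * find_threshold(model, protocol$stim_duration)
}

#' Pace a single cell
#'
#' Runs the pacing protocol on one cell and records the membrane voltage over
#' the trailing beats. The final state (end of the last cycle, in diastole) is
#' returned for reuse, e.g. to initialize tissue simulations from the
#' pre-paced cellular state.
#'
#' @param model A `cell_model` or name.
#' @param scaling A [scaling()] map (default: baseline).
#' @param protocol A [pacing_protocol()].
#' @param dt Integration step in ms. The default is 0.005 ms for the atrial
#'   ionic models (single-cell biomarkers are dt-converged to well under 1 ms
#'   at that step) and the model's own default step otherwise.
#' @param sample_dt Recording interval in ms (fine enough that linear
#'   interpolation of repolarization levels is sub-millisecond accurate).
#' @param init Optional initial state (default: the model's initial state).
#' @return An `ap_trace`: list with `time`, `V`, `stim_onsets`,
#'   `stim_duration`, `final_state` and protocol metadata.
#' @export
pace <- function(model, scaling = NULL, protocol = pacing_protocol(),
                 dt = NULL, sample_dt = 0.05, init = NULL) {
  name <- as_model_name(model)
  if (is.null(dt) && name %in% c("courtemanche", "grandi")) dt <- 0.005
  sc <- as_scaling(scaling)
  amp <- resolve_amplitude(name, protocol)
  r <- .pace0d(name, as.numeric(sc),
               if (is.null(init)) numeric(0) else as.numeric(init),
               as.integer(protocol$n_beats), protocol$bcl, amp,
               protocol$stim_duration, if (is.null(dt)) -1 else dt,
               as.integer(protocol$record_last_n), sample_dt)
  structure(list(time = r$time, V = r$V, stim_onsets = r$stim_onsets,
                 stim_duration = protocol$stim_duration,
                 stim_amplitude = amp, final_state = r$final_state,
                 model = name, scaling = sc, bcl = r$bcl,
                 n_beats = r$n_beats, dt = r$dt),
            class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat("<ap_trace> ", x$model, ": ", length(x$stim_onsets),
      " recorded beat(s) of ", x$n_beats, " at BCL ", x$bcl, " ms\n", sep = "")
  invisible(x)
}

#' Action-potential biomarkers
#'
#' Measures one beat of an [pace()] trace. The AP onset is the time of maximal
#' dV/dt within 10 ms of the stimulus onset; the repolarization reference for
#' x% recovery is the pre-upstroke voltage at stimulus onset, so
#' `V_threshold(x) = V_peak - x/100 * (V_peak - V_onset)`, located with linear
#' interpolation. Repolarization failure is flagged when the 90% level is
#' never crossed downward before the next stimulus (or end of trace), and also
#' when the membrane sits arrested at depolarized potentials (pre-stimulus
#' voltage above -55 mV; plateau arrest from an earlier failed beat),
#' whether or not the arrested plateau drifts above the capture level;
#' APDs are then `NA`. `no_ap` is reserved for the sub-threshold case: the
#' membrane rests polarized but the stimulus fails to elicit an overshoot
#' beyond the capture level.
#'
#' @param trace An `ap_trace`.
#' @param beat Index among the recorded beats (default: last fully recorded).
#' @return A one-row `data.frame`: `apd20`, `apd50`, `apd90` (ms), `rmp`,
#'   `v_peak`, `amplitude` (mV), `dvdt_max` (mV/ms), `repolarization_failure`,
#'   `no_ap`.
#' @export
measure_biomarkers <- function(trace, beat = NULL) {
  stopifnot(inherits(trace, "ap_trace"))
  tt <- trace$time
  if (is.unsorted(tt, strictly = TRUE)) stop("non-monotone time grid")
  onsets <- trace$stim_onsets
  if (is.null(beat)) beat <- length(onsets)
  if (beat < 1 || beat > length(onsets)) stop("beat not found in trace")
  t_on <- onsets[beat]
  t_next <- if (beat < length(onsets)) onsets[beat + 1] else max(tt)
  win <- tt >= t_on - 1e-9 & tt <= t_next + 1e-9
  t <- tt[win]
  v <- trace$V[win]
  if (length(t) < 5) stop("beat not fully contained in trace")

  rmp <- v[1]
  capture_v <- cell_model(trace$model)$capture_voltage
  fail_row <- function(no_ap, repol_fail, vp, dvdtm) {
    data.frame(apd20 = NA_real_, apd50 = NA_real_, apd90 = NA_real_,
               rmp = rmp, v_peak = vp, amplitude = vp - rmp,
               dvdt_max = dvdtm, repolarization_failure = repol_fail,
               no_ap = no_ap)
  }

  dv <- diff(v) / diff(t)
  tm <- t[-length(t)]
  up <- which(tm <= t_on + 10)
  if (!length(up)) up <- 1L
  i_on <- up[which.max(dv[up])]
  t_act <- tm[i_on]
  dvdt_max <- dv[i_on]
  v_peak <- max(v)
  if (rmp > -55) {
    # plateau arrest: the membrane never returned near rest before this
    # stimulus, so no genuine action potential can be measured even if the
    # arrested plateau drifts above the capture level
    return(fail_row(FALSE, TRUE, v_peak, dvdt_max))
  }
  if (v_peak < capture_v) {
    return(fail_row(TRUE, FALSE, v_peak, dvdt_max))
  }

  apd_x <- function(x) {
    thr <- v_peak - x / 100 * (v_peak - rmp)
    i_pk <- which.max(v)
    idx <- which(v[-1] <= thr & v[-length(v)] > thr)
    idx <- idx[idx >= i_pk & tm[idx] >= t_act]
    if (!length(idx)) return(NA_real_)
    i <- idx[1]
    t_cross <- t[i] + (thr - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
    t_cross - t_act
  }
  a20 <- apd_x(20); a50 <- apd_x(50); a90 <- apd_x(90)
  data.frame(apd20 = a20, apd50 = a50, apd90 = a90, rmp = rmp,
             v_peak = v_peak, amplitude = v_peak - rmp, dvdt_max = dvdt_max,
             repolarization_failure = is.na(a90), no_ap = FALSE)
}

#' Conductance-sensitivity scan
#'
#' Paces the model to quasi-steady state once per scale of one current (all
#' other currents held at the reference scaling) and tabulates the biomarkers
#' of the final beat. Rows whose action potential fails to repolarize carry
#' the failure flag with `NA` durations rather than a number; rows whose
#' simulation errors are recorded with the error message.
#'
#' @param model A `cell_model` or name.
#' @param current One of [CURRENT_IDS].
#' @param scales Numeric multipliers in `[0, 4]`.
#' @param protocol A [pacing_protocol()].
#' @param reference Scaling applied to all other currents (default baseline).
#' @param dt Integration step (default: model step).
#' @return A `data.frame`, one row per scale, biomarker columns plus `scale`,
#'   `current` and `error`.
#' @export
conductance_scan <- function(model, current, scales,
                             protocol = pacing_protocol(),
                             reference = NULL, dt = NULL) {
  current <- match.arg(current, CURRENT_IDS)
  stopifnot(all(scales >= 0), all(scales <= 4))
  ref <- as_scaling(reference)
  rows <- lapply(scales, function(s) {
    sc <- ref
    sc[current] <- unclass(ref)[current] * s
    res <- tryCatch({
      tr <- pace(model, sc, protocol, dt = dt)
      cbind(data.frame(scale = s, current = current),
            measure_biomarkers(tr), error = NA_character_)
    }, error = function(e) {
      data.frame(scale = s, current = current, apd20 = NA_real_,
                 apd50 = NA_real_, apd90 = NA_real_, rmp = NA_real_,
                 v_peak = NA_real_, amplitude = NA_real_, dvdt_max = NA_real_,
                 repolarization_failure = NA, no_ap = NA,
                 error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, rows)
}
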
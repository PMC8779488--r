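#' Tissue geometry
#'
#' Regular isotropic 2D grid for the monodomain solver. The default matches
#' the study sheet: 4 x 4 cm discretized as 200 x 200 nodes (dx = 0.02 cm).
#' The diffusion coefficient `D` (cm^2/ms) is set after CV calibration (see
#' [calibrate_cv()]).
#'
#' @param nx,ny Node counts (>= 3).
#' @param dx Node spacing in cm.
#' @param D Diffusion coefficient in cm^2/ms.
#' @return A `tissue_geometry` list.
#' @export
tissue_geometry <- function(nx = 200, ny = 200, dx = 0.02, D = 1e-3) {
  stopifnot(nx >= 3, ny >= 3, dx > 0, D >= 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, D = D),
            class = "tissue_geometry")
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat("<tissue_geometry> ", x$nx, " x ", x$ny, " nodes, dx = ", x$dx,
      " cm (", round(x$nx * x$dx, 2), " x ", round(x$ny * x$dx, 2),
      " cm), D = ", signif(x$D, 4), " cm^2/ms\n", sep = "")
  invisible(x)
}

# 1-based linear node index for column ix (1..nx), row iy (1..ny);
# the solver orders nodes row-fastest (n = iy + (ix-1)*ny)
node_index <- function(ix, iy, ny) (ix - 1L) * ny + iy

#' Stimulus region
#'
#' A set of nodes driven by a rectangular current pulse.
#'
#' @param nodes 1-based linear node indices (see [region_columns()],
#'   [region_quadrant()]).
#' @param onset Pulse onset in ms (absolute simulation time).
#' @param duration Pulse width in ms.
#' @param amplitude Amplitude in pA/pF (positive depolarizes).
#' @return A `stimulus_region` list.
#' @export
stimulus_region <- function(nodes, onset, duration = 2, amplitude) {
  nodes <- as.integer(nodes)
  stopifnot(length(nodes) > 0, duration > 0, is.finite(amplitude))
  structure(list(nodes = nodes, onset = onset, duration = duration,
                 amplitude = amplitude), class = "stimulus_region")
}

#' Stimulus region helpers
#'
#' `region_columns()` selects whole columns (used for the planar S1 line,
#' default: the two leftmost columns); `region_quadrant()` selects the
#' upper-left quadrant including its shared edges (columns `1..floor(nx/2)`,
#' rows `1..floor(ny/2)`), the cross-field S2 region.
#'
#' @param geometry A [tissue_geometry()].
#' @param cols Column indices.
#' @return Integer vector of 1-based node indices.
#' @export
region_columns <- function(geometry, cols = 1:2) {
  as.integer(outer(seq_len(geometry$ny), (cols - 1L) * geometry$ny, `+`))
}

#' @rdname region_columns
#' @export
region_quadrant <- function(geometry) {
  nx2 <- geometry$nx %/% 2L
  ny2 <- geometry$ny %/% 2L
  as.integer(outer(seq_len(ny2), (seq_len(nx2) - 1L) * geometry$ny, `+`))
}

scaling_key <- function(sc) paste(signif(as.numeric(sc), 12), collapse = ",")

#' Pre-paced cellular state
#'
#' The single-cell state after the standard 100-beat 1 Hz pre-pacing under
#' the given scaling, used to initialize every tissue node (tissue runs start
#' from the cellular quasi-steady state; pre-pacing is done in 0D). Cached
#' per (model, scaling, protocol).
#'
#' @param model A `cell_model` or name.
#' @param scaling A [scaling()] map.
#' @param protocol A [pacing_protocol()].
#' @return Named numeric state vector.
#' @export
prepaced_state <- function(model, scaling = NULL, protocol = pacing_protocol()) {
  name <- as_model_name(model)
  sc <- as_scaling(scaling)
  key <- paste0("prepace:", name, ":", scaling_key(sc), ":",
                protocol$bcl, ":", protocol$n_beats)
  if (!is.null(the[[key]])) return(the[[key]])
  tr <- pace(name, sc, protocol, sample_dt = 1)
  the[[key]] <- tr$final_state
  tr$final_state
}

# default tissue step: the model's step, reduced to the diffusion stability
# bound when D is large enough to require it (explicit dt is passed through)
tissue_dt <- function(model, dt, geometry = NULL) {
  if (!is.null(dt)) return(dt)
  dt <- cell_model(as_model_name(model))$default_dt
  if (!is.null(geometry)) dt <- min(dt, 0.9 * geometry$dx^2 / (4 * geometry$D))
  dt
}

# planar/cross-field stimulus amplitude: four times the cellular diastolic
# threshold (twice the cellular threshold is sub-threshold in tissue, the
# resting neighborhood drains the stimulated nodes electrotonically)
tissue_amplitude <- function(model) 4 * find_threshold(model)

as_recording <- function(raw, geometry, model, sc, frame_dt, meta) {
  nn <- geometry$nx * geometry$ny
  nt <- length(raw$frame_times)
  frames <- if (nt > 0) {
    array(raw$frame_v, dim = c(geometry$ny, geometry$nx, nt))
  } else {
    array(numeric(0), dim = c(geometry$ny, geometry$nx, 0))
  }
  n <- raw$act_node + 1L
  ix <- (n - 1L) %/% geometry$ny + 1L
  iy <- (n - 1L) %% geometry$ny + 1L
  structure(list(
    frames = frames, frame_times = raw$frame_times,
    activations = data.frame(ix = ix, iy = iy,
                             x = (ix - 1) * geometry$dx,
                             y = (iy - 1) * geometry$dx, t = raw$act_time),
    geometry = geometry, model = model, scaling = sc,
    dt = raw$dt, frame_dt = frame_dt,
    t_end = raw$t_end, stopped = raw$stopped,
    final_state = raw$final_state, meta = meta), class = "tissue_recording")
}

#' @export
print.tissue_recording <- function(x, ...) {
  cat("<tissue_recording> ", x$model, " on ", x$geometry$nx, " x ",
      x$geometry$ny, " nodes; ", length(x$frame_times), " frames; ",
      nrow(x$activations), " activations; t_end = ", round(x$t_end, 1),
      " ms (", x$stopped, ")\n", sep = "")
  invisible(x)
}

#' Run a 2D monodomain simulation
#'
#' Advances homogeneous isotropic monodomain tissue
#' (dV/dt = D lap(V) - I_ion/Cm + I_stim, 5-point Laplacian, no-flux mirror
#' boundaries, operator splitting with Rush-Larsen reaction steps) under a
#' list of stimulus regions. Voltage snapshots are stored every `frame_dt` ms
#' (0 disables frames); upward crossings of `act_threshold` are logged per
#' node with re-arming below `act_reset`. The run stops early once every node
#' stays below `quiescent_v` for `quiescent_ms` (if enabled).
#'
#' @param model A `cell_model` or name.
#' @param scaling A [scaling()] map.
#' @param geometry A [tissue_geometry()].
#' @param init Initial state: one state vector (applied to every node) or an
#'   `n_state x (nx*ny)` matrix. Default: the pre-paced cellular state.
#' @param stimuli List of [stimulus_region()].
#' @param duration Simulated time in ms (from `t0`).
#' @param t0 Start time in ms.
#' @param dt Integration step in ms (default: the model's tissue step). Must
#'   satisfy the diffusion stability bound `dt <= dx^2 / (4 D)`.
#' @param frame_dt Snapshot stride in ms (0 = no frames).
#' @param stop_when_quiescent Stop early once the tissue is quiescent.
#' @param quiescent_v,quiescent_ms Quiescence definition (all V below
#'   `quiescent_v` for `quiescent_ms` ms).
#' @param act_threshold,act_reset Activation detector levels in mV.
#' @param meta Free-form metadata list carried on the recording.
#' @return A `tissue_recording`: voltage frames `[ny, nx, time]`, frame
#'   times, activation log (`ix`, `iy`, `x`, `y`, `t`), final state and run
#'   metadata.
#' @export
run_tissue <- function(model, scaling = NULL, geometry, init = NULL,
                       stimuli = list(), duration, t0 = 0, dt = NULL,
                       frame_dt = 5, stop_when_quiescent = FALSE,
                       quiescent_v = -70, quiescent_ms = 100,
                       act_threshold = -40, act_reset = -60, meta = list()) {
  name <- as_model_name(model)
  sc <- as_scaling(scaling)
  stopifnot(inherits(geometry, "tissue_geometry"), duration > 0)
  ns <- cell_model(name)$n_state
  nn <- geometry$nx * geometry$ny
  if (is.null(init)) init <- prepaced_state(name, sc)
  y0 <- if (is.matrix(init)) init else matrix(init, nrow = ns, ncol = nn)
  stim <- lapply(stimuli, function(s) {
    stopifnot(inherits(s, "stimulus_region"))
    list(nodes = s$nodes - 1L, onset = s$onset, duration = s$duration,
         amplitude = s$amplitude)
  })
  raw <- .run_tissue(name, as.numeric(sc), y0, geometry$nx, geometry$ny,
                     geometry$dx, geometry$D, tissue_dt(name, dt, geometry), t0,
                     duration, stim, frame_dt, act_threshold, act_reset,
                     stop_when_quiescent, quiescent_v, quiescent_ms)
  as_recording(raw, geometry, name, sc, frame_dt, meta)
}

#' Planar-wave conduction velocity
#'
#' Measures CV on a thin strip (default 200 x 15 nodes): pre-paced cells, a
#' planar stimulus on the leftmost 0.04 cm at t = 0, activation times
#' (upward crossing of -40 mV) read at the mid-row sensors placed at 25% and
#' 75% of strip length.
#'
#' @param model A `cell_model` or name.
#' @param scaling A [scaling()] map.
#' @param D Diffusion coefficient in cm^2/ms.
#' @param dx Node spacing in cm.
#' @param nx,ny Strip dimensions in nodes.
#' @param dt Integration step (default: model tissue step).
#' @param duration Simulated time in ms.
#' @return List with `cv` (cm/s), sensor columns and times, and the strip
#'   recording's activation log. `cv` is `NA` with `blocked = TRUE` when the
#'   distal sensor never activates (conduction block at this `D`).
#' @export
measure_cv <- function(model, scaling = NULL, D, dx = 0.02, nx = 200,
                       ny = 15, dt = NULL, duration = 250) {
  geom <- tissue_geometry(nx, ny, dx, D)
  amp <- tissue_amplitude(model)
  # fixed physical stimulus width (0.04 cm, at least two columns) so the
  # launched wave is grid-independent
  cols <- seq_len(max(2L, as.integer(ceiling(0.04 / dx))))
  rec <- run_tissue(model, scaling, geom,
                    stimuli = list(stimulus_region(region_columns(geom, cols),
                                                   onset = 0, amplitude = amp)),
                    duration = duration, dt = dt, frame_dt = 0)
  mid <- (ny + 1L) %/% 2L
  sensor <- function(ix) {
    tt <- rec$activations$t[rec$activations$ix == ix & rec$activations$iy == mid]
    if (length(tt)) min(tt) else NA_real_
  }
  ix1 <- as.integer(round(0.25 * nx))
  ix2 <- as.integer(round(0.75 * nx))
  t1 <- sensor(ix1)
  t2 <- sensor(ix2)
  blocked <- is.na(t1) || is.na(t2) || t2 <= t1
  cv <- if (blocked) NA_real_ else (ix2 - ix1) * dx / (t2 - t1) * 1000
  list(cv = cv, blocked = blocked, sensor_cols = c(ix1, ix2),
       sensor_times = c(t1, t2), D = D, dx = dx,
       activations = rec$activations)
}

#' Calibrate the diffusion coefficient to a CV band
#'
#' Finds a scalar D whose planar-wave CV (see [measure_cv()]) lies inside
#' `target` cm/s. A first guess is refined by the continuous-limit scaling
#' law CV ~ sqrt(D), then bisection narrows in; conduction block at a trial D
#' is treated as CV below the band.
#'
#' @param model A `cell_model` or name.
#' @param scaling A [scaling()] map.
#' @param target CV band in cm/s (within 10-100 cm/s).
#' @param dx,nx,ny,dt,duration Passed to [measure_cv()].
#' @param D_init Starting guess in cm^2/ms.
#' @param max_iter Iteration cap.
#' @return List with `D` (cm^2/ms), `cv` (cm/s) and the search `history`
#'   data frame.
#' @export
calibrate_cv <- function(model, scaling = NULL, target = c(45, 50),
                         dx = 0.02, nx = 200, ny = 15, dt = NULL,
                         duration = 250, D_init = 1e-3, max_iter = 30) {
  stopifnot(length(target) == 2, target[1] < target[2],
            target[1] >= 10, target[2] <= 100)
  mid <- mean(target)
  hist <- list()
  eval_cv <- function(D) {
    m <- measure_cv(model, scaling, D, dx, nx, ny, dt, duration)
    hist[[length(hist) + 1L]] <<- data.frame(D = D, cv = m$cv,
                                             blocked = m$blocked)
    if (m$blocked) -Inf else m$cv
  }
  D <- D_init
  cv <- eval_cv(D)
  # sqrt-law jump towards the band center when the first guess conducts
  if (is.finite(cv)) {
    D2 <- D * (mid / cv)^2
    cv2 <- eval_cv(D2)
    if (cv2 >= target[1] && cv2 <= target[2]) {
      return(list(D = D2, cv = cv2, history = do.call(rbind, hist)))
    }
    D <- D2; cv <- cv2
  }
  # bracket the band, then bisect
  lo <- D; hi <- D
  if (cv < target[1]) {
    while (eval_cv(hi <- hi * 2) < target[1]) {
      lo <- hi
      if (length(hist) > max_iter) stop("CV calibration failed to bracket")
    }
  } else if (cv > target[2]) {
    while (eval_cv(lo <- lo / 2) > target[2]) {
      hi <- lo
      if (length(hist) > max_iter) stop("CV calibration failed to bracket")
    }
  } else {
    return(list(D = D, cv = cv, history = do.call(rbind, hist)))
  }
  for (i in seq_len(max_iter)) {
    Dm <- (lo + hi) / 2
    cvm <- eval_cv(Dm)
    if (cvm >= target[1] && cvm <= target[2]) {
      return(list(D = Dm, cv = cvm, history = do.call(rbind, hist)))
    }
    if (cvm < target[1]) lo <- Dm else hi <- Dm
  }
  stop("CV calibration did not converge into [", target[1], ", ", target[2],
       "] cm/s")
}

# cached S1 (planar conditioning wave) segment: returns the tissue state at
# `t_stop` for (model, scaling, geometry, dt, amplitude), advancing an earlier
# cached state when one exists so ascending S1S2 scans reuse work
s1_state_at <- function(model, sc, geometry, t_stop, dt, amp) {
  key <- paste0("s1:", as_model_name(model), ":", scaling_key(sc), ":",
                geometry$nx, ":", geometry$ny, ":", signif(geometry$dx, 12),
                ":", signif(geometry$D, 12), ":", signif(dt, 12), ":",
                signif(amp, 12))
  cached <- the[[key]]
  if (!is.null(cached) && cached$t <= t_stop + 1e-9) {
    if (abs(cached$t - t_stop) < 1e-9) return(cached)
    t0 <- cached$t
    init <- cached$state
    acts <- cached$activations
    stimuli <- list()
  } else {
    t0 <- 0
    init <- NULL
    acts <- NULL
    stimuli <- list(stimulus_region(region_columns(geometry), onset = 0,
                                    amplitude = amp))
  }
  rec <- run_tissue(model, sc, geometry, init = init, stimuli = stimuli,
                    duration = t_stop - t0, t0 = t0, dt = dt, frame_dt = 0)
  out <- list(t = t_stop, state = rec$final_state,
              activations = rbind(acts, rec$activations))
  the[[key]] <- out
  out
}

#' S1S2 cross-field induction protocol
#'
#' One planar conditioning beat (S1: the two leftmost columns at t = 0) on
#' pre-paced tissue, followed by a premature cross-field stimulus (S2: the
#' upper-left quadrant) at `s1s2_interval` ms (onset-to-onset). The run
#' continues to `duration` ms total or stops once the tissue is quiescent
#' (all V < -70 mV for 100 ms, checked after S2). Voltage frames are stored
#' from S2 onset (the S1 segment is activation-logged only and cached across
#' calls, so interval scans reuse the conditioning wave).
#'
#' An optional instantaneous conductance switch (`scaling_after` at
#' `t_switch`) supports acute interventions: the state is carried over
#' exactly and only the scaling map changes.
#'
#' @param model A `cell_model` or name.
#' @param scaling A [scaling()] map (applied from t = 0 and to pre-pacing).
#' @param geometry A [tissue_geometry()] with calibrated `D`.
#' @param s1s2_interval S1-to-S2 onset interval in ms.
#' @param duration Total horizon in ms (from S1 onset).
#' @param frame_dt Snapshot stride in ms.
#' @param dt Integration step (default: model tissue step).
#' @param amplitude Stimulus amplitude in pA/pF for both S1 and S2 (default:
#'   twice the model's baseline diastolic threshold).
#' @param scaling_after Optional scaling applied from `t_switch` onward.
#' @param t_switch Switch time in ms (must exceed `s1s2_interval`).
#' @return A `tissue_recording`; `meta` carries `s2_onset`, `s2_nodes`,
#'   `s1s2_interval`, `horizon` and `frames_from`.
#' @export
run_s1s2 <- function(model, scaling = NULL, geometry, s1s2_interval,
                     duration, frame_dt = 5, dt = NULL, amplitude = NULL,
                     scaling_after = NULL, t_switch = NULL) {
  name <- as_model_name(model)
  sc <- as_scaling(scaling)
  stopifnot(s1s2_interval > 0, duration > s1s2_interval)
  if (!is.null(scaling_after)) {
    stopifnot(!is.null(t_switch), t_switch > s1s2_interval,
              t_switch < duration)
  }
  dt <- tissue_dt(name, dt, geometry)
  amp <- if (is.null(amplitude)) tissue_amplitude(name) else amplitude
  s2_nodes <- region_quadrant(geometry)

  s1 <- s1_state_at(name, sc, geometry, s1s2_interval, dt, amp)
  s2_stim <- list(stimulus_region(s2_nodes, onset = s1s2_interval,
                                  amplitude = amp))
  meta <- list(s2_onset = s1s2_interval, s2_nodes = s2_nodes,
               s1s2_interval = s1s2_interval, horizon = duration,
               frames_from = s1s2_interval, amplitude = amp)

  seg_end <- if (is.null(scaling_after)) duration else t_switch
  seg_key <- paste0("s2seg:", name, ":", scaling_key(sc), ":", geometry$nx,
                    ":", geometry$ny, ":", signif(geometry$dx, 12), ":",
                    signif(geometry$D, 12), ":", signif(dt, 12), ":",
                    signif(amp, 12), ":", s1s2_interval, ":", seg_end, ":",
                    frame_dt)
  rec <- the[[seg_key]]
  if (is.null(rec)) {
    rec <- run_tissue(name, sc, geometry, init = s1$state, stimuli = s2_stim,
                      duration = seg_end - s1s2_interval, t0 = s1s2_interval,
                      dt = dt, frame_dt = frame_dt,
                      stop_when_quiescent = TRUE, meta = meta)
    rec$activations <- rbind(s1$activations, rec$activations)
    # memoize only the shared untreated segment of acute interventions (a
    # treated and a control arm branch from the same pre-switch state)
    if (!is.null(scaling_after)) the[[seg_key]] <- rec
  }
  if (is.null(scaling_after) || rec$stopped == "quiescent") {
    if (!is.null(scaling_after) && rec$stopped == "quiescent") {
      rec$meta$note <- "quiescent before t_switch; scaling_after never applied"
    }
    return(rec)
  }

  sc2 <- as_scaling(scaling_after)
  rec2 <- run_tissue(name, sc2, geometry, init = rec$final_state,
                     stimuli = list(), duration = duration - t_switch,
                     t0 = t_switch, dt = dt, frame_dt = frame_dt,
                     stop_when_quiescent = TRUE, meta = meta)
  # the first segment appends a final frame at t_switch which the second
  # segment records again; keep a single copy at the junction
  nt1 <- length(rec$frame_times)
  if (nt1 > 0 && length(rec2$frame_times) > 0 &&
      abs(rec$frame_times[nt1] - rec2$frame_times[1]) < 1e-9) {
    rec$frames <- rec$frames[, , -nt1, drop = FALSE]
    rec$frame_times <- rec$frame_times[-nt1]
  }
  rec2$frames <- array(c(rec$frames, rec2$frames),
                       dim = c(geometry$ny, geometry$nx,
                               length(rec$frame_times) +
                                 length(rec2$frame_times)))
  rec2$frame_times <- c(rec$frame_times, rec2$frame_times)
  rec2$activations <- rbind(rec$activations, rec2$activations)
  rec2$meta$t_switch <- t_switch
  rec2$meta$scaling_after <- as.numeric(sc2)
  rec2$pre_switch <- list(activations = rec$activations, t_end = rec$t_end)
  rec2
}
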
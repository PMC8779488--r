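#' Synthetic test fixtures with ground truth
#'
#' Deterministic generators for every analysis stage, emitting the same
#' objects the simulators produce (an `ap_trace` or a `tissue_recording`)
#' together with their analytic ground truth, so downstream modules can be
#' validated without any simulation:
#' \describe{
#'   \item{triangle_ap}{instantaneous upstroke, linear repolarization over
#'     `fall` ms; ground-truth APD90 = 0.9 `fall`.}
#'   \item{sinusoid_field}{every node oscillates sinusoidally with period
#'     `period`; `phase_field = "uniform"` has no singularities,
#'     `"random"` draws node phases from the seed.}
#'   \item{planar_wave}{a rightward-travelling pulse at `velocity` cm/s;
#'     smooth phase field (no singularities), analytic activation log.}
#'   \item{archimedean_spiral}{rotating spiral(s) around fixed cores with
#'     prescribed chirality; ground-truth singularity locations.}
#'   \item{drifting_spiral}{one spiral whose core drifts along +x at
#'     `velocity` cm/s; ground-truth core track and path length.}
#'   \item{surrogate_reentry}{a real S1S2 run of the fast surrogate cell
#'     that produces a self-terminating reentry; ground truth (termination
#'     time) read off its own activation log.}
#' }
#'
#' @param kind Fixture kind (see above).
#' @param seed Seed for any randomized component (default 0).
#' @param ... Kind-specific parameters (see the generator defaults in the
#'   source; all have working defaults).
#' @return List with `data` (an `ap_trace` or `tissue_recording`) and
#'   `ground_truth` (kind-specific list).
#' @examples
#' fx <- generate_fixture("triangle_ap")
#' fx$ground_truth$apd90
#' @export
generate_fixture <- function(kind = c("triangle_ap", "sinusoid_field",
                                      "planar_wave", "archimedean_spiral",
                                      "drifting_spiral",
                                      "surrogate_reentry"),
                             seed = 0, ...) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
         triangle_ap = fixture_triangle_ap(...),
         sinusoid_field = fixture_sinusoid_field(...),
         planar_wave = fixture_planar_wave(...),
         archimedean_spiral = fixture_archimedean_spiral(...),
         drifting_spiral = fixture_drifting_spiral(...),
         surrogate_reentry = fixture_surrogate_reentry(...))
}

fixture_triangle_ap <- function(fall = 300, v_rest = -80, v_peak = 20,
                                bcl = 1000, t_on = 50, sample_dt = 0.1) {
  tt <- seq(0, bcl, by = sample_dt)
  s <- tt - t_on
  # the onset sample keeps the resting value (pre-upstroke reference); the
  # upstroke is the jump to the next sample
  V <- ifelse(s <= 0 | s > fall, v_rest,
              v_peak - (v_peak - v_rest) * s / fall)
  tr <- structure(list(time = tt, V = V, stim_onsets = t_on,
                       stim_duration = 2, stim_amplitude = NA_real_,
                       final_state = NULL, model = "surrogate",
                       scaling = scaling(), bcl = bcl, n_beats = 1,
                       dt = sample_dt), class = "ap_trace")
  list(data = tr,
       ground_truth = list(apd90 = 0.9 * fall, apd50 = 0.5 * fall,
                           rmp = v_rest, v_peak = v_peak))
}

# assemble a synthetic tissue_recording from V(x_cm, y_cm, t_ms)
synth_recording <- function(vfun, geometry, times,
                            activations = NULL, meta = list()) {
  xs <- (seq_len(geometry$nx) - 1) * geometry$dx
  ys <- (seq_len(geometry$ny) - 1) * geometry$dx
  X <- matrix(xs, nrow = geometry$ny, ncol = geometry$nx, byrow = TRUE)
  Y <- matrix(ys, nrow = geometry$ny, ncol = geometry$nx)
  frames <- array(NA_real_, dim = c(geometry$ny, geometry$nx, length(times)))
  for (j in seq_along(times)) frames[, , j] <- vfun(X, Y, times[j])
  if (is.null(activations)) {
    activations <- data.frame(ix = integer(0), iy = integer(0),
                              x = numeric(0), y = numeric(0), t = numeric(0))
  }
  structure(list(frames = frames, frame_times = times,
                 activations = activations, geometry = geometry,
                 model = "synthetic", scaling = scaling(),
                 dt = NA_real_, frame_dt = times[2] - times[1],
                 t_end = max(times), stopped = "duration",
                 final_state = matrix(as.numeric(frames[, , length(times)]),
                                      nrow = 1),
                 meta = meta), class = "tissue_recording")
}

fixture_sinusoid_field <- function(nx = 40, ny = 40, dx = 0.02,
                                   period = 100, duration = 300, stride = 2,
                                   amp = 30, v0 = -50,
                                   phase_field = c("uniform", "random")) {
  phase_field <- match.arg(phase_field)
  phi <- if (phase_field == "uniform") {
    matrix(0, ny, nx)
  } else {
    matrix(stats::runif(nx * ny, -pi, pi), ny, nx)
  }
  g <- tissue_geometry(nx, ny, dx, D = 1e-3)
  rec <- synth_recording(function(X, Y, t) {
    v0 + amp * sin(2 * pi * t / period + phi)
  }, g, seq(0, duration, by = stride))
  list(data = rec,
       ground_truth = list(period = period, n_singularities = 0))
}

fixture_planar_wave <- function(nx = 60, ny = 40, dx = 0.02, velocity = 50,
                                t0 = 10, duration = 120, stride = 2,
                                v_rest = -80, amp = 100, apd_tau = 60,
                                rise_tau = 0.3) {
  pulse <- function(s) ifelse(s < 0, 0,
                              exp(-s / apd_tau) * (1 - exp(-s / rise_tau)))
  v_ms <- velocity / 1000  # cm/ms
  g <- tissue_geometry(nx, ny, dx, D = 1e-3)
  # analytic -40 mV upward crossing: first s with v_rest + amp*pulse(s) = -40
  ss <- seq(0, 5, by = 1e-4)
  s_star <- ss[which(v_rest + amp * pulse(ss) >= -40)[1]]
  ix <- rep(seq_len(nx), each = ny)
  iy <- rep(seq_len(ny), times = nx)
  acts <- data.frame(ix = ix, iy = iy, x = (ix - 1) * dx, y = (iy - 1) * dx,
                     t = (ix - 1) * dx / v_ms + t0 + s_star)
  acts <- acts[acts$t <= duration, ]
  rec <- synth_recording(function(X, Y, t) {
    v_rest + amp * pulse(t - t0 - X / v_ms)
  }, g, seq(0, duration, by = stride), activations = acts)
  list(data = rec,
       ground_truth = list(cv = velocity, n_singularities = 0,
                           activation_offset = t0 + s_star))
}

spiral_phase <- function(X, Y, cores, wavelength) {
  psi <- 0
  rmin <- Inf
  for (k in seq_len(nrow(cores))) {
    dxk <- X - cores$x[k]
    dyk <- Y - cores$y[k]
    psi <- psi + cores$chirality[k] * atan2(dyk, dxk)
    rmin <- pmin(rmin, sqrt(dxk^2 + dyk^2))
  }
  psi - 2 * pi * rmin / wavelength
}

fixture_archimedean_spiral <- function(nx = 80, ny = 80, dx = 0.02,
                                       cores = NULL, period = 100,
                                       wavelength = 1, duration = 300,
                                       stride = 2, amp = 30, v0 = -50) {
  g <- tissue_geometry(nx, ny, dx, D = 1e-3)
  if (is.null(cores)) {
    cores <- data.frame(x = (nx %/% 2 - 0.5) * dx, y = (ny %/% 2 - 0.5) * dx,
                        chirality = 1)
  }
  rec <- synth_recording(function(X, Y, t) {
    v0 + amp * cos(spiral_phase(X, Y, cores, wavelength) - 2 * pi * t / period)
  }, g, seq(0, duration, by = stride))
  list(data = rec, ground_truth = list(cores = cores, period = period))
}

fixture_drifting_spiral <- function(nx = 80, ny = 80, dx = 0.05,
                                    velocity = 1, duration = 3000,
                                    stride = 5, period = 100,
                                    wavelength = 1.5, amp = 30, v0 = -50,
                                    y_core = NULL, x_start = 0.5) {
  g <- tissue_geometry(nx, ny, dx, D = 1e-3)
  if (is.null(y_core)) y_core <- (ny - 1) * dx / 2
  v_ms <- velocity / 1000
  times <- seq(0, duration, by = stride)
  rec <- synth_recording(function(X, Y, t) {
    cores <- data.frame(x = x_start + v_ms * t, y = y_core, chirality = 1)
    v0 + amp * cos(spiral_phase(X, Y, cores, wavelength) - 2 * pi * t / period)
  }, g, times)
  list(data = rec,
       ground_truth = list(
         track = data.frame(t = times, x = x_start + v_ms * times,
                            y = y_core),
         velocity = velocity, path_length = v_ms * duration,
         lifetime = duration, chirality = 1))
}

fixture_surrogate_reentry <- function(apd90 = 140, nx = 60, ny = 60,
                                      dx = 0.05, D = 1e-3,
                                      s1s2_interval = 190, duration = 1500,
                                      frame_dt = 5) {
  surrogate_model(apd90)
  g <- tissue_geometry(nx, ny, dx, D)
  rec <- run_s1s2("surrogate", NULL, g, s1s2_interval = s1s2_interval,
                  duration = duration, frame_dt = frame_dt)
  acts <- rec$activations
  post <- acts[acts$t > s1s2_interval, , drop = FALSE]
  node <- node_index(post$ix, post$iy, ny)
  list(data = rec,
       ground_truth = list(
         termination = if (nrow(post)) max(post$t) else NA_real_,
         reexcited = any(duplicated(node)),
         quiescent = rec$stopped == "quiescent"))
}
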
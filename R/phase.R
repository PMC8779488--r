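#' Phase map of a tissue recording
#'
#' Time-delay phase embedding of the voltage movie:
#' `theta(x, y, t) = atan2(V(t) - V*, V(t - tau) - V*)` with delay `tau`
#' (default 5 ms) and per-node offset `V*` = midpoint of that node's voltage
#' range over the recording. Nodes whose voltage range stays below
#' `min_range` mV are masked (quiescent, phase undefined). The snapshot
#' stride must be uniform and no coarser than 5 ms, with `tau` a multiple of
#' the stride.
#'
#' @param recording A `tissue_recording` (or fixture emitting the same
#'   format) with voltage frames.
#' @param tau Embedding delay in ms.
#' @param min_range Minimal voltage range in mV for phase to be defined.
#' @return A `phase_map`: `theta` array `[ny, nx, time]` (phase in
#'   `(-pi, pi]`, `NA` where masked), `times`, `mask` (`[ny, nx]`, TRUE where
#'   defined) and the geometry.
#' @export
compute_phase <- function(recording, tau = 5, min_range = 5) {
  stopifnot(inherits(recording, "tissue_recording"))
  tt <- recording$frame_times
  if (length(tt) < 3) stop("too few frames for phase embedding")
  strides <- diff(tt)
  stride <- stats::median(strides)
  if (max(abs(strides - stride)) > 1e-6 * max(1, stride)) {
    stop("non-uniform snapshot stride; phase embedding needs a uniform grid")
  }
  if (stride > 5 + 1e-9) {
    stop("snapshot stride ", stride, " ms too coarse for phase embedding; ",
         "a stride <= 5 ms is required")
  }
  # the embedding delay is realized as a whole number of strides
  k <- max(1L, as.integer(round(tau / stride)))
  tau <- k * stride
  fr <- recording$frames
  ny <- dim(fr)[1]; nx <- dim(fr)[2]; nt <- dim(fr)[3]
  if (nt <= k) stop("recording shorter than the embedding delay")
  vmin <- apply(fr, c(1, 2), min)
  vmax <- apply(fr, c(1, 2), max)
  mask <- (vmax - vmin) >= min_range
  vstar <- (vmin + vmax) / 2
  idx <- (k + 1L):nt
  theta <- array(NA_real_, dim = c(ny, nx, length(idx)))
  for (j in seq_along(idx)) {
    th <- atan2(fr[, , idx[j]] - vstar, fr[, , idx[j] - k] - vstar)
    th[!mask] <- NA_real_
    theta[, , j] <- th
  }
  structure(list(theta = theta, times = tt[idx], mask = mask,
                 stride = stride, tau = tau,
                 geometry = recording$geometry), class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat("<phase_map> ", dim(x$theta)[1], " x ", dim(x$theta)[2], " nodes, ",
      length(x$times), " frames (stride ", x$stride, " ms, tau ", x$tau,
      " ms); ", sum(x$mask), " nodes unmasked\n", sep = "")
  invisible(x)
}

wrap_pi <- function(a) a - 2 * pi * round(a / (2 * pi))

#' Detect phase singularities
#'
#' Topological-charge detector: for every 2x2 node plaquette with all four
#' phases defined, the wrapped phase differences around the loop are summed;
#' a winding of +-2pi (tolerance +-0.2 pi) marks a phase singularity at the
#' plaquette center, with the winding sign as chirality.
#'
#' @param phase A [compute_phase()] map.
#' @param t Time in ms (nearest phase frame is used).
#' @return Data frame with `x`, `y` (cm, plaquette centers), `chirality`
#'   (+1/-1) and the plaquette corner indices `ix`, `iy`; zero rows when no
#'   singularity is present.
#' @export
detect_singularities <- function(phase, t) {
  stopifnot(inherits(phase, "phase_map"))
  j <- which.min(abs(phase$times - t))
  th <- phase$theta[, , j]
  ny <- nrow(th); nx <- ncol(th)
  p1 <- th[-ny, -nx]  # (iy, ix)
  p2 <- th[-ny, -1]   # (iy, ix+1)
  p3 <- th[-1, -1]    # (iy+1, ix+1)
  p4 <- th[-1, -nx]   # (iy+1, ix)
  w <- wrap_pi(p2 - p1) + wrap_pi(p3 - p2) + wrap_pi(p4 - p3) + wrap_pi(p1 - p4)
  hit <- which(!is.na(w) & abs(abs(w) - 2 * pi) <= 0.2 * pi, arr.ind = TRUE)
  dx <- phase$geometry$dx
  data.frame(x = (hit[, 2] - 0.5) * dx, y = (hit[, 1] - 0.5) * dx,
             chirality = sign(w[hit]), ix = as.integer(hit[, 2]),
             iy = as.integer(hit[, 1]),
             t = rep(phase$times[j], nrow(hit)))
}

#' Track rotor cores
#'
#' Detects phase singularities on every phase frame up to `t_max` ms after
#' the first frame and links them into trajectories by nearest-neighbor
#' matching: a detection continues a live trajectory of the same chirality
#' if it lies within `link_max` cm per elapsed snapshot stride; trajectories
#' missing for more than `gap` strides are closed.
#'
#' @param recording A `tissue_recording` with frames, or a ready
#'   [compute_phase()] map.
#' @param t_max Tracking horizon in ms from the first phase frame.
#' @param tau,min_range Passed to [compute_phase()].
#' @param link_max Maximal link distance in cm per snapshot stride.
#' @param gap Gap tolerance in strides.
#' @return List of `rotor_trajectory` objects: `points` (data frame `t`,
#'   `x`, `y`), `chirality`, `path_length` (cm), `meander_extent` (cm, max
#'   pairwise core distance), `lifetime` (ms).
#' @export
track_cores <- function(recording, t_max = 3000, tau = 5, min_range = 5,
                        link_max = 0.3, gap = 2) {
  phase <- if (inherits(recording, "phase_map")) recording
           else compute_phase(recording, tau, min_range)
  times <- phase$times
  keep <- times <= times[1] + t_max + 1e-9
  live <- list()    # open trajectories
  done <- list()
  for (j in which(keep)) {
    det <- detect_singularities(phase, times[j])
    claimed <- rep(FALSE, nrow(det))
    for (i in seq_along(live)) {
      tr <- live[[i]]
      lag <- round((times[j] - tr$last_t) / phase$stride)
      if (lag > gap + 1) next
      cand <- which(!claimed & det$chirality == tr$chirality)
      if (!length(cand)) next
      d <- sqrt((det$x[cand] - tr$last_x)^2 + (det$y[cand] - tr$last_y)^2)
      best <- which.min(d)
      if (d[best] <= link_max * lag) {
        ci <- cand[best]
        claimed[ci] <- TRUE
        tr$points <- rbind(tr$points,
                           data.frame(t = times[j], x = det$x[ci],
                                      y = det$y[ci]))
        tr$last_t <- times[j]; tr$last_x <- det$x[ci]; tr$last_y <- det$y[ci]
        live[[i]] <- tr
      }
    }
    # expire stale trajectories
    if (length(live)) {
      stale <- vapply(live, function(tr) {
        round((times[j] - tr$last_t) / phase$stride) > gap
      }, logical(1))
      done <- c(done, live[stale])
      live <- live[!stale]
    }
    # new trajectories from unclaimed detections
    for (ci in which(!claimed)) {
      live[[length(live) + 1L]] <- list(
        points = data.frame(t = times[j], x = det$x[ci], y = det$y[ci]),
        chirality = det$chirality[ci],
        last_t = times[j], last_x = det$x[ci], last_y = det$y[ci])
    }
  }
  done <- c(done, live)
  lapply(done, function(tr) {
    p <- tr$points
    seg <- if (nrow(p) > 1) sum(sqrt(diff(p$x)^2 + diff(p$y)^2)) else 0
    ext <- if (nrow(p) > 1) max(stats::dist(cbind(p$x, p$y))) else 0
    structure(list(points = p, chirality = tr$chirality,
                   path_length = seg, meander_extent = ext,
                   lifetime = max(p$t) - min(p$t)),
              class = "rotor_trajectory")
  })
}

#' @export
print.rotor_trajectory <- function(x, ...) {
  cat("<rotor_trajectory> chirality ", x$chirality, ", ", nrow(x$points),
      " points, lifetime ", round(x$lifetime), " ms, path ",
      signif(x$path_length, 3), " cm, meander ",
      signif(x$meander_extent, 3), " cm\n", sep = "")
  invisible(x)
}
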
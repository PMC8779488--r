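#' Classify the outcome of an S1S2 run
#'
#' Maps a [run_s1s2()] recording to one of four outcome classes:
#' \describe{
#'   \item{NO_CAPTURE}{no propagated activation outside the S2 region after
#'     S2 onset;}
#'   \item{NO_REENTRY}{activity extinguishes with no node activated more than
#'     once after S2 (the S2 primary wave clears without re-excitation);}
#'   \item{TRANSIENT_REENTRY}{re-excitation occurs (some node activates at
#'     least twice after S2 onset) but activity extinguishes before the
#'     horizon; `reentry_duration` = last activation time minus S2 onset;}
#'   \item{STABLE_REENTRY}{reentrant activity persists at the horizon (some
#'     activation falls in the final 200 ms before it).}
#' }
#' Classification is refused when the recording is truncated (it neither
#' reached quiescence nor spans the horizon).
#'
#' @param recording A `tissue_recording` from [run_s1s2()] (its `meta` must
#'   carry `s2_onset` and `s2_nodes`).
#' @param horizon Stability horizon in ms measured from S1 onset (default:
#'   the recording's own horizon; the study convention for stability claims
#'   is 12,000 ms).
#' @return An `s1s2_outcome`: list with `class`, `reentry_duration` (ms; `NA`
#'   for the non-reentry classes), `last_activation` and counts.
#' @export
classify_outcome <- function(recording, horizon = NULL) {
  stopifnot(inherits(recording, "tissue_recording"))
  meta <- recording$meta
  if (is.null(meta$s2_onset) || is.null(meta$s2_nodes)) {
    stop("recording lacks S2 metadata (s2_onset, s2_nodes); ",
         "classification requires an S1S2 recording")
  }
  if (is.null(horizon)) horizon <- meta$horizon
  if (is.null(horizon)) stop("no horizon available")
  if (recording$stopped != "quiescent" && recording$t_end < horizon - 1e-6) {
    stop("truncated recording: neither quiescent nor spanning the ",
         horizon, " ms horizon (t_end = ", round(recording$t_end, 1),
         " ms); classification refused")
  }
  acts <- recording$activations
  ny <- recording$geometry$ny
  post <- acts[acts$t > meta$s2_onset + 1e-9, , drop = FALSE]
  node <- node_index(post$ix, post$iy, ny)
  outside <- !(node %in% meta$s2_nodes)

  res <- function(class, dur) {
    structure(list(class = class, reentry_duration = dur,
                   s2_onset = meta$s2_onset, horizon = horizon,
                   last_activation = if (nrow(post)) max(post$t) else NA_real_,
                   n_post_s2_activations = nrow(post),
                   stopped = recording$stopped, t_end = recording$t_end),
              class = "s1s2_outcome")
  }
  if (!any(outside)) return(res("NO_CAPTURE", NA_real_))
  reexcited <- any(duplicated(node))
  if (!reexcited) return(res("NO_REENTRY", NA_real_))
  stable <- recording$t_end >= horizon - 1e-6 &&
    any(post$t >= horizon - 200)
  if (stable) return(res("STABLE_REENTRY", horizon - meta$s2_onset))
  res("TRANSIENT_REENTRY", max(post$t) - meta$s2_onset)
}

#' @export
print.s1s2_outcome <- function(x, ...) {
  cat("<s1s2_outcome> ", x$class,
      if (!is.na(x$reentry_duration)) {
        paste0(" (reentry duration ", round(x$reentry_duration), " ms)")
      } else "",
      "; horizon ", x$horizon, " ms\n", sep = "")
  invisible(x)
}

#' Vulnerable-window scan
#'
#' Runs [run_s1s2()] once per coupling interval and classifies each outcome.
#' The window size is the span from the smallest to the largest interval with
#' a reentry-class outcome (0 if none); the per-interval reentry durations
#' profile stability across the window. Runs are independent; per-interval
#' simulation failures are recorded in the `error` column rather than
#' dropped.
#'
#' @param model A `cell_model` or name.
#' @param scaling A [scaling()] map.
#' @param geometry A [tissue_geometry()] with calibrated `D`.
#' @param intervals Strictly increasing S1S2 intervals in ms.
#' @param horizon Run horizon in ms from S1 onset.
#' @param frame_dt Snapshot stride in ms.
#' @param dt Integration step.
#' @param amplitude Stimulus amplitude override (pA/pF).
#' @return A `vulnerable_window`: list with `records` (data frame: interval,
#'   outcome, reentry_duration, error), `window_start`, `window_end`, `size`.
#' @export
scan_vulnerable_window <- function(model, scaling = NULL, geometry,
                                   intervals, horizon = 3000, frame_dt = 25,
                                   dt = NULL, amplitude = NULL) {
  stopifnot(length(intervals) >= 1, !is.unsorted(intervals, strictly = TRUE))
  rows <- lapply(intervals, function(ci) {
    tryCatch({
      rec <- run_s1s2(model, scaling, geometry, s1s2_interval = ci,
                      duration = horizon, frame_dt = frame_dt, dt = dt,
                      amplitude = amplitude)
      out <- classify_outcome(rec, horizon)
      data.frame(interval = ci, outcome = out$class,
                 reentry_duration = out$reentry_duration,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(interval = ci, outcome = NA_character_,
                 reentry_duration = NA_real_,
                 error = conditionMessage(e))
    })
  })
  records <- do.call(rbind, rows)
  reent <- records$interval[!is.na(records$outcome) &
                              records$outcome %in%
                                c("TRANSIENT_REENTRY", "STABLE_REENTRY")]
  structure(list(records = records,
                 window_start = if (length(reent)) min(reent) else NA_real_,
                 window_end = if (length(reent)) max(reent) else NA_real_,
                 size = if (length(reent)) max(reent) - min(reent) else 0,
                 horizon = horizon),
            class = "vulnerable_window")
}

#' @export
print.vulnerable_window <- function(x, ...) {
  cat("<vulnerable_window> size ", x$size, " ms",
      if (x$size > 0 || !is.na(x$window_start)) {
        paste0(" [", x$window_start, ", ", x$window_end, "]")
      } else "", "; horizon ", x$horizon, " ms\n", sep = "")
  print(x$records, row.names = FALSE)
  invisible(x)
}
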
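#' Persist a tissue recording
#'
#' Writes a `tissue_recording` as a plain-text directory: `meta.yaml` (model,
#' scaling, geometry, solver settings, stop status and protocol metadata),
#' `frames.csv` (one row per snapshot: time then one column per node in
#' solver order), `activations.csv` (`ix`, `iy`, `x`, `y`, `t`) and
#' `final_state.csv` (state variables x nodes). [read_recording()] restores
#' an equivalent object, so analyses can run on stored recordings and on
#' fixtures indistinguishably from fresh simulations.
#'
#' @param recording A `tissue_recording`.
#' @param dir Target directory (created; must not already contain a
#'   recording unless `overwrite`).
#' @param overwrite Replace an existing recording.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir, overwrite = FALSE) {
  stopifnot(inherits(recording, "tissue_recording"))
  if (file.exists(file.path(dir, "meta.yaml")) && !overwrite) {
    stop("recording already exists at ", dir, " (set overwrite = TRUE)")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- recording$geometry
  meta <- list(
    format = "atriawave_recording_v1",
    model = recording$model,
    scaling = as.list(unclass(recording$scaling)),
    geometry = list(nx = g$nx, ny = g$ny, dx = g$dx, D = g$D),
    dt = recording$dt, frame_dt = recording$frame_dt,
    t_end = recording$t_end, stopped = recording$stopped,
    meta = recording$meta)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"), precision = 15)
  nt <- length(recording$frame_times)
  fr <- matrix(recording$frames, nrow = g$nx * g$ny * (nt > 0), ncol = nt)
  utils::write.csv(
    cbind(data.frame(time = recording$frame_times),
          as.data.frame(t(fr))),
    file.path(dir, "frames.csv"), row.names = FALSE)
  utils::write.csv(recording$activations, file.path(dir, "activations.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(recording$final_state),
                   file.path(dir, "final_state.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a stored tissue recording
#'
#' @param dir Directory written by [write_recording()].
#' @return A `tissue_recording`.
#' @export
read_recording <- function(dir) {
  mf <- file.path(dir, "meta.yaml")
  if (!file.exists(mf)) stop("no recording at ", dir, " (meta.yaml missing)")
  meta <- yaml::read_yaml(mf)
  if (!identical(meta$format, "atriawave_recording_v1")) {
    stop("unrecognized recording format in ", mf)
  }
  g <- tissue_geometry(meta$geometry$nx, meta$geometry$ny,
                       meta$geometry$dx, meta$geometry$D)
  fr <- utils::read.csv(file.path(dir, "frames.csv"))
  times <- fr$time
  frames <- if (length(times) > 0) {
    array(t(as.matrix(fr[, -1, drop = FALSE])),
          dim = c(g$ny, g$nx, length(times)))
  } else {
    array(numeric(0), dim = c(g$ny, g$nx, 0))
  }
  acts <- utils::read.csv(file.path(dir, "activations.csv"))
  fin <- as.matrix(utils::read.csv(file.path(dir, "final_state.csv")))
  dimnames(fin) <- NULL
  rmeta <- meta$meta
  if (!is.null(rmeta$s2_nodes)) rmeta$s2_nodes <- as.integer(rmeta$s2_nodes)
  structure(list(frames = frames, frame_times = as.numeric(times),
                 activations = acts, geometry = g, model = meta$model,
                 scaling = as_scaling(unlist(meta$scaling)),
                 dt = meta$dt, frame_dt = meta$frame_dt,
                 t_end = meta$t_end, stopped = meta$stopped,
                 final_state = fin, meta = rmeta),
            class = "tissue_recording")
}
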
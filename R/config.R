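#' Run configuration
#'
#' A run is fully described by a YAML-serializable configuration: model,
#' conductance scaling, a protocol block (single-cell pacing or the tissue
#' S1S2 protocol), geometry and solver settings, and output paths. A stored
#' configuration plus the package version reproduce the run exactly (the
#' whole pipeline is deterministic). Unknown keys are rejected and all
#' violations are reported at once.
#'
#' Schema (top-level keys):
#' \describe{
#'   \item{model}{one of [list_models()] (required).}
#'   \item{scaling}{named map of multipliers over [CURRENT_IDS] (optional).}
#'   \item{protocol}{list with `kind` = `"pace0d"` (`bcl`, `n_beats`,
#'     `stim_duration`, `stim_amplitude`, `record_last_n`) or `"s1s2"`
#'     (`s1s2_interval`, `duration`, `frame_dt`) (required).}
#'   \item{geometry}{`nx`, `ny`, `dx`, `D` (required for `"s1s2"`).}
#'   \item{solver}{`dt`, `sample_dt` (optional).}
#'   \item{output}{`dir` (optional).}
#'   \item{provenance}{added automatically on load: package version and a
#'     configuration hash.}
#' }
#'
#' @param path YAML file path.
#' @return A validated `run_config` list with a `provenance` block.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

known_keys <- list(
  top = c("model", "scaling", "protocol", "geometry", "solver", "output",
          "provenance"),
  protocol_pace0d = c("kind", "bcl", "n_beats", "stim_duration",
                      "stim_amplitude", "record_last_n"),
  protocol_s1s2 = c("kind", "s1s2_interval", "duration", "frame_dt"),
  geometry = c("nx", "ny", "dx", "D"),
  solver = c("dt", "sample_dt"),
  output = c("dir"))

#' @rdname read_run_config
#' @param cfg A configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  errs <- character(0)
  add <- function(...) errs <<- c(errs, paste0(...))
  if (!is.list(cfg)) {
    stop("configuration must be a mapping (named list)")
  }
  unknown <- setdiff(names(cfg), known_keys$top)
  if (length(unknown)) add("unknown top-level key(s): ",
                           paste(unknown, collapse = ", "))
  if (is.null(cfg$model)) {
    add("missing required key: model")
  } else if (!is.character(cfg$model) || !cfg$model %in% list_models()) {
    add("model must be one of: ", paste(list_models(), collapse = ", "))
  }
  if (!is.null(cfg$scaling)) {
    bad <- setdiff(names(cfg$scaling), CURRENT_IDS)
    if (length(bad) || is.null(names(cfg$scaling))) {
      add("scaling keys must be among: ", paste(CURRENT_IDS, collapse = ", "))
    }
    vals <- suppressWarnings(as.numeric(unlist(cfg$scaling)))
    if (any(!is.finite(vals) | vals < 0)) {
      add("scaling multipliers must be finite and >= 0")
    }
  }
  kind <- NULL
  if (is.null(cfg$protocol) || !is.list(cfg$protocol)) {
    add("missing required block: protocol (with kind: pace0d | s1s2)")
  } else {
    kind <- cfg$protocol$kind
    if (is.null(kind) || !kind %in% c("pace0d", "s1s2")) {
      add("protocol$kind must be \"pace0d\" or \"s1s2\"")
      kind <- NULL
    } else {
      allowed <- known_keys[[paste0("protocol_", kind)]]
      unknown <- setdiff(names(cfg$protocol), allowed)
      if (length(unknown)) add("unknown protocol key(s) for ", kind, ": ",
                               paste(unknown, collapse = ", "))
      if (kind == "s1s2") {
        for (k in c("s1s2_interval", "duration")) {
          if (is.null(cfg$protocol[[k]])) add("protocol$", k, " is required")
        }
      }
    }
  }
  if (!is.null(cfg$geometry)) {
    unknown <- setdiff(names(cfg$geometry), known_keys$geometry)
    if (length(unknown)) add("unknown geometry key(s): ",
                             paste(unknown, collapse = ", "))
  } else if (identical(kind, "s1s2")) {
    add("geometry block (nx, ny, dx, D) is required for protocol s1s2")
  }
  for (blk in c("solver", "output")) {
    if (!is.null(cfg[[blk]])) {
      unknown <- setdiff(names(cfg[[blk]]), known_keys[[blk]])
      if (length(unknown)) add("unknown ", blk, " key(s): ",
                               paste(unknown, collapse = ", "))
    }
  }
  if (length(errs)) {
    stop("invalid run configuration:\n", paste0("  - ", errs, collapse = "\n"))
  }
  cfg$provenance <- list(
    package = as.character(utils::packageVersion("atriawave")),
    config_hash = config_hash(cfg[setdiff(names(cfg), "provenance")]))
  structure(cfg, class = "run_config")
}

# stable polynomial hash of the canonical (deparsed) configuration; double
# arithmetic keeps every intermediate exactly representable
config_hash <- function(x) {
  s <- paste(deparse(x[order(names(x))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Execute a run configuration
#'
#' Dispatches a validated [read_run_config()] configuration: `pace0d` runs
#' the pacing protocol and returns the final-beat biomarkers (plus the
#' trace); `s1s2` runs the induction protocol and returns the recording and
#' its classified outcome. When `cfg$output$dir` is set, results are written
#' there (biomarkers as CSV, recordings via [write_recording()], plus a
#' timestamped `run.log` with the configuration hash).
#'
#' @param cfg A `run_config`.
#' @return Result list (protocol dependent).
#' @export
execute_run_config <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  sc <- if (is.null(cfg$scaling)) scaling() else
    do.call(scaling, lapply(cfg$scaling, as.numeric))
  p <- cfg$protocol
  out_dir <- cfg$output$dir
  log_line <- function(...) {
    if (is.null(out_dir)) return(invisible())
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...,
        "\n", sep = "", file = file.path(out_dir, "run.log"), append = TRUE)
  }
  log_line("start model=", cfg$model, " kind=", p$kind,
           " config_hash=", cfg$provenance$config_hash)
  if (p$kind == "pace0d") {
    proto <- pacing_protocol(
      bcl = p$bcl %||% 1000, n_beats = p$n_beats %||% 100,
      stim_amplitude = p$stim_amplitude,
      stim_duration = p$stim_duration %||% 2,
      record_last_n = p$record_last_n %||% 2)
    tr <- pace(cfg$model, sc, proto, dt = cfg$solver$dt,
               sample_dt = cfg$solver$sample_dt %||% 0.05)
    bio <- measure_biomarkers(tr)
    if (!is.null(out_dir)) {
      utils::write.csv(bio, file.path(out_dir, "biomarkers.csv"),
                       row.names = FALSE)
    }
    log_line("done apd90=", signif(bio$apd90, 6))
    list(trace = tr, biomarkers = bio)
  } else {
    g <- tissue_geometry(cfg$geometry$nx, cfg$geometry$ny,
                         cfg$geometry$dx, cfg$geometry$D)
    rec <- run_s1s2(cfg$model, sc, g, s1s2_interval = p$s1s2_interval,
                    duration = p$duration, frame_dt = p$frame_dt %||% 5,
                    dt = cfg$solver$dt)
    out <- classify_outcome(rec, p$duration)
    if (!is.null(out_dir)) {
      write_recording(rec, file.path(out_dir, "recording"), overwrite = TRUE)
    }
    log_line("done outcome=", out$class)
    list(recording = rec, outcome = out)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
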
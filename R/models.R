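#' Scalable transmembrane currents
#'
#' The nine currents whose maximum conductance (or, for the NCX exchanger and
#' the Na/K pump, whole-flux magnitude) can be rescaled in every cell model:
#' fast sodium (INa), transient-outward potassium (Ito), L-type calcium
#' (ICaL), ultra-rapid (IKur), rapid (IKr) and slow (IKs) delayed-rectifier
#' potassium, inward-rectifier potassium (IK1), sodium-calcium exchange
#' (INCX) and the sodium-potassium pump (INaK).
#'
#' @format A character vector of nine current identifiers.
#' @export
CURRENT_IDS <- c("INa", "Ito", "ICaL", "IKur", "IKr", "IKs", "IK1", "INCX", "INaK")

#' Available cell models
#' @return Character vector of model names accepted by [cell_model()].
#' @export
list_models <- function() c("courtemanche", "grandi", "surrogate")

#' Cell model definition
#'
#' Returns the definition of one of the packaged excitable-cell models:
#' `"courtemanche"` (Courtemanche-1998 human atrial myocyte, 21 states),
#' `"grandi"` (Grandi-2011 human atrial myocyte, sinus-rhythm
#' parameterization, 38 states, intracellular K+ clamped at 120 mM as in the
#' published code) or `"surrogate"` (a two-variable activator-recovery cell
#' used to exercise tissue-level machinery quickly; it is *not* one of the
#' atrial ionic models and approximates an action potential only
#' qualitatively).
#'
#' All models share one right-hand-side contract: voltage in mV, time in ms,
#' concentrations in mM, currents in pA/pF, and a nine-entry conductance
#' scaling (see [scaling()]). A positive stimulus current depolarizes.
#'
#' @param name Model name, one of [list_models()].
#' @return An object of class `cell_model`: a list with the state layout,
#'   default initial state, current names and solver defaults.
#' @examples
#' m <- cell_model("courtemanche")
#' m$state_names
#' @export
cell_model <- function(name = c("courtemanche", "grandi", "surrogate")) {
  name <- match.arg(name)
  info <- .model_info(name)
  names(info$init_state) <- info$state_names
  structure(info, class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model> ", x$name, ": ", x$n_state, " states, dt = ",
      x$default_dt, " ms\n", sep = "")
  invisible(x)
}

as_model_name <- function(model) {
  if (inherits(model, "cell_model")) model$name
  else match.arg(model, list_models())
}

#' Conductance scaling
#'
#' A map from current identifier to a dimensionless multiplier (>= 0) applied
#' to that current's maximum conductance (or whole-flux magnitude for INCX
#' and INaK). A multiplier of 1 is the published baseline, 0 a full block.
#' Two scalings compose element-wise (see `*.conductance_scaling`).
#'
#' @param ... Named multipliers among [CURRENT_IDS]; unnamed currents stay 1.
#' @return A named numeric vector of class `conductance_scaling`.
#' @examples
#' scaling(Ito = 0.5)          # 50% Ito block
#' scaling() * scaling(IK1 = 3) # composition = element-wise product
#' @export
scaling <- function(...) {
  vals <- c(...)
  out <- setNames(rep(1, length(CURRENT_IDS)), CURRENT_IDS)
  if (length(vals)) {
    if (is.null(names(vals)) || any(!names(vals) %in% CURRENT_IDS)) {
      stop("scaling entries must be named after one of: ",
           paste(CURRENT_IDS, collapse = ", "))
    }
    if (any(!is.finite(vals) | vals < 0)) {
      stop("scaling multipliers must be finite and >= 0")
    }
    out[names(vals)] <- vals
  }
  structure(out, class = "conductance_scaling")
}

as_scaling <- function(x) {
  if (is.null(x)) return(scaling())
  if (inherits(x, "conductance_scaling")) return(x)
  if (is.numeric(x) && !is.null(names(x))) return(do.call(scaling, as.list(x)))
  stop("expected a conductance_scaling (see scaling())")
}

#' @export
`*.conductance_scaling` <- function(e1, e2) {
  out <- unclass(as_scaling(e1)) * unclass(as_scaling(e2))
  structure(out, class = "conductance_scaling")
}

#' @export
print.conductance_scaling <- function(x, ...) {
  cat("<conductance_scaling>\n")
  print(unclass(x))
  invisible(x)
}

#' Chronic-AF electrical remodeling variant
#'
#' Composes a scaling with the chronic atrial fibrillation remodeling set
#' used for the Courtemanche model: INa x0.90, Ito x0.20, ICaL x0.50,
#' IKur x0.45, IKs x2.0, IK1 x2.0, INCX x1.4 (IKr and INaK unchanged).
#'
#' @param base Scaling to compose with (default: all ones).
#' @return A `conductance_scaling`.
#' @examples
#' af_scaling()
#' @export
af_scaling <- function(base = scaling()) {
  as_scaling(base) * scaling(INa = 0.90, Ito = 0.20, ICaL = 0.50,
                             IKur = 0.45, IKs = 2.0, IK1 = 2.0, INCX = 1.4)
}

#' Evaluate the model right-hand side
#'
#' Time derivatives of all state variables (units per ms) at a given state,
#' with each scalable current multiplied by its scaling entry before summation
#' into dV/dt. Errors if any derivative is non-finite, naming the offending
#' state.
#'
#' @param model A `cell_model` or model name.
#' @param state Numeric state vector (model ordering).
#' @param scaling A [scaling()] map.
#' @param i_stim Stimulus current in pA/pF (positive depolarizes).
#' @return Named numeric vector of derivatives.
#' @export
cell_rhs <- function(model, state, scaling = NULL, i_stim = 0) {
  .cell_rhs(as_model_name(model), as.numeric(state),
            as.numeric(as_scaling(scaling)), i_stim)
}

#' Instantaneous membrane currents
#'
#' Named vector of membrane currents (pA/pF) at a frozen state, after
#' conductance scaling. Useful to verify scaling behavior (a zero multiplier
#' zeroes its current; doubling a multiplier doubles its current).
#'
#' @inheritParams cell_rhs
#' @return Named numeric vector of currents.
#' @export
cell_currents <- function(model, state, scaling = NULL) {
  .cell_currents(as_model_name(model), as.numeric(state),
                 as.numeric(as_scaling(scaling)))
}

#' Surrogate excitable model
#'
#' Returns the two-variable activator-recovery surrogate cell, re-tuned so
#' that its measured steady-pacing APD90 equals `apd90` ms. The closed-form
#' estimate APD ~ tau_close * log(tau_out / (4 tau_in)) only seeds the
#' search; the recovery time constant is then calibrated numerically against
#' the package's own biomarker convention (bisection on a short 1 Hz pace,
#' cached per target). The surrogate exposes the inward flux under the "INa"
#' multiplier and the outward flux under "IKr"; the remaining
#' scalable-current identifiers are accepted as no-ops.
#'
#' Re-tuning invalidates any cached surrogate thresholds and pre-paced
#' states, which are recomputed on demand.
#'
#' @param apd90 Target action potential duration in ms (default 210 ms).
#' @return A `cell_model`.
#' @export
surrogate_model <- function(apd90 = 210) {
  stopifnot(is.numeric(apd90), length(apd90) == 1, apd90 > 10)
  key <- paste0("surcal:", signif(apd90, 12))
  tc <- the[[key]]
  if (is.null(tc)) {
    tc <- calibrate_surrogate_tau(apd90)
    the[[key]] <- tc
  }
  set_surrogate_tau(tc)
  cell_model("surrogate")
}

# measured APD90 of the surrogate at a given recovery time constant
surrogate_apd90_at <- function(tc, amp, bcl) {
  .surrogate_tau_close(tc)
  r <- .pace0d("surrogate", as.numeric(scaling()), numeric(0), 5L, bcl,
               amp, 2, -1, 1L, 0.05)
  tr <- structure(list(time = r$time, V = r$V, stim_onsets = r$stim_onsets,
                       stim_duration = 2, model = "surrogate", bcl = bcl),
                  class = "ap_trace")
  measure_biomarkers(tr)$apd90
}

calibrate_surrogate_tau <- function(apd90) {
  bcl <- max(1000, 3 * apd90)
  # a fixed supra-threshold pulse; the excitation threshold is set by the
  # fast inward kinetics and is insensitive to the recovery time constant
  tc0 <- apd90 / log(6 / (4 * 0.3))
  .surrogate_tau_close(tc0)
  amp <- 2 * threshold_bisect("surrogate", 2, 0.02)
  f <- function(tc) surrogate_apd90_at(tc, amp, bcl) - apd90
  lo <- tc0 / 4
  hi <- tc0 * 2
  while (f(hi) < 0) hi <- hi * 2
  while (f(lo) > 0) lo <- lo / 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-4 * tc0) break
  }
  (lo + hi) / 2
}

# set the recovery time constant, flushing surrogate-derived caches when the
# value actually changes (thresholds, pre-paced states, S1/S2 segments)
set_surrogate_tau <- function(tc) {
  cur <- the[["sur_tau"]]
  if (!is.null(cur) && identical(cur, tc)) return(invisible())
  .surrogate_tau_close(tc)
  stale <- grep("surrogate", ls(the), value = TRUE, fixed = TRUE)
  stale <- setdiff(stale, grep("^surcal:", stale, value = TRUE))
  if (length(stale)) rm(list = stale, envir = the)
  the[["sur_tau"]] <- tc
  invisible()
}
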
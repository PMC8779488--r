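#' Named conductance interventions
#'
#' The intervention set studied against chronic-AF electrical remodeling:
#' \describe{
#'   \item{AF}{the untreated AF remodeling variant ([af_scaling()]);}
#'   \item{AF_recover_Ito}{AF with the Ito remodeling recovered (Ito reset
#'     to 1.0);}
#'   \item{AF_recover_ICaL}{AF with the ICaL remodeling recovered (ICaL
#'     reset to 1.0);}
#'   \item{AF_IKr_block80}{AF with an 80% IKr block (IKr x 0.20), the class
#'     III antiarrhythmic surrogate;}
#'   \item{SR}{the unremodeled baseline (identity scaling).}
#' }
#'
#' @param name One of the names above.
#' @return An `intervention`: list with `name` and `scaling`.
#' @examples
#' build_intervention("AF_IKr_block80")$scaling
#' @export
build_intervention <- function(name = c("AF", "AF_recover_Ito",
                                        "AF_recover_ICaL", "AF_IKr_block80",
                                        "SR")) {
  name <- match.arg(name)
  af <- af_scaling()
  sc <- switch(name,
    AF = af,
    AF_recover_Ito = { af["Ito"] <- 1; af },
    AF_recover_ICaL = { af["ICaL"] <- 1; af },
    AF_IKr_block80 = af * scaling(IKr = 0.20),
    SR = scaling())
  structure(list(name = name, scaling = sc), class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat("<intervention> ", x$name, "\n", sep = "")
  print(unclass(x$scaling))
  invisible(x)
}

#' Run an intervention experiment
#'
#' Applies an intervention to the S1S2 reentry protocol either chronically
#' or acutely:
#' \describe{
#'   \item{chronic}{the intervention scaling is in force throughout — 0D
#'     pre-pacing, S1, S2 and the whole tissue run;}
#'   \item{acute}{the untreated AF substrate runs through pre-pacing, S1, S2
#'     and established reentry; at `t_switch` (default: 1000 ms after S2
#'     onset) the intervention scaling replaces the AF scaling
#'     instantaneously and spatially uniformly, with the tissue state
#'     carried over exactly. The run is refused when the untreated substrate
#'     shows no ongoing reentry at `t_switch` (no reentry to treat).}
#' }
#'
#' @param model A `cell_model` or name.
#' @param spec An [build_intervention()] result (or a name passed to it).
#' @param geometry A [tissue_geometry()] with calibrated `D`.
#' @param s1s2_interval S1-to-S2 onset interval in ms.
#' @param horizon Total horizon in ms from S1 onset.
#' @param timing `"chronic"` or `"acute"`.
#' @param t_switch Acute switch time in ms (default: S2 onset + 1000).
#' @param base Substrate scaling for the acute phase before the switch
#'   (default: the AF variant).
#' @param frame_dt,dt,amplitude Passed to [run_s1s2()].
#' @return List with the `recording` and its classified `outcome`.
#' @export
run_intervention <- function(model, spec, geometry, s1s2_interval,
                             horizon = 3000,
                             timing = c("chronic", "acute"),
                             t_switch = NULL, base = af_scaling(),
                             frame_dt = 5, dt = NULL, amplitude = NULL) {
  timing <- match.arg(timing)
  if (is.character(spec)) spec <- build_intervention(spec)
  stopifnot(inherits(spec, "intervention"))
  if (timing == "chronic") {
    rec <- run_s1s2(model, spec$scaling, geometry, s1s2_interval, horizon,
                    frame_dt = frame_dt, dt = dt, amplitude = amplitude)
  } else {
    if (is.null(t_switch)) t_switch <- s1s2_interval + 1000
    stopifnot(t_switch > s1s2_interval, t_switch < horizon)
    rec <- run_s1s2(model, base, geometry, s1s2_interval, horizon,
                    frame_dt = frame_dt, dt = dt, amplitude = amplitude,
                    scaling_after = spec$scaling, t_switch = t_switch)
    pre <- rec$pre_switch
    treated <- !is.null(pre)
    if (!treated) {
      stop("no reentry to treat: the untreated substrate was quiescent ",
           "before t_switch = ", t_switch, " ms (last activity ",
           round(rec$t_end, 1), " ms)")
    }
    acts <- pre$activations
    post <- acts[acts$t > s1s2_interval + 1e-9, , drop = FALSE]
    node <- node_index(post$ix, post$iy, geometry$ny)
    reexcited <- any(duplicated(node))
    ongoing <- nrow(post) > 0 && max(post$t) >= t_switch - 200
    if (!reexcited || !ongoing) {
      stop("no reentry to treat: the untreated substrate shows ",
           if (!reexcited) "no re-excitation" else "no ongoing activity",
           " at t_switch = ", t_switch, " ms")
    }
  }
  list(recording = rec, outcome = classify_outcome(rec, horizon),
       intervention = spec$name, timing = timing)
}
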
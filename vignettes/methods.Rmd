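---
title: "Methods: models, numerics, and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, numerics, and protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Overview

`atriawave` simulates human atrial electrophysiology across three scales:

1. **Cell (0D):** two ionic models of the human atrial action potential —
   Courtemanche--Ramirez--Nattel (1998) and the Grandi--Pandit--Voigt (2011)
   sinus-rhythm atrial model — plus a two-variable surrogate used to exercise
   tissue machinery cheaply. All models sit behind one right-hand-side
   contract with per-current conductance scaling.
2. **Tissue (2D):** an isotropic monodomain sheet with S1S2 cross-field
   reentry induction, vulnerable-window classification, and rotor-core
   tracking by phase-singularity detection.
3. **Experiment:** conductance-sensitivity scans, conduction-velocity
   calibration, and chronic/acute intervention runs for atrial-fibrillation
   (AF) electrical remodeling, driven by the numbered scripts in `analysis/`.

Everything is deterministic: no random numbers enter any simulation path.

# Ionic models

## Courtemanche-1998

Transcribed from the published model equations (Courtemanche, Ramirez &
Nattel, *Am J Physiol* 1998): 21 state variables (V, Na/K/Ca homeostasis
with SR uptake/release compartments, and the standard gate set), published
parameter values and initial conditions. Intracellular Na+, K+ and Ca2+ are
dynamic.

## Grandi-2011 atrial

Transcribed from the published sinus-rhythm atrial parameterization (Grandi
et al., *Circ Res* 2011): 38 states with subsarcolemmal/junctional Ca and Na
sub-compartments and buffering. As in the published code, intracellular K+
is clamped (120 mM). Our transcription reproduces the model's own dynamics
against an adaptive-step reference integration (below); its quasi-steady
APD90 at 1 Hz comes out a few percent longer than the value commonly quoted
for the model, a known sensitivity of beat-100 APD90 to the Na-state
initialization (about -33 ms per +1 mM initial [Na+]_i). We report what the
transcription produces rather than adjusting initial conditions toward a
published number.

## Surrogate

A two-variable activator--recovery (Mitchell--Schaeffer-type) cell mapped to
a physiological voltage range (V = -80 + 100 u mV). It is plumbing, not an
atrial model: `surrogate_model(apd90)` calibrates the recovery time constant
by bisection against the package's own APD90 convention (accurate to < 0.1
ms), so tissue-level tests can fix an APD by construction. Its inward flux
responds to the `INa` multiplier and its outward flux to `IKr`; other
current identifiers are accepted as no-ops.

## Conductance scaling

Nine currents are scalable everywhere: `INa, Ito, ICaL, IKur, IKr, IKs,
IK1, INCX, INaK` (multipliers on maximum conductance, or maximal flux for
NCX and NaK). `scaling()` builds a map, `compose_scaling()` multiplies
element-wise, and `af_scaling()` is the chronic-AF remodeling variant:
INa 0.90, Ito 0.20, ICaL 0.50, IKur 0.45, IKs 2.0, IK1 2.0, INCX 1.4.

# Numerics

- **0D integration:** fixed-step Rush--Larsen for gating variables (exact
  exponential update toward the voltage-dependent steady state, rate
  constants from lookup tables) and forward Euler for the remaining states.
  Default dt = 0.005 ms for the two ionic models (final-beat APD90 is
  dt-converged well under 1 ms there); the surrogate uses dt = 0.02 ms.
- **Verification:** the same right-hand side is integrated with
  `deSolve::lsoda` (rtol 1e-6, atol 1e-8) for 5 beats from the published
  initial state. Both models agree with the adaptive reference to RMS
  voltage error < 0.05 mV and |ΔAPD90| < 0.5 ms; the test suite asserts the
  looser documented bounds (1 mV, 2 ms).
- **2D monodomain:** operator splitting per step — reaction (the cell
  kernel) then diffusion by an explicit 5-point Laplacian with mirror
  (no-flux) boundaries. The stability bound dt < dx²/(4D) is enforced;
  default steps are dt = 0.02 ms (Courtemanche), 0.005 ms (Grandi), capped
  automatically at 0.9 dx²/(4D).
- **Activation log:** a node activates when V up-crosses -40 mV, re-arming
  only after V falls below -60 mV (hysteresis). Runs can stop early on
  quiescence (all V < -70 mV for 100 ms).

# Protocols and conventions

- **Pacing:** 1 Hz, 100 beats, 2 ms pulse at twice the single-cell
  diastolic threshold (threshold by bisection). Tissue stimuli use four
  times the cellular threshold: under electrotonic load the 0D 2x amplitude
  fails to capture, so the tissue convention is documented as 4x.
- **Biomarkers:** AP onset at maximal dV/dt within 10 ms of the stimulus;
  APD_x to the linearly interpolated downward crossing of
  V_peak − x/100 (V_peak − V_onset), with the pre-upstroke voltage as the
  repolarization reference. Plateau arrest (depolarized, no overshoot) is
  flagged as repolarization failure; a sub-threshold response from rest is
  `no_ap`.
- **CV calibration:** planar wave on a 200 x 15 strip (dx = 0.02 cm),
  sensors at 25% and 75% of strip length, -40 mV crossing times; the scalar
  diffusion coefficient is bisected into the 45--50 cm/s band (square-root
  jump start, then bisection).
- **S1S2 induction:** S1 excites the two leftmost columns at t = 0; S2
  excites the upper-left quadrant at the coupling interval
  (onset-to-onset). Frames are recorded from S2 onset. Outcomes:
  `NO_CAPTURE` (no propagated activation outside the S2 region),
  `NO_REENTRY` (no node re-excited), `TRANSIENT_REENTRY` (duration = last
  activation minus S2 onset), `STABLE_REENTRY` (activity within the final
  200 ms of the horizon). Truncated recordings are refused, not guessed.
- **Phase and rotors:** time-delay phase θ = atan2(V(t) − V*, V(t−τ) − V*)
  with τ = 5 ms and per-node midpoint offset V*, masked where the local V
  range is < 5 mV; snapshot stride must be uniform and ≤ 5 ms. Phase
  singularities are ±2π plaquette windings (tolerance 0.2π); cores are
  linked nearest-neighbor (≤ 0.3 cm per stride, 2-stride gap tolerance)
  into trajectories with path length, meander extent (max pairwise
  distance) and lifetime.

# Scaled-down tissue sizes

Full-size, 12 s reentry runs are cluster work. The package's in-repo
experiments run at reduced scale, chosen so each run costs seconds to a few
minutes on one CPU:

- surrogate sheets: 60 x 60 nodes at dx = 0.05 cm;
- Courtemanche reentry sheets: 100 x 100 nodes at dx = 0.04 cm with the
  coarse-grid CV re-calibrated into the same 45--50 cm/s band;
- horizons of 2--3 s.

Sheet size affects reentry stability, so tissue-level claims are treated as
qualitative orderings at this scale (e.g. AF remodeling and 300% IK1
produce longer-lived reentry than baseline at a matched S1S2 interval), not
as quantitative reproductions.

# Recording format and configs

Tissue recordings persist as a directory: `meta.yaml` (format tag,
geometry, protocol metadata), `frames.csv` (V snapshots),
`activations.csv`, and `final_state.csv`; `read_recording()` reconstructs
an object the analysis functions cannot distinguish from a live simulation.
Runs are also drivable from validated YAML configurations
(`read_run_config()` / `execute_run_config()`), which reject unknown keys,
enumerate all violations at once, and stamp results with a configuration
hash in a timestamped run log.

```{r}
library(atriawave)
b <- measure_biomarkers(pace("courtemanche"))
b$apd90

cal <- calibrate_cv("courtemanche")
cal$cv
```
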
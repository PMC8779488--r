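# atriawave

Multiscale simulation of human atrial electrophysiology and reentry in R:
ionic cell models, a 2D monodomain tissue solver, S1S2 reentry induction,
vulnerable-window classification, rotor tracking, and chronic/acute
conductance-intervention experiments for atrial-fibrillation (AF)
electrical remodeling. Deterministic throughout; no external data needed.

## What's inside

- **Cell models** (`cell_model()`, `pace()`, `measure_biomarkers()`):
  Courtemanche-1998 and Grandi-2011 atrial ionic models behind one
  right-hand-side contract, plus a fast two-variable surrogate with a
  numerically calibrated APD (`surrogate_model()`). Nine currents are
  scalable everywhere (`scaling()`, `af_scaling()`, `compose_scaling()`).
- **0D protocols**: threshold finding, 100-beat 1 Hz pacing, APD/RMP
  biomarkers with explicit failure semantics, and conductance-sensitivity
  scans (`conductance_scan()`).
- **2D tissue** (`run_tissue()`, `run_s1s2()`, `measure_cv()`,
  `calibrate_cv()`): isotropic monodomain sheet (operator splitting,
  Rush-Larsen + Euler, no-flux boundaries), S1S2 cross-field induction,
  conduction-velocity calibration.
- **Vulnerability** (`classify_outcome()`, `scan_vulnerable_window()`):
  NO_CAPTURE / NO_REENTRY / TRANSIENT_REENTRY / STABLE_REENTRY with
  refusal on truncated recordings.
- **Rotor tracking** (`compute_phase()`, `detect_singularities()`,
  `track_cores()`): time-delay phase maps, plaquette topological charge,
  nearest-neighbor core trajectories with meander metrics.
- **Interventions** (`build_intervention()`, `run_intervention()`):
  AF remodeling, Ito/ICaL-remodeling recovery, 80% IKr block; chronic or
  acute (mid-reentry switch).
- **Fixtures** (`generate_fixture()`): analytic APs, spiral/planar phase
  movies and surrogate reentry scenarios that emit their own ground truth.
- **IO** (`write_recording()`/`read_recording()`, `read_run_config()` /
  `execute_run_config()`): on-disk recordings and validated YAML run
  configurations with config-hash provenance logging.

## Quick start

```r
library(atriawave)

# single cell: quasi-steady APD90 at 1 Hz
measure_biomarkers(pace("courtemanche"))$apd90

# tissue: calibrate conduction velocity, then induce reentry
cal <- calibrate_cv("courtemanche")                    # 200 x 15 strip
g   <- tissue_geometry(100, 100, dx = 0.04,
                       D = calibrate_cv("courtemanche", dx = 0.04)$D)
rec <- run_s1s2("courtemanche", af_scaling(), g,
                s1s2_interval = 200, duration = 3000, frame_dt = 25)
classify_outcome(rec, 3000)
```

## Analysis workflow

Numbered drivers under `analysis/` write CSV results under `results/`:

1. `01_cell_scans.R` — baseline/variant biomarkers, 50%-block sensitivity,
   Grandi ICaL repolarization-failure scan.
2. `02_cv_calibration.R` — diffusion-coefficient calibration and dx/dt
   convergence checks.
3. `03_vulnerable_window.R` — surrogate and Courtemanche S1S2 windows
   (`--full` for the full interval grids).
4. `04_rotor_tracking.R` — rotor-core trajectories and meander metrics
   (`--full` adds the Courtemanche rotors).
5. `05_interventions.R` — chronic and acute intervention suite at the
   matched S1S2 interval.

`scripts/acceptance.R --seed 0 --out results.json` recomputes the headline
reproduction numbers from scratch and writes them as JSON.

## Notes

- See `vignettes/methods.Rmd` for models, numerics, conventions, and the
  scaled-down tissue sizes (and why tissue claims are qualitative at this
  scale).
- Tests: `testthat` 3e under `tests/testthat/`; synthetic fixtures make
  every stage testable offline.
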
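Model transcription sources
===========================

courtemanche
  Courtemanche M, Ramirez RJ, Nattel S. Ionic mechanisms underlying human
  atrial action potential properties: insights from a mathematical model.
  Am J Physiol. 1998;275(1 Pt 2):H301-H321.
  Transcribed from the published equations, parameter tables, and initial
  conditions. 21 state variables; dynamic intracellular Na+, K+, Ca2+ with
  SR uptake/release compartments.

grandi
  Grandi E, Pandit SV, Voigt N, et al. Human atrial action potential and
  Ca2+ model: sinus rhythm and chronic atrial fibrillation. Circ Res.
  2011;109(9):1055-1066.
  Sinus-rhythm parameterization, 38 state variables, intracellular K+
  clamped at 120 mM as in the authors' published code. The AF-remodeling
  conductance set used by af_scaling() follows the same publication's
  remodeling description.

surrogate
  Two-variable activator-recovery excitable cell with Mitchell-Schaeffer
  kinetics (Mitchell CC, Schaeffer DG. A two-current model for the dynamics
  of cardiac membrane. Bull Math Biol. 2003;65(5):767-793), mapped onto a
  physiological voltage range. Package plumbing for fast tissue-level
  testing, not a human atrial model; its APD is calibrated numerically by
  surrogate_model().

Verification
  Each ionic model's fixed-step production integrator is cross-checked
  against deSolve::lsoda on the identical right-hand side (5 beats, 1 Hz);
  see the methods vignette and tests/testthat/helper-shared.R.
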
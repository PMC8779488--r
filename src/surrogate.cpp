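// Two-variable activator-recovery excitable cell (Mitchell-Schaeffer kinetics
// mapped onto a physiological voltage range). Not an atrial ionic model: it is
// package plumbing that makes tissue-level machinery testable in seconds, with
// an action potential duration set (approximately) in closed form by
// tau_close and a conduction velocity set by the tissue diffusion coefficient.
//
// u = (V - V0)/Vamp in [0,1]
// du/dt = s_in * h u^2 (1-u)/tau_in - s_out * u/tau_out    (+ stimulus)
// dh/dt = (1-h)/tau_open if u < u_gate else -h/tau_close
// APDmax ~= tau_close * ln(tau_out / (4 tau_in)).
// The inward flux scales with the "INa" multiplier, the outward flux with
// "IKr"; the other seven scalable-current identifiers are accepted no-ops.

#include "cellmodel.h"

namespace msur {
const double V0 = -80.0, Vamp = 100.0;
const double tau_in = 0.3, tau_out = 6.0, tau_open = 120.0;
const double u_gate = 0.13;
}

class Surrogate : public CellModel {
public:
  explicit Surrogate(double tau_close = 130.0) : tau_close_(tau_close) {
    state_names_ = {"V", "h"};
    current_names_ = {"Jin", "Jout"};
    init_ = {msur::V0, 1.0};
  }

  const char* name() const { return "surrogate"; }
  int n_state() const { return 2; }
  int n_gate() const { return 0; }   // h handled explicitly (u-dependent switch)
  int n_aux() const { return 0; }
  const std::vector<std::string>& state_names() const { return state_names_; }
  const std::vector<double>& init_state() const { return init_; }
  const std::vector<std::string>& current_names() const { return current_names_; }
  double default_dt() const { return 0.02; }
  double capture_voltage() const { return -20.0; }
  void set_tau_close(double tc) { tau_close_ = tc; }
  double tau_close() const { return tau_close_; }

  void vdep(double, double, double*) const {}

  void eval(const double*, const double* y, const double* sc,
            double istim, double* dy, double* cur) const {
    using namespace msur;
    double u = (y[0] - V0) / Vamp;
    if (u < 0.0) u = 0.0;
    if (u > 1.5) u = 1.5;
    const double h = y[1];
    const double jin = sc[S_INA] * h * u * u * (1.0 - u) / tau_in;
    const double jout = sc[S_IKR] * u / tau_out;
    dy[0] = Vamp * (jin - jout) + istim;
    dy[1] = u < u_gate ? (1.0 - h) / tau_open : -h / tau_close_;
    if (cur) {
      // report as membrane-current-convention values (pA/pF, outward positive)
      cur[0] = -Vamp * jin;
      cur[1] = Vamp * jout;
    }
  }

  void step(const double*, double* y, const double* sc,
            double istim, double dt) const {
    using namespace msur;
    double dy[2];
    eval(0, y, sc, istim, dy, 0);
    y[0] += dt * dy[0];
    // exponential update of the recovery gate toward its piecewise target
    double u = (y[0] - V0) / Vamp;
    if (u < u_gate) {
      y[1] += (1.0 - y[1]) * -std::expm1(-dt / tau_open);
    } else {
      y[1] *= std::exp(-dt / tau_close_);
    }
    if (y[1] < 0.0) y[1] = 0.0; else if (y[1] > 1.0) y[1] = 1.0;
  }

private:
  std::vector<std::string> state_names_, current_names_;
  std::vector<double> init_;
  double tau_close_;
};

CellModel* make_surrogate() { return new Surrogate(); }

void surrogate_set_tau_close(CellModel* m, double tc) {
  static_cast<Surrogate*>(m)->set_tau_close(tc);
}
double surrogate_get_tau_close(CellModel* m) {
  return static_cast<Surrogate*>(m)->tau_close();
}
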
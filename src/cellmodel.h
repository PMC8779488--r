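#ifndef ATRIAWAVE_CELLMODEL_H
#define ATRIAWAVE_CELLMODEL_H

#include <vector>
#include <string>
#include <cmath>
#include <stdexcept>

// Scalable current multiplier order shared by all models.
// INa, Ito, ICaL, IKur, IKr, IKs, IK1, INCX, INaK
enum ScaleIdx { S_INA = 0, S_ITO, S_ICAL, S_IKUR, S_IKR, S_IKS, S_IK1, S_INCX, S_INAK, N_SCALE };

// Voltage-dependent quantities are evaluated either exactly (reference path,
// used by the plain RHS) or from a per-model lookup table built for a fixed
// time step (production path, used by the pacing and tissue kernels).
//
// vdep() row layout per model: [inf_0..inf_{NG-1} | rt_0..rt_{NG-1} | aux_0..aux_{NA-1}]
// where rt_k is 1-exp(-dt/tau_k) when dt > 0 (Rush-Larsen coefficient) and
// tau_k itself when dt <= 0 (reference path).

class CellModel {
public:
  virtual ~CellModel() {}

  virtual const char* name() const = 0;
  virtual int n_state() const = 0;
  virtual int n_gate() const = 0;          // leading Rush-Larsen gates start at state 1
  virtual int n_aux() const = 0;
  virtual const std::vector<std::string>& state_names() const = 0;
  virtual const std::vector<double>& init_state() const = 0;
  virtual const std::vector<std::string>& current_names() const = 0;
  virtual double default_dt() const = 0;
  // Membrane voltage assumed above which a stimulus has captured the cell.
  virtual double capture_voltage() const { return 0.0; }

  // Exact voltage-dependent row (see layout above).
  virtual void vdep(double V, double dt, double* row) const = 0;

  // Non-gate derivatives and instantaneous currents given a vdep row.
  // dy must have n_state entries; entries for V-tabulated gates are left 0.
  // cur (may be NULL) receives current_names().size() values in pA/pF.
  virtual void eval(const double* row, const double* y, const double* sc,
                    double istim, double* dy, double* cur) const = 0;

  // In-place Rush-Larsen (+ forward Euler) step using a vdep row whose rt
  // entries are RL coefficients for the step size dt.
  virtual void step(const double* row, double* y, const double* sc,
                    double istim, double dt) const = 0;

  // Full reference RHS (gates as (inf-y)/tau), no tables.
  void rhs(const double* y, const double* sc, double istim, double* dy) const {
    std::vector<double> row(2 * n_gate() + n_aux());
    vdep(y[0], -1.0, row.data());
    eval(row.data(), y, sc, istim, dy, 0);
    const double* inf = row.data();
    const double* tau = row.data() + n_gate();
    for (int g = 0; g < n_gate(); ++g) dy[1 + g] = (inf[g] - y[1 + g]) / tau[g];
  }
};

// Voltage lookup table for one (model, dt) pair.
class VTable {
public:
  VTable() : m_(0), dt_(-1), v0_(0), dv_(0), n_(0), ncol_(0) {}

  void build(const CellModel* m, double dt, double v0 = -120.0, double v1 = 80.0,
             double dv = 0.05) {
    m_ = m; dt_ = dt; v0_ = v0; dv_ = dv;
    n_ = (int)std::floor((v1 - v0) / dv) + 1;
    ncol_ = 2 * m->n_gate() + m->n_aux();
    data_.assign((size_t)n_ * ncol_, 0.0);
    for (int i = 0; i < n_; ++i) m->vdep(v0_ + i * dv_, dt, &data_[(size_t)i * ncol_]);
  }

  bool matches(const CellModel* m, double dt) const { return m_ == m && dt_ == dt; }

  // Linear interpolation of the whole row into out (ncol_ doubles).
  inline void lookup(double V, double* out) const {
    double x = (V - v0_) / dv_;
    if (x < 0) x = 0;
    if (x > n_ - 1.000001) x = n_ - 1.000001;
    int i = (int)x;
    double w = x - i;
    const double* a = &data_[(size_t)i * ncol_];
    const double* b = a + ncol_;
    for (int k = 0; k < ncol_; ++k) out[k] = a[k] + w * (b[k] - a[k]);
  }

  int ncol() const { return ncol_; }

private:
  const CellModel* m_;
  double dt_, v0_, dv_;
  int n_, ncol_;
  std::vector<double> data_;
};

CellModel* get_model(const std::string& name);

#endif
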
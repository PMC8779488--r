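// Model registry and the R-facing simulation kernels (single cell + 2D tissue).

#include <Rcpp.h>
#include <map>
#include <memory>
#include "cellmodel.h"

using namespace Rcpp;

CellModel* make_courtemanche();
CellModel* make_grandi();
CellModel* make_surrogate();
void surrogate_set_tau_close(CellModel* m, double tc);
double surrogate_get_tau_close(CellModel* m);

namespace {

struct Entry {
  std::unique_ptr<CellModel> model;
  VTable table;
};

std::map<std::string, Entry>& registry() {
  static std::map<std::string, Entry> reg;
  if (reg.empty()) {
    reg["courtemanche"].model.reset(make_courtemanche());
    reg["grandi"].model.reset(make_grandi());
    reg["surrogate"].model.reset(make_surrogate());
  }
  return reg;
}

Entry& entry(const std::string& name) {
  auto& reg = registry();
  auto it = reg.find(name);
  if (it == reg.end()) stop("unknown cell model '" + name + "'");
  return it->second;
}

const VTable& table_for(const std::string& name, double dt) {
  Entry& e = entry(name);
  if (!e.table.matches(e.model.get(), dt)) e.table.build(e.model.get(), dt);
  return e.table;
}

void check_scale(const NumericVector& sc) {
  if (sc.size() != N_SCALE) stop("scaling vector must have 9 entries");
  for (int i = 0; i < N_SCALE; ++i) {
    if (!R_finite(sc[i]) || sc[i] < 0) stop("scaling multipliers must be finite and >= 0");
  }
}

}  // namespace

CellModel* get_model(const std::string& name) { return entry(name).model.get(); }

// [[Rcpp::export(name = ".model_info")]]
List model_info_cpp(std::string name) {
  CellModel* m = entry(name).model.get();
  return List::create(
      _["name"] = std::string(m->name()),
      _["n_state"] = m->n_state(),
      _["state_names"] = m->state_names(),
      _["init_state"] = m->init_state(),
      _["current_names"] = m->current_names(),
      _["default_dt"] = m->default_dt(),
      _["capture_voltage"] = m->capture_voltage());
}

// [[Rcpp::export(name = ".surrogate_tau_close")]]
double surrogate_tau_close_cpp(double tau_close = -1.0) {
  CellModel* m = entry("surrogate").model.get();
  if (tau_close > 0) surrogate_set_tau_close(m, tau_close);
  return surrogate_get_tau_close(m);
}

// [[Rcpp::export(name = ".cell_rhs")]]
NumericVector cell_rhs_cpp(std::string name, NumericVector y, NumericVector scale,
                           double i_stim = 0.0) {
  CellModel* m = entry(name).model.get();
  check_scale(scale);
  if (y.size() != m->n_state()) stop("state vector has wrong length");
  NumericVector dy(m->n_state());
  m->rhs(REAL(y), REAL(scale), i_stim, REAL(dy));
  for (int i = 0; i < dy.size(); ++i) {
    if (!R_finite(dy[i]))
      stop("non-finite derivative for state '" + m->state_names()[i] + "'");
  }
  dy.attr("names") = m->state_names();
  return dy;
}

// [[Rcpp::export(name = ".cell_currents")]]
NumericVector cell_currents_cpp(std::string name, NumericVector y,
                                NumericVector scale) {
  CellModel* m = entry(name).model.get();
  check_scale(scale);
  if (y.size() != m->n_state()) stop("state vector has wrong length");
  std::vector<double> row(2 * m->n_gate() + m->n_aux());
  m->vdep(y[0], -1.0, row.data());
  std::vector<double> dy(m->n_state());
  NumericVector cur(m->current_names().size());
  m->eval(row.data(), REAL(y), REAL(scale), 0.0, dy.data(), REAL(cur));
  cur.attr("names") = m->current_names();
  return cur;
}

// Single-cell pacing with a rectangular stimulus train.
// Records V on a uniform sample grid over the last `record_last_n` beats.
// [[Rcpp::export(name = ".pace0d")]]
List pace0d_cpp(std::string name, NumericVector scale, NumericVector y0,
                int n_beats, double bcl, double stim_amp, double stim_dur,
                double dt, int record_last_n, double sample_dt) {
  CellModel* m = entry(name).model.get();
  check_scale(scale);
  if (n_beats < 1) stop("n_beats must be >= 1");
  if (bcl <= stim_dur || stim_dur <= 0) stop("need BCL > stim_duration > 0");
  if (dt <= 0) dt = m->default_dt();
  if (sample_dt < dt) sample_dt = dt;
  if (record_last_n > n_beats) record_last_n = n_beats;

  const VTable& tab = table_for(name, dt);
  std::vector<double> row(std::max(1, tab.ncol()));

  std::vector<double> y(m->n_state());
  if (y0.size() == m->n_state()) {
    std::copy(y0.begin(), y0.end(), y.begin());
  } else if (y0.size() == 0) {
    y = m->init_state();
  } else {
    stop("y0 has wrong length");
  }

  const double t_total = n_beats * bcl;
  const double rec_start = (n_beats - record_last_n) * bcl;
  const long nsteps = (long)std::llround(t_total / dt);
  std::vector<double> ts, vs;
  ts.reserve((size_t)(record_last_n * bcl / sample_dt) + 2);
  vs.reserve(ts.capacity());
  double next_sample = rec_start;
  long check_every = std::max(1L, (long)std::llround(1.0 / dt));

  const double* sc = REAL(scale);
  for (long i = 0; i < nsteps; ++i) {
    const double t = i * dt;
    if (t >= next_sample - 1e-9) {
      ts.push_back(t);
      vs.push_back(y[0]);
      next_sample += sample_dt;
    }
    const double tb = t - bcl * std::floor(t / bcl);
    const double istim = (tb < stim_dur) ? stim_amp : 0.0;
    if (tab.ncol() > 0) tab.lookup(y[0], row.data());
    m->step(row.data(), y.data(), sc, istim, dt);
    if (i % check_every == 0 && !R_finite(y[0])) {
      stop("solver divergence at beat %d (t = %.2f ms): non-finite membrane voltage",
           (int)(t / bcl) + 1, t);
    }
  }
  ts.push_back(t_total);
  vs.push_back(y[0]);

  std::vector<double> onsets;
  for (int b = 0; b < n_beats; ++b) {
    double on = b * bcl;
    if (on >= rec_start - 1e-9) onsets.push_back(on);
  }

  NumericVector fin(y.begin(), y.end());
  fin.attr("names") = m->state_names();
  return List::create(_["time"] = ts, _["V"] = vs, _["stim_onsets"] = onsets,
                      _["final_state"] = fin, _["dt"] = dt,
                      _["sample_dt"] = sample_dt, _["bcl"] = bcl,
                      _["n_beats"] = n_beats);
}

// 2D monodomain solver: operator-split reaction (Rush-Larsen / forward Euler)
// and diffusion (5-point Laplacian, mirror boundaries) on a ny x nx lattice.
// Node index = iy + ix*ny (column-major, matching an R matrix V[ny, nx]).
// [[Rcpp::export(name = ".run_tissue")]]
List run_tissue_cpp(std::string name, NumericVector scale, NumericMatrix y0,
                    int nx, int ny, double dx, double D, double dt,
                    double t0, double duration, List stimuli,
                    double frame_dt, double act_threshold, double act_reset,
                    bool stop_when_quiescent, double quiescent_v,
                    double quiescent_ms) {
  CellModel* m = entry(name).model.get();
  check_scale(scale);
  const int ns = m->n_state();
  const int nn = nx * ny;
  if (nx < 3 || ny < 3) stop("tissue must be at least 3 x 3 nodes");
  if (y0.nrow() != ns || y0.ncol() != nn)
    stop("y0 must be n_state x (nx*ny)");
  if (dt <= 0) dt = m->default_dt();
  const double cfl = dx * dx / (4.0 * D);
  if (dt > cfl)
    stop("time step %.4g ms violates the diffusion stability bound %.4g ms "
         "(dx = %.3g cm, D = %.3g cm^2/ms)", dt, cfl, dx, D);

  const VTable& tab = table_for(name, dt);
  std::vector<double> row(std::max(1, tab.ncol()));

  // node-major state copy
  std::vector<double> Y((size_t)nn * ns);
  for (int n = 0; n < nn; ++n)
    for (int s = 0; s < ns; ++s) Y[(size_t)n * ns + s] = y0(s, n);

  // stimuli
  const int nstim = stimuli.size();
  std::vector<std::vector<int>> stim_nodes(nstim);
  std::vector<double> stim_on(nstim), stim_off(nstim), stim_amp(nstim);
  for (int k = 0; k < nstim; ++k) {
    List s = stimuli[k];
    IntegerVector nodes = s["nodes"];  // 0-based
    stim_nodes[k].assign(nodes.begin(), nodes.end());
    for (int id : stim_nodes[k])
      if (id < 0 || id >= nn) stop("stimulus node index out of range");
    stim_on[k] = as<double>(s["onset"]);
    stim_off[k] = stim_on[k] + as<double>(s["duration"]);
    stim_amp[k] = as<double>(s["amplitude"]);
  }
  std::vector<double> istim(nn, 0.0);
  std::vector<char> stim_active(nstim, 0);

  // activation bookkeeping
  std::vector<char> armed(nn);
  for (int n = 0; n < nn; ++n) armed[n] = Y[(size_t)n * ns] < act_reset;
  std::vector<int> act_node;
  std::vector<double> act_time;

  // frames
  const bool record_frames = frame_dt > 0;
  long max_frames = record_frames ? (long)(duration / frame_dt) + 2 : 0;
  std::vector<double> frames;
  std::vector<double> frame_times;
  if (record_frames) frames.reserve((size_t)max_frames * nn);
  double next_frame = t0;

  std::vector<double> Vold(nn), lap(nn);
  const double r = D * dt / (dx * dx);
  const long nsteps = (long)std::llround(duration / dt);
  const long check_every = std::max(1L, (long)std::llround(1.0 / dt));
  double quiet_ms = 0.0;
  std::string stopped = "duration";
  double t_end = t0 + duration;
  const double* sc = REAL(scale);

  for (long i = 0; i < nsteps; ++i) {
    const double t = t0 + i * dt;

    if (record_frames && t >= next_frame - 1e-9) {
      for (int n = 0; n < nn; ++n) frames.push_back(Y[(size_t)n * ns]);
      frame_times.push_back(t);
      next_frame += frame_dt;
    }

    // refresh stimulus field when any stimulus switches state
    bool changed = false;
    for (int k = 0; k < nstim; ++k) {
      char on = (t >= stim_on[k] - 1e-9 && t < stim_off[k] - 1e-9) ? 1 : 0;
      if (on != stim_active[k]) { stim_active[k] = on; changed = true; }
    }
    if (changed) {
      std::fill(istim.begin(), istim.end(), 0.0);
      for (int k = 0; k < nstim; ++k)
        if (stim_active[k])
          for (int id : stim_nodes[k]) istim[id] += stim_amp[k];
    }

    for (int n = 0; n < nn; ++n) Vold[n] = Y[(size_t)n * ns];

    // reaction
    for (int n = 0; n < nn; ++n) {
      double* y = &Y[(size_t)n * ns];
      if (tab.ncol() > 0) tab.lookup(y[0], row.data());
      m->step(row.data(), y, sc, istim[n], dt);
    }

    // diffusion on V with mirror (no-flux) boundaries
    for (int ix = 0; ix < nx; ++ix) {
      const int xm = (ix == 0 ? 1 : ix - 1), xp = (ix == nx - 1 ? nx - 2 : ix + 1);
      for (int iy = 0; iy < ny; ++iy) {
        const int ym = (iy == 0 ? 1 : iy - 1), yp = (iy == ny - 1 ? ny - 2 : iy + 1);
        const int n = iy + ix * ny;
        const double v = Y[(size_t)n * ns];
        lap[n] = Y[(size_t)(ym + ix * ny) * ns] + Y[(size_t)(yp + ix * ny) * ns] +
                 Y[(size_t)(iy + xm * ny) * ns] + Y[(size_t)(iy + xp * ny) * ns] -
                 4.0 * v;
      }
    }
    for (int n = 0; n < nn; ++n) Y[(size_t)n * ns] += r * lap[n];

    // activation detection (linear interpolation of the upward crossing)
    for (int n = 0; n < nn; ++n) {
      const double v = Y[(size_t)n * ns];
      if (armed[n]) {
        if (v >= act_threshold && Vold[n] < act_threshold) {
          const double frac = (act_threshold - Vold[n]) / (v - Vold[n]);
          act_node.push_back(n);
          act_time.push_back(t + frac * dt);
          armed[n] = 0;
        }
      } else if (v < act_reset) {
        armed[n] = 1;
      }
    }

    if (i % check_every == 0) {
      double vmax = -1e300;
      int nmax = 0;
      for (int n = 0; n < nn; ++n) {
        const double v = Y[(size_t)n * ns];
        if (!R_finite(v)) {
          stop("non-finite voltage at node (x = %d, y = %d) at t = %.2f ms",
               n / ny + 1, n % ny + 1, t);
        }
        if (v > vmax) { vmax = v; nmax = n; }
      }
      (void)nmax;
      if (stop_when_quiescent) {
        if (vmax < quiescent_v) quiet_ms += 1.0; else quiet_ms = 0.0;
        if (quiet_ms >= quiescent_ms) {
          stopped = "quiescent";
          t_end = t + dt;
          break;
        }
      }
    }
  }

  if (record_frames && stopped == "duration") {
    // final frame at the end of the run
    for (int n = 0; n < nn; ++n) frames.push_back(Y[(size_t)n * ns]);
    frame_times.push_back(t_end);
  }

  NumericMatrix fin(ns, nn);
  for (int n = 0; n < nn; ++n)
    for (int s = 0; s < ns; ++s) fin(s, n) = Y[(size_t)n * ns + s];

  List out = List::create(
      _["frame_v"] = frames, _["frame_times"] = frame_times,
      _["act_node"] = act_node, _["act_time"] = act_time,
      _["final_state"] = fin, _["t_end"] = t_end, _["stopped"] = stopped,
      _["nx"] = nx, _["ny"] = ny, _["dt"] = dt);
  return out;
}
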
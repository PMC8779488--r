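// Courtemanche-Ramirez-Nattel 1998 human atrial action potential model.
// Transcribed from the original publication; native units (mV, ms, mM, pA/pF).
// The stimulus charge is assigned to K+ so long pacing runs do not drift.

#include "cellmodel.h"

namespace crn {

const double R = 8.3143, T = 310.0, F = 96.4867;
const double RTF = R * T / F;
const double Cm = 100.0;                 // pF
const double Vi = 13668.0;               // um^3
const double Vup = 1109.52, Vrel = 96.48;
const double Ko = 5.4, Nao = 140.0, Cao = 1.8;
const double gNa = 7.8, gK1 = 0.09, gto = 0.1652;
const double gKr = 0.029411765, gKs = 0.12941176, gCaL = 0.12375;
const double gbNa = 0.0006744375, gbCa = 0.001131;
const double INaK_max = 0.59933874, KmNai = 10.0, KmKo = 1.5;
const double INaCa_max = 1600.0, KmNa = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35;
const double IpCa_max = 0.275;
const double Krel = 30.0;
const double Kup_max = 0.005, Kup = 0.00092, Caup_max = 15.0;
const double CMDN_max = 0.05, TRPN_max = 0.07, CSQN_max = 10.0;
const double KmCMDN = 0.00238, KmTRPN = 0.0005, KmCSQN = 0.8;
const double KQ10 = 3.0;

// states: 0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs, 10 d,
//         11 f, 12 w, 13 fca, 14 u, 15 v, 16 Nai, 17 Ki, 18 Cai, 19 Caup, 20 Carel
// V-tabulated gates (RL): states 1..12 (m h j oa oi ua ui xr xs d f w), NG = 12.
// fca, u, v are RL-updated in eval/step from non-voltage arguments.
const int NG = 12, NA = 6;
// aux: 0 ik1_r, 1 ikr_r, 2 gkur, 3 fnak, 4 ncx_e1, 5 ncx_e2

inline double rt_of(double tau, double dt) {
  return dt > 0 ? -std::expm1(-dt / tau) : tau;
}

}  // namespace crn

class Courtemanche : public CellModel {
public:
  Courtemanche() {
    state_names_ = {"V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                    "d", "f", "w", "fca", "u", "v", "Nai", "Ki", "Cai",
                    "Caup", "Carel"};
    current_names_ = {"INa", "Ito", "ICaL", "IKur", "IKr", "IKs", "IK1",
                      "INCX", "INaK", "IbNa", "IbCa", "IpCa"};
    init_ = {-81.18, 2.908e-3, 9.649e-1, 9.775e-1, 3.043e-2, 9.992e-1,
             4.966e-3, 9.986e-1, 3.296e-5, 1.869e-2, 1.367e-4, 9.996e-1,
             9.992e-1, 7.755e-1, 0.0, 1.0, 11.17, 139.0, 1.013e-4,
             1.488, 1.488};
  }

  const char* name() const { return "courtemanche"; }
  int n_state() const { return 21; }
  int n_gate() const { return crn::NG; }
  int n_aux() const { return crn::NA; }
  const std::vector<std::string>& state_names() const { return state_names_; }
  const std::vector<double>& init_state() const { return init_; }
  const std::vector<std::string>& current_names() const { return current_names_; }
  double default_dt() const { return 0.02; }

  void vdep(double V, double dt, double* row) const {
    using namespace crn;
    double* inf = row;
    double* rt = row + NG;
    double* aux = row + 2 * NG;

    // m
    double am = std::fabs(V + 47.13) < 1e-10
                    ? 3.2
                    : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
    double bm = 0.08 * std::exp(-V / 11.0);
    inf[0] = am / (am + bm);
    rt[0] = rt_of(1.0 / (am + bm), dt);
    // h
    double ah, bh;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
      bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    }
    inf[1] = ah / (ah + bh);
    rt[1] = rt_of(1.0 / (ah + bh), dt);
    // j
    double aj, bj;
    if (V >= -40.0) {
      aj = 0.0;
      bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    inf[2] = aj / (aj + bj);
    rt[2] = rt_of(1.0 / (aj + bj), dt);
    // oa / ua share alpha-beta forms
    double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
    double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
    inf[3] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
    rt[3] = rt_of(1.0 / ((aoa + boa) * KQ10), dt);
    // oi
    double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
    double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
    inf[4] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
    rt[4] = rt_of(1.0 / ((aoi + boi) * KQ10), dt);
    // ua
    inf[5] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
    rt[5] = rt_of(1.0 / ((aoa + boa) * KQ10), dt);
    // ui
    double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
    double bui = std::exp((V - 158.0) / 16.0);
    inf[6] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
    rt[6] = rt_of(1.0 / ((aui + bui) * KQ10), dt);
    // xr
    double axr = std::fabs(V + 14.1) < 1e-10
                     ? 0.0015
                     : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
    double bxr = std::fabs(V - 3.3328) < 1e-10
                     ? 7.3898e-5 * 5.1237
                     : 7.3898e-5 * (V - 3.3328) /
                           (std::exp((V - 3.3328) / 5.1237) - 1.0);
    inf[7] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
    rt[7] = rt_of(1.0 / (axr + bxr), dt);
    // xs
    double axs = std::fabs(V - 19.9) < 1e-10
                     ? 6.8e-4
                     : 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
    double bxs = std::fabs(V - 19.9) < 1e-10
                     ? 3.15e-4
                     : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
    inf[8] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
    rt[8] = rt_of(0.5 / (axs + bxs), dt);
    // d
    double taud;
    if (std::fabs(V + 10.0) < 1e-10) {
      taud = 4.579 / (1.0 + std::exp(-(V + 10.0) / 6.24));
    } else {
      double e = std::exp(-(V + 10.0) / 6.24);
      taud = (1.0 - e) / (0.035 * (V + 10.0) * (1.0 + e));
    }
    inf[9] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
    rt[9] = rt_of(taud, dt);
    // f
    double arg = 0.0337 * (V + 10.0);
    double tauf = 9.0 / (0.0197 * std::exp(-arg * arg) + 0.02);
    inf[10] = std::exp(-(V + 28.0) / 6.9) / (1.0 + std::exp(-(V + 28.0) / 6.9));
    rt[10] = rt_of(tauf, dt);
    // w
    double tauw;
    if (std::fabs(V - 7.9) < 1e-10) {
      tauw = 6.0 * 0.2 / 1.3;
    } else {
      double e = std::exp(-(V - 7.9) / 5.0);
      tauw = 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (V - 7.9));
    }
    inf[11] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
    rt[11] = rt_of(tauw, dt);

    // aux
    aux[0] = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));               // IK1 rectification
    aux[1] = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));               // IKr rectification
    aux[2] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));     // gKur(V)
    double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
    double fvrt = F * V / (R * T);
    aux[3] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * fvrt) +
                    0.0365 * sigma * std::exp(-fvrt));                // fNaK
    aux[4] = std::exp(gam * fvrt);                                    // NCX forward
    aux[5] = std::exp((gam - 1.0) * fvrt);                            // NCX reverse
  }

  void eval(const double* row, const double* y, const double* sc,
            double istim, double* dy, double* cur) const {
    using namespace crn;
    const double* aux = row + 2 * NG;
    const double V = y[0], m = y[1], h = y[2], j = y[3], oa = y[4], oi = y[5],
                 ua = y[6], ui = y[7], xr = y[8], xs = y[9], d = y[10],
                 f = y[11], w = y[12], fca = y[13], u = y[14], v = y[15],
                 Nai = y[16], Ki = y[17], Cai = y[18], Caup = y[19],
                 Carel = y[20];

    const double ENa = RTF * std::log(Nao / Nai);
    const double EK = RTF * std::log(Ko / Ki);
    const double ECa = 0.5 * RTF * std::log(Cao / Cai);

    const double INa = sc[S_INA] * gNa * m * m * m * h * j * (V - ENa);
    const double IK1 = sc[S_IK1] * gK1 * (V - EK) * aux[0];
    const double Ito = sc[S_ITO] * gto * oa * oa * oa * oi * (V - EK);
    const double IKur = sc[S_IKUR] * aux[2] * ua * ua * ua * ui * (V - EK);
    const double IKr = sc[S_IKR] * gKr * xr * (V - EK) * aux[1];
    const double IKs = sc[S_IKS] * gKs * xs * xs * (V - EK);
    const double ICaL = sc[S_ICAL] * gCaL * d * f * fca * (V - 65.0);
    const double IpCa = IpCa_max * Cai / (0.0005 + Cai);
    const double INaK = sc[S_INAK] * INaK_max * aux[3] /
                        (1.0 + std::pow(KmNai / Nai, 1.5)) * Ko / (Ko + KmKo);
    const double den = (KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) *
                       (1.0 + ksat * aux[5]);
    const double INaCa = sc[S_INCX] * INaCa_max *
                         (aux[4] * Nai * Nai * Nai * Cao -
                          aux[5] * Nao * Nao * Nao * Cai) / den;
    const double IbNa = gbNa * (V - ENa);
    const double IbCa = gbCa * (V - ECa);

    const double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa +
                        INaK + INaCa + IbNa + IbCa;
    dy[0] = -Iion + istim;

    const double Irel = Krel * u * u * v * w * (Carel - Cai);
    const double Fn = 1e-12 * Vrel * Irel -
                      5e-13 / F * (0.5 * ICaL * Cm - 0.2 * INaCa * Cm);

    const double sig_u = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 1.367e-15));
    const double u_inf = sig_u;
    const double tau_v = 1.91 + 2.09 * sig_u;
    const double v_inf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 1.367e-15));
    const double fca_inf = 1.0 / (1.0 + Cai / 0.00035);

    // fca, u, v derivatives (used by the reference RHS; step() redoes these
    // as exponential updates)
    dy[13] = (fca_inf - fca) / 2.0;
    dy[14] = (u_inf - u) / 8.0;
    dy[15] = (v_inf - v) / tau_v;
    for (int g = 1; g <= 12; ++g) dy[g] = 0.0;

    const double Iup = Kup_max / (1.0 + Kup / Cai);
    const double Iupleak = Kup_max * Caup / Caup_max;
    const double Itr = (Caup - Carel) / 180.0;

    dy[16] = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * Cm / (F * Vi);
    dy[17] = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs + istim) * Cm / (F * Vi);
    const double b1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * Cm / (2.0 * F * Vi) +
                      (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
    const double ct = Cai + KmTRPN, cc = Cai + KmCMDN;
    const double b2 = 1.0 + TRPN_max * KmTRPN / (ct * ct) +
                      CMDN_max * KmCMDN / (cc * cc);
    dy[18] = b1 / b2;
    dy[19] = Iup - Iupleak - Itr * Vrel / Vup;
    const double cs = Carel + KmCSQN;
    dy[20] = (Itr - Irel) / (1.0 + CSQN_max * KmCSQN / (cs * cs));

    if (cur) {
      cur[0] = INa; cur[1] = Ito; cur[2] = ICaL; cur[3] = IKur; cur[4] = IKr;
      cur[5] = IKs; cur[6] = IK1; cur[7] = INaCa; cur[8] = INaK; cur[9] = IbNa;
      cur[10] = IbCa; cur[11] = IpCa;
    }
  }

  void step(const double* row, double* y, const double* sc,
            double istim, double dt) const {
    using namespace crn;
    double dy[21];
    eval(row, y, sc, istim, dy, 0);

    // voltage-tabulated gates: Rush-Larsen with precomputed coefficients
    const double* inf = row;
    const double* rlc = row + NG;
    for (int g = 0; g < NG; ++g) {
      double& gv = y[1 + g];
      gv += (inf[g] - gv) * rlc[g];
      if (gv < 0.0) gv = 0.0; else if (gv > 1.0) gv = 1.0;
    }
    // fca (tau = 2 ms), u (tau = 8 ms), v (Fn-dependent tau): exponential
    // updates from the derivative-form targets computed in eval()
    if (dt != cached_dt_) {
      cached_dt_ = dt;
      rlc2_ = -std::expm1(-dt / 2.0);
      rlc8_ = -std::expm1(-dt / 8.0);
    }
    y[13] += dy[13] * 2.0 * rlc2_;
    y[14] += dy[14] * 8.0 * rlc8_;
    // v: dy[15] = (v_inf - v)/tau_v; forward Euler is adequate (tau >= 1.91)
    y[15] += dt * dy[15];
    if (y[13] < 0.0) y[13] = 0.0; else if (y[13] > 1.0) y[13] = 1.0;
    if (y[14] < 0.0) y[14] = 0.0; else if (y[14] > 1.0) y[14] = 1.0;
    if (y[15] < 0.0) y[15] = 0.0; else if (y[15] > 1.0) y[15] = 1.0;

    y[0] += dt * dy[0];
    for (int k = 16; k < 21; ++k) y[k] += dt * dy[k];
  }

private:
  std::vector<std::string> state_names_, current_names_;
  std::vector<double> init_;
  mutable double cached_dt_ = -1.0, rlc2_ = 0.0, rlc8_ = 0.0;
};

CellModel* make_courtemanche() { return new Courtemanche(); }
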
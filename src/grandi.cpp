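// Grandi et al. 2011 human atrial myocyte model, sinus-rhythm parameterization
// (no isoproterenol, no built-in AF switch: chronic-AF remodeling is applied
// externally through the conductance-scaling interface). Ki is held constant at
// 120 mM as in the published code. Native units: mV, ms, mM, A/F.

#include "cellmodel.h"

namespace gpv {

const double Frdy = 96485.0;            // C/mol
const double Rgas = 8314.0;             // J/(kmol K)
const double Temp = 310.0;
const double FoRT = Frdy / (Rgas * Temp);
const double Cmem = 1.10e-10;           // F

// geometry
const double pi = 3.141592653589793;
const double cellLength = 100.0, cellRadius = 10.25;  // um
const double Vcell = pi * cellRadius * cellRadius * cellLength * 1e-15;  // L
const double Vmyo = 0.65 * Vcell, Vsr = 0.035 * Vcell, Vsl = 0.02 * Vcell;
const double Vjunc = 0.0539 * 0.01 * Vcell;
const double Jca_juncsl = 8.2413e-13, Jca_slmyo = 3.7243e-12;  // L/ms
const double Jna_juncsl = 1.8313e-14, Jna_slmyo = 1.6386e-12;
const double Fjunc = 0.11, Fsl = 1.0 - Fjunc;
const double FjuncCaL = 0.9, FslCaL = 1.0 - FjuncCaL;

// fixed ionic conditions
const double Ko = 5.4, Nao = 140.0, Cao = 1.8, Ki = 120.0;
const double Cli = 15.0, Clo = 150.0, Mgi = 1.0;

// membrane currents
const double GNa = 23.0;
const double GNaB = 0.597e-3;
const double IbarNaK = 1.26, KmNaip = 11.0, KmKo = 1.5;
const double gkr = 0.035;               // * sqrt(Ko/5.4) applied in code
const double gks = 0.0035;
const double gkp = 0.002;
const double GtoFast = 0.165;
const double Gkur = 0.045;
const double gk1 = 0.0525;              // * sqrt(Ko/5.4)
const double GClCa = 0.0548, KdClCa = 100e-3, GClB = 9e-3;
const double pNa = 0.75e-8, pCa = 2.7e-4, pK = 1.35e-7;
const double IbarNCX = 3.15, KmCai = 3.59e-3, KmCao = 1.3, KmNai = 12.29,
             KmNao = 87.5, ksat = 0.27, nu = 0.35, Kdact = 0.384e-3;
const double IbarSLCaP = 0.0471, KmPCa = 0.5e-3;
const double GCaB = 6.0643e-4;

// SR
const double ks_ryr = 25.0, koCa = 10.0, kom = 0.06, kiCa = 0.5, kim = 0.005;
const double ec50SR = 0.45, MaxSR = 15.0, MinSR = 1.0;
const double Vmax_SRCaP = 5.3114e-3, Kmf = 2.5 * 0.246e-3, Kmr = 1.7,
             hillSRCaP = 1.787;
const double leak_coef = 5.348e-6;

// buffering
const double Bmax_Naj = 7.561, Bmax_Nasl = 1.65, koff_na = 1e-3, kon_na = 0.1e-3;
const double Bmax_TnClow = 70e-3, koff_tncl = 19.6e-3, kon_tncl = 32.7;
const double Bmax_TnChigh = 140e-3, koff_tnchca = 0.032e-3, kon_tnchca = 2.37,
             koff_tnchmg = 3.33e-3, kon_tnchmg = 3e-3;
const double Bmax_CaM = 24e-3, koff_cam = 238e-3, kon_cam = 34.0;
const double Bmax_myosin = 140e-3, koff_myoca = 0.46e-3, kon_myoca = 13.8,
             koff_myomg = 0.057e-3, kon_myomg = 0.0157;
const double Bmax_SR = 19.0 * 0.9e-3, koff_sr = 60e-3, kon_sr = 100.0;
const double Bmax_SLlowsl = 37.4e-3 * Vmyo / Vsl,
             Bmax_SLlowj = 4.6e-3 * Vmyo / Vjunc * 0.1,
             Bmax_SLhighsl = 13.4e-3 * Vmyo / Vsl,
             Bmax_SLhighj = 1.65e-3 * Vmyo / Vjunc * 0.1;
const double koff_sll = 1300e-3, kon_sll = 100.0;
const double koff_slh = 30e-3, kon_slh = 100.0;
const double Bmax_Csqn = 140e-3 * Vmyo / Vsr, koff_csqn = 65.0, kon_csqn = 100.0;

const int NG = 11, NA = 12;
// gates (states 1..11): m h j d f xtof ytof xkur ykur xkr xks
// aux: 0 fnak, 1 ncx_e1, 2 ncx_e2, 3 A_Ca, 4 B_Ca, 5 A_K, 6 B_K,
//      7 A_Na, 8 B_Na, 9 ik1v (kiss*(V-ek)), 10 rkr, 11 kp_kp

inline double rt_of(double tau, double dt) {
  return dt > 0 ? -std::expm1(-dt / tau) : tau;
}

}  // namespace gpv

class GrandiAtrial : public CellModel {
public:
  GrandiAtrial() {
    state_names_ = {"V", "m", "h", "j", "d", "f", "xtof", "ytof", "xkur",
                    "ykur", "xkr", "xks", "fcaBj", "fcaBsl", "ryr_r", "ryr_o",
                    "ryr_i", "NaBj", "NaBsl", "TnCL", "TnCHc", "TnCHm", "CaM",
                    "Myoc", "Myom", "SRB", "SLLj", "SLLsl", "SLHj", "SLHsl",
                    "Csqn", "Casr", "Naj", "Nasl", "Nai", "Caj", "Casl", "Cai"};
    current_names_ = {"INa", "Ito", "ICaL", "IKur", "IKr", "IKs", "IK1",
                      "INCX", "INaK", "INaB", "ICaB", "IpCa", "IClCa", "IClB",
                      "IKp", "ICaK", "ICaNa"};
    // Quiescent steady state obtained by long unpaced relaxation of the
    // transcribed equations (see model provenance notes).
    init_ = {-73.4, 1.4e-2, 2.9e-1, 2.7e-1, 1.0e-5, 1.0, 4.0e-3, 9.4e-1,
             2.5e-4, 9.5e-1, 8.0e-3, 1.0e-2, 2.0e-2, 1.4e-2, 8.9e-1, 9e-7,
             2e-7, 3.54, 0.78, 9.5e-3, 1.2e-1, 6.8e-3, 3.4e-4, 2.0e-3,
             1.37e-1, 2.3e-3, 8.5e-3, 1.1e-1, 7.5e-2, 1.3e-1, 1.21, 0.53,
             9.2, 9.2, 9.2, 1.9e-4, 1.2e-4, 1.1e-4};
  }

  const char* name() const { return "grandi"; }
  int n_state() const { return 38; }
  int n_gate() const { return gpv::NG; }
  int n_aux() const { return gpv::NA; }
  const std::vector<std::string>& state_names() const { return state_names_; }
  const std::vector<double>& init_state() const { return init_; }
  void set_init(const std::vector<double>& y) { init_ = y; }
  const std::vector<std::string>& current_names() const { return current_names_; }
  double default_dt() const { return 0.005; }

  void vdep(double V, double dt, double* row) const {
    using namespace gpv;
    double* inf = row;
    double* rt = row + NG;
    double* aux = row + 2 * NG;

    // INa gates
    double sm = 1.0 / (1.0 + std::exp(-(56.86 + V) / 9.03));
    inf[0] = sm * sm;
    double am = (V + 45.79) / 15.54, bm = (V - 4.823) / 51.12;
    rt[0] = rt_of(0.1292 * std::exp(-am * am) + 0.06487 * std::exp(-bm * bm), dt);
    double ah, bh, aj, bj;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
      aj = ((-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
            (V + 37.78)) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    double sh = 1.0 / (1.0 + std::exp((V + 71.55) / 7.43));
    inf[1] = sh * sh;
    rt[1] = rt_of(1.0 / (ah + bh), dt);
    inf[2] = inf[1];
    rt[2] = rt_of(1.0 / (aj + bj), dt);

    // ICaL d, f
    double dss = 1.0 / (1.0 + std::exp(-(V + 9.0) / 6.0));
    double taud;
    if (std::fabs(V + 9.0) < 1e-10) {
      taud = dss * 1.0 / 0.035 / 6.0;
    } else {
      taud = dss * (1.0 - std::exp(-(V + 9.0) / 6.0)) / (0.035 * (V + 9.0));
    }
    inf[3] = dss;
    rt[3] = rt_of(taud, dt);
    double fa = 0.0337 * (V + 25.0);
    inf[4] = 1.0 / (1.0 + std::exp((V + 30.0) / 7.0)) +
             0.2 / (1.0 + std::exp((50.0 - V) / 20.0));
    rt[4] = rt_of(1.0 / (0.0197 * std::exp(-fa * fa) + 0.02), dt);

    // Ito fast
    inf[5] = 1.0 / (1.0 + std::exp(-(V + 1.0) / 11.0));
    rt[5] = rt_of(3.5 * std::exp(-(V / 30.0) * (V / 30.0)) + 1.5, dt);
    inf[6] = 1.0 / (1.0 + std::exp((V + 40.5) / 11.5));
    double ya = (V + 52.45) / 15.8827;
    rt[6] = rt_of(25.635 * std::exp(-ya * ya) + 24.14, dt);

    // IKur
    inf[7] = 1.0 / (1.0 + std::exp(-(V + 6.0) / 8.6));
    rt[7] = rt_of(9.0 / (1.0 + std::exp((V + 5.0) / 12.0)) + 0.5, dt);
    inf[8] = 1.0 / (1.0 + std::exp((V + 7.5) / 10.0));
    rt[8] = rt_of(590.0 / (1.0 + std::exp((V + 60.0) / 10.0)) + 3050.0, dt);

    // IKr xkr
    inf[9] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 5.0));
    double tkr = 550.0 / (1.0 + std::exp((-22.0 - V) / 9.0)) * 6.0 /
                     (1.0 + std::exp((V + 11.0) / 9.0)) +
                 230.0 / (1.0 + std::exp((V + 40.0) / 20.0));
    rt[9] = rt_of(tkr, dt);

    // IKs xks
    inf[10] = 1.0 / (1.0 + std::exp(-(V + 3.8) / 14.25));
    rt[10] = rt_of(990.1 / (1.0 + std::exp(-(V + 2.436) / 14.12)), dt);

    // aux
    double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
    double vfrt = V * FoRT;
    aux[0] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * vfrt) +
                    0.0365 * sigma * std::exp(-vfrt));
    aux[1] = std::exp(nu * vfrt);
    aux[2] = std::exp((nu - 1.0) * vfrt);
    // GHK driving terms; ibar = p * (A * C_in - B), guarded at V = 0
    double e2 = std::exp(2.0 * vfrt), e1 = std::exp(vfrt);
    if (std::fabs(vfrt) >= 1e-6) {
      double f4 = 4.0 * V * Frdy * FoRT;
      aux[3] = f4 * 0.341 * e2 / (e2 - 1.0);
      aux[4] = f4 * 0.341 * Cao / (e2 - 1.0);
      double f1 = V * Frdy * FoRT;
      aux[5] = f1 * 0.75 * e1 / (e1 - 1.0);
      aux[6] = f1 * 0.75 * Ko / (e1 - 1.0);
      aux[7] = f1 * 0.75 * e1 / (e1 - 1.0);
      aux[8] = f1 * 0.75 * Nao / (e1 - 1.0);
    } else {
      // exact V->0 limits: V/(exp(kV)-1) -> 1/k
      double f4 = 4.0 * Frdy * FoRT;
      aux[3] = f4 * 0.341 / (2.0 * FoRT);
      aux[4] = f4 * 0.341 * Cao / (2.0 * FoRT);
      double f1 = Frdy * FoRT;
      aux[5] = f1 * 0.75 / FoRT;
      aux[6] = f1 * 0.75 * Ko / FoRT;
      aux[7] = f1 * 0.75 / FoRT;
      aux[8] = f1 * 0.75 * Nao / FoRT;
    }
    // IK1 voltage factor (ek constant because Ki, Ko are fixed)
    double ek = (1.0 / FoRT) * std::log(Ko / Ki);
    double aki = 1.02 / (1.0 + std::exp(0.2385 * (V - ek - 59.215)));
    double bki = (0.49124 * std::exp(0.08032 * (V + 5.476 - ek)) +
                  std::exp(0.06175 * (V - ek - 594.31))) /
                 (1.0 + std::exp(-0.5143 * (V - ek + 4.753)));
    aux[9] = aki / (aki + bki) * (V - ek);
    aux[10] = 1.0 / (1.0 + std::exp((V + 74.0) / 24.0));
    aux[11] = 1.0 / (1.0 + std::exp(7.488 - V / 5.98));
  }

  void eval(const double* row, const double* y, const double* sc,
            double istim, double* dy, double* cur) const {
    using namespace gpv;
    const double* aux = row + 2 * NG;
    const double V = y[0];
    const double m = y[1], h = y[2], j = y[3], d = y[4], f = y[5];
    const double xtof = y[6], ytof = y[7], xkur = y[8], ykur = y[9];
    const double xkr = y[10], xks = y[11];
    const double fcaBj = y[12], fcaBsl = y[13];
    const double ryr_r = y[14], ryr_o = y[15], ryr_i = y[16];
    const double NaBj = y[17], NaBsl = y[18];
    const double TnCL = y[19], TnCHc = y[20], TnCHm = y[21], CaM = y[22];
    const double Myoc = y[23], Myom = y[24], SRB = y[25];
    const double SLLj = y[26], SLLsl = y[27], SLHj = y[28], SLHsl = y[29];
    const double Csqn = y[30], Casr = y[31];
    const double Naj = y[32], Nasl = y[33], Nai = y[34];
    const double Caj = y[35], Casl = y[36], Cai = y[37];

    const double ena_junc = (1.0 / FoRT) * std::log(Nao / Naj);
    const double ena_sl = (1.0 / FoRT) * std::log(Nao / Nasl);
    const double ek = (1.0 / FoRT) * std::log(Ko / Ki);
    const double eca_junc = (0.5 / FoRT) * std::log(Cao / Caj);
    const double eca_sl = (0.5 / FoRT) * std::log(Cao / Casl);
    const double ecl = (1.0 / FoRT) * std::log(Cli / Clo);

    // INa
    const double gate_na = m * m * m * h * j;
    const double INa_junc = sc[S_INA] * Fjunc * GNa * gate_na * (V - ena_junc);
    const double INa_sl = sc[S_INA] * Fsl * GNa * gate_na * (V - ena_sl);

    // background Na
    const double INaB_junc = Fjunc * GNaB * (V - ena_junc);
    const double INaB_sl = Fsl * GNaB * (V - ena_sl);

    // INaK
    const double fnak = aux[0];
    const double kj = KmNaip / Naj, ksl = KmNaip / Nasl;
    const double INaK_junc = sc[S_INAK] * Fjunc * IbarNaK * fnak * Ko /
                             (1.0 + kj * kj * kj * kj) / (Ko + KmKo);
    const double INaK_sl = sc[S_INAK] * Fsl * IbarNaK * fnak * Ko /
                           (1.0 + ksl * ksl * ksl * ksl) / (Ko + KmKo);
    const double INaK = INaK_junc + INaK_sl;

    // IKr, IKs, IKp, Ito, IKur, IK1
    const double IKr = sc[S_IKR] * gkr * std::sqrt(Ko / 5.4) * xkr * aux[10] * (V - ek);
    const double pNaK = 0.01833;
    const double eks = (1.0 / FoRT) *
                       std::log((Ko + pNaK * Nao) / (Ki + pNaK * Nai));
    const double IKs = sc[S_IKS] * gks * xks * xks * (V - eks);
    const double IKp = gkp * aux[11] * (V - ek);
    const double Ito = sc[S_ITO] * GtoFast * xtof * ytof * (V - ek);
    const double IKur = sc[S_IKUR] * Gkur * xkur * ykur * (V - ek);
    const double IK1 = sc[S_IK1] * gk1 * std::sqrt(Ko / 5.4) * aux[9];

    // IClCa, IClB
    const double IClCa = GClCa * (Fjunc / (1.0 + KdClCa / Caj) +
                                  Fsl / (1.0 + KdClCa / Casl)) * (V - ecl);
    const double IClB = GClB * (V - ecl);

    // ICaL (GHK), total open fraction
    const double po = d * f * 0.45;
    const double ibarca_j = sc[S_ICAL] * pCa * (aux[3] * Caj - aux[4]);
    const double ibarca_sl = sc[S_ICAL] * pCa * (aux[3] * Casl - aux[4]);
    const double ibark = sc[S_ICAL] * pK * (aux[5] * Ki - aux[6]);
    const double ibarna_j = sc[S_ICAL] * pNa * (aux[7] * Naj - aux[8]);
    const double ibarna_sl = sc[S_ICAL] * pNa * (aux[7] * Nasl - aux[8]);
    const double ICa_junc = FjuncCaL * ibarca_j * po * (1.0 - fcaBj);
    const double ICa_sl = FslCaL * ibarca_sl * po * (1.0 - fcaBsl);
    const double ICaK = ibark * po *
                        (FjuncCaL * (1.0 - fcaBj) + FslCaL * (1.0 - fcaBsl));
    const double ICaNa_junc = FjuncCaL * ibarna_j * po * (1.0 - fcaBj);
    const double ICaNa_sl = FslCaL * ibarna_sl * po * (1.0 - fcaBsl);

    // INCX
    const double Ka_junc = 1.0 / (1.0 + (Kdact / Caj) * (Kdact / Caj));
    const double Ka_sl = 1.0 / (1.0 + (Kdact / Casl) * (Kdact / Casl));
    const double Naj3 = Naj * Naj * Naj, Nasl3 = Nasl * Nasl * Nasl;
    const double Nao3 = Nao * Nao * Nao;
    const double KmNai3 = KmNai * KmNai * KmNai;
    const double s1j = aux[1] * Naj3 * Cao, s2j = aux[2] * Nao3 * Caj;
    const double s3j = KmCai * Nao3 * (1.0 + Naj3 / KmNai3) +
                       KmNao * KmNao * KmNao * Caj * (1.0 + Caj / KmCai) +
                       KmCao * Naj3 + Naj3 * Cao + Nao3 * Caj;
    const double s1sl = aux[1] * Nasl3 * Cao, s2sl = aux[2] * Nao3 * Casl;
    const double s3sl = KmCai * Nao3 * (1.0 + Nasl3 / KmNai3) +
                        KmNao * KmNao * KmNao * Casl * (1.0 + Casl / KmCai) +
                        KmCao * Nasl3 + Nasl3 * Cao + Nao3 * Casl;
    const double ksat_f = 1.0 + ksat * aux[2];
    const double INCX_junc =
        sc[S_INCX] * Fjunc * IbarNCX * Ka_junc * (s1j - s2j) / s3j / ksat_f;
    const double INCX_sl =
        sc[S_INCX] * Fsl * IbarNCX * Ka_sl * (s1sl - s2sl) / s3sl / ksat_f;

    // IpCa, ICaB
    const double cj16 = std::pow(Caj, 1.6), csl16 = std::pow(Casl, 1.6);
    const double km16 = std::pow(KmPCa, 1.6);
    const double IpCa_junc = Fjunc * IbarSLCaP * cj16 / (km16 + cj16);
    const double IpCa_sl = Fsl * IbarSLCaP * csl16 / (km16 + csl16);
    const double ICaB_junc = Fjunc * GCaB * (V - eca_junc);
    const double ICaB_sl = Fsl * GCaB * (V - eca_sl);

    // SR fluxes
    const double kCaSR =
        MaxSR - (MaxSR - MinSR) / (1.0 + std::pow(ec50SR / Casr, 2.5));
    const double koSRCa = koCa / kCaSR;
    const double kiSRCa = kiCa * kCaSR;
    const double RI = 1.0 - ryr_r - ryr_o - ryr_i;
    dy[14] = kim * RI - kiSRCa * Caj * ryr_r -
             (koSRCa * Caj * Caj * ryr_r - kom * ryr_o);
    dy[15] = koSRCa * Caj * Caj * ryr_r - kom * ryr_o -
             (kiSRCa * Caj * ryr_o - kim * ryr_i);
    dy[16] = kiSRCa * Caj * ryr_o - kim * ryr_i -
             (kom * ryr_i - koSRCa * Caj * Caj * RI);
    const double J_SRCarel = ks_ryr * ryr_o * (Casr - Caj);
    const double hf = std::pow(Cai / Kmf, hillSRCaP);
    const double hr = std::pow(Casr / Kmr, hillSRCaP);
    const double J_serca = Vmax_SRCaP * (hf - hr) / (1.0 + hf + hr);
    const double J_SRleak = leak_coef * (Casr - Caj);

    // Na buffering
    dy[17] = kon_na * Naj * (Bmax_Naj - NaBj) - koff_na * NaBj;
    dy[18] = kon_na * Nasl * (Bmax_Nasl - NaBsl) - koff_na * NaBsl;

    // cytosolic Ca buffers
    dy[19] = kon_tncl * Cai * (Bmax_TnClow - TnCL) - koff_tncl * TnCL;
    dy[20] = kon_tnchca * Cai * (Bmax_TnChigh - TnCHc - TnCHm) -
             koff_tnchca * TnCHc;
    dy[21] = kon_tnchmg * Mgi * (Bmax_TnChigh - TnCHc - TnCHm) -
             koff_tnchmg * TnCHm;
    dy[22] = kon_cam * Cai * (Bmax_CaM - CaM) - koff_cam * CaM;
    dy[23] = kon_myoca * Cai * (Bmax_myosin - Myoc - Myom) - koff_myoca * Myoc;
    dy[24] = kon_myomg * Mgi * (Bmax_myosin - Myoc - Myom) - koff_myomg * Myom;
    dy[25] = kon_sr * Cai * (Bmax_SR - SRB) - koff_sr * SRB;
    const double J_CaB_cytosol =
        dy[19] + dy[20] + dy[21] + dy[22] + dy[23] + dy[24] + dy[25];

    // junctional and SL Ca buffers
    dy[26] = kon_sll * Caj * (Bmax_SLlowj - SLLj) - koff_sll * SLLj;
    dy[27] = kon_sll * Casl * (Bmax_SLlowsl - SLLsl) - koff_sll * SLLsl;
    dy[28] = kon_slh * Caj * (Bmax_SLhighj - SLHj) - koff_slh * SLHj;
    dy[29] = kon_slh * Casl * (Bmax_SLhighsl - SLHsl) - koff_slh * SLHsl;
    const double J_CaB_junction = dy[26] + dy[28];
    const double J_CaB_sl = dy[27] + dy[29];

    // SR Ca and csqn
    dy[30] = kon_csqn * Casr * (Bmax_Csqn - Csqn) - koff_csqn * Csqn;
    dy[31] = J_serca - (J_SRleak * Vmyo / Vsr + J_SRCarel) - dy[30];

    // Na concentrations
    const double INa_tot_junc =
        INa_junc + INaB_junc + 3.0 * INCX_junc + 3.0 * INaK_junc + ICaNa_junc;
    const double INa_tot_sl =
        INa_sl + INaB_sl + 3.0 * INCX_sl + 3.0 * INaK_sl + ICaNa_sl;
    dy[32] = -INa_tot_junc * Cmem / (Vjunc * Frdy) +
             Jna_juncsl / Vjunc * (Nasl - Naj) - dy[17];
    dy[33] = -INa_tot_sl * Cmem / (Vsl * Frdy) +
             Jna_juncsl / Vsl * (Naj - Nasl) +
             Jna_slmyo / Vsl * (Nai - Nasl) - dy[18];
    dy[34] = Jna_slmyo / Vmyo * (Nasl - Nai);

    // Ca concentrations
    const double ICa_tot_junc =
        ICa_junc + ICaB_junc + IpCa_junc - 2.0 * INCX_junc;
    const double ICa_tot_sl = ICa_sl + ICaB_sl + IpCa_sl - 2.0 * INCX_sl;
    dy[35] = -ICa_tot_junc * Cmem / (Vjunc * 2.0 * Frdy) +
             Jca_juncsl / Vjunc * (Casl - Caj) - J_CaB_junction +
             J_SRCarel * Vsr / Vjunc + J_SRleak * Vmyo / Vjunc;
    dy[36] = -ICa_tot_sl * Cmem / (Vsl * 2.0 * Frdy) +
             Jca_juncsl / Vsl * (Caj - Casl) +
             Jca_slmyo / Vsl * (Cai - Casl) - J_CaB_sl;
    dy[37] = -J_serca * Vsr / Vmyo - J_CaB_cytosol +
             Jca_slmyo / Vmyo * (Casl - Cai);

    // fCa (Ca-dependent inactivation) derivatives
    dy[12] = 1.7 * Caj * (1.0 - fcaBj) - 11.9e-3 * fcaBj;
    dy[13] = 1.7 * Casl * (1.0 - fcaBsl) - 11.9e-3 * fcaBsl;
    for (int g = 1; g <= 11; ++g) dy[g] = 0.0;

    // membrane potential
    const double INa_tot = INa_tot_junc + INa_tot_sl;
    const double ICl_tot = IClCa + IClB;
    const double ICa_tot = ICa_tot_junc + ICa_tot_sl;
    const double IK_tot = Ito + IKr + IKs + IK1 - 2.0 * INaK + ICaK + IKp + IKur;
    dy[0] = -(INa_tot + ICl_tot + ICa_tot + IK_tot) + istim;

    if (cur) {
      cur[0] = INa_junc + INa_sl;
      cur[1] = Ito;
      cur[2] = ICa_junc + ICa_sl;
      cur[3] = IKur;
      cur[4] = IKr;
      cur[5] = IKs;
      cur[6] = IK1;
      cur[7] = INCX_junc + INCX_sl;
      cur[8] = INaK;
      cur[9] = INaB_junc + INaB_sl;
      cur[10] = ICaB_junc + ICaB_sl;
      cur[11] = IpCa_junc + IpCa_sl;
      cur[12] = IClCa;
      cur[13] = IClB;
      cur[14] = IKp;
      cur[15] = ICaK;
      cur[16] = ICaNa_junc + ICaNa_sl;
    }
  }

  void step(const double* row, double* y, const double* sc,
            double istim, double dt) const {
    using namespace gpv;
    double dy[38];
    eval(row, y, sc, istim, dy, 0);

    const double* inf = row;
    const double* rlc = row + NG;
    for (int g = 0; g < NG; ++g) {
      double& gv = y[1 + g];
      gv += (inf[g] - gv) * rlc[g];
      if (gv < 0.0) gv = 0.0; else if (gv > 1.0) gv = 1.0;
    }
    y[0] += dt * dy[0];
    for (int k = 12; k < 38; ++k) y[k] += dt * dy[k];
    // fCa states live in [0,1]
    if (y[12] < 0.0) y[12] = 0.0; else if (y[12] > 1.0) y[12] = 1.0;
    if (y[13] < 0.0) y[13] = 0.0; else if (y[13] > 1.0) y[13] = 1.0;
  }

private:
  std::vector<std::string> state_names_, current_names_;
  std::vector<double> init_;
};

CellModel* make_grandi() { return new GrandiAtrial(); }
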
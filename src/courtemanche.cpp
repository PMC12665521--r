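// Courtemanche-Ramirez-Nattel (1998) human atrial ionic model with
// conductance-scaling remodeling variants, plus a graph-Laplacian monodomain
// stepper.  Gates advance by Rush-Larsen with voltage lookup tables; Vm and
// concentrations by forward Euler.  Units: mV, ms, mM, pA/pF, nS/pF.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace crn {

const double R_ = 8.3143, T_ = 310.0, F_ = 96.4867;
const double RTF = R_ * T_ / F_;
const double Cm = 100.0;                  // pF
const double Vi = 13668.0, Vup = 1109.52, Vrel = 96.48; // um^3
const double Ko = 5.4, Nao = 140.0, Cao = 1.8;

const double gNa0 = 7.8, gK1 = 0.09, gto0 = 0.1652;
const double gKr = 0.029411765, gKs = 0.12941176, gCaL0 = 0.12375;
const double gbCa = 0.001131, gbNa = 0.0006744375;
const double iNaKmax = 0.59933874, iNaCamax = 1600.0, ipCamax = 0.275;
const double KmNai = 10.0, KmKo = 1.5;
const double KmNa = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35;
const double krel = 30.0, iupmax = 0.005, Kup = 0.00092, Caupmax = 15.0;
const double tautr = 180.0, tauu = 8.0, taufca = 2.0;
const double CMDNmax = 0.05, TRPNmax = 0.07, CSQNmax = 10.0;
const double KmCMDN = 0.00238, KmTRPN = 0.0005, KmCSQN = 0.8;

// state layout
enum { V = 0, M, H, J, OA, OI, UA, UI, XR, XS, D, F_G, FCA, U, Vg, W,
       NAI, KI, CAI, CAUP, CAREL, NSTATE };

// resting state (quiescent model, baseline conductances)
static const double rest[NSTATE] = {
  -81.18, 2.908e-3, 0.9649, 0.9775, 3.043e-2, 0.9992, 4.966e-3, 0.9986,
  3.296e-5, 1.869e-2, 1.367e-4, 0.9996, 0.7755, 2.35e-112, 1.0, 0.9992,
  11.17, 139.0, 1.013e-4, 1.488, 1.488 };

inline double safe_div(double num, double den, double lim) {
  return std::fabs(den) < 1e-10 ? lim : num / den;
}

// Voltage lookup tables: for each V-dependent gate, steady state and the
// Rush-Larsen factor exp(-dt/tau); plus V-dependent current factors.
struct Tables {
  double vmin, vmax, dv, inv_dv;
  double rl_fca, rl_u;   // constant-tau Rush-Larsen factors
  int n;
  // per entry: 12 gates x (inf, rl) then 6 current factors
  std::vector<double> tab; // n x 30
  static const int NG = 12, NC = 6, STRIDE = 30;

  void build(double dt) {
    rl_fca = std::exp(-dt / taufca);
    rl_u = std::exp(-dt / tauu);
    vmin = -150.0; vmax = 100.0; dv = 0.1;
    inv_dv = 1.0 / dv;
    n = (int)((vmax - vmin) * inv_dv) + 2;
    tab.assign((size_t)n * STRIDE, 0.0);
    double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
    for (int k = 0; k < n; ++k) {
      double v = vmin + k * dv;
      double *row = &tab[(size_t)k * STRIDE];
      double a, b, inf, tau;
      int g = 0;
      // m
      a = safe_div(0.32 * (v + 47.13), 1.0 - std::exp(-0.1 * (v + 47.13)), 3.2);
      b = 0.08 * std::exp(-v / 11.0);
      inf = a / (a + b); tau = 1.0 / (a + b);
      row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      // h
      if (v >= -40.0) { a = 0.0; b = 1.0 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1))); }
      else { a = 0.135 * std::exp(-(v + 80.0) / 6.8);
             b = 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v); }
      inf = a / (a + b); tau = 1.0 / (a + b);
      row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      // j
      if (v >= -40.0) { a = 0.0;
        b = 0.3 * std::exp(-2.535e-7 * v) / (1.0 + std::exp(-0.1 * (v + 32.0))); }
      else {
        a = (-1.2714e5 * std::exp(0.2444 * v) - 3.474e-5 * std::exp(-0.04391 * v)) *
            (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
        b = 0.1212 * std::exp(-0.01052 * v) / (1.0 + std::exp(-0.1378 * (v + 40.14)));
      }
      inf = a / (a + b); tau = 1.0 / (a + b);
      row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      // oa (KQ10 = 3)
      a = 0.65 / (std::exp(-(v + 10.0) / 8.5) + std::exp(-(v - 30.0) / 59.0));
      b = 0.65 / (2.5 + std::exp((v + 82.0) / 17.0));
      tau = 1.0 / ((a + b) * 3.0);
      inf = 1.0 / (1.0 + std::exp(-(v + 20.47) / 17.54));
      row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      // oi
      a = 1.0 / (18.53 + std::exp((v + 113.7) / 10.95));
      b = 1.0 / (35.56 + std::exp(-(v + 1.26) / 7.44));
      tau = 1.0 / ((a + b) * 3.0);
      inf = 1.0 / (1.0 + std::exp((v + 43.1) / 5.3));
      row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      // ua
      a = 0.65 / (std::exp(-(v + 10.0) / 8.5) + std::exp(-(v - 30.0) / 59.0));
      b = 0.65 / (2.5 + std::exp((v + 82.0) / 17.0));
      tau = 1.0 / ((a + b) * 3.0);
      inf = 1.0 / (1.0 + std::exp(-(v + 30.3) / 9.6));
      row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      // ui
      a = 1.0 / (21.0 + std::exp(-(v - 185.0) / 28.0));
      b = std::exp((v - 158.0) / 16.0);
      tau = 1.0 / ((a + b) * 3.0);
      inf = 1.0 / (1.0 + std::exp((v - 99.45) / 27.48));
      row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      // xr
      a = safe_div(0.0003 * (v + 14.1), 1.0 - std::exp(-(v + 14.1) / 5.0), 0.0015);
      b = safe_div(7.3898e-5 * (v - 3.3328), std::exp((v - 3.3328) / 5.1237) - 1.0,
                   7.3898e-5 * 5.1237);
      tau = 1.0 / (a + b);
      inf = 1.0 / (1.0 + std::exp(-(v + 14.1) / 6.5));
      row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      // xs
      a = safe_div(4e-5 * (v - 19.9), 1.0 - std::exp(-(v - 19.9) / 17.0), 4e-5 * 17.0);
      b = safe_div(3.5e-5 * (v - 19.9), std::exp((v - 19.9) / 9.0) - 1.0, 3.5e-5 * 9.0);
      tau = 0.5 / (a + b);
      inf = std::pow(1.0 + std::exp(-(v - 19.9) / 12.7), -0.5);
      row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      // d
      {
        double e1 = std::exp(-(v + 10.0) / 6.24);
        tau = std::fabs(v + 10.0) < 1e-10
          ? 1.0 / (0.035 * 6.24 * 2.0)   // L'Hopital limit at V = -10
          : (1.0 - e1) / (0.035 * (v + 10.0) * (1.0 + e1));
        inf = 1.0 / (1.0 + std::exp(-(v + 10.0) / 8.0));
        row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      }
      // f
      tau = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (v + 10.0) * (v + 10.0)) + 0.02);
      inf = 1.0 / (1.0 + std::exp((v + 28.0) / 6.9));
      row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      // w
      {
        double e2 = std::exp(-(v - 7.9) / 5.0);
        tau = std::fabs(v - 7.9) < 1e-10
          ? 6.0 * 0.2 / 1.3
          : 6.0 * (1.0 - e2) / ((1.0 + 0.3 * e2) * (v - 7.9));
        inf = 1.0 - 1.0 / (1.0 + std::exp(-(v - 40.0) / 17.0));
        row[2*g] = inf; row[2*g+1] = std::exp(-dt / tau); ++g;
      }
      // current factors
      double *cf = row + 2 * NG;
      cf[0] = 1.0 / (1.0 + std::exp(0.07 * (v + 80.0)));            // IK1 rectification
      cf[1] = 0.005 + 0.05 / (1.0 + std::exp(-(v - 15.0) / 13.0));  // gKur(V)
      cf[2] = 1.0 / (1.0 + std::exp((v + 15.0) / 22.4));            // IKr rectification
      cf[3] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v / RTF) +
                     0.0365 * sigma * std::exp(-v / RTF));          // fNaK
      cf[4] = std::exp(gam * v / RTF);                              // INaCa fwd
      cf[5] = std::exp((gam - 1.0) * v / RTF);                      // INaCa rev
    }
  }

  inline void lookup(double v, double *out) const {
    if (v < vmin) v = vmin;
    if (v > vmax) v = vmax;
    double x = (v - vmin) * inv_dv;
    int k = (int)x;
    if (k >= n - 1) k = n - 2;
    double f = x - k;
    const double *r0 = &tab[(size_t)k * STRIDE], *r1 = r0 + STRIDE;
    for (int i = 0; i < STRIDE; ++i) out[i] = r0[i] + f * (r1[i] - r0[i]);
  }
};

// One cell update (dt implicit in tables). scales: gKur, gto, gCaL, gNa.
// Returns the ionic current sum (pA/pF) used for dV/dt = -(i_ion + i_stim) + diff.
// Slowly varying concentration-derived terms, refreshed every ~0.5 ms.
struct NernstCache { double ENa, EK, ECa, fnk; };

inline void refresh_nernst(const double *s, NernstCache &nc) {
  nc.ENa = RTF * std::log(Nao / s[NAI]);
  nc.EK  = RTF * std::log(Ko / s[KI]);
  nc.ECa = 0.5 * RTF * std::log(Cao / s[CAI]);
  nc.fnk = 1.0 / (1.0 + std::pow(KmNai / s[NAI], 1.5));
}

inline double cell_step(double *s, const Tables &tb, double dt,
                        const double *scales, const NernstCache &nc) {
  double row[Tables::STRIDE];
  double v = s[V];
  tb.lookup(v, row);

  double ENa = nc.ENa, EK = nc.EK, ECa = nc.ECa;

  double iNa  = scales[3] * gNa0 * s[M]*s[M]*s[M] * s[H] * s[J] * (v - ENa);
  double iK1  = gK1 * (v - EK) * row[24];
  double ito  = scales[1] * gto0 * s[OA]*s[OA]*s[OA] * s[OI] * (v - EK);
  double iKur = scales[0] * row[25] * s[UA]*s[UA]*s[UA] * s[UI] * (v - EK);
  double iKr  = gKr * s[XR] * (v - EK) * row[26];
  double iKs  = gKs * s[XS]*s[XS] * (v - EK);
  double iCaL = scales[2] * gCaL0 * s[D] * s[F_G] * s[FCA] * (v - 65.0);
  double iNaK = iNaKmax * row[27] * nc.fnk * (Ko / (Ko + KmKo));
  double e1 = row[28], e2 = row[29];
  double na3 = s[NAI]*s[NAI]*s[NAI];
  double iNaCa = iNaCamax *
    (e1 * na3 * Cao - e2 * Nao*Nao*Nao * s[CAI]) /
    ((KmNa*KmNa*KmNa + Nao*Nao*Nao) * (KmCa + Cao) * (1.0 + ksat * e2));
  double ibNa = gbNa * (v - ENa);
  double ibCa = gbCa * (v - ECa);
  double ipCa = ipCamax * s[CAI] / (0.0005 + s[CAI]);

  // SR fluxes (mM/ms)
  double irel = krel * s[U]*s[U] * s[Vg] * s[W] * (s[CAREL] - s[CAI]);
  double itr  = (s[CAUP] - s[CAREL]) / tautr;
  double iup  = iupmax / (1.0 + Kup / s[CAI]);
  double iupleak = iupmax * s[CAUP] / Caupmax;

  double Fn = 1e-12 * Vrel * irel -
              (5e-13 / F_) * (0.5 * iCaL * Cm - 0.2 * iNaCa * Cm);

  // Rush-Larsen gates (V-dependent from tables)
  s[M]   = row[0]  + (s[M]   - row[0])  * row[1];
  s[H]   = row[2]  + (s[H]   - row[2])  * row[3];
  s[J]   = row[4]  + (s[J]   - row[4])  * row[5];
  s[OA]  = row[6]  + (s[OA]  - row[6])  * row[7];
  s[OI]  = row[8]  + (s[OI]  - row[8])  * row[9];
  s[UA]  = row[10] + (s[UA]  - row[10]) * row[11];
  s[UI]  = row[12] + (s[UI]  - row[12]) * row[13];
  s[XR]  = row[14] + (s[XR]  - row[14]) * row[15];
  s[XS]  = row[16] + (s[XS]  - row[16]) * row[17];
  s[D]   = row[18] + (s[D]   - row[18]) * row[19];
  s[F_G] = row[20] + (s[F_G] - row[20]) * row[21];
  s[W]   = row[22] + (s[W]   - row[22]) * row[23];

  // Ca/Fn-dependent gates
  double fcainf = 1.0 / (1.0 + s[CAI] / 0.00035);
  s[FCA] = fcainf + (s[FCA] - fcainf) * tb.rl_fca;
  double eFn = std::exp(-(Fn - 3.4175e-13) / 13.67e-16);
  double uinf = 1.0 / (1.0 + eFn);
  s[U] = uinf + (s[U] - uinf) * tb.rl_u;
  double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  double tauv = 1.91 + 2.09 / (1.0 + eFn);
  s[Vg] = vinf + (s[Vg] - vinf) * std::exp(-dt / tauv);

  // concentrations (forward Euler)
  double cfv = Cm / (F_ * Vi);
  double dNai = cfv * (-3.0 * iNaK - 3.0 * iNaCa - ibNa - iNa);
  double dKi  = cfv * (2.0 * iNaK - iK1 - ito - iKur - iKr - iKs);
  double b1 = cfv * 0.5 * (2.0 * iNaCa - ipCa - iCaL - ibCa) +
              (Vup * (iupleak - iup) + irel * Vrel) / Vi;
  double kc1 = s[CAI] + KmCMDN, kc2 = s[CAI] + KmTRPN;
  double b2 = 1.0 + TRPNmax * KmTRPN / (kc2 * kc2) + CMDNmax * KmCMDN / (kc1 * kc1);
  double dCaup  = iup - iupleak - itr * Vrel / Vup;
  double kcs = s[CAREL] + KmCSQN;
  double dCarel = (itr - irel) / (1.0 + CSQNmax * KmCSQN / (kcs * kcs));

  s[NAI]  += dt * dNai;
  s[KI]   += dt * dKi;
  s[CAI]  += dt * b1 / b2;
  s[CAUP] += dt * dCaup;
  s[CAREL] += dt * dCarel;

  return iNa + iK1 + ito + iKur + iKr + iKs + iCaL + iNaK + iNaCa +
         ibNa + ibCa + ipCa;
}

} // namespace crn

// [[Rcpp::export]]
NumericVector crn_rest_state_cpp() {
  NumericVector out(crn::NSTATE);
  for (int i = 0; i < crn::NSTATE; ++i) out[i] = crn::rest[i];
  return out;
}

// Pace a single cell; record Vm at record_dt over the whole protocol and the
// full state trajectory over the final cycle (n_cycle_samples rows).
// [[Rcpp::export]]
List crn_pace_cpp(NumericVector scales, double bcl, int nbeats, double dt,
                  double record_dt, double stim_amp, double stim_dur,
                  int n_cycle_samples) {
  crn::Tables tb;
  tb.build(dt);
  double s[crn::NSTATE];
  for (int i = 0; i < crn::NSTATE; ++i) s[i] = crn::rest[i];
  double sc[4] = { scales[0], scales[1], scales[2], scales[3] };

  double total = bcl * nbeats;
  long nsteps = (long)std::llround(total / dt);
  int rec_every = (int)std::llround(record_dt / dt);
  int nernst_every = std::max(1, (int)std::llround(0.5 / dt));
  crn::NernstCache nc;
  long nrec = nsteps / rec_every + 1;
  NumericVector tout(nrec), vout(nrec);
  NumericMatrix cyc(n_cycle_samples, crn::NSTATE);
  long cyc_start = (long)std::llround(bcl * (nbeats - 1) / dt);
  double cyc_stride = bcl / dt / n_cycle_samples;
  int cyc_i = 0;
  long ri = 0;
  tout[0] = 0.0; vout[0] = s[crn::V];
  ri = 1;
  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    double tin = t - bcl * std::floor(t / bcl);
    double istim = (tin < stim_dur) ? stim_amp : 0.0;
    if (step % nernst_every == 0) crn::refresh_nernst(s, nc);
    double iion = crn::cell_step(s, tb, dt, sc, nc);
    s[crn::V] += dt * (-(iion + istim));
    if (step >= cyc_start && cyc_i < n_cycle_samples &&
        (step - cyc_start) >= std::llround(cyc_i * cyc_stride)) {
      for (int k = 0; k < crn::NSTATE; ++k) cyc(cyc_i, k) = s[k];
      ++cyc_i;
    }
    if ((step + 1) % rec_every == 0 && ri < nrec) {
      tout[ri] = (step + 1) * dt;
      vout[ri] = s[crn::V];
      ++ri;
    }
  }
  if (!R_finite(s[crn::V])) stop("cell integration diverged (Vm non-finite)");
  return List::create(_["time"] = tout, _["vm"] = vout, _["cycle"] = cyc);
}

// Monodomain on an arbitrary weighted graph (CSR, 0-based).
// states0: n x 21; scales: n x 4; weights w are D/dx^2-style coupling rates.
// stim_nodes 0-based; stimulus applied at each time in stim_times for stim_dur.
// block_nodes become non-conductive (all their couplings removed) from t=0.
// Records Vm every record_dt; returns vm (nt x n) and final states.
// [[Rcpp::export]]
List monodomain_cpp(NumericMatrix states0, IntegerVector nbr_ptr,
                    IntegerVector nbr_idx, NumericVector nbr_w,
                    NumericMatrix scales, double dt, double duration,
                    double record_dt, IntegerVector stim_nodes,
                    NumericVector stim_times, double stim_dur, double stim_amp,
                    IntegerVector block_nodes) {
  int n = states0.nrow();
  if (states0.ncol() != crn::NSTATE) stop("states0 must have 21 columns");
  crn::Tables tb;
  tb.build(dt);
  std::vector<double> S((size_t)n * crn::NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < crn::NSTATE; ++k) S[(size_t)i * crn::NSTATE + k] = states0(i, k);
  std::vector<char> blocked(n, 0);
  for (int b = 0; b < block_nodes.size(); ++b) blocked[block_nodes[b]] = 1;
  std::vector<double> scl((size_t)n * 4);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 4; ++k) scl[(size_t)i * 4 + k] = scales(i, k);
  std::vector<char> stim(n, 0);
  for (int i = 0; i < stim_nodes.size(); ++i) stim[stim_nodes[i]] = 1;

  long nsteps = (long)std::llround(duration / dt);
  int rec_every = (int)std::llround(record_dt / dt);
  int nernst_every = std::max(1, (int)std::llround(0.5 / dt));
  std::vector<crn::NernstCache> nc(n);
  long nrec = nsteps / rec_every + 1;
  NumericMatrix vm(nrec, n);
  NumericVector tout(nrec);
  std::vector<double> vold(n), dvdiff(n);
  long ri = 0;
  for (int i = 0; i < n; ++i) vm(0, i) = S[(size_t)i * crn::NSTATE + crn::V];
  tout[0] = 0.0; ri = 1;

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    bool stim_on = false;
    for (int k = 0; k < stim_times.size(); ++k)
      if (t >= stim_times[k] && t < stim_times[k] + stim_dur) { stim_on = true; break; }
    for (int i = 0; i < n; ++i) vold[i] = S[(size_t)i * crn::NSTATE + crn::V];
    // diffusion (skip edges touching blocked nodes)
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      if (!blocked[i]) {
        for (int p = nbr_ptr[i]; p < nbr_ptr[i + 1]; ++p) {
          int j = nbr_idx[p];
          if (!blocked[j]) acc += nbr_w[p] * (vold[j] - vold[i]);
        }
      }
      dvdiff[i] = acc;
    }
    bool refresh = (step % nernst_every == 0);
    for (int i = 0; i < n; ++i) {
      double *s = &S[(size_t)i * crn::NSTATE];
      if (refresh) crn::refresh_nernst(s, nc[i]);
      double istim = (stim_on && stim[i]) ? stim_amp : 0.0;
      double iion = crn::cell_step(s, tb, dt, &scl[(size_t)i * 4], nc[i]);
      s[crn::V] += dt * (-(iion + istim) + dvdiff[i]);
    }
    if ((step + 1) % rec_every == 0 && ri < nrec) {
      tout[ri] = (step + 1) * dt;
      double vmax = -1e9;
      for (int i = 0; i < n; ++i) {
        double vi = S[(size_t)i * crn::NSTATE + crn::V];
        vm(ri, i) = vi;
        if (vi > vmax) vmax = vi;
      }
      ++ri;
      // dead tissue stays dead: once everything is deeply repolarized and
      // no stimulus is pending, freeze the remaining recording at rest
      if (vmax < -75.0) {
        bool stim_left = false;
        for (int k = 0; k < stim_times.size(); ++k)
          if (stim_times[k] + stim_dur > (step + 1) * dt) stim_left = true;
        if (!stim_left) {
          for (long r2 = ri; r2 < nrec; ++r2) {
            tout[r2] = tout[ri - 1] + (r2 - ri + 1) * record_dt;
            for (int i = 0; i < n; ++i) vm(r2, i) = vm(ri - 1, i);
          }
          ri = nrec;
          break;
        }
      }
    }
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < n; ++i)
    if (!R_finite(S[(size_t)i * crn::NSTATE + crn::V]))
      stop("tissue integration diverged (Vm non-finite)");
  NumericMatrix sf(n, crn::NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < crn::NSTATE; ++k) sf(i, k) = S[(size_t)i * crn::NSTATE + k];
  return List::create(_["time"] = tout, _["vm"] = vm, _["states"] = sf);
}
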
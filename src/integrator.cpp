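// Single-compartment Hodgkin-Huxley-type integrator.
//
// Ionic currents: transient Na (m,h), fast-inactivating Na "NaT" (mh,hh),
// delayed-rectifier K (n), muscarinic K (p), Kv3.1 (v), high-threshold Ca
// (q,r) and leak. Minimal-model kinetics with a VT threshold shift for
// m/h/n/p/q/r; Allen-style kinetics for the NaT and Kv3.1 gates. All gate
// rates are scaled by Q10^((T - Tref)/10); the m, h and n gates additionally
// by rSS (steady states unaffected); tau_p scales with tau_max.
//
// Integration is exponential-Euler in every state variable (the membrane
// equation is conditionally linear given the gates), fixed step dt. The
// voltage update uses gate values from the previous step and vice versa.
//
// Units: V mV, t ms, per-area conductances mS/cm2, C uF/cm2, currents uA
// internally (injected current supplied in pA). Membrane area reconciles the
// passive triple (C, Rinput, tau): A = tau / (C * Rinput * 1e3) cm2, and the
// total leak conductance is exactly 1/Rinput.

#include <Rcpp.h>
using namespace Rcpp;

// x / (1 - exp(-x/k)), continuous limit k at x -> 0
static inline double vtrap(double x, double k) {
  if (std::fabs(x / k) < 1e-7) return k * (1.0 + x / (2.0 * k));
  return x / (1.0 - std::exp(-x / k));
}

struct GateKin { double xinf; double tau; };

// Minimal-model transient Na activation/inactivation (rates in 1/ms)
static inline GateKin kin_m(double V, double VT) {
  double am = 0.32 * vtrap(V - VT - 13.0, 4.0);
  double bm = 0.28 * vtrap(-(V - VT - 40.0), 5.0);
  return { am / (am + bm), 1.0 / (am + bm) };
}
static inline GateKin kin_h(double V, double VT) {
  double ah = 0.128 * std::exp(-(V - VT - 17.0) / 18.0);
  double bh = 4.0 / (1.0 + std::exp(-(V - VT - 40.0) / 5.0));
  return { ah / (ah + bh), 1.0 / (ah + bh) };
}
// Delayed-rectifier K
static inline GateKin kin_n(double V, double VT) {
  double an = 0.032 * vtrap(V - VT - 15.0, 5.0);
  double bn = 0.5 * std::exp(-(V - VT - 10.0) / 40.0);
  return { an / (an + bn), 1.0 / (an + bn) };
}
// Muscarinic K (tau in units of tau_max)
static inline GateKin kin_p(double V) {
  double pinf = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
  double taup = 1.0 / (3.3 * std::exp((V + 35.0) / 20.0) + std::exp(-(V + 35.0) / 20.0));
  return { pinf, taup };
}
// High-threshold Ca activation/inactivation
static inline GateKin kin_q(double V) {
  double aq = 0.055 * vtrap(V + 27.0, 3.8);
  double bq = 0.94 * std::exp((-75.0 - V) / 17.0);
  return { aq / (aq + bq), 1.0 / (aq + bq) };
}
static inline GateKin kin_r(double V) {
  double ar = 0.000457 * std::exp((-13.0 - V) / 50.0);
  double br = 0.0065 / (std::exp((-15.0 - V) / 28.0) + 1.0);
  return { ar / (ar + br), 1.0 / (ar + br) };
}
// Fast-inactivating Na (Allen-style)
static inline GateKin kin_mh(double V) {
  double a = 0.182 * vtrap(V + 38.0, 6.0);
  double b = 0.124 * vtrap(-(V + 38.0), 6.0);
  return { a / (a + b), 1.0 / (a + b) };
}
static inline GateKin kin_hh(double V) {
  double a = 0.015 * vtrap(-(V + 66.0), 6.0);
  double b = 0.015 * vtrap(V + 66.0, 6.0);
  return { a / (a + b), 1.0 / (a + b) };
}
// Kv3.1 (tau in ms)
static inline GateKin kin_v(double V) {
  double vinf = 1.0 / (1.0 + std::exp(-(V - 18.7) / 9.7));
  double tauv = 4.0 / (1.0 + std::exp(-(V + 46.56) / 44.14));
  return { vinf, tauv };
}

static inline double expdecay(double dt, double tau) {
  return std::exp(-dt / tau);
}

// Gate kinetics for a single voltage, after temperature/rSS/tau_max scaling.
// Returns a 9 x 2 matrix (xinf, tau) with rows m,h,mh,hh,n,p,v,q,r.
// [[Rcpp::export]]
NumericMatrix hh_gate_kinetics(double V, double VT, double tau_max, double rss,
                               double phi) {
  NumericMatrix out(9, 2);
  GateKin g;
  g = kin_m(V, VT);  out(0, 0) = g.xinf; out(0, 1) = g.tau / (phi * rss);
  g = kin_h(V, VT);  out(1, 0) = g.xinf; out(1, 1) = g.tau / (phi * rss);
  g = kin_mh(V);     out(2, 0) = g.xinf; out(2, 1) = g.tau / phi;
  g = kin_hh(V);     out(3, 0) = g.xinf; out(3, 1) = g.tau / phi;
  g = kin_n(V, VT);  out(4, 0) = g.xinf; out(4, 1) = g.tau / (phi * rss);
  g = kin_p(V);      out(5, 0) = g.xinf; out(5, 1) = g.tau * tau_max / phi;
  g = kin_v(V);      out(6, 0) = g.xinf; out(6, 1) = g.tau / phi;
  g = kin_q(V);      out(7, 0) = g.xinf; out(7, 1) = g.tau / phi;
  g = kin_r(V);      out(8, 0) = g.xinf; out(8, 1) = g.tau / phi;
  return out;
}

// Batch integrator. theta: n_sim x 13, columns
// C, Rinput, tau, gNat, gNa, gKd, gM, gKv31, gL, Eleak, tau_max, VT, rSS.
// Returns list(vm = n_sim x (n_steps+1) matrix, failed = logical).
// Uses R's RNG for the noise current (reproducible via set.seed()).
// [[Rcpp::export]]
List hh_integrate_batch(NumericMatrix theta,
                        double dt, double duration, double onset, double offset,
                        double amplitude_pA, double noise_mean_pA,
                        double noise_sd_pA, bool noise_on,
                        double temperature, double t_ref, double q10,
                        double e_na, double e_k, double e_ca,
                        double v_guard) {
  const int n_sim = theta.nrow();
  const int n_steps = (int) std::lround(duration / dt);
  NumericMatrix vm(n_sim, n_steps + 1);
  LogicalVector failed(n_sim);
  const double phi = std::pow(q10, (temperature - t_ref) / 10.0);

  for (int s = 0; s < n_sim; ++s) {
    const double C = theta(s, 0), Rin = theta(s, 1), tau = theta(s, 2);
    const double gNat = theta(s, 3), gNa = theta(s, 4), gKd = theta(s, 5);
    const double gM = theta(s, 6), gKv = theta(s, 7), gL = theta(s, 8);
    const double Eleak = theta(s, 9), tau_max = theta(s, 10);
    const double VT = theta(s, 11), rss = theta(s, 12);

    // membrane area reconciling (C, Rinput, tau); total quantities
    const double A = tau / (C * Rin * 1e3);          // cm2
    const double Cm = C * A;                          // uF
    const double g_leak = 1e-3 / Rin;                 // mS (= 1/Rinput)
    const double gNat_t = gNat * A, gNa_t = gNa * A, gKd_t = gKd * A;
    const double gM_t = gM * A, gKv_t = gKv * A, gL_t = gL * A;

    double V = Eleak;
    GateKin g;
    g = kin_m(V, VT);  double m  = g.xinf;
    g = kin_h(V, VT);  double h  = g.xinf;
    g = kin_mh(V);     double mh = g.xinf;
    g = kin_hh(V);     double hh = g.xinf;
    g = kin_n(V, VT);  double n  = g.xinf;
    g = kin_p(V);      double p  = g.xinf;
    g = kin_v(V);      double vv = g.xinf;
    g = kin_q(V);      double q  = g.xinf;
    g = kin_r(V);      double r  = g.xinf;

    vm(s, 0) = V;
    bool fail = false;

    for (int i = 0; i < n_steps; ++i) {
      const double t = i * dt;
      double I_inj = (t >= onset && t < offset) ? amplitude_pA : 0.0; // pA
      double I_noise = noise_on ? R::rnorm(noise_mean_pA, noise_sd_pA) : 0.0;
      const double I_ext = (I_inj + I_noise) * 1e-6;  // uA

      // conductance terms from current gate state
      const double cNa = gNa_t * m * m * m * h;
      const double cNat = gNat_t * mh * mh * mh * hh;
      const double cKd = gKd_t * n * n * n * n;
      const double cM = gM_t * p;
      const double cKv = gKv_t * vv;
      const double cL = gL_t * q * q * r;
      const double G = cNa + cNat + cKd + cM + cKv + cL + g_leak;
      const double numer = (cNa + cNat) * e_na + (cKd + cM + cKv) * e_k +
        cL * e_ca + g_leak * Eleak + I_ext;
      const double E_eff = numer / G;
      const double tau_eff = Cm / G;
      const double V_new = E_eff + (V - E_eff) * expdecay(dt, tau_eff);

      // gate updates from the previous voltage
      g = kin_m(V, VT);  m  = g.xinf + (m  - g.xinf) * expdecay(dt, g.tau / (phi * rss));
      g = kin_h(V, VT);  h  = g.xinf + (h  - g.xinf) * expdecay(dt, g.tau / (phi * rss));
      g = kin_mh(V);     mh = g.xinf + (mh - g.xinf) * expdecay(dt, g.tau / phi);
      g = kin_hh(V);     hh = g.xinf + (hh - g.xinf) * expdecay(dt, g.tau / phi);
      g = kin_n(V, VT);  n  = g.xinf + (n  - g.xinf) * expdecay(dt, g.tau / (phi * rss));
      g = kin_p(V);      p  = g.xinf + (p  - g.xinf) * expdecay(dt, g.tau * tau_max / phi);
      g = kin_v(V);      vv = g.xinf + (vv - g.xinf) * expdecay(dt, g.tau / phi);
      g = kin_q(V);      q  = g.xinf + (q  - g.xinf) * expdecay(dt, g.tau / phi);
      g = kin_r(V);      r  = g.xinf + (r  - g.xinf) * expdecay(dt, g.tau / phi);

      // exponential-Euler keeps gates in [0,1] given xinf in [0,1]; clamp
      // guards against rounding at the boundaries
      if (m < 0) m = 0; else if (m > 1) m = 1;
      if (h < 0) h = 0; else if (h > 1) h = 1;
      if (mh < 0) mh = 0; else if (mh > 1) mh = 1;
      if (hh < 0) hh = 0; else if (hh > 1) hh = 1;
      if (n < 0) n = 0; else if (n > 1) n = 1;
      if (p < 0) p = 0; else if (p > 1) p = 1;
      if (vv < 0) vv = 0; else if (vv > 1) vv = 1;
      if (q < 0) q = 0; else if (q > 1) q = 1;
      if (r < 0) r = 0; else if (r > 1) r = 1;

      V = V_new;
      if (!std::isfinite(V) || std::fabs(V) > v_guard) { fail = true; break; }
      vm(s, i + 1) = V;
    }
    if (fail) {
      failed[s] = true;
      for (int i = 0; i <= n_steps; ++i) vm(s, i) = NA_REAL;
    }
  }
  return List::create(_["vm"] = vm, _["failed"] = failed);
}
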
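// Fixed-step RK4 integrator for the closed-loop compartment circuit.
//
// The state is the vector of compartment volumes; the cardiac phase and the
// baroreflex controller are advanced once per step (forward Euler), which is
// adequate because their time constants are orders of magnitude above dt.
// All pressure/flow laws mirror the exported R reference functions
// (compartment_pressure, varying_elastance, edge_flow, lymphatic_flow);
// a test asserts the two implementations agree on recorded samples.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// squared half-sine activation over [0, sf)
inline double act_vent(double phase, double sf) {
  if (phase < sf) {
    double s = std::sin(M_PI * phase / sf);
    return s * s;
  }
  return 0.0;
}

// atrial activation window [w0, 1): atrial kick just before ventricular systole
inline double act_atr(double phase, double w0) {
  if (phase >= w0) {
    double s = std::sin(M_PI * (phase - w0) / (1.0 - w0));
    return s * s;
  }
  return 0.0;
}

// smoothstep in [0,1]
inline double sstep(double x) {
  if (x <= 0.0) return 0.0;
  if (x >= 1.0) return 1.0;
  return x * x * (3.0 - 2.0 * x);
}

struct Protocol {
  std::vector<double> t0, ramp, g, ps, sh;
  // piecewise-linear interpolation: segment k's values are reached by a
  // linear ramp of length ramp[k] starting at t0[k] from segment k-1's values
  void sample(double t, double& g_out, double& ps_out, double& sh_out) const {
    int n = (int)t0.size();
    int k = 0;
    for (int i = 0; i < n; ++i) if (t >= t0[i]) k = i;
    if (t < t0[0]) k = 0;
    double gk = g[k], pk = ps[k], sk = sh[k];
    if (k > 0 && ramp[k] > 0.0 && t < t0[k] + ramp[k]) {
      double f = (t - t0[k]) / ramp[k];
      gk = g[k - 1] + f * (g[k] - g[k - 1]);
      pk = ps[k - 1] + f * (ps[k] - ps[k - 1]);
      sk = sh[k - 1] + f * (sh[k] - sh[k - 1]);
    }
    g_out = gk; ps_out = pk; sh_out = sk;
  }
};

} // namespace

// column layout of `cpar` (one row per compartment):
// 0 E, 1 emin, 2 emax, 3 vu, 4 height, 5 dvu0g, 6 thoracic, 7 cardiac,
// 8 atrial, 9 vuctl, 10 emaxctl
// `epar`: 0 from, 1 to (0-based), 2 R, 3 valved, 4 rctl
// `lpar`: 0 from, 1 to (0-based), 2 conductance
// `glob`: 0 pit, 1 rho_factor, 2 hr0, 3 aorta index (0-based)
// `rcfg`: 0 set_point, 1 tau_sensor, then per effector (hr, emax, r, vu):
//         gain, tau, lo, hi  (4 blocks of 4)
// [[Rcpp::export]]
List sim_core_cpp(NumericMatrix cpar, NumericMatrix epar, NumericMatrix lpar,
                  NumericMatrix prot, NumericVector glob, NumericVector rcfg,
                  NumericVector v0, double dt, double duration, int stride,
                  double atrial_w0, double sf_coef, bool open_loop) {
  const int n = cpar.nrow(), ne = epar.nrow(), nl = lpar.nrow();
  const double pit = glob[0], rho = glob[1], hr0 = glob[2];
  const int iao = (int)glob[3];

  Protocol pr;
  for (int i = 0; i < prot.nrow(); ++i) {
    pr.t0.push_back(prot(i, 0)); pr.ramp.push_back(prot(i, 1));
    pr.g.push_back(prot(i, 2));  pr.ps.push_back(prot(i, 3));
    pr.sh.push_back(prot(i, 4));
  }

  // unpack compartment params
  std::vector<double> E(n), emin(n), emax(n), vu(n), hh(n), dvu(n);
  std::vector<int> thor(n), card(n), atr(n), vuctl(n), emaxctl(n);
  for (int i = 0; i < n; ++i) {
    E[i] = cpar(i, 0); emin[i] = cpar(i, 1); emax[i] = cpar(i, 2);
    vu[i] = cpar(i, 3); hh[i] = cpar(i, 4); dvu[i] = cpar(i, 5);
    thor[i] = (int)cpar(i, 6); card[i] = (int)cpar(i, 7);
    atr[i] = (int)cpar(i, 8); vuctl[i] = (int)cpar(i, 9);
    emaxctl[i] = (int)cpar(i, 10);
  }
  std::vector<int> ef(ne), et(ne), ev(ne), erc(ne);
  std::vector<double> eR(ne);
  for (int i = 0; i < ne; ++i) {
    ef[i] = (int)epar(i, 0); et[i] = (int)epar(i, 1); eR[i] = epar(i, 2);
    ev[i] = (int)epar(i, 3); erc[i] = (int)epar(i, 4);
  }
  std::vector<int> lf(nl), lt(nl);
  std::vector<double> lc(nl);
  for (int i = 0; i < nl; ++i) {
    lf[i] = (int)lpar(i, 0); lt[i] = (int)lpar(i, 1); lc[i] = lpar(i, 2);
  }

  // reflex configuration
  const double set_point = rcfg[0], tau_s = rcfg[1];
  double gain[4], tauE[4], lo[4], hi[4];
  for (int e = 0; e < 4; ++e) {
    gain[e] = rcfg[2 + 4 * e]; tauE[e] = rcfg[3 + 4 * e];
    lo[e] = rcfg[4 + 4 * e];   hi[e] = rcfg[5 + 4 * e];
  }
  const double esign[4] = {1.0, 1.0, 1.0, -1.0}; // hr, emax, r, vu

  const long nstep = (long)std::llround(duration / dt);
  const int nsamp = (int)(nstep / stride) + 1;

  NumericVector Ts(nsamp), HRs(nsamp), PHs(nsamp), PSs(nsamp),
                SFs(nsamp);
  NumericMatrix Vs(nsamp, n), Ps(nsamp, n), Qs(nsamp, ne), Ls(nsamp, nl),
                Ms(nsamp, 4);
  std::vector<double> beats;

  std::vector<double> V(n), P(n), k1(n), k2(n), k3(n), k4(n), Vt(n), Q(ne),
                      QL(nl);
  for (int i = 0; i < n; ++i) V[i] = v0[i];

  double psense = set_point;
  double m[4] = {1.0, 1.0, 1.0, 1.0};
  double phase = 0.0;
  double hr = hr0;
  double sf = sf_coef * std::sqrt(hr / 60.0);
  if (sf > 0.6) sf = 0.6; if (sf < 0.05) sf = 0.05;

  bool failed = false;
  double fail_t = NA_REAL;
  int isamp = 0;

  // derivative evaluation; fills P (heads), Q, QL for state v at time tt/phase
  auto deriv = [&](const std::vector<double>& v, double tt, double ph,
                   std::vector<double>& dv, bool record) {
    double g, ps, sh;
    pr.sample(tt, g, ps, sh);
    const double geff = g * ps;
    double phm = ph - std::floor(ph);
    for (int i = 0; i < n; ++i) {
      double Enow;
      if (card[i]) {
        double a = atr[i] ? act_atr(phm, atrial_w0) : act_vent(phm, sf);
        double em = emax[i] * (emaxctl[i] ? m[1] : 1.0);
        Enow = emin[i] + (em - emin[i]) * a;
      } else {
        Enow = E[i];
      }
      double vue = vu[i] * (vuctl[i] ? m[3] : 1.0) + dvu[i] * sh;
      double el = Enow * (v[i] - vue);
      if (el < 0.0) el = 0.0;
      P[i] = el + (thor[i] ? pit : 0.0) + geff * hh[i] * rho;
    }
    for (int i = 0; i < n; ++i) dv[i] = 0.0;
    for (int j = 0; j < ne; ++j) {
      double Reff = eR[j] * (erc[j] ? m[2] : 1.0);
      double q = (P[ef[j]] - P[et[j]]) / Reff;
      if (ev[j] && q <= 0.0) q = 0.0;
      // venous-collapse outflow guard on vascular source compartments
      if (q > 0.0 && !card[ef[j]] && vu[ef[j]] > 1.0) {
        double x = (v[ef[j]] - 0.8 * vu[ef[j]]) / (0.1 * vu[ef[j]]);
        q *= sstep(x);
      }
      dv[ef[j]] -= q; dv[et[j]] += q;
      if (record) Q[j] = q;
    }
    for (int j = 0; j < nl; ++j) {
      double q = lc[j] * (P[lf[j]] - P[lt[j]]);
      if (q < 0.0) q = 0.0;
      if (q > 0.0 && vu[lf[j]] > 1.0) {
        double x = (v[lf[j]] - 0.8 * vu[lf[j]]) / (0.1 * vu[lf[j]]);
        q *= sstep(x);
      }
      dv[lf[j]] -= q; dv[lt[j]] += q;
      if (record) QL[j] = q;
    }
  };

  double t = 0.0;
  for (long s = 0; s <= nstep; ++s) {
    const double prate = hr / 60.0;
    // record sample
    if (s % stride == 0 && isamp < nsamp) {
      deriv(V, t, phase, k1, true);
      Ts[isamp] = t; HRs[isamp] = hr; PHs[isamp] = phase; PSs[isamp] = psense;
      SFs[isamp] = sf;
      for (int i = 0; i < n; ++i) { Vs(isamp, i) = V[i]; Ps(isamp, i) = P[i]; }
      for (int j = 0; j < ne; ++j) Qs(isamp, j) = Q[j];
      for (int j = 0; j < nl; ++j) Ls(isamp, j) = QL[j];
      for (int e = 0; e < 4; ++e) Ms(isamp, e) = m[e];
      // stability check at output resolution
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(V[i]) || !std::isfinite(P[i]) || V[i] < -1e-6 ||
            std::fabs(P[i]) > 500.0) {
          failed = true; fail_t = t;
        }
      }
      ++isamp;
      if (failed) break;
    }
    if (s == nstep) break;

    // RK4 on volumes
    deriv(V, t, phase, k1, false);
    for (int i = 0; i < n; ++i) Vt[i] = V[i] + 0.5 * dt * k1[i];
    deriv(Vt, t + 0.5 * dt, phase + 0.5 * dt * prate, k2, false);
    for (int i = 0; i < n; ++i) Vt[i] = V[i] + 0.5 * dt * k2[i];
    deriv(Vt, t + 0.5 * dt, phase + 0.5 * dt * prate, k3, false);
    for (int i = 0; i < n; ++i) Vt[i] = V[i] + dt * k3[i];
    deriv(Vt, t + dt, phase + dt * prate, k4, false);
    for (int i = 0; i < n; ++i)
      V[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    // reflex update (per-step Euler); sensor sees the aortic head
    deriv(V, t + dt, phase + dt * prate, k1, false); // refresh P at new state
    if (!open_loop) {
      psense += dt / tau_s * (P[iao] - psense);
      for (int e = 0; e < 4; ++e) {
        double target = 1.0 + esign[e] * gain[e] * (set_point - psense);
        if (target < lo[e]) target = lo[e];
        if (target > hi[e]) target = hi[e];
        m[e] += dt / tauE[e] * (target - m[e]);
      }
    }
    hr = hr0 * m[0];

    // cardiac phase advance; beat boundary on wrap
    phase += dt * prate;
    t += dt;
    if (phase >= 1.0) {
      phase -= 1.0;
      beats.push_back(t - phase / prate);
      sf = sf_coef * std::sqrt(hr / 60.0);
      if (sf > 0.6) sf = 0.6; if (sf < 0.05) sf = 0.05;
    }
  }

  if (isamp < nsamp) {
    // truncated by failure
    Ts = Ts[Range(0, std::max(isamp - 1, 0))];
  }

  return List::create(
    _["time"] = Ts, _["V"] = Vs, _["P"] = Ps, _["Q"] = Qs, _["QL"] = Ls,
    _["HR"] = HRs, _["phase"] = PHs, _["p_sensed"] = PSs, _["mult"] = Ms,
    _["sf"] = SFs,
    _["beats"] = NumericVector(beats.begin(), beats.end()),
    _["n_recorded"] = isamp, _["failed"] = failed, _["fail_time"] = fail_t);
}
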
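// Implicit integrator for the branched cable equation with
// Hodgkin-Huxley-style membrane mechanisms on a compartment tree.
//
// Voltage is advanced by a backward-Euler (or trapezoid) solve of the
// tree-structured linear system (Hines elimination: children carry larger
// indices than their parent). Gating variables advance by exact
// exponential (Rush-Larsen) updates staggered with the voltage solve,
// using steady-state/time-constant tables precomputed in R from the rate
// functions, so the kinetics are defined in exactly one place.
//
// Units: mV, ms, mS, uA, uF; current densities in mA/cm^2 where the
// calcium and ion-accumulation constants expect them; concentrations mM.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct GateTable {
  double vmin, dv;
  int n;
  const double *inf, *ex; // steady state and exp(-dt/tau) on the grid
};

inline void lookup(const GateTable& t, double v, double& xinf, double& xex) {
  double u = (v - t.vmin) / t.dv;
  if (u <= 0.0) { xinf = t.inf[0]; xex = t.ex[0]; return; }
  if (u >= t.n - 1) { xinf = t.inf[t.n - 1]; xex = t.ex[t.n - 1]; return; }
  int k = (int)u;
  double f = u - k;
  xinf = t.inf[k] + f * (t.inf[k + 1] - t.inf[k]);
  xex  = t.ex[k]  + f * (t.ex[k + 1]  - t.ex[k]);
}

GateTable make_table(const List& tab) {
  GateTable t;
  t.vmin = as<double>(tab["xmin"]);
  t.dv   = as<double>(tab["dx"]);
  NumericVector inf = tab["inf"], ex = tab["ex"];
  t.n = inf.size();
  t.inf = REAL(inf);
  t.ex  = REAL(ex);
  return t;
}

} // namespace

// [[Rcpp::export]]
List cpp_run(List sys, List state0, List ctrl) {
  // ---- topology and passive structure ----
  IntegerVector parent = sys["parent"];       // 1-based, 0 = root
  NumericVector g_ax   = sys["g_axial"];      // mS to parent
  NumericVector area   = sys["area_cm2"];     // cm^2
  NumericVector cm     = sys["cm_uF"];        // uF per compartment
  const int n = parent.size();

  // ---- mechanism conductances (absolute, mS per compartment) ----
  NumericVector gna   = sys["g_na"],  gkdr = sys["g_kdr"], gkcnq = sys["g_kcnq"];
  NumericVector gca   = sys["g_ca"],  gsk  = sys["g_sk"],  gleak = sys["g_leak"];
  NumericVector eleak = sys["e_leak"];
  NumericVector ena0  = sys["e_na"],  ek0  = sys["e_k"];   // fixed reversals (mV)

  // gate rate tables (over V except SK which is over log10(Ca))
  List tabs = sys["tables"];
  GateTable Tm  = make_table(tabs["nav_m"]),  Th = make_table(tabs["nav_h"]);
  GateTable Tn  = make_table(tabs["kdr_n"]),  Tl = make_table(tabs["kdr_l"]);
  GateTable Tq  = make_table(tabs["kcnq_m"]), Tc = make_table(tabs["cav_m"]);
  GateTable Ts  = make_table(tabs["sk_q"]);

  // calcium dynamics
  const double ca_rest = as<double>(sys["ca_rest"]);   // mM
  const double ca_k    = as<double>(sys["ca_k"]);      // mM/ms per mA/cm^2
  const double ca_tau  = as<double>(sys["ca_tau"]);    // ms
  const double eca_coef = as<double>(sys["eca_coef"]); // RT/2F in mV
  const double ca_out  = as<double>(sys["ca_out"]);    // mM

  // pump and ion accumulation
  const bool pump_on = as<bool>(sys["pump_on"]);
  const bool ions_on = as<bool>(sys["ions_on"]);
  NumericVector ipump_max = sys["ipump_max"];          // mA/cm^2 per compartment
  const double pump_km = as<double>(sys["pump_km"]);   // mM
  NumericVector fin  = sys["flux_in"];   // mM/ms per mA/cm^2, intracellular pool
  NumericVector fout = sys["flux_out"];  // mM/ms per mA/cm^2, periaxonal shell
  NumericVector base_na = sys["base_flux_na"], base_k = sys["base_flux_k"]; // mA/cm^2
  const double rt_f = as<double>(sys["rt_f"]);         // RT/F in mV

  // stimuli: columns comp(1-based), onset, width, period, npulse, amp_nA
  NumericMatrix stim = sys["stimuli"];

  // ---- state ----
  NumericVector V  = clone(as<NumericVector>(state0["v"]));
  NumericVector m  = clone(as<NumericVector>(state0["m"]));
  NumericVector h  = clone(as<NumericVector>(state0["h"]));
  NumericVector nn = clone(as<NumericVector>(state0["n"]));
  NumericVector ll = clone(as<NumericVector>(state0["l"]));
  NumericVector mq = clone(as<NumericVector>(state0["mq"]));
  NumericVector mc = clone(as<NumericVector>(state0["mc"]));
  NumericVector qq = clone(as<NumericVector>(state0["q"]));
  NumericVector ca = clone(as<NumericVector>(state0["ca"]));
  NumericVector nai = clone(as<NumericVector>(state0["na_i"]));
  NumericVector nao = clone(as<NumericVector>(state0["na_o"]));
  NumericVector ki  = clone(as<NumericVector>(state0["k_i"]));
  NumericVector ko  = clone(as<NumericVector>(state0["k_o"]));

  // ---- control ----
  const double dt = as<double>(ctrl["dt"]);
  const int nsteps = as<int>(ctrl["nsteps"]);
  const int stride = as<int>(ctrl["stride"]);
  IntegerVector rec = ctrl["record"];                  // 1-based compartment ids
  const bool trapezoid = as<bool>(ctrl["trapezoid"]);
  const bool rec_extra = as<bool>(ctrl["record_extra"]);
  const int nrec = rec.size();
  const int nout = nsteps / stride + 1;

  NumericMatrix Vout(nout, nrec);
  NumericVector tout(nout);
  NumericMatrix CAout, ENAout, EKout, INAout, IKout;
  if (rec_extra) {
    CAout = NumericMatrix(nout, nrec);  ENAout = NumericMatrix(nout, nrec);
    EKout = NumericMatrix(nout, nrec);  INAout = NumericMatrix(nout, nrec);
    IKout = NumericMatrix(nout, nrec);
  }
  NumericVector vmax(n, -1e30); // per-compartment running maximum of V

  // work arrays
  std::vector<double> diag(n), rhs(n), ena(n), ek(n);
  for (int i = 0; i < n; ++i) { ena[i] = ena0[i]; ek[i] = ek0[i]; }

  // membrane evaluation shared by output and assembly
  const int nstim = stim.nrow();

  auto record_row = [&](int row, double t) {
    tout[row] = t;
    for (int r = 0; r < nrec; ++r) {
      int i = rec[r] - 1;
      Vout(row, r) = V[i];
      if (rec_extra) {
        CAout(row, r)  = ca[i];
        ENAout(row, r) = ena[i];
        EKout(row, r)  = ek[i];
        double a = area[i] > 0 ? area[i] : 1.0;
        double ipmp = pump_on ? ipump_max[i] * nai[i] / (nai[i] + pump_km) : 0.0;
        // channel current densities in mA/cm^2 (outward positive)
        INAout(row, r) = 1e-3 * gna[i]  * m[i]*m[i]*m[i]*h[i] * (V[i] - ena[i]) / a
                         + 3.0 * ipmp;
        IKout(row, r)  = 1e-3 * (gkdr[i] * nn[i]*nn[i]*nn[i]*ll[i]
                         + gkcnq[i] * mq[i] + gsk[i] * qq[i]*qq[i]) * (V[i] - ek[i]) / a
                         - 2.0 * ipmp;
      }
    }
  };

  record_row(0, 0.0);
  for (int i = 0; i < n; ++i) if (V[i] > vmax[i]) vmax[i] = V[i];

  int row = 1;
  for (int step = 1; step <= nsteps; ++step) {
    const double t0 = (step - 1) * dt;   // time at start of step
    const double tmid = t0 + 0.5 * dt;   // stimulus evaluated mid-step

    // 1. gating: exact exponential update at V^n
    for (int i = 0; i < n; ++i) {
      const double v = V[i];
      double xinf, xex;
      if (gna[i] > 0) {
        lookup(Tm, v, xinf, xex); m[i] = xinf + (m[i] - xinf) * xex;
        lookup(Th, v, xinf, xex); h[i] = xinf + (h[i] - xinf) * xex;
      }
      if (gkdr[i] > 0) {
        lookup(Tn, v, xinf, xex); nn[i] = xinf + (nn[i] - xinf) * xex;
        lookup(Tl, v, xinf, xex); ll[i] = xinf + (ll[i] - xinf) * xex;
      }
      if (gkcnq[i] > 0) {
        lookup(Tq, v, xinf, xex); mq[i] = xinf + (mq[i] - xinf) * xex;
      }
      if (gca[i] > 0) {
        lookup(Tc, v, xinf, xex); mc[i] = xinf + (mc[i] - xinf) * xex;
        // calcium pool driven by I_Ca (mA/cm^2): dCa/dt = -k*I - (Ca-rest)/tau
        const double ecai = eca_coef * std::log(ca_out / ca[i]);
        const double ica = 1e-3 * gca[i] * mc[i] * mc[i] * (v - ecai) / area[i];
        const double cainf = ca_rest - ca_k * ica * ca_tau;
        ca[i] = cainf + (ca[i] - cainf) * std::exp(-dt / ca_tau);
        if (ca[i] < 1e-9) ca[i] = 1e-9;
      }
      if (gsk[i] > 0) {
        const double u = std::log10(ca[i]);
        lookup(Ts, u, xinf, xex); qq[i] = xinf + (qq[i] - xinf) * xex;
      }
    }

    // 2. ion accumulation (explicit) and reversal update
    if (ions_on) {
      for (int i = 0; i < n; ++i) {
        if (area[i] <= 0) continue;
        const double v = V[i];
        double ina = 1e-3 * gna[i] * m[i]*m[i]*m[i]*h[i] * (v - ena[i]) / area[i];
        double ik  = 1e-3 * (gkdr[i] * nn[i]*nn[i]*nn[i]*ll[i]
                     + gkcnq[i] * mq[i] + gsk[i] * qq[i]*qq[i]) * (v - ek[i]) / area[i];
        if (pump_on) {
          const double ipmp = ipump_max[i] * nai[i] / (nai[i] + pump_km);
          ina += 3.0 * ipmp;
          ik  -= 2.0 * ipmp;
        }
        // activity-dependent flux relative to the resting baseline
        ina -= base_na[i];
        ik  -= base_k[i];
        nai[i] += -ina * fin[i]  * dt;
        nao[i] +=  ina * fout[i] * dt;
        ki[i]  += -ik  * fin[i]  * dt;
        ko[i]  +=  ik  * fout[i] * dt;
        if (nai[i] < 1e-3) nai[i] = 1e-3;
        if (nao[i] < 1e-3) nao[i] = 1e-3;
        if (ki[i]  < 1e-3) ki[i]  = 1e-3;
        if (ko[i]  < 1e-3) ko[i]  = 1e-3;
        ena[i] = rt_f * std::log(nao[i] / nai[i]);
        ek[i]  = rt_f * std::log(ko[i] / ki[i]);
      }
    }

    // 3. assemble linear system for V^{n+1}
    for (int i = 0; i < n; ++i) {
      double G = gleak[i];
      double src = gleak[i] * eleak[i];
      if (gna[i] > 0) {
        const double g = gna[i] * m[i]*m[i]*m[i]*h[i];
        G += g; src += g * ena[i];
      }
      if (gkdr[i] > 0) {
        const double g = gkdr[i] * nn[i]*nn[i]*nn[i]*ll[i];
        G += g; src += g * ek[i];
      }
      if (gkcnq[i] > 0) {
        const double g = gkcnq[i] * mq[i];
        G += g; src += g * ek[i];
      }
      if (gca[i] > 0) {
        const double ecai = eca_coef * std::log(ca_out / ca[i]);
        const double g = gca[i] * mc[i] * mc[i];
        G += g; src += g * ecai;
      }
      if (gsk[i] > 0) {
        const double g = gsk[i] * qq[i] * qq[i];
        G += g; src += g * ek[i];
      }
      if (pump_on && area[i] > 0) {
        // net electrogenic pump current, uA (outward positive)
        src -= 1e3 * area[i] * ipump_max[i] * nai[i] / (nai[i] + pump_km);
      }
      if (trapezoid) {
        diag[i] = cm[i] / dt + 0.5 * G;
        rhs[i]  = (cm[i] / dt - 0.5 * G) * V[i] + src;
      } else {
        diag[i] = cm[i] / dt + G;
        rhs[i]  = cm[i] / dt * V[i] + src;
      }
    }
    // stimulus currents (nA -> uA)
    for (int s = 0; s < nstim; ++s) {
      const double onset = stim(s, 1), width = stim(s, 2);
      const double period = stim(s, 3);
      const int npulse = (int)stim(s, 4);
      if (tmid < onset) continue;
      double rel = tmid - onset;
      int k = period > 0 ? (int)(rel / period) : 0;
      if (k >= npulse) continue;
      const double phase = rel - k * period;
      if (phase <= width) rhs[(int)stim(s, 0) - 1] += 1e-3 * stim(s, 5);
    }
    // axial coupling
    const double w = trapezoid ? 0.5 : 1.0;
    for (int i = 1; i < n; ++i) {  // root has no parent
      const int p = parent[i] - 1;
      const double g = g_ax[i];
      diag[i] += w * g;
      diag[p] += w * g;
      if (trapezoid) {
        const double ax = 0.5 * g * (V[p] - V[i]);
        rhs[i] += ax;
        rhs[p] -= ax;
      }
    }
    // Hines elimination (children have larger indices than parents)
    for (int i = n - 1; i >= 1; --i) {
      const int p = parent[i] - 1;
      const double f = (-w * g_ax[i]) / diag[i];
      diag[p] -= f * (-w * g_ax[i]);
      rhs[p]  -= f * rhs[i];
    }
    V[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      const int p = parent[i] - 1;
      V[i] = (rhs[i] + w * g_ax[i] * V[p]) / diag[i];
    }

    for (int i = 0; i < n; ++i) {
      if (V[i] > vmax[i]) vmax[i] = V[i];
      if (!std::isfinite(V[i]))
        stop("numerical failure: non-finite voltage at compartment %d, t = %.4f ms",
             i + 1, step * dt);
    }
    if (step % stride == 0) record_row(row++, step * dt);
  }

  List fin_state = List::create(
    _["v"] = V, _["m"] = m, _["h"] = h, _["n"] = nn, _["l"] = ll,
    _["mq"] = mq, _["mc"] = mc, _["q"] = qq, _["ca"] = ca,
    _["na_i"] = nai, _["na_o"] = nao, _["k_i"] = ki, _["k_o"] = ko);

  List out = List::create(
    _["time"] = tout, _["v"] = Vout, _["vmax"] = vmax,
    _["state"] = fin_state);
  if (rec_extra) {
    out["ca"] = CAout; out["e_na"] = ENAout; out["e_k"] = EKout;
    out["i_na"] = INAout; out["i_k"] = IKout;
  }
  return out;
}
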
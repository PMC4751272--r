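// Cable-equation time-stepping kernel.
//
// All state vectors arrive in SOLVE ORDER: a reversed Cuthill-McKee
// permutation of the morphology vertices under which every vertex has at
// most one neighbour with a larger index (its tree parent, `sup`).  The
// implicit axial system (diag(C/dt) + Laplacian) then factorizes without
// fill in a single O(n) sweep -- the linear-complexity sparse LU the
// tree structure affords.
//
// Scheme per step (mixed implicit/explicit Euler):
//   1. CFL estimate: dt = min(dt_max, safety * min_i C_i / Gmem_i) with
//      Gmem the present total membrane conductance (channels at current
//      gate states + active synapses).
//   2. Inner states (HH gates, VDCC gates, synapse activations) advance
//      explicitly from the PREVIOUS step's solution only.
//   3. Membrane currents evaluated at the previous solution (outward
//      positive), axial fluxes treated implicitly; tree solve.
//   4. Same structure for the calcium species (axial diffusion implicit,
//      membrane fluxes explicit).
//
// Units are SI throughout (V, s, S, A, m); concentrations in mM
// (= mol m^-3).  HH rate functions work in mV-above-rest and 1/ms as
// originally published.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double FARADAY = 96485.33212;
static const double GAS_R = 8.31446;

struct HHRates { double an, bn, am, bm, ah, bh; };

// x / (exp(x/10) - 1) with the analytic limit 10 - x/2 near x = 0
static inline double expm1_frac(double x) {
  if (std::fabs(x) < 1e-7) return 10.0 - x / 2.0;
  return x / std::expm1(x / 10.0);
}

static inline HHRates hh_rates(double v_mV) {
  HHRates r;
  r.an = 0.01 * expm1_frac(10.0 - v_mV);
  r.bn = 0.125 * std::exp(-v_mV / 80.0);
  r.am = 0.1 * expm1_frac(25.0 - v_mV);
  r.bm = 4.0 * std::exp(-v_mV / 18.0);
  r.ah = 0.07 * std::exp(-v_mV / 20.0);
  r.bh = 1.0 / (std::exp((30.0 - v_mV) / 10.0) + 1.0);
  return r;
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// GHK current density per unit permeability, divalent ion, mM == mol/m^3
static inline double ghk(double V, double ca_in, double ca_out, double rtfz) {
  double u = V / rtfz;             // z F V / (R T)
  if (std::fabs(u) < 1e-9) return 2.0 * FARADAY * (ca_in - ca_out);
  double e = std::exp(-u);
  return 2.0 * FARADAY * u * (ca_in - ca_out * e) / (1.0 - e);
}

// Solve (diag(dg) + L(g_sup)) x = b in place, where the off-diagonal entry
// of row k is -g_sup[k] in column sup[k] (> k).  O(n), no fill.
static void tree_solve(const IntegerVector &sup, const NumericVector &g_sup,
                       std::vector<double> &dg, std::vector<double> &b,
                       std::vector<double> &x) {
  int n = dg.size();
  for (int k = 0; k < n; ++k) {
    int p = sup[k];
    if (p >= 0) {
      double g = g_sup[k];
      dg[p] -= g * g / dg[k];
      b[p] += g * b[k] / dg[k];
    }
  }
  for (int k = n - 1; k >= 0; --k) {
    int p = sup[k];
    double rhs = b[k] + (p >= 0 ? g_sup[k] * x[p] : 0.0);
    x[k] = rhs / dg[k];
  }
}

// [[Rcpp::export]]
List cable_kernel(List mesh, List membrane, List calcium, List syn_primary,
                  List syn_inter, List injections, List state, double t_end,
                  double dt_max, double safety, double dt_fixed,
                  double record_dt, IntegerVector probes, int max_steps,
                  bool record_dt_history) {
  // --- unpack mesh (solve order) ---
  IntegerVector sup = mesh["sup"];            // 0-based, -1 for none
  NumericVector g_sup = mesh["g_sup"];        // S
  NumericVector Cm = mesh["Cm"];              // F
  NumericVector area = mesh["area"];          // m^2
  NumericVector sumG = mesh["sumG"];          // S
  IntegerVector region = mesh["region"];      // 0 axon, 1 soma, 2 dendrite
  int n = sup.size();

  // --- membrane ---
  bool hh_on = as<bool>(membrane["hh_on"]);
  bool leak_on = as<bool>(membrane["leak_on"]);
  NumericVector gK = membrane["g_K"], gNa = membrane["g_Na"],
                gl = membrane["g_l"], El = membrane["E_l"];
  double EK = membrane["E_K"], ENa = membrane["E_Na"],
         Vr = membrane["V_r"], cT = membrane["c_T"];

  // --- calcium ---
  bool ca_on = as<bool>(calcium["on"]);
  NumericVector vol, gc_sup, sum_gc;
  double ca_ext = 0, rtfz = 1, P_vdcc = 0, z_m = 0, V12_m = 0, tau_m = 1,
         p_m = 1, z_h = 0, V12_h = 0, tau_h = 1, ncx_f = 0, ncx_K = 1,
         pmca_f = 0, pmca_K = 1, ca_leak = 0, ampa_frac = 0, kT = 1;
  if (ca_on) {
    vol = as<NumericVector>(calcium["vol"]);
    gc_sup = as<NumericVector>(calcium["gc_sup"]);
    sum_gc = as<NumericVector>(calcium["sum_gc"]);
    ca_ext = as<double>(calcium["ca_ext"]);
    double temperature = as<double>(calcium["temperature"]);
    rtfz = GAS_R * temperature / (2.0 * FARADAY);
    kT = FARADAY / (GAS_R * temperature);
    P_vdcc = as<double>(calcium["P"]);
    z_m = as<double>(calcium["z_m"]); V12_m = as<double>(calcium["V12_m"]);
    tau_m = as<double>(calcium["tau_m"]); p_m = as<double>(calcium["p_m"]);
    z_h = as<double>(calcium["z_h"]); V12_h = as<double>(calcium["V12_h"]);
    tau_h = as<double>(calcium["tau_h"]);
    ncx_f = as<double>(calcium["ncx_f"]); ncx_K = as<double>(calcium["ncx_K"]);
    pmca_f = as<double>(calcium["pmca_f"]);
    pmca_K = as<double>(calcium["pmca_K"]);
    ca_leak = as<double>(calcium["leak"]);
    ampa_frac = as<double>(calcium["ampa_frac"]);
  }

  // --- primary synapses (alpha kinetics, SI) ---
  IntegerVector ps_vertex = syn_primary["vertex"];
  NumericVector ps_onset = syn_primary["onset"], ps_tau = syn_primary["tau"],
                ps_gmax = syn_primary["gmax"], ps_erev = syn_primary["erev"];
  int n_ps = ps_vertex.size();

  // --- interconnecting synapses ---
  IntegerVector is_pre = syn_inter["pre_vertex"], is_post = syn_inter["post_vertex"];
  NumericVector is_gmax = syn_inter["gmax"], is_tau1 = syn_inter["tau1"],
                is_tau2 = syn_inter["tau2"], is_erev = syn_inter["erev"],
                is_vth = syn_inter["vth"], is_norm = syn_inter["norm"];
  LogicalVector is_active0 = syn_inter["active"];
  List is_events0 = syn_inter["events"];
  int n_is = is_pre.size();
  std::vector<char> is_active(n_is);
  std::vector< std::vector<double> > is_events(n_is);
  for (int s = 0; s < n_is; ++s) {
    is_active[s] = is_active0[s];
    NumericVector ev = is_events0[s];
    is_events[s].assign(ev.begin(), ev.end());
  }

  // --- injections ---
  IntegerVector inj_vertex = injections["vertex"];
  NumericVector inj_amp = injections["amp"], inj_t0 = injections["t0"],
                inj_t1 = injections["t1"];
  int n_inj = inj_vertex.size();

  // --- state ---
  std::vector<double> V = as< std::vector<double> >(state["V"]);
  std::vector<double> gn = as< std::vector<double> >(state["n"]);
  std::vector<double> gm = as< std::vector<double> >(state["m"]);
  std::vector<double> gh = as< std::vector<double> >(state["h"]);
  std::vector<double> ca, vm, vh;
  if (ca_on) {
    ca = as< std::vector<double> >(state["ca"]);
    vm = as< std::vector<double> >(state["vdcc_m"]);
    vh = as< std::vector<double> >(state["vdcc_h"]);
  }
  double t = as<double>(state["t"]);

  // --- recording ---
  int n_probe = probes.size();
  std::vector<double> rec_times;
  std::vector<double> rec_V, rec_ca;  // row-major n_probe columns
  std::vector<double> dts, dt_times;
  double next_rec = t + record_dt;

  std::vector<double> gmem(n), Iout(n), dg(n), b(n), x(n);
  std::vector<double> dgc(n), bc(n), xc(n), jout(n);

  int step_count = 0;
  while (t < t_end - 1e-15 && step_count < max_steps) {
    // 1. membrane conductance now -> CFL estimate
    for (int i = 0; i < n; ++i) {
      int r = region[i];
      double g = 0.0;
      if (hh_on)
        g += cT * (gK[r] * gn[i]*gn[i]*gn[i]*gn[i] +
                   gNa[r] * gm[i]*gm[i]*gm[i] * gh[i]);
      if (leak_on) g += cT * gl[r];
      gmem[i] = g * area[i];
    }
    for (int s = 0; s < n_ps; ++s) {
      double ts = t - ps_onset[s];
      if (ts >= 0 && ts <= 6.0 * ps_tau[s]) {
        double g = ps_gmax[s] * (ts / ps_tau[s]) *
                   std::exp(-(ts - ps_tau[s]) / ps_tau[s]);
        gmem[ps_vertex[s]] += g;
      }
    }
    for (int s = 0; s < n_is; ++s) {
      const std::vector<double> &ev = is_events[s];
      if (ev.empty()) continue;
      double g = 0.0, cutoff = 20.0 * is_tau2[s];
      for (size_t k = 0; k < ev.size(); ++k) {
        double ts = t - ev[k];
        if (ts >= 0 && ts < cutoff)
          g += is_gmax[s] * is_norm[s] *
               (std::exp(-ts / is_tau2[s]) - std::exp(-ts / is_tau1[s]));
      }
      gmem[is_post[s]] += g;
    }

    double dt;
    if (dt_fixed > 0) {
      dt = dt_fixed;
    } else {
      dt = dt_max;
      for (int i = 0; i < n; ++i) {
        if (gmem[i] > 0) {
          double lim = safety * Cm[i] / gmem[i];
          if (lim < dt) dt = lim;
        }
      }
      if (t + dt > next_rec && record_dt > 0) dt = next_rec - t;
      if (t + dt > t_end) dt = t_end - t;
      if (dt <= 0) dt = 1e-12;
    }

    // 2. explicit inner-state updates from the previous solution
    double dt_ms = dt * 1e3;
    if (hh_on) {
      for (int i = 0; i < n; ++i) {
        double v_mV = (V[i] - Vr) * 1e3;
        HHRates r = hh_rates(v_mV);
        gn[i] = clamp01(gn[i] + cT * (r.an * (1 - gn[i]) - r.bn * gn[i]) * dt_ms);
        gm[i] = clamp01(gm[i] + cT * (r.am * (1 - gm[i]) - r.bm * gm[i]) * dt_ms);
        gh[i] = clamp01(gh[i] + cT * (r.ah * (1 - gh[i]) - r.bh * gh[i]) * dt_ms);
      }
    }
    if (ca_on) {
      for (int i = 0; i < n; ++i) {
        double m_inf = 1.0 / (1.0 + std::exp(-z_m * (V[i] - V12_m) * kT));
        double h_inf = 1.0 / (1.0 + std::exp(-z_h * (V[i] - V12_h) * kT));
        vm[i] = clamp01(vm[i] + dt / tau_m * (m_inf - vm[i]));
        vh[i] = clamp01(vh[i] + dt / tau_h * (h_inf - vh[i]));
      }
    }
    // synapse activation from previous-step presynaptic potential; a new
    // event at time t contributes zero conductance at t itself, so its
    // effect arrives one step later (the structural one-step lag)
    for (int s = 0; s < n_is; ++s) {
      bool above = V[is_pre[s]] >= is_vth[s];
      if (above && !is_active[s]) is_events[s].push_back(t);
      is_active[s] = above;
    }

    // 3. membrane currents at the previous solution (outward positive)
    for (int i = 0; i < n; ++i) {
      int r = region[i];
      double i_dens = 0.0;
      if (hh_on)
        i_dens += cT * (gK[r] * gn[i]*gn[i]*gn[i]*gn[i] * (V[i] - EK) +
                        gNa[r] * gm[i]*gm[i]*gm[i] * gh[i] * (V[i] - ENa));
      if (leak_on) i_dens += cT * gl[r] * (V[i] - El[r]);
      Iout[i] = i_dens * area[i];
      if (ca_on) jout[i] = 0.0;
    }
    for (int s = 0; s < n_ps; ++s) {
      double ts = t - ps_onset[s];
      if (ts >= 0 && ts <= 6.0 * ps_tau[s]) {
        double g = ps_gmax[s] * (ts / ps_tau[s]) *
                   std::exp(-(ts - ps_tau[s]) / ps_tau[s]);
        int i = ps_vertex[s];
        double Is = g * (V[i] - ps_erev[s]);
        Iout[i] += Is;
        if (ca_on) jout[i] += ampa_frac * Is / (2.0 * FARADAY * area[i]);
      }
    }
    for (int s = 0; s < n_is; ++s) {
      const std::vector<double> &ev = is_events[s];
      if (ev.empty()) continue;
      double g = 0.0, cutoff = 20.0 * is_tau2[s];
      for (size_t k = 0; k < ev.size(); ++k) {
        double ts = t - ev[k];
        if (ts >= 0 && ts < cutoff)
          g += is_gmax[s] * is_norm[s] *
               (std::exp(-ts / is_tau2[s]) - std::exp(-ts / is_tau1[s]));
      }
      int i = is_post[s];
      double Is = g * (V[i] - is_erev[s]);
      Iout[i] += Is;
      if (ca_on) jout[i] += ampa_frac * Is / (2.0 * FARADAY * area[i]);
    }
    for (int k = 0; k < n_inj; ++k) {
      if (t >= inj_t0[k] && t < inj_t1[k]) Iout[inj_vertex[k]] -= inj_amp[k];
    }

    // 4. implicit axial solve for V
    for (int i = 0; i < n; ++i) {
      dg[i] = Cm[i] / dt + sumG[i];
      b[i] = Cm[i] / dt * V[i] - Iout[i];
    }
    tree_solve(sup, g_sup, dg, b, x);
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1.0) {
        stop("membrane potential diverged at t = %g s (dt = %g s); "
             "the explicit membrane part violates its CFL bound "
             "min(C_m/G_mem) -- reduce dt_max or the safety factor", t, dt);
      }
    }

    // 5. calcium species: membrane fluxes explicit, axial diffusion implicit
    if (ca_on) {
      for (int i = 0; i < n; ++i) {
        double open = std::pow(vm[i], p_m) * vh[i];
        double i_vdcc = open * P_vdcc * ghk(V[i], ca[i], ca_ext, rtfz);
        double j = i_vdcc / (2.0 * FARADAY)
                 + ncx_f * ca[i] / (ncx_K + ca[i])
                 + pmca_f * ca[i] * ca[i] / (pmca_K * pmca_K + ca[i] * ca[i])
                 - ca_leak;
        jout[i] += j;
        dgc[i] = vol[i] / dt + sum_gc[i];
        bc[i] = vol[i] / dt * ca[i] - jout[i] * area[i];
      }
      tree_solve(sup, gc_sup, dgc, bc, xc);
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(xc[i]))
          stop("calcium concentration diverged at t = %g s (dt = %g s)", t, dt);
        ca[i] = xc[i] < 0 ? 0.0 : xc[i];
      }
    }

    for (int i = 0; i < n; ++i) V[i] = x[i];
    t += dt;
    ++step_count;
    if (record_dt_history) { dts.push_back(dt); dt_times.push_back(t); }

    if (record_dt > 0 && t >= next_rec - 1e-15) {
      rec_times.push_back(t);
      for (int p = 0; p < n_probe; ++p) {
        rec_V.push_back(V[probes[p]]);
        if (ca_on) rec_ca.push_back(ca[probes[p]]);
      }
      next_rec += record_dt;
    }
  }

  // package results
  int n_rec = rec_times.size();
  NumericMatrix trace_V(n_rec, n_probe), trace_ca(ca_on ? n_rec : 0, n_probe);
  for (int r = 0; r < n_rec; ++r)
    for (int p = 0; p < n_probe; ++p) {
      trace_V(r, p) = rec_V[r * n_probe + p];
      if (ca_on) trace_ca(r, p) = rec_ca[r * n_probe + p];
    }

  List events(n_is);
  LogicalVector active_out(n_is);
  for (int s = 0; s < n_is; ++s) {
    events[s] = NumericVector(is_events[s].begin(), is_events[s].end());
    active_out[s] = (bool)is_active[s];
  }

  List out_state = List::create(
    _["V"] = NumericVector(V.begin(), V.end()),
    _["n"] = NumericVector(gn.begin(), gn.end()),
    _["m"] = NumericVector(gm.begin(), gm.end()),
    _["h"] = NumericVector(gh.begin(), gh.end()),
    _["t"] = t);
  if (ca_on) {
    out_state["ca"] = NumericVector(ca.begin(), ca.end());
    out_state["vdcc_m"] = NumericVector(vm.begin(), vm.end());
    out_state["vdcc_h"] = NumericVector(vh.begin(), vh.end());
  }

  return List::create(
    _["state"] = out_state,
    _["times"] = NumericVector(rec_times.begin(), rec_times.end()),
    _["trace_V"] = trace_V,
    _["trace_ca"] = trace_ca,
    _["events"] = events,
    _["active"] = active_out,
    _["steps"] = step_count,
    _["dt_history"] = NumericVector(dts.begin(), dts.end()),
    _["dt_times"] = NumericVector(dt_times.begin(), dt_times.end()));
}

// Minimum distances between two sets of 3D segments, with cell-list
// binning at the cutoff radius.  Returns pairs (i, j, distance) with
// distance < cutoff.  Used by the distance-rule synapse generator.
static inline double seg_seg_dist2(const double *p1, const double *q1,
                                   const double *p2, const double *q2,
                                   double &s_out, double &t_out) {
  // closest points of segments [p1,q1], [p2,q2] (Ericson, Real-Time
  // Collision Detection, 5.1.9)
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = q1[k] - p1[k]; d2[k] = q2[k] - p2[k]; r[k] = p1[k] - p2[k];
  }
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  double s, tt;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { s = tt = 0.0; }
  else if (a <= EPS) { s = 0.0; tt = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (e <= EPS) { tt = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double bb = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
      double denom = a * e - bb * bb;
      s = denom > EPS ? std::min(1.0, std::max(0.0, (bb * f - c * e) / denom)) : 0.0;
      tt = (bb * s + f) / e;
      if (tt < 0.0) { tt = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (tt > 1.0) { tt = 1.0; s = std::min(1.0, std::max(0.0, (bb - c) / a)); }
    }
  }
  double c1[3], c2[3], dd = 0.0;
  for (int k = 0; k < 3; ++k) {
    c1[k] = p1[k] + d1[k] * s;
    c2[k] = p2[k] + d2[k] * tt;
    dd += (c1[k] - c2[k]) * (c1[k] - c2[k]);
  }
  s_out = s; t_out = tt;
  return dd;
}

// [[Rcpp::export]]
List segment_pairs_within(NumericMatrix a_p, NumericMatrix a_q,
                          NumericMatrix b_p, NumericMatrix b_q,
                          double cutoff) {
  int na = a_p.nrow(), nb = b_p.nrow();
  // bin B segments by midpoint on a grid of cell size = cutoff + max B
  // segment half-length (so a segment is findable from any bin its
  // capsule of radius `cutoff` touches via the 27-neighbourhood)
  double max_half = 0.0;
  for (int j = 0; j < nb; ++j) {
    double l2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = b_q(j, k) - b_p(j, k);
      l2 += d * d;
    }
    max_half = std::max(max_half, std::sqrt(l2) / 2.0);
  }
  for (int i = 0; i < na; ++i) {
    double l2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = a_q(i, k) - a_p(i, k);
      l2 += d * d;
    }
    max_half = std::max(max_half, std::sqrt(l2) / 2.0);
  }
  double cell = cutoff + 2.0 * max_half + 1e-9;

  double lo[3] = {1e300, 1e300, 1e300};
  for (int j = 0; j < nb; ++j)
    for (int k = 0; k < 3; ++k)
      lo[k] = std::min(lo[k], std::min(b_p(j, k), b_q(j, k)));

  auto bin_index = [&](double mx, double my, double mz, int &ix, int &iy, int &iz) {
    ix = (int)std::floor((mx - lo[0]) / cell);
    iy = (int)std::floor((my - lo[1]) / cell);
    iz = (int)std::floor((mz - lo[2]) / cell);
  };
  std::map<long long, std::vector<int> > bins;
  auto key = [](int ix, int iy, int iz) {
    return ((long long)(ix + 1048576) << 42) |
           ((long long)(iy + 1048576) << 21) | (long long)(iz + 1048576);
  };
  for (int j = 0; j < nb; ++j) {
    int ix, iy, iz;
    bin_index((b_p(j,0) + b_q(j,0)) / 2, (b_p(j,1) + b_q(j,1)) / 2,
              (b_p(j,2) + b_q(j,2)) / 2, ix, iy, iz);
    bins[key(ix, iy, iz)].push_back(j);
  }

  std::vector<int> out_i, out_j;
  std::vector<double> out_d, out_s, out_t;
  double cutoff2 = cutoff * cutoff;
  for (int i = 0; i < na; ++i) {
    double p1[3] = {a_p(i,0), a_p(i,1), a_p(i,2)};
    double q1[3] = {a_q(i,0), a_q(i,1), a_q(i,2)};
    int ix, iy, iz;
    bin_index((p1[0]+q1[0])/2, (p1[1]+q1[1])/2, (p1[2]+q1[2])/2, ix, iy, iz);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          std::map<long long, std::vector<int> >::iterator it =
            bins.find(key(ix + dx, iy + dy, iz + dz));
          if (it == bins.end()) continue;
          const std::vector<int> &cand = it->second;
          for (size_t c = 0; c < cand.size(); ++c) {
            int j = cand[c];
            double p2[3] = {b_p(j,0), b_p(j,1), b_p(j,2)};
            double q2[3] = {b_q(j,0), b_q(j,1), b_q(j,2)};
            double s, tt;
            double d2 = seg_seg_dist2(p1, q1, p2, q2, s, tt);
            if (d2 < cutoff2) {
              out_i.push_back(i + 1);
              out_j.push_back(j + 1);
              out_d.push_back(std::sqrt(d2));
              out_s.push_back(s);
              out_t.push_back(tt);
            }
          }
        }
  }
  return List::create(_["i"] = out_i, _["j"] = out_j, _["distance"] = out_d,
                      _["offset_i"] = out_s, _["offset_j"] = out_t);
}
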
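// Conductance-based E-I network core: Hodgkin-Huxley interneurons,
// two-compartment pyramidal cells, AMPA/NMDA/GABA receptor kinetics,
// Poisson background drive, Heun (second-order Runge-Kutta) integration.
// Units: mV, ms, nA, uS, nF, uM throughout (g/C in 1/ms, I/C in mV/ms).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// alpha expressions of the form a*u/(1 - exp(-0.1*u)) have a removable
// singularity at u = 0 with analytic limit 10*a.
inline double trap01(double a, double u) {
  if (std::fabs(u) < 1e-7) return 10.0 * a;
  return a * u / (1.0 - std::exp(-0.1 * u));
}

struct Rates { double am, bm, ah, bh, an, bn; };

inline Rates int_rates(double V, bool printed_bn) {
  Rates r;
  r.am = trap01(0.1, V + 35.0);
  r.bm = 4.0 * std::exp(-(V + 60.0) / 18.0);
  r.ah = 0.07 * std::exp(-(V + 58.0) / 20.0);
  r.bh = 1.0 / (1.0 + std::exp(-0.1 * (V + 28.0)));
  r.an = trap01(0.01, V + 34.0);
  r.bn = printed_bn ? 1.0 / (1.0 + std::exp(-0.1 * (V + 44.0) / 80.0))
                    : 0.125 * std::exp(-(V + 44.0) / 80.0);
  return r;
}

inline Rates pyr_rates(double V) {
  Rates r;
  r.am = trap01(0.1, V + 33.0);
  r.bm = 4.0 * std::exp(-(V + 58.0) / 12.0);
  r.ah = 0.07 * std::exp(-0.1 * (V + 50.0));
  r.bh = 1.0 / (1.0 + std::exp(-0.1 * (V + 20.0)));
  r.an = trap01(0.01, V + 33.0);
  r.bn = 0.125 * std::exp(-0.04 * (V + 44.0));
  return r;
}

// [[Rcpp::export]]
NumericMatrix cpp_gating_rates(int kind, std::string gate, NumericVector V,
                               bool printed_beta_n) {
  int n = V.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    Rates r = (kind == 0) ? int_rates(V[i], printed_beta_n) : pyr_rates(V[i]);
    double a, b;
    if (gate == "m")      { a = r.am; b = r.bm; }
    else if (gate == "h") { a = r.ah; b = r.bh; }
    else if (gate == "n") { a = r.an; b = r.bn; }
    else stop("unknown gate");
    out(i, 0) = a; out(i, 1) = b;
  }
  return out;
}

struct IntP {
  double cm, gl, gna, gk, el, ena, ek, phim, phih, phin;
  bool printed_bn;
};
struct PyrP {
  double cm, gl, gna, gk, gca, gahp, el, ena, ek, eca;
  double gsd, gds, p, alpha_ca, tau_ca, k_ahp, phim, phih, phin;
};

static IntP read_intp(const List& ip) {
  IntP q;
  q.cm = ip["c_m"]; q.gl = ip["g_l"]; q.gna = ip["g_na"]; q.gk = ip["g_k"];
  q.el = ip["e_l"]; q.ena = ip["e_na"]; q.ek = ip["e_k"];
  q.phim = ip["phi_m"]; q.phih = ip["phi_h"]; q.phin = ip["phi_n"];
  q.printed_bn = as<bool>(ip["use_printed_beta_n"]);
  return q;
}
static PyrP read_pyrp(const List& pp) {
  PyrP q;
  q.cm = pp["c_m"]; q.gl = pp["g_l"]; q.gna = pp["g_na"]; q.gk = pp["g_k"];
  q.gca = pp["g_ca"]; q.gahp = pp["g_ahp"];
  q.el = pp["e_l"]; q.ena = pp["e_na"]; q.ek = pp["e_k"]; q.eca = pp["e_ca"];
  q.gsd = pp["g_sd"]; q.gds = pp["g_ds"]; q.p = pp["p_soma"];
  q.alpha_ca = pp["alpha_ca"]; q.tau_ca = pp["tau_ca"]; q.k_ahp = pp["k_ahp"];
  q.phim = pp["phi_m"]; q.phih = pp["phi_h"]; q.phin = pp["phi_n"];
  return q;
}

// dV and gate derivatives for one interneuron
inline void int_deriv(const IntP& q, double V, double m, double h, double n,
                      double isyn, double iext,
                      double& dV, double& dm, double& dh, double& dn) {
  Rates r = int_rates(V, q.printed_bn);
  double ina = q.gna * m * m * m * h * (V - q.ena);
  double ik  = q.gk * n * n * n * n * (V - q.ek);
  double il  = q.gl * (V - q.el);
  dV = (-il - ina - ik - isyn + iext) / q.cm;
  dm = q.phim * (r.am * (1.0 - m) - r.bm * m);
  dh = q.phih * (r.ah * (1.0 - h) - r.bh * h);
  dn = q.phin * (r.an * (1.0 - n) - r.bn * n);
}

// soma/dendrite derivatives for one pyramidal cell; synaptic current
// enters the soma only
inline void pyr_deriv(const PyrP& q, double Vs, double Vd, double m, double h,
                      double n, double ca, double isyn, double iext,
                      double& dVs, double& dVd, double& dm, double& dh,
                      double& dn, double& dca) {
  Rates r = pyr_rates(Vs);
  double ina = q.gna * m * m * m * h * (Vs - q.ena);
  double ik  = q.gk * n * n * n * n * (Vs - q.ek);
  double ils = q.gl * (Vs - q.el);
  dVs = (-ils - ina - ik - q.gsd * (Vs - Vd) / q.p - isyn + iext) / q.cm;
  double minf = 1.0 / (1.0 + std::exp(-(Vd + 20.0) / 9.0));
  double ica = q.gca * minf * minf * (Vd - q.eca);
  double iahp = q.gahp * (Vd - q.ek) * ca / (ca + q.k_ahp);
  double ild = q.gl * (Vd - q.el);
  dVd = (-ild - ica - iahp - q.gds * (Vd - Vs) / (1.0 - q.p)) / q.cm;
  dm = q.phim * (r.am * (1.0 - m) - r.bm * m);
  dh = q.phih * (r.ah * (1.0 - h) - r.bh * h);
  dn = q.phin * (r.an * (1.0 - n) - r.bn * n);
  dca = -q.alpha_ca * ica - ca / q.tau_ca;
}

inline double xinf(double a, double b) { return a / (a + b); }

// Heun trajectory of a single interneuron under constant injected current.
// Returns matrix [n_steps+1] x 4: V, m, h, n (t = row * dt).
// [[Rcpp::export]]
NumericMatrix cpp_integrate_interneuron(List ip, double i_ext,
                                        double duration, double dt,
                                        double v0) {
  IntP q = read_intp(ip);
  int ns = (int)std::round(duration / dt);
  NumericMatrix out(ns + 1, 4);
  Rates r0 = int_rates(v0, q.printed_bn);
  double V = v0, m = xinf(r0.am, r0.bm), h = xinf(r0.ah, r0.bh),
         n = xinf(r0.an, r0.bn);
  out(0, 0) = V; out(0, 1) = m; out(0, 2) = h; out(0, 3) = n;
  for (int s = 0; s < ns; ++s) {
    double dV1, dm1, dh1, dn1, dV2, dm2, dh2, dn2;
    int_deriv(q, V, m, h, n, 0.0, i_ext, dV1, dm1, dh1, dn1);
    int_deriv(q, V + dt * dV1, m + dt * dm1, h + dt * dh1, n + dt * dn1,
              0.0, i_ext, dV2, dm2, dh2, dn2);
    V += 0.5 * dt * (dV1 + dV2); m += 0.5 * dt * (dm1 + dm2);
    h += 0.5 * dt * (dh1 + dh2); n += 0.5 * dt * (dn1 + dn2);
    out(s + 1, 0) = V; out(s + 1, 1) = m; out(s + 1, 2) = h;
    out(s + 1, 3) = n;
  }
  return out;
}

// Heun trajectory of a single pyramidal cell under constant somatic current.
// Returns [n_steps+1] x 6: Vs, Vd, m, h, n, Ca.
// [[Rcpp::export]]
NumericMatrix cpp_integrate_pyramidal(List pp, double i_ext,
                                      double duration, double dt,
                                      double v0) {
  PyrP q = read_pyrp(pp);
  int ns = (int)std::round(duration / dt);
  NumericMatrix out(ns + 1, 6);
  Rates r0 = pyr_rates(v0);
  double Vs = v0, Vd = v0, m = xinf(r0.am, r0.bm), h = xinf(r0.ah, r0.bh),
         n = xinf(r0.an, r0.bn), ca = 0.0;
  out(0, 0) = Vs; out(0, 1) = Vd; out(0, 2) = m; out(0, 3) = h;
  out(0, 4) = n; out(0, 5) = ca;
  for (int s = 0; s < ns; ++s) {
    double d1[6], d2[6];
    pyr_deriv(q, Vs, Vd, m, h, n, ca, 0.0, i_ext,
              d1[0], d1[1], d1[2], d1[3], d1[4], d1[5]);
    pyr_deriv(q, Vs + dt * d1[0], Vd + dt * d1[1], m + dt * d1[2],
              h + dt * d1[3], n + dt * d1[4], ca + dt * d1[5], 0.0, i_ext,
              d2[0], d2[1], d2[2], d2[3], d2[4], d2[5]);
    Vs += 0.5 * dt * (d1[0] + d2[0]); Vd += 0.5 * dt * (d1[1] + d2[1]);
    m += 0.5 * dt * (d1[2] + d2[2]); h += 0.5 * dt * (d1[3] + d2[3]);
    n += 0.5 * dt * (d1[4] + d2[4]); ca += 0.5 * dt * (d1[5] + d2[5]);
    if (ca < 0.0) ca = 0.0;
    out(s + 1, 0) = Vs; out(s + 1, 1) = Vd; out(s + 1, 2) = m;
    out(s + 1, 3) = h; out(s + 1, 4) = n; out(s + 1, 5) = ca;
  }
  return out;
}

// adjacency stored post-major: for each postsynaptic neuron the list of
// presynaptic indices (0-based)
struct CSR {
  std::vector<int> ptr, idx;
  bool empty() const { return idx.empty(); }
};

static CSR build_csr(const IntegerVector& pre, const IntegerVector& post,
                     int n_post) {
  CSR c;
  c.ptr.assign(n_post + 1, 0);
  int m = pre.size();
  for (int k = 0; k < m; ++k) c.ptr[post[k] + 1]++;
  for (int i = 0; i < n_post; ++i) c.ptr[i + 1] += c.ptr[i];
  c.idx.resize(m);
  std::vector<int> cur(c.ptr.begin(), c.ptr.end() - 1);
  for (int k = 0; k < m; ++k) c.idx[cur[post[k]]++] = pre[k];
  return c;
}

// per-post summed gating: out[i] = g * sum_{j in pre(i)} S[j]
static inline void gather(const CSR& c, const std::vector<double>& S,
                          double g, std::vector<double>& out) {
  int n = (int)out.size();
  if (c.empty() || g == 0.0) {
    std::fill(out.begin(), out.end(), 0.0);
    return;
  }
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = c.ptr[i]; k < c.ptr[i + 1]; ++k) acc += S[c.idx[k]];
    out[i] = g * acc;
  }
}

static inline double vmean(const std::vector<double>& v) {
  if (v.empty()) return 0.0;
  double s = 0.0;
  for (double x : v) s += x;
  return s / (double)v.size();
}

// Full network simulation. cfg/conn/ip/pp/kin assembled on the R side;
// uses the R RNG (caller seeds). Returns rasters, 1-ms-binned population
// traces and optional voltage dumps.
// [[Rcpp::export]]
List cpp_simulate(List cfg, List conn, List ip, List pp, List kin, List rec) {
  const int n_e = cfg["n_e"], n_i = cfg["n_i"];
  const double dt = cfg["dt_ms"], duration = cfg["duration_ms"];
  const int ns = (int)std::round(duration / dt);
  const double g_ee = cfg["g_ee"], g_ei = cfg["g_ei"], g_ie = cfg["g_ie"],
               g_ii = cfg["g_ii"], g_nmda = cfg["g_nmda"];
  const double gbg_e = cfg["g_bg_e_us"], gbg_i = cfg["g_bg_i_us"];
  const double nu_e = cfg["nu_e"], nu_i = cfg["nu_i"];
  const double t_off = cfg["t_off_ms"];
  const bool nmda = as<bool>(cfg["nmda_enabled"]);
  const double mg = cfg["mg_mm"], thr = cfg["threshold_mv"];
  const double iext_e = cfg["i_ext_e"], iext_i = cfg["i_ext_i"];

  const double tau_ar = kin["tau_a_r"], tau_ad = kin["tau_a_d"],
               tau_gr = kin["tau_g_r"], tau_gd = kin["tau_g_d"],
               tau_nr = kin["tau_n_r"], tau_nd = kin["tau_n_d"],
               e_ampa = kin["e_ampa"], e_gaba = kin["e_gaba"];

  IntP qi = read_intp(ip);
  PyrP qp = read_pyrp(pp);

  CSR ee, ei, ie, ii;
  if (n_e > 0) {
    ee = build_csr(conn["ee_pre"], conn["ee_post"], n_e);
    ie = build_csr(conn["ie_pre"], conn["ie_post"], n_e);
  }
  if (n_i > 0) {
    ei = build_csr(conn["ei_pre"], conn["ei_post"], n_i);
    ii = build_csr(conn["ii_pre"], conn["ii_post"], n_i);
  }

  // state
  std::vector<double> Vs(n_e), Vd(n_e), pm(n_e), ph(n_e), pn(n_e), ca(n_e, 0);
  std::vector<double> xa(n_e, 0), sa(n_e, 0), xn_(n_e, 0), sn(n_e, 0);
  std::vector<double> xbe(n_e, 0), sbe(n_e, 0);
  std::vector<double> Vi(n_i), im(n_i), ih(n_i), in_(n_i);
  std::vector<double> xg(n_i, 0), sg(n_i, 0), xbi(n_i, 0), sbi(n_i, 0);

  RNGScope rng;
  for (int i = 0; i < n_e; ++i) {
    double v = qp.el + 10.0 * unif_rand();
    Rates r = pyr_rates(v);
    Vs[i] = v; Vd[i] = v;
    pm[i] = xinf(r.am, r.bm); ph[i] = xinf(r.ah, r.bh);
    pn[i] = xinf(r.an, r.bn);
  }
  for (int i = 0; i < n_i; ++i) {
    double v = qi.el + 10.0 * unif_rand();
    Rates r = int_rates(v, qi.printed_bn);
    Vi[i] = v;
    im[i] = xinf(r.am, r.bm); ih[i] = xinf(r.ah, r.bh);
    in_[i] = xinf(r.an, r.bn);
  }

  // predictor & derivative buffers
  std::vector<double> Vs2(n_e), Vd2(n_e), pm2(n_e), ph2(n_e), pn2(n_e),
      ca2(n_e), xa2(n_e), sa2(n_e), xn2(n_e), sn2(n_e), xbe2(n_e), sbe2(n_e);
  std::vector<double> Vi2(n_i), im2(n_i), ih2(n_i), in2(n_i), xg2(n_i),
      sg2(n_i), xbi2(n_i), sbi2(n_i);
  std::vector<double> kVs1(n_e), kVd1(n_e), kpm1(n_e), kph1(n_e), kpn1(n_e),
      kca1(n_e), kVs2(n_e), kVd2(n_e), kpm2(n_e), kph2(n_e), kpn2(n_e),
      kca2(n_e);
  std::vector<double> kVi1(n_i), kim1(n_i), kih1(n_i), kin1(n_i), kVi2(n_i),
      kim2(n_i), kih2(n_i), kin2(n_i);
  std::vector<double> gA_e(n_e), gN_e(n_e), gG_e(n_e), gA_i(n_i), gG_i(n_i);
  std::vector<double> gA_e2(n_e), gN_e2(n_e), gG_e2(n_e), gA_i2(n_i),
      gG_i2(n_i);

  // spike bookkeeping: previous two voltage samples per neuron
  std::vector<double> vprev1_e(Vs), vprev2_e(Vs), vprev1_i(Vi), vprev2_i(Vi);
  std::vector<int> pend_e, pend_i;   // spikes detected last step
  std::vector<int> sp_e_id, sp_i_id;
  std::vector<double> sp_e_t, sp_i_t;

  // traces: 1-ms bins (population means)
  const double bin_ms = rec["bin_ms"];
  const int bin_steps = std::max(1, (int)std::round(bin_ms / dt));
  const int n_bins = (ns + bin_steps - 1) / bin_steps;
  const int NCH = 10;
  NumericMatrix traces(n_bins, NCH);
  std::vector<double> acc(NCH, 0.0);
  int acc_n = 0, bin_i = 0;

  // voltage dumps
  IntegerVector vids_e = rec["v_ids_e"], vids_i = rec["v_ids_i"];
  const int vstride = rec["v_stride"];
  const int nvrec = ns / vstride + 1;
  NumericMatrix vdump_e(vids_e.size() > 0 ? nvrec : 0, vids_e.size());
  NumericMatrix vdump_i(vids_i.size() > 0 ? nvrec : 0, vids_i.size());
  int vrow = 0;
  if (vids_e.size() > 0 || vids_i.size() > 0) {
    for (int k = 0; k < vids_e.size(); ++k) vdump_e(0, k) = Vs[vids_e[k]];
    for (int k = 0; k < vids_i.size(); ++k) vdump_i(0, k) = Vi[vids_i[k]];
    vrow = 1;
  }

  long ca_clamps = 0;

  for (int s = 0; s < ns; ++s) {
    double t = s * dt;
    // impulses: recurrent spikes from last step, then background events
    for (int j : pend_e) { xa[j] += 1.0; if (nmda) xn_[j] += 1.0; }
    for (int j : pend_i) xg[j] += 1.0;
    pend_e.clear(); pend_i.clear();
    if (t < t_off) {
      if (nu_e > 0.0) {
        double lam = nu_e * dt;
        for (int i = 0; i < n_e; ++i) {
          double k = R::rpois(lam);
          if (k > 0) xbe[i] += k;
        }
      }
      if (nu_i > 0.0) {
        double lam = nu_i * dt;
        for (int i = 0; i < n_i; ++i) {
          double k = R::rpois(lam);
          if (k > 0) xbi[i] += k;
        }
      }
    }

    // stage 1
    gather(ee, sa, g_ee, gA_e);
    gather(ee, sn, nmda ? g_nmda : 0.0, gN_e);
    gather(ie, sg, g_ie, gG_e);
    gather(ei, sa, g_ei, gA_i);
    gather(ii, sg, g_ii, gG_i);
    for (int i = 0; i < n_e; ++i) {
      double v = Vs[i];
      double denom = 1.0 + mg * std::exp(-0.062 * v) / 3.57;
      double isyn = (v - e_ampa) * (gA_e[i] + gbg_e * sbe[i]) +
                    (v - e_ampa) * gN_e[i] / denom +
                    (v - e_gaba) * gG_e[i];
      pyr_deriv(qp, Vs[i], Vd[i], pm[i], ph[i], pn[i], ca[i], isyn, iext_e,
                kVs1[i], kVd1[i], kpm1[i], kph1[i], kpn1[i], kca1[i]);
    }
    for (int i = 0; i < n_i; ++i) {
      double v = Vi[i];
      double isyn = (v - e_ampa) * (gA_i[i] + gbg_i * sbi[i]) +
                    (v - e_gaba) * gG_i[i];
      int_deriv(qi, Vi[i], im[i], ih[i], in_[i], isyn, iext_i,
                kVi1[i], kim1[i], kih1[i], kin1[i]);
    }

    // predictor
    for (int i = 0; i < n_e; ++i) {
      Vs2[i] = Vs[i] + dt * kVs1[i]; Vd2[i] = Vd[i] + dt * kVd1[i];
      pm2[i] = pm[i] + dt * kpm1[i]; ph2[i] = ph[i] + dt * kph1[i];
      pn2[i] = pn[i] + dt * kpn1[i]; ca2[i] = ca[i] + dt * kca1[i];
      xa2[i] = xa[i] - dt * xa[i] / tau_ar;
      sa2[i] = sa[i] + dt * (-sa[i] / tau_ad + xa[i]);
      xn2[i] = xn_[i] - dt * xn_[i] / tau_nr;
      sn2[i] = sn[i] + dt * (-sn[i] / tau_nd + xn_[i]);
      xbe2[i] = xbe[i] - dt * xbe[i] / tau_ar;
      sbe2[i] = sbe[i] + dt * (-sbe[i] / tau_ad + xbe[i]);
    }
    for (int i = 0; i < n_i; ++i) {
      Vi2[i] = Vi[i] + dt * kVi1[i]; im2[i] = im[i] + dt * kim1[i];
      ih2[i] = ih[i] + dt * kih1[i]; in2[i] = in_[i] + dt * kin1[i];
      xg2[i] = xg[i] - dt * xg[i] / tau_gr;
      sg2[i] = sg[i] + dt * (-sg[i] / tau_gd + xg[i]);
      xbi2[i] = xbi[i] - dt * xbi[i] / tau_ar;
      sbi2[i] = sbi[i] + dt * (-sbi[i] / tau_ad + xbi[i]);
    }

    // stage 2
    gather(ee, sa2, g_ee, gA_e2);
    gather(ee, sn2, nmda ? g_nmda : 0.0, gN_e2);
    gather(ie, sg2, g_ie, gG_e2);
    gather(ei, sa2, g_ei, gA_i2);
    gather(ii, sg2, g_ii, gG_i2);
    for (int i = 0; i < n_e; ++i) {
      double v = Vs2[i];
      double denom = 1.0 + mg * std::exp(-0.062 * v) / 3.57;
      double isyn = (v - e_ampa) * (gA_e2[i] + gbg_e * sbe2[i]) +
                    (v - e_ampa) * gN_e2[i] / denom +
                    (v - e_gaba) * gG_e2[i];
      pyr_deriv(qp, Vs2[i], Vd2[i], pm2[i], ph2[i], pn2[i], ca2[i], isyn,
                iext_e, kVs2[i], kVd2[i], kpm2[i], kph2[i], kpn2[i], kca2[i]);
    }
    for (int i = 0; i < n_i; ++i) {
      double v = Vi2[i];
      double isyn = (v - e_ampa) * (gA_i2[i] + gbg_i * sbi2[i]) +
                    (v - e_gaba) * gG_i2[i];
      int_deriv(qi, Vi2[i], im2[i], ih2[i], in2[i], isyn, iext_i,
                kVi2[i], kim2[i], kih2[i], kin2[i]);
    }

    // corrector
    const double hdt = 0.5 * dt;
    for (int i = 0; i < n_e; ++i) {
      Vs[i] += hdt * (kVs1[i] + kVs2[i]); Vd[i] += hdt * (kVd1[i] + kVd2[i]);
      pm[i] += hdt * (kpm1[i] + kpm2[i]); ph[i] += hdt * (kph1[i] + kph2[i]);
      pn[i] += hdt * (kpn1[i] + kpn2[i]); ca[i] += hdt * (kca1[i] + kca2[i]);
      if (ca[i] < 0.0) { ca[i] = 0.0; ++ca_clamps; }
      xa[i] += hdt * (-xa[i] / tau_ar - xa2[i] / tau_ar);
      sa[i] += hdt * ((-sa[i] / tau_ad + xa[i]) + (-sa2[i] / tau_ad + xa2[i]));
      xn_[i] += hdt * (-xn_[i] / tau_nr - xn2[i] / tau_nr);
      sn[i] += hdt * ((-sn[i] / tau_nd + xn_[i]) + (-sn2[i] / tau_nd + xn2[i]));
      xbe[i] += hdt * (-xbe[i] / tau_ar - xbe2[i] / tau_ar);
      sbe[i] += hdt * ((-sbe[i] / tau_ad + xbe[i]) +
                       (-sbe2[i] / tau_ad + xbe2[i]));
    }
    for (int i = 0; i < n_i; ++i) {
      Vi[i] += hdt * (kVi1[i] + kVi2[i]); im[i] += hdt * (kim1[i] + kim2[i]);
      ih[i] += hdt * (kih1[i] + kih2[i]); in_[i] += hdt * (kin1[i] + kin2[i]);
      xg[i] += hdt * (-xg[i] / tau_gr - xg2[i] / tau_gr);
      sg[i] += hdt * ((-sg[i] / tau_gd + xg[i]) + (-sg2[i] / tau_gd + xg2[i]));
      xbi[i] += hdt * (-xbi[i] / tau_ar - xbi2[i] / tau_ar);
      sbi[i] += hdt * ((-sbi[i] / tau_ad + xbi[i]) +
                       (-sbi2[i] / tau_ad + xbi2[i]));
    }

    // spike detection: peak above threshold at the previous sample (time t);
    // detected spikes deliver their impulses at the start of the next step
    for (int i = 0; i < n_e; ++i) {
      double vp = vprev1_e[i];
      if (vp > thr && vp >= vprev2_e[i] && vp > Vs[i]) {
        sp_e_id.push_back(i); sp_e_t.push_back(t); pend_e.push_back(i);
      }
      vprev2_e[i] = vprev1_e[i]; vprev1_e[i] = Vs[i];
    }
    for (int i = 0; i < n_i; ++i) {
      double vp = vprev1_i[i];
      if (vp > thr && vp >= vprev2_i[i] && vp > Vi[i]) {
        sp_i_id.push_back(i); sp_i_t.push_back(t); pend_i.push_back(i);
      }
      vprev2_i[i] = vprev1_i[i]; vprev1_i[i] = Vi[i];
    }

    // traces (population means at step start, i.e. stage-1 values)
    acc[0] += vmean(sa); acc[1] += vmean(sg); acc[2] += vmean(sn);
    acc[3] += vmean(gA_e); acc[4] += vmean(gN_e); acc[5] += vmean(gG_e);
    acc[6] += vmean(gA_i); acc[7] += vmean(gG_i);
    acc[8] += vmean(Vs); acc[9] += vmean(Vi);
    ++acc_n;
    if (acc_n == bin_steps || s == ns - 1) {
      for (int c = 0; c < NCH; ++c) {
        traces(bin_i, c) = acc[c] / acc_n;
        acc[c] = 0.0;
      }
      acc_n = 0; ++bin_i;
    }

    if ((vids_e.size() > 0 || vids_i.size() > 0) && ((s + 1) % vstride == 0) &&
        vrow < nvrec) {
      for (int k = 0; k < vids_e.size(); ++k) vdump_e(vrow, k) = Vs[vids_e[k]];
      for (int k = 0; k < vids_i.size(); ++k) vdump_i(vrow, k) = Vi[vids_i[k]];
      ++vrow;
    }

    if ((s & 1023) == 0) {
      for (int i = 0; i < n_e; ++i)
        if (!std::isfinite(Vs[i]))
          stop("non-finite somatic potential (pyramidal %d) at step %d", i + 1,
               s);
      for (int i = 0; i < n_i; ++i)
        if (!std::isfinite(Vi[i]))
          stop("non-finite potential (interneuron %d) at step %d", i + 1, s);
      Rcpp::checkUserInterrupt();
    }
  }

  colnames(traces) = CharacterVector::create(
      "s_ampa", "s_gaba", "s_nmda", "g_ampa_on_e", "g_nmda_on_e",
      "g_gaba_on_e", "g_ampa_on_i", "g_gaba_on_i", "v_soma_mean",
      "v_int_mean");

  return List::create(
      _["spike_e_id"] = wrap(sp_e_id), _["spike_e_t"] = wrap(sp_e_t),
      _["spike_i_id"] = wrap(sp_i_id), _["spike_i_t"] = wrap(sp_i_t),
      _["traces"] = traces, _["trace_bin_ms"] = bin_ms,
      _["vdump_e"] = vdump_e, _["vdump_i"] = vdump_i,
      _["v_stride"] = vstride, _["ca_clamps"] = (double)ca_clamps);
}
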
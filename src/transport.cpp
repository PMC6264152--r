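// Conservative finite-volume transport of an inert tracer on the mean-path
// airway tree.  Cells are linked by a parent pointer (the mouthward
// neighbour); the adjacency graph of cells is itself a tree, so the
// implicit-Euler system is solved exactly by leaf-to-root elimination with
// zero fill-in, O(n) per step.  Upwind advective fluxes keep the scheme
// monotone; diffusive fluxes use Taylor dispersion in conducting cells and
// sac-enhanced molecular diffusion in acinar cells.
//
// The breathing cycle is periodic, so the eliminated (LU) operator of every
// cycle step is identical across breaths: it is built on the first breath
// and cached, leaving only the O(n) right-hand-side sweep per step
// afterwards.  Working units: cm, cm^2, cm^3, s.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Grid {
  int n;                       // cells
  int nu;                      // lung units
  std::vector<int> parent;     // 0-based, -1 for mouth cell
  std::vector<double> dx, s;
  std::vector<int> unit;       // -1 or 0-based
  std::vector<double> sacw;    // unit sac fraction per cell
  std::vector<double> s_int, d_int, dist, wq;
  std::vector<int> acinar_int, ulo, uhi;
  std::vector<int> elim;       // leaf-to-root cell order
  std::vector<double> Vduct;   // per-unit duct volume (cm^3)
  double D0, Cinsp, Cexp, phi;
  int mouth_bc;                // 0 washout, 1 closed (zero-gradient)

  // per-cycle-step cached eliminated operator
  bool cached = false;
  int n_steps = 0;
  std::vector<double> cSndx, cf, cinvdiag, cdtA;  // n_steps * n
  std::vector<double> cBmouth, cQ0;               // n_steps

  std::vector<double> rhs, cwork, pref, Stmp;

  void init_scratch() {
    rhs.assign(n, 0.0); cwork.assign(n, 0.0);
    pref.assign(nu + 1, 0.0); Stmp.assign(n, 0.0);
  }

  void fill_S(const double* V, std::vector<double>& S) const {
    for (int j = 0; j < n; ++j) {
      double extra = 0.0;
      if (unit[j] >= 0 && sacw[j] > 0.0)
        extra = sacw[j] * (V[unit[j]] - Vduct[unit[j]]) / dx[j];
      S[j] = s[j] + extra;
    }
  }

  // build and cache the eliminated operator for cycle step `st`
  void build_step(int st, const double* V0, const double* V1, double dt) {
    double* Sndx = &cSndx[(size_t)st * n];
    double* f = &cf[(size_t)st * n];
    double* invdiag = &cinvdiag[(size_t)st * n];
    double* dtA = &cdtA[(size_t)st * n];
    std::vector<double> Sn(n), Sn1(n), diag(n), B(n);
    fill_S(V0, Sn);
    fill_S(V1, Sn1);
    pref[0] = 0.0;
    double q0 = 0.0;
    for (int u = 0; u < nu; ++u) {
      pref[u + 1] = pref[u] + (V1[u] - V0[u]) / dt;
      q0 += (V1[u] - V0[u]) / dt;
    }
    cQ0[st] = q0;
    for (int j = 0; j < n; ++j) {
      double q = wq[j] * (pref[uhi[j] + 1] - pref[ulo[j]]);
      double G;
      if (acinar_int[j]) {
        G = D0 * (1.0 + phi * (Sn1[j] / s[j] - 1.0)) * s_int[j] / dist[j];
      } else {
        double u_loc = std::fabs(q) / s_int[j];
        double C = q > 0 ? Cinsp : Cexp;
        G = (D0 + C * u_loc * d_int[j]) * s_int[j] / dist[j];
      }
      double A;
      if (parent[j] < 0) {               // mouth interface
        A = 0.0;
        if (mouth_bc == 1)      B[j] = q;            // zero-gradient
        else if (q > 0)         B[j] = -G;           // inhalation: c = 0
        else                    B[j] = q;            // exhalation: no diff.
        cBmouth[st] = B[j];
      } else {
        A = (q > 0 ? q : 0.0) + G;
        B[j] = (q < 0 ? q : 0.0) - G;
      }
      dtA[j] = dt * A;
      Sndx[j] = Sn[j] * dx[j];
      diag[j] = Sn1[j] * dx[j] - dt * B[j];
    }
    for (int j = 0; j < n; ++j)
      if (parent[j] >= 0) diag[parent[j]] += dtA[j];
    // leaf-to-root elimination of the matrix part
    for (int k = 0; k < n; ++k) {
      int i = elim[k];
      int p = parent[i];
      if (p < 0) { f[i] = 0.0; continue; }
      f[i] = dt * B[i] / diag[i];
      diag[p] += f[i] * dtA[i];
    }
    for (int j = 0; j < n; ++j) invdiag[j] = 1.0 / diag[j];
  }

  // advance one step using the cached operator; returns tracer volume
  // leaving through the mouth (cm^3, positive out)
  double step_cached(int st, std::vector<double>& c, double dt) {
    const double* Sndx = &cSndx[(size_t)st * n];
    const double* f = &cf[(size_t)st * n];
    const double* invdiag = &cinvdiag[(size_t)st * n];
    const double* dtA = &cdtA[(size_t)st * n];
    for (int j = 0; j < n; ++j) rhs[j] = Sndx[j] * c[j];
    for (int k = 0; k < n; ++k) {
      int i = elim[k];
      if (parent[i] >= 0) rhs[parent[i]] -= f[i] * rhs[i];
    }
    for (int k = n - 1; k >= 0; --k) {
      int i = elim[k];
      int p = parent[i];
      double num = rhs[i];
      if (p >= 0) num += dtA[i] * cwork[p];
      cwork[i] = num * invdiag[i];
    }
    c.swap(cwork);
    int root = elim[n - 1];
    return -dt * cBmouth[st] * c[root];
  }

  double total_tracer(const std::vector<double>& c, const double* V) {
    fill_S(V, Stmp);
    double tot = 0.0;
    for (int j = 0; j < n; ++j) tot += Stmp[j] * dx[j] * c[j];
    return tot;
  }
};

static Grid make_grid(const List& disc, const List& gas, int mouth_bc) {
  Grid g;
  IntegerVector parent = disc["parent"];
  g.n = parent.size();
  g.parent.resize(g.n);
  for (int j = 0; j < g.n; ++j) g.parent[j] = parent[j] - 1;
  NumericVector dx = disc["dx"], s = disc["s"], sacw = disc["sacw"],
    s_int = disc["s_int"], d_int = disc["d_int"], dist = disc["dist"],
    wq = disc["wq"], Vduct = disc["Vduct"];
  IntegerVector unit = disc["unit"], acinar_int = disc["acinar_int"],
    ulo = disc["ulo"], uhi = disc["uhi"], elim = disc["elim_order"];
  g.dx.assign(dx.begin(), dx.end());
  g.s.assign(s.begin(), s.end());
  g.sacw.assign(sacw.begin(), sacw.end());
  g.s_int.assign(s_int.begin(), s_int.end());
  g.d_int.assign(d_int.begin(), d_int.end());
  g.dist.assign(dist.begin(), dist.end());
  g.wq.assign(wq.begin(), wq.end());
  g.Vduct.assign(Vduct.begin(), Vduct.end());
  g.nu = Vduct.size();
  g.acinar_int.assign(acinar_int.begin(), acinar_int.end());
  g.unit.resize(g.n);
  g.ulo.resize(g.n); g.uhi.resize(g.n);
  for (int j = 0; j < g.n; ++j) {
    g.unit[j] = unit[j] - 1;
    g.ulo[j] = ulo[j] - 1;
    g.uhi[j] = uhi[j] - 1;
  }
  g.elim.resize(g.n);
  for (int j = 0; j < g.n; ++j) g.elim[j] = elim[j] - 1;
  g.D0 = as<double>(gas["D0"]);
  g.Cinsp = as<double>(gas["C_insp"]);
  g.Cexp = as<double>(gas["C_exp"]);
  g.phi = as<double>(gas["phi"]);
  g.mouth_bc = mouth_bc;
  g.init_scratch();
  return g;
}

// [[Rcpp::export]]
List washout_core(List disc, List gas, NumericMatrix cycleV, double dt,
                  NumericVector c_init, int max_breaths, double stop_frac,
                  int extra_breaths, int fixed_breaths, int mouth_bc) {
  Grid g = make_grid(disc, gas, mouth_bc);
  const int n_steps = cycleV.nrow() - 1;
  g.n_steps = n_steps;
  g.cSndx.resize((size_t)n_steps * g.n);
  g.cf.resize((size_t)n_steps * g.n);
  g.cinvdiag.resize((size_t)n_steps * g.n);
  g.cdtA.resize((size_t)n_steps * g.n);
  g.cBmouth.resize(n_steps);
  g.cQ0.resize(n_steps);
  std::vector<double> c(c_init.begin(), c_init.end());

  std::vector<double> mouth_c, mouth_q;
  std::vector<double> br_inh, br_exh, br_net, br_et;
  std::vector<std::vector<double> > unit_tracer;

  std::vector<double> Vrow0(g.nu), Vrow1(g.nu);
  for (int u = 0; u < g.nu; ++u) Vrow0[u] = cycleV(0, u);
  double total_init = g.total_tracer(c, Vrow0.data());
  {
    std::vector<double> ut(g.nu, 0.0);
    g.fill_S(Vrow0.data(), g.Stmp);
    for (int j = 0; j < g.n; ++j)
      if (g.unit[j] >= 0) ut[g.unit[j]] += g.Stmp[j] * g.dx[j] * c[j];
    unit_tracer.push_back(ut);
  }

  double cum_net = 0.0;
  int crossing = 0, n_done = 0;
  bool stop = false;
  for (int b = 1; b <= max_breaths && !stop; ++b) {
    double inh = 0.0, exh = 0.0, net = 0.0, et = NA_REAL;
    for (int st = 0; st < n_steps; ++st) {
      if (b == 1) {
        for (int u = 0; u < g.nu; ++u) {
          Vrow0[u] = cycleV(st, u);
          Vrow1[u] = cycleV(st + 1, u);
        }
        g.build_step(st, Vrow0.data(), Vrow1.data(), dt);
      }
      net += g.step_cached(st, c, dt);
      double q0 = g.cQ0[st];
      if (q0 > 0) inh += q0 * dt; else exh -= q0 * dt;
      double cm = c[g.elim[g.n - 1]];
      mouth_c.push_back(cm);
      mouth_q.push_back(q0);
      if (q0 < 0) et = cm;
    }
    cum_net += net;
    br_inh.push_back(inh);
    br_exh.push_back(exh);
    br_net.push_back(net);
    br_et.push_back(et);
    {
      std::vector<double> ut(g.nu, 0.0);
      for (int u = 0; u < g.nu; ++u) Vrow1[u] = cycleV(n_steps, u);
      g.fill_S(Vrow1.data(), g.Stmp);
      for (int j = 0; j < g.n; ++j)
        if (g.unit[j] >= 0) ut[g.unit[j]] += g.Stmp[j] * g.dx[j] * c[j];
      unit_tracer.push_back(ut);
    }
    n_done = b;
    if (crossing == 0 && R_finite(et) && et < stop_frac) crossing = b;
    if (fixed_breaths > 0) {
      if (b >= fixed_breaths) stop = true;
    } else if (crossing > 0 && b >= crossing + extra_breaths) {
      stop = true;
    }
  }
  for (int u = 0; u < g.nu; ++u) Vrow1[u] = cycleV(n_steps, u);
  double total_final = g.total_tracer(c, Vrow1.data());

  NumericMatrix ut(n_done + 1, g.nu);
  for (int b = 0; b <= n_done; ++b)
    for (int u = 0; u < g.nu; ++u) ut(b, u) = unit_tracer[b][u];

  return List::create(
    _["mouth_c"] = NumericVector(mouth_c.begin(), mouth_c.end()),
    _["mouth_q"] = NumericVector(mouth_q.begin(), mouth_q.end()),
    _["n_breaths"] = n_done,
    _["crossing_breath"] = crossing,
    _["inhaled"] = NumericVector(br_inh.begin(), br_inh.end()),
    _["exhaled"] = NumericVector(br_exh.begin(), br_exh.end()),
    _["net_out"] = NumericVector(br_net.begin(), br_net.end()),
    _["end_tidal"] = NumericVector(br_et.begin(), br_et.end()),
    _["unit_tracer"] = ut,
    _["total_init"] = total_init,
    _["total_final"] = total_final,
    _["cum_net_out"] = cum_net,
    _["c_final"] = NumericVector(c.begin(), c.end()));
}

// Advance the concentration field over the steps of a supplied volume
// sequence (m+1 rows); exposed for direct testing of the finite-volume
// update and boundary closures.
// [[Rcpp::export]]
List transport_advance(List disc, List gas, NumericMatrix Vseq, double dt,
                       NumericVector c_init, int mouth_bc) {
  Grid g = make_grid(disc, gas, mouth_bc);
  int m = Vseq.nrow() - 1;
  g.n_steps = 1;
  g.cSndx.resize(g.n); g.cf.resize(g.n);
  g.cinvdiag.resize(g.n); g.cdtA.resize(g.n);
  g.cBmouth.resize(1); g.cQ0.resize(1);
  std::vector<double> c(c_init.begin(), c_init.end());
  std::vector<double> V0(g.nu), V1(g.nu);
  double net = 0.0;
  for (int st = 0; st < m; ++st) {
    for (int u = 0; u < g.nu; ++u) {
      V0[u] = Vseq(st, u);
      V1[u] = Vseq(st + 1, u);
    }
    g.build_step(0, V0.data(), V1.data(), dt);
    net += g.step_cached(0, c, dt);
  }
  for (int u = 0; u < g.nu; ++u) V1[u] = Vseq(m, u);
  double total = g.total_tracer(c, V1.data());
  return List::create(_["c"] = NumericVector(c.begin(), c.end()),
                      _["net_out"] = net,
                      _["total_tracer"] = total);
}
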
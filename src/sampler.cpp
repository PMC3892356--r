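// Metropolis-within-Gibbs sampler for the three-level dynamic occupancy
// model: exact Bernoulli full conditionals for the latent occupancy (X) and
// use (Z) states, adaptive random-walk Metropolis for all continuous
// parameter blocks, conjugate Beta draws for the initial-use probabilities.
// All indices arriving from R are 0-based.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
#include <map>
#include <algorithm>
using namespace Rcpp;

static inline double log_il(double x) {
  // log(invlogit(x)), stable
  return x > 0 ? -log1p(exp(-x)) : x - log1p(exp(x));
}
static inline double lbern(int y, double eta) {
  return log_il(y ? eta : -eta);
}
static inline double ldnorm(double x, double sd) {
  return -0.918938533204672742 - log(sd) - x * x / (2.0 * sd * sd);
}

struct AdaptScale {
  double ls;      // log proposal sd
  int acc, att;
  AdaptScale(double s = 0.2) : ls(log(s)), acc(0), att(0) {}
  double sd() const { return exp(ls); }
  void tally(bool a) { att++; if (a) acc++; }
  void adapt(int batch) {
    if (att == 0) return;
    double rate = (double)acc / att;
    double step = std::min(0.1, 1.0 / sqrt((double)batch));
    ls += (rate > 0.44 ? step : -step);
    if (ls < -8) ls = -8;
    if (ls > 4) ls = 4;
    acc = 0; att = 0;
  }
};

struct Model {
  // structure
  int n, T1, T2, Tt, n_seasons, H, P, K1, K2, C;
  std::vector<int> adj_ptr, adj_idx, n_nb;
  NumericMatrix sdesign;          // n x P
  std::vector<int> col_hab;       // 0 for beta cols, habitat (1..H) for u cols
  // checklists
  std::vector<int> cl_cell, cl_season, cl_year, cl_prot, cl_status, cl_obs,
      cl_det, cl_m, cl_int, cl_fh;
  std::vector<int> cy_ptr, cy_ord;
  std::vector<int> obs1_ptr, obs1_idx, obs2_ptr, obs2_idx;
  std::vector<int> cp1_ptr, cp1_idx, cp2_ptr, cp2_idx;
  std::vector<int> Zforce;        // ncy
  std::vector<int> Xforce;        // n*2, column-major [i + s*n]
  int ncy;
  // hyperpriors
  double sd_fixed, sd_upper, sd_upper_dyn, sd_dyn;

  // parameters
  double a0;
  std::vector<double> coef;       // P
  std::vector<double> sigma_u;    // H
  double tau_b, sigma_eps;
  std::vector<double> b, eps;     // n
  double phi0, gamma0, phi_slope, gamma_slope, sigma_phi, sigma_gamma;
  std::vector<double> phi_cell, gamma_cell;  // n
  double mu_init[2], psi0[2], theta0[2];
  std::vector<double> psi_cell, theta_cell;  // n*2 [i + s*n]
  double sigma_psi_cell, sigma_theta_cell, sigma_psi_year, sigma_theta_year;
  std::vector<double> psi_year, theta_year;  // concat by season
  int yoff[2], py;
  double p_status[2][2];          // [prot][status], status 0=breeding
  double delta_par;
  std::vector<double> omega1, omega2;        // K1, K2
  double sigma_omega[2];
  std::vector<double> b_det1, b_det2;        // n
  double tau_det[2];

  // latent state
  std::vector<int> X;             // n*2 [i + s*n]
  std::vector<int> Z;             // ncy

  // caches
  std::vector<double> eta1;       // n : occ1 logit
  std::vector<double> det_lp;     // C : detection logit sans delta
  std::vector<int> nb_occ;        // n : occupied neighbors in period 1

  int cy(int i, int s, int t) const {
    return i * Tt + (s == 0 ? t : T1 + t);
  }
  int Ts(int s) const { return s == 0 ? T1 : T2; }

  double psi_eta(int i, int s, int t) const {  // transition index t
    return psi0[s] + psi_cell[i + s * n] + psi_year[yoff[s] + t];
  }
  double theta_eta(int i, int s, int t) const {
    return theta0[s] + theta_cell[i + s * n] + theta_year[yoff[s] + t];
  }
  double phi_eta(int i, double D) const {
    return phi0 + phi_cell[i] + phi_slope * D;
  }
  double gamma_eta(int i, double D) const {
    return gamma0 + gamma_cell[i] + gamma_slope * D;
  }
  double Dprop(int i) const { return (double)nb_occ[i] / n_nb[i]; }

  void rebuild_caches() {
    eta1.assign(n, 0.0);
    for (int i = 0; i < n; i++) {
      double e = a0 + b[i] + eps[i];
      for (int j = 0; j < P; j++) e += sdesign(i, j) * coef[j];
      eta1[i] = e;
    }
    det_lp.assign(C, 0.0);
    for (int c = 0; c < C; c++) {
      int pr = cl_prot[c];
      double lp = p_status[pr][cl_status[c]];
      lp += pr == 0 ? omega1[cl_obs[c]] : omega2[cl_obs[c]];
      lp += pr == 0 ? b_det1[cl_cell[c]] : b_det2[cl_cell[c]];
      det_lp[c] = lp;
    }
    nb_occ.assign(n, 0);
    for (int i = 0; i < n; i++)
      for (int a = adj_ptr[i]; a < adj_ptr[i + 1]; a++)
        nb_occ[i] += X[adj_idx[a]];
  }

  // checklist log-likelihood given use z, at detection logit lp
  double cl_ll(int c, int z, double lp) const {
    if (z == 0) return cl_det[c] ? R_NegInf : 0.0;
    if (cl_prot[c] == 0) return lbern(cl_det[c], lp);
    int m = cl_m[c];
    if (cl_det[c] == 0)
      return m * log_il(-lp) + log_il(-(lp + delta_par));
    if (cl_int[c] == 1)
      return (cl_fh[c] - 1) * log_il(-lp) + log_il(lp);
    return m * log_il(-lp) + log_il(lp + delta_par);
  }
  double cl_ll(int c, int z) const { return cl_ll(c, z, det_lp[c]); }

  double cy_ll(int icy, int z) const {
    double s = 0;
    for (int a = cy_ptr[icy]; a < cy_ptr[icy + 1]; a++)
      s += cl_ll(cy_ord[a], z);
    return s;
  }

  // log P(Z chain of cell i, season s | X = 1), current Z values
  double use_chain_ll(int i, int s) const {
    int T = Ts(s);
    double lp = 0;
    int z0 = Z[cy(i, s, 0)];
    lp += z0 ? log(mu_init[s]) : log1p(-mu_init[s]);
    for (int t = 1; t < T; t++) {
      int zp = Z[cy(i, s, t - 1)], z = Z[cy(i, s, t)];
      lp += lbern(z, zp ? psi_eta(i, s, t - 1) : theta_eta(i, s, t - 1));
    }
    return lp;
  }
  bool any_use(int i, int s) const {
    for (int t = 0; t < Ts(s); t++) if (Z[cy(i, s, t)]) return true;
    return false;
  }

  // ---------------- latent updates ----------------
  //
  // Blocked Gibbs per (cell, season): the year-to-year use chain Z is a
  // two-state hidden Markov chain of length T, so it is marginalized
  // exactly by a forward filter, X is drawn from its marginal full
  // conditional, and Z is then backward-sampled given X. Sampling X with Z
  // integrated out removes the bottleneck of single-site updates, where an
  // occupancy flip had to wait for the whole use chain to hit zero.

  // log P(checklists and use chain | X = 0): Z forced to 0
  double chain_ll_x0(int i, int s) const {
    double lp = 0;
    for (int t = 0; t < Ts(s); t++) lp += cy_ll(cy(i, s, t), 0);
    return lp;
  }

  // forward filter over the use chain given X = 1; la must hold 2*T doubles
  // (filtered log-weights per year and state); returns marginal loglik
  double chain_forward(int i, int s, double* la) const {
    int T = Ts(s);
    la[0] = log1p(-mu_init[s]) + cy_ll(cy(i, s, 0), 0);
    la[1] = log(mu_init[s]) + cy_ll(cy(i, s, 0), 1);
    for (int t = 1; t < T; t++) {
      double pe = psi_eta(i, s, t - 1), te = theta_eta(i, s, t - 1);
      for (int z = 0; z < 2; z++) {
        double from0 = la[2 * (t - 1)] + lbern(z, te);
        double from1 = la[2 * (t - 1) + 1] + lbern(z, pe);
        double mx = std::max(from0, from1);
        la[2 * t + z] = (mx == R_NegInf ? R_NegInf
                         : mx + log(exp(from0 - mx) + exp(from1 - mx))) +
                        cy_ll(cy(i, s, t), z);
      }
    }
    double m = std::max(la[2 * (T - 1)], la[2 * (T - 1) + 1]);
    if (m == R_NegInf) return R_NegInf;
    return m + log(exp(la[2 * (T - 1)] - m) + exp(la[2 * (T - 1) + 1] - m));
  }

  void chain_backward(int i, int s, const double* la) {
    int T = Ts(s);
    double w1 = 1.0 / (1.0 + exp(la[2 * (T - 1)] - la[2 * (T - 1) + 1]));
    Z[cy(i, s, T - 1)] = R::unif_rand() < w1 ? 1 : 0;
    for (int t = T - 2; t >= 0; t--) {
      int zn = Z[cy(i, s, t + 1)];
      double pe = psi_eta(i, s, t), te = theta_eta(i, s, t);
      double l0 = la[2 * t] + lbern(zn, te);
      double l1 = la[2 * t + 1] + lbern(zn, pe);
      double p1 = 1.0 / (1.0 + exp(l0 - l1));
      Z[cy(i, s, t)] = R::unif_rand() < p1 ? 1 : 0;
    }
  }

  void update_cell_season(int i, int s) {
    std::vector<double> la(2 * std::max(Ts(s), 1));
    double l0 = chain_ll_x0(i, s);
    double l1 = chain_forward(i, s, la.data());
    if (s == 0) {
      l1 += lbern(1, eta1[i]);
      l0 += lbern(0, eta1[i]);
      if (n_seasons == 2) {
        double Di = Dprop(i);
        int x2 = X[i + n];
        l1 += lbern(x2, phi_eta(i, Di));
        l0 += lbern(x2, gamma_eta(i, Di));
        int cur = X[i];
        for (int a = adj_ptr[i]; a < adj_ptr[i + 1]; a++) {
          int k = adj_idx[a];
          double base = nb_occ[k] - cur;
          double D1 = (base + 1) / n_nb[k], D0 = base / n_nb[k];
          int xk2 = X[k + n];
          if (X[k] == 1) {
            l1 += lbern(xk2, phi_eta(k, D1));
            l0 += lbern(xk2, phi_eta(k, D0));
          } else {
            l1 += lbern(xk2, gamma_eta(k, D1));
            l0 += lbern(xk2, gamma_eta(k, D0));
          }
        }
      }
    } else {
      double Di = Dprop(i);
      double te = X[i] ? phi_eta(i, Di) : gamma_eta(i, Di);
      l1 += lbern(1, te);
      l0 += lbern(0, te);
    }
    int xnew;
    if (l0 == R_NegInf && l1 == R_NegInf)
      stop("latent update: both occupancy states impossible");
    if (l0 == R_NegInf) xnew = 1;
    else if (l1 == R_NegInf) xnew = 0;
    else xnew = R::unif_rand() < 1.0 / (1.0 + exp(l0 - l1)) ? 1 : 0;
    int old = X[i + s * n];
    X[i + s * n] = xnew;
    if (s == 0 && xnew != old) {
      int d = xnew - old;
      for (int a = adj_ptr[i]; a < adj_ptr[i + 1]; a++)
        nb_occ[adj_idx[a]] += d;
    }
    if (xnew == 1) chain_backward(i, s, la.data());
    else for (int t = 0; t < Ts(s); t++) Z[cy(i, s, t)] = 0;
  }

  // Collapsed cluster flip: propose flipping first-period occupancy of a
  // cell and its whole queen neighborhood at once (use chains marginalized,
  // resampled on acceptance). Single-cell moves cross the autologistic
  // field's domain boundaries slowly; cluster flips let whole patches of
  // poorly surveyed cells change state in one step.
  void cluster_flip() {
    if (n_seasons < 2) return;  // only useful with transition coupling
    int center = (int)(R::unif_rand() * n);
    if (center >= n) center = n - 1;
    std::vector<int> cluster;
    if (!Xforce[center]) cluster.push_back(center);
    for (int a = adj_ptr[center]; a < adj_ptr[center + 1]; a++)
      if (!Xforce[adj_idx[a]]) cluster.push_back(adj_idx[a]);
    if (cluster.empty()) return;
    // affected cells: cluster plus all their neighbors (D changes there)
    std::vector<int> affected(cluster);
    for (int j : cluster)
      for (int a = adj_ptr[j]; a < adj_ptr[j + 1]; a++)
        affected.push_back(adj_idx[a]);
    std::sort(affected.begin(), affected.end());
    affected.erase(std::unique(affected.begin(), affected.end()),
                   affected.end());
    double d = 0;
    std::vector<double> la(2 * std::max(T1, 1));
    for (int j : cluster) {
      int xj = X[j], xn = 1 - xj;
      d += lbern(xn, eta1[j]) - lbern(xj, eta1[j]);
      double L1 = chain_forward(j, 0, la.data());
      double L0 = chain_ll_x0(j, 0);
      d += (xn == 1 ? L1 - L0 : L0 - L1);
      if (d == R_NegInf) return;  // flip to 0 impossible (detections)
    }
    double before = 0;
    for (int k : affected) {
      double Dk = Dprop(k);
      before += lbern(X[k + n], X[k] ? phi_eta(k, Dk) : gamma_eta(k, Dk));
    }
    // apply flips
    for (int j : cluster) {
      int dlt = 1 - 2 * X[j];
      X[j] += dlt;
      for (int a = adj_ptr[j]; a < adj_ptr[j + 1]; a++)
        nb_occ[adj_idx[a]] += dlt;
    }
    double after = 0;
    for (int k : affected) {
      double Dk = Dprop(k);
      after += lbern(X[k + n], X[k] ? phi_eta(k, Dk) : gamma_eta(k, Dk));
    }
    d += after - before;
    if (!mh_accept_d(d)) {
      for (int j : cluster) {  // revert
        int dlt = 1 - 2 * X[j];
        X[j] += dlt;
        for (int a = adj_ptr[j]; a < adj_ptr[j + 1]; a++)
          nb_occ[adj_idx[a]] += dlt;
      }
      return;
    }
    for (int j : cluster) {
      if (X[j] == 1) {
        chain_forward(j, 0, la.data());
        chain_backward(j, 0, la.data());
      } else {
        for (int t = 0; t < T1; t++) Z[cy(j, 0, t)] = 0;
      }
    }
  }

  static bool mh_accept_d(double dlp) {
    if (dlp >= 0) return true;
    if (dlp == R_NegInf) return false;
    return log(R::unif_rand()) < dlp;
  }

  void latent_sweep() {
    for (int s = 0; s < n_seasons; s++)
      for (int i = 0; i < n; i++) update_cell_season(i, s);
    int n_flip = n / 4 + 1;
    for (int f = 0; f < n_flip; f++) cluster_flip();
  }

  // ---------------- derived quantities ----------------

  double car_Q(const std::vector<double>& v) const {
    double Q = 0;
    for (int i = 0; i < n; i++)
      for (int a = adj_ptr[i]; a < adj_ptr[i + 1]; a++) {
        int k = adj_idx[a];
        if (k > i) { double d = v[i] - v[k]; Q += d * d; }
      }
    return Q;
  }
};

// scalar Metropolis step helper: caller computes delta log-posterior for a
// proposed increment d; here we just draw d and the accept decision.
static inline double propose(AdaptScale& sc) {
  return R::norm_rand() * sc.sd();
}
static inline bool mh_accept(double dlp) {
  if (dlp >= 0) return true;
  return log(R::unif_rand()) < dlp;
}

// ---------------------------------------------------------------------------
// parameter updates
// ---------------------------------------------------------------------------

struct Sampler {
  Model& M;
  bool upd_latent;
  std::map<std::string, bool> blk;
  // adapt scales
  AdaptScale s_a0, s_tau_b, s_sigma_eps, s_phi0, s_gamma0, s_phi_slope,
      s_gamma_slope, s_sigma_phi, s_sigma_gamma, s_delta, s_phi_ridge,
      s_gamma_ridge;
  AdaptScale s_psi0[2], s_theta0[2], s_p[2][2], s_sigma_omega[2], s_tau_det[2];
  AdaptScale s_sigma_psi_cell, s_sigma_theta_cell, s_sigma_psi_year,
      s_sigma_theta_year;
  std::vector<AdaptScale> s_coef, s_sigma_u;
  AdaptScale s_b, s_eps, s_phi_cell, s_gamma_cell, s_psi_cell, s_theta_cell,
      s_psi_year, s_theta_year, s_omega1, s_omega2, s_bdet1, s_bdet2;

  Sampler(Model& m, bool ul, const std::vector<std::string>& blocks)
      : M(m), upd_latent(ul) {
    const char* all[] = {"a0", "spline", "sigma_u", "b_car", "tau_b", "eps",
                         "sigma_eps", "dyn_intercepts", "dyn_cells",
                         "dyn_sigmas", "mu_init", "use_intercepts",
                         "use_cells", "use_years", "use_sigmas", "p_status",
                         "delta", "observers", "obs_sigmas", "b_det",
                         "tau_det"};
    for (auto nm : all) blk[nm] = false;
    for (auto& nm : blocks) {
      if (blk.find(nm) == blk.end())
        stop("unknown update block: " + nm);
      blk[nm] = true;
    }
    s_coef.assign(M.P, AdaptScale(0.1));
    s_sigma_u.assign(M.H, AdaptScale(0.3));
    s_b = s_eps = AdaptScale(0.3);
    s_phi_cell = s_gamma_cell = s_psi_cell = s_theta_cell = AdaptScale(0.3);
    s_psi_year = s_theta_year = AdaptScale(0.3);
    s_omega1 = s_omega2 = s_bdet1 = s_bdet2 = AdaptScale(0.3);
    s_tau_b = s_sigma_eps = s_sigma_phi = s_sigma_gamma = AdaptScale(0.3);
    s_sigma_psi_cell = s_sigma_theta_cell = AdaptScale(0.3);
    s_sigma_psi_year = s_sigma_theta_year = AdaptScale(0.3);
    for (int a = 0; a < 2; a++) {
      s_sigma_omega[a] = s_tau_det[a] = AdaptScale(0.3);
      s_psi0[a] = s_theta0[a] = AdaptScale(0.2);
      for (int u = 0; u < 2; u++) s_p[a][u] = AdaptScale(0.1);
    }
  }

  // --- occupancy level ---

  void upd_a0() {
    double d = propose(s_a0);
    double dlp = ldnorm(M.a0 + d, M.sd_fixed) - ldnorm(M.a0, M.sd_fixed);
    for (int i = 0; i < M.n; i++)
      dlp += lbern(M.X[i], M.eta1[i] + d) - lbern(M.X[i], M.eta1[i]);
    bool a = mh_accept(dlp);
    s_a0.tally(a);
    if (a) { M.a0 += d; for (int i = 0; i < M.n; i++) M.eta1[i] += d; }
  }

  void upd_coef(int j) {
    double d = propose(s_coef[j]);
    int hab = M.col_hab[j];
    double sd = hab == 0 ? M.sd_fixed : M.sigma_u[hab - 1];
    double dlp = ldnorm(M.coef[j] + d, sd) - ldnorm(M.coef[j], sd);
    for (int i = 0; i < M.n; i++) {
      double x = M.sdesign(i, j);
      if (x != 0)
        dlp += lbern(M.X[i], M.eta1[i] + d * x) - lbern(M.X[i], M.eta1[i]);
    }
    bool a = mh_accept(dlp);
    s_coef[j].tally(a);
    if (a) {
      M.coef[j] += d;
      for (int i = 0; i < M.n; i++) M.eta1[i] += d * M.sdesign(i, j);
    }
  }

  void upd_sigma_u(int h) {
    double d = propose(s_sigma_u[h]);
    double s0 = M.sigma_u[h], s1 = s0 * exp(d);
    if (s1 >= M.sd_upper) { s_sigma_u[h].tally(false); return; }
    double dlp = d;  // log-scale Jacobian, uniform prior
    for (int j = 0; j < M.P; j++)
      if (M.col_hab[j] == h + 1)
        dlp += ldnorm(M.coef[j], s1) - ldnorm(M.coef[j], s0);
    bool a = mh_accept(dlp);
    s_sigma_u[h].tally(a);
    if (a) M.sigma_u[h] = s1;
  }

  void upd_b_car() {
    for (int i = 0; i < M.n; i++) {
      double d = propose(s_b);
      double S = 0;
      for (int a = M.adj_ptr[i]; a < M.adj_ptr[i + 1]; a++)
        S += M.b[M.adj_idx[a]];
      double t2 = M.tau_b * M.tau_b;
      double b0 = M.b[i], b1 = b0 + d;
      double dlp = -(M.n_nb[i] * (b1 * b1 - b0 * b0) - 2 * S * d) / (2 * t2);
      dlp += lbern(M.X[i], M.eta1[i] + d) - lbern(M.X[i], M.eta1[i]);
      bool a = mh_accept(dlp);
      s_b.tally(a);
      if (a) { M.b[i] = b1; M.eta1[i] += d; }
    }
    double m = 0;
    for (int i = 0; i < M.n; i++) m += M.b[i];
    m /= M.n;
    for (int i = 0; i < M.n; i++) { M.b[i] -= m; M.eta1[i] -= m; }
  }

  void upd_tau_b() {
    double d = propose(s_tau_b);
    double t0 = M.tau_b, t1 = t0 * exp(d);
    if (t1 >= M.sd_upper) { s_tau_b.tally(false); return; }
    double Q = M.car_Q(M.b);
    double dlp = d - (M.n - 1) * (log(t1) - log(t0)) -
                 Q / 2 * (1 / (t1 * t1) - 1 / (t0 * t0));
    bool a = mh_accept(dlp);
    s_tau_b.tally(a);
    if (a) M.tau_b = t1;
  }

  void upd_eps() {
    for (int i = 0; i < M.n; i++) {
      double d = propose(s_eps);
      double e0 = M.eps[i], e1 = e0 + d;
      double dlp = ldnorm(e1, M.sigma_eps) - ldnorm(e0, M.sigma_eps);
      dlp += lbern(M.X[i], M.eta1[i] + d) - lbern(M.X[i], M.eta1[i]);
      bool a = mh_accept(dlp);
      s_eps.tally(a);
      if (a) { M.eps[i] = e1; M.eta1[i] += d; }
    }
  }

  void upd_sd_normal(AdaptScale& sc, double& sig,
                     const std::vector<double>& v, int len,
                     double upper = -1) {
    if (upper < 0) upper = M.sd_upper;
    double d = propose(sc);
    double s0 = sig, s1 = s0 * exp(d);
    if (s1 >= upper) { sc.tally(false); return; }
    double ss = 0;
    for (int i = 0; i < len; i++) ss += v[i] * v[i];
    double dlp = d - len * (log(s1) - log(s0)) -
                 ss / 2 * (1 / (s1 * s1) - 1 / (s0 * s0));
    bool a = mh_accept(dlp);
    sc.tally(a);
    if (a) sig = s1;
  }

  // --- dynamics level ---

  double dyn_ll(int i, double dphi0, double dgam0, double dslope_phi,
                double dslope_gam, double dcell_phi, double dcell_gam) {
    double D = M.Dprop(i);
    int x2 = M.X[i + M.n];
    if (M.X[i] == 1)
      return lbern(x2, M.phi_eta(i, D) + dphi0 + dslope_phi * D + dcell_phi);
    return lbern(x2, M.gamma_eta(i, D) + dgam0 + dslope_gam * D + dcell_gam);
  }

  void upd_dyn_scalar(AdaptScale& sc, double& par, int which) {
    // which: 0 phi0, 1 gamma0, 2 phi_slope, 3 gamma_slope
    double d = propose(sc);
    double dlp = ldnorm(par + d, M.sd_dyn) - ldnorm(par, M.sd_dyn);
    for (int i = 0; i < M.n; i++) {
      bool occ = M.X[i] == 1;
      if ((which == 0 || which == 2) && !occ) continue;
      if ((which == 1 || which == 3) && occ) continue;
      double D = M.Dprop(i);
      double e = occ ? M.phi_eta(i, D) : M.gamma_eta(i, D);
      double de = (which >= 2) ? d * D : d;
      int x2 = M.X[i + M.n];
      dlp += lbern(x2, e + de) - lbern(x2, e);
    }
    bool a = mh_accept(dlp);
    sc.tally(a);
    if (a) par += d;
  }

  // joint move along the intercept/slope ridge: the transition data only
  // constrain the predictor over the observed range of D, so axis moves
  // alone mix slowly; propose slope += e, intercept -= e * Dbar (symmetric,
  // fixed direction within the step, so detailed balance holds)
  void upd_dyn_ridge(bool persistence) {
    AdaptScale& sc = persistence ? s_phi_ridge : s_gamma_ridge;
    int want = persistence ? 1 : 0;
    double Dbar = 0;
    int cnt = 0;
    for (int i = 0; i < M.n; i++)
      if (M.X[i] == want) { Dbar += M.Dprop(i); cnt++; }
    if (cnt == 0) return;
    Dbar /= cnt;
    double e = propose(sc);
    double& b0 = persistence ? M.phi0 : M.gamma0;
    double& b1 = persistence ? M.phi_slope : M.gamma_slope;
    double dlp = ldnorm(b0 - e * Dbar, M.sd_dyn) - ldnorm(b0, M.sd_dyn) +
                 ldnorm(b1 + e, M.sd_dyn) - ldnorm(b1, M.sd_dyn);
    for (int i = 0; i < M.n; i++) {
      if (M.X[i] != want) continue;
      double D = M.Dprop(i);
      double eta = persistence ? M.phi_eta(i, D) : M.gamma_eta(i, D);
      int x2 = M.X[i + M.n];
      dlp += lbern(x2, eta + e * (D - Dbar)) - lbern(x2, eta);
    }
    bool a = mh_accept(dlp);
    sc.tally(a);
    if (a) { b0 -= e * Dbar; b1 += e; }
  }

  void upd_dyn_cells() {
    for (int i = 0; i < M.n; i++) {
      // phi_cell[i]
      double d = propose(s_phi_cell);
      double dlp = ldnorm(M.phi_cell[i] + d, M.sigma_phi) -
                   ldnorm(M.phi_cell[i], M.sigma_phi);
      if (M.X[i] == 1) {
        double D = M.Dprop(i);
        int x2 = M.X[i + M.n];
        dlp += lbern(x2, M.phi_eta(i, D) + d) - lbern(x2, M.phi_eta(i, D));
      }
      bool a = mh_accept(dlp);
      s_phi_cell.tally(a);
      if (a) M.phi_cell[i] += d;
      // gamma_cell[i]
      d = propose(s_gamma_cell);
      dlp = ldnorm(M.gamma_cell[i] + d, M.sigma_gamma) -
            ldnorm(M.gamma_cell[i], M.sigma_gamma);
      if (M.X[i] == 0) {
        double D = M.Dprop(i);
        int x2 = M.X[i + M.n];
        dlp += lbern(x2, M.gamma_eta(i, D) + d) -
               lbern(x2, M.gamma_eta(i, D));
      }
      a = mh_accept(dlp);
      s_gamma_cell.tally(a);
      if (a) M.gamma_cell[i] += d;
    }
  }

  // --- use level ---

  void upd_mu_init() {
    for (int s = 0; s < M.n_seasons; s++) {
      double n1 = 0, n0 = 0;
      for (int i = 0; i < M.n; i++)
        if (M.X[i + s * M.n] == 1) {
          if (M.Z[M.cy(i, s, 0)]) n1++; else n0++;
        }
      M.mu_init[s] = R::rbeta(1.0 + n1, 1.0 + n0);
    }
  }

  // delta log-lik of use transitions in season s when the psi (zprev = 1)
  // or theta (zprev = 0) logit changes by d, restricted by cell / year.
  double use_dll(int s, int zprev_sel, double d, int only_cell,
                 int only_t) {
    double dlp = 0;
    int T = M.Ts(s);
    int i_lo = only_cell >= 0 ? only_cell : 0;
    int i_hi = only_cell >= 0 ? only_cell + 1 : M.n;
    for (int i = i_lo; i < i_hi; i++) {
      if (M.X[i + s * M.n] == 0) continue;
      for (int t = 0; t < T - 1; t++) {
        if (only_t >= 0 && t != only_t) continue;
        int zp = M.Z[M.cy(i, s, t)];
        if (zp != zprev_sel) continue;
        int z = M.Z[M.cy(i, s, t + 1)];
        double e = zp ? M.psi_eta(i, s, t) : M.theta_eta(i, s, t);
        dlp += lbern(z, e + d) - lbern(z, e);
      }
    }
    return dlp;
  }

  void upd_use_intercepts() {
    for (int s = 0; s < M.n_seasons; s++) {
      if (M.Ts(s) < 2) continue;
      double d = propose(s_psi0[s]);
      double dlp = ldnorm(M.psi0[s] + d, M.sd_fixed) -
                   ldnorm(M.psi0[s], M.sd_fixed) + use_dll(s, 1, d, -1, -1);
      bool a = mh_accept(dlp);
      s_psi0[s].tally(a);
      if (a) M.psi0[s] += d;
      d = propose(s_theta0[s]);
      dlp = ldnorm(M.theta0[s] + d, M.sd_fixed) -
            ldnorm(M.theta0[s], M.sd_fixed) + use_dll(s, 0, d, -1, -1);
      a = mh_accept(dlp);
      s_theta0[s].tally(a);
      if (a) M.theta0[s] += d;
    }
  }

  void upd_use_cells() {
    for (int s = 0; s < M.n_seasons; s++) {
      if (M.Ts(s) < 2) continue;
      for (int i = 0; i < M.n; i++) {
        double d = propose(s_psi_cell);
        double& pc = M.psi_cell[i + s * M.n];
        double dlp = ldnorm(pc + d, M.sigma_psi_cell) -
                     ldnorm(pc, M.sigma_psi_cell) + use_dll(s, 1, d, i, -1);
        bool a = mh_accept(dlp);
        s_psi_cell.tally(a);
        if (a) pc += d;
        d = propose(s_theta_cell);
        double& tc = M.theta_cell[i + s * M.n];
        dlp = ldnorm(tc + d, M.sigma_theta_cell) -
              ldnorm(tc, M.sigma_theta_cell) + use_dll(s, 0, d, i, -1);
        a = mh_accept(dlp);
        s_theta_cell.tally(a);
        if (a) tc += d;
      }
    }
  }

  void upd_use_years() {
    for (int s = 0; s < M.n_seasons; s++)
      for (int t = 0; t < M.Ts(s) - 1; t++) {
        double d = propose(s_psi_year);
        double& pv = M.psi_year[M.yoff[s] + t];
        double dlp = ldnorm(pv + d, M.sigma_psi_year) -
                     ldnorm(pv, M.sigma_psi_year) + use_dll(s, 1, d, -1, t);
        bool a = mh_accept(dlp);
        s_psi_year.tally(a);
        if (a) pv += d;
        d = propose(s_theta_year);
        double& tv = M.theta_year[M.yoff[s] + t];
        dlp = ldnorm(tv + d, M.sigma_theta_year) -
              ldnorm(tv, M.sigma_theta_year) + use_dll(s, 0, d, -1, t);
        a = mh_accept(dlp);
        s_theta_year.tally(a);
        if (a) tv += d;
      }
  }

  // --- observation level ---

  int cl_z(int c) const {
    return M.Z[M.cy(M.cl_cell[c], M.cl_season[c], M.cl_year[c])];
  }

  void upd_p_status() {
    for (int pr = 0; pr < 2; pr++)
      for (int st = 0; st < 2; st++) {
        double d = propose(s_p[pr][st]);
        double cur = M.p_status[pr][st];
        double dlp = ldnorm(cur + d, M.sd_fixed) - ldnorm(cur, M.sd_fixed);
        for (int c = 0; c < M.C; c++) {
          if (M.cl_prot[c] != pr || M.cl_status[c] != st) continue;
          if (!cl_z(c)) continue;
          dlp += M.cl_ll(c, 1, M.det_lp[c] + d) - M.cl_ll(c, 1);
        }
        bool a = mh_accept(dlp);
        s_p[pr][st].tally(a);
        if (a) {
          M.p_status[pr][st] += d;
          for (int c = 0; c < M.C; c++)
            if (M.cl_prot[c] == pr && M.cl_status[c] == st)
              M.det_lp[c] += d;
        }
      }
  }

  void upd_observers() {
    for (int k = 0; k < M.K1; k++) {
      double d = propose(s_omega1);
      double dlp = ldnorm(M.omega1[k] + d, M.sigma_omega[0]) -
                   ldnorm(M.omega1[k], M.sigma_omega[0]);
      for (int a = M.obs1_ptr[k]; a < M.obs1_ptr[k + 1]; a++) {
        int c = M.obs1_idx[a];
        if (cl_z(c)) dlp += M.cl_ll(c, 1, M.det_lp[c] + d) - M.cl_ll(c, 1);
      }
      bool acc = mh_accept(dlp);
      s_omega1.tally(acc);
      if (acc) {
        M.omega1[k] += d;
        for (int a = M.obs1_ptr[k]; a < M.obs1_ptr[k + 1]; a++)
          M.det_lp[M.obs1_idx[a]] += d;
      }
    }
    for (int k = 0; k < M.K2; k++) {
      double d = propose(s_omega2);
      double dlp = ldnorm(M.omega2[k] + d, M.sigma_omega[1]) -
                   ldnorm(M.omega2[k], M.sigma_omega[1]);
      for (int a = M.obs2_ptr[k]; a < M.obs2_ptr[k + 1]; a++) {
        int c = M.obs2_idx[a];
        if (cl_z(c)) dlp += M.cl_ll(c, 1, M.det_lp[c] + d) - M.cl_ll(c, 1);
      }
      bool acc = mh_accept(dlp);
      s_omega2.tally(acc);
      if (acc) {
        M.omega2[k] += d;
        for (int a = M.obs2_ptr[k]; a < M.obs2_ptr[k + 1]; a++)
          M.det_lp[M.obs2_idx[a]] += d;
      }
    }
  }

  void upd_b_det() {
    for (int prot = 0; prot < 2; prot++) {
      std::vector<double>& bd = prot == 0 ? M.b_det1 : M.b_det2;
      const std::vector<int>& ptr = prot == 0 ? M.cp1_ptr : M.cp2_ptr;
      const std::vector<int>& idx = prot == 0 ? M.cp1_idx : M.cp2_idx;
      AdaptScale& sc = prot == 0 ? s_bdet1 : s_bdet2;
      double tau = M.tau_det[prot];
      bool any = false;
      for (int c = 0; c < M.C; c++)
        if (M.cl_prot[c] == prot) { any = true; break; }
      if (!any) continue;
      for (int i = 0; i < M.n; i++) {
        double d = propose(sc);
        double S = 0;
        for (int a = M.adj_ptr[i]; a < M.adj_ptr[i + 1]; a++)
          S += bd[M.adj_idx[a]];
        double t2 = tau * tau;
        double b0 = bd[i], b1 = b0 + d;
        double dlp = -(M.n_nb[i] * (b1 * b1 - b0 * b0) - 2 * S * d) /
                     (2 * t2);
        for (int a = ptr[i]; a < ptr[i + 1]; a++) {
          int c = idx[a];
          if (cl_z(c)) dlp += M.cl_ll(c, 1, M.det_lp[c] + d) - M.cl_ll(c, 1);
        }
        bool acc = mh_accept(dlp);
        sc.tally(acc);
        if (acc) {
          bd[i] = b1;
          for (int a = ptr[i]; a < ptr[i + 1]; a++) M.det_lp[idx[a]] += d;
        }
      }
      double m = 0;
      for (int i = 0; i < M.n; i++) m += bd[i];
      m /= M.n;
      for (int i = 0; i < M.n; i++) bd[i] -= m;
      for (int c = 0; c < M.C; c++)
        if (M.cl_prot[c] == prot) M.det_lp[c] -= m;
    }
  }

  void upd_tau_det(int prot) {
    // with no checklists of this protocol the field is never updated and
    // tau's conditional is improper at 0; leave it fixed
    bool any = false;
    for (int c = 0; c < M.C; c++)
      if (M.cl_prot[c] == prot) { any = true; break; }
    if (!any) return;
    AdaptScale& sc = s_tau_det[prot];
    double d = propose(sc);
    double t0 = M.tau_det[prot], t1 = t0 * exp(d);
    if (t1 >= M.sd_upper) { sc.tally(false); return; }
    double Q = M.car_Q(prot == 0 ? M.b_det1 : M.b_det2);
    double dlp = d - (M.n - 1) * (log(t1) - log(t0)) -
                 Q / 2 * (1 / (t1 * t1) - 1 / (t0 * t0));
    bool a = mh_accept(dlp);
    sc.tally(a);
    if (a) M.tau_det[prot] = t1;
  }

  void upd_delta() {
    double d = propose(s_delta);
    double dlp = ldnorm(M.delta_par + d, M.sd_fixed) -
                 ldnorm(M.delta_par, M.sd_fixed);
    for (int c = 0; c < M.C; c++) {
      if (M.cl_prot[c] != 1) continue;
      if (M.cl_det[c] == 1 && M.cl_int[c] == 1) continue;  // no p'' term
      if (!cl_z(c)) continue;
      double lp = M.det_lp[c];
      double e = lp + M.delta_par, e2 = e + d;
      if (M.cl_det[c] == 0) dlp += log_il(-e2) - log_il(-e);
      else dlp += log_il(e2) - log_il(e);
    }
    bool a = mh_accept(dlp);
    s_delta.tally(a);
    if (a) M.delta_par += d;
  }

  void param_sweep() {
    if (blk["a0"]) upd_a0();
    if (blk["spline"]) for (int j = 0; j < M.P; j++) upd_coef(j);
    if (blk["sigma_u"]) for (int h = 0; h < M.H; h++) upd_sigma_u(h);
    if (blk["b_car"]) upd_b_car();
    if (blk["tau_b"]) upd_tau_b();
    if (blk["eps"]) upd_eps();
    if (blk["sigma_eps"])
      upd_sd_normal(s_sigma_eps, M.sigma_eps, M.eps, M.n, M.sd_upper_dyn);
    if (M.n_seasons == 2) {
      if (blk["dyn_intercepts"]) {
        // repeated cheap O(n) updates: one transition observation per cell
        // makes these intercept/slope pairs the slowest-mixing block
        for (int rep = 0; rep < 5; rep++) {
          upd_dyn_scalar(s_phi0, M.phi0, 0);
          upd_dyn_scalar(s_gamma0, M.gamma0, 1);
          upd_dyn_scalar(s_phi_slope, M.phi_slope, 2);
          upd_dyn_scalar(s_gamma_slope, M.gamma_slope, 3);
          upd_dyn_ridge(true);
          upd_dyn_ridge(false);
        }
      }
      if (blk["dyn_cells"]) upd_dyn_cells();
      if (blk["dyn_sigmas"]) {
        upd_sd_normal(s_sigma_phi, M.sigma_phi, M.phi_cell, M.n,
                      M.sd_upper_dyn);
        upd_sd_normal(s_sigma_gamma, M.sigma_gamma, M.gamma_cell, M.n,
                      M.sd_upper_dyn);
      }
    }
    if (blk["mu_init"]) upd_mu_init();
    if (blk["use_intercepts"]) upd_use_intercepts();
    if (blk["use_cells"]) upd_use_cells();
    if (blk["use_years"]) upd_use_years();
    if (blk["use_sigmas"]) {
      std::vector<double> tmp(M.psi_cell.begin(),
                              M.psi_cell.begin() + M.n_seasons * M.n);
      upd_sd_normal(s_sigma_psi_cell, M.sigma_psi_cell, tmp,
                    M.n_seasons * M.n, M.sd_upper_dyn);
      tmp.assign(M.theta_cell.begin(),
                 M.theta_cell.begin() + M.n_seasons * M.n);
      upd_sd_normal(s_sigma_theta_cell, M.sigma_theta_cell, tmp,
                    M.n_seasons * M.n, M.sd_upper_dyn);
      upd_sd_normal(s_sigma_psi_year, M.sigma_psi_year, M.psi_year, M.py);
      upd_sd_normal(s_sigma_theta_year, M.sigma_theta_year, M.theta_year,
                    M.py);
    }
    if (blk["p_status"]) upd_p_status();
    if (blk["observers"]) upd_observers();
    if (blk["obs_sigmas"]) {
      upd_sd_normal(s_sigma_omega[0], M.sigma_omega[0], M.omega1, M.K1);
      upd_sd_normal(s_sigma_omega[1], M.sigma_omega[1], M.omega2, M.K2);
    }
    if (blk["b_det"]) upd_b_det();
    if (blk["tau_det"]) { upd_tau_det(0); upd_tau_det(1); }
    if (blk["delta"]) upd_delta();
  }

  void adapt_all(int batch) {
    AdaptScale* sc[] = {&s_a0, &s_tau_b, &s_sigma_eps, &s_phi0, &s_gamma0,
                        &s_phi_slope, &s_gamma_slope, &s_sigma_phi,
                        &s_sigma_gamma, &s_delta, &s_phi_ridge,
                        &s_gamma_ridge, &s_psi0[0], &s_psi0[1],
                        &s_theta0[0], &s_theta0[1], &s_p[0][0], &s_p[0][1],
                        &s_p[1][0], &s_p[1][1], &s_sigma_omega[0],
                        &s_sigma_omega[1], &s_tau_det[0], &s_tau_det[1],
                        &s_sigma_psi_cell, &s_sigma_theta_cell,
                        &s_sigma_psi_year, &s_sigma_theta_year, &s_b, &s_eps,
                        &s_phi_cell, &s_gamma_cell, &s_psi_cell,
                        &s_theta_cell, &s_psi_year, &s_theta_year, &s_omega1,
                        &s_omega2, &s_bdet1, &s_bdet2};
    for (auto p : sc) p->adapt(batch);
    for (auto& p : s_coef) p.adapt(batch);
    for (auto& p : s_sigma_u) p.adapt(batch);
  }
};

// ---------------------------------------------------------------------------
// marshalling
// ---------------------------------------------------------------------------

static std::vector<int> as_ivec(SEXP x) {
  IntegerVector v(x);
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> as_dvec(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}

static void load_model(Model& M, List data, List params, List latent) {
  M.n = as<int>(data["n_cells"]);
  M.T1 = as<int>(data["T1"]);
  M.T2 = as<int>(data["T2"]);
  M.Tt = M.T1 + M.T2;
  M.n_seasons = M.T2 > 0 ? 2 : 1;
  M.adj_ptr = as_ivec(data["adj_ptr"]);
  M.adj_idx = as_ivec(data["adj_idx"]);
  M.n_nb = as_ivec(data["n_nb"]);
  M.sdesign = as<NumericMatrix>(data["sdesign"]);
  M.col_hab = as_ivec(data["col_hab"]);
  M.P = M.sdesign.ncol();
  M.H = as<int>(data["n_hab"]);
  M.K1 = as<int>(data["K1"]);
  M.K2 = as<int>(data["K2"]);
  M.cl_cell = as_ivec(data["cl_cell"]);
  M.cl_season = as_ivec(data["cl_season"]);
  M.cl_year = as_ivec(data["cl_year"]);
  M.cl_prot = as_ivec(data["cl_prot"]);
  M.cl_status = as_ivec(data["cl_status"]);
  M.cl_obs = as_ivec(data["cl_obs"]);
  M.cl_det = as_ivec(data["cl_det"]);
  M.cl_m = as_ivec(data["cl_m"]);
  M.cl_int = as_ivec(data["cl_int"]);
  M.cl_fh = as_ivec(data["cl_fh"]);
  M.C = (int)M.cl_cell.size();
  M.cy_ptr = as_ivec(data["cy_ptr"]);
  M.cy_ord = as_ivec(data["cy_ord"]);
  M.obs1_ptr = as_ivec(data["obs1_ptr"]);
  M.obs1_idx = as_ivec(data["obs1_idx"]);
  M.obs2_ptr = as_ivec(data["obs2_ptr"]);
  M.obs2_idx = as_ivec(data["obs2_idx"]);
  M.cp1_ptr = as_ivec(data["cp1_ptr"]);
  M.cp1_idx = as_ivec(data["cp1_idx"]);
  M.cp2_ptr = as_ivec(data["cp2_ptr"]);
  M.cp2_idx = as_ivec(data["cp2_idx"]);
  M.Zforce = as_ivec(data["Zforce"]);
  M.Xforce = as_ivec(data["Xforce"]);
  M.ncy = M.n * M.Tt;
  M.sd_fixed = as<double>(data["sd_fixed"]);
  M.sd_upper = as<double>(data["sd_upper"]);
  M.sd_upper_dyn = as<double>(data["sd_upper_dyn"]);
  M.sd_dyn = as<double>(data["sd_dyn"]);

  M.a0 = as<double>(params["a0"]);
  M.coef = as_dvec(params["coef"]);
  M.sigma_u = as_dvec(params["sigma_u"]);
  M.tau_b = as<double>(params["tau_b"]);
  M.sigma_eps = as<double>(params["sigma_eps"]);
  M.b = as_dvec(params["b"]);
  M.eps = as_dvec(params["eps"]);
  M.phi0 = as<double>(params["phi0"]);
  M.gamma0 = as<double>(params["gamma0"]);
  M.phi_slope = as<double>(params["phi_slope"]);
  M.gamma_slope = as<double>(params["gamma_slope"]);
  M.sigma_phi = as<double>(params["sigma_phi"]);
  M.sigma_gamma = as<double>(params["sigma_gamma"]);
  M.phi_cell = as_dvec(params["phi_cell"]);
  M.gamma_cell = as_dvec(params["gamma_cell"]);
  std::vector<double> mi = as_dvec(params["mu_init"]);
  M.mu_init[0] = mi[0]; M.mu_init[1] = mi[1];
  std::vector<double> p0 = as_dvec(params["psi0"]);
  M.psi0[0] = p0[0]; M.psi0[1] = p0[1];
  std::vector<double> t0 = as_dvec(params["theta0"]);
  M.theta0[0] = t0[0]; M.theta0[1] = t0[1];
  M.psi_cell = as_dvec(params["psi_cell"]);
  M.theta_cell = as_dvec(params["theta_cell"]);
  M.sigma_psi_cell = as<double>(params["sigma_psi_cell"]);
  M.sigma_theta_cell = as<double>(params["sigma_theta_cell"]);
  M.sigma_psi_year = as<double>(params["sigma_psi_year"]);
  M.sigma_theta_year = as<double>(params["sigma_theta_year"]);
  M.psi_year = as_dvec(params["psi_year"]);
  M.theta_year = as_dvec(params["theta_year"]);
  M.yoff[0] = 0;
  M.yoff[1] = std::max(M.T1 - 1, 0);
  M.py = M.yoff[1] + std::max(M.T2 - 1, 0);
  if ((int)M.psi_year.size() != M.py) stop("psi_year length mismatch");
  NumericMatrix ps = as<NumericMatrix>(params["p_status"]);
  for (int pr = 0; pr < 2; pr++)
    for (int st = 0; st < 2; st++) M.p_status[pr][st] = ps(pr, st);
  M.delta_par = as<double>(params["delta"]);
  M.omega1 = as_dvec(params["omega1"]);
  M.omega2 = as_dvec(params["omega2"]);
  std::vector<double> so = as_dvec(params["sigma_omega"]);
  M.sigma_omega[0] = so[0]; M.sigma_omega[1] = so[1];
  M.b_det1 = as_dvec(params["b_det1"]);
  M.b_det2 = as_dvec(params["b_det2"]);
  std::vector<double> td = as_dvec(params["tau_det"]);
  M.tau_det[0] = td[0]; M.tau_det[1] = td[1];

  M.X = as_ivec(latent["X"]);
  M.Z = as_ivec(latent["Z"]);
  if ((int)M.X.size() != 2 * M.n || (int)M.Z.size() != M.ncy)
    stop("latent state dimensions do not match the data");
  M.rebuild_caches();
}

static List dump_params(const Model& M) {
  NumericMatrix ps(2, 2);
  for (int pr = 0; pr < 2; pr++)
    for (int st = 0; st < 2; st++) ps(pr, st) = M.p_status[pr][st];
  List out;
  out["a0"] = M.a0; out["coef"] = M.coef; out["sigma_u"] = M.sigma_u;
  out["tau_b"] = M.tau_b; out["sigma_eps"] = M.sigma_eps; out["b"] = M.b;
  out["eps"] = M.eps; out["phi0"] = M.phi0; out["gamma0"] = M.gamma0;
  out["phi_slope"] = M.phi_slope; out["gamma_slope"] = M.gamma_slope;
  out["sigma_phi"] = M.sigma_phi; out["sigma_gamma"] = M.sigma_gamma;
  out["phi_cell"] = M.phi_cell; out["gamma_cell"] = M.gamma_cell;
  out["mu_init"] = NumericVector::create(M.mu_init[0], M.mu_init[1]);
  out["psi0"] = NumericVector::create(M.psi0[0], M.psi0[1]);
  out["theta0"] = NumericVector::create(M.theta0[0], M.theta0[1]);
  out["psi_cell"] = M.psi_cell; out["theta_cell"] = M.theta_cell;
  out["sigma_psi_cell"] = M.sigma_psi_cell;
  out["sigma_theta_cell"] = M.sigma_theta_cell;
  out["sigma_psi_year"] = M.sigma_psi_year;
  out["sigma_theta_year"] = M.sigma_theta_year;
  out["psi_year"] = M.psi_year; out["theta_year"] = M.theta_year;
  out["p_status"] = ps; out["delta"] = M.delta_par;
  out["omega1"] = M.omega1; out["omega2"] = M.omega2;
  out["sigma_omega"] = NumericVector::create(M.sigma_omega[0],
                                             M.sigma_omega[1]);
  out["b_det1"] = M.b_det1; out["b_det2"] = M.b_det2;
  out["tau_det"] = NumericVector::create(M.tau_det[0], M.tau_det[1]);
  return out;
}

// number of tracked scalar parameters
static int n_scalars(const Model& M) {
  return 1 + M.P + M.H + 2 + 4 + 2 + 2 + 2 + 2 + 2 + 2 + 2 * M.py + 4 + 1 +
         2 + 2;
}

static void write_scalars(const Model& M, double* out) {
  int k = 0;
  out[k++] = M.a0;
  for (int j = 0; j < M.P; j++) out[k++] = M.coef[j];
  for (int h = 0; h < M.H; h++) out[k++] = M.sigma_u[h];
  out[k++] = M.tau_b; out[k++] = M.sigma_eps;
  out[k++] = M.phi0; out[k++] = M.gamma0;
  out[k++] = M.phi_slope; out[k++] = M.gamma_slope;
  out[k++] = M.sigma_phi; out[k++] = M.sigma_gamma;
  out[k++] = M.mu_init[0]; out[k++] = M.mu_init[1];
  out[k++] = M.psi0[0]; out[k++] = M.psi0[1];
  out[k++] = M.theta0[0]; out[k++] = M.theta0[1];
  out[k++] = M.sigma_psi_cell; out[k++] = M.sigma_theta_cell;
  out[k++] = M.sigma_psi_year; out[k++] = M.sigma_theta_year;
  for (int j = 0; j < M.py; j++) out[k++] = M.psi_year[j];
  for (int j = 0; j < M.py; j++) out[k++] = M.theta_year[j];
  out[k++] = M.p_status[0][0]; out[k++] = M.p_status[0][1];
  out[k++] = M.p_status[1][0]; out[k++] = M.p_status[1][1];
  out[k++] = M.delta_par;
  out[k++] = M.sigma_omega[0]; out[k++] = M.sigma_omega[1];
  out[k++] = M.tau_det[0]; out[k++] = M.tau_det[1];
}

// derived per-cell quantities for one draw: q1, phi, gamma, q2, then the
// use probability mu for every (season, year) slot
static void write_derived(const Model& M, double* out) {
  int n = M.n;
  for (int i = 0; i < n; i++) out[i] = 1.0 / (1.0 + exp(-M.eta1[i]));
  for (int i = 0; i < n; i++) {
    double D = M.Dprop(i);
    double phi = 1.0 / (1.0 + exp(-M.phi_eta(i, D)));
    double gam = 1.0 / (1.0 + exp(-M.gamma_eta(i, D)));
    out[n + i] = phi;
    out[2 * n + i] = gam;
    out[3 * n + i] = M.X[i] ? phi : gam;
  }
  for (int s = 0; s < M.n_seasons; s++)
    for (int t = 0; t < M.Ts(s); t++) {
      int slot = (s == 0 ? t : M.T1 + t);
      double* o = out + (4 + slot) * n;
      for (int i = 0; i < n; i++) {
        if (M.X[i + s * n] == 0) { o[i] = 0; continue; }
        if (t == 0) { o[i] = M.mu_init[s]; continue; }
        int zp = M.Z[M.cy(i, s, t - 1)];
        double e = zp ? M.psi_eta(i, s, t - 1) : M.theta_eta(i, s, t - 1);
        o[i] = 1.0 / (1.0 + exp(-e));
      }
    }
}

// ---------------------------------------------------------------------------
// exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_sampler_cpp(List data, List params, List latent, List config) {
  Model M;
  load_model(M, data, params, latent);
  int n_burnin = as<int>(config["n_burnin"]);
  int n_iter = as<int>(config["n_iter"]);
  int thin = as<int>(config["thin"]);
  bool adapt = as<bool>(config["adapt"]);
  bool upd_latent = as<bool>(config["update_latent"]);
  bool store_derived = as<bool>(config["store_derived"]);
  bool store_latent = as<bool>(config["store_latent"]);
  std::vector<std::string> blocks =
      as<std::vector<std::string> >(config["update_blocks"]);
  Sampler S(M, upd_latent, blocks);

  int n_keep = n_iter / thin;
  int ns = n_scalars(M);
  int nd = store_derived ? M.n * (4 + M.Tt) : 0;
  NumericMatrix scalars(n_keep, ns);
  NumericMatrix derived(store_derived ? n_keep : 1, std::max(nd, 1));
  IntegerMatrix lat_draws(store_latent ? n_keep : 1,
                          store_latent ? 2 * M.n + M.ncy : 1);
  std::vector<double> Xsum(2 * M.n, 0.0), Zsum(M.ncy, 0.0);

  int batch = 0;
  for (int it = 0; it < n_burnin + n_iter; it++) {
    if (upd_latent) M.latent_sweep();
    S.param_sweep();
    if (it < n_burnin && adapt && (it + 1) % 50 == 0) S.adapt_all(++batch);
    if (it >= n_burnin) {
      int post = it - n_burnin;
      for (int j = 0; j < 2 * M.n; j++) Xsum[j] += M.X[j];
      for (int j = 0; j < M.ncy; j++) Zsum[j] += M.Z[j];
      if ((post + 1) % thin == 0) {
        int row = post / thin;
        if (row < n_keep) {
          std::vector<double> buf(ns);
          write_scalars(M, buf.data());
          for (int j = 0; j < ns; j++) scalars(row, j) = buf[j];
          if (store_derived) {
            std::vector<double> dbuf(nd);
            write_derived(M, dbuf.data());
            for (int j = 0; j < nd; j++) derived(row, j) = dbuf[j];
          }
          if (store_latent) {
            for (int j = 0; j < 2 * M.n; j++) lat_draws(row, j) = M.X[j];
            for (int j = 0; j < M.ncy; j++)
              lat_draws(row, 2 * M.n + j) = M.Z[j];
          }
        }
      }
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector Xmean(2 * M.n), Zmean(M.ncy);
  for (int j = 0; j < 2 * M.n; j++) Xmean[j] = Xsum[j] / n_iter;
  for (int j = 0; j < M.ncy; j++) Zmean[j] = Zsum[j] / n_iter;

  return List::create(
      _["scalars"] = scalars, _["derived"] = derived,
      _["latent_draws"] = lat_draws, _["X_mean"] = Xmean,
      _["Z_mean"] = Zmean, _["final_params"] = dump_params(M),
      _["final_latent"] = List::create(_["X"] = IntegerVector(M.X.begin(),
                                                              M.X.end()),
                                       _["Z"] = IntegerVector(M.Z.begin(),
                                                              M.Z.end())));
}

// Complete-data log posterior, accumulated independently of the R reference
// implementation (different order and grouping of terms). Returns the named
// components so callers can identify a non-finite term.
// [[Rcpp::export]]
List cpp_log_posterior(List data, List params, List latent) {
  Model M;
  load_model(M, data, params, latent);
  double lp_occ1 = 0, lp_occ2 = 0, lp_use = 0, lp_obs = 0, lp_prior = 0;

  for (int s = 0; s < M.n_seasons; s++)
    for (int i = 0; i < M.n; i++)
      for (int t = 0; t < M.Ts(s); t++)
        if (M.Z[M.cy(i, s, t)] == 1 && M.X[i + s * M.n] == 0)
          lp_use = R_NegInf;

  for (int i = 0; i < M.n; i++) lp_occ1 += lbern(M.X[i], M.eta1[i]);
  if (M.n_seasons == 2)
    for (int i = 0; i < M.n; i++) {
      double D = M.Dprop(i);
      double e = M.X[i] ? M.phi_eta(i, D) : M.gamma_eta(i, D);
      lp_occ2 += lbern(M.X[i + M.n], e);
    }
  if (lp_use == 0)
    for (int s = 0; s < M.n_seasons; s++)
      for (int i = 0; i < M.n; i++) {
        if (M.X[i + s * M.n] == 1) lp_use += M.use_chain_ll(i, s);
        // X = 0: all Z are 0 with probability 1 (checked above)
      }
  for (int c = 0; c < M.C; c++) {
    int z = M.Z[M.cy(M.cl_cell[c], M.cl_season[c], M.cl_year[c])];
    lp_obs += M.cl_ll(c, z);
  }

  // priors
  double sf = M.sd_fixed, su = M.sd_upper;
  std::vector<double> sds = {M.tau_b, M.sigma_psi_year, M.sigma_theta_year,
                             M.sigma_omega[0], M.sigma_omega[1],
                             M.tau_det[0], M.tau_det[1]};
  for (int h = 0; h < M.H; h++) sds.push_back(M.sigma_u[h]);
  for (double s : sds) if (s <= 0 || s >= su) lp_prior = R_NegInf;
  // per-cell effects seen through a handful of Bernoulli trials: tight bound
  std::vector<double> sds_dyn = {M.sigma_eps, M.sigma_phi, M.sigma_gamma,
                                 M.sigma_psi_cell, M.sigma_theta_cell};
  for (double s : sds_dyn)
    if (s <= 0 || s >= M.sd_upper_dyn) lp_prior = R_NegInf;
  for (int s = 0; s < 2; s++)
    if (M.mu_init[s] <= 0 || M.mu_init[s] >= 1) lp_prior = R_NegInf;
  if (lp_prior == 0) {
    lp_prior += ldnorm(M.a0, sf);
    for (int j = 0; j < M.P; j++) {
      int hab = M.col_hab[j];
      lp_prior += ldnorm(M.coef[j], hab == 0 ? sf : M.sigma_u[hab - 1]);
    }
    lp_prior += -(M.n - 1) * log(M.tau_b) -
                M.car_Q(M.b) / (2 * M.tau_b * M.tau_b);
    for (int i = 0; i < M.n; i++) lp_prior += ldnorm(M.eps[i], M.sigma_eps);
    lp_prior += ldnorm(M.phi0, M.sd_dyn) + ldnorm(M.gamma0, M.sd_dyn) +
                ldnorm(M.phi_slope, M.sd_dyn) +
                ldnorm(M.gamma_slope, M.sd_dyn);
    for (int i = 0; i < M.n; i++)
      lp_prior += ldnorm(M.phi_cell[i], M.sigma_phi) +
                  ldnorm(M.gamma_cell[i], M.sigma_gamma);
    for (int s = 0; s < M.n_seasons; s++) {
      lp_prior += ldnorm(M.psi0[s], sf) + ldnorm(M.theta0[s], sf);
      for (int i = 0; i < M.n; i++)
        lp_prior += ldnorm(M.psi_cell[i + s * M.n], M.sigma_psi_cell) +
                    ldnorm(M.theta_cell[i + s * M.n], M.sigma_theta_cell);
    }
    for (int j = 0; j < M.py; j++)
      lp_prior += ldnorm(M.psi_year[j], M.sigma_psi_year) +
                  ldnorm(M.theta_year[j], M.sigma_theta_year);
    for (int pr = 0; pr < 2; pr++)
      for (int st = 0; st < 2; st++) lp_prior += ldnorm(M.p_status[pr][st], sf);
    lp_prior += ldnorm(M.delta_par, sf);
    for (int k = 0; k < M.K1; k++)
      lp_prior += ldnorm(M.omega1[k], M.sigma_omega[0]);
    for (int k = 0; k < M.K2; k++)
      lp_prior += ldnorm(M.omega2[k], M.sigma_omega[1]);
    lp_prior += -(M.n - 1) * log(M.tau_det[0]) -
                M.car_Q(M.b_det1) / (2 * M.tau_det[0] * M.tau_det[0]);
    lp_prior += -(M.n - 1) * log(M.tau_det[1]) -
                M.car_Q(M.b_det2) / (2 * M.tau_det[1] * M.tau_det[1]);
  }
  double total = lp_occ1 + lp_occ2 + lp_use + lp_obs + lp_prior;
  return List::create(_["total"] = total, _["occupancy1"] = lp_occ1,
                      _["occupancy2"] = lp_occ2, _["use"] = lp_use,
                      _["observation"] = lp_obs, _["priors"] = lp_prior);
}
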
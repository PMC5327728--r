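// Semi-implicit time stepper for the Wnt/metabolism reaction-diffusion
// model.  Reactions are advanced explicitly; diffusion is advanced
// implicitly by dimensional splitting with precomputed dense inverse
// operators (I - dt*D*L)^-1 per axis, built on the R side.  The nutrient
// additionally treats its linear uptake and decay implicitly (pointwise)
// and carries Dirichlet boundary values tied to the instantaneous total
// glycolytic population.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::cube;

struct Pars {
  double tau_o, tau_g, tau_og, tau_go, alpha_W, kappa_W, kappa_WI;
  double mu_o, mu_g, mu_d, mu_W, mu_WI, mu_N, S_W, a, b;
  double gamma_W, gamma_N, nu_NG, nu_NO, N_s, alpha_N;
  double W_star, N_star, N_g_star, mu_Po, mu_Pg, live_floor;
  static Pars from(const List& p) {
    Pars q;
    q.tau_o = p["tau_o"]; q.tau_g = p["tau_g"]; q.tau_og = p["tau_og"];
    q.tau_go = p["tau_go"]; q.alpha_W = p["alpha_W"];
    q.kappa_W = p["kappa_W"]; q.kappa_WI = p["kappa_WI"];
    q.mu_o = p["mu_o"]; q.mu_g = p["mu_g"]; q.mu_d = p["mu_d"];
    q.mu_W = p["mu_W"]; q.mu_WI = p["mu_WI"]; q.mu_N = p["mu_N"];
    q.S_W = p["S_W"]; q.a = p["a"]; q.b = p["b"];
    q.gamma_W = p["gamma_W"]; q.gamma_N = p["gamma_N"];
    q.nu_NG = p["nu_NG"]; q.nu_NO = p["nu_NO"];
    q.N_s = p["N_s"]; q.alpha_N = p["alpha_N"];
    q.W_star = p["W_star"]; q.N_star = p["N_star"];
    q.N_g_star = p["N_g_star"];
    q.mu_Po = p["mu_Po"]; q.mu_Pg = p["mu_Pg"];
    q.live_floor = p["live_floor"];
    return q;
  }
};

static inline double clip_neg(mat& F) {
  arma::uvec idx = arma::find(F < 0.0);
  double m = 0.0;
  for (arma::uword i = 0; i < idx.n_elem; ++i) m -= F(idx(i));
  F.elem(idx).zeros();
  return m;
}
static inline double clip_neg3(cube& F) {
  arma::uvec idx = arma::find(F < 0.0);
  double m = 0.0;
  for (arma::uword i = 0; i < idx.n_elem; ++i) m -= F(idx(i));
  F.elem(idx).zeros();
  return m;
}

static inline void set_frame(mat& F, double v) {
  F.row(0).fill(v); F.row(F.n_rows - 1).fill(v);
  F.col(0).fill(v); F.col(F.n_cols - 1).fill(v);
}
static inline void set_faces(cube& F, double v) {
  F.slice(0).fill(v); F.slice(F.n_slices - 1).fill(v);
  for (arma::uword k = 0; k < F.n_slices; ++k) {
    F.slice(k).row(0).fill(v); F.slice(k).row(F.n_rows - 1).fill(v);
    F.slice(k).col(0).fill(v); F.slice(k).col(F.n_cols - 1).fill(v);
  }
}

// implicit diffusion sweep along each axis of a cube
static void diffuse3(cube& F, const mat& Ax, const mat& Ay, const mat& Az) {
  for (arma::uword k = 0; k < F.n_slices; ++k)
    F.slice(k) = Ax * F.slice(k) * Ay.t();
  const arma::uword nx = F.n_rows, ny = F.n_cols, nz = F.n_slices;
  mat M(nx, nz);
  for (arma::uword j = 0; j < ny; ++j) {
    for (arma::uword k = 0; k < nz; ++k) M.col(k) = F.slice(k).col(j);
    M = M * Az.t();
    for (arma::uword k = 0; k < nz; ++k) F.slice(k).col(j) = M.col(k);
  }
}

// Shared reaction-increment computation (2D).  Adds dt * reaction to the
// fields in place; N gets its pointwise-implicit update.  Returns the
// boundary value used for N.
static double react_2d(mat& Po, mat& Pg, mat& Pd, mat& W, mat& WI, mat& N,
                       const Pars& q, double dt, double cell_vol, double V,
                       double Nb_override, bool invitro,
                       mat* L, double D_feed_prod, double feed_rate,
                       double mu_L, double beta_L, double gel_N) {
  double NS = 0.0, Nb;
  if (invitro) {
    Nb = gel_N;
  } else {
    const double ipg = arma::accu(Pg) * cell_vol;
    const double itot = ipg + (arma::accu(Po) + arma::accu(Pd)) * cell_vol;
    double denom = itot > q.live_floor * V ? itot : q.live_floor * V;
    double frac = ipg / denom; if (frac > 1.0) frac = 1.0;
    NS = q.N_s * ((1.0 - q.alpha_N) * frac + q.alpha_N);
    Nb = (Nb_override >= 0.0) ? Nb_override : NS / q.N_s;
  }
  const mat chiW = 0.5 * (1.0 + arma::tanh(q.gamma_W * (W - q.W_star)));
  const mat chiN = 0.5 * (1.0 + arma::tanh(q.gamma_N * (N - q.N_star)));
  const mat chiNs = 0.5 * (1.0 + arma::tanh(q.gamma_N * (N - q.N_g_star)));
  const mat Tt = Po + Pg + Pd;
  const mat mm = W / (q.alpha_W + W);
  mat Neff = N;
  if (invitro && beta_L != 0.0) Neff = N + beta_L * (*L);
  const mat prolO = (1.0 / q.tau_o) * (Neff % Po % (1.0 - Tt));
  const mat prolG = (1.0 / q.tau_g) * (N % Pg % (1.0 - Tt) % mm);
  const mat sw_og = (1.0 / q.tau_og) * (chiW % chiNs % Po);
  const mat sw_go = (1.0 / q.tau_go) * ((1.0 - chiW) % Pg);
  const mat deathO = (q.mu_o * (1.0 - chiN) + q.mu_Po) % Po;
  const mat deathG = (q.mu_g * (1.0 - chiN) + q.mu_Pg) % Pg;
  const mat dW = q.kappa_W * (N % Pg % W % W) / (q.a + q.b * WI) +
                 q.S_W * (Po + Pg) - q.mu_W * W;
  const mat dWI = q.kappa_WI * (W % W) % (Po + Pg) - q.mu_WI * WI;
  if (invitro) {
    const mat dL = D_feed_prod * q.nu_NG * (N % Pg) - feed_rate * ((*L) % Po) -
                   mu_L * (*L);
    *L += dt * dL;
  }
  // pointwise-implicit nutrient update (uptake + decay implicit)
  N = (N + dt * NS) / (1.0 + dt * (q.nu_NO * Po + q.nu_NG * Pg + q.mu_N));
  Po += dt * (prolO - sw_og + sw_go - deathO);
  Pg += dt * (prolG + sw_og - sw_go - deathG);
  Pd += dt * (deathO + deathG - q.mu_d * Pd);
  W += dt * dW;
  WI += dt * dWI;
  return Nb;
}

static std::string check_fields_2d(const mat* F[], const char* names[],
                                   int nf, double divergence_cap) {
  for (int i = 0; i < nf; ++i) {
    if (!F[i]->is_finite()) return std::string(names[i]);
    if (F[i]->max() > divergence_cap) return std::string(names[i]);
  }
  return "";
}

// [[Rcpp::export]]
List rd_run_2d(arma::mat Po, arma::mat Pg, arma::mat Pd, arma::mat W, arma::mat WI, arma::mat N,
               List pars, List ops, int nsteps, double dt,
               double cell_vol, double V, double t0,
               int diag_every, double conv_tol, double Nb_override,
               bool invitro, List invitro_pars) {
  Pars q = Pars::from(pars);
  const mat AxO = ops["AxO"], AyO = ops["AyO"];
  const mat AxG = ops["AxG"], AyG = ops["AyG"];
  const mat AxD = ops["AxD"], AyD = ops["AyD"];
  const mat AxW = ops["AxW"], AyW = ops["AyW"];
  const mat AxI = ops["AxI"], AyI = ops["AyI"];
  const mat AxN = ops["AxN"], AyN = ops["AyN"];
  mat AxL, AyL, L;
  double c_prod = 0, c_feed = 0, mu_L = 0, beta_L = 0, gel_N = 1;
  if (invitro) {
    AxL = as<mat>(ops["AxL"]); AyL = as<mat>(ops["AyL"]);
    L = as<mat>(invitro_pars["L"]);
    c_prod = invitro_pars["c_prod"]; c_feed = invitro_pars["c_feed"];
    mu_L = invitro_pars["mu_L"]; beta_L = invitro_pars["beta_L"];
    gel_N = invitro_pars["gel_N"];
  }
  double clipped = 0.0;
  bool converged = false;
  std::string bad = "";
  std::vector<double> d_time, d_po, d_pg, d_pd, d_mn, d_rel;
  mat pPo = Po, pPg = Pg, pPd = Pd, pW = W, pWI = WI, pN = N;
  double t_prev = t0;
  int step = 0;
  for (step = 1; step <= nsteps; ++step) {
    double Nb = react_2d(Po, Pg, Pd, W, WI, N, q, dt, cell_vol, V,
                         Nb_override, invitro, &L, c_prod, c_feed,
                         mu_L, beta_L, gel_N);
    set_frame(N, Nb);
    Po = AxO * Po * AyO.t();
    Pg = AxG * Pg * AyG.t();
    Pd = AxD * Pd * AyD.t();
    W = AxW * W * AyW.t();
    WI = AxI * WI * AyI.t();
    N = AxN * N * AyN.t();
    if (invitro) L = AxL * L * AyL.t();
    set_frame(N, Nb);
    clipped += clip_neg(Po) + clip_neg(Pg) + clip_neg(Pd) +
               clip_neg(W) + clip_neg(WI) + clip_neg(N);
    if (invitro) clipped += clip_neg(L);
    const mat* FF[6] = { &Po, &Pg, &Pd, &W, &WI, &N };
    const char* nm[6] = { "P_o", "P_g", "P_d", "W", "W_I", "N" };
    if (step % diag_every == 0 || step == nsteps) {
      bad = check_fields_2d(FF, nm, 6, 1e6);
      if (!bad.empty()) break;
      double t = t0 + step * dt;
      double dt_el = t - t_prev;
      double rel = 0.0;
      if (dt_el > 0) {
        const mat* PP[6] = { &pPo, &pPg, &pPd, &pW, &pWI, &pN };
        for (int i = 0; i < 6; ++i) {
          double sc = PP[i]->max(); if (sc < 1e-8) sc = 1e-8;
          double ch = arma::abs(*FF[i] - *PP[i]).max() / (dt_el * sc);
          if (ch > rel) rel = ch;
        }
      }
      d_time.push_back(t);
      d_po.push_back(arma::accu(Po) * cell_vol);
      d_pg.push_back(arma::accu(Pg) * cell_vol);
      d_pd.push_back(arma::accu(Pd) * cell_vol);
      d_mn.push_back(arma::mean(arma::mean(N)));
      d_rel.push_back(rel);
      pPo = Po; pPg = Pg; pPd = Pd; pW = W; pWI = WI; pN = N;
      t_prev = t;
      if (conv_tol > 0 && step > diag_every && rel < conv_tol) {
        converged = true;
        break;
      }
    }
  }
  if (step > nsteps) step = nsteps;
  List out = List::create(
    _["P_o"] = Po, _["P_g"] = Pg, _["P_d"] = Pd, _["W"] = W,
    _["W_I"] = WI, _["N"] = N, _["steps"] = step,
    _["time"] = t0 + step * dt, _["converged"] = converged,
    _["diverged_field"] = bad, _["clipped_mass"] = clipped * cell_vol,
    _["diag"] = DataFrame::create(
      _["time"] = d_time, _["total_P_o"] = d_po, _["total_P_g"] = d_pg,
      _["total_P_d"] = d_pd, _["mean_N"] = d_mn, _["max_rel_change"] = d_rel));
  if (invitro) out["L"] = L;
  return out;
}

// [[Rcpp::export]]
List rd_run_3d(arma::cube Po, arma::cube Pg, arma::cube Pd, arma::cube W, arma::cube WI, arma::cube N,
               List pars, List ops, int nsteps, double dt,
               double cell_vol, double V, double t0,
               int diag_every, double conv_tol, double Nb_override) {
  Pars q = Pars::from(pars);
  const mat AxO = ops["AxO"], AyO = ops["AyO"], AzO = ops["AzO"];
  const mat AxG = ops["AxG"], AyG = ops["AyG"], AzG = ops["AzG"];
  const mat AxD = ops["AxD"], AyD = ops["AyD"], AzD = ops["AzD"];
  const mat AxW = ops["AxW"], AyW = ops["AyW"], AzW = ops["AzW"];
  const mat AxI = ops["AxI"], AyI = ops["AyI"], AzI = ops["AzI"];
  const mat AxN = ops["AxN"], AyN = ops["AyN"], AzN = ops["AzN"];
  double clipped = 0.0;
  bool converged = false;
  std::string bad = "";
  std::vector<double> d_time, d_po, d_pg, d_pd, d_mn, d_rel;
  cube pPg = Pg;
  double t_prev = t0;
  int step = 0;
  for (step = 1; step <= nsteps; ++step) {
    const double ipg = arma::accu(Pg) * cell_vol;
    const double itot = ipg + (arma::accu(Po) + arma::accu(Pd)) * cell_vol;
    double denom = itot > q.live_floor * V ? itot : q.live_floor * V;
    double frac = ipg / denom; if (frac > 1.0) frac = 1.0;
    const double NS = q.N_s * ((1.0 - q.alpha_N) * frac + q.alpha_N);
    const double Nb = (Nb_override >= 0.0) ? Nb_override : NS / q.N_s;
    const cube chiW = 0.5 * (1.0 + arma::tanh(q.gamma_W * (W - q.W_star)));
    const cube chiN = 0.5 * (1.0 + arma::tanh(q.gamma_N * (N - q.N_star)));
    const cube chiNs = 0.5 * (1.0 + arma::tanh(q.gamma_N * (N - q.N_g_star)));
    const cube Tt = Po + Pg + Pd;
    const cube mm = W / (q.alpha_W + W);
    const cube prolO = (1.0 / q.tau_o) * (N % Po % (1.0 - Tt));
    const cube prolG = (1.0 / q.tau_g) * (N % Pg % (1.0 - Tt) % mm);
    const cube sw_og = (1.0 / q.tau_og) * (chiW % chiNs % Po);
    const cube sw_go = (1.0 / q.tau_go) * ((1.0 - chiW) % Pg);
    const cube deathO = (q.mu_o * (1.0 - chiN) + q.mu_Po) % Po;
    const cube deathG = (q.mu_g * (1.0 - chiN) + q.mu_Pg) % Pg;
    const cube dW = q.kappa_W * (N % Pg % W % W) / (q.a + q.b * WI) +
                    q.S_W * (Po + Pg) - q.mu_W * W;
    const cube dWI = q.kappa_WI * (W % W) % (Po + Pg) - q.mu_WI * WI;
    N = (N + dt * NS) / (1.0 + dt * (q.nu_NO * Po + q.nu_NG * Pg + q.mu_N));
    Po += dt * (prolO - sw_og + sw_go - deathO);
    Pg += dt * (prolG + sw_og - sw_go - deathG);
    Pd += dt * (deathO + deathG - q.mu_d * Pd);
    W += dt * dW;
    WI += dt * dWI;
    set_faces(N, Nb);
    diffuse3(Po, AxO, AyO, AzO);
    diffuse3(Pg, AxG, AyG, AzG);
    diffuse3(Pd, AxD, AyD, AzD);
    diffuse3(W, AxW, AyW, AzW);
    diffuse3(WI, AxI, AyI, AzI);
    diffuse3(N, AxN, AyN, AzN);
    set_faces(N, Nb);
    clipped += clip_neg3(Po) + clip_neg3(Pg) + clip_neg3(Pd) +
               clip_neg3(W) + clip_neg3(WI) + clip_neg3(N);
    if (step % diag_every == 0 || step == nsteps) {
      const cube* FF[6] = { &Po, &Pg, &Pd, &W, &WI, &N };
      const char* nm[6] = { "P_o", "P_g", "P_d", "W", "W_I", "N" };
      for (int i = 0; i < 6; ++i) {
        if (!FF[i]->is_finite() || FF[i]->max() > 1e6) { bad = nm[i]; break; }
      }
      if (!bad.empty()) break;
      double t = t0 + step * dt;
      double dt_el = t - t_prev;
      double rel = 0.0;
      if (dt_el > 0) {
        double sc = pPg.max(); if (sc < 1e-8) sc = 1e-8;
        rel = arma::abs(Pg - pPg).max() / (dt_el * sc);
      }
      d_time.push_back(t);
      d_po.push_back(arma::accu(Po) * cell_vol);
      d_pg.push_back(arma::accu(Pg) * cell_vol);
      d_pd.push_back(arma::accu(Pd) * cell_vol);
      d_mn.push_back(arma::accu(N) / N.n_elem);
      d_rel.push_back(rel);
      pPg = Pg;
      t_prev = t;
      if (conv_tol > 0 && step > diag_every && rel < conv_tol) {
        converged = true;
        break;
      }
    }
  }
  if (step > nsteps) step = nsteps;
  return List::create(
    _["P_o"] = Po, _["P_g"] = Pg, _["P_d"] = Pd, _["W"] = W,
    _["W_I"] = WI, _["N"] = N, _["steps"] = step,
    _["time"] = t0 + step * dt, _["converged"] = converged,
    _["diverged_field"] = bad, _["clipped_mass"] = clipped * cell_vol,
    _["diag"] = DataFrame::create(
      _["time"] = d_time, _["total_P_o"] = d_po, _["total_P_g"] = d_pg,
      _["total_P_d"] = d_pd, _["mean_N"] = d_mn, _["max_rel_change"] = d_rel));
}
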
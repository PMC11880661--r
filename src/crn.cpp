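// Joint log posterior, analytic gradients and NUTS sampler for the five
// covariance-reaction-norm model structures:
//   1 "hybrid"     repeated Gaussian trait 1 + single Poisson trait 2
//   2 "nonrep_gp"  single Gaussian trait 1 + single Poisson trait 2
//   3 "nonrep_og"  single ordinal trait 1 + single Gaussian trait 2
//   4 "nonrep_gg"  single Gaussian traits (fully marginalised bivariate)
//   5 "full_gg"    repeated, paired Gaussian traits with among- and
//                  within-individual correlation reaction norms
//
// Parameter vector layout (unconstrained scale), in order:
//   b1 (P1) | b2 (P2) | br (P3) | bre (P3, variant 5 only) |
//   log-SDs | cutpoints (variant 3: c1, log-gaps) |
//   d1raw (n_year) | d2raw (n_year) | u1 (M) | u2 (M)
// Latent effects are non-centred: raw N(0,1) vectors scaled by the SDs and
// rotated by the context correlation.  Gradients are exact; every branch is
// checked against numerical differentiation in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::vec;
using arma::mat;
using arma::uvec;

// Gauss-Hermite nodes/weights (physicists' convention) via Golub-Welsch
struct GaussHermite {
  vec x, w;
  explicit GaussHermite(int n) {
    mat J(n, n, arma::fill::zeros);
    for (int i = 1; i < n; ++i) {
      J(i, i - 1) = J(i - 1, i) = std::sqrt(i / 2.0);
    }
    vec eval; mat evec;
    arma::eig_sym(eval, evec, J);
    x = eval;
    w = arma::square(evec.row(0).t()) * std::sqrt(M_PI);
  }
};

struct Layout {
  int P1 = 0, P2 = 0, P3 = 0, K = 0;
  int n_year = 0;
  bool has_d1 = false, has_d2 = false;
  int M = 0;          // latent pair count (v1, v5) or observation count (v2, v3)
  int nu1 = 0, nu2 = 0;
  int n_sd = 0;
  // offsets
  int b1 = 0, b2 = 0, br = 0, bre = -1, sd0 = 0, cut = -1,
      d1 = -1, d2 = -1, u1 = -1, u2 = -1, npar = 0;
};

struct CRN {
  int variant = 0;
  bool prior_only = false, trunc2 = false;
  mat X1, X2, X3;
  vec y1, y2;
  uvec pair1;   // v1, v5: trait-1 obs -> latent pair (0-based)
  uvec ctx;     // latent pair (v1, v5) or obs (v2..v4) -> context row of X3
  uvec yr1;     // trait-1 obs -> year group (if has_d1)
  uvec yr2;     // trait-2 obs -> year group (if has_d2)
  double coef_loc = 0.0, coef_scale = 1.0, sd_rate = 2.0, thr_scale = 2.0;
  vec ghx, ghw;   // Gauss-Hermite rule for the record-selection integral
  uvec trunc_grp; // groups of identical trait-2 predictor rows
  int n_trunc_grp = 0;
  Layout L;
};

static Layout make_layout(int variant, int P1, int P2, int P3, int K,
                          int n_year, bool has_d1, bool has_d2, int M) {
  Layout L;
  L.P1 = P1; L.P2 = P2; L.P3 = P3; L.K = K;
  L.n_year = n_year; L.has_d1 = has_d1; L.has_d2 = has_d2; L.M = M;
  switch (variant) {
    case 1: L.n_sd = 3; L.nu1 = M; L.nu2 = M; break;
    case 2: L.n_sd = 2; L.nu1 = 0; L.nu2 = M; break;
    case 3: L.n_sd = 2; L.nu1 = M; L.nu2 = 0; break;
    case 4: L.n_sd = 2; L.nu1 = 0; L.nu2 = 0; break;
    case 5: L.n_sd = 4; L.nu1 = M; L.nu2 = M; break;
    default: stop("unknown variant id");
  }
  if (variant != 5) L.n_sd += (has_d1 ? 1 : 0) + (has_d2 ? 1 : 0);
  int pos = 0;
  L.b1 = pos; pos += P1;
  L.b2 = pos; pos += P2;
  L.br = pos; pos += P3;
  if (variant == 5) { L.bre = pos; pos += P3; }
  L.sd0 = pos; pos += L.n_sd;
  if (variant == 3) { L.cut = pos; pos += (K - 1); }
  if (has_d1) { L.d1 = pos; pos += n_year; }
  if (has_d2) { L.d2 = pos; pos += n_year; }
  if (L.nu1 > 0) { L.u1 = pos; pos += L.nu1; }
  if (L.nu2 > 0) { L.u2 = pos; pos += L.nu2; }
  L.npar = pos;
  return L;
}

static CRN parse_data(const List& d) {
  CRN m;
  m.variant    = as<int>(d["variant"]);
  m.prior_only = as<bool>(d["prior_only"]);
  m.trunc2     = as<bool>(d["trunc2"]);
  m.X1 = as<mat>(d["X1"]); m.X2 = as<mat>(d["X2"]); m.X3 = as<mat>(d["X3"]);
  m.y1 = as<vec>(d["y1"]); m.y2 = as<vec>(d["y2"]);
  m.pair1 = as<uvec>(d["pair1"]);
  m.ctx   = as<uvec>(d["ctx"]);
  m.yr1   = as<uvec>(d["yr1"]);
  m.yr2   = as<uvec>(d["yr2"]);
  m.coef_loc   = as<double>(d["coef_location"]);
  m.coef_scale = as<double>(d["coef_scale"]);
  m.sd_rate    = as<double>(d["sd_rate"]);
  m.thr_scale  = as<double>(d["thr_scale"]);
  m.L = make_layout(m.variant, m.X1.n_cols, m.X2.n_cols, m.X3.n_cols,
                    as<int>(d["K"]), as<int>(d["n_year"]),
                    as<bool>(d["has_d1"]), as<bool>(d["has_d2"]),
                    as<int>(d["M"]));
  if (m.trunc2) {
    GaussHermite gh(24);
    m.ghx = gh.x; m.ghw = gh.w;
    m.trunc_grp = as<uvec>(d["trunc_grp"]);
    m.n_trunc_grp = as<int>(d["n_trunc_grp"]);
  }
  return m;
}

// plain Poisson log-likelihood and score wrt eta, vectorised
static double poisson_block(const vec& y, const vec& eta, vec& score) {
  double lp = 0.0;
  const int n = y.n_elem;
  score.set_size(n);
  for (int i = 0; i < n; ++i) {
    const double lam = std::exp(eta[i]);
    lp += y[i] * eta[i] - lam - std::lgamma(y[i] + 1.0);
    score[i] = y[i] - lam;
  }
  return lp;
}

// Correction for count records that exist only when y >= 1, with the
// selection acting through a N(0, sigma^2) latent in the log rate:
//   Pr(record) = D(mu) = 1 - E_z[exp(-exp(mu + z))],  z ~ N(0, sigma^2).
// Subtracts sum(log D) from lp and accumulates the scores wrt mu (into
// score_fix) and wrt log(sigma) (returned).  The latent's own score is
// untouched because D is a marginal quantity.
static double trunc_record_adjust(const vec& mu_fix, double sigma,
                                  const vec& ghx, const vec& ghw,
                                  const uvec& grp, int n_grp, double& lp,
                                  vec& score_fix) {
  // observations sharing a predictor row (grp) share the integral
  const double s2 = std::sqrt(2.0) * sigma;
  const int n = mu_fix.n_elem, K = ghx.n_elem;
  score_fix.set_size(n);
  double dlogsig = 0.0;
  const double isqpi = 1.0 / std::sqrt(M_PI);
  vec logD(n_grp), sc(n_grp), dls(n_grp);
  vec done(n_grp, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const int g0 = grp[i];
    if (!done[g0]) {
      double S = 0.0, E = 0.0, F = 0.0;
      for (int k = 0; k < K; ++k) {
        const double g = mu_fix[i] + s2 * ghx[k];
        const double lam = std::exp(g);
        const double e = std::exp(-lam);
        S += ghw[k] * e;
        const double de = e * lam;        // -d exp(-lam) / d g
        E += ghw[k] * de;
        F += ghw[k] * de * s2 * ghx[k];
      }
      double D = 1.0 - isqpi * S;
      if (D < 1e-300) D = 1e-300;
      logD[g0] = std::log(D);
      sc[g0] = -isqpi * E / D;
      dls[g0] = -isqpi * F / D;
      done[g0] = 1;
    }
    lp -= logD[g0];
    score_fix[i] = sc[g0];
    dlogsig += dls[g0];
  }
  return dlogsig;
}

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double log_sigmoid(double x) {
  return (x > 0) ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
}

// cumulative-logit block: y in 0..K-1, thresholds theta (K-1).
// Returns log-lik; fills score (d lp / d eta) and adds to dtheta.
static double ordinal_block(const vec& y, const vec& eta, const vec& theta,
                            vec& score, vec& dtheta) {
  double lp = 0.0;
  const int n = y.n_elem, K = theta.n_elem + 1;
  score.set_size(n);
  for (int i = 0; i < n; ++i) {
    const int k = (int) y[i];
    if (k == 0) {
      const double x = theta[0] - eta[i];
      lp += log_sigmoid(x);
      const double F = sigmoid(x);
      score[i] = -(1.0 - F);
      dtheta[0] += (1.0 - F);
    } else if (k == K - 1) {
      const double x = theta[K - 2] - eta[i];
      lp += log_sigmoid(-x);
      const double F = sigmoid(x);
      score[i] = F;
      dtheta[K - 2] -= F;
    } else {
      const double Fh = sigmoid(theta[k] - eta[i]);
      const double Fl = sigmoid(theta[k - 1] - eta[i]);
      double P = Fh - Fl;
      if (P < 1e-300) P = 1e-300;
      lp += std::log(P);
      const double dh = Fh * (1.0 - Fh), dl = Fl * (1.0 - Fl);
      score[i] = (dl - dh) / P;
      dtheta[k]     += dh / P;
      dtheta[k - 1] -= dl / P;
    }
  }
  return lp;
}

// bivariate Gaussian residual block on standardised scores z1, z2 with
// per-observation correlation rho (and q = 1 - rho^2).  Adds scores:
//   w1 = dlp/d z1 * (-1) etc. are returned so callers chain to mu and sigma.
static double bvn_block(const vec& z1, const vec& z2, const vec& rho,
                        vec& w1, vec& w2, vec& heta) {
  const int n = z1.n_elem;
  double lp = 0.0;
  w1.set_size(n); w2.set_size(n); heta.set_size(n);
  for (int i = 0; i < n; ++i) {
    const double p = rho[i], q = 1.0 - p * p;
    const double a = z1[i], b = z2[i];
    const double A = a * a - 2.0 * p * a * b + b * b;
    lp += -0.5 * std::log(q) - 0.5 * A / q;
    w1[i] = (a - p * b) / q;
    w2[i] = (b - p * a) / q;
    heta[i] = p + a * b - p * A / q;   // d lp / d atanh(rho)
  }
  return lp;
}

// The joint log posterior (unnormalised) and its gradient.
static double lp_grad(const CRN& m, const vec& q, vec& grad) {
  const Layout& L = m.L;
  grad.zeros(L.npar);
  double lp = 0.0;

  // --- priors on regression coefficients
  const double cs2 = m.coef_scale * m.coef_scale;
  auto coef_prior = [&](int off, int len) {
    for (int i = 0; i < len; ++i) {
      const double d = q[off + i] - m.coef_loc;
      lp -= 0.5 * d * d / cs2;
      grad[off + i] -= d / cs2;
    }
  };
  coef_prior(L.b1, L.P1);
  coef_prior(L.b2, L.P2);
  coef_prior(L.br, L.P3);
  if (L.bre >= 0) coef_prior(L.bre, L.P3);

  // --- SD parameters: sigma = exp(t), sigma ~ Exponential(rate); + Jacobian
  vec sig(L.n_sd);
  for (int i = 0; i < L.n_sd; ++i) {
    const double t = q[L.sd0 + i];
    sig[i] = std::exp(t);
    lp += t - m.sd_rate * sig[i];
    grad[L.sd0 + i] += 1.0 - m.sd_rate * sig[i];
  }

  // --- ordinal cutpoints: theta_1 = c1, theta_k = theta_{k-1} + exp(g_k)
  vec theta, dtheta;
  if (L.cut >= 0) {
    theta.set_size(L.K - 1);
    dtheta.zeros(L.K - 1);
    theta[0] = q[L.cut];
    for (int k = 1; k < L.K - 1; ++k) {
      const double g = q[L.cut + k];
      theta[k] = theta[k - 1] + std::exp(g);
      lp += g;                                  // Jacobian of the transform
      grad[L.cut + k] += 1.0;
    }
    const double ts2 = m.thr_scale * m.thr_scale;
    for (int k = 0; k < L.K - 1; ++k) {
      lp -= 0.5 * theta[k] * theta[k] / ts2;
      dtheta[k] -= theta[k] / ts2;
    }
  }

  // --- standard-normal priors on raw year effects and latents
  auto std_prior = [&](int off, int len) {
    for (int i = 0; i < len; ++i) {
      lp -= 0.5 * q[off + i] * q[off + i];
      grad[off + i] -= q[off + i];
    }
  };
  if (L.has_d1) std_prior(L.d1, L.n_year);
  if (L.has_d2) std_prior(L.d2, L.n_year);
  if (L.nu1 > 0) std_prior(L.u1, L.nu1);
  if (L.nu2 > 0) std_prior(L.u2, L.nu2);

  if (m.prior_only) {
    if (L.cut >= 0) {  // close out cutpoint gradient chain
      double acc = 0.0;
      for (int k = L.K - 2; k >= 1; --k) {
        acc += dtheta[k];
        grad[L.cut + k] += acc * std::exp(q[L.cut + k]);
      }
      grad[L.cut] += acc + dtheta[0];
    }
    return lp;
  }

  // --- context correlations
  const vec b1v = q.subvec(L.b1, L.b1 + L.P1 - 1);
  const vec b2v = q.subvec(L.b2, L.b2 + L.P2 - 1);
  const vec brv = q.subvec(L.br, L.br + L.P3 - 1);
  const vec eta_r = m.X3 * brv;
  const vec r = arma::tanh(eta_r);
  const vec s = arma::sqrt(1.0 - r % r);
  const int C = m.X3.n_rows;

  // SD aliases per variant (order fixed in make_layout)
  // v1: sa1 so2 se1 [sd1] [sd2];  v2/3/4: so1 so2 [sd1] [sd2];
  // v5: sa1 sa2 se1 se2
  int base = (m.variant == 1) ? 3 : 2;
  const int i_sd1 = (L.has_d1 && m.variant != 5) ? base : -1;
  const int i_sd2 = (L.has_d2 && m.variant != 5) ? base + (L.has_d1 ? 1 : 0) : -1;

  vec d1v, d2v;
  if (L.has_d1) d1v = sig[i_sd1] * q.subvec(L.d1, L.d1 + L.n_year - 1);
  if (L.has_d2) d2v = sig[i_sd2] * q.subvec(L.d2, L.d2 + L.n_year - 1);

  // helper: accumulate group sums into gradient for year effects
  auto delta_grad = [&](int off, int i_sd, const vec& dv, const uvec& yr,
                        const vec& score) {
    vec S(L.n_year, arma::fill::zeros);
    for (arma::uword j = 0; j < yr.n_elem; ++j) S[yr[j]] += score[j];
    for (int c = 0; c < L.n_year; ++c) grad[off + c] += S[c] * sig[i_sd];
    grad[L.sd0 + i_sd] += arma::dot(S, dv);
  };

  if (m.variant == 1) {
    // ---- hybrid: repeated Gaussian + Poisson -------------------------------
    const double sa1 = sig[0], so2 = sig[1], se1 = sig[2];
    const int N1 = m.y1.n_elem, M = L.M;
    const vec u1 = q.subvec(L.u1, L.u1 + M - 1);
    const vec u2 = q.subvec(L.u2, L.u2 + M - 1);
    const vec rc = r(m.ctx), sc = s(m.ctx);
    const vec alpha = sa1 * u1;
    const vec o2 = so2 * (rc % u1 + sc % u2);

    vec mu1 = m.X1 * b1v + alpha(m.pair1);
    if (L.has_d1) mu1 += d1v(m.yr1);
    const vec res = m.y1 - mu1;
    lp += -N1 * std::log(se1) - 0.5 * arma::dot(res, res) / (se1 * se1);
    const vec e = res / (se1 * se1);
    grad.subvec(L.b1, L.b1 + L.P1 - 1) += m.X1.t() * e;
    grad[L.sd0 + 2] += arma::dot(res, res) / (se1 * se1) - N1;
    if (L.has_d1) delta_grad(L.d1, i_sd1, d1v, m.yr1, e);

    vec A(M, arma::fill::zeros);
    for (int j = 0; j < N1; ++j) A[m.pair1[j]] += e[j];

    vec mu2fix = m.X2 * b2v;
    if (L.has_d2) mu2fix += d2v(m.yr2);
    vec eta2 = mu2fix + o2;
    vec g2;
    lp += poisson_block(m.y2, eta2, g2);
    vec g2tot = g2;
    if (m.trunc2) {
      vec sfx;
      grad[L.sd0 + 1] += trunc_record_adjust(mu2fix, so2, m.ghx, m.ghw,
                                             m.trunc_grp, m.n_trunc_grp,
                                             lp, sfx);
      g2tot += sfx;
    }
    grad.subvec(L.b2, L.b2 + L.P2 - 1) += m.X2.t() * g2tot;
    if (L.has_d2) delta_grad(L.d2, i_sd2, d2v, m.yr2, g2tot);

    grad.subvec(L.u1, L.u1 + M - 1) += A * sa1 + g2 % (so2 * rc);
    grad.subvec(L.u2, L.u2 + M - 1) += g2 % (so2 * sc);
    grad[L.sd0 + 0] += sa1 * arma::dot(A, u1);
    grad[L.sd0 + 1] += arma::dot(g2, o2);

    vec T(C, arma::fill::zeros);
    for (int mth = 0; mth < M; ++mth) {
      const int c = m.ctx[mth];
      T[c] += g2[mth] * so2 * s[c] * (s[c] * u1[mth] - r[c] * u2[mth]);
    }
    grad.subvec(L.br, L.br + L.P3 - 1) += m.X3.t() * T;

  } else if (m.variant == 2 || m.variant == 3) {
    // ---- non-repeated with one marginalised Gaussian trait -----------------
    // v2: Gaussian trait 1 observed/marginalised, Poisson trait 2 latent.
    // v3: Gaussian trait 2 observed/marginalised, ordinal trait 1 latent.
    const bool gp = (m.variant == 2);
    const double s_g = gp ? sig[0] : sig[1];   // SD of the marginalised trait
    const double s_l = gp ? sig[1] : sig[0];   // SD of the latent trait
    const int i_sg = gp ? 0 : 1, i_sl = gp ? 1 : 0;
    const vec& yg = gp ? m.y1 : m.y2;          // Gaussian responses
    const int N = yg.n_elem;
    const vec rc = r(m.ctx), sc = s(m.ctx);

    vec mug = (gp ? m.X1 * b1v : m.X2 * b2v);
    if (gp && L.has_d1) mug += d1v(m.yr1);
    if (!gp && L.has_d2) mug += d2v(m.yr2);
    const vec og = yg - mug;
    const vec v = og / s_g;
    lp += -N * std::log(s_g) - 0.5 * arma::dot(v, v);

    const int iu = gp ? L.u2 : L.u1;
    const vec u = q.subvec(iu, iu + N - 1);
    const vec ol = s_l * (rc % v + sc % u);
    vec mulfix = (gp ? m.X2 * b2v : m.X1 * b1v);
    if (gp && L.has_d2) mulfix += d2v(m.yr2);
    if (!gp && L.has_d1) mulfix += d1v(m.yr1);
    const vec etal = mulfix + ol;

    vec gl;
    if (gp) {
      lp += poisson_block(m.y2, etal, gl);
    } else {
      lp += ordinal_block(m.y1, etal, theta, gl, dtheta);
    }
    vec gltot = gl;
    if (gp && m.trunc2) {
      vec sfx;
      grad[L.sd0 + i_sl] += trunc_record_adjust(mulfix, s_l, m.ghx, m.ghw,
                                                m.trunc_grp, m.n_trunc_grp,
                                                lp, sfx);
      gltot += sfx;
    }

    // gradient wrt the latent-trait linear predictor covariates
    if (gp) {
      grad.subvec(L.b2, L.b2 + L.P2 - 1) += m.X2.t() * gltot;
      if (L.has_d2) delta_grad(L.d2, i_sd2, d2v, m.yr2, gltot);
    } else {
      grad.subvec(L.b1, L.b1 + L.P1 - 1) += m.X1.t() * gltot;
      if (L.has_d1) delta_grad(L.d1, i_sd1, d1v, m.yr1, gltot);
    }
    // gradient wrt the Gaussian-trait mean: e - gl * k, k = (s_l/s_g) r
    const vec e = v / s_g;
    const vec k = (s_l / s_g) * rc;
    const vec emix = e - gl % k;
    if (gp) {
      grad.subvec(L.b1, L.b1 + L.P1 - 1) += m.X1.t() * emix;
      if (L.has_d1) delta_grad(L.d1, i_sd1, d1v, m.yr1, emix);
    } else {
      grad.subvec(L.b2, L.b2 + L.P2 - 1) += m.X2.t() * emix;
      if (L.has_d2) delta_grad(L.d2, i_sd2, d2v, m.yr2, emix);
    }
    grad.subvec(iu, iu + N - 1) += gl % (s_l * sc);
    grad[L.sd0 + i_sg] += arma::dot(v, v) - N - s_l * arma::dot(gl, rc % v);
    grad[L.sd0 + i_sl] += arma::dot(gl, ol);

    vec T(C, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      const int c = m.ctx[n];
      T[c] += gl[n] * s_l * s[c] * (s[c] * v[n] - r[c] * u[n]);
    }
    grad.subvec(L.br, L.br + L.P3 - 1) += m.X3.t() * T;

  } else if (m.variant == 4) {
    // ---- non-repeated Gaussian pair: fully marginalised --------------------
    const double s1 = sig[0], s2 = sig[1];
    const int N = m.y1.n_elem;
    vec mu1 = m.X1 * b1v, mu2 = m.X2 * b2v;
    if (L.has_d1) mu1 += d1v(m.yr1);
    if (L.has_d2) mu2 += d2v(m.yr2);
    const vec z1 = (m.y1 - mu1) / s1, z2 = (m.y2 - mu2) / s2;
    const vec rho = r(m.ctx);
    vec w1, w2, heta;
    lp += bvn_block(z1, z2, rho, w1, w2, heta);
    lp += -N * std::log(s1) - N * std::log(s2);
    grad.subvec(L.b1, L.b1 + L.P1 - 1) += m.X1.t() * (w1 / s1);
    grad.subvec(L.b2, L.b2 + L.P2 - 1) += m.X2.t() * (w2 / s2);
    if (L.has_d1) { vec sc1 = w1 / s1; delta_grad(L.d1, i_sd1, d1v, m.yr1, sc1); }
    if (L.has_d2) { vec sc2 = w2 / s2; delta_grad(L.d2, i_sd2, d2v, m.yr2, sc2); }
    grad[L.sd0 + 0] += arma::dot(w1, z1) - N;
    grad[L.sd0 + 1] += arma::dot(w2, z2) - N;
    vec T(C, arma::fill::zeros);
    for (int n = 0; n < N; ++n) T[m.ctx[n]] += heta[n];
    grad.subvec(L.br, L.br + L.P3 - 1) += m.X3.t() * T;

  } else if (m.variant == 5) {
    // ---- full repeated-measures Gaussian pair ------------------------------
    const double sa1 = sig[0], sa2 = sig[1], se1 = sig[2], se2 = sig[3];
    const int N = m.y1.n_elem, M = L.M;
    const vec u1 = q.subvec(L.u1, L.u1 + M - 1);
    const vec u2 = q.subvec(L.u2, L.u2 + M - 1);
    const vec ra = r(m.ctx), sa = s(m.ctx);     // among-individual correlation
    const vec brev = q.subvec(L.bre, L.bre + L.P3 - 1);
    const vec re_all = arma::tanh(m.X3 * brev); // within-individual correlation
    const vec alpha1 = sa1 * u1;
    const vec alpha2 = sa2 * (ra % u1 + sa % u2);

    const vec mu1 = m.X1 * b1v + alpha1(m.pair1);
    const vec mu2 = m.X2 * b2v + alpha2(m.pair1);
    const vec z1 = (m.y1 - mu1) / se1, z2 = (m.y2 - mu2) / se2;
    uvec cobs(N);
    for (int j = 0; j < N; ++j) cobs[j] = m.ctx[m.pair1[j]];
    const vec rho = re_all(cobs);
    vec w1, w2, heta;
    lp += bvn_block(z1, z2, rho, w1, w2, heta);
    lp += -N * std::log(se1) - N * std::log(se2);

    grad.subvec(L.b1, L.b1 + L.P1 - 1) += m.X1.t() * (w1 / se1);
    grad.subvec(L.b2, L.b2 + L.P2 - 1) += m.X2.t() * (w2 / se2);
    grad[L.sd0 + 2] += arma::dot(w1, z1) - N;
    grad[L.sd0 + 3] += arma::dot(w2, z2) - N;

    vec Te(C, arma::fill::zeros);
    for (int j = 0; j < N; ++j) Te[cobs[j]] += heta[j];
    grad.subvec(L.bre, L.bre + L.P3 - 1) += m.X3.t() * Te;

    vec B1(M, arma::fill::zeros), B2(M, arma::fill::zeros);
    for (int j = 0; j < N; ++j) {
      B1[m.pair1[j]] += w1[j] / se1;
      B2[m.pair1[j]] += w2[j] / se2;
    }
    grad.subvec(L.u1, L.u1 + M - 1) += B1 * sa1 + B2 % (sa2 * ra);
    grad.subvec(L.u2, L.u2 + M - 1) += B2 % (sa2 * sa);
    grad[L.sd0 + 0] += sa1 * arma::dot(B1, u1);
    grad[L.sd0 + 1] += arma::dot(B2, alpha2);
    vec Ta(C, arma::fill::zeros);
    for (int mm = 0; mm < M; ++mm) {
      const int c = m.ctx[mm];
      Ta[c] += B2[mm] * sa2 * s[c] * (s[c] * u1[mm] - r[c] * u2[mm]);
    }
    grad.subvec(L.br, L.br + L.P3 - 1) += m.X3.t() * Ta;
  }

  // close out the cutpoint gradient chain (likelihood + prior accumulated)
  if (L.cut >= 0) {
    double acc = 0.0;
    for (int k = L.K - 2; k >= 1; --k) {
      acc += dtheta[k];
      grad[L.cut + k] += acc * std::exp(q[L.cut + k]);
    }
    grad[L.cut] += acc + dtheta[0];
  }

  if (!std::isfinite(lp)) lp = -std::numeric_limits<double>::infinity();
  return lp;
}

// [[Rcpp::export]]
List cpp_layout(List data) {
  CRN m = parse_data(data);
  const Layout& L = m.L;
  return List::create(
    _["npar"] = L.npar, _["b1"] = L.b1, _["b2"] = L.b2, _["br"] = L.br,
    _["bre"] = L.bre, _["sd0"] = L.sd0, _["n_sd"] = L.n_sd, _["cut"] = L.cut,
    _["d1"] = L.d1, _["d2"] = L.d2, _["u1"] = L.u1, _["u2"] = L.u2,
    _["nu1"] = L.nu1, _["nu2"] = L.nu2);
}

// [[Rcpp::export]]
List cpp_lp_grad(List data, NumericVector q) {
  CRN m = parse_data(data);
  vec qv(q.begin(), q.size());
  if ((int) qv.n_elem != m.L.npar) stop("parameter vector has wrong length");
  vec g;
  const double lp = lp_grad(m, qv, g);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(g.begin(), g.end()));
}

// ---------------------------------------------------------------------------
// No-U-Turn sampler with dual-averaging step-size adaptation and windowed
// diagonal metric estimation (Stan-style warmup schedule).  Uses R's RNG so
// that set.seed() on the R side makes runs reproducible.
// ---------------------------------------------------------------------------

struct Tree {
  vec qm, pm, gm, qp, pp, gp, qprop;
  double lpm, lpp, lpprop;
  double n;      // slice-acceptable points in subtree
  bool s;        // no U-turn / no divergence
  double alpha;  // sum of acceptance probabilities
  int nalpha;
  bool divergent;
};

struct NutsCtx {
  const CRN* m;
  vec minv;        // inverse mass diagonal (posterior variance estimate)
  double logu, H0;
  int n_div;
};

static double hamiltonian(const NutsCtx& c, double lp, const vec& p) {
  return -lp + 0.5 * arma::dot(p, c.minv % p);
}

static void leapfrog(const NutsCtx& c, vec& q, vec& p, vec& g, double& lp,
                     double eps) {
  p += 0.5 * eps * g;
  q += eps * (c.minv % p);
  lp = lp_grad(*c.m, q, g);
  p += 0.5 * eps * g;
}

static bool no_uturn(const NutsCtx& c, const vec& qm, const vec& qp,
                     const vec& pm, const vec& pp) {
  const vec dq = qp - qm;
  return arma::dot(dq, c.minv % pm) >= 0 && arma::dot(dq, c.minv % pp) >= 0;
}

static Tree build_tree(NutsCtx& c, const vec& q, const vec& p, const vec& g,
                       double lp, int dir, int depth, double eps) {
  Tree t;
  if (depth == 0) {
    vec q1 = q, p1 = p, g1 = g;
    double lp1 = lp;
    leapfrog(c, q1, p1, g1, lp1, dir * eps);
    const double H = hamiltonian(c, lp1, p1);
    const double joint = -H;
    t.qm = q1; t.pm = p1; t.gm = g1; t.lpm = lp1;
    t.qp = q1; t.pp = p1; t.gp = g1; t.lpp = lp1;
    t.qprop = q1; t.lpprop = lp1;
    t.n = (c.logu <= joint) ? 1.0 : 0.0;
    t.divergent = (c.logu - 1000.0 > joint) || !std::isfinite(joint);
    t.s = !t.divergent;
    double a = std::exp(joint + c.H0);
    t.alpha = std::min(1.0, std::isfinite(a) ? a : 0.0);
    t.nalpha = 1;
    if (t.divergent) c.n_div++;
    return t;
  }
  Tree t1 = build_tree(c, q, p, g, lp, dir, depth - 1, eps);
  if (!t1.s) return t1;
  Tree t2 = (dir == 1)
    ? build_tree(c, t1.qp, t1.pp, t1.gp, t1.lpp, dir, depth - 1, eps)
    : build_tree(c, t1.qm, t1.pm, t1.gm, t1.lpm, dir, depth - 1, eps);
  if (dir == 1) {
    t.qm = t1.qm; t.pm = t1.pm; t.gm = t1.gm; t.lpm = t1.lpm;
    t.qp = t2.qp; t.pp = t2.pp; t.gp = t2.gp; t.lpp = t2.lpp;
  } else {
    t.qm = t2.qm; t.pm = t2.pm; t.gm = t2.gm; t.lpm = t2.lpm;
    t.qp = t1.qp; t.pp = t1.pp; t.gp = t1.gp; t.lpp = t1.lpp;
  }
  t.n = t1.n + t2.n;
  const double ntot = std::max(t.n, 1.0);
  if (unif_rand() < t2.n / ntot) { t.qprop = t2.qprop; t.lpprop = t2.lpprop; }
  else { t.qprop = t1.qprop; t.lpprop = t1.lpprop; }
  t.s = t2.s && no_uturn(c, t.qm, t.qp, t.pm, t.pp);
  t.divergent = t1.divergent || t2.divergent;
  t.alpha = t1.alpha + t2.alpha;
  t.nalpha = t1.nalpha + t2.nalpha;
  return t;
}

static double find_eps(NutsCtx& c, const vec& q0) {
  vec g0;
  double lp0 = lp_grad(*c.m, q0, g0);
  double eps = 0.1;
  vec p(q0.n_elem);
  for (arma::uword i = 0; i < p.n_elem; ++i)
    p[i] = norm_rand() / std::sqrt(c.minv[i]);
  const double H0 = hamiltonian(c, lp0, p);
  vec q = q0, pp = p, g = g0;
  double lp = lp0;
  leapfrog(c, q, pp, g, lp, eps);
  double H1 = hamiltonian(c, lp, pp);
  double dH = std::isfinite(H1) ? H0 - H1 : -1e9;
  const double dir = (dH > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    q = q0; pp = p; g = g0; lp = lp0;
    eps = std::pow(2.0, dir) * eps;
    leapfrog(c, q, pp, g, lp, eps);
    H1 = hamiltonian(c, lp, pp);
    dH = std::isfinite(H1) ? H0 - H1 : -1e9;
    if (dir > 0 && dH <= std::log(0.5)) break;
    if (dir < 0 && dH >= std::log(0.5)) break;
    if (eps < 1e-10 || eps > 1e7) break;
  }
  return eps;
}

// [[Rcpp::export]]
List cpp_nuts(List data, NumericVector q_init, int n_warmup, int n_iter,
              double adapt_delta, int max_treedepth, IntegerVector keep_idx) {
  CRN m = parse_data(data);
  const int D = m.L.npar;
  vec q(q_init.begin(), q_init.size());
  if ((int) q.n_elem != D) stop("init vector has wrong length");

  NutsCtx c;
  c.m = &m;
  c.minv = vec(D, arma::fill::ones);
  c.n_div = 0;

  vec g;
  double lp = lp_grad(m, q, g);
  if (!std::isfinite(lp))
    stop("log posterior is not finite at the initial values");

  // Stan-style warmup schedule
  int init_buf = 75, term_buf = 50, base_win = 25;
  bool adapt_metric = n_warmup >= 150;
  if (!adapt_metric) { init_buf = n_warmup; term_buf = 0; }
  std::vector<int> win_ends;
  if (adapt_metric) {
    int wstart = init_buf, wsize = base_win;
    while (wstart < n_warmup - term_buf) {
      int wend = wstart + wsize;
      if (wend + 2 * wsize > n_warmup - term_buf) wend = n_warmup - term_buf;
      win_ends.push_back(wend);
      wstart = wend;
      wsize *= 2;
    }
  }

  double eps = find_eps(c, q);
  double mu = std::log(10.0 * eps), log_eps_bar = 0.0, Hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // Welford accumulator for the metric
  vec wf_mean(D, arma::fill::zeros), wf_m2(D, arma::fill::zeros);
  int wf_n = 0;
  size_t win_i = 0;

  const int n_keep = keep_idx.size();
  mat draws(n_iter, n_keep);
  IntegerVector treedepth(n_iter);
  IntegerVector divergent(n_iter);
  NumericVector lp_out(n_iter);
  double accept_sum = 0.0;
  int n_div_sampling = 0;

  const int total = n_warmup + n_iter;
  for (int it = 0; it < total; ++it) {
    // momentum refresh
    vec p(D);
    for (int i = 0; i < D; ++i) p[i] = norm_rand() / std::sqrt(c.minv[i]);
    c.H0 = hamiltonian(c, lp, p);
    c.logu = std::log(unif_rand()) - c.H0;
    // NB: joint = -H; slice u in (0, exp(-H0)) => logu = log(unif) - H0

    vec qm = q, qp = q, pm = p, pp = p, gm = g, gp = g;
    double lpm = lp, lpp = lp;
    vec qprop = q;
    double lpprop = lp;
    double n_acc = 1.0;
    bool s = true;
    int depth = 0;
    double alpha = 0.0;
    int nalpha = 0;
    bool any_div = false;

    c.n_div = 0;
    while (s && depth < max_treedepth) {
      const int dir = (unif_rand() < 0.5) ? -1 : 1;
      Tree t = (dir == 1)
        ? build_tree(c, qp, pp, gp, lpp, dir, depth, eps)
        : build_tree(c, qm, pm, gm, lpm, dir, depth, eps);
      if (dir == 1) { qp = t.qp; pp = t.pp; gp = t.gp; lpp = t.lpp; }
      else { qm = t.qm; pm = t.pm; gm = t.gm; lpm = t.lpm; }
      alpha = t.alpha; nalpha = t.nalpha;
      any_div = any_div || t.divergent;
      if (t.s && unif_rand() < t.n / n_acc) { qprop = t.qprop; lpprop = t.lpprop; }
      n_acc += t.n;
      s = t.s && no_uturn(c, qm, qp, pm, pp);
      depth++;
    }
    q = qprop;
    lp = lpprop;
    lp = lp_grad(m, q, g);   // refresh gradient at accepted point

    const double a_stat = (nalpha > 0) ? alpha / nalpha : 0.0;

    if (it < n_warmup) {
      // dual averaging
      da_count++;
      const double w = 1.0 / (da_count + t0);
      Hbar = (1.0 - w) * Hbar + w * (adapt_delta - a_stat);
      const double log_eps = mu - std::sqrt((double) da_count) / gamma * Hbar;
      const double x = std::pow((double) da_count, -kappa);
      log_eps_bar = x * log_eps + (1.0 - x) * log_eps_bar;
      eps = std::exp(log_eps);

      if (adapt_metric && it >= init_buf && win_i < win_ends.size()) {
        wf_n++;
        const vec d = q - wf_mean;
        wf_mean += d / wf_n;
        wf_m2 += d % (q - wf_mean);
        if (it + 1 == win_ends[win_i]) {
          if (wf_n > 2) {
            vec v = wf_m2 / (wf_n - 1);
            c.minv = (double) wf_n / (wf_n + 5.0) * v
                     + 1e-3 * (5.0 / (wf_n + 5.0));
          }
          wf_mean.zeros(); wf_m2.zeros(); wf_n = 0;
          win_i++;
          eps = find_eps(c, q);
          mu = std::log(10.0 * eps);
          Hbar = 0.0; log_eps_bar = 0.0; da_count = 0;
        }
      }
      if (it == n_warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      const int k = it - n_warmup;
      for (int i = 0; i < n_keep; ++i) draws(k, i) = q[keep_idx[i]];
      treedepth[k] = depth;
      divergent[k] = any_div ? 1 : 0;
      lp_out[k] = lp;
      accept_sum += a_stat;
      if (any_div) n_div_sampling++;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["treedepth"] = treedepth,
    _["divergent"] = divergent,
    _["lp"] = lp_out,
    _["step_size"] = eps,
    _["accept_stat"] = accept_sum / std::max(n_iter, 1),
    _["n_divergent"] = n_div_sampling,
    _["inv_metric"] = NumericVector(c.minv.begin(), c.minv.end()));
}
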
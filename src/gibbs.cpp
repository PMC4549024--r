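#include <Rcpp.h>
using namespace Rcpp;

// Unified site-by-site Gibbs sampler for the additive-dominance marker
// model  y = 1*mu + W m_a + S m_d + e.
//
// Marker-effect priors (selected by `family`):
//   0 normal-homogeneous : m_j ~ N(0, s2m) with a common variance s2m
//                          carrying a scaled-inv-chi2(df2, S2) prior
//                          (df2 = -2 -> flat);
//   1 laplace            : m_j | t2_j ~ N(0, t2_j),
//                          t2_j ~ Exp(rate lambda^2/2), lambda^2 = 2/s2m,
//                          s2m carrying a scaled-inv-chi2(df2, S2) prior
//                          (conjugate inverse-gamma update);
//   2 student-t          : m_j | t2_j ~ N(0, t2_j),
//                          t2_j ~ scaled-inv-chi2(df2, S2), which makes
//                          the marginal prior of m_j a t with df2 df;
//   3 fixed-heterogeneous: t2_j fixed to supplied values (no update).
//
// The residual variance has a scaled-inv-chi2(df1, S2e) prior
// (df1 = -2 -> flat).  Scaled-inv-chi2(nu, S2) posterior draws are taken
// as (SS + nu*S2)/rchisq(n + nu); a flat prior contributes nothing to SS
// and -2 to the degrees of freedom.
//
// Per retained sample the genetic variances are accumulated from the
// effects through the coding constants: sigma2_a = sum_j 2 p q m_aj^2 and
// sigma2_d = sum_j (2 p q)^2 m_dj^2.

static const double VAR_FLOOR = 1e-12;

static double rinvgauss(double mu, double lambda) {
  // Michael, Schucany & Haas transformation
  double nu = norm_rand();
  double z2 = nu * nu;
  double x = mu + mu * mu * z2 / (2.0 * lambda)
    - mu / (2.0 * lambda)
      * std::sqrt(4.0 * mu * lambda * z2 + mu * mu * z2 * z2);
  if (x <= 0) x = VAR_FLOOR;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static double draw_scaled_invchisq(double ss, double df_prior,
                                   double scale_prior, double n_data) {
  double num = ss + (df_prior > 0 ? df_prior * scale_prior : 0.0);
  double dof = n_data + df_prior;
  double chi = ::Rf_rchisq(dof);
  if (chi < VAR_FLOOR) chi = VAR_FLOOR;
  double v = num / chi;
  return v > VAR_FLOOR ? v : VAR_FLOOR;
}

struct EffectBlock {
  int m;
  int family;
  double df2, S2;          // hyper prior for the variance level
  std::vector<double> tau2;  // per-locus variances (family 0 uses s2m)
  double s2m;              // common variance / laplace hyper variance
  double lambda2;          // laplace rate parameter (= 2/s2m)
};

static void update_effects(std::vector<double>& eff, EffectBlock& blk,
                           const NumericMatrix& M,
                           const std::vector<double>& colSS,
                           std::vector<double>& e, double sigma2e) {
  const int n = M.nrow();
  for (int j = 0; j < blk.m; ++j) {
    double tau2 = (blk.family == 0) ? blk.s2m : blk.tau2[j];
    if (tau2 < VAR_FLOOR) tau2 = VAR_FLOOR;
    const double old = eff[j];
    double cj = 0.0;
    for (int i = 0; i < n; ++i) cj += M(i, j) * e[i];
    cj += colSS[j] * old;
    const double denom = colSS[j] + sigma2e / tau2;
    const double mean = cj / denom;
    const double sdv = std::sqrt(sigma2e / denom);
    const double neu = mean + sdv * norm_rand();
    const double delta = neu - old;
    if (delta != 0.0)
      for (int i = 0; i < n; ++i) e[i] -= M(i, j) * delta;
    eff[j] = neu;
  }
}

static void update_variances(std::vector<double>& eff, EffectBlock& blk) {
  if (blk.family == 3) return;  // fixed variances
  if (blk.family == 0) {
    double ss = 0.0;
    for (int j = 0; j < blk.m; ++j) ss += eff[j] * eff[j];
    blk.s2m = draw_scaled_invchisq(ss, blk.df2, blk.S2, blk.m);
    for (int j = 0; j < blk.m; ++j) blk.tau2[j] = blk.s2m;
  } else if (blk.family == 2) {
    for (int j = 0; j < blk.m; ++j)
      blk.tau2[j] = draw_scaled_invchisq(eff[j] * eff[j], blk.df2,
                                         blk.S2, 1.0);
  } else if (blk.family == 1) {
    double sumtau = 0.0;
    for (int j = 0; j < blk.m; ++j) {
      double aj = std::fabs(eff[j]);
      if (aj < 1e-10) aj = 1e-10;
      double mu_ig = std::sqrt(blk.lambda2) / aj;
      if (mu_ig > 1e8) mu_ig = 1e8;
      double inv_tau2 = rinvgauss(mu_ig, blk.lambda2);
      double t2 = 1.0 / inv_tau2;
      if (t2 < VAR_FLOOR) t2 = VAR_FLOOR;
      blk.tau2[j] = t2;
      sumtau += t2;
    }
    // conjugate inverse-gamma update of the variance hyperparameter
    double shape = blk.m + blk.df2 / 2.0;
    double rate = sumtau + (blk.df2 > 0 ? blk.df2 * blk.S2 / 2.0 : 0.0);
    if (shape < 0.5) shape = 0.5;
    double g = ::Rf_rgamma(shape, 1.0 / rate);
    if (g < VAR_FLOOR) g = VAR_FLOOR;
    blk.s2m = 1.0 / g;
    blk.lambda2 = 2.0 / blk.s2m;
    if (blk.lambda2 < VAR_FLOOR) blk.lambda2 = VAR_FLOOR;
  }
}

// [[Rcpp::export]]
List cpp_gibbs(const NumericVector& y, const NumericMatrix& W,
               const NumericMatrix& S, int family_a, int family_d,
               double df1, double df2, double S2e, double S2ma,
               double S2md, const NumericVector& tau2a_fixed,
               const NumericVector& tau2d_fixed, const NumericVector& wa,
               const NumericVector& wd, int n_iter, int burn_in, int thin,
               bool use_dominance, bool keep_effects) {
  const int n = y.size();
  const int ma_m = W.ncol();
  const int md_m = use_dominance ? S.ncol() : 0;
  if (W.nrow() != n || (use_dominance && S.nrow() != n))
    stop("incidence matrices do not match y");
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in");

  std::vector<double> colSSa(ma_m), colSSd(md_m);
  for (int j = 0; j < ma_m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    colSSa[j] = s;
  }
  for (int j = 0; j < md_m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += S(i, j) * S(i, j);
    colSSd[j] = s;
  }

  EffectBlock A, D;
  A.m = ma_m; A.family = family_a; A.df2 = df2; A.S2 = S2ma;
  A.tau2.assign(ma_m, S2ma > 0 ? S2ma : 1e-3);
  A.s2m = S2ma > 0 ? S2ma : 1e-3;
  A.lambda2 = 2.0 / A.s2m;
  D.m = md_m; D.family = family_d; D.df2 = df2; D.S2 = S2md;
  D.tau2.assign(md_m, S2md > 0 ? S2md : 1e-3);
  D.s2m = S2md > 0 ? S2md : 1e-3;
  D.lambda2 = 2.0 / D.s2m;
  if (family_a == 3)
    for (int j = 0; j < ma_m; ++j) A.tau2[j] = tau2a_fixed[j];
  if (family_d == 3)
    for (int j = 0; j < md_m; ++j) D.tau2[j] = tau2d_fixed[j];

  std::vector<double> eff_a(ma_m, 0.0), eff_d(md_m, 0.0), e(n);
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += y[i];
  mu /= n;
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double sigma2e = 0.0;
  for (int i = 0; i < n; ++i) sigma2e += e[i] * e[i];
  sigma2e /= (n - 1);
  sigma2e *= 0.5;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix samples(n_keep, 7);
  NumericMatrix effects(keep_effects ? n_keep : 0, keep_effects ? ma_m : 0);
  std::vector<double> mean_ma(ma_m, 0.0), mean_md(md_m, 0.0);
  std::vector<double> mean_t2a(ma_m, 0.0), mean_t2d(md_m, 0.0);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept (flat prior)
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += e[i];
    rbar = rbar / n + mu;
    double mu_new = rbar + std::sqrt(sigma2e / n) * norm_rand();
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    update_effects(eff_a, A, W, colSSa, e, sigma2e);
    if (use_dominance) update_effects(eff_d, D, S, colSSd, e, sigma2e);
    update_variances(eff_a, A);
    if (use_dominance) update_variances(eff_d, D);

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2e = draw_scaled_invchisq(sse, df1, S2e, n);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      double s2a = 0.0, s2d = 0.0;
      for (int j = 0; j < ma_m; ++j) s2a += wa[j] * eff_a[j] * eff_a[j];
      for (int j = 0; j < md_m; ++j) s2d += wd[j] * eff_d[j] * eff_d[j];
      double tot = s2a + s2d + sigma2e;
      samples(kept, 0) = mu;
      samples(kept, 1) = sigma2e;
      samples(kept, 2) = s2a;
      samples(kept, 3) = s2d;
      samples(kept, 4) = s2a / tot;
      samples(kept, 5) = s2d / tot;
      samples(kept, 6) = s2a > 0 ? s2d / s2a : NA_REAL;
      for (int j = 0; j < ma_m; ++j) {
        mean_ma[j] += eff_a[j];
        mean_t2a[j] += A.tau2[j];
      }
      for (int j = 0; j < md_m; ++j) {
        mean_md[j] += eff_d[j];
        mean_t2d[j] += D.tau2[j];
      }
      if (keep_effects)
        for (int j = 0; j < ma_m; ++j) effects(kept, j) = eff_a[j];
      ++kept;
    }
  }
  for (int j = 0; j < ma_m; ++j) {
    mean_ma[j] /= kept;
    mean_t2a[j] /= kept;
  }
  for (int j = 0; j < md_m; ++j) {
    mean_md[j] /= kept;
    mean_t2d[j] /= kept;
  }
  return List::create(
    _["samples"] = samples, _["post_mean_ma"] = NumericVector(mean_ma.begin(), mean_ma.end()),
    _["post_mean_md"] = NumericVector(mean_md.begin(), mean_md.end()),
    _["post_mean_tau2a"] = NumericVector(mean_t2a.begin(), mean_t2a.end()),
    _["post_mean_tau2d"] = NumericVector(mean_t2d.begin(), mean_t2d.end()),
    _["effects"] = effects);
}
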
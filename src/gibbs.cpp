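#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Pedigree: inbreeding coefficients (Meuwissen & Luo 1992).
// Mendelian-sampling variances d_i are accumulated alongside F so that the
// A-inverse rules never need the dense relationship matrix.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), L(n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;  // -1 = unknown parent
    double Fs = s >= 0 ? F[s] : 0.0, Fd = d >= 0 ? F[d] : 0.0;
    if (s >= 0 && d >= 0)      D[i] = 0.5 - 0.25 * (Fs + Fd);
    else if (s >= 0 || d >= 0) D[i] = 0.75 - 0.25 * (Fs + Fd);
    else                       D[i] = 1.0;
    if (s < 0 || d < 0) { F[i] = 0.0; continue; }
    // a_ii = sum_j L_j^2 D_j over the ancestors of i (L: generation shares)
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      aii += L[j] * L[j] * D[j];
      int sj = sire[j] - 1, dj = dam[j] - 1;
      if (sj >= 0) L[sj] += 0.5 * L[j];
      if (dj >= 0) L[dj] += 0.5 * L[j];
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// ---------------------------------------------------------------------------
// Truncated standard-normal draw on (a, b] by inverse CDF, evaluated in the
// complementary tail when the interval lies far from the origin so that
// extreme liabilities (|eta| large) do not collapse to the bound.
// ---------------------------------------------------------------------------

static double rtnorm_std(double a, double b) {
  double p, x;
  if (a > 0.0) {              // both bounds right of 0: work in upper tail
    double pa = R::pnorm(a, 0.0, 1.0, 0, 0);
    double pb = R::pnorm(b, 0.0, 1.0, 0, 0);
    p = pb + unif_rand() * (pa - pb);
    x = R::qnorm(p, 0.0, 1.0, 0, 0);
  } else {
    double pa = R::pnorm(a, 0.0, 1.0, 1, 0);
    double pb = R::pnorm(b, 0.0, 1.0, 1, 0);
    p = pa + unif_rand() * (pb - pa);
    x = R::qnorm(p, 0.0, 1.0, 1, 0);
  }
  if (!std::isfinite(x) || x <= a || x > b) {
    // interval so extreme that the CDF underflows: clamp to the near bound
    x = std::isfinite(a) ? a + 1e-10 : b - 1e-10;
    if (!std::isfinite(x)) x = 0.0;
  }
  return x;
}

// [[Rcpp::export]]
NumericVector rtnorm_cpp(int n, double mu, double sd, double lo, double hi) {
  NumericVector out(n);
  double a = (lo - mu) / sd, b = (hi - mu) / sd;
  for (int i = 0; i < n; ++i) out[i] = mu + sd * rtnorm_std(a, b);
  return out;
}

// ---------------------------------------------------------------------------
// Shared helpers for the samplers
// ---------------------------------------------------------------------------

// records grouped by animal: ord holds record indices sorted by animal,
// astart[k]..astart[k+1]-1 are the records of animal k
struct AnimalIndex {
  std::vector<int> ord, astart;
  AnimalIndex(const IntegerVector &anim, int N) {
    int n = anim.size();
    astart.assign(N + 1, 0);
    for (int r = 0; r < n; ++r) astart[anim[r] + 1]++;
    for (int k = 0; k < N; ++k) astart[k + 1] += astart[k];
    std::vector<int> pos(astart.begin(), astart.end() - 1);
    ord.resize(n);
    for (int r = 0; r < n; ++r) ord[pos[anim[r]]++] = r;
  }
};

// alpha' Ainv alpha (or cross product of two vectors) over CSC storage
static double quad_form(const IntegerVector &Ap, const IntegerVector &Ai,
                        const NumericVector &Ax, const std::vector<double> &u,
                        const std::vector<double> &v) {
  double out = 0.0;
  int N = Ap.size() - 1;
  for (int j = 0; j < N; ++j)
    for (int idx = Ap[j]; idx < Ap[j + 1]; ++idx)
      out += u[Ai[idx]] * Ax[idx] * v[j];
  return out;
}

// single-site update of one trait's location effects under residual
// variance se2, genetic variance sa2, with residual vector e updated in
// place.  offs_alpha adds a cross-trait term to the animal-effect rhs (zero
// for single-trait models); prec_extra scales the A-inverse prior.
static void update_locations(const IntegerVector &Xp, const IntegerVector &Xi,
                             const NumericVector &Xx,
                             const std::vector<double> &xtx,
                             std::vector<double> &beta,
                             const AnimalIndex &ai,
                             const IntegerVector &Ap, const IntegerVector &Ai,
                             const NumericVector &Ax,
                             std::vector<double> &alpha,
                             std::vector<double> &e,
                             double se2, double lambda) {
  int f = beta.size(), N = alpha.size();
  for (int j = 0; j < f; ++j) {
    double rhs = 0.0;
    for (int idx = Xp[j]; idx < Xp[j + 1]; ++idx)
      rhs += Xx[idx] * e[Xi[idx]];
    rhs += xtx[j] * beta[j];
    double mean = rhs / xtx[j], sd = std::sqrt(se2 / xtx[j]);
    double bnew = mean + sd * norm_rand();
    double delta = bnew - beta[j];
    beta[j] = bnew;
    for (int idx = Xp[j]; idx < Xp[j + 1]; ++idx)
      e[Xi[idx]] -= Xx[idx] * delta;
  }
  for (int k = 0; k < N; ++k) {
    double zz = ai.astart[k + 1] - ai.astart[k];
    double rhs = zz * alpha[k], diag = 0.0, offsum = 0.0;
    for (int r = ai.astart[k]; r < ai.astart[k + 1]; ++r)
      rhs += e[ai.ord[r]];
    for (int idx = Ap[k]; idx < Ap[k + 1]; ++idx) {
      int i = Ai[idx];
      if (i == k) diag = Ax[idx];
      else offsum += Ax[idx] * alpha[i];
    }
    double denom = zz + lambda * diag;
    rhs -= lambda * offsum;
    double mean = rhs / denom, sd = std::sqrt(se2 / denom);
    double anew = mean + sd * norm_rand();
    double delta = anew - alpha[k];
    alpha[k] = anew;
    for (int r = ai.astart[k]; r < ai.astart[k + 1]; ++r)
      e[ai.ord[r]] -= delta;
  }
}

static void check_finite(double x, const char *what, int cycle) {
  if (!std::isfinite(x) || x <= 0.0)
    stop("non-finite or non-positive %s draw at cycle %d", what, cycle + 1);
}

// ---------------------------------------------------------------------------
// Single-trait linear animal model
// y = X beta + Z alpha + e;  alpha | A, sa2 ~ N(0, A sa2);  e ~ N(0, I se2)
// Flat priors: scaled inverse chi-square conditionals with df N-2 and n-2.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gibbs_linear_cpp(IntegerVector Xp, IntegerVector Xi, NumericVector Xx,
                      int f, NumericVector y, IntegerVector anim, int N,
                      IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                      int n_cycles, int burn_in, int thin,
                      double start_sa2, double start_se2,
                      double nu_a, double nu_e) {
  int n = y.size();
  AnimalIndex ai(anim, N);
  std::vector<double> beta(f, 0.0), alpha(N, 0.0), e(y.begin(), y.end());
  std::vector<double> xtx(f, 0.0);
  for (int j = 0; j < f; ++j)
    for (int idx = Xp[j]; idx < Xp[j + 1]; ++idx)
      xtx[j] += Xx[idx] * Xx[idx];
  double sa2 = start_sa2, se2 = start_se2;
  int n_keep = (n_cycles - burn_in) / thin;
  NumericMatrix samples(n_keep, 5);
  colnames(samples) = CharacterVector::create("sigma_a2", "sigma_e2", "h2",
                                              "mu", "deviance");
  std::vector<double> beta_mean(f, 0.0), alpha_mean(N, 0.0);
  int kept = 0;
  const double LOG2PI = std::log(2.0 * M_PI);

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    update_locations(Xp, Xi, Xx, xtx, beta, ai, Ap, Ai, Ax, alpha, e,
                     se2, se2 / sa2);
    double ssa = quad_form(Ap, Ai, Ax, alpha, alpha);
    sa2 = ssa / R::rchisq(N + nu_a);
    check_finite(sa2, "sigma_a2", cyc);
    double sse = 0.0;
    for (int r = 0; r < n; ++r) sse += e[r] * e[r];
    se2 = sse / R::rchisq(n + nu_e);
    check_finite(se2, "sigma_e2", cyc);

    if (cyc >= burn_in && (cyc - burn_in + 1) % thin == 0) {
      samples(kept, 0) = sa2;
      samples(kept, 1) = se2;
      samples(kept, 2) = sa2 / (sa2 + se2);
      samples(kept, 3) = f > 0 ? beta[0] : 0.0;
      samples(kept, 4) = n * (LOG2PI + std::log(se2)) + sse / se2;
      for (int j = 0; j < f; ++j) beta_mean[j] += beta[j];
      for (int k = 0; k < N; ++k) alpha_mean[k] += alpha[k];
      ++kept;
    }
  }
  for (int j = 0; j < f; ++j) beta_mean[j] /= n_keep;
  for (int k = 0; k < N; ++k) alpha_mean[k] /= n_keep;
  return List::create(_["samples"] = samples,
                      _["beta_mean"] = NumericVector(beta_mean.begin(), beta_mean.end()),
                      _["alpha_mean"] = NumericVector(alpha_mean.begin(), alpha_mean.end()));
}

// log category probability under the probit link, clamped away from 0
static double log_cat_prob(double eta, const std::vector<double> &t, int cat,
                           int K, double sd = 1.0) {
  double lo = cat == 1 ? R_NegInf : t[cat - 2];
  double hi = cat == K ? R_PosInf : t[cat - 1];
  double p = R::pnorm((hi - eta) / sd, 0.0, 1.0, 1, 0) -
             R::pnorm((lo - eta) / sd, 0.0, 1.0, 1, 0);
  if (p < 1e-300) p = 1e-300;
  return std::log(p);
}

// Albert-Chib threshold update: t_j ~ U(max U in cat j, min U in cat j+1)
// for the free thresholds t_3..t_{K-1}; t_1 = 0 and t_2 = 1 stay fixed so
// the liability scale is pinned and the residual variance is estimable
static void update_thresholds(std::vector<double> &t, int K,
                              const std::vector<double> &U,
                              const IntegerVector &cat) {
  if (K <= 3) return;
  int n = U.size();
  std::vector<double> cmax(K, R_NegInf), cmin(K, R_PosInf);
  for (int r = 0; r < n; ++r) {
    int c = cat[r] - 1;
    if (U[r] > cmax[c]) cmax[c] = U[r];
    if (U[r] < cmin[c]) cmin[c] = U[r];
  }
  for (int j = 2; j < K - 1; ++j) {   // free thresholds t[2]..t[K-2]
    double lo = cmax[j], hi = cmin[j + 1];
    if (!std::isfinite(lo)) lo = t[j - 1];
    if (!std::isfinite(hi)) hi = lo + 1.0;
    t[j] = lo + unif_rand() * (hi - lo);
  }
}

// ---------------------------------------------------------------------------
// Single-trait threshold (liability) animal model.
// K >= 3: thresholds t_1 = 0 and t_2 = 1 fixed, t_3.. sampled, residual
//         variance estimated (flat prior) — the scale-pinned identification.
// K == 2: t_1 = 0, residual variance fixed at 1, proper prior on sigma_a2
//         (nu_a > 2, s2_a > 0) supplied by the caller.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gibbs_threshold_cpp(IntegerVector Xp, IntegerVector Xi, NumericVector Xx,
                         int f, IntegerVector cat, int K, IntegerVector anim,
                         int N, IntegerVector Ap, IntegerVector Ai,
                         NumericVector Ax, NumericVector t_start,
                         int n_cycles, int burn_in, int thin,
                         double start_sa2, double nu_a, double s2_a,
                         double nu_e, double s2_e) {
  int n = cat.size();
  bool free_resid = K >= 3;
  AnimalIndex ai(anim, N);
  std::vector<double> beta(f, 0.0), alpha(N, 0.0);
  std::vector<double> t(t_start.begin(), t_start.end()); // length K-1, t[0]=0
  std::vector<double> xtx(f, 0.0);
  for (int j = 0; j < f; ++j)
    for (int idx = Xp[j]; idx < Xp[j + 1]; ++idx)
      xtx[j] += Xx[idx] * Xx[idx];
  // initial liabilities at category midpoints
  std::vector<double> U(n), e(n);
  for (int r = 0; r < n; ++r) {
    int c = cat[r];
    double lo = c == 1 ? t[0] - 1.0 : t[c - 2];
    double hi = c == K ? t[K - 2] + 1.0 : t[c - 1];
    U[r] = 0.5 * (lo + hi);
    e[r] = U[r];               // beta, alpha start at zero
  }
  double sa2 = start_sa2, se2 = 1.0;
  int n_keep = (n_cycles - burn_in) / thin;
  NumericMatrix samples(n_keep, 5);
  colnames(samples) = CharacterVector::create("sigma_a2", "sigma_e2", "h2",
                                              "mu", "deviance");
  int n_free_t = K > 3 ? K - 3 : 0;
  NumericMatrix thr(n_keep, n_free_t);
  std::vector<double> beta_mean(f, 0.0), alpha_mean(N, 0.0),
      t_mean(K - 1, 0.0);
  double se2_sum = 0.0;
  int kept = 0;

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    // liabilities
    double sd = std::sqrt(se2);
    for (int r = 0; r < n; ++r) {
      double eta = U[r] - e[r];
      int c = cat[r];
      double lo = c == 1 ? R_NegInf : t[c - 2];
      double hi = c == K ? R_PosInf : t[c - 1];
      double Unew = eta + sd * rtnorm_std((lo - eta) / sd, (hi - eta) / sd);
      e[r] += Unew - U[r];
      U[r] = Unew;
    }
    update_thresholds(t, K, U, cat);
    update_locations(Xp, Xi, Xx, xtx, beta, ai, Ap, Ai, Ax, alpha, e,
                     se2, se2 / sa2);
    double ssa = quad_form(Ap, Ai, Ax, alpha, alpha);
    sa2 = (ssa + nu_a * s2_a) / R::rchisq(N + nu_a);
    check_finite(sa2, "sigma_a2", cyc);
    if (free_resid) {
      double sse = 0.0;
      for (int r = 0; r < n; ++r) sse += e[r] * e[r];
      se2 = (sse + nu_e * s2_e) / R::rchisq(n + nu_e);
      check_finite(se2, "sigma_e2", cyc);
    }

    if (cyc >= burn_in && (cyc - burn_in + 1) % thin == 0) {
      double dev = 0.0, sdk = std::sqrt(se2);
      for (int r = 0; r < n; ++r)
        dev += -2.0 * log_cat_prob(U[r] - e[r], t, cat[r], K, sdk);
      samples(kept, 0) = sa2;
      samples(kept, 1) = se2;
      samples(kept, 2) = sa2 / (sa2 + se2);
      samples(kept, 3) = f > 0 ? beta[0] : 0.0;
      samples(kept, 4) = dev;
      for (int j = 0; j < n_free_t; ++j) thr(kept, j) = t[j + 2];
      for (int j = 0; j < f; ++j) beta_mean[j] += beta[j];
      for (int k = 0; k < N; ++k) alpha_mean[k] += alpha[k];
      for (int j = 0; j < K - 1; ++j) t_mean[j] += t[j];
      se2_sum += se2;
      ++kept;
    }
  }
  for (int j = 0; j < f; ++j) beta_mean[j] /= n_keep;
  for (int k = 0; k < N; ++k) alpha_mean[k] /= n_keep;
  for (int j = 0; j < K - 1; ++j) t_mean[j] /= n_keep;
  return List::create(_["samples"] = samples, _["thresholds"] = thr,
                      _["beta_mean"] = NumericVector(beta_mean.begin(), beta_mean.end()),
                      _["alpha_mean"] = NumericVector(alpha_mean.begin(), alpha_mean.end()),
                      _["t_mean"] = NumericVector(t_mean.begin(), t_mean.end()),
                      _["se2_mean"] = se2_sum / n_keep);
}

// ---------------------------------------------------------------------------
// Bivariate threshold-linear model: trait 1 categorical on the liability
// scale (t_1 = 0, t_2 = 1 fixed, K >= 3, full R0 estimated), trait 2
// continuous
// ---------------------------------------------------------------------------

// 2x2 inverse-Wishart draw via Bartlett decomposition on the Wishart of the
// inverted scale; returns false if the draw is not positive definite
static bool riwish2(double df, const double S[3], double out[3]) {
  // S = (s11, s12, s22); invert scale
  double det = S[0] * S[2] - S[1] * S[1];
  if (det <= 0.0) return false;
  double V11 = S[2] / det, V12 = -S[1] / det, V22 = S[0] / det;
  // lower Cholesky of V
  double L11 = std::sqrt(V11), L21 = V12 / L11;
  double L22sq = V22 - L21 * L21;
  if (L22sq <= 0.0) return false;
  double L22 = std::sqrt(L22sq);
  // Bartlett factor
  double c11 = std::sqrt(R::rchisq(df)), c22 = std::sqrt(R::rchisq(df - 1.0));
  double z = norm_rand();
  // T = L * [[c11,0],[z,c22]];  W = T T'
  double T11 = L11 * c11, T21 = L21 * c11 + L22 * z, T22 = L22 * c22;
  double W11 = T11 * T11, W12 = T11 * T21, W22 = T21 * T21 + T22 * T22;
  double dW = W11 * W22 - W12 * W12;
  if (dW <= 0.0) return false;
  out[0] = W22 / dW; out[1] = -W12 / dW; out[2] = W11 / dW;
  return out[0] > 0.0 && out[2] > 0.0 &&
         out[0] * out[2] - out[1] * out[1] > 0.0;
}

// [[Rcpp::export]]
List gibbs_bivariate_cpp(IntegerVector X1p, IntegerVector X1i, NumericVector X1x,
                         int f1, IntegerVector cat, int K,
                         IntegerVector X2p, IntegerVector X2i, NumericVector X2x,
                         int f2, NumericVector y2, IntegerVector anim, int N,
                         IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                         NumericVector t_start, int n_cycles, int burn_in,
                         int thin, NumericVector G0_start, double r22_start,
                         double iw_df_extra, NumericVector s0g,
                         NumericVector s0r, double iw_eps) {
  if (K < 3) stop("bivariate threshold-linear model needs K >= 3");
  int n = cat.size();
  AnimalIndex ai(anim, N);
  std::vector<double> b1(f1, 0.0), b2(f2, 0.0), a1(N, 0.0), a2(N, 0.0);
  std::vector<double> t(t_start.begin(), t_start.end());
  std::vector<double> x1tx(f1, 0.0), x2tx(f2, 0.0);
  for (int j = 0; j < f1; ++j)
    for (int idx = X1p[j]; idx < X1p[j + 1]; ++idx)
      x1tx[j] += X1x[idx] * X1x[idx];
  for (int j = 0; j < f2; ++j)
    for (int idx = X2p[j]; idx < X2p[j + 1]; ++idx)
      x2tx[j] += X2x[idx] * X2x[idx];
  std::vector<double> U(n), e1(n), e2(n);
  for (int r = 0; r < n; ++r) {
    int c = cat[r];
    double lo = c == 1 ? t[0] - 1.0 : t[c - 2];
    double hi = c == K ? t[K - 2] + 1.0 : t[c - 1];
    U[r] = 0.5 * (lo + hi);
    e1[r] = U[r];
    e2[r] = y2[r];
  }
  // G0 = (g11, g12, g22); R0 = (r11, r12, r22)
  double G[3] = {G0_start[0], G0_start[1], G0_start[2]};
  double Rr[3] = {1.0, 0.0, r22_start};
  int n_keep = (n_cycles - burn_in) / thin;
  NumericMatrix samples(n_keep, 10);
  colnames(samples) = CharacterVector::create(
      "g11", "g12", "g22", "r11", "r12", "r22", "rg", "h2_cat", "h2_cont",
      "deviance");
  int n_free_t = K > 3 ? K - 3 : 0;
  NumericMatrix thr(n_keep, n_free_t);
  int kept = 0, n_jitter = 0;

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    // --- liabilities given the continuous record through R0
    double slope = Rr[1] / Rr[2];
    double cvar = Rr[0] - Rr[1] * Rr[1] / Rr[2];
    double csd = std::sqrt(cvar);
    for (int r = 0; r < n; ++r) {
      double eta1 = U[r] - e1[r];
      double mu = eta1 + slope * e2[r];
      int c = cat[r];
      double lo = c == 1 ? R_NegInf : t[c - 2];
      double hi = c == K ? R_PosInf : t[c - 1];
      double Unew = mu + csd * rtnorm_std((lo - mu) / csd, (hi - mu) / csd);
      e1[r] += Unew - U[r];
      U[r] = Unew;
    }
    update_thresholds(t, K, U, cat);

    // --- location effects, multivariate single-site
    double dR = Rr[0] * Rr[2] - Rr[1] * Rr[1];
    double Ri11 = Rr[2] / dR, Ri12 = -Rr[1] / dR, Ri22 = Rr[0] / dR;
    double dG = G[0] * G[2] - G[1] * G[1];
    double Gi11 = G[2] / dG, Gi12 = -G[1] / dG, Gi22 = G[0] / dG;

    // fixed effects: scalar updates per trait with the cross-residual term
    for (int tr = 0; tr < 2; ++tr) {
      const IntegerVector &Xp = tr == 0 ? X1p : X2p;
      const IntegerVector &Xi_ = tr == 0 ? X1i : X2i;
      const NumericVector &Xx = tr == 0 ? X1x : X2x;
      std::vector<double> &xtx = tr == 0 ? x1tx : x2tx;
      std::vector<double> &beta = tr == 0 ? b1 : b2;
      std::vector<double> &eT = tr == 0 ? e1 : e2;
      std::vector<double> &eO = tr == 0 ? e2 : e1;
      double Rtt = tr == 0 ? Ri11 : Ri22;
      double Rts = Ri12;
      int f = beta.size();
      for (int j = 0; j < f; ++j) {
        double rhs = 0.0;
        for (int idx = Xp[j]; idx < Xp[j + 1]; ++idx) {
          int r = Xi_[idx];
          rhs += Xx[idx] * (Rtt * eT[r] + Rts * eO[r]);
        }
        rhs += Rtt * xtx[j] * beta[j];
        double prec = Rtt * xtx[j];
        double mean = rhs / prec, sd = std::sqrt(1.0 / prec);
        double bnew = mean + sd * norm_rand();
        double delta = bnew - beta[j];
        beta[j] = bnew;
        for (int idx = Xp[j]; idx < Xp[j + 1]; ++idx)
          eT[Xi_[idx]] -= Xx[idx] * delta;
      }
    }

    // breeding values: both traits of an animal drawn jointly from their
    // bivariate normal conditional (keeps the chain mobile when |rg| is
    // large, where trait-at-a-time updates freeze)
    for (int k = 0; k < N; ++k) {
      double zz = ai.astart[k + 1] - ai.astart[k];
      // z'e~ with the animal's own effect added back on both traits
      double S1 = zz * a1[k], S2 = zz * a2[k];
      for (int r = ai.astart[k]; r < ai.astart[k + 1]; ++r) {
        int rec = ai.ord[r];
        S1 += e1[rec];
        S2 += e2[rec];
      }
      double diag = 0.0, off1 = 0.0, off2 = 0.0;
      for (int idx = Ap[k]; idx < Ap[k + 1]; ++idx) {
        int i = Ai[idx];
        if (i == k) diag = Ax[idx];
        else { off1 += Ax[idx] * a1[i]; off2 += Ax[idx] * a2[i]; }
      }
      double rhs1 = Ri11 * S1 + Ri12 * S2 - (Gi11 * off1 + Gi12 * off2);
      double rhs2 = Ri12 * S1 + Ri22 * S2 - (Gi12 * off1 + Gi22 * off2);
      double P11 = zz * Ri11 + diag * Gi11;
      double P12 = zz * Ri12 + diag * Gi12;
      double P22 = zz * Ri22 + diag * Gi22;
      double dP = P11 * P22 - P12 * P12;
      double m1 = (P22 * rhs1 - P12 * rhs2) / dP;
      double m2 = (P11 * rhs2 - P12 * rhs1) / dP;
      // draw from N(m, P^{-1}) via the Cholesky of the covariance
      double C11 = P22 / dP, C12 = -P12 / dP, C22 = P11 / dP;
      double L11 = std::sqrt(C11), L21 = C12 / L11;
      double L22 = std::sqrt(C22 - L21 * L21);
      double z1 = norm_rand(), z2 = norm_rand();
      double a1new = m1 + L11 * z1;
      double a2new = m2 + L21 * z1 + L22 * z2;
      double d1 = a1new - a1[k], d2 = a2new - a2[k];
      a1[k] = a1new; a2[k] = a2new;
      for (int r = ai.astart[k]; r < ai.astart[k + 1]; ++r) {
        int rec = ai.ord[r];
        e1[rec] -= d1;
        e2[rec] -= d2;
      }
    }

    // --- residual covariance (full R0: the fixed t_2 = 1 identifies r11);
    // the diagonal prior scale keeps the correlation off the +/-1 boundary
    double S[3] = {s0r[0], 0.0, s0r[1]};
    for (int r = 0; r < n; ++r) {
      S[0] += e1[r] * e1[r];
      S[1] += e1[r] * e2[r];
      S[2] += e2[r] * e2[r];
    }
    double draw[3];
    int tries = 0;
    while (!riwish2(n + iw_df_extra, S, draw)) {
      S[0] += iw_eps; S[2] += iw_eps;
      if (++tries > 10) stop("residual covariance draw failed at cycle %d",
                             cyc + 1);
      ++n_jitter;
    }
    Rr[0] = draw[0]; Rr[1] = draw[1]; Rr[2] = draw[2];

    // --- genetic covariance from A-inverse quadratic forms
    double Sg[3];
    Sg[0] = quad_form(Ap, Ai, Ax, a1, a1) + s0g[0];
    Sg[1] = quad_form(Ap, Ai, Ax, a1, a2);
    Sg[2] = quad_form(Ap, Ai, Ax, a2, a2) + s0g[1];
    tries = 0;
    while (!riwish2(N + iw_df_extra, Sg, draw)) {
      Sg[0] += iw_eps; Sg[2] += iw_eps;
      if (++tries > 10) stop("genetic covariance draw failed at cycle %d",
                             cyc + 1);
      ++n_jitter;
    }
    G[0] = draw[0]; G[1] = draw[1]; G[2] = draw[2];

    if (cyc >= burn_in && (cyc - burn_in + 1) % thin == 0) {
      double slope2 = Rr[1] / Rr[2];
      double cv = Rr[0] - Rr[1] * Rr[1] / Rr[2];
      double csd2 = std::sqrt(cv);
      double dev = 0.0;
      const double LOG2PI = std::log(2.0 * M_PI);
      for (int r = 0; r < n; ++r) {
        double eta2 = y2[r] - e2[r];
        dev += LOG2PI + std::log(Rr[2]) + e2[r] * e2[r] / Rr[2];
        double m = (U[r] - e1[r]) + slope2 * e2[r];
        dev += -2.0 * log_cat_prob(m, t, cat[r], K, csd2);
      }
      samples(kept, 0) = G[0];
      samples(kept, 1) = G[1];
      samples(kept, 2) = G[2];
      samples(kept, 3) = Rr[0];
      samples(kept, 4) = Rr[1];
      samples(kept, 5) = Rr[2];
      samples(kept, 6) = G[1] / std::sqrt(G[0] * G[2]);
      samples(kept, 7) = G[0] / (G[0] + Rr[0]);
      samples(kept, 8) = G[2] / (G[2] + Rr[2]);
      samples(kept, 9) = dev;
      for (int j = 0; j < n_free_t; ++j) thr(kept, j) = t[j + 2];
      ++kept;
    }
  }
  return List::create(_["samples"] = samples, _["thresholds"] = thr,
                      _["n_jitter"] = n_jitter);
}
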
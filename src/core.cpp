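#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// One draw from N(mean, sd^2) truncated to (lower, upper) by the inverse-CDF
// method.  One-sided truncations go through log-space tail probabilities so
// that bounds many SDs from the mean remain numerically exact.
static double rtnorm_one(double mean, double sd, double lower, double upper) {
  double a = (lower - mean) / sd;
  double b = (upper - mean) / sd;
  double u = unif_rand();
  double x;
  if (!R_finite(a) && !R_finite(b)) {
    x = norm_rand();
  } else if (!R_finite(a)) {            // X < b
    double lp = R::pnorm(b, 0.0, 1.0, 1, 1);
    x = R::qnorm(std::log(u) + lp, 0.0, 1.0, 1, 1);
  } else if (!R_finite(b)) {            // X >= a
    double lp = R::pnorm(a, 0.0, 1.0, 0, 1);
    x = R::qnorm(std::log(u) + lp, 0.0, 1.0, 0, 1);
  } else {
    double pa = R::pnorm(a, 0.0, 1.0, 1, 0);
    double pb = R::pnorm(b, 0.0, 1.0, 1, 0);
    if (pb <= pa) stop("degenerate truncation interval");
    x = R::qnorm(pa + u * (pb - pa), 0.0, 1.0, 1, 0);
  }
  return mean + sd * x;
}

// [[Rcpp::export]]
NumericVector rtruncnorm_cpp(int n, NumericVector mean, NumericVector sd,
                             NumericVector lower, NumericVector upper) {
  NumericVector out(n);
  int nm = mean.size(), ns = sd.size(), nl = lower.size(), nu = upper.size();
  for (int i = 0; i < n; ++i) {
    double s = sd[i % ns];
    if (!(s > 0)) stop("sd must be positive");
    out[i] = rtnorm_one(mean[i % nm], s, lower[i % nl], upper[i % nu]);
  }
  return out;
}

// Meuwissen & Luo (1992) recursion: F_i = sum_j L_j^2 D_j - 1 over the
// ancestors j of i, with D_j the Mendelian sampling variance using the
// convention F = -1 for an unknown parent.  sire/dam are 1-based positions
// with 0 for unknown; parents must precede offspring.
// [[Rcpp::export]]
NumericVector inbreeding_ml_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> Fpad(n + 1);
  Fpad[0] = -1.0;                       // unknown-parent slot
  std::vector<double> L(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s > i + 1 || d > i + 1) stop("pedigree not sorted: parent after offspring");
    if (s == 0 && d == 0) { F[i] = 0.0; Fpad[i + 1] = 0.0; continue; }
    std::set<int, std::greater<int> > anc;
    std::vector<int> touched;
    double aii = 0.0;
    L[i + 1] = 1.0; anc.insert(i + 1); touched.push_back(i + 1);
    while (!anc.empty()) {
      int j = *anc.begin();
      anc.erase(anc.begin());
      double lj = L[j];
      int sj = sire[j - 1], dj = dam[j - 1];
      double Dj = 0.5 - 0.25 * (Fpad[sj] + Fpad[dj]);
      aii += lj * lj * Dj;
      if (sj > 0) { if (L[sj] == 0.0) { anc.insert(sj); touched.push_back(sj); } L[sj] += 0.5 * lj; }
      if (dj > 0) { if (L[dj] == 0.0) { anc.insert(dj); touched.push_back(dj); } L[dj] += 0.5 * lj; }
    }
    for (size_t k = 0; k < touched.size(); ++k) L[touched[k]] = 0.0;
    F[i] = aii - 1.0;
    Fpad[i + 1] = F[i];
  }
  return F;
}

// Colleau's indirect method: multiply the numerator relationship matrix A
// by a set of vectors without forming A, using A = T D T' with T the
// gene-flow operator and D the Mendelian-sampling variances (F = -1
// convention for unknown parents).  O(n) per vector.
// [[Rcpp::export]]
NumericMatrix A_times_cpp(IntegerVector sire, IntegerVector dam,
                          NumericVector F, NumericMatrix V) {
  int n = sire.size();
  if (V.nrow() != n) stop("V must have one row per animal");
  NumericMatrix out(n, V.ncol());
  std::vector<double> t(n), d(n);
  for (int i = 0; i < n; ++i) {
    double Fs = sire[i] > 0 ? F[sire[i] - 1] : -1.0;
    double Fd = dam[i] > 0 ? F[dam[i] - 1] : -1.0;
    d[i] = 0.5 - 0.25 * (Fs + Fd);
  }
  for (int j = 0; j < V.ncol(); ++j) {
    for (int i = 0; i < n; ++i) t[i] = V(i, j);
    for (int i = n - 1; i >= 0; --i) {           // t = T' v
      if (sire[i] > 0) t[sire[i] - 1] += 0.5 * t[i];
      if (dam[i] > 0) t[dam[i] - 1] += 0.5 * t[i];
    }
    for (int i = 0; i < n; ++i) t[i] *= d[i];    // t = D T' v
    for (int i = 0; i < n; ++i) {                // w = T t
      double w = t[i];
      if (sire[i] > 0) w += 0.5 * out(sire[i] - 1, j);
      if (dam[i] > 0) w += 0.5 * out(dam[i] - 1, j);
      out(i, j) = w;
    }
  }
  return out;
}

// Single-site Gibbs sampler for the animal model with a general symmetric
// prior precision structure Kinv (A-inverse or H-inverse, CSC slots of a
// dgCMatrix).  Threshold mode augments record liabilities truncated at 0
// with residual variance fixed at 1; linear mode treats y as Gaussian and
// samples sigma_e2.  Variances use scaled inverse chi-square full
// conditionals with (nu, S) hyper-parameters; nu = -2, S = 0 is flat.
// [[Rcpp::export]]
List gibbs_animal_cpp(NumericVector y, IntegerVector rec_animal, IntegerVector rec_cg,
                      int n_animal, int n_cg,
                      IntegerVector Kp, IntegerVector Ki, NumericVector Kx,
                      int n_iter, int burn_in, int thin,
                      bool threshold_mode, bool update_sigma_u,
                      double nu_u, double S_u, double nu_e, double S_e,
                      double sigma_u2_init, double sigma_e2_init,
                      double threshold_t, double beta_prior_var) {
  int n_rec = y.size();
  if (rec_animal.size() != n_rec || rec_cg.size() != n_rec)
    stop("record index vectors must match y");

  // group records by cg and by animal (counting sort)
  std::vector<int> cg_count(n_cg, 0), an_count(n_animal, 0);
  for (int r = 0; r < n_rec; ++r) {
    int c = rec_cg[r], a = rec_animal[r];
    if (c < 0 || c >= n_cg || a < 0 || a >= n_animal) stop("record index out of range");
    cg_count[c]++; an_count[a]++;
  }
  std::vector<int> cg_ptr(n_cg + 1, 0), an_ptr(n_animal + 1, 0);
  for (int c = 0; c < n_cg; ++c) cg_ptr[c + 1] = cg_ptr[c] + cg_count[c];
  for (int a = 0; a < n_animal; ++a) an_ptr[a + 1] = an_ptr[a] + an_count[a];
  std::vector<int> cg_rec(n_rec), an_rec(n_rec), fill1(n_cg, 0), fill2(n_animal, 0);
  for (int r = 0; r < n_rec; ++r) {
    int c = rec_cg[r], a = rec_animal[r];
    cg_rec[cg_ptr[c] + fill1[c]++] = r;
    an_rec[an_ptr[a] + fill2[a]++] = r;
  }
  for (int c = 0; c < n_cg; ++c)
    if (cg_count[c] == 0) stop("contemporary group with zero records");

  std::vector<double> beta(n_cg, 0.0), u(n_animal, 0.0), l(n_rec);
  for (int r = 0; r < n_rec; ++r) l[r] = threshold_mode ? 0.0 : y[r];
  double sigma_u2 = sigma_u2_init, sigma_e2 = threshold_mode ? 1.0 : sigma_e2_init;

  int n_keep = 0;
  for (int it = burn_in + 1; it <= n_iter; ++it) if ((it - burn_in) % thin == 0) n_keep++;
  NumericMatrix chain(n_keep, 3);          // sigma_u2, sigma_e2, h2
  NumericVector u_mean(n_animal), beta_mean(n_cg);
  // Rao-Blackwellized running means: average the full-conditional means of
  // u over every post-burn-in sweep, cutting Monte-Carlo noise in the GEBV
  NumericVector u_rb(n_animal), cond_mean(n_animal);
  int n_rb = 0;
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    double sig_e = std::sqrt(sigma_e2);
    // 1. liabilities (threshold mode only)
    if (threshold_mode) {
      for (int r = 0; r < n_rec; ++r) {
        double m = beta[rec_cg[r]] + u[rec_animal[r]];
        l[r] = (y[r] >= 2.0)
          ? rtnorm_one(m, sig_e, threshold_t, R_PosInf)
          : rtnorm_one(m, sig_e, R_NegInf, threshold_t);
      }
    }
    // 2. CG effects; Gaussian prior N(0, beta_prior_var), flat when infinite
    double bvinv = R_finite(beta_prior_var) ? 1.0 / beta_prior_var : 0.0;
    for (int c = 0; c < n_cg; ++c) {
      double s = 0.0;
      for (int k = cg_ptr[c]; k < cg_ptr[c + 1]; ++k) {
        int r = cg_rec[k];
        s += l[r] - u[rec_animal[r]];
      }
      double denom = cg_count[c] + sigma_e2 * bvinv;
      beta[c] = s / denom + std::sqrt(sigma_e2 / denom) * norm_rand();
    }
    // 3. animal effects
    double lambda = sigma_e2 / sigma_u2;
    for (int a = 0; a < n_animal; ++a) {
      double rhs = 0.0;
      for (int k = an_ptr[a]; k < an_ptr[a + 1]; ++k) {
        int r = an_rec[k];
        rhs += l[r] - beta[rec_cg[r]];
      }
      double kdiag = 0.0, koff = 0.0;
      for (int k = Kp[a]; k < Kp[a + 1]; ++k) {
        int j = Ki[k];
        if (j == a) kdiag = Kx[k]; else koff += Kx[k] * u[j];
      }
      double denom = an_count[a] + lambda * kdiag;
      if (!(denom > 0) || !R_finite(denom)) stop("non-finite conditional variance");
      rhs -= lambda * koff;
      cond_mean[a] = rhs / denom;
      u[a] = cond_mean[a] + std::sqrt(sigma_e2 / denom) * norm_rand();
    }
    if (it > burn_in) {
      for (int a = 0; a < n_animal; ++a) u_rb[a] += cond_mean[a];
      n_rb++;
    }
    // 4. sigma_u2 | u  ~  (u'Ku + nu*S) / chisq(q + nu)
    if (update_sigma_u) {
      double quad = 0.0;
      for (int a = 0; a < n_animal; ++a)
        for (int k = Kp[a]; k < Kp[a + 1]; ++k)
          quad += u[a] * Kx[k] * u[Ki[k]];
      sigma_u2 = (quad + nu_u * S_u) / R::rchisq(n_animal + nu_u);
    }
    // 5. sigma_e2 (linear mode)
    if (!threshold_mode) {
      double sse = 0.0;
      for (int r = 0; r < n_rec; ++r) {
        double e = l[r] - beta[rec_cg[r]] - u[rec_animal[r]];
        sse += e * e;
      }
      sigma_e2 = (sse + nu_e * S_e) / R::rchisq(n_rec + nu_e);
    }
    // store
    if (it > burn_in && (it - burn_in) % thin == 0) {
      chain(kept, 0) = sigma_u2;
      chain(kept, 1) = sigma_e2;
      chain(kept, 2) = sigma_u2 / (sigma_u2 + sigma_e2);
      for (int a = 0; a < n_animal; ++a) u_mean[a] += u[a];
      for (int c = 0; c < n_cg; ++c) beta_mean[c] += beta[c];
      kept++;
    }
  }
  if (kept > 0) {
    for (int a = 0; a < n_animal; ++a) u_mean[a] /= kept;
    for (int c = 0; c < n_cg; ++c) beta_mean[c] /= kept;
  }
  if (n_rb > 0) for (int a = 0; a < n_animal; ++a) u_rb[a] /= n_rb;
  return List::create(_["chain"] = chain, _["u_mean"] = u_mean,
                      _["u_rb"] = u_rb,
                      _["beta_mean"] = beta_mean, _["n_kept"] = kept);
}
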
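#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the animal model
//   y = X b + Z u + e,  u ~ N(0, K sigma2_a),  e ~ N(0, I sigma2_e)
// with flat priors on b and scaled-inverse-chi-square priors on the
// variances (nu = -2, S2 = 0 gives flat priors on the variances, so the
// posterior means are comparable to REML estimates).
//
// X is dense (few fixed-effect columns), K^-1 is sparse (dgCMatrix slots),
// Z is an incidence matrix passed as a record -> animal index. Residuals
// are kept updated so every full conditional costs O(column nonzeros).
//
// [[Rcpp::export]]
List gibbs_animal_cpp(const NumericVector& y,
                      const NumericMatrix& X,
                      const IntegerVector& anim,       // 1-based per record
                      const IntegerVector& Ki,         // Kinv@i (0-based rows)
                      const IntegerVector& Kp,         // Kinv@p (col pointers)
                      const NumericVector& Kx,         // Kinv@x
                      int m,                           // number of animals
                      int chain, int burn, int thin,
                      double nu_a, double S2a, double nu_e, double S2e,
                      double sa0, double se0,
                      const IntegerVector& focal) {    // 1-based animal idx
  const int n = y.size();
  const int p = X.ncol();
  if (burn >= chain) stop("burn_in must be < chain length");
  const int kept = (chain - burn) / thin;
  if (kept < 1) stop("no retained samples: shorten burn-in or thinning");

  // records per animal
  std::vector<std::vector<int>> rec(m);
  for (int r = 0; r < n; ++r) rec[anim[r] - 1].push_back(r);

  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int r = 0; r < n; ++r) s += X(r, j) * X(r, j);
    xtx[j] = s;
  }

  std::vector<double> b(p, 0.0), u(m, 0.0), e(y.begin(), y.end());
  double sa = sa0, se = se0;

  const double df_a = m + nu_a, df_e = n + nu_e;
  if (df_a <= 0 || df_e <= 0) stop("non-positive degrees of freedom");

  NumericVector sa_trace(kept), se_trace(kept);
  NumericMatrix u_focal(focal.size(), kept);
  NumericVector u_mean(m);
  int stored = 0;

  RNGScope scope;
  for (int it = 1; it <= chain; ++it) {
    // fixed effects, flat prior
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) continue;
      double rhs = 0.0;
      for (int r = 0; r < n; ++r) rhs += X(r, j) * e[r];
      rhs += xtx[j] * b[j];
      double mean = rhs / xtx[j];
      double bn = mean + norm_rand() * std::sqrt(se / xtx[j]);
      double diff = bn - b[j];
      if (diff != 0.0)
        for (int r = 0; r < n; ++r) e[r] -= X(r, j) * diff;
      b[j] = bn;
    }
    // breeding values, single site
    double lambda = se / sa;
    for (int i = 0; i < m; ++i) {
      double kii = 0.0, cross = 0.0;
      for (int k = Kp[i]; k < Kp[i + 1]; ++k) {
        int row = Ki[k];
        if (row == i) kii = Kx[k];
        else cross += Kx[k] * u[row];
      }
      if (kii <= 0.0) stop("K-inverse has a non-positive diagonal at animal %d",
                           i + 1);
      double ni = (double) rec[i].size();
      double rhs_data = 0.0;
      for (int r : rec[i]) rhs_data += e[r];
      rhs_data += ni * u[i];
      double prec = ni / se + kii / sa;
      double mean = (rhs_data / se - cross / sa) / prec;
      double un = mean + norm_rand() / std::sqrt(prec);
      double diff = un - u[i];
      if (diff != 0.0) for (int r : rec[i]) e[r] -= diff;
      u[i] = un;
    }
    // sigma2_a | u  ~  (u'K^-1 u + nu S2) / chisq(m + nu)
    double uKu = 0.0;
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int k = Kp[i]; k < Kp[i + 1]; ++k) s += Kx[k] * u[Ki[k]];
      uKu += s * u[i];
    }
    sa = (uKu + nu_a * S2a) / R::rchisq(df_a);
    // sigma2_e | e
    double ee = 0.0;
    for (int r = 0; r < n; ++r) ee += e[r] * e[r];
    se = (ee + nu_e * S2e) / R::rchisq(df_e);

    if (!R_finite(sa) || !R_finite(se) || sa > 1e12 || se > 1e12 ||
        sa <= 0.0 || se <= 0.0)
      stop("Gibbs chain diverged at iteration %d (sigma2_a = %g, sigma2_e = %g)",
           it, sa, se);

    if (it > burn && (it - burn) % thin == 0) {
      sa_trace[stored] = sa;
      se_trace[stored] = se;
      for (int f = 0; f < focal.size(); ++f)
        u_focal(f, stored) = u[focal[f] - 1];
      for (int i = 0; i < m; ++i) u_mean[i] += u[i];
      ++stored;
    }
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  if (stored > 0)
    for (int i = 0; i < m; ++i) u_mean[i] /= stored;

  return List::create(_["sigma2_a"] = sa_trace,
                      _["sigma2_e"] = se_trace,
                      _["u_focal"] = u_focal,
                      _["u_mean"] = u_mean,
                      _["n_kept"] = stored);
}

// Gene dropping: transmit one uniformly chosen parental allele per locus.
// Haplotypes are integer matrices (animals x loci) built in pedigree order;
// founders are filled in beforehand by the caller.
//
// [[Rcpp::export]]
void gene_drop_cpp(IntegerMatrix h1, IntegerMatrix h2,
                   const IntegerVector& sire, const IntegerVector& dam) {
  const int n = h1.nrow(), mloc = h1.ncol();
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s == 0 && d == 0) continue;  // founder, already filled
    if (s == 0 || d == 0)
      stop("gene dropping requires both parents known for non-founders (animal %d)",
           i + 1);
    for (int l = 0; l < mloc; ++l) {
      h1(i, l) = (unif_rand() < 0.5) ? h1(s - 1, l) : h2(s - 1, l);
      h2(i, l) = (unif_rand() < 0.5) ? h1(d - 1, l) : h2(d - 1, l);
    }
  }
}
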
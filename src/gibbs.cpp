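// Single-site Gibbs sampler for linear / threshold colony models.
//
// State: augmented data z (observed continuous values, liabilities for
// threshold traits, conditional draws for missing traits), location
// effects (fixed columns, year x apiary cells, genetic effects with a
// G0 (x) A covariance over the pedigree), and the (co)variance
// components. All randomness comes from R's RNG so set.seed() on the R
// side makes chains bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rnorm1() { return R::norm_rand(); }

// truncated normal on (lo, hi) via inverse CDF with tail safeguards
static double rtruncnorm(double mu, double sd, double lo, double hi,
                         int *clamped) {
  double a = R::pnorm((lo - mu) / sd, 0.0, 1.0, 1, 0);
  double b = R::pnorm((hi - mu) / sd, 0.0, 1.0, 1, 0);
  if (b - a < 1e-14) { // far tail: clamp to the nearer boundary
    (*clamped)++;
    if (std::isfinite(lo) && (!std::isfinite(hi) || std::fabs(mu - lo) < std::fabs(mu - hi)))
      return lo + 1e-8 * sd;
    return hi - 1e-8 * sd;
  }
  double u = a + (b - a) * R::unif_rand();
  double zq = R::qnorm(u, 0.0, 1.0, 1, 0);
  double out = mu + sd * zq;
  if (!std::isfinite(out)) { (*clamped)++; out = mu; }
  return out;
}

// Wishart draw, Bartlett decomposition; S is the scale (covariance) matrix
static arma::mat rwishart(double df, const arma::mat &S) {
  int p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = rnorm1();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// inverse-Wishart posterior draw IW(Sscale, df) with jitter fallback
static arma::mat riwish_safe(double df, arma::mat Sscale, int *npd) {
  int p = Sscale.n_rows;
  for (int attempt = 0; attempt < 50; ++attempt) {
    arma::mat Sinv, W;
    bool ok = arma::inv_sympd(Sinv, Sscale);
    if (ok) {
      try {
        W = rwishart(df, Sinv);
        arma::mat out;
        if (arma::inv_sympd(out, W)) return out;
      } catch (...) { /* fall through to jitter */ }
    }
    (*npd)++;
    Sscale += (1e-8 * arma::trace(Sscale) / p + 1e-12) *
              arma::eye(p, p);
  }
  stop("Covariance sampling failed: scale matrix not positive definite.");
}

struct ColGroup {            // one incidence column (fixed or cell)
  std::vector<int> rec;      // 0-based record indices
};

// [[Rcpp::export]]
List gibbs_sampler_cpp(arma::mat z,              // n x T augmented data init
                       IntegerMatrix category,   // n x T: 1..K cat, 0 linear obs, -1 missing
                       IntegerVector trait_type, // T: 0 linear, 1 threshold
                       IntegerVector n_cat,      // per trait
                       IntegerVector scheme,     // per trait: 0 fix2, 1 unitvar
                       List fixed_cols,          // list of 1-based record index vectors
                       List cell_cols,
                       IntegerMatrix gen_carrier, // n x g, 1-based pedigree index
                       IntegerVector A_i, IntegerVector A_p, NumericVector A_x, // CSC of A-inverse (both triangles)
                       int q,                    // pedigree size
                       arma::mat G0, arma::mat R0,
                       arma::vec cellvar,        // per trait
                       arma::mat thr_init,       // (Kmax-1) x T thresholds (NA-free padding)
                       int n_iter, int burn_in, int thin,
                       bool update_variances, bool sample_residual) {
  const int n = z.n_rows, T = z.n_cols;
  const int g = gen_carrier.ncol();
  const int m = g * T; // genetic columns, c = k*T + t
  const int nfix = fixed_cols.size(), ncell = cell_cols.size();
  int clamped = 0, npd = 0;

  std::vector<ColGroup> fix(nfix), cell(ncell);
  for (int f = 0; f < nfix; ++f) {
    IntegerVector v = fixed_cols[f];
    fix[f].rec.assign(v.begin(), v.end());
    for (auto &r : fix[f].rec) r -= 1;
  }
  for (int f = 0; f < ncell; ++f) {
    IntegerVector v = cell_cols[f];
    cell[f].rec.assign(v.begin(), v.end());
    for (auto &r : cell[f].rec) r -= 1;
  }
  // CSR of records per (sub-effect, pedigree individual)
  std::vector<std::vector<std::vector<int>>> gen_rec(
      g, std::vector<std::vector<int>>(q));
  for (int k = 0; k < g; ++k)
    for (int r = 0; r < n; ++r) gen_rec[k][gen_carrier(r, k) - 1].push_back(r);

  arma::mat B_fix(nfix, T, arma::fill::zeros);
  arma::mat B_cell(ncell, T, arma::fill::zeros);
  arma::mat U(q, m, arma::fill::zeros);
  arma::mat E = z; // residual = z - fitted; fitted starts at 0
  arma::mat thr = thr_init; // rows: threshold index 1..K-1 (0-based), cols: traits

  const int Kmax = thr.n_rows + 1;
  arma::mat u_mean(q, m, arma::fill::zeros);
  int n_kept_u = 0;
  const int n_store = (n_iter - burn_in) / thin;
  // stored: G0 upper tri, cellvar, R0 upper tri, thresholds (K-1 per threshold trait)
  int p_g = m * (m + 1) / 2, p_r = T * (T + 1) / 2;
  int p_thr = 0;
  for (int t = 0; t < T; ++t) if (trait_type[t] == 1) p_thr += n_cat[t] - 1;
  arma::mat store(n_store, p_g + T + p_r + p_thr);
  int stored = 0;

  arma::mat Rinv = arma::inv_sympd(R0);
  arma::mat G0inv = arma::inv_sympd(G0);

  GetRNGstate();
  for (int it = 0; it < n_iter; ++it) {
    // ---- 1. liabilities and missing values ------------------------------
    for (int t = 0; t < T; ++t) {
      if (trait_type[t] == 0) { // linear: only missing records are drawn
        bool any_missing = false;
        for (int r = 0; r < n; ++r) if (category(r, t) == -1) { any_missing = true; break; }
        if (!any_missing) continue;
      }
      // conditional residual regression on the other traits
      arma::vec w(T, arma::fill::zeros);
      double cvar = R0(t, t);
      if (T > 1) {
        arma::uvec oth(T - 1);
        int c2 = 0;
        for (int s = 0; s < T; ++s) if (s != t) oth(c2++) = s;
        arma::mat Roo = R0.submat(oth, oth);
        arma::vec rot = R0.col(t); arma::vec rto = rot.elem(oth);
        arma::vec wv = arma::solve(Roo, rto);
        cvar = R0(t, t) - arma::dot(rto, wv);
        for (int s = 0; s < (int)oth.n_elem; ++s) w(oth(s)) = wv(s);
      }
      double csd = std::sqrt(std::max(cvar, 1e-300));
      for (int r = 0; r < n; ++r) {
        int cat = category(r, t);
        if (cat == 0) continue; // observed continuous value stays fixed
        double fitted = z(r, t) - E(r, t);
        double adj = 0.0;
        for (int s = 0; s < T; ++s) if (s != t) adj += w(s) * E(r, s);
        double cmu = fitted + adj;
        double znew;
        if (cat == -1) {
          znew = cmu + csd * rnorm1();
        } else {
          double lo = (cat == 1) ? R_NegInf : thr(cat - 2, t);
          double hi = (cat == n_cat[t]) ? R_PosInf : thr(cat - 1, t);
          znew = rtruncnorm(cmu, csd, lo, hi, &clamped);
        }
        E(r, t) += znew - z(r, t);
        z(r, t) = znew;
      }
    }
    // ---- 2. fixed and cell effects --------------------------------------
    for (int t = 0; t < T; ++t) {
      for (int f = 0; f < nfix; ++f) {
        const std::vector<int> &S = fix[f].rec;
        double num = 0.0;
        for (int r : S)
          for (int s = 0; s < T; ++s) num += Rinv(t, s) * E(r, s);
        num += S.size() * Rinv(t, t) * B_fix(f, t);
        double d = S.size() * Rinv(t, t);
        double bn = num / d + rnorm1() / std::sqrt(d);
        double diff = bn - B_fix(f, t);
        B_fix(f, t) = bn;
        for (int r : S) E(r, t) -= diff;
      }
      for (int f = 0; f < ncell; ++f) {
        const std::vector<int> &S = cell[f].rec;
        double num = 0.0;
        for (int r : S)
          for (int s = 0; s < T; ++s) num += Rinv(t, s) * E(r, s);
        num += S.size() * Rinv(t, t) * B_cell(f, t);
        double d = S.size() * Rinv(t, t) + 1.0 / cellvar(t);
        double bn = num / d + rnorm1() / std::sqrt(d);
        double diff = bn - B_cell(f, t);
        B_cell(f, t) = bn;
        for (int r : S) E(r, t) -= diff;
      }
    }
    // ---- 3. genetic effects ---------------------------------------------
    for (int j = 0; j < q; ++j) {
      // s(c) = sum over A-inverse row j of a_{j,j2} * U(j2, c)
      arma::rowvec srow(m, arma::fill::zeros);
      double ajj = 0.0;
      for (int idx = A_p[j]; idx < A_p[j + 1]; ++idx) {
        int j2 = A_i[idx];
        double a = A_x[idx];
        if (j2 == j) ajj = a;
        srow += a * U.row(j2);
      }
      for (int c = 0; c < m; ++c) {
        int t = c % T, k = c / T;
        const std::vector<int> &S = gen_rec[k][j];
        double num = 0.0;
        for (int r : S)
          for (int s = 0; s < T; ++s) num += Rinv(t, s) * E(r, s);
        num += S.size() * Rinv(t, t) * U(j, c);
        double prior_num = -(arma::dot(G0inv.row(c), srow) -
                             G0inv(c, c) * ajj * U(j, c));
        double d = S.size() * Rinv(t, t) + G0inv(c, c) * ajj;
        double un = (num + prior_num) / d + rnorm1() / std::sqrt(d);
        double diff = un - U(j, c);
        U(j, c) = un;
        srow(c) += ajj * diff;
        for (int r : S) E(r, t) -= diff;
      }
    }
    // ---- 4. variance components -----------------------------------------
    if (update_variances) {
      for (int t = 0; t < T; ++t) {
        double ss = arma::dot(B_cell.col(t), B_cell.col(t));
        cellvar(t) = ss / R::rchisq((double)ncell - 2.0);
      }
      // S_u = U' A^-1 U via CSC pass
      arma::mat AU(q, m, arma::fill::zeros);
      for (int j = 0; j < q; ++j)
        for (int idx = A_p[j]; idx < A_p[j + 1]; ++idx)
          AU.row(j) += A_x[idx] * U.row(A_i[idx]);
      arma::mat Su = U.t() * AU;
      Su = (Su + Su.t()) / 2;
      G0 = riwish_safe((double)q - m - 1.0, Su, &npd);
      G0inv = arma::inv_sympd(G0);
      if (sample_residual) {
        arma::mat Se = E.t() * E;
        Se = (Se + Se.t()) / 2;
        R0 = riwish_safe((double)n - T - 1.0, Se, &npd);
        Rinv = arma::inv_sympd(R0);
      }
    }
    // ---- 5. thresholds ---------------------------------------------------
    for (int t = 0; t < T; ++t) {
      if (trait_type[t] != 1) continue;
      int K = n_cat[t];
      int first_free = (scheme[t] == 0) ? 2 : 1; // 0-based threshold index
      if (first_free > K - 2) continue;           // nothing free
      arma::vec catmin(K + 1), catmax(K + 1);
      catmin.fill(R_PosInf); catmax.fill(R_NegInf);
      for (int r = 0; r < n; ++r) {
        int cat = category(r, t);
        if (cat < 1) continue;
        if (z(r, t) < catmin(cat)) catmin(cat) = z(r, t);
        if (z(r, t) > catmax(cat)) catmax(cat) = z(r, t);
      }
      for (int c = first_free; c <= K - 2; ++c) { // threshold t_{c+1}, 0-based c
        double lo = catmax(c + 1);
        double hi = catmin(c + 2);
        if (c > 0) lo = std::max(lo, thr(c - 1, t));
        if (c < K - 2) hi = std::min(hi, thr(c + 1, t));
        if (std::isfinite(lo) && std::isfinite(hi) && hi > lo)
          thr(c, t) = lo + (hi - lo) * R::unif_rand();
      }
    }
    // ---- 6. store --------------------------------------------------------
    if (it >= burn_in) {
      u_mean += U;
      n_kept_u++;
      if ((it - burn_in) % thin == 0 && stored < n_store) {
        int col = 0;
        for (int a = 0; a < m; ++a)
          for (int b = a; b < m; ++b) store(stored, col++) = G0(a, b);
        for (int t = 0; t < T; ++t) store(stored, col++) = cellvar(t);
        for (int a = 0; a < T; ++a)
          for (int b = a; b < T; ++b) store(stored, col++) = R0(a, b);
        for (int t = 0; t < T; ++t) {
          if (trait_type[t] != 1) continue;
          for (int c = 0; c < n_cat[t] - 1; ++c)
            store(stored, col++) = thr(c, t);
        }
        stored++;
      }
    }
  }
  PutRNGstate();
  if (n_kept_u > 0) u_mean /= (double)n_kept_u;
  return List::create(_["samples"] = store.rows(0, stored - 1),
                      _["u_mean"] = u_mean,
                      _["clamped"] = clamped,
                      _["n_not_pd"] = npd);
}
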
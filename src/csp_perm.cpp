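// Fast path for the block-permutation null of the sub-blocked CSP
// cross-validation: the full fold loop (CSP eigendecomposition,
// log-variance features, SMOTE balancing, shrinkage LDA, rank AUC) run
// once per permuted label series. Mirrors the R implementation; parity on
// balanced folds (where SMOTE is a no-op) is covered by a unit test.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// chronological sub-blocked folds, 0-based; remainder epochs appended to
// the final chunk of each sub-block (same rule as the R code)
std::vector<uvec> subblocked_folds(int n, int n_subblocks, int k) {
  int sb_len = n / n_subblocks;
  int chunk = sb_len / k;
  std::vector<uvec> folds(k);
  for (int f = 0; f < k; ++f) {
    std::vector<uword> idx;
    for (int b = 0; b < n_subblocks; ++b) {
      int start = b * sb_len;
      int lo = start + f * chunk;
      int hi;
      if (f == k - 1) {
        hi = (b == n_subblocks - 1) ? n : start + sb_len;
      } else {
        hi = start + (f + 1) * chunk;
      }
      for (int i = lo; i < hi; ++i) idx.push_back(i);
    }
    folds[f] = uvec(idx);
  }
  return folds;
}

mat whiten(const mat& C, double tol) {
  vec d; mat U;
  eig_sym(d, U, (C + C.t()) / 2);
  uvec keep = find(d > tol * d.max());
  if (keep.n_elem < 2) Rcpp::stop("covariance rank < 2 after truncation");
  return U.cols(keep) * diagmat(1.0 / sqrt(d.elem(keep)));
}

// CSP filters for the four feature components (two per end, descending
// eigenvalue order), from class-mean covariances.
mat csp_filters(const cube& C, const uvec& tr, const std::vector<int>& yhi) {
  const uword p = C.n_rows;
  mat C_hi(p, p, fill::zeros), C_lo(p, p, fill::zeros);
  int n_hi = 0, n_lo = 0;
  for (uword i = 0; i < tr.n_elem; ++i) {
    if (yhi[tr(i)]) { C_hi += C.slice(tr(i)); ++n_hi; }
    else { C_lo += C.slice(tr(i)); ++n_lo; }
  }
  if (n_hi < 2 || n_lo < 2) Rcpp::stop("need at least 2 epochs per class");
  C_hi /= n_hi; C_lo /= n_lo;
  mat P = whiten(C_hi + C_lo, 1e-10);
  mat M = P.t() * C_hi * P;
  vec d; mat V;
  eig_sym(d, V, (M + M.t()) / 2);          // ascending
  mat W = P * V;
  const uword m = W.n_cols;
  // descending order: top two = last two ascending, bottom two = first two
  uvec pick = {m - 1, m - 2, 1, 0};
  if (m < 2) Rcpp::stop("fewer than 2 components");
  return W.cols(pick);
}

mat log_var_features(const cube& C, const uvec& idx, const mat& W) {
  mat F(idx.n_elem, W.n_cols);
  for (uword i = 0; i < idx.n_elem; ++i) {
    const mat& Ce = C.slice(idx(i));
    for (uword j = 0; j < W.n_cols; ++j) {
      double v = as_scalar(W.col(j).t() * Ce * W.col(j));
      F(i, j) = std::log(std::max(v, 1e-12));
    }
  }
  return F;
}

// SMOTE: balance classes by convex combinations of minority points with
// one of their k nearest minority neighbours.
void smote(mat& F, std::vector<int>& yhi, int k_neighbors,
           std::mt19937& rng) {
  int n_hi = 0;
  for (int v : yhi) n_hi += v;
  int n_lo = yhi.size() - n_hi;
  if (n_hi == n_lo) return;
  int minority = (n_hi < n_lo) ? 1 : 0;
  int need = std::abs(n_hi - n_lo);
  std::vector<uword> mi;
  for (uword i = 0; i < yhi.size(); ++i)
    if (yhi[i] == minority) mi.push_back(i);
  mat synth(need, F.n_cols);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> pick_base(0, mi.size() - 1);
  int kn = std::min<int>(k_neighbors, mi.size() - 1);
  if (kn < 1) kn = 1;
  std::uniform_int_distribution<int> pick_nn(0, kn - 1);
  for (int s = 0; s < need; ++s) {
    int bi = (mi.size() > 1) ? pick_base(rng) : 0;
    rowvec xb = F.row(mi[bi]);
    if (mi.size() == 1) { synth.row(s) = xb; continue; }
    vec d(mi.size());
    for (uword j = 0; j < mi.size(); ++j)
      d(j) = accu(square(F.row(mi[j]) - xb));
    d(bi) = datum::inf;
    uvec ord = sort_index(d);
    uword nn = mi[ord(pick_nn(rng))];
    double u = unif(rng);
    synth.row(s) = xb + u * (F.row(nn) - xb);
  }
  F = join_cols(F, synth);
  for (int s = 0; s < need; ++s) yhi.push_back(minority);
}

// shrinkage LDA scores (Ledoit-Wolf analytic intensity, identity target)
vec lda_scores(const mat& Ftr, const std::vector<int>& yhi, const mat& Fte) {
  const uword p = Ftr.n_cols;
  rowvec mu0(p, fill::zeros), mu1(p, fill::zeros);
  int n0 = 0, n1 = 0;
  for (uword i = 0; i < Ftr.n_rows; ++i) {
    if (yhi[i]) { mu1 += Ftr.row(i); ++n1; } else { mu0 += Ftr.row(i); ++n0; }
  }
  mu0 /= n0; mu1 /= n1;
  mat Xc(Ftr.n_rows, p);
  for (uword i = 0; i < Ftr.n_rows; ++i)
    Xc.row(i) = Ftr.row(i) - (yhi[i] ? mu1 : mu0);
  const double n = Xc.n_rows;
  mat S = Xc.t() * Xc / n;
  double m = trace(S) / p;
  mat T = S; T.diag() -= m;
  double d2 = accu(square(T));
  vec q = sum(square(Xc), 1);
  vec xSx = sum((Xc * S) % Xc, 1);
  double b2bar = (accu(square(q)) - 2 * accu(xSx) + n * accu(square(S))) /
                 (n * n);
  double rho = (d2 > 0) ? std::min(b2bar, d2) / d2 : 1.0;
  mat Sigma = (1 - rho) * S;
  Sigma.diag() += rho * m;
  vec w = solve(Sigma, (mu1 - mu0).t());
  double b = -0.5 * dot(w, (mu1 + mu0).t());
  return Fte * w + b;
}

// tie-corrected Mann-Whitney AUC
double rank_auc(const vec& scores, const std::vector<int>& yhi) {
  const uword n = scores.n_elem;
  uvec ord = sort_index(scores);
  vec ranks(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && scores(ord(j + 1)) == scores(ord(i))) ++j;
    double r = (i + j) / 2.0 + 1.0;
    for (uword t = i; t <= j; ++t) ranks(ord(t)) = r;
    i = j + 1;
  }
  double rsum = 0; int n_pos = 0;
  for (uword t = 0; t < n; ++t)
    if (yhi[t]) { rsum += ranks(t); ++n_pos; }
  int n_neg = n - n_pos;
  if (n_pos == 0 || n_neg == 0) return datum::nan;
  return (rsum - n_pos * (n_pos + 1.0) / 2.0) / (double(n_pos) * n_neg);
}

double subblocked_auc_metric(const cube& C, const std::vector<int>& yhi,
                             const std::vector<uvec>& folds, int n,
                             int smote_k, unsigned smote_seed) {
  double auc_sum = 0; int auc_n = 0;
  for (uword f = 0; f < folds.size(); ++f) {
    const uvec& te = folds[f];
    std::vector<uword> trv;
    std::vector<bool> iste(n, false);
    for (uword i = 0; i < te.n_elem; ++i) iste[te(i)] = true;
    for (int i = 0; i < n; ++i) if (!iste[i]) trv.push_back(i);
    uvec tr(trv);
    mat W = csp_filters(C, tr, yhi);
    mat Ftr = log_var_features(C, tr, W);
    mat Fte = log_var_features(C, te, W);
    std::vector<int> ytr(tr.n_elem), yte(te.n_elem);
    for (uword i = 0; i < tr.n_elem; ++i) ytr[i] = yhi[tr(i)];
    for (uword i = 0; i < te.n_elem; ++i) yte[i] = yhi[te(i)];
    std::mt19937 rng(smote_seed + 1000003u * f);
    smote(Ftr, ytr, smote_k, rng);
    vec s = lda_scores(Ftr, ytr, Fte);
    double a = rank_auc(s, yte);
    if (std::isfinite(a)) { auc_sum += a; ++auc_n; }
  }
  return auc_n ? auc_sum / auc_n : datum::nan;
}

}  // namespace

// [[Rcpp::export(name = ".csp_blockperm_cpp")]]
Rcpp::List csp_blockperm_cpp(const arma::cube& C,
                             const Rcpp::IntegerVector& y_high,
                             int n_subblocks, int k, int n_blocks,
                             int n_perm, int seed, int smote_k = 5) {
  const int n = y_high.size();
  std::vector<int> yhi(y_high.begin(), y_high.end());
  std::vector<uvec> folds = subblocked_folds(n, n_subblocks, k);
  unsigned sseed = static_cast<unsigned>(seed);
  double observed = subblocked_auc_metric(C, yhi, folds, n, smote_k, sseed);
  // contiguous blocks, first blocks take the remainder (ceiling sizes)
  int base = n / n_blocks, rem = n % n_blocks;
  std::vector<std::pair<int, int>> blocks;
  int pos = 0;
  for (int b = 0; b < n_blocks; ++b) {
    int len = base + (b < rem ? 1 : 0);
    blocks.push_back({pos, len});
    pos += len;
  }
  std::mt19937 rng(sseed + 7919u);
  vec null(n_perm);
  std::vector<int> order(n_blocks);
  for (int b = 0; b < n_blocks; ++b) order[b] = b;
  int n_ge = 0;
  for (int p = 0; p < n_perm; ++p) {
    std::shuffle(order.begin(), order.end(), rng);
    std::vector<int> yp;
    yp.reserve(n);
    for (int b = 0; b < n_blocks; ++b)
      for (int i = 0; i < blocks[order[b]].second; ++i)
        yp.push_back(yhi[blocks[order[b]].first + i]);
    null(p) = subblocked_auc_metric(C, yp, folds, n, smote_k,
                                    sseed + 31u * (p + 1));
    if (null(p) >= observed) ++n_ge;
  }
  return Rcpp::List::create(
      Rcpp::Named("observed") = observed,
      Rcpp::Named("null") = null,
      Rcpp::Named("p_value") = (n_ge + 1.0) / (n_perm + 1.0));
}
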
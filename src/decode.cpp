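// Fast inner loops for pairwise LDA decoding and cluster search.
// LDA convention: w = solve(S_pooled + ridge*I, muA - muB); a sample x is
// assigned to class A iff w.(x - (muA+muB)/2) >= 0 (ties to the first class).
#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static vec lda_w(const rowvec& muA, const rowvec& muB, mat S, double n_eff,
                 double ridge_frac) {
  S /= n_eff;
  double lam = ridge_frac * trace(S) / S.n_rows + 1e-300;
  S.diag() += lam;
  return solve(S, (muA - muB).t());
}

// Leave-one-per-class-out CV accuracy over all k*k folds.
static double cv_pair(const mat& A, const mat& B, double ridge_frac) {
  const uword k = A.n_rows, p = A.n_cols;
  rowvec sumA = sum(A, 0), sumB = sum(B, 0);
  mat TA = A.t() * A, TB = B.t() * B;
  const double m = (double)(k - 1);
  double acc = 0.0;
  for (uword i = 0; i < k; ++i) {
    rowvec ai = A.row(i);
    rowvec muA = (sumA - ai) / m;
    mat SA = TA - ai.t() * ai - m * (muA.t() * muA);
    for (uword j = 0; j < k; ++j) {
      rowvec bj = B.row(j);
      rowvec muB = (sumB - bj) / m;
      mat SB = TB - bj.t() * bj - m * (muB.t() * muB);
      vec w = lda_w(muA, muB, SA + SB, 2.0 * m - 2.0, ridge_frac);
      double b = dot(w, 0.5 * (muA + muB).t());
      double correct = 0.0;
      if (dot(w, ai.t()) - b >= 0) correct += 1.0;
      if (dot(w, bj.t()) - b < 0) correct += 1.0;
      acc += 0.5 * correct;
    }
  }
  return acc / (double)(k * k);
}

// [[Rcpp::export]]
double cpp_cv_accuracy(const arma::mat& A, const arma::mat& B,
                       double ridge_frac) {
  if (A.n_rows != B.n_rows || A.n_cols != B.n_cols)
    Rcpp::stop("pseudo-trial count/feature mismatch between classes");
  return cv_pair(A, B, ridge_frac);
}

static mat slice_bin(const cube& X, uword t) {
  // X: pseudo x time x pc -> k x p matrix at time t
  mat out(X.n_rows, X.n_slices);
  for (uword j = 0; j < X.n_slices; ++j) out.col(j) = X.slice(j).col(t);
  return out;
}

// CV accuracy at each timebin; A, B are (pseudo x time x pc) cubes.
// [[Rcpp::export]]
arma::vec cpp_cv_accuracy_tc(const arma::cube& A, const arma::cube& B,
                             double ridge_frac) {
  if (A.n_cols != B.n_cols) Rcpp::stop("timebin mismatch between classes");
  vec out(A.n_cols);
  for (uword t = 0; t < A.n_cols; ++t)
    out(t) = cv_pair(slice_bin(A, t), slice_bin(B, t), ridge_frac);
  return out;
}

// Temporal generalization: train on (A vs B) at each t1 using all
// pseudo-trials, test on (C vs D) at each t2 with class correspondence
// A<->C, B<->D. If same_pair, diagonal cells are replaced by the
// leave-one-per-class-out CV accuracy to avoid testing on training samples.
// [[Rcpp::export]]
arma::mat cpp_generalization(const arma::cube& A, const arma::cube& B,
                             const arma::cube& C, const arma::cube& D,
                             double ridge_frac, bool same_pair) {
  const uword T = A.n_cols, p = A.n_slices;
  mat out(T, T);
  for (uword t1 = 0; t1 < T; ++t1) {
    mat At = slice_bin(A, t1), Bt = slice_bin(B, t1);
    rowvec muA = mean(At, 0), muB = mean(Bt, 0);
    mat SA = At.t() * At - (double)At.n_rows * (muA.t() * muA);
    mat SB = Bt.t() * Bt - (double)Bt.n_rows * (muB.t() * muB);
    vec w = lda_w(muA, muB, SA + SB,
                  (double)(At.n_rows + Bt.n_rows - 2), ridge_frac);
    double b = dot(w, 0.5 * (muA + muB).t());
    for (uword t2 = 0; t2 < T; ++t2) {
      if (same_pair && t1 == t2) {
        out(t1, t2) = cv_pair(At, Bt, ridge_frac);
        continue;
      }
      mat Ct = slice_bin(C, t2), Dt = slice_bin(D, t2);
      vec sc = Ct * w;
      double accC = mean(conv_to<vec>::from(sc - b >= 0));
      vec sd_ = Dt * w;
      double accD = mean(conv_to<vec>::from(sd_ - b < 0));
      out(t1, t2) = 0.5 * (accC + accD);
    }
  }
  return out;
}

// Discriminant normals per timebin, trained on all pseudo-trials.
// A, B: (pseudo x time x pc) cubes; returns (time x pc) matrix of w.
// [[Rcpp::export]]
arma::mat cpp_lda_normals(const arma::cube& A, const arma::cube& B,
                          double ridge_frac) {
  const uword T = A.n_cols, p = A.n_slices;
  mat out(T, p);
  for (uword t = 0; t < T; ++t) {
    mat At = slice_bin(A, t), Bt = slice_bin(B, t);
    rowvec muA = mean(At, 0), muB = mean(Bt, 0);
    mat SA = At.t() * At - (double)At.n_rows * (muA.t() * muA);
    mat SB = Bt.t() * Bt - (double)Bt.n_rows * (muB.t() * muB);
    out.row(t) = lda_w(muA, muB, SA + SB,
                       (double)(At.n_rows + Bt.n_rows - 2),
                       ridge_frac).t();
  }
  return out;
}

// Label 4-connected clusters of nonzero cells; returns an integer matrix of
// labels (0 = background) with labels ordered by first visit (column-major).
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_label_clusters(const Rcpp::IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  Rcpp::IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int>> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
        for (int d = 0; d < 4; ++d) {
          int rr = r + dr[d], cc = c + dc[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}

// Maximal 4-connected cluster size of nonzero cells.
// [[Rcpp::export]]
int cpp_max_cluster_size(const Rcpp::IntegerMatrix& mask) {
  Rcpp::IntegerMatrix lab = cpp_label_clusters(mask);
  int mx = 0;
  std::map<int, int> cnt;
  for (int k = 0; k < lab.size(); ++k)
    if (lab[k] > 0) mx = std::max(mx, ++cnt[lab[k]]);
  return mx;
}
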
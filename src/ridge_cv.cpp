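// Ridge-penalized logistic scorer and stratified cross-validated AUC.
// The forward-selection loop evaluates every candidate panel over
// n_repeats x n_folds training fits, so the inner loop lives here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Mann-Whitney AUC with ties counted 0.5, via midranks.
static double auc_from_scores(const vec& s, const uvec& y) {
  const uword n = s.n_elem;
  uvec ord = sort_index(s);
  vec ranks(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && s(ord(j + 1)) == s(ord(i))) ++j;
    double midrank = 0.5 * ((i + 1) + (j + 1));
    for (uword k = i; k <= j; ++k) ranks(ord(k)) = midrank;
    i = j + 1;
  }
  double n1 = accu(y), n0 = n - n1;
  if (n1 == 0 || n0 == 0) return datum::nan;
  double rank_sum = 0;
  for (uword k = 0; k < n; ++k) if (y(k) == 1) rank_sum += ranks(k);
  return (rank_sum - n1 * (n1 + 1) / 2.0) / (n1 * n0);
}

// Ridge logistic IRLS on standardized columns; intercept unpenalized.
// Returns coefficients (intercept first) on the standardized scale.
static vec irls_ridge(const mat& Xs, const vec& y, double lambda) {
  const uword n = Xs.n_rows, p = Xs.n_cols;
  mat A(n, p + 1, fill::ones);
  A.cols(1, p) = Xs;
  vec beta(p + 1, fill::zeros);
  mat pen(p + 1, p + 1, fill::zeros);
  for (uword j = 1; j <= p; ++j) pen(j, j) = lambda;
  for (int iter = 0; iter < 50; ++iter) {
    vec eta = A * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w = clamp(w, 1e-6, 0.25);
    vec z = eta + (y - mu) / w;
    mat Aw = A.each_col() % w;
    vec beta_new = solve(A.t() * Aw + pen, A.t() * (w % z),
                         solve_opts::likely_sympd);
    double step = max(abs(beta_new - beta));
    beta = beta_new;
    if (step < 1e-8) break;
  }
  return beta;
}

struct Standardizer {
  rowvec center, scale;
};

// Center/scale learned on training rows only; constant columns get
// scale 1 so they contribute a zero column (weight shrinks to 0).
static Standardizer learn_standardizer(const mat& Xtr) {
  Standardizer s;
  s.center = mean(Xtr, 0);
  s.scale = stddev(Xtr, 0, 0);
  s.scale.elem(find(s.scale < 1e-12)).ones();
  return s;
}

// [[Rcpp::export]]
Rcpp::List cpp_ridge_fit(const arma::mat& X, const arma::vec& y, double lambda) {
  Standardizer s = learn_standardizer(X);
  mat Xs = (X.each_row() - s.center).each_row() / s.scale;
  vec beta = irls_ridge(Xs, y, lambda);
  vec w_std = beta.subvec(1, beta.n_elem - 1);
  vec w_raw = w_std / s.scale.t();
  double b0 = beta(0) - dot(w_std, (s.center / s.scale).t());
  return Rcpp::List::create(
    Rcpp::Named("intercept") = b0,
    Rcpp::Named("weights") = w_raw,
    Rcpp::Named("weights_std") = w_std,
    Rcpp::Named("center") = s.center.t(),
    Rcpp::Named("scale") = s.scale.t());
}

// Held-out linear scores for one repeat's fold assignment (values 1..K).
static vec cv_scores_one_repeat(const mat& X, const vec& y,
                                const ivec& foldid, double lambda) {
  vec scores(X.n_rows, fill::zeros);
  int K = foldid.max();
  for (int k = 1; k <= K; ++k) {
    uvec test = find(foldid == k);
    uvec train = find(foldid != k);
    if (test.n_elem == 0) continue;
    mat Xtr = X.rows(train);
    Standardizer s = learn_standardizer(Xtr);
    mat Xtr_s = (Xtr.each_row() - s.center).each_row() / s.scale;
    vec beta = irls_ridge(Xtr_s, y.elem(train), lambda);
    mat Xte = X.rows(test);
    mat Xte_s = (Xte.each_row() - s.center).each_row() / s.scale;
    scores.elem(test) = beta(0) + Xte_s * beta.subvec(1, beta.n_elem - 1);
  }
  return scores;
}

// Per-repeat pooled-fold AUCs for one feature panel.
// foldids: n x R integer matrix of fold labels (1..K) per repeat.
// [[Rcpp::export]]
arma::vec cpp_cv_panel_aucs(const arma::mat& X, const arma::vec& y,
                            const arma::imat& foldids, double lambda) {
  const uword R = foldids.n_cols;
  uvec yi = conv_to<uvec>::from(y);
  vec aucs(R);
  for (uword r = 0; r < R; ++r) {
    vec scores = cv_scores_one_repeat(X, y, foldids.col(r), lambda);
    aucs(r) = auc_from_scores(scores, yi);
  }
  return aucs;
}

// Repeat-averaged CV AUC for every candidate added to the current panel.
// Xall: n x m matrix of all candidate expression columns; `current` and
// `candidates` are 0-based column indices into Xall.
// [[Rcpp::export]]
arma::vec cpp_candidate_mean_aucs(const arma::mat& Xall, const arma::vec& y,
                                  const arma::uvec& current,
                                  const arma::uvec& candidates,
                                  const arma::imat& foldids, double lambda) {
  vec out(candidates.n_elem);
  for (uword c = 0; c < candidates.n_elem; ++c) {
    uvec panel(current.n_elem + 1);
    if (current.n_elem) panel.subvec(0, current.n_elem - 1) = current;
    panel(current.n_elem) = candidates(c);
    mat X = Xall.cols(panel);
    out(c) = mean(cpp_cv_panel_aucs(X, y, foldids, lambda));
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_cv_scores(const arma::mat& X, const arma::vec& y,
                        const arma::ivec& foldid, double lambda) {
  return cv_scores_one_repeat(X, y, foldid, lambda);
}

// [[Rcpp::export]]
double cpp_auc(const arma::vec& scores, const arma::uvec& labels) {
  return auc_from_scores(scores, labels);
}
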
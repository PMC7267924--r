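// Hot numerical kernels: exact nearest-neighbour search, Parzen-window
// class densities and batched Euclidean projection onto the unit simplex.
// Distances use the expansion ||q - t||^2 = ||q||^2 + ||t||^2 - 2 q.t so
// the dominant cost is a BLAS gemm, blocked over query voxels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int QUERY_BLOCK = 2048;

// k-NN class-vote posteriors. train: n_t x m, query: n_q x m, labels in
// 0..nclass-1. Ties at the k-th distance are resolved by training-row
// order (stable): among equal distances the earlier row wins.
// [[Rcpp::export]]
arma::mat cpp_knn_posteriors(const arma::mat& train,
                             const arma::ivec& labels,
                             const arma::mat& query,
                             const int k, const int nclass) {
  const arma::uword nt = train.n_rows, nq = query.n_rows;
  if (train.n_cols != query.n_cols)
    stop("feature dimension mismatch between training and query data");
  if (k < 1 || (arma::uword)k > nt)
    stop("k must satisfy 1 <= k <= number of training rows");
  arma::mat post(nq, nclass, arma::fill::zeros);
  arma::vec tnorm = arma::sum(arma::square(train), 1);
  std::vector<std::pair<double, arma::uword>> best(k);
  for (arma::uword q0 = 0; q0 < nq; q0 += QUERY_BLOCK) {
    arma::uword q1 = std::min(q0 + (arma::uword)QUERY_BLOCK, nq) - 1;
    arma::mat Q = query.rows(q0, q1);
    arma::vec qnorm = arma::sum(arma::square(Q), 1);
    arma::mat D = -2.0 * (train * Q.t());       // nt x nb
    D.each_col() += tnorm;
    for (arma::uword j = 0; j < Q.n_rows; ++j) {
      const double* d = D.colptr(j);
      // partial selection of the k smallest, stable in training index
      arma::uword filled = 0;
      for (arma::uword i = 0; i < nt; ++i) {
        double di = d[i];
        if (filled < (arma::uword)k) {
          best[filled++] = std::make_pair(di, i);
          if (filled == (arma::uword)k)
            std::make_heap(best.begin(), best.end());
        } else if (di < best.front().first) {
          std::pop_heap(best.begin(), best.end());
          best.back() = std::make_pair(di, i);
          std::push_heap(best.begin(), best.end());
        }
        // strict '<' keeps the earliest row on ties at the k-th distance
      }
      for (arma::uword b = 0; b < filled; ++b)
        post(q0 + j, labels[best[b].second]) += 1.0;
    }
  }
  post /= (double)k;
  return post;
}

// Parzen-window posteriors: per class l, density(q) averaged over that
// class's training points with an isotropic Gaussian kernel of width h,
// multiplied by prior_l and normalised per row. Computed with a per-query
// shift by the minimal squared distance so h -> 0 degenerates smoothly to
// the 1-NN assignment instead of underflowing to 0/0.
// [[Rcpp::export]]
arma::mat cpp_parzen_posteriors(const arma::mat& train,
                                const arma::ivec& labels,
                                const arma::mat& query,
                                const double h, const int nclass,
                                const arma::vec& priors) {
  const arma::uword nt = train.n_rows, nq = query.n_rows;
  if (train.n_cols != query.n_cols)
    stop("feature dimension mismatch between training and query data");
  if (h <= 0) stop("h must be positive");
  arma::vec classn(nclass, arma::fill::zeros);
  for (arma::uword i = 0; i < nt; ++i) classn[labels[i]] += 1.0;
  arma::mat post(nq, nclass, arma::fill::zeros);
  arma::vec tnorm = arma::sum(arma::square(train), 1);
  const double inv2h2 = 1.0 / (2.0 * h * h);
  for (arma::uword q0 = 0; q0 < nq; q0 += QUERY_BLOCK) {
    arma::uword q1 = std::min(q0 + (arma::uword)QUERY_BLOCK, nq) - 1;
    arma::mat Q = query.rows(q0, q1);
    arma::vec qnorm = arma::sum(arma::square(Q), 1);
    arma::mat D = -2.0 * (train * Q.t());
    D.each_col() += tnorm;
    for (arma::uword j = 0; j < Q.n_rows; ++j) {
      const double* d = D.colptr(j);
      double dmin = d[0];
      for (arma::uword i = 1; i < nt; ++i) if (d[i] < dmin) dmin = d[i];
      arma::rowvec acc(nclass, arma::fill::zeros);
      for (arma::uword i = 0; i < nt; ++i)
        acc[labels[i]] += std::exp(-(d[i] - dmin) * inv2h2);
      for (int l = 0; l < nclass; ++l)
        if (classn[l] > 0) post(q0 + j, l) = priors[l] * acc[l] / classn[l];
    }
  }
  // row-normalise (the common exp(-(qnorm+dmin)/2h^2) factor cancels)
  for (arma::uword i = 0; i < nq; ++i) {
    double s = arma::accu(post.row(i));
    if (s > 0) post.row(i) /= s;
  }
  return post;
}

// Euclidean projection of every row onto the unit simplex (sort-based).
// [[Rcpp::export]]
arma::mat cpp_project_rows_simplex(const arma::mat& u) {
  const arma::uword n = u.n_rows, l = u.n_cols;
  arma::mat out(n, l);
  std::vector<double> v(l);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = 0; j < l; ++j) v[j] = u(i, j);
    std::vector<double> s(v);
    std::sort(s.begin(), s.end(), std::greater<double>());
    double cum = 0.0, theta = 0.0;
    int rho = 0;
    for (arma::uword j = 0; j < l; ++j) {
      cum += s[j];
      double t = (cum - 1.0) / (double)(j + 1);
      if (s[j] - t > 0) { rho = j + 1; theta = t; }
    }
    for (arma::uword j = 0; j < l; ++j)
      out(i, j) = std::max(v[j] - theta, 0.0);
    (void)rho;
  }
  return out;
}
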
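// Hot loops of the simulator and preprocessing stages. Everything here is
// a straight translation of the R contracts in R/simulate.R and
// R/preprocess.R; the R level owns all randomness and bookkeeping.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fused event synthesis: per-cell profile gather + Gaussian noise +
// per-sample additive offset and multiplicative gain, left-censored at
// zero, inverse-arcsinh-transformed to the raw scale.
// combo/subset/samp are 1-based row indices; eps is n*p column-major N(0,1).
// [[Rcpp::export]]
NumericMatrix cpp_synth_events(const NumericMatrix& prof,
                               const IntegerVector& combo,
                               const NumericMatrix& disp,
                               const IntegerVector& subset,
                               const NumericMatrix& addoff,
                               const NumericMatrix& gain,
                               const IntegerVector& samp,
                               const NumericVector& eps,
                               double cofactor) {
  const int n = combo.size(), p = prof.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double* ep = &eps[(size_t)j * n];
    double* oj = &out(0, j);
    for (int i = 0; i < n; ++i) {
      double v = prof(combo[i] - 1, j) + disp(subset[i] - 1, j) * ep[i] +
                 addoff(samp[i] - 1, j);
      v *= gain(samp[i] - 1, j);
      if (v < 0.0) v = 0.0;
      const double e = std::exp(v);          // sinh via one exp (v >= 0)
      oj[i] = cofactor * 0.5 * (e - 1.0 / e);
    }
  }
  return out;
}

// One anchor-based batch-correction pass: soft assignment of cells to
// anchor centroids (Gaussian kernel, bandwidth = median nearest squared
// distance), per-anchor per-batch location offsets subtracted, centroids
// refreshed. x is modified in place (the R wrapper passes its own copy);
// returns the centroids and the last sweep's RMS offset.
// [[Rcpp::export]]
List cpp_correct_batches(NumericMatrix x_, NumericMatrix centers_,
                         IntegerVector batch, int nb, int max_iter,
                         double tol) {
  arma::mat x(x_.begin(), x_.nrow(), x_.ncol(), false);
  arma::mat centers(centers_.begin(), centers_.nrow(), centers_.ncol());
  const arma::uword n = x.n_rows, K = centers.n_rows;
  std::vector<arma::uvec> rows_of(nb);
  {
    std::vector<std::vector<arma::uword>> tmp(nb);
    for (arma::uword i = 0; i < n; ++i) tmp[batch[i] - 1].push_back(i);
    for (int b = 0; b < nb; ++b)
      rows_of[b] = arma::uvec(tmp[b]);
  }
  double max_off = 0.0;
  for (int it = 0; it < max_iter; ++it) {
    arma::vec xx = arma::sum(arma::square(x), 1);
    arma::vec cc = arma::sum(arma::square(centers), 1);
    arma::mat r = x * centers.t();            // n x K gram
    for (arma::uword k = 0; k < K; ++k)       // r now holds d2
      r.col(k) = cc[k] - 2.0 * r.col(k) + xx;
    arma::vec dmin = arma::min(r, 1);
    arma::vec dsort = arma::sort(dmin);
    double bw = dsort[n / 2] + 1e-8;
    r.each_col() -= dmin;
    r = arma::exp(-r / bw);
    r.each_col() /= arma::sum(r, 1);
    arma::rowvec tot_w = arma::sum(r, 0);
    arma::mat glob = r.t() * x;
    glob.each_col() /= tot_w.t();
    max_off = 0.0;
    for (int b = 0; b < nb; ++b) {
      const arma::uvec& idx = rows_of[b];
      arma::mat rb = r.rows(idx);
      arma::rowvec wb = arma::sum(rb, 0);
      arma::mat offs = rb.t() * x.rows(idx);
      arma::uword used = 0;
      double ss = 0.0;
      for (arma::uword k = 0; k < K; ++k) {
        if (wb[k] > 1e-6) {
          offs.row(k) = offs.row(k) / wb[k] - glob.row(k);
          ss += arma::accu(arma::square(offs.row(k)));
          ++used;
        } else {
          offs.row(k).zeros();
        }
      }
      x.rows(idx) -= rb * offs;
      if (used > 0) {
        double rms = std::sqrt(ss / (used * x.n_cols));
        if (rms > max_off) max_off = rms;
      }
    }
    centers = r.t() * x;
    centers.each_col() /= tot_w.t();
    if (max_off < tol) break;
  }
  return List::create(Named("rms_offset") = max_off,
                      Named("centers") = centers);
}

// Counts per bin of sorted thresholds qs: bin j = #{qs[j] <= v < qs[j+1]},
// bin 0 = #{v < qs[0]}. Suffix sums give exceedance counts per threshold.
// [[Rcpp::export]]
NumericVector cpp_bin_counts(NumericVector v, NumericVector qs) {
  const R_xlen_t n = v.size();
  const int K = qs.size();
  NumericVector cnt(K + 1);
  const double* q0 = qs.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const int j = std::upper_bound(q0, q0 + K, v[i]) - q0;
    cnt[j] += 1.0;
  }
  return cnt;
}

// Single-pass arcsinh transform: asinh(x / cofactor).
// [[Rcpp::export]]
NumericMatrix cpp_asinh(NumericMatrix x, double cofactor) {
  const R_xlen_t n = x.size();
  NumericMatrix out(x.nrow(), x.ncol());
  const double* xi = x.begin();
  double* oi = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = xi[i] / cofactor, a = std::fabs(v);
    const double r = std::log(a + std::sqrt(a * a + 1.0));
    oi[i] = v < 0 ? -r : r;
  }
  out.attr("dimnames") = x.attr("dimnames");
  return out;
}

// Nearest-centroid assignment (1-based labels), blocked to bound memory.
// [[Rcpp::export]]
IntegerVector cpp_assign_nearest(NumericMatrix z_, NumericMatrix centroids_) {
  arma::mat z(z_.begin(), z_.nrow(), z_.ncol(), false);
  arma::mat c(centroids_.begin(), centroids_.nrow(), centroids_.ncol(),
              false);
  const arma::uword n = z.n_rows, K = c.n_rows;
  arma::vec cc = arma::sum(arma::square(c), 1);
  IntegerVector lab(n);
  const arma::uword block = 65536;
  for (arma::uword start = 0; start < n; start += block) {
    arma::uword end = std::min(n - 1, start + block - 1);
    arma::mat g = z.rows(start, end) * c.t();
    for (arma::uword i = 0; i < g.n_rows; ++i) {
      double best = arma::datum::inf;
      arma::uword bk = 0;
      for (arma::uword k = 0; k < K; ++k) {
        double d = cc[k] - 2.0 * g(i, k);
        if (d < best) { best = d; bk = k; }
      }
      lab[start + i] = bk + 1;
    }
  }
  return lab;
}
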
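#include <Rcpp.h>
using namespace Rcpp;

// Pairwise distances between two embedded series (rows = points).
// norm_type: 0 = euclidean, 1 = maximum (Chebyshev).
// [[Rcpp::export(name = ".cross_dist")]]
NumericMatrix cross_dist(NumericMatrix X, NumericMatrix Y, int norm_type) {
  const int nx = X.nrow(), ny = Y.nrow(), m = X.ncol();
  if (Y.ncol() != m) stop("embedding dimensions differ");
  NumericMatrix D(nx, ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double acc = 0.0;
      if (norm_type == 0) {
        for (int k = 0; k < m; ++k) {
          const double d = X(i, k) - Y(j, k);
          acc += d * d;
        }
        acc = std::sqrt(acc);
      } else {
        for (int k = 0; k < m; ++k) {
          const double d = std::fabs(X(i, k) - Y(j, k));
          if (d > acc) acc = d;
        }
      }
      D(i, j) = acc;
    }
  }
  return D;
}

// Maximal runs of recurrent points along every diagonal and every column
// of a binary recurrence matrix. Returns the raw run lengths; histograms
// are tabulated on the R side.
// [[Rcpp::export(name = ".line_runs")]]
List line_runs(IntegerMatrix R) {
  const int nr = R.nrow(), nc = R.ncol();
  std::vector<int> diag_runs, vert_runs;

  // diagonals: offset d = j - i from -(nr-1) .. (nc-1)
  for (int d = -(nr - 1); d <= nc - 1; ++d) {
    int i = d < 0 ? -d : 0;
    int j = d < 0 ? 0 : d;
    int run = 0;
    for (; i < nr && j < nc; ++i, ++j) {
      if (R(i, j)) {
        ++run;
      } else if (run > 0) {
        diag_runs.push_back(run);
        run = 0;
      }
    }
    if (run > 0) diag_runs.push_back(run);
  }
  for (int j = 0; j < nc; ++j) {
    int run = 0;
    for (int i = 0; i < nr; ++i) {
      if (R(i, j)) {
        ++run;
      } else if (run > 0) {
        vert_runs.push_back(run);
        run = 0;
      }
    }
    if (run > 0) vert_runs.push_back(run);
  }
  return List::create(_["diagonal"] = wrap(diag_runs),
                      _["vertical"] = wrap(vert_runs));
}

// False-nearest-neighbour fractions for embedding dimensions 1..max_dim
// (Kennel criterion: neighbour distance inflates by more than rtol when
// the next delay coordinate is appended). Self-matches and pairs closer
// in time than `theiler` samples are excluded as neighbours.
// [[Rcpp::export(name = ".fnn_fractions")]]
NumericVector fnn_fractions(NumericVector x, int delay, int max_dim,
                            double rtol, int theiler, double stop_frac,
                            int max_ref, double atol_abs) {
  const int n = x.size();
  NumericVector out(max_dim, NA_REAL);
  for (int m = 1; m <= max_dim; ++m) {
    const int n_emb = n - m * delay;  // need coordinate m*delay ahead too
    if (n_emb < 2) break;
    // subsample reference points for speed; all points remain candidate
    // neighbours
    const int stride = (max_ref > 0 && n_emb > max_ref)
                           ? (n_emb + max_ref - 1) / max_ref : 1;
    int false_nn = 0, total = 0;
    for (int i = 0; i < n_emb; i += stride) {
      double best = R_PosInf;
      int best_j = -1;
      for (int j = 0; j < n_emb; ++j) {
        if (std::abs(i - j) <= theiler) continue;
        double acc = 0.0;
        for (int k = 0; k < m; ++k) {
          const double d = x[i + k * delay] - x[j + k * delay];
          acc += d * d;
        }
        if (acc < best) { best = acc; best_j = j; }
      }
      if (best_j < 0) continue;
      const double dist_m = std::sqrt(best);
      if (dist_m <= 0) continue;
      const double extra =
          std::fabs(x[i + m * delay] - x[best_j + m * delay]);
      ++total;
      // a neighbour is false only if the appended coordinate inflates the
      // distance by rtol AND by a macroscopic amount (atol_abs, scaled to
      // the series SD by the caller): near-exact revisits of noiseless
      // trajectories otherwise explode the ratio test
      if (extra / dist_m > rtol && extra > atol_abs) ++false_nn;
    }
    out[m - 1] = total > 0 ? (double)false_nn / total : NA_REAL;
    if (out[m - 1] <= stop_frac) break;  // caller needs no higher dims
  }
  return out;
}


// Bisection radius calibration on a precomputed distance matrix:
// drives the recurrence rate to mid and stops inside [lo_band, hi_band].
// Returns (radius, rr) of the best iterate.
// [[Rcpp::export(name = ".calibrate_bisect")]]
NumericVector calibrate_bisect(NumericMatrix D, double lo_band,
                               double hi_band, int max_iter) {
  const R_xlen_t n = (R_xlen_t)D.nrow() * D.ncol();
  const double *d = D.begin();
  double hi = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) if (d[i] > hi) hi = d[i];
  const double mid = 0.5 * (lo_band + hi_band);
  double lo = 0.0, best_rr = R_PosInf, best_r = NA_REAL;
  for (int it = 0; it < max_iter; ++it) {
    const double r = 0.5 * (lo + hi);
    R_xlen_t cnt = 0;
    for (R_xlen_t i = 0; i < n; ++i) if (d[i] <= r) ++cnt;
    const double rr = (double)cnt / n;
    if (std::fabs(rr - mid) < std::fabs(best_rr - mid)) {
      best_rr = rr; best_r = r;
    }
    if (rr >= lo_band && rr <= hi_band) break;
    if (rr < mid) lo = r; else hi = r;
  }
  return NumericVector::create(best_r, best_rr);
}
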
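#include <Rcpp.h>
using namespace Rcpp;

// Statistic codes (must match gergm_statistics() order in R/statistics.R):
// 0 edge_sum, 1 reciprocity, 2 transitive_triads, 3 cyclic_triads,
// 4 in_two_stars, 5 out_two_stars.
//
// All kernels take the restricted network as a dense n x n matrix with a
// zero diagonal.  Every statistic is a sum of products of edge values over
// subgraphs, hence multilinear in each edge; edge deltas below are the
// exact affine slopes h(x_ij = 1) - h(x_ij = 0).

static double stat_value(const NumericMatrix& x, int code) {
  const int n = x.nrow();
  double s = 0.0;
  switch (code) {
  case 0: // edge_sum
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j) s += x(i, j);
    return s;
  case 1: // reciprocity: sum_{i<j} x_ij x_ji
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        s += x(i, j) * x(j, i);
    return s;
  case 2: // transitive triads: ordered distinct triples, x_ij x_jk x_ik
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double xij = x(i, j);
        if (xij == 0.0) continue;
        for (int k = 0; k < n; ++k) {
          if (k == i || k == j) continue;
          s += xij * x(j, k) * x(i, k);
        }
      }
    return s;
  case 3: // cyclic triads: both 3-cycles per unordered triple
    // = (1/3) sum over ordered distinct (i,j,k) of x_ij x_jk x_ki
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double xij = x(i, j);
        if (xij == 0.0) continue;
        for (int k = 0; k < n; ++k) {
          if (k == i || k == j) continue;
          s += xij * x(j, k) * x(k, i);
        }
      }
    return s / 3.0;
  case 4: // in two-stars: sum_j sum_{i<k} x_ij x_kj
    for (int j = 0; j < n; ++j) {
      double c1 = 0.0, c2 = 0.0;
      for (int i = 0; i < n; ++i) {
        if (i == j) continue;
        c1 += x(i, j);
        c2 += x(i, j) * x(i, j);
      }
      s += 0.5 * (c1 * c1 - c2);
    }
    return s;
  case 5: // out two-stars: sum_i sum_{j<k} x_ij x_ik
    for (int i = 0; i < n; ++i) {
      double r1 = 0.0, r2 = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        r1 += x(i, j);
        r2 += x(i, j) * x(i, j);
      }
      s += 0.5 * (r1 * r1 - r2);
    }
    return s;
  default:
    stop("unknown statistic code %d", code);
  }
  return s; // not reached
}

static double stat_delta(const NumericMatrix& x, int code, int a, int b) {
  const int n = x.nrow();
  double d = 0.0;
  switch (code) {
  case 0:
    return 1.0;
  case 1:
    return x(b, a);
  case 2:
    // edge (a,b) enters as x_ij (closure of a->c->... ), x_jk, or x_ik:
    // d = sum_c [ x_ac x_bc + x_ca x_cb + x_ac x_cb ]
    for (int c = 0; c < n; ++c) {
      if (c == a || c == b) continue;
      d += x(a, c) * x(b, c) + x(c, a) * x(c, b) + x(a, c) * x(c, b);
    }
    return d;
  case 3:
    // cycles a -> b -> c -> a
    for (int c = 0; c < n; ++c) {
      if (c == a || c == b) continue;
      d += x(b, c) * x(c, a);
    }
    return d;
  case 4:
    // other senders into receiver b
    for (int c = 0; c < n; ++c) {
      if (c == a || c == b) continue;
      d += x(c, b);
    }
    return d;
  case 5:
    // other receivers from sender a
    for (int c = 0; c < n; ++c) {
      if (c == a || c == b) continue;
      d += x(a, c);
    }
    return d;
  default:
    stop("unknown statistic code %d", code);
  }
  return d; // not reached
}

// [[Rcpp::export]]
NumericVector cpp_compute_stats(NumericMatrix x, IntegerVector codes) {
  NumericVector h(codes.size());
  for (int k = 0; k < codes.size(); ++k)
    h[k] = stat_value(x, codes[k]);
  return h;
}

// [[Rcpp::export]]
NumericVector cpp_edge_delta(NumericMatrix x, IntegerVector codes,
                             int i, int j) {
  NumericVector d(codes.size());
  for (int k = 0; k < codes.size(); ++k)
    d[k] = stat_delta(x, codes[k], i, j);
  return d;
}

// Inverse CDF of the truncated exponential density a e^{ax} / (e^a - 1)
// on (0,1); the uniform limit is taken for |a| below tol.  Evaluated in
// log space for large positive a so e^a never overflows.
static double inv_trunc_exp(double a, double u, double tol) {
  if (std::fabs(a) <= tol) return u;
  if (a > 30.0)
    return (a + std::log(u + (1.0 - u) * std::exp(-a))) / a;
  return std::log1p(u * std::expm1(a)) / a;
}

// [[Rcpp::export]]
NumericVector cpp_draw_edge(NumericVector a, NumericVector u, double tol) {
  const int m = a.size();
  NumericVector out(m);
  for (int e = 0; e < m; ++e) out[e] = inv_trunc_exp(a[e], u[e], tol);
  return out;
}

// One full Gibbs sweep in place: every off-diagonal edge is resampled once
// from its truncated-exponential full conditional, in row-major edge order
// (or a random scan when random_scan is true), using the current values of
// all other edges.  Uses R's RNG so set.seed() governs reproducibility.
static void gibbs_sweep_inplace(NumericMatrix& x, const NumericVector& theta,
                                const IntegerVector& codes,
                                const NumericVector& scaling,
                                bool random_scan, double tol) {
  const int n = x.nrow();
  const int m = n * (n - 1);
  for (int e = 0; e < m; ++e) {
    int idx = e;
    if (random_scan)
      idx = (int)std::floor(unif_rand() * m);
    const int i = idx / (n - 1);
    int j = idx % (n - 1);
    if (j >= i) ++j;
    double a = 0.0;
    for (int k = 0; k < codes.size(); ++k)
      a += theta[k] * stat_delta(x, codes[k], i, j) / scaling[k];
    x(i, j) = inv_trunc_exp(a, unif_rand(), tol);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_gibbs_sweep(NumericMatrix x, NumericVector theta,
                              IntegerVector codes, NumericVector scaling,
                              bool random_scan, double tol) {
  NumericMatrix out = clone(x);
  RNGScope scope;
  gibbs_sweep_inplace(out, theta, codes, scaling, random_scan, tol);
  return out;
}

// Run the full chain: `sweeps` full sweeps from `init`; after `burnin`
// sweeps keep every `thin`-th network.  Returns the retained networks as
// an m x kept matrix of edge vectors (row-major edge order), plus the
// per-sweep mean edge value and the per-sweep statistic vectors for
// diagnostics.
// [[Rcpp::export]]
List cpp_gibbs_run(NumericMatrix init, NumericVector theta,
                   IntegerVector codes, NumericVector scaling,
                   int sweeps, int burnin, int thin,
                   bool random_scan, double tol) {
  const int n = init.nrow();
  const int m = n * (n - 1);
  const int kept = (sweeps > burnin) ? (sweeps - burnin + thin - 1) / thin : 0;
  NumericMatrix x = clone(init);
  NumericMatrix draws(m, kept);
  NumericVector mean_trace(sweeps);
  NumericMatrix stat_trace(codes.size(), sweeps);
  RNGScope scope;
  int kept_i = 0;
  for (int s = 0; s < sweeps; ++s) {
    gibbs_sweep_inplace(x, theta, codes, scaling, random_scan, tol);
    double tot = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j) tot += x(i, j);
    mean_trace[s] = tot / m;
    for (int k = 0; k < codes.size(); ++k)
      stat_trace(k, s) = stat_value(x, codes[k]) / scaling[k];
    if (s >= burnin && ((s - burnin) % thin) == 0) {
      int e = 0;
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          if (i != j) draws(e++, kept_i) = x(i, j);
      ++kept_i;
    }
  }
  return List::create(_["draws"] = draws, _["mean_trace"] = mean_trace,
                      _["stat_trace"] = stat_trace, _["final"] = x);
}
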
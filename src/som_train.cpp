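#include <Rcpp.h>
using namespace Rcpp;

// Deterministic training loop for the four supervised SOM algorithms.
// All randomness (weight initialization, per-epoch balanced subsample
// orders) is drawn on the R side; this routine only applies the update
// rules, so identical inputs give bit-identical outputs.
//
// algorithm codes: 0 = cpann, 1 = xyf, 2 = cpann_v1, 3 = cpann_v2
//
// Neuron m (0-based) sits at grid position i = m / ny + 1, j = m % ny + 1;
// the grid-neighborhood metric is the Chebyshev distance and the kernel is
// triangular, h = max(0, 1 - d / (r + 1)), cut off to 0 for d > r.
//
// Schedules (t, e 0-based below):
//   eta(t)   linear eta_max -> eta_min over the T presented objects
//   r(t)     linear r0 -> 0 over the T presented objects
//   p(e)     linear 1 -> 0 over epochs (overridable via p_fixed >= 0)
//   alpha(e) linear alpha_start -> 0.5 over epochs
//
// X   : n x K   [0,1]-normalized descriptors
// SX  : n x K   descriptors range-scaled against the full training set
//               (argument of the damping factors of cpann_v1/v2)
// y   : n       binary targets; sy: their range-scaled values
// W0  : M x K   initial descriptor-layer weights, O0: M output weights
// ord : T       0-based row indices, concatenated over epochs
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix X, NumericMatrix SX,
                   NumericVector y, NumericVector sy,
                   NumericMatrix W0, NumericVector O0,
                   int nx, int ny,
                   IntegerVector ord, int epoch_len,
                   double eta_min, double eta_max, double r0,
                   int algorithm, double p_fixed, double alpha_start) {
  const int K = X.ncol();
  const int M = nx * ny;
  const int T = ord.size();
  const int E = (epoch_len > 0) ? T / epoch_len : 1;

  NumericMatrix W = clone(W0);
  NumericVector O = clone(O0);
  const double sqrtK = std::sqrt((double)K);

  std::vector<double> wmin(K), wmax(K);
  double omin = 0.0, omax = 1.0;

  for (int t = 0; t < T; ++t) {
    const int obj = ord[t];
    const int e = (epoch_len > 0) ? t / epoch_len : 0;
    const double eta = (T > 1)
      ? eta_max + (eta_min - eta_max) * ((double)t / (T - 1)) : eta_max;
    const double r = (T > 1) ? r0 * (1.0 - (double)t / (T - 1)) : 0.0;
    const double p = (p_fixed >= 0.0) ? p_fixed
      : ((E > 1) ? 1.0 - (double)e / (E - 1) : 1.0);
    const double alpha = (E > 1)
      ? alpha_start - (alpha_start - 0.5) * ((double)e / (E - 1)) : alpha_start;

    // winner search: descriptor-only Euclidean distance, except the X-Y
    // fused network which minimizes the fused normalized dissimilarity
    int win = 0;
    double best = R_PosInf;
    double win_sx = 0.0, win_sy = 0.0;  // winner dissimilarities (xyf)
    for (int m = 0; m < M; ++m) {
      double d2 = 0.0;
      for (int k = 0; k < K; ++k) {
        const double dd = X(obj, k) - W(m, k);
        d2 += dd * dd;
      }
      double crit;
      if (algorithm == 1) {
        const double s_x = std::sqrt(d2) / sqrtK;
        const double s_y = std::fabs(y[obj] - O[m]);
        crit = alpha * s_x + (1.0 - alpha) * s_y;
        if (crit < best) { best = crit; win = m; win_sx = s_x; win_sy = s_y; }
      } else {
        crit = d2;
        if (crit < best) { best = crit; win = m; }
      }
    }
    const int wi = win / ny, wj = win % ny;

    // adaptive weighting factor, evaluated at the winning neuron
    double F = 1.0;
    if (algorithm == 1) {
      F = 2.0 - (alpha * win_sx + (1.0 - alpha) * win_sy);
    }

    // level ranges for the damping factors, recomputed from the current
    // weight tensor at every iteration
    if (algorithm >= 2) {
      for (int k = 0; k < K; ++k) {
        double lo = W(0, k), hi = W(0, k);
        for (int m = 1; m < M; ++m) {
          if (W(m, k) < lo) lo = W(m, k);
          if (W(m, k) > hi) hi = W(m, k);
        }
        wmin[k] = lo; wmax[k] = hi;
      }
      omin = O[0]; omax = O[0];
      for (int m = 1; m < M; ++m) {
        if (O[m] < omin) omin = O[m];
        if (O[m] > omax) omax = O[m];
      }
    }

    for (int m = 0; m < M; ++m) {
      const int di = (m / ny) - wi, dj = (m % ny) - wj;
      const int d = std::max(std::abs(di), std::abs(dj));
      if ((double)d > r) continue;
      double h = 1.0 - (double)d / (r + 1.0);
      if (h <= 0.0) continue;
      const double base = eta * h;

      double m_tgt = 1.0;  // target damping factor (cpann_v1/v2)
      if (algorithm >= 2) {
        const double so = (omax > omin) ? (O[m] - omin) / (omax - omin) : 1.0;
        m_tgt = 1.0 - (1.0 - p) * std::fabs(sy[obj] - so);
      }

      for (int k = 0; k < K; ++k) {
        double fac = 1.0;
        if (algorithm == 1) {
          fac = F;
        } else if (algorithm >= 2) {
          const double sw = (wmax[k] > wmin[k])
            ? (W(m, k) - wmin[k]) / (wmax[k] - wmin[k]) : 1.0;
          double mk = 1.0 - (1.0 - p) * std::fabs(SX(obj, k) - sw);
          if (algorithm == 3) mk *= m_tgt;
          fac = mk;
        }
        W(m, k) += fac * base * (X(obj, k) - W(m, k));
      }

      // output layer: object value is the (binary) target; for cpann_v1 the
      // damping uses the target factor, for cpann_v2 the generic two-factor
      // rule degenerates to the squared target factor
      double ofac = 1.0;
      if (algorithm == 1) ofac = F;
      else if (algorithm == 2) ofac = m_tgt;
      else if (algorithm == 3) ofac = m_tgt * m_tgt;
      O[m] += ofac * base * (y[obj] - O[m]);
    }
  }

  return List::create(_["weights"] = W, _["output"] = O);
}

// Batch winner search by descriptor-only Euclidean distance (prediction and
// SOM-based set splitting).  Returns 1-based winner indices and distances.
// [[Rcpp::export]]
List find_winners_cpp(NumericMatrix X, NumericMatrix W) {
  const int n = X.nrow(), K = X.ncol(), M = W.nrow();
  IntegerVector win(n);
  NumericVector dist(n);
  for (int o = 0; o < n; ++o) {
    int best_m = 0;
    double best = R_PosInf;
    for (int m = 0; m < M; ++m) {
      double d2 = 0.0;
      for (int k = 0; k < K; ++k) {
        const double dd = X(o, k) - W(m, k);
        d2 += dd * dd;
      }
      if (d2 < best) { best = d2; best_m = m; }
    }
    win[o] = best_m + 1;
    dist[o] = std::sqrt(best);
  }
  return List::create(_["neuron"] = win, _["distance"] = dist);
}
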
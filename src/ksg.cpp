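#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (algorithm 1) mutual information and
// Frenzel-Pompe conditional mutual information for continuous samples.
// Max-norm in all joint spaces; neighbour counts use strict inequality,
// matching the original KSG prescription.  Returns nats; conversion to
// bits happens on the R side.
//
// All searches and counts honour a Theiler (dynamic-correlation)
// exclusion window `tw`: samples within `tw` temporal steps of the query
// point are never treated as neighbours.  Serially correlated series
// otherwise let temporal neighbours masquerade as statistical ones,
// which biases the estimates and de-calibrates permutation surrogates.
//
// Neighbour search: points are processed in the order of one coordinate,
// with every column stored contiguously in that order, so the projection
// scan stays in cache.  The scan stops once the projected distance
// exceeds the current k-th best; worst case degrades gracefully to
// O(n^2) but near-stationary series stay close to O(n * m) with small m.

namespace {

void check_finite(const double* v, int n, const char* name) {
  for (int i = 0; i < n; ++i)
    if (!R_finite(v[i]))
      stop("non-finite value in '%s' at position %d", name, i + 1);
}

// permutation sorting `key` ascending
std::vector<int> sort_order(const double* key, int n) {
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return key[a] < key[b]; });
  return ord;
}

void gather(const double* src, const std::vector<int>& ord,
            std::vector<double>& dst) {
  dst.resize(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) dst[i] = src[ord[i]];
}

// digamma(m + 1) for integer m looked up in a precomputed table
struct DigammaLUT {
  std::vector<double> tab;
  explicit DigammaLUT(int n) : tab(n + 1) {
    for (int m = 0; m <= n; ++m) tab[m] = R::digamma(m + 1.0);
  }
  double operator()(int m) const { return tab[m]; }
};

// k-th nearest neighbour distance (max-norm) for every point, scanning
// along the first (sorted) column; all columns are in sorted-by-first
// order and `eps` is returned in that same order.  `orig` maps sorted
// position to original (temporal) index.
void kth_nn_sorted(const std::vector<const std::vector<double>*>& cols,
                   const std::vector<int>& orig, int tw,
                   int n, int k, std::vector<double>& eps) {
  eps.resize(n);
  const int d = (int)cols.size();
  const std::vector<double>& a = *cols[0];
  std::vector<double> best(k);
  for (int i = 0; i < n; ++i) {
    std::fill(best.begin(), best.end(), R_PosInf);
    double worst = R_PosInf;
    int lo = i - 1, hi = i + 1;
    const double ai = a[i];
    const int oi = orig[i];
    while (lo >= 0 || hi < n) {
      double dlo = (lo >= 0) ? ai - a[lo] : R_PosInf;
      double dhi = (hi < n) ? a[hi] - ai : R_PosInf;
      if (dlo >= worst && dhi >= worst) break;
      int j;
      if (dlo <= dhi) { j = lo; --lo; } else { j = hi; ++hi; }
      if (std::abs(orig[j] - oi) <= tw) continue;
      double dist = std::fabs(ai - a[j]);
      for (int c = 1; c < d; ++c) {
        double dc = std::fabs((*cols[c])[i] - (*cols[c])[j]);
        if (dc > dist) dist = dc;
      }
      if (dist < worst) {
        int wi = 0;
        for (int b = 1; b < k; ++b) if (best[b] > best[wi]) wi = b;
        best[wi] = dist;
        worst = 0.0;
        for (int b = 0; b < k; ++b) if (best[b] > worst) worst = best[b];
      }
    }
    eps[i] = worst;
  }
}

// 1-D window counts by binary search, minus the temporally excluded
// samples.  `val`, `eps`, `orig` share one order; `sorted` is the sorted
// coordinate and `by_time` the same coordinate in temporal order.
double digamma_counts_1d(const std::vector<double>& val,
                         const std::vector<double>& eps,
                         const std::vector<int>& orig, int tw,
                         const std::vector<double>& sorted,
                         const std::vector<double>& by_time,
                         const DigammaLUT& dg) {
  const int n = (int)sorted.size();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = eps[i];
    int hi = (int)(std::lower_bound(sorted.begin(), sorted.end(),
                                    val[i] + e) - sorted.begin());
    int lo = (int)(std::upper_bound(sorted.begin(), sorted.end(),
                                    val[i] - e) - sorted.begin());
    int cnt = hi - lo - 1;
    const int oi = orig[i];
    const int wlo = std::max(0, oi - tw), whi = std::min(n - 1, oi + tw);
    for (int t = wlo; t <= whi; ++t) {
      if (t == oi) continue;
      if (std::fabs(by_time[t] - val[i]) < e) --cnt;
    }
    acc += dg(cnt);
  }
  return acc;
}

// 2-D window counts, scanning along the sorted first column with the
// second column stored in the same order; Theiler-excluded in the scan.
double digamma_counts_2d(const std::vector<double>& a,
                         const std::vector<double>& b,
                         const std::vector<double>& eps,
                         const std::vector<int>& orig, int tw,
                         const DigammaLUT& dg) {
  const int n = (int)a.size();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double e = eps[i], ai = a[i], bi = b[i];
    const int oi = orig[i];
    int cnt = 0;
    for (int p = i - 1; p >= 0 && ai - a[p] < e; --p)
      if (std::fabs(b[p] - bi) < e && std::abs(orig[p] - oi) > tw) ++cnt;
    for (int p = i + 1; p < n && a[p] - ai < e; ++p)
      if (std::fabs(b[p] - bi) < e && std::abs(orig[p] - oi) > tw) ++cnt;
    acc += dg(cnt);
  }
  return acc;
}

// mean of digamma(available neighbours + 1): the psi(N) term of the KSG
// formula with per-point Theiler exclusion (reduces to psi(n) at tw = 0)
double mean_digamma_N(int n, int tw, const DigammaLUT& dg) {
  double acc = 0.0;
  for (int o = 0; o < n; ++o) {
    int excl = std::min(o, tw) + std::min(n - 1 - o, tw);
    acc += dg(n - 1 - excl);   // available + 1 = (n - 1 - excl) + 1
  }
  return acc / n;
}

// xs, ys in x-sorted order; xt, yt in temporal order; orig maps sorted
// position to temporal index
double mi_core(const std::vector<double>& xs, const std::vector<double>& ys,
               const std::vector<double>& xt, const std::vector<double>& yt,
               const std::vector<int>& orig, int tw, int k,
               const DigammaLUT& dg) {
  const int n = (int)xs.size();
  std::vector<const std::vector<double>*> cols = { &xs, &ys };
  std::vector<double> eps;
  kth_nn_sorted(cols, orig, tw, n, k, eps);
  std::vector<double> ys_sorted(ys);
  std::sort(ys_sorted.begin(), ys_sorted.end());
  double acc = digamma_counts_1d(xs, eps, orig, tw, xs, xt, dg) +
               digamma_counts_1d(ys, eps, orig, tw, ys_sorted, yt, dg);
  return R::digamma((double)k) + mean_digamma_N(n, tw, dg) - acc / n;
}

} // namespace

// [[Rcpp::export(name = ".ksg_mi_cpp")]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k, int tw = 0) {
  const int n = (int)x.size();
  if ((int)y.size() != n) stop("length mismatch");
  if (n < k + 2 * tw + 2) stop("need at least k + 2*theiler + 2 samples");
  check_finite(REAL(x), n, "x"); check_finite(REAL(y), n, "y");
  std::vector<int> ord = sort_order(REAL(x), n);
  std::vector<double> xs, ys;
  gather(REAL(x), ord, xs);
  gather(REAL(y), ord, ys);
  std::vector<double> xt(REAL(x), REAL(x) + n), yt(REAL(y), REAL(y) + n);
  DigammaLUT dg(n);
  return mi_core(xs, ys, xt, yt, ord, tw, k, dg);
}

// [[Rcpp::export(name = ".ksg_mi_batch_cpp")]]
NumericVector ksg_mi_batch_cpp(NumericVector x, NumericMatrix Y, int k,
                               int tw = 0) {
  const int n = (int)x.size(), m = Y.ncol();
  if (Y.nrow() != n) stop("length mismatch");
  if (n < k + 2 * tw + 2) stop("need at least k + 2*theiler + 2 samples");
  check_finite(REAL(x), n, "x");
  std::vector<int> ord = sort_order(REAL(x), n);
  std::vector<double> xs, ys;
  gather(REAL(x), ord, xs);
  std::vector<double> xt(REAL(x), REAL(x) + n), yt(n);
  DigammaLUT dg(n);
  NumericVector out(m);
  for (int c = 0; c < m; ++c) {
    check_finite(&Y(0, c), n, "y");
    gather(&Y(0, c), ord, ys);
    std::copy(&Y(0, c), &Y(0, c) + n, yt.begin());
    out[c] = mi_core(xs, ys, xt, yt, ord, tw, k, dg);
  }
  return out;
}

// [[Rcpp::export(name = ".ksg_cmi_cpp")]]
double ksg_cmi_cpp(NumericVector x, NumericVector y, NumericVector z, int k,
                   int tw = 0) {
  const int n = (int)x.size();
  if ((int)y.size() != n || (int)z.size() != n) stop("length mismatch");
  if (n < k + 2 * tw + 2) stop("need at least k + 2*theiler + 2 samples");
  check_finite(REAL(x), n, "x"); check_finite(REAL(y), n, "y");
  check_finite(REAL(z), n, "z");
  std::vector<int> xord = sort_order(REAL(x), n);
  std::vector<double> xs, ys, zs;
  gather(REAL(x), xord, xs);
  gather(REAL(y), xord, ys);
  gather(REAL(z), xord, zs);
  // y-order structures for the (y, z) count
  std::vector<int> yord_local = sort_order(ys.data(), n);
  std::vector<int> pos_in_y(n);
  for (int p = 0; p < n; ++p) pos_in_y[yord_local[p]] = p;
  std::vector<double> ys2, zs2;
  gather(ys.data(), yord_local, ys2);
  gather(zs.data(), yord_local, zs2);
  std::vector<int> orig_y(n);
  for (int p = 0; p < n; ++p) orig_y[p] = xord[yord_local[p]];
  std::vector<double> zt(REAL(z), REAL(z) + n);
  DigammaLUT dg(n);

  std::vector<const std::vector<double>*> cols = { &xs, &ys, &zs };
  std::vector<double> eps;
  kth_nn_sorted(cols, xord, tw, n, k, eps);
  std::vector<double> zsorted(zs);
  std::sort(zsorted.begin(), zsorted.end());
  double acc = digamma_counts_2d(xs, zs, eps, xord, tw, dg);
  std::vector<double> eps_y(n);
  for (int i = 0; i < n; ++i) eps_y[pos_in_y[i]] = eps[i];
  acc += digamma_counts_2d(ys2, zs2, eps_y, orig_y, tw, dg);
  acc -= digamma_counts_1d(zs, eps, xord, tw, zsorted, zt, dg);
  return R::digamma((double)k) - acc / n;
}

// [[Rcpp::export(name = ".ksg_cmi_batch_cpp")]]
NumericVector ksg_cmi_batch_cpp(NumericVector x, NumericVector y,
                                NumericMatrix Z, int k, int tw = 0) {
  const int n = (int)x.size(), m = Z.ncol();
  if ((int)y.size() != n || Z.nrow() != n) stop("length mismatch");
  if (n < k + 2 * tw + 2) stop("need at least k + 2*theiler + 2 samples");
  check_finite(REAL(x), n, "x"); check_finite(REAL(y), n, "y");
  std::vector<int> xord = sort_order(REAL(x), n);
  std::vector<double> xs, ys;
  gather(REAL(x), xord, xs);
  gather(REAL(y), xord, ys);
  std::vector<int> yord_local = sort_order(ys.data(), n);
  std::vector<int> pos_in_y(n);
  for (int p = 0; p < n; ++p) pos_in_y[yord_local[p]] = p;
  std::vector<double> ys2;
  gather(ys.data(), yord_local, ys2);
  std::vector<int> orig_y(n);
  for (int p = 0; p < n; ++p) orig_y[p] = xord[yord_local[p]];
  DigammaLUT dg(n);

  // The (x, y) pair is fixed across the batch: precompute, per point, its
  // neighbours sorted by the 2-D (x, y) max-norm distance (Theiler window
  // already applied).  The 3-D distance to any neighbour is >= its 2-D
  // distance, so the k-th-NN search scans the list in order and stops
  // early; points whose k-th 3-D neighbour lies beyond the truncated list
  // fall back to the full projection scan.
  const int M = std::min(n - 1, 256);
  std::vector<double> d2val((size_t)n * M);
  std::vector<int>    d2idx((size_t)n * M);
  {
    std::vector<std::pair<double, int>> heap;
    heap.reserve(M + 1);
    for (int i = 0; i < n; ++i) {
      heap.clear();
      double worst = R_PosInf;
      int lo = i - 1, hi = i + 1;
      const double xi = xs[i], yi = ys[i];
      const int oi = xord[i];
      while (lo >= 0 || hi < n) {
        double dlo = (lo >= 0) ? xi - xs[lo] : R_PosInf;
        double dhi = (hi < n) ? xs[hi] - xi : R_PosInf;
        if (dlo >= worst && dhi >= worst) break;
        int j;
        if (dlo <= dhi) { j = lo; --lo; } else { j = hi; ++hi; }
        if (std::abs(xord[j] - oi) <= tw) continue;
        double d = std::fabs(xi - xs[j]);
        double dy = std::fabs(yi - ys[j]);
        if (dy > d) d = dy;
        if ((int)heap.size() < M) {
          heap.push_back({ d, j });
          std::push_heap(heap.begin(), heap.end());
          if ((int)heap.size() == M) worst = heap.front().first;
        } else if (d < worst) {
          std::pop_heap(heap.begin(), heap.end());
          heap.back() = { d, j };
          std::push_heap(heap.begin(), heap.end());
          worst = heap.front().first;
        }
      }
      std::sort_heap(heap.begin(), heap.end());
      const int got = (int)heap.size();
      for (int s = 0; s < got; ++s) {
        d2val[(size_t)i * M + s] = heap[s].first;
        d2idx[(size_t)i * M + s] = heap[s].second;
      }
      for (int s = got; s < M; ++s) {
        d2val[(size_t)i * M + s] = R_PosInf;
        d2idx[(size_t)i * M + s] = 0;
      }
    }
  }

  NumericVector out(m);
  std::vector<double> zs, zs2, zt(n), eps(n), eps_y(n), best(k), zsorted;
  for (int c = 0; c < m; ++c) {
    check_finite(&Z(0, c), n, "z");
    gather(&Z(0, c), xord, zs);
    gather(zs.data(), yord_local, zs2);
    std::copy(&Z(0, c), &Z(0, c) + n, zt.begin());
    for (int i = 0; i < n; ++i) {
      std::fill(best.begin(), best.end(), R_PosInf);
      double worst = R_PosInf;
      const size_t off = (size_t)i * M;
      const double zi = zs[i];
      bool complete = false;
      for (int s = 0; s < M; ++s) {
        double d2 = d2val[off + s];
        if (d2 >= worst) { complete = true; break; }
        int j = d2idx[off + s];
        double dz = std::fabs(zi - zs[j]);
        double d = (dz > d2) ? dz : d2;
        if (d < worst) {
          int wi = 0;
          for (int b = 1; b < k; ++b) if (best[b] > best[wi]) wi = b;
          best[wi] = d;
          worst = 0.0;
          for (int b = 0; b < k; ++b) if (best[b] > worst) worst = best[b];
        }
      }
      if (!complete && worst > d2val[off + M - 1]) {
        // exact fallback: full projection scan along x
        std::fill(best.begin(), best.end(), R_PosInf);
        worst = R_PosInf;
        int lo = i - 1, hi = i + 1;
        const double ai = xs[i];
        const int oi = xord[i];
        while (lo >= 0 || hi < n) {
          double dlo = (lo >= 0) ? ai - xs[lo] : R_PosInf;
          double dhi = (hi < n) ? xs[hi] - ai : R_PosInf;
          if (dlo >= worst && dhi >= worst) break;
          int j;
          if (dlo <= dhi) { j = lo; --lo; } else { j = hi; ++hi; }
          if (std::abs(xord[j] - oi) <= tw) continue;
          double d = std::fabs(ai - xs[j]);
          double dy = std::fabs(ys[i] - ys[j]); if (dy > d) d = dy;
          double dz = std::fabs(zi - zs[j]); if (dz > d) d = dz;
          if (d < worst) {
            int wi = 0;
            for (int b = 1; b < k; ++b) if (best[b] > best[wi]) wi = b;
            best[wi] = d;
            worst = 0.0;
            for (int b = 0; b < k; ++b) if (best[b] > worst) worst = best[b];
          }
        }
      }
      eps[i] = worst;
    }
    zsorted = zs;
    std::sort(zsorted.begin(), zsorted.end());
    double acc = digamma_counts_2d(xs, zs, eps, xord, tw, dg);
    for (int i = 0; i < n; ++i) eps_y[pos_in_y[i]] = eps[i];
    acc += digamma_counts_2d(ys2, zs2, eps_y, orig_y, tw, dg);
    acc -= digamma_counts_1d(zs, eps, xord, tw, zsorted, zt, dg);
    out[c] = R::digamma((double)k) - acc / n;
  }
  return out;
}
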
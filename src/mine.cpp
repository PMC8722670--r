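// Maximal information coefficient via the ApproxMaxMI heuristic:
// equipartition one axis, then dynamic programming over clumps to optimise
// the other axis, for every grid size (nx, ny) with nx * ny <= B(n).
// The score for a grid is I(P;Q) / log(min(nx, ny)); MIC is the maximum
// over the characteristic matrix (both axis orientations).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <functional>
#include <vector>

using std::vector;

// Assign each y-sorted point to one of <= q rows of roughly equal size,
// keeping tied y values together. Returns the actual number of rows used.
static int equipartition(const vector<double>& ys, int q, vector<int>& row) {
  int n = (int)ys.size();
  row.assign(n, 0);
  int i = 0, curr = 0;
  double in_row = 0.0;
  double desired = (double)n / q;
  while (i < n) {
    int j = i;
    while (j < n && ys[j] == ys[i]) ++j;       // tied block [i, j)
    double blk = j - i;
    if (in_row > 0.0 &&
        std::fabs(in_row + blk - desired) >= std::fabs(in_row - desired)) {
      ++curr;
      in_row = 0.0;
      int remaining_rows = q - curr;
      if (remaining_rows > 0) desired = (double)(n - i) / remaining_rows;
    }
    for (int k = i; k < j; ++k) row[k] = curr;
    in_row += blk;
    i = j;
  }
  return curr + 1;
}

// Clumps: maximal runs of x-sorted points sharing a row, with equal-x
// blocks never split. Then merge into <= k_hat superclumps of roughly
// equal point count. Returns cumulative end indices of superclumps.
static void superclumps(const vector<double>& xs, const vector<int>& row,
                        int k_hat, vector<int>& bound) {
  int n = (int)xs.size();
  vector<int> clump_end;                        // exclusive end of each clump
  int i = 0;
  while (i < n) {
    int j = i;
    int r = row[i];
    while (j < n) {
      int b = j;
      while (b < n && xs[b] == xs[j]) ++b;      // equal-x block [j, b)
      bool mixed = false;
      for (int k = j; k < b; ++k) if (row[k] != r) { mixed = true; break; }
      if (j > i && (mixed || row[j] != r)) break;
      r = row[b - 1];
      j = b;
      if (mixed) break;
    }
    clump_end.push_back(j);
    i = j;
  }
  int m = (int)clump_end.size();
  if (m <= k_hat) { bound = clump_end; return; }
  // merge clumps into k_hat groups: end group t at the clump boundary
  // closest to t * n / k_hat
  bound.clear();
  int j = 0;
  for (int t = 1; t <= k_hat && j < m; ++t) {
    double target = (double)t * n / k_hat;
    int bestj = j;
    double bestd = 1e300;
    for (int c = j; c < m; ++c) {
      double d = std::fabs((double)clump_end[c] - target);
      if (d <= bestd) { bestd = d; bestj = c; } else break;
    }
    bound.push_back(clump_end[bestj]);
    j = bestj + 1;
  }
  if (bound.empty() || bound.back() != n) bound.push_back(n);
}

// For a fixed row assignment (q rows), fill best[l] (l = 2..k) with the
// maximum I(P;Q) over column partitions built from superclump boundaries.
static void optimize_axis(const vector<int>& row, int q,
                          const vector<int>& bound, int k,
                          vector<double>& best) {
  int n = (int)row.size();
  int p = (int)bound.size();
  // cumulative per-row counts at each superclump boundary prefix
  vector<vector<double>> cum(p + 1, vector<double>(q, 0.0));
  {
    int start = 0;
    for (int t = 0; t < p; ++t) {
      cum[t + 1] = cum[t];
      for (int i = start; i < bound[t]; ++i) cum[t + 1][row[i]] += 1.0;
      start = bound[t];
    }
  }
  // H(Q)
  double hq = 0.0;
  for (int r = 0; r < q; ++r) {
    double pr = cum[p][r] / n;
    if (pr > 0) hq -= pr * std::log(pr);
  }
  // f(s, t): contribution -H(Q|P) of a column spanning superclumps (s, t]
  auto colf = [&](int s, int t) {
    double tot = 0.0, v = 0.0;
    for (int r = 0; r < q; ++r) tot += cum[t][r] - cum[s][r];
    if (tot <= 0) return 0.0;
    for (int r = 0; r < q; ++r) {
      double c = cum[t][r] - cum[s][r];
      if (c > 0) v += (c / n) * std::log(c / tot);
    }
    return v;
  };
  const double NEG = -1e300;
  // J[t][l]: best sum of colf over l columns covering superclumps 1..t
  vector<vector<double>> J(p + 1, vector<double>(k + 1, NEG));
  for (int t = 1; t <= p; ++t) J[t][1] = colf(0, t);
  for (int l = 2; l <= k; ++l)
    for (int t = l; t <= p; ++t)
      for (int s = l - 1; s < t; ++s) {
        if (J[s][l - 1] <= NEG / 2) continue;
        double v = J[s][l - 1] + colf(s, t);
        if (v > J[t][l]) J[t][l] = v;
      }
  best.assign(k + 1, 0.0);
  for (int l = 2; l <= k; ++l)
    best[l] = (J[p][l] <= NEG / 2) ? 0.0 : hq + J[p][l];
}

// One orientation: equipartition `a` (rows), optimise over `b` (columns).
// Accumulates normalised scores into M[(rows q, cols l)] via callback max.
static void orient(const vector<double>& a, const vector<double>& b,
                   double B, int cmax, int clumps_c,
                   std::function<void(int, int, double)> upd) {
  int n = (int)a.size();
  vector<size_t> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t u, size_t v) { return a[u] < a[v]; });
  vector<double> as(n);
  vector<double> bs(n);
  for (int i = 0; i < n; ++i) { as[i] = a[ord[i]]; bs[i] = b[ord[i]]; }

  int qmax = (int)std::floor(B / 2.0);
  for (int q = 2; q <= qmax; ++q) {
    vector<int> row;
    int q_act = equipartition(as, q, row);
    if (q_act < 2) continue;
    int k = std::max(2, (int)std::floor(B / q));
    if (k > cmax) k = cmax;
    // order the (row-labelled) points by the other variable
    vector<size_t> o2(n);
    for (int i = 0; i < n; ++i) o2[i] = i;
    std::sort(o2.begin(), o2.end(),
              [&](size_t u, size_t v) { return bs[u] < bs[v]; });
    vector<double> xs(n);
    vector<int> row2(n);
    for (int i = 0; i < n; ++i) { xs[i] = bs[o2[i]]; row2[i] = row[o2[i]]; }
    vector<int> bound;
    superclumps(xs, row2, std::max(1, clumps_c * k), bound);
    vector<double> best;
    optimize_axis(row2, q_act, bound, k, best);
    for (int l = 2; l <= k; ++l) {
      if (l * q > B) break;
      double denom = std::log(std::min(l, q_act));
      if (denom <= 0) continue;
      upd(q, l, best[l] / denom);
    }
  }
}

// [[Rcpp::export(name = ".mic_cpp")]]
double mic_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y,
               double alpha = 0.6, int clumps_c = 15) {
  int n = x.size();
  if (y.size() != n) Rcpp::stop("length mismatch");
  double B = std::max(std::pow((double)n, alpha), 4.0);
  int cmax = (int)std::floor(B / 2.0);
  vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double mic = 0.0;
  auto upd = [&](int, int, double v) { if (v > mic) mic = v; };
  // rows on y, columns optimised on x — and the transpose
  orient(yv, xv, B, cmax, clumps_c, upd);
  orient(xv, yv, B, cmax, clumps_c, upd);
  if (mic > 1.0) mic = 1.0;
  return mic;
}
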
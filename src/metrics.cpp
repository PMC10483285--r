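// Numerical kernels for binary-network metrics and sample entropy.
// Graphs here are small (26 nodes) but are evaluated thousands of times per
// cohort (31 thresholds x 3 bands x all subjects), so the whole metric set
// is computed in C++ on dense adjacency matrices.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <functional>
#include <limits>

using namespace Rcpp;

typedef std::vector<std::vector<double> > Mat;

// BFS all-pairs shortest paths on a binary adjacency; -1 marks unreachable.
static void bfs_apsp(const std::vector<std::vector<int> > &nb, int n,
                     std::vector<std::vector<int> > &dist) {
  for (int s = 0; s < n; ++s) {
    std::vector<int> &d = dist[s];
    std::fill(d.begin(), d.end(), -1);
    d[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (size_t t = 0; t < nb[u].size(); ++t) {
        int v = nb[u][t];
        if (d[v] < 0) { d[v] = d[u] + 1; q.push(v); }
      }
    }
  }
}

// Global efficiency of the (sub)graph given by 0/1 adjacency `a` over the
// node subset `idx`.
static double subgraph_efficiency(const std::vector<std::vector<int> > &adj,
                                  const std::vector<int> &idx) {
  int k = idx.size();
  if (k < 2) return 0.0;
  std::vector<std::vector<int> > nb(k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j && adj[idx[i]][idx[j]]) nb[i].push_back(j);
  std::vector<std::vector<int> > dist(k, std::vector<int>(k));
  bfs_apsp(nb, k, dist);
  double s = 0.0;
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j)
      if (dist[i][j] > 0) s += 1.0 / dist[i][j];
  return s / (k * (k - 1) / 2.0);
}

// One Louvain run on weighted symmetric adjacency W (self-loops on the
// diagonal count twice in strengths); first-level node sweep order given by
// `order`. Returns the modularity Q of the final partition.
static double louvain_once(const Mat &W0, const std::vector<int> &order0) {
  Mat W = W0;
  int n = W.size();
  double m2 = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) m2 += W[i][j];
  if (m2 <= 0.0) return 0.0;

  // membership of original nodes through the levels
  std::vector<int> member(n);
  for (int i = 0; i < n; ++i) member[i] = i;

  std::vector<int> order = order0;
  bool improved_any = true;
  while (improved_any) {
    int nn = W.size();
    std::vector<double> k(nn, 0.0);
    for (int i = 0; i < nn; ++i)
      for (int j = 0; j < nn; ++j) k[i] += W[i][j];
    std::vector<int> comm(nn);
    for (int i = 0; i < nn; ++i) comm[i] = i;
    std::vector<double> tot = k;

    bool moved = true, level_change = false;
    std::vector<double> w_to(nn, 0.0);
    std::vector<int> touched;
    touched.reserve(nn);
    while (moved) {
      moved = false;
      for (int oi = 0; oi < nn; ++oi) {
        int i = order[oi];
        int ci = comm[i];
        // weights from i to each community (excluding the self-loop)
        touched.clear();
        for (int j = 0; j < nn; ++j)
          if (j != i && W[i][j] > 0) {
            int c = comm[j];
            if (w_to[c] == 0.0) touched.push_back(c);
            w_to[c] += W[i][j];
          }
        tot[ci] -= k[i];
        double best_gain = 0.0;
        int best_c = ci;
        double base = w_to[ci] - k[i] * tot[ci] / m2;
        for (size_t tc = 0; tc < touched.size(); ++tc) {
          int c = touched[tc];
          if (c == ci) continue;
          double gain = (w_to[c] - k[i] * tot[c] / m2) - base;
          if (gain > best_gain + 1e-12) { best_gain = gain; best_c = c; }
        }
        tot[best_c] += k[i];
        for (size_t tc = 0; tc < touched.size(); ++tc) w_to[touched[tc]] = 0.0;
        if (best_c != ci) { comm[i] = best_c; moved = true; level_change = true; }
      }
    }
    if (!level_change) break;

    // relabel communities consecutively and aggregate
    std::vector<int> relab(nn, -1);
    int nc = 0;
    for (int i = 0; i < nn; ++i)
      if (relab[comm[i]] < 0) relab[comm[i]] = nc++;
    for (int i = 0; i < nn; ++i) comm[i] = relab[comm[i]];
    for (int i = 0; i < n; ++i) member[i] = comm[member[i]];
    Mat B(nc, std::vector<double>(nc, 0.0));
    for (int i = 0; i < nn; ++i)
      for (int j = 0; j < nn; ++j) B[comm[i]][comm[j]] += W[i][j];
    W = B;
    order.resize(nc);
    for (int i = 0; i < nc; ++i) order[i] = i;
    improved_any = true;
  }

  // Q of the final membership on the original graph
  int nc = 0;
  for (int i = 0; i < n; ++i) nc = std::max(nc, member[i] + 1);
  std::vector<double> win(nc, 0.0), wtot(nc, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      wtot[member[i]] += W0[i][j];
      if (member[i] == member[j]) win[member[i]] += W0[i][j];
    }
  double q = 0.0;
  for (int c = 0; c < nc; ++c)
    q += win[c] / m2 - (wtot[c] / m2) * (wtot[c] / m2);
  return q;
}

// Exact maximum-modularity search by enumeration of all set partitions
// (restricted growth strings); used for tiny graphs where Bell(n) is small,
// so M is provably optimal there.
static double modularity_exact(const std::vector<std::vector<int> > &adj,
                               int n) {
  double m2 = 0.0;
  std::vector<double> deg(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      deg[i] += adj[i][j];
      m2 += adj[i][j];
    }
  if (m2 <= 0.0) return 0.0;
  std::vector<int> rgs(n, 0);
  double best = -1.0;
  // recursive enumeration of restricted growth strings
  std::function<void(int, int)> rec = [&](int i, int maxc) {
    if (i == n) {
      int nc = maxc + 1;
      std::vector<double> win(nc, 0.0), wtot(nc, 0.0);
      for (int a = 0; a < n; ++a) {
        wtot[rgs[a]] += deg[a];
        for (int b = 0; b < n; ++b)
          if (rgs[a] == rgs[b]) win[rgs[a]] += adj[a][b];
      }
      double q = 0.0;
      for (int c = 0; c < nc; ++c)
        q += win[c] / m2 - (wtot[c] / m2) * (wtot[c] / m2);
      if (q > best) best = q;
      return;
    }
    for (int c = 0; c <= maxc + 1; ++c) {
      rgs[i] = c;
      rec(i + 1, std::max(maxc, c));
    }
  };
  rgs[0] = 0;
  rec(1, 0);
  return best;
}

static double modularity_restarts(const std::vector<std::vector<int> > &adj,
                                  int n, const IntegerMatrix &perms) {
  Mat W(n, std::vector<double>(n, 0.0));
  bool any_edge = false;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      W[i][j] = adj[i][j];
      if (adj[i][j]) any_edge = true;
    }
  if (!any_edge) return 0.0;
  double best = -1.0;
  for (int r = 0; r < perms.nrow(); ++r) {
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = perms(r, i);
    double q = louvain_once(W, order);
    if (q > best) best = q;
  }
  return best;
}

// Compute C, L, GE, LE, T, M for one binary adjacency.
static NumericVector metrics_one(const std::vector<std::vector<int> > &adj,
                                 int n, const IntegerMatrix &perms) {
  std::vector<std::vector<int> > nb(n);
  std::vector<int> deg(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj[i][j]) { nb[i].push_back(j); deg[i]++; }

  // triangles per node
  std::vector<double> tri(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (size_t a = 0; a < nb[i].size(); ++a)
      for (size_t b = a + 1; b < nb[i].size(); ++b)
        if (adj[nb[i][a]][nb[i][b]]) tri[i] += 1.0;

  double C = 0.0, triples = 0.0, tri_sum2 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (deg[i] >= 2) C += 2.0 * tri[i] / (deg[i] * (deg[i] - 1.0));
    triples += deg[i] * (deg[i] - 1.0) / 2.0;
    tri_sum2 += tri[i];
  }
  C /= n;
  double T = triples > 0 ? tri_sum2 / triples : 0.0;

  std::vector<std::vector<int> > dist(n, std::vector<int>(n));
  bfs_apsp(nb, n, dist);
  double lsum = 0.0, gesum = 0.0;
  long lcount = 0, pairs = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      ++pairs;
      if (dist[i][j] > 0) {
        lsum += dist[i][j];
        ++lcount;
        gesum += 1.0 / dist[i][j];
      }
    }
  double L = lcount > 0 ? lsum / lcount : NA_REAL;
  double GE = pairs > 0 ? gesum / pairs : 0.0;

  double LE = 0.0;
  for (int i = 0; i < n; ++i)
    if (deg[i] >= 2) LE += subgraph_efficiency(adj, nb[i]);
  LE /= n;

  // exact best-partition modularity where enumeration is cheap (provably
  // optimal Q); seeded Louvain restarts beyond that
  double M = (n <= 8) ? modularity_exact(adj, n)
                      : modularity_restarts(adj, n, perms);
  return NumericVector::create(_["C"] = C, _["L"] = L, _["GE"] = GE,
                               _["LE"] = LE, _["T"] = T, _["M"] = M);
}

// [[Rcpp::export]]
NumericVector cpp_network_metrics(IntegerMatrix a, IntegerMatrix perms) {
  int n = a.nrow();
  std::vector<std::vector<int> > adj(n, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) adj[i][j] = a(i, j) != 0;
  return metrics_one(adj, n, perms);
}

// Metric sweep over a descending-density threshold grid. `ei`/`ej` are the
// 0-based endpoints of all upper-triangle pairs sorted by descending
// connection weight (ties already broken); `ecounts[k]` is how many leading
// edges the k-th threshold keeps.
// [[Rcpp::export]]
NumericMatrix cpp_metric_sweep(int n, IntegerVector ei, IntegerVector ej,
                               IntegerVector ecounts, IntegerMatrix perms) {
  int nt = ecounts.size();
  NumericMatrix out(nt, 6);
  colnames(out) = CharacterVector::create("C", "L", "GE", "LE", "T", "M");
  for (int k = 0; k < nt; ++k) {
    int ne = ecounts[k];
    std::vector<std::vector<int> > adj(n, std::vector<int>(n, 0));
    for (int e = 0; e < ne; ++e) {
      adj[ei[e]][ej[e]] = 1;
      adj[ej[e]][ei[e]] = 1;
    }
    NumericVector m = metrics_one(adj, n, perms);
    for (int c = 0; c < 6; ++c) out(k, c) = m[c];
  }
  return out;
}

// Sample entropy with embedding delay tau. In the default mode the
// denominators follow the source formulation exactly:
//   C_i^m = B_i / (N - (m+1)*tau),  U^m = mean over i = 1..N - m*tau,
// with B_i counting j != i (over the same template range) whose Chebyshev
// distance to template i is <= r. `classical = true` switches to the
// Richman-Moorman convention (both template lengths share the range
// i = 1..N-(m+1)*tau and denominator N-(m+1)*tau-1).
// [[Rcpp::export]]
double cpp_sampen(NumericVector x, int m, double r, int tau, bool classical) {
  int N = x.size();
  int n_m = N - m * tau;          // number of m-templates
  int n_m1 = N - (m + 1) * tau;   // number of (m+1)-templates
  if (n_m1 < 2) return NA_REAL;

  long double Um = 0.0L, Um1 = 0.0L;
  if (!classical) {
    // symmetric pair sweep: each match at (i, j) counts for B_i and B_j
    std::vector<long> Bm(n_m, 0), Bm1(n_m1, 0);
    for (int i = 0; i < n_m; ++i) {
      for (int j = i + 1; j < n_m; ++j) {
        double d = 0.0;
        for (int k = 0; k < m; ++k) {
          double dd = std::fabs(x[i + k * tau] - x[j + k * tau]);
          if (dd > d) d = dd;
        }
        if (d <= r) {
          ++Bm[i]; ++Bm[j];
          if (j < n_m1) {
            double dd = std::fabs(x[i + m * tau] - x[j + m * tau]);
            if (std::max(d, dd) <= r) { ++Bm1[i]; ++Bm1[j]; }
          }
        }
      }
    }
    for (int i = 0; i < n_m; ++i)
      Um += (long double)Bm[i] / (double)(N - (m + 1) * tau);
    Um /= n_m;
    for (int i = 0; i < n_m1; ++i)
      Um1 += (long double)Bm1[i] / (double)(N - (m + 2) * tau);
    Um1 /= n_m1;
  } else {
    long B = 0, A = 0;
    for (int i = 0; i < n_m1; ++i)
      for (int j = i + 1; j < n_m1; ++j) {
        double d = 0.0;
        for (int k = 0; k < m; ++k) {
          double dd = std::fabs(x[i + k * tau] - x[j + k * tau]);
          if (dd > d) d = dd;
        }
        if (d <= r) {
          ++B;
          double dd = std::fabs(x[i + m * tau] - x[j + m * tau]);
          if (std::max(d, dd) <= r) ++A;
        }
      }
    if (B == 0) return R_PosInf;
    if (A == 0) return R_PosInf;
    return -std::log((double)A / (double)B);
  }
  if (Um <= 0.0L) return R_PosInf;
  if (Um1 <= 0.0L) return R_PosInf;
  return -(double)std::log((double)(Um1 / Um));
}
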
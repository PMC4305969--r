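#include <Rcpp.h>
#include <functional>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connected-component labelling (4- or 8-connectivity), deterministic labels
// in raster-scan order of first encounter.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_cc_label(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nd; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
// Distance of each TRUE pixel to the nearest FALSE pixel; FALSE pixels -> 0.
// If the mask has no FALSE pixel, distances are +Inf.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  // column pass
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? 1e20 : 0.0;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = d[c];
  }
  return out;
}

// 3x3 median filter; edge pixels use the neighbours that exist.
// [[Rcpp::export]]
NumericMatrix cpp_median3(const NumericMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(9);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      buf.clear();
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          buf.push_back(m(rr, cc));
        }
      size_t n = buf.size();
      std::sort(buf.begin(), buf.end());
      out(r, c) = (n % 2 == 1) ? buf[n / 2]
                               : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  return out;
}

// ---------------------------------------------------------------------------
// Seeded watershed by priority flooding, descending height order (basins grow
// from peaks downhill).  Deterministic: ties broken by insertion order.
// Pixels outside `mask` are never claimed.
// ---------------------------------------------------------------------------

struct WsEntry {
  double h;
  long order;
  int idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.h != b.h) return a.h < b.h;       // max-heap on height
    return a.order > b.order;               // FIFO for equal heights
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& height,
                            const IntegerMatrix& seeds,
                            const LogicalMatrix& mask) {
  const int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long order = 0;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        pq.push({height(r, c), order++, r + c * nr, seeds(r, c)});
      }
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    int pr = e.idx % nr, pc = e.idx / nr;
    for (int k = 0; k < 4; ++k) {
      int qr = pr + dr[k], qc = pc + dc[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (!mask(qr, qc) || lab(qr, qc) != 0) continue;
      lab(qr, qc) = e.label;
      pq.push({height(qr, qc), order++, qr + qc * nr, e.label});
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Multiresolution bottom-up region merging.
//
// Each tissue pixel starts as a region.  The merge cost of two adjacent
// regions is the weighted sum over channels of the increase in
// (area x within-region population SD) caused by the merge.  Merging always
// executes the globally cheapest admissible pair (ties by lowest region-id
// pair), which is a mutual-best pair by construction.  The full merge
// sequence down to one region per connected component is recorded so that
// segmentation levels are obtained by cutting a single tree -> strict nesting.
//
// Region ids are 1-based linear (column-major) pixel indices of the region's
// smallest member pixel, so ids are stable and reproducible.
// ---------------------------------------------------------------------------

struct MergeCand {
  double cost;
  int a, b;        // root ids at push time, a < b
  long va, vb;     // version stamps
};
struct MergeCmp {
  bool operator()(const MergeCand& x, const MergeCand& y) const {
    if (x.cost != y.cost) return x.cost > y.cost;  // min-heap on cost
    if (x.a != y.a) return x.a > y.a;
    return x.b > y.b;
  }
};

// [[Rcpp::export]]
List cpp_mrseg_merges(const NumericVector& channels,  // nr x nc x nch array
                      const NumericVector& weights,
                      const LogicalMatrix& mask,
                      double shape_weight, double compactness) {
  IntegerVector dims = channels.attr("dim");
  const int nr = dims[0], nc = dims[1], nch = dims[2];
  const int npx = nr * nc;
  const double* ch = channels.begin();

  // map pixel -> compact region slot (only tissue pixels), keyed by pixel idx
  std::vector<int> slot(npx, -1);
  std::vector<int> px_of;                     // slot -> pixel index
  px_of.reserve(npx);
  for (int p = 0; p < npx; ++p) {
    int r = p % nr, c = p / nr;
    if (mask(r, c)) { slot[p] = (int)px_of.size(); px_of.push_back(p); }
  }
  const int n = (int)px_of.size();
  if (n == 0) stop("empty tissue mask");

  // per-region stats
  std::vector<double> cnt(n, 1.0);
  std::vector<std::vector<double> > sum(n, std::vector<double>(nch));
  std::vector<std::vector<double> > ssq(n, std::vector<double>(nch));
  for (int s = 0; s < n; ++s) {
    int p = px_of[s];
    for (int k = 0; k < nch; ++k) {
      double v = ch[p + (size_t)k * npx];
      sum[s][k] = v;
      ssq[s][k] = v * v;
    }
  }
  // union-find over slots; root carries stats; id = pixel idx of min member
  std::vector<int> parent(n);
  std::vector<long> version(n, 0);
  for (int s = 0; s < n; ++s) parent[s] = s;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  // shape bookkeeping: perimeter (pixel edges, image border counts) and
  // bounding box per region; shared-border lengths in a global pair map
  std::vector<double> perim(n);
  std::vector<int> bb_r0(n), bb_r1(n), bb_c0(n), bb_c1(n);
  for (int s = 0; s < n; ++s) {
    perim[s] = 4.0;
    int p = px_of[s];
    bb_r0[s] = bb_r1[s] = p % nr;
    bb_c0[s] = bb_c1[s] = p / nr;
  }
  std::map<std::pair<int, int>, double> blen;
  auto bkey = [](int a, int b) {
    return a < b ? std::make_pair(a, b) : std::make_pair(b, a);
  };

  // adjacency lists of slots (sorted, unique), 4-connectivity
  std::vector<std::vector<int> > adj(n);
  for (int s = 0; s < n; ++s) {
    int p = px_of[s], r = p % nr, c = p / nr;
    if (r + 1 < nr && slot[p + 1] >= 0) {
      adj[s].push_back(slot[p + 1]);
      adj[slot[p + 1]].push_back(s);
      blen[bkey(s, slot[p + 1])] = 1.0;
    }
    if (c + 1 < nc && slot[p + nr] >= 0) {
      adj[s].push_back(slot[p + nr]);
      adj[slot[p + nr]].push_back(s);
      blen[bkey(s, slot[p + nr])] = 1.0;
    }
  }

  const double* w = weights.begin();
  auto hval = [&](int root) {
    double h = 0.0;
    double m = cnt[root];
    for (int k = 0; k < nch; ++k) {
      double mu = sum[root][k] / m;
      double var = ssq[root][k] / m - mu * mu;
      if (var < 0) var = 0;
      h += w[k] * m * std::sqrt(var);
    }
    return h;
  };
  // shape heterogeneity (reference region-merging convention):
  // compactness h = n * perimeter / sqrt(n); smoothness h = n * p / p_bbox
  auto hshape = [&](double m, double p, int r0, int r1, int c0, int c1) {
    double hc = p * std::sqrt(m);
    double pb = 2.0 * ((r1 - r0 + 1) + (c1 - c0 + 1));
    double hs = m * p / pb;
    return compactness * hc + (1.0 - compactness) * hs;
  };
  auto merge_cost = [&](int ra, int rb) {
    double m = cnt[ra] + cnt[rb];
    double h = 0.0;
    for (int k = 0; k < nch; ++k) {
      double su = sum[ra][k] + sum[rb][k];
      double sq = ssq[ra][k] + ssq[rb][k];
      double mu = su / m;
      double var = sq / m - mu * mu;
      if (var < 0) var = 0;
      h += w[k] * m * std::sqrt(var);
    }
    double cost = h - hval(ra) - hval(rb);
    if (shape_weight > 0) {
      auto it = blen.find(bkey(ra, rb));
      double shared = (it == blen.end()) ? 0.0 : it->second;
      double pm = perim[ra] + perim[rb] - 2.0 * shared;
      double hm = hshape(m, pm, std::min(bb_r0[ra], bb_r0[rb]),
                         std::max(bb_r1[ra], bb_r1[rb]),
                         std::min(bb_c0[ra], bb_c0[rb]),
                         std::max(bb_c1[ra], bb_c1[rb]));
      double ha = hshape(cnt[ra], perim[ra], bb_r0[ra], bb_r1[ra],
                         bb_c0[ra], bb_c1[ra]);
      double hb = hshape(cnt[rb], perim[rb], bb_r0[rb], bb_r1[rb],
                         bb_c0[rb], bb_c1[rb]);
      cost += shape_weight * (hm - ha - hb);
    }
    return cost;
  };

  std::priority_queue<MergeCand, std::vector<MergeCand>, MergeCmp> pq;
  auto push_pair = [&](int ra, int rb) {
    int ida = px_of[ra], idb = px_of[rb];
    int a = ra, b = rb;
    if (idb < ida) { std::swap(a, b); std::swap(ida, idb); }
    pq.push({merge_cost(a, b), a, b, version[a], version[b]});
  };
  for (int s = 0; s < n; ++s)
    for (int t : adj[s])
      if (px_of[s] < px_of[t]) push_pair(s, t);

  std::vector<int> out_a, out_b;
  std::vector<double> out_cost;
  out_a.reserve(n); out_b.reserve(n); out_cost.reserve(n);

  while (!pq.empty()) {
    MergeCand m = pq.top(); pq.pop();
    if (parent[m.a] != m.a || parent[m.b] != m.b) continue;
    if (version[m.a] != m.va || version[m.b] != m.vb) continue;
    int a = m.a, b = m.b;     // a has the smaller pixel id; keep a as root
    // record (1-based pixel ids)
    out_a.push_back(px_of[a] + 1);
    out_b.push_back(px_of[b] + 1);
    out_cost.push_back(m.cost < 0 ? 0.0 : m.cost);
    // union: b into a
    parent[b] = a;
    cnt[a] += cnt[b];
    for (int k = 0; k < nch; ++k) {
      sum[a][k] += sum[b][k];
      ssq[a][k] += ssq[b][k];
    }
    {
      auto it = blen.find(bkey(a, b));
      double shared = (it == blen.end()) ? 0.0 : it->second;
      if (it != blen.end()) blen.erase(it);
      perim[a] = perim[a] + perim[b] - 2.0 * shared;
      bb_r0[a] = std::min(bb_r0[a], bb_r0[b]);
      bb_r1[a] = std::max(bb_r1[a], bb_r1[b]);
      bb_c0[a] = std::min(bb_c0[a], bb_c0[b]);
      bb_c1[a] = std::max(bb_c1[a], bb_c1[b]);
    }
    ++version[a];
    // rebuild adjacency of a = union of neighbours' roots, minus a
    std::vector<int> nb;
    nb.reserve(adj[a].size() + adj[b].size());
    for (int t : adj[a]) { int rt = find(t); if (rt != a) nb.push_back(rt); }
    for (int t : adj[b]) { int rt = find(t); if (rt != a) nb.push_back(rt); }
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    // shared borders of the union with each neighbour root
    for (int t : nb) {
      double len = 0.0;
      auto ia = blen.find(bkey(a, t));
      if (ia != blen.end()) { len += ia->second; blen.erase(ia); }
      auto ib = blen.find(bkey(b, t));
      if (ib != blen.end()) { len += ib->second; blen.erase(ib); }
      blen[bkey(a, t)] = len;
    }
    adj[a] = nb;
    adj[b].clear(); adj[b].shrink_to_fit();
    for (int t : nb) push_pair(a, t);
  }

  return List::create(_["a"] = out_a, _["b"] = out_b, _["cost"] = out_cost);
}

// Replay the first k merges and return the label image (labels are 1-based
// pixel ids of region representatives; 0 outside the mask).
// [[Rcpp::export]]
IntegerMatrix cpp_cut_labels(const LogicalMatrix& mask,
                             const IntegerVector& a, const IntegerVector& b,
                             int k) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int npx = nr * nc;
  std::vector<int> parent(npx + 1);
  for (int i = 0; i <= npx; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int i = 0; i < k; ++i) {
    int ra = find(a[i]), rb = find(b[i]);
    if (ra == rb) continue;
    if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
  }
  IntegerMatrix lab(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      lab(r, c) = mask(r, c) ? find(r + c * nr + 1) : 0;
  return lab;
}

// ---------------------------------------------------------------------------
// Soft-disk stamping of optical-density contributions onto an accumulator
// defined over an arbitrary (sorted, increasing) pixel grid rows x cols.
// mode 0: additive (nuclei); mode 1: multiplicative clearing (lumens):
// M *= (1 - peak * profile).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
void cpp_stamp_disks(NumericMatrix M,
                     const NumericVector& rows, const NumericVector& cols,
                     const NumericVector& cy, const NumericVector& cx,
                     const NumericVector& rad, const NumericVector& peak,
                     double soft, int mode) {
  const int nr = rows.size(), nc = cols.size();
  const int n = cy.size();
  for (int i = 0; i < n; ++i) {
    double reach = rad[i] + soft;
    int r0 = std::lower_bound(rows.begin(), rows.end(), cy[i] - reach) -
             rows.begin();
    int r1 = std::upper_bound(rows.begin(), rows.end(), cy[i] + reach) -
             rows.begin();
    int c0 = std::lower_bound(cols.begin(), cols.end(), cx[i] - reach) -
             cols.begin();
    int c1 = std::upper_bound(cols.begin(), cols.end(), cx[i] + reach) -
             cols.begin();
    if (r0 >= r1 || c0 >= c1) continue;
    for (int c = c0; c < c1; ++c) {
      double dc2 = (cols[c] - cx[i]) * (cols[c] - cx[i]);
      for (int r = r0; r < r1; ++r) {
        double d = std::sqrt((rows[r] - cy[i]) * (rows[r] - cy[i]) + dc2);
        double p = (rad[i] + soft - d) / soft;
        if (p <= 0) continue;
        if (p > 1) p = 1;
        if (mode == 0) M(r, c) += peak[i] * p;
        else M(r, c) *= (1.0 - peak[i] * p);
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Region adjacency of a label image: pairs of distinct positive labels that
// share pixel edges (4-connectivity), with shared-border length in edges.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_label_adjacency(const IntegerMatrix& lab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  std::map<std::pair<int, int>, int> cnt;
  auto add = [&](int u, int v) {
    if (u <= 0 || v <= 0 || u == v) return;
    if (u > v) std::swap(u, v);
    ++cnt[std::make_pair(u, v)];
  };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (r + 1 < nr) add(lab(r, c), lab(r + 1, c));
      if (c + 1 < nc) add(lab(r, c), lab(r, c + 1));
    }
  const int m = (int)cnt.size();
  IntegerVector A(m), B(m), L(m);
  int i = 0;
  for (auto& kv : cnt) {
    A[i] = kv.first.first;
    B[i] = kv.first.second;
    L[i] = kv.second;
    ++i;
  }
  return DataFrame::create(_["a"] = A, _["b"] = B, _["border"] = L);
}

// Border length of each positive label against non-positive surroundings
// (image border counts): pixel edges from label L to pixels with a different
// value (any value, including 0) or off-image.
// [[Rcpp::export]]
DataFrame cpp_label_perimeter(const IntegerMatrix& lab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  std::map<int, int> per;
  auto edge = [&](int u, int v) {
    if (u > 0 && u != v) ++per[u];
    if (v > 0 && v != u) ++per[v];
  };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int u = lab(r, c);
      if (u > 0) {
        if (r == 0) ++per[u];
        if (r == nr - 1) ++per[u];
        if (c == 0) ++per[u];
        if (c == nc - 1) ++per[u];
      }
      if (r + 1 < nr) edge(lab(r, c), lab(r + 1, c));
      if (c + 1 < nc) edge(lab(r, c), lab(r, c + 1));
    }
  const int m = (int)per.size();
  IntegerVector id(m), p(m);
  int i = 0;
  for (auto& kv : per) { id[i] = kv.first; p[i] = kv.second; ++i; }
  return DataFrame::create(_["id"] = id, _["perimeter"] = p);
}
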
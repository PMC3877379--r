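// Marker-based 3-D watershed on a relief, 26-connectivity.
// Flooding proceeds from local-maximum markers downhill by priority queue;
// every masked voxel receives the label of the basin that reaches it first.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Entry {
  double value;
  std::int64_t seq;
  int idx;
  int label;
};

struct EntryCmp {
  // max-heap on value; FIFO on ties for determinism
  bool operator()(const Entry& a, const Entry& b) const {
    if (a.value != b.value) return a.value < b.value;
    return a.seq > b.seq;
  }
};

inline void neighbours26(int idx, int nx, int ny, int nz, std::vector<int>& out) {
  out.clear();
  int x = idx % nx;
  int y = (idx / nx) % ny;
  int z = idx / (nx * ny);
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int X = x + dx, Y = y + dy, Z = z + dz;
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        out.push_back(X + nx * (Y + ny * Z));
      }
}

} // namespace

// Markers: local maxima of `relief` over the 26-neighbourhood within mask.
// Equal-valued plateau maxima are collapsed to a single marker at the lowest
// linear index of their connected (26) equal-value component.
// Returns 1-based linear indices ordered by decreasing relief value, ties by
// increasing index.
// [[Rcpp::export(name = ".find_markers_cpp")]]
IntegerVector find_markers_cpp(NumericVector relief, LogicalVector mask,
                               IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nvox = nx * ny * nz;
  std::vector<int> nb;
  std::vector<char> cand(nvox, 0);

  for (int i = 0; i < nvox; ++i) {
    if (!mask[i]) continue;
    neighbours26(i, nx, ny, nz, nb);
    bool is_max = true;
    for (int j : nb) {
      if (mask[j] && relief[j] > relief[i]) { is_max = false; break; }
    }
    cand[i] = is_max ? 1 : 0;
  }

  // collapse equal-value plateau components of candidates (26-connected)
  std::vector<int> comp(nvox, -1);
  std::vector<std::pair<double, int> > markers; // (-value, min index)
  for (int i = 0; i < nvox; ++i) {
    if (!cand[i] || comp[i] != -1) continue;
    int cid = static_cast<int>(markers.size());
    int min_idx = i;
    double v = relief[i];
    std::queue<int> q;
    q.push(i);
    comp[i] = cid;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      if (c < min_idx) min_idx = c;
      neighbours26(c, nx, ny, nz, nb);
      for (int j : nb) {
        if (cand[j] && comp[j] == -1 && relief[j] == v) {
          comp[j] = cid;
          q.push(j);
        }
      }
    }
    markers.push_back(std::make_pair(-v, min_idx));
  }
  std::sort(markers.begin(), markers.end());
  IntegerVector out(markers.size());
  for (size_t k = 0; k < markers.size(); ++k) out[k] = markers[k].second + 1;
  return out;
}

// Priority flood from markers. `markers` are 1-based linear indices; marker k
// seeds label k. Returns an integer volume of labels (0 outside mask).
// [[Rcpp::export(name = ".watershed_flood_cpp")]]
IntegerVector watershed_flood_cpp(NumericVector relief, LogicalVector mask,
                                  IntegerVector dim, IntegerVector markers) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nvox = nx * ny * nz;
  IntegerVector labels(nvox, 0);
  std::priority_queue<Entry, std::vector<Entry>, EntryCmp> pq;
  std::int64_t seq = 0;
  std::vector<int> nb;

  for (int k = 0; k < markers.size(); ++k) {
    int idx = markers[k] - 1;
    pq.push(Entry{relief[idx], seq++, idx, k + 1});
  }

  while (!pq.empty()) {
    Entry e = pq.top(); pq.pop();
    if (labels[e.idx] != 0) continue;
    labels[e.idx] = e.label;
    neighbours26(e.idx, nx, ny, nz, nb);
    for (int j : nb) {
      if (mask[j] && labels[j] == 0) {
        pq.push(Entry{relief[j], seq++, j, e.label});
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// 26-connected component labelling of a logical volume (oracle-independent
// implementation detail used for plateau handling and atlas bookkeeping).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nvox = nx * ny * nz;
  IntegerVector labels(nvox, 0);
  std::vector<int> nb;
  int next = 0;
  for (int i = 0; i < nvox; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    std::queue<int> q;
    q.push(i);
    labels[i] = next;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      neighbours26(c, nx, ny, nz, nb);
      for (int j : nb) {
        if (mask[j] && labels[j] == 0) { labels[j] = next; q.push(j); }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}
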
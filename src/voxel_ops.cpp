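// Voxel-lattice algorithms used by the segmentation and phantom modules:
// seeded 26-connected region growing, connected-component labelling,
// anisotropic squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// and sequential topological thinning with the Bertrand-Malandain simple-point
// characterisation for the (26, 6) adjacency pair.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Dim3 {
  int nx, ny, nz;
  Dim3(const IntegerVector &d) : nx(d[0]), ny(d[1]), nz(d[2]) {}
  inline long size() const { return (long)nx * ny * nz; }
  inline long idx(int i, int j, int k) const {
    return (long)i + (long)nx * ((long)j + (long)ny * k);
  }
  inline bool inside(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
  }
};

// 26-neighbourhood offsets
static const int OFF26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}
};
static const int OFF6[6][3] = {
  {-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}
};

inline void lin2ijk(long v, const Dim3 &d, int &i, int &j, int &k) {
  i = (int)(v % d.nx);
  long r = v / d.nx;
  j = (int)(r % d.ny);
  k = (int)(r / d.ny);
}

// Extract the 3x3x3 neighbourhood of voxel (i,j,k); out-of-bounds = background.
inline void local_cube(const LogicalVector &mask, const Dim3 &d,
                       int i, int j, int k, bool cube[27]) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ii = i + dx, jj = j + dy, kk = k + dz;
        cube[n++] = d.inside(ii, jj, kk) && mask[d.idx(ii, jj, kk)];
      }
}

inline int cube_at(int dx, int dy, int dz) {  // dx,dy,dz in {-1,0,1}
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

// Number of 26-connected foreground components in N26(p) (centre excluded).
int n_fg_components26(const bool cube[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int c = 0; c < 27; ++c) {
    if (c == 13 || !cube[c] || seen[c]) continue;
    ++comps;
    std::vector<int> stack(1, c);
    seen[c] = true;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int vx = v % 3, vy = (v / 3) % 3, vz = v / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int wx = vx + dx, wy = vy + dy, wz = vz + dz;
            if (wx < 0 || wy < 0 || wz < 0 || wx > 2 || wy > 2 || wz > 2) continue;
            int w = wx + 3 * (wy + 3 * wz);
            if (w == 13 || w == v || seen[w] || !cube[w]) continue;
            seen[w] = true;
            stack.push_back(w);
          }
    }
  }
  return comps;
}

// Number of 6-connected background components in N18(p) that are 6-adjacent
// to the centre (i.e. contain a face neighbour). 6-connectivity is evaluated
// within the 18-neighbourhood only.
int n_bg_components6(const bool cube[27]) {
  bool in18[27] = {false};
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 1 || m == 2) in18[cube_at(dx, dy, dz)] = true;
      }
  bool seen[27] = {false};
  int comps = 0;
  for (int df = 0; df < 6; ++df) {  // grow only from face neighbours
    int c = cube_at(OFF6[df][0], OFF6[df][1], OFF6[df][2]);
    if (cube[c] || seen[c]) continue;
    ++comps;
    std::vector<int> stack(1, c);
    seen[c] = true;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int vx = v % 3, vy = (v / 3) % 3, vz = v / 9;
      for (int f = 0; f < 6; ++f) {
        int wx = vx + OFF6[f][0], wy = vy + OFF6[f][1], wz = vz + OFF6[f][2];
        if (wx < 0 || wy < 0 || wz < 0 || wx > 2 || wy > 2 || wz > 2) continue;
        int w = wx + 3 * (wy + 3 * wz);
        if (!in18[w] || seen[w] || cube[w]) continue;
        seen[w] = true;
        stack.push_back(w);
      }
    }
  }
  return comps;
}

inline bool is_simple(const bool cube[27]) {
  return n_fg_components26(cube) == 1 && n_bg_components6(cube) == 1;
}

int count_fg26(const LogicalVector &mask, const Dim3 &d, int i, int j, int k) {
  int n = 0;
  for (int m = 0; m < 26; ++m) {
    int ii = i + OFF26[m][0], jj = j + OFF26[m][1], kk = k + OFF26[m][2];
    if (d.inside(ii, jj, kk) && mask[d.idx(ii, jj, kk)]) ++n;
  }
  return n;
}

bool has_bg6(const LogicalVector &mask, const Dim3 &d, int i, int j, int k) {
  for (int m = 0; m < 6; ++m) {
    int ii = i + OFF6[m][0], jj = j + OFF6[m][1], kk = k + OFF6[m][2];
    if (!d.inside(ii, jj, kk) || !mask[d.idx(ii, jj, kk)]) return true;
  }
  return false;
}

// 1D lower envelope of parabolas (squared-distance transform pass).
void edt1d(std::vector<double> &f, double w2) {
  int n = (int)f.size();
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int p = 1; p < n; ++p) {
    double s;
    while (true) {
      s = ((f[p] + w2 * p * p) - (f[v[q]] + w2 * v[q] * v[q])) /
          (2.0 * w2 * (p - v[q]));
      if (s <= z[q]) { --q; } else break;
    }
    ++q;
    v[q] = p;
    z[q] = s;
    z[q + 1] = std::numeric_limits<double>::infinity();
  }
  q = 0;
  for (int p = 0; p < n; ++p) {
    while (z[q + 1] < p) ++q;
    d[p] = w2 * (p - v[q]) * (p - v[q]) + f[v[q]];
  }
  f = d;
}

}  // namespace

// [[Rcpp::export]]
LogicalVector cpp_seed_component(LogicalVector mask, IntegerVector dim, int seed) {
  // 26-connected component of `mask` containing 0-based linear index `seed`.
  Dim3 d(dim);
  LogicalVector out(mask.size(), false);
  if (seed < 0 || seed >= mask.size() || !mask[seed]) return out;
  std::vector<long> stack(1, (long)seed);
  out[seed] = true;
  while (!stack.empty()) {
    long v = stack.back(); stack.pop_back();
    int i, j, k;
    lin2ijk(v, d, i, j, k);
    for (int m = 0; m < 26; ++m) {
      int ii = i + OFF26[m][0], jj = j + OFF26[m][1], kk = k + OFF26[m][2];
      if (!d.inside(ii, jj, kk)) continue;
      long w = d.idx(ii, jj, kk);
      if (mask[w] && !out[w]) {
        out[w] = true;
        stack.push_back(w);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  // 26-connected component labels, 0 for background; labels ordered by
  // first-encountered linear index (deterministic).
  Dim3 d(dim);
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  for (long s = 0; s < (long)mask.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    std::vector<long> stack(1, s);
    lab[s] = next;
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int i, j, k;
      lin2ijk(v, d, i, j, k);
      for (int m = 0; m < 26; ++m) {
        int ii = i + OFF26[m][0], jj = j + OFF26[m][1], kk = k + OFF26[m][2];
        if (!d.inside(ii, jj, kk)) continue;
        long w = d.idx(ii, jj, kk);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  // Squared Euclidean distance (mm^2) from each foreground voxel centre to the
  // nearest background voxel centre; 0 on background. Anisotropic spacing.
  Dim3 d(dim);
  const double INF = 1e30;
  std::vector<double> g(d.size());
  for (long v = 0; v < d.size(); ++v) g[v] = mask[v] ? INF : 0.0;

  std::vector<double> line;
  // x pass
  line.resize(d.nx);
  for (int k = 0; k < d.nz; ++k)
    for (int j = 0; j < d.ny; ++j) {
      for (int i = 0; i < d.nx; ++i) line[i] = g[d.idx(i, j, k)];
      edt1d(line, spacing[0] * spacing[0]);
      for (int i = 0; i < d.nx; ++i) g[d.idx(i, j, k)] = line[i];
    }
  // y pass
  line.resize(d.ny);
  for (int k = 0; k < d.nz; ++k)
    for (int i = 0; i < d.nx; ++i) {
      for (int j = 0; j < d.ny; ++j) line[j] = g[d.idx(i, j, k)];
      edt1d(line, spacing[1] * spacing[1]);
      for (int j = 0; j < d.ny; ++j) g[d.idx(i, j, k)] = line[j];
    }
  // z pass
  line.resize(d.nz);
  for (int j = 0; j < d.ny; ++j)
    for (int i = 0; i < d.nx; ++i) {
      for (int k = 0; k < d.nz; ++k) line[k] = g[d.idx(i, j, k)];
      edt1d(line, spacing[2] * spacing[2]);
      for (int k = 0; k < d.nz; ++k) g[d.idx(i, j, k)] = line[k];
    }

  NumericVector out(d.size());
  for (long v = 0; v < d.size(); ++v) out[v] = g[v];
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim,
                              NumericVector priority) {
  // Sequential thinning to a medially-centred curve skeleton. Anchor voxels
  // — non-strict local maxima of the priority (distance transform) over the
  // foreground 26-neighbourhood, i.e. the medial ridge — are never removed.
  // All other border voxels are deleted in increasing priority order when
  // they are simple points; iterated to stability. The sequential re-check
  // keeps topology exact, and anchoring the ridge (rather than protecting
  // emergent curve endpoints) avoids spurs crawling to cap rims.
  Dim3 d(dim);
  LogicalVector m = clone(mask);

  std::vector<bool> anchor(d.size(), false);
  for (long v = 0; v < d.size(); ++v) {
    if (!m[v]) continue;
    int i, j, k;
    lin2ijk(v, d, i, j, k);
    bool amax = true;
    for (int t = 0; t < 26 && amax; ++t) {
      int ii = i + OFF26[t][0], jj = j + OFF26[t][1], kk = k + OFF26[t][2];
      if (d.inside(ii, jj, kk)) {
        long w = d.idx(ii, jj, kk);
        if (m[w] && priority[w] > priority[v]) amax = false;
      }
    }
    anchor[v] = amax;
  }

  bool cube[27];
  bool changed = true;
  while (changed) {
    changed = false;
    std::vector<std::pair<double, long> > border;
    for (long v = 0; v < d.size(); ++v) {
      if (!m[v] || anchor[v]) continue;
      int i, j, k;
      lin2ijk(v, d, i, j, k);
      if (has_bg6(m, d, i, j, k)) border.push_back(std::make_pair(priority[v], v));
    }
    std::sort(border.begin(), border.end());
    for (size_t b = 0; b < border.size(); ++b) {
      long v = border[b].second;
      if (!m[v]) continue;
      int i, j, k;
      lin2ijk(v, d, i, j, k);
      local_cube(m, d, i, j, k, cube);
      if (is_simple(cube)) {
        m[v] = false;
        changed = true;
      }
    }
  }
  return m;
}

// [[Rcpp::export]]
LogicalVector cpp_is_simple_point(LogicalVector mask, IntegerVector dim,
                                  IntegerVector idx) {
  // Exposed for testing: simple-point status of 0-based linear indices.
  Dim3 d(dim);
  LogicalVector out(idx.size());
  bool cube[27];
  for (int n = 0; n < idx.size(); ++n) {
    int i, j, k;
    lin2ijk(idx[n], d, i, j, k);
    local_cube(mask, d, i, j, k, cube);
    out[n] = is_simple(cube);
  }
  return out;
}
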
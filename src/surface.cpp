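// Isosurface extraction by marching tetrahedra on the Kuhn (6-tetrahedra)
// subdivision of each lattice cube. The Kuhn subdivision tiles space
// consistently across cube faces, so the extracted triangle mesh of a closed
// region is watertight without the ambiguous-case tables marching cubes needs.

#include <Rcpp.h>
#include <map>
#include <utility>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct MeshBuilder {
  std::map<std::pair<long, long>, int> edge_vertex;  // (lo corner, hi corner) -> vertex id
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  int edge_point(long ga, long gb, const double *px, const double *py,
                 const double *pz, double va, double vb, double level) {
    std::pair<long, long> key = ga < gb ? std::make_pair(ga, gb)
                                        : std::make_pair(gb, ga);
    std::map<std::pair<long, long>, int>::iterator it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - va) / (vb - va);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    int id = (int)vx.size();
    vx.push_back(px[0] + t * (px[1] - px[0]));
    vy.push_back(py[0] + t * (py[1] - py[0]));
    vz.push_back(pz[0] + t * (pz[1] - pz[0]));
    edge_vertex[key] = id;
    return id;
  }

  void add_tri(int a, int b, int c, const double nref[3]) {
    // orient so the normal points along nref (inside -> outside)
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
    if (nx * nref[0] + ny * nref[1] + nz * nref[2] < 0) std::swap(b, c);
    f0.push_back(a);
    f1.push_back(b);
    f2.push_back(c);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector vals, IntegerVector dim,
                        NumericVector spacing, NumericVector origin,
                        double level) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  MeshBuilder mb;

  // Kuhn subdivision: tetrahedra follow the 6 axis orderings along the main
  // diagonal (0,0,0) -> (1,1,1) of each cube.
  static const int PERMS[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // skip uniform cubes quickly
        double cmin = 1e300, cmax = -1e300;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          double v = vals[(long)ci + (long)nx * ((long)cj + (long)ny * ck)];
          if (v < cmin) cmin = v;
          if (v > cmax) cmax = v;
        }
        if (cmin > level || cmax <= level) continue;

        for (int t = 0; t < 6; ++t) {
          int corner[4][3];
          corner[0][0] = 0; corner[0][1] = 0; corner[0][2] = 0;
          for (int s = 1; s <= 3; ++s) {
            for (int a = 0; a < 3; ++a) corner[s][a] = corner[s - 1][a];
            corner[s][PERMS[t][s - 1]] = 1;
          }
          long gid[4];
          double tvals[4], tx[4], ty[4], tz[4];
          int inside[4], nin = 0;
          for (int s = 0; s < 4; ++s) {
            int ci = i + corner[s][0], cj = j + corner[s][1], ck = k + corner[s][2];
            gid[s] = (long)ci + (long)nx * ((long)cj + (long)ny * ck);
            tvals[s] = vals[gid[s]];
            tx[s] = origin[0] + ci * spacing[0];
            ty[s] = origin[1] + cj * spacing[1];
            tz[s] = origin[2] + ck * spacing[2];
            inside[s] = tvals[s] > level;
            nin += inside[s];
          }
          if (nin == 0 || nin == 4) continue;

          // reference direction: inside centroid -> outside centroid
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          for (int s = 0; s < 4; ++s) {
            double *acc = inside[s] ? cin : cout;
            acc[0] += tx[s]; acc[1] += ty[s]; acc[2] += tz[s];
          }
          double nref[3];
          for (int a = 0; a < 3; ++a)
            nref[a] = cout[a] / (4 - nin) - cin[a] / nin;

          int in_ids[4], out_ids[4], ni = 0, no = 0;
          for (int s = 0; s < 4; ++s) {
            if (inside[s]) in_ids[ni++] = s; else out_ids[no++] = s;
          }

          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in_ids[0] : out_ids[0];
            int others[3], m = 0;
            for (int s = 0; s < 4; ++s) if (s != apex) others[m++] = s;
            int vid[3];
            for (int e = 0; e < 3; ++e) {
              int b = others[e];
              double px[2] = {tx[apex], tx[b]}, py[2] = {ty[apex], ty[b]},
                     pz[2] = {tz[apex], tz[b]};
              vid[e] = mb.edge_point(gid[apex], gid[b], px, py, pz,
                                     tvals[apex], tvals[b], level);
            }
            mb.add_tri(vid[0], vid[1], vid[2], nref);
          } else {  // 2 in, 2 out -> quad
            int a = in_ids[0], b = in_ids[1], c = out_ids[0], dd = out_ids[1];
            int q[4];
            int pairs[4][2] = {{a, c}, {a, dd}, {b, dd}, {b, c}};
            for (int e = 0; e < 4; ++e) {
              int u = pairs[e][0], w = pairs[e][1];
              double px[2] = {tx[u], tx[w]}, py[2] = {ty[u], ty[w]},
                     pz[2] = {tz[u], tz[w]};
              q[e] = mb.edge_point(gid[u], gid[w], px, py, pz,
                                   tvals[u], tvals[w], level);
            }
            mb.add_tri(q[0], q[1], q[2], nref);
            mb.add_tri(q[0], q[2], q[3], nref);
          }
        }
      }

  int nv = (int)mb.vx.size(), nf = (int)mb.f0.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = mb.vx[v]; V(v, 1) = mb.vy[v]; V(v, 2) = mb.vz[v];
  }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = mb.f0[f] + 1; F(f, 1) = mb.f1[f] + 1; F(f, 2) = mb.f2[f] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
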
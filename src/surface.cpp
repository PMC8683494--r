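#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Kuhn (6-tet) decomposition of the unit cube around the 0-7 diagonal.
// Corner ids encode offsets: bit0 = x, bit1 = y, bit2 = z. The split is
// translation invariant, so shared cube faces are triangulated identically
// in neighboring cubes and the extracted surface is conforming.
static const int KUHN[6][4] = {
  {0, 1, 3, 7}, {0, 2, 3, 7}, {0, 2, 6, 7},
  {0, 4, 6, 7}, {0, 4, 5, 7}, {0, 1, 5, 7}
};

struct MTState {
  std::map<std::pair<R_xlen_t, R_xlen_t>, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

// Marching tetrahedra over a scalar field sampled at voxel centers.
// Extracts the level set {field == level}; "inside" means field < level.
// [[Rcpp::export(name = ".marching_tets_cpp")]]
List marching_tets_cpp(NumericVector field, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  MTState st;
  auto lin = [&](int i, int j, int k) {
    return (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
  };
  auto coord = [&](R_xlen_t id, double *p) {
    int i = (int)(id % nx);
    int j = (int)((id / nx) % ny);
    int k = (int)(id / ((R_xlen_t)nx * ny));
    p[0] = origin[0] + i * spacing[0];
    p[1] = origin[1] + j * spacing[1];
    p[2] = origin[2] + k * spacing[2];
  };
  auto edge_vert = [&](R_xlen_t a, R_xlen_t b) {
    if (a > b) std::swap(a, b);
    auto key = std::make_pair(a, b);
    auto it = st.edge_vertex.find(key);
    if (it != st.edge_vertex.end()) return it->second;
    double pa[3], pb[3];
    coord(a, pa); coord(b, pb);
    double fa = field[a], fb = field[b];
    double t = (fa == fb) ? 0.5 : (level - fa) / (fb - fa);
    if (t < 0) t = 0; if (t > 1) t = 1;
    st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int)st.vx.size();  // 1-based
    st.edge_vertex[key] = id;
    return id;
  };
  auto add_tri = [&](int a, int b, int c,
                     const double *cin, const double *cout) {
    // orient so the normal points from inside (field < level) to outside
    const double &ax = st.vx[a - 1], &ay = st.vy[a - 1], &az = st.vz[a - 1];
    double u[3] = {st.vx[b - 1] - ax, st.vy[b - 1] - ay, st.vz[b - 1] - az};
    double v[3] = {st.vx[c - 1] - ax, st.vy[c - 1] - ay, st.vz[c - 1] - az};
    double nrm[3] = {u[1] * v[2] - u[2] * v[1],
                     u[2] * v[0] - u[0] * v[2],
                     u[0] * v[1] - u[1] * v[0]};
    double dir[3] = {cout[0] - cin[0], cout[1] - cin[1], cout[2] - cin[2]};
    double dot = nrm[0] * dir[0] + nrm[1] * dir[1] + nrm[2] * dir[2];
    if (dot < 0) std::swap(b, c);
    st.tri.push_back(a); st.tri.push_back(b); st.tri.push_back(c);
  };

  R_xlen_t corner[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c)
          corner[c] = lin(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
        for (int t = 0; t < 6; ++t) {
          R_xlen_t vtx[4];
          bool in[4];
          int nin = 0;
          for (int m = 0; m < 4; ++m) {
            vtx[m] = corner[KUHN[t][m]];
            in[m] = field[vtx[m]] < level;
            if (in[m]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0}, p[3];
          for (int m = 0; m < 4; ++m) {
            coord(vtx[m], p);
            double *dst = in[m] ? cin : cout;
            dst[0] += p[0]; dst[1] += p[1]; dst[2] += p[2];
          }
          for (int d = 0; d < 3; ++d) {
            cin[d] /= nin; cout[d] /= (4 - nin);
          }
          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int m = 0; m < 4; ++m)
              if (in[m] == (nin == 1)) apex = m;
            int vids[3], w = 0;
            for (int m = 0; m < 4; ++m)
              if (m != apex) vids[w++] = edge_vert(vtx[apex], vtx[m]);
            add_tri(vids[0], vids[1], vids[2], cin, cout);
          } else {  // 2-2 case: quad
            int ia[2], ib[2], wa = 0, wb = 0;
            for (int m = 0; m < 4; ++m)
              (in[m] ? ia[wa++] : ib[wb++]) = m;
            int q1 = edge_vert(vtx[ia[0]], vtx[ib[0]]);
            int q2 = edge_vert(vtx[ia[0]], vtx[ib[1]]);
            int q3 = edge_vert(vtx[ia[1]], vtx[ib[1]]);
            int q4 = edge_vert(vtx[ia[1]], vtx[ib[0]]);
            add_tri(q1, q2, q3, cin, cout);
            add_tri(q1, q3, q4, cin, cout);
          }
        }
      }

  int nv = (int)st.vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  int nf = (int)st.tri.size() / 3;
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = st.tri[3 * i];
    F(i, 1) = st.tri[3 * i + 1];
    F(i, 2) = st.tri[3 * i + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Closest point on triangle (Ericson, Real-Time Collision Detection).
static void closest_on_tri(const double *p, const double *a, const double *b,
                           const double *c, double *out) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Nearest point on a triangle soup for each query point.
// [[Rcpp::export(name = ".mesh_nearest_cpp")]]
List mesh_nearest_cpp(NumericMatrix query, NumericMatrix V, IntegerMatrix F) {
  int nq = query.nrow(), nf = F.nrow();
  NumericMatrix pts(nq, 3);
  NumericVector dist(nq);
  for (int q = 0; q < nq; ++q) {
    double p[3] = {query(q, 0), query(q, 1), query(q, 2)};
    double best = std::numeric_limits<double>::infinity();
    double bestp[3] = {p[0], p[1], p[2]};
    for (int f = 0; f < nf; ++f) {
      double a[3] = {V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2)};
      double b[3] = {V(F(f, 1) - 1, 0), V(F(f, 1) - 1, 1), V(F(f, 1) - 1, 2)};
      double c[3] = {V(F(f, 2) - 1, 0), V(F(f, 2) - 1, 1), V(F(f, 2) - 1, 2)};
      double out[3];
      closest_on_tri(p, a, b, c, out);
      double dx = out[0] - p[0], dy = out[1] - p[1], dz = out[2] - p[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bestp[0] = out[0]; bestp[1] = out[1]; bestp[2] = out[2];
      }
    }
    pts(q, 0) = bestp[0]; pts(q, 1) = bestp[1]; pts(q, 2) = bestp[2];
    dist[q] = std::sqrt(best);
  }
  return List::create(_["points"] = pts, _["distance"] = dist);
}

// Nearest (smallest |t|) intersection of the line origin + t*dir with the
// mesh, t of either sign. Returns hit flag, t, and the point.
// [[Rcpp::export(name = ".mesh_line_hit_cpp")]]
List mesh_line_hit_cpp(NumericVector origin, NumericVector dir,
                       NumericMatrix V, IntegerMatrix F) {
  int nf = F.nrow();
  double best_t = std::numeric_limits<double>::infinity();
  bool hit = false;
  const double eps = 1e-12;
  for (int f = 0; f < nf; ++f) {
    double a[3] = {V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2)};
    double e1[3] = {V(F(f, 1) - 1, 0) - a[0], V(F(f, 1) - 1, 1) - a[1],
                    V(F(f, 1) - 1, 2) - a[2]};
    double e2[3] = {V(F(f, 2) - 1, 0) - a[0], V(F(f, 2) - 1, 1) - a[1],
                    V(F(f, 2) - 1, 2) - a[2]};
    double p[3] = {dir[1] * e2[2] - dir[2] * e2[1],
                   dir[2] * e2[0] - dir[0] * e2[2],
                   dir[0] * e2[1] - dir[1] * e2[0]};
    double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
    if (std::fabs(det) < eps) continue;
    double inv = 1.0 / det;
    double tv[3] = {origin[0] - a[0], origin[1] - a[1], origin[2] - a[2]};
    double u = (tv[0] * p[0] + tv[1] * p[1] + tv[2] * p[2]) * inv;
    if (u < -1e-9 || u > 1 + 1e-9) continue;
    double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                    tv[2] * e1[0] - tv[0] * e1[2],
                    tv[0] * e1[1] - tv[1] * e1[0]};
    double v = (dir[0] * qv[0] + dir[1] * qv[1] + dir[2] * qv[2]) * inv;
    if (v < -1e-9 || u + v > 1 + 1e-9) continue;
    double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
    if (std::fabs(t) < std::fabs(best_t)) { best_t = t; hit = true; }
  }
  NumericVector pt(3);
  if (hit)
    for (int i = 0; i < 3; ++i) pt[i] = origin[i] + best_t * dir[i];
  return List::create(_["hit"] = hit, _["t"] = hit ? best_t : NA_REAL,
                      _["point"] = pt);
}
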
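#include <Rcpp.h>
#include <array>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental 3D Delaunay tetrahedralization (Bowyer-Watson) with ghost
// tetrahedra representing the outside of the convex hull. Inputs are assumed
// to be pre-conditioned by the R wrapper (centred, scaled, symbolically
// jittered), which also audits the result and retries with a larger jitter
// if a degenerate configuration slipped through.

struct Tet {
  int v[4];     // vertex ids; v[3] == -1 marks a ghost tet (virtual apex)
  bool alive;
};

static inline double orient3d(const double *a, const double *b,
                              const double *c, const double *d) {
  // > 0 when d lies on the positive side of plane (a,b,c) (right-handed)
  double adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  double bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  double cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy)
       - ady * (bdx * cdz - bdz * cdx)
       + adz * (bdx * cdy - bdy * cdx);
}

static inline double insphere(const double *a, const double *b, const double *c,
                              const double *d, const double *p) {
  // for a positively oriented tet (orient3d(a,b,c,d) > 0), > 0 iff p lies
  // inside the circumsphere
  double ax = a[0] - p[0], ay = a[1] - p[1], az = a[2] - p[2];
  double bx = b[0] - p[0], by = b[1] - p[1], bz = b[2] - p[2];
  double cx = c[0] - p[0], cy = c[1] - p[1], cz = c[2] - p[2];
  double dx = d[0] - p[0], dy = d[1] - p[1], dz = d[2] - p[2];
  double a2 = ax * ax + ay * ay + az * az;
  double b2 = bx * bx + by * by + bz * bz;
  double c2 = cx * cx + cy * cy + cz * cz;
  double d2 = dx * dx + dy * dy + dz * dz;
  // det of 4x4 [ax ay az a2; bx ...; cx ...; dx ...]
  auto det3 = [](double m00, double m01, double m02,
                 double m10, double m11, double m12,
                 double m20, double m21, double m22) {
    return m00 * (m11 * m22 - m12 * m21)
         - m01 * (m10 * m22 - m12 * m20)
         + m02 * (m10 * m21 - m11 * m20);
  };
  double det = a2 * det3(bx, by, bz, cx, cy, cz, dx, dy, dz)
             - b2 * det3(ax, ay, az, cx, cy, cz, dx, dy, dz)
             + c2 * det3(ax, ay, az, bx, by, bz, dx, dy, dz)
             - d2 * det3(ax, ay, az, bx, by, bz, cx, cy, cz);
  return det; // sign convention checked against centroid-of-tet in tests
}

typedef std::array<int, 3> FaceKey;
static inline FaceKey facekey(int a, int b, int c) {
  FaceKey f{a, b, c};
  std::sort(f.begin(), f.end());
  return f;
}

// [[Rcpp::export]]
List cpp_delaunay3d(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<std::array<double, 3>> P(n);
  for (int i = 0; i < n; ++i) P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};

  // initial tet: points 0,1 then first non-collinear, then first non-coplanar
  int i2 = -1, i3 = -1;
  for (int i = 2; i < n; ++i) {
    // area of triangle 0,1,i
    double u0 = P[1][0] - P[0][0], u1 = P[1][1] - P[0][1], u2 = P[1][2] - P[0][2];
    double v0 = P[i][0] - P[0][0], v1 = P[i][1] - P[0][1], v2 = P[i][2] - P[0][2];
    double cx = u1 * v2 - u2 * v1, cy = u2 * v0 - u0 * v2, cz = u0 * v1 - u1 * v0;
    if (std::sqrt(cx * cx + cy * cy + cz * cz) > 1e-12) { i2 = i; break; }
  }
  if (i2 < 0) stop("degenerate input: all points collinear");
  for (int i = 2; i < n; ++i) {
    if (i == i2) continue;
    if (std::fabs(orient3d(P[0].data(), P[1].data(), P[i2].data(), P[i].data())) > 1e-14) { i3 = i; break; }
  }
  if (i3 < 0) stop("degenerate input: all points coplanar");

  std::vector<Tet> T;
  {
    int a = 0, b = 1, c = i2, d = i3;
    if (orient3d(P[a].data(), P[b].data(), P[c].data(), P[d].data()) < 0) std::swap(c, d);
    T.push_back({{a, b, c, d}, true});
    // ghost tets on each face, real face stored in v[0..2], ghost apex v[3]=-1.
    // face orientation: outward (opposite vertex on the negative side)
    int f[4][3] = {{b, d, c}, {a, c, d}, {a, d, b}, {a, b, c}};
    // ensure outward orientation: for face opposite vertex x, orient3d(face, x) < 0
    int opp[4] = {a, b, c, d};
    for (int m = 0; m < 4; ++m) {
      int fa = f[m][0], fb = f[m][1], fc = f[m][2];
      if (orient3d(P[fa].data(), P[fb].data(), P[fc].data(), P[opp[m]].data()) > 0)
        std::swap(fb, fc);
      T.push_back({{fa, fb, fc, -1}, true});
    }
  }

  std::vector<int> bad;
  std::vector<char> isbad;
  for (int ip = 0; ip < n; ++ip) {
    if (ip == 0 || ip == 1 || ip == i2 || ip == i3) continue;
    const double *p = P[ip].data();
    bad.clear();
    isbad.assign(T.size(), 0);
    for (size_t t = 0; t < T.size(); ++t) {
      if (!T[t].alive) continue;
      const Tet &tt = T[t];
      bool conflict;
      if (tt.v[3] == -1) {
        conflict = orient3d(P[tt.v[0]].data(), P[tt.v[1]].data(),
                            P[tt.v[2]].data(), p) > 0; // p visible from hull face
      } else {
        conflict = insphere(P[tt.v[0]].data(), P[tt.v[1]].data(),
                            P[tt.v[2]].data(), P[tt.v[3]].data(), p) > 0;
      }
      if (conflict) { bad.push_back((int)t); isbad[t] = 1; }
    }
    if (bad.empty()) continue; // duplicate / degenerate point: skip

    // boundary faces of the conflict cavity: faces of bad tets shared with a
    // live non-bad tet, or unshared. Count faces over bad tets.
    std::map<FaceKey, std::pair<std::array<int, 3>, int>> fcount;
    for (int t : bad) {
      const Tet &tt = T[t];
      const int fidx[4][3] = {{1, 3, 2}, {0, 2, 3}, {0, 3, 1}, {0, 1, 2}};
      for (int m = 0; m < 4; ++m) {
        std::array<int, 3> fv = {tt.v[fidx[m][0]], tt.v[fidx[m][1]], tt.v[fidx[m][2]]};
        FaceKey key = facekey(fv[0], fv[1], fv[2]);
        auto it = fcount.find(key);
        if (it == fcount.end()) fcount[key] = {fv, 1};
        else it->second.second += 1;
      }
    }
    for (int t : bad) T[t].alive = false;
    std::vector<int> created;
    for (auto &kv : fcount) {
      if (kv.second.second != 1) continue; // interior to cavity
      std::array<int, 3> fv = kv.second.first;
      Tet nt;
      if (fv[0] == -1 || fv[1] == -1 || fv[2] == -1) {
        // face containing the ghost apex: silhouette edge -> new ghost tet
        int e[2], ne = 0;
        for (int m = 0; m < 3; ++m) if (fv[m] != -1) e[ne++] = fv[m];
        nt.v[0] = e[0]; nt.v[1] = e[1]; nt.v[2] = ip; nt.v[3] = -1;
        // orient outward later (after insertion we fix using centroid)
      } else {
        nt.v[0] = fv[0]; nt.v[1] = fv[1]; nt.v[2] = fv[2]; nt.v[3] = ip;
        if (orient3d(P[nt.v[0]].data(), P[nt.v[1]].data(), P[nt.v[2]].data(),
                     P[nt.v[3]].data()) < 0)
          std::swap(nt.v[1], nt.v[2]);
      }
      nt.alive = true;
      created.push_back((int)T.size());
      T.push_back(nt);
    }
    // fix ghost orientations: outward means all other points on negative side;
    // use the (interior) centroid of the initial tet
    static double cen[3];
    cen[0] = (P[0][0] + P[1][0] + P[i2][0] + P[i3][0]) / 4.0;
    cen[1] = (P[0][1] + P[1][1] + P[i2][1] + P[i3][1]) / 4.0;
    cen[2] = (P[0][2] + P[1][2] + P[i2][2] + P[i3][2]) / 4.0;
    for (int t : created) {
      Tet &tt = T[t];
      if (tt.v[3] != -1) continue;
      if (orient3d(P[tt.v[0]].data(), P[tt.v[1]].data(), P[tt.v[2]].data(), cen) > 0)
        std::swap(tt.v[1], tt.v[2]);
    }
  }

  // collect live real tets; compute circumradii
  std::vector<std::array<int, 4>> out;
  std::vector<double> crad;
  for (const Tet &tt : T) {
    if (!tt.alive || tt.v[3] == -1) continue;
    out.push_back({tt.v[0], tt.v[1], tt.v[2], tt.v[3]});
    // circumcenter: solve 2 (B-A; C-A; D-A) x = (|B|^2-|A|^2; ...)
    const double *A = P[tt.v[0]].data(), *B = P[tt.v[1]].data(),
                 *C = P[tt.v[2]].data(), *D = P[tt.v[3]].data();
    double M[3][3] = {
      {B[0] - A[0], B[1] - A[1], B[2] - A[2]},
      {C[0] - A[0], C[1] - A[1], C[2] - A[2]},
      {D[0] - A[0], D[1] - A[1], D[2] - A[2]}};
    // in the frame with A at the origin the circumcenter x solves
    // M x = rhs with rhs[m] = |row_m|^2 / 2; |x| is then the circumradius
    double rhs[3];
    for (int m = 0; m < 3; ++m)
      rhs[m] = 0.5 * (M[m][0] * M[m][0] + M[m][1] * M[m][1] + M[m][2] * M[m][2]);
    double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1])
               - M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0])
               + M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
    double r;
    if (std::fabs(det) < 1e-300) {
      r = R_PosInf; // flat sliver: infinite circumradius
    } else {
      auto solve = [&](int col) {
        double N[3][3];
        for (int rr = 0; rr < 3; ++rr)
          for (int cc = 0; cc < 3; ++cc) N[rr][cc] = (cc == col) ? rhs[rr] : M[rr][cc];
        return (N[0][0] * (N[1][1] * N[2][2] - N[1][2] * N[2][1])
              - N[0][1] * (N[1][0] * N[2][2] - N[1][2] * N[2][0])
              + N[0][2] * (N[1][0] * N[2][1] - N[1][1] * N[2][0])) / det;
      };
      double x = solve(0), y = solve(1), z = solve(2);
      r = std::sqrt(x * x + y * y + z * z);
    }
    crad.push_back(r);
  }
  IntegerMatrix tm(out.size(), 4);
  NumericVector rv(out.size());
  for (size_t t = 0; t < out.size(); ++t) {
    for (int m = 0; m < 4; ++m) tm(t, m) = out[t][m] + 1; // 1-based for R
    rv[t] = crad[t];
  }
  return List::create(_["tets"] = tm, _["circumradius"] = rv);
}
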
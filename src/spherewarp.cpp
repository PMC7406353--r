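#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Point location and warp optimization on triangulated spheres.
//
// Conventions: vertices are unit 3-vectors, faces are counter-clockwise seen
// from outside (det[a,b,c] > 0). A query direction q is located by central
// projection: solve [va vb vc] x = q; q lies in the spherical triangle iff all
// coefficients are non-negative. Location walks across the face adjacency from
// a hint (or the nearest vertex found through a uniform spatial grid).

namespace {

struct Mesh {
  int n = 0, m = 0;
  const double* V;            // n x 3, column-major (R layout)
  const int* F;               // m x 3, 0-based, column-major
  std::vector<int> adj;       // m x 3: neighbor across edge opposite corner j
  std::vector<int> vface;     // one incident face per vertex
  int G = 0;                  // grid resolution
  std::vector<std::vector<int>> cells;

  double vx(int i, int k) const { return V[i + (size_t)n * k]; }
  int fv(int f, int k) const { return F[f + (size_t)m * k]; }

  int cellIndex(double x, double y, double z) const {
    int ix = std::min(G - 1, std::max(0, (int)((x + 1.0) * 0.5 * G)));
    int iy = std::min(G - 1, std::max(0, (int)((y + 1.0) * 0.5 * G)));
    int iz = std::min(G - 1, std::max(0, (int)((z + 1.0) * 0.5 * G)));
    return ix + G * (iy + G * iz);
  }

  void build() {
    adj.assign((size_t)m * 3, -1);
    vface.assign(n, -1);
    // pair half-edges by sorting (edge key, half-edge id) — much faster than
    // hashing for large meshes
    std::vector<int64_t> enc((size_t)m * 3);
    const int64_t H = (int64_t)m * 3;
    for (int f = 0; f < m; ++f) {
      for (int j = 0; j < 3; ++j) {
        int a = fv(f, (j + 1) % 3), b = fv(f, (j + 2) % 3);
        if (vface[a] < 0) vface[a] = f;
        int64_t lo = std::min(a, b), hi = std::max(a, b);
        int64_t key = lo * (int64_t)n + hi;
        enc[(size_t)f * 3 + j] = key * H + ((int64_t)f * 3 + j);
      }
    }
    std::sort(enc.begin(), enc.end());
    for (size_t i = 0; i + 1 < enc.size(); ++i) {
      if (enc[i] / H == enc[i + 1] / H) {
        int64_t h1 = enc[i] % H, h2 = enc[i + 1] % H;
        adj[(size_t)h1] = (int)(h2 / 3);
        adj[(size_t)h2] = (int)(h1 / 3);
        ++i;
      }
    }
    G = std::max(4, (int)std::cbrt((double)n));
    cells.assign((size_t)G * G * G, {});
    for (int i = 0; i < n; ++i)
      cells[cellIndex(vx(i, 0), vx(i, 1), vx(i, 2))].push_back(i);
  }

  int nearestVertex(const double q[3]) const {
    int qx = std::min(G - 1, std::max(0, (int)((q[0] + 1.0) * 0.5 * G)));
    int qy = std::min(G - 1, std::max(0, (int)((q[1] + 1.0) * 0.5 * G)));
    int qz = std::min(G - 1, std::max(0, (int)((q[2] + 1.0) * 0.5 * G)));
    int best = -1;
    double bestd = 1e300;
    for (int r = 0; r < G; ++r) {
      bool any = false;
      for (int ix = std::max(0, qx - r); ix <= std::min(G - 1, qx + r); ++ix)
        for (int iy = std::max(0, qy - r); iy <= std::min(G - 1, qy + r); ++iy)
          for (int iz = std::max(0, qz - r); iz <= std::min(G - 1, qz + r); ++iz) {
            if (std::max(std::abs(ix - qx),
                         std::max(std::abs(iy - qy), std::abs(iz - qz))) != r)
              continue;  // only the shell at radius r
            for (int i : cells[ix + G * (iy + G * iz)]) {
              any = true;
              double dx = vx(i, 0) - q[0], dy = vx(i, 1) - q[1],
                     dz = vx(i, 2) - q[2];
              double d = dx * dx + dy * dy + dz * dz;
              if (d < bestd) { bestd = d; best = i; }
            }
          }
      if (best >= 0 && !any && r > 0) break;
      if (best >= 0 && r >= 1 && any) break;  // scanned one extra shell
    }
    return best < 0 ? 0 : best;
  }
};

// Solve [a b c] x = q for a triangle given by vertex indices of face f over
// point coordinates P (n x 3 column-major, np rows). Returns false if the
// system is numerically singular.
inline bool solveFace(const Mesh& M, const double* P, int np, int f,
                      const double q[3], double x[3]) {
  int ia = M.fv(f, 0), ib = M.fv(f, 1), ic = M.fv(f, 2);
  double a0 = P[ia], a1 = P[ia + np], a2 = P[ia + 2 * np];
  double b0 = P[ib], b1 = P[ib + np], b2 = P[ib + 2 * np];
  double c0 = P[ic], c1 = P[ic + np], c2 = P[ic + 2 * np];
  double det = a0 * (b1 * c2 - b2 * c1) - b0 * (a1 * c2 - a2 * c1) +
               c0 * (a1 * b2 - a2 * b1);
  if (std::abs(det) < 1e-300) return false;
  x[0] = (q[0] * (b1 * c2 - b2 * c1) - b0 * (q[1] * c2 - q[2] * c1) +
          c0 * (q[1] * b2 - q[2] * b1)) / det;
  x[1] = (a0 * (q[1] * c2 - q[2] * c1) - q[0] * (a1 * c2 - a2 * c1) +
          c0 * (a1 * q[2] - a2 * q[1])) / det;
  x[2] = (a0 * (b1 * q[2] - b2 * q[1]) - b0 * (a1 * q[2] - a2 * q[1]) +
          q[0] * (a1 * b2 - a2 * b1)) / det;
  return true;
}

// Locate the face of mesh M (geometry P, np rows = M.n) containing direction
// q, walking from face `hint`. On success fills bary (normalized, clamped).
int locate(const Mesh& M, const double* P, int np, const double q[3],
           int hint, double bary[3], int* fallbacks) {
  int f = hint;
  if (f < 0 || f >= M.m) f = M.vface[M.nearestVertex(q)];
  const double eps = -1e-12;
  int prev = -1;
  for (int step = 0; step < 2000; ++step) {
    double x[3];
    if (!solveFace(M, P, np, f, q, x)) break;
    int worst = 0;
    for (int k = 1; k < 3; ++k) if (x[k] < x[worst]) worst = k;
    double s = x[0] + x[1] + x[2];
    if (x[worst] >= eps * std::max(1.0, std::abs(s)) && s > 0) {
      double inv = 1.0 / s;
      for (int k = 0; k < 3; ++k) {
        bary[k] = std::max(0.0, x[k] * inv);
      }
      double bs = bary[0] + bary[1] + bary[2];
      for (int k = 0; k < 3; ++k) bary[k] /= bs;
      return f;
    }
    int nf = M.adj[(size_t)f * 3 + worst];
    if (nf < 0 || nf == prev) break;
    prev = f;
    f = nf;
  }
  // fallback: brute-force scan, keep face with the least-negative coefficient
  ++(*fallbacks);
  int bestf = 0;
  double bestmin = -1e300, bx[3] = {1, 0, 0};
  for (int g = 0; g < M.m; ++g) {
    double x[3];
    if (!solveFace(M, P, np, g, q, x)) continue;
    double s = x[0] + x[1] + x[2];
    if (s <= 0) continue;
    double mn = std::min(x[0], std::min(x[1], x[2])) / s;
    if (mn > bestmin) {
      bestmin = mn;
      bestf = g;
      for (int k = 0; k < 3; ++k) bx[k] = x[k] / s;
    }
  }
  for (int k = 0; k < 3; ++k) bary[k] = std::max(0.0, bx[k]);
  double bs = bary[0] + bary[1] + bary[2];
  if (bs > 0) for (int k = 0; k < 3; ++k) bary[k] /= bs;
  return bestf;
}

inline void inverse3(const double A[9], double Ainv[9]) {
  // A column-major [a|b|c]; Ainv column-major
  double a0 = A[0], a1 = A[1], a2 = A[2], b0 = A[3], b1 = A[4], b2 = A[5],
         c0 = A[6], c1 = A[7], c2 = A[8];
  double det = a0 * (b1 * c2 - b2 * c1) - b0 * (a1 * c2 - a2 * c1) +
               c0 * (a1 * b2 - a2 * b1);
  double id = 1.0 / det;
  Ainv[0] = (b1 * c2 - b2 * c1) * id;
  Ainv[3] = (b2 * c0 - b0 * c2) * id;
  Ainv[6] = (b0 * c1 - b1 * c0) * id;
  Ainv[1] = (a2 * c1 - a1 * c2) * id;
  Ainv[4] = (a0 * c2 - a2 * c0) * id;
  Ainv[7] = (a1 * c0 - a0 * c1) * id;
  Ainv[2] = (a1 * b2 - a2 * b1) * id;
  Ainv[5] = (a2 * b0 - a0 * b2) * id;
  Ainv[8] = (a0 * b1 - a1 * b0) * id;
}

}  // namespace

// [[Rcpp::export]]
List sphere_locate_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix Q,
                       IntegerVector hints) {
  Mesh M;
  M.n = V.nrow(); M.m = F.nrow();
  M.V = V.begin(); M.F = F.begin();
  M.build();
  int nq = Q.nrow();
  IntegerVector face(nq);
  NumericMatrix bary(nq, 3);
  int fallbacks = 0;
  bool useHints = hints.size() == nq;
  for (int i = 0; i < nq; ++i) {
    double q[3] = {Q(i, 0), Q(i, 1), Q(i, 2)};
    double b[3];
    int h = useHints ? hints[i] : -1;
    int f = locate(M, V.begin(), M.n, q, h, b, &fallbacks);
    face[i] = f + 1;  // 1-based for R
    for (int k = 0; k < 3; ++k) bary(i, k) = b[k];
  }
  return List::create(_["face"] = face, _["bary"] = bary,
                      _["fallbacks"] = fallbacks);
}

// One coarse-to-fine level of spherical warp optimization.
//
// V, F         standard icosphere (geometry of both subject maps and template)
// subj         n x K per-vertex subject maps (K = 1 curvature [+ landmarks])
// templ        n x K template maps
// wk           K map weights in the data term
// warp0        n x 3 initial per-vertex warp positions (unit vectors)
// E, rest      mesh edges (0-based) and their rest lengths
// lambda       metric-distortion regularization weight
// step0        initial step size in units of mean rest edge length
// iters        maximum gradient iterations
//
// Cost = sum_i sum_k wk[k] (subj_k(warp_i) - templ_k(i))^2
//        + lambda * sum_e (|w_a - w_b| - rest_e)^2.
// Steps are accepted only if the cost does not increase and no spherical
// triangle flips; otherwise the step is halved (up to 12 times).
// [[Rcpp::export]]
List warp_level_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix subj,
                    NumericMatrix templ, NumericVector wk, NumericMatrix warp0,
                    IntegerMatrix E, NumericVector rest, double lambda,
                    double step0, int iters) {
  Mesh M;
  M.n = V.nrow(); M.m = F.nrow();
  M.V = V.begin(); M.F = F.begin();
  M.build();
  const int n = M.n, K = subj.ncol(), ne = E.nrow();
  int fallbacks = 0;

  std::vector<double> W(warp0.begin(), warp0.begin() + (size_t)3 * n);
  std::vector<int> faces(n, -1);
  for (int i = 0; i < n; ++i) faces[i] = M.vface[i];

  double meanRest = 0.0;
  for (int e = 0; e < ne; ++e) meanRest += rest[e];
  meanRest /= std::max(1, ne);

  auto dataCost = [&](const std::vector<double>& P, std::vector<int>& fc) {
    double c = 0.0;
    for (int i = 0; i < n; ++i) {
      double q[3] = {P[i], P[i + n], P[i + 2 * n]};
      double b[3];
      fc[i] = locate(M, V.begin(), n, q, fc[i], b, &fallbacks);
      int ia = M.fv(fc[i], 0), ib = M.fv(fc[i], 1), ic = M.fv(fc[i], 2);
      for (int k = 0; k < K; ++k) {
        double s = b[0] * subj(ia, k) + b[1] * subj(ib, k) + b[2] * subj(ic, k);
        double r = s - templ(i, k);
        c += wk[k] * r * r;
      }
    }
    return c;
  };
  auto regCost = [&](const std::vector<double>& P) {
    double c = 0.0;
    for (int e = 0; e < ne; ++e) {
      int a = E(e, 0), b = E(e, 1);
      double dx = P[a] - P[b], dy = P[a + n] - P[b + n],
             dz = P[a + 2 * n] - P[b + 2 * n];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - rest[e];
      c += d * d;
    }
    return lambda * c;
  };
  auto countFlips = [&](const std::vector<double>& P) {
    int nf = 0;
    for (int f = 0; f < M.m; ++f) {
      int ia = M.fv(f, 0), ib = M.fv(f, 1), ic = M.fv(f, 2);
      double det =
          P[ia] * (P[ib + n] * P[ic + 2 * n] - P[ib + 2 * n] * P[ic + n]) -
          P[ib] * (P[ia + n] * P[ic + 2 * n] - P[ia + 2 * n] * P[ic + n]) +
          P[ic] * (P[ia + n] * P[ib + 2 * n] - P[ia + 2 * n] * P[ib + n]);
      if (det <= 0) ++nf;
    }
    return nf;
  };

  // gradient at current warp, using the face assignment of the last eval
  std::vector<double> g((size_t)3 * n);
  auto gradient = [&](const std::vector<double>& P) {
    std::fill(g.begin(), g.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int f = faces[i];
      int ia = M.fv(f, 0), ib = M.fv(f, 1), ic = M.fv(f, 2);
      double A[9] = {V(ia, 0), V(ia, 1), V(ia, 2), V(ib, 0), V(ib, 1),
                     V(ib, 2), V(ic, 0), V(ic, 1), V(ic, 2)};
      double Ai[9];
      inverse3(A, Ai);
      double q[3] = {P[i], P[i + n], P[i + 2 * n]};
      // x = A^-1 q ; s_k = f_k^T x / (1^T x)
      double x[3] = {Ai[0] * q[0] + Ai[3] * q[1] + Ai[6] * q[2],
                     Ai[1] * q[0] + Ai[4] * q[1] + Ai[7] * q[2],
                     Ai[2] * q[0] + Ai[5] * q[1] + Ai[8] * q[2]};
      double ssum = x[0] + x[1] + x[2];
      if (std::abs(ssum) < 1e-12) continue;
      // rows of A^-1 give gradients of x wrt q: dx_j/dq = Ai row j
      double r1[3] = {Ai[0], Ai[3], Ai[6]};
      double r2[3] = {Ai[1], Ai[4], Ai[7]};
      double r3[3] = {Ai[2], Ai[5], Ai[8]};
      double gs[3] = {r1[0] + r2[0] + r3[0], r1[1] + r2[1] + r3[1],
                      r1[2] + r2[2] + r3[2]};  // grad of 1^T x
      for (int k = 0; k < K; ++k) {
        double fk[3] = {subj(ia, k), subj(ib, k), subj(ic, k)};
        double num = fk[0] * x[0] + fk[1] * x[1] + fk[2] * x[2];
        double sval = num / ssum;
        double res = sval - templ(i, k);
        // grad of (f^T x)/(1^T x)
        for (int d = 0; d < 3; ++d) {
          double gnum = fk[0] * r1[d] + fk[1] * r2[d] + fk[2] * r3[d];
          double gd = (gnum * ssum - num * gs[d]) / (ssum * ssum);
          g[i + (size_t)d * n] += 2.0 * wk[k] * res * gd;
        }
      }
    }
    for (int e = 0; e < ne; ++e) {
      int a = E(e, 0), b = E(e, 1);
      double dx = P[a] - P[b], dy = P[a + n] - P[b + n],
             dz = P[a + 2 * n] - P[b + 2 * n];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < 1e-14) continue;
      double c = 2.0 * lambda * (d - rest[e]) / d;
      g[a] += c * dx; g[a + n] += c * dy; g[a + 2 * n] += c * dz;
      g[b] -= c * dx; g[b + n] -= c * dy; g[b + 2 * n] -= c * dz;
    }
    // project onto tangent planes
    for (int i = 0; i < n; ++i) {
      double wx = P[i], wy = P[i + n], wz = P[i + 2 * n];
      double dot = g[i] * wx + g[i + n] * wy + g[i + 2 * n] * wz;
      g[i] -= dot * wx; g[i + n] -= dot * wy; g[i + 2 * n] -= dot * wz;
    }
  };

  double cost = dataCost(W, faces) + regCost(W);
  std::vector<double> trace;
  trace.push_back(cost);
  double etaMax = step0 * meanRest, eta = etaMax;
  int accepted = 0;

  std::vector<double> Wt((size_t)3 * n);
  std::vector<int> facesT(n);
  for (int it = 0; it < iters; ++it) {
    gradient(W);
    bool ok = false;
    double etaTry = eta;
    for (int t = 0; t < 12; ++t) {
      for (int i = 0; i < n; ++i) {
        double x = W[i] - etaTry * g[i];
        double y = W[i + n] - etaTry * g[i + n];
        double z = W[i + 2 * n] - etaTry * g[i + 2 * n];
        double nn = std::sqrt(x * x + y * y + z * z);
        Wt[i] = x / nn; Wt[i + n] = y / nn; Wt[i + 2 * n] = z / nn;
      }
      facesT = faces;
      double c = dataCost(Wt, facesT) + regCost(Wt);
      if (c <= cost && countFlips(Wt) == 0) {
        W.swap(Wt);
        faces.swap(facesT);
        cost = c;
        eta = std::min(etaTry * 1.2, etaMax);
        ok = true;
        ++accepted;
        break;
      }
      etaTry *= 0.5;
    }
    if (!ok) break;
    trace.push_back(cost);
  }

  NumericMatrix Wout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) Wout(i, d) = W[i + (size_t)d * n];
  return List::create(_["warp"] = Wout, _["cost_trace"] = wrap(trace),
                      _["accepted"] = accepted, _["fallbacks"] = fallbacks,
                      _["flips"] = countFlips(W));
}
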
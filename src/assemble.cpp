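#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Linear isotropic elasticity on 4-node (constant-strain) and 10-node
// (quadratic) tetrahedra. Strain Voigt order: xx, yy, zz, xy, yz, zx
// with ENGINEERING shear inside B; tensor components are emitted by the
// strain-recovery kernel.

// 4-point Gauss rule on the reference tetrahedron (degree 2, exact for
// the stiffness of straight-sided TET10), barycentric coordinates.
static const double GA = 0.5854101966249685;
static const double GB = 0.1381966011250105;
static const double GP[4][4] = {
    {GA, GB, GB, GB},
    {GB, GA, GB, GB},
    {GB, GB, GA, GB},
    {GB, GB, GB, GA}};

// gradients of the 4 barycentric coordinates for a straight tet;
// returns 6*signed volume, grads in gl[4][3]
static double baryGrads(const double x[4][3], double gl[4][3]) {
  double a[3], b[3], c[3];
  for (int k = 0; k < 3; ++k) {
    a[k] = x[1][k] - x[0][k];
    b[k] = x[2][k] - x[0][k];
    c[k] = x[3][k] - x[0][k];
  }
  double det = a[0] * (b[1] * c[2] - b[2] * c[1]) -
               a[1] * (b[0] * c[2] - b[2] * c[0]) +
               a[2] * (b[0] * c[1] - b[1] * c[0]);
  // rows of inverse of M = [a b c] (columns), times det
  double inv[3][3];
  inv[0][0] = (b[1] * c[2] - b[2] * c[1]);
  inv[0][1] = -(b[0] * c[2] - b[2] * c[0]);
  inv[0][2] = (b[0] * c[1] - b[1] * c[0]);
  inv[1][0] = -(a[1] * c[2] - a[2] * c[1]);
  inv[1][1] = (a[0] * c[2] - a[2] * c[0]);
  inv[1][2] = -(a[0] * c[1] - a[1] * c[0]);
  inv[2][0] = (a[1] * b[2] - a[2] * b[1]);
  inv[2][1] = -(a[0] * b[2] - a[2] * b[0]);
  inv[2][2] = (a[0] * b[1] - a[1] * b[0]);
  for (int r = 0; r < 3; ++r)
    for (int k = 0; k < 3; ++k) gl[r + 1][k] = inv[r][k] / det;
  for (int k = 0; k < 3; ++k)
    gl[0][k] = -(gl[1][k] + gl[2][k] + gl[3][k]);
  return det;  // = 6 V
}

// B matrix (6 x 3*nn) for nn node gradients g[nn][3]
static void fillB(int nn, const double g[10][3], double B[6][30]) {
  for (int r = 0; r < 6; ++r)
    for (int cidx = 0; cidx < 3 * nn; ++cidx) B[r][cidx] = 0.0;
  for (int a = 0; a < nn; ++a) {
    int c0 = 3 * a;
    B[0][c0 + 0] = g[a][0];
    B[1][c0 + 1] = g[a][1];
    B[2][c0 + 2] = g[a][2];
    B[3][c0 + 0] = g[a][1];
    B[3][c0 + 1] = g[a][0];
    B[4][c0 + 1] = g[a][2];
    B[4][c0 + 2] = g[a][1];
    B[5][c0 + 0] = g[a][2];
    B[5][c0 + 2] = g[a][0];
  }
}

// shape-function gradients of TET10 at barycentric point L
static void tet10Grads(const double L[4], const double gl[4][3],
                       double g[10][3]) {
  for (int i = 0; i < 4; ++i)
    for (int k = 0; k < 3; ++k) g[i][k] = (4.0 * L[i] - 1.0) * gl[i][k];
  // C3D10 edge order (0-based corner pairs): (0,1),(1,2),(2,0),(0,3),(1,3),(2,3)
  static const int E[6][2] = {{0, 1}, {1, 2}, {2, 0}, {0, 3}, {1, 3}, {2, 3}};
  for (int e = 0; e < 6; ++e) {
    int i = E[e][0], j = E[e][1];
    for (int k = 0; k < 3; ++k)
      g[4 + e][k] = 4.0 * (L[i] * gl[j][k] + L[j] * gl[i][k]);
  }
}

// accumulate w * B^T D B into Ke, D = lam * J + mu * diag(2,2,2,1,1,1)
static void addBtDB(int ndof, const double B[6][30], double lam, double mu,
                    double w, double Ke[30][30]) {
  double DB[6][30];
  for (int cidx = 0; cidx < ndof; ++cidx) {
    double tr = B[0][cidx] + B[1][cidx] + B[2][cidx];
    DB[0][cidx] = lam * tr + 2.0 * mu * B[0][cidx];
    DB[1][cidx] = lam * tr + 2.0 * mu * B[1][cidx];
    DB[2][cidx] = lam * tr + 2.0 * mu * B[2][cidx];
    DB[3][cidx] = mu * B[3][cidx];
    DB[4][cidx] = mu * B[4][cidx];
    DB[5][cidx] = mu * B[5][cidx];
  }
  for (int i = 0; i < ndof; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int r = 0; r < 6; ++r) s += B[r][i] * DB[r][j];
      Ke[i][j] += w * s;
    }
}

// element stiffness, lower triangle in Ke (symmetrized on read)
static double elementKe(int nn, const double x[4][3], double lam, double mu,
                        double Ke[30][30]) {
  int ndof = 3 * nn;
  for (int i = 0; i < ndof; ++i)
    for (int j = 0; j < ndof; ++j) Ke[i][j] = 0.0;
  double gl[4][3];
  double det = baryGrads(x, gl);
  double V = det / 6.0;
  if (nn == 4) {
    double g[10][3];
    for (int a = 0; a < 4; ++a)
      for (int k = 0; k < 3; ++k) g[a][k] = gl[a][k];
    double B[6][30];
    fillB(4, g, B);
    addBtDB(12, B, lam, mu, V, Ke);
  } else {
    for (int q = 0; q < 4; ++q) {
      double g[10][3];
      tet10Grads(GP[q], gl, g);
      double B[6][30];
      fillB(10, g, B);
      addBtDB(30, B, lam, mu, V / 4.0, Ke);
    }
  }
  return V;
}

// [[Rcpp::export(name = ".assembleTriplets")]]
List assembleTriplets(NumericMatrix nodes, IntegerMatrix elements,
                      NumericVector lambda, NumericVector mu) {
  int m = elements.nrow();
  int nn = elements.ncol();
  if (nn != 4 && nn != 10) stop("elements must have 4 or 10 nodes");
  int ndof = 3 * nn;
  size_t per = (size_t)ndof * (ndof + 1) / 2;
  // exactly one triplet per local lower pair, so sizes are known upfront
  IntegerVector ii(no_init(per * m)), jj(no_init(per * m));
  NumericVector xx(no_init(per * m));
  size_t pos = 0;

  double x[4][3], Ke[30][30];
  int gdof[30];
  for (int e = 0; e < m; ++e) {
    for (int a = 0; a < 4; ++a) {
      int nidx = elements(e, a) - 1;
      for (int k = 0; k < 3; ++k) x[a][k] = nodes(nidx, k);
    }
    double V = elementKe(nn, x, lambda[e], mu[e], Ke);
    if (!(V > 0.0))
      stop("non-positive element volume at element %d", e + 1);
    for (int a = 0; a < nn; ++a) {
      int base = 3 * (elements(e, a) - 1);
      gdof[3 * a] = base;
      gdof[3 * a + 1] = base + 1;
      gdof[3 * a + 2] = base + 2;
    }
    for (int i = 0; i < ndof; ++i)
      for (int j = 0; j <= i; ++j) {
        double v = Ke[i][j];
        int gi = gdof[i], gj = gdof[j];
        // keep one (lower) triangle of the global matrix
        if (gi >= gj) {
          ii[pos] = gi + 1;
          jj[pos] = gj + 1;
        } else {
          ii[pos] = gj + 1;
          jj[pos] = gi + 1;
        }
        xx[pos] = v;
        ++pos;
      }
  }
  return List::create(Named("i") = ii, Named("j") = jj,
                      Named("x") = xx);
}

// Per-element strain recovery: centroid strain for TET4 (exact, the
// field is constant), average of the 4 integration-point strains for
// TET10. Returns m x 6 TENSOR strain components (xx,yy,zz,xy,yz,zx).
// [[Rcpp::export(name = ".elementStrains")]]
NumericMatrix elementStrains(NumericMatrix nodes, IntegerMatrix elements,
                             NumericMatrix U) {
  int m = elements.nrow();
  int nn = elements.ncol();
  NumericMatrix out(m, 6);
  double x[4][3];
  for (int e = 0; e < m; ++e) {
    for (int a = 0; a < 4; ++a) {
      int nidx = elements(e, a) - 1;
      for (int k = 0; k < 3; ++k) x[a][k] = nodes(nidx, k);
    }
    double gl[4][3];
    baryGrads(x, gl);
    double eps[6] = {0, 0, 0, 0, 0, 0};
    int nq = (nn == 4) ? 1 : 4;
    for (int q = 0; q < nq; ++q) {
      double g[10][3];
      if (nn == 4) {
        for (int a = 0; a < 4; ++a)
          for (int k = 0; k < 3; ++k) g[a][k] = gl[a][k];
      } else {
        tet10Grads(GP[q], gl, g);
      }
      // displacement gradient H = sum_a u_a (grad N_a)^T
      double H[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      for (int a = 0; a < nn; ++a) {
        int nidx = elements(e, a) - 1;
        for (int r = 0; r < 3; ++r)
          for (int k = 0; k < 3; ++k) H[r][k] += U(nidx, r) * g[a][k];
      }
      eps[0] += H[0][0];
      eps[1] += H[1][1];
      eps[2] += H[2][2];
      eps[3] += 0.5 * (H[0][1] + H[1][0]);
      eps[4] += 0.5 * (H[1][2] + H[2][1]);
      eps[5] += 0.5 * (H[0][2] + H[2][0]);
    }
    for (int r = 0; r < 6; ++r) out(e, r) = eps[r] / nq;
  }
  return out;
}

// ---- IC(0)-preconditioned conjugate gradients on the lower-triangle
// CSC storage of a symmetric positive-definite stiffness matrix. Used
// above the direct-factorization size threshold; deterministic, fixed
// relative-residual tolerance supplied by the caller.

// y = A x where only the lower triangle (incl. diagonal) is stored
static void symMatvec(int n, const int *Ap, const int *Ai,
                      const double *Ax, const double *x, double *y) {
  for (int i = 0; i < n; ++i) y[i] = 0.0;
  for (int j = 0; j < n; ++j) {
    double xj = x[j];
    double acc = 0.0;
    for (int p = Ap[j]; p < Ap[j + 1]; ++p) {
      int i = Ai[p];
      double v = Ax[p];
      y[i] += v * xj;
      if (i != j) acc += v * x[i];
    }
    y[j] += acc;
  }
}

// in-place IC(0) of the lower-CSC matrix; returns false on breakdown
static bool ic0(int n, const int *Ap, const int *Ai, double *Lx) {
  // column-wise left-looking IC(0) restricted to the pattern of A
  std::vector<int> next(n), head(n, -1), pos(n);
  std::vector<double> work(n, 0.0);
  for (int j = 0; j < n; ++j) {
    for (int p = Ap[j]; p < Ap[j + 1]; ++p) work[Ai[p]] = Lx[p];
    // subtract contributions of previous columns k with L(j,k) != 0
    for (int k = head[j]; k != -1;) {
      int nk = next[k];
      int pk = pos[k];
      double ljk = Lx[pk];
      for (int p = pk; p < Ap[k + 1]; ++p) {
        int i = Ai[p];
        if (i >= j) work[i] -= ljk * Lx[p];
      }
      // advance column k to its next row below j
      int pn = pk + 1;
      if (pn < Ap[k + 1]) {
        pos[k] = pn;
        int inext = Ai[pn];
        next[k] = head[inext];
        head[inext] = k;
      }
      k = nk;
    }
    double djj = work[j];
    if (!(djj > 0.0)) {
      for (int p = Ap[j]; p < Ap[j + 1]; ++p) work[Ai[p]] = 0.0;
      return false;
    }
    double lj = std::sqrt(djj);
    for (int p = Ap[j]; p < Ap[j + 1]; ++p) {
      int i = Ai[p];
      Lx[p] = (i == j) ? lj : work[i] / lj;
      work[i] = 0.0;
    }
    // register column j for its first off-diagonal row
    if (Ap[j] + 1 < Ap[j + 1]) {
      pos[j] = Ap[j] + 1;
      int inext = Ai[Ap[j] + 1];
      next[j] = head[inext];
      head[inext] = j;
    }
  }
  return true;
}

static void lowerSolve(int n, const int *Ap, const int *Ai,
                       const double *Lx, double *b) {
  for (int j = 0; j < n; ++j) {
    b[j] /= Lx[Ap[j]];
    double bj = b[j];
    for (int p = Ap[j] + 1; p < Ap[j + 1]; ++p) b[Ai[p]] -= Lx[p] * bj;
  }
}

static void upperSolve(int n, const int *Ap, const int *Ai,
                       const double *Lx, double *b) {
  for (int j = n - 1; j >= 0; --j) {
    double s = b[j];
    for (int p = Ap[j] + 1; p < Ap[j + 1]; ++p) s -= Lx[p] * b[Ai[p]];
    b[j] = s / Lx[Ap[j]];
  }
}

// [[Rcpp::export(name = ".icpcgSolve")]]
List icpcgSolve(S4 A, NumericVector b, double tol, int maxit) {
  IntegerVector Ap = A.slot("p"), Ai = A.slot("i");
  NumericVector Ax = A.slot("x");
  std::string uplo = as<std::string>(A.slot("uplo"));
  if (uplo != "L") stop("expected lower-triangle symmetric storage");
  int n = b.size();
  const int *ap = Ap.begin();
  const int *ai = Ai.begin();

  // IC(0) with progressive diagonal shift on breakdown
  std::vector<double> Lx(Ax.begin(), Ax.end());
  double shift = 0.0;
  for (int attempt = 0; attempt < 12; ++attempt) {
    if (attempt > 0) {
      shift = (shift == 0.0) ? 1e-4 : shift * 10.0;
      std::copy(Ax.begin(), Ax.end(), Lx.begin());
      for (int j = 0; j < n; ++j) Lx[ap[j]] *= (1.0 + shift);
    }
    if (ic0(n, ap, ai, Lx.data())) break;
    if (attempt == 11) stop("incomplete Cholesky breakdown");
  }

  std::vector<double> x(n, 0.0), r(b.begin(), b.end()), z(n), p(n), q(n);
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0)
    return List::create(Named("x") = wrap(x), Named("iterations") = 0,
                        Named("relres") = 0.0);
  std::copy(r.begin(), r.end(), z.begin());
  lowerSolve(n, ap, ai, Lx.data(), z.data());
  upperSolve(n, ap, ai, Lx.data(), z.data());
  std::copy(z.begin(), z.end(), p.begin());
  double rz = 0.0;
  for (int i = 0; i < n; ++i) rz += r[i] * z[i];
  double relres = 1.0;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    symMatvec(n, ap, ai, Ax.begin(), p.data(), q.data());
    double pq = 0.0;
    for (int i = 0; i < n; ++i) pq += p[i] * q[i];
    double alpha = rz / pq;
    double rn = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * q[i];
      rn += r[i] * r[i];
    }
    relres = std::sqrt(rn) / bnorm;
    if (relres <= tol) break;
    std::copy(r.begin(), r.end(), z.begin());
    lowerSolve(n, ap, ai, Lx.data(), z.data());
    upperSolve(n, ap, ai, Lx.data(), z.data());
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) rz_new += r[i] * z[i];
    double beta = rz_new / rz;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    rz = rz_new;
  }
  return List::create(Named("x") = wrap(x), Named("iterations") = it,
                      Named("relres") = relres);
}
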
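// Core element routines for the thin-slice inflation solver.
//
// Trilinear hexahedra with selective reduced integration: the deviatoric
// (isochoric) part of the modified Mooney-Rivlin + fiber energy is
// integrated at 2x2x2 Gauss points, the volumetric penalty kappa/2 (J-1)^2
// at the element centroid only (mean-dilatation style), which avoids
// volumetric locking in the nearly-incompressible regime. Consistent
// tangents are obtained by forward finite differences of the exact element
// residual, assembled as sparse triplets on the R side.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GP = 0.5773502691896258; // 1/sqrt(3)

// material row layout: c1, c2, D1, D2, K1, K2, phi(rad), kappa
struct Mat {
  double c1, c2, D1, D2, K1, K2, phi, kappa;
};

static inline double det3(const double A[3][3]) {
  return A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
       - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
       + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
}

static inline void inv3(const double A[3][3], double d, double Ai[3][3]) {
  double id = 1.0 / d;
  Ai[0][0] =  (A[1][1] * A[2][2] - A[1][2] * A[2][1]) * id;
  Ai[0][1] = -(A[0][1] * A[2][2] - A[0][2] * A[2][1]) * id;
  Ai[0][2] =  (A[0][1] * A[1][2] - A[0][2] * A[1][1]) * id;
  Ai[1][0] = -(A[1][0] * A[2][2] - A[1][2] * A[2][0]) * id;
  Ai[1][1] =  (A[0][0] * A[2][2] - A[0][2] * A[2][0]) * id;
  Ai[1][2] = -(A[0][0] * A[1][2] - A[0][2] * A[1][0]) * id;
  Ai[2][0] =  (A[1][0] * A[2][1] - A[1][1] * A[2][0]) * id;
  Ai[2][1] = -(A[0][0] * A[2][1] - A[0][1] * A[2][0]) * id;
  Ai[2][2] =  (A[0][0] * A[1][1] - A[0][1] * A[1][0]) * id;
}

// local node coordinates of the trilinear hex
static const double XI[8][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}};

static inline void shape_deriv(double xi, double eta, double ze,
                               double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    double sx = XI[a][0], sy = XI[a][1], sz = XI[a][2];
    dN[a][0] = 0.125 * sx * (1 + sy * eta) * (1 + sz * ze);
    dN[a][1] = 0.125 * sy * (1 + sx * xi) * (1 + sz * ze);
    dN[a][2] = 0.125 * sz * (1 + sx * xi) * (1 + sy * eta);
  }
}

// status codes
enum { OK = 0, INVERTED = 1, OVERFLOW_GUARD = 2 };

// Deviatoric (isochoric) second Piola-Kirchhoff stress. Returns status.
static int Sdev(const double F[3][3], const Mat& m,
                const double ec[3], const double ea[3],
                double S[3][3], double* Jout) {
  double C[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += F[k][i] * F[k][j];
      C[i][j] = s;
    }
  double J = det3(F);
  if (Jout) *Jout = J;
  if (J <= 0) return INVERTED;
  double Ci[3][3];
  double dC = det3(C);
  inv3(C, dC, Ci);
  double I1 = C[0][0] + C[1][1] + C[2][2];
  double CC = 0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) CC += C[i][j] * C[i][j];
  double I2 = 0.5 * (I1 * I1 - CC);
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double Jm43 = Jm23 * Jm23;
  double I1b = Jm23 * I1, I2b = Jm43 * I2;
  double x = m.D2 * (I1b - 3.0);
  if (x > 50.0) return OVERFLOW_GUARD;
  double psi1 = m.c1 + m.D1 * m.D2 * std::exp(x);
  double psi2 = m.c2;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double id = (i == j) ? 1.0 : 0.0;
      S[i][j] = 2.0 * (psi1 * Jm23 * (id - (I1 / 3.0) * Ci[i][j]) +
                       psi2 * Jm43 * (I1 * id - C[i][j] -
                                      (2.0 * I2 / 3.0) * Ci[i][j]));
    }
  if (m.K1 > 0) {
    double ca = std::cos(m.phi), sa = std::sin(m.phi);
    for (int fam = 0; fam < 2; ++fam) {
      double sgn = fam == 0 ? 1.0 : -1.0;
      double v[3];
      for (int i = 0; i < 3; ++i) v[i] = ca * ec[i] + sgn * sa * ea[i];
      double I4 = 0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) I4 += v[i] * C[i][j] * v[j];
      double I4b = Jm23 * I4;
      if (I4b > 1.0) {
        double xf = m.K2 * (I4b - 1.0) * (I4b - 1.0);
        if (xf > 50.0) return OVERFLOW_GUARD;
        double psi4 = 0.5 * 2.0 * m.K1 * (I4b - 1.0) * std::exp(xf);
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            S[i][j] += 2.0 * psi4 * Jm23 *
              (v[i] * v[j] - (I4 / 3.0) * Ci[i][j]);
      }
    }
  }
  return OK;
}

// Element internal force (24 components). SRI deviatoric + centroid
// volumetric penalty. Returns status.
static int elem_force(const double Xe[8][3], const double Ue[8][3],
                      const Mat& m, const double ec[3], const double ea[3],
                      double fe[24]) {
  for (int k = 0; k < 24; ++k) fe[k] = 0.0;
  double dN[8][3], Jm[3][3], Ji[3][3], dNdX[8][3], F[3][3], S[3][3], P[3][3];
  // deviatoric part: 2x2x2
  for (int g = 0; g < 8; ++g) {
    shape_deriv(GP * XI[g][0], GP * XI[g][1], GP * XI[g][2], dN);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int a = 0; a < 8; ++a) s += Xe[a][i] * dN[a][j];
        Jm[i][j] = s;
      }
    double dJ = det3(Jm);
    if (dJ <= 0) return INVERTED;
    inv3(Jm, dJ, Ji);
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) {
        double s = 0;
        for (int j = 0; j < 3; ++j) s += dN[a][j] * Ji[j][i];
        dNdX[a][i] = s;
      }
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = (i == j) ? 1.0 : 0.0;
        for (int a = 0; a < 8; ++a) s += Ue[a][i] * dNdX[a][j];
        F[i][j] = s;
      }
    double J;
    int st = Sdev(F, m, ec, ea, S, &J);
    if (st != OK) return st;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += F[i][k] * S[k][j];
        P[i][j] = s;
      }
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) {
        double s = 0;
        for (int j = 0; j < 3; ++j) s += P[i][j] * dNdX[a][j];
        fe[3 * a + i] += dJ * s;
      }
  }
  // volumetric part at centroid
  shape_deriv(0, 0, 0, dN);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int a = 0; a < 8; ++a) s += Xe[a][i] * dN[a][j];
      Jm[i][j] = s;
    }
  double dJ0 = det3(Jm);
  if (dJ0 <= 0) return INVERTED;
  inv3(Jm, dJ0, Ji);
  for (int a = 0; a < 8; ++a)
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int j = 0; j < 3; ++j) s += dN[a][j] * Ji[j][i];
      dNdX[a][i] = s;
    }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = (i == j) ? 1.0 : 0.0;
      for (int a = 0; a < 8; ++a) s += Ue[a][i] * dNdX[a][j];
      F[i][j] = s;
    }
  double J0 = det3(F);
  if (J0 <= 0) return INVERTED;
  double Fi[3][3];
  inv3(F, J0, Fi);
  double V0 = 8.0 * dJ0; // centroid quadrature of reference volume
  double fac = V0 * m.kappa * (J0 - 1.0) * J0;
  for (int a = 0; a < 8; ++a)
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int j = 0; j < 3; ++j) s += Fi[j][i] * dNdX[a][j];
      fe[3 * a + i] += fac * s;
    }
  return OK;
}

static Mat mat_row(const NumericMatrix& mats, int e) {
  Mat m;
  m.c1 = mats(e, 0); m.c2 = mats(e, 1); m.D1 = mats(e, 2);
  m.D2 = mats(e, 3); m.K1 = mats(e, 4); m.K2 = mats(e, 5);
  m.phi = mats(e, 6); m.kappa = mats(e, 7);
  return m;
}

static void gather(const NumericMatrix& X, const NumericMatrix& U,
                   const IntegerMatrix& elems, int e,
                   double Xe[8][3], double Ue[8][3]) {
  for (int a = 0; a < 8; ++a) {
    int n = elems(e, a);
    for (int i = 0; i < 3; ++i) {
      Xe[a][i] = X(n, i);
      Ue[a][i] = U(n, i);
    }
  }
}

static void check_status(int st, int e) {
  if (st == INVERTED)
    stop("element %d: inverted (non-positive Jacobian) during update", e + 1);
  if (st == OVERFLOW_GUARD)
    stop("element %d: constitutive overflow guard tripped "
         "(deformation outside the physical range)", e + 1);
}

// [[Rcpp::export]]
NumericVector fem_internal_force(NumericMatrix X, NumericMatrix U,
                                 IntegerMatrix elems, NumericMatrix mats,
                                 NumericMatrix ecirc, NumericMatrix eax) {
  int nn = X.nrow(), ne = elems.nrow();
  NumericVector f(3 * nn);
  double Xe[8][3], Ue[8][3], fe[24], ec[3], ea[3];
  for (int e = 0; e < ne; ++e) {
    gather(X, U, elems, e, Xe, Ue);
    for (int i = 0; i < 3; ++i) { ec[i] = ecirc(e, i); ea[i] = eax(e, i); }
    Mat m = mat_row(mats, e);
    check_status(elem_force(Xe, Ue, m, ec, ea, fe), e);
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        f[3 * elems(e, a) + i] += fe[3 * a + i];
  }
  return f;
}

// [[Rcpp::export]]
List fem_tangent(NumericMatrix X, NumericMatrix U, IntegerMatrix elems,
                 NumericMatrix mats, NumericMatrix ecirc, NumericMatrix eax,
                 double h = 1e-7) {
  int ne = elems.nrow();
  IntegerVector ti(ne * 576), tj(ne * 576);
  NumericVector tx(ne * 576);
  double Xe[8][3], Ue[8][3], fe0[24], fep[24], Ke[24][24], ec[3], ea[3];
  R_xlen_t pos = 0;
  for (int e = 0; e < ne; ++e) {
    gather(X, U, elems, e, Xe, Ue);
    for (int i = 0; i < 3; ++i) { ec[i] = ecirc(e, i); ea[i] = eax(e, i); }
    Mat m = mat_row(mats, e);
    check_status(elem_force(Xe, Ue, m, ec, ea, fe0), e);
    for (int d = 0; d < 24; ++d) {
      int a = d / 3, i = d % 3;
      double keep = Ue[a][i];
      Ue[a][i] = keep + h;
      check_status(elem_force(Xe, Ue, m, ec, ea, fep), e);
      Ue[a][i] = keep;
      for (int r = 0; r < 24; ++r) Ke[r][d] = (fep[r] - fe0[r]) / h;
    }
    // symmetrize (the elastic tangent is symmetric analytically)
    for (int r = 0; r < 24; ++r)
      for (int d = 0; d < r; ++d) {
        double v = 0.5 * (Ke[r][d] + Ke[d][r]);
        Ke[r][d] = v; Ke[d][r] = v;
      }
    for (int r = 0; r < 24; ++r) {
      int gr = 3 * elems(e, r / 3) + r % 3;
      for (int d = 0; d < 24; ++d) {
        ti[pos] = gr + 1;
        tj[pos] = 3 * elems(e, d / 3) + d % 3 + 1;
        tx[pos] = Ke[r][d];
        ++pos;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// follower pressure on bilinear quad faces of the deformed surface;
// face node order chosen so x_,xi x x_,eta points from the fluid into the
// wall (the direction the pressure pushes).
static void face_force(const double xe[4][3], double p, double fe[12]) {
  for (int k = 0; k < 12; ++k) fe[k] = 0.0;
  static const double Q[4][2] = {{-GP, -GP}, {GP, -GP}, {GP, GP}, {-GP, GP}};
  static const double S4[4][2] = {{-1, -1}, {1, -1}, {1, 1}, {-1, 1}};
  for (int g = 0; g < 4; ++g) {
    double xi = Q[g][0], eta = Q[g][1];
    double N[4], dNxi[4], dNeta[4];
    for (int a = 0; a < 4; ++a) {
      N[a] = 0.25 * (1 + S4[a][0] * xi) * (1 + S4[a][1] * eta);
      dNxi[a] = 0.25 * S4[a][0] * (1 + S4[a][1] * eta);
      dNeta[a] = 0.25 * S4[a][1] * (1 + S4[a][0] * xi);
    }
    double tx[3] = {0, 0, 0}, te[3] = {0, 0, 0};
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        tx[i] += dNxi[a] * xe[a][i];
        te[i] += dNeta[a] * xe[a][i];
      }
    double n[3] = {tx[1] * te[2] - tx[2] * te[1],
                   tx[2] * te[0] - tx[0] * te[2],
                   tx[0] * te[1] - tx[1] * te[0]};
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        fe[3 * a + i] += p * N[a] * n[i];
  }
}

// [[Rcpp::export]]
NumericVector fem_pressure_force(NumericMatrix X, NumericMatrix U,
                                 IntegerMatrix faces, double p) {
  int nn = X.nrow(), nf = faces.nrow();
  NumericVector f(3 * nn);
  double xe[4][3], fe[12];
  for (int e = 0; e < nf; ++e) {
    for (int a = 0; a < 4; ++a) {
      int n = faces(e, a);
      for (int i = 0; i < 3; ++i) xe[a][i] = X(n, i) + U(n, i);
    }
    face_force(xe, p, fe);
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        f[3 * faces(e, a) + i] += fe[3 * a + i];
  }
  return f;
}

// [[Rcpp::export]]
List fem_pressure_tangent(NumericMatrix X, NumericMatrix U,
                          IntegerMatrix faces, double p, double h = 1e-7) {
  int nf = faces.nrow();
  IntegerVector ti(nf * 144), tj(nf * 144);
  NumericVector tx(nf * 144);
  double xe[4][3], fe0[12], fep[12];
  R_xlen_t pos = 0;
  for (int e = 0; e < nf; ++e) {
    for (int a = 0; a < 4; ++a) {
      int n = faces(e, a);
      for (int i = 0; i < 3; ++i) xe[a][i] = X(n, i) + U(n, i);
    }
    face_force(xe, p, fe0);
    for (int d = 0; d < 12; ++d) {
      int a = d / 3, i = d % 3;
      double keep = xe[a][i];
      xe[a][i] = keep + h;
      face_force(xe, p, fep);
      xe[a][i] = keep;
      for (int r = 0; r < 12; ++r) {
        ti[pos] = 3 * faces(e, r / 3) + r % 3 + 1;
        tj[pos] = 3 * faces(e, d / 3) + d % 3 + 1;
        tx[pos] = (fep[r] - fe0[r]) / h;
        ++pos;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// Per-element Cauchy stress and Green-Lagrange strain extrapolated from
// the 2x2x2 Gauss points to the element nodes (standard trilinear
// extrapolation: Gauss values treated as nodal values of the mini-element
// at +/- 1/sqrt(3) and evaluated at the corner coordinates), stored
// node-major as ne x 48 (node a, component k -> column 6*a + k). Also the
// per-element mean and centroid J. Volumetric pressure taken from the
// centroid J (consistent with the SRI residual).
// [[Rcpp::export]]
List fem_element_fields(NumericMatrix X, NumericMatrix U, IntegerMatrix elems,
                        NumericMatrix mats, NumericMatrix ecirc,
                        NumericMatrix eax) {
  int ne = elems.nrow();
  NumericMatrix sig(ne, 48), egl(ne, 48);
  NumericMatrix sig_gp(ne, 48), egl_gp(ne, 48); // raw Gauss values, g-major
  // extrapolation matrix E[a][g]
  double E[8][8];
  for (int a = 0; a < 8; ++a)
    for (int g = 0; g < 8; ++g) {
      double w = 1.0;
      for (int i = 0; i < 3; ++i)
        w *= 0.5 * (1.0 + 3.0 * XI[a][i] * GP * XI[g][i]);
      E[a][g] = w;
    }
  NumericVector Jmean(ne), Jcent(ne);
  double Xe[8][3], Ue[8][3], ec[3], ea[3];
  double dN[8][3], Jm[3][3], Ji[3][3], dNdX[8][3], F[3][3], S[3][3];
  static const int II[6] = {0, 1, 2, 0, 1, 0};
  static const int JJ[6] = {0, 1, 2, 1, 2, 2};
  for (int e = 0; e < ne; ++e) {
    gather(X, U, elems, e, Xe, Ue);
    for (int i = 0; i < 3; ++i) { ec[i] = ecirc(e, i); ea[i] = eax(e, i); }
    Mat m = mat_row(mats, e);
    // centroid J for the volumetric pressure
    double J0 = 1.0;
    {
      shape_deriv(0, 0, 0, dN);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int a = 0; a < 8; ++a) s += Xe[a][i] * dN[a][j];
          Jm[i][j] = s;
        }
      double dJ = det3(Jm);
      if (dJ <= 0) stop("element %d: non-positive reference Jacobian", e + 1);
      inv3(Jm, dJ, Ji);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0;
          for (int j = 0; j < 3; ++j) s += dN[a][j] * Ji[j][i];
          dNdX[a][i] = s;
        }
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = (i == j) ? 1.0 : 0.0;
          for (int a = 0; a < 8; ++a) s += Ue[a][i] * dNdX[a][j];
          F[i][j] = s;
        }
      J0 = det3(F);
    }
    Jcent[e] = J0;
    double pvol = m.kappa * (J0 - 1.0);
    double sgp[8][6], egp[8][6];
    double jacc = 0;
    for (int g = 0; g < 8; ++g) {
      shape_deriv(GP * XI[g][0], GP * XI[g][1], GP * XI[g][2], dN);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int a = 0; a < 8; ++a) s += Xe[a][i] * dN[a][j];
          Jm[i][j] = s;
        }
      double dJ = det3(Jm);
      if (dJ <= 0) stop("element %d: non-positive reference Jacobian", e + 1);
      inv3(Jm, dJ, Ji);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0;
          for (int j = 0; j < 3; ++j) s += dN[a][j] * Ji[j][i];
          dNdX[a][i] = s;
        }
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = (i == j) ? 1.0 : 0.0;
          for (int a = 0; a < 8; ++a) s += Ue[a][i] * dNdX[a][j];
          F[i][j] = s;
        }
      double J;
      check_status(Sdev(F, m, ec, ea, S, &J), e);
      jacc += J;
      // sigma = (1/J) F S F^T + pvol I
      double FS[3][3], sg[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int k = 0; k < 3; ++k) s += F[i][k] * S[k][j];
          FS[i][j] = s;
        }
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int k = 0; k < 3; ++k) s += FS[i][k] * F[j][k];
          sg[i][j] = s / J + ((i == j) ? pvol : 0.0);
        }
      // Green-Lagrange strain (F^T F - I)/2
      double Eg[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int k = 0; k < 3; ++k) s += F[k][i] * F[k][j];
          Eg[i][j] = 0.5 * (s - ((i == j) ? 1.0 : 0.0));
        }
      for (int k = 0; k < 6; ++k) {
        sgp[g][k] = sg[II[k]][JJ[k]];
        egp[g][k] = Eg[II[k]][JJ[k]];
        sig_gp(e, 6 * g + k) = sgp[g][k];
        egl_gp(e, 6 * g + k) = egp[g][k];
      }
    }
    for (int a = 0; a < 8; ++a)
      for (int k = 0; k < 6; ++k) {
        double sv = 0, ev = 0;
        for (int g = 0; g < 8; ++g) {
          sv += E[a][g] * sgp[g][k];
          ev += E[a][g] * egp[g][k];
        }
        sig(e, 6 * a + k) = sv;
        egl(e, 6 * a + k) = ev;
      }
    Jmean[e] = jacc / 8.0;
  }
  return List::create(_["stress"] = sig, _["strain"] = egl,
                      _["stress_gp"] = sig_gp, _["strain_gp"] = egl_gp,
                      _["J"] = Jmean, _["J_centroid"] = Jcent);
}

// reference volume and minimum reference Jacobian determinant per element
// [[Rcpp::export]]
List fem_mesh_quality(NumericMatrix X, IntegerMatrix elems) {
  int ne = elems.nrow();
  NumericVector vol(ne), mindet(ne);
  double Xe[8][3], dN[8][3], Jm[3][3];
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a);
      for (int i = 0; i < 3; ++i) Xe[a][i] = X(n, i);
    }
    double v = 0, md = R_PosInf;
    for (int g = 0; g < 8; ++g) {
      shape_deriv(GP * XI[g][0], GP * XI[g][1], GP * XI[g][2], dN);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int a = 0; a < 8; ++a) s += Xe[a][i] * dN[a][j];
          Jm[i][j] = s;
        }
      double dJ = det3(Jm);
      v += dJ;
      if (dJ < md) md = dJ;
    }
    vol[e] = v;
    mindet[e] = md;
  }
  return List::create(_["volume"] = vol, _["min_detJ"] = mindet);
}
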
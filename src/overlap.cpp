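#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Gaussian-product cross overlap: V = sum_ij p_i p_j (pi/(a_i+a_j))^{3/2}
// exp(-a_i a_j d_ij^2 / (a_i + a_j)). Coordinates are n x 3 matrices in A.

// [[Rcpp::export]]
double cpp_overlap(const NumericMatrix& A, const NumericVector& aA,
                   const NumericVector& pA, const NumericMatrix& B,
                   const NumericVector& aB, const NumericVector& pB) {
  const int nA = A.nrow(), nB = B.nrow();
  const double pi = M_PI;
  double v = 0.0;
  for (int i = 0; i < nA; ++i) {
    const double ai = aA[i], pi_amp = pA[i];
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nB; ++j) {
      const double s = ai + aB[j];
      const double g = ai * aB[j] / s;
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      v += pi_amp * pB[j] * std::pow(pi / s, 1.5) * std::exp(-g * d2);
    }
  }
  return v;
}

// Rotation matrix from an (unnormalized) quaternion q = (w,x,y,z):
// R = M(q) / (q.q) with M quadratic in q.
static void quat_rotmat(const double* q, double R[3][3]) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  const double n = w * w + x * x + y * y + z * z;
  R[0][0] = (w * w + x * x - y * y - z * z) / n;
  R[0][1] = 2.0 * (x * y - w * z) / n;
  R[0][2] = 2.0 * (x * z + w * y) / n;
  R[1][0] = 2.0 * (x * y + w * z) / n;
  R[1][1] = (w * w - x * x + y * y - z * z) / n;
  R[1][2] = 2.0 * (y * z - w * x) / n;
  R[2][0] = 2.0 * (x * z - w * y) / n;
  R[2][1] = 2.0 * (y * z + w * x) / n;
  R[2][2] = (w * w - x * x - y * y + z * z) / n;
}

// dR/dq_k for the normalized-from-unnormalized parameterization:
// dR/dq_k = (dM/dq_k - 2 q_k R) / (q.q)
static void quat_rotmat_grad(const double* q, const double R[3][3],
                             double dR[4][3][3]) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  const double n = w * w + x * x + y * y + z * z;
  const double dM[4][3][3] = {
      {{2 * w, -2 * z, 2 * y}, {2 * z, 2 * w, -2 * x}, {-2 * y, 2 * x, 2 * w}},
      {{2 * x, 2 * y, 2 * z}, {2 * y, -2 * x, -2 * w}, {2 * z, 2 * w, -2 * x}},
      {{-2 * y, 2 * x, 2 * w}, {2 * x, 2 * y, 2 * z}, {-2 * w, 2 * z, -2 * y}},
      {{-2 * z, -2 * w, 2 * x}, {2 * w, -2 * z, 2 * y}, {2 * x, 2 * y, 2 * z}}};
  for (int k = 0; k < 4; ++k)
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        dR[k][r][c] = (dM[k][r][c] - 2.0 * q[k] * R[r][c]) / n;
}

// Overlap of A with B transformed by (quaternion, translation) packed in
// par = (w, x, y, z, tx, ty, tz), plus the analytic 7-gradient.
// [[Rcpp::export]]
List cpp_overlap_qgrad(const NumericMatrix& A, const NumericVector& aA,
                       const NumericVector& pA, const NumericMatrix& B,
                       const NumericVector& aB, const NumericVector& pB,
                       const NumericVector& par) {
  const int nA = A.nrow(), nB = B.nrow();
  const double pi = M_PI;
  double q[4] = {par[0], par[1], par[2], par[3]};
  double t[3] = {par[4], par[5], par[6]};
  double R[3][3], dR[4][3][3];
  quat_rotmat(q, R);
  quat_rotmat_grad(q, R, dR);

  // transformed B coordinates
  std::vector<double> Bt(3 * nB);
  for (int j = 0; j < nB; ++j)
    for (int r = 0; r < 3; ++r)
      Bt[3 * j + r] = R[r][0] * B(j, 0) + R[r][1] * B(j, 1) +
                      R[r][2] * B(j, 2) + t[r];

  double v = 0.0;
  std::vector<double> gB(3 * nB, 0.0);  // dV / d(Bt_j)
  for (int i = 0; i < nA; ++i) {
    const double ai = aA[i], pamp = pA[i];
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nB; ++j) {
      const double s = ai + aB[j];
      const double g = ai * aB[j] / s;
      const double dx = Bt[3 * j] - ax, dy = Bt[3 * j + 1] - ay,
                   dz = Bt[3 * j + 2] - az;
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double term = pamp * pB[j] * std::pow(pi / s, 1.5) *
                          std::exp(-g * d2);
      v += term;
      const double c = -2.0 * g * term;
      gB[3 * j] += c * dx;
      gB[3 * j + 1] += c * dy;
      gB[3 * j + 2] += c * dz;
    }
  }

  NumericVector grad(7);
  for (int j = 0; j < nB; ++j) {
    grad[4] += gB[3 * j];
    grad[5] += gB[3 * j + 1];
    grad[6] += gB[3 * j + 2];
    for (int k = 0; k < 4; ++k) {
      double acc = 0.0;
      for (int r = 0; r < 3; ++r)
        acc += gB[3 * j + r] * (dR[k][r][0] * B(j, 0) + dR[k][r][1] * B(j, 1) +
                                dR[k][r][2] * B(j, 2));
      grad[k] += acc;
    }
  }
  return List::create(_["value"] = v, _["gradient"] = grad);
}

// Overlap of centered A against centered B under a stack of rotations
// (3*nrot x 3, rotations stacked row-blocks); used by the rotation-grid
// oracle so the grid sweep stays cheap.
// [[Rcpp::export]]
NumericVector cpp_overlap_rotgrid(const NumericMatrix& A,
                                  const NumericVector& aA,
                                  const NumericVector& pA,
                                  const NumericMatrix& B,
                                  const NumericVector& aB,
                                  const NumericVector& pB,
                                  const NumericMatrix& rots) {
  const int nrot = rots.nrow() / 3;
  const int nB = B.nrow();
  NumericVector out(nrot);
  NumericMatrix Bt(nB, 3);
  for (int m = 0; m < nrot; ++m) {
    for (int j = 0; j < nB; ++j)
      for (int r = 0; r < 3; ++r)
        Bt(j, r) = rots(3 * m + r, 0) * B(j, 0) + rots(3 * m + r, 1) * B(j, 1) +
                   rots(3 * m + r, 2) * B(j, 2);
    out[m] = cpp_overlap(A, aA, pA, Bt, aB, pB);
  }
  return out;
}
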
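// Pairwise superposed-RMSD matrix between all trajectory frames.
//
// For each ordered pair (i, j): frame j is superposed onto frame i by a
// least-squares fit over the fit-atom subset (Horn's quaternion method,
// equivalent to Kabsch with the proper-rotation determinant correction),
// then RMSD is measured over the measure-atom subset with both frames
// expressed relative to their fit-subset centroids.  The matrix is
// symmetrized by averaging the two directions; they coincide when the
// fit and measure subsets are equal, in which case only one direction is
// computed.
//
// The inner loop avoids LAPACK: the 4x4 symmetric quaternion matrix is
// diagonalized by a short cyclic Jacobi sweep.

#include <RcppArmadillo.h>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

// Cyclic Jacobi on a symmetric 4x4; returns eigenvector of the largest
// eigenvalue in q[4].
static void max_eigvec4(double A[4][4], double q[4]) {
  double V[4][4] = {{1, 0, 0, 0}, {0, 1, 0, 0}, {0, 0, 1, 0}, {0, 0, 0, 1}};
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 3; ++p)
      for (int r = p + 1; r < 4; ++r) off += A[p][r] * A[p][r];
    if (off < 1e-22) break;
    for (int p = 0; p < 3; ++p) {
      for (int r = p + 1; r < 4; ++r) {
        double apr = A[p][r];
        if (std::fabs(apr) < 1e-300) continue;
        double theta = (A[r][r] - A[p][p]) / (2.0 * apr);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 4; ++k) {
          double akp = A[k][p], akr = A[k][r];
          A[k][p] = c * akp - s * akr;
          A[k][r] = s * akp + c * akr;
        }
        for (int k = 0; k < 4; ++k) {
          double apk = A[p][k], ark = A[r][k];
          A[p][k] = c * apk - s * ark;
          A[r][k] = s * apk + c * ark;
        }
        for (int k = 0; k < 4; ++k) {
          double vkp = V[k][p], vkr = V[k][r];
          V[k][p] = c * vkp - s * vkr;
          V[k][r] = s * vkp + c * vkr;
        }
      }
    }
  }
  int best = 0;
  for (int k = 1; k < 4; ++k) if (A[k][k] > A[best][best]) best = k;
  for (int k = 0; k < 4; ++k) q[k] = V[k][best];
}

// Optimal proper rotation R (row-major) mapping centered mobile p onto
// centered target t: maximize sum t_k . (R p_k).
static void horn_rotation(const double* S, double R[9]) {
  // S: 3x3 column-major, S_ab = sum p_a t_b
  double Sxx = S[0], Syx = S[1], Szx = S[2];
  double Sxy = S[3], Syy = S[4], Szy = S[5];
  double Sxz = S[6], Syz = S[7], Szz = S[8];
  double N[4][4] = {
    {Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx},
    {Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz},
    {Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy},
    {Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz}};
  double q[4];
  max_eigvec4(N, q);
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

// [[Rcpp::export]]
arma::mat cpp_pairwise_rmsd(const arma::cube& coords,
                            const arma::uvec& fit_idx,
                            const arma::uvec& meas_idx) {
  // coords: n_atoms x 3 x n_frames (Angstrom); indices are 1-based.
  const arma::uword nf = coords.n_slices;
  const arma::uword nfit = fit_idx.n_elem, nmeas = meas_idx.n_elem;
  arma::uvec fi = fit_idx - 1, mi = meas_idx - 1;
  bool same = (nfit == nmeas) && arma::all(fi == mi);

  // fitc: centered fit coords; measc: measure coords relative to the
  // frame's fit centroid.  Layout: per frame, atom-major [x y z] rows.
  std::vector<double> fitc(nf * nfit * 3), measc(nf * nmeas * 3);
  for (arma::uword k = 0; k < nf; ++k) {
    double cx = 0, cy = 0, cz = 0;
    for (arma::uword a = 0; a < nfit; ++a) {
      cx += coords(fi[a], 0, k);
      cy += coords(fi[a], 1, k);
      cz += coords(fi[a], 2, k);
    }
    cx /= nfit; cy /= nfit; cz /= nfit;
    double* f = &fitc[k * nfit * 3];
    for (arma::uword a = 0; a < nfit; ++a) {
      f[3 * a] = coords(fi[a], 0, k) - cx;
      f[3 * a + 1] = coords(fi[a], 1, k) - cy;
      f[3 * a + 2] = coords(fi[a], 2, k) - cz;
    }
    double* m = &measc[k * nmeas * 3];
    for (arma::uword a = 0; a < nmeas; ++a) {
      m[3 * a] = coords(mi[a], 0, k) - cx;
      m[3 * a + 1] = coords(mi[a], 1, k) - cy;
      m[3 * a + 2] = coords(mi[a], 2, k) - cz;
    }
  }

  auto dir_rmsd = [&](arma::uword i, arma::uword j) {
    // superpose j (mobile) onto i (target)
    const double* fj = &fitc[j * nfit * 3];
    const double* fi_ = &fitc[i * nfit * 3];
    double S[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (arma::uword a = 0; a < nfit; ++a) {
      const double px = fj[3 * a], py = fj[3 * a + 1], pz = fj[3 * a + 2];
      const double tx = fi_[3 * a], ty = fi_[3 * a + 1], tz = fi_[3 * a + 2];
      S[0] += px * tx; S[1] += py * tx; S[2] += pz * tx;
      S[3] += px * ty; S[4] += py * ty; S[5] += pz * ty;
      S[6] += px * tz; S[7] += py * tz; S[8] += pz * tz;
    }
    double R[9];
    horn_rotation(S, R);
    const double* mj = &measc[j * nmeas * 3];
    const double* mi_ = &measc[i * nmeas * 3];
    double ss = 0;
    for (arma::uword a = 0; a < nmeas; ++a) {
      const double px = mj[3 * a], py = mj[3 * a + 1], pz = mj[3 * a + 2];
      double dx = R[0] * px + R[1] * py + R[2] * pz - mi_[3 * a];
      double dy = R[3] * px + R[4] * py + R[5] * pz - mi_[3 * a + 1];
      double dz = R[6] * px + R[7] * py + R[8] * pz - mi_[3 * a + 2];
      ss += dx * dx + dy * dy + dz * dz;
    }
    return std::sqrt(ss / nmeas);
  };

  arma::mat out(nf, nf, arma::fill::zeros);
  for (arma::uword i = 0; i < nf; ++i) {
    for (arma::uword j = i + 1; j < nf; ++j) {
      double d = dir_rmsd(i, j);
      if (!same) d = 0.5 * (d + dir_rmsd(j, i));
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
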
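// KSG (Kraskov-Stogbauer-Grassberger) conditional mutual information
// estimator, algorithm-1 form, with max-norm (Chebyshev) distances in
// the joint space:
//
//   I(X; Y | Z) = psi(k) - < psi(n_xz + 1) + psi(n_yz + 1) - psi(n_z + 1) >
//
// where eps_i is the distance to the k-th nearest neighbor of point i in
// the joint (X,Y,Z) space and n_* counts neighbors strictly within eps_i
// in the corresponding marginal subspace. Transfer entropy is this CMI
// with X the target's future, Y the source's past, Z the target's past.
//
// Brute-force O(N^2) neighbor search: N is at most a few tens of
// thousands here and the embedding dimensions are tiny, so a cache-
// friendly scan beats tree overhead. The inner loop is specialized for
// the default history length 1 (scalar Y and Z).

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".ksg_cmi_cpp")]]
double ksg_cmi_cpp(NumericVector x, NumericMatrix Y, NumericMatrix Z,
                   int k) {
  const int n = x.size();
  const int py = Y.ncol(), pz = Z.ncol();
  if (Y.nrow() != n || Z.nrow() != n)
    stop("inconsistent sample sizes");
  if (k < 1 || k >= n - 1)
    stop("k_neighbors must be in [1, n - 2]");

  const double *xp = &x[0];
  std::vector<const double *> yp(py), zp(pz);
  for (int c = 0; c < py; ++c) yp[c] = &Y[0] + (size_t)c * n;
  for (int c = 0; c < pz; ++c) zp[c] = &Z[0] + (size_t)c * n;

  std::vector<double> dxz(n), dyz(n), dz(n), djoint(n);
  const bool scalar_hist = (py == 1 && pz == 1);
  double acc = 0.0;

  for (int i = 0; i < n; ++i) {
    if (scalar_hist) {
      const double xi = xp[i], yi = yp[0][i], zi = zp[0][i];
      const double *yy = yp[0], *zz = zp[0];
      for (int j = 0; j < n; ++j) {
        const double dzv = std::fabs(zi - zz[j]);
        const double dxv = std::fabs(xi - xp[j]);
        const double dyv = std::fabs(yi - yy[j]);
        const double dxzv = dzv > dxv ? dzv : dxv;
        const double dyzv = dzv > dyv ? dzv : dyv;
        dz[j] = dzv;
        dxz[j] = dxzv;
        dyz[j] = dyzv;
        djoint[j] = dxzv > dyzv ? dxzv : dyzv;
      }
    } else {
      for (int j = 0; j < n; ++j) {
        double dzv = 0.0, dyv = 0.0;
        for (int c = 0; c < pz; ++c) {
          const double v = std::fabs(zp[c][i] - zp[c][j]);
          if (v > dzv) dzv = v;
        }
        for (int c = 0; c < py; ++c) {
          const double v = std::fabs(yp[c][i] - yp[c][j]);
          if (v > dyv) dyv = v;
        }
        const double dxv = std::fabs(xp[i] - xp[j]);
        const double dxzv = dzv > dxv ? dzv : dxv;
        const double dyzv = dzv > dyv ? dzv : dyv;
        dz[j] = dzv;
        dxz[j] = dxzv;
        dyz[j] = dyzv;
        djoint[j] = dxzv > dyzv ? dxzv : dyzv;
      }
    }
    djoint[i] = R_PosInf; // exclude self
    // djoint is scratch from here on: partial-select the k-th NN distance
    std::nth_element(djoint.begin(), djoint.begin() + (k - 1),
                     djoint.end());
    const double eps = djoint[k - 1];

    int nxz = 0, nyz = 0, nz = 0;
    for (int j = 0; j < n; ++j) {
      if (dxz[j] < eps) ++nxz;
      if (dyz[j] < eps) ++nyz;
      if (dz[j] < eps) ++nz;
    }
    // the self point (distance 0 in every subspace) was counted once in
    // each tally whenever eps > 0; remove it
    if (eps > 0.0) { --nxz; --nyz; --nz; }
    acc += R::digamma(nxz + 1.0) + R::digamma(nyz + 1.0) -
           R::digamma(nz + 1.0);
  }
  return R::digamma((double)k) - acc / n;
}
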
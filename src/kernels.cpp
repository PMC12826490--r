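// Inner loops of the finite-volume surface operators. The padded (ghost)
// field arrays and all index bookkeeping are prepared in R; these kernels
// only evaluate fluxes, make interface fluxes single-valued, and accumulate
// the divergence.

#include <Rcpp.h>
using namespace Rcpp;

// Diffusive flux divergence of one padded scalar field.
// P: padded field, (n+2) x (n+2) x 8 column-major.
// Cu1/Cu2: u-face coefficient arrays ((n+1) x n x 8); Cv1/Cv2 v-face
// (n x (n+1) x 8); invA: 1/area per cell; pA/pB/sym: 1-based indices into
// the concatenated flux vector c(Fu, Fv); sA/sB: outward-orientation signs.
// [[Rcpp::export]]
NumericVector diff_flux_div_cpp(NumericVector P, int n,
                                NumericVector Cu1, NumericVector Cu2,
                                NumericVector Cv1, NumericVector Cv2,
                                NumericVector invA,
                                IntegerVector pA, IntegerVector pB,
                                NumericVector sA, NumericVector sB,
                                IntegerVector sym) {
  const int np = n + 2;
  const int NU = 8 * (n + 1) * n;
  const int NV = 8 * n * (n + 1);
  std::vector<double> Fall(NU + NV);
  const double *p = P.begin();

  for (int z = 0; z < 8; ++z) {
    const double *pz = p + (size_t)z * np * np;
    // u-faces
    for (int j = 0; j < n; ++j) {
      const double *c0 = pz + (size_t)j * np;       // column j   (v index j-1+1)
      const double *c1 = c0 + np;                   // column j+1 (cell row)
      const double *c2 = c1 + np;                   // column j+2
      double *f = &Fall[(size_t)z * (n + 1) * n + (size_t)j * (n + 1)];
      const double *a1 = Cu1.begin() + (size_t)z * (n + 1) * n + (size_t)j * (n + 1);
      const double *a2 = Cu2.begin() + (size_t)z * (n + 1) * n + (size_t)j * (n + 1);
      for (int i = 0; i <= n; ++i) {
        double dU = c1[i + 1] - c1[i];
        double cr = (c2[i] - c0[i]) + (c2[i + 1] - c0[i + 1]);
        f[i] = a1[i] * dU + a2[i] * cr;
      }
    }
    // v-faces
    for (int j = 0; j <= n; ++j) {
      const double *cD = pz + (size_t)j * np;       // column j
      const double *cU = cD + np;                   // column j+1
      double *f = &Fall[NU + (size_t)z * n * (n + 1) + (size_t)j * n];
      const double *b1 = Cv1.begin() + (size_t)z * n * (n + 1) + (size_t)j * n;
      const double *b2 = Cv2.begin() + (size_t)z * n * (n + 1) + (size_t)j * n;
      for (int i = 0; i < n; ++i) {
        double dV = cU[i + 1] - cD[i + 1];
        double cr = (cD[i + 2] - cD[i]) + (cU[i + 2] - cU[i]);
        f[i] = b1[i] * dV + b2[i] * cr;
      }
    }
  }

  // single-valued interface fluxes (average of the two one-sided estimates)
  for (int t = 0; t < pA.size(); ++t) {
    int a = pA[t] - 1, b = pB[t] - 1;
    double outA = Fall[a] * sA[t], outB = Fall[b] * sB[t];
    double q = 0.5 * (outA - outB);
    Fall[a] = q * sA[t];
    Fall[b] = -q * sB[t];
  }
  for (int t = 0; t < sym.size(); ++t) Fall[sym[t] - 1] = 0.0;

  NumericVector out(8 * n * n);
  for (int z = 0; z < 8; ++z) {
    for (int j = 0; j < n; ++j) {
      const double *fu = &Fall[(size_t)z * (n + 1) * n + (size_t)j * (n + 1)];
      const double *fb = &Fall[NU + (size_t)z * n * (n + 1) + (size_t)j * n];
      const double *ft = fb + n;
      double *o = out.begin() + (size_t)z * n * n + (size_t)j * n;
      const double *ia = invA.begin() + (size_t)z * n * n + (size_t)j * n;
      for (int i = 0; i < n; ++i) {
        o[i] = (fu[i + 1] - fu[i] + ft[i] - fb[i]) * ia[i];
      }
    }
  }
  return out;
}

// Upwind advective flux divergence of k species stacked along the zone
// dimension. P: padded stack (n+2) x (n+2) x (8k); Qp/Qn: positive/negative
// parts of the face flux velocities (length NU+NV, shared by all species);
// qo: single-valued interface outflow (A-side) per pair; cA/cB: 1-based
// interior cell indices (within one species block) adjacent to each pair;
// X: N x k matrix of cell values (for interface upwinding).
// [[Rcpp::export]]
NumericMatrix adv_flux_div_cpp(NumericVector P, int n, int k,
                               NumericVector Qp, NumericVector Qn,
                               NumericVector qo,
                               IntegerVector pA, IntegerVector pB,
                               NumericVector sA, NumericVector sB,
                               IntegerVector cA, IntegerVector cB,
                               IntegerVector sym,
                               NumericMatrix X,
                               NumericVector invA) {
  const int np = n + 2;
  const int NU = 8 * (n + 1) * n;
  const int NV = 8 * n * (n + 1);
  const int N = 8 * n * n;
  NumericMatrix out(N, k);
  std::vector<double> Fall(NU + NV);

  for (int s = 0; s < k; ++s) {
    const double *p = P.begin() + (size_t)s * np * np * 8;
    const double *x = &X(0, s);
    for (int z = 0; z < 8; ++z) {
      const double *pz = p + (size_t)z * np * np;
      for (int j = 0; j < n; ++j) {
        const double *c1 = pz + (size_t)(j + 1) * np;
        double *f = &Fall[(size_t)z * (n + 1) * n + (size_t)j * (n + 1)];
        const double *qp = Qp.begin() + (size_t)z * (n + 1) * n + (size_t)j * (n + 1);
        const double *qn = Qn.begin() + (size_t)z * (n + 1) * n + (size_t)j * (n + 1);
        for (int i = 0; i <= n; ++i) {
          f[i] = qp[i] * c1[i] + qn[i] * c1[i + 1];
        }
      }
      for (int j = 0; j <= n; ++j) {
        const double *cD = pz + (size_t)j * np;
        const double *cU = cD + np;
        double *f = &Fall[NU + (size_t)z * n * (n + 1) + (size_t)j * n];
        const double *qp = Qp.begin() + NU + (size_t)z * n * (n + 1) + (size_t)j * n;
        const double *qn = Qn.begin() + NU + (size_t)z * n * (n + 1) + (size_t)j * n;
        for (int i = 0; i < n; ++i) {
          f[i] = qp[i] * cD[i + 1] + qn[i] * cU[i + 1];
        }
      }
    }
    for (int t = 0; t < pA.size(); ++t) {
      int a = pA[t] - 1, b = pB[t] - 1;
      double q = qo[t];
      double fup = (q > 0) ? x[cA[t] - 1] : x[cB[t] - 1];
      double FA = q * fup;
      Fall[a] = FA * sA[t];
      Fall[b] = -FA * sB[t];
    }
    for (int t = 0; t < sym.size(); ++t) Fall[sym[t] - 1] = 0.0;

    for (int z = 0; z < 8; ++z) {
      for (int j = 0; j < n; ++j) {
        const double *fu = &Fall[(size_t)z * (n + 1) * n + (size_t)j * (n + 1)];
        const double *fb = &Fall[NU + (size_t)z * n * (n + 1) + (size_t)j * n];
        const double *ft = fb + n;
        double *o = &out(0, s) + (size_t)z * n * n + (size_t)j * n;
        const double *ia = invA.begin() + (size_t)z * n * n + (size_t)j * n;
        for (int i = 0; i < n; ++i) {
          o[i] = (fu[i + 1] - fu[i] + ft[i] - fb[i]) * ia[i];
        }
      }
    }
  }
  return out;
}
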
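// Low-level texture kernels: separable 3D convolution, per-voxel GLCM
// statistics, structure-tensor dominant orientations, column ranks.
// Array layout matches R: column-major, dim = (slice, depth, ascan),
// linear index = s + S*(d + D*a).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric reflection with edge repeat: (-1 -> 0), (n -> n-1)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// 1D correlation pass along one axis (0 = slice, 1 = depth, 2 = ascan)
// with reflect padding; kernel is centered (odd or even length; center
// index = (len-1)/2, integer division).
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int S, int D, int A, int axis,
                      const std::vector<double>& k) {
  int len = (int)k.size();
  int c = (len - 1) / 2;
  int n[3] = {S, D, A};
  int na = n[axis];
  for (int a = 0; a < A; ++a) {
    for (int d = 0; d < D; ++d) {
      for (int s = 0; s < S; ++s) {
        int pos[3] = {s, d, a};
        double acc = 0.0;
        for (int t = 0; t < len; ++t) {
          int p = pos[axis] + t - c;
          p = reflect_idx(p, na);
          int q[3] = {pos[0], pos[1], pos[2]};
          q[axis] = p;
          acc += k[t] * in[q[0] + (size_t)S * (q[1] + (size_t)D * q[2])];
        }
        out[s + (size_t)S * (d + (size_t)D * a)] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sepconv3(NumericVector arr, IntegerVector dims,
                           NumericVector kDepth, NumericVector kAscan,
                           NumericVector kSlice) {
  int S = dims[0], D = dims[1], A = dims[2];
  size_t N = (size_t)S * D * A;
  std::vector<double> buf1(arr.begin(), arr.end()), buf2(N);
  conv_axis(buf1, buf2, S, D, A, 1,
            std::vector<double>(kDepth.begin(), kDepth.end()));
  conv_axis(buf2, buf1, S, D, A, 2,
            std::vector<double>(kAscan.begin(), kAscan.end()));
  conv_axis(buf1, buf2, S, D, A, 0,
            std::vector<double>(kSlice.begin(), kSlice.end()));
  NumericVector out(N);
  std::copy(buf2.begin(), buf2.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_boxmean3(NumericVector arr, IntegerVector dims, int w) {
  int S = dims[0], D = dims[1], A = dims[2];
  size_t N = (size_t)S * D * A;
  std::vector<double> k(w, 1.0 / w);
  std::vector<double> buf1(arr.begin(), arr.end()), buf2(N);
  conv_axis(buf1, buf2, S, D, A, 1, k);
  conv_axis(buf2, buf1, S, D, A, 2, k);
  conv_axis(buf1, buf2, S, D, A, 0, k);
  NumericVector out(N);
  std::copy(buf2.begin(), buf2.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

static inline double xlogx(double p) { return p > 0.0 ? p * std::log(p) : 0.0; }

// Per-voxel GLCM Haralick statistics over a sliding cubic window clipped to
// the mask.  levels: 0-based gray levels (int array); maskIdx: 0-based linear
// indices of voxels to evaluate (in R's which() order); offsets: 13 x 3
// matrix of (slice, depth, ascan) displacement classes, counted
// symmetrically.  Returns nVox x 13 matrix; rows with an empty GLCM are NaN.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_stats(IntegerVector levels, IntegerVector dims,
                             LogicalVector mask, IntegerVector maskIdx,
                             int nLevels, int w, IntegerMatrix offsets) {
  int S = dims[0], D = dims[1], A = dims[2];
  int h = (w - 1) / 2;
  int nOff = offsets.nrow();
  int nVox = maskIdx.size();
  int nL = nLevels;
  NumericMatrix out(nVox, 13);
  std::vector<double> glcm((size_t)nL * nL);
  std::vector<double> px(nL), psum(2 * nL - 1), pdiff(nL);

  for (int v = 0; v < nVox; ++v) {
    size_t idx = (size_t)maskIdx[v];
    int s0 = idx % S;
    int rem = idx / S;
    int d0 = rem % D;
    int a0 = rem / D;

    std::fill(glcm.begin(), glcm.end(), 0.0);
    double total = 0.0;

    int sLo = std::max(0, s0 - h), sHi = std::min(S - 1, s0 + h);
    int dLo = std::max(0, d0 - h), dHi = std::min(D - 1, d0 + h);
    int aLo = std::max(0, a0 - h), aHi = std::min(A - 1, a0 + h);

    for (int a = aLo; a <= aHi; ++a)
      for (int d = dLo; d <= dHi; ++d)
        for (int s = sLo; s <= sHi; ++s) {
          size_t pi = s + (size_t)S * (d + (size_t)D * a);
          if (!mask[pi]) continue;
          int lp = levels[pi];
          for (int o = 0; o < nOff; ++o) {
            int s2 = s + offsets(o, 0), d2 = d + offsets(o, 1),
                a2 = a + offsets(o, 2);
            if (s2 < sLo || s2 > sHi || d2 < dLo || d2 > dHi ||
                a2 < aLo || a2 > aHi) continue;
            size_t qi = s2 + (size_t)S * (d2 + (size_t)D * a2);
            if (!mask[qi]) continue;
            int lq = levels[qi];
            glcm[lp + (size_t)nL * lq] += 1.0;
            glcm[lq + (size_t)nL * lp] += 1.0;
            total += 2.0;
          }
        }

    if (total <= 0.0) {
      for (int m = 0; m < 13; ++m) out(v, m) = NA_REAL;
      continue;
    }

    std::fill(px.begin(), px.end(), 0.0);
    std::fill(psum.begin(), psum.end(), 0.0);
    std::fill(pdiff.begin(), pdiff.end(), 0.0);

    double energy = 0.0, contrast = 0.0, homog = 0.0, entropy = 0.0;
    double sij = 0.0;
    for (int i = 0; i < nL; ++i)
      for (int j = 0; j < nL; ++j) {
        double p = glcm[i + (size_t)nL * j] / total;
        if (p <= 0.0) continue;
        energy += p * p;
        int dd = i - j;
        contrast += (double)dd * dd * p;
        homog += p / (1.0 + (double)dd * dd);
        entropy -= xlogx(p);
        sij += (double)i * j * p;
        px[i] += p;
        psum[i + j] += p;
        pdiff[std::abs(dd)] += p;
      }

    double mu = 0.0;
    for (int i = 0; i < nL; ++i) mu += i * px[i];
    double var = 0.0;
    for (int i = 0; i < nL; ++i) var += (i - mu) * (i - mu) * px[i];
    double corr = var > 1e-12 ? (sij - mu * mu) / var : 0.0;

    double sumAvg = 0.0;
    for (int k2 = 0; k2 <= 2 * (nL - 1); ++k2) sumAvg += k2 * psum[k2];
    double sumVar = 0.0, sumEnt = 0.0;
    for (int k2 = 0; k2 <= 2 * (nL - 1); ++k2) {
      sumVar += (k2 - sumAvg) * (k2 - sumAvg) * psum[k2];
      sumEnt -= xlogx(psum[k2]);
    }
    double diffAvg = 0.0;
    for (int k2 = 0; k2 < nL; ++k2) diffAvg += k2 * pdiff[k2];
    double diffVar = 0.0, diffEnt = 0.0;
    for (int k2 = 0; k2 < nL; ++k2) {
      diffVar += (k2 - diffAvg) * (k2 - diffAvg) * pdiff[k2];
      diffEnt -= xlogx(pdiff[k2]);
    }

    // information measures of correlation (symmetric GLCM: py = px)
    double hx = 0.0;
    for (int i = 0; i < nL; ++i) hx -= xlogx(px[i]);
    double hxy1 = 0.0, hxy2 = 0.0;
    for (int i = 0; i < nL; ++i)
      for (int j = 0; j < nL; ++j) {
        double pipj = px[i] * px[j];
        double p = glcm[i + (size_t)nL * j] / total;
        if (pipj > 0.0) {
          hxy1 -= p * std::log(pipj);
          hxy2 -= xlogx(pipj);
        }
      }
    double imc1 = hx > 1e-12 ? (entropy - hxy1) / hx : 0.0;
    double arg = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
    double imc2 = arg > 0.0 ? std::sqrt(arg) : 0.0;

    out(v, 0) = energy;   out(v, 1) = contrast; out(v, 2) = corr;
    out(v, 3) = var;      out(v, 4) = homog;    out(v, 5) = sumAvg;
    out(v, 6) = sumVar;   out(v, 7) = sumEnt;   out(v, 8) = entropy;
    out(v, 9) = diffVar;  out(v, 10) = diffEnt; out(v, 11) = imc1;
    out(v, 12) = imc2;
  }
  return out;
}

// Dominant local gradient orientation per voxel from the windowed structure
// tensor (sum over a w^3 window clipped to bounds of the outer products of
// central-difference gradients).  Returns in-plane angle theta in [0, pi)
// (within the depth x A-scan B-scan plane), through-plane angle phi in
// [-pi/2, pi/2], and the count of zero-gradient (undefined) voxels, which
// are assigned angle 0.
// [[Rcpp::export]]
List cpp_orientation_angles(NumericVector g1, NumericVector g2,
                            NumericVector g3, IntegerVector dims, int w,
                            LogicalVector mask) {
  int S = dims[0], D = dims[1], A = dims[2];
  size_t N = (size_t)S * D * A;
  int h = (w - 1) / 2;
  NumericVector theta(N), phi(N);
  int zeroCount = 0;
  arma::mat T(3, 3), vecs(3, 3);
  arma::vec vals(3);

  for (int a = 0; a < A; ++a)
    for (int d = 0; d < D; ++d)
      for (int s = 0; s < S; ++s) {
        if (!mask[s + (size_t)S * (d + (size_t)D * a)]) continue;
        double t11 = 0, t12 = 0, t13 = 0, t22 = 0, t23 = 0, t33 = 0;
        for (int a2 = std::max(0, a - h); a2 <= std::min(A - 1, a + h); ++a2)
          for (int d2 = std::max(0, d - h); d2 <= std::min(D - 1, d + h); ++d2)
            for (int s2 = std::max(0, s - h); s2 <= std::min(S - 1, s + h); ++s2) {
              size_t i = s2 + (size_t)S * (d2 + (size_t)D * a2);
              double x = g1[i], y = g2[i], z = g3[i];
              t11 += x * x; t12 += x * y; t13 += x * z;
              t22 += y * y; t23 += y * z; t33 += z * z;
            }
        size_t idx = s + (size_t)S * (d + (size_t)D * a);
        double tr = t11 + t22 + t33;
        if (tr < 1e-12) {
          theta[idx] = 0.0; phi[idx] = 0.0; ++zeroCount;
          continue;
        }
        T(0, 0) = t11; T(0, 1) = t12; T(0, 2) = t13;
        T(1, 0) = t12; T(1, 1) = t22; T(1, 2) = t23;
        T(2, 0) = t13; T(2, 1) = t23; T(2, 2) = t33;
        arma::eig_sym(vals, vecs, T);
        arma::vec v = vecs.col(2);  // largest eigenvalue
        // resolve sign ambiguity: first significant component positive
        double eps = 1e-10;
        if (v(0) < -eps || (std::abs(v(0)) <= eps &&
            (v(1) < -eps || (std::abs(v(1)) <= eps && v(2) < 0))))
          v = -v;
        double th = std::atan2(v(1), v(0));
        while (th < 0) th += M_PI;
        while (th >= M_PI) th -= M_PI;
        theta[idx] = th;
        double r = std::sqrt(v(0) * v(0) + v(1) * v(1));
        phi[idx] = std::atan2(v(2), r);
      }
  theta.attr("dim") = dims;
  phi.attr("dim") = dims;
  return List::create(_["theta"] = theta, _["phi"] = phi,
                      _["zeroCount"] = zeroCount);
}

// Column-wise ranks with average ties (for the vectorized rank-sum test).
// [[Rcpp::export]]
NumericMatrix cpp_colranks(NumericMatrix x) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  std::vector<int> ord(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    NumericMatrix::Column col = x(_, j);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    int i = 0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && col[ord[k + 1]] == col[ord[i]]) ++k;
      double r = 0.5 * (i + k) + 1.0;
      for (int t = i; t <= k; ++t) out(ord[t], j) = r;
      i = k + 1;
    }
  }
  return out;
}
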
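#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// PCIT trio elimination over a Pearson correlation matrix.
//
// For every unordered trio (x, y, z) the three first-order partial
// correlations are computed,
//   r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2)),
// the trio tolerance is the average of the partial/marginal ratios,
//   eps = (r_xy.z / r_xy + r_xz.y / r_xz + r_yz.x / r_yz) / 3,
// and a pair is eliminated when its |r| falls below eps times |r| of
// BOTH other legs. Pairs never eliminated by any third gene are
// significant. Numerical guards (shared with the pure-R reference used
// in the tests): legs are clipped to |r| <= 1 - 1e-12 before entering
// the partial-correlation formula, and a ratio with a zero denominator
// contributes 0 to eps.

static inline double clip_r(double v) {
  const double cap = 1.0 - 1e-12;
  if (v > cap) return cap;
  if (v < -cap) return -cap;
  return v;
}

// [[Rcpp::export(name = ".pcit_significance_cpp")]]
LogicalMatrix pcit_significance_cpp(NumericMatrix r) {
  const int n = r.nrow();
  if (r.ncol() != n) stop("correlation matrix must be square");
  std::vector<char> elim((size_t)n * n, 0);

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = r(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = r(x, z);
        const double ryz = r(y, z);
        const double cxy = clip_r(rxy), cxz = clip_r(rxz), cyz = clip_r(ryz);
        const double dxy = 1.0 - cxy * cxy;
        const double dxz = 1.0 - cxz * cxz;
        const double dyz = 1.0 - cyz * cyz;
        const double pxy = (cxy - cxz * cyz) / std::sqrt(dxz * dyz);
        const double pxz = (cxz - cxy * cyz) / std::sqrt(dxy * dyz);
        const double pyz = (cyz - cxy * cxz) / std::sqrt(dxy * dxz);
        const double t1 = (cxy != 0.0) ? pxy / cxy : 0.0;
        const double t2 = (cxz != 0.0) ? pxz / cxz : 0.0;
        const double t3 = (cyz != 0.0) ? pyz / cyz : 0.0;
        const double ae = std::fabs((t1 + t2 + t3) / 3.0);
        const double axy = std::fabs(rxy);
        const double axz = std::fabs(rxz);
        const double ayz = std::fabs(ryz);
        if (axy < ae * axz && axy < ae * ayz) elim[(size_t)x * n + y] = 1;
        if (axz < ae * axy && axz < ae * ayz) elim[(size_t)x * n + z] = 1;
        if (ayz < ae * axy && ayz < ae * axz) elim[(size_t)y * n + z] = 1;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  LogicalMatrix keep(n, n);
  for (int i = 0; i < n; ++i) {
    keep(i, i) = true;
    for (int j = i + 1; j < n; ++j) {
      bool k = !elim[(size_t)i * n + j];
      keep(i, j) = k;
      keep(j, i) = k;
    }
  }
  return keep;
}
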
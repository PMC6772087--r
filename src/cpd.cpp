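#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One E-step of the Gaussian-mixture alignment plus the sufficient
// statistics of the similarity M-step, computed in a single pass.
//
// TY: transformed instance points (n x 3); Y: untransformed instance
// points (n x 3); M: mean-cloud points (m x 3); sigma2: kernel
// variance; w: uniform-outlier weight over volume vol.
//
// Returns: P (responsibilities, n x m), logLik, pk = rowSums(P),
// PM = P * M (n x 3), cs = colSums(P), S1 = PM' Y (3 x 3),
// S2 = colSums(PM), Sy = sum_i pk_i y_i, sumPkY2 = sum_i pk_i |y_i|^2,
// W = sum(pk).
// [[Rcpp::export(name = ".cpdEStep")]]
List cpdEStep(NumericMatrix TY, NumericMatrix Y, NumericMatrix M,
              double sigma2, double w, double vol) {
  const int n = TY.nrow(), m = M.nrow();
  NumericMatrix P(n, m);
  NumericMatrix PM(n, 3);
  NumericVector pk(n), cs(m);
  NumericMatrix S1(3, 3);
  NumericVector S2(3), Sy(3);
  const double inv2s = 1.0 / (2.0 * sigma2);
  // exp(-34) ~ 1.7e-15: responsibilities beyond this are numerically 0
  const double d2cut = 34.0 / inv2s;
  const double norm3 = std::pow(2.0 * M_PI * sigma2, 1.5);
  const double cOut = w > 0 ? w / (1.0 - w) * m * norm3 / vol : 0.0;
  const double outDens = w > 0 ? w / vol : 0.0;
  double ll = 0.0, Wtot = 0.0, sumPkY2 = 0.0;

  std::vector<double> mx(m), my(m), mz(m);
  for (int j = 0; j < m; ++j) {
    mx[j] = M(j, 0);
    my[j] = M(j, 1);
    mz[j] = M(j, 2);
  }

  for (int i = 0; i < n; ++i) {
    const double x = TY(i, 0), y = TY(i, 1), z = TY(i, 2);
    double rs = 0.0;
    for (int j = 0; j < m; ++j) {
      const double dx = x - mx[j], dy = y - my[j], dz = z - mz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < d2cut) {
        const double g = std::exp(-d2 * inv2s);
        P(i, j) = g;
        rs += g;
      }
    }
    ll += std::log((1.0 - w) / (m * norm3) * rs + outDens + 1e-300);
    const double denom = rs + cOut > 1e-300 ? rs + cOut : 1e-300;
    const double inv = 1.0 / denom;
    double pmx = 0.0, pmy = 0.0, pmz = 0.0, rowSum = 0.0;
    for (int j = 0; j < m; ++j) {
      double p = P(i, j);
      if (p == 0.0) continue;
      p *= inv;
      P(i, j) = p;
      rowSum += p;
      cs[j] += p;
      pmx += p * mx[j];
      pmy += p * my[j];
      pmz += p * mz[j];
    }
    pk[i] = rowSum;
    Wtot += rowSum;
    PM(i, 0) = pmx;
    PM(i, 1) = pmy;
    PM(i, 2) = pmz;
    const double yx = Y(i, 0), yy = Y(i, 1), yz = Y(i, 2);
    S1(0, 0) += pmx * yx; S1(0, 1) += pmx * yy; S1(0, 2) += pmx * yz;
    S1(1, 0) += pmy * yx; S1(1, 1) += pmy * yy; S1(1, 2) += pmy * yz;
    S1(2, 0) += pmz * yx; S1(2, 1) += pmz * yy; S1(2, 2) += pmz * yz;
    S2[0] += pmx; S2[1] += pmy; S2[2] += pmz;
    Sy[0] += rowSum * yx; Sy[1] += rowSum * yy; Sy[2] += rowSum * yz;
    sumPkY2 += rowSum * (yx * yx + yy * yy + yz * yz);
  }
  return List::create(
    _["P"] = P, _["logLik"] = ll, _["pk"] = pk, _["PM"] = PM,
    _["cs"] = cs, _["S1"] = S1, _["S2"] = S2, _["Sy"] = Sy,
    _["sumPkY2"] = sumPkY2, _["W"] = Wtot
  );
}
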
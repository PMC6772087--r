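#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Rectangular linear sum assignment (rows <= cols) by shortest augmenting
// paths with dual-variable updates (Jonker-Volgenant style). Minimises
// sum_i cost(i, assign[i]) over injective assignments of rows to columns.
//
// Returns a 1-based column index per row.
// [[Rcpp::export(name = ".lapSolve")]]
IntegerVector lapSolve(NumericMatrix cost) {
  const int n = cost.nrow();
  const int m = cost.ncol();
  if (m < n) stop("cost matrix must have at least as many columns as rows");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(n, 0.0), v(m, 0.0);
  std::vector<int> col4row(n, -1), row4col(m, -1);

  std::vector<double> shortest(m);
  std::vector<int> pred(m);
  std::vector<char> SR(n), SC(m);

  for (int curRow = 0; curRow < n; ++curRow) {
    std::fill(shortest.begin(), shortest.end(), INF);
    std::fill(SR.begin(), SR.end(), 0);
    std::fill(SC.begin(), SC.end(), 0);
    std::fill(pred.begin(), pred.end(), -1);

    int sink = -1;
    int i = curRow;
    double minVal = 0.0;

    while (sink == -1) {
      SR[i] = 1;
      double lowest = INF;
      int jLow = -1;
      for (int j = 0; j < m; ++j) {
        if (SC[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) {
          shortest[j] = r;
          pred[j] = i;
        }
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && row4col[j] == -1)) {
          lowest = shortest[j];
          jLow = j;
        }
      }
      minVal = lowest;
      if (!std::isfinite(minVal)) stop("infeasible assignment problem");
      SC[jLow] = 1;
      if (row4col[jLow] == -1) {
        sink = jLow;
      } else {
        i = row4col[jLow];
      }
    }

    u[curRow] += minVal;
    for (int k = 0; k < n; ++k) {
      if (SR[k] && k != curRow) u[k] += minVal - shortest[col4row[k]];
    }
    for (int j = 0; j < m; ++j) {
      if (SC[j]) v[j] -= minVal - shortest[j];
    }

    int j = sink;
    while (true) {
      int ii = pred[j];
      row4col[j] = ii;
      int tmp = col4row[ii];
      col4row[ii] = j;
      j = tmp;
      if (ii == curRow) break;
    }
  }

  IntegerVector out(n);
  for (int k = 0; k < n; ++k) out[k] = col4row[k] + 1;
  return out;
}
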
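#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming fill for pairwise alignment of a read x against a
// reference window y.  Two models:
//   simple: single matrix, every gapped base costs gap_extend;
//   affine: Gotoh three-matrix recursion, a gap of length k costs
//           gap_open + k * gap_extend.  M is the overall-best matrix
//           (it takes the max over the diagonal case and the two gap
//           matrices), X holds alignments ending with a read base against
//           a gap (insertion to the reference), Y alignments ending with a
//           window base against a gap (deletion from the reference).
// fitting = true gives the window free overhangs: row 0 costs nothing
// (any window prefix may be skipped) and the optimum is read off the last
// row rather than the corner.  Invalid states carry NEG (< -1e29).

static const double NEG = -1e30;

// [[Rcpp::export]]
List gotoh_fill_cpp(std::string x, std::string y,
                    double match, double mismatch,
                    double gap_open, double gap_extend,
                    bool simple, bool fitting) {
  const int n = (int)x.size(), m = (int)y.size();
  NumericMatrix M(n + 1, m + 1);

  if (simple) {
    for (int i = 0; i <= n; ++i) M(i, 0) = i * gap_extend;
    for (int j = 0; j <= m; ++j) M(0, j) = fitting ? 0.0 : j * gap_extend;
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        double d = M(i - 1, j - 1) + (x[i - 1] == y[j - 1] ? match : mismatch);
        double a = M(i - 1, j) + gap_extend;
        double b = M(i, j - 1) + gap_extend;
        M(i, j) = std::max(d, std::max(a, b));
      }
    }
    return List::create(_["M"] = M);
  }

  NumericMatrix X(n + 1, m + 1), Y(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    X(i, 0) = gap_open + i * gap_extend;
    M(i, 0) = X(i, 0);
    Y(i, 0) = NEG;
  }
  for (int j = 1; j <= m; ++j) {
    if (fitting) { M(0, j) = 0.0; Y(0, j) = NEG; }
    else         { Y(0, j) = gap_open + j * gap_extend; M(0, j) = Y(0, j); }
    X(0, j) = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      X(i, j) = std::max(M(i - 1, j) + gap_open + gap_extend,
                         X(i - 1, j) + gap_extend);
      Y(i, j) = std::max(M(i, j - 1) + gap_open + gap_extend,
                         Y(i, j - 1) + gap_extend);
      double d = M(i - 1, j - 1) + (x[i - 1] == y[j - 1] ? match : mismatch);
      M(i, j) = std::max(d, std::max(X(i, j), Y(i, j)));
    }
  }
  return List::create(_["M"] = M, _["X"] = X, _["Y"] = Y);
}
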
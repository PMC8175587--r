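#include <Rcpp.h>
using namespace Rcpp;

// Differential box-counting kernel: sum over s x s spatial blocks of
// floor(max/h) - floor(min/h) + 1 with box height h = s G / M.
// classic = TRUE truncates incomplete border blocks; otherwise shrunken
// border blocks cover every pixel.
// [[Rcpp::export]]
double dbc_count_cpp(NumericMatrix gray, int s, double G, bool classic) {
  const int M = gray.nrow();
  const int limit = classic ? M - (M % s) : M;
  const double h = static_cast<double>(s) * G / M;
  double total = 0.0;
  for (int c0 = 0; c0 < limit; c0 += s) {
    const int c1 = std::min(c0 + s, limit);
    for (int r0 = 0; r0 < limit; r0 += s) {
      const int r1 = std::min(r0 + s, limit);
      double mn = gray(r0, c0), mx = mn;
      for (int c = c0; c < c1; ++c)
        for (int r = r0; r < r1; ++r) {
          const double v = gray(r, c);
          if (v < mn) mn = v;
          else if (v > mx) mx = v;
        }
      total += std::floor(mx / h) - std::floor(mn / h) + 1.0;
    }
  }
  return total;
}
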
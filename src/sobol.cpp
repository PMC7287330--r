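#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Base-2 Sobol sequence, direction numbers from Joe & Kuo (new-joe-kuo-6),
// dimensions <= 21. 32-bit resolution; the optional digital shift XORs each
// dimension's integer stream with a fixed word, preserving the (t,m,s)-net
// structure while making independent seeded replicates possible.

static const int SOBOL_MAXDIM = 21;
// degree s, polynomial coefficient a, initial direction numbers m (per dim >= 2)
static const int sob_s[20] = {1,2,3,3,4,4,5,5,5,5,5,5,6,6,6,6,6,6,7,7};
static const int sob_a[20] = {0,1,1,2,1,4,2,4,7,11,13,14,1,13,16,19,22,25,1,4};
static const int sob_m[20][7] = {
  {1,0,0,0,0,0,0},
  {1,3,0,0,0,0,0},
  {1,3,1,0,0,0,0},
  {1,1,1,0,0,0,0},
  {1,1,3,3,0,0,0},
  {1,3,5,13,0,0,0},
  {1,1,5,5,17,0,0},
  {1,1,5,5,5,0,0},
  {1,1,7,11,19,0,0},
  {1,1,5,1,1,0,0},
  {1,1,1,3,11,0,0},
  {1,3,5,5,31,0,0},
  {1,3,3,9,7,49,0},
  {1,1,1,15,21,21,0},
  {1,3,1,13,27,49,0},
  {1,1,1,15,7,5,0},
  {1,3,1,15,13,25,0},
  {1,1,5,5,19,61,0},
  {1,3,7,11,23,15,103},
  {1,3,7,13,13,15,69}
};

// [[Rcpp::export(name = ".sobol_matrix")]]
NumericMatrix sobol_matrix(int n, int d, IntegerVector shift) {
  if (d < 1 || d > SOBOL_MAXDIM)
    stop("Sobol generator supports 1..%d dimensions", SOBOL_MAXDIM);
  if (n < 1) stop("n must be >= 1");
  const int L = 32;
  // direction numbers v[dim][bit], scaled so v corresponds to 2^-(bit+1)
  std::vector< std::vector<uint32_t> > v(d, std::vector<uint32_t>(L));
  for (int j = 0; j < d; ++j) {
    if (j == 0) {
      for (int i = 0; i < L; ++i) v[j][i] = 1u << (31 - i);
    } else {
      int s = sob_s[j - 1];
      int a = sob_a[j - 1];
      for (int i = 0; i < s; ++i)
        v[j][i] = ((uint32_t)sob_m[j - 1][i]) << (31 - i);
      for (int i = s; i < L; ++i) {
        v[j][i] = v[j][i - s] ^ (v[j][i - s] >> s);
        for (int k = 1; k < s; ++k)
          if ((a >> (s - 1 - k)) & 1) v[j][i] ^= v[j][i - k];
      }
    }
  }
  NumericMatrix out(n, d);
  std::vector<uint32_t> x(d, 0u);
  const double scale = std::pow(2.0, -32);
  // skip the all-zeros point: start the Gray-code recursion at index 1
  for (int row = 0; row < n; ++row) {
    // x holds point(row); advancing to point(row+1) flips the direction
    // number indexed by the rightmost zero bit of row (Gray-code recursion)
    uint32_t c = 0;
    uint32_t val = (uint32_t)row;
    while (val & 1) { val >>= 1; ++c; }
    for (int j = 0; j < d; ++j) {
      x[j] ^= v[j][c];
      uint32_t xs = x[j] ^ (shift.size() > 0 ? (uint32_t)(int64_t)shift[j % shift.size()] : 0u);
      out(row, j) = (double)xs * scale;
      if (out(row, j) <= 0.0) out(row, j) = 0.5 * scale;
    }
  }
  return out;
}
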
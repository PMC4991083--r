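#include <Rcpp.h>
using namespace Rcpp;

// Gotoh local alignment with affine gaps and full traceback.
// A gap of length L costs gap_open + L * gap_extend (the convention used by
// Biostrings::pairwiseAlignment, which serves as the cross-check in tests).
//
// Returns 0-based half-open coordinates on both sequences, a compact op string
// over {M, I, D} (I = gap in `a`, i.e. extra base in `b`; D = gap in `b`), and
// the list of substitution positions within aligned M columns.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -2.0,
                  double gap_open = 4.0, double gap_extend = 1.0) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0);

  const double NEG = -1e18;
  // score matrices, (m+1) x (n+1), row-major
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG); // gap in a (move along b)
  std::vector<double> F((m + 1) * (n + 1), NEG); // gap in b (move along a)
  // traceback: tbH: 0 stop, 1 diag, 2 from E, 3 from F; tbE/tbF: 1 open, 2 extend
  std::vector<unsigned char> tbH((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbF((m + 1) * (n + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * (n + 1) + j;
      const int up = (i - 1) * (n + 1) + j;
      const int left = idx - 1;
      const int diag = up - 1;

      double e_open = H[left] - gap_open - gap_extend;
      double e_ext  = E[left] - gap_extend;
      E[idx] = std::max(e_open, e_ext);
      tbE[idx] = (e_open >= e_ext) ? 1 : 2;

      double f_open = H[up] - gap_open - gap_extend;
      double f_ext  = F[up] - gap_extend;
      F[idx] = std::max(f_open, f_ext);
      tbF[idx] = (f_open >= f_ext) ? 1 : 2;

      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double d = H[diag] + s;

      double h = 0.0;
      unsigned char t = 0;
      if (d > h) { h = d; t = 1; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      H[idx] = h;
      tbH[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0);

  // traceback from (bi, bj) in H
  std::string ops;
  std::vector<int> mm_a, mm_b;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    const int idx = i * (n + 1) + j;
    if (state == 0) {
      unsigned char t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        ops.push_back('M');
        if (a[i - 1] != b[j - 1]) { mm_a.push_back(i - 1); mm_b.push_back(j - 1); }
        --i; --j;
      } else if (t == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ops.push_back('I');
      if (tbE[idx] == 1) state = 0;
      --j;
    } else {
      ops.push_back('D');
      if (tbF[idx] == 1) state = 0;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(mm_a.begin(), mm_a.end());
  std::reverse(mm_b.begin(), mm_b.end());

  return List::create(
    _["score"] = best,
    _["a_start"] = i, _["a_end"] = bi,   // 0-based half-open on a
    _["b_start"] = j, _["b_end"] = bj,   // 0-based half-open on b
    _["ops"] = ops,
    _["mm_a"] = IntegerVector(mm_a.begin(), mm_a.end()),
    _["mm_b"] = IntegerVector(mm_b.begin(), mm_b.end()));
}
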
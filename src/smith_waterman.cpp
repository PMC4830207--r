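// Smith-Waterman local alignment with affine gaps (Gotoh), deterministic
// traceback. A gap of length L costs open + L * extend. Tie-breaking during
// the DP prefers diagonal over up (gap in target) over left (gap in query),
// and the traceback starts at the first maximal cell in row-major order, so
// repeated runs are byte-identical.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
              int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int NEG = INT_MIN / 4;
  const int open_cost = gap_open + gap_extend;

  // Flattened (n+1) x (m+1) matrices.
  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, NEG),
      F((n + 1) * W, NEG);
  // ptrH: 0 = stop, 1 = diag, 2 = up (F), 3 = left (E)
  std::vector<signed char> ptrH((n + 1) * W, 0), extF((n + 1) * W, 0),
      extE((n + 1) * W, 0);

  int best = 0, best_i = 0, best_j = 0;
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      // F: gap in b, consuming a[i] (vertical / "up")
      int f_open = H[idx - W] - open_cost;
      int f_ext = F[idx - W] - gap_extend;
      if (f_open >= f_ext) { F[idx] = f_open; extF[idx] = 0; }
      else { F[idx] = f_ext; extF[idx] = 1; }
      // E: gap in a, consuming b[j] (horizontal / "left")
      int e_open = H[idx - 1] - open_cost;
      int e_ext = E[idx - 1] - gap_extend;
      if (e_open >= e_ext) { E[idx] = e_open; extE[idx] = 0; }
      else { E[idx] = e_ext; extE[idx] = 1; }

      int diag = H[idx - W - 1] + sub(ai, b[j - 1] - 1);
      int h = diag; signed char p = 1;
      if (F[idx] > h) { h = F[idx]; p = 2; }
      if (E[idx] > h) { h = E[idx]; p = 3; }
      if (h <= 0) { h = 0; p = 0; }
      H[idx] = h; ptrH[idx] = p;
      if (h > best) { best = h; best_i = i; best_j = j; }
    }
  }

  if (best == 0) {
    return List::create(_["score"] = 0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["a_aln"] = IntegerVector(0),
                        _["b_aln"] = IntegerVector(0));
  }

  // Traceback; 0 in the emitted vectors marks a gap.
  std::vector<int> a_aln, b_aln;
  int i = best_i, j = best_j;
  int state = 0;  // 0 = H, 1 = F, 2 = E
  while (true) {
    const int idx = i * W + j;
    if (state == 0) {
      signed char p = ptrH[idx];
      if (p == 0) break;
      if (p == 1) {
        a_aln.push_back(a[i - 1]); b_aln.push_back(b[j - 1]);
        --i; --j;
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      a_aln.push_back(a[i - 1]); b_aln.push_back(0);
      signed char e = extF[idx];
      --i;
      state = (e == 1) ? 1 : 0;
    } else {
      a_aln.push_back(0); b_aln.push_back(b[j - 1]);
      signed char e = extE[idx];
      --j;
      state = (e == 1) ? 2 : 0;
    }
  }
  std::reverse(a_aln.begin(), a_aln.end());
  std::reverse(b_aln.begin(), b_aln.end());

  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = best_i,
                      _["b_start"] = j, _["b_end"] = best_j,
                      _["a_aln"] = IntegerVector(a_aln.begin(), a_aln.end()),
                      _["b_aln"] = IntegerVector(b_aln.begin(), b_aln.end()));
}
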
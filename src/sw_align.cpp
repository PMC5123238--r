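#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local alignment (Smith-Waterman) with affine gap penalties.
//
// Scoring: +match for identical bases, +mismatch (negative) otherwise;
// 'N' against anything scores 0. A gap of length L costs
// gap_open + L * gap_extend (both negative). Traceback is deterministic:
// the maximum-scoring cell with the smallest read index, then the
// smallest target index, wins; on score ties within a cell the
// preference order is diagonal, then target gap (D), then read gap (I).
//
// Returns op codes 0=M (match/mismatch), 1=I (read-only base),
// 2=D (target-only base). Unaligned read ends are reported via
// read_start/read_end and become soft clips in R.
// [[Rcpp::export]]
List sw_align_cpp(std::string read, std::string target,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int) read.size();
  const int m = (int) target.size();
  const int NEG = -1000000000;
  const int W = m + 1;

  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, NEG),
      F((n + 1) * W, NEG);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char rc = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char tc = target[j - 1];
      const int s = (rc == 'N' || tc == 'N') ? 0
                    : (rc == tc ? match : mismatch);
      int e = H[(i - 1) * W + j] + gap_open + gap_extend;
      const int e2 = E[(i - 1) * W + j] + gap_extend;
      if (e2 > e) e = e2;
      E[i * W + j] = e;
      int f = H[i * W + (j - 1)] + gap_open + gap_extend;
      const int f2 = F[i * W + (j - 1)] + gap_extend;
      if (f2 > f) f = f2;
      F[i * W + j] = f;
      int h = H[(i - 1) * W + (j - 1)] + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      H[i * W + j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::vector<int> rev_ops;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E (I op), 2 = F (D op)
  while (i > 0 || j > 0) {
    if (state == 0) {
      const int h = H[i * W + j];
      if (h == 0) break;
      const char rc = read[i - 1];
      const char tc = (j > 0) ? target[j - 1] : 'N';
      const int s = (j > 0 && (rc == 'N' || tc == 'N')) ? 0
                    : (rc == tc ? match : mismatch);
      if (i > 0 && j > 0 && h == H[(i - 1) * W + (j - 1)] + s) {
        rev_ops.push_back(0); --i; --j;
      } else if (h == F[i * W + j]) {
        state = 2;
      } else if (h == E[i * W + j]) {
        state = 1;
      } else {
        stop("traceback inconsistency");
      }
    } else if (state == 1) {  // gap in target: read base consumed
      rev_ops.push_back(1);
      if (E[i * W + j] == H[(i - 1) * W + j] + gap_open + gap_extend) {
        state = 0;
      }
      --i;
    } else {  // gap in read: target base consumed
      rev_ops.push_back(2);
      if (F[i * W + j] == H[i * W + (j - 1)] + gap_open + gap_extend) {
        state = 0;
      }
      --j;
    }
  }

  // run-length encode (ops are in reverse order)
  std::vector<int> ops, lens;
  for (int k = (int) rev_ops.size() - 1; k >= 0; --k) {
    if (!ops.empty() && ops.back() == rev_ops[k]) {
      ++lens.back();
    } else {
      ops.push_back(rev_ops[k]);
      lens.push_back(1);
    }
  }

  return List::create(
      _["score"] = best,
      _["target_start"] = j,       // 0-based first consumed target base
      _["target_end"] = bj,        // half-open
      _["read_start"] = i,         // 0-based first aligned read base
      _["read_end"] = bi,          // half-open
      _["ops"] = IntegerVector(ops.begin(), ops.end()),
      _["lens"] = IntegerVector(lens.begin(), lens.end()));
}
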
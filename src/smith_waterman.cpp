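#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// Gap cost convention: a gap of length L costs |gap_open| + (L-1)*|gap_extend|,
// i.e. the first gap symbol pays the opening penalty, each further symbol the
// extension penalty.
// Traceback is deterministic: the maximal cell with the smallest (i, j) in
// row-major order is chosen, and within a cell ties resolve
// diagonal > up (gap in reference) > left (gap in query).
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string query, std::string ref,
              int match, int mismatch, int gap_open, int gap_extend) {
  const int n = query.size(), m = ref.size();
  const int go = -gap_open;   // positive costs
  const int ge = -gap_extend;
  const int NEG = -1000000000;

  // H: best local score ending at (i, j); E: ending with gap in query
  // (consumes reference, "left"); F: ending with gap in reference
  // (consumes query, "up"). Flat row-major (m + 1)-strided matrices.
  const size_t stride = m + 1;
  std::vector<int> H((n + 1) * stride, 0);
  std::vector<int> E((n + 1) * stride, NEG);
  std::vector<int> F((n + 1) * stride, NEG);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = query[i - 1];
    int *Hr = &H[i * stride], *Hp = &H[(i - 1) * stride];
    int *Er = &E[i * stride];
    int *Fr = &F[i * stride], *Fp = &F[(i - 1) * stride];
    for (int j = 1; j <= m; ++j) {
      int sub = (qc == ref[j - 1] && qc != 'N') ? match : mismatch;
      Er[j] = std::max(Hr[j - 1] - go, Er[j - 1] - ge);
      Fr[j] = std::max(Hp[j] - go, Fp[j] - ge);
      int h = Hp[j - 1] + sub;
      h = std::max(h, std::max(Er[j], Fr[j]));
      h = std::max(h, 0);
      Hr[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  auto Hat = [&](int i, int j) { return H[i * stride + j]; };
  auto Eat = [&](int i, int j) { return E[i * stride + j]; };
  auto Fat = [&](int i, int j) { return F[i * stride + j]; };

  std::string qa, ra;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E (left), 2 = F (up)
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (Hat(i, j) == 0) break;
      bool is_match = i > 0 && j > 0 && query[i - 1] == ref[j - 1] &&
                      query[i - 1] != 'N';
      int sub = is_match ? match : mismatch;
      if (i > 0 && j > 0 && Hat(i, j) == Hat(i - 1, j - 1) + sub) {
        qa += query[i - 1]; ra += ref[j - 1];
        --i; --j;
      } else if (i > 0 && Hat(i, j) == Fat(i, j)) {
        state = 2;
      } else if (j > 0 && Hat(i, j) == Eat(i, j)) {
        state = 1;
      } else {
        stop("internal traceback error");
      }
    } else if (state == 2) { // gap in reference, consume query
      qa += query[i - 1]; ra += '-';
      // prefer closing the gap (back to H) when both moves explain the score
      if (Fat(i, j) == Hat(i - 1, j) - go) state = 0;
      else if (Fat(i, j) == Fat(i - 1, j) - ge) state = 2;
      else stop("internal traceback error");
      --i;
    } else { // state == 1: gap in query, consume reference
      qa += '-'; ra += ref[j - 1];
      if (Eat(i, j) == Hat(i, j - 1) - go) state = 0;
      else if (Eat(i, j) == Eat(i, j - 1) - ge) state = 1;
      else stop("internal traceback error");
      --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ra.begin(), ra.end());

  return List::create(
    _["score"] = best,
    _["query_aligned"] = qa,
    _["ref_aligned"] = ra,
    _["query_start"] = i,  // 0-based, half-open [i, bi)
    _["query_end"] = bi,
    _["ref_start"] = j,
    _["ref_end"] = bj);
}
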
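#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Residue codes: A=0, C=1, G=2, T=3; every other symbol (N, IUPAC
// ambiguity codes, the pad symbol) collapses to 4 and scores `mismatch`
// against everything, including itself.
static const int OTHER = 4;

// [[Rcpp::export]]
IntegerVector encode_residues(std::string s) {
  const R_xlen_t n = (R_xlen_t) s.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    switch (s[i]) {
      case 'A': out[i] = 0; break;
      case 'C': out[i] = 1; break;
      case 'G': out[i] = 2; break;
      case 'T': out[i] = 3; break;
      default:  out[i] = OTHER;
    }
  }
  return out;
}

static inline int subst(int a, int b, int match, int mismatch) {
  return (a == b && a < OTHER) ? match : mismatch;
}

static inline int max2(int a, int b) { return a > b ? a : b; }

// Full-matrix reference engine. With keep_matrices the (m+1) x (n+1)
// H/E/F matrices are returned (row/column 0 is the zero-initialisation
// border); without it only two O(n) rows are held. Positions are 1-based;
// (0,0) means no positive cell.
// [[Rcpp::export]]
List cpp_sw_full(IntegerVector s1, IntegerVector s2,
                 int match, int mismatch, int gap_open, int gap_extend,
                 bool keep_matrices = false) {
  const int m = s1.size(), n = s2.size();
  const int goe = gap_open + gap_extend, ge = gap_extend;
  int best = 0, bi = 0, bj = 0;

  if (keep_matrices) {
    IntegerMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
    for (int i = 1; i <= m; ++i) {
      for (int j = 1; j <= n; ++j) {
        E(i, j) = max2(H(i, j - 1) - goe, E(i, j - 1) - ge);
        F(i, j) = max2(H(i - 1, j) - goe, F(i - 1, j) - ge);
        int h = max2(0, H(i - 1, j - 1) + subst(s1[i - 1], s2[j - 1], match, mismatch));
        h = max2(h, max2(E(i, j), F(i, j)));
        H(i, j) = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    return List::create(_["score"] = best, _["max_i"] = bi, _["max_j"] = bj,
                        _["H"] = H, _["E"] = E, _["F"] = F);
  }

  std::vector<int> hup(n + 1, 0), f(n + 1, 0);
  const int *p1 = s1.begin(), *p2 = s2.begin();
  int *hu = hup.data(), *fv = f.data();
  for (int i = 1; i <= m; ++i) {
    int diag = 0, hleft = 0, e = 0;
    const int a = p1[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int up = hu[j];
      e = max2(hleft - goe, e - ge);
      const int fj = max2(up - goe, fv[j] - ge);
      fv[j] = fj;
      int h = max2(0, diag + subst(a, p2[j - 1], match, mismatch));
      h = max2(h, max2(e, fj));
      diag = up; hu[j] = h; hleft = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  return List::create(_["score"] = best, _["max_i"] = bi, _["max_j"] = bj);
}

// One vertical block of the tiled engine: a BW-column stripe of H,
// processed row by row with two row buffers (H and F). h_in/e_in carry the
// last-column H and E values of the previous block (all zero for the first
// block, encoding the j = 0 initialisation column); h_out/e_out are this
// block's last column, consumed by the next block.
// [[Rcpp::export]]
List cpp_process_block(IntegerVector s1, IntegerVector block,
                       int match, int mismatch, int gap_open, int gap_extend,
                       IntegerVector h_in, IntegerVector e_in) {
  const int m = s1.size(), bw = block.size();
  if (h_in.size() != m || e_in.size() != m)
    stop("boundary length mismatch: expected %d, got %d/%d",
         m, (int) h_in.size(), (int) e_in.size());
  const int goe = gap_open + gap_extend, ge = gap_extend;

  std::vector<int> hrow(bw, 0), frow(bw, 0);  // previous-row H, F
  IntegerVector h_out(m), e_out(m);
  int best = 0, bi = 0, bj = 0;
  const int *p1 = s1.begin(), *pb = block.begin();
  const int *hi = h_in.begin(), *ei = e_in.begin();
  int *ho = h_out.begin(), *eo = e_out.begin();
  int *hr = hrow.data(), *fr = frow.data();

  for (int i = 1; i <= m; ++i) {
    int diag = (i == 1) ? 0 : hi[i - 2];  // H_{i-1, j0-1}
    int hleft = hi[i - 1], e = ei[i - 1];
    const int a = p1[i - 1];
    for (int k = 0; k < bw; ++k) {
      const int up = hr[k];
      e = max2(hleft - goe, e - ge);
      const int fk = max2(up - goe, fr[k] - ge);
      fr[k] = fk;
      int h = max2(0, diag + subst(a, pb[k], match, mismatch));
      h = max2(h, max2(e, fk));
      diag = up; hr[k] = h; hleft = h;
      if (h > best) { best = h; bi = i; bj = k + 1; }
    }
    ho[i - 1] = hleft;
    eo[i - 1] = e;
  }
  return List::create(_["h_out"] = h_out, _["e_out"] = e_out,
                      _["block_max"] = best, _["max_i"] = bi, _["max_j"] = bj);
}
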
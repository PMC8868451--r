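#include <Rcpp.h>
#include <unordered_set>
#include <string>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment (Gotoh affine gaps) with traceback.
// Gap of length L scores gap_open + L * gap_extend (both negative), i.e.
// the first gapped base already pays open + extend.
// Returns 0-based half-open coordinates on both sequences.
// [[Rcpp::export]]
List sw_align_cpp(std::string read, std::string ref,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = read.size(), m = ref.size();
  const int open_ext = -(gap_open + gap_extend); // cost of first gap base
  const int ext = -gap_extend;                   // cost of later gap bases
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0, _["read_start"] = 0, _["read_end"] = 0,
                        _["ref_start"] = 0, _["ref_end"] = 0,
                        _["aligned_bases"] = 0);

  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, INT_MIN / 4),
      F((n + 1) * W, INT_MIN / 4);
  // traceback codes for H: 0 stop, 1 diag, 2 from E (gap in read), 3 from F
  std::vector<unsigned char> tbH((n + 1) * W, 0), tbE((n + 1) * W, 0),
      tbF((n + 1) * W, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char ri = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      // E: gap in the read (consumes ref base)
      int e_open = H[idx - 1] - open_ext, e_ext = E[idx - 1] - ext;
      if (e_open >= e_ext) { E[idx] = e_open; tbE[idx] = 1; }
      else                 { E[idx] = e_ext;  tbE[idx] = 0; }
      // F: gap in the ref (consumes read base)
      int f_open = H[idx - W] - open_ext, f_ext = F[idx - W] - ext;
      if (f_open >= f_ext) { F[idx] = f_open; tbF[idx] = 1; }
      else                 { F[idx] = f_ext;  tbF[idx] = 0; }
      int diag = H[idx - W - 1] + (ri == ref[j - 1] ? match : mismatch);
      int h = 0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[idx] > h) { h = E[idx]; tb = 2; }
      if (F[idx] > h) { h = F[idx]; tb = 3; }
      H[idx] = h; tbH[idx] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from the best cell
  int i = bi, j = bj, state = 0; // 0 = in H
  int read_end = bi, ref_end = bj;
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      unsigned char tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) { --i; --j; }
      else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      if (tbE[idx]) state = 0;
      --j;
    } else {
      if (tbF[idx]) state = 0;
      --i;
    }
  }
  return List::create(_["score"] = best, _["read_start"] = i,
                      _["read_end"] = read_end, _["ref_start"] = j,
                      _["ref_end"] = ref_end,
                      _["aligned_bases"] = read_end - i);
}

// Local alignment score only (no traceback), linear memory.
// [[Rcpp::export]]
int sw_score_cpp(std::string read, std::string ref,
                 int match, int mismatch, int gap_open, int gap_extend) {
  const int n = read.size(), m = ref.size();
  if (n == 0 || m == 0) return 0;
  const int open_ext = -(gap_open + gap_extend), ext = -gap_extend;
  std::vector<int> H(m + 1, 0), E(m + 1, INT_MIN / 4);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int diag = 0, f = INT_MIN / 4; // H[i-1][j-1] and F for this row
    const char ri = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      int up = H[j];
      E[j] = std::max(H[j - 1] - open_ext, E[j - 1] - ext);
      f = std::max(up - open_ext, f - ext);
      int h = std::max(0, diag + (ri == ref[j - 1] ? match : mismatch));
      h = std::max(h, std::max(E[j], f));
      diag = up; H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Leftmost position (1-based) in each sequence whose k-mer is in the adapter
// k-mer set; 0 when no k-mer matches.
// [[Rcpp::export]]
IntegerVector adapter_hit_cpp(CharacterVector seqs, CharacterVector kmers,
                              int k) {
  std::unordered_set<std::string> set;
  for (int i = 0; i < kmers.size(); ++i) set.insert(as<std::string>(kmers[i]));
  const int nseq = seqs.size();
  IntegerVector out(nseq);
  for (int s = 0; s < nseq; ++s) {
    const std::string x = as<std::string>(seqs[s]);
    const int L = (int)x.size();
    int hit = 0;
    for (int i = 0; i + k <= L; ++i) {
      if (set.count(x.substr(i, k))) { hit = i + 1; break; }
    }
    out[s] = hit;
  }
  return out;
}

// Mott-style 3' quality trimming. For each Phred+33 quality string, returns
// the kept prefix length after removing the suffix that maximises
// sum(threshold - Q_i); score ties keep the longer read, and a best score
// <= 0 keeps the read whole.
// [[Rcpp::export]]
IntegerVector mott_cut_cpp(CharacterVector quals, int threshold) {
  const int nq = quals.size();
  IntegerVector out(nq);
  for (int s = 0; s < nq; ++s) {
    const std::string q = as<std::string>(quals[s]);
    const int L = (int)q.size();
    long cum = 0, bestscore = 0;
    int keep = L;
    for (int i = L - 1; i >= 0; --i) {
      cum += threshold - ((int)q[i] - 33);
      if (cum > bestscore) { bestscore = cum; keep = i; }
    }
    out[s] = keep;
  }
  return out;
}
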
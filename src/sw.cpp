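#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment score, BLAST gap convention:
// a gap of length k costs gap_open + k * gap_extend.
static const int NEG = -1000000000;

static std::vector<int> encode(const std::string &s,
                               const int *lut) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = static_cast<unsigned char>(s[i]);
    int idx = lut[c];
    if (idx < 0)
      stop("invalid residue '%c' in sequence", s[i]);
    v[i] = idx;
  }
  return v;
}

static int sw_one(const std::vector<int> &a, const std::vector<int> &b,
                  const int *sub, int K, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  // rolling rows: M (match), X (gap in b / deletion), Y (gap in a / insertion)
  std::vector<int> Mprev(m + 1, 0), Mcur(m + 1, 0);
  std::vector<int> Xprev(m + 1, NEG), Xcur(m + 1, NEG);
  std::vector<int> Yprev(m + 1, NEG), Ycur(m + 1, NEG);
  int best = 0;
  const int oe = gap_open + gap_extend;
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = 0; Xcur[0] = NEG; Ycur[0] = NEG;
    const int *srow = sub + static_cast<size_t>(a[i - 1]) * K;
    const int *Mp = Mprev.data(), *Xp = Xprev.data(), *Yp = Yprev.data();
    int *Mc = Mcur.data(), *Xc = Xcur.data(), *Yc = Ycur.data();
    for (int j = 1; j <= m; ++j) {
      int diag = Mp[j - 1];
      if (Xp[j - 1] > diag) diag = Xp[j - 1];
      if (Yp[j - 1] > diag) diag = Yp[j - 1];
      if (diag < 0) diag = 0;
      const int mc = diag + srow[b[j - 1]];
      Mc[j] = mc;
      const int x1 = Mp[j] - oe, x2 = Xp[j] - gap_extend;
      Xc[j] = x1 > x2 ? x1 : x2;
      const int y1 = Mc[j - 1] - oe, y2 = Yc[j - 1] - gap_extend;
      Yc[j] = y1 > y2 ? y1 : y2;
      if (mc > best) best = mc;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  return best;
}

static void build_lut(const std::string &alphabet, int *lut) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[static_cast<unsigned char>(alphabet[i])] = static_cast<int>(i);
}

static std::vector<int> flatten(const IntegerMatrix &sub) {
  const int K = sub.nrow();
  std::vector<int> flat(static_cast<size_t>(K) * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      flat[static_cast<size_t>(i) * K + j] = sub(i, j);
  return flat;
}

// [[Rcpp::export]]
IntegerVector sw_pair_scores(CharacterVector a, CharacterVector b,
                             IntegerMatrix sub, std::string alphabet,
                             int gap_open, int gap_extend) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<int> flat = flatten(sub);
  const int K = sub.nrow();
  IntegerVector out(a.size());
  for (R_xlen_t k = 0; k < a.size(); ++k) {
    std::vector<int> ea = encode(as<std::string>(a[k]), lut);
    std::vector<int> eb = encode(as<std::string>(b[k]), lut);
    out[k] = sw_one(ea, eb, flat.data(), K, gap_open, gap_extend);
  }
  return out;
}

// All-vs-all score matrix over one set of sequences (symmetric).
// [[Rcpp::export]]
IntegerMatrix sw_all_pairs(CharacterVector seqs, IntegerMatrix sub,
                           std::string alphabet, int gap_open,
                           int gap_extend) {
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<int> flat = flatten(sub);
  const int K = sub.nrow();
  const int n = seqs.size();
  std::vector<std::vector<int> > enc(n);
  for (int i = 0; i < n; ++i)
    enc[i] = encode(as<std::string>(seqs[i]), lut);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      int s = sw_one(enc[i], enc[j], flat.data(), K, gap_open, gap_extend);
      out(i, j) = s;
      out(j, i) = s;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
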
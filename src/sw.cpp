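// Local protein alignment (Smith-Waterman, affine gaps) used by the homology
// layer. Sequences arrive as integer vectors (0..25 = A..Z) produced in R;
// the substitution matrix is a 26x26 integer matrix (BLOSUM62 by default).
// A gap of length L costs gap_open + L * gap_extend.
#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {

struct AlnResult {
  int score = 0;
  int matches = 0;
  int align_len = 0;      // aligned columns including gap columns
  int qstart = -1, qend = -1; // 0-based inclusive
  int tstart = -1, tend = -1;
  std::vector<int> qpos;  // 0-based query index per match/mismatch column
  std::vector<int> tpos;
};

// traceback codes
enum { TB_STOP = 0, TB_DIAG = 1, TB_UP = 2, TB_LEFT = 3 };

AlnResult sw_core(const int* a, int la, const int* b, int lb,
                  const int* sub, int gap_open, int gap_extend,
                  bool traceback) {
  AlnResult res;
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_extend; // cost of a length-1 gap
  std::vector<int> H(lb + 1, 0), E(lb + 1, NEG);
  // F is maintained per row scalar
  std::vector<unsigned char> tb;
  if (traceback) tb.assign((size_t)(la + 1) * (lb + 1), TB_STOP);

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= la; ++i) {
    int Hdiag = H[0]; // H[i-1][0]
    H[0] = 0;
    int F = NEG;
    const int* srow = sub + 26 * a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      E[j] = std::max(H[j] - open_cost, E[j] - gap_extend);      // gap in b? (up)
      F    = std::max(H[j - 1] - open_cost, F - gap_extend);     // gap in a (left)
      int diag = Hdiag + srow[b[j - 1]];
      Hdiag = H[j];
      int h = 0; unsigned char dir = TB_STOP;
      if (diag > h) { h = diag; dir = TB_DIAG; }
      if (E[j] > h) { h = E[j]; dir = TB_UP; }
      if (F > h)    { h = F;    dir = TB_LEFT; }
      H[j] = h;
      if (traceback) tb[(size_t)i * (lb + 1) + j] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  res.score = best;
  if (best <= 0 || !traceback) return res;

  // retrace (greedy local path: at each cell follow the stored direction)
  int i = bi, j = bj;
  res.qend = bi - 1; res.tend = bj - 1;
  std::vector<int> qp, tp;
  int matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    unsigned char dir = tb[(size_t)i * (lb + 1) + j];
    if (dir == TB_STOP) break;
    if (dir == TB_DIAG) {
      ++cols;
      if (a[i - 1] == b[j - 1]) ++matches;
      qp.push_back(i - 1); tp.push_back(j - 1);
      --i; --j;
    } else if (dir == TB_UP) {
      ++cols; --i;
    } else {
      ++cols; --j;
    }
  }
  res.qstart = i; res.tstart = j;
  res.matches = matches;
  res.align_len = cols;
  std::reverse(qp.begin(), qp.end());
  std::reverse(tp.begin(), tp.end());
  res.qpos = std::move(qp);
  res.tpos = std::move(tp);
  return res;
}

} // namespace

// [[Rcpp::export(name = ".cpp_sw_align")]]
List cpp_sw_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  if (sub.nrow() != 26 || sub.ncol() != 26) stop("substitution matrix must be 26x26");
  AlnResult r = sw_core(a.begin(), a.size(), b.begin(), b.size(),
                        sub.begin(), gap_open, gap_extend, true);
  double alen = r.align_len > 0 ? (double)r.align_len : 0.0;
  double ident = alen > 0 ? 100.0 * r.matches / alen : 0.0;
  double qspan = r.qend >= r.qstart && r.qend >= 0 ? (double)(r.qend - r.qstart + 1) : 0.0;
  double tspan = r.tend >= r.tstart && r.tend >= 0 ? (double)(r.tend - r.tstart + 1) : 0.0;
  return List::create(
    _["score"] = r.score,
    _["matches"] = r.matches,
    _["align_len"] = r.align_len,
    _["pct_identity"] = ident,
    _["query_cov"] = a.size() > 0 ? 100.0 * qspan / a.size() : 0.0,
    _["target_cov"] = b.size() > 0 ? 100.0 * tspan / b.size() : 0.0,
    _["qstart"] = r.qstart, _["qend"] = r.qend,
    _["tstart"] = r.tstart, _["tend"] = r.tend,
    _["qpos"] = IntegerVector(r.qpos.begin(), r.qpos.end()),
    _["tpos"] = IntegerVector(r.tpos.begin(), r.tpos.end()));
}

namespace {

const int PREFILTER_K = 6; // 26^6 < 2^31

// sorted k-mer codes of a protein (26-letter alphabet)
std::vector<int> kmer_codes(const std::vector<int>& s) {
  std::vector<int> out;
  if ((int)s.size() < PREFILTER_K) return out;
  for (size_t i = 0; i + PREFILTER_K <= s.size(); ++i) {
    long code = 0;
    for (int k = 0; k < PREFILTER_K; ++k) code = code * 26 + s[i + k];
    out.push_back((int)code);
  }
  std::sort(out.begin(), out.end());
  return out;
}

bool share_kmer(const std::vector<int>& a, const std::vector<int>& b) {
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) return true;
    if (a[i] < b[j]) ++i; else ++j;
  }
  return false;
}

} // namespace

// All-vs-all local alignment summary for two lists of encoded proteins.
// Returns score / pct identity / coverage-of-query / coverage-of-target
// matrices (queries in rows, targets in columns). When `prefilter` is true,
// pairs in which both sequences have >= `prefilter_min_len` residues but
// share no 6-mer are reported as empty alignments without running the DP;
// any pair well above the 50%-identity gate shares 6-mers with
// overwhelming probability at those lengths.
// [[Rcpp::export(name = ".cpp_sw_batch")]]
List cpp_sw_batch(List qs, List ts, IntegerMatrix sub, int gap_open, int gap_extend,
                  bool prefilter, int prefilter_min_len) {
  int nq = qs.size(), nt = ts.size();
  NumericMatrix score(nq, nt), ident(nq, nt), qcov(nq, nt), tcov(nq, nt);
  std::vector<std::vector<int>> Q(nq), T(nt);
  for (int i = 0; i < nq; ++i) { IntegerVector v = qs[i]; Q[i].assign(v.begin(), v.end()); }
  for (int j = 0; j < nt; ++j) { IntegerVector v = ts[j]; T[j].assign(v.begin(), v.end()); }
  std::vector<std::vector<int>> QK(nq), TK(nt);
  if (prefilter) {
    for (int i = 0; i < nq; ++i) QK[i] = kmer_codes(Q[i]);
    for (int j = 0; j < nt; ++j) TK[j] = kmer_codes(T[j]);
  }
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nt; ++j) {
      if (prefilter && (int)Q[i].size() >= prefilter_min_len &&
          (int)T[j].size() >= prefilter_min_len && !share_kmer(QK[i], TK[j])) {
        continue; // matrices stay zero: no alignment
      }
      AlnResult r = sw_core(Q[i].data(), Q[i].size(), T[j].data(), T[j].size(),
                            sub.begin(), gap_open, gap_extend, true);
      score(i, j) = r.score;
      ident(i, j) = r.align_len > 0 ? 100.0 * r.matches / r.align_len : 0.0;
      qcov(i, j) = Q[i].size() ? 100.0 * std::max(0, r.qend - r.qstart + 1) / (double)Q[i].size() : 0.0;
      tcov(i, j) = T[j].size() ? 100.0 * std::max(0, r.tend - r.tstart + 1) / (double)T[j].size() : 0.0;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = score, _["pct_identity"] = ident,
                      _["query_cov"] = qcov, _["target_cov"] = tcov);
}
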
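// Fragment-based whole-genome ANI and seeded local match registration.
// Nucleotides are encoded in R as integers: 0=A, 1=C, 2=G, 3=T, >=4 ambiguous.
// Seeding is by exact k-mers (sorted (kmer, pos) index, binary search);
// extension is banded local alignment with match +1 / mismatch -1 / gap -2.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

typedef std::pair<uint64_t, uint32_t> KPos;

const int MATCH = 1, MISMATCH = -1, GAP = -2;
const int MAX_KMER_OCC = 32;

struct BandAln {
  int score = 0, matches = 0, align_len = 0;
  int qstart = -1, qend = -1, tstart = -1, tend = -1; // 0-based inclusive
};

// banded local alignment of q against t restricted to diagonals
// (tpos - qpos) in [cdiag - band, cdiag + band]
BandAln banded_local(const int* q, int lq, const int* t, int lt,
                     int cdiag, int band) {
  BandAln res;
  int W = 2 * band + 1;
  const int NEG = -1000000000;
  std::vector<int> H((size_t)W, 0), Hprev((size_t)W, 0);
  std::vector<unsigned char> tb((size_t)(lq + 1) * W, 0); // 0 stop,1 diag,2 up,3 left
  int best = 0, bi = -1, boff = -1;
  for (int i = 1; i <= lq; ++i) {
    std::swap(H, Hprev);
    for (int off = 0; off < W; ++off) {
      int j = i + cdiag + off - band; // target position (1-based)
      if (j < 1 || j > lt) { H[off] = NEG; continue; }
      int qc = q[i - 1], tc = t[j - 1];
      int s = (qc < 4 && qc == tc) ? MATCH : MISMATCH;
      // diagonal predecessor is (i-1, j-1): same offset in previous row
      int dprev = (i == 1 || j == 1) ? 0 : Hprev[off];
      if (dprev <= NEG / 2) dprev = NEG;
      int up   = (off + 1 < W) ? Hprev[off + 1] : NEG; // (i-1, j)
      int left = (off - 1 >= 0) ? H[off - 1] : NEG;    // (i, j-1)
      int h = 0; unsigned char dir = 0;
      if (dprev > NEG / 2 && dprev + s > h) { h = dprev + s; dir = 1; }
      if (up > NEG / 2 && up + GAP > h)     { h = up + GAP;  dir = 2; }
      if (left > NEG / 2 && left + GAP > h) { h = left + GAP; dir = 3; }
      H[off] = h;
      tb[(size_t)i * W + off] = dir;
      if (h > best) { best = h; bi = i; boff = off; }
    }
  }
  res.score = best;
  if (best <= 0) return res;
  int i = bi, off = boff;
  res.qend = i - 1;
  res.tend = i + cdiag + off - band - 1;
  int matches = 0, cols = 0;
  while (i > 0) {
    unsigned char dir = tb[(size_t)i * W + off];
    if (dir == 0) break;
    int j = i + cdiag + off - band;
    if (dir == 1) {
      ++cols;
      if (q[i - 1] < 4 && q[i - 1] == t[j - 1]) ++matches;
      --i; // offset unchanged for diagonal step
    } else if (dir == 2) {
      ++cols; --i; ++off;
    } else {
      ++cols; --off;
    }
  }
  res.qstart = i;
  res.tstart = i + cdiag + off - band;
  res.matches = matches;
  res.align_len = cols;
  return res;
}

void build_index(const std::vector<int>& seq, int k, std::vector<KPos>& idx) {
  idx.clear();
  int n = seq.size();
  if (n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t kmer = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = seq[i];
    if (c >= 4) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++valid >= k) idx.push_back(KPos(kmer, (uint32_t)(i - k + 1)));
  }
  std::sort(idx.begin(), idx.end());
}

// enumerate (qpos, kmer) of a query
void query_kmers(const std::vector<int>& seq, int k,
                 std::vector<std::pair<uint64_t, int>>& out) {
  out.clear();
  int n = seq.size();
  if (n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t kmer = 0; int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = seq[i];
    if (c >= 4) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++valid >= k) out.push_back(std::make_pair(kmer, i - k + 1));
  }
}

std::vector<int> revcomp(const std::vector<int>& s) {
  std::vector<int> r(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = s[s.size() - 1 - i];
    r[i] = (c < 4) ? 3 - c : 4;
  }
  return r;
}

// hits of query kmers against a sorted index, as (qpos, tpos)
void seed_hits(const std::vector<std::pair<uint64_t, int>>& qk,
               const std::vector<KPos>& idx,
               std::vector<std::pair<int, int>>& hits) {
  hits.clear();
  for (size_t a = 0; a < qk.size(); ++a) {
    KPos lo(qk[a].first, 0), hi(qk[a].first, ~0U);
    auto r1 = std::lower_bound(idx.begin(), idx.end(), lo);
    auto r2 = std::upper_bound(idx.begin(), idx.end(), hi);
    if (r2 - r1 > MAX_KMER_OCC) continue;
    for (auto it = r1; it != r2; ++it)
      hits.push_back(std::make_pair(qk[a].second, (int)it->second));
  }
}

} // namespace

// Per-fragment alignment statistics of every frag_len window of the query
// replicons against the concatenated target. Returns one row per fragment.
// [[Rcpp::export(name = ".cpp_ani_fragments")]]
DataFrame cpp_ani_fragments(List query_reps, List target_reps,
                            int frag_len, int k, int band, int min_seeds,
                            int min_tail) {
  // concatenate target with k ambiguous separators
  std::vector<int> target;
  for (int r = 0; r < target_reps.size(); ++r) {
    IntegerVector v = target_reps[r];
    if (r > 0) target.insert(target.end(), k, 4);
    target.insert(target.end(), v.begin(), v.end());
  }
  std::vector<KPos> idx;
  build_index(target, k, idx);
  int lt = target.size();

  std::vector<int> flen_v;
  std::vector<double> id_v, cov_v, alen_v;
  std::vector<std::pair<uint64_t, int>> qk;
  std::vector<std::pair<int, int>> hits;

  for (int r = 0; r < query_reps.size(); ++r) {
    IntegerVector v = query_reps[r];
    std::vector<int> rep(v.begin(), v.end());
    int L = rep.size();
    for (int s = 0; s < L; s += frag_len) {
      int fl = std::min(frag_len, L - s);
      if (fl < min_tail) break;
      std::vector<int> frag(rep.begin() + s, rep.begin() + s + fl);
      std::vector<int> fragrc = revcomp(frag);
      // vote per (strand, diagonal bucket)
      double best_id = NA_REAL, best_cov = 0, best_alen = 0;
      int bestStrand = -1, bestDiag = 0, bestVotes = 0;
      for (int strand = 0; strand < 2; ++strand) {
        const std::vector<int>& f = strand == 0 ? frag : fragrc;
        query_kmers(f, k, qk);
        seed_hits(qk, idx, hits);
        if (hits.empty()) continue;
        // bucket votes by diagonal
        std::vector<int> diags;
        diags.reserve(hits.size());
        for (auto& h : hits) diags.push_back(h.second - h.first);
        std::sort(diags.begin(), diags.end());
        // best window of diagonals within `band`
        int i0 = 0, votes = 0, cdiag = 0;
        for (size_t i1 = 0; i1 < diags.size(); ++i1) {
          while (diags[i1] - diags[i0] > band) ++i0;
          int w = (int)(i1 - i0 + 1);
          if (w > votes) {
            votes = w;
            cdiag = diags[(i0 + i1) / 2];
          }
        }
        if (votes > bestVotes) {
          bestVotes = votes; bestStrand = strand; bestDiag = cdiag;
        }
      }
      if (bestVotes >= min_seeds && bestStrand >= 0) {
        const std::vector<int>& f = bestStrand == 0 ? frag : fragrc;
        BandAln a = banded_local(f.data(), fl, target.data(), lt, bestDiag, band);
        if (a.align_len > 0) {
          best_id = 100.0 * a.matches / a.align_len;
          best_cov = 100.0 * (a.qend - a.qstart + 1) / (double)fl;
          best_alen = a.align_len;
        }
      }
      flen_v.push_back(fl);
      id_v.push_back(best_id);
      cov_v.push_back(best_cov);
      alen_v.push_back(best_alen);
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
    _["frag_len"] = IntegerVector(flen_v.begin(), flen_v.end()),
    _["pct_identity"] = NumericVector(id_v.begin(), id_v.end()),
    _["frag_cov"] = NumericVector(cov_v.begin(), cov_v.end()),
    _["align_len"] = NumericVector(alen_v.begin(), alen_v.end()));
}

// Seeded local matches between two replicon sequences, both strands.
// Returns 0-based half-open coordinates on the forward strand of each input.
// [[Rcpp::export(name = ".cpp_register_matches")]]
DataFrame cpp_register_matches(IntegerVector a, IntegerVector b,
                               int k, int band, int min_len, int max_seed_gap) {
  std::vector<int> A(a.begin(), a.end()), B(b.begin(), b.end());
  std::vector<KPos> idx;
  build_index(B, k, idx);
  int la = A.size(), lb = B.size();

  struct Cand { int qlo, qhi, diag, strand, nseeds; };
  std::vector<Cand> cands;
  std::vector<std::pair<uint64_t, int>> qk;
  std::vector<std::pair<int, int>> hits;
  std::vector<int> Arc = revcomp(A);

  for (int strand = 0; strand < 2; ++strand) {
    const std::vector<int>& Q = strand == 0 ? A : Arc;
    query_kmers(Q, k, qk);
    seed_hits(qk, idx, hits);
    if (hits.empty()) continue;
    // sort by diagonal then query position; split into colinear groups
    std::vector<std::pair<int, int>> hd(hits.size()); // (diag, qpos)
    for (size_t i = 0; i < hits.size(); ++i)
      hd[i] = std::make_pair(hits[i].second - hits[i].first, hits[i].first);
    std::sort(hd.begin(), hd.end());
    size_t g0 = 0;
    for (size_t i = 1; i <= hd.size(); ++i) {
      bool brk = i == hd.size() ||
        hd[i].first - hd[i - 1].first > band ||
        (hd[i].first == hd[i - 1].first && hd[i].second - hd[i - 1].second > max_seed_gap);
      if (brk) {
        int qlo = hd[g0].second, qhi = hd[g0].second;
        long dsum = 0;
        for (size_t j = g0; j < i; ++j) {
          qlo = std::min(qlo, hd[j].second);
          qhi = std::max(qhi, hd[j].second);
          dsum += hd[j].first;
        }
        Cand c;
        c.qlo = std::max(0, qlo - 2 * band);
        c.qhi = std::min((int)Q.size(), qhi + k + 2 * band);
        c.diag = (int)(dsum / (long)(i - g0));
        c.strand = strand;
        c.nseeds = (int)(i - g0);
        cands.push_back(c);
        g0 = i;
      }
    }
  }
  std::sort(cands.begin(), cands.end(),
            [](const Cand& x, const Cand& y) { return x.nseeds > y.nseeds; });

  std::vector<int> qs_v, qe_v, ts_v, te_v;
  std::vector<double> id_v, len_v;
  std::vector<std::string> strand_v;
  std::vector<std::pair<int, int>> accepted; // query intervals on forward strand of a

  for (const Cand& c : cands) {
    const std::vector<int>& Q = c.strand == 0 ? A : Arc;
    int lq = c.qhi - c.qlo;
    if (lq <= 0) continue;
    BandAln r = banded_local(Q.data() + c.qlo, lq, B.data(), lb,
                             c.diag + c.qlo, band);
    if (r.align_len <= min_len) continue;
    int qs = c.qlo + r.qstart, qe = c.qlo + r.qend + 1; // half-open on Q
    int fqs = qs, fqe = qe;
    if (c.strand == 1) { fqs = la - qe; fqe = la - qs; } // map back to forward a
    bool overlap = false;
    for (auto& iv : accepted) {
      int ov = std::min(fqe, iv.second) - std::max(fqs, iv.first);
      if (ov > 0 && 2 * ov > (fqe - fqs)) { overlap = true; break; }
    }
    if (overlap) continue;
    accepted.push_back(std::make_pair(fqs, fqe));
    qs_v.push_back(fqs); qe_v.push_back(fqe);
    ts_v.push_back(r.tstart); te_v.push_back(r.tend + 1);
    id_v.push_back(100.0 * r.matches / r.align_len);
    len_v.push_back(r.align_len);
    strand_v.push_back(c.strand == 0 ? "+" : "-");
  }
  return DataFrame::create(
    _["start_a"] = IntegerVector(qs_v.begin(), qs_v.end()),
    _["end_a"] = IntegerVector(qe_v.begin(), qe_v.end()),
    _["start_b"] = IntegerVector(ts_v.begin(), ts_v.end()),
    _["end_b"] = IntegerVector(te_v.begin(), te_v.end()),
    _["pct_identity"] = NumericVector(id_v.begin(), id_v.end()),
    _["length"] = NumericVector(len_v.begin(), len_v.end()),
    _["strand"] = strand_v,
    _["stringsAsFactors"] = false);
}

// Exact permutation p-value for the Spearman correlation: enumerates all
// distinct permutations of the y ranks (two-sided on |rho|).
// [[Rcpp::export(name = ".cpp_spearman_perm")]]
double cpp_spearman_perm(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  std::vector<double> x(rx.begin(), rx.end()), y(ry.begin(), ry.end());
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sx = 0, sy = 0;
  for (int i = 0; i < n; ++i) { sx += (x[i] - mx) * (x[i] - mx); sy += (y[i] - my) * (y[i] - my); }
  double denom = std::sqrt(sx * sy);
  if (denom <= 0) stop("zero variance");
  double sobs = 0;
  for (int i = 0; i < n; ++i) sobs += (x[i] - mx) * (y[i] - my);
  double robs = std::fabs(sobs / denom);
  std::sort(y.begin(), y.end());
  long total = 0, extreme = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; ++i) s += (x[i] - mx) * (y[i] - my);
    double r = std::fabs(s / denom);
    if (r >= robs - 1e-12) ++extreme;
    ++total;
  } while (std::next_permutation(y.begin(), y.end()));
  return (double)extreme / (double)total;
}
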
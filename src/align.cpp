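#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Ungapped suffix(fwd) / prefix(rev_rc) overlap scan. Maximizes
// matches - mismatches over overlap lengths in [min_ov, hi]; ties go to the
// longer overlap. best_len stays -1 when no candidate length exists or when
// even the best candidate has more mismatches than matches (no credible
// overlap at all).
static void scan_overlap(const char* f, int nf, const char* r, int nr,
                         int min_ov, int max_ov,
                         int& best_len, int& best_m, int& best_mm) {
  best_len = -1; best_m = 0; best_mm = 0;
  int best_score = INT_MIN;
  int hi = std::min(std::min(nf, nr), max_ov);
  for (int L = min_ov; L <= hi; ++L) {
    const char* fs = f + nf - L;
    int m = 0;
    for (int i = 0; i < L; ++i) if (fs[i] == r[i]) ++m;
    int mm = L - m;
    int score = m - mm;
    if (score > best_score || (score == best_score && L > best_len)) {
      best_score = score; best_len = L; best_m = m; best_mm = mm;
    }
  }
  if (best_len > 0 && best_m < best_mm) best_len = -1;
}

// [[Rcpp::export]]
IntegerVector cpp_best_overlap(std::string fwd, std::string rev_rc,
                               int min_overlap, int max_overlap) {
  int len, m, mm;
  scan_overlap(fwd.c_str(), (int) fwd.size(), rev_rc.c_str(),
               (int) rev_rc.size(), min_overlap, max_overlap, len, m, mm);
  if (len < 0) return IntegerVector(0);
  return IntegerVector::create(len, m, mm);
}

// Merge a batch of mate pairs. seq2/qual2 must already be
// reverse-complemented / reversed. Status codes: 0 assembled,
// 1 low_quality (score < threshold), 2 unassembled (no overlap found).
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2rc, CharacterVector qual2rc,
                     int min_overlap, int max_overlap,
                     double score_threshold) {
  int n = seq1.size();
  IntegerVector status(n), ov_len(n), ov_mm(n);
  NumericVector score(n);
  CharacterVector out_seq(n), out_qual(n);
  std::string merged, mq;
  for (int k = 0; k < n; ++k) {
    const char* s1 = CHAR(STRING_ELT(seq1, k));
    const char* q1 = CHAR(STRING_ELT(qual1, k));
    const char* s2 = CHAR(STRING_ELT(seq2rc, k));
    const char* q2 = CHAR(STRING_ELT(qual2rc, k));
    int n1 = (int) LENGTH(STRING_ELT(seq1, k));
    int n2 = (int) LENGTH(STRING_ELT(seq2rc, k));
    int maxov = max_overlap > 0 ? max_overlap : std::min(n1, n2);
    int L, m, mm;
    scan_overlap(s1, n1, s2, n2, min_overlap, maxov, L, m, mm);
    if (L < 0) {
      status[k] = 2; ov_len[k] = NA_INTEGER; ov_mm[k] = NA_INTEGER;
      score[k] = NA_REAL;
      out_seq[k] = NA_STRING; out_qual[k] = NA_STRING;
      continue;
    }
    double sc = (double) m / (double) L;
    ov_len[k] = L; ov_mm[k] = mm; score[k] = sc;
    if (sc < score_threshold) {
      status[k] = 1;
      out_seq[k] = NA_STRING; out_qual[k] = NA_STRING;
      continue;
    }
    status[k] = 0;
    merged.assign(s1, s1 + (n1 - L));
    mq.assign(q1, q1 + (n1 - L));
    // consensus over the overlap: mate1 bases sit at s1[n1-L .. n1-1],
    // mate2 bases at s2[0 .. L-1]; PHRED+33 chars compare like PHRED ints
    for (int i = 0; i < L; ++i) {
      char b1 = s1[n1 - L + i], b2 = s2[i];
      char c1 = q1[n1 - L + i], c2 = q2[i];
      if (b1 == b2) {
        merged.push_back(b1);
        mq.push_back(c1 >= c2 ? c1 : c2);
      } else {
        merged.push_back(c2 > c1 ? b2 : b1);  // tie -> mate1 base
        mq.push_back(c1 <= c2 ? c1 : c2);
      }
    }
    merged.append(s2 + L, s2 + n2);
    mq.append(q2 + L, q2 + n2);
    out_seq[k] = merged;
    out_qual[k] = mq;
  }
  return List::create(_["status"] = status, _["sequence"] = out_seq,
                      _["quality"] = out_qual, _["overlap_length"] = ov_len,
                      _["mismatches"] = ov_mm, _["score"] = score);
}

// Banded end-free (overlap) global alignment identity: fraction of matching
// columns over the aligned core (terminal overhangs are cost- and
// denominator-free). Scoring: match +1, mismatch -1, gap -2; ties resolved
// diagonal > up > left. Band is widened automatically so the length
// difference always fits.
static double identity_endfree(const char* a, int n, const char* b, int m,
                               int band) {
  if (n == 0 || m == 0) return 0.0;
  int delta = m - n;
  int lo = std::min(0, delta) - band;   // allowed j - i range
  int hi = std::max(0, delta) + band;
  int W = hi - lo + 1;
  const int NEG = INT_MIN / 4;
  static std::vector<int> Hprev, Hcur, Mprev, Mcur, Cprev, Ccur;
  Hprev.assign(W, NEG); Hcur.assign(W, NEG);
  Mprev.assign(W, 0); Mcur.assign(W, 0);
  Cprev.assign(W, 0); Ccur.assign(W, 0);
  // row i = 0: free leading gaps in b
  for (int j = 0; j <= m; ++j) {
    int d = j - 0 - lo;
    if (d < 0 || d >= W) continue;
    Hprev[d] = 0; Mprev[d] = 0; Cprev[d] = 0;
  }
  // empty alignment (all free gaps) scores 0 with identity 0; any aligned
  // core with positive score beats it
  int best = 0, best_m = 0, best_c = 0;
  for (int i = 1; i <= n; ++i) {
    for (int d = 0; d < W; ++d) { Hcur[d] = NEG; Mcur[d] = 0; Ccur[d] = 0; }
    int jmin = std::max(0, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      int d = j - i - lo;
      int h = NEG, mm = 0, cc = 0;
      if (j == 0) {  // free leading gaps in a
        h = 0; mm = 0; cc = 0;
      } else {
        // diagonal: prev row, j-1 -> same offset d
        if (Hprev[d] > NEG) {
          int sc = Hprev[d] + ((a[i - 1] == b[j - 1]) ? 1 : -1);
          h = sc; mm = Mprev[d] + (a[i - 1] == b[j - 1] ? 1 : 0);
          cc = Cprev[d] + 1;
        }
        // up (gap in b): prev row, same j -> offset d+1
        if (d + 1 < W && Hprev[d + 1] > NEG) {
          int sc = Hprev[d + 1] - 2;
          if (sc > h) { h = sc; mm = Mprev[d + 1]; cc = Cprev[d + 1] + 1; }
        }
        // left (gap in a): same row, j-1 -> offset d-1
        if (d - 1 >= 0 && Hcur[d - 1] > NEG) {
          int sc = Hcur[d - 1] - 2;
          if (sc > h) { h = sc; mm = Mcur[d - 1]; cc = Ccur[d - 1] + 1; }
        }
      }
      Hcur[d] = h; Mcur[d] = mm; Ccur[d] = cc;
      // final score: any cell on last row or last column (free trailing gaps)
      if ((i == n || j == m) && h > best) { best = h; best_m = mm; best_c = cc; }
    }
    std::swap(Hprev, Hcur); std::swap(Mprev, Mcur); std::swap(Cprev, Ccur);
  }
  if (best_c <= 0) return 0.0;
  return (double) best_m / (double) best_c;
}

// [[Rcpp::export]]
double cpp_identity_endfree(std::string a, std::string b, int band) {
  int d = (int) b.size() - (int) a.size();
  int w = std::max(band, std::abs(d) + 8);
  return identity_endfree(a.c_str(), (int) a.size(), b.c_str(),
                          (int) b.size(), w);
}

// First centroid (in list order) whose identity with the query reaches the
// threshold; 0 when none does. Exact-equality shortcut avoids the DP.
// [[Rcpp::export]]
int cpp_assign_first(std::string query, CharacterVector centroids,
                     double threshold, int band) {
  int nq = (int) query.size();
  for (int k = 0; k < centroids.size(); ++k) {
    const char* c = CHAR(STRING_ELT(centroids, k));
    int nc = (int) LENGTH(STRING_ELT(centroids, k));
    if (nc == nq && query.compare(0, nq, c) == 0) return k + 1;
    int w = std::max(band, std::abs(nc - nq) + 8);
    if (identity_endfree(query.c_str(), nq, c, nc, w) >= threshold)
      return k + 1;
  }
  return 0;
}

// Full greedy clustering pass over abundance-sorted unique sequences.
// Each query joins the first centroid whose banded end-free identity
// reaches the threshold, else founds a centroid (unless it is a singleton
// and discard_singletons is set). A shared-8-mer bitset prescreen skips the
// DP for centroids that cannot possibly reach the threshold (only applied
// when both sequences are >= 64 bp; a near-identical pair of that size
// must share far more than 8 distinct 8-mers).
// [[Rcpp::export]]
List cpp_greedy_cluster(CharacterVector seqs, IntegerVector sizes,
                        double threshold, int band,
                        bool discard_singletons) {
  const int NW = 65536 / 64;  // 4^8 k-mer codes as a bitset
  int n = seqs.size();
  IntegerVector membership(n, NA_INTEGER);
  std::vector<int> cent_idx;
  std::vector<std::vector<uint64_t>> bits;
  std::vector<int> qk;
  qk.reserve(512);
  auto kmercodes = [&qk](const char* s, int L) {
    qk.clear();
    uint32_t code = 0; int valid = 0;
    for (int i = 0; i < L; ++i) {
      int b;
      switch (s[i]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
      }
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t) b) & 0xFFFFu;
      if (++valid >= 8) qk.push_back((int) code);
    }
  };
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int L = (int) LENGTH(STRING_ELT(seqs, i));
    kmercodes(s, L);
    int hit = 0;
    for (size_t c = 0; c < cent_idx.size(); ++c) {
      const char* t = CHAR(STRING_ELT(seqs, cent_idx[c]));
      int Lt = (int) LENGTH(STRING_ELT(seqs, cent_idx[c]));
      if (L >= 64 && Lt >= 64) {
        int sh = 0;
        for (size_t q = 0; q < qk.size(); ++q) {
          int code = qk[q];
          if ((bits[c][code >> 6] >> (code & 63)) & 1ULL) {
            if (++sh >= 8) break;
          }
        }
        if (sh < 8) continue;
      }
      int w = std::max(band, std::abs(Lt - L) + 8);
      if (identity_endfree(s, L, t, Lt, w) >= threshold) {
        hit = (int) c + 1;
        break;
      }
    }
    if (hit > 0) {
      membership[i] = hit;
    } else if (!discard_singletons || sizes[i] > 1) {
      cent_idx.push_back(i);
      bits.emplace_back(NW, 0ULL);
      std::vector<uint64_t>& B = bits.back();
      for (size_t q = 0; q < qk.size(); ++q) {
        int code = qk[q];
        B[code >> 6] |= 1ULL << (code & 63);
      }
      membership[i] = (int) cent_idx.size();
    }
  }
  return List::create(
    _["membership"] = membership,
    _["centroid_index"] = IntegerVector(cent_idx.begin(), cent_idx.end()));
}

// Greedy minimum-distance subset: scan equal-length sequences in the given
// order, keep each one whose Hamming distance to every kept sequence is
// >= min_dist.
// [[Rcpp::export]]
LogicalVector cpp_greedy_mindist(CharacterVector seqs, int min_dist) {
  int n = seqs.size();
  LogicalVector keep(n);
  std::vector<const char*> kept;
  int L = n > 0 ? (int) LENGTH(STRING_ELT(seqs, 0)) : 0;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    bool ok = true;
    for (size_t k = 0; k < kept.size(); ++k) {
      int d = 0;
      const char* t = kept[k];
      for (int p = 0; p < L && d < min_dist; ++p) if (s[p] != t[p]) ++d;
      if (d < min_dist) { ok = false; break; }
    }
    keep[i] = ok;
    if (ok) kept.push_back(s);
  }
  return keep;
}
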
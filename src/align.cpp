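// Semi-global (glocal) affine-gap alignment of short queries against a long
// reference: the query is aligned end-to-end, gaps on the reference before
// the first and after the last query base are free. Gotoh three-state DP
// with traceback; a gap of length L costs gap_open + L * gap_extend.
//
// Two engines with identical semantics on their shared domain:
//  - full DP over the whole reference (always correct, O(n*m));
//  - k-mer-seeded banded DP (default): exact 13-mer hits locate the read's
//    diagonal range and the DP runs in a band around it. Reads that seed in
//    neither orientation, or whose banded alignment falls below the
//    identity threshold, fall back to the full DP, so the band is an
//    accelerator, not a filter.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
#include <unordered_map>
#include <limits>

using namespace Rcpp;

static const int NEG = std::numeric_limits<int>::min() / 4;
static const int KMER = 13;
static const int SEED_STEP = 4;   // query k-mers sampled every 4 bases
static const int BAND_PAD = 16;   // indel allowance around the seed diagonals
static const int MAX_BAND = 256;  // widest band before clustering diagonals

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

struct AlnResult {
  int score = NEG, ref_start = -1, ref_end = -1, matches = 0,
      aligned_len = 0;
  bool ok = false;
};

class Aligner {
public:
  Aligner(const std::string& ref, int match, int mismatch, int gap_open,
          int gap_extend)
      : ref_(ref), m_((int)ref.size()), ma_(match), mi_(mismatch),
        go_(gap_open), ge_(gap_extend) {
    build_index();
  }

  // ---- full DP --------------------------------------------------------------
  AlnResult full_align(const std::string& q) {
    const int n = (int)q.size();
    AlnResult res;
    if (n == 0 || m_ == 0) return res;
    const int W = m_ + 1;
    ensure_rows(W);
    tbM_.resize((size_t)(n + 1) * W);
    tbIq_.resize((size_t)(n + 1) * W);
    tbIr_.resize((size_t)(n + 1) * W);

    int *Mp = rowM_[0].data(), *Mc = rowM_[1].data();
    int *Iqp = rowIq_[0].data(), *Iqc = rowIq_[1].data();
    int *Irp = rowIr_[0].data(), *Irc = rowIr_[1].data();
    for (int j = 0; j <= m_; ++j) { Mp[j] = 0; Iqp[j] = NEG; Irp[j] = NEG; }

    for (int i = 1; i <= n; ++i) {
      const char qc = q[i - 1];
      size_t row = (size_t)i * W;
      uint8_t *tM = &tbM_[row], *tIq = &tbIq_[row], *tIr = &tbIr_[row];
      // column 0: query ahead of the reference start (query-gap run)
      Mc[0] = NEG;
      Iqc[0] = go_ + i * ge_;
      tIq[0] = (i == 1) ? 0 : 1;
      Irc[0] = NEG;
      for (int j = 1; j <= m_; ++j) {
        const int s = (qc == ref_[j - 1]) ? ma_ : mi_;
        int best = Mp[j - 1]; uint8_t tb = (i == 1) ? 3 : 0;
        if (Iqp[j - 1] > best) { best = Iqp[j - 1]; tb = 1; }
        if (Irp[j - 1] > best) { best = Irp[j - 1]; tb = 2; }
        Mc[j] = best + s; tM[j] = tb;

        int open = std::max(Mp[j], Irp[j]) + go_ + ge_;
        uint8_t tbq = (Mp[j] >= Irp[j]) ? 0 : 2;
        int ext = Iqp[j] + ge_;
        if (open >= ext) { Iqc[j] = open; tIq[j] = tbq; }
        else             { Iqc[j] = ext;  tIq[j] = 1; }

        int openr = std::max(Mc[j - 1], Iqc[j - 1]) + go_ + ge_;
        uint8_t tbr = (Mc[j - 1] >= Iqc[j - 1]) ? 0 : 1;
        int extr = Irc[j - 1] + ge_;
        if (openr >= extr) { Irc[j] = openr; tIr[j] = tbr; }
        else               { Irc[j] = extr;  tIr[j] = 2; }
      }
      std::swap(Mp, Mc); std::swap(Iqp, Iqc); std::swap(Irp, Irc);
    }
    // last computed row now sits in the "previous" pointers
    int bj = -1, bstate = 0, bscore = NEG;
    for (int j = 0; j <= m_; ++j) {
      if (Mp[j] > bscore) { bscore = Mp[j]; bj = j; bstate = 0; }
    }
    for (int j = 0; j <= m_; ++j) {
      if (Iqp[j] > bscore) { bscore = Iqp[j]; bj = j; bstate = 1; }
    }
    if (bj < 0 || bscore <= NEG / 2) return res;

    int i = n, j = bj, state = bstate;
    res.score = bscore;
    while (i > 0) {
      size_t c = (size_t)i * W + j;
      if (state == 0) {
        uint8_t tb = tbM_[c];
        --i; --j;
        res.aligned_len++;
        if (q[i] == ref_[j]) res.matches++;
        if (res.ref_end < 0) res.ref_end = j;
        res.ref_start = j;
        if (tb == 3) break;
        state = tb;
      } else if (state == 1) {
        uint8_t tb = tbIq_[c];
        --i;
        state = tb;
      } else {
        uint8_t tb = tbIr_[c];
        --j;
        state = tb;
      }
    }
    res.ok = res.aligned_len > 0;
    return res;
  }

  // ---- seeding --------------------------------------------------------------
  // diagonal range (ref_pos - query_pos) of exact k-mer hits; false if none
  bool seed(const std::string& q, int& dlo, int& dhi) {
    const int n = (int)q.size();
    if (n < KMER) return false;
    std::vector<int> diags;
    for (int i = 0; i + KMER <= n; i += SEED_STEP) {
      uint64_t key = 0;
      bool okk = true;
      for (int t = 0; t < KMER; ++t) {
        int b = base2bits(q[i + t]);
        if (b < 0) { okk = false; break; }
        key = (key << 2) | (uint64_t)b;
      }
      if (!okk) continue;
      auto it = index_.find(key);
      if (it == index_.end()) continue;
      for (int j : it->second) diags.push_back(j - i);
    }
    if (diags.empty()) return false;
    std::sort(diags.begin(), diags.end());
    dlo = diags.front(); dhi = diags.back();
    if (dhi - dlo > MAX_BAND) {
      // densest run of diagonals within the band cap (spurious hits happen)
      size_t best_lo = 0, best_cnt = 0;
      for (size_t a = 0, b = 0; a < diags.size(); ++a) {
        while (diags[a] - diags[b] > MAX_BAND) ++b;
        if (a - b + 1 > best_cnt) { best_cnt = a - b + 1; best_lo = b; }
      }
      dlo = diags[best_lo];
      dhi = diags[best_lo + best_cnt - 1];
    }
    return true;
  }

  // ---- banded DP ------------------------------------------------------------
  AlnResult banded_align(const std::string& q, int dlo, int dhi) {
    const int n = (int)q.size();
    AlnResult res;
    if (n == 0 || m_ == 0) return res;
    dlo -= BAND_PAD; dhi += BAND_PAD;
    const int Wb = dhi - dlo + 1;
    ensure_rows(Wb);
    tbM_.resize((size_t)(n + 1) * Wb);
    tbIq_.resize((size_t)(n + 1) * Wb);
    tbIr_.resize((size_t)(n + 1) * Wb);

    int *Mp = rowM_[0].data(), *Mc = rowM_[1].data();
    int *Iqp = rowIq_[0].data(), *Iqc = rowIq_[1].data();
    int *Irp = rowIr_[0].data(), *Irc = rowIr_[1].data();
    for (int x = 0; x < Wb; ++x) { Mp[x] = NEG; Iqp[x] = NEG; Irp[x] = NEG; }

    for (int i = 1; i <= n; ++i) {
      const char qc = q[i - 1];
      const int jlo = std::max(1, i + dlo), jhi = std::min(m_, i + dhi);
      size_t row = (size_t)i * Wb;
      uint8_t *tM = &tbM_[row], *tIq = &tbIq_[row], *tIr = &tbIr_[row];
      for (int x = 0; x < Wb; ++x) { Mc[x] = NEG; Iqc[x] = NEG; Irc[x] = NEG; }
      for (int j = jlo; j <= jhi; ++j) {
        const int x = j - (i + dlo);  // buffer index on this row
        const int s = (qc == ref_[j - 1]) ? ma_ : mi_;
        // (i-1, j-1) -> same x on previous row; row 0 is the free start
        int dM = (i == 1) ? 0 : Mp[x];
        int dIq = (i == 1) ? NEG : Iqp[x];
        int dIr = (i == 1) ? NEG : Irp[x];
        if (i > 1 && j - 1 == 0) { dM = NEG; dIq = NEG; dIr = NEG; }
        int best = dM; uint8_t tb = (i == 1) ? 3 : 0;
        if (dIq > best) { best = dIq; tb = 1; }
        if (dIr > best) { best = dIr; tb = 2; }
        Mc[x] = (best <= NEG / 2) ? NEG : best + s;
        tM[x] = tb;
        // (i-1, j) -> x + 1 on previous row
        int uM = NEG, uIq = NEG, uIr = NEG;
        if (i == 1) { uM = 0; }
        else if (x + 1 < Wb) { uM = Mp[x + 1]; uIq = Iqp[x + 1]; uIr = Irp[x + 1]; }
        int open = std::max(uM, uIr);
        uint8_t tbq = (uM >= uIr) ? 0 : 2;
        int ext = uIq;
        int vopen = (open <= NEG / 2) ? NEG : open + go_ + ge_;
        int vext = (ext <= NEG / 2) ? NEG : ext + ge_;
        if (vopen >= vext) { Iqc[x] = vopen; tIq[x] = tbq; }
        else               { Iqc[x] = vext;  tIq[x] = 1; }
        // (i, j-1) -> x - 1 on current row
        int lM = NEG, lIq = NEG, lIr = NEG;
        if (x - 1 >= 0 && j - 1 >= 1) { lM = Mc[x - 1]; lIq = Iqc[x - 1]; lIr = Irc[x - 1]; }
        int openr = std::max(lM, lIq);
        uint8_t tbr = (lM >= lIq) ? 0 : 1;
        int ropen = (openr <= NEG / 2) ? NEG : openr + go_ + ge_;
        int rext = (lIr <= NEG / 2) ? NEG : lIr + ge_;
        if (ropen >= rext) { Irc[x] = ropen; tIr[x] = tbr; }
        else               { Irc[x] = rext;  tIr[x] = 2; }
      }
      std::swap(Mp, Mc); std::swap(Iqp, Iqc); std::swap(Irp, Irc);
    }
    int bx = -1, bstate = 0, bscore = NEG;
    for (int x = 0; x < Wb; ++x) {
      if (Mp[x] > bscore) { bscore = Mp[x]; bx = x; bstate = 0; }
    }
    for (int x = 0; x < Wb; ++x) {
      if (Iqp[x] > bscore) { bscore = Iqp[x]; bx = x; bstate = 1; }
    }
    if (bx < 0 || bscore <= NEG / 2) return res;

    int i = n, x = bx, state = bstate;
    res.score = bscore;
    while (i > 0) {
      size_t c = (size_t)i * Wb + x;
      if (state == 0) {
        uint8_t tb = tbM_[c];
        const int j = x + i + dlo;  // 1-based ref column of this cell
        --i;                        // diagonal: same x on previous row
        res.aligned_len++;
        if (q[i] == ref_[j - 1]) res.matches++;
        if (res.ref_end < 0) res.ref_end = j - 1;
        res.ref_start = j - 1;
        if (tb == 3) break;
        state = tb;
      } else if (state == 1) {
        uint8_t tb = tbIq_[c];
        --i; ++x;                   // up: x shifts right on previous row
        state = tb;
      } else {
        uint8_t tb = tbIr_[c];
        --x;                        // left on the same row
        state = tb;
      }
    }
    res.ok = res.aligned_len > 0;
    return res;
  }

  AlnResult align(const std::string& q, bool banded, double min_identity) {
    if (!banded) return full_align(q);
    int dlo, dhi;
    if (!seed(q, dlo, dhi)) { AlnResult r; return r; }  // caller may fall back
    AlnResult r = banded_align(q, dlo, dhi);
    // guard: a banded result below the identity bar is re-checked in full
    if (!r.ok ||
        (r.aligned_len > 0 &&
         (double)r.matches / r.aligned_len < min_identity)) {
      return full_align(q);
    }
    return r;
  }

  bool has_seed(const std::string& q) {
    int a, b;
    return seed(q, a, b);
  }

private:
  void build_index() {
    if (m_ < KMER) return;
    index_.reserve((size_t)m_ * 2);
    for (int j = 0; j + KMER <= m_; ++j) {
      uint64_t key = 0;
      bool okk = true;
      for (int t = 0; t < KMER; ++t) {
        int b = base2bits(ref_[j + t]);
        if (b < 0) { okk = false; break; }
        key = (key << 2) | (uint64_t)b;
      }
      if (okk) index_[key].push_back(j);
    }
  }

  void ensure_rows(int w) {
    for (int r = 0; r < 2; ++r) {
      if ((int)rowM_[r].size() < w) {
        rowM_[r].resize(w); rowIq_[r].resize(w); rowIr_[r].resize(w);
      }
    }
  }

  std::string ref_;
  int m_, ma_, mi_, go_, ge_;
  std::unordered_map<uint64_t, std::vector<int>> index_;
  std::vector<int> rowM_[2], rowIq_[2], rowIr_[2];
  std::vector<uint8_t> tbM_, tbIq_, tbIr_;
};

// [[Rcpp::export(name = ".cpp_align_batch")]]
DataFrame cpp_align_batch(CharacterVector queries, std::string reference,
                          int match, int mismatch, int gap_open,
                          int gap_extend, bool try_revcomp = true,
                          bool banded = true, double min_identity = 0.0) {
  const int n = queries.size();
  Aligner al(reference, match, mismatch, gap_open, gap_extend);
  IntegerVector score(n), ref_start(n), ref_end(n), matches(n),
      aligned_len(n);
  CharacterVector orientation(n);
  for (int k = 0; k < n; ++k) {
    std::string q = as<std::string>(queries[k]);
    std::string qr = try_revcomp ? revcomp(q) : std::string();
    AlnResult fw, rv;
    if (banded) {
      bool sf = al.has_seed(q);
      bool sr = try_revcomp && al.has_seed(qr);
      if (!sf && !sr) {  // no anchor in either orientation: honest full DP
        fw = al.full_align(q);
        if (try_revcomp) rv = al.full_align(qr);
      } else {
        if (sf) fw = al.align(q, true, min_identity);
        if (sr) rv = al.align(qr, true, min_identity);
      }
    } else {
      fw = al.full_align(q);
      if (try_revcomp) rv = al.full_align(qr);
    }
    AlnResult best = fw;
    std::string ori = "forward";
    if (rv.ok && (!fw.ok || rv.score > fw.score)) {  // tie keeps forward
      best = rv; ori = "reverse";
    }
    if (!best.ok) {
      score[k] = NA_INTEGER; ref_start[k] = NA_INTEGER;
      ref_end[k] = NA_INTEGER; matches[k] = NA_INTEGER;
      aligned_len[k] = NA_INTEGER; orientation[k] = NA_STRING;
    } else {
      score[k] = best.score; ref_start[k] = best.ref_start;
      ref_end[k] = best.ref_end; matches[k] = best.matches;
      aligned_len[k] = best.aligned_len; orientation[k] = ori;
    }
  }
  return DataFrame::create(
      _["score"] = score, _["ref_start"] = ref_start,
      _["ref_end"] = ref_end, _["matches"] = matches,
      _["aligned_len"] = aligned_len, _["orientation"] = orientation,
      _["stringsAsFactors"] = false);
}
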
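#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Ungapped alignment of short reads to a circular reference.
// Seeding: exact k-mer index over the wrap-extended reference, with a
// shorter supplementary seed so heavily deaminated reads (whose long k-mers
// are all damaged) remain alignable. Scoring: +match per identity, -mismatch
// per substitution, with a reduced penalty for damage-consistent mismatches
// (reference C read as T, reference G read as A, in the orientation being
// scored); positions where either base is ambiguous score 0.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::vector<int> encode(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

struct KmerIndex {
  int k;
  std::vector<int> head;   // 4^k entries, -1 = empty
  std::vector<int> next;   // chain over reference positions
  void build(const std::vector<int> &ref, int k_) {
    k = k_;
    size_t nslots = (size_t)1 << (2 * k);
    head.assign(nslots, -1);
    next.assign(ref.size(), -1);
    if ((int)ref.size() < k) return;
    size_t mask = nslots - 1;
    size_t code = 0;
    int valid = 0;
    for (size_t i = 0; i < ref.size(); ++i) {
      if (ref[i] < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (size_t)ref[i]) & mask;
      if (++valid >= k) {
        size_t start = i - k + 1;
        next[start] = head[code];
        head[code] = (int)start;
      }
    }
  }
};

// collect distinct candidate start offsets (mod L) for one oriented read
static void gather_candidates(const std::vector<int> &read, const KmerIndex &idx,
                              int L, std::vector<int> &stamp, int gen,
                              std::vector<int> &out) {
  int k = idx.k;
  int n = (int)read.size();
  if (n < k) return;
  size_t mask = ((size_t)1 << (2 * k)) - 1;
  size_t code = 0;
  int valid = 0;
  for (int j = 0; j < n; ++j) {
    if (read[j] < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (size_t)read[j]) & mask;
    if (++valid >= k) {
      int jstart = j - k + 1;
      for (int p = idx.head[code]; p >= 0; p = idx.next[p]) {
        int off = p - jstart;
        off %= L; if (off < 0) off += L;
        if (stamp[off] != gen) { stamp[off] = gen; out.push_back(off); }
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame align_reads_cpp(CharacterVector seqs, std::string ref,
                          int k = 12, int k_supp = 8,
                          double match = 1.0, double mismatch = 1.0,
                          double damage_mismatch = 0.5,
                          double min_score_frac = 0.2) {
  int L = (int)ref.size();
  int n_reads = seqs.size();
  int max_len = 0;
  for (int i = 0; i < n_reads; ++i)
    max_len = std::max(max_len, (int)LENGTH(STRING_ELT(seqs, i)));
  int wrap = std::min(L, std::max(max_len - 1, 0));
  std::string ext_s = ref + ref.substr(0, wrap);
  std::vector<int> ext = encode(ext_s);

  KmerIndex primary, supp;
  primary.build(ext, k);
  bool use_supp = (k_supp > 0 && k_supp < k);
  if (use_supp) supp.build(ext, k_supp);

  std::vector<int> stamp(L, -1);
  int gen = 0;

  IntegerVector ref_start(n_reads), nmis(n_reads);
  NumericVector score(n_reads);
  CharacterVector strand(n_reads);
  LogicalVector aligned(n_reads);

  std::vector<int> cand;
  for (int r = 0; r < n_reads; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int len = (int)s.size();
    std::vector<int> fwd = encode(s);
    std::vector<int> rev(len);
    for (int i = 0; i < len; ++i) {
      int b = fwd[len - 1 - i];
      rev[i] = (b < 0) ? -1 : 3 - b;
    }
    double best = R_NegInf;
    int best_off = -1, best_mis = 0;
    char best_strand = '+';
    bool found = false;
    if (len > L) { aligned[r] = false; score[r] = NA_REAL;
                   ref_start[r] = NA_INTEGER; nmis[r] = NA_INTEGER;
                   strand[r] = NA_STRING; continue; }
    for (int st = 0; st < 2; ++st) {
      const std::vector<int> &rd = (st == 0) ? fwd : rev;
      cand.clear();
      ++gen;
      gather_candidates(rd, primary, L, stamp, gen, cand);
      if (use_supp) gather_candidates(rd, supp, L, stamp, gen, cand);
      std::sort(cand.begin(), cand.end());
      for (size_t c = 0; c < cand.size(); ++c) {
        int off = cand[c];
        double sc = 0.0;
        int mis = 0;
        for (int i = 0; i < len; ++i) {
          int rb = rd[i], gb = ext[off + i];
          if (rb < 0 || gb < 0) continue;
          if (rb == gb) { sc += match; continue; }
          ++mis;
          if ((gb == 1 && rb == 3) || (gb == 2 && rb == 0))
            sc -= damage_mismatch;
          else
            sc -= mismatch;
        }
        if (sc > best) {
          best = sc; best_off = off; best_mis = mis;
          best_strand = (st == 0) ? '+' : '-';
          found = true;
        }
      }
    }
    if (found && best >= min_score_frac * match * len) {
      aligned[r] = true;
      ref_start[r] = best_off + 1;
      score[r] = best;
      nmis[r] = best_mis;
      strand[r] = std::string(1, best_strand);
    } else {
      aligned[r] = false;
      ref_start[r] = NA_INTEGER;
      score[r] = found ? best : NA_REAL;
      nmis[r] = NA_INTEGER;
      strand[r] = NA_STRING;
    }
  }
  return DataFrame::create(_["aligned"] = aligned, _["ref_start"] = ref_start,
                           _["strand"] = strand, _["score"] = score,
                           _["n_mismatch"] = nmis,
                           _["stringsAsFactors"] = false);
}
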
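// Seed-and-extend placement kernels shared by the read mapper and the
// fragment-ANI engine. Sequences are plain ACGT strings; anything else
// (including the N hard-masking used for removed ribosomal operons and
// contig spacers) never matches and never seeds.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static KmerIndex build_index(const std::string& s, int k) {
  KmerIndex idx;
  const int n = (int)s.size();
  if (n < k) return idx;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) {
      valid = 0;
      key = 0;
      continue;
    }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++valid >= k) idx[key].push_back(i - k + 1);
  }
  return idx;
}

static bool encode_kmer(const std::string& s, int pos, int k, uint64_t* key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bit(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  *key = v;
  return true;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  const size_t n = s.size();
  for (size_t i = 0; i < n; ++i) {
    switch (s[n - 1 - i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default: r[i] = 'N';
    }
  }
  return r;
}

// Map reads onto a (concatenated, hard-masked) reference by exact k-mer
// seeds at both read ends and ungapped full-length extension on both
// strands. Each read is reported at most once, at its best-identity
// placement; ties break to the lowest reference coordinate, then to the
// forward strand. Placements below min_identity_pct are suppressed.
// Returns 0-based start coordinates.
// [[Rcpp::export]]
DataFrame cpp_map_reads(std::string ref, CharacterVector reads, int k,
                        double min_identity_pct) {
  if (k < 4 || k > 32) stop("seed size k must be in [4, 32]");
  KmerIndex idx = build_index(ref, k);
  const int reflen = (int)ref.size();

  std::vector<int> o_read, o_start, o_matches, o_len, o_strand;

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int len = (int)fwd.size();
    if (len < k) continue;
    std::string rev = revcomp(fwd);

    int best_m = -1, best_st = -1, best_strand = 0;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = (strand == 0) ? fwd : rev;
      std::vector<int> cands;
      int offs[2] = {0, len - k};
      int noffs = (offs[1] > 0) ? 2 : 1;
      for (int oi = 0; oi < noffs; ++oi) {
        uint64_t key;
        if (!encode_kmer(rd, offs[oi], k, &key)) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int st = it->second[h] - offs[oi];
          if (st < 0 || st + len > reflen) continue;
          cands.push_back(st);
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (size_t c = 0; c < cands.size(); ++c) {
        const int st = cands[c];
        int m = 0;
        for (int i = 0; i < len; ++i) {
          char rc = ref[st + i];
          if (rc != 'N' && rc == rd[i]) ++m;
        }
        if (m > best_m || (m == best_m && st < best_st)) {
          best_m = m;
          best_st = st;
          best_strand = strand;
        }
      }
    }
    if (best_m < 0) continue;
    double ident = 100.0 * best_m / len;
    if (ident < min_identity_pct - 1e-9) continue;
    o_read.push_back(r + 1);
    o_start.push_back(best_st);
    o_matches.push_back(best_m);
    o_len.push_back(len);
    o_strand.push_back(best_strand == 0 ? 1 : -1);
  }
  return DataFrame::create(_["read"] = o_read, _["start"] = o_start,
                           _["matches"] = o_matches,
                           _["aligned_length"] = o_len,
                           _["strand"] = o_strand);
}

// Best ungapped placement of each query fragment on a subject sequence:
// exact k-mer seeds every seed_step bp define candidate diagonals, the
// whole fragment is compared on each diagonal (partial overlap allowed at
// subject ends), and the placement with the most matches wins (ties:
// lowest subject coordinate, then forward strand). Used for fragment ANI
// and for HSP discovery in the d4 statistic.
// [[Rcpp::export]]
DataFrame cpp_fragment_hits(CharacterVector fragments, std::string subject,
                            int k, int seed_step) {
  if (k < 4 || k > 32) stop("seed size k must be in [4, 32]");
  if (seed_step < 1) stop("seed_step must be >= 1");
  KmerIndex idx = build_index(subject, k);
  const int slen = (int)subject.size();
  const int n = fragments.size();

  IntegerVector o_matches(n), o_overlap(n), o_start(n), o_strand(n);
  LogicalVector o_found(n);

  for (int f = 0; f < n; ++f) {
    std::string fwd = as<std::string>(fragments[f]);
    const int flen = (int)fwd.size();
    o_found[f] = false;
    o_matches[f] = 0;
    o_overlap[f] = 0;
    o_start[f] = NA_INTEGER;
    o_strand[f] = NA_INTEGER;
    if (flen < k) continue;
    std::string rev = revcomp(fwd);

    int best_m = -1, best_st = 0, best_ov = 0, best_strand = 0;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& fr = (strand == 0) ? fwd : rev;
      std::vector<int> cands;
      for (int o = 0; o + k <= flen; o += seed_step) {
        uint64_t key;
        if (!encode_kmer(fr, o, k, &key)) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h)
          cands.push_back(it->second[h] - o);
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (size_t c = 0; c < cands.size(); ++c) {
        const int st = cands[c];
        const int lo = std::max(0, st);
        const int hi = std::min(slen, st + flen);
        const int ov = hi - lo;
        if (ov < k) continue;
        int m = 0;
        for (int j = lo; j < hi; ++j) {
          char sc = subject[j];
          if (sc != 'N' && sc == fr[j - st]) ++m;
        }
        if (m > best_m || (m == best_m && st < best_st)) {
          best_m = m;
          best_st = st;
          best_ov = ov;
          best_strand = strand;
        }
      }
    }
    if (best_m < 0) continue;
    o_found[f] = true;
    o_matches[f] = best_m;
    o_overlap[f] = best_ov;
    o_start[f] = best_st;
    o_strand[f] = (best_strand == 0) ? 1 : -1;
  }
  return DataFrame::create(_["fragment"] = seq_len(n), _["found"] = o_found,
                           _["start"] = o_start, _["matches"] = o_matches,
                           _["overlap"] = o_overlap, _["strand"] = o_strand);
}
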
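#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else = -1.
// Packed big-endian, so numeric order on the packed word equals
// lexicographic order on the k-mer string.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// [[Rcpp::export]]
List kmer_spectrum_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 20);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  double total_windows = 0.0;

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int run = 0;  // valid bases accumulated in current window
    for (const char *p = str; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++counts[canon];
        total_windows += 1.0;
      }
    }
  }

  // tally distinct k-mers by copy number
  std::map<uint32_t, double> hist;
  for (const auto &kv : counts) hist[kv.second] += 1.0;

  IntegerVector copy_number(hist.size());
  NumericVector n_kmers(hist.size());
  R_xlen_t i = 0;
  for (const auto &kv : hist) {
    copy_number[i] = (int)kv.first;
    n_kmers[i] = kv.second;
    ++i;
  }
  return List::create(_["copy_number"] = copy_number,
                      _["n_kmers"] = n_kmers,
                      _["total_instances"] = total_windows,
                      _["n_distinct"] = (double)counts.size());
}

// Split a scaffold at every maximal run of >= min_run consecutive 'N'.
// Zero-length fragments are dropped.
// [[Rcpp::export]]
CharacterVector split_on_n_runs_cpp(std::string seq, int min_run) {
  std::vector<std::string> out;
  const size_t n = seq.size();
  size_t i = 0, frag_start = 0;
  while (i <= n) {
    if (i == n || seq[i] == 'N') {
      size_t run_start = i;
      while (i < n && seq[i] == 'N') ++i;
      size_t run_len = i - run_start;
      bool is_gap = (run_start == n) || ((int)run_len >= min_run);
      if (is_gap) {
        if (run_start > frag_start)
          out.push_back(seq.substr(frag_start, run_start - frag_start));
        frag_start = i;
      }
      if (run_start == n) break;
    } else {
      ++i;
    }
  }
  return wrap(out);
}

// Per-window G+C and A+C+G+T counts over non-overlapping windows anchored
// at the sequence origin; the trailing partial window is excluded.
// [[Rcpp::export]]
List window_base_counts_cpp(std::string seq, double window) {
  const size_t n = seq.size();
  const size_t w = (size_t)window;
  const size_t n_win = (w == 0) ? 0 : n / w;
  IntegerVector gc((R_xlen_t)n_win), acgt((R_xlen_t)n_win);
  for (size_t j = 0; j < n_win; ++j) {
    int g = 0, a = 0;
    const char *p = seq.data() + j * w;
    for (size_t i = 0; i < w; ++i) {
      switch (p[i]) {
        case 'G': case 'C': ++g; ++a; break;
        case 'A': case 'T': ++a; break;
        default: break;
      }
    }
    gc[(R_xlen_t)j] = g;
    acgt[(R_xlen_t)j] = a;
  }
  return List::create(_["gc"] = gc, _["acgt"] = acgt);
}

// G+C and A+C+G+T counts over a whole string (used for component GC).
// [[Rcpp::export]]
NumericVector base_counts_cpp(std::string seq) {
  double g = 0, a = 0, nn = 0;
  for (char c : seq) {
    switch (c) {
      case 'G': case 'C': ++g; ++a; break;
      case 'A': case 'T': ++a; break;
      case 'N': ++nn; break;
      default: break;
    }
  }
  return NumericVector::create(_["gc"] = g, _["acgt"] = a, _["n"] = nn);
}
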
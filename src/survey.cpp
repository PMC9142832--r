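#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// Canonical k-mer depth histogram over a set of reads.  Each N-free window
// of length k contributes one occurrence to the lexicographically smaller of
// the window and its reverse complement (2-bit packed, so k <= 31).
// [[Rcpp::export(name = ".kmer_histogram_cpp")]]
List kmer_histogram_cpp(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, uint32_t> tab;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP el = STRING_ELT(reads, r);
    if (el == NA_STRING) continue;
    const char *s = CHAR(el);
    const int len = LENGTH(el);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int i = 0; i < len; ++i) {
      const int c = base_code(s[i]);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) ++tab[fwd < rev ? fwd : rev];
    }
  }
  std::unordered_map<uint32_t, double> histo;
  for (const auto &kv : tab) histo[kv.second] += 1.0;
  const int n = (int)histo.size();
  IntegerVector depth(n);
  NumericVector count(n);
  int i = 0;
  for (const auto &kv : histo) {
    depth[i] = (int)kv.first;
    count[i] = kv.second;
    ++i;
  }
  return List::create(_["depth"] = depth, _["count"] = count);
}

// Single-pass FASTQ tallies: per-position base counts (rows A,C,G,T,other),
// quality exceedance counts at Q20/Q30 (strict >), summed error
// probabilities 10^(-Q/10), and GC counters over unambiguous bases.
// [[Rcpp::export(name = ".fastq_stats_cpp")]]
List fastq_stats_cpp(CharacterVector reads, CharacterVector quals) {
  const R_xlen_t n = reads.size();
  if (quals.size() != n) stop("reads and qualities differ in length");
  int maxlen = 0;
  for (R_xlen_t r = 0; r < n; ++r) {
    const int len = LENGTH(STRING_ELT(reads, r));
    if (LENGTH(STRING_ELT(quals, r)) != len)
      stop("malformed FASTQ record %d: sequence and quality lengths differ",
           (int)(r + 1));
    if (len > maxlen) maxlen = len;
  }
  IntegerMatrix pos_counts(5, maxlen);
  double n_bases = 0, q20 = 0, q30 = 0, err_sum = 0, gc = 0, acgt = 0;
  for (R_xlen_t r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    const char *q = CHAR(STRING_ELT(quals, r));
    const int len = LENGTH(STRING_ELT(reads, r));
    for (int i = 0; i < len; ++i) {
      const int c = base_code(s[i]);
      pos_counts(c < 0 ? 4 : c, i) += 1;
      if (c >= 0) { acgt += 1; if (c == 1 || c == 2) gc += 1; }
      const int phred = (int)q[i] - 33;
      if (phred < 0) stop("malformed FASTQ record %d: quality below '!'",
                          (int)(r + 1));
      if (phred > 20) q20 += 1;
      if (phred > 30) q30 += 1;
      err_sum += std::pow(10.0, -phred / 10.0);
      n_bases += 1;
    }
  }
  return List::create(
    _["n_reads"] = (double)n, _["n_bases"] = n_bases,
    _["pos_counts"] = pos_counts, _["q20"] = q20, _["q30"] = q30,
    _["err_sum"] = err_sum, _["gc"] = gc, _["acgt"] = acgt);
}

// Longest common circular subsequence of two integer sequences, maximised
// over all rotation pairs (exact for the <= 40-feature mitogenome case).
// Returns the matched values of `a` in rotated order.
// [[Rcpp::export(name = ".lccs_cpp")]]
IntegerVector lccs_cpp(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return IntegerVector(0);
  std::vector<int> A(n), B(m), best;
  std::vector<std::vector<int> > dp(n + 1, std::vector<int>(m + 1, 0));
  for (int ra = 0; ra < n; ++ra) {
    for (int i = 0; i < n; ++i) A[i] = a[(i + ra) % n];
    for (int rb = 0; rb < m; ++rb) {
      for (int j = 0; j < m; ++j) B[j] = b[(j + rb) % m];
      for (int i = 1; i <= n; ++i)
        for (int j = 1; j <= m; ++j)
          dp[i][j] = (A[i - 1] == B[j - 1])
                         ? dp[i - 1][j - 1] + 1
                         : std::max(dp[i - 1][j], dp[i][j - 1]);
      if (dp[n][m] > (int)best.size()) {
        std::vector<int> kept;
        int i = n, j = m;
        while (i > 0 && j > 0) {
          if (A[i - 1] == B[j - 1]) { kept.push_back(A[i - 1]); --i; --j; }
          else if (dp[i - 1][j] >= dp[i][j - 1]) --i;
          else --j;
        }
        best.assign(kept.rbegin(), kept.rend());
      }
    }
  }
  return wrap(best);
}
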
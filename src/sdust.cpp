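// Symmetric DUST low-complexity masking.
//
// The score of an interval of length L (L >= 4) is
//   10 * sum_t c_t (c_t - 1) / 2 / (L - 3)
// over the 64 trinucleotide counts c_t (L - 3 == #triplets - 1). An interval
// qualifies when its score meets the threshold and no window longer than
// `window` is considered; a qualifying interval is "perfect" when no proper
// subinterval scores strictly higher. The mask is the merged union of perfect
// intervals. Runs of non-ACGT characters break candidate windows.
//
// Complexity is O(n * w^2) in the worst case, intended for exome-scale
// targets and fixtures rather than whole genomes.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int nt2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

struct Ival { int start, end; };  // 0-based half-open

// score10 of [i, j] inclusive within code vector; caller guarantees j-i+1 >= 4
static double interval_score(const std::vector<int>& code, int i, int j) {
  int cnt[64] = {0};
  long pairs = 0;
  for (int k = i + 2; k <= j; k++) {
    int t = (code[k - 2] << 4) | (code[k - 1] << 2) | code[k];
    pairs += cnt[t];
    cnt[t]++;
  }
  return 10.0 * (double)pairs / (double)(j - i - 2);
}

static void sdust_chunk(const std::vector<int>& code, int offset, double threshold,
                        int window, std::vector<Ival>& out) {
  int n = (int)code.size();
  if (n < 4) return;
  std::vector<Ival> cand;
  for (int i = 0; i + 3 < n; i++) {
    int cnt[64] = {0};
    long pairs = 0;
    int jmax = std::min(n - 1, i + window - 1);
    for (int j = i + 2; j <= jmax; j++) {
      int t = (code[j - 2] << 4) | (code[j - 1] << 2) | code[j];
      pairs += cnt[t];
      cnt[t]++;
      int L = j - i + 1;
      if (L < 4) continue;
      double s = 10.0 * (double)pairs / (double)(L - 3);
      if (s >= threshold) cand.push_back({i, j});
    }
  }
  // perfection: drop candidates containing a strictly higher-scoring proper
  // subinterval. Candidates already inside the accumulated mask cannot change
  // the union and are skipped (keeps long repeat runs near O(n * w)).
  std::sort(cand.begin(), cand.end(), [](const Ival& a, const Ival& b) {
    return a.start < b.start || (a.start == b.start && a.end < b.end);
  });
  int cov_start = -1, cov_end = -1;
  for (const Ival& iv : cand) {
    if (iv.start >= cov_start && iv.end + 1 <= cov_end) continue;
    double s = interval_score(code, iv.start, iv.end);
    bool perfect = true;
    for (int i2 = iv.start; i2 <= iv.end - 3 && perfect; i2++) {
      int cnt[64] = {0};
      long pairs = 0;
      for (int j2 = i2 + 2; j2 <= iv.end && perfect; j2++) {
        int t = (code[j2 - 2] << 4) | (code[j2 - 1] << 2) | code[j2];
        pairs += cnt[t];
        cnt[t]++;
        int L = j2 - i2 + 1;
        if (L < 4) continue;
        if (i2 == iv.start && j2 == iv.end) continue;
        double s2 = 10.0 * (double)pairs / (double)(L - 3);
        if (s2 > s + 1e-12) perfect = false;
      }
    }
    if (perfect) {
      out.push_back({offset + iv.start, offset + iv.end + 1});
      if (iv.start <= cov_end) {  // extend / start covered block (local coords)
        if (cov_start < 0) cov_start = iv.start;
        cov_end = std::max(cov_end, iv.end + 1);
      } else {
        cov_start = iv.start;
        cov_end = iv.end + 1;
      }
    }
  }
}

// [[Rcpp::export(name = ".sdust_intervals")]]
DataFrame sdust_cpp(std::string seq, double threshold, int window) {
  if (window < 4) stop("window must be >= 4");
  int n = (int)seq.size();
  std::vector<Ival> raw;
  int i = 0;
  while (i < n) {
    while (i < n && nt2(seq[i]) < 0) i++;
    int start = i;
    std::vector<int> code;
    while (i < n && nt2(seq[i]) >= 0) code.push_back(nt2(seq[i++]));
    if ((int)code.size() >= 4) sdust_chunk(code, start, threshold, window, raw);
  }
  // merge union (raw is sorted by start from construction order; sort to be safe)
  std::sort(raw.begin(), raw.end(), [](const Ival& a, const Ival& b) {
    return a.start < b.start || (a.start == b.start && a.end < b.end);
  });
  std::vector<Ival> merged;
  for (const Ival& iv : raw) {
    if (!merged.empty() && iv.start <= merged.back().end)
      merged.back().end = std::max(merged.back().end, iv.end);
    else
      merged.push_back(iv);
  }
  IntegerVector s((int)merged.size()), e((int)merged.size());
  for (int k = 0; k < (int)merged.size(); k++) { s[k] = merged[k].start; e[k] = merged[k].end; }
  return DataFrame::create(_["start"] = s, _["end"] = e);
}
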
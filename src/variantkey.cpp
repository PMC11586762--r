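// 64-bit reversible variant encoding ("VariantKey" layout):
//   bits 63..59  chromosome code (1-22, X=23, Y=24, MT=25)
//   bits 58..31  0-based position (28 bits)
//   bits 30..0   REF+ALT block: reversible when len(ref)+len(alt) <= 11,
//                otherwise a 30-bit hash bucket with the low bit set.
// The packed value is surfaced to R as a 16-char lowercase hex string so that
// lexicographic order equals unsigned 64-bit order (base R lacks uint64).
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static const int VK_MAX_REVERSIBLE = 11;

static int chrom_code(const std::string& chrom) {
  if (chrom == "X") return 23;
  if (chrom == "Y") return 24;
  if (chrom == "MT" || chrom == "M") return 25;
  if (chrom.empty() || chrom.size() > 2) return -1;
  int v = 0;
  for (char c : chrom) {
    if (c < '0' || c > '9') return -1;
    v = v * 10 + (c - '0');
  }
  return (v >= 1 && v <= 22) ? v : -1;
}

static std::string chrom_name(int code) {
  if (code >= 1 && code <= 22) return std::to_string(code);
  if (code == 23) return "X";
  if (code == 24) return "Y";
  if (code == 25) return "MT";
  return "";
}

static int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// FNV-1a, folded to 30 bits: bucket for alleles too long to pack reversibly.
static uint32_t allele_hash30(const std::string& ref, const std::string& alt) {
  uint64_t h = 1469598103934665603ULL;
  for (char c : ref) { h ^= (uint8_t)toupper(c); h *= 1099511628211ULL; }
  h ^= (uint8_t)'|'; h *= 1099511628211ULL;
  for (char c : alt) { h ^= (uint8_t)toupper(c); h *= 1099511628211ULL; }
  return (uint32_t)((h ^ (h >> 32)) & 0x3FFFFFFFu);
}

static std::string to_hex(uint64_t x) {
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)x);
  return std::string(buf);
}

// [[Rcpp::export(name = ".vk_encode")]]
List vk_encode_cpp(CharacterVector chrom, NumericVector pos,
                   CharacterVector ref, CharacterVector alt) {
  int n = chrom.size();
  CharacterVector packed(n);
  LogicalVector reversible(n);
  for (int i = 0; i < n; i++) {
    std::string c = as<std::string>(chrom[i]);
    if (c.rfind("chr", 0) == 0) c = c.substr(3);
    int cc = chrom_code(c);
    if (cc < 0) stop("invalid chromosome '%s' (accepted: 1-22, X, Y, MT)", c.c_str());
    double p = pos[i];
    if (!(p >= 1) || p != floor(p) || p > 268435456.0)
      stop("invalid position %g at record %d (must be integer in [1, 2^28])", p, i + 1);
    std::string r = as<std::string>(ref[i]);
    std::string a = as<std::string>(alt[i]);
    if (r.empty() || a.empty())
      stop("empty ref/alt allele at record %d", i + 1);
    for (char b : r) if (base2(b) < 0)
      stop("invalid nucleotide '%c' in ref at record %d", b, i + 1);
    for (char b : a) if (base2(b) < 0)
      stop("invalid nucleotide '%c' in alt at record %d", b, i + 1);
    uint64_t key = ((uint64_t)cc) << 59;
    key |= ((uint64_t)(p - 1)) << 31;
    size_t lr = r.size(), la = a.size();
    if (lr + la <= (size_t)VK_MAX_REVERSIBLE) {
      // [4 bits lref][4 bits lalt][22 bits of 2-bit bases, ref then alt, MSB first][flag 0]
      uint32_t block = ((uint32_t)lr << 27) | ((uint32_t)la << 23);
      int shift = 21;
      for (char b : r) { block |= ((uint32_t)base2(b)) << shift; shift -= 2; }
      for (char b : a) { block |= ((uint32_t)base2(b)) << shift; shift -= 2; }
      key |= (uint64_t)block;  // flag bit 0 is naturally 0
      reversible[i] = true;
    } else {
      key |= ((uint64_t)allele_hash30(r, a) << 1) | 1ULL;
      reversible[i] = false;
    }
    packed[i] = to_hex(key);
  }
  return List::create(_["packed"] = packed, _["reversible"] = reversible);
}

// [[Rcpp::export(name = ".vk_decode")]]
List vk_decode_cpp(CharacterVector packed) {
  int n = packed.size();
  CharacterVector chrom(n), ref(n), alt(n);
  NumericVector pos(n);
  LogicalVector reversible(n);
  for (int i = 0; i < n; i++) {
    std::string hex = as<std::string>(packed[i]);
    if (hex.size() != 16) stop("packed key must be a 16-char hex string, got '%s'", hex.c_str());
    uint64_t key = 0;
    for (char c : hex) {
      int d;
      if (c >= '0' && c <= '9') d = c - '0';
      else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
      else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
      else stop("packed key must be hex, got '%s'", hex.c_str());
      key = (key << 4) | (uint64_t)d;
    }
    int cc = (int)(key >> 59);
    std::string cn = chrom_name(cc);
    if (cn.empty()) stop("packed key decodes to invalid chromosome code %d", cc);
    chrom[i] = cn;
    pos[i] = (double)((key >> 31) & 0xFFFFFFFULL) + 1.0;
    uint32_t block = (uint32_t)(key & 0x7FFFFFFFULL);
    if (block & 1u) {  // hash bucket: alleles unrecoverable
      ref[i] = NA_STRING; alt[i] = NA_STRING; reversible[i] = false;
      continue;
    }
    int lr = (block >> 27) & 0xF, la = (block >> 23) & 0xF;
    if (lr + la > VK_MAX_REVERSIBLE || lr < 1 || la < 1)
      stop("packed key has inconsistent allele lengths (%d + %d)", lr, la);
    static const char bases[] = "ACGT";
    std::string r, a;
    int shift = 21;
    for (int k = 0; k < lr; k++) { r += bases[(block >> shift) & 3u]; shift -= 2; }
    for (int k = 0; k < la; k++) { a += bases[(block >> shift) & 3u]; shift -= 2; }
    ref[i] = r; alt[i] = a; reversible[i] = true;
  }
  return List::create(_["chrom"] = chrom, _["pos"] = pos, _["ref"] = ref,
                      _["alt"] = alt, _["reversible"] = reversible);
}
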
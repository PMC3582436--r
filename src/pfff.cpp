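// Core primitives: the keyed pseudorandom index stream (64-bit Mersenne
// twister) and the poly61 almost-universal compression stage.  These live in
// C++ because they are defined on exact 64-bit unsigned words, which base R
// numerics cannot represent.
#include <Rcpp.h>
#include <random>
#include <cstdint>
#include <cstring>
#include <string>

using namespace Rcpp;

typedef unsigned __int128 u128;
static const uint64_t P61 = ((uint64_t)1 << 61) - 1;  // Mersenne prime 2^61 - 1

// Accept a key as an integer-valued double (exact up to 2^53) or as a
// decimal / 0x-hex string covering the full unsigned 64-bit range.
static uint64_t parse_key(SEXP key) {
  if (TYPEOF(key) == STRSXP && Rf_length(key) == 1) {
    std::string s = as<std::string>(key);
    size_t i = 0;
    int base = 10;
    if (s.size() >= 2 && s[0] == '0' && (s[1] == 'x' || s[1] == 'X')) {
      base = 16; i = 2;
    }
    if (i >= s.size())
      stop("invalid key string '%s' (decimal or 0x-prefixed hex expected)",
           s.c_str());
    uint64_t v = 0;
    for (; i < s.size(); i++) {
      char c = s[i];
      int digit;
      if (c >= '0' && c <= '9') digit = c - '0';
      else if (base == 16 && c >= 'a' && c <= 'f') digit = 10 + (c - 'a');
      else if (base == 16 && c >= 'A' && c <= 'F') digit = 10 + (c - 'A');
      else stop("invalid key string '%s' (decimal or 0x-prefixed hex expected)",
                s.c_str());
      if (v > (UINT64_MAX - (uint64_t)digit) / (uint64_t)base)
        stop("key '%s' exceeds the unsigned 64-bit range", s.c_str());
      v = v * base + digit;
    }
    return v;
  }
  double d = as<double>(key);
  if (!R_finite(d) || d < 0 || d != std::floor(d))
    stop("key must be a non-negative integer");
  if (d > 9007199254740992.0)  // 2^53
    stop("numeric keys above 2^53 lose precision; pass the key as a string");
  return (uint64_t)d;
}

// [[Rcpp::export]]
std::string cpp_key_canonical(SEXP key) {
  char buf[32];
  snprintf(buf, sizeof(buf), "%llu", (unsigned long long)parse_key(key));
  return std::string(buf);
}

// ---------------------------------------------------------------------------
// Index generation: successive 64-bit Mersenne-twister outputs reduced modulo
// the block count.  `skip` discards leading words (the fingerprint format
// reserves the first word for compression key material, so the sampling
// stage and the compression stage draw from disjoint parts of one stream).
// [[Rcpp::export]]
NumericVector cpp_generate_indices(SEXP key, double block_count, int samples,
                                   int skip) {
  if (block_count < 1 || block_count != std::floor(block_count))
    stop("block_count must be a positive integer");
  if (block_count > 9007199254740992.0)
    stop("block_count too large");
  if (samples < 1) stop("samples must be >= 1");
  if (skip < 0) stop("skip must be >= 0");
  uint64_t bc = (uint64_t)block_count;
  std::mt19937_64 eng(parse_key(key));
  for (int i = 0; i < skip; i++) eng();
  NumericVector out(samples);
  for (int i = 0; i < samples; i++) out[i] = (double)(eng() % bc);
  return out;
}

static inline uint64_t mulmod61(uint64_t a, uint64_t b) {
  u128 z = (u128)a * b;
  uint64_t r = (uint64_t)(z & P61) + (uint64_t)(z >> 61);
  if (r >= P61) r -= P61;
  return r;
}

static inline uint64_t addmod61(uint64_t a, uint64_t b) {
  uint64_t r = a + b;  // both < 2^61, no overflow
  if (r >= P61) r -= P61;
  return r;
}

// First word of the key's twister stream, mapped into [2, p - 2].
static uint64_t poly61_r(uint64_t key) {
  std::mt19937_64 eng(key);
  return 2 + eng() % (P61 - 3);
}

// Polynomial evaluation hash over GF(2^61 - 1): split the message into
// 7-byte little-endian chunks c_0..c_{t-1} (last chunk zero-padded) and
// evaluate sum(c_j * r^(t - j)) + t mod p.  For messages of at most L bytes
// any fixed pair collides over a random key with probability
// <= ceil(L / 7) / (2^61 - 1): the difference is a nonzero polynomial in r
// of degree at most t, hence has at most t roots.
static uint64_t poly61_eval(uint64_t r, const uint8_t *msg, size_t len) {
  uint64_t h = 0;
  size_t t = (len + 6) / 7;
  for (size_t j = 0; j < t; j++) {
    uint64_t c = 0;
    size_t base = j * 7, navail = len - base < 7 ? len - base : 7;
    for (size_t b = 0; b < navail; b++)
      c |= (uint64_t)msg[base + b] << (8 * b);
    h = addmod61(mulmod61(h, r), c % P61);
  }
  return addmod61(mulmod61(h, r), (uint64_t)(t % P61));
}

// splitmix64 finalizer: a 64-bit bijection used to widen the 61-bit field
// element to the digest width.  Being a bijection it neither creates nor
// destroys collisions.
static inline uint64_t fmix64(uint64_t x) {
  x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
  x ^= x >> 27; x *= 0x94d049bb133111ebULL;
  x ^= x >> 31;
  return x;
}

static std::string hex64(uint64_t x) {
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)x);
  return std::string(buf);
}

// [[Rcpp::export]]
std::string cpp_poly61_digest(SEXP key, RawVector message, int digest_bits) {
  if (digest_bits != 64 && digest_bits != 128) stop("digest_bits must be 64 or 128");
  uint64_t k = parse_key(key);
  uint64_t h = poly61_eval(poly61_r(k),
                           message.size() ? (const uint8_t *)RAW(message) : NULL,
                           (size_t)message.size());
  std::string out = hex64(fmix64(h + 0x9e3779b97f4a7c15ULL));
  if (digest_bits == 128) out += hex64(fmix64(h + 0x3c6ef372fe94f82aULL));
  return out;
}

// [[Rcpp::export]]
double cpp_poly61_r(SEXP key) {
  // exposed for documentation/diagnostics; exact as double (r < 2^61 may
  // exceed 2^53, so return it as a string when precision matters)
  return (double)poly61_r(parse_key(key));
}

// [[Rcpp::export]]
RawVector cpp_key_bytes(SEXP key) {
  uint64_t k = parse_key(key);
  RawVector out(8);
  for (int i = 0; i < 8; i++) out[i] = (Rbyte)((k >> (8 * i)) & 0xff);
  return out;  // little-endian
}

// ---------------------------------------------------------------------------
// Monte-Carlo support: for one synthetic pair whose differing blocks are
// flagged in `is_diff`, count how many keys yield a sampling collision
// (no sampled index falls on a differing block, so the two sample vectors
// are byte-identical).  Mirrors the fingerprint's draw order (skip = 1).
// [[Rcpp::export]]
int cpp_sampling_collision_count(NumericVector keys, double block_count,
                                 int samples, LogicalVector is_diff, int skip) {
  if (block_count < 1 || (double)is_diff.size() != block_count)
    stop("is_diff must have one entry per block");
  uint64_t bc = (uint64_t)block_count;
  int n = keys.size(), count = 0;
  for (int i = 0; i < n; i++) {
    double d = keys[i];
    if (!R_finite(d) || d < 0 || d != std::floor(d) || d > 9007199254740992.0)
      stop("keys must be non-negative integer-valued numerics below 2^53");
    std::mt19937_64 eng((uint64_t)d);
    for (int s = 0; s < skip; s++) eng();
    bool collide = true;
    for (int s = 0; s < samples; s++) {
      uint64_t idx = eng() % bc;
      if (is_diff[(R_xlen_t)idx]) { collide = false; break; }
    }
    if (collide) count++;
  }
  return count;
}

// Number of block-aligned positions at which two equal-offset byte ranges
// differ; the tail block (shorter than block_size) counts as one block.
// [[Rcpp::export]]
double cpp_count_diff_blocks(RawVector a, RawVector b, double block_size) {
  if (a.size() != b.size()) stop("chunks must have equal length");
  if (block_size < 1) stop("block_size must be >= 1");
  R_xlen_t n = a.size(), bs = (R_xlen_t)block_size;
  const uint8_t *pa = (const uint8_t *)RAW(a), *pb = (const uint8_t *)RAW(b);
  double ndiff = 0;
  for (R_xlen_t start = 0; start < n; start += bs) {
    R_xlen_t end = start + bs < n ? start + bs : n;
    if (std::memcmp(pa + start, pb + start, end - start) != 0) ndiff++;
  }
  return ndiff;
}
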
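// Stream-cipher cores (ChaCha family, Salsa20) and SHA-256.
// Implemented from the public algorithm specifications so that key
// generation and per-scheme keystream timing are uniform across schemes.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>

using namespace Rcpp;

static inline uint32_t rotl32(uint32_t x, int n) {
  return (x << n) | (x >> (32 - n));
}

static inline uint32_t load_le32(const unsigned char *p) {
  return (uint32_t)p[0] | ((uint32_t)p[1] << 8) |
         ((uint32_t)p[2] << 16) | ((uint32_t)p[3] << 24);
}

static inline void store_le32(unsigned char *p, uint32_t v) {
  p[0] = (unsigned char)(v & 0xff);
  p[1] = (unsigned char)((v >> 8) & 0xff);
  p[2] = (unsigned char)((v >> 16) & 0xff);
  p[3] = (unsigned char)((v >> 24) & 0xff);
}

// ---------------------------------------------------------------- ChaCha ---

#define CHACHA_QR(a, b, c, d)                        \
  x[a] += x[b]; x[d] ^= x[a]; x[d] = rotl32(x[d], 16); \
  x[c] += x[d]; x[b] ^= x[c]; x[b] = rotl32(x[b], 12); \
  x[a] += x[b]; x[d] ^= x[a]; x[d] = rotl32(x[d], 8);  \
  x[c] += x[d]; x[b] ^= x[c]; x[b] = rotl32(x[b], 7);

static void chacha_block(unsigned char out[64], const uint32_t state[16],
                         int rounds) {
  uint32_t x[16];
  std::memcpy(x, state, sizeof(x));
  for (int i = 0; i < rounds; i += 2) {
    CHACHA_QR(0, 4, 8, 12)
    CHACHA_QR(1, 5, 9, 13)
    CHACHA_QR(2, 6, 10, 14)
    CHACHA_QR(3, 7, 11, 15)
    CHACHA_QR(0, 5, 10, 15)
    CHACHA_QR(1, 6, 11, 12)
    CHACHA_QR(2, 7, 8, 13)
    CHACHA_QR(3, 4, 9, 14)
  }
  for (int i = 0; i < 16; ++i) store_le32(out + 4 * i, x[i] + state[i]);
}

// ChaCha keystream, 96-bit nonce / 32-bit block counter layout (RFC 8439).
// counter is passed as double so values beyond 2^31 survive the R boundary.
// [[Rcpp::export(name = ".chacha_keystream")]]
RawVector chacha_keystream_cpp(RawVector key, RawVector nonce, double counter,
                               double length, int rounds) {
  if (key.size() != 32) stop("chacha requires a 32-byte key");
  if (nonce.size() != 12) stop("chacha requires a 12-byte nonce");
  if (rounds <= 0 || rounds % 2 != 0) stop("rounds must be a positive even number");
  if (length < 0) stop("length must be non-negative");
  R_xlen_t n = (R_xlen_t)length;
  RawVector out(n);
  uint32_t state[16];
  state[0] = 0x61707865u; state[1] = 0x3320646eu;
  state[2] = 0x79622d32u; state[3] = 0x6b206574u;
  const unsigned char *k = RAW(key);
  for (int i = 0; i < 8; ++i) state[4 + i] = load_le32(k + 4 * i);
  const unsigned char *nn = RAW(nonce);
  state[13] = load_le32(nn);
  state[14] = load_le32(nn + 4);
  state[15] = load_le32(nn + 8);
  uint64_t ctr = (uint64_t)counter;
  unsigned char block[64];
  R_xlen_t pos = 0;
  while (pos < n) {
    state[12] = (uint32_t)(ctr & 0xffffffffu);
    chacha_block(block, state, rounds);
    R_xlen_t take = std::min((R_xlen_t)64, n - pos);
    std::memcpy(RAW(out) + pos, block, (size_t)take);
    pos += take;
    ++ctr;
  }
  return out;
}

// --------------------------------------------------------------- Salsa20 ---

#define SALSA_QR(a, b, c, d)             \
  x[b] ^= rotl32(x[a] + x[d], 7);        \
  x[c] ^= rotl32(x[b] + x[a], 9);        \
  x[d] ^= rotl32(x[c] + x[b], 13);       \
  x[a] ^= rotl32(x[d] + x[c], 18);

static void salsa_block(unsigned char out[64], const uint32_t state[16]) {
  uint32_t x[16];
  std::memcpy(x, state, sizeof(x));
  for (int i = 0; i < 20; i += 2) {
    // column round
    SALSA_QR(0, 4, 8, 12)
    SALSA_QR(5, 9, 13, 1)
    SALSA_QR(10, 14, 2, 6)
    SALSA_QR(15, 3, 7, 11)
    // row round
    SALSA_QR(0, 1, 2, 3)
    SALSA_QR(5, 6, 7, 4)
    SALSA_QR(10, 11, 8, 9)
    SALSA_QR(15, 12, 13, 14)
  }
  for (int i = 0; i < 16; ++i) store_le32(out + 4 * i, x[i] + state[i]);
}

// Salsa20 keystream, 64-bit nonce / 64-bit block counter (Bernstein spec).
// [[Rcpp::export(name = ".salsa_keystream")]]
RawVector salsa_keystream_cpp(RawVector key, RawVector nonce, double counter,
                              double length) {
  if (key.size() != 32) stop("salsa20 requires a 32-byte key");
  if (nonce.size() != 8) stop("salsa20 requires an 8-byte nonce");
  if (length < 0) stop("length must be non-negative");
  R_xlen_t n = (R_xlen_t)length;
  RawVector out(n);
  uint32_t state[16];
  const unsigned char *k = RAW(key);
  const unsigned char *nn = RAW(nonce);
  state[0] = 0x61707865u;                 // "expa"
  for (int i = 0; i < 4; ++i) state[1 + i] = load_le32(k + 4 * i);
  state[5] = 0x3320646eu;                 // "nd 3"
  state[6] = load_le32(nn);
  state[7] = load_le32(nn + 4);
  state[10] = 0x79622d32u;                // "2-by"
  for (int i = 0; i < 4; ++i) state[11 + i] = load_le32(k + 16 + 4 * i);
  state[15] = 0x6b206574u;                // "te k"
  uint64_t ctr = (uint64_t)counter;
  unsigned char block[64];
  R_xlen_t pos = 0;
  while (pos < n) {
    state[8] = (uint32_t)(ctr & 0xffffffffu);
    state[9] = (uint32_t)(ctr >> 32);
    salsa_block(block, state);
    R_xlen_t take = std::min((R_xlen_t)64, n - pos);
    std::memcpy(RAW(out) + pos, block, (size_t)take);
    pos += take;
    ++ctr;
  }
  return out;
}

// --------------------------------------------------------------- SHA-256 ---

static const uint32_t SHA256_K[64] = {
  0x428a2f98u, 0x71374491u, 0xb5c0fbcfu, 0xe9b5dba5u,
  0x3956c25bu, 0x59f111f1u, 0x923f82a4u, 0xab1c5ed5u,
  0xd807aa98u, 0x12835b01u, 0x243185beu, 0x550c7dc3u,
  0x72be5d74u, 0x80deb1feu, 0x9bdc06a7u, 0xc19bf174u,
  0xe49b69c1u, 0xefbe4786u, 0x0fc19dc6u, 0x240ca1ccu,
  0x2de92c6fu, 0x4a7484aau, 0x5cb0a9dcu, 0x76f988dau,
  0x983e5152u, 0xa831c66du, 0xb00327c8u, 0xbf597fc7u,
  0xc6e00bf3u, 0xd5a79147u, 0x06ca6351u, 0x14292967u,
  0x27b70a85u, 0x2e1b2138u, 0x4d2c6dfcu, 0x53380d13u,
  0x650a7354u, 0x766a0abbu, 0x81c2c92eu, 0x92722c85u,
  0xa2bfe8a1u, 0xa81a664bu, 0xc24b8b70u, 0xc76c51a3u,
  0xd192e819u, 0xd6990624u, 0xf40e3585u, 0x106aa070u,
  0x19a4c116u, 0x1e376c08u, 0x2748774cu, 0x34b0bcb5u,
  0x391c0cb3u, 0x4ed8aa4au, 0x5b9cca4fu, 0x682e6ff3u,
  0x748f82eeu, 0x78a5636fu, 0x84c87814u, 0x8cc70208u,
  0x90befffau, 0xa4506cebu, 0xbef9a3f7u, 0xc67178f2u
};

static inline uint32_t rotr32(uint32_t x, int n) {
  return (x >> n) | (x << (32 - n));
}

static void sha256_compress(uint32_t h[8], const unsigned char *chunk) {
  uint32_t w[64];
  for (int i = 0; i < 16; ++i)
    w[i] = ((uint32_t)chunk[4 * i] << 24) | ((uint32_t)chunk[4 * i + 1] << 16) |
           ((uint32_t)chunk[4 * i + 2] << 8) | (uint32_t)chunk[4 * i + 3];
  for (int i = 16; i < 64; ++i) {
    uint32_t s0 = rotr32(w[i - 15], 7) ^ rotr32(w[i - 15], 18) ^ (w[i - 15] >> 3);
    uint32_t s1 = rotr32(w[i - 2], 17) ^ rotr32(w[i - 2], 19) ^ (w[i - 2] >> 10);
    w[i] = w[i - 16] + s0 + w[i - 7] + s1;
  }
  uint32_t a = h[0], b = h[1], c = h[2], d = h[3];
  uint32_t e = h[4], f = h[5], g = h[6], hh = h[7];
  for (int i = 0; i < 64; ++i) {
    uint32_t S1 = rotr32(e, 6) ^ rotr32(e, 11) ^ rotr32(e, 25);
    uint32_t ch = (e & f) ^ (~e & g);
    uint32_t t1 = hh + S1 + ch + SHA256_K[i] + w[i];
    uint32_t S0 = rotr32(a, 2) ^ rotr32(a, 13) ^ rotr32(a, 22);
    uint32_t maj = (a & b) ^ (a & c) ^ (b & c);
    uint32_t t2 = S0 + maj;
    hh = g; g = f; f = e; e = d + t1;
    d = c; c = b; b = a; a = t1 + t2;
  }
  h[0] += a; h[1] += b; h[2] += c; h[3] += d;
  h[4] += e; h[5] += f; h[6] += g; h[7] += hh;
}

// [[Rcpp::export(name = ".sha256")]]
RawVector sha256_cpp(RawVector data) {
  uint32_t h[8] = {
    0x6a09e667u, 0xbb67ae85u, 0x3c6ef372u, 0xa54ff53au,
    0x510e527fu, 0x9b05688cu, 0x1f83d9abu, 0x5be0cd19u
  };
  R_xlen_t n = data.size();
  const unsigned char *p = n ? RAW(data) : NULL;
  R_xlen_t full = n / 64;
  for (R_xlen_t i = 0; i < full; ++i) sha256_compress(h, p + 64 * i);
  unsigned char tail[128];
  R_xlen_t rem = n - 64 * full;
  if (rem > 0) std::memcpy(tail, p + 64 * full, (size_t)rem);
  tail[rem] = 0x80;
  R_xlen_t padlen = (rem < 56) ? 64 : 128;
  for (R_xlen_t i = rem + 1; i < padlen - 8; ++i) tail[i] = 0;
  uint64_t bits = (uint64_t)n * 8u;
  for (int i = 0; i < 8; ++i)
    tail[padlen - 1 - i] = (unsigned char)((bits >> (8 * i)) & 0xff);
  sha256_compress(h, tail);
  if (padlen == 128) sha256_compress(h, tail + 64);
  RawVector out(32);
  for (int i = 0; i < 8; ++i) {
    RAW(out)[4 * i] = (unsigned char)((h[i] >> 24) & 0xff);
    RAW(out)[4 * i + 1] = (unsigned char)((h[i] >> 16) & 0xff);
    RAW(out)[4 * i + 2] = (unsigned char)((h[i] >> 8) & 0xff);
    RAW(out)[4 * i + 3] = (unsigned char)(h[i] & 0xff);
  }
  return out;
}

// XOR two equal-length raw vectors (keystream application).
// [[Rcpp::export(name = ".xor_bytes")]]
RawVector xor_bytes_cpp(RawVector a, RawVector b) {
  if (a.size() != b.size()) stop("byte vectors must have equal length");
  R_xlen_t n = a.size();
  RawVector out(n);
  const unsigned char *pa = n ? RAW(a) : NULL;
  const unsigned char *pb = n ? RAW(b) : NULL;
  for (R_xlen_t i = 0; i < n; ++i) RAW(out)[i] = pa[i] ^ pb[i];
  return out;
}
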
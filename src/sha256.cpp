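// SHA-256 (FIPS 180-4) and the keyed fold-hash reduction used by all
// deterministic split methods: fold = uint64(first 8 digest bytes, big
// endian) mod n_folds, over the message secret || 0x00 || key.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>

namespace {

inline uint32_t rotr(uint32_t x, int n) { return (x >> n) | (x << (32 - n)); }

const uint32_t K[64] = {
    0x428a2f98u, 0x71374491u, 0xb5c0fbcfu, 0xe9b5dba5u, 0x3956c25bu,
    0x59f111f1u, 0x923f82a4u, 0xab1c5ed5u, 0xd807aa98u, 0x12835b01u,
    0x243185beu, 0x550c7dc3u, 0x72be5d74u, 0x80deb1feu, 0x9bdc06a7u,
    0xc19bf174u, 0xe49b69c1u, 0xefbe4786u, 0x0fc19dc6u, 0x240ca1ccu,
    0x2de92c6fu, 0x4a7484aau, 0x5cb0a9dcu, 0x76f988dau, 0x983e5152u,
    0xa831c66du, 0xb00327c8u, 0xbf597fc7u, 0xc6e00bf3u, 0xd5a79147u,
    0x06ca6351u, 0x14292967u, 0x27b70a85u, 0x2e1b2138u, 0x4d2c6dfcu,
    0x53380d13u, 0x650a7354u, 0x766a0abbu, 0x81c2c92eu, 0x92722c85u,
    0xa2bfe8a1u, 0xa81a664bu, 0xc24b8b70u, 0xc76c51a3u, 0xd192e819u,
    0xd6990624u, 0xf40e3585u, 0x106aa070u, 0x19a4c116u, 0x1e376c08u,
    0x2748774cu, 0x34b0bcb5u, 0x391c0cb3u, 0x4ed8aa4au, 0x5b9cca4fu,
    0x682e6ff3u, 0x748f82eeu, 0x78a5636fu, 0x84c87814u, 0x8cc70208u,
    0x90befffau, 0xa4506cebu, 0xbef9a3f7u, 0xc67178f2u};

void sha256_digest(const unsigned char *msg, size_t len, unsigned char out[32]) {
  uint32_t h[8] = {0x6a09e667u, 0xbb67ae85u, 0x3c6ef372u, 0xa54ff53au,
                   0x510e527fu, 0x9b05688cu, 0x1f83d9abu, 0x5be0cd19u};

  // padded message: msg || 0x80 || zeros || 64-bit big-endian bit length
  size_t total = len + 1 + 8;
  size_t padded = ((total + 63) / 64) * 64;
  std::vector<unsigned char> buf(padded, 0);
  std::memcpy(buf.data(), msg, len);
  buf[len] = 0x80;
  uint64_t bits = static_cast<uint64_t>(len) * 8u;
  for (int i = 0; i < 8; ++i)
    buf[padded - 1 - i] = static_cast<unsigned char>((bits >> (8 * i)) & 0xffu);

  uint32_t w[64];
  for (size_t block = 0; block < padded; block += 64) {
    const unsigned char *p = buf.data() + block;
    for (int t = 0; t < 16; ++t)
      w[t] = (uint32_t(p[4 * t]) << 24) | (uint32_t(p[4 * t + 1]) << 16) |
             (uint32_t(p[4 * t + 2]) << 8) | uint32_t(p[4 * t + 3]);
    for (int t = 16; t < 64; ++t) {
      uint32_t s0 = rotr(w[t - 15], 7) ^ rotr(w[t - 15], 18) ^ (w[t - 15] >> 3);
      uint32_t s1 = rotr(w[t - 2], 17) ^ rotr(w[t - 2], 19) ^ (w[t - 2] >> 10);
      w[t] = w[t - 16] + s0 + w[t - 7] + s1;
    }
    uint32_t a = h[0], b = h[1], c = h[2], d = h[3], e = h[4], f = h[5],
             g = h[6], hh = h[7];
    for (int t = 0; t < 64; ++t) {
      uint32_t S1 = rotr(e, 6) ^ rotr(e, 11) ^ rotr(e, 25);
      uint32_t ch = (e & f) ^ (~e & g);
      uint32_t t1 = hh + S1 + ch + K[t] + w[t];
      uint32_t S0 = rotr(a, 2) ^ rotr(a, 13) ^ rotr(a, 22);
      uint32_t maj = (a & b) ^ (a & c) ^ (b & c);
      uint32_t t2 = S0 + maj;
      hh = g; g = f; f = e; e = d + t1;
      d = c; c = b; b = a; a = t1 + t2;
    }
    h[0] += a; h[1] += b; h[2] += c; h[3] += d;
    h[4] += e; h[5] += f; h[6] += g; h[7] += hh;
  }
  for (int i = 0; i < 8; ++i) {
    out[4 * i] = static_cast<unsigned char>((h[i] >> 24) & 0xffu);
    out[4 * i + 1] = static_cast<unsigned char>((h[i] >> 16) & 0xffu);
    out[4 * i + 2] = static_cast<unsigned char>((h[i] >> 8) & 0xffu);
    out[4 * i + 3] = static_cast<unsigned char>(h[i] & 0xffu);
  }
}

} // namespace

// [[Rcpp::export(name = ".sha256_hex")]]
Rcpp::CharacterVector sha256_hex(Rcpp::CharacterVector keys) {
  static const char *hexd = "0123456789abcdef";
  Rcpp::CharacterVector out(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    std::string s = Rcpp::as<std::string>(keys[i]);
    unsigned char d[32];
    sha256_digest(reinterpret_cast<const unsigned char *>(s.data()), s.size(), d);
    char hex[65];
    for (int j = 0; j < 32; ++j) {
      hex[2 * j] = hexd[d[j] >> 4];
      hex[2 * j + 1] = hexd[d[j] & 0xf];
    }
    hex[64] = '\0';
    out[i] = hex;
  }
  return out;
}

// [[Rcpp::export(name = ".hash_to_fold_cpp")]]
Rcpp::IntegerVector hash_to_fold_cpp(Rcpp::CharacterVector keys, int n_folds,
                                     std::string secret) {
  if (n_folds < 1) Rcpp::stop("n_folds must be >= 1");
  Rcpp::IntegerVector out(keys.size());
  std::vector<unsigned char> msg;
  const uint64_t n = static_cast<uint64_t>(n_folds);
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    if (keys[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    std::string key = Rcpp::as<std::string>(keys[i]);
    msg.clear();
    msg.insert(msg.end(), secret.begin(), secret.end());
    msg.push_back(0x00); // separator: disambiguates secret/key boundary
    msg.insert(msg.end(), key.begin(), key.end());
    unsigned char d[32];
    sha256_digest(msg.data(), msg.size(), d);
    uint64_t v = 0;
    for (int j = 0; j < 8; ++j) v = (v << 8) | uint64_t(d[j]);
    out[i] = static_cast<int>(v % n);
  }
  return out;
}
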
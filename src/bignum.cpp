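// Multiprecision arithmetic for the commutative cipher, backed by OpenSSL
// BIGNUM.  Integers cross the R boundary as decimal strings; raw byte
// payloads as RawVector.  All routines are deterministic: randomness for
// parameter generation comes from a caller-supplied seed expanded with a
// SHA-256 counter stream, never from OpenSSL's RNG.

#include <Rcpp.h>
#include <openssl/bn.h>
#include <openssl/sha.h>
#include <openssl/opensslv.h>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct BnCtx {
  BN_CTX *ctx;
  BnCtx() : ctx(BN_CTX_new()) {
    if (!ctx) stop("BN_CTX allocation failed");
  }
  ~BnCtx() { BN_CTX_free(ctx); }
};

struct Bn {
  BIGNUM *n;
  Bn() : n(BN_new()) {
    if (!n) stop("BIGNUM allocation failed");
  }
  explicit Bn(const std::string &dec) : n(NULL) {
    if (BN_dec2bn(&n, dec.c_str()) == 0 || n == NULL)
      stop("invalid decimal integer: '%s'", dec.c_str());
  }
  ~Bn() { BN_free(n); }
  std::string dec() const {
    char *s = BN_bn2dec(n);
    std::string out(s);
    OPENSSL_free(s);
    return out;
  }
private:
  Bn(const Bn &);
  Bn &operator=(const Bn &);
};

bool is_prime(const BIGNUM *n, BN_CTX *ctx, int nchecks) {
#if OPENSSL_VERSION_NUMBER >= 0x30000000L
  (void)nchecks;  // BN_check_prime runs enough Miller-Rabin rounds for < 2^-128
  int r = BN_check_prime(n, ctx, NULL);
#else
  int r = BN_is_prime_fasttest_ex(n, nchecks, ctx, 1, NULL);
#endif
  if (r < 0) stop("primality test failed internally");
  return r == 1;
}

// Deterministic byte stream: block i is SHA256(seed || uint32_be(i)).
class Sha256Stream {
  std::vector<unsigned char> seed_;
  uint32_t block_;
  unsigned char buf_[SHA256_DIGEST_LENGTH];
  size_t pos_;
  void refill() {
    std::vector<unsigned char> in(seed_);
    in.push_back((block_ >> 24) & 0xff);
    in.push_back((block_ >> 16) & 0xff);
    in.push_back((block_ >> 8) & 0xff);
    in.push_back(block_ & 0xff);
    SHA256(in.data(), in.size(), buf_);
    ++block_;
    pos_ = 0;
  }
public:
  explicit Sha256Stream(const std::vector<unsigned char> &seed)
      : seed_(seed), block_(0), pos_(SHA256_DIGEST_LENGTH) {}
  void bytes(unsigned char *out, size_t len) {
    while (len > 0) {
      if (pos_ == SHA256_DIGEST_LENGTH) refill();
      size_t take = std::min(len, SHA256_DIGEST_LENGTH - pos_);
      std::memcpy(out, buf_ + pos_, take);
      pos_ += take;
      out += take;
      len -= take;
    }
  }
};

std::vector<unsigned char> raw_to_vec(const RawVector &r) {
  return std::vector<unsigned char>(r.begin(), r.end());
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".bn_mod_exp")]]
CharacterVector bn_mod_exp_c(CharacterVector base, std::string exponent,
                             std::string modulus) {
  BnCtx ctx;
  Bn e(exponent), m(modulus);
  int n = base.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    Bn b(as<std::string>(base[i])), r;
    if (BN_mod_exp(r.n, b.n, e.n, m.n, ctx.ctx) != 1)
      stop("modular exponentiation failed");
    out[i] = r.dec();
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".bn_mod_inverse")]]
std::string bn_mod_inverse_c(std::string a, std::string modulus) {
  BnCtx ctx;
  Bn x(a), m(modulus), r;
  if (BN_mod_inverse(r.n, x.n, m.n, ctx.ctx) == NULL)
    stop("no modular inverse exists");
  return r.dec();
}

//' @noRd
// [[Rcpp::export(name = ".bn_mod")]]
std::string bn_mod_c(std::string a, std::string modulus) {
  BnCtx ctx;
  Bn x(a), m(modulus), r;
  if (BN_nnmod(r.n, x.n, m.n, ctx.ctx) != 1) stop("modular reduction failed");
  return r.dec();
}

//' @noRd
// [[Rcpp::export(name = ".bn_sub")]]
std::string bn_sub_c(std::string a, std::string b) {
  Bn x(a), y(b), r;
  if (BN_sub(r.n, x.n, y.n) != 1) stop("subtraction failed");
  if (BN_is_negative(r.n)) stop("negative result not representable");
  return r.dec();
}

//' @noRd
// [[Rcpp::export(name = ".bn_div")]]
std::string bn_div_c(std::string a, std::string b) {
  BnCtx ctx;
  Bn x(a), y(b), q, r;
  if (BN_div(q.n, r.n, x.n, y.n, ctx.ctx) != 1) stop("division failed");
  return q.dec();
}

//' @noRd
// [[Rcpp::export(name = ".bn_is_prime")]]
bool bn_is_prime_c(std::string n, int nchecks = 40) {
  BnCtx ctx;
  Bn x(n);
  return is_prime(x.n, ctx.ctx, nchecks);
}

//' @noRd
// [[Rcpp::export(name = ".bn_num_bits")]]
int bn_num_bits_c(std::string n) {
  Bn x(n);
  return BN_num_bits(x.n);
}

//' @noRd
// [[Rcpp::export(name = ".bn_cmp")]]
int bn_cmp_c(std::string a, std::string b) {
  Bn x(a), y(b);
  return BN_cmp(x.n, y.n);
}

// Reduce a big-endian byte string into [1, q-1].
//' @noRd
// [[Rcpp::export(name = ".bn_bytes_to_exponent")]]
std::string bn_bytes_to_exponent_c(RawVector bytes, std::string q) {
  BnCtx ctx;
  Bn qq(q), one, range, r;
  BN_one(one.n);
  if (BN_sub(range.n, qq.n, one.n) != 1) stop("range computation failed");
  Bn x;
  if (BN_bin2bn(&bytes[0], bytes.size(), x.n) == NULL)
    stop("byte conversion failed");
  if (BN_nnmod(r.n, x.n, range.n, ctx.ctx) != 1) stop("reduction failed");
  if (BN_add(r.n, r.n, one.n) != 1) stop("shift failed");
  return r.dec();
}

//' @noRd
// [[Rcpp::export(name = ".sha256_hex")]]
std::string sha256_hex_c(RawVector bytes) {
  unsigned char md[SHA256_DIGEST_LENGTH];
  SHA256(bytes.size() ? &bytes[0] : (const unsigned char *)"", bytes.size(),
         md);
  static const char *hex = "0123456789abcdef";
  std::string out(2 * SHA256_DIGEST_LENGTH, '0');
  for (int i = 0; i < SHA256_DIGEST_LENGTH; ++i) {
    out[2 * i] = hex[md[i] >> 4];
    out[2 * i + 1] = hex[md[i] & 0x0f];
  }
  return out;
}

// Hash byte strings onto the order-q subgroup of Z_p^*:
//   e = (int(SHA256(msg || uint32_be(counter))) mod p) ^ cofactor mod p
// with counter the least value >= 0 for which e != 1 (and the pre-image
// is nonzero).  Cofactor exponentiation guarantees subgroup membership.
//' @noRd
// [[Rcpp::export(name = ".hash_to_group")]]
CharacterVector hash_to_group_c(List messages, std::string p,
                                std::string cofactor, int max_counter = 65536) {
  BnCtx ctx;
  Bn pp(p), cof(cofactor), one;
  BN_one(one.n);
  int n = messages.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    RawVector msg = messages[i];
    if (msg.size() == 0) stop("empty message cannot be hashed to the group");
    std::vector<unsigned char> buf = raw_to_vec(msg);
    size_t base_len = buf.size();
    buf.resize(base_len + 4);
    bool done = false;
    for (int counter = 0; counter < max_counter; ++counter) {
      buf[base_len] = (counter >> 24) & 0xff;
      buf[base_len + 1] = (counter >> 16) & 0xff;
      buf[base_len + 2] = (counter >> 8) & 0xff;
      buf[base_len + 3] = counter & 0xff;
      unsigned char md[SHA256_DIGEST_LENGTH];
      SHA256(buf.data(), buf.size(), md);
      Bn x, e;
      if (BN_bin2bn(md, SHA256_DIGEST_LENGTH, x.n) == NULL)
        stop("digest conversion failed");
      if (BN_nnmod(x.n, x.n, pp.n, ctx.ctx) != 1) stop("reduction failed");
      if (BN_is_zero(x.n)) continue;
      if (BN_mod_exp(e.n, x.n, cof.n, pp.n, ctx.ctx) != 1)
        stop("cofactor exponentiation failed");
      if (BN_cmp(e.n, one.n) != 0) {
        out[i] = e.dec();
        done = true;
        break;
      }
    }
    if (!done)
      stop("hash-to-group exhausted %d counters (degenerate group?)",
           max_counter);
  }
  return out;
}

// Deterministic Schnorr-style group generation: a q_bits prime q, then a
// p_bits prime p = cofactor * q + 1 with cofactor even.  Candidates are
// drawn from a SHA-256 counter stream keyed by `seed`, so a given
// (p_bits, q_bits, seed) always yields the same group.
//' @noRd
// [[Rcpp::export(name = ".gen_group_params")]]
List gen_group_params_c(int p_bits, int q_bits, RawVector seed,
                        int max_candidates = 100000) {
  if (q_bits < 16 || p_bits < 16 || q_bits >= p_bits)
    stop("require 16 <= q_bits < p_bits");
  BnCtx ctx;
  Sha256Stream rng(raw_to_vec(seed));

  // subgroup order q
  Bn q;
  {
    int nbytes = (q_bits + 7) / 8;
    std::vector<unsigned char> buf(nbytes);
    bool found = false;
    for (int it = 0; it < max_candidates; ++it) {
      rng.bytes(buf.data(), nbytes);
      if (BN_bin2bn(buf.data(), nbytes, q.n) == NULL) stop("bin2bn failed");
      // trim to exactly q_bits, force top and low bit
      if (BN_num_bits(q.n) > q_bits) {
        Bn mask;
        BN_one(mask.n);
        BN_lshift(mask.n, mask.n, q_bits);
        BN_sub_word(mask.n, 1);
        Bn tmp;
        // q = q & mask  (via mod 2^q_bits)
        Bn pow2;
        BN_one(pow2.n);
        BN_lshift(pow2.n, pow2.n, q_bits);
        BN_nnmod(q.n, q.n, pow2.n, ctx.ctx);
      }
      BN_set_bit(q.n, q_bits - 1);
      BN_set_bit(q.n, 0);
      if (BN_num_bits(q.n) != q_bits) continue;
      if (is_prime(q.n, ctx.ctx, 40)) {
        found = true;
        break;
      }
    }
    if (!found) stop("no %d-bit prime subgroup order found within budget",
                     q_bits);
  }

  // modulus p = cof * q + 1
  int cof_bits = p_bits - q_bits;
  Bn cof, p;
  {
    int nbytes = (cof_bits + 7) / 8;
    std::vector<unsigned char> buf(std::max(nbytes, 1));
    bool found = false;
    for (int it = 0; it < max_candidates; ++it) {
      rng.bytes(buf.data(), nbytes);
      if (BN_bin2bn(buf.data(), nbytes, cof.n) == NULL) stop("bin2bn failed");
      {
        Bn pow2;
        BN_one(pow2.n);
        BN_lshift(pow2.n, pow2.n, cof_bits);
        BN_nnmod(cof.n, cof.n, pow2.n, ctx.ctx);
      }
      BN_set_bit(cof.n, cof_bits - 1);
      BN_clear_bit(cof.n, 0);  // even cofactor keeps p odd
      if (BN_is_zero(cof.n)) continue;
      if (BN_mul(p.n, cof.n, q.n, ctx.ctx) != 1) stop("multiply failed");
      BN_add_word(p.n, 1);
      if (BN_num_bits(p.n) != p_bits) continue;
      if (is_prime(p.n, ctx.ctx, 40)) {
        found = true;
        break;
      }
    }
    if (!found)
      stop("no %d-bit prime modulus found within budget for this q", p_bits);
  }

  return List::create(_["p"] = p.dec(), _["q"] = q.dec(),
                      _["cofactor"] = cof.dec());
}
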
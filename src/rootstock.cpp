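// Core k-mer machinery: 2-bit canonical k-mer encoding, exact counting,
// Bloom filter membership, and the per-base scanning SNV caller.
// k-mers are packed into a 128-bit word, so k <= 64.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <fstream>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

typedef unsigned __int128 u128;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline u128 kmask(int k) {
  if (k >= 64) return ~(u128)0;
  return (((u128)1) << (2 * k)) - 1;
}

// Encode seq[0..k-1] forward and reverse-complement; false if non-ACGT.
static bool encode_kmer(const char* s, int k, u128& fwd, u128& rc) {
  fwd = 0;
  rc = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    fwd = (fwd << 2) | (u128)b;
    rc |= ((u128)(3 - b)) << (2 * i);
  }
  return true;
}

// With A<C<G<T mapped to 0<1<2<3, numeric order on equal-length encodings
// equals lexicographic order, so canonical = min(fwd, rc).
static inline u128 canon(u128 fwd, u128 rc) { return fwd < rc ? fwd : rc; }

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct U128Hash {
  size_t operator()(u128 x) const {
    return (size_t)splitmix64((uint64_t)x ^ splitmix64((uint64_t)(x >> 64)));
  }
};

// ---------------------------------------------------------------------------
// Membership indexes

struct KmerIndex {
  int k;
  virtual bool contains(u128 key) const = 0;
  virtual std::string type() const = 0;
  virtual double n_inserted() const = 0;
  virtual ~KmerIndex() {}
};

struct BloomFilter : KmerIndex {
  std::vector<uint64_t> bits;
  uint64_t m;  // bit length
  int h;       // number of hash functions
  uint64_t n_ins;

  BloomFilter(uint64_t m_, int h_, int k_) : bits((m_ + 63) / 64, 0), m(m_), h(h_), n_ins(0) {
    k = k_;
  }

  inline void hashes(u128 key, uint64_t& h1, uint64_t& h2) const {
    uint64_t a = splitmix64((uint64_t)key);
    uint64_t b = splitmix64((uint64_t)(key >> 64) ^ a);
    h1 = a ^ (b << 1);
    h2 = splitmix64(b + 0x632be59bd9b4e019ULL) | 1ULL;
  }
  inline void insert(u128 key) {
    uint64_t h1, h2;
    hashes(key, h1, h2);
    for (int i = 0; i < h; ++i) {
      uint64_t idx = (h1 + (uint64_t)i * h2) % m;
      bits[idx >> 6] |= (1ULL << (idx & 63));
    }
    ++n_ins;
  }
  bool contains(u128 key) const {
    uint64_t h1, h2;
    hashes(key, h1, h2);
    for (int i = 0; i < h; ++i) {
      uint64_t idx = (h1 + (uint64_t)i * h2) % m;
      if (!((bits[idx >> 6] >> (idx & 63)) & 1ULL)) return false;
    }
    return true;
  }
  std::string type() const { return "bloom"; }
  double n_inserted() const { return (double)n_ins; }
};

struct ExactSet : KmerIndex {
  std::unordered_set<u128, U128Hash> s;
  ExactSet(int k_) { k = k_; }
  bool contains(u128 key) const { return s.count(key) > 0; }
  std::string type() const { return "exact"; }
  double n_inserted() const { return (double)s.size(); }
};

// ---------------------------------------------------------------------------
// Exact k-mer counting (solidity pre-pass)

struct KmerCounts {
  int k;
  uint64_t n_kmers_seen;    // k-mers processed (incl. duplicates)
  uint64_t n_kmers_skipped; // windows containing non-ACGT
  std::unordered_map<u128, uint32_t, U128Hash> map;
};

static void count_sequence(KmerCounts& kc, const char* s, R_xlen_t len) {
  const int k = kc.k;
  const u128 mask = kmask(k);
  u128 fwd = 0, rc = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < len; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) {
      if (run > 0 && run < k) kc.n_kmers_skipped += run;
      run = 0;
      fwd = 0;
      rc = 0;
      continue;
    }
    fwd = ((fwd << 2) | (u128)b) & mask;
    rc = (rc >> 2) | (((u128)(3 - b)) << (2 * (k - 1)));
    if (++run >= k) {
      u128 key = canon(fwd, rc);
      uint32_t& c = kc.map[key];
      if (c < UINT32_MAX) ++c;
      ++kc.n_kmers_seen;
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_kmer_count(CharacterVector seqs, int k) {
  if (k < 2 || k > 64) stop("k must be between 2 and 64");
  KmerCounts* kc = new KmerCounts();
  kc->k = k;
  kc->n_kmers_seen = 0;
  kc->n_kmers_skipped = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    SEXP el = STRING_ELT(seqs, i);
    count_sequence(*kc, CHAR(el), LENGTH(el));
  }
  XPtr<KmerCounts> ptr(kc, true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector cpp_count_histogram(SEXP counts_ptr, int max_bin) {
  XPtr<KmerCounts> kc(counts_ptr);
  NumericVector hist(max_bin);
  for (const auto& kv : kc->map) {
    int b = kv.second > (uint32_t)max_bin ? max_bin : (int)kv.second;
    hist[b - 1] += 1;
  }
  return hist;
}

// [[Rcpp::export]]
List cpp_count_info(SEXP counts_ptr) {
  XPtr<KmerCounts> kc(counts_ptr);
  return List::create(_["k"] = kc->k, _["n_distinct"] = (double)kc->map.size(),
                      _["n_kmers"] = (double)kc->n_kmers_seen);
}

// [[Rcpp::export]]
double cpp_count_solid(SEXP counts_ptr, int min_count) {
  XPtr<KmerCounts> kc(counts_ptr);
  if (min_count <= 1) return (double)kc->map.size();
  double n = 0;
  for (const auto& kv : kc->map)
    if (kv.second >= (uint32_t)min_count) ++n;
  return n;
}

// [[Rcpp::export]]
SEXP cpp_bf_from_counts(SEXP counts_ptr, int min_count, double m, int h) {
  XPtr<KmerCounts> kc(counts_ptr);
  if (m < 8) stop("Bloom filter size must be at least 8 bits");
  if (h < 1) stop("need at least one hash function");
  BloomFilter* bf = new BloomFilter((uint64_t)m, h, kc->k);
  for (const auto& kv : kc->map)
    if (kv.second >= (uint32_t)min_count) bf->insert(kv.first);
  XPtr<KmerIndex> ptr(bf, true);
  return ptr;
}

// [[Rcpp::export]]
SEXP cpp_exact_from_counts(SEXP counts_ptr, int min_count) {
  XPtr<KmerCounts> kc(counts_ptr);
  ExactSet* es = new ExactSet(kc->k);
  for (const auto& kv : kc->map)
    if (kv.second >= (uint32_t)min_count) es->s.insert(kv.first);
  XPtr<KmerIndex> ptr(es, true);
  return ptr;
}

// ---------------------------------------------------------------------------
// Index queries

// [[Rcpp::export]]
List cpp_index_info(SEXP idx_ptr) {
  XPtr<KmerIndex> idx(idx_ptr);
  double m = NA_REAL;
  int h = NA_INTEGER;
  if (idx->type() == "bloom") {
    BloomFilter* bf = static_cast<BloomFilter*>(idx.get());
    m = (double)bf->m;
    h = bf->h;
  }
  return List::create(_["type"] = idx->type(), _["k"] = idx->k, _["m"] = m, _["h"] = h,
                      _["n_inserted"] = idx->n_inserted());
}

// [[Rcpp::export]]
LogicalVector cpp_index_contains(SEXP idx_ptr, CharacterVector kmers) {
  XPtr<KmerIndex> idx(idx_ptr);
  const int k = idx->k;
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    SEXP el = STRING_ELT(kmers, i);
    if (el == NA_STRING || LENGTH(el) != k) {
      out[i] = NA_LOGICAL;
      continue;
    }
    u128 fwd, rc;
    if (!encode_kmer(CHAR(el), k, fwd, rc)) {
      out[i] = NA_LOGICAL;  // skip signal: caller discards
      continue;
    }
    out[i] = idx->contains(canon(fwd, rc));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  std::string buf;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    SEXP el = STRING_ELT(kmers, i);
    if (el == NA_STRING) {
      out[i] = NA_STRING;
      continue;
    }
    int k = LENGTH(el);
    if (k < 1 || k > 64) {
      out[i] = NA_STRING;
      continue;
    }
    u128 fwd, rc;
    if (!encode_kmer(CHAR(el), k, fwd, rc)) {
      out[i] = NA_STRING;
      continue;
    }
    u128 c = canon(fwd, rc);
    buf.assign(k, 'A');
    for (int p = k - 1; p >= 0; --p) {
      buf[p] = BITS2BASE[(int)(c & 3)];
      c >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bloom filter (de)serialization: magic, k, h, m, n_inserted, raw bit words.

static const char BF_MAGIC[8] = {'R', 'S', 'T', 'K', 'B', 'F', '0', '1'};

// [[Rcpp::export]]
void cpp_bf_save(SEXP idx_ptr, std::string path) {
  XPtr<KmerIndex> idx(idx_ptr);
  if (idx->type() != "bloom") stop("only Bloom filters can be serialized");
  BloomFilter* bf = static_cast<BloomFilter*>(idx.get());
  std::ofstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  f.write(BF_MAGIC, 8);
  int32_t k = bf->k, h = bf->h;
  uint64_t m = bf->m, n = bf->n_ins;
  f.write((char*)&k, 4);
  f.write((char*)&h, 4);
  f.write((char*)&m, 8);
  f.write((char*)&n, 8);
  f.write((char*)bf->bits.data(), bf->bits.size() * 8);
  if (!f) stop("write failure on '%s'", path.c_str());
}

// [[Rcpp::export]]
SEXP cpp_bf_load(std::string path) {
  std::ifstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s'", path.c_str());
  char magic[8];
  f.read(magic, 8);
  if (!f || std::memcmp(magic, BF_MAGIC, 8) != 0) stop("'%s' is not a Bloom filter file", path.c_str());
  int32_t k, h;
  uint64_t m, n;
  f.read((char*)&k, 4);
  f.read((char*)&h, 4);
  f.read((char*)&m, 8);
  f.read((char*)&n, 8);
  if (!f || k < 2 || k > 64 || h < 1 || m < 8) stop("corrupt Bloom filter header in '%s'", path.c_str());
  BloomFilter* bf = new BloomFilter(m, h, k);
  bf->n_ins = n;
  f.read((char*)bf->bits.data(), bf->bits.size() * 8);
  if (!f) {
    delete bf;
    stop("truncated Bloom filter file '%s'", path.c_str());
  }
  XPtr<KmerIndex> ptr(bf, true);
  return ptr;
}

// ---------------------------------------------------------------------------
// SNV caller: at each reference base, probe the k-mers covering it (anchored
// at the k-mer whose 3'-most base is the position, stepping starts by +j),
// substituting each candidate base, and count membership hits.

struct ProbeResult {
  int n_valid;
  int hits[4];
};

static void probe_position(const char* s, R_xlen_t L, R_xlen_t p, int k, int j,
                           const KmerIndex* idx, ProbeResult& pr) {
  pr.n_valid = 0;
  pr.hits[0] = pr.hits[1] = pr.hits[2] = pr.hits[3] = 0;
  R_xlen_t s0 = p - (R_xlen_t)(k - 1);
  for (R_xlen_t st = s0; st <= p; st += j) {
    if (st < 0 || st + k > L) continue;  // k-mers past contig ends dropped
    u128 fwd, rc;
    if (!encode_kmer(s + st, k, fwd, rc)) continue;  // non-ACGT in window
    ++pr.n_valid;
    int off = (int)(p - st);
    int fshift = 2 * (k - 1 - off);
    int rshift = 2 * off;
    u128 fclear = fwd & ~(((u128)3) << fshift);
    u128 rclear = rc & ~(((u128)3) << rshift);
    for (int b = 0; b < 4; ++b) {
      u128 f = fclear | (((u128)b) << fshift);
      u128 r = rclear | (((u128)(3 - b)) << rshift);
      if (idx->contains(canon(f, r))) ++pr.hits[b];
    }
  }
}

// [[Rcpp::export]]
List cpp_call_snvs(CharacterVector seqs, CharacterVector names, SEXP idx_ptr, int j,
                   double Y, int min_queried) {
  XPtr<KmerIndex> idx(idx_ptr);
  const int k = idx->k;
  if (j < 1 || j > k) stop("j must be in [1, k]");
  if (Y <= 0 || Y > 1) stop("Y must be in (0, 1]");

  std::vector<int> out_contig;
  std::vector<double> out_pos, out_ksf, out_rsf;
  std::vector<int> out_nq;
  std::string out_ref, out_alt;
  double n_skipped = 0;

  ProbeResult pr;
  for (R_xlen_t ci = 0; ci < seqs.size(); ++ci) {
    SEXP el = STRING_ELT(seqs, ci);
    const char* s = CHAR(el);
    R_xlen_t L = LENGTH(el);
    for (R_xlen_t p = 0; p < L; ++p) {
      int rb = base2bits(s[p]);
      if (rb < 0) {
        ++n_skipped;
        continue;
      }
      probe_position(s, L, p, k, j, idx.get(), pr);
      if (pr.n_valid < min_queried) {
        ++n_skipped;
        continue;
      }
      double rsf = (double)pr.hits[rb] / pr.n_valid;
      for (int b = 0; b < 4; ++b) {
        if (b == rb) continue;
        double frac = (double)pr.hits[b] / pr.n_valid;
        if (frac >= Y) {
          out_contig.push_back((int)ci + 1);
          out_pos.push_back((double)(p + 1));
          out_ref.push_back(BITS2BASE[rb]);
          out_alt.push_back(BITS2BASE[b]);
          out_ksf.push_back(frac);
          out_rsf.push_back(rsf);
          out_nq.push_back(pr.n_valid);
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  R_xlen_t n = (R_xlen_t)out_pos.size();
  CharacterVector chrom(n), ref(n), alt(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    chrom[i] = names[out_contig[i] - 1];
    ref[i] = std::string(1, out_ref[i]);
    alt[i] = std::string(1, out_alt[i]);
  }
  return List::create(_["chrom"] = chrom, _["pos"] = NumericVector(out_pos.begin(), out_pos.end()),
                      _["ref"] = ref, _["alt"] = alt,
                      _["ksf"] = NumericVector(out_ksf.begin(), out_ksf.end()),
                      _["rsf"] = NumericVector(out_rsf.begin(), out_rsf.end()),
                      _["nq"] = IntegerVector(out_nq.begin(), out_nq.end()),
                      _["n_skipped"] = n_skipped);
}

// [[Rcpp::export]]
List cpp_evaluate_base(std::string seq, double pos1, std::string base, SEXP idx_ptr, int j) {
  XPtr<KmerIndex> idx(idx_ptr);
  const int k = idx->k;
  if (j < 1 || j > k) stop("j must be in [1, k]");
  R_xlen_t p = (R_xlen_t)pos1 - 1;
  if (p < 0 || p >= (R_xlen_t)seq.size()) stop("position out of contig bounds");
  int b = base.size() == 1 ? base2bits(base[0]) : -1;
  if (b < 0) stop("base must be one of A, C, G, T");
  ProbeResult pr;
  probe_position(seq.c_str(), (R_xlen_t)seq.size(), p, k, j, idx.get(), pr);
  return List::create(_["hits"] = pr.hits[b], _["n_queried"] = pr.n_valid);
}
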
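// Core machinery: 2-bit k-mer packing, canonicalization, minimizer-partitioned
// (k+1)-mer counting, BBHash-style minimal perfect hashing, the per-vertex
// DFA, and the piecewise traversals that extract maximal unitigs / path covers.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>
#include <fstream>

using namespace Rcpp;

// ---------------------------------------------------------------- alphabet

// A=0 < C=1 < G=2 < T=3 so that packed-word comparison is lexicographic.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static inline char code_base(int x) { return "ACGT"[x]; }
static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static std::string rc_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}
static inline std::string canon_str(const std::string& s) {
  std::string r = rc_str(s);
  return (s <= r) ? s : r;
}

// ------------------------------------------------------------- bit packing

// j symbols -> ceil(j/32) 64-bit words, most-significant symbol first; the
// trailing word is left-padded so that word-wise comparison of equal-length
// mers equals lexicographic comparison of the strings.
static inline int words_for(int j) { return (j + 31) / 32; }

static void pack_words(const std::string& s, uint64_t* w) {
  int j = (int)s.size(), nw = words_for(j);
  for (int i = 0; i < nw; ++i) w[i] = 0;
  for (int i = 0; i < j; ++i) {
    int word = i / 32, off = i % 32;
    int c = base_code(s[i]);
    w[word] |= (uint64_t)c << ((31 - off) * 2);
  }
}
static std::string unpack_words(const uint64_t* w, int j) {
  std::string s(j, 'A');
  for (int i = 0; i < j; ++i) {
    int word = i / 32, off = i % 32;
    s[i] = code_base((int)((w[word] >> ((31 - off) * 2)) & 3u));
  }
  return s;
}

// [[Rcpp::export]]
RawVector cpp_pack_mer(std::string s) {
  int j = (int)s.size(), nw = words_for(j);
  for (char c : s)
    if (base_code(c) < 0) stop("non-ACGT symbol in mer");
  std::vector<uint64_t> w(nw);
  pack_words(s, w.data());
  RawVector out(8 * nw);
  std::memcpy(RAW(out), w.data(), 8 * nw);
  return out;
}

// [[Rcpp::export]]
std::string cpp_unpack_mer(RawVector words, int j) {
  int nw = words_for(j);
  if ((int)words.size() != 8 * nw) stop("word count does not match mer length");
  std::vector<uint64_t> w(nw);
  std::memcpy(w.data(), RAW(words), 8 * nw);
  return unpack_words(w.data(), j);
}

// Sign of lexicographic comparison computed purely on packed words.
// [[Rcpp::export]]
int cpp_packed_compare(RawVector a, RawVector b) {
  if (a.size() != b.size()) stop("packed mers must have equal length");
  int nw = (int)a.size() / 8;
  std::vector<uint64_t> wa(nw), wb(nw);
  std::memcpy(wa.data(), RAW(a), 8 * nw);
  std::memcpy(wb.data(), RAW(b), 8 * nw);
  for (int i = 0; i < nw; ++i) {
    if (wa[i] < wb[i]) return -1;
    if (wa[i] > wb[i]) return 1;
  }
  return 0;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    for (char c : s)
      if (base_code(c) < 0) stop("non-ACGT symbol in mer");
    std::string u(s);
    for (auto& c : u) c = code_base(base_code(c));
    out[i] = rc_str(u);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_canonical(CharacterVector x) {
  CharacterVector mer(x.size());
  LogicalVector fwd(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    for (auto& c : s) {
      int b = base_code(c);
      if (b < 0) stop("non-ACGT symbol in mer");
      c = code_base(b);
    }
    std::string r = rc_str(s);
    bool f = (s <= r);
    mer[i] = f ? s : r;
    fwd[i] = f;
  }
  return List::create(_["mer"] = mer, _["forward"] = fwd);
}

// All length-j windows consisting solely of A/C/G/T (case-insensitive);
// any other symbol splits the sequence. 1-based positions.
// [[Rcpp::export]]
List cpp_valid_jmers(std::string seq, int j) {
  std::vector<int> pos;
  std::vector<std::string> mers;
  int n = (int)seq.size();
  int run = 0; // length of current ACGT run ending at i
  std::string up(seq);
  for (auto& c : up) {
    int b = base_code(c);
    c = (b < 0) ? 'N' : code_base(b);
  }
  for (int i = 0; i < n; ++i) {
    run = (up[i] == 'N') ? 0 : run + 1;
    if (run >= j) {
      pos.push_back(i - j + 2); // 1-based start
      mers.push_back(up.substr(i - j + 1, j));
    }
  }
  return List::create(_["position"] = wrap(pos), _["mer"] = wrap(mers));
}

// ----------------------------------------------------- signatures / bins

// Smallest canonical m-mer window of `window` (the adopted signature).
static std::string signature_of(const std::string& window, int m) {
  std::string best;
  for (size_t i = 0; i + m <= window.size(); ++i) {
    std::string c = canon_str(window.substr(i, m));
    if (best.empty() || c < best) best = c;
  }
  return best;
}

// [[Rcpp::export]]
std::string cpp_signature(std::string window, int msig) {
  if (msig <= 0 || (size_t)msig > window.size())
    stop("signature length must be in [1, window length]");
  for (auto& c : window) {
    int b = base_code(c);
    if (b < 0) stop("non-ACGT symbol in window");
    c = code_base(b);
  }
  return signature_of(window, msig);
}

// Deterministic FNV-1a for bin assignment.
static inline uint64_t fnv1a(const std::string& s) {
  uint64_t h = 1469598103934665603ULL;
  for (char c : s) { h ^= (uint64_t)(unsigned char)c; h *= 1099511628211ULL; }
  return h;
}

// Splits the ACGT runs of `seq` into super l-mers: maximal substrings whose
// l-mer windows all share one signature. Emits (bin, substring) pairs.
static void split_region(const std::string& region, int l, int msig, int bins,
                         std::vector<int>& bin_out,
                         std::vector<std::string>& sup_out) {
  int nwin = (int)region.size() - l + 1;
  if (nwin <= 0) return;
  int start = 0;
  std::string cur_sig = signature_of(region.substr(0, l), msig);
  for (int t = 1; t <= nwin; ++t) {
    std::string sig = (t < nwin) ? signature_of(region.substr(t, l), msig) : "";
    if (t == nwin || sig != cur_sig) {
      bin_out.push_back((int)(fnv1a(cur_sig) % (uint64_t)bins));
      sup_out.push_back(region.substr(start, (t - 1) - start + l));
      start = t;
      cur_sig = sig;
    }
  }
}

static std::vector<std::string> acgt_regions(const std::string& seq) {
  std::vector<std::string> out;
  std::string cur;
  for (char c0 : seq) {
    int b = base_code(c0);
    if (b < 0) {
      if (!cur.empty()) { out.push_back(cur); cur.clear(); }
    } else cur.push_back(code_base(b));
  }
  if (!cur.empty()) out.push_back(cur);
  return out;
}

// [[Rcpp::export]]
List cpp_split_super_mers(std::string seq, int l, int msig, int bins) {
  if (msig >= l) msig = l; // clamp; a window is its own only sub-window then
  std::vector<int> bin_out;
  std::vector<std::string> sup_out;
  for (const auto& region : acgt_regions(seq))
    split_region(region, l, msig, bins, bin_out, sup_out);
  return List::create(_["bin"] = wrap(bin_out), _["super_mer"] = wrap(sup_out));
}

// ------------------------------------------------------------ edge counting

// Canonical (k+1)-mers with abundance >= f0, via signature-partitioned
// per-bin sort-and-count. Bin buffers spill to temporary files in `workdir`
// once the in-memory footprint exceeds `budget_bytes`.
// [[Rcpp::export]]
List cpp_enumerate_edges(CharacterVector seqs, int k, int f0, int msig,
                         int bins, double budget_bytes, std::string workdir) {
  const int l = k + 1;
  int ms = std::min(msig, l);
  std::vector<std::vector<std::string>> buf(bins);
  std::vector<bool> spilled(bins, false);
  size_t bytes = 0;

  auto bin_path = [&](int i) {
    return workdir + "/cdbg_bin_" + std::to_string(i) + ".tmp";
  };
  auto flush = [&]() {
    for (int i = 0; i < bins; ++i) {
      if (buf[i].empty()) continue;
      std::ofstream f(bin_path(i), std::ios::app);
      for (const auto& s : buf[i]) f << s << '\n';
      spilled[i] = true;
      buf[i].clear();
      buf[i].shrink_to_fit();
    }
    bytes = 0;
  };

  std::vector<int> bin_ids;
  std::vector<std::string> sups;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string seq = as<std::string>(seqs[si]);
    for (const auto& region : acgt_regions(seq)) {
      bin_ids.clear(); sups.clear();
      split_region(region, l, ms, bins, bin_ids, sups);
      for (size_t i = 0; i < sups.size(); ++i) {
        bytes += sups[i].size() + 32;
        buf[bin_ids[i]].push_back(std::move(sups[i]));
      }
      if (bytes > (size_t)budget_bytes) flush();
    }
  }

  // Per-bin: expand super-mers to canonical l-mer occurrences, sort, count.
  std::vector<std::pair<std::string, int>> result;
  for (int i = 0; i < bins; ++i) {
    std::vector<std::string> occ;
    auto expand = [&](const std::string& sup) {
      for (size_t t = 0; t + l <= sup.size(); ++t)
        occ.push_back(canon_str(sup.substr(t, l)));
    };
    if (spilled[i]) {
      std::ifstream f(bin_path(i));
      std::string line;
      while (std::getline(f, line))
        if (!line.empty()) expand(line);
      f.close();
      std::remove(bin_path(i).c_str());
    }
    for (const auto& s : buf[i]) expand(s);
    buf[i].clear();
    if (occ.empty()) continue;
    std::sort(occ.begin(), occ.end());
    size_t a = 0;
    while (a < occ.size()) {
      size_t b = a;
      while (b < occ.size() && occ[b] == occ[a]) ++b;
      if ((int)(b - a) >= f0) result.emplace_back(occ[a], (int)(b - a));
      a = b;
    }
  }
  std::sort(result.begin(), result.end());
  CharacterVector mers(result.size());
  IntegerVector counts(result.size());
  for (size_t i = 0; i < result.size(); ++i) {
    mers[i] = result[i].first;
    counts[i] = result[i].second;
  }
  return List::create(_["mer"] = mers, _["count"] = counts);
}

// Distinct canonical k-mers occurring as prefix or suffix of the edges.
// [[Rcpp::export]]
CharacterVector cpp_extract_vertices(CharacterVector edges, int k) {
  std::vector<std::string> v;
  v.reserve(2 * edges.size());
  for (R_xlen_t i = 0; i < edges.size(); ++i) {
    std::string e = as<std::string>(edges[i]);
    v.push_back(canon_str(e.substr(0, k)));
    v.push_back(canon_str(e.substr(1, k)));
  }
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  return wrap(v);
}

// ---------------------------------------------------------------- MPHF

// Avalanche mixer (splitmix64 finalizer).
static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
  x ^= x >> 27; x *= 0x94d049bb133111ebULL;
  x ^= x >> 31;
  return x;
}
static inline uint64_t hash_key(const uint64_t* kw, int w, uint64_t level,
                                uint64_t seed) {
  uint64_t h = mix64(seed + 0x9e3779b97f4a7c15ULL * (level + 1));
  for (int i = 0; i < w; ++i) h = mix64(h ^ (kw[i] + 0x9e3779b97f4a7c15ULL * (i + 1)));
  return h;
}

struct Mphf {
  uint64_t n = 0;
  int k = 0, w = 0, max_levels = 0;
  double gamma = 2.0;
  uint64_t seed = 0;
  std::vector<uint64_t> nbits;                 // codomain size per level
  std::vector<std::vector<uint64_t>> A;        // collision-free bit arrays
  std::vector<std::vector<uint64_t>> rankblk;  // cum. popcount per 512-bit block
  std::vector<uint64_t> offset;                // set bits before each level
  std::vector<uint64_t> fb_keys;               // packed fallback keys (sorted)
  uint64_t fb_base = 0;
};

static inline bool get_bit(const std::vector<uint64_t>& a, uint64_t p) {
  return (a[p >> 6] >> (p & 63)) & 1u;
}
static inline void set_bit(std::vector<uint64_t>& a, uint64_t p) {
  a[p >> 6] |= (1ULL << (p & 63));
}

static void build_rank(const std::vector<uint64_t>& a,
                       std::vector<uint64_t>& blk) {
  size_t nblk = (a.size() + 7) / 8;
  blk.assign(nblk, 0);
  uint64_t cum = 0;
  for (size_t b = 0; b < nblk; ++b) {
    blk[b] = cum;
    for (size_t wi = b * 8; wi < std::min(a.size(), (b + 1) * 8); ++wi)
      cum += __builtin_popcountll(a[wi]);
  }
}
static inline uint64_t rank1(const std::vector<uint64_t>& a,
                             const std::vector<uint64_t>& blk, uint64_t p) {
  uint64_t r = blk[p >> 9];
  for (uint64_t wi = (p >> 9) << 3; wi < (p >> 6); ++wi)
    r += __builtin_popcountll(a[wi]);
  r += __builtin_popcountll(a[p >> 6] & ((1ULL << (p & 63)) - 1));
  return r;
}

static int mer_words(int k) { return words_for(k); }

static void pack_key(const std::string& s, uint64_t* out) { pack_words(s, out); }

// [[Rcpp::export]]
SEXP cpp_mphf_build(CharacterVector keys, double gamma, double seed,
                    int max_levels, int k) {
  if (gamma <= 0) stop("gamma must be > 0");
  if (max_levels < 1) stop("max_levels must be >= 1");
  Mphf* h = new Mphf();
  h->n = (uint64_t)keys.size();
  h->k = k;
  h->w = mer_words(k);
  h->gamma = gamma;
  h->seed = (uint64_t)seed;
  h->max_levels = max_levels;
  const int w = h->w;

  std::vector<uint64_t> packed(h->n * w);
  for (uint64_t i = 0; i < h->n; ++i) {
    std::string s = as<std::string>(keys[i]);
    if ((int)s.size() != k) stop("all keys must have length k");
    pack_key(s, &packed[i * w]);
  }
  { // duplicate check
    std::vector<uint64_t> idx(h->n);
    for (uint64_t i = 0; i < h->n; ++i) idx[i] = i;
    auto cmp = [&](uint64_t a, uint64_t b) {
      return std::lexicographical_compare(&packed[a * w], &packed[a * w] + w,
                                          &packed[b * w], &packed[b * w] + w);
    };
    std::sort(idx.begin(), idx.end(), cmp);
    for (uint64_t i = 1; i < h->n; ++i)
      if (std::equal(&packed[idx[i - 1] * w], &packed[idx[i - 1] * w] + w,
                     &packed[idx[i] * w]))
        { delete h; stop("duplicate keys in MPHF build set"); }
  }

  std::vector<uint64_t> cur(h->n);
  for (uint64_t i = 0; i < h->n; ++i) cur[i] = i;
  uint64_t total_set = 0;
  for (int lev = 0; lev < max_levels && !cur.empty(); ++lev) {
    uint64_t sz = (uint64_t)std::ceil(gamma * (double)cur.size());
    if (sz == 0) sz = 1;
    std::vector<uint64_t> occ((sz + 63) / 64, 0), col((sz + 63) / 64, 0);
    for (uint64_t id : cur) {
      uint64_t p = hash_key(&packed[id * w], w, lev, h->seed) % sz;
      if (!get_bit(occ, p)) set_bit(occ, p); else set_bit(col, p);
    }
    std::vector<uint64_t> nxt;
    for (uint64_t id : cur) {
      uint64_t p = hash_key(&packed[id * w], w, lev, h->seed) % sz;
      if (get_bit(col, p)) nxt.push_back(id);
    }
    for (size_t i = 0; i < occ.size(); ++i) occ[i] &= ~col[i];
    h->nbits.push_back(sz);
    h->offset.push_back(total_set);
    std::vector<uint64_t> blk;
    build_rank(occ, blk);
    uint64_t setbits = 0;
    for (uint64_t word : occ) setbits += __builtin_popcountll(word);
    total_set += setbits;
    h->A.push_back(std::move(occ));
    h->rankblk.push_back(std::move(blk));
    cur.swap(nxt);
  }
  // stragglers: exact sorted map
  h->fb_base = total_set;
  if (!cur.empty()) {
    std::sort(cur.begin(), cur.end(), [&](uint64_t a, uint64_t b) {
      return std::lexicographical_compare(&packed[a * w], &packed[a * w] + w,
                                          &packed[b * w], &packed[b * w] + w);
    });
    h->fb_keys.resize(cur.size() * w);
    for (size_t i = 0; i < cur.size(); ++i)
      std::copy(&packed[cur[i] * w], &packed[cur[i] * w] + w,
                &h->fb_keys[i * w]);
  }
  XPtr<Mphf> ptr(h, true);
  return ptr;
}

static uint64_t mphf_query_one(const Mphf* h, const uint64_t* kw, int* levels) {
  for (size_t lev = 0; lev < h->A.size(); ++lev) {
    uint64_t hv = hash_key(kw, h->w, lev, h->seed);
    uint64_t p = hv % h->nbits[lev];
    if (levels) *levels = (int)lev + 1;
    if (get_bit(h->A[lev], p))
      return h->offset[lev] + rank1(h->A[lev], h->rankblk[lev], p);
  }
  // fallback binary search
  size_t nf = h->fb_keys.size() / std::max(1, h->w);
  size_t lo = 0, hi = nf;
  while (lo < hi) {
    size_t mid = (lo + hi) / 2;
    if (std::lexicographical_compare(&h->fb_keys[mid * h->w],
                                     &h->fb_keys[mid * h->w] + h->w, kw,
                                     kw + h->w))
      lo = mid + 1;
    else hi = mid;
  }
  if (lo < nf && std::equal(kw, kw + h->w, &h->fb_keys[lo * h->w]))
    return h->fb_base + lo;
  // alien key: total but unspecified, stay inside [0, n)
  return h->n ? (hash_key(kw, h->w, 0, h->seed) % h->n) : 0;
}

// [[Rcpp::export]]
NumericVector cpp_mphf_query(SEXP hp, CharacterVector keys) {
  XPtr<Mphf> h(hp);
  NumericVector out(keys.size());
  std::vector<uint64_t> kw(h->w);
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    std::string s = as<std::string>(keys[i]);
    if ((int)s.size() != h->k) stop("key length differs from build length");
    pack_key(s, kw.data());
    out[i] = (double)mphf_query_one(h, kw.data(), nullptr);
  }
  return out;
}

// Number of hash levels probed per key (fallback probes count as max+1).
// [[Rcpp::export]]
IntegerVector cpp_mphf_probe_levels(SEXP hp, CharacterVector keys) {
  XPtr<Mphf> h(hp);
  IntegerVector out(keys.size());
  std::vector<uint64_t> kw(h->w);
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    std::string s = as<std::string>(keys[i]);
    pack_key(s, kw.data());
    int lev = (int)h->A.size() + 1;
    uint64_t p = mphf_query_one(h, kw.data(), &lev);
    (void)p;
    out[i] = lev;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_mphf_info(SEXP hp) {
  XPtr<Mphf> h(hp);
  NumericVector lv(h->nbits.size());
  for (size_t i = 0; i < h->nbits.size(); ++i) lv[i] = (double)h->nbits[i];
  double abits = 0, rbits = 0;
  for (size_t i = 0; i < h->A.size(); ++i) {
    abits += (double)h->nbits[i];
    rbits += 64.0 * (double)h->rankblk[i].size();
  }
  double meta = 128.0 * (double)h->A.size() + 320.0;
  double fb = (double)(h->fb_keys.size()) * 64.0 +
              64.0 * (double)(h->fb_keys.size() / std::max(1, h->w));
  return List::create(
      _["n"] = (double)h->n, _["k"] = h->k, _["gamma"] = h->gamma,
      _["seed"] = (double)h->seed, _["max_levels"] = h->max_levels,
      _["n_levels"] = (int)h->A.size(), _["level_bits"] = lv,
      _["n_fallback"] = (double)(h->fb_keys.size() / std::max(1, h->w)),
      _["bits_arrays"] = abits, _["bits_rank"] = rbits,
      _["bits_fallback"] = fb, _["bits_meta"] = meta,
      _["size_bits"] = abits + rbits + fb + meta);
}

static const uint64_t MPHF_MAGIC = 0x4d50484631ULL; // "MPHF1"

// [[Rcpp::export]]
void cpp_mphf_save(SEXP hp, std::string path) {
  XPtr<Mphf> h(hp);
  std::ofstream f(path, std::ios::binary);
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  auto w64 = [&](uint64_t x) { f.write((const char*)&x, 8); };
  w64(MPHF_MAGIC); w64(1); // version
  w64(h->n); w64((uint64_t)h->k); w64((uint64_t)h->w);
  double g = h->gamma; f.write((const char*)&g, 8);
  w64(h->seed); w64((uint64_t)h->max_levels);
  w64((uint64_t)h->A.size());
  for (size_t i = 0; i < h->A.size(); ++i) {
    w64(h->nbits[i]); w64(h->offset[i]); w64((uint64_t)h->A[i].size());
    f.write((const char*)h->A[i].data(), 8 * h->A[i].size());
  }
  w64(h->fb_base);
  w64((uint64_t)h->fb_keys.size());
  f.write((const char*)h->fb_keys.data(), 8 * h->fb_keys.size());
}

// [[Rcpp::export]]
SEXP cpp_mphf_load(std::string path) {
  std::ifstream f(path, std::ios::binary);
  if (!f) stop("cannot open '%s'", path.c_str());
  auto r64 = [&]() { uint64_t x; f.read((char*)&x, 8); return x; };
  if (r64() != MPHF_MAGIC) stop("not a serialized minimal perfect hash");
  if (r64() != 1) stop("unsupported serialization version");
  Mphf* h = new Mphf();
  h->n = r64(); h->k = (int)r64(); h->w = (int)r64();
  f.read((char*)&h->gamma, 8);
  h->seed = r64(); h->max_levels = (int)r64();
  uint64_t nlev = r64();
  for (uint64_t i = 0; i < nlev; ++i) {
    h->nbits.push_back(r64());
    h->offset.push_back(r64());
    uint64_t nw = r64();
    std::vector<uint64_t> a(nw);
    f.read((char*)a.data(), 8 * nw);
    std::vector<uint64_t> blk;
    build_rank(a, blk);
    h->A.push_back(std::move(a));
    h->rankblk.push_back(std::move(blk));
  }
  h->fb_base = r64();
  uint64_t nfk = r64();
  h->fb_keys.resize(nfk);
  f.read((char*)h->fb_keys.data(), 8 * nfk);
  if (!f) { delete h; stop("truncated serialization"); }
  XPtr<Mphf> ptr(h, true);
  return ptr;
}

// ---------------------------------------------------------------- DFA

// Side states: 0 = none, 1 = multi, 2..5 = unique A/C/G/T.
// State code = front * 6 + back, in [0, 36).
static inline int side_transit(int st, int c) {
  if (st == 0) return 2 + c;       // none -> unique_c
  if (st == 1) return 1;           // multi absorbs
  return (st == 2 + c) ? st : 1;   // same symbol self-loop, else multi
}
static inline int state_front(int q) { return q / 6; }
static inline int state_back(int q) { return q % 6; }
static inline int make_state(int f, int b) { return f * 6 + b; }
// side: 0 = front, 1 = back
static inline int apply_input(int q, int side, int c) {
  int f = state_front(q), b = state_back(q);
  if (side == 0) f = side_transit(f, c); else b = side_transit(b, c);
  return make_state(f, b);
}

// [[Rcpp::export]]
int cpp_transit(int q, int side, int sym) {
  if (q < 0 || q > 35) stop("state code must be in [0, 36)");
  if (side != 0 && side != 1) stop("side must be 0 (front) or 1 (back)");
  if (sym < 0 || sym > 3) stop("symbol code must be in [0, 4)");
  return apply_input(q, side, sym);
}

// Per-endpoint DFA inputs of a (k+1)-mer edge. The two incidences are
// invariant under reverse complement, so either orientation may be given;
// they are computed on the canonical form. Returns, for each endpoint: the
// canonical k-mer, the incidence side, and the symbol encoding the edge at
// that side (the form of the edge containing the endpoint's canonical
// k-mer).
// [[Rcpp::export]]
List cpp_edge_inputs(std::string edge, int k) {
  if ((int)edge.size() != k + 1) stop("edge must be a (k+1)-mer");
  for (auto& c : edge) {
    int b = base_code(c);
    if (b < 0) stop("non-ACGT symbol in edge");
    c = code_base(b);
  }
  std::string er = rc_str(edge);
  if (er < edge) edge = er;
  std::string u = edge.substr(0, k), v = edge.substr(1, k);
  std::string ur = rc_str(u), vr = rc_str(v);
  bool u_canon = (u <= ur), v_canon = (v <= vr);
  std::string uhat = u_canon ? u : ur;
  std::string vhat = v_canon ? v : vr;
  // exits u's back iff prefix canonical; enters v's front iff suffix canonical
  int su = u_canon ? 1 : 0;
  int sv = v_canon ? 0 : 1;
  char cu = u_canon ? edge[k] : comp_base(edge[k]);
  char cv = v_canon ? edge[0] : comp_base(edge[0]);
  return List::create(
      _["u"] = List::create(_["vertex"] = uhat, _["side"] = su,
                            _["symbol"] = std::string(1, cu)),
      _["v"] = List::create(_["vertex"] = vhat, _["side"] = sv,
                            _["symbol"] = std::string(1, cv)));
}

struct EdgeInc {
  std::string uhat, vhat;
  int su, sv, cu, cv;
};
static EdgeInc edge_incidence(const std::string& edge, int k) {
  EdgeInc e;
  std::string u = edge.substr(0, k), v = edge.substr(1, k);
  std::string ur = rc_str(u), vr = rc_str(v);
  bool u_canon = (u <= ur), v_canon = (v <= vr);
  e.uhat = u_canon ? u : ur;
  e.vhat = v_canon ? v : vr;
  e.su = u_canon ? 1 : 0;
  e.sv = v_canon ? 0 : 1;
  e.cu = base_code(u_canon ? edge[k] : comp_base(edge[k]));
  e.cv = base_code(v_canon ? edge[0] : comp_base(edge[0]));
  return e;
}

// ------------------------------------------------------- states computation

// Unitig mode: fold every edge's two endpoint inputs into the state table.
// Path-cover mode: examine edges in `order`; admit an edge iff both endpoint
// sides are currently empty (loops never admitted), feeding inputs only for
// admitted edges. States indexed by MPHF value.
// [[Rcpp::export]]
IntegerVector cpp_compute_states(CharacterVector edges, SEXP hp, int k,
                                 bool path_cover, IntegerVector order) {
  XPtr<Mphf> h(hp);
  IntegerVector states((R_xlen_t)h->n);
  std::fill(states.begin(), states.end(), 0);
  std::vector<uint64_t> kw(h->w);
  R_xlen_t m = edges.size();
  for (R_xlen_t t = 0; t < m; ++t) {
    R_xlen_t i = path_cover ? (R_xlen_t)(order[t] - 1) : t;
    std::string edge = as<std::string>(edges[i]);
    EdgeInc e = edge_incidence(edge, k);
    pack_key(e.uhat, kw.data());
    uint64_t hu = mphf_query_one(h, kw.data(), nullptr);
    pack_key(e.vhat, kw.data());
    uint64_t hv = mphf_query_one(h, kw.data(), nullptr);
    if (path_cover) {
      if (e.uhat == e.vhat) continue; // a loop cannot join two paths
      int qu = states[hu], qv = states[hv];
      int stu = (e.su == 0) ? state_front(qu) : state_back(qu);
      int stv = (e.sv == 0) ? state_front(qv) : state_back(qv);
      if (stu != 0 || stv != 0) continue; // a side already occupied
    }
    states[hu] = apply_input(states[hu], e.su, e.cu);
    states[hv] = apply_input(states[hv], e.sv, e.cv);
  }
  return states;
}

// ------------------------------------------------------------- traversal

struct WalkOut {
  std::string spelling;     // observed orientation, starts with the start form
  std::string terminal;     // canonical k-mer where the walk stopped
  int terminal_side;        // side of terminal through which walk would exit
  bool cycle = false;
  std::vector<uint64_t> hashes; // hash of every vertex added beyond the start
};

// Walk out of `start` through side s (0 front / 1 back), following unique
// edges until a flanking condition, a loop, or a full cycle.
static WalkOut walk_unitig(const std::string& start, int s,
                           const IntegerVector& states, const Mphf* h, int k) {
  WalkOut out;
  std::vector<uint64_t> kw(h->w);
  std::string vhat = start;
  std::string cur = (s == 1) ? start : rc_str(start);
  out.spelling = cur;
  while (true) {
    pack_key(vhat, kw.data());
    uint64_t hv = mphf_query_one(h, kw.data(), nullptr);
    int q = states[hv];
    int exit_side = (cur == vhat) ? 1 : 0; // back iff observed form canonical
    int st = (exit_side == 0) ? state_front(q) : state_back(q);
    out.terminal = vhat;
    out.terminal_side = exit_side;
    if (st < 2) break; // none or multi: flanking here
    int c = st - 2;
    char ext = (exit_side == 1) ? code_base(c) : comp_base(code_base(c));
    std::string w = cur.substr(1) + ext;
    std::string wr = rc_str(w);
    std::string what = (w <= wr) ? w : wr;
    if (what == vhat) break;          // loop edge: vertex is flanking
    if (what == start) { out.cycle = true; break; }
    int entr_side = (w == what) ? 0 : 1; // enters front iff observed canonical
    pack_key(what, kw.data());
    uint64_t hw = mphf_query_one(h, kw.data(), nullptr);
    int qw = states[hw];
    int stw = (entr_side == 0) ? state_front(qw) : state_back(qw);
    if (stw < 2) { // neighbor side fuzzy: both are flanking; retract
      break;
    }
    out.spelling.push_back(ext);
    out.hashes.push_back(hw);
    cur = w;
    vhat = what;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_walk_unitig(std::string vhat, int side, IntegerVector states,
                     SEXP hp, int k) {
  XPtr<Mphf> h(hp);
  WalkOut w = walk_unitig(vhat, side, states, h.get(), k);
  return List::create(_["spelling"] = w.spelling, _["terminal"] = w.terminal,
                      _["terminal_side"] = w.terminal_side,
                      _["is_cycle"] = w.cycle);
}

// Canonical presentation of a cyclic spelling: over both orientations and all
// rotations starting at an occurrence of the smallest canonical k-mer, the
// lexicographically least linear spelling (length n + k - 1).
static std::string cycle_canonical(const std::string& s, int k) {
  int n = (int)s.size() - k + 1;
  std::string circ = s.substr(0, n);
  std::string best;
  for (int o = 0; o < 2; ++o) {
    std::string c = (o == 0) ? circ : rc_str(circ);
    std::string d = c + c + c.substr(0, (size_t)std::min((int)c.size(), k));
    std::string minmer;
    std::vector<int> at;
    for (int i = 0; i < n; ++i) {
      std::string cm = canon_str(d.substr(i, k));
      if (minmer.empty() || cm < minmer) { minmer = cm; at.clear(); }
      if (cm == minmer) at.push_back(i);
    }
    for (int i : at) {
      std::string cand = d.substr(i, n + k - 1);
      if (best.empty() || cand < best) best = cand;
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_extract_unitigs(CharacterVector vertices, IntegerVector states,
                         SEXP hp, int k) {
  XPtr<Mphf> h(hp);
  uint64_t n = h->n;
  std::vector<bool> visited(n, false);
  std::vector<uint64_t> kw(h->w);
  std::vector<std::string> spell;
  std::vector<int> vcount;
  std::vector<bool> cyc;
  for (R_xlen_t i = 0; i < vertices.size(); ++i) {
    std::string v = as<std::string>(vertices[i]);
    pack_key(v, kw.data());
    uint64_t hv = mphf_query_one(h, kw.data(), nullptr);
    if (visited[hv]) continue;
    WalkOut wb = walk_unitig(v, 1, states, h.get(), k);
    std::string s;
    bool is_cycle = wb.cycle;
    if (is_cycle) {
      s = cycle_canonical(wb.spelling, k);
    } else {
      WalkOut wf = walk_unitig(v, 0, states, h.get(), k);
      if (wf.cycle) { // cycle reachable only via front (defensive)
        s = cycle_canonical(wf.spelling, k);
        is_cycle = true;
        wb = wf;
      } else {
        std::string left = rc_str(wf.spelling);
        s = left + wb.spelling.substr(k);
        std::string sr = rc_str(s);
        if (sr < s) s = sr;
        for (uint64_t hx : wf.hashes) visited[hx] = true;
      }
    }
    visited[hv] = true;
    for (uint64_t hx : wb.hashes) visited[hx] = true;
    spell.push_back(s);
    vcount.push_back((int)s.size() - k + 1);
    cyc.push_back(is_cycle);
  }
  return List::create(_["spelling"] = wrap(spell),
                      _["vertex_count"] = wrap(vcount),
                      _["is_cycle"] = wrap(cyc));
}
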
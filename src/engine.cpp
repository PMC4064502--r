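// Core simulation engine: bit-packed DNA, K2P mutation, sex-appropriate
// transmission, mating systems, one-generation update, diversity statistics.
//
// DNA layout: 2 bits per site (A=00, C=01, G=10, T=11), 32 sites per 64-bit
// word, site 0 in the lowest bits of word 0 (little-endian site order).
// Words cross the R boundary as raw vectors, 8 bytes per word, little-endian
// byte order, so state files are portable across platforms.
//
// All randomness flows through R's RNG (unif_rand / rbinom), so set.seed()
// at R level fully determines every trajectory and .Random.seed is the
// complete serializable RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <map>
#include <set>
#include <string>

using namespace Rcpp;

static const uint64_t PAIR_MASK = 0x5555555555555555ULL;

static inline int words_for(int L) { return (L + 31) / 32; }

// ---------- raw <-> word conversion (explicit little-endian bytes) ----------

static void bytes_to_words(const Rbyte* b, uint64_t* w, int W) {
  for (int i = 0; i < W; i++) {
    uint64_t v = 0;
    for (int k = 7; k >= 0; k--) v = (v << 8) | (uint64_t)b[i * 8 + k];
    w[i] = v;
  }
}

static void words_to_bytes(const uint64_t* w, Rbyte* b, int W) {
  for (int i = 0; i < W; i++) {
    uint64_t v = w[i];
    for (int k = 0; k < 8; k++) { b[i * 8 + k] = (Rbyte)(v & 0xFF); v >>= 8; }
  }
}

// ---------- sequence primitives ----------

static inline int uidx(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static int hamming_words(const uint64_t* a, const uint64_t* b, int W) {
  int d = 0;
  for (int i = 0; i < W; i++) {
    uint64_t x = a[i] ^ b[i];
    x = (x | (x >> 1)) & PAIR_MASK;
#if defined(__GNUC__) || defined(__clang__)
    d += __builtin_popcountll(x);
#else
    while (x) { d += (int)(x & 1); x >>= 1; }
#endif
  }
  return d;
}

// K2P mutation in place: m ~ Binomial(L, mu) sites hit, positions distinct,
// transition (XOR 0b10) with probability tstv/(tstv+1), else one of the two
// transversions (XOR 0b01 or 0b11) equiprobably. A hit always changes state.
static void mutate_words(uint64_t* w, int L, double mu, double tstv) {
  if (mu <= 0.0) return;
  int m;
  if ((double)L * mu <= 30.0) {
    // exact Binomial(L, mu) by CDF inversion: a single uniform draw almost
    // always resolves to m = 0 at realistic per-locus rates
    double q = 1.0 - mu;
    double pmf = std::pow(q, (double)L);
    double cdf = pmf;
    double u = unif_rand();
    m = 0;
    while (u > cdf && m < L) {
      pmf *= ((double)(L - m) / (double)(m + 1)) * (mu / q);
      cdf += pmf;
      m++;
    }
  } else {
    m = (int)R::rbinom((double)L, mu);
  }
  if (m <= 0) return;
  double p_ts = tstv / (tstv + 1.0);
  if (m > 64) {
    // dense regime: flag-array sampling of distinct positions
    std::vector<char> used(L, 0);
    int placed = 0;
    while (placed < m) {
      int p = uidx(L);
      if (used[p]) continue;
      used[p] = 1; placed++;
      double u = unif_rand();
      uint64_t x = (u < p_ts) ? 2ULL : (u < p_ts + (1.0 - p_ts) * 0.5 ? 1ULL : 3ULL);
      w[p >> 5] ^= (x << ((p & 31) * 2));
    }
  } else {
    int pos[64];
    int placed = 0;
    while (placed < m) {
      int p = uidx(L);
      bool dup = false;
      for (int q = 0; q < placed; q++) if (pos[q] == p) { dup = true; break; }
      if (dup) continue;
      pos[placed++] = p;
      double u = unif_rand();
      uint64_t x = (u < p_ts) ? 2ULL : (u < p_ts + (1.0 - p_ts) * 0.5 ? 1ULL : 3ULL);
      w[p >> 5] ^= (x << ((p & 31) * 2));
    }
  }
}

// ---------- summary statistics on a panel of packed sequences ----------

struct StatRow { int S; double thetaw; double pi; int h; double HA; double HN; };

static StatRow stats_on(const std::vector<const uint64_t*>& s, int n, int L) {
  StatRow r; r.S = 0; r.thetaw = 0; r.pi = 0; r.h = 0; r.HA = 0; r.HN = 0;
  if (n < 1) return r;
  int W = words_for(L);
  // per-site allele counts give S, H_N and (exactly) the mean pairwise
  // difference: unequal pairs at a site = (n^2 - sum c_a^2) / 2
  double hn = 0;
  double unequal2 = 0;  // sum over sites of n^2 - sum c^2
  for (int site = 0; site < L; site++) {
    int word = site >> 5, off = (site & 31) * 2;
    int cnt[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; i++) cnt[(int)((s[i][word] >> off) & 3ULL)]++;
    int alleles = 0; double sq = 0; double c2 = 0;
    for (int a = 0; a < 4; a++) {
      if (cnt[a]) alleles++;
      double q = (double)cnt[a] / n;
      sq += q * q;
      c2 += (double)cnt[a] * cnt[a];
    }
    if (alleles > 1) r.S++;
    hn += 1.0 - sq;
    unequal2 += (double)n * n - c2;
  }
  r.pi = n > 1 ? unequal2 / ((double)n * (n - 1)) : 0.0;
  r.HN = hn / L;
  double an = 0;
  for (int i = 1; i < n; i++) an += 1.0 / i;
  r.thetaw = an > 0 ? (double)r.S / an : 0.0;
  std::map<std::vector<uint64_t>, int> hap;
  for (int i = 0; i < n; i++) hap[std::vector<uint64_t>(s[i], s[i] + W)]++;
  r.h = (int)hap.size();
  double sp2 = 0;
  for (std::map<std::vector<uint64_t>, int>::iterator it = hap.begin(); it != hap.end(); ++it) {
    double p = (double)it->second / n;
    sp2 += p * p;
  }
  r.HA = n > 1 ? ((double)n / (n - 1)) * (1.0 - sp2) : 0.0;
  return r;
}

// ---------- population state ----------

// locus class codes: 0 = autosomal, 1 = X, 2 = Y, 3 = mt
static inline int copies_for(int cls, int sex) { // sex: 1 female, 2 male
  switch (cls) {
    case 0: return 2;
    case 1: return sex == 1 ? 2 : 1;
    case 2: return sex == 1 ? 0 : 1;
    default: return 1;
  }
}

struct LocusDat {
  int cls, index, L, W;
  double mu, tstv;
  std::vector<uint64_t> data; // W words per copy, copies contiguous
  uint64_t* col(int j) { return &data[(size_t)j * W]; }
  const uint64_t* col(int j) const { return &data[(size_t)j * W]; }
};

struct PopDat {
  int generation;
  int next_id;
  std::vector<int> ids, sexes, mid, fid; // mid/fid: -1 for founders
  std::vector<LocusDat> loci;
};

static std::vector<int> class_offsets(const std::vector<int>& sexes, int cls) {
  int n = (int)sexes.size();
  std::vector<int> off(n + 1, 0);
  for (int i = 0; i < n; i++) off[i + 1] = off[i] + copies_for(cls, sexes[i]);
  return off;
}

static PopDat pop_from_list(List pop) {
  PopDat P;
  P.generation = as<int>(pop["generation"]);
  P.next_id = as<int>(pop["next_id"]);
  IntegerVector ids = pop["ids"], sexes = pop["sexes"];
  IntegerVector mid = pop["mother_id"], fid = pop["father_id"];
  int n = ids.size();
  P.ids.assign(ids.begin(), ids.end());
  P.sexes.assign(sexes.begin(), sexes.end());
  P.mid.resize(n); P.fid.resize(n);
  for (int i = 0; i < n; i++) {
    P.mid[i] = (mid[i] == NA_INTEGER) ? -1 : mid[i];
    P.fid[i] = (fid[i] == NA_INTEGER) ? -1 : fid[i];
  }
  List loci = pop["loci"];
  for (int k = 0; k < loci.size(); k++) {
    List lk = loci[k];
    LocusDat d;
    d.cls = as<int>(lk["class_code"]);
    d.index = as<int>(lk["index"]);
    d.L = as<int>(lk["length"]);
    d.W = words_for(d.L);
    d.mu = as<double>(lk["mu"]);
    d.tstv = as<double>(lk["tstv"]);
    RawMatrix seq = lk["seq"];
    if (seq.nrow() != d.W * 8) stop("locus %d: raw matrix has wrong row count", k + 1);
    int nc = seq.ncol();
    d.data.resize((size_t)d.W * nc);
    for (int j = 0; j < nc; j++) bytes_to_words(&seq[(size_t)j * seq.nrow()], d.col(j), d.W);
    P.loci.push_back(d);
  }
  return P;
}

static List pop_to_list(const PopDat& P) {
  int n = (int)P.ids.size();
  IntegerVector mid(n), fid(n);
  for (int i = 0; i < n; i++) {
    mid[i] = P.mid[i] < 0 ? NA_INTEGER : P.mid[i];
    fid[i] = P.fid[i] < 0 ? NA_INTEGER : P.fid[i];
  }
  List loci(P.loci.size());
  CharacterVector cls_names = CharacterVector::create("autosomal", "x", "y", "mt");
  for (size_t k = 0; k < P.loci.size(); k++) {
    const LocusDat& d = P.loci[k];
    int nc = (int)(d.data.size() / d.W);
    RawMatrix seq(d.W * 8, nc);
    for (int j = 0; j < nc; j++) words_to_bytes(d.col(j), &seq[(size_t)j * seq.nrow()], d.W);
    loci[k] = List::create(
      _["class"] = as<std::string>(cls_names[d.cls]),
      _["class_code"] = d.cls,
      _["index"] = d.index,
      _["length"] = d.L,
      _["mu"] = d.mu,
      _["tstv"] = d.tstv,
      _["seq"] = seq);
  }
  List out = List::create(
    _["generation"] = P.generation,
    _["next_id"] = P.next_id,
    _["ids"] = IntegerVector(P.ids.begin(), P.ids.end()),
    _["sexes"] = IntegerVector(P.sexes.begin(), P.sexes.end()),
    _["mother_id"] = mid,
    _["father_id"] = fid,
    _["loci"] = loci);
  return out;
}

// ---------- mating ----------

// system codes: 1 monogamy, 2 polygamy, 3 polygyny, 4 polyandry
struct MatingDat {
  int system;
  bool avoid;
  int max_rej;
};

struct Unions {
  // monogamy: pf[k]/pm[k] adult indices of pair k
  std::vector<int> pf, pm;
  // polygyny: husband[j] = adult index of female j's husband (j indexes fem)
  // polyandry: wife[j] = adult index of male j's wife (j indexes mal)
  std::vector<int> spouse;
};

static void shuffle_idx(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; i--) {
    int j = uidx(i + 1);
    std::swap(v[i], v[j]);
  }
}

static Unions form_unions_c(const std::vector<int>& fem, const std::vector<int>& mal,
                            const MatingDat& M) {
  Unions U;
  int nf = (int)fem.size(), nm = (int)mal.size();
  if (M.system == 1) { // monogamy: random perfect matching of min(nf, nm)
    std::vector<int> sf = fem, sm = mal;
    shuffle_idx(sf); shuffle_idx(sm);
    int k = nf < nm ? nf : nm;
    U.pf.assign(sf.begin(), sf.begin() + k);
    U.pm.assign(sm.begin(), sm.begin() + k);
  } else if (M.system == 3) { // polygyny: each female a uniform husband
    U.spouse.resize(nf);
    for (int j = 0; j < nf; j++) U.spouse[j] = mal[uidx(nm)];
  } else if (M.system == 4) { // polyandry: each male a uniform wife
    U.spouse.resize(nm);
    for (int j = 0; j < nm; j++) U.spouse[j] = fem[uidx(nf)];
  }
  return U;
}

static inline bool siblings_c(int am, int af, int bm, int bf) {
  return (am >= 0 && am == bm) || (af >= 0 && af == bf);
}

static void draw_pair_c(const PopDat& P, const Unions& U,
                        const std::vector<int>& fem, const std::vector<int>& mal,
                        const MatingDat& M, int& mo, int& fa) {
  int nf = (int)fem.size(), nm = (int)mal.size();
  for (int t = 0; t < M.max_rej; t++) {
    if (M.system == 1) {
      int k = uidx((int)U.pf.size());
      mo = U.pf[k]; fa = U.pm[k];
    } else if (M.system == 3) {
      int j = uidx(nf);
      mo = fem[j]; fa = U.spouse[j];
    } else if (M.system == 4) {
      int j = uidx(nm);
      fa = mal[j]; mo = U.spouse[j];
    } else {
      mo = fem[uidx(nf)]; fa = mal[uidx(nm)];
    }
    if (!M.avoid || !siblings_c(P.mid[mo], P.fid[mo], P.mid[fa], P.fid[fa])) return;
  }
  stop("no valid non-sibling parent pair after %d rejections at generation %d",
       M.max_rej, P.generation);
}

static MatingDat mating_from_list(List m) {
  MatingDat M;
  M.system = as<int>(m["system_code"]);
  M.avoid = as<bool>(m["avoid_siblings"]);
  M.max_rej = as<int>(m["max_rejections"]);
  return M;
}

// ---------- one generation ----------

static void step_once(PopDat& P, int Nnext, const MatingDat& M, double mu_mult) {
  int N = (int)P.ids.size();
  if (Nnext < 2) stop("population size below 2 at generation %d", P.generation + 1);
  std::vector<int> fem, mal;
  for (int i = 0; i < N; i++) (P.sexes[i] == 1 ? fem : mal).push_back(i);
  if (fem.empty() || mal.empty())
    stop("a sex class is empty at generation %d", P.generation);
  Unions U = form_unions_c(fem, mal, M);

  // offspring sexes: i.i.d. Bernoulli(1/2), whole-vector redraw until mixed
  std::vector<int> csex(Nnext);
  for (;;) {
    int cf = 0;
    for (int i = 0; i < Nnext; i++) {
      csex[i] = unif_rand() < 0.5 ? 1 : 2;
      if (csex[i] == 1) cf++;
    }
    if (cf > 0 && cf < Nnext) break;
  }

  // parent assignment
  std::vector<int> cmo(Nnext), cfa(Nnext);
  for (int i = 0; i < Nnext; i++) draw_pair_c(P, U, fem, mal, M, cmo[i], cfa[i]);

  // transmission per locus
  std::vector<LocusDat> newloci(P.loci.size());
  for (size_t k = 0; k < P.loci.size(); k++) {
    const LocusDat& d = P.loci[k];
    LocusDat nd;
    nd.cls = d.cls; nd.index = d.index; nd.L = d.L; nd.W = d.W;
    nd.mu = d.mu; nd.tstv = d.tstv;
    std::vector<int> ooff = class_offsets(P.sexes, d.cls);
    std::vector<int> noff = class_offsets(csex, d.cls);
    nd.data.assign((size_t)nd.W * noff[Nnext], 0ULL);
    double mu = d.mu * mu_mult;
    size_t wb = (size_t)d.W * sizeof(uint64_t);
    for (int c = 0; c < Nnext; c++) {
      int mo = cmo[c], fa = cfa[c];
      switch (d.cls) {
        case 0: { // autosomal: one uniform copy from each parent
          std::memcpy(nd.col(noff[c]), d.col(ooff[mo] + (unif_rand() < 0.5 ? 0 : 1)), wb);
          mutate_words(nd.col(noff[c]), d.L, mu, d.tstv);
          std::memcpy(nd.col(noff[c] + 1), d.col(ooff[fa] + (unif_rand() < 0.5 ? 0 : 1)), wb);
          mutate_words(nd.col(noff[c] + 1), d.L, mu, d.tstv);
          break;
        }
        case 1: { // X: maternal X always; paternal X only to daughters
          std::memcpy(nd.col(noff[c]), d.col(ooff[mo] + (unif_rand() < 0.5 ? 0 : 1)), wb);
          mutate_words(nd.col(noff[c]), d.L, mu, d.tstv);
          if (csex[c] == 1) {
            std::memcpy(nd.col(noff[c] + 1), d.col(ooff[fa]), wb);
            mutate_words(nd.col(noff[c] + 1), d.L, mu, d.tstv);
          }
          break;
        }
        case 2: { // Y: father to son only
          if (csex[c] == 2) {
            std::memcpy(nd.col(noff[c]), d.col(ooff[fa]), wb);
            mutate_words(nd.col(noff[c]), d.L, mu, d.tstv);
          }
          break;
        }
        default: { // mtDNA: mother to every child
          std::memcpy(nd.col(noff[c]), d.col(ooff[mo]), wb);
          mutate_words(nd.col(noff[c]), d.L, mu, d.tstv);
          break;
        }
      }
    }
    newloci[k] = nd;
  }

  // replace generation wholesale
  std::vector<int> nids(Nnext), nmid(Nnext), nfid(Nnext);
  for (int c = 0; c < Nnext; c++) {
    nids[c] = P.next_id++;
    nmid[c] = P.ids[cmo[c]];
    nfid[c] = P.ids[cfa[c]];
  }
  P.ids.swap(nids);
  P.sexes.swap(csex);
  P.mid.swap(nmid);
  P.fid.swap(nfid);
  P.loci.swap(newloci);
  P.generation++;
}

// whole-deme mean per-locus pi over all loci of one class
static double deme_pi(const PopDat& P, int cls) {
  double tot = 0; int nl = 0;
  for (size_t k = 0; k < P.loci.size(); k++) {
    const LocusDat& d = P.loci[k];
    if (d.cls != cls) continue;
    int nc = (int)(d.data.size() / d.W);
    std::vector<const uint64_t*> s(nc);
    for (int j = 0; j < nc; j++) s[j] = d.col(j);
    StatRow r = stats_on(s, nc, d.L);
    tot += r.pi; nl++;
  }
  if (nl == 0) stop("no locus of the requested class");
  return tot / nl;
}

// ---------- exported engine entry points ----------

struct StatsAcc {
  std::vector<int> generation, class_code, locus_index, n, L, S, h;
  std::vector<double> thetaw, pi, HA, HN;
  void record(const PopDat& P) {
    for (size_t k = 0; k < P.loci.size(); k++) {
      const LocusDat& d = P.loci[k];
      int nc = (int)(d.data.size() / d.W);
      std::vector<const uint64_t*> s(nc);
      for (int j = 0; j < nc; j++) s[j] = d.col(j);
      generation.push_back(P.generation);
      class_code.push_back(d.cls);
      locus_index.push_back(d.index);
      n.push_back(nc);
      L.push_back(d.L);
      if (nc >= 2) {
        StatRow r = stats_on(s, nc, d.L);
        S.push_back(r.S); thetaw.push_back(r.thetaw); pi.push_back(r.pi);
        h.push_back(r.h); HA.push_back(r.HA); HN.push_back(r.HN);
      } else {
        S.push_back(NA_INTEGER); thetaw.push_back(NA_REAL); pi.push_back(NA_REAL);
        h.push_back(NA_INTEGER); HA.push_back(NA_REAL); HN.push_back(NA_REAL);
      }
    }
  }
  List to_list() const {
    return List::create(
      _["generation"] = wrap(generation), _["class_code"] = wrap(class_code),
      _["locus_index"] = wrap(locus_index), _["n"] = wrap(n), _["L"] = wrap(L),
      _["S"] = wrap(S), _["theta_w"] = wrap(thetaw), _["pi"] = wrap(pi),
      _["h"] = wrap(h), _["H_A"] = wrap(HA), _["H_N"] = wrap(HN));
  }
};

// [[Rcpp::export]]
List cpp_engine_run(List pop, IntegerVector sizes, IntegerVector record_at,
                    List mating, double mu_mult) {
  PopDat P = pop_from_list(pop);
  MatingDat M = mating_from_list(mating);
  std::set<int> rec(record_at.begin(), record_at.end());
  StatsAcc acc;
  if (rec.count(P.generation)) acc.record(P);
  for (int k = 0; k < sizes.size(); k++) {
    step_once(P, sizes[k], M, mu_mult);
    if (rec.count(P.generation)) acc.record(P);
    if ((k & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["pop"] = pop_to_list(P), _["stats"] = acc.to_list());
}

// [[Rcpp::export]]
List cpp_engine_buffer(List pop, double target_pi, double boost, int class_code,
                       int max_gens, List mating) {
  PopDat P = pop_from_list(pop);
  MatingDat M = mating_from_list(mating);
  int N = (int)P.ids.size();
  std::vector<double> traj;
  double pi = deme_pi(P, class_code);
  traj.push_back(pi);
  bool reached = pi >= target_pi;
  int used = 0;
  while (!reached && used < max_gens) {
    step_once(P, N, M, boost);
    used++;
    pi = deme_pi(P, class_code);
    traj.push_back(pi);
    reached = pi >= target_pi;
    if ((used & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["pop"] = pop_to_list(P),
    _["reached"] = reached,
    _["achieved_pi"] = pi,
    _["generations_used"] = used,
    _["trajectory"] = wrap(traj));
}

// [[Rcpp::export]]
double cpp_deme_pi(List pop, int class_code) {
  PopDat P = pop_from_list(pop);
  return deme_pi(P, class_code);
}

// ---------- exported sequence primitives ----------

// [[Rcpp::export]]
RawVector cpp_encode(std::string dna) {
  int L = (int)dna.size();
  if (L < 1) stop("empty sequence");
  int W = words_for(L);
  std::vector<uint64_t> w(W, 0ULL);
  for (int i = 0; i < L; i++) {
    uint64_t code;
    switch (dna[i]) {
      case 'A': code = 0; break;
      case 'C': code = 1; break;
      case 'G': code = 2; break;
      case 'T': code = 3; break;
      default: stop("invalid character '%c' at position %d: alphabet is ACGT", dna[i], i + 1);
    }
    w[i >> 5] |= code << ((i & 31) * 2);
  }
  RawVector out(W * 8);
  words_to_bytes(w.data(), &out[0], W);
  return out;
}

// [[Rcpp::export]]
std::string cpp_decode(RawVector words, int L) {
  int W = words_for(L);
  if ((int)words.size() != W * 8) stop("word storage does not match length %d", L);
  std::vector<uint64_t> w(W);
  bytes_to_words(&words[0], w.data(), W);
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string s(L, 'A');
  for (int i = 0; i < L; i++) s[i] = B[(w[i >> 5] >> ((i & 31) * 2)) & 3ULL];
  return s;
}

// [[Rcpp::export]]
int cpp_hamming(RawVector a, RawVector b, int L) {
  int W = words_for(L);
  if ((int)a.size() != W * 8 || (int)b.size() != W * 8)
    stop("sequence storage does not match length %d", L);
  std::vector<uint64_t> wa(W), wb(W);
  bytes_to_words(&a[0], wa.data(), W);
  bytes_to_words(&b[0], wb.data(), W);
  return hamming_words(wa.data(), wb.data(), W);
}

// [[Rcpp::export]]
RawVector cpp_mutate(RawVector seq, int L, double mu, double tstv) {
  int W = words_for(L);
  if ((int)seq.size() != W * 8) stop("sequence storage does not match length %d", L);
  std::vector<uint64_t> w(W);
  bytes_to_words(&seq[0], w.data(), W);
  mutate_words(w.data(), L, mu, tstv);
  RawVector out(W * 8);
  words_to_bytes(w.data(), &out[0], W);
  return out;
}

// [[Rcpp::export]]
List cpp_panel_stats(RawMatrix seq, int L, IntegerVector cols) {
  int W = words_for(L);
  if (seq.nrow() != W * 8) stop("panel storage does not match length %d", L);
  int n = cols.size();
  std::vector<std::vector<uint64_t> > store(n, std::vector<uint64_t>(W));
  std::vector<const uint64_t*> s(n);
  for (int i = 0; i < n; i++) {
    int j = cols[i] - 1;
    if (j < 0 || j >= seq.ncol()) stop("column index out of range");
    bytes_to_words(&seq[(size_t)j * seq.nrow()], store[i].data(), W);
    s[i] = store[i].data();
  }
  StatRow r = stats_on(s, n, L);
  return List::create(
    _["S"] = r.S, _["theta_w"] = r.thetaw, _["pi"] = r.pi,
    _["h"] = r.h, _["H_A"] = r.HA, _["H_N"] = r.HN);
}

// FNV-1a 64-bit checksum, hex string (state-file integrity)
// [[Rcpp::export]]
std::string cpp_fnv1a(RawVector x) {
  uint64_t h = 1469598103934665603ULL;
  for (int i = 0; i < x.size(); i++) {
    h ^= (uint64_t)x[i];
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
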
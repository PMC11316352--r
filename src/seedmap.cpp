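#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode; -1 for anything outside A/C/G/T (N breaks seeds and never
// matches during extension, which is how masked positions are excluded).
static inline int code_of(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void build_index(const std::string& ref, int k, KmerIndex& idx) {
  const int n = (int)ref.size();
  if (n < k) return;
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;  // length of current valid suffix
  for (int i = 0; i < n; ++i) {
    int c = code_of(ref[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[key].push_back(i - k + 1);
  }
}

struct Hit { int start; int strand; };  // strand: 0 = '+', 1 = '-'

static void collect_candidates(const std::string& q, int strand, int k,
                               const KmerIndex& idx, std::vector<Hit>& out) {
  const int n = (int)q.size();
  if (n < k) return;
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = code_of(q[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      KmerIndex::const_iterator it = idx.find(key);
      if (it != idx.end()) {
        int off = i - k + 1;
        for (int p : it->second) out.push_back({p - off, strand});
      }
    }
  }
}

// Count matches of q placed at `start` on ref (ungapped, full q length).
static inline int count_matches(const std::string& q, const std::string& ref,
                                int start) {
  const int n = (int)q.size(), rn = (int)ref.size();
  int lo = std::max(0, -start), hi = std::min(n, rn - start);
  int m = 0;
  for (int i = lo; i < hi; ++i) {
    int a = code_of(q[i]), b = code_of(ref[start + i]);
    if (a >= 0 && a == b) ++m;
  }
  return m;
}

// Place each query on ref by exact k-mer seeding + ungapped extension over
// the full query. Best placement by matches/alen (cross-multiplied exact
// comparison); ties resolved to the leftmost start, '+' before '-'.
// If full_query is true the alignment length is the full query length
// (overhangs count as mismatches: the fragment-ANI convention); otherwise
// the alignment is clipped to the reference (the read-mapping convention).
// [[Rcpp::export]]
DataFrame cpp_seed_extend(CharacterVector queries, std::string ref, int k,
                          bool full_query) {
  KmerIndex idx;
  build_index(ref, k, idx);
  const int nq = queries.size(), rn = (int)ref.size();
  IntegerVector start(nq), alen(nq), matches(nq);
  CharacterVector strand(nq);
  LogicalVector placed(nq);
  std::vector<Hit> cand;
  for (int qi = 0; qi < nq; ++qi) {
    std::string fwd = as<std::string>(queries[qi]);
    std::string rev = revcomp(fwd);
    cand.clear();
    collect_candidates(fwd, 0, k, idx, cand);
    collect_candidates(rev, 1, k, idx, cand);
    std::sort(cand.begin(), cand.end(), [](const Hit& a, const Hit& b) {
      return a.start != b.start ? a.start < b.start : a.strand < b.strand;
    });
    cand.erase(std::unique(cand.begin(), cand.end(),
                           [](const Hit& a, const Hit& b) {
                             return a.start == b.start && a.strand == b.strand;
                           }),
               cand.end());
    const int n = (int)fwd.size();
    long best_m = -1, best_a = 1;
    int best_start = NA_INTEGER, best_strand = 0, best_alen = 0;
    for (const Hit& h : cand) {
      const std::string& q = h.strand == 0 ? fwd : rev;
      int m = count_matches(q, ref, h.start);
      int lo = std::max(0, -h.start), hi = std::min(n, rn - h.start);
      int a = full_query ? n : std::max(0, hi - lo);
      if (a <= 0) continue;
      // better identity wins; candidates are pre-sorted so first best stays
      if (best_m < 0 || (long)m * best_a > best_m * (long)a) {
        best_m = m; best_a = a;
        best_alen = a;
        best_start = full_query ? h.start : h.start + lo;
        best_strand = h.strand;
      }
    }
    if (best_m < 0) {
      placed[qi] = false;
      start[qi] = NA_INTEGER; alen[qi] = 0; matches[qi] = 0;
      strand[qi] = NA_STRING;
    } else {
      placed[qi] = true;
      start[qi] = best_start; alen[qi] = best_alen;
      matches[qi] = (int)best_m;
      strand[qi] = best_strand == 0 ? "+" : "-";
    }
  }
  return DataFrame::create(_["placed"] = placed, _["start"] = start,
                           _["strand"] = strand, _["alen"] = alen,
                           _["matches"] = matches,
                           _["stringsAsFactors"] = false);
}

// Per-base substitution errors at `rate`, using R's RNG stream so that
// set.seed() governs reproducibility. Returns mutated sequences and the
// per-sequence substitution count.
// [[Rcpp::export]]
List cpp_inject_errors(CharacterVector seqs, double rate) {
  const char* bases = "ACGT";
  int n = seqs.size();
  CharacterVector out(n);
  IntegerVector nsub(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int cnt = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      int c = code_of(s[j]);
      if (c < 0) continue;
      if (unif_rand() < rate) {
        int repl = (c + 1 + (int)(unif_rand() * 3)) & 3;
        s[j] = bases[repl];
        ++cnt;
      }
    }
    out[i] = s;
    nsub[i] = cnt;
  }
  return List::create(_["seq"] = out, _["n_sub"] = nsub);
}
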
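#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <string>
#include <vector>
using namespace Rcpp;

// Hamming distance of q against t at offset `off`, capped at max_mm.
// Returns -1 when the cap is exceeded.
static inline int mm_at(const std::string& q, const std::string& t,
                        int off, int max_mm) {
  int mm = 0;
  const int n = (int) q.size();
  for (int p = 0; p < n; ++p) {
    if (q[p] != t[off + p]) {
      if (++mm > max_mm) return -1;
    }
  }
  return mm;
}

typedef std::unordered_map<std::string,
                           std::vector<std::pair<int, int> > > KmerIndex;

static KmerIndex build_kmer_index(const std::vector<std::string>& tg, int k) {
  KmerIndex idx;
  for (int t = 0; t < (int) tg.size(); ++t) {
    const std::string& s = tg[t];
    for (int p = 0; p + k <= (int) s.size(); ++p)
      idx[s.substr(p, k)].push_back(std::make_pair(t, p));
  }
  return idx;
}

// Candidate (target, offset) placements of `q` seeded by exact k-mers.
static void candidates(const std::string& q,
                       const std::vector<std::string>& tg,
                       const KmerIndex& idx, int k,
                       std::set<std::pair<int, int> >& cand) {
  for (int p = 0; p + k <= (int) q.size(); ++p) {
    KmerIndex::const_iterator it = idx.find(q.substr(p, k));
    if (it == idx.end()) continue;
    for (size_t c = 0; c < it->second.size(); ++c) {
      int t = it->second[c].first;
      int off = it->second[c].second - p;
      if (off >= 0 && off + (int) q.size() <= (int) tg[t].size())
        cand.insert(std::make_pair(t, off));
    }
  }
}

// All substring placements of each query inside any target with at most
// max_mm mismatches, found by exact k-mer seeding + verification.
// Returns, per query, an integer matrix with columns target/offset/mismatches
// (1-based target index and offset).
// [[Rcpp::export]]
List kmer_match_all_cpp(CharacterVector queries, CharacterVector targets,
                        int k, int max_mm) {
  const int nt = targets.size(), nq = queries.size();
  std::vector<std::string> tg(nt);
  for (int i = 0; i < nt; ++i) tg[i] = as<std::string>(targets[i]);
  KmerIndex idx = build_kmer_index(tg, k);
  List out(nq);
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    std::set<std::pair<int, int> > cand;
    if ((int) q.size() >= k) candidates(q, tg, idx, k, cand);
    std::vector<int> ht, ho, hm;
    for (std::set<std::pair<int, int> >::iterator it = cand.begin();
         it != cand.end(); ++it) {
      int mm = mm_at(q, tg[it->first], it->second, max_mm);
      if (mm >= 0) {
        ht.push_back(it->first + 1);
        ho.push_back(it->second + 1);
        hm.push_back(mm);
      }
    }
    IntegerMatrix hits(ht.size(), 3);
    for (size_t r = 0; r < ht.size(); ++r) {
      hits(r, 0) = ht[r]; hits(r, 1) = ho[r]; hits(r, 2) = hm[r];
    }
    colnames(hits) = CharacterVector::create("target", "offset", "mismatches");
    out[qi] = hits;
  }
  return out;
}

// Best hit per query: fewest mismatches, ties broken by lowest target index
// (callers sort targets lexicographically by id). target 0 = no hit.
// [[Rcpp::export]]
List kmer_match_best_cpp(CharacterVector queries, CharacterVector targets,
                         int k, int max_mm) {
  const int nt = targets.size(), nq = queries.size();
  std::vector<std::string> tg(nt);
  for (int i = 0; i < nt; ++i) tg[i] = as<std::string>(targets[i]);
  KmerIndex idx = build_kmer_index(tg, k);
  IntegerVector best(nq, 0), bmm(nq, NA_INTEGER);
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    std::set<std::pair<int, int> > cand;
    if ((int) q.size() >= k) candidates(q, tg, idx, k, cand);
    int bt = 0, bm = max_mm + 1;
    for (std::set<std::pair<int, int> >::iterator it = cand.begin();
         it != cand.end(); ++it) {
      int mm = mm_at(q, tg[it->first], it->second, max_mm);
      if (mm < 0) continue;
      int t1 = it->first + 1;
      if (mm < bm || (mm == bm && (bt == 0 || t1 < bt))) {
        bm = mm; bt = t1;
      }
    }
    if (bt > 0) { best[qi] = bt; bmm[qi] = bm; }
  }
  return List::create(_["target"] = best, _["mismatches"] = bmm);
}

// Leftmost 3' adapter occurrence per read. The adapter may run off the 3'
// end (suffix overlap); an occurrence at offset i needs overlap >= min_overlap
// and mismatches <= floor(max_mm_rate * overlap). Returns the 0-based offset
// (= insert length), or -1 when no occurrence qualifies.
// [[Rcpp::export]]
IntegerVector adapter_offsets_cpp(CharacterVector reads, std::string adapter,
                                  int min_overlap, double max_mm_rate) {
  const int nr = reads.size(), alen = (int) adapter.size();
  IntegerVector out(nr, -1);
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(reads[r]);
    const int rlen = (int) s.size();
    for (int i = 0; i + min_overlap <= rlen; ++i) {
      int overlap = std::min(alen, rlen - i);
      int allowed = (int) std::floor(max_mm_rate * overlap);
      int mm = 0;
      bool ok = true;
      for (int p = 0; p < overlap; ++p) {
        if (s[i + p] != adapter[p]) {
          if (++mm > allowed) { ok = false; break; }
        }
      }
      if (ok) { out[r] = i; break; }
    }
  }
  return out;
}
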
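#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Exact k-mer lookup index over the forward strand of a concatenated genome.
// Reverse-strand hits are found by aligning the reverse complement of the
// read, so the index itself is single-stranded.
struct MiniIndex {
  std::string seq;                      // concatenated chroms, '|' separators
  std::vector<long> offset;             // start of each chrom in seq
  std::vector<int>  clen;
  std::vector<std::string> names;
  std::vector<int>  lexrank;            // lexicographic rank of chrom i
  int k;
  std::unordered_map<uint32_t, std::vector<long> > kmers;
};

static inline int base2code(char c) {
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
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector chrom_names, CharacterVector chrom_seqs,
                     int seed_length) {
  if (seed_length < 1 || seed_length > 15)
    stop("seed_length must be in [1, 15]");
  MiniIndex* idx = new MiniIndex();
  idx->k = seed_length;
  long total = 0;
  for (int i = 0; i < chrom_seqs.size(); ++i)
    total += LENGTH(STRING_ELT(chrom_seqs, i)) + 1;
  idx->seq.reserve(total);
  for (int i = 0; i < chrom_names.size(); ++i) {
    idx->offset.push_back((long) idx->seq.size());
    std::string s = as<std::string>(chrom_seqs[i]);
    if ((int) s.size() < seed_length) {
      delete idx;
      stop("chromosome '%s' is shorter than seed_length",
           as<std::string>(chrom_names[i]).c_str());
    }
    idx->clen.push_back((int) s.size());
    idx->names.push_back(as<std::string>(chrom_names[i]));
    idx->seq += s;
    idx->seq += '|';
  }
  // lexicographic rank of chrom names (canonical record ordering)
  std::vector<int> ord(idx->names.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int) i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return idx->names[a] < idx->names[b];
  });
  idx->lexrank.resize(ord.size());
  for (size_t r = 0; r < ord.size(); ++r) idx->lexrank[ord[r]] = (int) r;

  const int k = idx->k;
  const std::string& g = idx->seq;
  uint32_t key = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  int run = 0;  // length of current valid (ACGT) run ending at i
  for (long i = 0; i < (long) g.size(); ++i) {
    int c = base2code(g[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t) c) & mask;
    if (++run >= k) idx->kmers[key].push_back(i - k + 1);
  }
  XPtr<MiniIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<MiniIndex> idx(xp);
  return List::create(_["chrom"] = wrap(idx->names),
                      _["length"] = wrap(idx->clen),
                      _["seed_length"] = idx->k);
}

// Positions (0-based, per chrom) of exact occurrences of a k-mer on the
// forward strand. Used by the index contract tests.
// [[Rcpp::export]]
DataFrame cpp_index_query(SEXP xp, std::string kmer) {
  XPtr<MiniIndex> idx(xp);
  if ((int) kmer.size() != idx->k) stop("query length must equal seed_length");
  uint32_t key = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int c = base2code(kmer[i]);
    if (c < 0) stop("query contains a non-ACGT base");
    key = (key << 2) | (uint32_t) c;
  }
  std::vector<int> ci; std::vector<int> pos;
  std::unordered_map<uint32_t, std::vector<long> >::const_iterator it =
    idx->kmers.find(key);
  if (it != idx->kmers.end()) {
    for (size_t j = 0; j < it->second.size(); ++j) {
      long p = it->second[j];
      // locate chrom
      int lo = 0, hi = (int) idx->offset.size() - 1;
      while (lo < hi) {
        int mid = (lo + hi + 1) / 2;
        if (idx->offset[mid] <= p) lo = mid; else hi = mid - 1;
      }
      ci.push_back(lo + 1);
      pos.push_back((int) (p - idx->offset[lo]));
    }
  }
  return DataFrame::create(_["chrom_idx"] = wrap(ci), _["start"] = wrap(pos));
}

struct Hit { int chrom; int start; char strand; int mm; };

static void verify_candidates(const MiniIndex* idx, const std::string& q,
                              char strand, int v,
                              const std::vector<long>& starts,
                              std::vector<Hit>& out) {
  const std::string& g = idx->seq;
  const int L = (int) q.size();
  for (size_t i = 0; i < starts.size(); ++i) {
    long s = starts[i];
    if (s < 0 || s + L > (long) g.size()) continue;
    int mm = 0; bool ok = true;
    for (int j = 0; j < L; ++j) {
      char gc = g[s + j];
      if (gc == '|') { ok = false; break; }          // crosses a chrom boundary
      if ((gc != q[j]) && ++mm > v) { ok = false; break; }
    }
    if (!ok) continue;
    // locate chrom
    int lo = 0, hi = (int) idx->offset.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (idx->offset[mid] <= s) lo = mid; else hi = mid - 1;
    }
    Hit h; h.chrom = lo; h.start = (int) (s - idx->offset[lo]);
    h.strand = strand; h.mm = mm;
    out.push_back(h);
  }
}

static void gather_candidates(const MiniIndex* idx, const std::string& q,
                              int v, std::vector<long>& starts) {
  const int k = idx->k, L = (int) q.size();
  std::unordered_set<long> seen;
  if (L >= (v + 1) * k) {
    // pigeonhole: some length-floor(L/(v+1)) chunk of any <=v-mismatch
    // placement is exact, hence its leading k-mer is exact
    for (int c = 0; c <= v; ++c) {
      int cs = (int) ((long) c * L / (v + 1));
      uint32_t key = 0; bool valid = true;
      for (int j = 0; j < k; ++j) {
        int b = base2code(q[cs + j]);
        if (b < 0) { valid = false; break; }
        key = (key << 2) | (uint32_t) b;
      }
      if (!valid) continue;
      std::unordered_map<uint32_t, std::vector<long> >::const_iterator it =
        idx->kmers.find(key);
      if (it == idx->kmers.end()) continue;
      for (size_t j = 0; j < it->second.size(); ++j) {
        long s = it->second[j] - cs;
        if (seen.insert(s).second) starts.push_back(s);
      }
    }
  } else {
    // read too short for pigeonhole seeding at this k: exhaustive offsets
    for (long s = 0; s + L <= (long) idx->seq.size(); ++s) starts.push_back(s);
  }
}

// Align reads end-to-end with <= v substitutions against both strands.
// Returns one row per reported placement; n_placements is the retained
// stratum size before truncation to report_cap, itself capped at report_cap.
// [[Rcpp::export]]
DataFrame cpp_align_reads(SEXP xp, CharacterVector reads, int v,
                          int report_cap, bool best_strata) {
  XPtr<MiniIndex> idx(xp);
  if (v < 0 || v > 3) stop("v must be in {0,1,2,3}");
  if (report_cap < 1) stop("report_cap must be >= 1");
  std::vector<int> o_read, o_chrom, o_start, o_mm, o_n;
  std::vector<char> o_strand;
  for (int r = 0; r < reads.size(); ++r) {
    std::string q = as<std::string>(reads[r]);
    const int L = (int) q.size();
    if (L < idx->k) continue;                         // unmapped by contract
    std::vector<Hit> hits;
    std::vector<long> starts;
    gather_candidates(idx, q, v, starts);
    verify_candidates(idx, q, '+', v, starts, hits);
    std::string qr = revcomp(q);
    starts.clear();
    gather_candidates(idx, qr, v, starts);
    verify_candidates(idx, qr, '-', v, starts, hits);
    if (hits.empty()) continue;
    if (best_strata) {
      int best = v + 1;
      for (size_t i = 0; i < hits.size(); ++i) best = std::min(best, hits[i].mm);
      std::vector<Hit> keep;
      for (size_t i = 0; i < hits.size(); ++i)
        if (hits[i].mm == best) keep.push_back(hits[i]);
      hits.swap(keep);
    }
    const MiniIndex* ix = idx;
    std::sort(hits.begin(), hits.end(), [ix](const Hit& a, const Hit& b) {
      if (ix->lexrank[a.chrom] != ix->lexrank[b.chrom])
        return ix->lexrank[a.chrom] < ix->lexrank[b.chrom];
      if (a.start != b.start) return a.start < b.start;
      return a.strand < b.strand;                     // '+' (43) < '-' (45)
    });
    int n = std::min((int) hits.size(), report_cap);
    for (int i = 0; i < n; ++i) {
      o_read.push_back(r + 1);
      o_chrom.push_back(hits[i].chrom + 1);
      o_start.push_back(hits[i].start);
      o_strand.push_back(hits[i].strand);
      o_mm.push_back(hits[i].mm);
      o_n.push_back(n);
    }
  }
  CharacterVector strand(o_strand.size());
  for (size_t i = 0; i < o_strand.size(); ++i)
    strand[i] = (o_strand[i] == '+') ? "+" : "-";
  return DataFrame::create(
    _["read_idx"] = wrap(o_read), _["chrom_idx"] = wrap(o_chrom),
    _["start"] = wrap(o_start), _["strand"] = strand,
    _["mismatches"] = wrap(o_mm), _["n_placements"] = wrap(o_n),
    _["stringsAsFactors"] = false);
}

// 3' adapter search: best semi-global suffix match with
// errors/overlap <= max_error_rate and overlap >= min_overlap;
// minimal errors first, then longest overlap (earliest cut).
// Returns the 0-based cut position per read (== read length if no match).
// [[Rcpp::export]]
IntegerVector cpp_adapter_cut(CharacterVector seqs, std::string adapter,
                              double max_error_rate, int min_overlap) {
  const int alen = (int) adapter.size();
  IntegerVector cut(seqs.size());
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    const int L = (int) s.size();
    int best_err = INT_MAX, best_cut = L;
    for (int j = 0; j <= L - min_overlap; ++j) {
      int overlap = std::min(alen, L - j);
      if (overlap < min_overlap) break;
      int allowed = (int) (max_error_rate * overlap + 1e-9);
      int err = 0; bool ok = true;
      for (int t = 0; t < overlap; ++t)
        if (s[j + t] != adapter[t] && ++err > allowed) { ok = false; break; }
      if (!ok) continue;
      if (err < best_err) { best_err = err; best_cut = j; }
      // equal errors: earlier j == longer overlap already kept (j ascending)
    }
    cut[r] = best_cut;
  }
  return cut;
}

// 3' quality trimming by the running-sum rule: accumulate (cutoff - q)
// from the 3' end and cut where the sum is maximal (and positive).
// Returns the number of bases to keep.
// [[Rcpp::export]]
IntegerVector cpp_quality_keep(CharacterVector quals, int cutoff, int offset) {
  IntegerVector keep(quals.size());
  for (int r = 0; r < quals.size(); ++r) {
    std::string qs = as<std::string>(quals[r]);
    const int L = (int) qs.size();
    long s = 0, smax = 0; int cutpos = L;
    for (int i = L - 1; i >= 0; --i) {
      s += cutoff - ((int) qs[i] - offset);
      if (s > smax) { smax = s; cutpos = i; }
    }
    keep[r] = cutpos;
  }
  return keep;
}
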
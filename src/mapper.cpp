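// Seed-and-extend ungapped read mapper.
//
// The index stores every k-mer occurrence of every reference on both
// strands (minus-strand occurrences keyed by the reverse complement of the
// forward k-mer). Mapping slides a seed across every read offset, gathers
// candidate ungapped placements, scores them by full Hamming distance, and
// reports the unique best placement if it passes the mismatch budget; ties
// on mismatch count leave the read unmapped.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct MapperIndex {
  int k;
  std::vector<std::string> ref_names;
  std::vector<std::string> ref_seqs;
  // value packs: ref_id (high), pos (mid), strand (low bit)
  std::unordered_map<uint64_t, std::vector<uint64_t>> table;
  size_t n_entries = 0;
};

static inline uint64_t pack_hit(uint32_t ref, uint32_t pos, int strand) {
  return (static_cast<uint64_t>(ref) << 33) |
         (static_cast<uint64_t>(pos) << 1) | static_cast<uint64_t>(strand);
}

// Encode k-mer at s[pos..pos+k); returns false when a non-ACGT base occurs.
static bool encode_kmer(const std::string& s, size_t pos, int k,
                        uint64_t& fwd, uint64_t& rc) {
  fwd = 0; rc = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    fwd = (fwd << 2) | static_cast<uint64_t>(c);
    rc |= static_cast<uint64_t>(3 - c) << (2 * i);
  }
  return true;
}

// [[Rcpp::export(name = "cpp_build_index")]]
SEXP cpp_build_index(CharacterVector refs, CharacterVector ref_names, int k) {
  if (k < 11 || k > 31) stop("seed length k must be in [11, 31]");
  if (refs.size() == 0) stop("empty reference set");
  MapperIndex* idx = new MapperIndex();
  idx->k = k;
  for (R_xlen_t r = 0; r < refs.size(); ++r) {
    std::string s = as<std::string>(refs[r]);
    if (static_cast<int>(s.size()) < k) {
      delete idx;
      stop("reference '%s' is shorter than k", as<std::string>(ref_names[r]));
    }
    idx->ref_names.push_back(as<std::string>(ref_names[r]));
    idx->ref_seqs.push_back(s);
  }
  for (size_t r = 0; r < idx->ref_seqs.size(); ++r) {
    const std::string& s = idx->ref_seqs[r];
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t fwd, rc;
      if (!encode_kmer(s, p, k, fwd, rc)) continue;
      idx->table[fwd].push_back(pack_hit(r, p, 0));
      idx->n_entries++;
      if (rc != fwd) {  // palindromic k-mers stored once
        idx->table[rc].push_back(pack_hit(r, p, 1));
        idx->n_entries++;
      }
    }
  }
  XPtr<MapperIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = "cpp_index_info")]]
List cpp_index_info(SEXP xp) {
  XPtr<MapperIndex> idx(xp);
  return List::create(_["k"] = idx->k,
                      _["n_entries"] = static_cast<double>(idx->n_entries),
                      _["ref_names"] = wrap(idx->ref_names));
}

// Number of stored index entries under one k-mer key (test oracle hook).
// [[Rcpp::export(name = "cpp_index_lookup")]]
double cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<MapperIndex> idx(xp);
  if (static_cast<int>(kmer.size()) != idx->k) stop("k-mer length must equal k");
  uint64_t fwd = 0, rc = 0;
  if (!encode_kmer(kmer, 0, idx->k, fwd, rc)) return 0;
  auto it = idx->table.find(fwd);
  return it == idx->table.end() ? 0.0 : static_cast<double>(it->second.size());
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

struct Placement {
  uint32_t ref; int64_t pos; int strand;
  bool operator==(const Placement& o) const {
    return ref == o.ref && pos == o.pos && strand == o.strand;
  }
};
struct PlacementHash {
  size_t operator()(const Placement& p) const {
    return std::hash<uint64_t>()((static_cast<uint64_t>(p.ref) << 34) ^
                                 (static_cast<uint64_t>(p.pos) << 1) ^ p.strand);
  }
};

static void map_one(const MapperIndex& idx, const std::string& read,
                    double max_mm_frac,
                    bool& mapped, int& ref_out, int& pos_out,
                    int& strand_out, int& nm_out) {
  mapped = false; ref_out = NA_INTEGER; pos_out = NA_INTEGER;
  strand_out = NA_INTEGER; nm_out = NA_INTEGER;
  const int k = idx.k;
  const int L = static_cast<int>(read.size());
  if (L < k) stop("read shorter than seed length k");
  const int max_mm = static_cast<int>(max_mm_frac * L);

  std::string rcread(L, 'N');
  for (int i = 0; i < L; ++i) rcread[i] = comp_base(read[L - 1 - i]);

  std::unordered_set<Placement, PlacementHash> cands;
  for (int o = 0; o + k <= L; ++o) {
    uint64_t fwd, rc;
    if (!encode_kmer(read, o, k, fwd, rc)) continue;
    auto it = idx.table.find(fwd);
    if (it == idx.table.end()) continue;
    for (uint64_t h : it->second) {
      uint32_t r = static_cast<uint32_t>(h >> 33);
      int64_t p = static_cast<int64_t>((h >> 1) & 0xFFFFFFFFULL);
      int strand = static_cast<int>(h & 1ULL);
      // strand 0: read k-mer matches + strand at p -> read start p - o.
      // strand 1: read k-mer matches the reverse complement; the read's
      // reverse complement aligns forward with start p - (L - k - o).
      int64_t start = strand == 0 ? p - o : p - (L - k - o);
      if (start < 0) continue;
      if (start + L > static_cast<int64_t>(idx.ref_seqs[r].size())) continue;
      cands.insert(Placement{r, start, strand});
    }
  }
  if (cands.empty()) return;

  int best = L + 1, second = L + 1;
  Placement best_p{0, 0, 0};
  for (const Placement& c : cands) {
    const std::string& s = idx.ref_seqs[c.ref];
    const std::string& q = c.strand == 0 ? read : rcread;
    int mm = 0;
    const int limit = second;  // beyond this the candidate cannot matter
    for (int i = 0; i < L && mm <= limit; ++i)
      if (s[c.pos + i] != q[i]) ++mm;
    if (mm < best) { second = best; best = mm; best_p = c; }
    else if (mm < second) { second = mm; }
  }
  if (best > max_mm || best == second) return;  // over budget or ambiguous tie
  mapped = true;
  ref_out = static_cast<int>(best_p.ref) + 1;
  pos_out = static_cast<int>(best_p.pos);
  strand_out = best_p.strand;
  nm_out = best;
}

// [[Rcpp::export(name = "cpp_map_reads")]]
DataFrame cpp_map_reads(SEXP xp, CharacterVector reads, double max_mm_frac) {
  XPtr<MapperIndex> idx(xp);
  R_xlen_t n = reads.size();
  LogicalVector mapped(n);
  IntegerVector ref(n), pos(n), strand(n), nm(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    bool m; int r, p, s, d;
    map_one(*idx, as<std::string>(reads[i]), max_mm_frac, m, r, p, s, d);
    mapped[i] = m; ref[i] = r; pos[i] = p; strand[i] = s; nm[i] = d;
  }
  return DataFrame::create(_["mapped"] = mapped, _["ref"] = ref,
                           _["pos"] = pos, _["strand"] = strand,
                           _["nm"] = nm);
}
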
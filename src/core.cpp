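// Core sequence kernels: reverse complement, word indexing, ungapped
// seed-and-extend alignment, de Bruijn unitig assembly, and exhaustive
// <=1-mismatch placement. All coordinates are 0-based half-open; strand '-'
// means the subject's reverse complement aligns to the forward query.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline char cbase(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = cbase(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_str(as<std::string>(x[i]));
  }
  out.attr("names") = x.attr("names");
  return out;
}

static inline int b2(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

typedef std::unordered_map< uint64_t, std::vector< std::pair<int,int> > > WordIndex;

// every word_size-mer of the forward strand of each query; words with N skipped
static WordIndex build_index(const std::vector<std::string>& queries, int w) {
  WordIndex idx;
  const uint64_t mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  for (size_t qi = 0; qi < queries.size(); ++qi) {
    const std::string& q = queries[qi];
    if ((int)q.size() < w) continue;
    uint64_t key = 0; int run = 0;
    for (size_t p = 0; p < q.size(); ++p) {
      int b = b2(q[p]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= w) idx[key].push_back(std::make_pair((int)qi, (int)(p + 1 - w)));
    }
  }
  return idx;
}

// [[Rcpp::export]]
List cpp_word_index(CharacterVector queries, int word_size) {
  if (word_size < 2 || word_size > 31) stop("word_size must be in [2, 31]");
  std::vector<std::string> qs(queries.size());
  for (R_xlen_t i = 0; i < queries.size(); ++i) qs[i] = as<std::string>(queries[i]);
  WordIndex idx = build_index(qs, word_size);
  std::vector<uint64_t> keys; keys.reserve(idx.size());
  for (auto& kv : idx) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  List out(keys.size());
  CharacterVector nm(keys.size());
  const char* alpha = "ACGT";
  for (size_t i = 0; i < keys.size(); ++i) {
    std::string word(word_size, 'A');
    uint64_t k = keys[i];
    for (int j = word_size - 1; j >= 0; --j) { word[j] = alpha[k & 3]; k >>= 2; }
    nm[i] = word;
    auto& post = idx[keys[i]];
    IntegerMatrix m(post.size(), 2);
    for (size_t r = 0; r < post.size(); ++r) { m(r,0) = post[r].first + 1; m(r,1) = post[r].second; }
    colnames(m) = CharacterVector::create("query", "offset");
    out[i] = m;
  }
  out.attr("names") = nm;
  return out;
}

struct Hit {
  int subject, query; char strand;
  int q_start, q_end, s_start, s_end;
  int score, matches;
};

// x-drop extension left/right of an exact seed [qo, qo+w) x [so, so+w)
static void extend_seed(const std::string& Q, const std::string& S,
                        int qo, int so, int w,
                        int match, int mismatch, int xdrop,
                        int& q_start, int& q_end, int& s_start, int& s_end,
                        int& score, int& matches) {
  int bestL = 0, lenL = 0;
  {
    int cum = 0, i = qo - 1, j = so - 1;
    while (i >= 0 && j >= 0) {
      cum += (Q[i] == S[j] && Q[i] != 'N') ? match : mismatch;
      if (cum > bestL) { bestL = cum; lenL = qo - i; }
      if (cum < bestL - xdrop) break;
      --i; --j;
    }
  }
  int bestR = 0, lenR = 0;
  {
    int cum = 0; size_t i = qo + w, j = so + w;
    while (i < Q.size() && j < S.size()) {
      cum += (Q[i] == S[j] && Q[i] != 'N') ? match : mismatch;
      if (cum > bestR) { bestR = cum; lenR = (int)(i - (qo + w)) + 1; }
      if (cum < bestR - xdrop) break;
      ++i; ++j;
    }
  }
  q_start = qo - lenL; q_end = qo + w + lenR;
  s_start = so - lenL; s_end = so + w + lenR;
  score = w * match + bestL + bestR;
  matches = 0;
  for (int i = q_start, j = s_start; i < q_end; ++i, ++j)
    if (Q[i] == S[j] && Q[i] != 'N') ++matches;
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(CharacterVector subjects, CharacterVector queries,
                          int word_size, int match, int mismatch, int xdrop) {
  if (word_size < 2 || word_size > 31) stop("word_size must be in [2, 31]");
  std::vector<std::string> qs(queries.size());
  for (R_xlen_t i = 0; i < queries.size(); ++i) qs[i] = as<std::string>(queries[i]);
  WordIndex idx = build_index(qs, word_size);
  const uint64_t mask = (1ULL << (2 * word_size)) - 1;

  std::vector<Hit> hits;
  for (R_xlen_t si = 0; si < subjects.size(); ++si) {
    std::string fwd = as<std::string>(subjects[si]);
    int slen = (int)fwd.size();
    for (int strand = 0; strand < 2; ++strand) {
      const std::string S = strand == 0 ? fwd : revcomp_str(fwd);
      if ((int)S.size() < word_size) continue;
      // per (query, diagonal): rightmost extension end (merge) and best hit
      std::map< std::pair<int,long>, std::pair<int,Hit> > diag;
      uint64_t key = 0; int run = 0;
      for (int p = 0; p < (int)S.size(); ++p) {
        int b = b2(S[p]);
        if (b < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run < word_size) continue;
        int so = p + 1 - word_size;
        auto it = idx.find(key);
        if (it == idx.end()) continue;
        for (auto& post : it->second) {
          int qi = post.first, qo = post.second;
          std::pair<int,long> dk(qi, (long)so - qo);
          auto de = diag.find(dk);
          if (de != diag.end() && so < de->second.first) continue; // inside merged extension
          Hit h; h.subject = (int)si; h.query = qi; h.strand = strand == 0 ? '+' : '-';
          extend_seed(qs[qi], S, qo, so, word_size, match, mismatch, xdrop,
                      h.q_start, h.q_end, h.s_start, h.s_end, h.score, h.matches);
          int cov_end = h.s_end;
          if (de == diag.end()) {
            diag[dk] = std::make_pair(cov_end, h);
          } else {
            de->second.first = std::max(de->second.first, cov_end);
            if (h.score > de->second.second.score) de->second.second = h; // leftmost kept on ties
          }
        }
      }
      for (auto& kv : diag) {
        Hit h = kv.second.second;
        if (h.strand == '-') { // report on subject forward coordinates
          int a = slen - h.s_end, bnd = slen - h.s_start;
          h.s_start = a; h.s_end = bnd;
        }
        hits.push_back(h);
      }
    }
  }

  int n = (int)hits.size();
  IntegerVector subject(n), query(n), q_start(n), q_end(n), s_start(n), s_end(n),
    score(n), matches(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    subject[i] = hits[i].subject + 1; query[i] = hits[i].query + 1;
    strand[i] = std::string(1, hits[i].strand);
    q_start[i] = hits[i].q_start; q_end[i] = hits[i].q_end;
    s_start[i] = hits[i].s_start; s_end[i] = hits[i].s_end;
    score[i] = hits[i].score; matches[i] = hits[i].matches;
  }
  return DataFrame::create(_["subject"] = subject, _["query"] = query,
                           _["strand"] = strand,
                           _["q_start"] = q_start, _["q_end"] = q_end,
                           _["s_start"] = s_start, _["s_end"] = s_end,
                           _["score"] = score, _["matches"] = matches,
                           _["stringsAsFactors"] = false);
}

static inline std::string canon(const std::string& kmer, bool* flipped = NULL) {
  std::string r = revcomp_str(kmer);
  if (r < kmer) { if (flipped) *flipped = true; return r; }
  if (flipped) *flipped = false;
  return kmer;
}

// de Bruijn unitig assembly over canonical k-mers.
// [[Rcpp::export]]
List cpp_assemble(CharacterVector reads, int k, int min_kmer_count) {
  if (k % 2 == 0) stop("k must be odd");
  std::unordered_map<std::string, int> counts;
  std::vector<std::string> rs(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    rs[i] = as<std::string>(reads[i]);
    const std::string& r = rs[i];
    if ((int)r.size() < k) continue;
    for (size_t p = 0; p + k <= r.size(); ++p) {
      std::string km = r.substr(p, k);
      if (km.find('N') != std::string::npos) continue;
      counts[canon(km)]++;
    }
  }
  std::unordered_map<std::string, int> kept; // canonical k-mer -> count
  for (auto& kv : counts) if (kv.second >= min_kmer_count) kept.insert(kv);

  // unique forward extension of oriented k-mer s among kept k-mers
  auto fwd_ext = [&](const std::string& s, std::string& out) -> int {
    int nfound = 0;
    static const char* A = "ACGT";
    for (int i = 0; i < 4; ++i) {
      std::string t = s.substr(1) + A[i];
      if (kept.count(canon(t))) { ++nfound; out = t; }
    }
    return nfound;
  };
  auto bwd_ext = [&](const std::string& s, std::string& out) -> int {
    int nfound = 0;
    static const char* A = "ACGT";
    for (int i = 0; i < 4; ++i) {
      std::string t = std::string(1, A[i]) + s.substr(0, s.size() - 1);
      if (kept.count(canon(t))) { ++nfound; out = t; }
    }
    return nfound;
  };

  std::unordered_set<std::string> used;
  struct Unitig { std::string seq; double depth; std::vector<std::string> path; };
  std::vector<Unitig> unitigs;

  // walk right from oriented k-mer, appending while the junction is unambiguous
  auto walk = [&](std::string cur, const std::string& origin,
                  std::vector<std::string>& path, std::string& grown) {
    while (true) {
      std::string nxt, back;
      if (fwd_ext(cur, nxt) != 1) break;
      std::string cn = canon(nxt);
      if (cn == origin || used.count(cn)) break;
      if (bwd_ext(nxt, back) != 1) break;
      used.insert(cn);
      path.push_back(cn);
      grown += nxt.back();
      cur = nxt;
    }
  };

  for (auto& kv : kept) {
    const std::string& c = kv.first;
    if (used.count(c)) continue;
    used.insert(c);
    std::vector<std::string> pathR, pathL;
    std::string right = c, left = revcomp_str(c);
    walk(c, c, pathR, right);
    walk(revcomp_str(c), c, pathL, left);
    // left walk grew the reverse-complement strand; flip it back
    std::string seq = revcomp_str(left.substr(k)) + right;
    Unitig u;
    u.path.insert(u.path.end(), pathL.rbegin(), pathL.rend());
    u.path.push_back(c);
    u.path.insert(u.path.end(), pathR.begin(), pathR.end());
    double tot = 0; for (auto& km : u.path) tot += kept[km];
    u.depth = tot / (double)u.path.size();
    std::string rcs = revcomp_str(seq);
    u.seq = (rcs < seq) ? rcs : seq;
    unitigs.push_back(u);
  }

  std::vector<int> ord(unitigs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (unitigs[a].seq.size() != unitigs[b].seq.size())
      return unitigs[a].seq.size() > unitigs[b].seq.size();
    return unitigs[a].seq < unitigs[b].seq;
  });

  // kmer -> unitig (each retained k-mer belongs to exactly one unitig)
  std::unordered_map<std::string, int> owner;
  for (size_t r = 0; r < ord.size(); ++r)
    for (auto& km : unitigs[ord[r]].path) owner[km] = (int)r;

  IntegerVector n_reads(ord.size(), 0);
  std::unordered_set<int> touched;
  for (auto& r : rs) {
    if ((int)r.size() < k) continue;
    touched.clear();
    for (size_t p = 0; p + k <= r.size(); ++p) {
      std::string km = r.substr(p, k);
      if (km.find('N') != std::string::npos) continue;
      auto it = owner.find(canon(km));
      if (it != owner.end()) touched.insert(it->second);
    }
    for (int u : touched) n_reads[u]++;
  }

  CharacterVector seqs(ord.size());
  NumericVector depth(ord.size());
  for (size_t r = 0; r < ord.size(); ++r) {
    seqs[r] = unitigs[ord[r]].seq;
    depth[r] = unitigs[ord[r]].depth;
  }
  return List::create(_["seq"] = seqs, _["mean_depth"] = depth, _["n_reads"] = n_reads);
}

// exhaustive placement of short reads on references, Hamming distance <= max_mm;
// only minimum-mismatch placements per read are returned (N never matches)
// [[Rcpp::export]]
DataFrame cpp_map_hamming(CharacterVector reads, CharacterVector refs, int max_mm) {
  std::vector<std::string> rf(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i) rf[i] = as<std::string>(refs[i]);

  std::vector<int> o_read, o_ref, o_pos, o_mm;
  std::vector<char> o_strand;
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    std::string rev = revcomp_str(fwd);
    int L = (int)fwd.size();
    int best = max_mm + 1;
    std::vector<int> p_ref, p_pos, p_mm; std::vector<char> p_str;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = strand == 0 ? fwd : rev; // '-': read == revcomp(ref substring)
      for (size_t fi = 0; fi < rf.size(); ++fi) {
        const std::string& R = rf[fi];
        if ((int)R.size() < L) continue;
        for (int pos = 0; pos + L <= (int)R.size(); ++pos) {
          int mm = 0;
          for (int j = 0; j < L; ++j) {
            if (rd[j] != R[pos + j] || rd[j] == 'N' || R[pos + j] == 'N') {
              if (++mm > best || mm > max_mm) break;
            }
          }
          if (mm <= max_mm && mm <= best) {
            if (mm < best) { best = mm; p_ref.clear(); p_pos.clear(); p_mm.clear(); p_str.clear(); }
            p_ref.push_back((int)fi); p_pos.push_back(pos); p_mm.push_back(mm);
            p_str.push_back(strand == 0 ? '+' : '-');
          }
        }
      }
    }
    for (size_t i = 0; i < p_ref.size(); ++i) {
      o_read.push_back((int)ri + 1); o_ref.push_back(p_ref[i] + 1);
      o_pos.push_back(p_pos[i]); o_strand.push_back(p_str[i]); o_mm.push_back(p_mm[i]);
    }
  }
  int n = (int)o_read.size();
  IntegerVector read(n), ref(n), pos(n), mm(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    read[i] = o_read[i]; ref[i] = o_ref[i]; pos[i] = o_pos[i];
    strand[i] = std::string(1, o_strand[i]); mm[i] = o_mm[i];
  }
  return DataFrame::create(_["read"] = read, _["ref"] = ref, _["pos"] = pos,
                           _["strand"] = strand, _["mismatches"] = mm,
                           _["stringsAsFactors"] = false);
}
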
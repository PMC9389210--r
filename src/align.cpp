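#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---- basic sequence helpers -------------------------------------------------

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = complement(r[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp(s);
  }
  return out;
}

// Apply point substitutions to sequences: edit `idx[j]`-th sequence at
// position `pos[j]` (1-based) to `base[j]`. Used by the simulator so that
// mutation bookkeeping stays in R's RNG while the string surgery stays fast.
// [[Rcpp::export]]
CharacterVector cpp_substitute(CharacterVector seqs, IntegerVector idx,
                               IntegerVector pos, CharacterVector base) {
  std::vector<std::string> s(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) s[i] = as<std::string>(seqs[i]);
  for (R_xlen_t j = 0; j < idx.size(); ++j) {
    int i = idx[j] - 1;
    int p = pos[j] - 1;
    std::string b = as<std::string>(base[j]);
    if (i >= 0 && i < (int)s.size() && p >= 0 && p < (int)s[i].size())
      s[i][p] = b[0];
  }
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) out[i] = s[i];
  return out;
}

// ---- seed index -------------------------------------------------------------

struct SeedIndex {
  int k;
  std::vector<std::string> seqs;
  std::vector<std::string> names;
  // kmer code -> (contig index, position)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > table;
};

static void index_sequence(SeedIndex& idx, int cid) {
  const std::string& s = idx.seqs[cid];
  const int k = idx.k;
  if ((int)s.size() < k) return;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    int b = base2code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) idx.table[code].push_back(std::make_pair(cid, i - k + 1));
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    idx->seqs.push_back(as<std::string>(seqs[i]));
    idx->names.push_back(as<std::string>(names[i]));
  }
  for (int i = 0; i < (int)idx->seqs.size(); ++i) index_sequence(*idx, i);
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP index_ptr) {
  XPtr<SeedIndex> idx(index_ptr);
  return idx->k;
}

// ---- mapping ----------------------------------------------------------------

struct Segment {
  int qstart, qend;      // 0-based half-open, original query orientation
  int cid;
  int tstart, tend;
  bool fwd;
  int matches;
  double identity;
};

struct Hit { int cid; int diag; int qpos; };

static bool hit_lt(const Hit& a, const Hit& b) {
  if (a.cid != b.cid) return a.cid < b.cid;
  if (a.diag != b.diag) return a.diag < b.diag;
  return a.qpos < b.qpos;
}

// X-drop extension along a fixed diagonal; mismatch penalty 2, N never matches.
static void extend_diag(const std::string& q, const std::string& t, int diag,
                        int& qs, int& qe, int& matches, int xdrop) {
  const int qlen = (int)q.size(), tlen = (int)t.size();
  // right
  {
    long s = 0, best = 0;
    int bq = qe, mloc = 0, mbest = 0;
    for (int i = qe; i < qlen && i + diag < tlen; ++i) {
      bool eq = (q[i] == t[i + diag]) && base2code(q[i]) >= 0;
      s += eq ? 1 : -2;
      if (eq) ++mloc;
      if (s > best) { best = s; bq = i + 1; mbest = mloc; }
      else if (best - s > xdrop) break;
    }
    qe = bq; matches += mbest;
  }
  // left
  {
    long s = 0, best = 0;
    int bq = qs, mloc = 0, mbest = 0;
    for (int i = qs - 1; i >= 0 && i + diag >= 0; --i) {
      bool eq = (q[i] == t[i + diag]) && base2code(q[i]) >= 0;
      s += eq ? 1 : -2;
      if (eq) ++mloc;
      if (s > best) { best = s; bq = i; mbest = mloc; }
      else if (best - s > xdrop) break;
    }
    qs = bq; matches += mbest;
  }
}

static void map_oriented(const SeedIndex& idx, const std::string& q, bool fwd,
                         int qlen_orig, int xdrop, int max_diag_gap,
                         int max_seed_gap, int max_bucket, int seed_step,
                         std::vector<Segment>& out) {
  const int k = idx.k;
  const int qlen = (int)q.size();
  if (qlen < k) return;
  std::vector<Hit> hits;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < qlen; ++i) {
    int b = base2code(q[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      int qp0 = i - k + 1;
      if (seed_step > 1 && qp0 % seed_step != 0 && qp0 != qlen - k) continue;
      std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::const_iterator
        it = idx.table.find(code);
      if (it != idx.table.end() && (int)it->second.size() <= max_bucket) {
        int qp = i - k + 1;
        for (size_t j = 0; j < it->second.size(); ++j) {
          Hit h; h.cid = it->second[j].first;
          h.diag = it->second[j].second - qp; h.qpos = qp;
          hits.push_back(h);
        }
      }
    }
  }
  if (hits.empty()) return;
  std::sort(hits.begin(), hits.end(), hit_lt);

  // cluster sorted hits: break on contig change, diagonal jump, or seed gap
  size_t start = 0;
  std::vector<std::pair<size_t, size_t> > clusters; // [start, end)
  for (size_t i = 1; i <= hits.size(); ++i) {
    bool brk = (i == hits.size());
    if (!brk) {
      const Hit& a = hits[i - 1];
      const Hit& b = hits[i];
      if (b.cid != a.cid) brk = true;
      else if (b.diag - a.diag > max_diag_gap) brk = true;
      else if (b.diag == a.diag && b.qpos - a.qpos > max_seed_gap) brk = true;
    }
    if (brk) { clusters.push_back(std::make_pair(start, i)); start = i; }
  }

  for (size_t c = 0; c < clusters.size(); ++c) {
    size_t cs = clusters[c].first, ce = clusters[c].second;
    // representative diagonal: mode of exact diagonals in cluster
    int best_diag = hits[cs].diag, best_n = 0;
    for (size_t i = cs; i < ce;) {
      size_t j = i;
      while (j < ce && hits[j].diag == hits[i].diag) ++j;
      if ((int)(j - i) > best_n) { best_n = (int)(j - i); best_diag = hits[i].diag; }
      i = j;
    }
    int qs = qlen, qe = 0;
    for (size_t i = cs; i < ce; ++i) {
      if (hits[i].diag != best_diag) continue;
      if (hits[i].qpos < qs) qs = hits[i].qpos;
      if (hits[i].qpos + k > qe) qe = hits[i].qpos + k;
    }
    const std::string& t = idx.seqs[hits[cs].cid];
    int matches = 0;
    for (int i = qs; i < qe; ++i) {
      if (i + best_diag < 0 || i + best_diag >= (int)t.size()) continue;
      if (q[i] == t[i + best_diag] && base2code(q[i]) >= 0) ++matches;
    }
    extend_diag(q, t, best_diag, qs, qe, matches, xdrop);
    if (qe <= qs) continue;
    Segment seg;
    seg.cid = hits[cs].cid;
    seg.fwd = fwd;
    seg.tstart = qs + best_diag;
    seg.tend = qe + best_diag;
    seg.matches = matches;
    seg.identity = (double)matches / (double)(qe - qs);
    if (fwd) { seg.qstart = qs; seg.qend = qe; }
    else { seg.qstart = qlen_orig - qe; seg.qend = qlen_orig - qs; }
    out.push_back(seg);
  }
}

static bool seg_better(const Segment& a, const Segment& b) {
  if (a.matches != b.matches) return a.matches > b.matches;
  if (a.identity != b.identity) return a.identity > b.identity;
  if (a.qstart != b.qstart) return a.qstart < b.qstart;
  if (a.cid != b.cid) return a.cid < b.cid;
  return a.fwd && !b.fwd;
}

static int interval_overlap(int a1, int a2, int b1, int b2) {
  int lo = std::max(a1, b1), hi = std::min(a2, b2);
  return hi > lo ? hi - lo : 0;
}

// Map each query against the indexed target. Returns maximal high-identity
// local segments per query (greedy non-overlapping selection, overlap
// tolerance max_overlap on query, or on target when nonoverlap_on_target,
// used for duplicate-marker detection).
// [[Rcpp::export]]
DataFrame cpp_map_batch(CharacterVector queries, SEXP index_ptr,
                        double min_identity, int min_seg_len, int xdrop,
                        int max_diag_gap, int max_seed_gap,
                        int max_overlap, bool nonoverlap_on_target,
                        int max_segments, int seed_step) {
  XPtr<SeedIndex> idx(index_ptr);
  std::vector<int> r_query; std::vector<int> r_qs, r_qe, r_ts, r_te, r_matches;
  std::vector<std::string> r_contig, r_strand;
  std::vector<double> r_ident;

  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    int qlen = (int)q.size();
    std::vector<Segment> cand;
    map_oriented(*idx, q, true, qlen, xdrop, max_diag_gap, max_seed_gap, 64,
                 seed_step, cand);
    std::string qr = revcomp(q);
    map_oriented(*idx, qr, false, qlen, xdrop, max_diag_gap, max_seed_gap, 64,
                 seed_step, cand);

    // filter
    std::vector<Segment> keep;
    for (size_t i = 0; i < cand.size(); ++i) {
      if (cand[i].identity < min_identity) continue;
      if (cand[i].qend - cand[i].qstart < min_seg_len) continue;
      keep.push_back(cand[i]);
    }
    std::sort(keep.begin(), keep.end(), seg_better);
    std::vector<Segment> sel;
    for (size_t i = 0; i < keep.size() && (int)sel.size() < max_segments; ++i) {
      bool ok = true;
      for (size_t j = 0; j < sel.size(); ++j) {
        int ov;
        if (nonoverlap_on_target) {
          ov = (keep[i].cid == sel[j].cid)
            ? interval_overlap(keep[i].tstart, keep[i].tend, sel[j].tstart, sel[j].tend)
            : 0;
        } else {
          ov = interval_overlap(keep[i].qstart, keep[i].qend, sel[j].qstart, sel[j].qend);
        }
        if (ov > max_overlap) { ok = false; break; }
      }
      if (ok) sel.push_back(keep[i]);
    }
    for (size_t i = 0; i < sel.size(); ++i) {
      r_query.push_back((int)qi + 1);
      r_qs.push_back(sel[i].qstart); r_qe.push_back(sel[i].qend);
      r_contig.push_back(idx->names[sel[i].cid]);
      r_ts.push_back(sel[i].tstart); r_te.push_back(sel[i].tend);
      r_strand.push_back(sel[i].fwd ? "+" : "-");
      r_matches.push_back(sel[i].matches);
      r_ident.push_back(sel[i].identity);
    }
  }
  return DataFrame::create(
    _["query"] = r_query, _["qstart"] = r_qs, _["qend"] = r_qe,
    _["contig"] = r_contig, _["tstart"] = r_ts, _["tend"] = r_te,
    _["strand"] = r_strand, _["matches"] = r_matches,
    _["identity"] = r_ident, _["stringsAsFactors"] = false);
}

// ---- banded global alignment identity ---------------------------------------

// Needleman-Wunsch inside a band (match +1, mismatch -1, gap -2), tracking
// matches and alignment columns along the optimal path. Returns fraction of
// matching columns. Band is widened to cover the length difference.
// [[Rcpp::export]]
double cpp_global_identity(std::string a, std::string b, int band) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0) return NA_REAL;
  int diff = lb - la;
  int lo = std::min(0, diff) - band;   // j - i lower bound
  int hi = std::max(0, diff) + band;   // j - i upper bound
  const int w = hi - lo + 1;
  const double NEG = -1e18;
  std::vector<double> S(w, NEG), Sp(w, NEG);
  std::vector<int> M(w, 0), Mp(w, 0), L(w, 0), Lp(w, 0);

  // row i = 0: only gaps in b
  for (int d = 0; d < w; ++d) {
    int j = 0 + lo + d;
    if (j >= 0 && j <= lb) { Sp[d] = -2.0 * j; Mp[d] = 0; Lp[d] = j; }
  }
  for (int i = 1; i <= la; ++i) {
    for (int d = 0; d < w; ++d) { S[d] = NEG; M[d] = 0; L[d] = 0; }
    for (int d = 0; d < w; ++d) {
      int j = i + lo + d;
      if (j < 0 || j > lb) continue;
      double best = NEG; int bm = 0, bl = 0;
      if (j > 0) { // diagonal from (i-1, j-1): same offset d in previous row
        if (Sp[d] > NEG / 2) {
          bool eq = (a[i - 1] == b[j - 1]) && base2code(a[i - 1]) >= 0;
          double sc = Sp[d] + (eq ? 1.0 : -1.0);
          if (sc > best) { best = sc; bm = Mp[d] + (eq ? 1 : 0); bl = Lp[d] + 1; }
        }
      }
      // up from (i-1, j): offset d+1 in previous row
      if (d + 1 < w && Sp[d + 1] > NEG / 2) {
        double sc = Sp[d + 1] - 2.0;
        if (sc > best) { best = sc; bm = Mp[d + 1]; bl = Lp[d + 1] + 1; }
      }
      // left from (i, j-1): offset d-1 in current row
      if (d - 1 >= 0 && S[d - 1] > NEG / 2) {
        double sc = S[d - 1] - 2.0;
        if (sc > best) { best = sc; bm = M[d - 1]; bl = L[d - 1] + 1; }
      }
      S[d] = best; M[d] = bm; L[d] = bl;
    }
    std::swap(S, Sp); std::swap(M, Mp); std::swap(L, Lp);
  }
  int d_end = lb - la - lo;
  if (d_end < 0 || d_end >= w || Sp[d_end] < NEG / 2 || Lp[d_end] == 0) return NA_REAL;
  return (double)Mp[d_end] / (double)Lp[d_end];
}
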
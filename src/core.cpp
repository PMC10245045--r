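#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <unordered_map>
#include <vector>
#include <climits>
using namespace Rcpp;

// 2-bit base codes; anything outside ACGT maps to -1 (callers pre-clean input)
static inline int base2bit(char c) {
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
    default: return c;
  }
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (auto &c : out) c = comp(c);
  return out;
}

// ---------------------------------------------------------------------------
// k-mer index: flat (code, read, pos) triplets sorted by code.
// k-mers present in more than max_occ distinct reads are dropped entirely.
// ---------------------------------------------------------------------------

struct KmerHit { uint64_t code; int read; int pos; };

static void enumerate_kmers(const std::string &s, int k,
                            std::vector<std::pair<uint64_t,int>> &out) {
  out.clear();
  int n = (int) s.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) b) & mask;
    if (++run >= k) out.emplace_back(code, i - k + 1);
  }
}

// [[Rcpp::export]]
List cpp_build_kmer_index(CharacterVector seqs, int k, int max_occ) {
  std::vector<KmerHit> hits;
  std::vector<std::pair<uint64_t,int>> km;
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    enumerate_kmers(s, k, km);
    for (auto &p : km) hits.push_back({p.first, r + 1, p.second});
  }
  std::sort(hits.begin(), hits.end(), [](const KmerHit &a, const KmerHit &b) {
    if (a.code != b.code) return a.code < b.code;
    if (a.read != b.read) return a.read < b.read;
    return a.pos < b.pos;
  });
  // drop k-mers seen in more than max_occ distinct reads
  std::vector<char> keep(hits.size(), 1);
  size_t i = 0; int dropped = 0;
  while (i < hits.size()) {
    size_t j = i; int nreads = 0; int last = -1;
    while (j < hits.size() && hits[j].code == hits[i].code) {
      if (hits[j].read != last) { ++nreads; last = hits[j].read; }
      ++j;
    }
    if (nreads > max_occ) { for (size_t t = i; t < j; ++t) keep[t] = 0; ++dropped; }
    i = j;
  }
  size_t nkeep = 0;
  for (char c : keep) nkeep += c;
  NumericVector code(nkeep); IntegerVector read(nkeep), pos(nkeep);
  size_t o = 0;
  for (size_t t = 0; t < hits.size(); ++t) if (keep[t]) {
    code[o] = (double) hits[t].code; read[o] = hits[t].read; pos[o] = hits[t].pos; ++o;
  }
  return List::create(_["code"] = code, _["read"] = read, _["pos"] = pos,
                      _["k"] = k, _["n_reads"] = seqs.size(),
                      _["n_dropped_kmers"] = dropped,
                      _["n_positions"] = (double) nkeep);
}

// ---------------------------------------------------------------------------
// Candidate finding: shared k-mers binned onto diagonals; the densest diagonal
// window (spread <= max_diag_spread) per read/strand becomes one candidate.
// ---------------------------------------------------------------------------

struct Cand {
  int read, strand, score;
  int t_start, t_end, c_start, c_end, diag_lo, diag_hi;
  int jump, j_t1, j_c1, j_t2, j_c2;  // seed-diagonal jump (structural indel)
};

// [[Rcpp::export]]
DataFrame cpp_find_candidates(std::string tmpl, int tmpl_idx, List index,
                              IntegerVector read_lens, int min_seed,
                              int max_candidates, int max_diag_spread,
                              int min_jump) {
  NumericVector code = index["code"];
  IntegerVector iread = index["read"];
  IntegerVector ipos = index["pos"];
  int k = as<int>(index["k"]);
  int Lt = (int) tmpl.size();
  const double *cb = REAL(code);
  const double *ce = cb + code.size();

  // hits[(read, strand)] -> vector of (tpos, cpos) in forward-template frame
  std::unordered_map<int64_t, std::vector<std::pair<int,int>>> hits;
  std::vector<std::pair<uint64_t,int>> km;

  for (int strand = 0; strand < 2; ++strand) {
    std::string s = strand == 0 ? tmpl : cpp_revcomp(tmpl);
    enumerate_kmers(s, k, km);
    for (auto &p : km) {
      double target = (double) p.first;
      const double *lo = std::lower_bound(cb, ce, target);
      for (const double *it = lo; it != ce && *it == target; ++it) {
        size_t idx = it - cb;
        int r = iread[idx];
        if (r == tmpl_idx) continue;
        int cpos = ipos[idx], tpos = p.second;
        if (strand == 1) {
          // rc(T)[i..] == C[p..]  =>  T[Lt-k-i..] == rc(C)[Lc-k-p..]
          tpos = Lt - k - tpos;
          cpos = read_lens[r - 1] - k - cpos;
        }
        hits[(int64_t) r * 2 + strand].emplace_back(tpos, cpos);
      }
    }
  }

  // per read keep the best strand
  std::unordered_map<int, Cand> best;
  for (auto &kv : hits) {
    int r = (int) (kv.first / 2), strand = (int) (kv.first % 2);
    auto &v = kv.second;
    std::vector<std::pair<int,int>> dg(v.size());  // (diag, index)
    for (size_t t = 0; t < v.size(); ++t) dg[t] = {v[t].first - v[t].second, (int) t};
    std::sort(dg.begin(), dg.end());
    // densest window of diagonals with spread <= max_diag_spread
    size_t bi = 0, bj = 0, a = 0;
    bool init = false;
    for (size_t b2 = 0; b2 < dg.size(); ++b2) {
      while (dg[b2].first - dg[a].first > max_diag_spread) ++a;
      if (!init || b2 - a > bj - bi) { bi = a; bj = b2; init = true; }
    }
    int score = (int) (bj - bi + 1);
    int t_lo = INT_MAX, t_hi = INT_MIN, c_lo = INT_MAX, c_hi = INT_MIN;
    for (size_t t = bi; t <= bj; ++t) {
      auto &h = v[dg[t].second];
      t_lo = std::min(t_lo, h.first);  t_hi = std::max(t_hi, h.first + k);
      c_lo = std::min(c_lo, h.second); c_hi = std::max(c_hi, h.second + k);
    }
    int Lc = read_lens[r - 1];
    int ext_l = std::min(t_lo, c_lo);
    int ext_r = std::min(Lt - t_hi, Lc - c_hi);
    Cand cd{r, strand, score, t_lo - ext_l, t_hi + ext_r,
            c_lo - ext_l, c_hi + ext_r, dg[bi].first, dg[bj].first,
            0, 0, 0, 0, 0};
    // one dominant diagonal jump inside the seed chain marks a structural
    // indel relative to the template (e.g. a skipped exon)
    if (min_jump > 0 && bj - bi + 1 >= 6) {
      std::vector<std::pair<int,int>> chain;  // (tpos, cpos) sorted by tpos
      for (size_t t = bi; t <= bj; ++t) chain.push_back(v[dg[t].second]);
      std::sort(chain.begin(), chain.end());
      int n = (int) chain.size();
      int best_s = -1, best_abs = 0;
      for (int s2 = 0; s2 + 1 < n; ++s2) {
        int dj = (chain[s2].first - chain[s2].second) -
                 (chain[s2 + 1].first - chain[s2 + 1].second);
        if (std::abs(dj) > best_abs) { best_abs = std::abs(dj); best_s = s2; }
      }
      if (best_s >= 2 && best_s + 3 < n && best_abs >= min_jump) {
        int k2 = as<int>(index["k"]);
        int dj = (chain[best_s].first - chain[best_s].second) -
                 (chain[best_s + 1].first - chain[best_s + 1].second);
        cd.jump = dj;  // > 0: candidate carries extra sequence (insertion)
        cd.j_t1 = chain[best_s].first + k2;
        cd.j_c1 = chain[best_s].second + k2;
        cd.j_t2 = chain[best_s + 1].first;
        cd.j_c2 = chain[best_s + 1].second;
      }
    }
    auto it = best.find(r);
    if (it == best.end() || cd.score > it->second.score ||
        (cd.score == it->second.score && cd.strand < it->second.strand))
      best[r] = cd;
  }

  std::vector<Cand> out;
  for (auto &kv : best) if (kv.second.score >= min_seed) out.push_back(kv.second);
  std::sort(out.begin(), out.end(), [](const Cand &a, const Cand &b) {
    if (a.score != b.score) return a.score > b.score;
    return a.read < b.read;
  });
  if ((int) out.size() > max_candidates) out.resize(max_candidates);

  int n = (int) out.size();
  IntegerVector candidate(n), strand(n), t_start(n), t_end(n), c_start(n),
      c_end(n), seed_score(n), diag_lo(n), diag_hi(n), jump(n), j_t1(n),
      j_c1(n), j_t2(n), j_c2(n);
  for (int t = 0; t < n; ++t) {
    candidate[t] = out[t].read; strand[t] = out[t].strand;
    t_start[t] = out[t].t_start; t_end[t] = out[t].t_end;
    c_start[t] = out[t].c_start; c_end[t] = out[t].c_end;
    seed_score[t] = out[t].score;
    diag_lo[t] = out[t].diag_lo; diag_hi[t] = out[t].diag_hi;
    jump[t] = out[t].jump; j_t1[t] = out[t].j_t1; j_c1[t] = out[t].j_c1;
    j_t2[t] = out[t].j_t2; j_c2[t] = out[t].j_c2;
  }
  return DataFrame::create(_["candidate"] = candidate, _["strand"] = strand,
                           _["t_start"] = t_start, _["t_end"] = t_end,
                           _["c_start"] = c_start, _["c_end"] = c_end,
                           _["seed_score"] = seed_score,
                           _["diag_lo"] = diag_lo, _["diag_hi"] = diag_hi,
                           _["jump"] = jump, _["j_t1"] = j_t1,
                           _["j_c1"] = j_c1, _["j_t2"] = j_t2,
                           _["j_c2"] = j_c2);
}

// ---------------------------------------------------------------------------
// Banded global alignment minimising edit distance (Gotoh layout with zero
// gap-open cost, i.e. unit costs). Tie preference diag > del > ins
// (del = template base against '-'; ins = candidate base against '-'),
// and gap extension over re-opening, which keeps equal-cost gaps together.
// `dist` is the unit error count along the returned alignment; with zero
// open cost `score` equals `dist` and both equal the edit distance.
// ---------------------------------------------------------------------------

static const int BIG = INT_MAX / 4;
static const int MIS_COST = 1, GAP_OPEN = 0, GAP_EXT = 1;

// [[Rcpp::export]]
List cpp_align_banded(std::string a, std::string b, int band) {
  int na = (int) a.size(), nb = (int) b.size();
  int dlo = std::min(0, nb - na) - band;
  int dhi = std::max(0, nb - na) + band;
  if (dlo < -na) dlo = -na;
  if (dhi > nb) dhi = nb;
  int W = dhi - dlo + 1;
  // layers: 0 = M (diag), 1 = D (gap in b), 2 = I (gap in a)
  std::vector<int> pM(W, BIG), pD(W, BIG), pI(W, BIG);
  std::vector<int> cM(W, BIG), cD(W, BIG), cI(W, BIG);
  // packed predecessor layers: bits 0-1 for M, 2-3 for D, 4-5 for I
  // (value = source layer + 1; 0 = unset)
  std::vector<uint8_t> mv((size_t) (na + 1) * W, 0);

  for (int idx = 0; idx < W; ++idx) {
    int j = dlo + idx;  // i = 0
    if (j == 0) pM[idx] = 0;
    else if (j > 0 && j <= nb) {
      pI[idx] = GAP_OPEN + GAP_EXT * j;
      mv[idx] |= (uint8_t) ((j == 1 ? 1 : 3) << 4);  // from M at j=1, else extend
    }
  }
  for (int i = 1; i <= na; ++i) {
    size_t row = (size_t) i * W;
    for (int idx = 0; idx < W; ++idx) {
      cM[idx] = cD[idx] = cI[idx] = BIG;
      int j = i + dlo + idx;
      if (j < 0 || j > nb) continue;
      uint8_t pack = 0;
      if (j >= 1) {  // M: prev row, same idx (d unchanged)
        int base = BIG; uint8_t src = 0;
        if (pM[idx] < base) { base = pM[idx]; src = 1; }
        if (pD[idx] < base) { base = pD[idx]; src = 2; }
        if (pI[idx] < base) { base = pI[idx]; src = 3; }
        if (base < BIG) {
          cM[idx] = base + (a[i - 1] == b[j - 1] ? 0 : MIS_COST);
          pack |= src;
        }
      }
      if (idx + 1 < W) {  // D: prev row, d+1; tie preference M > D > I
        int best = BIG; uint8_t src = 0;
        if (pM[idx + 1] < BIG && pM[idx + 1] + GAP_OPEN + GAP_EXT < best) {
          best = pM[idx + 1] + GAP_OPEN + GAP_EXT; src = 1;
        }
        if (pD[idx + 1] < BIG && pD[idx + 1] + GAP_EXT < best) {
          best = pD[idx + 1] + GAP_EXT; src = 2;
        }
        if (pI[idx + 1] < BIG && pI[idx + 1] + GAP_OPEN + GAP_EXT < best) {
          best = pI[idx + 1] + GAP_OPEN + GAP_EXT; src = 3;
        }
        if (best < BIG) { cD[idx] = best; pack |= (uint8_t) (src << 2); }
      }
      if (idx >= 1 && j >= 1) {  // I: same row, d-1; tie preference M > D > I
        int best = BIG; uint8_t src = 0;
        if (cM[idx - 1] < BIG && cM[idx - 1] + GAP_OPEN + GAP_EXT < best) {
          best = cM[idx - 1] + GAP_OPEN + GAP_EXT; src = 1;
        }
        if (cD[idx - 1] < BIG && cD[idx - 1] + GAP_OPEN + GAP_EXT < best) {
          best = cD[idx - 1] + GAP_OPEN + GAP_EXT; src = 2;
        }
        if (cI[idx - 1] < BIG && cI[idx - 1] + GAP_EXT < best) {
          best = cI[idx - 1] + GAP_EXT; src = 3;
        }
        if (best < BIG) { cI[idx] = best; pack |= (uint8_t) (src << 4); }
      }
      mv[row + idx] = pack;
    }
    std::swap(pM, cM); std::swap(pD, cD); std::swap(pI, cI);
  }
  int endidx = (nb - na) - dlo;
  int score = BIG; int layer = 0;
  if (endidx >= 0 && endidx < W) {
    if (pM[endidx] < score) { score = pM[endidx]; layer = 0; }
    if (pD[endidx] < score) { score = pD[endidx]; layer = 1; }
    if (pI[endidx] < score) { score = pI[endidx]; layer = 2; }
  }
  bool ok = score < BIG;
  std::string tstr, qstr;
  int nmat = 0, nmis = 0, nins = 0, ndel = 0;
  if (ok) {
    tstr.reserve(na + nb); qstr.reserve(na + nb);
    int i = na, j = nb;
    while (i > 0 || j > 0) {
      int idx = (j - i) - dlo;
      uint8_t pack = mv[(size_t) i * W + idx];
      uint8_t src;
      if (layer == 0) {
        src = pack & 3;
        tstr.push_back(a[i - 1]); qstr.push_back(b[j - 1]);
        if (a[i - 1] == b[j - 1]) ++nmat; else ++nmis;
        --i; --j;
      } else if (layer == 1) {
        src = (pack >> 2) & 3;
        tstr.push_back(a[i - 1]); qstr.push_back('-'); ++ndel; --i;
      } else {
        src = (pack >> 4) & 3;
        tstr.push_back('-'); qstr.push_back(b[j - 1]); ++nins; --j;
      }
      if (src == 0) break;
      layer = src - 1;
    }
    std::reverse(tstr.begin(), tstr.end());
    std::reverse(qstr.begin(), qstr.end());
  }
  int dist = nmis + nins + ndel;
  return List::create(_["tstr"] = tstr, _["qstr"] = qstr,
                      _["dist"] = ok ? dist : NA_INTEGER,
                      _["score"] = ok ? score : NA_INTEGER, _["ok"] = ok,
                      _["nmat"] = nmat, _["nmis"] = nmis,
                      _["nins"] = nins, _["ndel"] = ndel);
}

// ---------------------------------------------------------------------------
// Mismatch splitting: (X,Y) with X != Y becomes (X,-)(-,Y).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_normalize_alignment(std::string tstr, std::string qstr) {
  if (tstr.size() != qstr.size()) stop("alignment rows differ in length");
  std::string t2, q2;
  t2.reserve(tstr.size() * 2); q2.reserve(qstr.size() * 2);
  for (size_t i = 0; i < tstr.size(); ++i) {
    char t = tstr[i], q = qstr[i];
    if (t == '-' && q == '-') stop("gap/gap column at %d", (int) i + 1);
    if (t != '-' && q != '-' && t != q) {
      t2.push_back(t); q2.push_back('-');
      t2.push_back('-'); q2.push_back(q);
    } else {
      t2.push_back(t); q2.push_back(q);
    }
  }
  return List::create(_["tstr"] = t2, _["qstr"] = q2);
}

// ---------------------------------------------------------------------------
// Sliding-window masking. The window anchored at column i (length
// min(window_length, L - i)) is scored by identity; when it fires
// (identity <= threshold, and < 1) the anchor column's candidate character
// is replaced by 'N'. Gap characters are never replaced.
// threshold <= 0 disables masking entirely.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string cpp_mask_low_identity(std::string tstr, std::string qstr,
                                  int window_length, double threshold) {
  int L = (int) tstr.size();
  if ((int) qstr.size() != L) stop("alignment rows differ in length");
  if (threshold <= 0.0 || L == 0) return qstr;
  std::vector<int> pre(L + 1, 0);
  for (int i = 0; i < L; ++i)
    pre[i + 1] = pre[i] + (tstr[i] != '-' && tstr[i] == qstr[i] ? 1 : 0);
  std::string out = qstr;
  for (int i = 0; i < L; ++i) {
    if (out[i] == '-') continue;
    int wl = std::min(window_length, L - i);
    int m = pre[i + wl] - pre[i];
    bool fire = (m < wl) && ((double) m <= threshold * wl + 1e-9);
    if (fire) out[i] = 'N';
  }
  return out;
}

// ---------------------------------------------------------------------------
// Consensus-table accumulation over one flavor (rows = qstr or newqstr).
// Columns: match, mis, insert, ins_reads, del, skip, A, C, G, T.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_build_table(CharacterVector tstrs, CharacterVector rows,
                              IntegerVector t_starts, int tlen) {
  IntegerMatrix M(tlen, 10);
  for (int r = 0; r < tstrs.size(); ++r) {
    std::string ts = as<std::string>(tstrs[r]);
    std::string qs = as<std::string>(rows[r]);
    if (ts.size() != qs.size()) stop("row %d: length mismatch", r + 1);
    int tpos = t_starts[r] - 1;
    bool ins_flagged = false;
    for (size_t c = 0; c < ts.size(); ++c) {
      char t = ts[c], q = qs[c];
      if (t != '-') {
        ++tpos; ins_flagged = false;
        if (tpos < 0 || tpos >= tlen) stop("row %d: template position out of range", r + 1);
        if (q == '-') M(tpos, 4)++;
        else if (q == 'N') M(tpos, 5)++;
        else {
          int b = base2bit(q);
          if (b >= 0) M(tpos, 6 + b)++;
          if (q == t) M(tpos, 0)++; else M(tpos, 1)++;
        }
      } else {
        if (q != 'N' && q != '-' && tpos >= 0 && tpos < tlen) {
          M(tpos, 2)++;
          if (!ins_flagged) { M(tpos, 3)++; ins_flagged = true; }
        }
      }
    }
  }
  colnames(M) = CharacterVector::create("match", "mis", "insert", "ins_reads",
                                        "del", "skip", "A", "C", "G", "T");
  return M;
}

// Inserted strings observed between template position p and p+1 (left-
// attributed); masked characters terminate a run and are not recorded.
// [[Rcpp::export]]
List cpp_collect_inserts(CharacterVector tstrs, CharacterVector rows,
                         IntegerVector t_starts, int tlen) {
  std::vector<std::vector<std::string>> acc(tlen);
  for (int r = 0; r < tstrs.size(); ++r) {
    std::string ts = as<std::string>(tstrs[r]);
    std::string qs = as<std::string>(rows[r]);
    int tpos = t_starts[r] - 1;
    std::string run;
    int run_pos = -1;
    auto flush = [&]() {
      if (!run.empty() && run_pos >= 0 && run_pos < tlen)
        acc[run_pos].push_back(run);
      run.clear(); run_pos = -1;
    };
    for (size_t c = 0; c < ts.size(); ++c) {
      if (ts[c] != '-') { flush(); ++tpos; continue; }
      char q = qs[c];
      if (q == 'N' || q == '-') { flush(); continue; }
      if (run.empty()) run_pos = tpos;
      run.push_back(q);
    }
    flush();
  }
  List out(tlen);
  for (int p = 0; p < tlen; ++p) out[p] = wrap(acc[p]);
  return out;
}

// ---------------------------------------------------------------------------
// Extraction of per-candidate rows over a template area [s, e).
// Keys encode (template position, insertion rank): key = pos * 2048 + rank.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_area_rows(CharacterVector tstrs, CharacterVector rows,
                   IntegerVector t_starts, int area_start, int area_end) {
  int n = tstrs.size();
  List out(n);
  for (int r = 0; r < n; ++r) {
    std::string ts = as<std::string>(tstrs[r]);
    std::string qs = as<std::string>(rows[r]);
    int tpos = t_starts[r] - 1;
    int off = 0;
    std::vector<int> keys;
    std::string chars;
    int t_cons = 0;
    for (size_t c = 0; c < ts.size(); ++c) {
      char q = qs[c];
      if (ts[c] != '-') {
        ++tpos; ++t_cons; off = 0;
        if (tpos >= area_start && tpos < area_end && q != '-') {
          keys.push_back(tpos * 2048);
          chars.push_back(q);
        }
      } else {
        if (off < 2047) ++off;
        if (q != '-' && tpos >= area_start && tpos <= area_end - 1) {
          keys.push_back(tpos * 2048 + off);
          chars.push_back(q);
        }
      }
    }
    int t_end = t_starts[r] + t_cons;
    bool full = (t_starts[r] <= area_start) && (t_end >= area_end);
    out[r] = List::create(_["keys"] = wrap(keys), _["chars"] = chars,
                          _["full"] = full);
  }
  return out;
}

// Single-pass variant: extract rows for several disjoint sorted areas at
// once (one walk per alignment).
// [[Rcpp::export]]
List cpp_area_rows_multi(CharacterVector tstrs, CharacterVector rows,
                         IntegerVector t_starts, IntegerVector starts,
                         IntegerVector ends) {
  int na = starts.size(), nr = tstrs.size();
  std::vector<std::vector<std::vector<int>>> keys(na);
  std::vector<std::vector<std::string>> chars(na);
  std::vector<std::vector<char>> full(na);
  for (int a = 0; a < na; ++a) {
    keys[a].resize(nr); chars[a].resize(nr); full[a].assign(nr, 0);
  }
  for (int r = 0; r < nr; ++r) {
    const char *ts = CHAR(STRING_ELT(tstrs, r));
    const char *qs = CHAR(STRING_ELT(rows, r));
    int L = (int) LENGTH(STRING_ELT(tstrs, r));
    int tpos = t_starts[r] - 1;
    int off = 0, a = 0, t_cons = 0;
    for (int c = 0; c < L; ++c) {
      char q = qs[c];
      if (ts[c] != '-') { ++tpos; ++t_cons; off = 0; } else if (off < 2047) ++off;
      if (q == '-') continue;
      while (a < na && tpos >= ends[a]) ++a;
      if (a >= na) break;
      if (tpos < starts[a]) continue;
      keys[a][r].push_back(tpos * 2048 + (ts[c] != '-' ? 0 : off));
      chars[a][r].push_back(q);
    }
    int t_end = t_starts[r] + t_cons;
    for (int a2 = 0; a2 < na; ++a2)
      full[a2][r] = (t_starts[r] <= starts[a2]) && (t_end >= ends[a2]);
  }
  List out(na);
  for (int a = 0; a < na; ++a) {
    List kl(nr); CharacterVector cv(nr); LogicalVector fl(nr);
    for (int r = 0; r < nr; ++r) {
      kl[r] = wrap(keys[a][r]); cv[r] = chars[a][r]; fl[r] = (bool) full[a][r];
    }
    out[a] = List::create(_["keys"] = kl, _["chars"] = cv, _["full"] = fl);
  }
  return out;
}

// ---------------------------------------------------------------------------
// DAG construction from candidate rows (template row included by the caller).
// Rows are split at 'N' characters; fragments contribute internal edges only,
// and a fragment attaches to source/sink only when it reaches its row's own
// first/last character and the row spans the whole area.
// Nodes not on any source->sink path are pruned.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_build_dag(List row_keys, CharacterVector row_chars,
                   LogicalVector row_full, LogicalVector row_is_template,
                   bool drop_n) {
  int nrows = row_keys.size();
  // collect unique (key, base) nodes
  struct NodeInfo { int key; char base; bool templ; };
  std::unordered_map<int64_t, int> node_id;  // (key*4 + base2bit) -> tmp id
  std::vector<NodeInfo> nodes;
  auto get_node = [&](int key, char base, bool templ) -> int {
    int64_t h = (int64_t) key * 4 + base2bit(base);
    auto it = node_id.find(h);
    if (it != node_id.end()) {
      if (templ) nodes[it->second].templ = true;
      return it->second;
    }
    int id = (int) nodes.size();
    nodes.push_back({key, base, templ});
    node_id[h] = id;
    return id;
  };

  struct EdgeInfo { int w; bool templ; };
  std::unordered_map<int64_t, EdgeInfo> edges;  // (u+1)*M + (v+1); -1 source, -2 sink
  const int64_t M = 1 << 21;
  auto add_edge = [&](int u, int v, bool templ) {
    int64_t h = (int64_t) (u + 3) * M + (v + 3);
    auto it = edges.find(h);
    if (it == edges.end()) edges[h] = {1, templ};
    else { it->second.w += 1; it->second.templ = it->second.templ || templ; }
  };

  for (int r = 0; r < nrows; ++r) {
    IntegerVector keys = row_keys[r];
    std::string chars = as<std::string>(row_chars[r]);
    bool templ = row_is_template[r];
    bool full = row_full[r];
    int n = (int) chars.size();
    if (n == 0) continue;
    bool has_n = chars.find('N') != std::string::npos;
    if (has_n && !drop_n)
      stop("rows containing masked characters require drop_n_edges = TRUE");
    int i = 0;
    while (i < n) {
      while (i < n && chars[i] == 'N') ++i;
      if (i >= n) break;
      int start = i;
      while (i < n && chars[i] != 'N') ++i;  // fragment [start, i)
      int prev = -10;
      for (int t = start; t < i; ++t) {
        int id = get_node(keys[t], chars[t], templ);
        if (t == start) {
          if (full && start == 0) add_edge(-1, id, templ);  // source
        } else {
          add_edge(prev, id, templ);
        }
        prev = id;
      }
      if (full && i == n) add_edge(prev, -2, templ);  // sink
    }
  }

  int nn = (int) nodes.size();
  // topological order: sort by (key, base); source first, sink last
  std::vector<int> order(nn);
  for (int i = 0; i < nn; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (nodes[a].key != nodes[b].key) return nodes[a].key < nodes[b].key;
    return nodes[a].base < nodes[b].base;
  });
  std::vector<int> rank(nn);
  for (int i = 0; i < nn; ++i) rank[order[i]] = i + 1;  // 1..nn; source 0, sink nn+1

  // reachability pruning
  int N = nn + 2;
  std::vector<std::vector<std::pair<int,int>>> adj(N), radj(N);  // (to, edge idx)
  std::vector<int> efrom, eto, ew; std::vector<char> etempl;
  for (auto &kv : edges) {
    int u = (int) (kv.first / M) - 3, v = (int) (kv.first % M) - 3;
    int uu = (u == -1) ? 0 : rank[u];
    int vv = (v == -2) ? nn + 1 : rank[v];
    int idx = (int) efrom.size();
    efrom.push_back(uu); eto.push_back(vv);
    ew.push_back(kv.second.w); etempl.push_back(kv.second.templ ? 1 : 0);
    adj[uu].push_back({vv, idx}); radj[vv].push_back({uu, idx});
  }
  std::vector<char> fwd(N, 0), bwd(N, 0);
  std::vector<int> stack = {0}; fwd[0] = 1;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    for (auto &p : adj[u]) if (!fwd[p.first]) { fwd[p.first] = 1; stack.push_back(p.first); }
  }
  stack = {nn + 1}; bwd[nn + 1] = 1;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    for (auto &p : radj[u]) if (!bwd[p.first]) { bwd[p.first] = 1; stack.push_back(p.first); }
  }
  // renumber kept internal nodes, preserving topological order
  std::vector<int> newid(N, -1);
  int m = 0;
  for (int i = 1; i <= nn; ++i) if (fwd[i] && bwd[i]) newid[i] = ++m;
  std::vector<int> kf, kt, kw; std::vector<char> ktm;
  for (size_t idx = 0; idx < efrom.size(); ++idx) {
    int u = efrom[idx], v = eto[idx];
    if (!(fwd[u] && bwd[u] && fwd[v] && bwd[v])) continue;
    int uu = (u == 0) ? 0 : newid[u];
    int vv = (v == nn + 1) ? m + 1 : newid[v];
    kf.push_back(uu); kt.push_back(vv); kw.push_back(ew[idx]); ktm.push_back(etempl[idx]);
  }
  IntegerVector nid(m), npos(m), noff(m); CharacterVector nbase(m); LogicalVector ntempl(m);
  for (int i = 1; i <= nn; ++i) if (newid[i] > 0) {
    int orig = order[i - 1];
    int id = newid[i];
    nid[id - 1] = id;
    npos[id - 1] = nodes[orig].key / 2048;
    noff[id - 1] = nodes[orig].key % 2048;
    nbase[id - 1] = std::string(1, nodes[orig].base);
    ntempl[id - 1] = nodes[orig].templ;
  }
  return List::create(
      _["nodes"] = DataFrame::create(_["node"] = nid, _["pos"] = npos,
                                     _["off"] = noff, _["base"] = nbase,
                                     _["from_template"] = ntempl),
      _["edges"] = DataFrame::create(_["from"] = wrap(kf), _["to"] = wrap(kt),
                                     _["weight"] = wrap(kw),
                                     _["template"] = LogicalVector(ktm.begin(), ktm.end())),
      _["n_nodes"] = m);
}

// ---------------------------------------------------------------------------
// Max-weight source->sink path by DP over the topological node order
// (node ids 0 = source, 1..n internal in topological order, n+1 = sink).
// Ties prefer template-supporting edges, then the lexicographically smaller
// predecessor base, then the smaller predecessor id.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_max_weight_path(int n_nodes, IntegerVector efrom, IntegerVector eto,
                         IntegerVector weight, LogicalVector etempl,
                         CharacterVector node_base, double center) {
  int N = n_nodes + 2;
  const double NEG = -1e18;
  std::vector<double> dp(N, NEG);
  std::vector<long long> raw(N, 0);
  std::vector<int> pred(N, -1);
  std::vector<char> pred_templ(N, 0);
  dp[0] = 0;
  int ne = efrom.size();
  std::vector<int> ord(ne);
  for (int i = 0; i < ne; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return eto[a] < eto[b]; });
  auto base_of = [&](int u) -> char {
    if (u <= 0 || u > n_nodes) return '\0';
    return as<std::string>(node_base[u - 1])[0];
  };
  for (int oi = 0; oi < ne; ++oi) {
    int e = ord[oi];
    int u = efrom[e], v = eto[e];
    if (dp[u] == NEG) continue;
    double cand = dp[u] + weight[e] - center;
    long long craw = raw[u] + weight[e];
    bool better = cand > dp[v];
    if (!better && cand == dp[v]) {
      bool t_new = etempl[e], t_old = pred_templ[v];
      if (t_new != t_old) better = t_new;
      else {
        char b_new = base_of(u), b_old = base_of(pred[v]);
        if (b_new != b_old) better = b_new < b_old;
        else better = u < pred[v];
      }
    }
    if (better) { dp[v] = cand; raw[v] = craw; pred[v] = u; pred_templ[v] = etempl[e]; }
  }
  int sink = n_nodes + 1;
  if (dp[sink] == NEG)
    return List::create(_["path"] = IntegerVector(0), _["weight"] = NA_INTEGER);
  std::vector<int> path;
  int u = pred[sink];
  while (u > 0) { path.push_back(u); u = pred[u]; }
  std::reverse(path.begin(), path.end());
  return List::create(_["path"] = wrap(path),
                      _["weight"] = (double) raw[sink],
                      _["score"] = dp[sink]);
}

// ---------------------------------------------------------------------------
// Fitting alignment (read global, reference prefix/suffix free), banded.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cpp_fit_distance(std::string q, std::string ref, int band) {
  int Lr = (int) q.size(), Lt = (int) ref.size();
  int delta = Lt - Lr;
  int dlo = std::min(0, delta) - band, dhi = std::max(0, delta) + band;
  if (dlo < -Lr) dlo = -Lr;
  if (dhi > Lt) dhi = Lt;
  int W = dhi - dlo + 1;
  std::vector<int> prev(W, BIG), cur(W, BIG);
  for (int idx = 0; idx < W; ++idx) {
    int j = dlo + idx;
    if (j >= 0 && j <= Lt) prev[idx] = 0;  // free reference prefix
  }
  for (int i = 1; i <= Lr; ++i) {
    for (int idx = 0; idx < W; ++idx) {
      cur[idx] = BIG;
      int j = i + dlo + idx;
      if (j < 0 || j > Lt) continue;
      int best = BIG;
      if (j >= 1 && prev[idx] < BIG)
        best = prev[idx] + (q[i - 1] == ref[j - 1] ? 0 : 1);
      if (idx + 1 < W && prev[idx + 1] < BIG)
        best = std::min(best, prev[idx + 1] + 1);   // read base vs gap
      if (idx >= 1 && j >= 1 && cur[idx - 1] < BIG)
        best = std::min(best, cur[idx - 1] + 1);    // ref base vs gap
      cur[idx] = best;
    }
    std::swap(prev, cur);
  }
  int ans = BIG;
  for (int idx = 0; idx < W; ++idx) ans = std::min(ans, prev[idx]);
  return ans >= BIG ? NA_INTEGER : ans;
}

// [[Rcpp::export]]
List cpp_fit_align_counts(std::string q, std::string ref, int band) {
  int Lr = (int) q.size(), Lt = (int) ref.size();
  int delta = Lt - Lr;
  int dlo = std::min(0, delta) - band, dhi = std::max(0, delta) + band;
  if (dlo < -Lr) dlo = -Lr;
  if (dhi > Lt) dhi = Lt;
  int W = dhi - dlo + 1;
  std::vector<int> prev(W, BIG), cur(W, BIG);
  std::vector<uint8_t> mv((size_t) (Lr + 1) * W, 0);  // 1 diag, 2 ins(read), 3 del(ref)
  for (int idx = 0; idx < W; ++idx) {
    int j = dlo + idx;
    if (j >= 0 && j <= Lt) prev[idx] = 0;
  }
  for (int i = 1; i <= Lr; ++i) {
    size_t row = (size_t) i * W;
    for (int idx = 0; idx < W; ++idx) {
      cur[idx] = BIG;
      int j = i + dlo + idx;
      if (j < 0 || j > Lt) continue;
      int best = BIG; uint8_t bm = 0;
      if (j >= 1 && prev[idx] < BIG) {
        int v = prev[idx] + (q[i - 1] == ref[j - 1] ? 0 : 1);
        if (v < best) { best = v; bm = 1; }
      }
      if (idx + 1 < W && prev[idx + 1] < BIG) {
        int v = prev[idx + 1] + 1;
        if (v < best) { best = v; bm = 2; }
      }
      if (idx >= 1 && j >= 1 && cur[idx - 1] < BIG) {
        int v = cur[idx - 1] + 1;
        if (v < best) { best = v; bm = 3; }
      }
      cur[idx] = best; mv[row + idx] = bm;
    }
    std::swap(prev, cur);
  }
  int best = BIG, bestj = -1;
  for (int idx = 0; idx < W; ++idx) {
    int j = Lr + dlo + idx;
    if (j < 0 || j > Lt) continue;
    if (prev[idx] < best) { best = prev[idx]; bestj = j; }
  }
  if (best >= BIG)
    return List::create(_["dist"] = NA_INTEGER);
  int i = Lr, j = bestj;
  int nmat = 0, nmis = 0, nins = 0, ndel = 0;
  while (i > 0) {
    int idx = (j - i) - dlo;
    uint8_t m = mv[(size_t) i * W + idx];
    if (m == 1) {
      if (q[i - 1] == ref[j - 1]) ++nmat; else ++nmis;
      --i; --j;
    } else if (m == 2) { ++nins; --i; }
    else if (m == 3) { ++ndel; --j; }
    else break;
  }
  return List::create(_["dist"] = best, _["nmat"] = nmat, _["nmis"] = nmis,
                      _["nins"] = nins, _["ndel"] = ndel,
                      _["ref_start"] = j, _["ref_end"] = bestj);
}
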
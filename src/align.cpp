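// Fit alignment of tRNA-seq reads against mature tRNA references.
//
// The aligner consumes the whole read except clipped ends, while the aligned
// span may start and end anywhere on the reference (free reference flanks).
// Scoring: match 0, mismatch -5, affine gaps (a gap of length L costs
// open + L*extend = -5 - 3L), up to clip5_max_free read bases clippable at the
// 5' end at zero cost (further 5' clips and all internal 3' clips cost -5 per
// base), and 3' clips are free only when the alignment ends at the reference
// 3' terminus (read bases extending past the molecule end, e.g. non-templated
// tails). At least min_cols reference-consuming columns are required;
// otherwise the read is reported unalignable.

#include <Rcpp.h>
#include <climits>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

const int NEG = INT_MIN / 4;

struct Scheme {
  int match_s, mismatch, gap_open, gap_ext, clip5_free, clip3_free, clip_pen,
      min_cols;
};

Scheme scheme_from_list(const List &s) {
  Scheme sc;
  sc.match_s = as<int>(s["match"]);
  sc.mismatch = as<int>(s["mismatch"]);
  sc.gap_open = as<int>(s["gap_open"]);
  sc.gap_ext = as<int>(s["gap_extend"]);
  sc.clip5_free = as<int>(s["clip5_max_free"]);
  sc.clip3_free = as<int>(s["clip3_max_free"]);
  sc.clip_pen = as<int>(s["clip_penalty"]);
  sc.min_cols = as<int>(s["min_ref_cols"]);
  return sc;
}

inline int clip5_cost(int len, const Scheme &sc) {
  return len <= sc.clip5_free ? 0 : sc.clip_pen * (len - sc.clip5_free);
}
// 3' clips are free only past the reference terminus, and only up to
// clip3_free bases (non-templated additions are short; an unbounded free
// clip would let junk reads pay nothing for aligning a token terminal seed).
inline int clip3_cost(int len, bool at_terminus, const Scheme &sc) {
  if (len == 0) return 0;
  if (at_terminus) return len <= sc.clip3_free ? 0 : sc.clip_pen * (len - sc.clip3_free);
  return sc.clip_pen * len;
}

struct AlnResult {
  bool ok = false;
  int score = NEG;
  int ref_start = -1, ref_end = -1;
  int clip5 = 0, clip3 = 0;
  int n_sub = 0, n_del = 0, n_ins = 0;
  std::string cigar;
};

// Reusable DP buffers (score, clip5-at-start, ref-start).
struct DPBuf {
  std::vector<int> V, C, R;
  void ensure(size_t sz) {
    if (V.size() < sz) { V.resize(sz); C.resize(sz); R.resize(sz); }
  }
};

// State encoding: 0 = M (diagonal), 1 = I (insertion, consumes read),
// 2 = D (deletion, consumes ref).
struct DP {
  int m, n, K;
  size_t stride_j, stride_k;
  int *V; int *C; int *R;
  inline size_t idx(int i, int j, int k, int s) const {
    return ((size_t)i * stride_j + j) * stride_k + (size_t)k * 3 + s;
  }
};

// Lexicographic improvement: higher score, then smaller clip5, then smaller
// ref_start. Used both for DP cell updates and end-cell selection.
inline bool better(int sc, int c, int r, int sc0, int c0, int r0) {
  if (sc != sc0) return sc > sc0;
  if (c != c0) return c < c0;
  return r < r0;
}

AlnResult fit_align_core(const std::string &read, const std::string &ref,
                         const Scheme &sc, DPBuf &buf) {
  AlnResult res;
  const int m = (int)read.size(), n = (int)ref.size(), K = sc.min_cols;
  if (m < 1 || n < K) return res;
  DP dp;
  dp.m = m; dp.n = n; dp.K = K;
  dp.stride_j = (size_t)n + 1;
  dp.stride_k = (size_t)(K + 1) * 3;
  size_t sz = (size_t)(m + 1) * dp.stride_j * dp.stride_k;
  buf.ensure(sz);
  dp.V = buf.V.data(); dp.C = buf.C.data(); dp.R = buf.R.data();
  std::fill(dp.V, dp.V + sz, NEG);

  const int go = sc.gap_open, ge = sc.gap_ext;

  for (int i = 1; i <= m; ++i) {
    const char rb = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int subsc = (rb == ref[j - 1]) ? sc.match_s : sc.mismatch;
      for (int k = 1; k <= K; ++k) {
        // ---- M: diagonal from (i-1, j-1, k') ----
        int bs = NEG, bc = INT_MAX, br = INT_MAX;
        for (int pass = 0; pass < 2; ++pass) {
          int kp = (pass == 0) ? k - 1 : K;
          if (pass == 1 && k != K) break;
          if (kp >= 1) {
            for (int s = 0; s < 3; ++s) {
              size_t p = dp.idx(i - 1, j - 1, kp, s);
              if (dp.V[p] > NEG && better(dp.V[p], dp.C[p], dp.R[p], bs, bc, br)) {
                bs = dp.V[p]; bc = dp.C[p]; br = dp.R[p];
              }
            }
          }
        }
        if (k == 1) {  // fresh start: clip5 = i-1 read bases, ref_start = j-1
          int s0 = clip5_cost(i - 1, sc);
          if (better(s0, i - 1, j - 1, bs, bc, br)) { bs = s0; bc = i - 1; br = j - 1; }
        }
        size_t q = dp.idx(i, j, k, 0);
        if (bs > NEG) { dp.V[q] = bs + subsc; dp.C[q] = bc; dp.R[q] = br; }

        // ---- I: insertion from (i-1, j, k) ----
        bs = NEG; bc = INT_MAX; br = INT_MAX;
        {
          size_t pM = dp.idx(i - 1, j, k, 0), pI = dp.idx(i - 1, j, k, 1),
                 pD = dp.idx(i - 1, j, k, 2);
          if (dp.V[pM] > NEG && better(dp.V[pM] + go + ge, dp.C[pM], dp.R[pM], bs, bc, br)) {
            bs = dp.V[pM] + go + ge; bc = dp.C[pM]; br = dp.R[pM];
          }
          if (dp.V[pI] > NEG && better(dp.V[pI] + ge, dp.C[pI], dp.R[pI], bs, bc, br)) {
            bs = dp.V[pI] + ge; bc = dp.C[pI]; br = dp.R[pI];
          }
          if (dp.V[pD] > NEG && better(dp.V[pD] + go + ge, dp.C[pD], dp.R[pD], bs, bc, br)) {
            bs = dp.V[pD] + go + ge; bc = dp.C[pD]; br = dp.R[pD];
          }
        }
        q = dp.idx(i, j, k, 1);
        if (bs > NEG) { dp.V[q] = bs; dp.C[q] = bc; dp.R[q] = br; }

        // ---- D: deletion from (i, j-1, k') ----
        bs = NEG; bc = INT_MAX; br = INT_MAX;
        for (int pass = 0; pass < 2; ++pass) {
          int kp = (pass == 0) ? k - 1 : K;
          if (pass == 1 && k != K) break;
          if (kp >= 1) {
            size_t pM = dp.idx(i, j - 1, kp, 0), pI = dp.idx(i, j - 1, kp, 1),
                   pD = dp.idx(i, j - 1, kp, 2);
            if (dp.V[pM] > NEG && better(dp.V[pM] + go + ge, dp.C[pM], dp.R[pM], bs, bc, br)) {
              bs = dp.V[pM] + go + ge; bc = dp.C[pM]; br = dp.R[pM];
            }
            if (dp.V[pI] > NEG && better(dp.V[pI] + go + ge, dp.C[pI], dp.R[pI], bs, bc, br)) {
              bs = dp.V[pI] + go + ge; bc = dp.C[pI]; br = dp.R[pI];
            }
            if (dp.V[pD] > NEG && better(dp.V[pD] + ge, dp.C[pD], dp.R[pD], bs, bc, br)) {
              bs = dp.V[pD] + ge; bc = dp.C[pD]; br = dp.R[pD];
            }
          }
        }
        q = dp.idx(i, j, k, 2);
        if (bs > NEG) { dp.V[q] = bs; dp.C[q] = bc; dp.R[q] = br; }
      }
    }
  }

  // ---- end-cell selection ----
  int bestT = NEG, bestClips = INT_MAX, bestR = INT_MAX;
  int ei = -1, ej = -1, es = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      for (int s = 0; s < 3; ++s) {
        size_t p = dp.idx(i, j, K, s);
        if (dp.V[p] <= NEG) continue;
        int tot = dp.V[p] + clip3_cost(m - i, j == n, sc);
        int clips = dp.C[p] + (m - i);
        if (better(tot, clips, dp.R[p], bestT, bestClips, bestR)) {
          bestT = tot; bestClips = clips; bestR = dp.R[p];
          ei = i; ej = j; es = s;
        }
      }
    }
  }
  if (ei < 0) return res;

  // ---- traceback (preference M > D > I, consistent with stored aux) ----
  std::string ops;  // reversed
  int i = ei, j = ej, k = K, s = es;
  size_t cur = dp.idx(i, j, k, s);
  int curV = dp.V[cur], curC = dp.C[cur], curR = dp.R[cur];
  while (true) {
    if (s == 0) {
      const int subsc = (read[i - 1] == ref[j - 1]) ? sc.match_s : sc.mismatch;
      ops.push_back(subsc == sc.match_s ? '=' : 'X');
      if (k == 1) {
        int s0 = clip5_cost(i - 1, sc);
        if (curV == s0 + subsc && curC == i - 1 && curR == j - 1) {
          i -= 1; j -= 1;  // reached the start
          break;
        }
      }
      bool found = false;
      for (int pass = 0; pass < 2 && !found; ++pass) {
        int kp = (pass == 0) ? k - 1 : K;
        if (pass == 1 && k != K) break;
        if (kp < 1) continue;
        static const int pref[3] = {0, 2, 1};
        for (int t = 0; t < 3 && !found; ++t) {
          int sp = pref[t];
          size_t p = dp.idx(i - 1, j - 1, kp, sp);
          if (dp.V[p] > NEG && dp.V[p] + subsc == curV && dp.C[p] == curC && dp.R[p] == curR) {
            i -= 1; j -= 1; k = kp; s = sp;
            curV = dp.V[p]; found = true;
          }
        }
      }
      if (!found) stop("internal error: fit_align traceback failed (M)");
    } else if (s == 1) {  // insertion consumed read[i-1]
      ops.push_back('I');
      bool found = false;
      static const int pref[3] = {0, 2, 1};
      for (int t = 0; t < 3 && !found; ++t) {
        int sp = pref[t];
        int cost = (sp == 1) ? ge : go + ge;
        size_t p = dp.idx(i - 1, j, k, sp);
        if (dp.V[p] > NEG && dp.V[p] + cost == curV && dp.C[p] == curC && dp.R[p] == curR) {
          i -= 1; s = sp; curV = dp.V[p]; found = true;
        }
      }
      if (!found) stop("internal error: fit_align traceback failed (I)");
    } else {  // deletion consumed ref[j-1]
      ops.push_back('D');
      bool found = false;
      for (int pass = 0; pass < 2 && !found; ++pass) {
        int kp = (pass == 0) ? k - 1 : K;
        if (pass == 1 && k != K) break;
        if (kp < 1) continue;
        static const int pref[3] = {0, 2, 1};
        for (int t = 0; t < 3 && !found; ++t) {
          int sp = pref[t];
          int cost = (sp == 2) ? ge : go + ge;
          size_t p = dp.idx(i, j - 1, kp, sp);
          if (dp.V[p] > NEG && dp.V[p] + cost == curV && dp.C[p] == curC && dp.R[p] == curR) {
            j -= 1; k = kp; s = sp; curV = dp.V[p]; found = true;
          }
        }
      }
      if (!found) stop("internal error: fit_align traceback failed (D)");
    }
  }

  res.ok = true;
  res.score = bestT;
  res.clip5 = i;           // read bases clipped at 5'
  res.clip3 = m - ei;      // read bases clipped at 3'
  res.ref_start = j;
  res.ref_end = ej;
  // compress reversed ops into CIGAR (with clips)
  std::string cig;
  auto append_run = [&cig](char op, int len) {
    if (len > 0) cig += std::to_string(len) + op;
  };
  append_run('S', res.clip5);
  int run = 0; char cur_op = 0;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    char o = *it;
    if (o == 'X') res.n_sub++;
    else if (o == 'D') res.n_del++;
    else if (o == 'I') res.n_ins++;
    if (o == cur_op) run++;
    else { append_run(cur_op, run); cur_op = o; run = 1; }
  }
  append_run(cur_op, run);
  append_run('S', res.clip3);
  res.cigar = cig;
  return res;
}

// Exact score-0 search: alignment with no mismatches/gaps, 5' clip of at most
// clip5_free bases, and 3' clip only past the reference terminus. Returns the
// candidate with the fewest clipped bases (then smallest ref_start).
bool score0_align(const std::string &read, const std::string &ref,
                  const Scheme &sc, AlnResult &out) {
  const int m = (int)read.size(), n = (int)ref.size();
  bool found = false;
  int bestClips = INT_MAX, bestStart = INT_MAX, bestJ = 0, bestL = 0;
  bool bestOverhang = false;
  int jmax = std::min(sc.clip5_free, m - sc.min_cols);
  for (int j = 0; j <= jmax; ++j) {
    int slen = m - j;
    // (a) full suffix as exact substring
    if (slen >= sc.min_cols && slen <= n) {
      size_t pos = ref.find(read.c_str() + j, 0, slen);
      if (pos != std::string::npos) {
        int clips = j;
        if (clips < bestClips || (clips == bestClips && (int)pos < bestStart)) {
          bestClips = clips; bestStart = (int)pos; bestJ = j; bestL = slen;
          bestOverhang = false; found = true;
        }
        if (clips == 0) break;  // cannot do better
        continue;  // (b) would clip more at this j
      }
    }
    // (b) prefix of the suffix matches the reference 3' end; rest clipped
    // free (at most clip3_free bases)
    int Lmax = std::min(slen - 1, n);
    int Lmin = std::max(sc.min_cols, slen - sc.clip3_free);
    for (int L = Lmax; L >= Lmin; --L) {
      int clips = j + (slen - L);
      if (clips >= bestClips) break;
      if (std::memcmp(read.c_str() + j, ref.c_str() + (n - L), L) == 0) {
        bestClips = clips; bestStart = n - L; bestJ = j; bestL = L;
        bestOverhang = true; found = true;
        break;
      }
    }
  }
  if (!found) return false;
  out.ok = true;
  out.score = 0;
  out.clip5 = bestJ;
  out.clip3 = m - bestJ - bestL;
  out.ref_start = bestStart;
  out.ref_end = bestStart + bestL;
  out.n_sub = out.n_del = out.n_ins = 0;
  std::string cig;
  if (out.clip5) cig += std::to_string(out.clip5) + 'S';
  cig += std::to_string(bestL) + '=';
  if (out.clip3) cig += std::to_string(out.clip3) + 'S';
  out.cigar = cig;
  (void)bestOverhang;
  return true;
}

List result_to_list(const AlnResult &r) {
  return List::create(
      _["unalignable"] = !r.ok, _["score"] = r.score, _["ref_start"] = r.ref_start,
      _["ref_end"] = r.ref_end, _["clip5"] = r.clip5, _["clip3"] = r.clip3,
      _["n_sub"] = r.n_sub, _["n_del"] = r.n_del, _["n_ins"] = r.n_ins,
      _["cigar"] = r.cigar);
}

}  // namespace

// [[Rcpp::export(name = ".fit_align_cpp")]]
List fit_align_cpp(std::string read, std::string ref, List scheme) {
  Scheme sc = scheme_from_list(scheme);
  DPBuf buf;
  AlnResult fast;
  if (score0_align(read, ref, sc, fast)) return result_to_list(fast);
  AlnResult r = fit_align_core(read, ref, sc, buf);
  return result_to_list(r);
}

// Batch mapper: aligns every read against every reference, using the exact
// score-0 fast path where possible and the full DP otherwise. References must
// be passed sorted by gene id (the tie-break among equal best scores is the
// first reference in that order, making the result permutation-invariant).
// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector reads, CharacterVector refs, List scheme,
                   double min_score_intercept, double min_score_slope) {
  Scheme sc = scheme_from_list(scheme);
  int nr = reads.size(), ng = refs.size();
  std::vector<std::string> refv(ng);
  for (int g = 0; g < ng; ++g) refv[g] = as<std::string>(refs[g]);

  IntegerVector gene(nr, NA_INTEGER);
  IntegerVector score(nr, NA_INTEGER), ref_start(nr, NA_INTEGER),
      ref_end(nr, NA_INTEGER), clip5(nr, NA_INTEGER), clip3(nr, NA_INTEGER),
      n_sub(nr, NA_INTEGER), n_del(nr, NA_INTEGER), n_ins(nr, NA_INTEGER);
  LogicalVector ambiguous(nr, false), unmapped(nr, true);
  CharacterVector cigar(nr, NA_STRING), tied(nr, NA_STRING);

  DPBuf buf;
  std::vector<AlnResult> per_gene(ng);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    double thr = min_score_intercept + min_score_slope * (double)rd.size();
    int best = NEG;
    std::vector<int> tie;
    bool any_fast = false;
    for (int g = 0; g < ng; ++g) {
      per_gene[g] = AlnResult();
      if (score0_align(rd, refv[g], sc, per_gene[g])) any_fast = true;
    }
    if (!any_fast) {
      for (int g = 0; g < ng; ++g) per_gene[g] = fit_align_core(rd, refv[g], sc, buf);
    }
    for (int g = 0; g < ng; ++g) {
      if (!per_gene[g].ok) continue;
      if (per_gene[g].score > best) { best = per_gene[g].score; tie.clear(); tie.push_back(g); }
      else if (per_gene[g].score == best) tie.push_back(g);
    }
    if (tie.empty() || (double)best < thr) continue;
    int win = tie[0];
    const AlnResult &a = per_gene[win];
    unmapped[r] = false;
    gene[r] = win + 1;
    score[r] = a.score; ref_start[r] = a.ref_start; ref_end[r] = a.ref_end;
    clip5[r] = a.clip5; clip3[r] = a.clip3;
    n_sub[r] = a.n_sub; n_del[r] = a.n_del; n_ins[r] = a.n_ins;
    cigar[r] = a.cigar;
    if (tie.size() > 1) {
      ambiguous[r] = true;
      std::string t;
      for (size_t z = 0; z < tie.size(); ++z) {
        if (z) t += ",";
        t += std::to_string(tie[z] + 1);
      }
      tied[r] = t;
    }
  }
  return List::create(
      _["gene"] = gene, _["score"] = score, _["ref_start"] = ref_start,
      _["ref_end"] = ref_end, _["clip5"] = clip5, _["clip3"] = clip3,
      _["n_sub"] = n_sub, _["n_del"] = n_del, _["n_ins"] = n_ins,
      _["cigar"] = cigar, _["ambiguous"] = ambiguous, _["tied"] = tied,
      _["unmapped"] = unmapped);
}
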
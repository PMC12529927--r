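#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick complement of an RNA base; 0 for anything else.
static inline char rna_comp(char c) {
  switch (c) {
  case 'A': return 'U';
  case 'U': return 'A';
  case 'G': return 'C';
  case 'C': return 'G';
  default:  return 0;
  }
}

// target base r pairs guide base g (antiparallel); wobble adds G:U.
static inline bool base_pairs(char r, char g, bool wobble) {
  char c = rna_comp(g);
  if (c != 0 && r == c) return true;
  if (wobble && ((r == 'G' && g == 'U') || (r == 'U' && g == 'G'))) return true;
  return false;
}

struct Run {
  int gs, ge;  // guide positions, 1-based, gs <= ge
  int rs, re;  // target (read) positions, 1-based, rs <= re
};

// All maximal contiguous paired runs between `read` and guide positions
// [gmin, gmax], antiparallel: read position r pairs guide position g along
// diagonals r + g = const. Runs are maximal within the guide region.
static void find_runs(const std::string &read, const std::string &guide,
                      int gmin, int gmax, int min_len, bool wobble,
                      std::vector<Run> &out) {
  const int R = (int)read.size();
  const int L = (int)guide.size();
  if (gmax > L) gmax = L;
  if (gmin < 1) gmin = 1;
  if (gmin > gmax || R == 0) return;
  for (int s = 1 + gmin; s <= R + gmax; ++s) {
    const int rlo = std::max(1, s - gmax);
    const int rhi = std::min(R, s - gmin);
    if (rlo > rhi) continue;
    int runstart = -1;
    for (int r = rlo; r <= rhi + 1; ++r) {
      bool ok = (r <= rhi) && base_pairs(read[r - 1], guide[s - r - 1], wobble);
      if (ok && runstart < 0) runstart = r;
      if (!ok && runstart >= 0) {
        int i = runstart, j = r - 1;
        if (j - i + 1 >= min_len) {
          Run rn;
          rn.gs = s - j; rn.ge = s - i; rn.rs = i; rn.re = j;
          out.push_back(rn);
        }
        runstart = -1;
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_find_runs(std::string read, std::string guide,
                            int gmin, int gmax, int min_len, bool wobble) {
  std::vector<Run> runs;
  find_runs(read, guide, gmin, gmax, min_len, wobble, runs);
  IntegerMatrix out((int)runs.size(), 4);
  for (size_t k = 0; k < runs.size(); ++k) {
    out(k, 0) = runs[k].gs;
    out(k, 1) = runs[k].ge;
    out(k, 2) = runs[k].rs;
    out(k, 3) = runs[k].re;
  }
  colnames(out) = CharacterVector::create("guide_start", "guide_end",
                                          "target_start", "target_end");
  return out;
}

// Canonical class ranks: 1 8mer, 2 7mer-m8, 3 7mer-A1, 4 6mer, 5 6mer-m8,
// 6 6mer-A1; 0 none. Span of the class-defining positions written to sp/ep.
static int canonical_rank(const std::string &read, const Run &run,
                          int *sp, int *ep) {
  const int C = run.rs + run.ge;  // r + g along the diagonal
  const int R = (int)read.size();
  bool hasA = (C - 1 >= 1 && C - 1 <= R && read[C - 2] == 'A');
  bool c28 = (run.gs <= 2 && run.ge >= 8);
  bool c27 = (run.gs <= 2 && run.ge >= 7);
  bool c38 = (run.gs <= 3 && run.ge >= 8);
  bool c26 = (run.gs <= 2 && run.ge >= 6);
  if (c28 && hasA) { *sp = C - 8; *ep = C - 1; return 1; }
  if (c28)         { *sp = C - 8; *ep = C - 2; return 2; }
  if (c27 && hasA) { *sp = C - 7; *ep = C - 1; return 3; }
  if (c27)         { *sp = C - 7; *ep = C - 2; return 4; }
  if (c38)         { *sp = C - 8; *ep = C - 3; return 5; }
  if (c26 && hasA) { *sp = C - 6; *ep = C - 1; return 6; }
  return 0;
}

// Single-best-site assignment per read (RBNS-style precedence):
// compound > longest 3' register > canonical rank > none.
// category codes: 0 none, 1..6 canonical ranks above, 7 3p_only, 8 compound.
// [[Rcpp::export]]
DataFrame cpp_assign_reads(CharacterVector reads, std::string guide,
                           int min3p_start, int min3p_len, int max_seed_run,
                           int off_min, int off_max, int max_compound_seed,
                           bool wobble) {
  const int n = reads.size();
  const int L = (int)guide.size();
  IntegerVector cat(n), t3s(n, NA_INTEGER), t3e(n, NA_INTEGER),
      ss(n, NA_INTEGER), se(n, NA_INTEGER), off(n, NA_INTEGER),
      tstart(n, NA_INTEGER), tend(n, NA_INTEGER);
  LogicalVector ambig(n, false);
  std::vector<Run> seed_runs, p3_runs;
  for (int k = 0; k < n; ++k) {
    const std::string read = as<std::string>(reads[k]);
    seed_runs.clear(); p3_runs.clear();
    find_runs(read, guide, 1, 8, 2, wobble, seed_runs);
    find_runs(read, guide, min3p_start, L, min3p_len, wobble, p3_runs);

    // -- compound candidates ------------------------------------------------
    bool have_cmp = false, cmp_tie = false;
    Run cmp_t, cmp_s; int cmp_off = 0;
    for (size_t a = 0; a < p3_runs.size(); ++a) {
      const Run &t = p3_runs[a];
      for (size_t b = 0; b < seed_runs.size(); ++b) {
        const Run &s = seed_runs[b];
        int slen = s.ge - s.gs + 1;
        if (slen <= max_seed_run || slen > max_compound_seed) continue;
        if (s.rs <= t.re) continue;  // seed must lie 3' of the 3' match
        int bridge = s.rs - t.re - 1;
        int o = bridge - (t.gs - s.ge);
        if (o < off_min || o > off_max) continue;
        if (!have_cmp) {
          have_cmp = true; cmp_t = t; cmp_s = s; cmp_off = o;
        } else {
          // precedence key: t3 len desc, seed len desc, then left-most
          // (t3 target start, seed target start), then seed guide start,
          // then offset; a tie on the first two keys flags ambiguity
          int cand[6] = {-(t.ge - t.gs), -(s.ge - s.gs), t.rs, s.rs,
                         s.gs, o};
          int cur[6] = {-(cmp_t.ge - cmp_t.gs), -(cmp_s.ge - cmp_s.gs),
                        cmp_t.rs, cmp_s.rs, cmp_s.gs, cmp_off};
          int cmp = 0;
          for (int q = 0; q < 6 && cmp == 0; ++q)
            cmp = (cand[q] < cur[q]) ? -1 : (cand[q] > cur[q]) ? 1 : 0;
          bool rank_tie = (cand[0] == cur[0] && cand[1] == cur[1]);
          if (cmp < 0) {
            cmp_t = t; cmp_s = s; cmp_off = o;
            cmp_tie = rank_tie;
          } else if (rank_tie) {
            cmp_tie = true;
          }
        }
      }
    }
    if (have_cmp) {
      cat[k] = 8;
      t3s[k] = cmp_t.gs; t3e[k] = cmp_t.ge;
      ss[k] = cmp_s.gs; se[k] = cmp_s.ge;
      off[k] = cmp_off;
      tstart[k] = cmp_t.rs; tend[k] = cmp_s.re;
      ambig[k] = cmp_tie;
      continue;
    }

    // -- 3'-only ------------------------------------------------------------
    if (!p3_runs.empty()) {
      size_t best = 0; bool tie = false;
      for (size_t a = 1; a < p3_runs.size(); ++a) {
        int dl = (p3_runs[a].ge - p3_runs[a].gs) -
                 (p3_runs[best].ge - p3_runs[best].gs);
        if (dl > 0) { best = a; tie = false; }
        else if (dl == 0) {
          if (p3_runs[a].rs < p3_runs[best].rs) { best = a; tie = true; }
          else tie = true;
        }
      }
      const Run &t = p3_runs[best];
      cat[k] = 7;
      t3s[k] = t.gs; t3e[k] = t.ge;
      tstart[k] = t.rs; tend[k] = t.re;
      ambig[k] = tie;
      continue;
    }

    // -- canonical ----------------------------------------------------------
    int best_rank = 0, bsp = 0, bep = 0; bool tie = false;
    for (size_t b = 0; b < seed_runs.size(); ++b) {
      int sp, ep;
      int rk = canonical_rank(read, seed_runs[b], &sp, &ep);
      if (rk == 0) continue;
      if (best_rank == 0 || rk < best_rank) {
        best_rank = rk; bsp = sp; bep = ep; tie = false;
      } else if (rk == best_rank && (sp != bsp || ep != bep)) {
        if (sp < bsp) { bsp = sp; bep = ep; }
        tie = true;
      }
    }
    if (best_rank > 0) {
      cat[k] = best_rank;
      tstart[k] = bsp; tend[k] = bep;
      ambig[k] = tie;
    }
  }
  return DataFrame::create(
      _["category"] = cat, _["threep_start"] = t3s, _["threep_end"] = t3e,
      _["seed_start"] = ss, _["seed_end"] = se, _["offset"] = off,
      _["target_start"] = tstart, _["target_end"] = tend,
      _["ambiguous"] = ambig);
}
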
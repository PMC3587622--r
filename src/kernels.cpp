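// Edit-distance, alignment, k-mer index and duplex-stability kernels.
// '*' is the internal wildcard symbol (zero substitution cost against any
// base, zero gap cost); 'N' in a read matches nothing (unit cost everywhere).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline int sub_cost(char a, char b) {
  if (a == '*' || b == '*') return 0;
  if (a == 'N' || b == 'N') return 1;
  return a == b ? 0 : 1;
}

static inline int gap_cost(char c) { return c == '*' ? 0 : 1; }

static std::string pad_wild(const std::string& s, int P) {
  if (P <= 0) return s;
  return std::string(P, '*') + s + std::string(P, '*');
}

// Global edit distance with generalized wildcard costs.
// limit >= 0 enables the Ukkonen-style row-minimum cutoff: the return value is
// capped at limit + 1 (meaning "greater than limit").
static int edit_dist(const std::string& a, const std::string& b, int limit) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  prev[0] = 0;
  for (int j = 1; j <= m; ++j) prev[j] = prev[j - 1] + gap_cost(b[j - 1]);
  for (int i = 1; i <= n; ++i) {
    cur[0] = prev[0] + gap_cost(a[i - 1]);
    int rowmin = cur[0];
    for (int j = 1; j <= m; ++j) {
      int d  = prev[j - 1] + sub_cost(a[i - 1], b[j - 1]);
      int up = prev[j] + gap_cost(a[i - 1]);
      int lf = cur[j - 1] + gap_cost(b[j - 1]);
      int v = d < up ? d : up;
      if (lf < v) v = lf;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (limit >= 0 && rowmin > limit) return limit + 1;
    std::swap(prev, cur);
  }
  int res = prev[m];
  if (limit >= 0 && res > limit) return limit + 1;
  return res;
}

// [[Rcpp::export]]
IntegerVector lev_dist_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i % a.size()]);
    std::string sb = as<std::string>(b[i % b.size()]);
    out[i] = edit_dist(sa, sb, -1);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector padded_dist_cpp(CharacterVector a, CharacterVector b, int P) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = pad_wild(as<std::string>(a[i % a.size()]), P);
    std::string sb = pad_wild(as<std::string>(b[i % b.size()]), P);
    out[i] = edit_dist(sa, sb, -1);
  }
  return out;
}

// Minimum padded distance from `cand` to every string in `set`, with each
// pairwise computation capped at cap + 1. Early exit on a zero distance.
// [[Rcpp::export]]
int min_dist_to_set_cpp(std::string cand, CharacterVector set, int P, int cap) {
  std::string pc = pad_wild(cand, P);
  int best = INT_MAX;
  for (R_xlen_t i = 0; i < set.size(); ++i) {
    std::string pb = pad_wild(as<std::string>(set[i]), P);
    int d = edit_dist(pc, pb, cap);
    if (d < best) best = d;
    if (best == 0) break;
  }
  return best == INT_MAX ? NA_INTEGER : best;
}

// Counts of pairwise padded distances over all unordered pairs.
// Returns a vector c where c[d + 1] = number of pairs at distance d.
// [[Rcpp::export]]
IntegerVector pair_dist_counts_cpp(CharacterVector set, int P) {
  int n = set.size();
  int L = n > 0 ? (int)std::string(set[0]).size() : 0;
  int maxd = L + 2 * P + 1;
  IntegerVector counts(maxd + 1);
  std::vector<std::string> padded(n);
  for (int i = 0; i < n; ++i) padded[i] = pad_wild(as<std::string>(set[i]), P);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = edit_dist(padded[i], padded[j], -1);
      if (d > maxd) d = maxd;
      counts[d]++;
    }
    Rcpp::checkUserInterrupt();
  }
  return counts;
}

// ---------------------------------------------------------------------------
// Semi-global alignment: every character of `pat` is aligned, the flanks of
// `win` are free. Returns distance; traceback gives offset and the window
// positions of the unit-cost columns.

struct SGResult {
  int dist;
  int offset;        // window position where the (core) pattern starts
  int indels;
  std::vector<int> mism;  // 0-based window positions of cost-bearing columns
};

static void sg_fill(const std::string& pat, const std::string& win,
                    std::vector<std::vector<int> >& D) {
  int n = (int)pat.size(), m = (int)win.size();
  D.assign(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 1; i <= n; ++i) {
    D[i][0] = D[i - 1][0] + gap_cost(pat[i - 1]);
    for (int j = 1; j <= m; ++j) {
      int d  = D[i - 1][j - 1] + sub_cost(pat[i - 1], win[j - 1]);
      int up = D[i - 1][j] + gap_cost(pat[i - 1]);
      int lf = D[i][j - 1] + gap_cost(win[j - 1]);
      int v = d < up ? d : up;
      if (lf < v) v = lf;
      D[i][j] = v;
    }
  }
}

// Canonical traceback from end column `jend` (preference: diagonal, then
// pattern-gap, then window-gap). P is the wildcard pad width of `pat`; the
// reported offset is the window position of the first core (non-pad) pattern
// character consumed against a window character.
static SGResult sg_traceback(const std::string& pat, const std::string& win,
                             const std::vector<std::vector<int> >& D,
                             int jend, int P) {
  int n = (int)pat.size(), m = (int)win.size();
  int i = n, j = jend;
  SGResult r;
  r.dist = D[n][jend];
  r.indels = 0;
  int core_lo = P, core_hi = n - P;  // pattern core is [core_lo, core_hi)
  int offset = -1;
  while (i > 0) {
    int here = D[i][j];
    if (j > 0 && here == D[i - 1][j - 1] + sub_cost(pat[i - 1], win[j - 1])) {
      if (sub_cost(pat[i - 1], win[j - 1]) > 0) r.mism.push_back(j - 1);
      if (i - 1 >= core_lo && i - 1 < core_hi) offset = j - 1;
      --i; --j;
    } else if (here == D[i - 1][j] + gap_cost(pat[i - 1])) {
      if (gap_cost(pat[i - 1]) > 0) {
        r.mism.push_back(std::min(j, m - 1) < 0 ? 0 : std::min(j, m - 1));
        r.indels++;
      }
      --i;
    } else {
      if (gap_cost(win[j - 1]) > 0) {
        r.mism.push_back(j - 1);
        r.indels++;
      }
      --j;
    }
  }
  if (offset < 0) offset = j;  // degenerate: core never consumed a window base
  r.offset = offset;
  std::reverse(r.mism.begin(), r.mism.end());
  return r;
}

static SGResult sg_align(const std::string& pat, const std::string& win, int P) {
  std::vector<std::vector<int> > D;
  sg_fill(pat, win, D);
  int n = (int)pat.size(), m = (int)win.size();
  int best = D[n][0];
  for (int j = 1; j <= m; ++j) if (D[n][j] < best) best = D[n][j];
  // smallest offset among minimal-distance end columns, then fewest indels
  SGResult chosen;
  bool have = false;
  for (int j = 0; j <= m; ++j) {
    if (D[n][j] != best) continue;
    SGResult r = sg_traceback(pat, win, D, j, P);
    if (!have || r.offset < chosen.offset ||
        (r.offset == chosen.offset && r.indels < chosen.indels)) {
      chosen = r;
      have = true;
    }
  }
  return chosen;
}

// [[Rcpp::export]]
List sg_align_cpp(std::string pattern, std::string window, int P) {
  std::string pat = pad_wild(pattern, P);
  SGResult r = sg_align(pat, window, P);
  return List::create(_["distance"] = r.dist,
                      _["offset"] = r.offset,
                      _["mismatch_positions"] = IntegerVector(r.mism.begin(), r.mism.end()));
}

// Distance-only batch with cutoff; values capped at limit + 1 when limit >= 0.
static int sg_dist_only(const std::string& pat, const std::string& win, int limit) {
  int n = (int)pat.size(), m = (int)win.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1);
  for (int i = 1; i <= n; ++i) {
    cur[0] = prev[0] + gap_cost(pat[i - 1]);
    int rowmin = cur[0];
    for (int j = 1; j <= m; ++j) {
      int d  = prev[j - 1] + sub_cost(pat[i - 1], win[j - 1]);
      int up = prev[j] + gap_cost(pat[i - 1]);
      int lf = cur[j - 1] + gap_cost(win[j - 1]);
      int v = d < up ? d : up;
      if (lf < v) v = lf;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (limit >= 0 && rowmin > limit) return limit + 1;
    std::swap(prev, cur);
  }
  int best = prev[0];
  for (int j = 1; j <= m; ++j) if (prev[j] < best) best = prev[j];
  if (limit >= 0 && best > limit) return limit + 1;
  return best;
}

// [[Rcpp::export]]
IntegerVector sg_dist_batch_cpp(CharacterVector patterns, std::string window,
                                int P, int limit) {
  IntegerVector out(patterns.size());
  for (R_xlen_t i = 0; i < patterns.size(); ++i) {
    std::string pat = pad_wild(as<std::string>(patterns[i]), P);
    out[i] = sg_dist_only(pat, window, limit);
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-mer index + batch classification

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerMap;

static void index_kmers(const std::string& s, int k, int id, KmerMap& map) {
  int n = (int)s.size();
  if (n < k) return;
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      std::vector<int>& v = map[key];
      if (v.empty() || v.back() != id) v.push_back(id);
    }
  }
}

// status codes: 1 = matched, 2 = ambiguous, 3 = unmatched
// [[Rcpp::export]]
List classify_batch_cpp(CharacterVector seqs, CharacterVector quals,
                        CharacterVector barcodes, int k, int start, int pe,
                        int max_distance, int P) {
  int nb = barcodes.size();
  if (nb == 0) stop("empty barcode set");
  std::vector<std::string> bcs(nb);
  int L = -1;
  for (int i = 0; i < nb; ++i) {
    bcs[i] = as<std::string>(barcodes[i]);
    if (L < 0) L = (int)bcs[i].size();
    else if ((int)bcs[i].size() != L) stop("barcodes must have equal length");
  }
  if (k < 1 || k > L) stop("k must be between 1 and the barcode length");
  KmerMap map;
  for (int i = 0; i < nb; ++i) index_kmers(bcs[i], k, i, map);
  std::vector<std::string> padded(nb);
  for (int i = 0; i < nb; ++i) padded[i] = pad_wild(bcs[i], P);

  R_xlen_t nr = seqs.size();
  bool have_qual = quals.size() == nr;
  IntegerVector status(nr), bc_id(nr), distance(nr), offset(nr);
  std::vector<int> stamp(nb, -1);
  std::vector<int> cands;
  cands.reserve(256);

  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  for (R_xlen_t r = 0; r < nr; ++r) {
    bc_id[r] = NA_INTEGER; distance[r] = NA_INTEGER; offset[r] = NA_INTEGER;
    std::string seq = as<std::string>(seqs[r]);
    int len = (int)seq.size();
    int ws, we;
    if (pe < 0) { ws = 0; we = len; }
    else {
      ws = std::max(0, start - pe);
      we = std::min(len, start + L + pe);
    }
    if (we - ws <= 0) { status[r] = 3; continue; }
    std::string win = seq.substr(ws, we - ws);

    // candidate retrieval
    cands.clear();
    uint64_t key = 0;
    int run = 0;
    for (int i = 0; i < (int)win.size(); ++i) {
      int c = base_code(win[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        KmerMap::const_iterator it = map.find(key);
        if (it != map.end()) {
          for (size_t t = 0; t < it->second.size(); ++t) {
            int id = it->second[t];
            if (stamp[id] != (int)r) { stamp[id] = (int)r; cands.push_back(id); }
          }
        }
      }
    }
    if (cands.empty()) { status[r] = 3; continue; }

    int best = max_distance + 1;
    std::vector<int> ties;
    for (size_t t = 0; t < cands.size(); ++t) {
      int d = sg_dist_only(padded[cands[t]], win, best);
      if (d < best) { best = d; ties.clear(); ties.push_back(cands[t]); }
      else if (d == best && best <= max_distance) ties.push_back(cands[t]);
    }
    if (best > max_distance) { status[r] = 3; continue; }

    int winner = -1;
    if (ties.size() == 1) {
      winner = ties[0];
    } else if (have_qual) {
      // quality tie-break: lowest Phred sum over mismatch positions wins
      std::string q = as<std::string>(quals[r]);
      long best_sum = -1;
      int n_best = 0;
      for (size_t t = 0; t < ties.size(); ++t) {
        SGResult a = sg_align(padded[ties[t]], win, P);
        long sum = 0;
        for (size_t p = 0; p < a.mism.size(); ++p) {
          int rp = ws + a.mism[p];
          if (rp >= 0 && rp < (int)q.size()) sum += (int)q[rp] - 33;
        }
        if (best_sum < 0 || sum < best_sum) { best_sum = sum; n_best = 1; winner = ties[t]; }
        else if (sum == best_sum) { n_best++; }
      }
      if (n_best != 1) winner = -1;
    }
    if (winner < 0) {
      status[r] = 2;
      distance[r] = best;
    } else {
      SGResult a = sg_align(padded[winner], win, P);
      status[r] = 1;
      bc_id[r] = winner + 1;
      distance[r] = best;
      offset[r] = ws + a.offset;
    }
    if ((r & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["status"] = status, _["barcode_id"] = bc_id,
                      _["distance"] = distance, _["offset"] = offset);
}

// ---------------------------------------------------------------------------
// Nearest-neighbor duplex stability (unified parameter set, two-state model,
// 50 mM monovalent salt, 0.25 uM strand concentration for bimolecular Tm).

static double NN_DH[4][4];  // kcal/mol, indexed by [x][y] for 5'-xy-3'
static double NN_DS[4][4];  // cal/mol/K
static bool nn_ready = false;

static void nn_init() {
  if (nn_ready) return;
  struct Row { const char* d; double dh, ds; };
  static const Row rows[] = {
    {"AA", -7.9, -22.2}, {"AT", -7.2, -20.4}, {"TA", -7.2, -21.3},
    {"CA", -8.5, -22.7}, {"GT", -8.4, -22.4}, {"CT", -7.8, -21.0},
    {"GA", -8.2, -22.2}, {"CG", -10.6, -27.2}, {"GC", -9.8, -24.4},
    {"GG", -8.0, -19.9}
  };
  const char comp[4] = {3, 2, 1, 0};  // A<->T, C<->G in code space
  for (size_t i = 0; i < sizeof(rows) / sizeof(rows[0]); ++i) {
    int x = base_code(rows[i].d[0]), y = base_code(rows[i].d[1]);
    NN_DH[x][y] = rows[i].dh; NN_DS[x][y] = rows[i].ds;
    // reverse complement of the doublet has identical thermodynamics
    int rx = comp[y], ry = comp[x];
    NN_DH[rx][ry] = rows[i].dh; NN_DS[rx][ry] = rows[i].ds;
  }
  nn_ready = true;
}

static const double R_GAS = 1.9872;       // cal/mol/K
static const double SALT_M = 0.05;        // mol/L monovalent
static const double STRAND_CT = 0.25e-6;  // mol/L
static const double T37 = 310.15;

// stack sums over a perfectly paired run given by the top-strand sequence
static void run_stacks(const std::string& s, int from, int len,
                       double& dh, double& ds) {
  nn_init();
  dh = 0.0; ds = 0.0;
  for (int i = 0; i < len - 1; ++i) {
    int x = base_code(s[from + i]), y = base_code(s[from + i + 1]);
    dh += NN_DH[x][y];
    ds += NN_DS[x][y];
  }
  ds += 0.368 * (len - 1) * std::log(SALT_M);  // salt correction
}

static void terminal_init(char c, double& dh, double& ds) {
  if (c == 'G' || c == 'C') { dh += 0.1; ds += -2.8; }
  else { dh += 2.3; ds += 4.1; }
}

struct Duplex { double dh, ds, tm; int stem; int kind; };  // kind 1=hairpin 2=self 3=cross

static double bimol_tm(double dh, double ds) {
  double denom = ds + R_GAS * std::log(STRAND_CT / 4.0);
  if (denom >= 0 || dh >= 0) return R_NegInf;
  return 1000.0 * dh / denom - 273.15;
}

static double hairpin_loop_ds(int loop) {
  // Jacobson-Stockmayer extrapolation from a 3.5 kcal/mol tri-loop penalty
  double g = 3.5 + 1.75 * 0.0019872 * T37 * std::log((double)loop / 3.0);
  return -1000.0 * g / T37;
}

static inline bool wc_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'C' && b == 'G') || (a == 'G' && b == 'C');
}

static Duplex best_hairpin(const std::string& s) {
  Duplex best; best.tm = R_NegInf; best.stem = 0; best.kind = 1;
  best.dh = NA_REAL; best.ds = NA_REAL;
  int n = (int)s.size();
  for (int st = 3; st <= (n - 3) / 2; ++st) {
    for (int i = 0; i + 2 * st + 3 <= n; ++i) {
      for (int j = i + st + 3; j + st <= n; ++j) {
        bool ok = true;
        for (int x = 0; x < st && ok; ++x)
          ok = wc_pair(s[i + x], s[j + st - 1 - x]);
        if (!ok) continue;
        double dh, ds;
        run_stacks(s, i, st, dh, ds);
        ds += hairpin_loop_ds(j - (i + st));
        if (dh >= 0 || ds >= 0) continue;
        double tm = 1000.0 * dh / ds - 273.15;
        if (tm > best.tm) {
          best.tm = tm; best.stem = st; best.dh = dh; best.ds = ds;
        }
      }
    }
  }
  return best;
}

// best bimolecular duplex over all ungapped registers of a against
// reverse_complement(b); complementary runs >= 3 bp are scored
static Duplex best_cross(const std::string& a, const std::string& b, int kind) {
  Duplex best; best.tm = R_NegInf; best.stem = 0; best.kind = kind;
  best.dh = NA_REAL; best.ds = NA_REAL;
  int la = (int)a.size(), lb = (int)b.size();
  std::string brc(lb, 'N');
  for (int i = 0; i < lb; ++i) {
    char c = b[lb - 1 - i];
    brc[i] = c == 'A' ? 'T' : c == 'T' ? 'A' : c == 'C' ? 'G' : c == 'G' ? 'C' : 'N';
  }
  for (int off = -(lb - 1); off <= la - 1; ++off) {
    int i0 = std::max(0, off), i1 = std::min(la, lb + off);
    int run = 0;
    for (int i = i0; i <= i1; ++i) {
      bool match = (i < i1) && a[i] == brc[i - off] && base_code(a[i]) >= 0;
      if (match) { run++; continue; }
      if (run >= 3) {
        int from = i - run;
        double dh, ds;
        run_stacks(a, from, run, dh, ds);
        terminal_init(a[from], dh, ds);
        terminal_init(a[from + run - 1], dh, ds);
        double tm = bimol_tm(dh, ds);
        if (tm > best.tm) {
          best.tm = tm; best.stem = run; best.dh = dh; best.ds = ds;
        }
      }
      run = 0;
    }
  }
  return best;
}

static List duplex_to_list(const Duplex& d) {
  const char* kinds[] = {"none", "hairpin", "self-dimer", "cross-dimer"};
  bool found = d.stem > 0 && d.tm > R_NegInf;
  double dg = NA_REAL;
  if (found) dg = d.dh - T37 * d.ds / 1000.0;
  return List::create(
    _["delta_g"] = dg,
    _["tm"] = found ? d.tm : R_NegInf,
    _["stem_length"] = found ? d.stem : 0,
    _["structure_kind"] = std::string(found ? kinds[d.kind] : kinds[0]));
}

// [[Rcpp::export]]
List thermo_self_cpp(std::string s) {
  if ((int)s.size() < 8) {
    Duplex d; d.tm = R_NegInf; d.stem = 0; d.kind = 1; d.dh = NA_REAL; d.ds = NA_REAL;
    return duplex_to_list(d);
  }
  Duplex h = best_hairpin(s);
  Duplex sd = best_cross(s, s, 2);
  return duplex_to_list(h.tm >= sd.tm ? h : sd);
}

// [[Rcpp::export]]
List thermo_cross_cpp(std::string a, std::string b) {
  return duplex_to_list(best_cross(a, b, 3));
}
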
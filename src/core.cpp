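// Core computational kernels: exact local alignment, k-mer indexing,
// gapless dovetail overlaps, layout union-find and quality-weighted
// consensus. All coordinates are 0-based half-open at this level.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char compbase(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = compbase(s[i]);
  return r;
}

// Enumerate valid (ACGT-only) k-mers of seq; calls fn(fwd_code, rc_code, pos).
template <typename F>
static void each_kmer(const std::string& s, int k, F fn) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) fn(fwd, rc, (int)(i + 1 - k));
  }
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment, affine gaps, full traceback matrix.
// Gap of length L costs gap_open + L * gap_ext (penalties passed positive).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  const double cells = (double)(n + 1) * (double)(m + 1);
  if (cells > 6.5e7) stop("sequences too long for exact local alignment");
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Fprev(m + 1, -1e18), Fcur(m + 1, -1e18);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  const double go = gap_open + gap_ext;
  for (int i = 1; i <= n; ++i) {
    double E = -1e18;
    Hcur[0] = 0.0; Fcur[0] = -1e18;
    const int ab = base2bits(a[i - 1]);
    uint8_t* tbrow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      // E: gap in a (consume b[j-1])
      double e_open = Hcur[j - 1] - go, e_ext = E - gap_ext;
      uint8_t flag = 0;
      if (e_ext > e_open) { E = e_ext; flag |= 4; } else { E = e_open; }
      // F: gap in b (consume a[i-1])
      double f_open = Hprev[j] - go, f_ext = Fprev[j] - gap_ext;
      double F;
      if (f_ext > f_open) { F = f_ext; flag |= 8; } else { F = f_open; }
      Fcur[j] = F;
      const int bb = base2bits(b[j - 1]);
      const double sub = (ab >= 0 && ab == bb) ? match : mismatch;
      const double diag = Hprev[j - 1] + sub;
      double h = 0.0; uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (E > h) { h = E; src = 2; }
      if (F > h) { h = F; src = 3; }
      Hcur[j] = h;
      tbrow[j] = flag | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  // traceback
  int i = bi, j = bj, cols = 0, ids = 0;
  int state = 0; // 0=H, 1=E, 2=F
  while (i > 0 || j > 0) {
    uint8_t c = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      uint8_t src = c & 3;
      if (src == 0) break;
      if (src == 1) {
        ++cols;
        int ab = base2bits(a[i - 1]), bb = base2bits(b[j - 1]);
        if (ab >= 0 && ab == bb) ++ids;
        --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++cols; // gap column consuming b[j-1]
      bool ext = (c & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else {
      ++cols; // gap column consuming a[i-1]
      bool ext = (c & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
    if (i == 0 && j == 0) break;
  }
  return List::create(_["score"] = best, _["a0"] = i, _["a1"] = bi,
                      _["b0"] = j, _["b1"] = bj, _["columns"] = cols,
                      _["identities"] = ids);
}

// Which strands of b share an exact seed k-mer with a: c(fwd, rev) logicals.
// [[Rcpp::export]]
LogicalVector cpp_shared_seed_strands(std::string a, std::string b, int k) {
  std::unordered_set<uint64_t> seen;
  each_kmer(a, k, [&](uint64_t f, uint64_t, int) { seen.insert(f); });
  bool fwd = false, rev = false;
  each_kmer(b, k, [&](uint64_t f, uint64_t r, int) {
    if (!fwd && seen.count(f)) fwd = true;
    if (!rev && seen.count(r)) rev = true;
  });
  return LogicalVector::create(fwd, rev);
}

// ---------------------------------------------------------------------------
// Seeded candidate pairs for all-vs-all style searches: a pair (i<j, strand)
// is a candidate when >= min_seeds shared seed k-mers fall in one diagonal
// band of width `band`.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_seed_candidates(CharacterVector seqs, int k, int min_seeds,
                              int band, int maxocc) {
  const int n = seqs.size();
  std::vector<std::string> S(n), R(n);
  for (int i = 0; i < n; ++i) { S[i] = as<std::string>(seqs[i]); R[i] = revcomp_str(S[i]); }
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > idx;
  for (int i = 0; i < n; ++i)
    each_kmer(S[i], k, [&](uint64_t f, uint64_t, int p) {
      auto& v = idx[f];
      if ((int)v.size() <= maxocc) v.push_back(std::make_pair(i, p));
    });
  std::vector<int> out_i, out_j, out_s;
  for (int j = 0; j < n; ++j) {
    for (int s = 0; s < 2; ++s) {
      const std::string& Q = s ? R[j] : S[j];
      std::unordered_map<int64_t, std::vector<int> > diags; // key = target i
      each_kmer(Q, k, [&](uint64_t f, uint64_t, int p) {
        auto it = idx.find(f);
        if (it == idx.end() || (int)it->second.size() > maxocc) return;
        for (auto& hit : it->second)
          if (hit.first < j) diags[hit.first].push_back(hit.second - p);
      });
      for (auto& kv : diags) {
        std::vector<int>& d = kv.second;
        if ((int)d.size() < min_seeds) continue;
        std::sort(d.begin(), d.end());
        bool ok = (min_seeds <= 1);
        for (size_t x = 0; !ok && x + min_seeds - 1 < d.size(); ++x)
          if (d[x + min_seeds - 1] - d[x] <= band) ok = true;
        if (ok) { out_i.push_back(kv.first + 1); out_j.push_back(j + 1); out_s.push_back(s ? -1 : 1); }
      }
    }
  }
  return DataFrame::create(_["i"] = out_i, _["j"] = out_j, _["strand"] = out_s);
}

// ---------------------------------------------------------------------------
// Gapless dovetail overlaps between reads. For each unordered pair the best
// shift (by score) over both orientations is kept when it satisfies the
// minimum overlap length and relative score. `offset` places the oriented j
// (forward if strand==1, reverse-complemented if -1) in i's forward frame.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_overlaps(CharacterVector seqs, double match, double mismatch,
                       int min_overlap, double min_rs, int k, int maxocc) {
  const int n = seqs.size();
  std::vector<std::string> S(n), R(n);
  for (int i = 0; i < n; ++i) { S[i] = as<std::string>(seqs[i]); R[i] = revcomp_str(S[i]); }
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > idx;
  for (int i = 0; i < n; ++i)
    each_kmer(S[i], k, [&](uint64_t f, uint64_t, int p) {
      auto& v = idx[f];
      if ((int)v.size() <= maxocc) v.push_back(std::make_pair(i, p));
    });
  std::vector<int> out_i, out_j, out_s, out_off, out_olen;
  std::vector<double> out_score, out_rs;
  for (int j = 0; j < n; ++j) {
    // best candidate per target i over both strands
    std::unordered_map<int, std::tuple<double,int,int,int> > best; // i -> (score, s, off, olen)
    for (int s = 0; s < 2; ++s) {
      const std::string& Q = s ? R[j] : S[j];
      std::unordered_map<int, std::vector<int> > diags;
      each_kmer(Q, k, [&](uint64_t f, uint64_t, int p) {
        auto it = idx.find(f);
        if (it == idx.end() || (int)it->second.size() > maxocc) return;
        for (auto& hit : it->second)
          if (hit.first < j) diags[hit.first].push_back(hit.second - p);
      });
      for (auto& kv : diags) {
        const int i = kv.first;
        std::vector<int>& d = kv.second;
        std::sort(d.begin(), d.end());
        d.erase(std::unique(d.begin(), d.end()), d.end());
        const std::string& A = S[i];
        for (int dd : d) {
          int lo = std::max(0, dd);
          int hi = std::min((int)A.size(), dd + (int)Q.size());
          int olen = hi - lo;
          if (olen < min_overlap) continue;
          int mcnt = 0;
          for (int x = lo; x < hi; ++x) {
            int ba = base2bits(A[x]), bb = base2bits(Q[x - dd]);
            if (ba >= 0 && ba == bb) ++mcnt;
          }
          double score = mcnt * match + (olen - mcnt) * mismatch;
          auto it2 = best.find(i);
          if (it2 == best.end() || score > std::get<0>(it2->second) ||
              (score == std::get<0>(it2->second) && olen > std::get<3>(it2->second))) {
            best[i] = std::make_tuple(score, s ? -1 : 1, dd, olen);
          }
        }
      }
    }
    for (auto& kv : best) {
      double score = std::get<0>(kv.second);
      int olen = std::get<3>(kv.second);
      double rs = score / (match * olen);
      if (rs >= min_rs) {
        out_i.push_back(kv.first + 1); out_j.push_back(j + 1);
        out_s.push_back(std::get<1>(kv.second)); out_off.push_back(std::get<2>(kv.second));
        out_olen.push_back(olen); out_score.push_back(score); out_rs.push_back(rs);
      }
    }
  }
  return DataFrame::create(_["i"] = out_i, _["j"] = out_j, _["strand"] = out_s,
                           _["offset"] = out_off, _["olen"] = out_olen,
                           _["score"] = out_score, _["rs"] = out_rs);
}

// ---------------------------------------------------------------------------
// Greedy layout by union-find with orientation/offset transforms.
// Transform of read r into its root frame is x -> a*x + b (a = +/-1) over
// forward-strand coordinates x of r.
// ---------------------------------------------------------------------------

struct LayoutUF {
  std::vector<int> par, sz;
  std::vector<long long> aa, bb; // child -> parent transform
  LayoutUF(int n) : par(n), sz(n, 1), aa(n, 1), bb(n, 0) {
    for (int i = 0; i < n; ++i) par[i] = i;
  }
  int find(int x) {
    // two-pass iterative path compression composing transforms top-down;
    // a root's stored transform is always the identity
    std::vector<int> path;
    int r = x;
    while (par[r] != r) { path.push_back(r); r = par[r]; }
    for (int i = (int)path.size() - 1; i >= 0; --i) {
      int node = path[i];
      int p = par[node];
      if (p == r) continue; // already stored relative to root
      // p was compressed to the root earlier in this loop
      aa[node] = aa[p] * aa[node];
      bb[node] = aa[p] * bb[node] + bb[p];
      par[node] = r;
    }
    return r;
  }
  // transform of x into root frame (after find)
  void transform(int x, long long& a, long long& b) {
    int r = find(x);
    if (x == r) { a = 1; b = 0; } else { a = aa[x]; b = bb[x]; }
  }
};

// [[Rcpp::export]]
List cpp_greedy_layout(int n, IntegerVector lens, IntegerVector ov_i,
                       IntegerVector ov_j, IntegerVector ov_strand,
                       IntegerVector ov_offset, IntegerVector order,
                       IntegerVector mate, int insert_min, int insert_max,
                       bool enforce_pairs) {
  LayoutUF uf(n);
  auto span_of = [&](long long a, long long b, int len, long long& lo, long long& hi) {
    long long p0 = b, p1 = a * (long long)(len - 1) + b;
    lo = std::min(p0, p1); hi = std::max(p0, p1) + 1;
  };
  // returns true if merge committed, 2 codes: 0 skip-inconsistent, 1 merged, 2 defer
  auto try_merge = [&](int e, bool allow_violation) -> int {
    int i = ov_i[e] - 1, j = ov_j[e] - 1;
    int s = ov_strand[e]; long long d = ov_offset[e];
    long long aji = (s == 1) ? 1 : -1;
    long long bji = (s == 1) ? d : d + (long long)lens[j] - 1;
    long long Ai, Bi, a2, b2;
    int ri = uf.find(i), rj = uf.find(j);
    uf.transform(i, Ai, Bi);
    long long Ad = Ai * aji, Bd = Ai * bji + Bi; // desired j -> ri frame
    uf.transform(j, a2, b2);
    if (ri == rj) return (a2 == Ad && b2 == Bd) ? 1 : 0;
    // mate advisory check
    if (enforce_pairs && !allow_violation) {
      // root rj -> ri transform
      long long ag = Ad * a2, bg = Bd - Ad * a2 * b2;
      auto pair_ok = [&](int r1, int r2, long long a1, long long b1,
                         long long a2_, long long b2_) {
        long long lo1, hi1, lo2, hi2;
        span_of(a1, b1, lens[r1], lo1, hi1);
        span_of(a2_, b2_, lens[r2], lo2, hi2);
        if (a1 * a2_ != -1) return false;
        long long span = std::max(hi1, hi2) - std::min(lo1, lo2);
        return span >= insert_min && span <= insert_max;
      };
      int mi = mate[i], mj = mate[j];
      if (mi > 0) {
        int rm = uf.find(mi - 1);
        if (rm == rj) {
          long long am, bm; uf.transform(mi - 1, am, bm);
          long long amr = ag * am, bmr = ag * bm + bg; // mate into ri frame
          long long ai, bi2; uf.transform(i, ai, bi2);
          if (!pair_ok(i, mi - 1, ai, bi2, amr, bmr)) return 2;
        }
      }
      if (mj > 0) {
        int rm = uf.find(mj - 1);
        if (rm == ri) {
          long long am, bm; uf.transform(mj - 1, am, bm);
          if (!pair_ok(j, mj - 1, Ad, Bd, am, bm)) return 2;
        }
      }
    }
    // attach smaller under larger
    long long ag = Ad * a2, bg = Bd - Ad * a2 * b2; // rj -> ri
    if (uf.sz[ri] >= uf.sz[rj]) {
      uf.par[rj] = ri; uf.aa[rj] = ag; uf.bb[rj] = bg; uf.sz[ri] += uf.sz[rj];
    } else {
      // invert: ri -> rj
      long long ainv = ag, binv = -ag * bg;
      uf.par[ri] = rj; uf.aa[ri] = ainv; uf.bb[ri] = binv; uf.sz[rj] += uf.sz[ri];
    }
    return 1;
  };
  std::vector<int> deferred;
  for (int t = 0; t < order.size(); ++t) {
    int e = order[t] - 1;
    int res = try_merge(e, false);
    if (res == 2) deferred.push_back(e);
  }
  for (size_t t = 0; t < deferred.size(); ++t) try_merge(deferred[t], true);
  IntegerVector root(n), ori(n); NumericVector pos(n);
  for (int x = 0; x < n; ++x) {
    int r = uf.find(x);
    long long a, b; uf.transform(x, a, b);
    root[x] = r + 1; ori[x] = (int)a;
    pos[x] = (double)((a == 1) ? b : b - (long long)(lens[x] - 1));
  }
  return List::create(_["root"] = root, _["ori"] = ori, _["start"] = pos);
}

// ---------------------------------------------------------------------------
// Quality-weighted consensus over a gapless layout of oriented reads.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_consensus(CharacterVector seqs, CharacterVector quals,
                   IntegerVector starts, double qcap,
                   int conflict_min_support, int conflict_min_qual,
                   double match, double mismatch) {
  const int n = seqs.size();
  int L = 0;
  std::vector<std::string> S(n), Q(n);
  for (int r = 0; r < n; ++r) {
    S[r] = as<std::string>(seqs[r]);
    Q[r] = as<std::string>(quals[r]);
    if (S[r].size() != Q[r].size()) stop("sequence/quality length mismatch");
    L = std::max(L, starts[r] + (int)S[r].size());
  }
  if (L <= 0) stop("empty layout");
  std::vector<double> w(4 * (size_t)L, 0.0), sumq(4 * (size_t)L, 0.0);
  std::vector<int> hq(4 * (size_t)L, 0), cnt(4 * (size_t)L, 0), cov(L, 0);
  for (int r = 0; r < n; ++r) {
    const int st = starts[r];
    for (size_t x = 0; x < S[r].size(); ++x) {
      int b = base2bits(S[r][x]);
      if (b < 0) continue;
      int q = (int)Q[r][x] - 33;
      size_t col = (size_t)(st + (int)x);
      w[4 * col + b] += 1.0 - std::pow(10.0, -q / 10.0);
      sumq[4 * col + b] += q;
      cnt[4 * col + b] += 1;
      cov[col] += 1;
      if (q >= conflict_min_qual) hq[4 * col + b] += 1;
    }
  }
  std::string cons(L, 'N');
  NumericVector err(L);
  IntegerVector coverage(L);
  std::vector<int> conf_pos;
  std::vector<int> conf_minor;
  const char* bases = "ACGT";
  const double floor_err = std::pow(10.0, -qcap / 10.0);
  for (int c = 0; c < L; ++c) {
    coverage[c] = cov[c];
    double tot = 0.0; int win = -1; double wmax = -1.0;
    for (int b = 0; b < 4; ++b) {
      double v = w[4 * (size_t)c + b];
      tot += v;
      if (v > wmax) { wmax = v; win = b; }
    }
    if (cov[c] == 0 || tot <= 0.0) { cons[c] = 'N'; err[c] = 0.75; continue; }
    cons[c] = bases[win];
    double losing = tot - wmax;
    int n_disagree = cov[c] - cnt[4 * (size_t)c + win];
    if (losing > 1e-12 && n_disagree >= 2) {
      // genuinely contested column
      err[c] = losing / tot;
    } else {
      // unanimous (or a lone dissenter, treated as a sequencing error):
      // error = product of supporting reads' error probabilities, floored
      err[c] = std::max(std::pow(10.0, -sumq[4 * (size_t)c + win] / 10.0), floor_err);
    }
    if (losing > 1e-12) {
      // strongest minority allele
      int minor = -1; double mw = -1.0;
      for (int b = 0; b < 4; ++b)
        if (b != win && w[4 * (size_t)c + b] > mw) { mw = w[4 * (size_t)c + b]; minor = b; }
      if (minor >= 0 && hq[4 * (size_t)c + minor] >= conflict_min_support) {
        conf_pos.push_back(c);
        conf_minor.push_back(minor);
      }
    }
  }
  // per-read relative score vs consensus, and alleles at conflict columns
  NumericVector read_rs(n);
  IntegerMatrix alleles(n, (int)conf_pos.size());
  std::fill(alleles.begin(), alleles.end(), -1);
  for (int r = 0; r < n; ++r) {
    const int st = starts[r];
    int mcnt = 0, len = (int)S[r].size();
    for (int x = 0; x < len; ++x) {
      int b = base2bits(S[r][x]);
      if (b >= 0 && cons[st + x] == bases[b]) ++mcnt;
    }
    read_rs[r] = (mcnt * match + (len - mcnt) * mismatch) / (match * (double)len);
    for (size_t ci = 0; ci < conf_pos.size(); ++ci) {
      int c = conf_pos[ci];
      if (c >= st && c < st + len) {
        int b = base2bits(S[r][c - st]);
        alleles(r, (int)ci) = (b >= 0) ? b : 4;
      }
    }
  }
  return List::create(_["consensus"] = cons, _["per_base_error"] = err,
                      _["coverage"] = coverage, _["read_rs"] = read_rs,
                      _["conflict_pos"] = wrap(conf_pos),
                      _["conflict_minor"] = wrap(conf_minor),
                      _["alleles"] = alleles);
}

// ---------------------------------------------------------------------------
// Canonical k-mer machinery for the cluster module.
// ---------------------------------------------------------------------------

struct PlainUF {
  std::vector<int> par;
  PlainUF(int n) : par(n) { for (int i = 0; i < n; ++i) par[i] = i; }
  int find(int x) { while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) par[std::max(a,b)] = std::min(a,b); }
};

// [[Rcpp::export]]
IntegerVector cpp_kmer_components(CharacterVector seqs, int k) {
  const int n = seqs.size();
  PlainUF uf(n);
  std::unordered_map<uint64_t, int> first;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    each_kmer(s, k, [&](uint64_t f, uint64_t r, int) {
      uint64_t canon = std::min(f, r);
      auto it = first.find(canon);
      if (it == first.end()) first[canon] = i;
      else uf.unite(it->second, i);
    });
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = uf.find(i) + 1;
  return out;
}

// [[Rcpp::export]]
List cpp_kmer_assign(CharacterVector reads, CharacterVector contigs, int k) {
  std::unordered_map<uint64_t, std::vector<int> > idx;
  for (int i = 0; i < contigs.size(); ++i) {
    std::string s = as<std::string>(contigs[i]);
    each_kmer(s, k, [&](uint64_t f, uint64_t r, int) {
      uint64_t canon = std::min(f, r);
      auto& v = idx[canon];
      if (v.empty() || v.back() != i) v.push_back(i);
    });
  }
  List out(reads.size());
  for (int j = 0; j < reads.size(); ++j) {
    std::string s = as<std::string>(reads[j]);
    std::unordered_set<int> hits;
    each_kmer(s, k, [&](uint64_t f, uint64_t r, int) {
      uint64_t canon = std::min(f, r);
      auto it = idx.find(canon);
      if (it != idx.end())
        for (int c : it->second) hits.insert(c);
    });
    std::vector<int> v(hits.begin(), hits.end());
    std::sort(v.begin(), v.end());
    for (auto& x : v) x += 1;
    out[j] = wrap(v);
  }
  return out;
}

// Longest read suffix matching an adapter prefix with <= max_mm mismatches
// (minimum match length min_match). Returns kept length per read.
// [[Rcpp::export]]
IntegerVector cpp_trim_adapter(CharacterVector seqs, std::string adapter,
                               int max_mm, int min_match) {
  const int alen = (int)adapter.size();
  IntegerVector out(seqs.size());
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    const int len = (int)s.size();
    int keep = len;
    int smin = std::max(0, len - alen);
    for (int st = smin; st <= len - min_match; ++st) {
      int ml = len - st, mm = 0;
      // tolerate at most one mismatch per 10 matched bases (capped at
      // max_mm) so short chance matches never trigger trimming
      int allow = std::min(max_mm, ml / 10);
      bool ok = true;
      for (int x = 0; x < ml; ++x) {
        char ca = s[st + x], cb = adapter[x];
        if (std::toupper(ca) != std::toupper(cb) && ++mm > allow) { ok = false; break; }
      }
      if (ok) { keep = st; break; }
    }
    out[r] = keep;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp_str(s);
  }
  return out;
}
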
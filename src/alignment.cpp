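// Alignment kernels: global Needleman-Wunsch (character and profile
// versions) and the banded fragment aligner behind the ANI estimator.
// All scoring is linear-gap; traceback ties are broken deterministically
// (diagonal > up > left) so results are reproducible bit-for-bit.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
#include <numeric>
using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) S(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) S(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = S(i - 1, j) + gap;   // consume a[i], gap in b
      double l = S(i, j - 1) + gap;   // consume b[j], gap in a
      double best = d;
      if (u > best) best = u;
      if (l > best) best = l;
      S(i, j) = best;
    }
  }
  // traceback, preferring diagonal > up > left among optimal moves
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S(i, j) == S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch)) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && S(i, j) == S(i - 1, j) + gap) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = S(n, m));
}

// Profile-profile global alignment. Profiles are 5 x L frequency matrices
// (rows A, C, G, T, gap; columns sum to 1). Column-pair score is the
// expected pairwise score; a residue opposite a gap costs `gap`, gap-gap
// costs 0. Returns the merge path: 1 = take column from both, 2 = column
// from A only (gap inserted in B), 3 = column from B only.
// [[Rcpp::export(name = ".profile_nw_cpp")]]
List profile_nw_cpp(NumericMatrix pa, NumericMatrix pb,
                    double match, double mismatch, double gap) {
  int n = pa.ncol(), m = pb.ncol();
  std::vector<double> resa(n), resb(m); // residue (non-gap) mass per column
  for (int i = 0; i < n; ++i) {
    double s = 0; for (int r = 0; r < 4; ++r) s += pa(r, i);
    resa[i] = s;
  }
  for (int j = 0; j < m; ++j) {
    double s = 0; for (int r = 0; r < 4; ++r) s += pb(r, j);
    resb[j] = s;
  }
  NumericMatrix S(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) S(i, 0) = S(i - 1, 0) + resa[i - 1] * gap;
  for (int j = 1; j <= m; ++j) S(0, j) = S(0, j - 1) + resb[j - 1] * gap;
  std::vector<double> colsc((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0;
      for (int x = 0; x < 4; ++x) {
        double fx = pa(x, i);
        if (fx == 0) continue;
        for (int y = 0; y < 4; ++y)
          s += fx * pb(y, j) * (x == y ? match : mismatch);
      }
      s += (pa(4, i) * resb[j] + pb(4, j) * resa[i]) * gap;
      colsc[(size_t)i * m + j] = s;
    }
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = S(i - 1, j - 1) + colsc[(size_t)(i - 1) * m + (j - 1)];
      double u = S(i - 1, j) + resa[i - 1] * gap;
      double l = S(i, j - 1) + resb[j - 1] * gap;
      double best = d;
      if (u > best) best = u;
      if (l > best) best = l;
      S(i, j) = best;
    }
  }
  std::vector<int> path;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S(i, j) == S(i - 1, j - 1) + colsc[(size_t)(i - 1) * m + (j - 1)]) {
      path.push_back(1); --i; --j;
    } else if (i > 0 && S(i, j) == S(i - 1, j) + resa[i - 1] * gap) {
      path.push_back(2); --i;
    } else {
      path.push_back(3); --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["path"] = wrap(path), _["score"] = S(n, m));
}

struct KmerIndex {
  std::unordered_map<uint64_t, std::vector<int> > pos;
  int k;
  void build(const std::vector<int>& s, int k_) {
    k = k_;
    uint64_t key = 0, mask = (k < 32) ? ((uint64_t(1) << (2 * k)) - 1) : ~uint64_t(0);
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      if (s[i] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)s[i]) & mask;
      if (++run >= k) pos[key].push_back((int)(i - k + 1));
    }
  }
};

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

static std::vector<int> rc_enc(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int c = v[v.size() - 1 - i];
    r[i] = (c < 0) ? -1 : 3 - c;
  }
  return r;
}

// Banded alignment of one fragment against a window of the target,
// global on the fragment, ends-free on the window. Integer scoring
// (match +1, mismatch -1, gap -2), byte traceback matrix (reused scratch
// buffer), counters recovered by a single path walk. Returns identity
// (matches / alignment columns) and coverage (fragment residues aligned
// to target residues / fragment length); false when the band is empty.
static bool band_align(const std::vector<int>& frag,
                       const std::vector<int>& tgt,
                       int wstart, int wlen, int center0, int band,
                       std::vector<int8_t>& moves_buf,
                       double& identity, double& coverage) {
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  const int NEG = INT_MIN / 4;
  int m = (int)frag.size();
  int W = 2 * band + 1;
  if ((int)moves_buf.size() < (m + 1) * W) moves_buf.resize((size_t)(m + 1) * W);
  int8_t* moves = moves_buf.data();
  std::vector<int> sc_prev(W, NEG), sc_cur(W, NEG);
  // row i covers j in [max(0, c_i - band), min(wlen, c_i + band)],
  // c_i = center0 + i; array index of (i, j) is j - (c_i - band)
  int c0 = center0;
  int l0 = c0 - band < 0 ? 0 : c0 - band;
  int h0 = c0 + band > wlen ? wlen : c0 + band;
  if (l0 > h0) return false;
  for (int j = l0; j <= h0; ++j) {
    sc_prev[j - (c0 - band)] = 0;           // free leading window gaps
    moves[j - (c0 - band)] = 0;
  }
  for (int i = 1; i <= m; ++i) {
    int ci = center0 + i;
    int li = ci - band < 0 ? 0 : ci - band;
    int hi_i = ci + band > wlen ? wlen : ci + band;
    if (li > hi_i) return false;
    int base_cur = ci - band;               // j -> index: j - base_cur
    int base_prev = ci - 1 - band;
    int8_t* mrow = moves + (size_t)i * W;
    int fc = frag[i - 1];
    const int* tg = tgt.data() + wstart;     // tg[j-1] = tgt[wstart + j - 1]
    std::fill(sc_cur.begin(), sc_cur.end(), NEG);
    for (int j = li; j <= hi_i; ++j) {
      int best = NEG; int8_t mv = 0;
      int pi = j - 1 - base_prev;           // diagonal predecessor
      if (j >= 1 && pi >= 0 && pi < W && sc_prev[pi] > NEG / 2) {
        best = sc_prev[pi] + ((fc >= 0 && fc == tg[j - 1]) ? MATCH : MISMATCH);
        mv = 1;
      }
      pi = j - base_prev;                   // up: gap in window
      if (pi >= 0 && pi < W && sc_prev[pi] > NEG / 2) {
        int v = sc_prev[pi] + GAP;
        if (v > best) { best = v; mv = 2; }
      }
      pi = j - 1 - base_cur;                // left: gap in fragment
      if (pi >= 0 && sc_cur[pi] > NEG / 2) {
        int v = sc_cur[pi] + GAP;
        if (v > best) { best = v; mv = 3; }
      }
      sc_cur[j - base_cur] = best;
      mrow[j - base_cur] = mv;
    }
    std::swap(sc_prev, sc_cur);
  }
  int cm = center0 + m;
  int lm = cm - band < 0 ? 0 : cm - band;
  int hm = cm + band > wlen ? wlen : cm + band;
  int best = NEG, bj = -1;
  for (int j = lm; j <= hm; ++j) {
    int v = sc_prev[j - (cm - band)];
    if (v > best) { best = v; bj = j; }
  }
  if (best <= NEG / 2) return false;
  // walk the traceback, counting matches / columns / diagonal steps
  int i = m, j = bj, matches = 0, cols = 0, diags = 0;
  while (i > 0) {
    int8_t mv = moves[(size_t)i * W + (j - (center0 + i - band))];
    if (mv == 1) {
      ++cols; ++diags;
      if (frag[i - 1] >= 0 && frag[i - 1] == tgt[wstart + j - 1]) ++matches;
      --i; --j;
    } else if (mv == 2) { ++cols; --i; }
    else if (mv == 3) { ++cols; --j; }
    else break;
  }
  if (cols == 0) return false;
  identity = (double)matches / (double)cols;
  coverage = (double)diags / (double)m;
  return true;
}

// shared implementation: map fragments of `a` (encoded) onto target `b`
// given prebuilt forward/reverse indices; appends per-fragment results
static void map_fragments(const std::vector<int>& ea,
                          const std::vector<int>& eb,
                          const std::vector<int>& ebrc,
                          const KmerIndex& fwd, const KmerIndex& rev,
                          int frag_len, int k, int band,
                          std::vector<int8_t>& moves_buf,
                          std::vector<double>& identity,
                          std::vector<double>& coverage,
                          std::vector<bool>& found) {
  int nfrag = (int)(ea.size() / frag_len);
  uint64_t mask = (k < 32) ? ((uint64_t(1) << (2 * k)) - 1) : ~uint64_t(0);
  identity.assign(nfrag, NA_REAL);
  coverage.assign(nfrag, NA_REAL);
  found.assign(nfrag, false);
  for (int f = 0; f < nfrag; ++f) {
    int s = f * frag_len;
    std::unordered_map<int, int> vf, vr;
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < frag_len; ++p) {
      int c = ea[s + p];
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      int kpos = p - k + 1;
      auto itf = fwd.pos.find(key);
      if (itf != fwd.pos.end())
        for (int q : itf->second) ++vf[q - kpos];
      auto itr = rev.pos.find(key);
      if (itr != rev.pos.end())
        for (int q : itr->second) ++vr[q - kpos];
    }
    int bestv = 0, bestoff = 0; bool useRev = false;
    for (auto& kv : vf)
      if (kv.second > bestv || (kv.second == bestv && bestv > 0 && kv.first < bestoff))
        { bestv = kv.second; bestoff = kv.first; useRev = false; }
    for (auto& kv : vr)
      if (kv.second > bestv)
        { bestv = kv.second; bestoff = kv.first; useRev = true; }
    if (bestv == 0) continue;
    const std::vector<int>& tgt = useRev ? ebrc : eb;
    int wstart = bestoff - band;
    if (wstart < 0) wstart = 0;
    int wend = bestoff + frag_len + band;
    if (wend > (int)tgt.size()) wend = (int)tgt.size();
    int wlen = wend - wstart;
    if (wlen <= 0) continue;
    int center0 = bestoff - wstart;
    std::vector<int> frag(ea.begin() + s, ea.begin() + s + frag_len);
    double id = 0, cov = 0;
    if (band_align(frag, tgt, wstart, wlen, center0, band, moves_buf, id, cov)) {
      found[f] = true; identity[f] = id; coverage[f] = cov;
    }
  }
}

// All-pairs ANI fragment mapping: indices are built once per genome and
// reused across pairs. Returns, for each unordered pair (row-major upper
// triangle), the filtered fragment identities of both directions pooled,
// plus the per-direction means and totals needed for the symmetrized ANI.
// [[Rcpp::export(name = ".ani_all_pairs_cpp")]]
List ani_all_pairs_cpp(CharacterVector genomes, int frag_len, int k,
                       int band, double min_id, double min_cov) {
  int n = genomes.size();
  std::vector<std::vector<int> > enc_g(n), enc_rc(n);
  std::vector<KmerIndex> fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    enc_g[i] = encode_seq(as<std::string>(genomes[i]));
    enc_rc[i] = rc_enc(enc_g[i]);
    fwd[i].build(enc_g[i], k);
    rev[i].build(enc_rc[i], k);
  }
  int npair = n * (n - 1) / 2;
  List out(npair);
  std::vector<int8_t> moves_buf;
  std::vector<double> id1, cov1, id2, cov2;
  std::vector<bool> fnd1, fnd2;
  int p = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++p) {
      map_fragments(enc_g[i], enc_g[j], enc_rc[j], fwd[j], rev[j],
                    frag_len, k, band, moves_buf, id1, cov1, fnd1);
      map_fragments(enc_g[j], enc_g[i], enc_rc[i], fwd[i], rev[i],
                    frag_len, k, band, moves_buf, id2, cov2, fnd2);
      std::vector<double> keep_ab, keep_ba;
      for (size_t f = 0; f < id1.size(); ++f)
        if (fnd1[f] && id1[f] >= min_id && cov1[f] >= min_cov)
          keep_ab.push_back(id1[f]);
      for (size_t f = 0; f < id2.size(); ++f)
        if (fnd2[f] && id2[f] >= min_id && cov2[f] >= min_cov)
          keep_ba.push_back(id2[f]);
      double mab = keep_ab.empty() ? NA_REAL :
        std::accumulate(keep_ab.begin(), keep_ab.end(), 0.0) / keep_ab.size();
      double mba = keep_ba.empty() ? NA_REAL :
        std::accumulate(keep_ba.begin(), keep_ba.end(), 0.0) / keep_ba.size();
      std::vector<double> pooled(keep_ab);
      pooled.insert(pooled.end(), keep_ba.begin(), keep_ba.end());
      out[p] = List::create(_["mean_ab"] = mab, _["mean_ba"] = mba,
                            _["identities"] = wrap(pooled));
    }
  }
  return out;
}

// Map every non-overlapping frag_len window of `a` onto `b` (both strands)
// by shared-k-mer diagonal voting, align the best candidate locus with a
// banded global alignment, and report per-fragment identity and coverage.
// [[Rcpp::export(name = ".ani_fragments_cpp")]]
DataFrame ani_fragments_cpp(std::string a, std::string b,
                            int frag_len, int k, int band) {
  std::vector<int> ea = encode_seq(a), eb = encode_seq(b);
  std::vector<int> ebrc = rc_enc(eb);
  KmerIndex fwd, rev;
  fwd.build(eb, k);
  rev.build(ebrc, k);
  int nfrag = (int)(ea.size() / frag_len);
  NumericVector identity(nfrag), coverage(nfrag);
  LogicalVector found(nfrag);
  std::vector<int8_t> moves_buf;
  uint64_t mask = (k < 32) ? ((uint64_t(1) << (2 * k)) - 1) : ~uint64_t(0);
  for (int f = 0; f < nfrag; ++f) {
    int s = f * frag_len;
    // diagonal voting on both strands
    std::unordered_map<int, int> vf, vr;
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < frag_len; ++p) {
      int c = ea[s + p];
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      int kpos = p - k + 1;
      auto itf = fwd.pos.find(key);
      if (itf != fwd.pos.end())
        for (int q : itf->second) ++vf[q - kpos];
      auto itr = rev.pos.find(key);
      if (itr != rev.pos.end())
        for (int q : itr->second) ++vr[q - kpos];
    }
    int bestv = 0, bestoff = 0; bool useRev = false;
    for (auto& kv : vf)
      if (kv.second > bestv || (kv.second == bestv && bestv > 0 && kv.first < bestoff))
        { bestv = kv.second; bestoff = kv.first; useRev = false; }
    for (auto& kv : vr)
      if (kv.second > bestv)
        { bestv = kv.second; bestoff = kv.first; useRev = true; }
    if (bestv == 0) { found[f] = false; identity[f] = NA_REAL; coverage[f] = NA_REAL; continue; }
    const std::vector<int>& tgt = useRev ? ebrc : eb;
    int wstart = bestoff - band;
    if (wstart < 0) wstart = 0;
    int wend = bestoff + frag_len + band;
    if (wend > (int)tgt.size()) wend = (int)tgt.size();
    int wlen = wend - wstart;
    if (wlen <= 0) { found[f] = false; identity[f] = NA_REAL; coverage[f] = NA_REAL; continue; }
    int center0 = bestoff - wstart; // expected window offset of fragment start
    std::vector<int> frag(ea.begin() + s, ea.begin() + s + frag_len);
    double id = 0, cov = 0;
    bool ok = band_align(frag, tgt, wstart, wlen, center0, band, moves_buf, id, cov);
    found[f] = ok;
    identity[f] = ok ? id : NA_REAL;
    coverage[f] = ok ? cov : NA_REAL;
  }
  return DataFrame::create(_["fragment"] = seq(1, nfrag > 0 ? nfrag : 0),
                           _["identity"] = identity,
                           _["coverage"] = coverage,
                           _["found"] = found);
}
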
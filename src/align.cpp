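// Alignment kernels: full Smith-Waterman (affine gaps, traceback), a seeded
// heuristic local search (exact word seeds -> X-drop ungapped extension ->
// banded affine extension), and a profile-profile Needleman-Wunsch used by
// the progressive MSA. Sequences arrive as 0-based integer code vectors;
// scoring matrices are indexed by those codes.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int NEG_INF = -1000000000;

struct AlnResult {
  int score;
  int a_beg, a_end, b_beg, b_end; // 0-based half-open
  int n_ident, n_cols;
  std::string cigar;
};

// append run-length op to cigar being built in reverse order of ops
static std::string build_cigar(const std::vector<char> &ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full Smith-Waterman, affine gaps: gap of length L costs go + L*ge.
// ---------------------------------------------------------------------------
static AlnResult sw_full(const std::vector<int> &a, const std::vector<int> &b,
                         const IntegerMatrix &sub, int go, int ge) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<int> H(m + 1, 0), E(m + 1, NEG_INF);
  // traceback: 2 bits H-source (0 stop, 1 diag, 2 left/E, 3 up/F),
  // bit2: E extended, bit3: F extended
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  std::vector<int> F(m + 1, NEG_INF);
  for (int i = 1; i <= n; ++i) {
    int Hdiag = H[0]; // H[i-1][0]
    H[0] = 0;
    E[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      uint8_t t = 0;
      int e_open = H[j - 1] - go - ge; // H[i][j-1] already updated this row
      int e_ext = E[j - 1] - ge;
      int e = e_open >= e_ext ? e_open : e_ext;
      if (e_ext > e_open) t |= 4;
      E[j] = e;
      int f_open = H[j] - go - ge; // H[i-1][j] (not yet updated)
      int f_ext = F[j] - ge;
      int f = f_open >= f_ext ? f_open : f_ext;
      if (f_ext > f_open) t |= 8;
      F[j] = f;
      int d = Hdiag + sub(a[i - 1], b[j - 1]);
      int h = 0;
      uint8_t src = 0;
      if (d > h) { h = d; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      Hdiag = H[j];
      H[j] = h;
      tb[(size_t)i * (m + 1) + j] = t | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  AlnResult r;
  r.score = best;
  if (best <= 0) {
    r.a_beg = r.a_end = r.b_beg = r.b_end = 0;
    r.n_ident = r.n_cols = 0;
    r.cigar = "";
    return r;
  }
  // traceback
  std::vector<char> ops;
  int i = bi, j = bj, nid = 0;
  int state = 0; // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      uint8_t src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        ops.push_back('M');
        if (a[i - 1] == b[j - 1]) ++nid;
        --i; --j;
      } else if (src == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // gap in a, consume b
      ops.push_back('I');
      if (!(t & 4)) state = 0;
      --j;
    } else { // gap in b, consume a
      ops.push_back('D');
      if (!(t & 8)) state = 0;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  r.a_beg = i; r.a_end = bi;
  r.b_beg = j; r.b_end = bj;
  r.n_ident = nid;
  r.n_cols = (int)ops.size();
  r.cigar = build_cigar(ops);
  return r;
}

// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  AlnResult r = sw_full(av, bv, sub, gap_open, gap_extend);
  return List::create(_["score"] = r.score, _["a_beg"] = r.a_beg,
                      _["a_end"] = r.a_end, _["b_beg"] = r.b_beg,
                      _["b_end"] = r.b_end, _["n_ident"] = r.n_ident,
                      _["n_cols"] = r.n_cols, _["cigar"] = r.cigar);
}

// ---------------------------------------------------------------------------
// Banded Smith-Waterman over diagonals d = j - i in [dlo, dhi].
// ---------------------------------------------------------------------------
static AlnResult sw_banded(const std::vector<int> &a, const std::vector<int> &b,
                           const IntegerMatrix &sub, int go, int ge,
                           int dlo, int dhi) {
  int n = (int)a.size(), m = (int)b.size();
  if (dlo < -n) dlo = -n;
  if (dhi > m) dhi = m;
  if (dlo > dhi) { AlnResult r; r.score = 0; r.a_beg=r.a_end=r.b_beg=r.b_end=0; r.n_ident=r.n_cols=0; return r; }
  int W = dhi - dlo + 1;
  std::vector<int> H((size_t)W, 0), E((size_t)W, NEG_INF), F((size_t)W, NEG_INF);
  std::vector<int> Hp((size_t)W, 0), Ep((size_t)W, NEG_INF), Fp((size_t)W, NEG_INF);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);
  int best = 0, bi = 0, bk = 0;
  // row i = 0: H = 0 along valid cells
  for (int i = 1; i <= n; ++i) {
    std::swap(H, Hp); std::swap(E, Ep); std::swap(F, Fp);
    for (int k = 0; k < W; ++k) { H[k] = NEG_INF; E[k] = NEG_INF; F[k] = NEG_INF; }
    for (int k = 0; k < W; ++k) {
      int j = i + dlo + k;
      if (j < 1 || j > m) continue;
      uint8_t t = 0;
      // left: (i, j-1) = same row, k-1
      int e = NEG_INF;
      if (k >= 1 && H[k - 1] > NEG_INF / 2) {
        int e_open = H[k - 1] - go - ge;
        int e_ext = (E[k - 1] > NEG_INF / 2) ? E[k - 1] - ge : NEG_INF;
        e = e_open >= e_ext ? e_open : e_ext;
        if (e_ext > e_open) t |= 4;
      } else if (k >= 1 && E[k - 1] > NEG_INF / 2) {
        e = E[k - 1] - ge; t |= 4;
      }
      E[k] = e;
      // up: (i-1, j) = prev row, k+1
      int f = NEG_INF;
      if (k + 1 < W) {
        int f_open = (Hp[k + 1] > NEG_INF / 2) ? Hp[k + 1] - go - ge : NEG_INF;
        int f_ext = (Fp[k + 1] > NEG_INF / 2) ? Fp[k + 1] - ge : NEG_INF;
        f = f_open >= f_ext ? f_open : f_ext;
        if (f_ext > f_open && f_ext > NEG_INF / 2) t |= 8;
      }
      F[k] = f;
      // diag: (i-1, j-1) = prev row, same k
      int dvalprev = (j - 1 >= i - 1 + dlo && j - 1 <= i - 1 + dhi)
                         ? ((i - 1 == 0 || j - 1 == 0) ? 0 : Hp[k])
                         : NEG_INF;
      if (i - 1 == 0 || j - 1 == 0) dvalprev = 0;
      int d = (dvalprev > NEG_INF / 2) ? dvalprev + sub(a[i - 1], b[j - 1]) : NEG_INF;
      int h = 0;
      uint8_t src = 0;
      if (d > h) { h = d; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      H[k] = h;
      tb[(size_t)i * W + k] = t | src;
      if (h > best) { best = h; bi = i; bk = k; }
    }
  }
  AlnResult r;
  r.score = best;
  if (best <= 0) {
    r.a_beg = r.a_end = r.b_beg = r.b_end = 0;
    r.n_ident = r.n_cols = 0;
    r.cigar = "";
    return r;
  }
  std::vector<char> ops;
  int i = bi, k = bk, nid = 0, state = 0;
  while (i > 0) {
    int j = i + dlo + k;
    if (j <= 0) break;
    uint8_t t = tb[(size_t)i * W + k];
    if (state == 0) {
      uint8_t src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        ops.push_back('M');
        if (a[i - 1] == b[j - 1]) ++nid;
        --i; // k unchanged (diag)
      } else if (src == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ops.push_back('I');
      if (!(t & 4)) state = 0;
      --k; // (i, j-1)
      if (k < 0) break;
    } else {
      ops.push_back('D');
      if (!(t & 8)) state = 0;
      --i; ++k; // (i-1, j)
      if (k >= W) break;
    }
  }
  std::reverse(ops.begin(), ops.end());
  int j = i + dlo + k;
  r.a_beg = i; r.a_end = bi;
  r.b_beg = j; r.b_end = bi + dlo + bk;
  r.n_ident = nid;
  r.n_cols = (int)ops.size();
  r.cigar = build_cigar(ops);
  return r;
}

// ---------------------------------------------------------------------------
// Seeded search: one query against a list of targets.
// ---------------------------------------------------------------------------
struct Seg { int diag, tlo, thi, score; };

// [[Rcpp::export]]
DataFrame cpp_seeded_search(IntegerVector query, List targets, IntegerMatrix sub,
                            int gap_open, int gap_extend, int word,
                            int seed_alpha, int xdrop, int trigger,
                            int band_pad, int diag_sep, int min_report_score,
                            int gapped_gate) {
  std::vector<int> q(query.begin(), query.end());
  int qlen = (int)q.size();
  // build query word index
  std::unordered_map<uint64_t, std::vector<int> > idx;
  if (qlen >= word) {
    for (int i = 0; i + word <= qlen; ++i) {
      uint64_t key = 0;
      bool ok = true;
      for (int w = 0; w < word; ++w) {
        int c = q[i + w];
        if (c < 0 || c >= seed_alpha) { ok = false; break; }
        key = key * (uint64_t)seed_alpha + (uint64_t)c;
      }
      if (ok) idx[key].push_back(i);
    }
  }
  std::vector<int> out_t, out_score, out_qb, out_qe, out_tb, out_te, out_nid, out_ncol;
  std::vector<std::string> out_cig;

  for (int ti = 0; ti < targets.size(); ++ti) {
    IntegerVector tv = targets[ti];
    std::vector<int> t(tv.begin(), tv.end());
    int tlen = (int)t.size();
    if (tlen < word || idx.empty()) continue;
    std::vector<Seg> segs;
    std::unordered_map<int, int> diag_done; // diag -> max target pos already extended
    for (int j = 0; j + word <= tlen; ++j) {
      uint64_t key = 0;
      bool ok = true;
      for (int w = 0; w < word; ++w) {
        int c = t[j + w];
        if (c < 0 || c >= seed_alpha) { ok = false; break; }
        key = key * (uint64_t)seed_alpha + (uint64_t)c;
      }
      if (!ok) continue;
      std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(key);
      if (it == idx.end()) continue;
      for (size_t s = 0; s < it->second.size(); ++s) {
        int qi = it->second[s];
        int d = j - qi;
        std::unordered_map<int, int>::iterator dd = diag_done.find(d);
        if (dd != diag_done.end() && j < dd->second) continue;
        // ungapped X-drop extension around seed [qi, qi+word) vs [j, j+word)
        int sc = 0;
        for (int w = 0; w < word; ++w) sc += sub(q[qi + w], t[j + w]);
        int bestsc = sc, cur = sc;
        int lo_q = qi, best_lo = qi;
        // left
        int iq = qi - 1, jt = j - 1;
        while (iq >= 0 && jt >= 0) {
          cur += sub(q[iq], t[jt]);
          if (cur > bestsc) { bestsc = cur; best_lo = iq; }
          if (cur < bestsc - xdrop) break;
          --iq; --jt;
        }
        lo_q = best_lo;
        // right
        cur = bestsc;
        int hi_q = qi + word, best_hi = qi + word;
        iq = qi + word; jt = j + word;
        while (iq < qlen && jt < tlen) {
          cur += sub(q[iq], t[jt]);
          if (cur > bestsc) { bestsc = cur; best_hi = iq + 1; }
          if (cur < bestsc - xdrop) break;
          ++iq; ++jt;
        }
        hi_q = best_hi;
        diag_done[d] = (iq + d) + 1; // forward extent explored on this diagonal
        if (bestsc >= trigger) {
          Seg sg;
          sg.diag = d;
          sg.tlo = lo_q + d;
          sg.thi = hi_q + d;
          sg.score = bestsc;
          segs.push_back(sg);
        }
      }
    }
    if (segs.empty()) continue;
    // cluster segments into candidate loci
    std::sort(segs.begin(), segs.end(),
              [](const Seg &a, const Seg &b) { return a.tlo < b.tlo; });
    struct Clust { int dmin, dmax, tmin, tmax, best; };
    std::vector<Clust> clusters;
    int merge_margin = 3 * band_pad + 60;
    for (size_t s = 0; s < segs.size(); ++s) {
      bool merged = false;
      for (size_t c = 0; c < clusters.size(); ++c) {
        Clust &cl = clusters[c];
        if (segs[s].diag >= cl.dmin - diag_sep && segs[s].diag <= cl.dmax + diag_sep &&
            segs[s].tlo <= cl.tmax + merge_margin && segs[s].thi >= cl.tmin - merge_margin) {
          cl.dmin = std::min(cl.dmin, segs[s].diag);
          cl.dmax = std::max(cl.dmax, segs[s].diag);
          cl.tmin = std::min(cl.tmin, segs[s].tlo);
          cl.tmax = std::max(cl.tmax, segs[s].thi);
          cl.best = std::max(cl.best, segs[s].score);
          merged = true;
          break;
        }
      }
      if (!merged) {
        Clust cl;
        cl.dmin = cl.dmax = segs[s].diag;
        cl.tmin = segs[s].tlo;
        cl.tmax = segs[s].thi;
        cl.best = segs[s].score;
        clusters.push_back(cl);
      }
    }
    // banded extension per cluster passing the gapped-extension gate,
    // restricted to the cluster's query neighbourhood
    std::vector<AlnResult> hits;
    int qmargin = 250;
    for (size_t c = 0; c < clusters.size(); ++c) {
      if (clusters[c].best < gapped_gate) continue;
      int dlo = clusters[c].dmin - band_pad;
      int dhi = clusters[c].dmax + band_pad;
      int qlo = clusters[c].tmin - dhi - qmargin;
      int qhi = clusters[c].tmax - dlo + qmargin;
      if (qlo < 0) qlo = 0;
      if (qhi > qlen) qhi = qlen;
      if (qhi - qlo < 1) continue;
      std::vector<int> qsub(q.begin() + qlo, q.begin() + qhi);
      AlnResult r = sw_banded(qsub, t, sub, gap_open, gap_extend,
                              dlo + qlo, dhi + qlo);
      if (r.score >= min_report_score && r.n_cols > 0) {
        r.a_beg += qlo;
        r.a_end += qlo;
        hits.push_back(r);
      }
    }
    // greedy non-overlapping selection on target columns
    std::vector<int> ord(hits.size());
    for (size_t h = 0; h < hits.size(); ++h) ord[h] = (int)h;
    std::sort(ord.begin(), ord.end(), [&](int x, int y) {
      if (hits[x].score != hits[y].score) return hits[x].score > hits[y].score;
      if (hits[x].b_beg != hits[y].b_beg) return hits[x].b_beg < hits[y].b_beg;
      return hits[x].a_beg < hits[y].a_beg;
    });
    std::vector<std::pair<int, int> > taken;
    for (size_t o = 0; o < ord.size(); ++o) {
      AlnResult &h = hits[ord[o]];
      bool overlap = false;
      for (size_t k = 0; k < taken.size(); ++k) {
        if (h.b_beg < taken[k].second && taken[k].first < h.b_end) { overlap = true; break; }
      }
      if (overlap) continue;
      taken.push_back(std::make_pair(h.b_beg, h.b_end));
      out_t.push_back(ti + 1);
      out_score.push_back(h.score);
      out_qb.push_back(h.a_beg);
      out_qe.push_back(h.a_end);
      out_tb.push_back(h.b_beg);
      out_te.push_back(h.b_end);
      out_nid.push_back(h.n_ident);
      out_ncol.push_back(h.n_cols);
      out_cig.push_back(h.cigar);
    }
  }
  return DataFrame::create(
      _["target_idx"] = out_t, _["score"] = out_score, _["q_beg"] = out_qb,
      _["q_end"] = out_qe, _["t_beg"] = out_tb, _["t_end"] = out_te,
      _["n_ident"] = out_nid, _["n_cols"] = out_ncol, _["cigar"] = out_cig,
      _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Profile-profile global alignment (Needleman-Wunsch, affine, free end gaps
// optional) over a precomputed column-similarity matrix. Returns the aligned
// column paths: 1-based column index or 0 for a gap.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_nw_profile(NumericMatrix sim, double gap_open, double gap_extend,
                    bool free_ends) {
  int n = sim.nrow(), m = sim.ncol();
  const double NI = -1e30;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix tb(n + 1, m + 1); // bits as in sw_full
  double end_open = free_ends ? 0.0 : gap_open;
  double end_ext = free_ends ? 0.0 : gap_extend;
  H(0, 0) = 0; E(0, 0) = NI; F(0, 0) = NI;
  for (int j = 1; j <= m; ++j) {
    E(0, j) = -end_open - end_ext * j;
    H(0, j) = E(0, j);
    F(0, j) = NI;
    tb(0, j) = 2 | 4;
  }
  for (int i = 1; i <= n; ++i) {
    F(i, 0) = -end_open - end_ext * i;
    H(i, 0) = F(i, 0);
    E(i, 0) = NI;
    tb(i, 0) = 3 | 8;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      bool edge_i = (i == n), edge_j = (j == m);
      double go_h = (free_ends && edge_i) ? 0.0 : gap_open;
      double ge_h = (free_ends && edge_i) ? 0.0 : gap_extend;
      double go_v = (free_ends && edge_j) ? 0.0 : gap_open;
      double ge_v = (free_ends && edge_j) ? 0.0 : gap_extend;
      int t = 0;
      double e_open = H(i, j - 1) - go_h - ge_h;
      double e_ext = E(i, j - 1) - ge_h;
      double e = e_open >= e_ext ? e_open : e_ext;
      if (e_ext > e_open) t |= 4;
      E(i, j) = e;
      double f_open = H(i - 1, j) - go_v - ge_v;
      double f_ext = F(i - 1, j) - ge_v;
      double f = f_open >= f_ext ? f_open : f_ext;
      if (f_ext > f_open) t |= 8;
      F(i, j) = f;
      double d = H(i - 1, j - 1) + sim(i - 1, j - 1);
      double h = d;
      int src = 1;
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      H(i, j) = h;
      tb(i, j) = t | src;
    }
  }
  // traceback from (n, m)
  std::vector<int> p1, p2;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    if (i == 0) { p1.push_back(0); p2.push_back(j); --j; continue; }
    if (j == 0) { p1.push_back(i); p2.push_back(0); --i; continue; }
    int t = tb(i, j);
    if (state == 0) {
      int src = t & 3;
      if (src == 1) { p1.push_back(i); p2.push_back(j); --i; --j; }
      else if (src == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      p1.push_back(0); p2.push_back(j);
      if (!(t & 4)) state = 0;
      --j;
    } else {
      p1.push_back(i); p2.push_back(0);
      if (!(t & 8)) state = 0;
      --i;
    }
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());
  return List::create(_["score"] = H(n, m), _["path1"] = wrap(p1),
                      _["path2"] = wrap(p2));
}
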
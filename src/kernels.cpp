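#include <Rcpp.h>
using namespace Rcpp;

// bases encoded A=0, C=1, G=2, U=3
static inline bool can_pair(int a, int b) {
  // AU, UA, GC, CG, GU, UG
  int x = a * 4 + b;
  return x == 3 || x == 12 || x == 6 || x == 9 || x == 11 || x == 14;
}

// Nussinov base-pair maximization, hairpin loop >= 3 unpaired bases.
// Deterministic traceback: pairing is preferred over leaving the right end
// unpaired, and the leftmost admissible partner wins.
// [[Rcpp::export(name = ".nussinov_fold")]]
IntegerVector nussinov_fold(IntegerVector seq) {
  int n = seq.size();
  IntegerVector pairing(n, -1);
  if (n < 5) return pairing;
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i][j - 1];
      for (int k = i; k <= j - 4; ++k) {
        if (!can_pair(seq[k], seq[j])) continue;
        int v = 1 + (k > i ? M[i][k - 1] : 0) + M[k + 1][j - 1];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  // iterative traceback over intervals
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < 4) continue;
    bool paired = false;
    for (int k = i; k <= j - 4; ++k) {  // leftmost admissible partner first
      if (!can_pair(seq[k], seq[j])) continue;
      int v = 1 + (k > i ? M[i][k - 1] : 0) + M[k + 1][j - 1];
      if (v == M[i][j]) {
        pairing[k] = j;
        pairing[j] = k;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        stack.push_back(std::make_pair(k + 1, j - 1));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i, j - 1));
  }
  return pairing;  // 0-based partner, -1 = unpaired
}

struct Aln {
  double score;
  std::vector<int> ai, bi;  // aligned 0-based positions, -1 = gap
};

// structure-annotated local alignment (Smith-Waterman, affine gaps).
// struct codes: 0 unpaired, 1 opening '(', 2 closing ')'.
// column score = nt (match_nt / mismatch_nt) + structure term
// (+struct_bonus if both paired same orientation, struct_mismatch if one
// paired one unpaired, 0 otherwise).
// [[Rcpp::export(name = ".sw_struct_align")]]
List sw_struct_align(IntegerVector a, IntegerVector astr,
                     IntegerVector b, IntegerVector bstr,
                     double match_nt, double mismatch_nt,
                     double struct_bonus, double struct_mismatch,
                     double gap_open, double gap_extend,
                     double min_score, int max_alignments) {
  int n = a.size(), m = b.size();
  const double NEG = -1e18;
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double>> E(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> F(n + 1, std::vector<double>(m + 1, NEG));
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double col = (a[i - 1] == b[j - 1]) ? match_nt : mismatch_nt;
      int sa = astr[i - 1], sb = bstr[j - 1];
      // structure term: bonus for agreeing pairing orientation, penalty for
      // any structural disagreement (orientation flip or paired/unpaired)
      if (sa != 0 && sb != 0 && sa == sb) col += struct_bonus;
      else if (sa != 0 || sb != 0) col += struct_mismatch;
      E[i][j] = std::max(H[i][j - 1] + gap_open, E[i][j - 1] + gap_extend);
      F[i][j] = std::max(H[i - 1][j] + gap_open, F[i - 1][j] + gap_extend);
      double h = H[i - 1][j - 1] + col;
      h = std::max(h, std::max(E[i][j], F[i][j]));
      H[i][j] = std::max(0.0, h);
    }
  }
  // candidate end cells sorted by score
  std::vector<std::pair<double, std::pair<int, int>>> cells;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      if (H[i][j] >= min_score)
        cells.push_back(std::make_pair(H[i][j], std::make_pair(i, j)));
  std::sort(cells.begin(), cells.end(),
            [](const std::pair<double, std::pair<int, int>> &x,
               const std::pair<double, std::pair<int, int>> &y) {
              if (x.first != y.first) return x.first > y.first;
              if (x.second.first != y.second.first)
                return x.second.first < y.second.first;
              return x.second.second < y.second.second;
            });
  std::vector<bool> used_a(n, false), used_b(m, false);
  std::vector<Aln> out;
  for (size_t c = 0; c < cells.size(); ++c) {
    if ((int)out.size() >= max_alignments) break;
    int i = cells[c].second.first, j = cells[c].second.second;
    if (used_a[i - 1] || used_b[j - 1]) continue;
    // traceback
    Aln al;
    al.score = cells[c].first;
    int ci = i, cj = j;
    bool overlap = false;
    std::vector<int> rai, rbi;
    int state = 0;  // 0 = H, 1 = E (gap in a), 2 = F (gap in b)
    while (ci > 0 && cj > 0) {
      if (state == 0) {
        if (H[ci][cj] == 0.0) break;
        if (used_a[ci - 1] || used_b[cj - 1]) { overlap = true; break; }
        if (H[ci][cj] == E[ci][cj]) { state = 1; continue; }
        if (H[ci][cj] == F[ci][cj]) { state = 2; continue; }
        rai.push_back(ci - 1); rbi.push_back(cj - 1);
        --ci; --cj;
      } else if (state == 1) {
        rai.push_back(-1); rbi.push_back(cj - 1);
        if (used_b[cj - 1]) { overlap = true; break; }
        if (E[ci][cj] == H[ci][cj - 1] + gap_open) state = 0;
        --cj;
      } else {
        rai.push_back(ci - 1); rbi.push_back(-1);
        if (used_a[ci - 1]) { overlap = true; break; }
        if (F[ci][cj] == H[ci - 1][cj] + gap_open) state = 0;
        --ci;
      }
    }
    if (overlap || rai.empty()) continue;
    std::reverse(rai.begin(), rai.end());
    std::reverse(rbi.begin(), rbi.end());
    al.ai = rai; al.bi = rbi;
    for (size_t t = 0; t < rai.size(); ++t) {
      if (rai[t] >= 0) used_a[rai[t]] = true;
      if (rbi[t] >= 0) used_b[rbi[t]] = true;
    }
    out.push_back(al);
  }
  List res(out.size());
  for (size_t t = 0; t < out.size(); ++t) {
    res[t] = List::create(_["score"] = out[t].score,
                          _["a_pos"] = IntegerVector(out[t].ai.begin(), out[t].ai.end()),
                          _["b_pos"] = IntegerVector(out[t].bi.begin(), out[t].bi.end()));
  }
  return res;
}

// batched pairwise structure alignment: aligns every pair of pre-encoded
// bins and returns the spans of all retained local alignments.
// [[Rcpp::export(name = ".sw_struct_align_all")]]
DataFrame sw_struct_align_all(List seqs, List strs,
                              double match_nt, double mismatch_nt,
                              double struct_bonus, double struct_mismatch,
                              double gap_open, double gap_extend,
                              double min_score, int max_alignments) {
  int n = seqs.size();
  std::vector<int> ia, ib;
  std::vector<double> sc;
  std::vector<int> len, as_, ae_, bs_, be_;
  for (int i = 0; i < n - 1; ++i) {
    IntegerVector a = seqs[i], astr = strs[i];
    for (int j = i + 1; j < n; ++j) {
      IntegerVector b = seqs[j], bstr = strs[j];
      List res = sw_struct_align(a, astr, b, bstr, match_nt, mismatch_nt,
                                 struct_bonus, struct_mismatch, gap_open,
                                 gap_extend, min_score, max_alignments);
      for (int t = 0; t < res.size(); ++t) {
        List al = res[t];
        IntegerVector ap = al["a_pos"], bp = al["b_pos"];
        int amin = INT_MAX, amax = -1, bmin = INT_MAX, bmax = -1;
        for (int u = 0; u < ap.size(); ++u) {
          if (ap[u] >= 0) { amin = std::min(amin, (int)ap[u]); amax = std::max(amax, (int)ap[u]); }
          if (bp[u] >= 0) { bmin = std::min(bmin, (int)bp[u]); bmax = std::max(bmax, (int)bp[u]); }
        }
        ia.push_back(i + 1); ib.push_back(j + 1);
        sc.push_back(as<double>(al["score"]));
        len.push_back(ap.size());
        as_.push_back(amin); ae_.push_back(amax + 1);
        bs_.push_back(bmin); be_.push_back(bmax + 1);
      }
    }
  }
  return DataFrame::create(_["i"] = ia, _["j"] = ib, _["score"] = sc,
                           _["length"] = len, _["a_start"] = as_,
                           _["a_end"] = ae_, _["b_start"] = bs_,
                           _["b_end"] = be_);
}

// gapless log-odds scan of a structure profile over a sequence.
// unpaired: W (width x 4) log-odds; paired: rows (i, j) into pair_lod
// (n_pairs x 16, ordered pair code = base_i * 4 + base_j).  Unpaired
// columns listed in `unpaired_cols` (0-based).
// [[Rcpp::export(name = ".profile_scan")]]
NumericVector profile_scan(IntegerVector seq, int width,
                           IntegerVector unpaired_cols, NumericMatrix W,
                           IntegerVector pair_i, IntegerVector pair_j,
                           NumericMatrix pair_lod) {
  int n = seq.size();
  int n_off = n - width + 1;
  if (n_off < 1) return NumericVector(0);
  NumericVector out(n_off);
  int nu = unpaired_cols.size(), np = pair_i.size();
  for (int off = 0; off < n_off; ++off) {
    double s = 0.0;
    for (int u = 0; u < nu; ++u) {
      int c = unpaired_cols[u];
      s += W(u, seq[off + c]);
    }
    for (int p = 0; p < np; ++p) {
      int code = seq[off + pair_i[p]] * 4 + seq[off + pair_j[p]];
      s += pair_lod(p, code);
    }
    out[off] = s;
  }
  return out;
}
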
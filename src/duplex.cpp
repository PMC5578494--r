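#include <Rcpp.h>
using namespace Rcpp;

// Base codes: A=0, C=1, G=2, U=3 (prepared on the R side).
// Pair ids over the allowed intermolecular pairs:
//   0 AU, 1 UA, 2 CG, 3 GC, 4 GU, 5 UG, -1 not pairable.
static inline int pair_id(int x, int y) {
  if (x == 0 && y == 3) return 0;
  if (x == 3 && y == 0) return 1;
  if (x == 1 && y == 2) return 2;
  if (x == 2 && y == 1) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

static inline bool closing_penalty(int pid) {
  // terminal AU/GU penalty applies to any non-GC/CG helix-end pair
  return pid == 0 || pid == 1 || pid == 4 || pid == 5;
}

static const double INF = 1e9;

// Minimum free energy intermolecular hybrid between strand m (5'->3') and
// strand s (5'->3'), antiparallel, no intramolecular structure.  Stacks,
// bulges and interior loops up to max_loop unpaired nt per strand.  A finite
// structure must contain at least one stacked doublet (>= 2 adjacent pairs).
//
// stack_mat: 6x6, stack_mat(p1, p2) = dG of doublet with pair p1 = (m[i],s[j])
// followed by pair p2 = (m[i+1], s[j-1]).
// bulge:    dG by total unpaired length 1..len(bulge)
// interior: dG by total unpaired length 2..len(interior)+1
// [[Rcpp::export(name = ".duplex_mfe_cpp")]]
List duplex_mfe_cpp(IntegerVector m, IntegerVector s, NumericMatrix stack_mat,
                    NumericVector bulge, NumericVector interior,
                    double init, double terminal_au, double asym_per_nt,
                    double asym_cap, int max_loop) {
  const int n = m.size(), L = s.size();
  // layer 0: any structure ending at pair (i,j); layer 1: contains a stack
  std::vector<double> E(2 * n * L, INF);
  std::vector<int> par(2 * n * L, -1); // encodes (layer, i', j') or -1 = first pair
  auto idx = [&](int layer, int i, int j) { return layer * n * L + i * L + j; };

  std::vector<int> pid(n * L, -1);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < L; ++j) pid[i * L + j] = pair_id(m[i], s[j]);

  for (int i = 0; i < n; ++i) {
    for (int j = L - 1; j >= 0; --j) {
      int p = pid[i * L + j];
      if (p < 0) continue;
      // open a duplex at (i, j)
      double best0 = init + (closing_penalty(p) ? terminal_au : 0.0);
      int par0 = -1;
      double best1 = INF;
      int par1 = -1;
      // extend from a previous pair (i2, j2), i2 < i, j2 > j
      int ilo = std::max(0, i - 1 - max_loop);
      for (int i2 = i - 1; i2 >= ilo; --i2) {
        int jhi = std::min(L - 1, j + 1 + max_loop);
        for (int j2 = j + 1; j2 <= jhi; ++j2) {
          int p2 = pid[i2 * L + j2];
          if (p2 < 0) continue;
          int a = i - i2 - 1;      // unpaired on m
          int b = j2 - j - 1;      // unpaired on s
          double cost;
          bool is_stack = (a == 0 && b == 0);
          if (is_stack) {
            cost = stack_mat(p2, p);
          } else if (a == 0 || b == 0) {
            int len = a + b;
            if (len > bulge.size()) continue;
            cost = bulge[len - 1];
          } else {
            int len = a + b;
            if (len - 1 > interior.size()) continue;
            cost = interior[len - 2] +
                   std::min(asym_cap, asym_per_nt * std::abs(a - b));
          }
          double c0 = E[idx(0, i2, j2)] + cost;
          if (c0 < best0 - 1e-12) { best0 = c0; par0 = idx(0, i2, j2); }
          double c1 = E[idx(1, i2, j2)] + cost;
          if (is_stack) c1 = std::min(c1, E[idx(0, i2, j2)] + cost);
          if (c1 < best1 - 1e-12) {
            best1 = c1;
            par1 = (is_stack && E[idx(0, i2, j2)] + cost <=
                                E[idx(1, i2, j2)] + cost)
                     ? idx(0, i2, j2) : idx(1, i2, j2);
          }
        }
      }
      E[idx(0, i, j)] = best0; par[idx(0, i, j)] = par0;
      E[idx(1, i, j)] = best1; par[idx(1, i, j)] = par1;
    }
  }

  // close the duplex: add terminal penalty at the last pair
  double best = INF;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = L - 1; j >= 0; --j) {
      int p = pid[i * L + j];
      if (p < 0) continue;
      double v = E[idx(1, i, j)];
      if (v >= INF / 2) continue;
      v += closing_penalty(p) ? terminal_au : 0.0;
      if (v < best - 1e-12) { best = v; bi = i; bj = j; }
    }
  }
  if (bi < 0)
    return List::create(_["dg"] = R_PosInf,
                        _["pairs"] = IntegerMatrix(0, 2));

  // traceback (last pair first)
  std::vector<std::pair<int, int>> pr;
  int cur = idx(1, bi, bj);
  while (cur >= 0) {
    int rem = cur % (n * L);
    pr.push_back(std::make_pair(rem / L + 1, rem % L + 1)); // 1-based
    cur = par[cur];
  }
  IntegerMatrix pm(pr.size(), 2);
  for (size_t k = 0; k < pr.size(); ++k) { // reverse into 5'->3' m order
    pm(k, 0) = pr[pr.size() - 1 - k].first;
    pm(k, 1) = pr[pr.size() - 1 - k].second;
  }
  return List::create(_["dg"] = best, _["pairs"] = pm);
}

// Local antiparallel complementarity alignment (miRanda-style), affine gaps.
// m: miRNA 5'->3'; r: site reversed (so the alignment is co-linear).
// subst: 6x... scoring by complementarity: match_w if Watson-Crick,
// wobble_w if GU, mismatch_w otherwise; scores at miRNA seed positions
// (1-based, in `seed_pos`) are multiplied by seed_scale.
// [[Rcpp::export(name = ".sw_complement_cpp")]]
List sw_complement_cpp(IntegerVector m, IntegerVector r,
                       double match_w, double wobble_w, double mismatch_w,
                       double gap_open, double gap_extend,
                       IntegerVector seed_pos, double seed_scale) {
  const int n = m.size(), L = r.size();
  std::vector<bool> in_seed(n + 1, false);
  for (int k = 0; k < seed_pos.size(); ++k)
    if (seed_pos[k] >= 1 && seed_pos[k] <= n) in_seed[seed_pos[k]] = true;

  auto subst = [&](int i, int j) { // 1-based
    int p = pair_id(m[i - 1], r[j - 1]);
    double w = (p < 0) ? mismatch_w : ((p == 4 || p == 5) ? wobble_w : match_w);
    return in_seed[i] ? w * seed_scale : w;
  };

  const double NEG = -1e9;
  // H: pair/mismatch ends; Gx: gap in m (consumes r); Gy: gap in r
  std::vector<double> H((n + 1) * (L + 1), 0.0), Gx((n + 1) * (L + 1), NEG),
      Gy((n + 1) * (L + 1), NEG);
  std::vector<int> trb((n + 1) * (L + 1), 0); // traceback for H: 0 stop,1 diag,2 fromGx,3 fromGy
  auto id = [&](int i, int j) { return i * (L + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= L; ++j) {
      double gx1 = H[id(i, j - 1)] + gap_open;
      double gx2 = Gx[id(i, j - 1)] + gap_extend;
      Gx[id(i, j)] = std::max(gx1, gx2);
      double gy1 = H[id(i - 1, j)] + gap_open;
      double gy2 = Gy[id(i - 1, j)] + gap_extend;
      Gy[id(i, j)] = std::max(gy1, gy2);
      double dprev = std::max(std::max(H[id(i - 1, j - 1)],
                                       Gx[id(i - 1, j - 1)]),
                              Gy[id(i - 1, j - 1)]);
      double d = dprev + subst(i, j);
      double h = 0.0;
      int tb = 0;
      if (d > h) {
        h = d;
        tb = (dprev == H[id(i - 1, j - 1)]) ? 1
             : (dprev == Gx[id(i - 1, j - 1)] ? 2 : 3);
      }
      H[id(i, j)] = h;
      trb[id(i, j)] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["pairs"] = IntegerMatrix(0, 2),
                        _["m_range"] = IntegerVector::create(0, 0),
                        _["r_range"] = IntegerVector::create(0, 0));

  // traceback aligned (i, j) columns; gaps tracked to find alignment start
  std::vector<std::pair<int, int>> cols;
  int i = bi, j = bj;
  int state = 1; // in H
  while (i > 0 && j > 0) {
    if (state == 1) {
      int tb = trb[id(i, j)];
      if (tb == 0) break;
      cols.push_back(std::make_pair(i, j));
      state = tb;
      --i; --j;
      if (state == 1 && trb[id(i, j)] == 0 && H[id(i, j)] <= 0.0) break;
    } else if (state == 2) { // Gx: gap in m, consume r
      if (Gx[id(i, j)] == H[id(i, j - 1)] + gap_open) state = 1;
      --j;
    } else { // Gy
      if (Gy[id(i, j)] == H[id(i - 1, j)] + gap_open) state = 1;
      --i;
    }
  }
  IntegerMatrix pm(cols.size(), 2);
  int mlo = bi, rlo = bj;
  for (size_t k = 0; k < cols.size(); ++k) {
    pm(k, 0) = cols[cols.size() - 1 - k].first;
    pm(k, 1) = cols[cols.size() - 1 - k].second;
    mlo = std::min(mlo, (int)cols[k].first);
    rlo = std::min(rlo, (int)cols[k].second);
  }
  return List::create(_["score"] = best, _["pairs"] = pm,
                      _["m_range"] = IntegerVector::create(mlo, bi),
                      _["r_range"] = IntegerVector::create(rlo, bj));
}
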
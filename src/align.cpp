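#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Contact-map alignment by iterative double dynamic programming, in the
// spirit of map_align: an inner pass scores the compatibility of the
// contact neighborhoods of every residue pair (i in A, j in B); an outer
// affine-gap alignment on that similarity matrix yields a strictly
// monotone partial mapping; the similarity matrix is then recomputed
// restricted to the current mapping and the process repeats.
//
// The reported score is always recomputed from the mapping itself:
//   sum over contact pairs (i,k) in A matched onto contacts (m[i],m[k])
//   in B of min(1, sA/sB, sB/sA) with s the sequence separations,
//   plus affine penalties for internal gaps (end gaps are free).

static inline double sep_score(int sa, int sb) {
  const double lo = std::min(sa, sb), hi = std::max(sa, sb);
  return lo / hi; // both >= 1
}

struct Maps {
  int nA, nB;
  std::vector<std::vector<int>> pA, pB; // sorted contact partners, 0-based
  std::vector<bool> bcon;               // nB*nB contact lookup for B
  bool has_b(int i, int j) const { return bcon[i * (size_t)nB + j]; }
};

// inner gapless monotone matching of two signed-offset lists
static double neighborhood_score(const std::vector<int> &pa, int i,
                                 const std::vector<int> &pb, int j) {
  const int p = pa.size(), q = pb.size();
  if (p == 0 || q == 0) return 0.0;
  std::vector<double> prev(q + 1, 0.0), cur(q + 1, 0.0);
  for (int a = 1; a <= p; ++a) {
    const int oa = pa[a - 1] - i;
    for (int b = 1; b <= q; ++b) {
      const int ob = pb[b - 1] - j;
      double best = std::max(prev[b], cur[b - 1]);
      if ((oa > 0) == (ob > 0)) {
        const double s = prev[b - 1] + sep_score(std::abs(oa), std::abs(ob));
        if (s > best) best = s;
      }
      cur[b] = best;
    }
    std::swap(prev, cur);
  }
  return prev[q];
}

// Outer alignment: overlap-style Gotoh. Matches score S[i][j] >= 0;
// internal gaps cost open + ext*(len-1); leading/trailing gaps are free.
// Returns matched pairs via `mi`, `mj` (0-based, increasing).
static void outer_align(const std::vector<std::vector<double>> &S,
                        double gap_open, double gap_ext,
                        std::vector<int> &mi, std::vector<int> &mj) {
  const int nA = S.size(), nB = S[0].size();
  const double NEG = -1e30;
  // state matrices: M ends in a match at (i,j); X ends in a gap in B
  // (A residues skipped); Y ends in a gap in A.
  std::vector<std::vector<double>> M(nA, std::vector<double>(nB, NEG)),
      X(nA, std::vector<double>(nB, NEG)), Y(nA, std::vector<double>(nB, NEG));
  std::vector<std::vector<char>> fromM(nA, std::vector<char>(nB, 0)),
      fromX(nA, std::vector<char>(nB, 0)), fromY(nA, std::vector<char>(nB, 0));
  for (int i = 0; i < nA; ++i) {
    for (int j = 0; j < nB; ++j) {
      // start fresh (free leading gaps) or continue from a previous
      // state; ties prefer continuing the diagonal so zero-score cells
      // bridge matched clusters instead of breaking the path
      double best = 0.0; char arg = 0; // 0 = start
      if (i > 0 && j > 0) {
        if (M[i - 1][j - 1] >= best) { best = M[i - 1][j - 1]; arg = 1; }
        if (X[i - 1][j - 1] > best) { best = X[i - 1][j - 1]; arg = 2; }
        if (Y[i - 1][j - 1] > best) { best = Y[i - 1][j - 1]; arg = 3; }
      }
      M[i][j] = S[i][j] + best;
      fromM[i][j] = arg;
      if (i > 0) {
        double xo = M[i - 1][j] + gap_open, xe = X[i - 1][j] + gap_ext;
        if (xo >= xe) { X[i][j] = xo; fromX[i][j] = 1; }
        else          { X[i][j] = xe; fromX[i][j] = 2; }
      }
      if (j > 0) {
        double yo = M[i][j - 1] + gap_open, ye = Y[i][j - 1] + gap_ext;
        if (yo >= ye) { Y[i][j] = yo; fromY[i][j] = 1; }
        else          { Y[i][j] = ye; fromY[i][j] = 3; }
      }
    }
  }
  // best end match (trailing gaps free); last maximum in row-major order
  // so zero-score diagonal continuations are kept in the mapping
  int bi = 0, bj = 0; double best = NEG;
  for (int i = 0; i < nA; ++i)
    for (int j = 0; j < nB; ++j)
      if (M[i][j] >= best) { best = M[i][j]; bi = i; bj = j; }
  mi.clear(); mj.clear();
  int i = bi, j = bj; char state = 1; // 1 = M, 2 = X, 3 = Y
  while (state != 0) {
    if (state == 1) {
      mi.push_back(i); mj.push_back(j);
      state = fromM[i][j]; --i; --j;
    } else if (state == 2) {
      state = fromX[i][j]; --i;
    } else {
      state = fromY[i][j]; --j;
    }
  }
  std::reverse(mi.begin(), mi.end());
  std::reverse(mj.begin(), mj.end());
}

// objective recomputed from the mapping alone
static double objective(const Maps &mp, const std::vector<int> &map_a,
                        double gap_open, double gap_ext, int *n_matched) {
  double score = 0.0;
  int matched_contacts = 0;
  for (int i = 0; i < mp.nA; ++i) {
    if (map_a[i] < 0) continue;
    for (int k : mp.pA[i]) {
      if (k <= i || map_a[k] < 0) continue; // count each pair once
      if (mp.has_b(map_a[i], map_a[k])) {
        score += sep_score(k - i, map_a[k] - map_a[i]);
        ++matched_contacts;
      }
    }
  }
  int prev_i = -1, prev_j = -1;
  for (int i = 0; i < mp.nA; ++i) {
    if (map_a[i] < 0) continue;
    if (prev_i >= 0) {
      const int dA = i - prev_i - 1, dB = map_a[i] - prev_j - 1;
      if (dA > 0) score += gap_open + gap_ext * (dA - 1);
      if (dB > 0) score += gap_open + gap_ext * (dB - 1);
    }
    prev_i = i; prev_j = map_a[i];
  }
  if (n_matched) *n_matched = matched_contacts;
  return score;
}

// run the outer-DP / restricted-M iteration from a given similarity
// matrix; updates best_map/best_score with the best objective seen
static void iterate_from(const Maps &mp, std::vector<std::vector<double>> S,
                         double gap_open, double gap_ext, int max_iter,
                         double tol, std::vector<int> &best_map,
                         double &best_score, int &iterations) {
  const int nA = mp.nA, nB = mp.nB;
  std::vector<int> mi, mj, map_a(nA, -1);
  double prev_score = R_NegInf;
  for (int it = 0; it < max_iter; ++it) {
    ++iterations;
    outer_align(S, gap_open, gap_ext, mi, mj);
    std::fill(map_a.begin(), map_a.end(), -1);
    for (size_t k = 0; k < mi.size(); ++k) map_a[mi[k]] = mj[k];
    const double score = objective(mp, map_a, gap_open, gap_ext, nullptr);
    if (score > best_score) { best_score = score; best_map = map_a; }
    if (it > 0 && std::abs(score - prev_score) < tol) break;
    prev_score = score;
    for (int i = 0; i < nA; ++i) {
      for (int j = 0; j < nB; ++j) {
        double s = 0.0;
        for (int k : mp.pA[i]) {
          const int l = map_a[k];
          if (l < 0 || l == j || !mp.has_b(j, l)) continue;
          s += sep_score(std::abs(k - i), std::abs(l - j));
        }
        S[i][j] = 0.5 * s;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_align_maps(int nA, int nB, IntegerMatrix Ac, IntegerMatrix Bc,
                    double gap_open, double gap_ext, int max_iter, double tol,
                    int restart_limit = 24) {
  Maps mp;
  mp.nA = nA; mp.nB = nB;
  mp.pA.assign(nA, {}); mp.pB.assign(nB, {});
  mp.bcon.assign((size_t)nB * nB, false);
  for (int r = 0; r < Ac.nrow(); ++r) {
    const int i = Ac(r, 0) - 1, j = Ac(r, 1) - 1;
    mp.pA[i].push_back(j); mp.pA[j].push_back(i);
  }
  for (int r = 0; r < Bc.nrow(); ++r) {
    const int i = Bc(r, 0) - 1, j = Bc(r, 1) - 1;
    mp.pB[i].push_back(j); mp.pB[j].push_back(i);
    mp.bcon[i * (size_t)nB + j] = true;
    mp.bcon[j * (size_t)nB + i] = true;
  }
  for (auto &v : mp.pA) std::sort(v.begin(), v.end());
  for (auto &v : mp.pB) std::sort(v.begin(), v.end());

  std::vector<std::vector<double>> S0(nA, std::vector<double>(nB, 0.0));
  for (int i = 0; i < nA; ++i)
    for (int j = 0; j < nB; ++j)
      S0[i][j] = 0.5 * neighborhood_score(mp.pA[i], i, mp.pB[j], j);

  std::vector<int> best_map(nA, -1);
  double best_score = 0.0;
  int iterations = 0;
  iterate_from(mp, S0, gap_open, gap_ext, max_iter, tol,
               best_map, best_score, iterations);

  // Also restart from contact-pair anchors (contact (i,k) of A matched
  // onto contact (j,l) of B): the iteration is a local search and the
  // neighborhood seeding alone can lock onto a wrong register when the
  // fold is self-similar (helices) or contacts are sparse. All anchors
  // are tried when few; otherwise the `restart_limit` best by the
  // neighborhood-similarity prior S0[i][j] + S0[k][l].
  {
    const long total = (long)Ac.nrow() * Bc.nrow();
    std::vector<std::pair<int, int>> picked;
    if (total <= 300) {
      for (int a = 0; a < Ac.nrow(); ++a)
        for (int b = 0; b < Bc.nrow(); ++b)
          picked.push_back({a, b});
    } else {
      std::vector<std::pair<double, long>> ranked;
      ranked.reserve(total);
      for (int a = 0; a < Ac.nrow(); ++a) {
        const int i = Ac(a, 0) - 1, k = Ac(a, 1) - 1;
        for (int b = 0; b < Bc.nrow(); ++b) {
          const int j = Bc(b, 0) - 1, l = Bc(b, 1) - 1;
          ranked.push_back({-(S0[i][j] + S0[k][l]),
                            (long)a * Bc.nrow() + b});
        }
      }
      const size_t keep = std::min<size_t>(restart_limit, ranked.size());
      std::partial_sort(ranked.begin(), ranked.begin() + keep, ranked.end());
      for (size_t r = 0; r < keep; ++r)
        picked.push_back({(int)(ranked[r].second / Bc.nrow()),
                          (int)(ranked[r].second % Bc.nrow())});
    }
    std::vector<int> anchor(nA, -1);
    for (auto &pk : picked) {
      const int a = pk.first, b = pk.second;
      {
        const int i = Ac(a, 0) - 1, k = Ac(a, 1) - 1;
        const int j = Bc(b, 0) - 1, l = Bc(b, 1) - 1;
        std::fill(anchor.begin(), anchor.end(), -1);
        anchor[i] = j; anchor[k] = l;
        std::vector<std::vector<double>> S(nA, std::vector<double>(nB, 0.0));
        for (int r = 0; r < nA; ++r) {
          for (int c = 0; c < nB; ++c) {
            double s = 0.0;
            for (int p : mp.pA[r]) {
              const int q = anchor[p];
              if (q < 0 || q == c || !mp.has_b(c, q)) continue;
              s += sep_score(std::abs(p - r), std::abs(q - c));
            }
            S[r][c] = 0.5 * s;
          }
        }
        // force the first pass through the anchor; the bonus is not part
        // of the objective, which is always recomputed from the mapping
        S[i][j] += 1e3; S[k][l] += 1e3;
        iterate_from(mp, S, gap_open, gap_ext, max_iter, tol,
                     best_map, best_score, iterations);
      }
    }
  }

  // a mapping with no matched contact never beats the empty mapping
  IntegerVector mapping(nA, 0);
  if (best_score > 0.0)
    for (int i = 0; i < nA; ++i) mapping[i] = best_map[i] + 1;
  else
    best_score = 0.0;
  return List::create(_["mapping"] = mapping, _["score"] = best_score,
                      _["iterations"] = iterations);
}
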
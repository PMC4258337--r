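#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Two-pass sequential connected-component labeling with union-find.
// Raster order: rows top to bottom, columns left to right. Labels are
// renumbered consecutively 1..K in order of first appearance.
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a < b) parent[b] = a; else if (b < a) parent[a] = b;
}

// [[Rcpp::export]]
IntegerMatrix label_mask_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  int next = 0;

  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c)) continue;
      int labs[4];
      int n = 0;
      if (c > 0 && mask(r, c - 1)) labs[n++] = lab(r, c - 1);
      if (r > 0 && mask(r - 1, c)) labs[n++] = lab(r - 1, c);
      if (connectivity == 8 && r > 0) {
        if (c > 0 && mask(r - 1, c - 1)) labs[n++] = lab(r - 1, c - 1);
        if (c < W - 1 && mask(r - 1, c + 1)) labs[n++] = lab(r - 1, c + 1);
      }
      if (n == 0) {
        parent.push_back(++next);
        lab(r, c) = next;
      } else {
        int best = labs[0];
        for (int k = 1; k < n; ++k) if (labs[k] < best) best = labs[k];
        lab(r, c) = best;
        for (int k = 0; k < n; ++k) uf_union(parent, best, labs[k]);
      }
    }
  }

  std::vector<int> renum(next + 1, 0);
  int K = 0;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      if (lab(r, c)) {
        int root = uf_find(parent, lab(r, c));
        if (!renum[root]) renum[root] = ++K;
        lab(r, c) = renum[root];
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Greedy region growing with fusion of color and space information.
//
// State per pixel: 0 unseen, 1 in frontier, 2 rejected, 3 accepted.
// Flags per accepted pixel: 1 substance, 2 coating (hole filling adds 3 on
// the R side). Each iteration picks the frontier pixel whose shifted hue is
// closest (circular distance) to the running circular mean of accepted
// substance hues, earliest insertion winning ties; undefined hue ranks after
// every defined hue. An accepted pixel pushes its unseen neighbors; a
// rejected pixel leaves the frontier for good, so the loop performs at most
// H*W acceptances plus H*W rejections.
// ---------------------------------------------------------------------------

static inline double circ_dist(double a, double b) {
  // both arguments lie in [0, 360), so no modular reduction is needed
  double d = std::fabs(a - b);
  return d > 180.0 ? 360.0 - d : d;
}

// [[Rcpp::export]]
List grow_region_cpp(NumericMatrix hs, NumericMatrix sat, NumericMatrix inten,
                     int seed_r, int seed_c,
                     double hue_center, double hue_half_width,
                     double intensity_min, double saturation_min,
                     double white_s_max, double white_i_min,
                     double yellow_lo, double yellow_hi,
                     int enclosure_min, int connectivity) {
  const int H = hs.nrow(), W = hs.ncol();
  IntegerMatrix state(H, W), flags(H, W);

  auto is_substance = [&](int r, int c) -> bool {
    double h = hs(r, c);
    if (ISNAN(h)) return false;
    return circ_dist(h, hue_center) <= hue_half_width &&
           sat(r, c) >= saturation_min && inten(r, c) >= intensity_min;
  };
  auto coating_color = [&](int r, int c) -> bool {
    if (sat(r, c) < white_s_max && inten(r, c) > white_i_min) return true;
    double h = hs(r, c);
    return !ISNAN(h) && h >= yellow_lo && h <= yellow_hi;
  };
  auto accepted_neighbors = [&](int r, int c) -> int {
    int n = 0;
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (!dr && !dc) continue;
        int rr = r + dr, cc = c + dc;
        if (rr >= 0 && rr < H && cc >= 0 && cc < W && state(rr, cc) == 3) ++n;
      }
    return n;
  };
  auto is_coating_admissible = [&](int r, int c) -> bool {
    return coating_color(r, c) && inten(r, c) >= intensity_min &&
           accepted_neighbors(r, c) >= enclosure_min;
  };

  std::vector<int> fr_r, fr_c;  // frontier in insertion order (dead entries skipped)
  fr_r.reserve(4096); fr_c.reserve(4096);
  int n_dead = 0;

  auto push_neighbors = [&](int r, int c) {
    const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
    const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1},
              dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
    const int *dr = connectivity == 8 ? dr8 : dr4;
    const int *dc = connectivity == 8 ? dc8 : dc4;
    int nn = connectivity == 8 ? 8 : 4;
    for (int k = 0; k < nn; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (state(rr, cc) == 0) {
        state(rr, cc) = 1;
        fr_r.push_back(rr);
        fr_c.push_back(cc);
      }
    }
  };

  // Seed: assumed pre-validated as substance on the R side.
  double sum_sin = 0.0, sum_cos = 0.0;
  state(seed_r, seed_c) = 3;
  flags(seed_r, seed_c) = 1;
  {
    double h = hs(seed_r, seed_c) * M_PI / 180.0;
    sum_sin += std::sin(h); sum_cos += std::cos(h);
  }
  push_neighbors(seed_r, seed_c);

  long accepted = 1, rejected = 0;
  while (true) {
    if (n_dead > (int)fr_r.size() / 2) {  // compact, preserving insertion order
      std::vector<int> nr, nc;
      nr.reserve(fr_r.size() - n_dead); nc.reserve(fr_r.size() - n_dead);
      for (size_t k = 0; k < fr_r.size(); ++k)
        if (state(fr_r[k], fr_c[k]) == 1) { nr.push_back(fr_r[k]); nc.push_back(fr_c[k]); }
      fr_r.swap(nr); fr_c.swap(nc);
      n_dead = 0;
    }
    double mean_h = std::atan2(sum_sin, sum_cos) * 180.0 / M_PI;
    if (mean_h < 0) mean_h += 360.0;
    double best = 1e18;
    long best_k = -1;
    for (size_t k = 0; k < fr_r.size(); ++k) {
      if (state(fr_r[k], fr_c[k]) != 1) continue;
      double h = hs(fr_r[k], fr_c[k]);
      double d = ISNAN(h) ? 361.0 : circ_dist(h, mean_h);
      if (d < best) { best = d; best_k = (long)k; }
    }
    if (best_k < 0) break;  // frontier exhausted: no pass can accept anything
    int r = fr_r[best_k], c = fr_c[best_k];
    bool substance = is_substance(r, c);
    if (substance || is_coating_admissible(r, c)) {
      state(r, c) = 3;
      flags(r, c) = substance ? 1 : 2;
      if (substance && !ISNAN(hs(r, c))) {
        double h = hs(r, c) * M_PI / 180.0;
        sum_sin += std::sin(h); sum_cos += std::cos(h);
      }
      ++accepted;
      ++n_dead;
      push_neighbors(r, c);
    } else {
      state(r, c) = 2;
      ++rejected;
      ++n_dead;
    }
  }

  return List::create(_["flags"] = flags,
                      _["accepted"] = (double)accepted,
                      _["rejected"] = (double)rejected);
}
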
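#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a logical matrix by iterative flood fill.
// Returns an integer matrix with 0 for background and 1..k for components.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline int nb(const LogicalMatrix &m, int i, int j) {
  // safe accessor treating out-of-bounds as background
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen topology-preserving thinning of a binary matrix.
// Produces an 8-connected, 1-pixel-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  bool changed = true;
  std::vector<int> del;
  del.reserve(1024);
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img(i, j)) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = nb(img, i - 1, j);
          int p3 = nb(img, i - 1, j + 1);
          int p4 = nb(img, i, j + 1);
          int p5 = nb(img, i + 1, j + 1);
          int p6 = nb(img, i + 1, j);
          int p7 = nb(img, i + 1, j - 1);
          int p8 = nb(img, i, j - 1);
          int p9 = nb(img, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(i + j * nr);
        }
      }
      if (!del.empty()) changed = true;
      for (size_t k = 0; k < del.size(); ++k)
        img(del[k] % nr, del[k] / nr) = false;
    }
  }
  return img;
}

// Number of true 8-neighbours for every pixel (used for endpoint/junction
// classification of skeletons).
// [[Rcpp::export]]
IntegerMatrix neighbor_count_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int s = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          s += nb(mask, i + di, j + dj);
        }
      out(i, j) = s;
    }
  return out;
}

static inline int crossing_number(const LogicalMatrix &m, int i, int j) {
  // number of 0->1 transitions in the clockwise neighbour ring: 1 for an
  // endpoint, 2 for a path pixel (staircase corners included), >=3 for a
  // true junction
  int p[8] = {nb(m, i - 1, j),     nb(m, i - 1, j + 1), nb(m, i, j + 1),
              nb(m, i + 1, j + 1), nb(m, i + 1, j),     nb(m, i + 1, j - 1),
              nb(m, i, j - 1),     nb(m, i - 1, j - 1)};
  int a = 0;
  for (int k = 0; k < 8; ++k) a += (p[k] == 0 && p[(k + 1) % 8] == 1);
  return a;
}

// Remove terminal spurs shorter than min_px (Euclidean path length) from a
// skeleton: walk from each endpoint to the first true junction (crossing
// number >= 3); if reached within min_px, delete the walked path. Branches
// at least min_px long keep their endpoints. Repeats until stable.
// [[Rcpp::export]]
LogicalMatrix prune_cpp(LogicalMatrix skel, double min_px) {
  int nr = skel.nrow(), nc = skel.ncol();
  LogicalMatrix img = clone(skel);
  if (min_px <= 0) return img;
  const double diag = std::sqrt(2.0);
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 10) {
    changed = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!img(i, j)) continue;
        // endpoint?
        int degree = 0;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            degree += nb(img, i + di, j + dj);
          }
        if (degree != 1) continue;
        // walk towards the first true junction
        std::vector<int> path;
        std::vector<int> visited;
        int ci = i, cj = j;
        double len = 0.0;
        bool del = false;
        while (true) {
          if (crossing_number(img, ci, cj) >= 3) { del = true; break; }
          path.push_back(ci + cj * nr);
          visited.push_back(ci + cj * nr);
          int ni = -1, njj = -1;
          int found = 0;
          bool at_junction = false;
          double jstep = 0.0;
          for (int dj2 = -1; dj2 <= 1; ++dj2)
            for (int di2 = -1; di2 <= 1; ++di2) {
              if (di2 == 0 && dj2 == 0) continue;
              int ti = ci + di2, tj = cj + dj2;
              if (ti < 0 || tj < 0 || ti >= nr || tj >= nc) continue;
              if (!img(ti, tj)) continue;
              int id = ti + tj * nr;
              bool seen = false;
              for (size_t v = 0; v < visited.size(); ++v)
                if (visited[v] == id) { seen = true; break; }
              if (seen) continue;
              if (crossing_number(img, ti, tj) >= 3) {
                at_junction = true;
                jstep = (di2 != 0 && dj2 != 0) ? diag : 1.0;
              }
              if (found == 0) { ni = ti; njj = tj; }
              ++found;
            }
          if (at_junction) {               // branch attaches here
            if (len + jstep < min_px) del = true;
            break;
          }
          if (found == 0) break;           // free path end: keep
          len += (ni != ci && njj != cj) ? diag : 1.0;
          if (len >= min_px) break;        // long enough: keep
          ci = ni; cj = njj;
        }
        if (del && len < min_px) {
          for (size_t k = 0; k < path.size(); ++k)
            img(path[k] % nr, path[k] / nr) = false;
          changed = true;
        }
      }
    }
  }
  return img;
}

// Resolve blunt branch ends left by thinning: a terminal pixel whose
// neighbours form a single adjacent group (crossing number 1) but which has
// degree >= 2 (a triangle cap) carries no degree-1 endpoint. Removing such
// pixels (repeatedly) exposes a proper endpoint without changing topology.
// [[Rcpp::export]]
LogicalMatrix clean_blunt_ends_cpp(LogicalMatrix skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  LogicalMatrix img = clone(skel);
  bool changed = true;
  int guard = 0;
  std::vector<int> del;
  while (changed && guard++ < 8) {
    changed = false;
    del.clear();
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        if (!img(i, j)) continue;
        int degree = 0;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            degree += nb(img, i + di, j + dj);
          }
        if (degree >= 2 && crossing_number(img, i, j) == 1)
          del.push_back(i + j * nr);
      }
    if (!del.empty()) changed = true;
    for (size_t k = 0; k < del.size(); ++k)
      img(del[k] % nr, del[k] / nr) = false;
  }
  return img;
}
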
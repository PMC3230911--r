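#include <Rcpp.h>
using namespace Rcpp;

// 8-neighbourhood offsets; bit k of a configuration code corresponds to
// neighbour k being foreground. Order is fixed and shared with the R side.
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Directional thinning. `deletable` is a 256-entry lookup, indexed by the
// 8-neighbour configuration code, precomputed in R from the Euler
// characteristic of the 3x3 neighbourhood (TRUE iff removing the centre
// pixel leaves the local Euler number unchanged). A border pixel (its
// neighbour in the current sweep direction is background) with at least two
// foreground neighbours is deleted immediately when the lookup allows it,
// so deletions within a sweep are sequential and the result deterministic.
// Sweep order per iteration: N, S, W, E; stops when a full iteration
// deletes nothing.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask, LogicalVector deletable) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix m = clone(mask);
  const int bdr[4] = {-1, 1, 0, 0};
  const int bdc[4] = {0, 0, -1, 1};
  bool changed = true;
  std::vector<int> border;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      // collect this direction's border pixels before deleting, so a
      // sweep erodes only the current one-pixel contour and cannot
      // cascade into the interior
      border.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m(r, c)) continue;
          int rb = r + bdr[d], cb = c + bdc[d];
          if ((rb < 0 || rb >= nr || cb < 0 || cb >= nc) || m(rb, cb) == 0)
            border.push_back(r + c * nr);
        }
      }
      for (size_t i = 0; i < border.size(); ++i) {
        int r = border[i] % nr, c = border[i] / nr;
        int cfg = 0, nn = 0;
        for (int k = 0; k < 8; ++k) {
          int rr = r + DR[k], cc = c + DC[k];
          if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && m(rr, cc)) {
            cfg |= (1 << k);
            ++nn;
          }
        }
        if (nn >= 2 && deletable[cfg]) {
          m(r, c) = 0;
          changed = true;
        }
      }
    }
  }
  return m;
}

// Connected-component labelling by flood fill, 8- or 4-connectivity.
// Labels are assigned in column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nnb = (connectivity == 8) ? 8 : 4;
  static const int DR4[4] = {-1, 1, 0, 0};
  static const int DC4[4] = {0, 0, -1, 1};
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int rr = pr + (nnb == 8 ? DR[k] : DR4[k]);
          int cc = pc + (nnb == 8 ? DC[k] : DC4[k]);
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  }
  return lab;
}
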
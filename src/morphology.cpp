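#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Grayscale morphology and segmentation kernels for the TIRF puncta pipeline.
// Conventions: matrices are row x col; coordinates returned to R are 1-based.
// Structuring elements arrive as n x 2 integer offset matrices (drow, dcol).
// Border policy: pixels outside the image are ignored (erosion over the
// in-image part of the neighbourhood), which maps constants to constants and
// keeps the white top-hat offset-invariant.

// [[Rcpp::export]]
NumericMatrix cpp_erode(NumericMatrix img, IntegerMatrix offsets) {
  int nr = img.nrow(), nc = img.ncol(), k = offsets.nrow();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = R_PosInf;
      for (int i = 0; i < k; ++i) {
        int rr = r + offsets(i, 0), cc = c + offsets(i, 1);
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = img(rr, cc);
        if (v < m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_dilate(NumericMatrix img, IntegerMatrix offsets) {
  int nr = img.nrow(), nc = img.ncol(), k = offsets.nrow();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = R_NegInf;
      for (int i = 0; i < k; ++i) {
        int rr = r + offsets(i, 0), cc = c + offsets(i, 1);
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = img(rr, cc);
        if (v > m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// Non-maximal suppression: a pixel is a peak when its value is >= threshold
// and >= every pixel within Chebyshev distance `radius`. Connected (8-way)
// plateaus of equal-valued candidate pixels are collapsed to their
// lexicographically smallest (row, col) member. Peaks are returned sorted by
// (row, col), 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_nms(NumericMatrix img, int radius, double threshold) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<bool> cand(static_cast<size_t>(nr) * nc, false);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = img(r, c);
      if (v < threshold) continue;
      bool ok = true;
      int r0 = std::max(0, r - radius), r1 = std::min(nr - 1, r + radius);
      int c0 = std::max(0, c - radius), c1 = std::min(nc - 1, c + radius);
      for (int cc = c0; cc <= c1 && ok; ++cc)
        for (int rr = r0; rr <= r1; ++rr)
          if (img(rr, cc) > v) { ok = false; break; }
      if (ok) cand[static_cast<size_t>(c) * nr + r] = true;
    }
  }
  // collapse connected equal-valued candidate plateaus
  std::vector<bool> seen(static_cast<size_t>(nr) * nc, false);
  std::vector<std::pair<int,int> > peaks;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      size_t idx = static_cast<size_t>(c) * nr + r;
      if (!cand[idx] || seen[idx]) continue;
      double v = img(r, c);
      int br = r, bc = c;  // lexicographic min (row, then col)
      std::queue<std::pair<int,int> > q;
      q.push(std::make_pair(r, c));
      seen[idx] = true;
      while (!q.empty()) {
        int pr = q.front().first, pc = q.front().second;
        q.pop();
        if (pr < br || (pr == br && pc < bc)) { br = pr; bc = pc; }
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int rr = pr + dr, cc = pc + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            size_t j = static_cast<size_t>(cc) * nr + rr;
            if (cand[j] && !seen[j] && img(rr, cc) == v) {
              seen[j] = true;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
      peaks.push_back(std::make_pair(br, bc));
    }
  }
  std::sort(peaks.begin(), peaks.end());
  IntegerMatrix out(static_cast<int>(peaks.size()), 2);
  for (size_t i = 0; i < peaks.size(); ++i) {
    out(static_cast<int>(i), 0) = peaks[i].first + 1;
    out(static_cast<int>(i), 1) = peaks[i].second + 1;
  }
  return out;
}

struct WsEntry {
  double elev;
  int bg;       // 1 when seeded from the background marker
  long order;   // FIFO tie-break for determinism
  int r, c, label;
};

struct WsCompare {
  bool operator()(const WsEntry &a, const WsEntry &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;       // lowest elevation first
    if (a.bg != b.bg) return a.bg > b.bg;               // foreground before background
    return a.order > b.order;                           // earlier push first
  }
};

// Marker-controlled watershed by priority flooding on an elevation map
// (callers pass the negated enhanced image so peaks are minima). `markers`
// holds 0 for unassigned pixels and positive labels for seeds; `bg_label`
// identifies the background basin (its frontier loses elevation ties so that
// bright plateaus belong to their peak basin). 8-connectivity.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix elev, IntegerMatrix markers, int bg_label) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix labels(clone(markers));
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCompare> pq;
  long counter = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (labels(r, c) == 0) continue;
      int lab = labels(r, c);
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (labels(rr, cc) != 0) continue;
          WsEntry e;
          e.elev = elev(rr, cc);
          e.bg = (lab == bg_label) ? 1 : 0;
          e.order = counter++;
          e.r = rr; e.c = cc; e.label = lab;
          pq.push(e);
        }
      }
    }
  }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    if (labels(e.r, e.c) != 0) continue;
    labels(e.r, e.c) = e.label;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        int rr = e.r + dr, cc = e.c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (labels(rr, cc) != 0) continue;
        WsEntry n;
        n.elev = elev(rr, cc);
        n.bg = (e.label == bg_label) ? 1 : 0;
        n.order = counter++;
        n.r = rr; n.c = cc; n.label = e.label;
        pq.push(n);
      }
    }
  }
  return labels;
}

// Connected-component labelling of a logical mask. Components are numbered in
// raster-scan (column-major) discovery order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next;
      labels(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        int pr = q.front().first, pc = q.front().second;
        q.pop();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            if (connectivity == 4 && dr != 0 && dc != 0) continue;
            int rr = pr + dr, cc = pc + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && labels(rr, cc) == 0) {
              labels(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return labels;
}

// Fill holes: background is flood-filled (4-connectivity) from the image
// border; any background pixel not reached is an interior hole and becomes
// foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reached(nr, nc);
  std::queue<std::pair<int,int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; c += (nc > 1 ? nc - 1 : 1)) {
      if (!mask(r, c) && !reached(r, c)) { reached(r, c) = true; q.push(std::make_pair(r, c)); }
      if (nc == 1) break;
    }
  }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; r += (nr > 1 ? nr - 1 : 1)) {
      if (!mask(r, c) && !reached(r, c)) { reached(r, c) = true; q.push(std::make_pair(r, c)); }
      if (nr == 1) break;
    }
  }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int pr = q.front().first, pc = q.front().second;
    q.pop();
    for (int i = 0; i < 4; ++i) {
      int rr = pr + dr[i], cc = pc + dc[i];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) && !reached(rr, cc)) {
        reached(rr, cc) = true;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) || !reached(r, c);
  return out;
}
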
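#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Median filtering with edge replication. Two paths: a sliding-histogram
// path for 8-bit integer images (the pipeline's hot path) and a naive
// nth_element path for arbitrary numeric images.

// Build an edge-replicated padded copy, pad p on each side.
template <typename T, typename S>
static std::vector<T> pad_replicate(const S &img, int h, int w, int p) {
  int H = h + 2 * p, W = w + 2 * p;
  std::vector<T> out((size_t)H * W);
  for (int x = 0; x < W; ++x) {
    int sx = std::min(std::max(x - p, 0), w - 1);
    for (int y = 0; y < H; ++y) {
      int sy = std::min(std::max(y - p, 0), h - 1);
      out[(size_t)x * H + y] = (T)img(sy, sx);
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_median_u8(IntegerMatrix img, int window) {
  int h = img.nrow(), w = img.ncol(), p = window / 2;
  int H = h + 2 * p;
  std::vector<uint8_t> pad = pad_replicate<uint8_t>(img, h, w, p);
  IntegerMatrix out(h, w);
  int n = window * window, half = n / 2;  // median rank: half+1 smallest (n odd)

  std::vector<int> hist(256);
  // slide the window down each output column (R matrices are column-major)
  for (int x = 0; x < w; ++x) {
    std::fill(hist.begin(), hist.end(), 0);
    for (int dx = 0; dx < window; ++dx)
      for (int dy = 0; dy < window; ++dy)
        ++hist[pad[(size_t)(x + dx) * H + dy]];
    for (int y = 0; y < h; ++y) {
      if (y > 0) {
        for (int dx = 0; dx < window; ++dx) {
          --hist[pad[(size_t)(x + dx) * H + (y - 1)]];
          ++hist[pad[(size_t)(x + dx) * H + (y - 1 + window)]];
        }
      }
      int acc = 0, m = 0;
      while (acc <= half) acc += hist[m++];
      out(y, x) = m - 1;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_naive(NumericMatrix img, int window) {
  int h = img.nrow(), w = img.ncol(), p = window / 2;
  int H = h + 2 * p;
  std::vector<double> pad = pad_replicate<double>(img, h, w, p);
  NumericMatrix out(h, w);
  int n = window * window;
  std::vector<double> buf(n);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      int k = 0;
      for (int dx = 0; dx < window; ++dx)
        for (int dy = 0; dy < window; ++dy)
          buf[k++] = pad[(size_t)(x + dx) * H + (y + dy)];
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      out(y, x) = buf[n / 2];
    }
  }
  return out;
}

// 8-connected component labelling of a binary mask. Components are returned
// in order of first encounter in a column-major scan, with pixel count and
// unweighted centroid in 0-based (x right, y down) pixel coordinates.
// [[Rcpp::export]]
List cpp_components(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  std::vector<int32_t> label((size_t)h * w, 0);
  std::vector<double> areas, sx, sy;
  std::vector<int> stack;
  int next = 0;

  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      size_t idx = (size_t)x * h + y;
      if (!mask(y, x) || label[idx]) continue;
      ++next;
      areas.push_back(0.0);
      sx.push_back(0.0);
      sy.push_back(0.0);
      label[idx] = next;
      stack.push_back((int)idx);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int cx = cur / h, cy = cur % h;
        areas[next - 1] += 1.0;
        sx[next - 1] += cx;
        sy[next - 1] += cy;
        for (int dx = -1; dx <= 1; ++dx) {
          int nx = cx + dx;
          if (nx < 0 || nx >= w) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int ny = cy + dy;
            if (ny < 0 || ny >= h) continue;
            size_t nidx = (size_t)nx * h + ny;
            if (mask(ny, nx) && !label[nidx]) {
              label[nidx] = next;
              stack.push_back((int)nidx);
            }
          }
        }
      }
    }
  }

  int k = next;
  NumericVector area(k), cx(k), cy(k);
  for (int i = 0; i < k; ++i) {
    area[i] = areas[i];
    cx[i] = sx[i] / areas[i];
    cy[i] = sy[i] / areas[i];
  }
  return List::create(_["area"] = area, _["cx"] = cx, _["cy"] = cy);
}

// Fused crop + clipped channel-dominance differences for the analysis hot
// path: crops an H x W x 3 integer array to a 0-based inclusive window and
// returns the red (R - G)+ and green (G - R)+ images of the crop in one pass.
// [[Rcpp::export]]
List cpp_crop_diffs(IntegerVector px, int h, int w,
                    int x0, int y0, int x1, int y1) {
  int ch = y1 - y0 + 1, cw = x1 - x0 + 1;
  IntegerMatrix red(ch, cw), green(ch, cw);
  const int *pr = INTEGER(px);
  const int *pg = pr + (size_t)h * w;
  int *dr = INTEGER(red), *dg = INTEGER(green);
  for (int x = 0; x < cw; ++x) {
    const int *cr = pr + (size_t)(x + x0) * h + y0;
    const int *cg = pg + (size_t)(x + x0) * h + y0;
    int *orr = dr + (size_t)x * ch;
    int *org = dg + (size_t)x * ch;
    for (int y = 0; y < ch; ++y) {
      int d = cr[y] - cg[y];
      orr[y] = d > 0 ? d : 0;
      org[y] = d < 0 ? -d : 0;
    }
  }
  return List::create(_["red"] = red, _["green"] = green);
}

// Fused range-relative threshold + largest 8-connected component, matching
// threshold_mask() followed by largest_component_centroid() exactly:
// mask = v >= min + fraction * (max - min); constant images yield no mask.
// Returns the largest component's unweighted centroid (0-based), area, and
// an ok flag (area >= min_area).
// [[Rcpp::export]]
List cpp_blob(IntegerMatrix den, double fraction, double min_area) {
  int h = den.nrow(), w = den.ncol();
  const int *pd = INTEGER(den);
  size_t n = (size_t)h * w;
  int lo = pd[0], hi = pd[0];
  for (size_t i = 1; i < n; ++i) {
    if (pd[i] < lo) lo = pd[i];
    if (pd[i] > hi) hi = pd[i];
  }
  List fail = List::create(_["cx"] = NA_REAL, _["cy"] = NA_REAL,
                           _["area"] = NA_REAL, _["ok"] = false);
  if (lo == hi) return fail;
  double thresh = lo + fraction * (hi - lo);

  std::vector<uint8_t> mask(n);
  for (size_t i = 0; i < n; ++i) mask[i] = pd[i] >= thresh;

  std::vector<uint8_t> seen(n, 0);
  std::vector<int> stack;
  double best_area = 0, best_sx = 0, best_sy = 0;
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      size_t idx = (size_t)x * h + y;
      if (!mask[idx] || seen[idx]) continue;
      double area = 0, sx = 0, sy = 0;
      seen[idx] = 1;
      stack.push_back((int)idx);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int cx = cur / h, cy = cur % h;
        area += 1.0; sx += cx; sy += cy;
        for (int dx = -1; dx <= 1; ++dx) {
          int nx = cx + dx;
          if (nx < 0 || nx >= w) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int ny = cy + dy;
            if (ny < 0 || ny >= h) continue;
            size_t nidx = (size_t)nx * h + ny;
            if (mask[nidx] && !seen[nidx]) {
              seen[nidx] = 1;
              stack.push_back((int)nidx);
            }
          }
        }
      }
      if (area > best_area) {  // first-encounter order breaks ties
        best_area = area; best_sx = sx; best_sy = sy;
      }
    }
  }
  if (best_area == 0) return fail;
  return List::create(_["cx"] = best_sx / best_area,
                      _["cy"] = best_sy / best_area,
                      _["area"] = best_area,
                      _["ok"] = best_area >= min_area);
}

// Clipped channel-dominance difference max(a - b, 0) for integer matrices.
// [[Rcpp::export]]
IntegerMatrix cpp_channel_diff(IntegerMatrix a, IntegerMatrix b) {
  int h = a.nrow(), w = a.ncol();
  IntegerMatrix out(h, w);
  const int *pa = INTEGER(a), *pb = INTEGER(b);
  int *po = INTEGER(out);
  R_xlen_t n = (R_xlen_t)h * w;
  for (R_xlen_t i = 0; i < n; ++i) {
    int d = pa[i] - pb[i];
    po[i] = d > 0 ? d : 0;
  }
  return out;
}
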
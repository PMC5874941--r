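#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Standard normal CDF
static inline double phi(double x) { return 0.5 * std::erfc(-x / 1.4142135623730951); }

// Alias table (Vose) over the 256 possible 8-bit pixel values, holding the
// exact distribution of round(clip(mu + N(0, sd), 0, 255)). Background pixels
// (the vast majority of a frame) are sampled from this in O(1) per pixel with
// one 32-bit random draw, which is what makes rendering long 720p sequences
// tractable.
struct AliasTable {
  float prob[256];
  int alias[256];

  void build(double mu, double sd) {
    double p[256];
    p[0] = phi((0.5 - mu) / sd);
    for (int k = 1; k < 255; ++k)
      p[k] = phi((k + 0.5 - mu) / sd) - phi((k - 0.5 - mu) / sd);
    p[255] = 1.0 - phi((254.5 - mu) / sd);

    std::vector<int> small, large;
    double scaled[256];
    for (int k = 0; k < 256; ++k) {
      scaled[k] = p[k] * 256.0;
      if (scaled[k] < 1.0) small.push_back(k); else large.push_back(k);
    }
    for (int k = 0; k < 256; ++k) { prob[k] = 1.0f; alias[k] = k; }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = (float)scaled[s];
      alias[s] = l;
      scaled[l] = (scaled[l] + scaled[s]) - 1.0;
      if (scaled[l] < 1.0) small.push_back(l); else large.push_back(l);
    }
  }

  // one 32-bit draw: top 8 bits pick the bin, low 24 the accept test
  inline int sample(uint32_t r) const {
    int i = (int)(r >> 24);
    float v = (float)(r & 0xFFFFFFu) * (1.0f / 16777216.0f);
    return v < prob[i] ? i : alias[i];
  }
};

// Anti-aliased disc coverage: fraction of the pixel covered, approximated by
// clamp(r + 0.5 - d, 0, 1) on the centre distance d (standard coverage ramp).
static inline double disc_cov(double px, double py, double cx, double cy, double r) {
  double d = std::sqrt((px - cx) * (px - cx) + (py - cy) * (py - cy));
  double c = r + 0.5 - d;
  if (c < 0.0) return 0.0;
  if (c > 1.0) return 1.0;
  return c;
}

static inline int clip255(double v) {
  if (v < 0.0) return 0;
  if (v > 255.0) return 255;
  return (int)std::lround(v);
}

// rectangular patch of clean (noise-free) scene around the discs
struct Patch {
  int x0, x1, y0, y1;          // inclusive, frame coordinates
  std::vector<double> px;      // 3 planes, column-major within the patch
  int w() const { return x1 - x0 + 1; }
  int h() const { return y1 - y0 + 1; }
  double &at(int c, int x, int y) {
    return px[((size_t)c * w() + x) * h() + y];
  }
};

static Patch make_patch(int x0, int x1, int y0, int y1) {
  Patch p;
  p.x0 = x0; p.x1 = x1; p.y0 = y0; p.y1 = y1;
  p.px.assign((size_t)3 * (x1 - x0 + 1) * (y1 - y0 + 1), 0.0);
  return p;
}

// Render one RGB frame of the two-dot pattern.
// Pixel coordinates are 0-based, x right, y down, pixel centres at integers.
// A per-frame rigid camera-shake translation N(0, jitter_sd) is drawn from
// the frame's own RNG stream and applied to both discs; the jittered centres
// are returned alongside the pixels as ground truth.
// [[Rcpp::export]]
List cpp_render_frame(int h, int w,
                      double red_x, double red_y, double red_r,
                      double green_x, double green_y, double green_r,
                      IntegerVector red_rgb, IntegerVector green_rgb,
                      IntegerVector bg_rgb,
                      double blur_sd, double noise_sd, double jitter_sd,
                      double seed, int frame_index) {
  gcrng::Xoshiro256pp rng((uint64_t)seed, (uint64_t)frame_index);

  if (jitter_sd > 0) {
    double jx = jitter_sd * rng.norm(), jy = jitter_sd * rng.norm();
    red_x += jx; red_y += jy;
    green_x += jx; green_y += jy;
  }

  // both discs must be fully inside the frame
  if (red_x - red_r < -0.5 || red_x + red_r > w - 0.5 ||
      red_y - red_r < -0.5 || red_y + red_r > h - 0.5 ||
      green_x - green_r < -0.5 || green_x + green_r > w - 0.5 ||
      green_y - green_r < -0.5 || green_y + green_r > h - 0.5)
    stop("dot leaves the frame: enlarge the image or reduce separation/radii");

  // one clean patch per disc (merged if they touch), big enough for the blur
  int margin = (int)std::ceil(4.0 * blur_sd) + 2;
  auto bbox = [&](double cx, double cy, double r, int out[4]) {
    out[0] = std::max(0, (int)std::floor(cx - r) - margin);
    out[1] = std::min(w - 1, (int)std::ceil(cx + r) + margin);
    out[2] = std::max(0, (int)std::floor(cy - r) - margin);
    out[3] = std::min(h - 1, (int)std::ceil(cy + r) + margin);
  };
  int br[4], bg_[4];
  bbox(red_x, red_y, red_r, br);
  bbox(green_x, green_y, green_r, bg_);
  bool overlap = br[0] <= bg_[1] && bg_[0] <= br[1] &&
                 br[2] <= bg_[3] && bg_[2] <= br[3];

  std::vector<Patch> patches;
  if (overlap) {
    patches.push_back(make_patch(std::min(br[0], bg_[0]), std::max(br[1], bg_[1]),
                                 std::min(br[2], bg_[2]), std::max(br[3], bg_[3])));
  } else {
    patches.push_back(make_patch(br[0], br[1], br[2], br[3]));
    patches.push_back(make_patch(bg_[0], bg_[1], bg_[2], bg_[3]));
  }

  for (Patch &p : patches) {
    int pw = p.w(), ph = p.h();
    std::vector<double> covr((size_t)pw * ph), covg((size_t)pw * ph);
    for (int x = 0; x < pw; ++x) {
      for (int y = 0; y < ph; ++y) {
        covr[(size_t)x * ph + y] = disc_cov(x + p.x0, y + p.y0, red_x, red_y, red_r);
        covg[(size_t)x * ph + y] = disc_cov(x + p.x0, y + p.y0, green_x, green_y, green_r);
      }
    }
    for (int c = 0; c < 3; ++c) {
      double bg = bg_rgb[c], fr = red_rgb[c], fg = green_rgb[c];
      double *pl = &p.px[(size_t)c * pw * ph];
      for (size_t i = 0; i < (size_t)pw * ph; ++i)
        pl[i] = bg * (1.0 - covr[i] - covg[i]) + fr * covr[i] + fg * covg[i];
    }

    // separable Gaussian blur; outside the patch the scene is uniform
    // background, so padding with bg is exact (margin covers the kernel)
    if (blur_sd > 0) {
      int kr = (int)std::ceil(4.0 * blur_sd);
      std::vector<double> kern(2 * kr + 1);
      double ks = 0.0;
      for (int i = -kr; i <= kr; ++i) {
        kern[i + kr] = std::exp(-0.5 * (double)i * i / (blur_sd * blur_sd));
        ks += kern[i + kr];
      }
      for (double &k : kern) k /= ks;

      std::vector<double> tmp((size_t)pw * ph);
      for (int c = 0; c < 3; ++c) {
        double bg = bg_rgb[c];
        for (int x = 0; x < pw; ++x) {
          for (int y = 0; y < ph; ++y) {
            double acc = 0.0;
            for (int i = -kr; i <= kr; ++i) {
              int yy = y + i;
              double v = (yy < 0 || yy >= ph) ? bg : p.at(c, x, yy);
              acc += kern[i + kr] * v;
            }
            tmp[(size_t)x * ph + y] = acc;
          }
        }
        for (int x = 0; x < pw; ++x) {
          for (int y = 0; y < ph; ++y) {
            double acc = 0.0;
            for (int i = -kr; i <= kr; ++i) {
              int xx = x + i;
              double v = (xx < 0 || xx >= pw) ? bg : tmp[(size_t)xx * ph + y];
              acc += kern[i + kr] * v;
            }
            p.at(c, x, y) = acc;
          }
        }
      }
    }
  }

  IntegerVector out((R_xlen_t)h * w * 3);
  int *po = INTEGER(out);
  size_t plane = (size_t)h * w;

  if (noise_sd > 0) {
    // background fill from the exact discrete distribution, then overwrite
    // the disc patches with continuous Gaussian noise on the clean values
    for (int c = 0; c < 3; ++c) {
      AliasTable tab;
      tab.build((double)bg_rgb[c], noise_sd);
      int *pc = po + c * plane;
      size_t n = plane, i = 0;
      while (i + 1 < n) {
        uint64_t r = rng.next();
        pc[i++] = tab.sample((uint32_t)r);
        pc[i++] = tab.sample((uint32_t)(r >> 32));
      }
      if (i < n) pc[i] = tab.sample((uint32_t)rng.next());
    }
    for (Patch &p : patches) {
      for (int c = 0; c < 3; ++c) {
        int *pc = po + c * plane;
        for (int x = p.x0; x <= p.x1; ++x) {
          for (int y = p.y0; y <= p.y1; ++y) {
            pc[(size_t)x * h + y] =
              clip255(p.at(c, x - p.x0, y - p.y0) + noise_sd * rng.norm());
          }
        }
      }
    }
  } else {
    for (int c = 0; c < 3; ++c) {
      int *pc = po + c * plane;
      int bg = bg_rgb[c];
      for (size_t i = 0; i < plane; ++i) pc[i] = bg;
      for (Patch &p : patches) {
        for (int x = p.x0; x <= p.x1; ++x)
          for (int y = p.y0; y <= p.y1; ++y)
            pc[(size_t)x * h + y] = clip255(p.at(c, x - p.x0, y - p.y0));
      }
    }
  }

  out.attr("dim") = IntegerVector::create(h, w, 3);
  return List::create(_["pixels"] = out,
                      _["red_x"] = red_x, _["red_y"] = red_y,
                      _["green_x"] = green_x, _["green_y"] = green_y);
}
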
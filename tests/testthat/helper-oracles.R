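# Small test scene: same geometry as the default, scaled down for speed.
test_scene <- function(...) {
  scene_config(image_w = 320, image_h = 240, center_x = 160, center_y = 120,
               red_radius_px = 18, green_radius_px = 11,
               dot_separation_px = 120, ...)
}

# mild noise for small-scene tests
test_noise <- function(seed = 7L) {
  noise_model(pixel_noise_sd = 4, blur_sd_px = 0.8, jitter_sd_px = 0.3,
              decenter_px = 6, seed = seed)
}

# Brute-force median filter with edge replication: per-pixel clamped-index
# window and stats::median. Independent of the package's C++ paths.
median_oracle <- function(img, w) {
  p <- w %/% 2
  h <- nrow(img)
  wd <- ncol(img)
  out <- img
  for (y in seq_len(h)) {
    ys <- pmin(pmax((y - p):(y + p), 1), h)
    for (x in seq_len(wd)) {
      xs <- pmin(pmax((x - p):(x + p), 1), wd)
      out[y, x] <- stats::median(img[ys, xs])
    }
  }
  out
}

# Single-argument arctangent of (Rx-Gx)/(Ry-Gy) plus explicit quadrant
# casework, resolving the theta vs theta + 180 ambiguity; independent oracle
# for the package's two-argument-arctangent angle. Convention: red above
# green (y down) is 0 degrees, clockwise positive.
eq1_quadrant_oracle <- function(rx, ry, gx, gy) {
  dx <- rx - gx
  dy <- ry - gy
  if (dy == 0) {
    if (dx > 0) return(90)
    if (dx < 0) return(270)
    stop("coincident points")
  }
  base <- atan(dx / (-dy)) * 180 / pi    # in (-90, 90)
  if (-dy > 0) base %% 360 else (base + 180) %% 360
}

# brute-force smallest circular distance: min over k of |a - b + 360 k|
circ_dev_oracle <- function(a, b) {
  min(abs(a - b + 360 * (-3:3)))
}

# a hand-built dot pair tibble for angle tests
make_pair <- function(rx, ry, gx, gy) {
  tibble::tibble(
    colour = c("red", "green"),
    cx = c(rx, gx), cy = c(ry, gy),
    radius_px = c(10, 6), area_px = c(314, 113),
    ok = TRUE
  )
}

# render a short clip and return the frame source (noiseless by default)
render_static_clip <- function(scene, gantry_deg, seconds, fps = 30,
                               lead_in_s = 0, noise = noise_off()) {
  render_trajectory(
    scene,
    data.frame(time_s = c(0, seconds), gantry_deg = gantry_deg),
    fps = fps, lead_in_s = lead_in_s, noise = noise
  )
}
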
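#' Synthetic Double Dot scene geometry
#'
#' Describes the rendered stand-in for the physical setup: two coloured discs
#' of different radii on a light background, rigidly rotating about an
#' image-plane centre as the gantry turns. Defaults are scaled to 720p
#' footage; the accuracy of the method is resolution-relative, and the
#' defaults are chosen so that noiseless recovery error is well below
#' 0.05 degrees.
#'
#' @param image_w,image_h frame size in pixels (default 1280 x 720).
#' @param center_x,center_y rotation centre in pixels (default frame centre).
#' @param red_radius_px,green_radius_px disc radii (defaults 40 and 25; the
#'   sizes differ by design so radius can disambiguate the dots).
#' @param dot_separation_px centre-to-centre dot distance (default 260).
#'   Larger separation improves angular resolution.
#' @param red_rgb,green_rgb,background_rgb 8-bit colours.
#' @param pattern_offset_deg fixed orientation of the printed sheet,
#'   emulating arbitrary pattern placement on the gantry face (absorbed by
#'   calibration; default 0).
#' @return a `dd_scene` list.
#' @export
scene_config <- function(image_w = 1280, image_h = 720,
                         center_x = image_w / 2, center_y = image_h / 2,
                         red_radius_px = 40, green_radius_px = 25,
                         dot_separation_px = 260,
                         red_rgb = c(200, 30, 30),
                         green_rgb = c(30, 160, 40),
                         background_rgb = c(245, 245, 245),
                         pattern_offset_deg = 0) {
  reach <- dot_separation_px / 2 + max(red_radius_px, green_radius_px)
  if (center_x - reach < 0 || center_x + reach > image_w - 1 ||
      center_y - reach < 0 || center_y + reach > image_h - 1) {
    abort("dots would leave the frame: shrink separation/radii or enlarge the image")
  }
  structure(
    list(image_w = image_w, image_h = image_h,
         center_x = center_x, center_y = center_y,
         red_radius_px = red_radius_px, green_radius_px = green_radius_px,
         dot_separation_px = dot_separation_px,
         red_rgb = as.integer(red_rgb), green_rgb = as.integer(green_rgb),
         background_rgb = as.integer(background_rgb),
         pattern_offset_deg = pattern_offset_deg),
    class = "dd_scene"
  )
}

#' Camera noise model for the synthetic renderer
#'
#' A parameterized stand-in for a phone camera on the treatment couch:
#' additive per-pixel Gaussian intensity noise, Gaussian optical blur, a
#' per-frame rigid translation (hand/couch shake), and a constant
#' decentration of the rotation axis from the optical axis. Defaults are the
#' package's stated "realistic camera" conditions; with them, static
#' per-frame angle scatter sits in the vicinity of the 0.04-degree stability
#' the method exhibits in practice.
#'
#' @param pixel_noise_sd additive intensity noise SD, 8-bit units (default 5).
#' @param blur_sd_px Gaussian blur SD in pixels (default 1).
#' @param jitter_sd_px per-frame rigid translation SD in pixels (default
#'   0.5); common to both dots, so it cancels in the relative angle.
#' @param decenter_px constant offset of the rotation centre from the frame
#'   centre along +x, in pixels (default 20).
#' @param seed RNG seed; a fixed seed makes footage bit-identical.
#' @return a `dd_noise` list.
#' @export
noise_model <- function(pixel_noise_sd = 5, blur_sd_px = 1.0,
                        jitter_sd_px = 0.5, decenter_px = 20, seed = 1L) {
  if (pixel_noise_sd < 0 || blur_sd_px < 0 || jitter_sd_px < 0) {
    abort("noise SDs must be >= 0")
  }
  structure(
    list(pixel_noise_sd = pixel_noise_sd, blur_sd_px = blur_sd_px,
         jitter_sd_px = jitter_sd_px, decenter_px = decenter_px,
         seed = as.numeric(seed)),
    class = "dd_noise"
  )
}

#' @rdname noise_model
#' @export
noise_off <- function() {
  noise_model(pixel_noise_sd = 0, blur_sd_px = 0, jitter_sd_px = 0,
              decenter_px = 0, seed = 0L)
}

# nominal (un-jittered) dot centres at a given gantry angle
dot_positions <- function(scene, gantry_deg, decenter_px = 0) {
  a <- (gantry_deg + scene$pattern_offset_deg) * pi / 180
  ux <- sin(a)          # clockwise on the y-down image
  uy <- -cos(a)
  cx <- scene$center_x + decenter_px
  cy <- scene$center_y
  half <- scene$dot_separation_px / 2
  list(
    red = c(x = cx + half * ux, y = cy + half * uy),
    green = c(x = cx - half * ux, y = cy - half * uy)
  )
}

#' Render one frame of the Double Dot scene
#'
#' Draws anti-aliased red and green discs at the positions given by rotating
#' the red-up dot axis clockwise (on the y-down image) by
#' `gantry_deg + pattern_offset_deg` about the (decentered, jittered)
#' rotation centre, then applies Gaussian blur and additive pixel noise.
#' The actual (jittered) disc centres are recorded in the frame's `truth`
#' attribute.
#'
#' @param scene a [scene_config()].
#' @param gantry_deg commanded gantry angle in degrees.
#' @param noise a [noise_model()]; noise is reproducible per
#'   `(seed, frame_index)`.
#' @param frame_index 0-based frame index.
#' @param fps frame rate used to timestamp the frame.
#' @return a `dd_frame`; `attr(frame, "truth")` holds `gantry_deg` and the
#'   true disc centres.
#' @export
render_frame <- function(scene, gantry_deg, noise = noise_model(),
                         frame_index = 0L, fps = 30) {
  pos <- dot_positions(scene, gantry_deg, noise$decenter_px)
  res <- cpp_render_frame(
    as.integer(scene$image_h), as.integer(scene$image_w),
    pos$red[["x"]], pos$red[["y"]], scene$red_radius_px,
    pos$green[["x"]], pos$green[["y"]], scene$green_radius_px,
    scene$red_rgb, scene$green_rgb, scene$background_rgb,
    noise$blur_sd_px, noise$pixel_noise_sd, noise$jitter_sd_px,
    noise$seed, as.integer(frame_index)
  )
  fr <- new_frame(res$pixels, index = frame_index, fps = fps, validate = FALSE)
  attr(fr, "truth") <- list(
    gantry_deg = wrap_deg_180(gantry_deg),
    red = c(x = res$red_x, y = res$red_y),
    green = c(x = res$green_x, y = res$green_y)
  )
  fr
}

#' Render footage of a commanded gantry trajectory
#'
#' Produces one frame per `1/fps` seconds: a stationary 0-degree lead-in of
#' `lead_in_s` seconds (the self-calibration window) followed by the
#' commanded trajectory, with the gantry angle linearly interpolated between
#' command samples. Frames are rendered lazily; the paired ground-truth
#' trajectory is attached for scoring.
#'
#' @param scene a [scene_config()].
#' @param traj the commanded motion: a `gantry_trajectory` (e.g. from
#'   [plan_to_trajectory()]), a `gantry_plan`, or any data frame with
#'   `time_s` and `gantry_deg` columns. Times start at 0.
#' @param fps frame rate in Hz (default 30).
#' @param lead_in_s stationary 0-degree lead-in duration (default 12 s).
#' @param noise a [noise_model()].
#' @return a `dd_frame_source` whose `truth` element is the frame-by-frame
#'   ground-truth `gantry_trajectory`.
#' @export
render_trajectory <- function(scene, traj, fps = 30, lead_in_s = 12,
                              noise = noise_model()) {
  if (fps <= 0) abort("`fps` must be positive")
  if (inherits(traj, "gantry_plan")) traj <- plan_to_trajectory(traj)
  if (!is.data.frame(traj) || !all(c("time_s", "gantry_deg") %in% names(traj))) {
    abort("`traj` must have `time_s` and `gantry_deg` columns")
  }

  cmd_t <- traj$time_s
  cmd_u <- unwrap_deg(traj$gantry_deg)
  duration <- lead_in_s + max(cmd_t, 0)
  n <- round(duration * fps)

  angle_at <- function(t) {
    if (t < lead_in_s || length(cmd_t) == 0L) return(0)
    if (length(cmd_t) == 1L) return(cmd_u[1])
    approx(cmd_t, cmd_u, xout = min(t - lead_in_s, cmd_t[length(cmd_t)]),
           rule = 2)$y
  }

  frame_times <- (seq_len(n) - 1) / fps
  truth_deg <- vapply(frame_times, angle_at, numeric(1))
  truth <- trajectory(frame_times, truth_deg, rate_hz = fps,
                      source = "plan_truth")

  get <- function(i) {
    render_frame(scene, truth_deg[i], noise, frame_index = i - 1L, fps = fps)
  }
  new_frame_source(get, n, fps, truth = truth, origin = "synthetic")
}
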
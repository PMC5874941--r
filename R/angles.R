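#' Raw red-to-green pattern angle of a dot pair
#'
#' The full-circle orientation of the red-to-green centroid direction,
#' computed with the two-argument arctangent of
#' `(R_x - G_x, R_y - G_y)`. Convention: red directly above green in the
#' y-down image is 0 degrees, and the angle increases clockwise on the image.
#' The two-argument form resolves the 180-degree quadrant ambiguity of the
#' single-argument arctangent of `(R_x - G_x) / (R_y - G_y)` and is defined
#' on the axis `R_y = G_y` where that ratio is not.
#'
#' @param pair a `dd_dotpair` from [detect_dots()], or any two-row data frame
#'   with columns `colour`, `cx`, `cy`, `ok`.
#' @return the raw angle in degrees, `[0, 360)`.
#' @export
raw_relative_angle <- function(pair) {
  red <- pair[pair$colour == "red", ]
  green <- pair[pair$colour == "green", ]
  if (nrow(red) != 1L || nrow(green) != 1L) {
    abort("`pair` must contain exactly one red and one green detection")
  }
  if (!isTRUE(red$ok) || !isTRUE(green$ok)) {
    abort("both detections must be ok to measure an angle",
          class = "gantrycam_bad_sample")
  }
  dx <- red$cx - green$cx
  dy <- red$cy - green$cy
  if (dx == 0 && dy == 0) {
    abort("coincident centroids: dot pair carries no orientation",
          class = "gantrycam_bad_sample")
  }
  wrap_deg_360(atan2(dx, -dy) * 180 / pi)
}

#' Self-calibrate the angle zero from a stationary lead-in
#'
#' The raw red-to-green angle depends on how the printed pattern happens to
#' sit on the gantry face. Footage therefore starts with the gantry
#' stationary at true 0 degrees; the circular mean of the raw angle over the
#' first `window_s` seconds defines the calibration angle `theta0`, which is
#' subtracted from every subsequent measurement. This makes the method
#' independent of the absolute pattern placement. Calibration is rejected if
#' the circular SD over the window exceeds `sd_limit_deg` (the gantry was
#' moving) or if too few frames detected successfully.
#'
#' @param raw_deg raw angles in degrees (may contain `NA` for failed frames).
#' @param time_s frame timestamps in seconds, same length.
#' @param window_s seconds of footage used (default 10).
#' @param sign image-to-gantry rotation sense, +1 or -1.
#' @param sd_limit_deg stability gate on the circular SD (default 0.2).
#' @param min_frames minimum usable frames in the window (default 10).
#' @return a `gantry_calibration`: list with `theta0_deg` (in `[0, 360)`),
#'   `sign`, `window_s`, `n_frames`, `circ_sd_deg`.
#' @export
calibrate <- function(raw_deg, time_s, window_s = 10, sign = 1,
                      sd_limit_deg = 0.2, min_frames = 10) {
  use <- is.finite(raw_deg) & time_s < window_s
  n <- sum(use)
  if (n < min_frames) {
    abort(sprintf(
      "calibration failed: only %d usable frames in the first %g s (need >= %d)",
      n, window_s, min_frames
    ), class = "gantrycam_calibration_error")
  }
  x <- raw_deg[use]
  theta0 <- circ_mean_deg(x)
  csd <- circ_sd_deg(x)
  if (csd > sd_limit_deg) {
    abort(sprintf(
      paste0("calibration rejected: circular SD %.3f deg exceeds %.3f deg - ",
             "the gantry appears to be moving; record a longer stationary ",
             "lead-in at 0 degrees"),
      csd, sd_limit_deg
    ), class = "gantrycam_calibration_error")
  }
  structure(
    list(theta0_deg = theta0, sign = sign, window_s = window_s,
         n_frames = n, circ_sd_deg = csd),
    class = "gantry_calibration"
  )
}

#' @export
print.gantry_calibration <- function(x, ...) {
  cat(sprintf(
    "<gantry_calibration> theta0 = %.3f deg (sign %+d), %d frames over %g s, circular SD %.4f deg\n",
    x$theta0_deg, x$sign, x$n_frames, x$window_s, x$circ_sd_deg
  ))
  invisible(x)
}

#' @export
glance.gantry_calibration <- function(x, ...) {
  tibble(theta0_deg = x$theta0_deg, sign = x$sign, window_s = x$window_s,
         n_frames = x$n_frames, circ_sd_deg = x$circ_sd_deg)
}

#' Convert raw pattern angles to gantry angles
#'
#' `gantry = wrap(sign * (raw - theta0))` into the signed `[-180, +180)`
#' scale. At the calibration angle the result is exactly 0.
#'
#' @param raw_deg raw angles in degrees (vectorized; `NA` passes through).
#' @param cal a [calibrate()] result.
#' @return gantry angles in degrees, `[-180, +180)`.
#' @export
to_gantry <- function(raw_deg, cal) {
  if (!inherits(cal, "gantry_calibration")) abort("`cal` must be a gantry_calibration")
  wrap_deg_180(cal$sign * (raw_deg - cal$theta0_deg))
}

#' Build a gantry-angle trajectory
#'
#' The package's tabular time-series container: a tibble with columns
#' `time_s`, `gantry_deg` (wrapped to `[-180, 180)`), `ok`, plus any extra
#' columns, carrying the sampling rate and source label as attributes.
#'
#' @param time_s strictly increasing timestamps in seconds.
#' @param gantry_deg gantry angles in degrees (wrapped on construction).
#' @param ok per-sample quality flags (recycled).
#' @param rate_hz nominal sampling rate.
#' @param source label: `"double_dot"`, `"dynalog"`, `"encoder"`,
#'   `"inclinometer"`, `"plan_truth"`, ...
#' @param ... further per-sample columns (e.g. `dose_rate`).
#' @param calibration optional `gantry_calibration` to attach.
#' @return a `gantry_trajectory` tibble.
#' @export
trajectory <- function(time_s, gantry_deg, ok = TRUE, rate_hz = NA_real_,
                       source = "unknown", ..., calibration = NULL) {
  if (length(time_s) != length(gantry_deg)) {
    abort("`time_s` and `gantry_deg` must have the same length")
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    abort("`time_s` must be strictly increasing")
  }
  tbl <- tibble(time_s = as.numeric(time_s),
                gantry_deg = wrap_deg_180(as.numeric(gantry_deg)),
                ok = rep_len(as.logical(ok), length(time_s)), ...)
  structure(tbl, rate_hz = rate_hz, source = source,
            calibration = calibration,
            class = c("gantry_trajectory", class(tbl)))
}

#' @export
print.gantry_trajectory <- function(x, ...) {
  cat(sprintf(
    "<gantry_trajectory> source '%s', %d samples at %s Hz, %d ok\n",
    attr(x, "source"), nrow(x),
    format(attr(x, "rate_hz")), sum(x$ok)
  ))
  NextMethod()
}

#' @export
glance.gantry_trajectory <- function(x, ...) {
  okd <- x$gantry_deg[x$ok]
  tibble(
    source = attr(x, "source"),
    n_samples = nrow(x),
    n_ok = sum(x$ok),
    rate_hz = attr(x, "rate_hz"),
    span_s = diff(range(x$time_s)),
    start_deg = okd[1],
    end_deg = okd[length(okd)]
  )
}

#' Restrict a trajectory to a time window
#'
#' Keeps samples with `from <= time_s <= to`, preserving the trajectory's
#' sampling-rate and source metadata. Useful for dropping the calibration
#' lead-in before comparing against a reference that only covers the arc.
#'
#' @param traj a `gantry_trajectory`.
#' @param from,to window bounds in seconds (defaults: unbounded).
#' @return a `gantry_trajectory`.
#' @export
trim_trajectory <- function(traj, from = -Inf, to = Inf) {
  keep <- traj$time_s >= from & traj$time_s <= to
  if (!any(keep)) abort("no samples inside the requested window")
  out <- traj[keep, , drop = FALSE]
  for (a in setdiff(names(attributes(traj)),
                    c("names", "row.names", "class"))) {
    attr(out, a) <- attr(traj, a)
  }
  class(out) <- class(traj)
  out
}

#' Measure a gantry-angle trajectory from footage
#'
#' The full measurement pipeline: per-frame dot detection
#' ([detect_dots()]), raw angle extraction ([raw_relative_angle()]),
#' self-calibration from the stationary lead-in ([calibrate()]) unless an
#' explicit calibration is supplied, and conversion to calibrated gantry
#' angles ([to_gantry()]). Frames whose detection fails become gap samples
#' (`ok = FALSE`, angle `NA`); they are kept in the trajectory but excluded
#' from all statistics. More than `max_bad_frac` failed frames aborts the
#' analysis (a setup problem, not noise).
#'
#' @param frames footage: a `dd_frame_source`, list of frames, or directory
#'   path (see [as_frame_source()]).
#' @param config a [detection_config()].
#' @param calibration optional `gantry_calibration`; when `NULL` the footage
#'   must begin with a stationary 0-degree lead-in to calibrate from.
#' @param fps_override frame rate when `frames` carries none.
#' @return a `gantry_trajectory` (source `"double_dot"`) with one sample per
#'   frame and the calibration attached as an attribute.
#' @export
analyze <- function(frames, config = detection_config(), calibration = NULL,
                    fps_override = NULL) {
  src <- as_frame_source(frames, fps_override)
  n <- length(src)
  if (n == 0L) abort("footage contains no frames")

  raw <- rep(NA_real_, n)
  times <- rep(NA_real_, n)
  roi <- if (is.numeric(config$roi) && length(config$roi) == 4L) config$roi else NULL
  auto_roi <- identical(config$roi, "auto")

  for (i in seq_len(n)) {
    fr <- src[[i]]
    times[i] <- fr$time_s
    px <- fr$pixels
    off_x <- 0
    off_y <- 0
    if (!is.null(roi)) {
      d <- dim(px)
      x0 <- max(0L, as.integer(roi[1]))
      y0 <- max(0L, as.integer(roi[2]))
      x1 <- min(d[2] - 1L, as.integer(roi[3]))
      y1 <- min(d[1] - 1L, as.integer(roi[4]))
      diffs <- cpp_crop_diffs(px, d[1], d[2], x0, y0, x1, y1)
      off_x <- x0
      off_y <- y0
      det <- list(red = detect_one_core(diffs$red, config),
                  green = detect_one_core(diffs$green, config))
      collided <- det$red$ok && det$green$ok &&
        sqrt((det$red$cx - det$green$cx)^2 +
             (det$red$cy - det$green$cy)^2) <= config$collision_px
      if (collided || (!det$red$ok && !det$green$ok)) {
        det <- detect_core(crop_roi(px, roi)$px, config)  # slow fallback path
      }
    } else {
      det <- detect_core(px, config)
    }
    red <- det$red
    green <- det$green
    if (red$ok && green$ok &&
        (red$cx != green$cx || red$cy != green$cy)) {
      raw[i] <- wrap_deg_360(
        atan2(red$cx - green$cx, -(red$cy - green$cy)) * 180 / pi
      )
      if (auto_roi && is.null(roi)) {
        # fix a processing window around the first successful detection; the
        # rotation centre is static, so one window covers the whole arc
        mx <- (red$cx + green$cx) / 2 + off_x
        my <- (red$cy + green$cy) / 2 + off_y
        sep <- sqrt((red$cx - green$cx)^2 + (red$cy - green$cy)^2)
        half <- sep / 2 + sqrt(max(red$area, green$area) / pi) + 20
        roi <- c(floor(mx - half), floor(my - half),
                 ceiling(mx + half), ceiling(my + half))
      }
    }
  }

  bad <- mean(!is.finite(raw))
  if (bad > config$max_bad_frac) {
    abort(sprintf(
      "analysis failed: %.0f%% of frames had no usable dot pair (limit %.0f%%) - check setup",
      100 * bad, 100 * config$max_bad_frac
    ))
  }

  cal <- calibration %||% calibrate(
    raw, times,
    window_s = config$calibration_window_s,
    sign = config$sign,
    sd_limit_deg = config$calibration_sd_limit_deg
  )

  trajectory(
    time_s = times,
    gantry_deg = to_gantry(raw, cal),
    ok = is.finite(raw),
    rate_hz = src$fps,
    source = "double_dot",
    calibration = cal
  )
}

#' Detect the start of gantry motion
#'
#' Scans the trajectory with a short window and returns the time at which the
#' windowed angular speed first exceeds a threshold. Used as the beam-on
#' proxy: the first frame of gantry rotation is taken to represent beam-on.
#'
#' @param traj a `gantry_trajectory`.
#' @param rate_thresh_deg_per_s speed threshold (default 0.5 deg/s).
#' @param window_frames window length in samples (default 5).
#' @return time in seconds of the first sample whose trailing window exceeds
#'   the threshold, or `NA_real_` if the trajectory never moves.
#' @export
detect_motion_start <- function(traj, rate_thresh_deg_per_s = 0.5,
                                window_frames = 5L) {
  okt <- traj$time_s[traj$ok]
  oka <- traj$gantry_deg[traj$ok]
  if (length(okt) < window_frames) {
    abort(sprintf("trajectory must have at least %d usable samples", window_frames))
  }
  u <- unwrap_deg(oka)
  w <- as.integer(window_frames)
  i <- w:length(u)
  speed <- abs(u[i] - u[i - w + 1L]) / (okt[i] - okt[i - w + 1L])
  hit <- which(speed > rate_thresh_deg_per_s)
  if (length(hit) == 0L) return(NA_real_)
  okt[i[hit[1]]]
}
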
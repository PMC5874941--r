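#' Detection pipeline configuration
#'
#' Parameters of the per-frame dot-detection chain and the angle engine.
#'
#' @param median_window side of the square median-filter window in pixels
#'   (odd; default 5, i.e. 5 x 5).
#' @param threshold_fraction global threshold as a fraction of each image's
#'   dynamic range (default 0.5, the "50 % global threshold").
#' @param min_area smallest connected-component pixel count accepted as a
#'   dot (default 25); smaller blobs are treated as noise specks.
#' @param red_larger radius-fallback colour assignment: when colour cannot
#'   separate the dots, the larger disc is labelled red (`TRUE`, default)
#'   or green (`FALSE`). Matches a pattern printed with unequal dot sizes.
#' @param collision_px if the red- and green-channel detections land within
#'   this distance (pixels) of each other, colour separation is deemed to
#'   have failed and the radius fallback is used (default 2).
#' @param sign mapping from apparent image rotation to gantry sense: `+1`
#'   (default) means clockwise on the image equals increasing gantry angle.
#'   Depends on which way the camera faces the pattern; verify once with a
#'   short known clockwise rotation.
#' @param calibration_window_s seconds of footage from the start used for
#'   self-calibration (default 10); the gantry must be stationary at 0 there.
#' @param calibration_sd_limit_deg largest circular SD (degrees) of the raw
#'   angle over the calibration window before calibration is rejected as
#'   non-stationary (default 0.2).
#' @param max_bad_frac largest tolerated fraction of frames with failed
#'   detection before [analyze()] aborts (default 0.2).
#' @param roi `"auto"` (default) restricts per-frame processing to a fixed
#'   window around the dots found in the first frame (a pure speed
#'   optimization: the threshold is range-relative and the crop always
#'   contains both dots and background, so results are unchanged);
#'   `"full"` processes entire frames; or an explicit `c(x0, y0, x1, y1)`
#'   0-based inclusive pixel window.
#' @return a `dd_config` list.
#' @export
detection_config <- function(median_window = 5L,
                             threshold_fraction = 0.5,
                             min_area = 25,
                             red_larger = TRUE,
                             collision_px = 2,
                             sign = 1,
                             calibration_window_s = 10,
                             calibration_sd_limit_deg = 0.2,
                             max_bad_frac = 0.2,
                             roi = "auto") {
  if (median_window %% 2 != 1 || median_window < 1) {
    abort("`median_window` must be an odd integer >= 1")
  }
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must be in (0, 1)")
  }
  if (!sign %in% c(-1, 1)) abort("`sign` must be +1 or -1")
  structure(
    list(
      median_window = as.integer(median_window),
      threshold_fraction = threshold_fraction,
      min_area = min_area,
      red_larger = isTRUE(red_larger),
      collision_px = collision_px,
      sign = sign,
      calibration_window_s = calibration_window_s,
      calibration_sd_limit_deg = calibration_sd_limit_deg,
      max_bad_frac = max_bad_frac,
      roi = roi
    ),
    class = "dd_config"
  )
}

#' Read a detection configuration from YAML
#'
#' @param path YAML file whose keys are arguments of [detection_config()].
#' @return a `dd_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(detection_config)))
  do.call(detection_config, vals[keep])
}

#' Isolate the red or green dot from an RGB frame
#'
#' Produces the colour-dominance image used to localize each dot: for red,
#' `max(R - G, 0)` per pixel; for green, `max(G - R, 0)`. The difference
#' suppresses the bright achromatic paper background (which drives all raw
#' channels high under room lighting) while leaving the opposing dot at zero.
#'
#' @param frame a `dd_frame`, or an `H x W x 3` intensity array.
#' @param colour `"red"` or `"green"`.
#' @return an integer matrix (`H x W`) with values in 0..255.
#' @export
channel_isolate <- function(frame, colour = c("red", "green")) {
  colour <- match.arg(colour)
  px <- if (inherits(frame, "dd_frame")) frame$pixels else frame
  if (length(dim(px)) != 3L) abort("`frame` must be an RGB frame")
  if (!is.integer(px)) storage.mode(px) <- "integer"
  r <- px[, , 1L]
  g <- px[, , 2L]
  if (colour == "red") cpp_channel_diff(r, g) else cpp_channel_diff(g, r)
}

#' Median-filter denoising
#'
#' Replaces each pixel by the median of its `window x window` neighbourhood;
#' image borders are handled by edge replication. Removes isolated noise
#' specks before thresholding.
#'
#' @param image a numeric matrix.
#' @param window odd window side length (default 5).
#' @return a matrix of the same dimensions.
#' @export
median_denoise <- function(image, window = 5L) {
  if (length(window) != 1L || is.na(window) || window %% 2 != 1 || window < 1) {
    abort("`window` must be an odd integer >= 1")
  }
  window <- as.integer(window)
  if (window == 1L) return(image)
  if (!is.matrix(image)) abort("`image` must be a matrix")
  is_u8 <- is.integer(image) ||
    (all(is.finite(image)) && all(image == round(image)))
  if (is_u8 && all(image >= 0) && all(image <= 255)) {
    m <- image
    storage.mode(m) <- "integer"
    out <- cpp_median_u8(m, window)
    if (!is.integer(image)) storage.mode(out) <- "double"
    out
  } else {
    cpp_median_naive(image, window)
  }
}

#' Global threshold mask
#'
#' Marks pixels at or above a fraction of the image's dynamic range:
#' `min + fraction * (max - min)`. Defined relative to the per-image range so
#' the mask is invariant to overall lighting and exposure scale. A constant
#' image has no dynamic range and yields an all-`FALSE` mask, flagged
#' degenerate via `attr(, "degenerate")`.
#'
#' @param image a numeric matrix.
#' @param fraction threshold fraction in (0, 1); default 0.5.
#' @return a logical matrix of the same dimensions.
#' @export
threshold_mask <- function(image, fraction = 0.5) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1)")
  lo <- min(image)
  hi <- max(image)
  if (lo == hi) {
    out <- matrix(FALSE, nrow(image), ncol(image))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- image >= lo + fraction * (hi - lo)
  attr(out, "degenerate") <- FALSE
  out
}

# plain-list detection record (hot path; tibbles are built only at the API
# boundary in detect_dots / largest_component_centroid)
det_record <- function(cx = NA_real_, cy = NA_real_, area = NA_real_,
                       ok = FALSE) {
  list(cx = cx, cy = cy, area = area, ok = ok)
}

det_as_tibble <- function(d, colour = NA_character_) {
  tibble(
    colour = colour,
    cx = d$cx,
    cy = d$cy,
    radius_px = if (is.na(d$area)) NA_real_ else sqrt(d$area / pi),
    area_px = d$area,
    ok = d$ok
  )
}

#' Centroid of the largest connected component
#'
#' Selects the largest 8-connected component of a binary mask and returns its
#' unweighted pixel centroid (mean of member coordinates, 0-based, sub-pixel),
#' pixel count, and equivalent-disc radius `sqrt(area / pi)`. Components
#' smaller than `min_area` are rejected (`ok = FALSE`), as is an empty mask.
#'
#' @param mask logical matrix.
#' @param min_area smallest accepted component area in pixels (default 25).
#' @return a one-row tibble with columns `colour` (unset), `cx`, `cy`,
#'   `radius_px`, `area_px`, `ok`.
#' @export
largest_component_centroid <- function(mask, min_area = 25) {
  det_as_tibble(largest_component_core(mask, min_area))
}

largest_component_core <- function(mask, min_area) {
  comp <- cpp_components(mask)
  if (length(comp$area) == 0L) return(det_record())
  i <- which.max(comp$area)
  det_record(cx = comp$cx[i], cy = comp$cy[i], area = comp$area[i],
             ok = comp$area[i] >= min_area)
}

# detection chain for one colour-dominance image (iso is an integer matrix
# in 0..255 by construction, so the 8-bit median path applies directly, and
# cpp_blob fuses thresholding + component selection with identical semantics
# to threshold_mask() + largest_component_centroid())
detect_one_core <- function(iso, config) {
  den <- if (config$median_window == 1L) iso else
    cpp_median_u8(iso, config$median_window)
  cpp_blob(den, config$threshold_fraction, config$min_area)
}

# radius-based fallback on the inverted luminance image: the dots are darker
# than the paper, so they remain detectable without colour. The two largest
# components are taken and assigned by radius (unequal dot sizes by design).
detect_fallback <- function(px, config) {
  lum <- (px[, , 1L] + px[, , 2L] + px[, , 3L]) %/% 3L
  inv <- 255L - lum
  den <- median_denoise(inv, config$median_window)
  mask <- threshold_mask(den, config$threshold_fraction)
  comp <- cpp_components(mask)
  keep <- which(comp$area >= config$min_area)
  if (length(keep) < 2L) {
    return(list(red = det_record(), green = det_record()))
  }
  keep <- keep[order(comp$area[keep], decreasing = TRUE)][1:2]
  big <- keep[1]
  small <- keep[2]
  as_det <- function(i) {
    det_record(cx = comp$cx[i], cy = comp$cy[i], area = comp$area[i], ok = TRUE)
  }
  if (config$red_larger) {
    list(red = as_det(big), green = as_det(small))
  } else {
    list(red = as_det(small), green = as_det(big))
  }
}

# full per-frame detection on a (possibly cropped) pixel array; plain lists
detect_core <- function(px, config) {
  r <- px[, , 1L]
  g <- px[, , 2L]
  red <- detect_one_core(cpp_channel_diff(r, g), config)
  green <- detect_one_core(cpp_channel_diff(g, r), config)

  collided <- red$ok && green$ok &&
    sqrt((red$cx - green$cx)^2 + (red$cy - green$cy)^2) <= config$collision_px
  if (collided || (!red$ok && !green$ok)) {
    fb <- detect_fallback(px, config)
    red <- fb$red
    green <- fb$green
  }
  list(red = red, green = green)
}

# crop a pixel array to a 0-based inclusive roi c(x0, y0, x1, y1), clamped
crop_roi <- function(px, roi) {
  x0 <- max(0L, as.integer(roi[1]))
  y0 <- max(0L, as.integer(roi[2]))
  x1 <- min(dim(px)[2] - 1L, as.integer(roi[3]))
  y1 <- min(dim(px)[1] - 1L, as.integer(roi[4]))
  list(px = px[(y0:y1) + 1L, (x0:x1) + 1L, , drop = FALSE],
       off_x = x0, off_y = y0)
}

#' Detect the red and green dots in one frame
#'
#' Runs the full per-frame detection chain for each colour: channel
#' isolation, median denoising, range-relative global thresholding, and
#' largest-component centroid extraction. If colour fails to separate the
#' dots (both channels select the same component within `collision_px`, or
#' both colour detections fail outright, e.g. colour-free footage), a
#' radius-based fallback on the inverted luminance image assigns the larger
#' disc per `red_larger`.
#'
#' @param frame a `dd_frame`.
#' @param config a [detection_config()].
#' @return a `dd_dotpair`: a two-row tibble (`colour` = red, green) with
#'   sub-pixel centroids `cx`, `cy` (0-based, y down), `radius_px`,
#'   `area_px`, `ok` flags, `frame_index`, and attribute `separation_px`
#'   (Euclidean centroid distance) when both detections succeeded.
#' @export
detect_dots <- function(frame, config = detection_config()) {
  px <- frame$pixels
  off_x <- 0L
  off_y <- 0L
  if (is.numeric(config$roi) && length(config$roi) == 4L) {
    cr <- crop_roi(px, config$roi)
    px <- cr$px
    off_x <- cr$off_x
    off_y <- cr$off_y
  }

  det <- detect_core(px, config)
  red <- det$red
  green <- det$green
  red$cx <- red$cx + off_x
  red$cy <- red$cy + off_y
  green$cx <- green$cx + off_x
  green$cy <- green$cy + off_y

  pair <- dplyr::bind_rows(det_as_tibble(red, "red"),
                           det_as_tibble(green, "green"))
  pair$frame_index <- frame$index
  sep <- if (red$ok && green$ok) {
    sqrt((red$cx - green$cx)^2 + (red$cy - green$cy)^2)
  } else {
    NA_real_
  }
  structure(pair, separation_px = sep,
            class = c("dd_dotpair", class(pair)))
}
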
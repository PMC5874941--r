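#' Construct a single video frame
#'
#' A frame is a timestamped 8-bit RGB image. Pixel coordinates throughout the
#' package are 0-based with x increasing rightwards and y increasing
#' downwards (the usual image convention), pixel centres at integers.
#'
#' @param pixels integer array of dimension `c(height, width, 3)`, values
#'   in 0..255 (a greyscale `height x width` matrix is promoted to RGB).
#' @param index 0-based frame index.
#' @param fps frame rate in Hz; `time_s` is `index / fps`.
#' @param time_s optional explicit timestamp (seconds from footage start).
#' @param validate check the intensity range (skipped by the internal
#'   renderer, whose output is in range by construction).
#' @return an object of class `dd_frame` with fields `pixels`, `index`,
#'   `time_s`, `width`, `height`, `fps`.
#' @export
new_frame <- function(pixels, index = 0L, fps = 30, time_s = index / fps,
                      validate = TRUE) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(nrow(pixels), ncol(pixels), 3L))
  }
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be a height x width x 3 array (or a greyscale matrix)")
  }
  storage.mode(pixels) <- "integer"
  if (validate) {
    rng <- range(pixels)
    if (is.na(rng[1]) || rng[1] < 0L || rng[2] > 255L) {
      abort("pixel intensities must be in 0..255")
    }
  }
  structure(
    list(
      pixels = pixels,
      index = as.integer(index),
      time_s = as.numeric(time_s),
      width = dim(pixels)[2],
      height = dim(pixels)[1],
      fps = as.numeric(fps)
    ),
    class = "dd_frame"
  )
}

#' @export
print.dd_frame <- function(x, ...) {
  cat(sprintf(
    "<dd_frame> index %d, t = %.4f s, %d x %d px\n",
    x$index, x$time_s, x$width, x$height
  ))
  invisible(x)
}

# A frame source is a lazy, ordered sequence of frames: `get(i)` (1-based)
# materializes frame i. Keeps memory O(1 frame) for long footage.
new_frame_source <- function(get, n, fps, truth = NULL, origin = "frames") {
  structure(
    list(get = get, n = as.integer(n), fps = as.numeric(fps),
         truth = truth, origin = origin),
    class = "dd_frame_source"
  )
}

#' @export
length.dd_frame_source <- function(x) x$n

#' @export
`[[.dd_frame_source` <- function(x, i) {
  i <- as.integer(i)
  if (i < 1L || i > x$n) abort(sprintf("frame index %d out of range 1..%d", i, x$n))
  x$get(i)
}

#' @export
print.dd_frame_source <- function(x, ...) {
  cat(sprintf(
    "<dd_frame_source> %d frames at %g fps (%.2f s) from %s\n",
    x$n, x$fps, x$n / x$fps, x$origin
  ))
  if (!is.null(x$truth)) cat("  with ground-truth trajectory\n")
  invisible(x)
}

#' Coerce footage to a frame source
#'
#' @param x a `dd_frame_source`, a list of `dd_frame` objects, or a directory
#'   path (passed to [load_frames()]).
#' @param fps_override frame rate, required when `x` carries none.
#' @return a `dd_frame_source`.
#' @export
as_frame_source <- function(x, fps_override = NULL) {
  if (inherits(x, "dd_frame_source")) return(x)
  if (inherits(x, "dd_frame")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "dd_frame"))) {
    if (length(x) == 0L) abort("empty frame list")
    fps <- fps_override %||% x[[1]]$fps
    return(new_frame_source(function(i) x[[i]], length(x), fps, origin = "memory"))
  }
  if (is.character(x) && length(x) == 1L) return(load_frames(x, fps_override))
  abort("cannot interpret `x` as footage (frame source, frame list, or directory)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load footage from a directory of ordered image frames
#'
#' Reads a directory of PNG frames named so that lexicographic order is
#' temporal order (e.g. `frame_000001.png`, `frame_000002.png`, ...). Frames
#' are read lazily. Video containers are not decoded; extract frames to
#' images first (e.g. `ffmpeg -i clip.mp4 frame_%06d.png`).
#'
#' @param source directory containing the frames.
#' @param fps_override frame rate in Hz. Required: plain image directories
#'   carry no rate metadata.
#' @return a `dd_frame_source`; element `i` has `index = i - 1` and
#'   `time_s = (i - 1) / fps`.
#' @export
load_frames <- function(source, fps_override = NULL) {
  if (!file.exists(source)) {
    abort(sprintf("cannot read footage: '%s' does not exist", source))
  }
  if (!dir.exists(source)) {
    abort(sprintf(
      "'%s' is not a frame directory; video containers are not decoded, extract frames to PNG first",
      source
    ))
  }
  files <- sort(list.files(source, pattern = "\\.png$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) {
    abort(sprintf("no PNG frames found in '%s'", source))
  }
  if (is.null(fps_override)) {
    abort("frame rate unknown: supply `fps_override` for image directories")
  }
  fps <- as.numeric(fps_override)
  get <- function(i) {
    px <- png::readPNG(files[[i]])
    if (length(dim(px)) == 3L && dim(px)[3] >= 3L) {
      px <- px[, , 1:3, drop = FALSE]  # drop alpha if present
    }
    new_frame(round(px * 255), index = i - 1L, fps = fps)
  }
  new_frame_source(get, length(files), fps, origin = source)
}

#' Write footage to a directory of PNG frames
#'
#' Materializes a frame source as zero-padded PNG files (readable back with
#' [load_frames()]); if the source carries a ground-truth trajectory it is
#' written alongside as `truth.csv`.
#'
#' @param source a `dd_frame_source` or list of frames.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(source, dir) {
  source <- as_frame_source(source, fps_override = 30)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(length(source))) {
    fr <- source[[i]]
    png::writePNG(fr$pixels / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  if (!is.null(source$truth)) {
    write_angle_csv(source$truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}
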
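#' DynaLog-style file dialect
#'
#' Machine log files record the gantry angle at 50 ms intervals, but the
#' column layout and angle encoding vary by control-software version. The
#' dialect object declares the layout explicitly rather than hard-coding
#' one vendor variant: a delimited text file, comment lines starting with
#' `#`, and rows `index<sep>beam_on<sep>gantry_stored`, where the stored
#' gantry value is `round(angle_0_360 * scale)` (so `scale = 10` quantizes
#' to 0.1 degrees on a 0..360 scale).
#'
#' @param scale stored-value units per degree (default 10).
#' @param sep field separator (default `","`).
#' @param sample_dt_s sampling interval (default 0.05 s).
#' @return a `dynalog_dialect` list.
#' @export
dynalog_dialect <- function(scale = 10, sep = ",", sample_dt_s = 0.05) {
  if (scale <= 0) abort("`scale` must be positive")
  structure(list(scale = scale, sep = sep, sample_dt_s = sample_dt_s),
            class = "dynalog_dialect")
}

#' Parse a DynaLog-style gantry log
#'
#' Reads a machine log under the declared [dynalog_dialect()]: sample times
#' are assigned at the dialect's 50 ms spacing from the row index, stored
#' gantry values are divided by the dialect scale and converted to the
#' signed `[-180, +180)` convention.
#'
#' @param path file to read.
#' @param dialect a [dynalog_dialect()].
#' @return a `gantry_trajectory` (source `"dynalog"`) with a `beam_on`
#'   column.
#' @export
parse_dynalog <- function(path, dialect = dynalog_dialect()) {
  if (!inherits(dialect, "dynalog_dialect")) {
    abort("`dialect` must be a dynalog_dialect()")
  }
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path)
  data_ln <- which(!grepl("^\\s*(#|$)", lines))
  if (length(data_ln) == 0L) abort(sprintf("'%s' contains no log records", path))

  parts <- strsplit(lines[data_ln], dialect$sep, fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed DynaLog record at line %d of '%s'",
                  data_ln[bad[1]], path))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(lapply(parts, `[`, 1:3)))),
              ncol = 3L, byrow = TRUE)
  if (anyNA(m)) {
    abort(sprintf("malformed DynaLog record at line %d of '%s'",
                  data_ln[which(rowSums(is.na(m)) > 0)[1]], path))
  }
  trajectory(
    time_s = m[, 1] * dialect$sample_dt_s,
    gantry_deg = wrap_deg_180(m[, 3] / dialect$scale),
    rate_hz = 1 / dialect$sample_dt_s,
    source = "dynalog",
    beam_on = m[, 2] != 0
  )
}

#' Write a trajectory as a DynaLog-style log
#'
#' Resamples the trajectory onto the dialect's 50 ms grid (relative to its
#' first sample), quantizes angles per the dialect scale, and writes a file
#' parseable by [parse_dynalog()]. Ships with the package so the comparison
#' path is testable without a linac; the round-trip error is at most half
#' the dialect's quantization step.
#'
#' @param traj a `gantry_trajectory` (at least one usable sample).
#' @param path output file.
#' @param dialect a [dynalog_dialect()].
#' @return `path`, invisibly.
#' @export
write_dynalog <- function(traj, path, dialect = dynalog_dialect()) {
  ok <- traj$ok & is.finite(traj$gantry_deg)
  if (sum(ok) < 1L) abort("trajectory has no usable samples to write")
  t0 <- traj$time_s[ok][1]
  t1 <- traj$time_s[ok][sum(ok)]
  grid <- seq(0, t1 - t0, by = dialect$sample_dt_s)
  ang <- if (sum(ok) == 1L) {
    rep(traj$gantry_deg[ok], length(grid))
  } else {
    resample(traj, grid + t0)
  }
  stored <- round(wrap_deg_360(ang) * dialect$scale) %% round(360 * dialect$scale)
  beam <- rep(1L, length(grid))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# gantrycam dynalog-style log v1",
    sprintf("# scale=%g sample_dt_s=%g", dialect$scale, dialect$sample_dt_s),
    paste(seq_along(grid) - 1L, beam, stored, sep = dialect$sep)
  ), con)
  invisible(path)
}

#' Read a generic time/angle CSV
#'
#' Reads `time_s,gantry_deg` CSVs (with optional `ok` and `source` columns),
#' the package's interchange format also used for encoder or inclinometer
#' exports. Angles outside `[-180, 180)` are wrapped with a warning; time
#' must be strictly increasing.
#'
#' @param path CSV file.
#' @return a `gantry_trajectory`.
#' @export
read_angle_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file", path))
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "gantry_deg") %in% names(df))) {
    abort("angle CSV must have `time_s` and `gantry_deg` columns")
  }
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0)) {
    abort("invalid angle CSV: `time_s` must be strictly increasing")
  }
  outside <- is.finite(df$gantry_deg) &
    (df$gantry_deg < -180 | df$gantry_deg >= 180)
  if (any(outside)) {
    warn(sprintf("%d angle(s) outside [-180, 180) wrapped on read", sum(outside)))
  }
  src <- if ("source" %in% names(df)) as.character(df$source[1]) else "csv"
  ok <- if ("ok" %in% names(df)) as.logical(df$ok) else is.finite(df$gantry_deg)
  trajectory(df$time_s, df$gantry_deg, ok = ok, source = src)
}

#' Write a trajectory as a time/angle CSV
#'
#' @param traj a `gantry_trajectory`.
#' @param path output file; columns `time_s,gantry_deg,ok,source`.
#' @return `path`, invisibly.
#' @export
write_angle_csv <- function(traj, path) {
  df <- data.frame(
    time_s = traj$time_s,
    gantry_deg = traj$gantry_deg,
    ok = if ("ok" %in% names(traj)) traj$ok else TRUE,
    source = attr(traj, "source") %||% "unknown"
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
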
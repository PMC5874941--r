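#' Resample a trajectory at arbitrary times
#'
#' Linear interpolation performed on the unwrapped angle (unwrap first,
#' wrap after), so interpolating across the +/-180-degree seam is correct:
#' halfway between 179 and -179 is -180, not 0. Only `ok` samples are used;
#' requested times must lie within their span.
#'
#' @param traj a `gantry_trajectory`.
#' @param times seconds at which to interpolate.
#' @return gantry angles in degrees, `[-180, 180)`, one per requested time.
#' @export
resample <- function(traj, times) {
  ok <- traj$ok & is.finite(traj$gantry_deg)
  tt <- traj$time_s[ok]
  aa <- traj$gantry_deg[ok]
  if (length(tt) == 0L) abort("trajectory has no usable samples")
  tol <- 1e-9
  if (any(times < tt[1] - tol | times > tt[length(tt)] + tol)) {
    abort(sprintf(
      "cannot resample outside the trajectory span [%.3f, %.3f] s",
      tt[1], tt[length(tt)]
    ), class = "gantrycam_range_error")
  }
  if (length(tt) == 1L) return(rep(aa, length(times)))
  u <- unwrap_deg(aa)
  wrap_deg_180(approx(tt, u, xout = pmin(pmax(times, tt[1]), tt[length(tt)]))$y)
}

#' Estimate the time offset between two trajectories
#'
#' Synchronizing an independent camera clock with a machine log is the
#' dominant error source in time-resolved comparisons. This grid search
#' finds the shift `s` minimizing the mean absolute circular deviation
#' between `a(t)` and `b(t + s)` over their overlap; ties resolve to the
#' smallest `|s|`. If the optimum lies on the search boundary the true
#' offset may be larger; a warning is issued and the boundary value
#' returned.
#'
#' @param a,b `gantry_trajectory` objects (`a` supplies the evaluation grid).
#' @param search_s half-width of the search window in seconds (default 1).
#' @param step_s grid step in seconds (default 0.001).
#' @return the estimated offset in seconds: `b` evaluated at `t + s` aligns
#'   with `a` at `t`.
#' @export
estimate_time_offset <- function(a, b, search_s = 1, step_s = 0.001) {
  shifts <- seq(-search_s, search_s, by = step_s)
  at <- a$time_s[a$ok & is.finite(a$gantry_deg)]
  av <- a$gantry_deg[a$ok & is.finite(a$gantry_deg)]
  bok <- b$ok & is.finite(b$gantry_deg)
  bt <- b$time_s[bok]
  bu <- unwrap_deg(b$gantry_deg[bok])
  if (length(at) == 0L || length(bt) < 2L) {
    abort("need usable samples in both trajectories")
  }

  dev_at <- function(s) {
    inside <- at + s >= bt[1] & at + s <= bt[length(bt)]
    if (!any(inside)) return(NA_real_)
    bv <- wrap_deg_180(approx(bt, bu, xout = at[inside] + s)$y)
    mean(circular_deviation(av[inside], bv))
  }
  devs <- vapply(shifts, dev_at, numeric(1))
  if (all(is.na(devs))) {
    abort("trajectories do not overlap at any shift in the search window")
  }
  best <- order(devs, abs(shifts), na.last = TRUE)[1]
  s <- shifts[best]
  if (abs(abs(s) - search_s) < step_s / 2) {
    warn(sprintf(
      "offset estimate %.3f s lies on the search boundary; widen `search_s`", s
    ))
  }
  s
}

#' Compare two gantry-angle trajectories
#'
#' Samples the absolute circular deviation between trajectory `a` and
#' trajectory `b` (resampled onto `a`'s time grid, optionally after a
#' synchronization shift) and summarizes it as mean, SD and maximum — the
#' standard report shape for time-resolved gantry-angle QA. The SD is the
#' 1-SD spread of the absolute deviations. Put the higher-rate source first:
#' deviations are evaluated on its grid.
#'
#' @param a,b `gantry_trajectory` objects.
#' @param sync `"off"` (default: clocks are taken as already aligned),
#'   `"auto"` (estimate the shift with [estimate_time_offset()]), or
#'   `"fixed"` (use `sync_s`).
#' @param sync_s shift in seconds when `sync = "fixed"`.
#' @param exclude_static drop samples recorded before both trajectories
#'   started moving (motion onset per [detect_motion_start()]), e.g. the
#'   calibration lead-in.
#' @param pair_label label for the report row (default built from the two
#'   source labels, e.g. `"double_dot-dynalog"`).
#' @param ... passed to [estimate_time_offset()] when `sync = "auto"`.
#' @return a `gantry_comparison` object; see [glance.gantry_comparison()]
#'   for the one-row statistics and [tidy.gantry_comparison()] for the
#'   per-sample deviations.
#' @export
compare_trajectories <- function(a, b, sync = c("off", "auto", "fixed"),
                                 sync_s = 0, exclude_static = FALSE,
                                 pair_label = NULL, ...) {
  sync <- match.arg(sync)
  offset <- switch(sync,
    off = 0,
    fixed = sync_s,
    auto = estimate_time_offset(a, b, ...)
  )

  aok <- a$ok & is.finite(a$gantry_deg)
  at <- a$time_s[aok]
  av <- a$gantry_deg[aok]
  bok <- b$ok & is.finite(b$gantry_deg)
  bspan <- range(b$time_s[bok])

  keep <- at + offset >= bspan[1] & at + offset <= bspan[2]
  if (exclude_static) {
    starts <- c(detect_motion_start(a), detect_motion_start(b) - offset)
    starts <- starts[is.finite(starts)]
    if (length(starts) > 0) keep <- keep & at >= max(starts)
  }
  if (!any(keep)) abort("trajectories do not overlap (after sync/exclusions)")

  bv <- resample(b, at[keep] + offset)
  dev <- circular_deviation(av[keep], bv)

  label <- pair_label %||% paste(attr(a, "source") %||% "a",
                                 attr(b, "source") %||% "b", sep = "-")
  structure(
    list(
      stats = tibble(
        pair_label = label,
        mean_abs_dev_deg = mean(dev),
        sd_dev_deg = if (length(dev) > 1) sd(dev) else 0,
        max_abs_dev_deg = max(dev),
        n_samples = length(dev),
        time_offset_s = offset
      ),
      deviations = tibble(time_s = at[keep], a_deg = av[keep],
                          b_deg = bv, dev_deg = dev)
    ),
    class = "gantry_comparison"
  )
}

#' @export
print.gantry_comparison <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<gantry_comparison> %s: mean |dev| %.3f deg, 1 SD %.3f deg, max %.3f deg (n = %d, offset %.3f s)\n",
    s$pair_label, s$mean_abs_dev_deg, s$sd_dev_deg, s$max_abs_dev_deg,
    s$n_samples, s$time_offset_s
  ))
  invisible(x)
}

#' Tidy a trajectory comparison
#'
#' @param x a `gantry_comparison`.
#' @param ... unused.
#' @return `tidy()`: the per-sample deviation tibble (`time_s`, `a_deg`,
#'   `b_deg`, `dev_deg`); `glance()`: the one-row summary statistics
#'   (`pair_label`, `mean_abs_dev_deg`, `sd_dev_deg`, `max_abs_dev_deg`,
#'   `n_samples`, `time_offset_s`).
#' @export
tidy.gantry_comparison <- function(x, ...) x$deviations

#' @rdname tidy.gantry_comparison
#' @export
glance.gantry_comparison <- function(x, ...) x$stats
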
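new_gantry_plan <- function(segments, kind, direction, max_speed) {
  structure(segments, kind = kind, direction = direction,
            max_speed = max_speed,
            class = c("gantry_plan", class(segments)))
}

#' @export
print.gantry_plan <- function(x, ...) {
  cat(sprintf("<gantry_plan> kind '%s', direction %s, %d segment(s), max speed %g deg/s\n",
              attr(x, "kind"), attr(x, "direction"), nrow(x), attr(x, "max_speed")))
  NextMethod()
}

# signed start/end for an arc centred on 0 (e.g. 358 deg -> -179..+179),
# respecting single-arc deliverability
arc_limits <- function(arc_deg, direction) {
  if (arc_deg <= 0 || arc_deg > 358) {
    abort("`arc_deg` must be in (0, 358] for a single deliverable arc")
  }
  if (direction == "CW") c(-arc_deg / 2, arc_deg / 2) else c(arc_deg / 2, -arc_deg / 2)
}

check_speeds <- function(speeds, max_speed) {
  if (any(speeds <= 0)) abort("gantry speeds must be positive")
  if (any(speeds > max_speed + 1e-12)) {
    abort(sprintf("gantry speed exceeds the machine limit of %g deg/s", max_speed))
  }
}

#' Constant-gantry-speed QA plan
#'
#' The least complex dynamic test: a single arc delivered at constant gantry
#' speed and constant dose rate (defaults 4.8 deg/s at 600 MU/min over a
#' 358-degree arc).
#'
#' @param arc_deg arc span in degrees (default 358; at most 358 for a single
#'   deliverable arc).
#' @param speed_deg_per_s gantry speed (default 4.8).
#' @param dose_rate_mu_min dose rate in MU/min (default 600).
#' @param direction `"CW"` or `"CCW"`.
#' @param max_speed_deg_per_s machine gantry-speed limit (default 6).
#' @return a `gantry_plan`: a segment tibble with columns `start_deg`,
#'   `end_deg`, `speed_deg_per_s` (signed), `dose_rate_mu_min`.
#' @export
constant_speed_plan <- function(arc_deg = 358, speed_deg_per_s = 4.8,
                                dose_rate_mu_min = 600,
                                direction = c("CW", "CCW"),
                                max_speed_deg_per_s = 6) {
  direction <- match.arg(direction)
  check_speeds(speed_deg_per_s, max_speed_deg_per_s)
  lim <- arc_limits(arc_deg, direction)
  sgn <- if (direction == "CW") 1 else -1
  seg <- tibble(
    start_deg = lim[1], end_deg = lim[2],
    speed_deg_per_s = sgn * speed_deg_per_s,
    dose_rate_mu_min = dose_rate_mu_min
  )
  new_gantry_plan(seg, "constant_speed", direction, max_speed_deg_per_s)
}

#' Gantry-speed-transition QA plan
#'
#' Simulates simultaneous changes in dose rate and gantry speed every
#' `block_deg` degrees of rotation: consecutive angular blocks cycle through
#' paired speed/dose levels, so every adjacent block differs in both. The
#' total arc is capped at 358 degrees (the final block is truncated).
#'
#' @param block_deg block span in degrees (default 30).
#' @param speed_levels gantry speeds cycled over the blocks
#'   (default `c(6, 3)` deg/s).
#' @param dose_levels dose rates paired with `speed_levels`
#'   (default `c(600, 300)` MU/min).
#' @param arc_deg total arc before capping (default 358).
#' @inheritParams constant_speed_plan
#' @return a `gantry_plan`.
#' @export
speed_transition_plan <- function(block_deg = 30,
                                  speed_levels = c(6, 3),
                                  dose_levels = c(600, 300),
                                  arc_deg = 358,
                                  direction = c("CW", "CCW"),
                                  max_speed_deg_per_s = 6) {
  direction <- match.arg(direction)
  if (length(speed_levels) == 0L) abort("`speed_levels` must be non-empty")
  check_speeds(speed_levels, max_speed_deg_per_s)
  dose_levels <- rep_len(dose_levels, length(speed_levels))
  lim <- arc_limits(arc_deg, direction)
  sgn <- if (direction == "CW") 1 else -1

  n_blocks <- ceiling(arc_deg / block_deg)
  spans <- rep(block_deg, n_blocks)
  spans[n_blocks] <- arc_deg - block_deg * (n_blocks - 1)  # truncated final block
  lev <- rep_len(seq_along(speed_levels), n_blocks)

  ends <- lim[1] + sgn * cumsum(spans)
  seg <- tibble(
    start_deg = c(lim[1], head(ends, -1)),
    end_deg = ends,
    speed_deg_per_s = sgn * speed_levels[lev],
    dose_rate_mu_min = dose_levels[lev]
  )
  new_gantry_plan(seg, "speed_transition", direction, max_speed_deg_per_s)
}

#' Maximum-inertia-overshoot QA plan
#'
#' Stresses gantry acceleration and deceleration: alternating segments
#' commanding maximum gantry speed and a near-stop crawl, with maximal dose
#' rate swings, adapted from the Maximum Allowable Inertia Overshoot (MAIO)
#' concept. Defaults: maximum speed over 20 degrees, then 0.5 deg/s over
#' 5 degrees, for 6 cycles.
#'
#' @param fast_span_deg arc covered at maximum speed per cycle (default 20).
#' @param slow_span_deg arc covered at the crawl speed per cycle (default 5).
#' @param slow_speed_deg_per_s crawl speed (default 0.5).
#' @param n_cycles number of fast/slow cycles (default 6).
#' @param dose_fast_mu_min,dose_slow_mu_min dose rates for the fast and slow
#'   segments (defaults 600 and 50 MU/min — maximal swings).
#' @inheritParams constant_speed_plan
#' @return a `gantry_plan`.
#' @export
maio_plan <- function(fast_span_deg = 20, slow_span_deg = 5,
                      slow_speed_deg_per_s = 0.5, n_cycles = 6,
                      dose_fast_mu_min = 600, dose_slow_mu_min = 50,
                      direction = c("CW", "CCW"),
                      max_speed_deg_per_s = 6) {
  direction <- match.arg(direction)
  check_speeds(c(slow_speed_deg_per_s, max_speed_deg_per_s), max_speed_deg_per_s)
  arc <- n_cycles * (fast_span_deg + slow_span_deg)
  lim <- arc_limits(arc, direction)
  sgn <- if (direction == "CW") 1 else -1

  spans <- rep(c(fast_span_deg, slow_span_deg), n_cycles)
  speeds <- rep(c(max_speed_deg_per_s, slow_speed_deg_per_s), n_cycles)
  doses <- rep(c(dose_fast_mu_min, dose_slow_mu_min), n_cycles)
  ends <- lim[1] + sgn * cumsum(spans)
  seg <- tibble(
    start_deg = c(lim[1], head(ends, -1)),
    end_deg = ends,
    speed_deg_per_s = sgn * speeds,
    dose_rate_mu_min = doses
  )
  new_gantry_plan(seg, "maio", direction, max_speed_deg_per_s)
}

#' Sample a plan into a ground-truth trajectory
#'
#' Piecewise-linear angle-versus-time sampling of a plan's segments, with
#' per-sample dose rate. Gantry acceleration is treated as instantaneous in
#' the commanded truth; the measured-versus-commanded deviation under finite
#' camera sampling is precisely what the method quantifies.
#'
#' @param plan a `gantry_plan`.
#' @param dt_s sampling interval in seconds (default 0.01).
#' @return a `gantry_trajectory` (source `"plan_truth"`) with columns
#'   `time_s`, `gantry_deg` (wrapped), `ok`, `gantry_unwrapped_deg`,
#'   `dose_rate_mu_min`. The exact segment end time is always included, so
#'   the endpoint angle equals the plan's full signed span.
#' @export
plan_to_trajectory <- function(plan, dt_s = 0.01) {
  if (dt_s <= 0) abort("`dt_s` must be positive")
  spans <- plan$end_deg - plan$start_deg
  if (any(spans != 0 & plan$speed_deg_per_s == 0)) {
    abort("zero-speed segment with nonzero span: plan duration would be infinite")
  }
  durations <- spans / plan$speed_deg_per_s
  if (any(durations < 0)) abort("segment speed sign inconsistent with its span")
  t_end <- cumsum(durations)
  t_start <- c(0, head(t_end, -1))

  total <- t_end[length(t_end)]
  tt <- seq(0, total, by = dt_s)
  if (total - tt[length(tt)] > 1e-9) tt <- c(tt, total)

  seg_of <- findInterval(tt, t_start, rightmost.closed = FALSE)
  ang <- plan$start_deg[seg_of] +
    plan$speed_deg_per_s[seg_of] * (tt - t_start[seg_of])
  dose <- plan$dose_rate_mu_min[seg_of]

  trajectory(
    time_s = tt, gantry_deg = ang, rate_hz = 1 / dt_s, source = "plan_truth",
    gantry_unwrapped_deg = ang, dose_rate_mu_min = dose
  )
}
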
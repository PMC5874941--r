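#' Wrap angles to the signed gantry scale
#'
#' Gantry angles are reported on a signed scale, `[-180, +180)` degrees;
#' raw red-to-green pattern angles live on `[0, 360)`.
#'
#' @param x angles in degrees.
#' @return `wrap_deg_180()` returns angles in `[-180, 180)`; `wrap_deg_360()`
#'   returns angles in `[0, 360)`.
#' @examples
#' wrap_deg_180(c(190, -180, 360))
#' wrap_deg_360(-10)
#' @export
wrap_deg_180 <- function(x) {
  ((x + 180) %% 360) - 180
}

#' @rdname wrap_deg_180
#' @export
wrap_deg_360 <- function(x) {
  x %% 360
}

#' Smallest absolute angular difference on the circle
#'
#' The per-sample deviation underlying all trajectory comparison statistics:
#' the shortest arc between two angles, in `[0, 180]` degrees. Respects the
#' +/-180 degree seam, so e.g. 179 and -179 differ by 2, not 358.
#'
#' @param a_deg,b_deg angles in degrees (vectorized, recycled).
#' @return absolute circular deviations in degrees, `[0, 180]`.
#' @examples
#' circular_deviation(179, -179)
#' circular_deviation(10, 10)
#' @export
circular_deviation <- function(a_deg, b_deg) {
  abs(wrap_deg_180(a_deg - b_deg))
}

# Unwrap a sequence of wrapped angles into a continuous trajectory:
# successive steps are taken as the smallest signed circular difference.
# Correct as long as true motion between consecutive samples is < 180 deg.
unwrap_deg <- function(x) {
  if (length(x) <= 1) return(x)
  steps <- wrap_deg_180(diff(x))
  x[1] + c(0, cumsum(steps))
}

# Circular mean of angles in degrees, on [0, 360).
circ_mean_deg <- function(x) {
  r <- x * pi / 180
  m <- wrap_deg_360(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
  if (360 - m < 1e-9) 0 else m  # canonicalize the 360 - epsilon corner
}

# Circular standard deviation in degrees (sqrt(-2 log R) definition);
# for tightly clustered angles this approaches the linear SD.
circ_sd_deg <- function(x) {
  r <- x * pi / 180
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rbar <- min(max(rbar, .Machine$double.xmin), 1)
  sqrt(-2 * log(rbar)) * 180 / pi
}
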
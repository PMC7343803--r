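#' Idealized orientation tuning channel basis
#'
#' Builds `k` hypothetical orientation channels tiling the 180-degree
#' orientation space. Each channel is a half-wave rectified sinusoid raised
#' to a power: its response to an orientation at circular distance `d`
#' degrees from the channel center is `cos(pi * d / 180)^exponent`, which is
#' 1 at the center and falls to 0 at 90 degrees (the largest possible
#' distance on the orientation circle). The analysis basis uses 9 channels
#' raised to the 9th power; the simulator's tuning channels use the 8th.
#'
#' @param k number of channels (>= 2), centers evenly spaced over 0-179.
#' @param exponent positive power applied to the rectified sinusoid.
#' @param n_points resolution of the tabulated orientation grid.
#' @return object of class `channel_basis`: list with `k`, `exponent`,
#'   `centers`, `grid` (degrees) and `M`, an `n_points x k` matrix of
#'   channel responses over the grid.
#' @examples
#' b <- make_channel_basis(9, 9)
#' b$M[1, 1]       # channel at 0 evaluated at 0 -> 1
#' b$M[61, 1]      # at 60 degrees -> 0.5^9
#' @export
make_channel_basis <- function(k = 9L, exponent = 9, n_points = 180L) {
  if (k < 2) stop("`k` must be >= 2")
  if (!is.finite(exponent) || exponent <= 0) {
    stop("`exponent` must be a positive number")
  }
  grid <- seq(0, 180 - 180 / n_points, length.out = n_points)
  centers <- 180 * (seq_len(k) - 1L) / k
  M <- channel_curve(grid, centers, exponent)
  structure(
    list(k = as.integer(k), exponent = exponent, centers = centers,
         grid = grid, M = M),
    class = "channel_basis"
  )
}

# Tuning-curve kernel: rows = orientations, cols = channel centers.
channel_curve <- function(theta, centers, exponent) {
  d <- circ_dist180(
    matrix(theta, length(theta), length(centers)),
    matrix(centers, length(theta), length(centers), byrow = TRUE)
  )
  cospi(d / 180)^exponent
}

#' Evaluate channel responses at arbitrary orientations
#'
#' The predicted (noise-free, unit-amplitude) channel responses used as the
#' design matrix for weight estimation: the basis is continuous, so it is
#' evaluated at each trial's exact jittered orientation rather than its
#' base bin.
#'
#' @param basis a `channel_basis`.
#' @param theta orientations in degrees.
#' @return `length(theta) x k` matrix.
#' @export
channel_response <- function(basis, theta) {
  stopifnot(inherits(basis, "channel_basis"))
  channel_curve(theta, basis$centers, basis$exponent)
}

#' @export
print.channel_basis <- function(x, ...) {
  cat(sprintf(
    "channel_basis: %d channels, exponent %g, centers %s\n",
    x$k, x$exponent, paste(round(x$centers, 1), collapse = ", ")
  ))
  invisible(x)
}

#' Gaussian stimulus drive over orientation space
#'
#' The stimulus input to the tuning channels: a delta at the presented
#' orientation convolved with a circular Gaussian (amplitude 1, sd 18
#' degrees by default), which admits some sensory uncertainty about the
#' exact orientation.
#'
#' @param theta_sample presented orientation in degrees, in `[0, 180)`.
#' @param amplitude peak value at `theta_sample`.
#' @param sd_deg Gaussian standard deviation in degrees.
#' @param n_points length of the orientation grid.
#' @return numeric vector of length `n_points`.
#' @export
stimulus_vector <- function(theta_sample, amplitude = 1, sd_deg = 18,
                            n_points = 180L) {
  grid <- seq(0, 180 - 180 / n_points, length.out = n_points)
  amplitude * exp(-0.5 * (circ_dist180(grid, theta_sample) / sd_deg)^2)
}
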
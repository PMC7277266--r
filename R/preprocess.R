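#' Centred running mean with symmetric edge truncation
#'
#' At each sample the mean is taken over a centred window of `2h + 1`
#' samples, `h = floor(window_samples / 2)`; near the record ends the
#' half-width shrinks symmetrically so the window never extends beyond the
#' data (no padding). Implemented with cumulative sums, O(n).
#'
#' @param x Numeric vector.
#' @param window_samples Window length in samples (>= 2).
#' @return Numeric vector, same length as `x`.
#' @keywords internal
running_mean <- function(x, window_samples) {
  n <- length(x)
  h <- max(1L, floor(window_samples / 2))
  i <- seq_len(n)
  k <- pmin(h, i - 1L, n - i)
  s <- c(0, cumsum(x))
  (s[i + k + 1L] - s[i - k]) / (2L * k + 1L)
}

#' Subsample a 50 Hz series to 20 Hz
#'
#' Values are linearly interpolated from the bracketing 50 Hz samples onto
#' the 20 Hz grid spanning the same time range. A series already at 20 Hz
#' passes through untouched (idempotent).
#'
#' @param x Numeric vector sampled uniformly at `rate` Hz, first sample at
#'   t = 0.
#' @param rate Input rate, 20 or 50 Hz.
#' @return Numeric vector on the 20 Hz grid.
#' @export
subsample_to_20hz <- function(x, rate = 50) {
  if (rate == 20) return(x)
  if (rate != 50) stop("input rate must be 20 or 50 Hz", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least two samples to resample", call. = FALSE)
  t_in <- (seq_len(n) - 1) / rate
  t_out <- seq(0, t_in[n] + 1e-12, by = 1 / 20)
  stats::approx(t_in, x, xout = pmin(t_out, t_in[n]), method = "linear")$y
}

#' @rdname subsample_to_20hz
#' @param record A `sensor_record`; all six IMU channels are resampled.
#' @return `subsample_record()` returns the record at 20 Hz.
#' @export
subsample_record <- function(record) {
  if (record$imu_rate == 20) return(record)
  a <- apply(record$a, 2, subsample_to_20hz, rate = record$imu_rate)
  g <- apply(record$g, 2, subsample_to_20hz, rate = record$imu_rate)
  out <- sensor_record(a, g, record$depth, imu_rate = 20,
                       depth_rate = record$depth_rate,
                       individual_id = record$individual_id, t0 = record$t0)
  out
}

#' Static acceleration vector
#'
#' The gravity (static) component of the acceleration is obtained by
#' averaging each axis over a centred running window (default 2 s), the
#' smallest window for which the norm of the static vector stays close to
#' 1 g on gravity-dominated data.
#'
#' @param a n x 3 acceleration matrix (g units).
#' @param window Window length in seconds.
#' @param rate Sampling rate (Hz).
#' @return n x 3 matrix of static acceleration.
#' @export
static_acceleration <- function(a, window = 2, rate = 20) {
  w <- round(window * rate)
  if (w < 2) stop("static window must span at least 2 samples", call. = FALSE)
  out <- apply(as.matrix(a), 2, running_mean, window_samples = w)
  colnames(out) <- colnames(a)
  out
}

#' Dynamic acceleration and dynamic body acceleration
#'
#' The dynamic acceleration is `d = a - a_static`; DBA is the per-sample
#' Euclidean norm of `d`.
#'
#' @param a,a_static n x 3 matrices.
#' @return List with `d` (n x 3) and `dba` (length n, >= 0).
#' @export
dynamic_and_dba <- function(a, a_static) {
  a <- as.matrix(a); a_static <- as.matrix(a_static)
  if (!all(dim(a) == dim(a_static)))
    stop("acceleration and static matrices differ in size", call. = FALSE)
  d <- a - a_static
  list(d = d, dba = sqrt(rowSums(d^2)))
}

#' Rotational activity
#'
#' Per-sample Euclidean norm of the tri-axial angular velocity.
#'
#' @param g n x 3 angular-velocity matrix (rad s^-1).
#' @return Numeric vector, >= 0.
#' @export
rotational_activity <- function(g) sqrt(rowSums(as.matrix(g)^2))

#' Device tilt estimate
#'
#' The logger sits on the carapace pitched about the sway (y) axis so that
#' the camera faces the head, which biases the surge and heave channels.
#' The tilt angle is recovered from the direction of the static
#' acceleration vector: `theta = atan2(mean(a_static_x), mean(a_static_z))`,
#' averaged over caller-supplied flat/rest intervals when given, otherwise
#' over the whole record.
#'
#' @param record A `sensor_record`.
#' @param reference Optional `data.frame(start, end)` of flat intervals (s).
#' @param window Static-averaging window (s).
#' @return List of class `tilt_estimate` with `theta` (radians) and
#'   `source` (`"estimated"`).
#' @export
estimate_tilt <- function(record, reference = NULL, window = 2) {
  if (record_duration(record) < 2)
    stop("need at least 2 s of data to estimate tilt", call. = FALSE)
  ast <- static_acceleration(record$a, window = window, rate = record$imu_rate)
  keep <- rep(TRUE, nrow(ast))
  if (!is.null(reference)) {
    tm <- imu_times(record)
    keep <- rep(FALSE, nrow(ast))
    for (i in seq_len(nrow(reference)))
      keep <- keep | (tm >= reference$start[i] & tm < reference$end[i])
    if (!any(keep)) {
      warning("reference intervals do not overlap the record; ",
              "using the whole record", call. = FALSE)
      keep <- rep(TRUE, nrow(ast))
    }
  }
  theta <- atan2(mean(ast[keep, 1]), mean(ast[keep, 3]))
  structure(list(theta = theta, source = "estimated"),
            class = "tilt_estimate")
}

#' @rdname estimate_tilt
#' @param theta Known tilt angle in radians.
#' @export
tilt_estimate <- function(theta) {
  if (abs(theta) >= pi / 2)
    stop("|theta| must be below pi/2", call. = FALSE)
  structure(list(theta = theta, source = "configured"),
            class = "tilt_estimate")
}

rotate_about_sway <- function(m, theta, cols = c(1L, 3L)) {
  x <- m[, cols[1]]; z <- m[, cols[2]]
  m[, cols[1]] <- x * cos(theta) + z * sin(theta)
  m[, cols[2]] <- -x * sin(theta) + z * cos(theta)
  m
}

#' Correct device tilt
#'
#' Rotates the surge/heave pairs of both the accelerometer and the
#' gyroscope by `-theta` about the sway axis, bringing the channels back to
#' the animal's body frame. Sway channels are untouched; per-sample norms
#' are preserved.
#'
#' @param record A `sensor_record`.
#' @param tilt A `tilt_estimate` (or numeric angle in radians).
#' @return The corrected `sensor_record` (tilt stored in `$tilt`).
#' @export
correct_tilt <- function(record, tilt) {
  theta <- if (inherits(tilt, "tilt_estimate")) tilt$theta else as.numeric(tilt)
  record$a <- rotate_about_sway(record$a, -theta)
  record$g <- rotate_about_sway(record$g, -theta)
  record$tilt <- theta
  record
}

#' Vertical speed from the 1 Hz depth channel
#'
#' Central finite difference of depth over a window (default 3 s), with the
#' window clipped at the record ends. Depth is positive downward, so with
#' the default sign convention (`sign = 1`) positive vertical speed means
#' the animal is descending.
#'
#' @param depth 1 Hz depth vector (m).
#' @param window Differencing window (s).
#' @param rate Depth rate (Hz).
#' @param sign +1 (positive = descending) or -1 to flip.
#' @return Numeric vector, m s^-1, same length as `depth`.
#' @export
vertical_speed <- function(depth, window = 3, rate = 1, sign = 1) {
  n <- length(depth)
  if (n < 2) stop("need at least two depth samples", call. = FALSE)
  h <- max(1L, floor(window * rate / 2))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  sign * (depth[hi] - depth[lo]) / ((hi - lo) / rate)
}

#' Preprocess a logger record
#'
#' Runs the full preprocessing chain: subsample 50 Hz records to 20 Hz,
#' estimate (or accept) the device tilt and rotate the IMU channels into
#' the body frame, decompose acceleration into static and dynamic parts
#' (2 s running mean), and derive DBA, RA and vertical speed. Derived
#' channels are stored in `record$derived`.
#'
#' @param record A `sensor_record`.
#' @param cfg A `diveseg_config`.
#' @param tilt Optional known tilt (`tilt_estimate` or radians); estimated
#'   from the record when `NULL`.
#' @return The augmented `sensor_record`.
#' @export
preprocess_record <- function(record, cfg = diveseg_config(), tilt = NULL) {
  record <- subsample_record(record)
  if (is.null(tilt)) tilt <- estimate_tilt(record, window = cfg$static_window)
  record <- correct_tilt(record, tilt)
  ast <- static_acceleration(record$a, window = cfg$static_window,
                             rate = record$imu_rate)
  dd <- dynamic_and_dba(record$a, ast)
  record$derived <- list(
    a_static = ast,
    a_dyn = dd$d,
    dba = dd$dba,
    ra = rotational_activity(record$g),
    vspeed = vertical_speed(record$depth, window = cfg$depth_window,
                            rate = record$depth_rate, sign = cfg$vspeed_sign))
  record
}
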
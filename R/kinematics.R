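#' Down-sample and low-pass filter a raw IMU recording
#'
#' Decimates the raw trace to `target_rate` by integer-factor sample picking,
#' then low-pass filters every axis with an order-`order` Butterworth IIR
#' filter at `cutoff` Hz. Filtering is zero-phase (forward-backward) by
#' default, which squares the magnitude response and preserves the timing of
#' event-locked segments; a causal single-pass mode is available.
#'
#' @param raw an [imu_recording()]; its rate must be at least `target_rate`
#'   (no upsampling) and an integer multiple of it.
#' @param target_rate output rate, Hz.
#' @param cutoff low-pass cutoff frequency, Hz.
#' @param order Butterworth filter order.
#' @param zero_phase logical; forward-backward filtering (default) or causal.
#' @return an [imu_recording()] at `target_rate`.
#' @export
preprocess <- function(raw, target_rate = 100, cutoff = 20, order = 4,
                       zero_phase = TRUE) {
  stopifnot(inherits(raw, "imu_recording"))
  if (raw$sample_rate_hz < target_rate - 1e-9)
    stop("recording rate (", raw$sample_rate_hz,
         " Hz) is below the target rate; upsampling is not supported")
  factor <- raw$sample_rate_hz / target_rate
  if (abs(factor - round(factor)) > 0.01)
    stop("recording rate must be an integer multiple of target_rate")
  factor <- as.integer(round(factor))
  if (length(raw$time) < raw$sample_rate_hz)
    stop("recording too short: need at least 1 s for filter warm-up")

  idx <- seq(1L, length(raw$time), by = factor)
  accel <- raw$accel[idx, , drop = FALSE]
  gyro <- raw$gyro[idx, , drop = FALSE]
  time <- raw$time[idx]

  bf <- signal::butter(order, cutoff / (target_rate / 2), type = "low")
  apply_filter <- function(x) {
    if (zero_phase) {
      # filter about the initial/final levels so edge transients do not ring
      x0 <- x[1]; x1 <- x[length(x)]
      trend <- x0 + (x1 - x0) * seq(0, 1, length.out = length(x))
      trend + signal::filtfilt(bf, x - trend)
    } else {
      signal::filter(bf, x)
    }
  }
  accel <- apply(accel, 2, apply_filter)
  gyro <- apply(gyro, 2, apply_filter)
  imu_recording(time, accel, gyro, target_rate)
}

#' Estimate device orientation by complementary filtering
#'
#' Fuses gyroscope strapdown integration (high-frequency) with the
#' accelerometer-implied gravity direction (low-frequency) to track the
#' rotation from the device frame to a world frame whose z axis points
#' vertically up. Each sample the quaternion is propagated by the measured
#' angular rate, then tilted a fraction `accel_weight` of the way toward
#' agreement with the measured specific-force direction. The correction
#' rotation axis is horizontal, so heading (yaw) is driven by the gyroscope
#' alone and accumulates drift; over a task of about 90 s this drift is
#' negligible relative to the movements of interest. No magnetometer is used.
#'
#' The initial orientation is taken from the mean accelerometer vector over
#' the first `init_window_s` seconds (tilt) with yaw defined as zero.
#' Samples with near-zero specific-force norm (free fall) skip the
#' accelerometer correction.
#'
#' @param rec a preprocessed [imu_recording()].
#' @param accel_weight per-sample blending weight in (0, 1); the default
#'   0.02 at 100 Hz gives a correction time constant of about 0.5 s.
#' @param init_window_s initialization window, seconds.
#' @return an `orientation_series`: an n x 4 matrix of unit quaternions
#'   (columns w, x, y, z) mapping device to world frame.
#' @export
estimate_orientation <- function(rec, accel_weight = 0.02,
                                 init_window_s = 0.5) {
  stopifnot(inherits(rec, "imu_recording"))
  if (accel_weight <= 0 || accel_weight >= 1)
    stop("accel_weight must be in (0, 1)")
  n <- length(rec$time)
  dt <- 1 / rec$sample_rate_hz
  gyro_rad <- rec$gyro * (pi / 180)

  n_init <- max(1L, min(n, as.integer(round(init_window_s *
                                              rec$sample_rate_hz))))
  a0 <- colMeans(rec$accel[seq_len(n_init), , drop = FALSE])
  if (sqrt(sum(a0^2)) < 0.05)
    stop("initialization window has near-zero specific force")
  a0 <- a0 / sqrt(sum(a0^2))
  # minimal rotation putting measured gravity onto world up; no yaw component
  q <- quat_between(a0, c(0, 0, 1))

  Q <- matrix(0, n, 4L)
  w <- accel_weight
  # tight scalar loop: quaternion products are inlined to avoid per-sample
  # allocations (the series is a few thousand samples per recording)
  qw <- q[1L]; qx <- q[2L]; qy <- q[3L]; qz <- q[4L]
  gx <- gyro_rad[, 1L] * dt; gy <- gyro_rad[, 2L] * dt
  gz <- gyro_rad[, 3L] * dt
  A <- rec$accel
  for (i in seq_len(n)) {
    if (i > 1L) {
      # strapdown propagation: body-frame rate, right multiplication
      wx <- gx[i - 1L]; wy <- gy[i - 1L]; wz <- gz[i - 1L]
      ang <- sqrt(wx * wx + wy * wy + wz * wz)
      if (ang > 0) {
        s <- sin(ang / 2) / ang
        dw <- cos(ang / 2); dx <- wx * s; dy <- wy * s; dz <- wz * s
        nw <- qw * dw - qx * dx - qy * dy - qz * dz
        nx <- qw * dx + qx * dw + qy * dz - qz * dy
        ny <- qw * dy - qx * dz + qy * dw + qz * dx
        nz <- qw * dz + qx * dy - qy * dx + qz * dw
        nrm <- sqrt(nw * nw + nx * nx + ny * ny + nz * nz)
        qw <- nw / nrm; qx <- nx / nrm; qy <- ny / nrm; qz <- nz / nrm
      }
    }
    ax <- A[i, 1L]; ay <- A[i, 2L]; az <- A[i, 3L]
    anorm <- sqrt(ax * ax + ay * ay + az * az)
    if (anorm > 0.05) {
      ax <- ax / anorm; ay <- ay / anorm; az <- az / anorm
      # world-frame direction of measured specific force: q (x) a (x) q*
      tx <- 2 * (qy * az - qz * ay)
      ty <- 2 * (qz * ax - qx * az)
      tz <- 2 * (qx * ay - qy * ax)
      vx <- ax + qw * tx + (qy * tz - qz * ty)
      vy <- ay + qw * ty + (qz * tx - qx * tz)
      vz <- az + qw * tz + (qx * ty - qy * tx)
      # tilt error: rotation about a horizontal axis taking v toward +z
      cx <- vy; cy <- -vx                  # v x z
      snorm <- sqrt(cx * cx + cy * cy)
      if (snorm > 1e-12) {
        theta <- atan2(snorm, vz) * w
        s2 <- sin(theta / 2) / snorm
        cw <- cos(theta / 2); cxn <- cx * s2; cyn <- cy * s2
        nw <- cw * qw - cxn * qx - cyn * qy
        nx <- cw * qx + cxn * qw + cyn * qz
        ny <- cw * qy - cxn * qz + cyn * qw
        nz <- cw * qz + cxn * qy - cyn * qx
        nrm <- sqrt(nw * nw + nx * nx + ny * ny + nz * nz)
        qw <- nw / nrm; qx <- nx / nrm; qy <- ny / nrm; qz <- nz / nrm
      }
    }
    Q[i, 1L] <- qw; Q[i, 2L] <- qx; Q[i, 3L] <- qy; Q[i, 4L] <- qz
  }
  structure(Q, class = c("orientation_series", "matrix"))
}

#' Derive the six world-referenced kinematic channels
#'
#' Resolves the preprocessed accelerometer and gyroscope signals in the
#' world frame and derives the six series used for feature extraction:
#' horizontal acceleration magnitude `ah` (m/s^2), gravity-removed vertical
#' acceleration `av` (m/s^2), horizontal angular-velocity magnitude
#' `omegah` (deg/s), vertical angular-velocity component `omegav` (deg/s),
#' tilt angle `alpha` (deg, inclination of the device z axis from vertical)
#' and yaw angle `gamma` (deg). `gamma` is the unwrapped heading rotation
#' about the vertical, referenced to zero at the first sample and reported
#' as absolute deviation from the initial heading.
#'
#' @param rec a preprocessed [imu_recording()].
#' @param orient the matching orientation series from
#'   [estimate_orientation()].
#' @return a `kinematic_channels` list with elements `time`, `ah`, `av`,
#'   `omegah`, `omegav`, `alpha`, `gamma` and `rate`.
#' @export
derive_channels <- function(rec, orient) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- length(rec$time)
  if (nrow(orient) != n)
    stop("orientation series and recording lengths differ")
  Q <- unclass(orient)

  acc_w <- quat_rotate_rows(Q, rec$accel * STANDARD_GRAVITY)
  gyr_w <- quat_rotate_rows(Q, rec$gyro)

  ah <- sqrt(acc_w[, 1]^2 + acc_w[, 2]^2)
  av <- acc_w[, 3] - STANDARD_GRAVITY
  omegah <- sqrt(gyr_w[, 1]^2 + gyr_w[, 2]^2)
  omegav <- gyr_w[, 3]

  # device z axis expressed in world coordinates
  zw <- quat_rotate_rows(Q, matrix(rep(c(0, 0, 1), each = n), n, 3L))
  alpha <- acos(pmin(1, pmax(-1, zw[, 3]))) * (180 / pi)

  # heading of the device x axis projected on the horizontal plane
  xw <- quat_rotate_rows(Q, matrix(rep(c(1, 0, 0), each = n), n, 3L))
  yaw <- atan2(xw[, 2], xw[, 1])
  yaw <- unwrap_radians(yaw)
  gamma <- abs(yaw - yaw[1]) * (180 / pi)

  structure(list(time = rec$time, ah = ah, av = av, omegah = omegah,
                 omegav = omegav, alpha = alpha, gamma = gamma,
                 rate = rec$sample_rate_hz),
            class = "kinematic_channels")
}

# remove 2*pi discontinuities from a wrapped angle series
unwrap_radians <- function(x) {
  d <- diff(x)
  jumps <- c(0, cumsum(round(d / (2 * pi))))
  x - 2 * pi * jumps
}

#' @export
print.kinematic_channels <- function(x, ...) {
  cat(sprintf("<kinematic_channels> %d samples @ %g Hz (ah av omegah omegav alpha gamma)\n",
              length(x$time), x$rate))
  invisible(x)
}

# channel names in canonical extraction order
KINEMATIC_CHANNEL_NAMES <- c("ah", "av", "omegah", "omegav", "alpha", "gamma")
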
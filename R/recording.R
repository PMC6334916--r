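#' Construct a raw IMU recording
#'
#' Container for a raw inertial measurement unit trace: per-sample time,
#' 3-axis specific force and 3-axis angular velocity. Acceleration is stored
#' in units of g (1 g = 9.80665 m/s^2) and angular velocity in deg/s;
#' conversions to SI happen internally when kinematic channels are derived.
#'
#' @param time numeric vector of sample times in seconds, strictly increasing.
#' @param accel n x 3 numeric matrix of specific force.
#' @param gyro n x 3 numeric matrix of angular velocity.
#' @param sample_rate_hz nominal sample rate in Hz.
#' @param accel_unit unit of `accel`: `"g"` (default) or `"m/s^2"`.
#' @param gyro_unit unit of `gyro`: `"deg/s"` (default) or `"rad/s"`.
#' @return An object of class `imu_recording` with accel in g and gyro in
#'   deg/s regardless of input units.
#' @export
imu_recording <- function(time, accel, gyro, sample_rate_hz,
                          accel_unit = c("g", "m/s^2"),
                          gyro_unit = c("deg/s", "rad/s")) {
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stop("accel and gyro must have exactly 3 columns")
  n <- length(time)
  if (nrow(accel) != n || nrow(gyro) != n)
    stop("time, accel and gyro must have equal lengths")
  if (n < 2L) stop("recording must contain at least 2 samples")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  if (accel_unit == "m/s^2") accel <- accel / STANDARD_GRAVITY
  if (gyro_unit == "rad/s") gyro <- gyro * (180 / pi)
  structure(
    list(time = as.numeric(time), accel = unname(accel), gyro = unname(gyro),
         sample_rate_hz = sample_rate_hz),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %g Hz, %.2f-%.2f s\n",
              length(x$time), x$sample_rate_hz, x$time[1],
              x$time[length(x$time)]))
  invisible(x)
}

# 1 g in m/s^2
STANDARD_GRAVITY <- 9.80665

#' Read a raw IMU recording from delimited text
#'
#' Expects a header with columns `time_s, ax_g, ay_g, az_g, gx_dps, gy_dps,
#' gz_dps` (other units may be declared via `accel_unit`/`gyro_unit`, in
#' which case column names are taken positionally after `time_s`).
#'
#' @param path CSV file path.
#' @param sample_rate_hz nominal rate; if `NULL`, estimated as the median
#'   reciprocal time step.
#' @inheritParams imu_recording
#' @return an [imu_recording()].
#' @export
read_imu_csv <- function(path, sample_rate_hz = NULL,
                         accel_unit = "g", gyro_unit = "deg/s") {
  df <- utils::read.csv(path)
  required <- c("time_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")
  if (all(required %in% names(df))) {
    df <- df[required]
  } else if (ncol(df) >= 7L) {
    df <- df[, 1:7]
  } else {
    stop("IMU CSV must have columns: ", paste(required, collapse = ", "))
  }
  if (is.null(sample_rate_hz))
    sample_rate_hz <- 1 / stats::median(diff(df[[1]]))
  imu_recording(df[[1]], as.matrix(df[, 2:4]), as.matrix(df[, 5:7]),
                sample_rate_hz, accel_unit = accel_unit,
                gyro_unit = gyro_unit)
}

#' Write a raw IMU recording as CSV
#'
#' @param rec an [imu_recording()].
#' @param path output file path.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(time_s = rec$time,
                   ax_g = rec$accel[, 1], ay_g = rec$accel[, 2],
                   az_g = rec$accel[, 3],
                   gx_dps = rec$gyro[, 1], gy_dps = rec$gyro[, 2],
                   gz_dps = rec$gyro[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a startle-event annotation
#'
#' Event annotations are JSON objects `{"startle_time_s": <number>}` paired
#' with each recording; the startle moment is an input, not detected from
#' the signal.
#'
#' @param path JSON file path.
#' @return the startle time in seconds.
#' @export
read_event_json <- function(path) {
  ev <- jsonlite::read_json(path)
  if (is.null(ev$startle_time_s))
    stop("event file must contain startle_time_s")
  as.numeric(ev$startle_time_s)
}

#' @rdname read_event_json
#' @param startle_time_s the startle moment, seconds in recording time.
#' @export
write_event_json <- function(startle_time_s, path) {
  jsonlite::write_json(list(startle_time_s = startle_time_s), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
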
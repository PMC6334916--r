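#' Specification of a synthetic two-group cohort
#'
#' Defines the study conditions the simulator emulates: a cohort of 21
#' diagnosed children and 41 controls whose diagnostic groups differ in the
#' yaw turn executed during the second half of the Potential Threat phase.
#' Diagnosed subjects turn away from the threat, ending the phase facing
#' roughly backwards (final yaw centered at 160 deg), while controls keep
#' facing forward (final yaw centered at 30 deg and capped below 60 deg).
#' Both groups receive an identical startle-locked acceleration jolt, since
#' the startle response itself does not separate the groups.
#'
#' @param n_case,n_control group sizes.
#' @param sample_rate_hz recording rate of the synthetic device.
#' @param duration_s recording length (must span all three phases).
#' @param startle_time_s startle moment in recording time.
#' @param case_yaw_mean,case_yaw_sd final-yaw distribution of diagnosed
#'   subjects, degrees.
#' @param case_yaw_range,control_yaw_range hard clamps applied to the
#'   final-yaw draws; the control default `[0, 58]` keeps controls below
#'   60 deg by construction, the case default `[90, 180]` keeps diagnosed
#'   subjects turned away. Setting the case parameters and range equal to
#'   the control values yields a zero-effect cohort.
#' @param control_yaw_mean,control_yaw_sd final-yaw distribution of
#'   controls, degrees.
#' @param turn_onset_frac onset of the turn as a fraction of the Potential
#'   Threat phase.
#' @param accel_noise_sd_g accelerometer white-noise SD, g.
#' @param gyro_noise_sd_dps gyroscope white-noise SD, deg/s.
#' @param sway_amp_deg amplitude of ambient postural sway (slow tilt
#'   oscillation and yaw wander), degrees.
#' @param jolt_amp_g amplitude of the 0.3 s, ~11 Hz startle jolt, g.
#' @param seed master seed; every subject derives its own substream.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_case = 21L, n_control = 41L, sample_rate_hz = 100,
                        duration_s = 52, startle_time_s = 28,
                        case_yaw_mean = 160, case_yaw_sd = 30,
                        case_yaw_range = c(90, 180),
                        control_yaw_mean = 30, control_yaw_sd = 20,
                        control_yaw_range = c(0, 58),
                        turn_onset_frac = 0.5,
                        accel_noise_sd_g = 0.02, gyro_noise_sd_dps = 1,
                        sway_amp_deg = 2, jolt_amp_g = 0.3, seed = 1L) {
  spec <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
               sample_rate_hz = sample_rate_hz, duration_s = duration_s,
               startle_time_s = startle_time_s,
               case_yaw_mean = case_yaw_mean, case_yaw_sd = case_yaw_sd,
               case_yaw_range = case_yaw_range,
               control_yaw_mean = control_yaw_mean,
               control_yaw_sd = control_yaw_sd,
               control_yaw_range = control_yaw_range,
               turn_onset_frac = turn_onset_frac,
               accel_noise_sd_g = accel_noise_sd_g,
               gyro_noise_sd_dps = gyro_noise_sd_dps,
               sway_amp_deg = sway_amp_deg, jolt_amp_g = jolt_amp_g,
               seed = as.integer(seed))
  if (spec$n_case < 1L || spec$n_control < 1L) stop("group sizes must be >= 1")
  if (spec$accel_noise_sd_g < 0 || spec$gyro_noise_sd_dps < 0 ||
      spec$sway_amp_deg < 0)
    stop("noise amplitudes must be nonnegative")
  if (spec$turn_onset_frac < 0 || spec$turn_onset_frac > 1)
    stop("turn_onset_frac must be in [0, 1]")
  if (spec$startle_time_s - 23 < 1 ||
      spec$startle_time_s + 23 > spec$duration_s)
    stop("recording must cover all three phases around the startle")
  structure(spec, class = "cohort_spec")
}

# smooth prescribed yaw trajectory, degrees: logistic turn of `final` deg
# starting at the given onset within the Potential Threat phase
yaw_trajectory <- function(t, spec, final_yaw, direction) {
  t_on <- (spec$startle_time_s - 23) + spec$turn_onset_frac * 20
  t_mid <- t_on + 2.5                   # logistic midpoint; turn lasts ~5 s
  direction * final_yaw * stats::plogis((t - t_mid) / 0.8)
}

#' Simulate one subject's raw IMU recording
#'
#' Works in the inverse direction: a world-frame orientation trajectory
#' (prescribed yaw turn + slow postural sway) is composed per sample, then
#' differentiated into exact device-frame gyroscope rates and used to
#' resolve gravity into device-frame accelerometer readings, to which the
#' startle jolt and sensor noise are added. Ground truth (the prescribed
#' final yaw) is therefore known exactly.
#'
#' @param group `"case"` or `"control"`.
#' @param spec a [cohort_spec()].
#' @param seed integer seed for this subject's substream.
#' @return list with `recording` (an [imu_recording()]), `startle_time_s`,
#'   `group` and `final_yaw_deg` (prescribed ground truth).
#' @export
simulate_subject <- function(group = c("control", "case"), spec = cohort_spec(),
                             seed = 1L) {
  group <- match.arg(group)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  rate <- spec$sample_rate_hz
  dt <- 1 / rate
  t <- seq(0, spec$duration_s, by = dt)
  n <- length(t)

  if (group == "case") {
    rng <- spec$case_yaw_range
    final_yaw <- min(rng[2], max(rng[1], stats::rnorm(1, spec$case_yaw_mean,
                                                      spec$case_yaw_sd)))
  } else {
    rng <- spec$control_yaw_range
    final_yaw <- min(rng[2], max(rng[1],
                                 stats::rnorm(1, spec$control_yaw_mean,
                                              spec$control_yaw_sd)))
  }
  direction <- sample(c(-1, 1), 1)
  psi <- yaw_trajectory(t, spec, final_yaw, direction) * pi / 180

  # ambient sway: slow tilt oscillation about both horizontal axes plus a
  # yaw wander at matching amplitude
  amp <- spec$sway_amp_deg * pi / 180
  f1 <- stats::runif(1, 0.2, 0.4); p1 <- stats::runif(1, 0, 2 * pi)
  f2 <- stats::runif(1, 0.2, 0.4); p2 <- stats::runif(1, 0, 2 * pi)
  f3 <- stats::runif(1, 0.05, 0.15); p3 <- stats::runif(1, 0, 2 * pi)
  th_x <- amp * sin(2 * pi * f1 * t + p1)
  th_y <- amp * sin(2 * pi * f2 * t + p2)
  psi <- psi + amp * sin(2 * pi * f3 * t + p3)

  # device-to-world quaternion: Rz(psi) * Rx(th_x) * Ry(th_y), all half-angles
  Q <- compose_zxy(psi, th_x, th_y)

  # exact discrete body rates from successive quaternions
  gyro <- body_rates(Q, dt)             # rad/s, n x 3

  # specific force: gravity resolved into the device frame (+ jolt), in g
  grav_w <- matrix(rep(c(0, 0, 1), each = n), n, 3L)
  jolt <- rep(0, n)
  in_jolt <- t >= spec$startle_time_s & t < spec$startle_time_s + 0.3
  tj <- t[in_jolt] - spec$startle_time_s
  jolt[in_jolt] <- spec$jolt_amp_g * exp(-tj / 0.08) * sin(2 * pi * 11 * tj)
  grav_w[, 1] <- grav_w[, 1] + jolt     # horizontal world-frame burst
  Qc <- cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4])
  accel <- quat_rotate_rows(Qc, grav_w)

  accel <- accel + matrix(stats::rnorm(3 * n, 0, spec$accel_noise_sd_g), n, 3L)
  gyro <- gyro * (180 / pi) +
    matrix(stats::rnorm(3 * n, 0, spec$gyro_noise_sd_dps), n, 3L)

  list(recording = imu_recording(t, accel, gyro, rate),
       startle_time_s = spec$startle_time_s, group = group,
       final_yaw_deg = final_yaw)
}

# compose Rz(psi) Rx(thx) Ry(thy) as quaternions, vectorized over samples
compose_zxy <- function(psi, thx, thy) {
  hz <- psi / 2; hx <- thx / 2; hy <- thy / 2
  cz <- cos(hz); sz <- sin(hz)
  cx <- cos(hx); sx <- sin(hx)
  cy <- cos(hy); sy <- sin(hy)
  # qz (x) qx
  w1 <- cz * cx; x1 <- cz * sx; y1 <- sz * sx; z1 <- sz * cx
  # (qz qx) (x) qy
  cbind(w1 * cy - y1 * sy,
        x1 * cy + z1 * sy,
        y1 * cy + w1 * sy,
        z1 * cy - x1 * sy)
}

# discrete body-frame angular rate (rad/s) from a quaternion trajectory:
# delta = conj(q_i) (x) q_{i+1}, rate = axis * angle / dt
body_rates <- function(Q, dt) {
  n <- nrow(Q)
  a <- Q[-n, , drop = FALSE]
  b <- Q[-1L, , drop = FALSE]
  dw <- a[, 1] * b[, 1] + a[, 2] * b[, 2] + a[, 3] * b[, 3] + a[, 4] * b[, 4]
  dx <- a[, 1] * b[, 2] - a[, 2] * b[, 1] - a[, 3] * b[, 4] + a[, 4] * b[, 3]
  dy <- a[, 1] * b[, 3] + a[, 2] * b[, 4] - a[, 3] * b[, 1] - a[, 4] * b[, 2]
  dz <- a[, 1] * b[, 4] - a[, 2] * b[, 3] + a[, 3] * b[, 2] - a[, 4] * b[, 1]
  # enforce shortest arc
  flip <- dw < 0
  dw[flip] <- -dw[flip]; dx[flip] <- -dx[flip]
  dy[flip] <- -dy[flip]; dz[flip] <- -dz[flip]
  vnorm <- sqrt(dx^2 + dy^2 + dz^2)
  ang <- 2 * atan2(vnorm, dw)
  scale <- ifelse(vnorm > 1e-15, ang / (vnorm * dt), 0)
  out <- cbind(dx * scale, dy * scale, dz * scale)
  rbind(out, out[n - 1L, , drop = FALSE])  # hold last rate
}

#' Simulate a labeled cohort of raw recordings
#'
#' Draws `n_case + n_control` subjects from [simulate_subject()], each with
#' a deterministic per-subject substream derived from the master seed, and
#' returns recordings, labels and a manifest.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort` list: `subjects` (list of [simulate_subject()]
#'   results), `labels` (1 = case), `manifest` (data.frame subject_id,
#'   group, seed).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  n <- spec$n_case + spec$n_control
  groups <- rep(c("case", "control"), c(spec$n_case, spec$n_control))
  seeds <- subject_seeds(spec$seed, n)
  subjects <- lapply(seq_len(n), function(i)
    simulate_subject(groups[i], spec, seed = seeds[i]))
  structure(list(
    subjects = subjects,
    labels = as.integer(groups == "case"),
    manifest = data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                          group = groups, seed = seeds,
                          stringsAsFactors = FALSE)),
    class = "cohort")
}

# deterministic per-subject substream seeds, kept within 32-bit range
subject_seeds <- function(master_seed, n) {
  as.integer((as.numeric(master_seed) * 10007 + seq_len(n) * 101) %%
               .Machine$integer.max)
}

#' Run the full signal pipeline on a simulated cohort
#'
#' Preprocesses each recording, estimates orientation, derives the six
#' kinematic channels, segments the three phases and extracts the
#' 174-value feature vector per phase.
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param phase one of `"PotentialThreat"`, `"Startle"`,
#'   `"ResponseModulation"` or `"all"`.
#' @param accel_weight complementary-filter blending weight.
#' @return a `feature_table` data.frame: `subject_id`, `phase`,
#'   `diagnosis`, then 174 feature columns.
#' @export
cohort_feature_table <- function(cohort, phase = "PotentialThreat",
                                 accel_weight = 0.02) {
  stopifnot(inherits(cohort, "cohort"))
  phases <- if (identical(phase, "all")) phase_windows()$phase else phase
  rows <- list()
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    feats <- extract_subject_features(sub$recording, sub$startle_time_s,
                                      accel_weight = accel_weight)
    for (ph in phases) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = cohort$manifest$subject_id[i], phase = ph,
        diagnosis = cohort$labels[i],
        as.list(feats[[ph]]), check.names = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Raw recording to per-phase feature vectors
#'
#' Convenience wrapper chaining [preprocess()], [estimate_orientation()],
#' [derive_channels()], [segment_phases()] and [extract_phase_features()].
#'
#' @param recording an [imu_recording()].
#' @param startle_time_s the annotated startle moment.
#' @param accel_weight complementary-filter blending weight.
#' @return named list of three 174-value feature vectors, one per phase.
#' @export
extract_subject_features <- function(recording, startle_time_s,
                                     accel_weight = 0.02) {
  rec <- preprocess(recording)
  orient <- estimate_orientation(rec, accel_weight = accel_weight)
  ch <- derive_channels(rec, orient)
  segs <- segment_phases(ch, startle_time_s)
  lapply(segs, extract_phase_features)
}

#' Simulate a pre-extracted feature table directly
#'
#' Statistical-surface shortcut: instead of synthesizing raw signals, draw
#' a subjects x features table of standard-normal noise and shift the
#' diagnosed group's mean on selected ("planted") features. Useful for
#' testing the selection/evaluation/chance stages at scale, where the
#' signal half of the pipeline would only add runtime.
#'
#' @param n_case,n_control group sizes.
#' @param feature_names_ feature column names (default the 174 kinematic
#'   names).
#' @param planted named numeric vector: between-class mean gap in SD units
#'   keyed by feature name (empty = pure-noise null table).
#' @param seed integer seed.
#' @return list with `table` (matrix subjects x features) and `labels`.
#' @export
simulate_feature_table <- function(n_case = 21L, n_control = 41L,
                                   feature_names_ = feature_names(),
                                   planted = numeric(0), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_case + n_control
  p <- length(feature_names_)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, feature_names_))
  labels <- rep(c(1L, 0L), c(n_case, n_control))
  if (length(planted)) {
    bad <- setdiff(names(planted), feature_names_)
    if (length(bad)) stop("unknown planted features: ",
                          paste(bad, collapse = ", "))
    for (f in names(planted))
      X[labels == 1L, f] <- X[labels == 1L, f] + planted[[f]]
  }
  list(table = X, labels = labels)
}

# save/restore the global RNG state so seeded simulators do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' The ten yaw-family feature names
#'
#' The features reported as most discriminative in the Potential Threat
#' phase: the 6th spectral peak location of `av`, the range of `omegav`
#' (vertical angular velocity is essentially yaw rate) and eight
#' yaw-channel features.
#'
#' @return character vector of length 10.
#' @export
yaw_family_features <- function() {
  c("av_peak6_loc", "omegav_range",
    "gamma_mean", "gamma_rms", "gamma_range", "gamma_max",
    "gamma_autocorr0_height", "gamma_peak1_height", "gamma_peak6_height",
    "gamma_band2_power")
}
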
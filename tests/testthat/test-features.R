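# The 29-feature channel descriptor and the 174-feature phase vector

test_that("feature schema: 29 names per channel, 174 per phase, stable", {
  expect_length(feature_names("gamma"), 29L)
  expect_length(feature_names(), 174L)
  expect_identical(feature_names(), feature_names())
  x <- rnorm(500)
  v <- extract_channel_features(x, 100)
  expect_length(v, 29L)
  expect_identical(names(v), sub("^gamma_", "", feature_names("gamma")))
  expect_true(all(is.finite(v)))
})

test_that("constant series maps to the degenerate closed forms", {
  v <- extract_channel_features(rep(3, 400), 100)
  expect_equal(v[["mean"]], 3)
  expect_equal(v[["rms"]], 3)
  expect_equal(v[["sd"]], 0)
  expect_equal(v[["range"]], 0)
  expect_equal(v[["max"]], 3)
  expect_equal(v[["min"]], 3)
  expect_equal(v[["skew"]], 0)       # degenerate rule
  expect_equal(v[["kurtosis"]], 0)   # degenerate rule
  expect_equal(v[["autocorr0_height"]], 0)
  expect_equal(unname(v[paste0("band", 1:7, "_power")]), rep(0, 7))
  expect_equal(unname(v[paste0("peak", 1:6, "_loc")]), rep(0, 6))
})

test_that("kurtosis is non-excess and skew matches moment formulas", {
  set.seed(1)
  x <- rnorm(200000)
  v <- extract_channel_features(x, 100)
  expect_equal(v[["kurtosis"]], 3, tolerance = 0.05)
  expect_equal(v[["skew"]], 0, tolerance = 0.05)
  y <- rexp(5000)
  w <- extract_channel_features(y, 100)
  m <- mean(y); s2 <- mean((y - m)^2)
  expect_equal(w[["skew"]], mean((y - m)^3) / s2^1.5)
  expect_equal(w[["kurtosis"]], mean((y - m)^4) / s2^2)
})

test_that("a 1 Hz unit sinusoid has the Parseval-predicted spectrum", {
  t <- seq(0, 20 - 0.01, by = 0.01)
  x <- sin(2 * pi * t)
  v <- extract_channel_features(x, 100)
  expect_equal(v[["rms"]], sqrt(0.5), tolerance = 1e-3)
  total <- sum(v[paste0("band", 1:7, "_power")])
  expect_gt(v[["band2_power"]] / total, 0.99)
  expect_equal(v[["peak1_loc"]], 1, tolerance = 0.05)
  expect_equal(v[["autocorr0_height"]], 0.5, tolerance = 1e-6)
  # single spectral line: peaks 2..6 padded with zeros
  expect_equal(unname(v[paste0("peak", 2:6, "_loc")]), rep(0, 5))
  expect_equal(unname(v[paste0("peak", 2:6, "_height")]), rep(0, 5))
})

test_that("band powers partition the total spectral power", {
  set.seed(7)
  for (n in c(1000, 1001, 2000)) {
    x <- rnorm(n)
    total <- sum(vapply(1:7, function(b) {
      edges <- c(0, 0.5, 1.5, 5, 10, 15, 20, 50)
      band_power(x, 100, edges[b], edges[b + 1])
    }, numeric(1)))
    expect_equal(total, mean((x - mean(x))^2), tolerance = 1e-9)
  }
  expect_error(band_power(rnorm(100), 100, 30, 20), "band edges")
  expect_equal(band_power(rep(0, 500), 100, 5, 10), 0)
})

test_that("an 8 Hz tone concentrates in the 5-10 Hz band", {
  t <- seq(0, 20 - 0.01, by = 0.01)
  x <- sin(2 * pi * 8 * t)
  pb <- vapply(1:7, function(b) {
    edges <- c(0, 0.5, 1.5, 5, 10, 15, 20, 50)
    band_power(x, 100, edges[b], edges[b + 1])
  }, numeric(1))
  expect_gt(pb[4] / sum(pb), 0.99)
  expect_true(all(pb[-4] / sum(pb) < 0.01))
})

test_that("spectral peaks are ordered by ascending frequency", {
  t <- seq(0, 20 - 0.01, by = 0.01)
  x <- sin(2 * pi * 2 * t) + sin(2 * pi * 6 * t)
  pk <- spectral_peaks(x, 100, k = 6)
  expect_equal(pk$loc[1], 2, tolerance = 0.05)
  expect_equal(pk$loc[2], 6, tolerance = 0.05)
  expect_equal(pk$loc[3:6], rep(0, 4))
  # heights of the two tones are equal
  expect_equal(pk$height[1], pk$height[2], tolerance = 1e-6)
})

test_that("autocorrelation zero-lag height matches closed forms", {
  expect_equal(autocorr_zero_height(rep(2, 50)), 0)
  t <- seq(0, 10 - 0.01, by = 0.01)      # integer number of cycles
  expect_equal(autocorr_zero_height(sin(2 * pi * t)), 0.5, tolerance = 1e-6)
  set.seed(3)
  expect_equal(autocorr_zero_height(rnorm(2000)), 1, tolerance = 0.1)
  expect_error(autocorr_zero_height(numeric(0)), "empty")
})

test_that("features scale as expected under series scaling", {
  set.seed(11)
  x <- rnorm(600) + sin(seq(0, 30, length.out = 600))
  c_ <- 2.5
  v1 <- extract_channel_features(x, 100)
  v2 <- extract_channel_features(c_ * x, 100)
  linear <- c("mean", "rms", "range", "max", "min", "sd")
  for (f in linear) expect_equal(v2[[f]], c_ * v1[[f]], tolerance = 1e-9)
  invariant <- c("skew", "kurtosis", "peak2rms",
                 paste0("peak", 1:6, "_loc"))
  for (f in invariant) expect_equal(v2[[f]], v1[[f]], tolerance = 1e-9)
  quadratic <- c(paste0("band", 1:7, "_power"),
                 paste0("peak", 1:6, "_height"), "autocorr0_height")
  for (f in quadratic)
    expect_equal(v2[[f]], c_^2 * v1[[f]], tolerance = 1e-9)
})

test_that("phase extraction is deterministic and ordered by channel", {
  sub <- simulate_subject("control", cohort_spec(), seed = 9)
  f1 <- extract_subject_features(sub$recording, sub$startle_time_s)
  f2 <- extract_subject_features(sub$recording, sub$startle_time_s)
  expect_identical(f1, f2)
  expect_identical(names(f1$PotentialThreat), feature_names())
  expect_length(f1$PotentialThreat, 174L)
})

test_that("larger yaw excursions give larger gamma statistics", {
  spec <- cohort_spec(accel_noise_sd_g = 0, gyro_noise_sd_dps = 0,
                      sway_amp_deg = 0)
  big <- simulate_subject("case", cohort_spec(
    case_yaw_mean = 175, case_yaw_sd = 1, accel_noise_sd_g = 0,
    gyro_noise_sd_dps = 0, sway_amp_deg = 0), seed = 2)
  small <- simulate_subject("control", spec, seed = 2)
  fb <- extract_subject_features(big$recording, big$startle_time_s)
  fs <- extract_subject_features(small$recording, small$startle_time_s)
  for (f in c("gamma_max", "gamma_range", "gamma_rms", "gamma_mean"))
    expect_gt(fb$PotentialThreat[[f]], fs$PotentialThreat[[f]])
})

test_that("too-short or non-finite series are rejected", {
  expect_error(extract_channel_features(rnorm(100), 100), "2 s")
  expect_error(extract_channel_features(c(rnorm(400), NA), 100),
               "non-finite")
})
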
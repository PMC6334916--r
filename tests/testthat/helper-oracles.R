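# Independent reference implementations used as oracles; deliberately
# brute-force and kept separate from the package code paths they check.

# AUC by exhaustive pair counting with half credit for ties
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# two-class Davies-Bouldin score, written straight from the formula
brute_db <- function(values, labels) {
  x1 <- values[labels == 1]
  x0 <- values[labels == 0]
  c1 <- sum(x1) / length(x1)
  c0 <- sum(x0) / length(x0)
  if (c1 == c0) return(Inf)
  s1 <- sum(abs(x1 - c1)) / length(x1)
  s0 <- sum(abs(x0 - c0)) / length(x0)
  (s1 + s0) / abs(c1 - c0)
}

# magnitude response of the digital Butterworth low-pass designed by
# bilinear transform with cutoff pre-warping (squared for forward-backward
# filtering)
butter_digital_gain <- function(f, fs, fc, order, zero_phase = TRUE) {
  h2 <- 1 / (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * order))
  if (zero_phase) h2 else sqrt(h2)
}

# measure the steady-state amplitude of a filtered sinusoid away from the
# edges of the recording
sine_response <- function(freq, fs = 100, raw_fs = 300, dur = 20) {
  t <- seq(0, dur, by = 1 / raw_fs)
  n <- length(t)
  sig <- sin(2 * pi * freq * t)
  rec <- imu_recording(t, cbind(sig, 0, 1), matrix(0, n, 3), raw_fs)
  out <- preprocess(rec)
  mid <- out$time > dur * 0.25 & out$time < dur * 0.75
  max(abs(out$accel[mid, 1]))
}

# a small fully synthetic feature table with one strongly separating column
planted_table <- function(n_case = 8, n_control = 12, p = 30, gap = 3,
                          seed = 1) {
  simulate_feature_table(n_case, n_control,
                         feature_names_ = paste0("f", seq_len(p)),
                         planted = stats::setNames(gap, "f1"), seed = seed)
}
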
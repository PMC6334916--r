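#' Task phase definitions
#'
#' The mood-induction task is segmented into three conceptual phases around
#' the startle moment (time 0): Potential Threat `[-23, -3)` s, Startle
#' `[-3, +3)` s and Response Modulation `[+3, +23)` s. Windows are half-open
#' on the right so boundary samples belong to the later phase and, at
#' 100 Hz, phase lengths are exactly 2000, 600 and 2000 samples.
#'
#' @format a data.frame with columns `phase`, `start_s`, `end_s`.
#' @export
phase_windows <- function() {
  data.frame(phase = c("PotentialThreat", "Startle", "ResponseModulation"),
             start_s = c(-23, -3, 3),
             end_s = c(-3, 3, 23),
             stringsAsFactors = FALSE)
}

#' Segment kinematic channels into the three task phases
#'
#' @param channels a `kinematic_channels` object from [derive_channels()].
#' @param startle_time the startle moment, seconds in recording time.
#' @return a named list of three `phase_segment` objects
#'   (`PotentialThreat`, `Startle`, `ResponseModulation`), each holding the
#'   channels restricted to its window plus the window itself.
#' @export
segment_phases <- function(channels, startle_time) {
  stopifnot(inherits(channels, "kinematic_channels"))
  wins <- phase_windows()
  t <- channels$time
  rate <- channels$rate
  out <- vector("list", nrow(wins))
  names(out) <- wins$phase
  # index arithmetic keeps lengths exact at the nominal rate
  for (i in seq_len(nrow(wins))) {
    t_lo <- startle_time + wins$start_s[i]
    t_hi <- startle_time + wins$end_s[i]
    i_lo <- as.integer(round((t_lo - t[1]) * rate)) + 1L
    n_seg <- as.integer(round((wins$end_s[i] - wins$start_s[i]) * rate))
    i_hi <- i_lo + n_seg - 1L
    if (i_lo < 1L || i_hi > length(t))
      stop(sprintf(
        "recording does not cover the %s phase [%g, %g) s around the startle",
        wins$phase[i], wins$start_s[i], wins$end_s[i]))
    idx <- i_lo:i_hi
    seg_channels <- structure(
      list(time = t[idx], ah = channels$ah[idx], av = channels$av[idx],
           omegah = channels$omegah[idx], omegav = channels$omegav[idx],
           alpha = channels$alpha[idx], gamma = channels$gamma[idx],
           rate = rate),
      class = "kinematic_channels")
    out[[i]] <- structure(
      list(phase = wins$phase[i], channels = seg_channels,
           window = c(wins$start_s[i], wins$end_s[i])),
      class = "phase_segment")
  }
  out
}

#' @export
print.phase_segment <- function(x, ...) {
  cat(sprintf("<phase_segment> %s [%g, %g) s, %d samples\n", x$phase,
              x$window[1], x$window[2], length(x$channels$time)))
  invisible(x)
}
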
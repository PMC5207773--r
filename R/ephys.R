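# Synaptic-physiology metrics for evoked EPSC traces. EPSCs are
# negative-going currents recorded in voltage clamp; all metrics are invariant
# to a constant holding-current offset.

sample_window <- function(trace, from_ms, to_ms) {
  which(trace$time_ms >= from_ms & trace$time_ms < to_ms)
}

# peak search window for stimulus k: [onset, onset + ISI), or the tail for
# the last stimulus
stim_window <- function(trace, k, max_ms = NULL) {
  stim <- trace$stimulus_times_ms
  end <- if (k < length(stim)) stim[k + 1] else {
    stim[k] + (max_ms %||% (if (length(stim) > 1)
      diff(stim)[1] else 50))
  }
  sample_window(trace, stim[k], end)
}

#' Detect a positive responder
#'
#' A recording counts as a responder when any post-stimulus EPSC peak
#' magnitude exceeds 6 times the standard deviation of the baseline (strictly
#' greater).
#'
#' @param trace an `epsc_trace`.
#' @param baseline_ms window length (ms) immediately before the first
#'   stimulus used as baseline.
#' @param sd_floor_pa absolute floor used instead of the baseline SD when the
#'   baseline is degenerate (zero variance, e.g. a noiseless synthetic trace).
#' @param sd_factor threshold multiple of the baseline SD (default 6).
#' @return `TRUE` or `FALSE`.
#' @export
detect_responder <- function(trace, baseline_ms = 50, sd_floor_pa = 1,
                             sd_factor = 6) {
  stim1 <- trace$stimulus_times_ms[1]
  base <- sample_window(trace, stim1 - baseline_ms, stim1)
  if (length(base) < 2) stop("detect_responder: baseline window is empty")
  mu <- mean(trace$current[base])
  s <- stats::sd(trace$current[base])
  if (!is.finite(s) || s == 0) s <- sd_floor_pa
  peaks <- vapply(seq_along(trace$stimulus_times_ms), function(k) {
    w <- stim_window(trace, k)
    if (!length(w)) return(0)
    max(abs(trace$current[w] - mu))
  }, numeric(1))
  any(peaks > sd_factor * s)
}

#' EPSC amplitude and kinetics
#'
#' Amplitude is the peak current minus the pre-stimulus baseline. Rise time is
#' the 10%-to-90% crossing interval on the rising phase; decay time the
#' 90%-to-10% interval on the falling phase, measured relative to the
#' post-EPSC plateau so that a sustained slow current does not inflate the
#' decay.
#'
#' @param trace an `epsc_trace`.
#' @param stimulus_index which stimulus to analyze.
#' @param baseline_ms pre-stimulus baseline window (ms).
#' @param plateau_window_ms window (ms, relative to stimulus onset) whose
#'   mean current defines the post-EPSC plateau for the decay measurement.
#' @return A list with `amplitude_pa` (negative), `rise_ms`, `decay_ms` and
#'   `peak_time_ms`; kinetics are `NA` when the peak is not resolved.
#' @export
epsc_kinetics <- function(trace, stimulus_index = 1, baseline_ms = 10,
                          plateau_window_ms = c(40, 50)) {
  onset <- trace$stimulus_times_ms[stimulus_index]
  base <- sample_window(trace, onset - baseline_ms, onset)
  mu <- mean(trace$current[base])
  w <- stim_window(trace, stimulus_index)
  if (!length(w)) stop("epsc_kinetics: no samples in the stimulus window")
  seg <- trace$current[w] - mu
  tt <- trace$time_ms[w]
  ipk <- which.min(seg)
  amp <- seg[ipk]
  if (ipk == length(seg) || amp >= 0) {
    return(list(amplitude_pa = amp, rise_ms = NA_real_, decay_ms = NA_real_,
                peak_time_ms = tt[ipk]))
  }
  cross <- function(y, t, level, idx) {
    # first crossing of `level` within index range, linearly interpolated
    for (i in idx) {
      if ((y[i] - level) * (y[i + 1] - level) <= 0 && y[i] != y[i + 1]) {
        return(t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i]))
      }
    }
    NA_real_
  }
  t10 <- cross(seg, tt, 0.1 * amp, seq_len(ipk - 1))
  t90 <- cross(seg, tt, 0.9 * amp, seq_len(ipk - 1))
  rise <- t90 - t10
  # decay relative to the post-EPSC plateau (slow-current offset subtracted);
  # a plateau below 2% of the peak is treated as zero so that ordinary traces
  # are not biased by residual kernel current in the plateau window
  pw <- sample_window(trace, onset + plateau_window_ms[1],
                      onset + plateau_window_ms[2])
  plateau <- if (length(pw)) mean(trace$current[pw]) - mu else 0
  if (abs(plateau) < 0.02 * abs(amp)) plateau <- 0
  rel <- seg - plateau
  apk <- rel[ipk]
  post <- ipk:(length(seg) - 1)
  d90 <- cross(rel, tt, 0.9 * apk, post)
  d10 <- cross(rel, tt, 0.1 * apk, post)
  list(amplitude_pa = amp, rise_ms = rise, decay_ms = d10 - d90,
       peak_time_ms = tt[ipk])
}

fit_tail <- function(trace, onset1, onset2, mu) {
  # single-exponential fit of the EPSC1 tail on [onset1 + 20 ms, onset2)
  w <- sample_window(trace, onset1 + 20, onset2)
  y <- trace$current[w] - mu
  t <- trace$time_ms[w]
  neg <- y < 0
  if (sum(neg) < 3) return(function(t) rep(0, length(t)))
  fit <- stats::lm(log(-y[neg]) ~ t[neg])
  a <- exp(stats::coef(fit)[1]); b <- stats::coef(fit)[2]
  function(tq) -a * exp(b * tq)
}

#' Paired-pulse ratio
#'
#' PPR = amplitude(EPSC2) / amplitude(EPSC1) for two stimuli 50 ms apart. The
#' second amplitude is measured against the decayed tail of the first EPSC
#' (single-exponential extrapolation fitted on the late tail) so that residual
#' EPSC1 current does not bias the ratio; set `tail_correction = FALSE` to use
#' the simple pre-stimulus mean instead.
#'
#' @param trace an `epsc_trace` with exactly 2 stimuli.
#' @param baseline_ms pre-stimulus baseline window (ms).
#' @param tail_correction subtract the extrapolated EPSC1 tail under EPSC2.
#' @param inclusion_floor_pa cells whose first EPSC amplitude is above this
#'   (i.e. weaker than `-100` pA) are excluded and give `NA`.
#' @return The paired-pulse ratio, or `NA` for excluded cells.
#' @export
paired_pulse_ratio <- function(trace, baseline_ms = 10,
                               tail_correction = TRUE,
                               inclusion_floor_pa = -100) {
  stim <- trace$stimulus_times_ms
  if (length(stim) != 2L) {
    stop("paired_pulse_ratio: expected exactly 2 stimuli")
  }
  base <- sample_window(trace, stim[1] - baseline_ms, stim[1])
  mu <- mean(trace$current[base])
  w1 <- sample_window(trace, stim[1], stim[2])
  a1 <- min(trace$current[w1]) - mu
  if (!include_cell(a1, floor_pa = inclusion_floor_pa)) return(NA_real_)
  w2 <- sample_window(trace, stim[2], stim[2] + diff(stim))
  if (tail_correction) {
    tail <- fit_tail(trace, stim[1], stim[2], mu)
    seg2 <- (trace$current[w2] - mu) - tail(trace$time_ms[w2])
    a2 <- min(seg2)
  } else {
    a2 <- min(trace$current[w2]) - mu
  }
  a2 / a1
}

#' Train dynamics: relative amplitudes, charge transfer, slow current
#'
#' For a 10-stimulus, 20 Hz train: per-stimulus amplitudes (measured against a
#' local pre-stimulus baseline) normalized to the first; charge transfer
#' integrated over a 50 ms episode from each stimulus onset (relative to the
#' pre-train baseline) normalized to the first; and the slow current, defined
#' as the change in mean current over 10 ms prior to the tenth stimulus
#' relative to 10 ms before the first stimulus, normalized to the first-EPSC
#' peak.
#'
#' @param trace an `epsc_trace` with >= 2 stimuli (10 at 20 Hz in the
#'   reference protocol).
#' @param episode_ms charge-integration episode per stimulus (default 50 ms).
#' @return A list with `relative_amplitude`, `relative_charge` (both length
#'   n_stimuli, first element 1) and `slow_current_fraction`.
#' @export
train_dynamics <- function(trace, episode_ms = 50) {
  stim <- trace$stimulus_times_ms
  n <- length(stim)
  if (n < 2) stop("train_dynamics: need a stimulus train")
  if (max(trace$time_ms) < stim[n] + episode_ms) {
    stop("train_dynamics: trace shorter than the last integration window")
  }
  mu0 <- mean(trace$current[sample_window(trace, stim[1] - 10, stim[1])])
  amps <- charges <- numeric(n)
  dt <- 1 / trace$sampling_khz
  for (k in seq_len(n)) {
    loc <- mean(trace$current[sample_window(trace, stim[k] - 2, stim[k])])
    w <- sample_window(trace, stim[k], stim[k] + episode_ms)
    amps[k] <- min(trace$current[w]) - loc
    charges[k] <- sum(trace$current[w] - mu0) * dt  # pA * ms
  }
  pre10 <- mean(trace$current[sample_window(trace, stim[n] - 10, stim[n])])
  slow <- (pre10 - mu0) / amps[1]
  list(
    relative_amplitude = amps / amps[1],
    relative_charge = charges / charges[1],
    slow_current_fraction = slow
  )
}

#' Cell inclusion rule
#'
#' Putative MSNs with a first evoked EPSC of at most -100 pA (i.e. at least
#' 100 pA of inward current) are included; the bound is inclusive.
#'
#' @param first_amplitude_pa first-EPSC amplitude in pA (negative-going).
#' @param floor_pa inclusion bound (default -100 pA).
#' @return `TRUE` if the cell is included.
#' @export
include_cell <- function(first_amplitude_pa, floor_pa = -100) {
  first_amplitude_pa <= floor_pa
}
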
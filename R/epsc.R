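# Synthetic optogenetically evoked EPSC traces with known ground truth.

epsc_kernel <- function(t_ms, rise_ms, decay_ms) {
  # difference of exponentials normalized to unit peak
  tpk <- rise_ms * decay_ms / (decay_ms - rise_ms) * log(decay_ms / rise_ms)
  pk <- exp(-tpk / decay_ms) - exp(-tpk / rise_ms)
  out <- numeric(length(t_ms))
  pos <- t_ms >= 0
  out[pos] <- (exp(-t_ms[pos] / decay_ms) - exp(-t_ms[pos] / rise_ms)) / pk
  out
}

#' Generate a synthetic EPSC trace
#'
#' A sum of per-stimulus difference-of-exponential EPSCs (negative-going,
#' voltage clamp convention), an optional slow sustained current component,
#' and seeded Gaussian noise. Stimulus trains follow the recording protocols
#' the metrics are designed for: paired pulses 50 ms apart, or 10 pulses at
#' 20 Hz.
#'
#' @param amplitude_pa first-EPSC peak amplitude in pA (negative).
#' @param rise_ms,decay_ms kernel time constants (decay > rise > 0).
#' @param ppr paired-pulse ratio; if given (with `n_stimuli = 2`), the second
#'   amplitude is `ppr * amplitude_pa`.
#' @param scale_per_stimulus per-stimulus amplitude scaling for trains:
#'   stimulus k has amplitude `amplitude_pa * scale_per_stimulus^(k-1)`.
#' @param slow_fraction amplitude of the sustained slow current as a fraction
#'   of the first-EPSC peak (0 = none). The slow component rises with
#'   `slow_rise_ms` after the first stimulus and is sustained thereafter.
#' @param slow_rise_ms rise time constant of the slow component.
#' @param n_stimuli,interval_ms stimulus count and inter-stimulus interval.
#' @param sampling_khz sampling rate (> 0).
#' @param baseline_ms,tail_ms pre-stimulus and post-train durations.
#' @param noise_sd_pa SD of additive Gaussian noise.
#' @param seed optional RNG seed for the noise.
#' @return An object of class `epsc_trace` with fields `current` (pA),
#'   `time_ms`, `sampling_khz`, `stimulus_times_ms` and `ground_truth`.
#' @export
make_epsc_trace <- function(amplitude_pa = -300, rise_ms = 1, decay_ms = 8,
                            ppr = NULL, scale_per_stimulus = 1,
                            slow_fraction = 0, slow_rise_ms = 8,
                            n_stimuli = 2, interval_ms = 50,
                            sampling_khz = 10, baseline_ms = 100,
                            tail_ms = 100, noise_sd_pa = 0, seed = NULL) {
  if (!is.finite(sampling_khz) || sampling_khz <= 0) {
    stop("make_epsc_trace: sampling rate must be positive")
  }
  if (!(rise_ms > 0 && decay_ms > rise_ms)) {
    stop("make_epsc_trace: need decay_ms > rise_ms > 0")
  }
  stim <- baseline_ms + (seq_len(n_stimuli) - 1) * interval_ms
  total_ms <- baseline_ms + (n_stimuli - 1) * interval_ms + tail_ms
  t <- seq(0, total_ms, by = 1 / sampling_khz)
  amps <- if (!is.null(ppr)) {
    stopifnot(n_stimuli == 2L)
    amplitude_pa * c(1, ppr)
  } else {
    amplitude_pa * scale_per_stimulus^(seq_len(n_stimuli) - 1)
  }
  cur <- numeric(length(t))
  for (k in seq_len(n_stimuli)) {
    cur <- cur + amps[k] * epsc_kernel(t - stim[k], rise_ms, decay_ms)
  }
  if (slow_fraction != 0) {
    dt <- t - stim[1]
    slow <- ifelse(dt >= 0, 1 - exp(-dt / slow_rise_ms), 0)
    cur <- cur + slow_fraction * amplitude_pa * slow
  }
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd_pa > 0) cur <- cur + stats::rnorm(length(t), 0, noise_sd_pa)
  structure(
    list(
      current = cur, time_ms = t, sampling_khz = sampling_khz,
      stimulus_times_ms = stim,
      ground_truth = list(
        amplitude_pa = amplitude_pa, rise_ms = rise_ms, decay_ms = decay_ms,
        ppr = ppr, scale_per_stimulus = scale_per_stimulus,
        slow_fraction = slow_fraction, noise_sd_pa = noise_sd_pa
      )
    ),
    class = "epsc_trace"
  )
}

#' @export
print.epsc_trace <- function(x, ...) {
  cat(sprintf(
    "<epsc_trace> %d samples @ %g kHz, %d stimuli, min %.1f pA\n",
    length(x$current), x$sampling_khz, length(x$stimulus_times_ms),
    min(x$current)
  ))
  invisible(x)
}

#' Write / read an EPSC trace as CSV + JSON sidecar
#'
#' @param trace an `epsc_trace`.
#' @param path output `.csv` path (columns time_ms, current_pA); stimulus
#'   times and sampling rate go to `<path>.json`.
#' @return `path` invisibly (write); an `epsc_trace` (read).
#' @export
write_epsc_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time_ms = trace$time_ms, current_pA = trace$current),
    path, row.names = FALSE
  )
  jsonlite::write_json(
    list(stimulus_times_ms = trace$stimulus_times_ms,
         sampling_khz = trace$sampling_khz),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_epsc_csv
#' @export
read_epsc_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(current = df$current_pA, time_ms = df$time_ms,
         sampling_khz = meta$sampling_khz,
         stimulus_times_ms = meta$stimulus_times_ms,
         ground_truth = NULL),
    class = "epsc_trace"
  )
}
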
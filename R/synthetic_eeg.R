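# Seeded two-class synthetic EEG generator in the Bonn dialect, so every
# downstream stage (clustering, entropy, classification, benchmarking) is
# testable without the external corpus.

#' Parameters of the synthetic EEG generator
#'
#' The generator emulates the geometry of the Bonn corpus (A = healthy
#' "normal", E = "ictal" seizure activity): a normal segment is a sum of
#' alpha-band sinusoids over coloured (AR(1)) background noise; an ictal
#' segment is a periodic ~3 Hz spike-and-wave train -- a narrow high-amplitude
#' Gaussian spike followed by a slow negative half-wave -- with 10% per-cycle
#' amplitude jitter, over the same noise model. Defaults give the ictal class
#' roughly four times the normal amplitude.
#'
#' @param n_samples samples per segment (Bonn: 4097).
#' @param fs sampling rate in Hz (Bonn: 173.61).
#' @param normal_rhythm_hz length-2 band (Hz) for the normal rhythm, default
#'   8-12 Hz (alpha).
#' @param normal_amp amplitude scale of the normal rhythm (arbitrary units,
#'   nominally microvolts).
#' @param ictal_spike_hz spike-wave fundamental frequency in Hz.
#' @param ictal_amp amplitude scale of the ictal spikes (default 4 x normal).
#' @param noise_sd marginal standard deviation of the additive AR(1) noise.
#' @param ar_coeff lag-1 autoregressive coefficient in `[0, 1)` of the noise.
#' @return a list of class `synth_params`.
#' @export
synth_params <- function(n_samples = 4097L, fs = BONN_FS,
                         normal_rhythm_hz = c(8, 12), normal_amp = 50,
                         ictal_spike_hz = 3, ictal_amp = 4 * normal_amp,
                         noise_sd = 15, ar_coeff = 0.9) {
  assert_number(n_samples, "n_samples", lower = 8)
  assert_number(fs, "fs", lower = .Machine$double.eps)
  stopifnot(length(normal_rhythm_hz) == 2L, diff(normal_rhythm_hz) >= 0)
  assert_number(normal_amp, "normal_amp", lower = .Machine$double.eps)
  assert_number(ictal_amp, "ictal_amp", lower = .Machine$double.eps)
  assert_number(ictal_spike_hz, "ictal_spike_hz", lower = .Machine$double.eps)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(ar_coeff, "ar_coeff", lower = 0, upper = 1 - 1e-12)
  structure(list(n_samples = as.integer(n_samples), fs = fs,
                 normal_rhythm_hz = as.numeric(normal_rhythm_hz),
                 normal_amp = normal_amp, ictal_spike_hz = ictal_spike_hz,
                 ictal_amp = ictal_amp, noise_sd = noise_sd,
                 ar_coeff = ar_coeff),
            class = "synth_params")
}

# AR(1) noise with marginal sd `noise_sd` (innovation sd scaled accordingly).
ar1_noise <- function(n, noise_sd, ar_coeff) {
  if (noise_sd == 0) return(numeric(n))
  innov_sd <- noise_sd * sqrt(1 - ar_coeff^2)
  e <- rnorm(n, sd = innov_sd)
  if (ar_coeff == 0) return(e)
  x <- numeric(n)
  x[1] <- rnorm(1, sd = noise_sd)
  for (t in 2:n) x[t] <- ar_coeff * x[t - 1] + e[t]
  x
}

# Deterministic part of a normal segment given pre-drawn freqs/phases.
normal_rhythm <- function(tt, freqs, phases, amp) {
  sig <- numeric(length(tt))
  for (j in seq_along(freqs))
    sig <- sig + (amp / length(freqs)) * sin(2 * pi * freqs[j] * tt + phases[j])
  sig
}

# Spike-and-wave train: per cycle, a Gaussian spike (sd = 2% of the period,
# centred at 15% of the period) and a slow negative half-sine over the last
# 70% of the period; per-cycle amplitude jitter of +-10% (uniform).
spike_wave_train <- function(tt, f0, amp, jitter) {
  period <- 1 / f0
  cyc <- floor(tt / period)
  tau <- tt - cyc * period
  n_cyc <- max(cyc) + 1L
  a_cyc <- amp * (1 + runif(n_cyc, -jitter, jitter))
  a <- a_cyc[cyc + 1L]
  spike <- a * exp(-((tau - 0.15 * period)^2) / (2 * (0.02 * period)^2))
  in_wave <- tau >= 0.3 * period
  wave <- numeric(length(tt))
  wave[in_wave] <- -0.5 * a[in_wave] *
    sin(pi * (tau[in_wave] - 0.3 * period) / (0.7 * period))
  spike + wave
}

#' Generate one synthetic EEG segment
#'
#' Deterministic given `(cls, params, seed)`.
#'
#' @param cls `"normal"` or `"ictal"`.
#' @param params a [synth_params()] object.
#' @param seed integer seed for this segment.
#' @param segment_id identifier stored in the segment.
#' @return an [eeg_segment()] labelled with `cls`.
#' @export
#' @examples
#' s <- generate_segment("ictal", synth_params(n_samples = 512), seed = 1)
generate_segment <- function(cls, params = synth_params(), seed = 1,
                             segment_id = NULL) {
  if (!cls %in% c("normal", "ictal"))
    stop_validation("unknown class '", cls, "': use 'normal' or 'ictal'")
  stopifnot(inherits(params, "synth_params"))
  if (is.null(segment_id)) segment_id <- sprintf("%s_seed%d", cls, seed)
  tt <- (seq_len(params$n_samples) - 1L) / params$fs
  samples <- with_seed(seed, {
    if (cls == "normal") {
      freqs <- runif(3, params$normal_rhythm_hz[1], params$normal_rhythm_hz[2])
      phases <- runif(3, 0, 2 * pi)
      det <- normal_rhythm(tt, freqs, phases, params$normal_amp)
    } else {
      det <- spike_wave_train(tt, params$ictal_spike_hz, params$ictal_amp,
                              jitter = 0.1)
    }
    det + ar1_noise(params$n_samples, params$noise_sd, params$ar_coeff)
  })
  eeg_segment(samples, fs = params$fs, segment_id = segment_id, label = cls)
}

#' Generate a balanced two-class synthetic dataset
#'
#' Per-segment seeds are derived deterministically from the master seed, the
#' class and the segment index (see [derive_seed()]), so any segment can be
#' regenerated independently of generation order.
#'
#' @param n_per_class segments per class (>= 1).
#' @param params a [synth_params()] object.
#' @param seed master integer seed.
#' @return an [eeg_dataset()] with `2 * n_per_class` segments, labels
#'   `"normal"` and `"ictal"` exactly balanced.
#' @export
generate_dataset <- function(n_per_class, params = synth_params(), seed = 1) {
  assert_number(n_per_class, "n_per_class", lower = 1)
  segs <- list()
  for (cls in c("normal", "ictal")) {
    for (i in seq_len(n_per_class)) {
      segs[[length(segs) + 1L]] <- generate_segment(
        cls, params, seed = derive_seed(seed, cls, i),
        segment_id = sprintf("%s_%03d", cls, i))
    }
  }
  eeg_dataset(segs)
}
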
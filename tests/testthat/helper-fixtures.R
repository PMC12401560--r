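# Shared fixtures: all built in code, sized for fast runs.

# single-channel epoch holding a pure tone (bin-aligned when freq is a
# multiple of oddball_freq / n_cycles)
tone_epoch <- function(freq_hz, amp_uv = 1, n_cycles = 26L, fs = 120,
                       oddball_freq = 0.6, phase = 0, channels = 1L) {
  n <- round(n_cycles / oddball_freq * fs)
  t <- (0:(n - 1)) / fs
  x <- amp_uv * sin(2 * pi * freq_hz * t + phase)
  data <- matrix(rep(x, each = channels), channels, n)
  extract_epoch(fb_recording(data, fs), 0, n_cycles, oddball_freq)
}

# fast simulator configuration: analysis rate, no artifacts
quick_sim_config <- function(...) {
  simulation_config(fs_hz = 120, artifact_rate_per_min = 0, ...)
}

# brute-force neighbour-bin SNR, independent of the vectorized path
snr_brute <- function(amp, df, half_width_hz = 0.10, n_excl = 1L) {
  nb <- length(amp)
  w <- floor(half_width_hz / df + 1e-9)
  out <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    if (k - w < 1 || k + w > nb) next
    idx <- c((k - w):(k - n_excl - 1), (k + n_excl + 1):(k + w))
    out[k] <- amp[k] / mean(amp[idx])
  }
  out
}

# global-average amplitude spectra for n simulated subjects (no
# re-referencing: simulated data are generated in an ideal reference)
simulate_global_spectra <- function(cfg, n_subjects, seed0, n_cycles = 104L,
                                    amp_mean = 1, amp_sd = 0.25) {
  G <- NULL
  freqs <- NULL
  for (i in seq_len(n_subjects)) {
    set.seed(seed0 + i)
    amp <- rnorm(1, amp_mean, amp_sd)
    rec <- simulate_recording(cfg, amp, seed = seed0 + i, n_cycles = n_cycles)
    sp <- amplitude_spectrum(extract_epoch(rec, 0, n_cycles, cfg$oddball_freq_hz))
    G <- rbind(G, global_average_spectrum(sp))
    freqs <- sp$freqs_hz
  }
  list(amp = G, freqs_hz = freqs)
}

# frequency mask for bins not at any oddball/base harmonic (for noise-floor
# checks), restricted to a band
nontagged_bins <- function(freqs_hz, lo = 1, hi = 20, oddball_freq = 0.6,
                           guard_hz = 0.05) {
  near_tag <- vapply(freqs_hz, function(f) {
    k <- round(f / oddball_freq)
    k >= 1 && abs(f - k * oddball_freq) < guard_hz
  }, logical(1))
  !near_tag & freqs_hz > lo & freqs_hz < hi
}
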
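#' Construct a multichannel EEG recording
#'
#' @param data Channels x samples numeric matrix, in microvolts.
#' @param fs_hz Sampling rate in Hz.
#' @param channel_labels Unique channel names (defaults to rownames).
#' @param reference `"as-recorded"` or `"common-average"`.
#' @return An object of class `fb_recording`.
#' @export
fb_recording <- function(data, fs_hz, channel_labels = rownames(data),
                         reference = "as-recorded") {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  stopifnot(fs_hz > 0, length(channel_labels) == nrow(data),
            !anyDuplicated(channel_labels))
  rownames(data) <- channel_labels
  structure(list(data = data, fs_hz = fs_hz,
                 channel_labels = channel_labels,
                 reference = reference,
                 processing = character(0)),
            class = "fb_recording")
}

#' @export
print.fb_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz,
              x$reference))
  if (length(x$processing)) cat("  processing:", paste(x$processing, collapse = " -> "), "\n")
  invisible(x)
}

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel,
#' so each sample's column sum becomes zero.
#'
#' @param rec An `fb_recording` in the as-recorded reference.
#' @return The re-referenced recording.
#' @export
rereference_common_average <- function(rec) {
  if (nrow(rec$data) < 2L)
    stop("common-average reference requires at least 2 channels")
  if (rec$reference == "common-average")
    stop("recording is already common-average referenced")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec$reference <- "common-average"
  rec$processing <- c(rec$processing, "rereference")
  rec
}

#' Zero-phase low-pass filter
#'
#' Forward-backward application of a 2nd-order Butterworth low-pass
#' (12 dB/oct per pass, 24 dB/oct combined magnitude roll-off; -6 dB at
#' the cutoff). The two-pass scheme cancels the filter's phase response,
#' so the group delay is zero.
#'
#' @param rec An `fb_recording`.
#' @param cutoff_hz Cutoff frequency (must be below Nyquist).
#' @param order Per-pass Butterworth order.
#' @return The filtered recording.
#' @export
lowpass_zero_phase <- function(rec, cutoff_hz = 40, order = 2L) {
  if (cutoff_hz >= rec$fs_hz / 2)
    stop("cutoff (", cutoff_hz, " Hz) must be below Nyquist (",
         rec$fs_hz / 2, " Hz)")
  bf <- signal::butter(order, cutoff_hz / (rec$fs_hz / 2), type = "low")
  rec$data <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  rownames(rec$data) <- rec$channel_labels
  rec$processing <- c(rec$processing, sprintf("lowpass_%ghz", cutoff_hz))
  rec
}

## full linear convolution via zero-padded FFTs
fft_convolve <- function(x, h) {
  nfft <- stats::nextn(length(x) + length(h) - 1L, 2L)
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
              fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(length(x) + length(h) - 1L)]
}

## Polyphase rational resampler: zero-stuff by p, FIR low-pass (Hamming
## fir1, cutoff at the tighter of the two Nyquist limits), compensate the
## linear-phase group delay, then keep every q-th sample.
resample_poly <- function(x, p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q); p <- p / d; q <- q / d
  if (p == 1 && q == 1) return(x)
  n <- length(x)
  ntaps <- 2L * 10L * max(p, q) + 1L          # odd length -> integer delay
  h <- p * signal::fir1(ntaps - 1L, 1 / max(p, q), "low")
  delay <- (ntaps - 1L) / 2L
  xu <- numeric(n * p)
  xu[seq(1L, n * p, by = p)] <- x
  z <- fft_convolve(xu, h)                    # full convolution, FFT-based
  centred <- z[seq_len(n * p) + delay]
  out <- centred[seq(1L, n * p, by = q)]
  n_out <- round(n * p / q)
  if (length(out) >= n_out) out[seq_len(n_out)] else c(out, numeric(n_out - length(out)))
}

#' Resample a recording to a lower rate
#'
#' Polyphase rational resampling (500 to 120 Hz is x6/25). To avoid
#' aliasing the pipeline requires the anti-alias low-pass
#' ([lowpass_zero_phase()]) to have been applied at the original rate
#' first; the output length is `round(n * target_hz / fs_hz)`.
#'
#' @param rec An `fb_recording`, already low-pass filtered.
#' @param target_hz Target sampling rate (integer Hz, at most `fs_hz`).
#' @return The resampled recording.
#' @export
resample_recording <- function(rec, target_hz = 120) {
  if (target_hz > rec$fs_hz)
    stop("target rate (", target_hz, " Hz) exceeds the recording rate (",
         rec$fs_hz, " Hz)")
  if (target_hz == rec$fs_hz) return(rec)
  if (!any(startsWith(rec$processing, "lowpass")))
    stop("apply lowpass_zero_phase() before resampling (anti-aliasing)")
  if (abs(target_hz - round(target_hz)) > 1e-9 || abs(rec$fs_hz - round(rec$fs_hz)) > 1e-9)
    stop("rational resampling requires integer sampling rates")
  rec$data <- t(apply(rec$data, 1L, resample_poly,
                      p = round(target_hz), q = round(rec$fs_hz)))
  rownames(rec$data) <- rec$channel_labels
  rec$fs_hz <- target_hz
  rec$processing <- c(rec$processing, sprintf("resample_%ghz", target_hz))
  rec
}

#' Extract an integer-cycle trial epoch
#'
#' Cuts exactly `round(n_cycles / oddball_freq_hz * fs_hz)` samples from
#' the trial onset, so that the FFT frequency grid of the epoch contains
#' the oddball frequency and all of its multiples (including the base
#' frequency) exactly. With the defaults at 120 Hz this is 20800 samples
#' (173.33 s) and a bin spacing of 0.6/104 Hz.
#'
#' @param rec An `fb_recording`.
#' @param onset_s Trial onset in seconds from the start of the recording.
#' @param n_cycles Number of oddball cycles the epoch spans.
#' @param oddball_freq_hz Oddball frequency in Hz.
#' @return An object of class `fb_epoch`.
#' @export
extract_epoch <- function(rec, onset_s = 0, n_cycles = 104L,
                          oddball_freq_hz = 0.6) {
  n_samp <- round(n_cycles / oddball_freq_hz * rec$fs_hz)
  start <- round(onset_s * rec$fs_hz) + 1L
  if (start < 1L || start + n_samp - 1L > ncol(rec$data))
    stop("recording too short: epoch needs ", n_samp, " samples from sample ",
         start, " but only ", ncol(rec$data), " are available")
  structure(list(data = rec$data[, start:(start + n_samp - 1L), drop = FALSE],
                 fs_hz = rec$fs_hz, onset_s = onset_s,
                 n_cycles = n_cycles, oddball_freq_hz = oddball_freq_hz,
                 channel_labels = rec$channel_labels,
                 zeroed_mask = NULL, fraction_zeroed = 0),
            class = "fb_epoch")
}

#' @export
print.fb_epoch <- function(x, ...) {
  cat(sprintf("Trial epoch: %d channels x %d samples @ %g Hz (%d cycles of %g Hz)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, x$n_cycles, x$oddball_freq_hz))
  if (x$fraction_zeroed > 0)
    cat(sprintf("  artifact-suppressed: %.2f%% of samples zeroed\n",
                100 * x$fraction_zeroed))
  invisible(x)
}

#' Polynomial detrending of an epoch
#'
#' Removes, per channel, the least-squares polynomial of the given order
#' (DC offset and slow drift) without materially affecting oscillations
#' at or above the oddball frequency.
#'
#' @param ep An `fb_epoch`.
#' @param order Polynomial order (order 0 removes the mean).
#' @return The detrended epoch.
#' @export
detrend_polynomial <- function(ep, order = 3L) {
  n <- ncol(ep$data)
  if (order < 0L) stop("order must be >= 0")
  if (order >= n) stop("polynomial order must be below the sample count")
  tt <- seq(-1, 1, length.out = n)
  basis <- cbind(1, if (order >= 1L) stats::poly(tt, order))
  fit <- qr(basis)
  ep$data <- ep$data - t(basis %*% qr.coef(fit, t(ep$data)))
  rownames(ep$data) <- ep$channel_labels
  ep
}

#' Suppress high-amplitude artifacts with half-Hanning tapers
#'
#' Per channel, every maximal contiguous run of samples exceeding the
#' amplitude threshold is replaced with zeros; the clean data flanking
#' each zeroed run is ramped down into the run with a half-Hanning
#' window over `taper_points` samples, so no discontinuity is introduced.
#' Where two runs fall closer than a taper length, overlapping envelopes
#' combine by their pointwise minimum. `fraction_zeroed` counts zeroed
#' (not tapered) samples across all channels.
#'
#' @param ep An `fb_epoch`.
#' @param threshold_uv Absolute amplitude threshold in microvolts.
#' @param taper_points Taper length in samples (at the epoch's rate).
#' @return The epoch with artifacts suppressed, `zeroed_mask` (channels x
#'   samples logical) and `fraction_zeroed` filled in.
#' @export
suppress_artifacts <- function(ep, threshold_uv = 250, taper_points = 670L) {
  stopifnot(taper_points >= 1L)
  n <- ncol(ep$data)
  mask <- matrix(FALSE, nrow(ep$data), n)
  ## gain at distance d from the run edge: ~0 adjacent, 1 at the far end
  ramp <- 0.5 * (1 - cos(pi * seq_len(taper_points) / taper_points))
  for (c in seq_len(nrow(ep$data))) {
    x <- ep$data[c, ]
    bad <- abs(x) > threshold_uv
    if (!any(bad)) next
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    env <- rep(1, n)
    for (j in which(r$values)) {
      e <- rep(1, n)
      e[starts[j]:ends[j]] <- 0
      li <- seq(starts[j] - 1L, by = -1L, length.out = taper_points)
      li <- li[li >= 1L]
      e[li] <- ramp[seq_along(li)]
      ri <- seq(ends[j] + 1L, by = 1L, length.out = taper_points)
      ri <- ri[ri <= n]
      e[ri] <- ramp[seq_along(ri)]
      env <- pmin(env, e)
    }
    ep$data[c, ] <- x * env
    mask[c, ] <- bad
  }
  ep$zeroed_mask <- mask
  ep$fraction_zeroed <- mean(mask)
  ep
}

#' Run the fixed preprocessing chain on a raw recording
#'
#' Common-average re-reference, zero-phase low-pass, polyphase
#' resampling, integer-cycle epoch extraction, polynomial detrend, and
#' amplitude-threshold artifact suppression, in that order. Detrending
#' precedes artifact zeroing so that zeroed stretches cannot bias the
#' polynomial fit.
#'
#' @param rec An `fb_recording` (as-recorded reference).
#' @param onset_s Trial onset in seconds.
#' @param config Parameter list, see [pipeline_config()].
#' @return An `fb_epoch` ready for spectral analysis.
#' @export
preprocess_recording <- function(rec, onset_s = 0, config = pipeline_config()) {
  p <- config$preprocessing
  if (isTRUE(p$rereference)) rec <- rereference_common_average(rec)
  if (rec$fs_hz > p$analysis_fs_hz) {
    rec <- lowpass_zero_phase(rec, p$lowpass_hz, p$filter_order)
    rec <- resample_recording(rec, p$analysis_fs_hz)
  }
  ep <- extract_epoch(rec, onset_s, p$n_cycles, config$oddball_freq_hz)
  ep <- detrend_polynomial(ep, p$detrend_order)
  suppress_artifacts(ep, p$artifact_threshold_uv, p$taper_points)
}
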
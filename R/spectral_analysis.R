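#' Single-sided amplitude spectrum of an epoch
#'
#' Discrete Fourier amplitude per channel with the normalization
#' \eqn{2|X_k|/N} for k > 0 (and \eqn{|X_0|/N} at DC), so a bin-aligned
#' unit-amplitude sinusoid yields amplitude 1. For an integer-cycle
#' epoch the bin spacing is `oddball_freq_hz / n_cycles`
#' (0.6/104 = 0.00577 Hz at the defaults, printing as 0.0058).
#'
#' @param ep An `fb_epoch`.
#' @return Object of class `fb_spectrum`: `freqs_hz`, `amp_uv`
#'   (channels x bins), `df_hz`, `channel_labels`.
#' @export
amplitude_spectrum <- function(ep) {
  n <- ncol(ep$data)
  if (n < 2L) stop("empty epoch")
  X <- stats::mvfft(t(ep$data))
  nb <- floor(n / 2) + 1L
  amp <- t(Mod(X[seq_len(nb), , drop = FALSE])) * 2 / n
  amp[, 1L] <- amp[, 1L] / 2
  rownames(amp) <- ep$channel_labels
  structure(list(freqs_hz = (seq_len(nb) - 1L) * ep$fs_hz / n,
                 amp_uv = amp, df_hz = ep$fs_hz / n,
                 channel_labels = ep$channel_labels),
            class = "fb_spectrum")
}

#' @export
print.fb_spectrum <- function(x, ...) {
  cat(sprintf("Amplitude spectrum: %d channels x %d bins, df = %.6f Hz (0-%.1f Hz)\n",
              nrow(x$amp_uv), length(x$freqs_hz), x$df_hz, max(x$freqs_hz)))
  invisible(x)
}

## indices of the +-half_width neighbourhood of bin k, excluding the bin
## itself and n_excl adjacent bins per side; NULL if incomplete at edges
neighbourhood_bins <- function(k, n_bins, w, n_excl) {
  if (k - w < 1L || k + w > n_bins) return(NULL)
  c((k - w):(k - n_excl - 1L), (k + n_excl + 1L):(k + w))
}

#' Neighbour-bin signal-to-noise spectrum
#'
#' SNR at each frequency bin is the amplitude there divided by the mean
#' amplitude of the surrounding bins within `half_width_hz`
#' (excluding the `n_adjacent_excluded` immediately adjacent bins on
#' each side). With the default 0.00577 Hz resolution the
#' neighbourhood is 17 bins per side minus 1 excluded, i.e. 32 bins.
#' Under noise alone the SNR fluctuates around 1. Bins whose
#' neighbourhood is truncated by the spectrum edges are `NA`.
#'
#' @param spec An `fb_spectrum`.
#' @param half_width_hz Half-width of the neighbourhood in Hz.
#' @param n_adjacent_excluded Bins excluded on each side of the centre.
#' @return Object of class `fb_snr`: `freqs_hz`, `snr` (channels x
#'   bins), `df_hz`, the parameters, and `channel_labels`.
#' @export
snr_spectrum <- function(spec, half_width_hz = 0.10, n_adjacent_excluded = 1L) {
  w <- floor(half_width_hz / spec$df_hz + 1e-9)
  if (w <= n_adjacent_excluded)
    stop("neighbourhood of +-", half_width_hz,
         " Hz is empty at a resolution of ", signif(spec$df_hz, 3), " Hz")
  nb <- length(spec$freqs_hz)
  n_used <- 2L * (w - n_adjacent_excluded)
  snr <- matrix(NA_real_, nrow(spec$amp_uv), nb,
                dimnames = dimnames(spec$amp_uv))
  valid <- (w + 1L):(nb - w)
  for (c in seq_len(nrow(spec$amp_uv))) {
    a <- spec$amp_uv[c, ]
    cs <- cumsum(a)
    win <- cs[valid + w] - c(0, cs)[valid - w]   # sum over k-w .. k+w
    excl <- a[valid]
    for (d in seq_len(n_adjacent_excluded))
      excl <- excl + a[valid - d] + a[valid + d]
    snr[c, valid] <- a[valid] / ((win - excl) / n_used)
  }
  structure(list(freqs_hz = spec$freqs_hz, snr = snr, df_hz = spec$df_hz,
                 half_width_hz = half_width_hz,
                 n_adjacent_excluded = as.integer(n_adjacent_excluded),
                 channel_labels = spec$channel_labels),
            class = "fb_snr")
}

#' Average a spectrum across channels (global average)
#'
#' @param spec An `fb_spectrum` or `fb_snr`.
#' @return Numeric vector, one value per frequency bin.
#' @export
global_average_spectrum <- function(spec) {
  m <- if (inherits(spec, "fb_snr")) spec$snr else spec$amp_uv
  colMeans(m)
}

#' Data-driven selection of oddball response harmonics
#'
#' Computes, on the grand average of the subjects' global-average
#' (all-electrode) amplitude spectra, a group Z score for each candidate
#' harmonic of the oddball frequency: the amplitude at the candidate bin
#' relative to the mean and standard deviation of the neighbouring bins
#' within `half_width_hz` (excluding the adjacent bins, as in the SNR).
#' Candidates are multiples of `oddball_freq` up to `max_candidate_hz`
#' that are not multiples of `base_freq`. The harmonic set used for the
#' f+ metric includes every candidate up to the highest one whose
#' Z exceeds `z_crit`; if none does, the nominal default family (all
#' candidates up to 6.6 Hz) is used with a warning.
#'
#' @param amp Matrix (subjects x bins) of global-average amplitude
#'   spectra, or a single spectrum vector.
#' @param freqs_hz Frequency grid of the spectra.
#' @param base_freq,oddball_freq Base and oddball frequencies in Hz.
#' @param max_candidate_hz Highest candidate frequency examined.
#' @param z_crit Inclusion threshold (1.96 = two-sided 5%).
#' @param half_width_hz,n_adjacent_excluded Neighbourhood definition.
#' @param use_snr If `TRUE`, Z scores are computed on the neighbour-bin
#'   SNR of the grand-average spectrum rather than on raw amplitude.
#' @return Object of class `fb_harmonic_selection` with `candidates`
#'   (data frame `freq_hz`, `group_z`), `z_crit`, `included`
#'   (frequencies), and `excluded_base_multiples`.
#' @export
harmonic_group_z <- function(amp, freqs_hz, base_freq = 3.0,
                             oddball_freq = 0.6, max_candidate_hz = 20,
                             z_crit = 1.96, half_width_hz = 0.10,
                             n_adjacent_excluded = 1L, use_snr = FALSE) {
  grand <- if (is.matrix(amp)) colMeans(amp) else as.numeric(amp)
  stopifnot(length(grand) == length(freqs_hz))
  df <- freqs_hz[2L] - freqs_hz[1L]
  if (use_snr) {
    pseudo <- structure(list(freqs_hz = freqs_hz,
                             amp_uv = matrix(grand, 1L), df_hz = df,
                             channel_labels = "grand"), class = "fb_spectrum")
    grand <- as.numeric(snr_spectrum(pseudo, half_width_hz,
                                     n_adjacent_excluded)$snr)
  }
  w <- floor(half_width_hz / df + 1e-9)
  nb <- length(grand)

  ratio <- base_freq / oddball_freq
  kmax <- floor(max_candidate_hz / oddball_freq + 1e-9)
  ks <- seq_len(kmax)
  is_base <- abs(ks / ratio - round(ks / ratio)) < 1e-9
  cand_f <- ks[!is_base] * oddball_freq

  zs <- vapply(cand_f, function(f) {
    k <- which.min(abs(freqs_hz - f))
    nbh <- neighbourhood_bins(k, nb, w, n_adjacent_excluded)
    if (is.null(nbh)) return(NA_real_)
    s <- sd(grand[nbh])
    if (!is.finite(s) || s == 0) return(NA_real_)
    (grand[k] - mean(grand[nbh])) / s
  }, numeric(1))

  candidates <- data.frame(freq_hz = cand_f, group_z = zs)
  sig <- which(!is.na(zs) & zs > z_crit)
  if (length(sig)) {
    included <- cand_f[cand_f <= cand_f[max(sig)] + 1e-9]
  } else {
    included <- cand_f[cand_f <= 6.6 + 1e-9]
    warning("no harmonic exceeded the Z criterion; falling back to the ",
            "nominal default family (up to 6.6 Hz)")
  }
  structure(list(candidates = candidates, z_crit = z_crit,
                 included = included,
                 excluded_base_multiples = base_freq *
                   seq_len(floor(max_candidate_hz / base_freq))),
            class = "fb_harmonic_selection")
}

#' @export
print.fb_harmonic_selection <- function(x, ...) {
  cat("Harmonic selection (Z >", x$z_crit, "):",
      paste(x$included, collapse = ", "), "Hz\n")
  invisible(x)
}

#' Steady-state summary metrics F and f+
#'
#' F is the neighbour-bin SNR at the base presentation frequency
#' (visuo-attentional engagement); f+ is the mean SNR over the included
#' oddball harmonics (neural recognition-memory response). Both are
#' reported per electrode, as the scalp average, and (for f+) at the
#' maximal electrode.
#'
#' @param snr An `fb_snr`.
#' @param sel An `fb_harmonic_selection` (or a numeric vector of
#'   harmonic frequencies).
#' @param base_freq Base frequency in Hz.
#' @param subject_id,session_id Identifiers carried into the result.
#' @return Object of class `fb_metrics`: per-electrode `F_snr` and
#'   `f_plus`, `F_scalp_avg`, `f_plus_scalp_avg`, `f_plus_max`,
#'   `max_electrode`, plus the harmonic list used.
#' @export
compute_fastball_metrics <- function(snr, sel, base_freq = 3.0,
                                     subject_id = NA_character_,
                                     session_id = NA_integer_) {
  freqs <- if (inherits(sel, "fb_harmonic_selection")) sel$included else sel
  bins <- vapply(c(base_freq, freqs), function(f) {
    k <- which.min(abs(snr$freqs_hz - f))
    if (abs(snr$freqs_hz[k] - f) > snr$df_hz / 2)
      stop("frequency ", f, " Hz is not on the spectrum grid")
    k
  }, integer(1))
  vals <- snr$snr[, bins, drop = FALSE]
  if (anyNA(vals)) {
    badf <- c(base_freq, freqs)[apply(is.na(vals), 2L, any)]
    stop("SNR unavailable at: ", paste(badf, collapse = ", "), " Hz")
  }
  F_snr <- vals[, 1L]
  f_plus <- rowMeans(vals[, -1L, drop = FALSE])
  names(F_snr) <- names(f_plus) <- snr$channel_labels
  imax <- which.max(f_plus)
  structure(list(subject_id = subject_id, session_id = session_id,
                 F_snr = F_snr, f_plus = f_plus,
                 F_scalp_avg = mean(F_snr),
                 f_plus_scalp_avg = mean(f_plus),
                 f_plus_max = unname(f_plus[imax]),
                 max_electrode = snr$channel_labels[imax],
                 harmonics_hz = freqs),
            class = "fb_metrics")
}

#' @export
print.fb_metrics <- function(x, ...) {
  cat(sprintf("Fastball metrics%s: F (scalp avg) = %.2f, f+ (scalp avg) = %.2f, f+ max = %.2f at %s\n",
              if (is.na(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
              x$F_scalp_avg, x$f_plus_scalp_avg, x$f_plus_max, x$max_electrode))
  invisible(x)
}

#' Stack per-subject metrics into a long cohort table
#'
#' One row per subject x session x electrode, with the scalp-average and
#' maximal-electrode summaries repeated on each row, ready for the group
#' statistics layer.
#'
#' @param metrics_list List of `fb_metrics`.
#' @param cohort Optional data frame with `subject_id` and `group` to
#'   merge group labels.
#' @return A data frame (`CohortTable` layout).
#' @export
metrics_table <- function(metrics_list, cohort = NULL) {
  rows <- lapply(metrics_list, function(m) {
    data.frame(subject_id = m$subject_id, session_id = m$session_id,
               electrode = names(m$f_plus),
               F_snr = unname(m$F_snr), f_plus = unname(m$f_plus),
               F_scalp_avg = m$F_scalp_avg,
               f_plus_scalp_avg = m$f_plus_scalp_avg,
               f_plus_max = m$f_plus_max, max_electrode = m$max_electrode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(cohort))
    out <- merge(out, unique(cohort[, c("subject_id", "group")]),
                 by = "subject_id", sort = FALSE)
  out
}
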
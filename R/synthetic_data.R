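#' Configuration of the synthetic FPVS cohort generator
#'
#' Describes the generative model used to emulate 8-channel steady-state
#' EEG recordings from an FPVS oddball experiment: a base steady-state
#' response at 3 Hz (plus harmonics), an oddball response family at
#' multiples of 0.6 Hz that are not multiples of 3 Hz, per-channel
#' topography gains, 1/f-plus-white background noise, occasional
#' high-amplitude square-pulse artifacts, group structure on the oddball
#' amplitude, and between-session correlation for retest designs.
#'
#' The oddball amplitude of subject \eqn{i} in group \eqn{g} is drawn as
#' \eqn{a_i \sim N(\mu_g, \sigma_g)}; group means are parameterized so
#' that standardized differences (Cohen's d) between groups are
#' configurable. Background noise is synthesized in the frequency domain
#' with a deterministic target amplitude spectrum
#' \eqn{\sqrt{c_p^2/f + c_w^2}} and uniformly random phases
#' (`noise_mode = "surrogate"`, giving exact spectral control), or with
#' complex-Gaussian spectral coefficients of the same expected power
#' (`noise_mode = "gaussian"`, giving the chi-square amplitude
#' fluctuations of real noise).
#'
#' @param n_channels Number of EEG channels.
#' @param channels Channel labels (10-10 positions).
#' @param fs_hz Sampling rate in Hz.
#' @param base_freq_hz Base (image presentation) frequency.
#' @param oddball_freq_hz Oddball frequency.
#' @param base_amp_uv Amplitudes (µV) of the base response harmonics at
#'   `base_freq_hz * (1, 2, ...)`.
#' @param oddball_amp_uv Amplitudes (µV) of the oddball harmonic family,
#'   at multiples of `oddball_freq_hz` that are not multiples of
#'   `base_freq_hz`, in ascending frequency order. The default family
#'   spans 0.6--6.6 Hz with geometric decay (ratio 0.7).
#' @param channel_gain_base,channel_gain_oddball Per-channel topography
#'   weights for the base and oddball responses (occipital-dominant base,
#'   Cz/P8-dominant oddball).
#' @param noise_pink_uv RMS (µV) of the 1/f noise component.
#' @param noise_white_uv RMS (µV) of the white noise component.
#' @param noise_mode `"surrogate"` (deterministic spectrum, random
#'   phases) or `"gaussian"`.
#' @param artifact_rate_per_min Expected number of artifact pulses per
#'   minute (Poisson).
#' @param artifact_amp_uv Artifact pulse amplitude (µV), must exceed 250.
#' @param artifact_dur_s Artifact pulse duration in seconds.
#' @param groups Named list; each element
#'   `list(n = ..., amp_mean = ..., amp_sd = ...)` gives a group's size
#'   and its oddball-amplitude distribution.
#' @param retest_r Correlation of a subject's oddball amplitude across
#'   two sessions.
#' @param session_shift Additive mean change of session 2.
#' @param behavior Parameters of the behavioural generators (see
#'   [simulate_behavior()]); defaults emulate a healthy-older-adult /
#'   amnestic-MCI / non-amnestic-MCI cohort.
#' @param seed Integer seed.
#' @return An object of class `fb_sim_config`.
#' @export
simulation_config <- function(n_channels = 8L,
                              channels = FB_CHANNELS,
                              fs_hz = 500,
                              base_freq_hz = 3.0,
                              oddball_freq_hz = 0.6,
                              base_amp_uv = c(2.0, 0.7, 0.25),
                              oddball_amp_uv = 0.8 * 0.7^(0:8),
                              channel_gain_base = c(O1 = 1.2, P7 = 0.8, Pz = 0.9, Cz = 0.8,
                                                    F3 = 0.5, F4 = 0.5, P8 = 0.8, O2 = 1.2),
                              channel_gain_oddball = c(O1 = 0.8, P7 = 0.9, Pz = 1.0, Cz = 1.2,
                                                       F3 = 0.6, F4 = 0.6, P8 = 1.2, O2 = 0.8),
                              noise_pink_uv = 1.0,
                              noise_white_uv = 0.5,
                              noise_mode = c("surrogate", "gaussian"),
                              artifact_rate_per_min = 0.5,
                              artifact_amp_uv = 300,
                              artifact_dur_s = 0.5,
                              groups = list(
                                HOA   = list(n = 54L, amp_mean = 1.00,  amp_sd = 0.25),
                                aMCI  = list(n = 33L, amp_mean = 0.840, amp_sd = 0.25),
                                naMCI = list(n = 20L, amp_mean = 1.085, amp_sd = 0.25)),
                              retest_r = 0.58,
                              session_shift = -0.05,
                              behavior = default_behavior_params(),
                              seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  cfg <- list(n_channels = as.integer(n_channels), channels = channels,
              fs_hz = fs_hz, base_freq_hz = base_freq_hz,
              oddball_freq_hz = oddball_freq_hz,
              base_amp_uv = base_amp_uv, oddball_amp_uv = oddball_amp_uv,
              channel_gain_base = channel_gain_base,
              channel_gain_oddball = channel_gain_oddball,
              noise_pink_uv = noise_pink_uv, noise_white_uv = noise_white_uv,
              noise_mode = noise_mode,
              artifact_rate_per_min = artifact_rate_per_min,
              artifact_amp_uv = artifact_amp_uv,
              artifact_dur_s = artifact_dur_s,
              groups = groups, retest_r = retest_r,
              session_shift = session_shift,
              behavior = behavior, seed = as.integer(seed))
  class(cfg) <- "fb_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$channels) == cfg$n_channels,
            cfg$fs_hz > 0, cfg$oddball_freq_hz > 0, cfg$base_freq_hz > 0,
            all(cfg$base_amp_uv >= 0), all(cfg$oddball_amp_uv >= 0),
            cfg$noise_pink_uv >= 0, cfg$noise_white_uv >= 0,
            cfg$retest_r >= -1, cfg$retest_r <= 1)
  hmax <- max(oddball_family_freqs(cfg), cfg$base_freq_hz * seq_along(cfg$base_amp_uv))
  if (cfg$fs_hz <= 2 * hmax)
    stop("sampling rate ", cfg$fs_hz, " Hz cannot represent the highest ",
         "simulated harmonic (", hmax, " Hz): aliasing")
  if (cfg$artifact_rate_per_min > 0 && cfg$artifact_amp_uv <= 250)
    stop("artifact_amp_uv must exceed the 250 uV suppression threshold")
  invisible(cfg)
}

#' Frequencies of the simulated oddball harmonic family
#'
#' Multiples of the oddball frequency that are not multiples of the base
#' frequency, one per configured amplitude. Defaults give
#' 0.6, 1.2, 1.8, 2.4, 3.6, 4.2, 4.8, 5.4, 6.6 Hz.
#'
#' @param cfg An `fb_sim_config`.
#' @return Numeric vector of frequencies in Hz.
#' @export
oddball_family_freqs <- function(cfg) {
  k <- 1L
  out <- numeric(0)
  ratio <- cfg$base_freq_hz / cfg$oddball_freq_hz
  while (length(out) < length(cfg$oddball_amp_uv)) {
    if (abs(k / ratio - round(k / ratio)) > 1e-9) out <- c(out, k * cfg$oddball_freq_hz)
    k <- k + 1L
  }
  out
}

## Frequency-domain noise synthesis. Returns a length-n time series whose
## one-sided amplitude spectrum targets sqrt(cp^2/f + cw^2) per bin, with
## cp, cw calibrated so each component contributes the requested RMS.
make_noise <- function(n, fs, pink_rms, white_rms, mode = "surrogate") {
  if (pink_rms == 0 && white_rms == 0) return(numeric(n))
  nb <- (n - 1L) %/% 2L                      # strictly positive, sub-Nyquist bins
  f <- (1:nb) * fs / n
  a_pink2 <- if (pink_rms > 0) {
    cp2 <- pink_rms^2 / (sum(1 / f) / 2)
    cp2 / f
  } else rep(0, nb)
  a_white2 <- rep(if (white_rms > 0) white_rms^2 * 2 / nb else 0, nb)
  amp <- sqrt(a_pink2 + a_white2)            # target per-bin amplitude (2|X|/n)
  if (mode == "gaussian") {
    z1 <- rnorm(nb); z2 <- rnorm(nb)
    re <- amp * z1 / sqrt(2); im <- amp * z2 / sqrt(2)
  } else {
    th <- runif(nb, 0, 2 * pi)
    re <- amp * cos(th); im <- amp * sin(th)
  }
  X <- complex(length.out = n)
  X[2:(nb + 1L)] <- complex(real = re, imaginary = im) * (n / 2)
  X[n:(n - nb + 1L)] <- Conj(X[2:(nb + 1L)])
  Re(fft(X, inverse = TRUE)) / n
}

#' Simulate one multichannel steady-state EEG recording
#'
#' Builds the deterministic steady-state signal (base harmonics plus the
#' oddball harmonic family scaled by `subject_amp`), adds background
#' noise per channel, and injects square-pulse artifacts at Poisson
#' times. Time zero of the steady-state phases is the trial onset
#' (`pad_s` seconds into the recording), so an epoch extracted at the
#' onset is exactly cycle-aligned.
#'
#' @param cfg An [simulation_config()].
#' @param subject_amp Multiplier applied to the oddball amplitudes
#'   (the subject's "true" oddball response strength).
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @param n_cycles Number of oddball cycles the recording must cover.
#' @param pad_s Padding in seconds before and after the trial.
#' @return An `fb_recording` whose `truth` attribute records the
#'   ground-truth amplitudes, trial onset, and injected artifact sample
#'   indices.
#' @export
simulate_recording <- function(cfg, subject_amp = 1, seed = cfg$seed,
                               n_cycles = 104L, pad_s = 0) {
  validate_sim_config(cfg)
  set.seed(seed)
  fs <- cfg$fs_hz
  dur <- n_cycles / cfg$oddball_freq_hz + 2 * pad_s
  n <- round(dur * fs)
  t <- (0:(n - 1L)) / fs - pad_s
  nch <- cfg$n_channels
  base_f <- cfg$base_freq_hz * seq_along(cfg$base_amp_uv)
  odd_f <- oddball_family_freqs(cfg)

  gb <- cfg$channel_gain_base[cfg$channels]
  go <- cfg$channel_gain_oddball[cfg$channels]
  ph_b <- matrix(runif(nch * length(base_f), 0, 2 * pi), nch)
  ph_o <- matrix(runif(nch * length(odd_f), 0, 2 * pi), nch)

  data <- matrix(0, nch, n, dimnames = list(cfg$channels, NULL))
  for (c in seq_len(nch)) {
    sig <- numeric(n)
    for (h in seq_along(base_f))
      sig <- sig + cfg$base_amp_uv[h] * gb[c] * sin(2 * pi * base_f[h] * t + ph_b[c, h])
    for (k in seq_along(odd_f))
      sig <- sig + cfg$oddball_amp_uv[k] * subject_amp * go[c] *
        sin(2 * pi * odd_f[k] * t + ph_o[c, k])
    data[c, ] <- sig + make_noise(n, fs, cfg$noise_pink_uv, cfg$noise_white_uv,
                                  cfg$noise_mode)
  }

  artifact_samples <- integer(0)
  if (cfg$artifact_rate_per_min > 0) {
    n_art <- rpois(1, cfg$artifact_rate_per_min * dur / 60)
    w <- max(1L, round(cfg$artifact_dur_s * fs))
    for (a in seq_len(n_art)) {
      s0 <- sample.int(max(1L, n - w), 1L)
      idx <- s0:(s0 + w - 1L)
      data[, idx] <- data[, idx] + sample(c(-1, 1), 1) * cfg$artifact_amp_uv
      artifact_samples <- c(artifact_samples, idx)
    }
  }

  rec <- fb_recording(data, fs, cfg$channels)
  attr(rec, "truth") <- list(subject_amp = subject_amp,
                             base_amp_uv = cfg$base_amp_uv,
                             oddball_amp_uv = cfg$oddball_amp_uv * subject_amp,
                             onset_s = pad_s,
                             artifact_samples = sort(unique(artifact_samples)))
  rec
}

## deterministic per-subject seeds derived from a cohort seed (kept < 2^31)
subject_seed <- function(seed, i, session = 1L) {
  (as.numeric(seed) * 7919 + i * 104729 + session * 1299709) %% 2147483647
}

#' Simulate a cohort of subjects with group structure
#'
#' Draws each subject's oddball amplitude from its group's normal
#' distribution and (optionally) generates a full EEG recording per
#' subject. Standardized group differences of the generated amplitudes
#' converge to the configured effect sizes as group sizes grow.
#'
#' @param cfg An [simulation_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @param make_recordings If `FALSE`, only the cohort table and
#'   ground-truth manifest are produced (fast; used for large
#'   sampling-distribution studies).
#' @param n_cycles,pad_s Passed to [simulate_recording()].
#' @return A list with `cohort` (data frame: `subject_id`, `group`,
#'   `session_id`, `true_oddball_amp`), `recordings` (named list of
#'   `fb_recording` or `NULL`), `events` (per-recording trial onset
#'   table), and `manifest` (ground truth, one row per recording).
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed, make_recordings = TRUE,
                            n_cycles = 104L, pad_s = 0) {
  validate_sim_config(cfg)
  set.seed(seed)
  rows <- list()
  for (g in names(cfg$groups)) {
    gs <- cfg$groups[[g]]
    amps <- rnorm(gs$n, gs$amp_mean, gs$amp_sd)
    rows[[g]] <- data.frame(
      subject_id = sprintf("%s_%02d", g, seq_len(gs$n)),
      group = g, session_id = 1L, true_oddball_amp = amps,
      stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL

  recordings <- NULL
  events <- NULL
  manifest <- cohort
  manifest$n_artifact_samples <- NA_integer_
  if (make_recordings) {
    recordings <- vector("list", nrow(cohort))
    names(recordings) <- cohort$subject_id
    events <- vector("list", nrow(cohort))
    names(events) <- cohort$subject_id
    for (i in seq_len(nrow(cohort))) {
      rec <- simulate_recording(cfg, cohort$true_oddball_amp[i],
                                seed = subject_seed(seed, i),
                                n_cycles = n_cycles, pad_s = pad_s)
      recordings[[i]] <- rec
      events[[i]] <- data.frame(onset_s = pad_s, trial_id = 1L)
      manifest$n_artifact_samples[i] <-
        length(attr(rec, "truth")$artifact_samples)
    }
  }
  list(cohort = cohort, recordings = recordings, events = events,
       manifest = manifest)
}

#' Simulate a two-session retest cohort
#'
#' Subject amplitudes in the two sessions follow a bivariate normal
#' model with correlation `retest_r` and an additive session-2 mean
#' shift `session_shift`; with equal session variances the population
#' consistency ICC(C,1) equals `retest_r`.
#'
#' @param cfg An [simulation_config()].
#' @param seed Integer seed.
#' @param groups Group specification (defaults to `cfg$groups`); pass a
#'   single-group list for homogeneous reliability studies.
#' @return A long-format cohort table: `subject_id`, `group`,
#'   `session_id` (1 or 2), `true_oddball_amp`.
#' @export
simulate_retest <- function(cfg, seed = cfg$seed, groups = cfg$groups) {
  set.seed(seed)
  r <- cfg$retest_r
  rows <- list()
  for (g in names(groups)) {
    gs <- groups[[g]]
    z1 <- rnorm(gs$n); z2 <- rnorm(gs$n)
    a1 <- gs$amp_mean + gs$amp_sd * z1
    a2 <- gs$amp_mean + cfg$session_shift +
      gs$amp_sd * (r * z1 + sqrt(1 - r^2) * z2)
    ids <- sprintf("%s_%02d", g, seq_len(gs$n))
    rows[[g]] <- data.frame(
      subject_id = rep(ids, 2L), group = g,
      session_id = rep(c(1L, 2L), each = gs$n),
      true_oddball_amp = c(a1, a2), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape a two-session cohort table to a subjects x sessions matrix
#'
#' @param tbl Long table with `subject_id`, `session_id` and a value column.
#' @param value Name of the value column.
#' @return Numeric matrix (subjects in rows, sessions in columns).
#' @export
retest_matrix <- function(tbl, value = "true_oddball_amp") {
  sess <- sort(unique(tbl$session_id))
  subj <- unique(tbl$subject_id)
  m <- sapply(sess, function(s) {
    v <- tbl[tbl$session_id == s, ]
    v[[value]][match(subj, v$subject_id)]
  })
  dimnames(m) <- list(subj, paste0("session", sess))
  m
}

#' Default behavioural generator parameters
#'
#' Group-level parameters of the behavioural instruments: binomial 2AFC
#' accuracy with log-normal decision times, a PVT reaction-time mixture
#' (log-normal base, occasional false starts, a slow lapse tail), per-
#' subset DMS-48 accuracies, and normal ACE-III subscale scores. The
#' cognitive-score means and SDs correspond to a typical healthy older
#' adult / amnestic MCI / non-amnestic MCI cohort (ACE-III memory /26:
#' 25(2), 14(4), 24(1)).
#'
#' @return A nested parameter list.
#' @export
default_behavior_params <- function() {
  list(
    twoafc = list(n_oddball = 8L, n_standard = 8L,
                  p_oddball = c(HOA = 0.90, aMCI = 0.70, naMCI = 0.85),
                  p_standard = c(HOA = 0.55, aMCI = 0.50, naMCI = 0.52),
                  rt_meanlog = c(HOA = log(1.9), aMCI = log(2.6), naMCI = log(2.2)),
                  rt_sdlog = 0.40),
    pvt = list(n_trials = 30L,
               rt_meanlog = c(HOA = log(0.35), aMCI = log(0.40), naMCI = log(0.37)),
               rt_sdlog = 0.12,
               lapse_p = c(HOA = 0.045, aMCI = 0.18, naMCI = 0.13),
               false_start_p = 0.02),
    dms48 = list(p = list(HOA = c(unique = 0.98, paired = 0.95, abstract = 0.90),
                          aMCI = c(unique = 0.85, paired = 0.72, abstract = 0.62),
                          naMCI = c(unique = 0.95, paired = 0.90, abstract = 0.83))),
    ace = list(memory_mean = c(HOA = 25, aMCI = 14, naMCI = 24),
               memory_sd = c(HOA = 2, aMCI = 4, naMCI = 1),
               total_mean = c(HOA = 96, aMCI = 76, naMCI = 90),
               total_sd = c(HOA = 3, aMCI = 7, naMCI = 4),
               memory_max = 26, total_max = 100)
  )
}

#' Simulate behavioural response tables for a cohort
#'
#' Generates long-format trial rows for the post-stream 2AFC task, the
#' psychomotor vigilance task and the DMS-48 recognition test, plus an
#' ACE-III summary table, one set per subject.
#'
#' @param cfg An [simulation_config()] (uses `cfg$behavior`).
#' @param cohort Data frame with `subject_id` and `group`
#'   (e.g. from [simulate_cohort()]).
#' @param seed Integer seed.
#' @return List with `responses` (rows: `subject_id`, `task`, `item_id`,
#'   `item_class`, `correct`, `rt_s`) and `ace` (rows: `subject_id`,
#'   `ace_total`, `ace_memory`).
#' @export
simulate_behavior <- function(cfg, cohort, seed = cfg$seed) {
  set.seed(seed)
  bp <- cfg$behavior
  res <- list(); ace <- list()
  cohort <- cohort[!duplicated(cohort$subject_id), ]
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]; g <- cohort$group[i]

    ## 2AFC: oddball and standard item classes
    n_o <- bp$twoafc$n_oddball; n_s <- bp$twoafc$n_standard
    cls <- c(rep("oddball", n_o), rep("standard", n_s))
    p <- ifelse(cls == "oddball", bp$twoafc$p_oddball[g], bp$twoafc$p_standard[g])
    afc <- data.frame(subject_id = sid, task = "fastball_2afc",
                      item_id = sprintf("afc_%02d", seq_along(cls)),
                      item_class = cls,
                      correct = rbinom(length(cls), 1L, p) == 1L,
                      rt_s = rlnorm(length(cls), bp$twoafc$rt_meanlog[g],
                                    bp$twoafc$rt_sdlog),
                      stringsAsFactors = FALSE)

    ## PVT: base lognormal RT, false starts (< 100 ms), lapse tail (> 500 ms)
    np <- bp$pvt$n_trials
    rt <- rlnorm(np, bp$pvt$rt_meanlog[g], bp$pvt$rt_sdlog)
    lapse <- runif(np) < bp$pvt$lapse_p[g]
    rt[lapse] <- 0.5 + rlnorm(sum(lapse), log(0.25), 0.5)
    fs_trial <- runif(np) < bp$pvt$false_start_p
    rt[fs_trial] <- runif(sum(fs_trial), 0.03, 0.099)
    pvt <- data.frame(subject_id = sid, task = "pvt",
                      item_id = sprintf("pvt_%02d", seq_len(np)),
                      item_class = "pvt", correct = NA, rt_s = rt,
                      stringsAsFactors = FALSE)

    ## DMS-48: three 16-item subsets
    sub <- rep(c("unique", "paired", "abstract"), each = 16L)
    pd <- bp$dms48$p[[g]][sub]
    dms <- data.frame(subject_id = sid, task = "dms48",
                      item_id = sprintf("dms_%02d", seq_along(sub)),
                      item_class = sub,
                      correct = rbinom(length(sub), 1L, pd) == 1L,
                      rt_s = NA_real_, stringsAsFactors = FALSE)

    res[[i]] <- rbind(afc, pvt, dms)
    mem <- round(min(bp$ace$memory_max,
                     max(0, rnorm(1, bp$ace$memory_mean[g], bp$ace$memory_sd[g]))))
    tot <- round(min(bp$ace$total_max,
                     max(0, rnorm(1, bp$ace$total_mean[g], bp$ace$total_sd[g]))))
    ace[[i]] <- data.frame(subject_id = sid, ace_total = tot, ace_memory = mem,
                           stringsAsFactors = FALSE)
  }
  list(responses = do.call(rbind, res), ace = do.call(rbind, ace))
}
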
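test_that("amplitude normalization recovers bin-aligned sinusoid amplitudes", {
  ep <- tone_epoch(0.6, amp_uv = 2, n_cycles = 26)
  sp <- amplitude_spectrum(ep)
  k <- which.min(abs(sp$freqs_hz - 0.6))
  expect_equal(unname(sp$amp_uv[1, k]), 2, tolerance = 1e-9)
  expect_lt(max(sp$amp_uv[1, -k]), 1e-9)
  # zero signal -> zero spectrum
  ep0 <- extract_epoch(fb_recording(matrix(0, 1, 5200), 120), 0, 26, 0.6)
  expect_equal(max(amplitude_spectrum(ep0)$amp_uv), 0)
})

test_that("SNR is a self-normalizing neighbour-bin ratio", {
  # flat spectrum -> SNR exactly 1 wherever evaluated
  fake <- structure(list(freqs_hz = (0:4000) * 0.0058, df_hz = 0.0058,
                         amp_uv = matrix(3.7, 1, 4001),
                         channel_labels = "ch"), class = "fb_spectrum")
  s <- snr_spectrum(fake)
  expect_equal(range(s$snr, na.rm = TRUE), c(1, 1))
  # edge bins lack a full neighbourhood
  expect_true(all(is.na(s$snr[1, 1:17])))
  # a single elevated bin has SNR equal to its ratio over the floor
  amp <- matrix(1, 1, 4001); amp[1, 2000] <- 10
  fake$amp_uv <- amp
  s2 <- snr_spectrum(fake)
  expect_equal(s2$snr[1, 2000], 10)
})

test_that("the vectorized SNR equals an independent brute-force loop", {
  cfg <- quick_sim_config(noise_mode = "gaussian")
  sp <- amplitude_spectrum(extract_epoch(simulate_recording(cfg, 1, seed = 12,
                                                            n_cycles = 26),
                                         0, 26, 0.6))
  s <- snr_spectrum(sp)
  for (ch in c(1, 5)) {
    brute <- snr_brute(sp$amp_uv[ch, ], sp$df_hz)
    idx <- which(!is.na(brute))
    expect_equal(s$snr[ch, idx], brute[idx], tolerance = 1e-12)
    expect_equal(which(is.na(s$snr[ch, ])), which(is.na(brute)))
  }
})

test_that("SNR is invariant to rescaling the epoch", {
  cfg <- quick_sim_config()
  ep <- extract_epoch(simulate_recording(cfg, 1, seed = 14, n_cycles = 26),
                      0, 26, 0.6)
  s1 <- snr_spectrum(amplitude_spectrum(ep))
  ep$data <- ep$data * 37.5
  s2 <- snr_spectrum(amplitude_spectrum(ep))
  expect_equal(s1$snr, s2$snr, tolerance = 1e-12)
})

test_that("harmonic selection recovers the injected family and matches a brute-force Z", {
  cfg <- quick_sim_config()
  gs <- simulate_global_spectra(cfg, 6, seed0 = 300, n_cycles = 104)
  sel <- harmonic_group_z(gs$amp, gs$freqs_hz)
  expect_equal(sel$included, c(0.6, 1.2, 1.8, 2.4, 3.6, 4.2, 4.8, 5.4, 6.6))
  expect_false(any(sel$included %% 3 == 0))
  # brute-force Z at 0.6 Hz on the grand average
  grand <- colMeans(gs$amp)
  df <- gs$freqs_hz[2] - gs$freqs_hz[1]
  k <- which.min(abs(gs$freqs_hz - 0.6))
  w <- floor(0.10 / df + 1e-9)
  nbh <- c((k - w):(k - 2), (k + 2):(k + w))
  z_ref <- (grand[k] - mean(grand[nbh])) / sd(grand[nbh])
  expect_equal(sel$candidates$group_z[sel$candidates$freq_hz == 0.6],
               z_ref, tolerance = 1e-12)
})

test_that("selection falls back to the nominal family when nothing is significant", {
  cfg <- quick_sim_config(oddball_amp_uv = rep(0, 9), noise_mode = "gaussian")
  gs <- simulate_global_spectra(cfg, 4, seed0 = 400, n_cycles = 26,
                                amp_mean = 0, amp_sd = 0)
  expect_warning(sel <- harmonic_group_z(gs$amp, gs$freqs_hz, z_crit = 50),
                 "falling back")
  expect_equal(sel$included, c(0.6, 1.2, 1.8, 2.4, 3.6, 4.2, 4.8, 5.4, 6.6))
})

test_that("F and f+ summarize the SNR spectrum per electrode", {
  # flat SNR gives F = f+ = 1 everywhere
  cfg <- quick_sim_config()
  fake <- structure(list(freqs_hz = (0:4000) * (0.6 / 104), df_hz = 0.6 / 104,
                         snr = matrix(1, 8, 4001,
                                      dimnames = list(cfg$channels, NULL)),
                         channel_labels = cfg$channels), class = "fb_snr")
  m <- compute_fastball_metrics(fake, c(0.6, 1.2))
  expect_equal(unname(m$f_plus), rep(1, 8))
  expect_equal(unname(m$F_snr), rep(1, 8))
  expect_equal(m$f_plus_max, 1)
  expect_equal(m$max_electrode, "O1")        # first channel wins ties

  # hand-built two-electrode table
  freqs <- seq(0, 8, by = 0.2)
  bin <- function(f) vapply(f, function(x) which.min(abs(freqs - x)), 1L)
  snrm <- matrix(1, 2, length(freqs), dimnames = list(c("A", "B"), NULL))
  snrm[1, bin(c(0.6, 1.2, 1.8))] <- c(4, 6, 8)
  snrm[2, bin(c(0.6, 1.2, 1.8))] <- c(2, 3, 4)
  snrm[, bin(3)] <- c(10, 20)
  fake2 <- structure(list(freqs_hz = freqs, df_hz = 0.2, snr = snrm,
                          channel_labels = c("A", "B")), class = "fb_snr")
  m2 <- compute_fastball_metrics(fake2, c(0.6, 1.2, 1.8))
  expect_equal(unname(m2$f_plus), c(mean(c(4, 6, 8)), mean(c(2, 3, 4))))
  expect_equal(unname(m2$F_snr), c(10, 20))
  expect_equal(m2$f_plus_scalp_avg, mean(c(6, 3)))
  expect_equal(m2$max_electrode, "A")

  # unavailable frequencies are reported by name
  snrm[1, bin(1.2)] <- NA
  fake2$snr <- snrm
  expect_error(compute_fastball_metrics(fake2, c(0.6, 1.2)), "1.2")
  expect_error(compute_fastball_metrics(fake2, 9.0), "grid")
})

test_that("f+ grows with the injected oddball amplitude and has a unit null floor", {
  cfg <- quick_sim_config(noise_mode = "gaussian")
  fplus_at <- function(amp, seed) {
    ep <- extract_epoch(simulate_recording(cfg, amp, seed = seed, n_cycles = 104),
                        0, 104, 0.6)
    s <- snr_spectrum(amplitude_spectrum(ep))
    compute_fastball_metrics(s, c(0.6, 1.2, 1.8, 2.4, 3.6, 4.2, 4.8,
                                  5.4, 6.6))$f_plus_scalp_avg
  }
  vals <- vapply(c(0, 0.5, 1, 2), fplus_at, numeric(1), seed = 77)
  expect_true(all(diff(vals) > 0))
  # null oddball: population mean f+ near 1 (CI contains 1)
  nulls <- vapply(1:10, function(i) fplus_at(0, seed = 500 + i), numeric(1))
  ci <- mean(nulls) + c(-1, 1) * qt(0.975, 9) * sd(nulls) / sqrt(10)
  expect_gt(1, ci[1])
  expect_lt(1, ci[2])
})

test_that("metrics stack into a long cohort table", {
  cfg <- quick_sim_config()
  mk <- function(id) {
    ep <- extract_epoch(simulate_recording(cfg, 1, seed = 600 + id, n_cycles = 26),
                        0, 26, 0.6)
    compute_fastball_metrics(snr_spectrum(amplitude_spectrum(ep)),
                             c(0.6, 1.2), subject_id = paste0("s", id),
                             session_id = 1L)
  }
  tbl <- metrics_table(list(mk(1), mk(2)),
                       cohort = data.frame(subject_id = c("s1", "s2"),
                                           group = c("HOA", "aMCI")))
  expect_equal(nrow(tbl), 16)
  expect_setequal(unique(tbl$group), c("HOA", "aMCI"))
  expect_true(all(c("F_snr", "f_plus", "f_plus_max", "max_electrode") %in%
                    names(tbl)))
})
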
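---
title: "Fastball FPVS analysis: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fastball FPVS analysis: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastball)
```

# The measurement model

Fastball is a fast periodic visual stimulation (FPVS) paradigm for
recognition memory. Images appear at a base rate of 3 per second
(166 ms image + 166 ms blank, so one onset every 332 ms); every fifth
image is an "oddball" drawn from a previously studied set, giving an
oddball rate of 0.6 per second. A brain that treats old and new images
identically produces EEG energy only at 3 Hz and its multiples. A brain
that discriminates them modulates its response with period 5 images,
which adds energy at 0.6 Hz and its harmonics — frequencies that do not
exist in the physical stimulus train. Recognition is therefore read out
as narrowband spectral energy at known frequencies, with the adjacent
bins of the same spectrum serving as a built-in noise estimate.

The default schedule has 416 standards and 8 oddball identities
repeated 13 times each: 520 images, 104 oddball presentations, and a
nominal duration of 172.64 s (analysed as an integer number of oddball
cycles, below). Oddball identities are placed so that the same
oddball never occurs in consecutive mini-sequences, and 10% of
mini-sequences are flagged as attention-check targets.

## Summary metrics

For each electrode the epoch's amplitude spectrum $A_k$ (scaled as
$2|X_k|/N$ so a sinusoid of amplitude $a$ µV yields $A = a$ at its bin)
is converted to a signal-to-noise ratio

$$\mathrm{SNR}_k = \frac{A_k}{\operatorname{mean}(A_j)},\qquad
j \in \pm 0.10\ \mathrm{Hz}\ \text{around } k,\ \text{excluding one
adjacent bin per side},$$

With the default 173.33-s epoch the bin spacing is
$0.6/104 \approx 0.0058$ Hz, so the ±0.10 Hz neighbourhood holds 17
bins per side and the noise estimate averages 32 bins. Two scalar
summaries follow:

- **F** — the SNR at the 3 Hz base frequency (general visual
  response);
- **f+** — the mean SNR over the *included* oddball harmonics
  (recognition response), reported per electrode, as the scalp average,
  and at the maximal electrode.

## Data-driven harmonic selection

Which oddball harmonics carry signal is decided on the group grand
average of each subject's channel-mean amplitude spectrum, not per
subject, so the same frequencies enter every subject's f+. Candidates
are the multiples of 0.6 Hz up to 20 Hz that are not multiples of 3 Hz
(those belong to the base response). Each candidate gets a Z score
against its 32 neighbour bins, and the included set is every candidate
up to the *highest* candidate with Z > 1.96 — harmonics below a
significant one stay in even if individually weak, keeping the set an
uninterrupted family. Under the default generative settings this
procedure returns {0.6, 1.2, 1.8, 2.4, 3.6, 4.2, 4.8, 5.4, 6.6} Hz. If
no candidate reaches threshold the nominal nine-member family up to
6.6 Hz is used, with a warning.

# The preprocessing chain

`preprocess_recording()` applies, in a fixed order:

1. **Common-average reference** (`rereference = TRUE`).
2. **Zero-phase low-pass**: 2nd-order Butterworth at 40 Hz applied
   forward and backward (`signal::filtfilt`), i.e. a two-pass 24
   dB/octave response with no phase distortion. Tests verify the
   realized magnitude against the analytic prewarped bilinear-transform
   response.
3. **Resampling to 120 Hz**. `signal::resample` showed amplitude
   errors above 10% on in-band tones in this configuration, so the
   package carries a small polyphase implementation (zero-stuffing, a
   windowed-sinc low-pass via `signal::fir1`, FFT convolution, exact
   group-delay compensation); its in-band error is below 1% and it is
   validated against analytic tones. Resampling refuses to run before
   the anti-alias low-pass.
4. **Integer-cycle epoching**: 104 oddball cycles = 20 800 samples =
   173.33 s. Truncating the recording to an exact integer number of
   0.6 Hz cycles puts every harmonic of interest exactly on an FFT bin,
   eliminating spectral leakage by construction — this is why epoch
   length is defined in cycles, not seconds.
5. **Polynomial detrend** (order 3) to remove drift without touching
   the tagged frequencies (a 0.6 Hz tone over 104 cycles is essentially
   orthogonal to a cubic).
6. **Artifact suppression**: samples exceeding ±250 µV are zeroed and
   each zeroed run is flanked by 670-point half-Hanning ramps
   (≈ 5.6 s at 120 Hz) so that no step discontinuity — itself a
   broadband spectral contaminant — is introduced. Overlapping ramps
   from nearby runs combine by the pointwise minimum envelope. The
   reported `fraction_zeroed` counts fully zeroed samples only.

# The generative model

`simulation_config()` fixes every parameter of the simulator. Signal:
a 3 Hz base response (harmonics at 3, 6, 9 Hz; default amplitudes 2.0,
0.7, 0.25 µV) and a 0.6 Hz oddball family (nine harmonics, geometric
decay from 0.8 µV) with distinct fixed scalp gain profiles — the base
response is occipital-dominant, the oddball response largest at
centro-parietal sites. A per-subject scalar `subject_amp` multiplies
the oddball family only; cohorts draw it from per-group normal
distributions. The default groups mirror a realistic clinical study:
healthy older adults (n = 54, mean 1.00), amnestic MCI (n = 33, mean
0.840) and non-amnestic MCI (n = 20, mean 1.085), all with SD 0.25 —
i.e. configured standardized differences of 0.64 (HOA vs aMCI) and 0.98
(aMCI vs naMCI). Two-session data use a bivariate-normal construction
with correlation `retest_r = 0.58` and a small session shift (−0.05).

## Noise: surrogate by default, Gaussian for Monte Carlo

Noise is synthesized in the frequency domain with target magnitude
$\sqrt{c_p^2/f + c_w^2}$ (pink + white, calibrated to the requested
RMS). Two modes differ in what is random:

- **`"surrogate"` (default)**: the per-bin magnitudes are exactly the
  deterministic target and only the phases are random. The amplitude
  spectrum of pure noise is then perfectly smooth, which gives the
  package exact spectral control: neighbour-bin Z scores of null
  candidates are ~0, so group-level harmonic selection recovers exactly
  the injected family rather than a family plus occasional false
  positives. With ~18 null candidates tested at Z > 1.96, magnitude
  randomness would make an occasional spurious inclusion a statistical
  certainty across seeds; phase-only randomness removes that without
  touching the thing being tested (the selection logic itself).
- **`"gaussian"`**: independent complex-Gaussian Fourier coefficients
  with the same expected magnitude — genuinely random amplitudes, used
  wherever the *distribution* of the estimator matters (SNR noise-floor
  checks, null f+ behaviour).

The surrogate choice is a deliberate design decision, not an attempt at
physiological realism: real EEG noise has random magnitudes, session-
specific spectra, and non-stationarities that neither mode reproduces.
What the generator does guarantee is exact ground truth for every
recovery test in the package.

Artifacts are simulated as brief (0.5 s) 300 µV boxcar excursions at a
configurable rate; their sample indices travel with the recording as
ground truth so suppression can be tested as a superset property.

One related subtlety: the common-average reference subtracts the mean
of eight *independently phased* noise channels, which reintroduces
magnitude fluctuations into each channel even under surrogate noise.
Validation of the group-level selection step therefore runs on the
simulator's ideal-reference output directly (the simulated channels are
already referenced), while the full pipeline keeps CAR for realism.

## Behaviour

The behavioural generator produces per-subject 2AFC recognition trials
(16), psychomotor vigilance RTs (30, lognormal with a lapse mixture and
occasional false starts), DMS-48 trials (48, in three 16-item subsets:
unique, paired, abstract), and ACE-III-style totals and memory
subscores, with group-specific parameters (e.g. slower PVT medians and
more lapses in aMCI). Scoring follows fixed conventions: PVT responses
under 100 ms are discarded from all statistics, retained responses over
500 ms count as lapses but stay in the median; the amnestic cutoff is
`floor(mean − 2·SD)` of control memory scores (25 and 2 give 21), and
scores ≤ 21 classify as amnestic.

# Statistical layer

- **ANCOVA**: group × electrode on the stacked per-electrode rows with
  sum-to-zero contrasts and type-III sums of squares (`car::Anova`),
  the base response F as covariate; electrode is treated as a fixed
  factor with no subject random effect. This mirrors a common reporting
  style in the FPVS literature and is implemented as a faithful
  reproduction, not a statistical endorsement; partial η² accompanies
  each term and pairwise Cohen's d is computed on subject-level
  (electrode-averaged) outcomes.
- **Nonparametrics**: Kruskal–Wallis omnibus plus pairwise tie-corrected
  normal-approximation Mann–Whitney tests reported in the convention of
  mainstream statistical software: U is the smaller of the two U
  statistics, Z is non-positive, no continuity correction, Bonferroni
  multiplication by the number of pairs.
- **Bootstrap regression**: case resampling (B = 1000), percentile
  intervals, and the +1-corrected two-sided bootstrap p value
  $2\min(P(\beta^* \le 0), P(\beta^* \ge 0))$. Case resampling was
  chosen over residual resampling because the cohort rows are the
  sampling units; coverage is verified empirically (500 simulated
  datasets, nominal 95%, accepted band 92–98%).
- **ICC**: two-way mixed-model intraclass correlations from the ANOVA
  mean squares — ICC(C,1), ICC(A,1), ICC(C,k), ICC(A,k) — with F-based
  confidence intervals (the absolute-agreement single-measure interval
  uses the Satterthwaite-style df of McGraw & Wong; the A,k interval
  applies Spearman–Brown to the A,1 bounds). The implementation was
  cross-checked against an independent reference implementation to full
  reported precision. Qualitative bands use left-closed boundaries:
  poor < 0.40 ≤ moderate < 0.60 ≤ good < 0.75 ≤ excellent.

# Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed and is
bit-reproducible; per-subject seeds derive deterministically from the
cohort seed. Validation runs at desk scale: single recordings at the
120 Hz analysis rate, 104-cycle epochs, cohorts of up to a few hundred
amplitude draws, 30 subjects for harmonic selection, and 500 × 1000
bootstrap refits — all within seconds to a few minutes. The
`run_manifest()` record (package version, configuration hash, input
hashes, per-stage counts) accompanies pipeline outputs so a run can be
audited after the fact.

Known limits worth restating: the generator's noise is stationary and
its artifacts are schematic; scalp topographies are fixed gain vectors,
not volume-conducted sources; and the clinical group means are
generative settings for recovery testing, not empirical claims. Within
those limits, every estimator exposed by the package is validated
against either an analytic oracle or parameter recovery from known
ground truth.
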
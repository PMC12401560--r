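#' Write / read a recording as a numeric matrix with a JSON sidecar
#'
#' The data file (`<prefix>.tsv`) holds one column per channel, one row
#' per sample; the sidecar (`<prefix>.json`) records the sampling rate,
#' channel labels, unit (µV) and reference.
#'
#' @param rec An `fb_recording`.
#' @param prefix Path prefix (without extension).
#' @return `prefix` invisibly (write) or an `fb_recording` (read).
#' @export
write_recording <- function(rec, prefix) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  data.table::fwrite(df, paste0(prefix, ".tsv"), sep = "\t")
  jsonlite::write_json(list(fs_hz = rec$fs_hz, channels = rec$channel_labels,
                            units = "uV", reference = rec$reference),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  data_path <- paste0(prefix, ".tsv")
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(data_path) || file.size(data_path) == 0)
    stop("missing or empty recording data file: ", data_path)
  if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs_hz)) stop("sidecar lacks the sampling rate (fs_hz)")
  if (!is.null(meta$units) && !meta$units %in% c("uV", "µV", "microvolt"))
    stop("unsupported unit '", meta$units, "': expected microvolts")
  df <- data.table::fread(data_path, sep = "\t")
  if (!is.null(meta$channels)) {
    if (length(meta$channels) != ncol(df))
      stop("sidecar lists ", length(meta$channels), " channels but data has ",
           ncol(df), " columns")
    if (!identical(names(df), as.character(meta$channels)))
      stop("channel labels in sidecar and data header disagree")
  }
  fb_recording(t(as.matrix(df)), meta$fs_hz,
               as.character(meta$channels %||% names(df)),
               meta$reference %||% "as-recorded")
}

#' Write / read a trial event table (TSV)
#'
#' @param events Data frame with `onset_s` (and optionally `trial_id`).
#' @param path TSV path.
#' @return `path` invisibly (write) or a data frame (read).
#' @export
write_events <- function(events, path) {
  data.table::fwrite(events, path, sep = "\t")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("missing events file: ", path)
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Full parameter set of the analysis pipeline
#'
#' Collects every tunable parameter with defaults equal to the
#' standard protocol: 3 Hz base / 0.6 Hz oddball frequency-tagging,
#' 40 Hz zero-phase low-pass, 120 Hz analysis rate, 104-cycle epochs,
#' 3rd-order polynomial detrend, ±250 µV artifact threshold with a
#' 670-point half-Hanning taper, ±0.10 Hz SNR neighbourhood excluding
#' one adjacent bin, Z > 1.96 harmonic selection up to 20 Hz, and 1000
#' bootstrap resamples. Unknown keys are rejected.
#'
#' @param ... Named overrides of nested defaults, e.g.
#'   `preprocessing = list(detrend_order = 2)`.
#' @return Object of class `fb_config` (a validated nested list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    base_freq_hz = 3.0,
    oddball_freq_hz = 0.6,
    preprocessing = list(rereference = TRUE, lowpass_hz = 40,
                         filter_order = 2L, analysis_fs_hz = 120,
                         n_cycles = 104L, detrend_order = 3L,
                         artifact_threshold_uv = 250, taper_points = 670L),
    spectral = list(half_width_hz = 0.10, n_adjacent_excluded = 1L,
                    z_crit = 1.96, max_candidate_hz = 20, use_snr = FALSE),
    stats = list(bootstrap_B = 1000L, conf = 0.95),
    seed = 1L)
  overrides <- list(...)
  merge_into <- function(base, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base))
        stop("unknown configuration key: ", paste0(path, nm))
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], over[[nm]], paste0(path, nm, "$"))
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_into(cfg, overrides)
  class(cfg) <- "fb_config"
  cfg
}

#' Serialize / load a pipeline configuration as YAML
#'
#' Round-trips through [pipeline_config()] so unknown keys in a file are
#' rejected and defaults fill any omitted key.
#'
#' @param config An `fb_config`.
#' @param path YAML file path.
#' @return `path` invisibly (write) or an `fb_config` (read).
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

## md5 of a serialized object, via a temporary file
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}

#' Build a reproducibility manifest for a pipeline run
#'
#' @param config The `fb_config` used.
#' @param input_files Character vector of input file paths (hashed).
#' @param counts Named list of per-stage counts (epochs processed,
#'   fraction of data zeroed, subjects excluded, ...).
#' @return A list suitable for [jsonlite::write_json()].
#' @export
run_manifest <- function(config, input_files = character(0), counts = list()) {
  list(package_version = as.character(utils::packageVersion("fastball")),
       config_hash = object_hash(unclass(config)),
       input_hashes = if (length(input_files))
         as.list(tools::md5sum(input_files)) else list(),
       counts = counts,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the end-to-end analysis on a simulated cohort
#'
#' Generates a cohort with [simulate_cohort()], preprocesses each
#' recording, computes per-subject spectra and global averages, selects
#' the oddball harmonics on the grand average, computes F / f+ metrics
#' per subject, scores the behavioural tables, and (optionally) writes
#' metrics, scores and a reproducibility manifest to `out_dir`.
#' Identical configuration and seed reproduce identical outputs.
#'
#' @param sim_cfg An [simulation_config()].
#' @param config An [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param n_cycles Oddball cycles per epoch (the protocol value is 104;
#'   smaller values give proportionally shorter demonstration runs with
#'   coarser frequency resolution).
#' @return List with `metrics` (long cohort table), `selection`,
#'   `scores`, `cohort` and `manifest`.
#' @export
run_pipeline <- function(sim_cfg = simulation_config(),
                         config = pipeline_config(),
                         out_dir = NULL, n_cycles = config$preprocessing$n_cycles) {
  config$preprocessing$n_cycles <- n_cycles
  sim <- simulate_cohort(sim_cfg, seed = sim_cfg$seed, make_recordings = TRUE,
                         n_cycles = n_cycles)
  sp <- config$spectral
  metrics <- vector("list", nrow(sim$cohort))
  globals <- NULL
  snrs <- vector("list", nrow(sim$cohort))
  frac_zeroed <- numeric(nrow(sim$cohort))
  for (i in seq_len(nrow(sim$cohort))) {
    ep <- preprocess_recording(sim$recordings[[i]],
                               onset_s = sim$events[[i]]$onset_s[1L],
                               config = config)
    frac_zeroed[i] <- ep$fraction_zeroed
    spec <- amplitude_spectrum(ep)
    snrs[[i]] <- snr_spectrum(spec, sp$half_width_hz, sp$n_adjacent_excluded)
    g <- global_average_spectrum(spec)
    if (is.null(globals)) globals <- matrix(NA_real_, nrow(sim$cohort), length(g))
    globals[i, ] <- g
    freqs <- spec$freqs_hz
  }
  sel <- harmonic_group_z(globals, freqs,
                          base_freq = config$base_freq_hz,
                          oddball_freq = config$oddball_freq_hz,
                          max_candidate_hz = sp$max_candidate_hz,
                          z_crit = sp$z_crit,
                          half_width_hz = sp$half_width_hz,
                          n_adjacent_excluded = sp$n_adjacent_excluded,
                          use_snr = sp$use_snr)
  for (i in seq_len(nrow(sim$cohort)))
    metrics[[i]] <- compute_fastball_metrics(
      snrs[[i]], sel, base_freq = config$base_freq_hz,
      subject_id = sim$cohort$subject_id[i],
      session_id = sim$cohort$session_id[i])
  mtab <- metrics_table(metrics, sim$cohort)

  beh <- simulate_behavior(sim_cfg, sim$cohort, seed = sim_cfg$seed)
  scores <- score_all(beh$responses, beh$ace)

  manifest <- run_manifest(config, counts = list(
    n_subjects = nrow(sim$cohort),
    n_epochs = nrow(sim$cohort),
    mean_fraction_zeroed = mean(frac_zeroed),
    harmonics_included = length(sel$included)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(mtab, file.path(out_dir, "metrics.csv"))
    data.table::fwrite(scores, file.path(out_dir, "scores.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(metrics = mtab, selection = sel, scores = scores,
       cohort = sim$cohort, manifest = manifest)
}
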
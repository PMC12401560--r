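#' Score a psychomotor vigilance task (PVT) run
#'
#' Responses faster than `min_rt_s` (false starts) are discarded from
#' all statistics; retained responses slower than `lapse_rt_s` count as
#' lapses. The median reaction time is computed over all retained
#' responses; by convention lapse trials stay in the median (only
#' sub-100 ms responses are discarded), which can be disabled.
#'
#' @param rts Reaction times in seconds.
#' @param min_rt_s Discard threshold (default 0.100 s).
#' @param lapse_rt_s Lapse threshold (default 0.500 s).
#' @param lapses_in_median Keep lapse trials in the median (default TRUE).
#' @return List: `median_rt_s`, `n_lapses`, `n_discarded`. If every
#'   response is discarded the median is `NA` with a warning.
#' @export
score_pvt <- function(rts, min_rt_s = 0.100, lapse_rt_s = 0.500,
                      lapses_in_median = TRUE) {
  stopifnot(all(rts > 0))
  keep <- rts >= min_rt_s
  retained <- rts[keep]
  n_lapses <- sum(retained > lapse_rt_s)
  med_pool <- if (lapses_in_median) retained else retained[retained <= lapse_rt_s]
  if (!length(med_pool)) {
    warning("all responses discarded; median unavailable")
    med <- NA_real_
  } else med <- median(med_pool)
  list(median_rt_s = med, n_lapses = n_lapses, n_discarded = sum(!keep))
}

#' Score a two-alternative forced-choice block per item class
#'
#' @param rows Data frame with `item_class`, `correct` (logical) and
#'   optionally `rt_s`.
#' @return Data frame, one row per item class: `item_class`, `n`,
#'   `accuracy`, `median_rt_s` (NA when no RTs are present).
#' @export
score_2afc <- function(rows) {
  stopifnot(all(c("item_class", "correct") %in% names(rows)))
  cls <- sort(unique(rows$item_class))
  out <- lapply(cls, function(cl) {
    r <- rows[rows$item_class == cl, ]
    data.frame(item_class = cl, n = nrow(r),
               accuracy = mean(r$correct),
               median_rt_s = if ("rt_s" %in% names(r) && any(!is.na(r$rt_s)))
                 median(r$rt_s, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Score a DMS-48 recognition block
#'
#' Accuracy over all 48 trials and over the three 16-item subsets
#' (unique images, paired pictures, abstract items).
#'
#' @param rows Data frame with `item_class` in
#'   `c("unique", "paired", "abstract")` and `correct`.
#' @return List: `total_acc`, `unique_acc`, `paired_acc`, `abstract_acc`.
#' @export
score_dms48 <- function(rows) {
  stopifnot(all(rows$item_class %in% c("unique", "paired", "abstract")))
  acc <- function(cl) {
    r <- rows$correct[rows$item_class == cl]
    if (!length(r)) NA_real_ else mean(r)
  }
  list(total_acc = mean(rows$correct),
       unique_acc = acc("unique"),
       paired_acc = acc("paired"),
       abstract_acc = acc("abstract"))
}

#' Derive an impairment cutoff from control norms
#'
#' The cutoff is `floor(mean - k * sd)` of the control scores; scores at
#' or below the cutoff are classed as amnestic. With control memory
#' scores of mean 25 and SD 2 (and k = 2) the cutoff is 21.
#'
#' @param control_scores Control-group scores (ignored if `mean`/`sd`
#'   are given).
#' @param k Number of standard deviations below the control mean.
#' @param mean,sd Optional known norms, bypassing estimation.
#' @return Integer cutoff.
#' @export
cutoff_from_norms <- function(control_scores = NULL, k = 2,
                              mean = NULL, sd = NULL) {
  if (is.null(mean)) mean <- base::mean(control_scores)
  if (is.null(sd)) sd <- stats::sd(control_scores)
  if (is.na(sd)) sd <- 0
  as.integer(floor(mean - k * sd))
}

#' Classify MCI subtype from an ACE-III memory subscale score
#'
#' @param ace_memory Memory subscale score(s) (/26).
#' @param cutoff Amnestic cutoff; scores `<= cutoff` are amnestic.
#' @return Character vector, `"aMCI"` or `"naMCI"`.
#' @export
classify_mci <- function(ace_memory, cutoff = 21L) {
  ifelse(ace_memory <= cutoff, "aMCI", "naMCI")
}

#' Score all behavioural instruments for every subject
#'
#' @param responses Long response table as produced by
#'   [simulate_behavior()] (columns `subject_id`, `task`, `item_class`,
#'   `correct`, `rt_s`).
#' @param ace Optional ACE-III summary table (`subject_id`, `ace_total`,
#'   `ace_memory`).
#' @return Data frame, one row per subject, with 2AFC accuracy and
#'   median RT per item class, PVT median RT / lapses / discards, and
#'   DMS-48 subset accuracies.
#' @export
score_all <- function(responses, ace = NULL) {
  subj <- unique(responses$subject_id)
  rows <- lapply(subj, function(s) {
    r <- responses[responses$subject_id == s, ]
    afc <- score_2afc(r[r$task == "fastball_2afc", ])
    geta <- function(cl, col) {
      v <- afc[[col]][afc$item_class == cl]
      if (length(v)) v else NA_real_
    }
    pvt <- if (any(r$task == "pvt"))
      score_pvt(r$rt_s[r$task == "pvt"]) else
      list(median_rt_s = NA, n_lapses = NA, n_discarded = NA)
    dms <- if (any(r$task == "dms48"))
      score_dms48(r[r$task == "dms48", ]) else
      list(total_acc = NA, unique_acc = NA, paired_acc = NA, abstract_acc = NA)
    data.frame(subject_id = s,
               acc_2afc_oddball = geta("oddball", "accuracy"),
               acc_2afc_standard = geta("standard", "accuracy"),
               rt_2afc_oddball = geta("oddball", "median_rt_s"),
               rt_2afc_standard = geta("standard", "median_rt_s"),
               pvt_median_rt_s = pvt$median_rt_s,
               pvt_lapses = pvt$n_lapses,
               pvt_discarded = pvt$n_discarded,
               dms48_total = dms$total_acc,
               dms48_unique = dms$unique_acc,
               dms48_paired = dms$paired_acc,
               dms48_abstract = dms$abstract_acc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(ace)) out <- merge(out, ace, by = "subject_id", sort = FALSE)
  out
}
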
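#' Specification of an FPVS oddball stimulus sequence
#'
#' Describes the trial structure of a fast periodic visual stimulation
#' stream: mini-sequences of `seq_len` images in which the first
#' `seq_len - 1` positions show novel standard images and the final
#' position shows one of a small set of repeatedly presented oddball
#' images. With the defaults (416 standards, 8 oddballs repeated 13
#' times, 166 ms stimulus duration and 166 ms inter-stimulus interval)
#' the stream presents 520 images at a ~3 Hz base rate with a ~0.6 Hz
#' oddball rate.
#'
#' @param n_standards Number of unique standard images (each shown once).
#' @param n_oddballs Number of distinct oddball images.
#' @param oddball_reps Presentations per oddball image.
#' @param seq_len Images per mini-sequence (oddball occupies the last slot).
#' @param stim_dur_s Stimulus duration in seconds.
#' @param isi_s Inter-stimulus interval in seconds.
#' @param target_seq_fraction Fraction of mini-sequences flagged as
#'   fixation-target sequences (fixation cross colour change).
#' @param seed Integer seed controlling the pseudo-randomized ordering.
#' @return An object of class `fb_sequence_spec`.
#' @export
sequence_spec <- function(n_standards = 416L, n_oddballs = 8L,
                          oddball_reps = 13L, seq_len = 5L,
                          stim_dur_s = 0.166, isi_s = 0.166,
                          target_seq_fraction = 0.10, seed = 1L) {
  spec <- list(n_standards = as.integer(n_standards),
               n_oddballs = as.integer(n_oddballs),
               oddball_reps = as.integer(oddball_reps),
               seq_len = as.integer(seq_len),
               stim_dur_s = stim_dur_s, isi_s = isi_s,
               target_seq_fraction = target_seq_fraction,
               seed = as.integer(seed))
  class(spec) <- "fb_sequence_spec"
  validate_sequence_spec(spec)
  spec
}

validate_sequence_spec <- function(spec) {
  stopifnot(spec$stim_dur_s > 0, spec$isi_s > 0,
            spec$target_seq_fraction >= 0, spec$target_seq_fraction <= 1,
            spec$seq_len >= 2, spec$n_oddballs >= 1, spec$oddball_reps >= 1)
  n_seq <- spec$n_oddballs * spec$oddball_reps
  if (spec$n_standards != n_seq * (spec$seq_len - 1L))
    stop("infeasible design: n_standards must equal ",
         "n_oddballs * oddball_reps * (seq_len - 1) = ",
         n_seq * (spec$seq_len - 1L), ", got ", spec$n_standards)
  invisible(spec)
}

#' Build a pseudo-randomized oddball stimulus schedule
#'
#' Places one oddball image at the end of every mini-sequence such that no
#' oddball image is ever shown on two consecutive oddball slots, each
#' oddball appears exactly `oddball_reps` times, and each standard image
#' appears exactly once. A configurable fraction of mini-sequences is
#' flagged as fixation-target sequences, sampled so that no two flagged
#' sequences are adjacent.
#'
#' Ordering uses a randomized greedy draw over remaining oddball counts
#' with a feasibility guard (an image whose remaining count exceeds half
#' the remaining slots is forced), which succeeds whenever the constraint
#' set is satisfiable.
#'
#' @param spec A [sequence_spec()].
#' @return An object of class `fb_schedule`: a data frame of schedule
#'   entries (`index`, `onset_s`, `image_id`, `role`,
#'   `is_target_sequence`) with attributes `total_images`, `n_sequences`
#'   and the originating spec. Onsets are filled by [schedule_timing()].
#' @export
build_sequence <- function(spec) {
  validate_sequence_spec(spec)
  n_seq <- spec$n_oddballs * spec$oddball_reps
  total <- spec$n_standards + n_seq

  ## feasibility of the no-adjacent-repeat constraint
  if (spec$oddball_reps > ceiling(n_seq / 2))
    stop("infeasible constraint: ", spec$oddball_reps, " repetitions of one ",
         "oddball cannot avoid consecutive presentations among ", n_seq,
         " oddball slots")

  set.seed(spec$seed)

  odd_ids <- sprintf("odd_%d", seq_len(spec$n_oddballs))
  odd_order <- draw_nonadjacent(spec$n_oddballs, spec$oddball_reps)
  std_ids <- sample(sprintf("std_%03d", seq_len(spec$n_standards)))

  role <- rep(c(rep("standard", spec$seq_len - 1L), "oddball"), n_seq)
  image_id <- character(total)
  image_id[role == "standard"] <- std_ids
  image_id[role == "oddball"] <- odd_ids[odd_order]

  ## fixation-target sequences: sampled without replacement, never adjacent
  n_target <- round(spec$target_seq_fraction * n_seq)
  tgt_seq <- draw_nonadjacent_subset(n_seq, n_target)
  seq_of_entry <- rep(seq_len(n_seq), each = spec$seq_len)

  sched <- data.frame(index = seq_len(total),
                      onset_s = NA_real_,
                      image_id = image_id,
                      role = role,
                      is_target_sequence = seq_of_entry %in% tgt_seq,
                      stringsAsFactors = FALSE)
  attr(sched, "total_images") <- total
  attr(sched, "n_sequences") <- n_seq
  attr(sched, "duration_s") <- NA_real_
  attr(sched, "spec") <- spec
  class(sched) <- c("fb_schedule", "data.frame")
  schedule_timing(sched, spec)
}

## randomized greedy sequence of n_ids symbols, reps each, no two adjacent equal
draw_nonadjacent <- function(n_ids, reps, max_tries = 100L) {
  total <- n_ids * reps
  for (try in seq_len(max_tries)) {
    counts <- rep(reps, n_ids)
    out <- integer(total)
    prev <- 0L
    ok <- TRUE
    for (i in seq_len(total)) {
      remaining <- total - i + 1L
      allowed <- which(counts > 0L)
      allowed <- setdiff(allowed, prev)
      if (!length(allowed)) { ok <- FALSE; break }
      forced <- allowed[counts[allowed] > (remaining + 1L) %/% 2L]
      pick <- if (length(forced)) forced[1L]
              else allowed[sample.int(length(allowed), 1L,
                                      prob = counts[allowed])]
      out[i] <- pick
      counts[pick] <- counts[pick] - 1L
      prev <- pick
    }
    if (ok) return(out)
  }
  stop("could not order oddballs without consecutive repeats after ",
       max_tries, " attempts")
}

## sample k of n sequence slots with no two adjacent
draw_nonadjacent_subset <- function(n, k, max_tries = 1000L) {
  if (k == 0L) return(integer(0))
  if (k > ceiling(n / 2)) stop("cannot place ", k,
                               " non-adjacent target sequences among ", n)
  for (try in seq_len(max_tries)) {
    s <- sort(sample.int(n, k))
    if (k == 1L || all(diff(s) > 1L)) return(s)
  }
  stop("failed to sample non-adjacent target sequences")
}

#' Fill in presentation timing for a stimulus schedule
#'
#' Onset of entry \eqn{k} is \eqn{(k-1)(\mathrm{stim} + \mathrm{isi})};
#' total duration is `total_images * (stim_dur_s + isi_s)`. Records both
#' the exact presentation rates implied by the timing (1/0.332 s = 3.012
#' Hz for the defaults) and the nominal rates used on the analysis
#' frequency grid (3 Hz base, 0.6 Hz oddball).
#'
#' @param sched An `fb_schedule`.
#' @param spec The [sequence_spec()] used to build it.
#' @return The schedule with onsets and timing attributes
#'   (`duration_s`, `base_rate_hz`, `oddball_rate_hz`,
#'   `nominal_base_hz`, `nominal_oddball_hz`).
#' @export
schedule_timing <- function(sched, spec = attr(sched, "spec")) {
  soa <- spec$stim_dur_s + spec$isi_s
  sched$onset_s <- (sched$index - 1L) * soa
  attr(sched, "duration_s") <- attr(sched, "total_images") * soa
  attr(sched, "base_rate_hz") <- 1 / soa
  attr(sched, "oddball_rate_hz") <- 1 / soa / spec$seq_len
  attr(sched, "nominal_base_hz") <- round(spec$seq_len / soa) / spec$seq_len
  attr(sched, "nominal_oddball_hz") <- attr(sched, "nominal_base_hz") / spec$seq_len
  sched
}

#' Validate the structural invariants of a stimulus schedule
#'
#' Checks that every `seq_len`-th entry is an oddball, that no oddball
#' image occupies two consecutive oddball slots, that each standard
#' appears exactly once and each oddball exactly `oddball_reps` times,
#' and that no two fixation-target sequences are adjacent.
#'
#' @param sched An `fb_schedule`.
#' @param spec The originating [sequence_spec()].
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_schedule <- function(sched, spec = attr(sched, "spec")) {
  odd_pos <- which(sched$role == "oddball")
  if (!identical(odd_pos, which(sched$index %% spec$seq_len == 0L)))
    stop("oddballs are not at every ", spec$seq_len, "th position")
  odd_ids <- sched$image_id[odd_pos]
  if (any(odd_ids[-1] == odd_ids[-length(odd_ids)]))
    stop("consecutive oddball slots share an image")
  std_tab <- table(sched$image_id[sched$role == "standard"])
  if (any(std_tab != 1L)) stop("a standard image appears more than once")
  if (any(table(odd_ids) != spec$oddball_reps))
    stop("an oddball image does not appear exactly oddball_reps times")
  tgt <- unique(rep(seq_len(attr(sched, "n_sequences")),
                    each = spec$seq_len)[sched$is_target_sequence])
  if (length(tgt) > 1L && any(diff(sort(tgt)) == 1L))
    stop("two fixation-target sequences are adjacent")
  invisible(TRUE)
}

#' @export
print.fb_schedule <- function(x, ...) {
  cat("FPVS stimulus schedule:", attr(x, "total_images"), "images,",
      attr(x, "n_sequences"), "sequences,",
      sprintf("%.2f s", attr(x, "duration_s")), "\n")
  cat(sprintf("  base rate %.3f Hz (nominal %g), oddball %.3f Hz (nominal %g)\n",
              attr(x, "base_rate_hz"), attr(x, "nominal_base_hz"),
              attr(x, "oddball_rate_hz"), attr(x, "nominal_oddball_hz")))
  invisible(x)
}

#' Write / read a stimulus schedule as TSV
#'
#' @param sched An `fb_schedule`.
#' @param path Output TSV path.
#' @return `path` invisibly (write) or the schedule data frame (read).
#' @export
write_schedule <- function(sched, path) {
  data.table::fwrite(as.data.frame(sched), path, sep = "\t")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
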
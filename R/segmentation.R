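# Subject-wise fold assignment and non-overlapping segmentation, in that
# order: the split happens at the subject level first, segments are cut
# afterwards, so no subject can contribute to both train and test sets.

#' Sliding-window specification
#'
#' @param window_s Window length in seconds (default 0.4).
#' @param step_s Step between window starts in seconds (default 0.2,
#'   i.e. 50 percent overlap).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_s = 0.4, step_s = 0.2) {
  if (!is_scalar_num(window_s) || !is_scalar_num(step_s) ||
      step_s <= 0 || step_s > window_s)
    cc_config_error("need 0 < step_s <= window_s")
  structure(list(window_s = window_s, step_s = step_s), class = "window_spec")
}

#' Assign subjects to cross-validation folds
#'
#' Seeded random partition of subjects into `k` folds, stratified by class
#' label so class balance is kept across folds. Segmentation happens after
#' this assignment; the fold sets are disjoint by construction.
#'
#' @param subjects `data.frame` with columns `subject_id` and `label`, or a
#'   list of recordings (converted via [cohort_subjects()]).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return An object of class `split_plan`: `k` plus an `assignment`
#'   data.frame (`subject_id`, `label`, `fold` in 1..k).
#' @export
assign_folds <- function(subjects, k, seed = 1L) {
  if (is.list(subjects) && !is.data.frame(subjects))
    subjects <- cohort_subjects(subjects)
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "label") %in% names(subjects)))
  if (anyDuplicated(subjects$subject_id))
    cc_config_error("duplicate subject_id in subject table")
  if (!is_count(k) || k < 2) cc_config_error("`k` must be an integer >= 2")
  tab <- table(subjects$label)
  if (any(tab < k))
    cc_config_error(sprintf(
      "fewer subjects than folds (k=%d) in class(es): %s", k,
      paste(names(tab)[tab < k], collapse = ", ")))
  assignment <- with_seed(seed, {
    out <- NULL
    for (lbl in sort(unique(subjects$label))) {
      ids <- subjects$subject_id[subjects$label == lbl]
      ids <- sample(ids)
      folds <- rep_len(seq_len(k), length(ids))
      out <- rbind(out, data.frame(subject_id = ids, label = lbl,
                                   fold = folds, stringsAsFactors = FALSE))
    }
    out[order(out$subject_id), , drop = FALSE]
  })
  rownames(assignment) <- NULL
  structure(list(k = as.integer(k), assignment = assignment),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> k=%d, %d subjects\n", x$k, nrow(x$assignment)))
  print(table(x$assignment$label, x$assignment$fold))
  invisible(x)
}

#' Assert that train and test subject sets are disjoint
#'
#' Part of the public evaluation contract: any overlap between training and
#' test subjects is a hard failure, never a warning.
#'
#' @param train_subjects,test_subjects Character vectors of subject ids.
#' @return `TRUE`, invisibly.
#' @export
assert_disjoint_subjects <- function(train_subjects, test_subjects) {
  leak <- intersect(train_subjects, test_subjects)
  if (length(leak))
    cc_contract_error(sprintf(
      "subject-level leakage: subject(s) %s present in both train and test",
      paste(leak, collapse = ", ")))
  invisible(TRUE)
}

#' Cut a recording into non-overlapping fixed-length segments
#'
#' Produces `floor(duration / segment_length_s)` segments; the trailing
#' remainder is dropped. Each segment inherits subject id and label
#' verbatim and becomes one independent classification sample.
#'
#' @param rec An [eeg_recording()].
#' @param segment_length_s Segment length in seconds (typically 10, 20 or 30).
#' @return List of `eeg_segment` objects (possibly empty, with a warning,
#'   when the recording is shorter than one segment).
#' @export
segment_recording <- function(rec, segment_length_s) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is_scalar_num(segment_length_s) || segment_length_s <= 0)
    cc_config_error("`segment_length_s` must be positive")
  len <- sec_to_samples(segment_length_s, rec$sfreq)
  n_seg <- ncol(rec$data) %/% len
  if (n_seg == 0L) {
    warning(sprintf("recording %s (%.1f s) shorter than one %g s segment; no segments",
                    rec$subject_id, ncol(rec$data) / rec$sfreq, segment_length_s))
    return(list())
  }
  lapply(seq_len(n_seg), function(i) {
    idx <- ((i - 1L) * len + 1L):(i * len)
    structure(
      list(subject_id = rec$subject_id, label = rec$label,
           segment_index = i, sfreq = rec$sfreq,
           channel_names = rec$channel_names,
           segment_length_s = segment_length_s,
           data = rec$data[, idx, drop = FALSE]),
      class = "eeg_segment")
  })
}

#' Cut a whole cohort into segments
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param segment_length_s Segment length in seconds.
#' @return Flat list of `eeg_segment` objects.
#' @export
segment_cohort <- function(recordings, segment_length_s) {
  do.call(c, lapply(recordings, segment_recording,
                    segment_length_s = segment_length_s))
}

#' Sliding analysis windows over a segment
#'
#' Window starts form an arithmetic sequence with common difference
#' `round(step_s * sfreq)` samples; the count is
#' `floor((L - w) / s) + 1`. At the defaults (0.4 s window, 0.2 s step,
#' 500 Hz) a 30 s segment yields 149 windows, 20 s yields 99, 10 s yields 49.
#'
#' @param seg An `eeg_segment` (or an [eeg_recording()]).
#' @param spec A [window_spec()].
#' @return List of channels x window-samples matrices, ordered by start time.
#' @export
slide_windows <- function(seg, spec = window_spec()) {
  stopifnot(inherits(seg, c("eeg_segment", "eeg_recording")),
            inherits(spec, "window_spec"))
  w <- sec_to_samples(spec$window_s, seg$sfreq)
  s <- sec_to_samples(spec$step_s, seg$sfreq)
  L <- ncol(seg$data)
  if (w > L)
    cc_input_error(sprintf("window (%d samples) longer than segment (%d samples)", w, L))
  starts <- seq(1L, L - w + 1L, by = s)
  lapply(starts, function(st) seg$data[, st:(st + w - 1L), drop = FALSE])
}
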
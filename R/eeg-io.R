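#' Standard 19-channel 10-20 montage
#'
#' Canonical channel order used throughout the package: the 19 scalp
#' electrodes of the international 10-20 system, excluding the mastoid
#' references A1/A2. Pair indexing of connectogram pixel rows is defined
#' relative to this order, so it is fixed once and reused everywhere.
#'
#' @format Character vector of 19 electrode names.
#' @export
eeg_channels_1020 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
  "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2"
)

#' Construct a multichannel EEG recording
#'
#' The canonical container for one subject's signal: a channels-by-samples
#' numeric matrix with an ordered channel list, a sampling rate, a subject
#' identifier and an optional class label.
#'
#' @param data Numeric matrix, channels x samples.
#' @param channel_names Character vector, one name per row of `data`.
#' @param sfreq Sampling rate in Hz (positive).
#' @param subject_id Subject identifier string.
#' @param label Optional class label (string) or `NULL`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_names, sfreq, subject_id, label = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    cc_input_error("`data` must be a numeric channels x samples matrix")
  if (nrow(data) < 2L)
    cc_input_error("a recording needs at least 2 channels")
  if (length(channel_names) != nrow(data))
    cc_input_error(sprintf(
      "channel_names length (%d) does not match number of data rows (%d)",
      length(channel_names), nrow(data)))
  if (anyDuplicated(channel_names))
    cc_input_error("channel names must be unique")
  if (!is_scalar_num(sfreq) || sfreq <= 0)
    cc_input_error("`sfreq` must be a positive number (Hz)")
  bad <- !apply(data, 1L, function(r) all(is.finite(r)))
  if (any(bad))
    cc_input_error(sprintf("non-finite samples in channel(s): %s",
                           paste(channel_names[bad], collapse = ", ")))
  rownames(data) <- channel_names
  structure(
    list(subject_id = as.character(subject_id),
         label = if (is.null(label)) NULL else as.character(label),
         channel_names = as.character(channel_names),
         sfreq = as.numeric(sfreq),
         data = data),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject=%s label=%s  %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, if (is.null(x$label)) "<none>" else x$label,
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  invisible(x)
}

#' Read a recording from disk
#'
#' Reads an EDF file (European Data Format, 16-bit) or an `.rds` file written
#' by [write_recording()] into an [eeg_recording()]. The sampling rate is
#' taken from file metadata; EDF samples are returned in physical units.
#'
#' @param path Path to an `.edf` or `.rds` file.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @param label Optional class label.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, subject_id = NULL, label = NULL) {
  if (!file.exists(path))
    cc_input_error(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    edf = {
      obj <- read_edf(path)
      if (is.null(subject_id) && nzchar(obj$subject_id))
        subject_id <- obj$subject_id
      if (is.null(label)) label <- obj$label
      obj
    },
    rds = {
      obj <- readRDS(path)
      if (!is.list(obj) ||
          !all(c("data", "channel_names", "sfreq") %in% names(obj)))
        cc_input_error(sprintf(
          "%s: not a recording (missing data/channel_names/sfreq)", path))
      if (is.null(label) && !is.null(obj$label)) label <- obj$label
      if (is.null(subject_id) && !is.null(obj$subject_id))
        subject_id <- obj$subject_id
      obj
    },
    cc_input_error(sprintf("%s: unsupported extension '%s' (use .edf or .rds)",
                           path, ext)))
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  bad <- !apply(raw$data, 1L, function(r) all(is.finite(r)))
  if (any(bad))
    cc_input_error(sprintf("%s: non-finite samples in channel(s): %s", path,
                           paste(raw$channel_names[bad], collapse = ", ")))
  eeg_recording(raw$data, raw$channel_names, raw$sfreq, subject_id, label)
}

#' Write a recording to disk
#'
#' `.edf` writes standard 16-bit EDF (quantized to the per-channel physical
#' range; round trips to within the digitization step). `.rds` is the
#' lossless native container holding data, channel names, sampling rate,
#' subject id and label.
#'
#' @param rec An [eeg_recording()].
#' @param path Destination path ending in `.edf` or `.rds`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    edf = write_edf(rec, path),
    rds = saveRDS(list(data = rec$data, channel_names = rec$channel_names,
                       sfreq = rec$sfreq, subject_id = rec$subject_id,
                       label = rec$label), path),
    cc_input_error(sprintf("unsupported extension '%s' (use .edf or .rds)", ext)))
  invisible(path)
}

#' Select and reorder channels
#'
#' Subsets a recording to exactly the requested channels, in the requested
#' order. Every downstream pair/pixel-row index is defined by this order.
#'
#' @param rec An [eeg_recording()].
#' @param names Ordered character vector of channel names to keep.
#' @return An [eeg_recording()] whose rows are exactly `names`.
#' @export
select_channels <- function(rec, names) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(names, rec$channel_names)
  if (length(missing))
    cc_input_error(sprintf("channel(s) not present in recording: %s",
                           paste(missing, collapse = ", ")))
  eeg_recording(rec$data[names, , drop = FALSE], names, rec$sfreq,
                rec$subject_id, rec$label)
}

#' Optional zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (`signal::filtfilt`)
#' per channel. Not applied anywhere by default: the image transform starts
#' from recordings as given.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Passband edges in Hz (default 0.5-45).
#' @param order Filter order (default 4).
#' @return The filtered [eeg_recording()].
#' @export
bandpass_recording <- function(rec, low = 0.5, high = 45, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sfreq / 2
  if (!(low > 0 && high > low && high < nyq))
    cc_config_error(sprintf("invalid passband (%g, %g) Hz for sfreq %g Hz",
                            low, high, rec$sfreq))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filt <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  eeg_recording(filt, rec$channel_names, rec$sfreq, rec$subject_id, rec$label)
}
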
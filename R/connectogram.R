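# The time-graph image: each sliding window's coherence adjacency matrix is
# reduced to its strictly-upper triangle (c(c-1)/2 values in row-major pair
# order), flattened to one pixel column, and the columns are tiled left to
# right over window start times. Coherence already lives in [0, 1], so the
# grayscale mapping is absolute: no per-image normalization, and images are
# directly comparable.

#' Row-major strictly-upper pair order
#'
#' Enumerates channel pairs `(i, j)` with `i < j` in row-major order:
#' (1,2), (1,3), ..., (1,c), (2,3), ..., (c-1,c). This order defines the
#' pixel-row identity of every connectogram image.
#'
#' @param channel_names Character vector of channel names.
#' @return `data.frame` with columns `i`, `j`, `pair` (e.g. `"Fp1-Fp2"`).
#' @export
pair_order <- function(channel_names) {
  c_ch <- length(channel_names)
  stopifnot(c_ch >= 2)
  idx <- which(upper.tri(matrix(0, c_ch, c_ch)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]   # row-major
  data.frame(i = idx[, 1L], j = idx[, 2L],
             pair = paste(channel_names[idx[, 1L]],
                          channel_names[idx[, 2L]], sep = "-"),
             stringsAsFactors = FALSE)
}

#' Flatten the strictly-upper triangle of a symmetric matrix
#'
#' Returns the `c(c-1)/2` strictly-upper entries in row-major pair order
#' (the [pair_order()] convention); 19 channels give a 171-vector, and in
#' general `c` channels give `c(c-1)/2` values. The diagonal is excluded.
#'
#' @param mat A symmetric numeric matrix, or a `coherence_matrix`.
#' @param tol Maximum tolerated asymmetry `max|M - t(M)|` (default 1e-9).
#' @return Numeric vector of length `c(c-1)/2`.
#' @export
flatten_upper <- function(mat, tol = 1e-9) {
  if (inherits(mat, "coherence_matrix")) mat <- mat$values
  if (!is.matrix(mat) || nrow(mat) != ncol(mat) || nrow(mat) < 2)
    cc_input_error("`mat` must be a square matrix with >= 2 rows")
  if (max(abs(mat - t(mat))) > tol)
    cc_contract_error(sprintf(
      "matrix asymmetric beyond tolerance %g (max |M - t(M)| = %g)",
      tol, max(abs(mat - t(mat)))))
  # row-major upper triangle == column-major lower triangle of the transpose
  tm <- t(mat)
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric unit-diagonal matrix from a flattened triangle
#'
#' Inverse of [flatten_upper()] for coherence-style matrices: places the
#' vector back in row-major strictly-upper order, mirrors it, and sets the
#' diagonal to 1.
#'
#' @param vec Numeric vector of length `c(c-1)/2`.
#' @param n_channels Channel count `c`.
#' @return A `c x c` symmetric numeric matrix with unit diagonal.
#' @export
unflatten_upper <- function(vec, n_channels) {
  if (!is_count(n_channels) || n_channels < 2)
    cc_input_error("`n_channels` must be an integer >= 2")
  expected <- n_channels * (n_channels - 1) / 2
  if (length(vec) != expected)
    cc_input_error(sprintf(
      "vector length %d does not match c(c-1)/2 = %d for c = %d",
      length(vec), expected, n_channels))
  m <- matrix(0, n_channels, n_channels)
  tm <- t(m)
  tm[lower.tri(tm)] <- vec
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- 1
  m
}

#' Build the Connectogram-COH image of a segment
#'
#' Column `j` of the image is the flattened upper triangle of window `j`'s
#' coherence adjacency matrix; columns run left to right in window start
#' order, rows follow [pair_order()]. A 30 s, 19-channel segment at the
#' defaults yields a 171 x 149 image; 20 s gives 171 x 99; 10 s gives
#' 171 x 49.
#'
#' @param seg An `eeg_segment` (from [segment_recording()]).
#' @param wspec A [window_spec()].
#' @param scfg A [spectral_config()].
#' @return Object of class `connectogram`: `pixels` (pairs x windows matrix
#'   in `[0, 1]`), `subject_id`, `label`, `segment_index`, `pair_order`,
#'   `window_spec`, `band`, `channel_names`.
#' @export
build_connectogram <- function(seg, wspec = window_spec(),
                               scfg = spectral_config()) {
  stopifnot(inherits(seg, "eeg_segment"))
  wins <- slide_windows(seg, wspec)
  po <- pair_order(seg$channel_names)
  pixels <- matrix(NA_real_, nrow(po), length(wins))
  for (j in seq_along(wins)) {
    adj <- tryCatch(
      window_adjacency(wins[[j]], seg$sfreq, scfg,
                       channel_names = seg$channel_names, window_index = j),
      error = function(e) cc_stop(
        sprintf("window %d of segment %s/%d: %s", j, seg$subject_id,
                seg$segment_index, conditionMessage(e)),
        class(e)[1]))
    pixels[, j] <- flatten_upper(adj)
  }
  rownames(pixels) <- po$pair
  structure(
    list(pixels = pixels, subject_id = seg$subject_id, label = seg$label,
         segment_index = seg$segment_index, pair_order = po,
         window_spec = wspec, band = scfg$band,
         channel_names = seg$channel_names),
    class = "connectogram")
}

#' @export
print.connectogram <- function(x, ...) {
  cat(sprintf("<connectogram> subject=%s label=%s segment=%d  %d pairs x %d windows\n",
              x$subject_id, if (is.null(x$label)) "<none>" else x$label,
              x$segment_index, nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Write a connectogram as an 8-bit grayscale PNG
#'
#' Quantization is `clamp(floor(v * 255 + 0.5), 0, 255)`: 0 maps to black,
#' 1 to white, 0.5 to gray level 128. Top row = first pair, leftmost
#' column = first window. The float image remains canonical; the PNG is for
#' inspection and interchange (quantization error per pixel <= 1/510).
#'
#' @param img A `connectogram`.
#' @param path Destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_connectogram_png <- function(img, path) {
  stopifnot(inherits(img, "connectogram"))
  q <- pmin(pmax(floor(img$pixels * 255 + 0.5), 0), 255)
  ok <- tryCatch({ png::writePNG(q / 255, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) cc_input_error(sprintf("cannot write PNG to %s", path))
  invisible(path)
}

connectogram_fields <- c("pixels", "subject_id", "segment_index",
                         "pair_order", "window_spec", "band", "channel_names")

#' Lossless connectogram round trip
#'
#' `write_connectogram()` stores the float image and all metadata in an
#' `.rds` file; `read_connectogram()` restores it, validating the schema.
#'
#' @param img A `connectogram`.
#' @param path An `.rds` path.
#' @return The path (write) or the `connectogram` (read).
#' @export
write_connectogram <- function(img, path) {
  stopifnot(inherits(img, "connectogram"))
  saveRDS(unclass(img), path)
  invisible(path)
}

#' @rdname write_connectogram
#' @export
read_connectogram <- function(path) {
  if (!file.exists(path)) cc_input_error(sprintf("file not found: %s", path))
  obj <- readRDS(path)
  missing <- setdiff(connectogram_fields, names(obj))
  if (length(missing))
    cc_input_error(sprintf("%s: not a connectogram (missing field(s): %s)",
                           path, paste(missing, collapse = ", ")))
  structure(obj, class = "connectogram")
}

#' Transform a cohort of recordings into connectogram images
#'
#' Segments every recording and builds one image per segment.
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param segment_length_s Segment length in seconds.
#' @param wspec A [window_spec()].
#' @param scfg A [spectral_config()].
#' @return List of `connectogram` objects.
#' @export
transform_cohort <- function(recordings, segment_length_s = 10,
                             wspec = window_spec(), scfg = spectral_config()) {
  segs <- segment_cohort(recordings, segment_length_s)
  lapply(segs, build_connectogram, wspec = wspec, scfg = scfg)
}
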
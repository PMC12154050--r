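# Shared test fixtures, all generated in code.

# unit-variance Gaussian noise band-limited with a zero-phase FFT brick wall
bl_noise <- function(n, lo, hi, fs) {
  z <- rnorm(n)
  Z <- fft(z)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  Z[!(f >= lo & f <= hi)] <- 0
  s <- Re(fft(Z, inverse = TRUE)) / n
  s / sd(s)
}

# a pair sharing one wide-band unit source plus white noise of sd sigma;
# wide-band source makes the per-frequency SNR flat across the analysis band
shared_source_pair <- function(n, sigma, fs = 500) {
  s <- bl_noise(n, 0.5, fs / 2 - 1, fs)
  list(x = s + sigma * rnorm(n), y = s + sigma * rnorm(n), fs = fs)
}

# analytic band-averaged MSC for the shared-source model: per-bin SNR is the
# source/noise power-density ratio inside the source band
shared_source_coherence <- function(sigma, src_band_hz, fs = 500) {
  snr <- (1 / diff(src_band_hz)) / (sigma^2 / (fs / 2))
  (snr / (1 + snr))^2
}

# small segment object without going through a full recording
make_segment <- function(data, sfreq, subject_id = "subA", label = "a",
                         segment_index = 1L, segment_length_s = ncol(data) / sfreq) {
  structure(list(subject_id = subject_id, label = label,
                 segment_index = segment_index, sfreq = sfreq,
                 channel_names = rownames(data) %||% sprintf("Ch%02d", seq_len(nrow(data))),
                 segment_length_s = segment_length_s, data = data),
            class = "eeg_segment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fake connectogram with a class-dependent mean shift in the top pixel block
fake_connectogram <- function(subject_id, label, h, w, shift = 0,
                              segment_index = 1L) {
  px <- matrix(runif(h * w, 0.3, 0.5), h, w)
  px[seq_len(max(1L, h %/% 3L)), ] <- px[seq_len(max(1L, h %/% 3L)), ] + shift
  px <- pmin(px, 1)
  structure(list(pixels = px, subject_id = subject_id, label = label,
                 segment_index = segment_index,
                 pair_order = pair_order(sprintf("C%02d", seq_len(ceiling((1 + sqrt(1 + 8 * h)) / 2)))),
                 window_spec = window_spec(), band = c(0.5, 45),
                 channel_names = sprintf("C%02d", seq_len(ceiling((1 + sqrt(1 + 8 * h)) / 2)))),
            class = "connectogram")
}

# a small labelled image set: n_per subjects per class, segs segments each
fake_image_set <- function(n_per = 5, segs = 2, h = 12, w = 8, shift = 0.3,
                           labels = c("a", "b")) {
  imgs <- list()
  sid <- 0
  for (lbl in labels) {
    for (s in seq_len(n_per)) {
      sid <- sid + 1
      for (g in seq_len(segs)) {
        imgs[[length(imgs) + 1L]] <- fake_connectogram(
          sprintf("sub-%03d", sid), lbl, h, w,
          shift = if (lbl == labels[1]) shift else 0, segment_index = g)
      }
    }
  }
  imgs
}
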
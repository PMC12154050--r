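# Magnitude-squared coherence via Welch cross-spectral estimation:
#   Coh_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))
# with P estimated from taper-windowed, overlap-averaged periodograms.
# A single averaged sub-segment makes the estimate identically 1, so at
# least two sub-segments are required. The per-pair scalar is the
# unweighted mean of Coh over an inclusive frequency band, excluding DC.

#' Spectral estimation configuration
#'
#' Defaults are sized for 0.4 s analysis windows at 500 Hz (200 samples):
#' 100-sample Hann sub-segments with 50 percent overlap give M = 3 averaged
#' periodograms and 5 Hz frequency resolution; the averaging band 0.5-45 Hz
#' spans the conventional delta-gamma EEG range.
#'
#' @param subwin_samples Welch sub-segment length in samples (>= 8).
#' @param subwin_overlap Fractional overlap between sub-segments in `[0, 1)`.
#' @param taper Taper name; `"hann"` (periodic) or `"boxcar"`.
#' @param band Inclusive averaging band `(f_lo, f_hi)` in Hz; DC is always
#'   excluded from the average.
#' @param detrend `"constant"` (remove each sub-segment's mean; default) or
#'   `"none"`.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(subwin_samples = 100L, subwin_overlap = 0.5,
                            taper = c("hann", "boxcar"), band = c(0.5, 45),
                            detrend = c("constant", "none")) {
  taper <- match.arg(taper)
  detrend <- match.arg(detrend)
  if (!is_count(subwin_samples) || subwin_samples < 8)
    cc_config_error("`subwin_samples` must be an integer >= 8")
  if (!is_scalar_num(subwin_overlap) || subwin_overlap < 0 || subwin_overlap >= 1)
    cc_config_error("`subwin_overlap` must be in [0, 1)")
  if (length(band) != 2 || !all(is.finite(band)) || band[1] < 0 ||
      band[2] <= band[1])
    cc_config_error("`band` must satisfy 0 <= f_lo < f_hi")
  structure(list(subwin_samples = as.integer(subwin_samples),
                 subwin_overlap = as.numeric(subwin_overlap),
                 taper = taper, band = as.numeric(band), detrend = detrend),
            class = "spectral_config")
}

taper_vector <- function(name, n) {
  switch(name,
         hann = 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n)),
         boxcar = rep(1, n),
         cc_config_error(sprintf("unknown taper '%s'", name)))
}

# Tapered, detrended sub-segment FFTs of a channels x samples matrix.
# Returns freq (length nfreq) and F, an nfreq x channels x M complex array.
welch_fft <- function(X, sfreq, cfg) {
  nsub <- cfg$subwin_samples
  L <- ncol(X)
  step <- max(1L, as.integer(round(nsub * (1 - cfg$subwin_overlap))))
  if (L < nsub + step)
    cc_estimation_error(sprintf(
      "only one %d-sample Welch sub-segment fits in %d samples; coherence would be degenerate (identically 1)",
      nsub, L))
  if (band_limits_invalid(cfg$band, sfreq))
    cc_config_error(sprintf("band (%g, %g) Hz outside (0, sfreq/2 = %g)",
                            cfg$band[1], cfg$band[2], sfreq / 2))
  v <- apply(X, 1L, stats::var)
  if (any(v == 0))
    cc_estimation_error(sprintf(
      "zero-variance input channel(s): %s",
      paste(which(v == 0), collapse = ", ")))
  starts <- seq(1L, L - nsub + 1L, by = step)
  M <- length(starts)
  w <- taper_vector(cfg$taper, nsub)
  nfreq <- nsub %/% 2 + 1L
  Fa <- array(0i, dim = c(nfreq, nrow(X), M))
  for (m in seq_len(M)) {
    seg <- X[, starts[m]:(starts[m] + nsub - 1L), drop = FALSE]
    if (cfg$detrend == "constant") seg <- seg - rowMeans(seg)
    tp <- t(seg) * w                       # nsub x channels
    Fa[, , m] <- stats::mvfft(tp)[seq_len(nfreq), , drop = FALSE]
  }
  list(freq = (seq_len(nfreq) - 1) * sfreq / nsub, F = Fa, M = M)
}

band_limits_invalid <- function(band, sfreq) {
  band[1] < 0 || band[2] <= band[1] || band[2] > sfreq / 2
}

#' Magnitude-squared coherence spectrum of two signals
#'
#' Welch estimate of `|P_xy|^2 / (P_xx P_yy)` per frequency bin. Values lie
#' in `[0, 1]` by the Cauchy-Schwarz inequality. Fails if fewer than two
#' sub-segments fit (the single-segment estimate is identically 1) or if an
#' input has zero variance.
#'
#' @param x,y Equal-length numeric sample vectors.
#' @param sfreq Sampling rate in Hz.
#' @param cfg A [spectral_config()].
#' @return List with `freq` (Hz) and `coherence` (same length, in `[0, 1]`).
#' @export
msc_spectrum <- function(x, y, sfreq, cfg = spectral_config()) {
  if (length(x) != length(y))
    cc_input_error("`x` and `y` must have equal length")
  wf <- welch_fft(rbind(x, y), sfreq, cfg)
  Fx <- wf$F[, 1L, , drop = TRUE]
  Fy <- wf$F[, 2L, , drop = TRUE]
  if (is.null(dim(Fx))) { Fx <- matrix(Fx, ncol = wf$M); Fy <- matrix(Fy, ncol = wf$M) }
  Pxy <- rowMeans(Fx * Conj(Fy))
  Pxx <- rowMeans(Mod(Fx)^2)
  Pyy <- rowMeans(Mod(Fy)^2)
  coh <- Mod(Pxy)^2 / (Pxx * Pyy)
  list(freq = wf$freq, coherence = pmin(pmax(coh, 0), 1))
}

#' Average a coherence spectrum over a frequency band
#'
#' Unweighted mean over bins with `f_lo <= f <= f_hi`, always excluding the
#' DC bin.
#'
#' @param freq Frequency grid in Hz.
#' @param coherence Coherence values on that grid.
#' @param band Inclusive band `(f_lo, f_hi)` in Hz.
#' @return Scalar in `[0, 1]`.
#' @export
band_average <- function(freq, coherence, band) {
  stopifnot(length(freq) == length(coherence))
  sel <- freq >= band[1] & freq <= band[2] & freq > 0
  if (!any(sel))
    cc_config_error(sprintf(
      "no frequency bins in band (%g, %g) Hz after DC exclusion", band[1], band[2]))
  mean(coherence[sel])
}

#' Per-window coherence adjacency matrix
#'
#' For every unordered channel pair, the band-averaged magnitude-squared
#' coherence of that pair within the window; symmetric by construction,
#' entries in `[0, 1]`, diagonal fixed at 1 (self-coherence). One such
#' matrix per 0.4 s sliding window defines the functional connectivity
#' graph sequence.
#'
#' @param window Channels x samples numeric matrix (>= 2 channels).
#' @param sfreq Sampling rate in Hz.
#' @param cfg A [spectral_config()].
#' @param channel_names Optional channel names (defaults to rownames).
#' @param window_index Optional window position recorded in the result.
#' @return Object of class `coherence_matrix` with fields `values`
#'   (c x c matrix), `band`, `channel_names`, `window_index`.
#' @export
window_adjacency <- function(window, sfreq, cfg = spectral_config(),
                             channel_names = NULL, window_index = NA_integer_) {
  if (inherits(window, "eeg_segment") || inherits(window, "eeg_recording")) {
    if (is.null(channel_names)) channel_names <- window$channel_names
    sfreq <- window$sfreq
    window <- window$data
  }
  if (!is.matrix(window) || nrow(window) < 2)
    cc_input_error("`window` must be a matrix with >= 2 channels")
  if (is.null(channel_names))
    channel_names <- rownames(window)
  if (is.null(channel_names))
    channel_names <- sprintf("Ch%02d", seq_len(nrow(window)))
  wf <- tryCatch(welch_fft(window, sfreq, cfg), error = function(e) {
    v <- apply(window, 1L, stats::var)
    if (inherits(e, "cc_estimation_error") && any(v == 0))
      cc_estimation_error(sprintf(
        "zero-variance channel(s) %s in window %s",
        paste(channel_names[v == 0], collapse = ", "), window_index))
    stop(e)
  })
  sel <- wf$freq >= cfg$band[1] & wf$freq <= cfg$band[2] & wf$freq > 0
  if (!any(sel))
    cc_config_error(sprintf(
      "no frequency bins in band (%g, %g) Hz after DC exclusion",
      cfg$band[1], cfg$band[2]))
  c_ch <- nrow(window)
  acc <- matrix(0, c_ch, c_ch)
  for (fi in which(sel)) {
    Ff <- wf$F[fi, , , drop = TRUE]          # channels x M
    if (is.null(dim(Ff))) Ff <- matrix(Ff, nrow = c_ch)
    Cf <- (Ff %*% Conj(t(Ff))) / wf$M        # cross-spectral matrix at f
    p <- Re(diag(Cf))
    acc <- acc + Mod(Cf)^2 / outer(p, p)
  }
  vals <- acc / sum(sel)
  vals <- pmin(pmax(vals, 0), 1)
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 1
  dimnames(vals) <- list(channel_names, channel_names)
  structure(list(values = vals, window_index = window_index,
                 band = cfg$band, channel_names = channel_names),
            class = "coherence_matrix")
}

#' Brute-force coherence oracle
#'
#' Independent re-implementation of the Welch magnitude-squared coherence
#' estimate by explicit loops over sub-segments and direct discrete Fourier
#' sums, sharing no code with [msc_spectrum()]. Used as a cross-check in the
#' test suite; numerically equivalent to the fast path at machine precision.
#'
#' @inheritParams msc_spectrum
#' @return List with `freq` and `coherence`.
#' @export
oracle_msc <- function(x, y, sfreq, cfg = spectral_config()) {
  if (length(x) != length(y)) cc_input_error("`x` and `y` must have equal length")
  nsub <- cfg$subwin_samples
  step <- max(1L, as.integer(round(nsub * (1 - cfg$subwin_overlap))))
  if (length(x) < nsub + step)
    cc_estimation_error("fewer than two Welch sub-segments fit; degenerate estimate")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    cc_estimation_error("zero-variance input")
  # taper built independently of taper_vector()
  idx <- 0:(nsub - 1)
  w <- if (cfg$taper == "hann") (1 - cos(2 * pi * idx / nsub)) / 2 else rep(1, nsub)
  starts <- seq(1L, length(x) - nsub + 1L, by = step)
  nfreq <- nsub %/% 2 + 1L
  Sxy <- complex(nfreq); Sxx <- numeric(nfreq); Syy <- numeric(nfreq)
  for (s0 in starts) {
    xs <- x[s0:(s0 + nsub - 1L)]
    ys <- y[s0:(s0 + nsub - 1L)]
    if (cfg$detrend == "constant") {
      xs <- xs - sum(xs) / nsub
      ys <- ys - sum(ys) / nsub
    }
    xs <- xs * w; ys <- ys * w
    for (k in seq_len(nfreq)) {
      e <- exp(-2i * pi * (k - 1) * idx / nsub)
      Xk <- sum(xs * e); Yk <- sum(ys * e)
      Sxy[k] <- Sxy[k] + Xk * Conj(Yk)
      Sxx[k] <- Sxx[k] + Mod(Xk)^2
      Syy[k] <- Syy[k] + Mod(Yk)^2
    }
  }
  M <- length(starts)
  coh <- Mod(Sxy / M)^2 / ((Sxx / M) * (Syy / M))
  list(freq = (seq_len(nfreq) - 1) * sfreq / nsub,
       coherence = pmin(pmax(coh, 0), 1))
}
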
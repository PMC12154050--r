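# Synthetic coupled-source EEG: groups of channels share a band-limited
# Gaussian latent source; independent white Gaussian noise is added per
# channel. Coherence between two channels sharing one unit-power source with
# per-channel noise variance s2 has the analytic in-band value
# (snr/(1+snr))^2 where snr is the per-frequency power density ratio.

#' Specify a coupled-source model for synthetic EEG
#'
#' Defines how one class of recordings is generated: `n_channels` channels,
#' where each group in `coupled_groups` shares a unit-variance band-limited
#' Gaussian latent source, plus independent white Gaussian noise of standard
#' deviation `noise_sigma` on every channel. Sources are filtered noise, not
#' sinusoids, so coherence is stable across an averaging band.
#'
#' @param n_channels Number of channels (default 19, the 10-20 montage).
#' @param coupled_groups List of integer vectors of channel indices; each
#'   group shares one latent source. A channel may belong to several groups.
#' @param source_band Passband `(low, high)` in Hz of each latent source;
#'   must lie within `(0, sfreq/2)`.
#' @param noise_sigma Independent-noise standard deviation relative to the
#'   unit-variance sources (default 1).
#' @param sfreq Sampling rate in Hz (default 500).
#' @param seed Integer RNG seed.
#' @return An object of class `coupling_model`.
#' @export
coupling_model <- function(n_channels = 19L, coupled_groups = list(),
                           source_band = c(4, 30), noise_sigma = 1,
                           sfreq = 500, seed = 1L) {
  if (!is_count(n_channels) || n_channels < 2)
    cc_config_error("`n_channels` must be an integer >= 2")
  if (!is.list(coupled_groups))
    cc_config_error("`coupled_groups` must be a list of index vectors")
  for (g in coupled_groups) {
    if (length(g) < 2 || any(g != as.integer(g)) || any(g < 1) ||
        any(g > n_channels) || anyDuplicated(g))
      cc_config_error(sprintf(
        "invalid coupled group {%s}: need >= 2 distinct channel indices in 1..%d",
        paste(g, collapse = ","), n_channels))
  }
  if (!is_scalar_num(sfreq) || sfreq <= 0)
    cc_config_error("`sfreq` must be positive")
  if (length(source_band) != 2 || !all(is.finite(source_band)) ||
      source_band[1] <= 0 || source_band[2] <= source_band[1] ||
      source_band[2] >= sfreq / 2)
    cc_config_error(sprintf(
      "`source_band` must satisfy 0 < low < high < sfreq/2 = %g", sfreq / 2))
  if (!is_scalar_num(noise_sigma) || noise_sigma < 0)
    cc_config_error("`noise_sigma` must be >= 0")
  structure(
    list(n_channels = as.integer(n_channels),
         coupled_groups = lapply(coupled_groups, as.integer),
         source_band = as.numeric(source_band),
         noise_sigma = as.numeric(noise_sigma),
         sfreq = as.numeric(sfreq), seed = as.integer(seed)),
    class = "coupling_model")
}

#' Specify a multi-class synthetic cohort
#'
#' @param classes List of class entries, each a list with fields `label`
#'   (string), `model` (a [coupling_model()]) and `n_subjects` (>= 1).
#' @param duration_s Recording duration per subject in seconds.
#' @param seed Integer global seed, expanded to per-subject sub-seeds by a
#'   fixed counter scheme so each subject is reproducible independently of
#'   generation order.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(classes, duration_s, seed = 1L) {
  if (!is.list(classes) || !length(classes))
    cc_config_error("`classes` must be a non-empty list")
  labels <- character(0)
  for (cl in classes) {
    if (!all(c("label", "model", "n_subjects") %in% names(cl)))
      cc_config_error("each class needs fields label, model, n_subjects")
    if (!inherits(cl$model, "coupling_model"))
      cc_config_error(sprintf("class '%s': model is not a coupling_model", cl$label))
    if (!is_count(cl$n_subjects) || cl$n_subjects < 1)
      cc_config_error(sprintf("class '%s': n_subjects must be >= 1", cl$label))
    labels <- c(labels, as.character(cl$label))
  }
  if (anyDuplicated(labels))
    cc_config_error(sprintf(
      "duplicate class label(s) with conflicting models: %s",
      paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  if (!is_scalar_num(duration_s) || duration_s <= 0)
    cc_config_error("`duration_s` must be positive")
  structure(list(classes = classes, duration_s = as.numeric(duration_s),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# unit-variance Gaussian noise band-limited by a zero-phase FFT brick-wall
band_limited_noise <- function(n, band, sfreq) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- (seq_len(n) - 1) * sfreq / n
  f <- pmin(f, sfreq - f)                      # fold to [0, sfreq/2]
  Z[!(f >= band[1] & f <= band[2])] <- 0
  s <- Re(stats::fft(Z, inverse = TRUE)) / n
  s / stats::sd(s)
}

#' Generate one synthetic recording
#'
#' Channel i is the sum of the latent sources of every group containing i,
#' plus `noise_sigma` times independent white Gaussian noise. Deterministic
#' given the model (including its seed) and duration.
#'
#' @param model A [coupling_model()].
#' @param duration_s Duration in seconds; must cover at least two default
#'   0.4 s analysis windows.
#' @param subject_id Subject identifier.
#' @param label Optional class label.
#' @return An [eeg_recording()] with 10-20 names when `n_channels == 19`,
#'   otherwise `Ch01`, `Ch02`, ...
#' @export
generate_recording <- function(model, duration_s, subject_id, label = NULL) {
  stopifnot(inherits(model, "coupling_model"))
  if (!is_scalar_num(duration_s) || duration_s <= 0)
    cc_config_error("`duration_s` must be positive")
  n <- sec_to_samples(duration_s, model$sfreq)
  if (n < 2L * sec_to_samples(0.4, model$sfreq))
    cc_config_error(sprintf(
      "duration %g s too short: need at least two 0.4 s analysis windows", duration_s))
  ch_names <- if (model$n_channels == 19L) eeg_channels_1020 else
    sprintf("Ch%02d", seq_len(model$n_channels))
  data <- with_seed(model$seed, {
    x <- matrix(0, model$n_channels, n)
    for (g in model$coupled_groups) {
      src <- band_limited_noise(n, model$source_band, model$sfreq)
      x[g, ] <- sweep(x[g, , drop = FALSE], 2L, src, `+`)
    }
    if (model$noise_sigma > 0)
      x <- x + model$noise_sigma * matrix(stats::rnorm(model$n_channels * n),
                                          model$n_channels, n)
    x
  })
  eeg_recording(data, ch_names, model$sfreq, subject_id, label)
}

#' Generate a multi-class synthetic cohort
#'
#' One recording per subject, with globally unique subject ids
#' (`sub-001`, `sub-002`, ...) and class labels attached. Each subject's
#' sub-seed is derived from the cohort seed by a fixed counter scheme.
#'
#' @param spec A [cohort_spec()].
#' @return List of [eeg_recording()] objects.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- list()
  counter <- 0L
  for (cl in spec$classes) {
    for (s in seq_len(cl$n_subjects)) {
      counter <- counter + 1L
      m <- cl$model
      m$seed <- mix_seed(spec$seed, counter)
      recs[[counter]] <- generate_recording(
        m, spec$duration_s, sprintf("sub-%03d", counter), cl$label)
    }
  }
  recs
}

#' Subject table of a cohort
#'
#' @param recordings List of [eeg_recording()] objects.
#' @return `data.frame` with columns `subject_id`, `label`.
#' @export
cohort_subjects <- function(recordings) {
  data.frame(
    subject_id = vapply(recordings, function(r) r$subject_id, ""),
    label = vapply(recordings, function(r) if (is.null(r$label)) NA_character_
                   else r$label, ""),
    stringsAsFactors = FALSE)
}
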
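test_that("coupled channels with zero noise are identical and fully coherent", {
  m <- coupling_model(n_channels = 4, coupled_groups = list(c(1, 2)),
                      noise_sigma = 0, seed = 7)
  expect_error(generate_recording(m, 10, "s1"), NA)
  # channels 3/4 have zero variance (no group, no noise); use a 2-group model
  m2 <- coupling_model(n_channels = 4,
                       coupled_groups = list(c(1, 2), c(3, 4)),
                       noise_sigma = 0, seed = 7)
  rec <- generate_recording(m2, 10, "s1")
  expect_identical(rec$data[1, ], rec$data[2, ])
  sp <- msc_spectrum(rec$data[1, ], rec$data[2, ], rec$sfreq)
  expect_true(all(abs(sp$coherence - 1) < 1e-12))
})

test_that("independent-noise coherence shows the known 1/M small-sample bias", {
  m <- coupling_model(n_channels = 2, coupled_groups = list(), noise_sigma = 1,
                      seed = 11)
  rec <- generate_recording(m, 820, "s1")   # many 0.4 s windows
  wins <- slide_windows(make_segment(rec$data, rec$sfreq), window_spec())
  wins <- wins[seq(1, length(wins), by = 4)]  # keep windows disjoint-ish
  est <- vapply(wins[seq_len(1000)], function(w) {
    sp <- msc_spectrum(w[1, ], w[2, ], rec$sfreq)
    band_average(sp$freq, sp$coherence, c(0.5, 45))
  }, 0)
  # M = 3 Welch sub-segments per window -> expected MSC for independent
  # Gaussians is approximately 1/M
  expect_equal(mean(est), 1 / 3, tolerance = 0.1)
  expect_lt(abs(mean(est) - 1 / 3), 0.03)
})

test_that("shared source plus noise recovers the analytic coherence", {
  fs <- 500
  set.seed(23)
  for (s2 in c(0.25, 1, 4)) {
    sig <- sqrt(s2)
    pr <- shared_source_pair(120 * fs, sig, fs)
    sp <- msc_spectrum(pr$x, pr$y, fs)  # ~1200 averaged sub-segments
    est <- band_average(sp$freq, sp$coherence, c(0.5, 45))
    expected <- shared_source_coherence(sig, c(0.5, fs / 2 - 1), fs)
    # expected is within 1% of the idealised (1/(1+sigma^2))^2
    expect_equal(expected, (1 / (1 + s2))^2, tolerance = 0.01)
    expect_equal(est, expected, tolerance = 0.15)
    expect_lt(abs(est - expected), 0.035)
  }
})

test_that("cohort generation counts, unique ids and determinism", {
  spec <- cohort_spec(
    classes = list(
      list(label = "a", model = coupling_model(n_channels = 3, seed = 1),
           n_subjects = 3),
      list(label = "b", model = coupling_model(n_channels = 3, seed = 1),
           n_subjects = 3)),
    duration_s = 60, seed = 5)
  recs <- generate_cohort(spec)
  expect_length(recs, 6)
  ids <- vapply(recs, function(r) r$subject_id, "")
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(table(cohort_subjects(recs)$label), table(rep(c("a", "b"), each = 3)),
               ignore_attr = TRUE)
  recs2 <- generate_cohort(spec)
  expect_identical(recs[[4]]$data, recs2[[4]]$data)
  # different cohort seed changes the signals
  spec2 <- spec; spec2$seed <- 6L
  expect_false(identical(generate_cohort(spec2)[[4]]$data, recs[[4]]$data))
})

test_that("duplicate class labels are rejected", {
  expect_error(
    cohort_spec(classes = list(
      list(label = "a", model = coupling_model(n_channels = 3), n_subjects = 2),
      list(label = "a", model = coupling_model(n_channels = 4), n_subjects = 2)),
      duration_s = 30),
    "duplicate class label")
})

test_that("channel variance matches group count plus noise power within 20%", {
  m <- coupling_model(n_channels = 5,
                      coupled_groups = list(c(1, 2, 3), c(1, 4)),
                      noise_sigma = 1, seed = 3)
  rec <- generate_recording(m, 60, "s1")
  v <- apply(rec$data, 1, var)
  # analytic: n_groups(i) * 1 + sigma^2
  groups_of <- c(2, 1, 1, 1, 0)
  expect_true(all(abs(v - (groups_of + 1)) / (groups_of + 1) < 0.2))
})

test_that("band-averaged coherence ranks coupled above uncoupled pairs (AUC >= 0.95)", {
  m <- coupling_model(coupled_groups = list(1:4), noise_sigma = 1, seed = 17)
  rec <- generate_recording(m, 30, "s1")   # default config: sigma 1, 4-30 Hz
  adj <- window_adjacency(rec$data, rec$sfreq,
                          spectral_config(band = c(4, 30)))
  v <- flatten_upper(adj)
  po <- pair_order(rec$channel_names)
  coupled <- po$i <= 4 & po$j <= 4
  auc <- mean(outer(v[coupled], v[!coupled], ">")) +
    0.5 * mean(outer(v[coupled], v[!coupled], "=="))
  expect_gte(auc, 0.95)
})

test_that("generator rejects invalid configurations", {
  expect_error(coupling_model(source_band = c(10, 300)), "source_band")
  expect_error(coupling_model(noise_sigma = -1), "noise_sigma")
  expect_error(coupling_model(coupled_groups = list(c(1, 99))), "invalid coupled group")
  m <- coupling_model(n_channels = 3)
  expect_error(generate_recording(m, -2, "s"), "positive")
  expect_error(generate_recording(m, 0.5, "s"), "too short")
})
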
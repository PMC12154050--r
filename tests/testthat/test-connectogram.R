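test_that("flattened length follows c(c-1)/2 for the montages of interest", {
  for (cc in c(2, 19, 20, 32, 64)) {
    m <- matrix(0, cc, cc)
    m[upper.tri(m)] <- runif(cc * (cc - 1) / 2)
    m <- m + t(m); diag(m) <- 1
    expect_length(flatten_upper(m), cc * (cc - 1) / 2)
  }
  expect_length(flatten_upper(unflatten_upper(runif(171), 19)), 171)
})

test_that("flattening uses row-major strictly-upper pair order", {
  cc <- 4
  m <- matrix(0, cc, cc)
  for (i in 1:(cc - 1)) for (j in (i + 1):cc) m[i, j] <- m[j, i] <- 10 * i + j
  diag(m) <- 1
  expect_equal(flatten_upper(m), c(12, 13, 14, 23, 24, 34))
  po <- pair_order(c("w", "x", "y", "z"))
  expect_equal(po$pair, c("w-x", "w-y", "w-z", "x-y", "x-z", "y-z"))
  # smallest case: single off-diagonal value
  m2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(flatten_upper(m2), 0.4)
})

test_that("unflatten is the exact inverse of flatten", {
  set.seed(20)
  m <- unflatten_upper(runif(171), 19)
  expect_identical(unflatten_upper(flatten_upper(m), 19), m)
  expect_true(all(unflatten_upper(rep(1, 171), 19) == 1))
  expect_error(unflatten_upper(runif(170), 19), "c\\(c-1\\)/2")
})

test_that("asymmetric matrices are rejected beyond tolerance", {
  m <- diag(3)
  m[1, 2] <- 0.5; m[2, 1] <- 0.5 + 1e-6
  expect_error(flatten_upper(m), "asymmetric")
  m[2, 1] <- 0.5 + 1e-12
  expect_silent(flatten_upper(m))
})

test_that("connectogram dimensions obey the pairs x windows law", {
  set.seed(21)
  cases <- list(list(c = 3, dur = 2, fs = 250), list(c = 5, dur = 3, fs = 200),
                list(c = 4, dur = 1.6, fs = 500))
  ws <- window_spec(0.4, 0.2)
  scfg <- spectral_config(subwin_samples = 40)  # >= 2 sub-segments at low rates
  for (cs in cases) {
    seg <- make_segment(matrix(rnorm(cs$c * cs$dur * cs$fs), cs$c), cs$fs)
    img <- build_connectogram(seg, ws, scfg)
    w <- round(0.4 * cs$fs); s <- round(0.2 * cs$fs)
    expect_equal(dim(img$pixels),
                 c(cs$c * (cs$c - 1) / 2,
                   floor((cs$dur * cs$fs - w) / s) + 1))
    expect_true(all(img$pixels >= 0 & img$pixels <= 1))
    expect_equal(nrow(img$pair_order), nrow(img$pixels))
  }
})

test_that("identical channels give an all-ones image", {
  x <- rnorm(500)
  seg <- make_segment(rbind(x, x, x), 250)
  img <- build_connectogram(seg, scfg = spectral_config(subwin_samples = 40))
  expect_true(all(abs(img$pixels - 1) < 1e-12))
})

test_that("perturbing one window's samples only changes overlapping columns", {
  set.seed(22)
  fs <- 500
  seg <- make_segment(matrix(rnorm(3 * 2 * fs), 3), fs)  # 9 windows
  img1 <- build_connectogram(seg)
  seg2 <- seg
  seg2$data[, 401:600] <- seg2$data[, 401:600] + matrix(rnorm(3 * 200), 3)
  img2 <- build_connectogram(seg2)
  changed <- which(colSums(abs(img1$pixels - img2$pixels)) > 1e-12)
  expect_equal(changed, 4:6)   # windows whose span overlaps samples 401-600
})

test_that("png export quantizes with round-half-up and read-back dims match", {
  set.seed(23)
  seg <- make_segment(matrix(rnorm(3 * 500), 3), 250)
  img <- build_connectogram(seg, scfg = spectral_config(subwin_samples = 40))
  img$pixels[1, 1] <- 0; img$pixels[2, 1] <- 1; img$pixels[3, 1] <- 0.5
  path <- withr::local_tempfile(fileext = ".png")
  write_connectogram_png(img, path)
  px <- png::readPNG(path)
  expect_equal(dim(px), dim(img$pixels))   # height = pairs, width = windows
  expect_equal(px[1, 1] * 255, 0)
  expect_equal(px[2, 1] * 255, 255)
  expect_equal(px[3, 1] * 255, 128)        # floor(0.5*255 + 0.5)
  # quantization error bound 1/510
  expect_lt(max(abs(px - img$pixels)), 1 / 510 + 1e-9)
})

test_that("rds round trip is lossless and schema violations error", {
  set.seed(24)
  seg <- make_segment(matrix(rnorm(3 * 500), 3), 250, subject_id = "sub-7",
                      label = "ctl", segment_index = 3L)
  img <- build_connectogram(seg, scfg = spectral_config(subwin_samples = 40))
  path <- withr::local_tempfile(fileext = ".rds")
  write_connectogram(img, path)
  back <- read_connectogram(path)
  expect_identical(back$pixels, img$pixels)
  expect_identical(back$pair_order, img$pair_order)
  expect_equal(back$subject_id, "sub-7")
  broken <- unclass(img)
  broken$pair_order <- NULL
  saveRDS(broken, path)
  expect_error(read_connectogram(path), "pair_order")
})

test_that("transform_cohort yields one image per segment with labels attached", {
  spec <- cohort_spec(
    classes = list(list(label = "a",
                        model = coupling_model(n_channels = 3, sfreq = 250,
                                               coupled_groups = list(c(1, 2)),
                                               source_band = c(4, 30)),
                        n_subjects = 2)),
    duration_s = 4, seed = 9)
  imgs <- transform_cohort(generate_cohort(spec), segment_length_s = 2,
                           scfg = spectral_config(subwin_samples = 40))
  expect_length(imgs, 4)
  expect_equal(unique(connectogram_labels(imgs)), "a")
  expect_equal(sort(unique(connectogram_subjects(imgs))),
               c("sub-001", "sub-002"))
})
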
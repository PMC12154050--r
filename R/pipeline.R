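# End-to-end pipeline: simulate -> split -> transform -> train/evaluate,
# with CSV manifests as the inter-stage contract and a run-metadata JSON
# tying every artifact to the configuration that produced it.

#' Default two-class demonstration cohort
#'
#' Two classes with contrasting planted coupling on the 19-channel 10-20
#' montage at 500 Hz: class `frontal` couples the seven frontal electrodes
#' (Fp1, Fp2, F7, F3, Fz, F4, F8), class `occipital` couples the seven
#' posterior electrodes (T5, P3, Pz, P4, T6, O1, O2). Sources are 4-30 Hz
#' band-limited Gaussian noise, independent channel noise has unit standard
#' deviation, six subjects per class, 60 s per recording.
#'
#' @param seed Integer cohort seed.
#' @param n_subjects Subjects per class (default 6).
#' @param duration_s Recording length in seconds (default 60).
#' @param noise_sigma Channel noise standard deviation (default 1).
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L, n_subjects = 6L, duration_s = 60,
                                noise_sigma = 1) {
  frontal <- match(c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"),
                   eeg_channels_1020)
  occipital <- match(c("T5", "P3", "Pz", "P4", "T6", "O1", "O2"),
                     eeg_channels_1020)
  cohort_spec(
    classes = list(
      list(label = "frontal",
           model = coupling_model(coupled_groups = list(frontal),
                                  noise_sigma = noise_sigma),
           n_subjects = n_subjects),
      list(label = "occipital",
           model = coupling_model(coupled_groups = list(occipital),
                                  noise_sigma = noise_sigma),
           n_subjects = n_subjects)),
    duration_s = duration_s, seed = seed)
}

#' Pipeline run configuration
#'
#' Bundles every stage's parameters. Defaults mirror the best-performing
#' regime of the method: 10 s segments, 0.4 s windows with 50 percent
#' overlap, 5 folds, the shallow ResNet, small batches.
#'
#' @param cohort A [cohort_spec()] (default [default_cohort_spec()]).
#' @param segment_length_s Segment length in seconds, one of 10/20/30
#'   typically (default 10).
#' @param wspec A [window_spec()].
#' @param scfg A [spectral_config()].
#' @param architecture Classifier architecture (default `"shallow_resnet"`).
#' @param tcfg A [train_config()].
#' @param k Cross-validation folds (default 5).
#' @param outdir Output directory.
#' @param seed Global seed propagated to all stochastic stages.
#' @param write_edf Also write cohort recordings as EDF (default TRUE).
#' @param write_png Also write images as PNG (default TRUE).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, segment_length_s = 10,
                       wspec = window_spec(), scfg = spectral_config(),
                       architecture = "shallow_resnet",
                       tcfg = train_config(), k = 5L,
                       outdir = tempfile("connectocoh-run-"), seed = 1L,
                       write_edf = TRUE, write_png = TRUE) {
  if (is.null(cohort)) cohort <- default_cohort_spec(seed = seed)
  stopifnot(inherits(cohort, "cohort_spec"), inherits(wspec, "window_spec"),
            inherits(scfg, "spectral_config"), inherits(tcfg, "train_config"))
  if (!segment_length_s %in% c(10, 20, 30))
    message(sprintf("note: segment_length_s = %g is outside the usual {10, 20, 30}",
                    segment_length_s))
  structure(list(cohort = cohort, segment_length_s = segment_length_s,
                 wspec = wspec, scfg = scfg, architecture = architecture,
                 tcfg = tcfg, k = as.integer(k), outdir = outdir,
                 seed = as.integer(seed), write_edf = write_edf,
                 write_png = write_png),
            class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Stage: simulate the cohort
#'
#' Writes one recording per subject under `outdir/cohort/` plus
#' `cohort/manifest.csv` (subject_id, label, path, sfreq, n_channels,
#' duration_s).
#'
#' @param cfg A [run_config()].
#' @return The cohort manifest `data.frame`, invisibly.
#' @export
stage_simulate <- function(cfg) {
  dir.create(file.path(cfg$outdir, "cohort"), recursive = TRUE, showWarnings = FALSE)
  recs <- generate_cohort(cfg$cohort)
  ext <- if (cfg$write_edf) "edf" else "rds"
  manifest <- do.call(rbind, lapply(recs, function(r) {
    path <- file.path(cfg$outdir, "cohort", sprintf("%s.%s", r$subject_id, ext))
    write_recording(r, path)
    data.frame(subject_id = r$subject_id, label = r$label, path = path,
               sfreq = r$sfreq, n_channels = nrow(r$data),
               duration_s = ncol(r$data) / r$sfreq, stringsAsFactors = FALSE)
  }))
  utils::write.csv(manifest, file.path(cfg$outdir, "cohort", "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

read_stage_manifest <- function(cfg, rel, stage) {
  path <- file.path(cfg$outdir, rel)
  if (!file.exists(path))
    cc_input_error(sprintf("stage '%s': missing input manifest %s (run the previous stage first)",
                           stage, path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Stage: subject-wise fold assignment
#'
#' Reads the cohort manifest and writes `folds.csv` (subject_id, label, fold).
#'
#' @param cfg A [run_config()].
#' @return The [assign_folds()] `split_plan`, invisibly.
#' @export
stage_split <- function(cfg) {
  manifest <- read_stage_manifest(cfg, file.path("cohort", "manifest.csv"), "split")
  plan <- assign_folds(manifest[, c("subject_id", "label")], cfg$k,
                       seed = mix_seed(cfg$seed, 1L))
  utils::write.csv(plan$assignment, file.path(cfg$outdir, "folds.csv"),
                   row.names = FALSE)
  invisible(plan)
}

#' Stage: transform recordings into connectogram images
#'
#' Segments every recording in the cohort manifest and writes one `.rds`
#' image (plus optional PNG) per segment under `outdir/images/`, with
#' `images/manifest.csv` (path, subject_id, label, segment_index, height,
#' width).
#'
#' @param cfg A [run_config()].
#' @return The image manifest `data.frame`, invisibly.
#' @export
stage_transform <- function(cfg) {
  manifest <- read_stage_manifest(cfg, file.path("cohort", "manifest.csv"), "transform")
  dir.create(file.path(cfg$outdir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- read_recording(manifest$path[i], manifest$subject_id[i],
                          manifest$label[i])
    segs <- segment_recording(rec, cfg$segment_length_s)
    for (seg in segs) {
      img <- build_connectogram(seg, cfg$wspec, cfg$scfg)
      base <- sprintf("%s_seg%03d", seg$subject_id, seg$segment_index)
      path <- file.path(cfg$outdir, "images", paste0(base, ".rds"))
      write_connectogram(img, path)
      if (cfg$write_png)
        write_connectogram_png(img, file.path(cfg$outdir, "images",
                                              paste0(base, ".png")))
      rows[[length(rows) + 1L]] <- data.frame(
        path = path, subject_id = seg$subject_id, label = seg$label,
        segment_index = seg$segment_index, height = nrow(img$pixels),
        width = ncol(img$pixels), stringsAsFactors = FALSE)
    }
  }
  im <- do.call(rbind, rows)
  utils::write.csv(im, file.path(cfg$outdir, "images", "manifest.csv"),
                   row.names = FALSE)
  invisible(im)
}

#' Stage: train and evaluate under subject-wise cross-validation
#'
#' Reads the image and fold manifests, runs [subject_wise_cv()], writes one
#' model per fold under `models/`, per-fold reports and confusion matrices
#' under `reports/`, and a `reports/summary.csv`.
#'
#' @param cfg A [run_config()].
#' @return The [subject_wise_cv()] result, invisibly.
#' @export
stage_train_eval <- function(cfg) {
  im <- read_stage_manifest(cfg, file.path("images", "manifest.csv"), "train")
  folds <- read_stage_manifest(cfg, "folds.csv", "train")
  plan <- structure(list(k = max(folds$fold), assignment = folds),
                    class = "split_plan")
  images <- lapply(im$path, read_connectogram)
  spec <- model_spec(cfg$architecture,
                     input_shape = c(im$height[1], im$width[1]),
                     n_classes = length(unique(im$label)))
  cv <- subject_wise_cv(images, plan, spec, cfg$tcfg)
  dir.create(file.path(cfg$outdir, "reports"), recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(cv$reports)) {
    rep <- cv$reports[[f]]
    jsonlite::write_json(
      list(fold = f, accuracy = rep$accuracy, per_class = rep$per_class),
      file.path(cfg$outdir, "reports", sprintf("fold-%d.json", f)),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(rep$confusion_matrix),
                     file.path(cfg$outdir, "reports",
                               sprintf("fold-%d-confusion.csv", f)),
                     row.names = FALSE)
  }
  utils::write.csv(
    data.frame(fold = seq_along(cv$accuracies), accuracy = cv$accuracies),
    file.path(cfg$outdir, "reports", "summary.csv"), row.names = FALSE)
  invisible(cv)
}

#' Run the full pipeline
#'
#' simulate -> split -> transform -> train/evaluate. Writes a
#' `run-metadata.json` capturing the configuration, its hash, package and R
#' versions and the seed, so every artifact in the run directory is
#' traceable.
#'
#' @param cfg A [run_config()].
#' @return List with the cross-validation result and the run directory.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    package = "connectocoh",
    package_version = as.character(utils::packageVersion("connectocoh")),
    r_version = R.version.string,
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    config = cfg)
  jsonlite::write_json(meta, file.path(cfg$outdir, "run-metadata.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA, pretty = TRUE)
  stage_simulate(cfg)
  stage_split(cfg)
  stage_transform(cfg)
  cv <- stage_train_eval(cfg)
  list(cv = cv, outdir = cfg$outdir,
       mean_accuracy = cv$mean_accuracy, sd_accuracy = cv$sd_accuracy)
}
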
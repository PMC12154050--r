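# Evaluation: confusion-matrix metrics plus one-vs-rest ROC AUC, and the
# subject-wise cross-validation driver. The train/test subject disjointness
# assertion runs on every fold and failure is a hard error, never a warning.

#' Classification report from predicted probabilities
#'
#' Computes accuracy, the confusion matrix (rows = true class, columns =
#' predicted; row sums equal supports), per-class precision/recall/F1 and
#' one-vs-rest ROC AUC from softmax scores. A class absent from the test
#' set gets `NA` AUC rather than an error.
#'
#' @param probs `n x n_classes` probability matrix with class column names.
#' @param y True labels (character/factor), one per row.
#' @return An object of class `eval_report`.
#' @export
evaluation_report <- function(probs, y) {
  if (is.null(colnames(probs))) cc_input_error("`probs` needs class column names")
  classes <- colnames(probs)
  classes <- classes[!startsWith(classes, ".unused_")]
  probs <- probs[, classes, drop = FALSE]
  y <- as.character(y)
  if (length(y) != nrow(probs)) cc_input_error("length(y) must match nrow(probs)")
  if (!length(y)) cc_input_error("empty test set")
  unknown <- setdiff(unique(y), classes)
  if (length(unknown))
    cc_input_error(sprintf("test label(s) not among model classes: %s",
                           paste(unknown, collapse = ", ")))
  pred <- classes[max.col(probs, ties.method = "first")]
  cm <- table(factor(y, levels = classes), factor(pred, levels = classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  support <- rowSums(cm)
  tp <- diag(cm)
  precision <- ifelse(colSums(cm) > 0, tp / colSums(cm), NA_real_)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  auc <- vapply(classes, function(cl) {
    resp <- as.integer(y == cl)
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, probs[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, 0)
  structure(
    list(accuracy = sum(tp) / length(y),
         per_class = data.frame(class = classes, precision = precision,
                                recall = recall, f1 = f1, support = support,
                                roc_auc = auc, row.names = NULL,
                                stringsAsFactors = FALSE),
         confusion_matrix = cm,
         n = length(y)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f on %d samples\n", x$accuracy, x$n))
  print(x$per_class, digits = 4)
  cat("confusion matrix (rows = true):\n")
  print(x$confusion_matrix)
  invisible(x)
}

#' Evaluate a fitted model on a test set
#'
#' @param model Fitted `nn_model`.
#' @param x Test input tensor.
#' @param y True labels.
#' @return An [evaluation_report()] `eval_report`.
#' @export
evaluate_model <- function(model, x, y) {
  if (is.null(model$classes)) cc_config_error("model has not been trained")
  evaluation_report(nn_predict(model, x), y)
}

#' Subject-wise k-fold cross-validation
#'
#' For each fold: all segments of the held-out fold's subjects form the test
#' set; all other subjects' segments form the training pool, from which a
#' small subject-wise validation holdout (`validation_frac` of training
#' subjects, at least one) is carved for the learning curve. Train/test
#' subject disjointness is asserted on every fold before any training. The
#' image transform has no fitted parameters, so per-fold preprocessing
#' independence holds structurally.
#'
#' @param images List of `connectogram` objects (each carries its subject
#'   and label).
#' @param plan A [assign_folds()] `split_plan` covering every subject.
#' @param spec A [model_spec()].
#' @param cfg A [train_config()]; fold-specific seeds are derived from
#'   `cfg$seed`.
#' @param validation_frac Fraction of training subjects held out for the
#'   per-epoch validation curve (default 0.1).
#' @param verbose Print fold progress.
#' @return List with `reports` (per-fold `eval_report`s), `accuracies`,
#'   `val_accuracies` (final-epoch validation accuracy per fold),
#'   `mean_accuracy`, `sd_accuracy`, `plan`.
#' @export
subject_wise_cv <- function(images, plan, spec, cfg = train_config(),
                            validation_frac = 0.1, verbose = FALSE) {
  stopifnot(inherits(plan, "split_plan"), inherits(spec, "model_spec"))
  subj <- connectogram_subjects(images)
  labs <- connectogram_labels(images)
  missing <- setdiff(unique(subj), plan$assignment$subject_id)
  if (length(missing))
    cc_config_error(sprintf("subjects missing from split plan: %s",
                            paste(missing, collapse = ", ")))
  fold_of <- stats::setNames(plan$assignment$fold, plan$assignment$subject_id)
  reports <- vector("list", plan$k)
  accs <- numeric(plan$k)
  val_accs <- rep(NA_real_, plan$k)
  for (f in seq_len(plan$k)) {
    test_subj <- plan$assignment$subject_id[plan$assignment$fold == f]
    train_subj <- plan$assignment$subject_id[plan$assignment$fold != f]
    assert_disjoint_subjects(train_subj, test_subj)
    te <- which(subj %in% test_subj)
    tr <- which(subj %in% train_subj)
    assert_disjoint_subjects(unique(subj[tr]), unique(subj[te]))
    if (!length(te) || !length(tr))
      cc_config_error(sprintf("fold %d has an empty train or test set", f))
    # subject-wise validation holdout inside the training fold
    val_subj <- with_seed(mix_seed(cfg$seed, 1000L + f), {
      n_val <- max(1L, round(validation_frac * length(train_subj)))
      sample(train_subj, min(n_val, length(train_subj) - 1L))
    })
    va <- which(subj %in% val_subj)
    tr_keep <- setdiff(tr, va)
    # never let the holdout starve the training set of a class
    if (length(unique(labs[tr_keep])) < 2L) {
      va <- integer(0)
    } else {
      tr <- tr_keep
    }
    model <- build_model(spec, seed = mix_seed(cfg$seed, f))
    fold_cfg <- cfg
    fold_cfg$seed <- mix_seed(cfg$seed, 2000L + f)
    fitted <- nn_train(model,
                       connectogram_tensor(images[tr], spec$architecture),
                       labs[tr], fold_cfg,
                       validation = if (length(va)) list(
                         x = connectogram_tensor(images[va], spec$architecture),
                         y = labs[va]) else NULL,
                       verbose = verbose)
    reports[[f]] <- evaluate_model(
      fitted, connectogram_tensor(images[te], spec$architecture), labs[te])
    accs[f] <- reports[[f]]$accuracy
    val_accs[f] <- utils::tail(fitted$history$val_accuracy, 1)
    if (verbose)
      message(sprintf("fold %d/%d: test subjects {%s}, accuracy %.4f",
                      f, plan$k, paste(test_subj, collapse = ", "), accs[f]))
  }
  list(reports = reports, accuracies = accs, val_accuracies = val_accs,
       mean_accuracy = mean(accs), sd_accuracy = stats::sd(accs),
       plan = plan)
}
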
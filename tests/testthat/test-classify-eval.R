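# independent metric oracle: plain loops over the prediction table
oracle_metrics <- function(truth, pred, classes) {
  out <- list()
  for (cl in classes) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    out[[cl]] <- c(precision = prec, recall = rec,
                   f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
                     2 * prec * rec / (prec + rec) else NA_real_)
  }
  out
}

# Mann-Whitney AUC, computed directly from the rank definition
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

probs_from_pred <- function(pred, classes, margin = 0.6) {
  p <- matrix((1 - margin) / (length(classes) - 1), length(pred), length(classes),
              dimnames = list(NULL, classes))
  p[cbind(seq_along(pred), match(pred, classes))] <- margin
  p
}

test_that("perfect predictions give accuracy 1 and a diagonal confusion matrix", {
  y <- rep(c("cn", "ad", "ftd"), times = c(5, 7, 4))
  rep1 <- evaluation_report(probs_from_pred(y, c("ad", "cn", "ftd")), y)
  expect_equal(rep1$accuracy, 1)
  expect_equal(diag(rep1$confusion_matrix), c(ad = 7, cn = 5, ftd = 4))
  expect_true(all(rep1$confusion_matrix[upper.tri(rep1$confusion_matrix)] == 0))
  expect_equal(rep1$per_class$support, c(7, 5, 4))
  expect_true(all(rep1$per_class$f1 == 1))
})

test_that("all-one-class predictions on a balanced 3-class set score 1/3", {
  y <- rep(c("a", "b", "c"), each = 6)
  rep1 <- evaluation_report(probs_from_pred(rep("a", 18), c("a", "b", "c")), y)
  expect_equal(rep1$accuracy, 1 / 3)
  expect_equal(unname(rowSums(rep1$confusion_matrix)), c(6, 6, 6))
})

test_that("per-class precision/recall/F1 match a brute-force oracle", {
  set.seed(40)
  classes <- c("a", "b", "c")
  y <- sample(classes, 60, TRUE)
  pred <- y
  flip <- sample(60, 20)
  pred[flip] <- sample(classes, 20, TRUE)
  rep1 <- evaluation_report(probs_from_pred(pred, classes), y)
  orc <- oracle_metrics(y, pred, classes)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    expect_equal(rep1$per_class$precision[i], unname(orc[[cl]]["precision"]))
    expect_equal(rep1$per_class$recall[i], unname(orc[[cl]]["recall"]))
    expect_equal(rep1$per_class$f1[i], unname(orc[[cl]]["f1"]))
  }
  expect_equal(unname(rowSums(rep1$confusion_matrix)),
               unname(rep1$per_class$support))
  expect_equal(rep1$accuracy, mean(pred == y))
})

test_that("one-vs-rest ROC AUC agrees with the rank-based definition", {
  set.seed(41)
  y <- rep(c("a", "b"), each = 15)
  sc_a <- c(rnorm(15, 1), rnorm(15, 0))
  probs <- cbind(a = 1 / (1 + exp(-sc_a)), b = 1 - 1 / (1 + exp(-sc_a)))
  rep1 <- evaluation_report(probs, y)
  expect_equal(rep1$per_class$roc_auc[1], oracle_auc(probs[, "a"], y == "a"))
  expect_equal(rep1$per_class$roc_auc[2], oracle_auc(probs[, "b"], y == "b"))
})

test_that("a class absent from the test set yields NA AUC, not an error", {
  y <- rep("a", 6)
  p <- probs_from_pred(rep("a", 6), c("a", "b"))
  rep1 <- evaluation_report(p, y)
  expect_true(is.na(rep1$per_class$roc_auc[2]))
  expect_true(is.na(rep1$per_class$roc_auc[1]))
  expect_equal(rep1$accuracy, 1)
})

test_that("subject-wise CV produces k reports with held-out subjects only", {
  set.seed(42)
  imgs <- fake_image_set(n_per = 5, segs = 2, h = 12, w = 8, shift = 0.3)
  subj <- unique(data.frame(subject_id = connectogram_subjects(imgs),
                            label = connectogram_labels(imgs)))
  plan <- assign_folds(subj, k = 5, seed = 7)
  spec <- model_spec("shallow_resnet", c(12, 8), 2)
  cv <- subject_wise_cv(imgs, plan, spec,
                        train_config(epochs = 2, batch_size = 4, seed = 1))
  expect_length(cv$reports, 5)
  for (f in 1:5) {
    test_subj <- plan$assignment$subject_id[plan$assignment$fold == f]
    expect_length(test_subj, 2)             # 10 subjects, k = 5
    expect_equal(cv$reports[[f]]$n, 2 * 2)  # 2 segments per subject
  }
  expect_equal(cv$mean_accuracy, mean(cv$accuracies))
  expect_equal(cv$sd_accuracy, sd(cv$accuracies))
})

test_that("CV refuses images whose subjects are missing from the plan", {
  set.seed(43)
  imgs <- fake_image_set(n_per = 2, segs = 1)
  subj <- unique(data.frame(subject_id = connectogram_subjects(imgs),
                            label = connectogram_labels(imgs)))
  plan <- assign_folds(subj, k = 2, seed = 1)
  plan$assignment <- plan$assignment[-1, ]
  expect_error(subject_wise_cv(imgs, plan, model_spec("shallow_resnet", c(12, 8), 2)),
               "missing from split plan")
})

test_that("a tampered plan putting one subject in two folds trips the leakage assertion", {
  set.seed(44)
  imgs <- fake_image_set(n_per = 2, segs = 1)
  subj <- unique(data.frame(subject_id = connectogram_subjects(imgs),
                            label = connectogram_labels(imgs)))
  plan <- assign_folds(subj, k = 2, seed = 1)
  extra <- plan$assignment[1, ]
  extra$fold <- 3 - extra$fold              # same subject, other fold
  plan$assignment <- rbind(plan$assignment, extra)
  expect_error(subject_wise_cv(imgs, plan, model_spec("shallow_resnet", c(12, 8), 2)),
               "leakage")
})
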
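test_that("split plans partition subjects exactly and deterministically", {
  subj <- sprintf("s%02d", 1:11)
  plan <- make_splits(subj, test_frac = 0.1, n_folds = 10L, seed = 1L)
  expect_length(plan$test_subjects, 1L)
  expect_length(plan$folds, 10L)
  expect_true(all(vapply(plan$folds,
                         function(f) length(f$val_subjects) == 1L, logical(1))))
  expect_identical(plan, make_splits(subj, 0.1, 10L, seed = 1L))
  expect_error(make_splits(sprintf("s%d", 1:10), 0.1, 10L), "at least")
})

test_that("subject disjointness holds across 50 random plans", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(12:60, 1)
    subj <- sprintf("s%03d", seq_len(n))
    nf <- sample(2:10, 1)
    if (n < nf + 1) nf <- 2L
    plan <- make_splits(subj, test_frac = 0.1, n_folds = nf,
                        seed = sample.int(1e6, 1))
    non_test <- setdiff(subj, plan$test_subjects)
    val_union <- character(0)
    for (f in plan$folds) {
      expect_length(intersect(f$train_subjects, f$val_subjects), 0L)
      expect_length(intersect(plan$test_subjects,
                              c(f$train_subjects, f$val_subjects)), 0L)
      expect_setequal(c(f$train_subjects, f$val_subjects), non_test)
      val_union <- c(val_union, f$val_subjects)
    }
    expect_setequal(val_union, non_test)   # folds cover all non-test subjects
    expect_equal(anyDuplicated(val_union), 0L)
  }
})

test_that("binary metrics reproduce the formula suite from counts", {
  # TP=90 FN=10 TN=80 FP=20, evaluated by hand from the definitions
  truth <- c(rep("abnormal", 100), rep("normal", 100))
  pred <- c(rep("abnormal", 90), rep("normal", 10),
            rep("abnormal", 20), rep("normal", 80))
  m <- compute_metrics(truth, pred)
  expect_equal(m$counts, list(TP = 90, TN = 80, FP = 20, FN = 10))
  expect_equal(m$metrics$sensitivity, 0.90)
  expect_equal(m$metrics$specificity, 0.80)
  expect_equal(m$metrics$accuracy, 0.85)
  expect_equal(m$metrics$score, 0.85)
  expect_equal(m$metrics$f1, 180 / 210)
  # perfect predictions
  p <- compute_metrics(truth, truth)
  expect_true(all(unlist(p$metrics) == 1))
  # degenerate all-positive classifier on a balanced set
  d <- compute_metrics(truth, rep("abnormal", 200))
  expect_equal(d$metrics$sensitivity, 1)
  expect_equal(d$metrics$specificity, 0)
  expect_equal(d$metrics$score, 0.5)
  expect_error(compute_metrics(character(0), character(0)), "non-empty")
})

test_that("metrics agree with an independent confusion oracle on random labels", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    truth <- sample(c("normal", "abnormal"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("normal", "abnormal")
    pred <- sample(c("normal", "abnormal"), n, replace = TRUE)
    m <- compute_metrics(truth, pred)
    TP <- sum(truth == "abnormal" & pred == "abnormal")
    TN <- sum(truth == "normal" & pred == "normal")
    FP <- sum(truth == "normal" & pred == "abnormal")
    FN <- sum(truth == "abnormal" & pred == "normal")
    expect_equal(m$counts, list(TP = TP, TN = TN, FP = FP, FN = FN))
    expect_equal(m$metrics$accuracy, (TP + TN) / n)
    expect_equal(m$n, n)
  }
})

test_that("multi-class metrics macro-average one-vs-rest values", {
  truth <- c(rep("present", 4), rep("unknown", 2), rep("absent", 4))
  pred <- c("present", "present", "present", "unknown",
            "present", "unknown", rep("absent", 4))
  m <- compute_metrics(truth, pred)
  # one-vs-rest by hand: present 3/4, unknown 1/2, absent 4/4
  expect_equal(m$metrics$sensitivity, mean(c(3 / 4, 1 / 2, 1)))
  expect_equal(m$metrics$accuracy, 8 / 10)
  expect_equal(dim(m$confusion), c(3L, 3L))
  # a class absent from truth is excluded with a warning
  expect_warning(
    m2 <- compute_metrics(c("present", "absent"), c("present", "absent"),
                          classes = c("present", "unknown", "absent")),
    "unknown")
  expect_equal(m2$metrics$sensitivity, 1)
})

test_that("weighted accuracy follows the stated weighting formula", {
  conf <- matrix(c(3, 1, 0, 1, 1, 0, 0, 0, 4), 3, byrow = TRUE,
                 dimnames = list(c("present", "unknown", "absent"),
                                 c("present", "unknown", "absent")))
  expect_equal(weighted_accuracy(conf, c(5, 3, 1)), 22 / 30)
  # default weights are the murmur convention
  expect_equal(weighted_accuracy(conf), 22 / 30)
  # equal weights reduce to plain accuracy; diagonal matrices score 1
  expect_equal(weighted_accuracy(conf, c(1, 1, 1)), 8 / 10)
  expect_equal(weighted_accuracy(diag(c(2, 5, 1)), c(9, 2, 4)), 1)
  expect_error(weighted_accuracy(matrix(0, 3, 3)), "all-zero")
})

test_that("tidy and glance methods expose metrics as tibbles", {
  m <- compute_metrics(c("normal", "abnormal"), c("normal", "abnormal"))
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("accuracy", "score") %in% td$metric))
  gl <- glance(m)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n, 2L)
})

test_that("training config validates the protocol invariants", {
  expect_error(train_config(lr = 0), "positive")
  expect_error(train_config(patience = 400L, max_epochs = 400L), "patience")
  tc <- train_config()
  expect_equal(tc$lr, 0.008)
  expect_equal(tc$batch_size, 32L)
  expect_equal(tc$max_epochs, 400L)
  expect_equal(tc$patience, 15L)
})

test_that("training on a tiny fold restores the best-validation weights", {
  data <- small_feature_data()
  plan <- make_splits(data, test_frac = 0.125, n_folds = 2L, seed = 3L)
  model <- build_model(model_config(seed = 3L),
                       classes = class_levels(data$label))
  fit <- train_model(model, data, plan$folds[[1]],
                     train_config(max_epochs = 8L, patience = 4L, seed = 3L))
  h <- fit$history
  expect_true(nrow(h) <= 8L)
  expect_equal(fit$best_val, max(h$val_acc))
  expect_equal(fit$best_epoch, which.max(h$val_acc))
  # early stopping never keeps weights from after the best epoch
  expect_lte(fit$best_epoch, nrow(h))
  # re-evaluating the restored weights reproduces the logged best accuracy
  va <- data[data$subject_id %in% plan$folds[[1]]$val_subjects, ]
  pred <- predict(fit, va)
  expect_equal(mean(pred$.pred_class == va$label), fit$best_val)
  # if patience fired, the run stopped exactly patience epochs past the best
  if (nrow(h) < 8L) expect_equal(nrow(h), fit$best_epoch + 4L)
})
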
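# Independent metric oracles.
auc_trapezoid <- function(scores, labels) {
  # trapezoidal integration of the empirical ROC over all thresholds
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- labels == "lacerated"
  tpr <- c(0, vapply(thr, function(t) mean(scores[pos] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!pos] >= t), 0), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

test_that("confusion metrics match the direct formulas", {
  m <- metrics_from_counts(tp = 3, fp = 1, fn = 1, tn = 5)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)
  expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                 (m$precision + m$sensitivity))
  expect_true(is.na(metrics_from_counts(0, 0, 0, 5)$sensitivity))
})

test_that("rank AUC agrees with trapezoidal ROC integration and pROC", {
  set.seed(41)
  for (i in 1:10) {
    n <- 60
    labels <- sample(c("healthy", "lacerated"), n, replace = TRUE,
                     prob = c(0.6, 0.4))
    scores <- rnorm(n) + 0.8 * (labels == "lacerated")
    a <- auc_rank(scores, labels)
    expect_equal(a, auc_trapezoid(scores, labels))
    expect_equal(a, as.numeric(pROC::auc(
      pROC::roc(response = factor(labels, c("healthy", "lacerated")),
                predictor = scores, quiet = TRUE, direction = "<"))))
  }
  # tie convention: constant scores -> 0.5
  expect_equal(auc_rank(rep(0.3, 20),
                        rep(c("healthy", "lacerated"), 10)), 0.5)
  # perfect separation -> 1
  expect_equal(auc_rank(c(1, 2, 3, 10, 11),
                        c(rep("healthy", 3), rep("lacerated", 2))), 1)
})

test_that("AUC of permuted labels stays in the chance band", {
  splenometrics:::with_seed(42L, {
    labels <- rep(c("healthy", "lacerated"), 40)      # n = 80
    scores <- rnorm(80)
    aucs <- replicate(20, auc_rank(scores, sample(labels)))
    expect_true(all(aucs >= 0.35 & aucs <= 0.65))
  })
})

test_that("stratified split has the right size, balance and determinism", {
  tab <- synthetic_feature_table(93, seed = 5L)
  # class mix mirroring the post-QC study cohort: 48 healthy / 45 lacerated
  tab$label <- c(rep("healthy", 48), rep("lacerated", 45))
  tab$ais_grade <- c(rep(0L, 48), rep(c(2L, 3L, 4L, 5L), c(15, 16, 10, 4)))
  sp <- split_train_test(tab, 0.2, seed = 6L)
  expect_true(nrow(sp$test) %in% c(18, 19))
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), tab$sample_id)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  # class ratio preserved within one sample
  frac <- nrow(sp$test) / nrow(tab)
  for (lab in c("healthy", "lacerated")) {
    n_lab <- sum(tab$label == lab)
    expect_lte(abs(sum(sp$test$label == lab) - frac * n_lab), 1)
  }
  sp2 <- split_train_test(tab, 0.2, seed = 6L)
  expect_identical(sp2$test$sample_id, sp$test$sample_id)
  expect_error(split_train_test(tab, 0), "test_fraction")
  one_class <- tab[tab$label == "healthy", ]
  expect_error(split_train_test(one_class, 0.2, 1L), "class")
})

test_that("all five models reach AUC 1 on linearly separable features", {
  tab <- synthetic_feature_table(40, sep = 8, p = 6, seed = 7L)
  for (kind in splenometrics:::MODEL_KINDS) {
    cv <- cross_validate(tab, model_spec(kind, seed = 8L), k = 5, seed = 9L)
    expect_equal(unname(cv$mean[["auc"]]), 1, info = kind)
    expect_equal(unname(cv$sd[["auc"]]), 0, info = kind)
  }
})

test_that("cross-validation is stratified and guards its preconditions", {
  tab <- synthetic_feature_table(30, sep = 1, seed = 10L)
  expect_error(cross_validate(tab, k = 1), "k must be")
  few <- tab[c(1:10, 12, 14), ]   # lacerated count < k
  expect_error(cross_validate(few, model_spec("random_forest"), k = 8),
               "smallest class")
  cv <- cross_validate(tab, model_spec("naive_bayes", seed = 2L), k = 5,
                       seed = 3L)
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(unlist(cv$folds[-1]) >= 0 & unlist(cv$folds[-1]) <= 1))
})

test_that("a duplicated redundant feature barely moves random-forest metrics", {
  tab <- synthetic_feature_table(80, sep = 1.2, p = 10, seed = 11L)
  tab2 <- tab
  tab2$f11 <- tab2$f01                    # fully redundant duplicate
  cv1 <- cross_validate(tab, model_spec("random_forest", seed = 12L),
                        k = 5, seed = 13L)
  cv2 <- cross_validate(tab2, model_spec("random_forest", seed = 12L),
                        k = 5, seed = 13L)
  expect_lt(abs(cv1$mean[["auc"]] - cv2$mean[["auc"]]), 0.05)
  expect_lt(abs(cv1$mean[["accuracy"]] - cv2$mean[["accuracy"]]), 0.05)
})

test_that("evaluation enforces train/test disjointness and flags degenerate tests", {
  tab <- synthetic_feature_table(60, sep = 3, seed = 14L)
  sp <- split_train_test(tab, 0.25, seed = 15L)
  model <- train_model(sp$train, model_spec("random_forest", seed = 16L))
  expect_error(evaluate(model, sp$train[1:4, ]), "leakage")
  rep <- evaluate(model, sp$test)
  expect_true(all(unlist(rep$metrics) >= 0 & unlist(rep$metrics) <= 1))
  expect_equal(sum(rep$confusion), nrow(sp$test))
  # healthy-only test set: sensitivity undefined, flagged
  healthy_only <- sp$test[sp$test$label == "healthy", ]
  expect_message(rep0 <- evaluate(model, healthy_only), "undefined")
  expect_true(is.na(rep0$metrics$sensitivity))
})

test_that("per-grade accuracy pools AIS 4/5 and omits empty bins", {
  pred <- data.frame(sample_id = sprintf("S%d", 1:8),
                     label = c(rep("healthy", 3), rep("lacerated", 5)),
                     ais_grade = c(0, 0, 0, 2, 2, 3, 4, 5),
                     score = 0.5,
                     predicted = c("healthy", "healthy", "lacerated",
                                   "healthy", "lacerated", "lacerated",
                                   "lacerated", "lacerated"))
  pg <- per_grade_accuracy(list(predictions = pred))
  expect_equal(pg$bin, c("healthy", "AIS2", "AIS3", "AIS4_5"))
  expect_equal(pg$accuracy, c(2 / 3, 1 / 2, 1, 1))
  expect_equal(pg$n, c(3, 2, 1, 2))
  # all-correct classifier: every nonempty bin at 1; empty bin absent
  pred2 <- pred[pred$ais_grade != 3, ]
  pred2$predicted <- pred2$label
  pg2 <- per_grade_accuracy(list(predictions = pred2))
  expect_false("AIS3" %in% pg2$bin)
  expect_true(all(pg2$accuracy == 1))
})

test_that("leave-one-site-out matches within-site performance for identical sites", {
  tab <- synthetic_feature_table(120, sep = 2.5, seed = 17L)
  spec <- model_spec("random_forest", seed = 18L)
  loso <- leave_one_site_out(tab, "site_A", "site_B", spec)
  cv <- cross_validate(tab[tab$site == "site_A", ], spec, k = 5, seed = 19L)
  expect_lt(abs(loso$metrics$auc - cv$mean[["auc"]]), 0.1)
  # stratified subsampling of the test site
  loso14 <- leave_one_site_out(tab, "site_A", "site_B", spec, n_test = 14,
                               seed = 20L)
  expect_equal(nrow(loso14$predictions), 14)
  expect_error(leave_one_site_out(tab, "site_A", "site_X", spec), "absent")
})
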
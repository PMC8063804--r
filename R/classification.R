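# Classification of healthy vs. lacerated spleens from the feature table:
# stratified 80/20 split, stratified 5-fold cross-validation on the
# training portion, held-out test evaluation, per-grade accuracy, and
# leave-one-site-out analysis.
#
# The positive class is "lacerated" throughout: sensitivity is the detection
# rate of injured spleens. Standardization is always fit on training data
# only (never on the fold or set being scored).

MODEL_KINDS <- c("random_forest", "naive_bayes", "svm",
                 "knn_subspace_ensemble", "subspace_discriminant_ensemble")

#' Specify a classifier
#'
#' Defaults: random forest with 500 trees and `sqrt(p)` candidate features
#' per split; Gaussian naive Bayes; RBF-kernel SVM with cost 1 on
#' unit-variance features; k-NN ensemble as a random-subspace ensemble of
#' 30 learners with `k = 5` on feature subsets of fraction 0.5; subspace
#' discriminant as 30 LDA learners on random subspaces of fraction 0.5.
#'
#' @param kind one of `"random_forest"`, `"naive_bayes"`, `"svm"`,
#'   `"knn_subspace_ensemble"`, `"subspace_discriminant_ensemble"`.
#' @param seed RNG seed used by stochastic models.
#' @param ... hyperparameter overrides: `n_trees`, `cost`, `k`,
#'   `n_learners`, `subspace_fraction`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(kind = MODEL_KINDS, seed = 1L, ...) {
  kind <- match.arg(kind)
  hp <- utils::modifyList(
    list(n_trees = 500L, cost = 1, k = 5L, n_learners = 30L,
         subspace_fraction = 0.5),
    list(...))
  structure(list(kind = kind, seed = as.integer(seed), hyper = hp),
            class = "model_spec")
}

label_factor <- function(labels) {
  factor(labels, levels = c("healthy", "lacerated"))
}

# --- standardization ------------------------------------------------------

scaler_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keep <- which(sd > 1e-10)
  list(mu = mu, sd = sd, keep = keep)
}

scaler_apply <- function(scaler, X) {
  X <- X[, scaler$keep, drop = FALSE]
  sweep(sweep(X, 2, scaler$mu[scaler$keep]), 2, scaler$sd[scaler$keep], "/")
}

# --- model fitting / scoring ---------------------------------------------

fit_classifier <- function(X, y, spec) {
  yf <- label_factor(y)
  hp <- spec$hyper
  p <- ncol(X)
  with_seed(spec$seed, switch(
    spec$kind,
    random_forest = list(
      fit = randomForest::randomForest(
        x = X, y = yf, ntree = hp$n_trees, mtry = max(1L, floor(sqrt(p))))),
    naive_bayes = {
      # drop features that are constant within a class: their Gaussian
      # density degenerates
      ok <- vapply(seq_len(p), function(j) {
        all(tapply(X[, j], yf, stats::sd) > 1e-8)
      }, TRUE)
      if (!any(ok)) stop("naive Bayes: no usable features")
      list(fit = e1071::naiveBayes(X[, ok, drop = FALSE], yf), cols = which(ok))
    },
    svm = list(
      fit = e1071::svm(X, yf, kernel = "radial", cost = hp$cost,
                       probability = TRUE, scale = FALSE)),
    knn_subspace_ensemble = {
      subsets <- lapply(seq_len(hp$n_learners), function(i)
        sort(sample.int(p, max(1L, round(hp$subspace_fraction * p)))))
      list(subsets = subsets, X = X, y = yf, k = hp$k)
    },
    subspace_discriminant_ensemble = {
      dim_cap <- max(1L, min(round(hp$subspace_fraction * p), nrow(X) - 3L))
      learners <- list()
      for (i in seq_len(hp$n_learners)) {
        cols <- sort(sample.int(p, dim_cap))
        fit <- tryCatch(
          suppressWarnings(MASS::lda(X[, cols, drop = FALSE], grouping = yf)),
          error = function(e) NULL)
        if (!is.null(fit)) learners[[length(learners) + 1L]] <-
            list(fit = fit, cols = cols)
      }
      if (!length(learners)) stop("subspace discriminant: all learners failed")
      list(learners = learners)
    }))
}

score_classifier <- function(model, spec, X) {
  switch(
    spec$kind,
    random_forest =
      unname(stats::predict(model$fit, X, type = "prob")[, "lacerated"]),
    naive_bayes =
      unname(stats::predict(model$fit, X[, model$cols, drop = FALSE],
                            type = "raw")[, "lacerated"]),
    svm = {
      pr <- stats::predict(model$fit, X, probability = TRUE)
      unname(attr(pr, "probabilities")[, "lacerated"])
    },
    knn_subspace_ensemble = {
      votes <- vapply(model$subsets, function(cols) {
        knn_vote(model$X[, cols, drop = FALSE], model$y,
                 X[, cols, drop = FALSE], model$k)
      }, numeric(nrow(X)))
      rowMeans(matrix(votes, nrow = nrow(X)))
    },
    subspace_discriminant_ensemble = {
      post <- vapply(model$learners, function(l) {
        stats::predict(l$fit,
                       X[, l$cols, drop = FALSE])$posterior[, "lacerated"]
      }, numeric(nrow(X)))
      rowMeans(matrix(post, nrow = nrow(X)))
    })
}

# Fraction of "lacerated" among the k nearest training rows (Euclidean).
knn_vote <- function(Xtr, ytr, Xte, k) {
  k <- min(k, nrow(Xtr))
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  apply(d2, 1, function(d) {
    nn <- order(d)[seq_len(k)]
    mean(ytr[nn] == "lacerated")
  })
}

#' Train a classifier on a feature table
#'
#' Fits the standardization (z-score) on the given table, then the model.
#' The returned object remembers the training sample IDs so that
#' [evaluate()] can enforce train/test disjointness.
#'
#' @param table feature table (training portion).
#' @param spec a [model_spec()].
#' @return A `spleen_model` object.
#' @export
train_model <- function(table, spec = model_spec()) {
  fc <- feature_columns(table)
  X <- as.matrix(table[, fc, drop = FALSE])
  scaler <- scaler_fit(X)
  Xs <- scaler_apply(scaler, X)
  fit <- fit_classifier(Xs, table$label, spec)
  structure(list(spec = spec, scaler = scaler, fit = fit,
                 feature_names = fc, train_ids = table$sample_id),
            class = "spleen_model")
}

#' Continuous laceration scores for new samples
#'
#' @param model a `spleen_model` from [train_model()].
#' @param table feature table to score.
#' @return Numeric vector of scores in `[0, 1]` (probability-like; higher
#'   means more likely lacerated).
#' @export
predict_scores <- function(model, table) {
  X <- as.matrix(table[, model$feature_names, drop = FALSE])
  score_classifier(model$fit, model$spec, scaler_apply(model$scaler, X))
}

# --- metrics --------------------------------------------------------------

#' Classification metrics from confusion counts
#'
#' Positive class is "lacerated": `TP` are correctly detected lacerations.
#'
#' @param tp,fp,fn,tn confusion counts.
#' @return Named list `accuracy, sensitivity, specificity, precision, f1`.
#'   Ratios with empty denominators are `NA`.
#' @export
metrics_from_counts <- function(tp, fp, fn, tn) {
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  prec <- div(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(accuracy = div(tp + tn, tp + fp + fn + tn),
       sensitivity = sens,
       specificity = div(tn, tn + fp),
       precision = prec,
       f1 = f1)
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann--Whitney formulation with midranks, so tied scores contribute 1/2;
#' all-equal scores give 0.5.
#'
#' @param scores numeric scores (higher = more lacerated).
#' @param labels `"healthy"` / `"lacerated"` vector.
#' @return AUC in `[0, 1]`, `NA` if a class is absent.
#' @export
auc_rank <- function(scores, labels) {
  y <- label_factor(labels)
  n1 <- sum(y == "lacerated")
  n0 <- sum(y == "healthy")
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == "lacerated"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

score_report <- function(scores, labels, threshold = 0.5) {
  y <- label_factor(labels)
  pred <- ifelse(scores >= threshold, "lacerated", "healthy")
  tp <- sum(pred == "lacerated" & y == "lacerated")
  fp <- sum(pred == "lacerated" & y == "healthy")
  fn <- sum(pred == "healthy" & y == "lacerated")
  tn <- sum(pred == "healthy" & y == "healthy")
  m <- metrics_from_counts(tp, fp, fn, tn)
  c(m, list(auc = auc_rank(scores, labels),
            confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
            predicted = pred))
}

# --- protocol -------------------------------------------------------------

#' Stratified train/test split
#'
#' Splits by sample, stratified by label and (when counts permit) by AIS
#' grade bin, targeting `round(n * test_fraction)` test samples with each
#' label's share preserved within one sample (largest-remainder
#' allocation).
#'
#' @param table feature table (or manifest) with `sample_id`, `label`,
#'   `ais_grade`.
#' @param test_fraction fraction held out (default 0.2); must leave both
#'   partitions nonempty.
#' @param seed RNG seed.
#' @return `list(train =, test =)` row subsets; every `sample_id` appears in
#'   exactly one.
#' @export
split_train_test <- function(table, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  if (any(table(label_factor(table$label)) < 2))
    stop("need at least 2 samples in each class")
  n_total <- round(nrow(table) * test_fraction)
  if (n_total < 1) stop("test_fraction leaves an empty test set")
  # label-level totals by largest remainder
  lab_n <- table(label_factor(table$label))
  exact <- as.numeric(lab_n) * test_fraction
  base <- floor(exact)
  rem <- n_total - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  names(base) <- names(lab_n)
  test_idx <- integer(0)
  with_seed(seed, {
    for (lab in names(lab_n)) {
      rows <- which(table$label == lab)
      bins <- grade_bin(table$ais_grade[rows])
      target <- base[[lab]]
      bin_n <- table(bins)
      bexact <- as.numeric(bin_n) / length(rows) * target
      bbase <- floor(bexact)
      brem <- target - sum(bbase)
      if (brem > 0) {
        ord <- order(bexact - bbase, decreasing = TRUE)
        bbase[ord[seq_len(brem)]] <- bbase[ord[seq_len(brem)]] + 1L
      }
      for (bi in seq_along(bin_n)) {
        cand <- rows[bins == names(bin_n)[bi]]
        if (bbase[bi] > 0)
          test_idx <- c(test_idx, sample(cand, min(bbase[bi], length(cand))))
      }
    }
  })
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

grade_bin <- function(ais_grade) {
  g <- as.integer(ais_grade)
  ifelse(g == 0L, "healthy",
         ifelse(g == 2L, "AIS2", ifelse(g == 3L, "AIS3", "AIS4_5")))
}

#' Stratified k-fold cross-validation
#'
#' Stratified by label; within each fold, standardization is fit on the
#' `k - 1` training folds only and the model retrained from scratch.
#' Reports each metric per fold with mean and SD.
#'
#' @param train_table training feature table.
#' @param spec a [model_spec()].
#' @param k number of folds (default 5); must not exceed the smallest class
#'   count.
#' @param seed RNG seed for fold assignment.
#' @return `list(kind, k, folds = <data.frame>, mean = <named>, sd = <named>)`.
#' @export
cross_validate <- function(train_table, spec = model_spec(), k = 5L,
                           seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  y <- label_factor(train_table$label)
  if (k > min(table(y)))
    stop("k exceeds the smallest class count")
  fold <- integer(nrow(train_table))
  with_seed(seed, {
    for (lab in levels(y)) {
      rows <- which(y == lab)
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  metrics <- c("accuracy", "sensitivity", "specificity", "f1", "auc")
  folds <- data.frame(fold = seq_len(k))
  for (m in metrics) folds[[m]] <- NA_real_
  for (f in seq_len(k)) {
    tr <- train_table[fold != f, , drop = FALSE]
    te <- train_table[fold == f, , drop = FALSE]
    fold_spec <- spec
    fold_spec$seed <- derive_seed(spec$seed, f)
    model <- train_model(tr, fold_spec)
    rep <- score_report(predict_scores(model, te), te$label)
    for (m in metrics) folds[[m]][f] <- rep[[m]]
  }
  list(kind = spec$kind, k = k, folds = folds,
       mean = vapply(metrics, function(m) mean(folds[[m]], na.rm = TRUE), 0),
       sd = vapply(metrics, function(m) stats::sd(folds[[m]], na.rm = TRUE), 0))
}

#' Evaluate a trained model on a held-out test table
#'
#' Hard-errors if any test `sample_id` was seen during training (leakage
#' guard). Scores every test sample, thresholds at 0.5 for the confusion
#' counts, and computes accuracy, sensitivity, specificity, F1 and the
#' rank-statistic AUC.
#'
#' @param model a `spleen_model` from [train_model()].
#' @param test_table test feature table, disjoint from training.
#' @return `list(metrics, confusion, predictions)`; `predictions` is a
#'   per-sample `data.frame` with scores and predicted labels.
#' @export
evaluate <- function(model, test_table) {
  overlap <- intersect(model$train_ids, test_table$sample_id)
  if (length(overlap))
    stop("train/test leakage: sample IDs in both sets: ",
         paste(overlap, collapse = ", "))
  scores <- predict_scores(model, test_table)
  rep <- score_report(scores, test_table$label)
  if (is.na(rep$sensitivity))
    message("evaluate: sensitivity undefined (no lacerated samples in test set)")
  list(metrics = rep[c("accuracy", "sensitivity", "specificity",
                       "precision", "f1", "auc")],
       confusion = rep$confusion,
       predictions = data.frame(sample_id = test_table$sample_id,
                                label = test_table$label,
                                ais_grade = test_table$ais_grade,
                                score = scores,
                                predicted = rep$predicted,
                                stringsAsFactors = FALSE))
}

#' Accuracy by injury grade bin
#'
#' Accuracy of an evaluation restricted to each grade bin, with AIS 4 and 5
#' pooled. Empty bins are absent from the result (never reported as zero).
#'
#' @param report result of [evaluate()].
#' @return `data.frame(bin, n, accuracy)` over the nonempty bins among
#'   `healthy, AIS2, AIS3, AIS4_5`.
#' @export
per_grade_accuracy <- function(report) {
  pr <- report$predictions
  bins <- grade_bin(pr$ais_grade)
  out <- do.call(rbind, lapply(c("healthy", "AIS2", "AIS3", "AIS4_5"),
    function(b) {
      rows <- bins == b
      if (!any(rows)) return(NULL)
      data.frame(bin = b, n = sum(rows),
                 accuracy = mean(pr$predicted[rows] == pr$label[rows]))
    }))
  rownames(out) <- NULL
  out
}

#' Leave-one-site-out evaluation
#'
#' Fits on all samples from one site and evaluates on the other, probing
#' cross-site generalizability. The test site can optionally be subsampled
#' (stratified by grade bin) to a fixed size.
#'
#' @param table full feature table with a `site` column.
#' @param train_site,test_site site names (both must be present).
#' @param spec a [model_spec()].
#' @param n_test optional test-set size after stratified subsampling.
#' @param seed RNG seed for the subsampling.
#' @return As [evaluate()], plus `train_site`/`test_site` fields.
#' @export
leave_one_site_out <- function(table, train_site = "site_A",
                               test_site = "site_B", spec = model_spec(),
                               n_test = NULL, seed = 1L) {
  tr <- table[table$site == train_site, , drop = FALSE]
  te <- table[table$site == test_site, , drop = FALSE]
  if (!nrow(tr)) stop("train site absent: ", train_site)
  if (!nrow(te)) stop("test site absent: ", test_site)
  if (!is.null(n_test) && n_test < nrow(te)) {
    bins <- grade_bin(te$ais_grade)
    bin_n <- table(bins)
    exact <- as.numeric(bin_n) / nrow(te) * n_test
    base <- floor(exact)
    rem <- n_test - sum(base)
    if (rem > 0) {
      ord <- order(exact - base, decreasing = TRUE)
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
    }
    keep <- integer(0)
    with_seed(seed, {
      for (bi in seq_along(bin_n)) {
        cand <- which(bins == names(bin_n)[bi])
        if (base[bi] > 0)
          keep <- c(keep, sample(cand, min(base[bi], length(cand))))
      }
    })
    te <- te[sort(keep), , drop = FALSE]
  }
  model <- train_model(tr, spec)
  rep <- evaluate(model, te)
  rep$train_site <- train_site
  rep$test_site <- test_site
  rep
}
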
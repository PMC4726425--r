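#' Confusion counts from truth and prediction
#'
#' @param y_true,y_pred Binary vectors (0 = negative, 1 = positive).
#' @return List of class `ConfusionCounts` with fields `n_pos`, `n_neg`
#'   (class totals), `fn` (positives predicted negative) and `fp`
#'   (negatives predicted positive).
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  structure(list(n_pos = sum(y_true == 1L),
                 n_neg = sum(y_true == 0L),
                 fn = sum(y_true == 1L & y_pred == 0L),
                 fp = sum(y_true == 0L & y_pred == 1L)),
            class = "ConfusionCounts")
}

#' Scalar classification metrics
#'
#' Sensitivity `Se = (N+ - FN)/N+`, specificity `Sp = (N- - FP)/N-`,
#' accuracy `Acc = (N+ - FN + N- - FP)/(N+ + N-)` and Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with
#' MCC defined as 0 when any factor under the root vanishes. A missing
#' class makes the corresponding rate `NA`; the others are still
#' computed.
#'
#' @param c A `ConfusionCounts`.
#' @return List with `acc`, `sp`, `se`, `mcc`.
#' @export
metrics <- function(c) {
  stopifnot(inherits(c, "ConfusionCounts"))
  if (c$n_pos + c$n_neg == 0L) stop("no samples")
  tp <- as.numeric(c$n_pos - c$fn)
  tn <- as.numeric(c$n_neg - c$fp)
  se <- if (c$n_pos > 0L) tp / c$n_pos else NA_real_
  sp <- if (c$n_neg > 0L) tn / c$n_neg else NA_real_
  acc <- (tp + tn) / (c$n_pos + c$n_neg)
  den2 <- (tp + c$fp) * (tp + c$fn) * (tn + c$fp) * (tn + c$fn)
  mcc <- if (den2 <= 0) 0 else (tp * tn - c$fp * c$fn) / sqrt(den2)
  list(acc = acc, sp = sp, se = se, mcc = mcc)
}

#' ROC points over a cutoff sweep
#'
#' For each cutoff `mu` the decision values are classified with
#' [classify()] and the true/false positive rates recorded. Sweeping
#' `mu` upward can only shrink the predicted-positive set, so both rates
#' are non-increasing along the grid.
#'
#' @param values Real-valued decision outputs.
#' @param y True binary labels.
#' @param mu_grid Ordered cutoff grid (default 201 points on `[-2, 2]`).
#' @return Data frame with columns `mu`, `fpr`, `tpr`.
#' @export
roc_points <- function(values, y, mu_grid = seq(-2, 2, length.out = 201L)) {
  stopifnot(!is.unsorted(mu_grid))
  y <- as.integer(y)
  out <- t(vapply(mu_grid, function(mu) {
    m <- metrics(confusion_counts(y, classify(values, mu)))
    c(fpr = 1 - m$sp, tpr = m$se)
  }, numeric(2L)))
  data.frame(mu = mu_grid, fpr = out[, "fpr"], tpr = out[, "tpr"])
}

#' Trainer objects for the cross-validation drivers
#'
#' A trainer bundles a `fit(X, y, X_valid, y_valid, X_pretrain)` closure
#' returning a fitted model with a `decide(model, X)` closure returning
#' 0/1 labels, plus the protocol flags the drivers need: whether a
#' validation split is required (`needs_valid`) and how training folds
#' are balanced (`balance`).
#'
#' `sda_trainer` fine-tunes on up-sampled folds with a held-out
#' validation fold; `svm_trainer` trains on down-sampled folds and needs
#' no validation split.
#'
#' @param arch SdA layer sizes, e.g. `c(109, 100, 2)`.
#' @param corruption Corruption level(s).
#' @param cfg An `SdATrainConfig` / `SVMConfig`.
#' @return List of class `Trainer`.
#' @export
sda_trainer <- function(arch, corruption = 0.1, cfg = sda_train_config()) {
  structure(list(
    name = "sda",
    needs_valid = TRUE,
    balance = "up",
    fit = function(X, y, X_valid, y_valid, X_pretrain = NULL) {
      train_sda(X, y, X_valid, y_valid, arch = arch,
                X_pretrain = X_pretrain, corruption = corruption, cfg = cfg)
    },
    decide = function(model, X) sda_predict(model, X)),
    class = "Trainer")
}

#' @rdname sda_trainer
#' @export
svm_trainer <- function(cfg = svm_config()) {
  structure(list(
    name = "svm",
    needs_valid = FALSE,
    balance = "down",
    fit = function(X, y, X_valid, y_valid, X_pretrain = NULL) {
      train_svm(X, y, cfg)
    },
    decide = function(model, X) classify(decision_values(model, X), cfg$mu)),
    class = "Trainer")
}

#' Leave-one-out cross-validation (scheme-1 protocol)
#'
#' Each sample is predicted once. For a validation-requiring trainer
#' (SdA) the remaining samples are split 50/50 at random into a
#' fine-tuning half and a validation half, and the fine-tuning half also
#' serves, unlabeled, as the pre-training set. For the SVM all remaining
#' samples train the model. Confusion counts are pooled over rounds; the
#' per-round mean accuracy is also reported (identical to pooled accuracy
#' for single-sample rounds).
#'
#' @param X Scaled feature matrix.
#' @param y Binary labels (0/1).
#' @param trainer A `Trainer`.
#' @param seed Seed for the per-round splits.
#' @return List with `counts` (`ConfusionCounts`), `metrics`,
#'   `predictions` and `mean_round_acc`.
#' @export
loocv_b1 <- function(X, y, trainer, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X)
  stopifnot(n >= 3L)
  set.seed(seed)
  pred <- integer(n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    if (trainer$needs_valid) {
      half <- sample(rest, size = floor(length(rest) / 2))
      valid <- setdiff(rest, half)
      model <- trainer$fit(X[half, , drop = FALSE], y[half],
                           X[valid, , drop = FALSE], y[valid],
                           X_pretrain = X[half, , drop = FALSE])
    } else {
      model <- trainer$fit(X[rest, , drop = FALSE], y[rest], NULL, NULL)
    }
    pred[i] <- trainer$decide(model, X[i, , drop = FALSE])
  }
  cc <- confusion_counts(y, pred)
  list(counts = cc, metrics = metrics(cc), predictions = pred,
       mean_round_acc = mean(pred == y))
}

# Stratified fold assignment: within each class, shuffled samples are
# dealt round-robin so fold sizes differ by at most one per class.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation (scheme-2 protocol)
#'
#' Folds are stratified by class. For a validation-requiring trainer
#' (SdA): per round, one fold is the untouched test set, the next fold
#' (cyclically) the validation set and the remaining `k - 2` folds the
#' fine-tuning set; fine-tuning and validation folds are up-sampled to
#' class balance, and pre-training uses `X_pretrain` when supplied
#' (otherwise the fine-tuning rows, unlabeled). For the SVM the `k - 1`
#' training folds are down-sampled. Metrics are reported per fold, as
#' the mean over folds, and from pooled confusion counts.
#'
#' @param X Scaled feature matrix.
#' @param y Binary labels (0/1).
#' @param trainer A `Trainer`.
#' @param k Number of folds (default 5).
#' @param X_pretrain Optional unlabeled pre-training matrix (SdA only).
#' @param seed Seed for fold assignment and balancing.
#' @return List with `fold_metrics` (data frame), `mean_acc`, `mean_mcc`,
#'   `pooled` metrics, `counts` and the fold assignment.
#' @export
kfold_b2 <- function(X, y, trainer, k = 5L, X_pretrain = NULL, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  set.seed(seed)
  fold <- stratified_folds(y, k)
  per_class <- table(y, fold)
  if (any(per_class == 0L))
    stop("stratification failed: a fold is missing a class")
  pred <- integer(length(y))
  rows <- vector("list", k)
  for (t in seq_len(k)) {
    test <- which(fold == t)
    if (trainer$needs_valid) {
      v <- t %% k + 1L
      valid <- which(fold == v)
      train <- which(!fold %in% c(t, v))
      bt <- train[upsample(y[train])]
      bv <- valid[upsample(y[valid])]
      pre <- if (is.null(X_pretrain)) X[bt, , drop = FALSE] else X_pretrain
      model <- trainer$fit(X[bt, , drop = FALSE], y[bt],
                           X[bv, , drop = FALSE], y[bv], X_pretrain = pre)
    } else {
      train <- which(fold != t)
      bt <- train[downsample(y[train])]
      model <- trainer$fit(X[bt, , drop = FALSE], y[bt], NULL, NULL)
    }
    p <- trainer$decide(model, X[test, , drop = FALSE])
    pred[test] <- p
    m <- metrics(confusion_counts(y[test], p))
    rows[[t]] <- data.frame(fold = t, acc = m$acc, sp = m$sp, se = m$se,
                            mcc = m$mcc)
  }
  fm <- do.call(rbind, rows)
  cc <- confusion_counts(y, pred)
  list(fold_metrics = fm, mean_acc = mean(fm$acc), mean_mcc = mean(fm$mcc),
       pooled = metrics(cc), counts = cc, fold = fold, predictions = pred)
}

#' Holdout (blind-test) evaluation
#'
#' Same machinery as the cross-validation drivers with explicit train and
#' test row sets: the trainer fits on the training rows (with its own
#' balancing and validation split carved from them) and is scored once on
#' the untouched test rows.
#'
#' @param X,y Full scaled feature matrix and labels.
#' @param train_idx,test_idx Disjoint row index vectors.
#' @param trainer A `Trainer`.
#' @param X_pretrain Optional unlabeled pre-training matrix.
#' @param valid_frac Fraction of training rows held out for validation
#'   when the trainer needs one (default 0.25, the 3:1 fine-tune to
#'   validation ratio).
#' @param balance Balance the training rows with the trainer's method
#'   (default `TRUE`; the blind-test protocol with pre-pooled samples
#'   uses `FALSE`).
#' @param seed Seed for the split and balancing.
#' @return List with `counts`, `metrics` and `predictions`.
#' @export
holdout <- function(X, y, train_idx, test_idx, trainer, X_pretrain = NULL,
                    valid_frac = 0.25, balance = TRUE, seed = 1L) {
  stopifnot(length(intersect(train_idx, test_idx)) == 0L)
  X <- as.matrix(X); y <- as.integer(y)
  set.seed(seed)
  if (trainer$needs_valid) {
    nv <- max(1L, round(valid_frac * length(train_idx)))
    valid <- sample(train_idx, nv)
    train <- setdiff(train_idx, valid)
    if (balance) {
      train <- train[upsample(y[train])]
      valid <- valid[upsample(y[valid])]
    }
    pre <- if (is.null(X_pretrain)) X[train, , drop = FALSE] else X_pretrain
    model <- trainer$fit(X[train, , drop = FALSE], y[train],
                         X[valid, , drop = FALSE], y[valid], X_pretrain = pre)
  } else {
    train <- train_idx
    if (balance) train <- train[downsample(y[train])]
    model <- trainer$fit(X[train, , drop = FALSE], y[train], NULL, NULL)
  }
  p <- trainer$decide(model, X[test_idx, , drop = FALSE])
  cc <- confusion_counts(y[test_idx], p)
  list(counts = cc, metrics = metrics(cc), predictions = p)
}
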
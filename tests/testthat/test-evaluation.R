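test_that("scalar metrics match the defining formulas", {
  perfect <- confusion_counts(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L))
  m <- metrics(perfect)
  expect_equal(unlist(m), c(acc = 1, sp = 1, se = 1, mcc = 1))

  # balanced classes: acc is the mean of se and sp
  cc <- confusion_counts(rep(c(1L, 0L), each = 500L),
                         c(rep(1L, 452L), rep(0L, 48L),
                           rep(1L, 76L), rep(0L, 424L)))
  m2 <- metrics(cc)
  expect_equal(m2$acc, (m2$se + m2$sp) / 2)

  # degenerate single-class truth: the undefined rate is NA, others valid
  one <- metrics(confusion_counts(c(1L, 1L), c(1L, 0L)))
  expect_true(is.na(one$sp))
  expect_equal(one$se, 0.5)
  expect_equal(one$mcc, 0)
})

test_that("metrics agree with a per-sample brute-force oracle", {
  set.seed(47)
  for (i in 1:25) {
    n <- 20L
    y <- rbinom(n, 1L, 0.5)
    if (length(unique(y)) < 2L) next
    p <- rbinom(n, 1L, 0.5)
    m <- metrics(confusion_counts(y, p))
    tp <- sum(y == 1 & p == 1); tn <- sum(y == 0 & p == 0)
    fp <- sum(y == 0 & p == 1); fn <- sum(y == 1 & p == 0)
    expect_equal(m$acc, (tp + tn) / n)
    expect_equal(m$se, tp / (tp + fn))
    expect_equal(m$sp, tn / (tn + fp))
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expect_equal(m$mcc, if (den == 0) 0 else (tp * tn - fp * fn) / den)
  }
})

test_that("ROC sweep has the right endpoints and is monotone", {
  set.seed(53)
  vals <- c(rnorm(50, 1), rnorm(50, -1))
  y <- rep(c(1L, 0L), each = 50L)
  roc <- roc_points(vals, y, mu_grid = seq(-6, 6, length.out = 101L))
  expect_equal(c(roc$fpr[1L], roc$tpr[1L]), c(1, 1))
  expect_equal(c(roc$fpr[101L], roc$tpr[101L]), c(0, 0))
  expect_true(all(diff(roc$tpr) <= 0))
  expect_true(all(diff(roc$fpr) <= 0))
})

# Stub trainer: thresholds the first feature at 0.5; no training at all.
stub_trainer <- function() {
  structure(list(name = "stub", needs_valid = FALSE, balance = "down",
                 fit = function(X, y, X_valid, y_valid, X_pretrain = NULL) TRUE,
                 decide = function(model, X) as.integer(X[, 1L] > 0.5)),
            class = "Trainer")
}

test_that("leave-one-out driver aggregates every round once", {
  X <- cbind(c(0.9, 0.8, 0.1, 0.2), c(0.5, 0.4, 0.6, 0.5))
  y <- c(1L, 1L, 0L, 0L)
  res <- loocv_b1(X, y, stub_trainer(), seed = 1L)
  expect_equal(res$metrics$acc, 1)
  expect_equal(res$counts$n_pos + res$counts$n_neg, 4L)
  res2 <- loocv_b1(X, y, stub_trainer(), seed = 1L)
  expect_identical(res2$predictions, res$predictions)
})

test_that("leave-one-out with the SdA splits the rest 50/50 and works", {
  set.seed(59)
  n <- 24L
  X <- pmin(pmax(cbind(c(runif(n / 2, 0.85, 1), runif(n / 2, 0, 0.15)),
                       runif(n)), 0), 1)
  y <- rep(c(1L, 0L), each = n / 2)
  tr <- sda_trainer(c(2L, 4L, 2L),
                    cfg = sda_train_config(pretrain_epochs = 3L,
                                           max_finetune_epochs = 60L,
                                           finetune_lr = 0.5,
                                           seed = 59L))
  res <- loocv_b1(X, y, tr, seed = 2L)
  expect_equal(res$counts$n_pos + res$counts$n_neg, n)
  expect_gte(res$metrics$acc, 0.75)
})

test_that("stratified k-fold partitions samples correctly", {
  set.seed(61)
  n <- 103L
  y <- rbinom(n, 1L, 0.3)
  X <- cbind(y + runif(n, -0.3, 0.3), runif(n))
  res <- kfold_b2(X, y, stub_trainer(), k = 5L, seed = 3L)
  # every sample in exactly one test fold; fold sizes differ by <= 1 per class
  expect_equal(sort(unique(res$fold)), 1:5)
  for (cls in 0:1) {
    sizes <- table(res$fold[y == cls])
    expect_lte(diff(range(sizes)), 1L)
  }
  expect_equal(res$counts$n_pos + res$counts$n_neg, n)
  expect_error(kfold_b2(X[1:6, ], y[1:6], stub_trainer(), k = 5L, seed = 3L),
               "stratification")
})

test_that("both trainers recover a planted signal in 5-fold CV", {
  set.seed(67)
  n <- 200L
  X <- pmin(pmax(cbind(sig = c(runif(n / 2, 0.55, 1), runif(n / 2, 0, 0.45)),
                       matrix(runif(3L * n), n)), 0), 1)
  y <- rep(c(1L, 0L), each = n / 2)
  svm_res <- kfold_b2(X, y, svm_trainer(svm_config("rbf", gamma = 9)),
                      seed = 5L)
  expect_gt(svm_res$mean_acc, 0.75)
  sda_res <- kfold_b2(X, y, sda_trainer(c(4L, 6L, 2L),
                                        cfg = sda_train_config(
                                          pretrain_epochs = 5L,
                                          max_finetune_epochs = 50L,
                                          seed = 67L)),
                      seed = 5L)
  expect_gt(sda_res$mean_acc, 0.75)
  # determinism of the whole driver
  svm_res2 <- kfold_b2(X, y, svm_trainer(svm_config("rbf", gamma = 9)),
                       seed = 5L)
  expect_identical(svm_res2$predictions, svm_res$predictions)
})

test_that("holdout evaluation keeps train and test disjoint", {
  set.seed(71)
  n <- 120L
  X <- pmin(pmax(cbind(c(runif(n / 2, 0.6, 1), runif(n / 2, 0, 0.4)),
                       runif(n)), 0), 1)
  y <- rep(c(1L, 0L), each = n / 2)
  idx <- sample(n)
  res <- holdout(X, y, idx[1:80], idx[81:120],
                 svm_trainer(svm_config("rbf", gamma = 2)), seed = 7L)
  expect_equal(res$counts$n_pos + res$counts$n_neg, 40L)
  expect_gte(res$metrics$acc, 0.9)
  expect_error(holdout(X, y, 1:80, 80:120, stub_trainer()), "intersect")
})
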
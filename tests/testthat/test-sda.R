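test_that("masking corruption zeroes the expected fraction, reproducibly", {
  x <- runif(10000)
  expect_identical(corrupt(x, 0), x)
  set.seed(2)
  xt <- corrupt(x, 0.5)
  frac <- mean(xt == 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  set.seed(2)
  expect_identical(corrupt(x, 0.5), xt)
  expect_error(corrupt(x, 1), "corruption level")
})

test_that("autoencoder forward pass respects the sigmoid bounds", {
  layer <- list(W = matrix(0, 3L, 2L), b = numeric(2L), b_prime = numeric(3L),
                corruption = 0)
  fw <- da_forward(layer, c(0.2, 0.5, 0.9))
  expect_equal(as.numeric(fw$y), c(0.5, 0.5))
  expect_equal(as.numeric(fw$z), rep(0.5, 3L))
  expect_error(da_forward(layer, c(0.1, 0.2)), "dimension")
})

test_that("reconstruction cross-entropy matches closed forms", {
  expect_equal(reconstruction_cost(rep(0.5, 4L), rep(0.5, 4L)), 4 * log(2))
  # binary target perfectly reconstructed -> cost ~ 0
  x <- c(0, 1, 1, 0)
  expect_lt(reconstruction_cost(x, pmin(pmax(x, 1e-9), 1 - 1e-9)), 1e-5)
  # Gibbs inequality: cost >= entropy of x, with equality iff z == x
  set.seed(13)
  for (i in 1:20) {
    x <- runif(6)
    z <- runif(6)
    entropy <- -sum(x * log(x) + (1 - x) * log(1 - x))
    expect_gte(reconstruction_cost(x, z) + 1e-12, entropy)
  }
})

test_that("analytic autoencoder gradients match finite differences", {
  set.seed(17)
  model <- new_sda(c(3L, 2L, 2L), corruption = 0)
  layer <- model$layers[[1L]]
  x <- matrix(runif(6L), 2L, 3L)
  xt <- x; xt[1L, 2L] <- 0       # a fixed corruption mask
  g <- methtopo:::da_grads(layer, x, xt)
  eps <- 1e-6
  num_grad <- function(get, set) {
    v <- get(layer)
    out <- v
    for (i in seq_along(v)) {
      lp <- layer; lm <- layer
      vp <- v; vp[i] <- vp[i] + eps
      vm <- v; vm[i] <- vm[i] - eps
      lp <- set(lp, vp); lm <- set(lm, vm)
      cp <- reconstruction_cost(x, da_forward(lp, xt)$z)
      cm <- reconstruction_cost(x, da_forward(lm, xt)$z)
      out[i] <- (cp - cm) / (2 * eps)
    }
    out
  }
  gW_num <- num_grad(function(l) l$W, function(l, v) { l$W <- v; l })
  gb_num <- num_grad(function(l) l$b, function(l, v) { l$b <- v; l })
  gp_num <- num_grad(function(l) l$b_prime,
                     function(l, v) { l$b_prime <- v; l })
  expect_lt(max(abs(g$W - gW_num)) / max(abs(gW_num)), 1e-5)
  expect_lt(max(abs(g$b - gb_num)) / max(abs(gb_num)), 1e-5)
  expect_lt(max(abs(g$b_prime - gp_num)) / max(abs(gp_num)), 1e-5)
})

test_that("layer-wise pre-training decreases reconstruction cost", {
  set.seed(23)
  X <- matrix(runif(60 * 8), 60L, 8L)
  cfg <- sda_train_config(pretrain_lr = 0.001, pretrain_epochs = 10L,
                          seed = 23L)
  model <- new_sda(c(8L, 5L, 2L), corruption = 0)
  trained <- sda_pretrain(model, X, cfg)
  log <- attr(trained, "pretrain_log")
  costs <- log$cost[log$layer == 1L]
  expect_length(costs, 10L)
  expect_true(all(diff(costs) <= 1e-8))
  expect_error(sda_pretrain(model, X[0, , drop = FALSE], cfg), "empty")
})

test_that("an overcomplete noiseless autoencoder memorizes one sample", {
  set.seed(29)
  x <- matrix(c(0.9, 0.1, 0.8, 0.2), 1L)
  model <- new_sda(c(4L, 8L, 2L), corruption = 0)
  layer <- model$layers[[1L]]
  for (i in 1:3000) {
    g <- methtopo:::da_grads(layer, x, x)
    layer$W <- layer$W - 0.5 * g$W
    layer$b <- layer$b - 0.5 * g$b
    layer$b_prime <- layer$b_prime - 0.5 * g$b_prime
  }
  z <- da_forward(layer, x)$z
  expect_lt(max(abs(z - x)), 0.01)
})

test_that("fine-tuning fits a separable problem and keeps the best model", {
  set.seed(37)
  n <- 200L
  X <- pmin(pmax(rbind(cbind(runif(n / 2, 0.6, 1), runif(n / 2)),
                       cbind(runif(n / 2, 0, 0.4), runif(n / 2))), 0), 1)
  y <- rep(c(1L, 0L), each = n / 2)
  idx <- sample(n)
  tr <- idx[1:150]; va <- idx[151:200]
  cfg <- sda_train_config(pretrain_epochs = 5L, max_finetune_epochs = 100L,
                          finetune_lr = 0.1, seed = 37L)
  model <- train_sda(X[tr, ], y[tr], X[va, ], y[va], arch = c(2L, 6L, 2L),
                     cfg = cfg)
  expect_lte(mean(sda_predict(model, X[tr, ]) != y[tr]), 0.05)
  expect_lte(attr(model, "best_valid_err"),
             attr(model, "finetune_log")$valid_err[1L])
  # determinism: same seed, same parameters
  model2 <- train_sda(X[tr, ], y[tr], X[va, ], y[va], arch = c(2L, 6L, 2L),
                      cfg = cfg)
  expect_identical(model$top_W, model2$top_W)
  expect_identical(model$layers[[1L]]$W, model2$layers[[1L]]$W)
  expect_error(train_sda(X[tr, ], rep(1L, 150L), X[va, ], y[va],
                         arch = c(2L, 6L, 2L), cfg = cfg), "single class")
})

test_that("softmax probabilities are normalized and argmax-consistent", {
  set.seed(41)
  model <- new_sda(c(5L, 3L, 2L))
  X <- matrix(runif(20L), 4L, 5L)
  P <- sda_predict_proba(model, X)
  expect_equal(rowSums(P), rep(1, 4L), tolerance = 1e-9)
  # zero top weights -> uniform probabilities, tie resolved to class 0
  expect_equal(as.numeric(P), rep(0.5, 8L))
  expect_equal(sda_predict(model, X), rep(0L, 4L))
  model$top_W <- matrix(rnorm(6L), 3L, 2L)
  P2 <- sda_predict_proba(model, X)
  expect_equal(sda_predict(model, X), max.col(P2, "first") - 1L)
  expect_error(sda_predict_proba(model, X[, 1:3]), "dimension")
})

test_that("models survive a serialization round-trip", {
  set.seed(43)
  model <- new_sda(c(4L, 3L, 2L))
  model$top_W <- matrix(rnorm(6L), 3L, 2L)
  p <- tempfile(fileext = ".json")
  save_sda(model, p)
  back <- load_sda(p)
  X <- matrix(runif(8L), 2L, 4L)
  expect_equal(sda_predict_proba(back, X), sda_predict_proba(model, X),
               tolerance = 1e-12)
})
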
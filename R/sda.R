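#' Training configuration for the stacked denoising autoencoder
#'
#' Defaults follow the reference training protocol: pre-training learning
#' rate 0.01 for 100 epochs, fine-tuning learning rate 0.1 with at most
#' 1000 epochs, corruption level 0.1 at every layer input, minibatch size
#' 20, plain (non-momentum) gradient descent, patience-based early
#' stopping on validation zero-one error.
#'
#' @param pretrain_lr,pretrain_epochs Unsupervised stage learning rate and
#'   epoch count.
#' @param finetune_lr,max_finetune_epochs Supervised stage learning rate
#'   and epoch cap.
#' @param batch_size Minibatch size for both stages.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Master seed; corruption, initialisation and shuffling all
#'   derive from it.
#' @return List of class `SdATrainConfig`.
#' @export
sda_train_config <- function(pretrain_lr = 0.01, pretrain_epochs = 100L,
                             finetune_lr = 0.1, max_finetune_epochs = 1000L,
                             batch_size = 20L, patience = 100L, seed = 1L) {
  stopifnot(pretrain_lr > 0, finetune_lr > 0,
            pretrain_epochs >= 1L, max_finetune_epochs >= 1L)
  structure(list(pretrain_lr = pretrain_lr,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_lr = finetune_lr,
                 max_finetune_epochs = as.integer(max_finetune_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "SdATrainConfig")
}

sigmoid <- function(a) 1 / (1 + exp(-a))

#' Initialise a stacked denoising autoencoder
#'
#' @param arch Integer vector of layer sizes, input first and number of
#'   classes last, e.g. `c(23, 500, 500, 2)` or `c(109, 100, 2)`.
#' @param corruption Corruption level(s) in `[0,1)`: scalar or one value
#'   per hidden layer.
#' @return List of class `SdAModel` with per-layer tied-weight denoising
#'   autoencoders and a zero-initialised softmax top layer. Hidden-layer
#'   weights use uniform Glorot-style initialisation scaled x4 for the
#'   sigmoid activation; biases start at zero.
#' @export
new_sda <- function(arch, corruption = 0.1) {
  stopifnot(length(arch) >= 2L, all(arch >= 1L))
  n_hidden <- length(arch) - 2L
  if (n_hidden < 1L) stop("need at least one hidden layer")
  if (length(corruption) == 1L) corruption <- rep(corruption, n_hidden)
  stopifnot(length(corruption) == n_hidden,
            all(corruption >= 0), all(corruption < 1))
  layers <- vector("list", n_hidden)
  for (k in seq_len(n_hidden)) {
    n_in <- arch[k]; n_out <- arch[k + 1L]
    lim <- 4 * sqrt(6 / (n_in + n_out))
    layers[[k]] <- list(
      W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
      b = numeric(n_out),
      b_prime = numeric(n_in),
      corruption = corruption[k])
  }
  n_last <- arch[length(arch) - 1L]
  n_class <- arch[length(arch)]
  structure(list(layers = layers,
                 top_W = matrix(0, n_last, n_class),
                 top_b = numeric(n_class),
                 arch = as.integer(arch)),
            class = "SdAModel")
}

#' @export
print.SdAModel <- function(x, ...) {
  cat("SdAModel:", paste(x$arch, collapse = "-"), "\n")
  invisible(x)
}

#' Masking corruption
#'
#' Each component is independently set to 0 with probability `level` and
#' kept otherwise, using the current RNG state.
#'
#' @param x Numeric vector or matrix in `[0,1]`.
#' @param level Corruption probability in `[0,1)`.
#' @return Corrupted copy of `x`.
#' @export
corrupt <- function(x, level) {
  if (level < 0 || level >= 1) stop("corruption level must be in [0,1)")
  if (level == 0) return(x)
  mask <- stats::runif(length(x)) >= level
  x * mask
}

#' Denoising-autoencoder forward pass
#'
#' Encodes `y = sigmoid(x_tilde W + b)` and reconstructs
#' `z = sigmoid(y W' + b_prime)` with tied weights (`W'` is the transpose
#' of `W`).
#'
#' @param layer One element of an `SdAModel`'s `layers`.
#' @param x_tilde (Corrupted) input row-matrix or vector in `[0,1]`.
#' @return List with hidden representation `y` and reconstruction `z`.
#' @export
da_forward <- function(layer, x_tilde) {
  if (is.vector(x_tilde)) x_tilde <- matrix(x_tilde, nrow = 1L)
  if (ncol(x_tilde) != nrow(layer$W)) stop("input dimension mismatch")
  y <- sigmoid(sweep(x_tilde %*% layer$W, 2L, layer$b, "+"))
  z <- sigmoid(sweep(y %*% t(layer$W), 2L, layer$b_prime, "+"))
  list(y = y, z = z)
}

#' Reconstruction cross-entropy
#'
#' `L = -sum_k [x_k log z_k + (1 - x_k) log(1 - z_k)]`, summed over
#' components and averaged over the minibatch rows. `z` is clamped to
#' `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param x Clean input (vector or row-matrix) in `[0,1]`.
#' @param z Reconstruction in `(0,1)`.
#' @return Mean per-sample cross-entropy.
#' @export
reconstruction_cost <- function(x, z) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(z)) z <- matrix(z, nrow = 1L)
  eps <- 1e-7
  z <- pmin(pmax(z, eps), 1 - eps)
  mean(rowSums(-(x * log(z) + (1 - x) * log(1 - z))))
}

# Analytic gradients of the minibatch-mean reconstruction cross-entropy
# w.r.t. W, b, b_prime of one tied-weight layer. Exposed (unexported) for
# the finite-difference tests.
da_grads <- function(layer, x, x_tilde) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(x_tilde)) x_tilde <- matrix(x_tilde, nrow = 1L)
  n <- nrow(x)
  fw <- da_forward(layer, x_tilde)
  y <- fw$y; z <- fw$z
  dz <- z - x                                  # d cost / d pre-sigmoid(z)
  dy <- (dz %*% layer$W) * y * (1 - y)         # back through decoder into y
  gW <- (t(x_tilde) %*% dy + t(dz) %*% y) / n  # encoder use + tied decoder use
  list(W = gW,
       b = colSums(dy) / n,
       b_prime = colSums(dz) / n,
       cost = reconstruction_cost(x, z))
}

# Map data through the first k trained encoder layers (no corruption).
sda_represent <- function(model, X, k = length(model$layers)) {
  H <- as.matrix(X)
  for (i in seq_len(k)) {
    l <- model$layers[[i]]
    H <- sigmoid(sweep(H %*% l$W, 2L, l$b, "+"))
  }
  H
}

#' Layer-wise unsupervised pre-training
#'
#' Trains each denoising autoencoder in turn by minibatch gradient
#' descent on the reconstruction cross-entropy of the previous layer's
#' (uncorrupted) representation, corrupting its own input at the layer's
#' corruption level. Labels are never consulted.
#'
#' @param model An `SdAModel`.
#' @param X Unlabeled row-matrix scaled to `[0,1]`.
#' @param cfg An `SdATrainConfig`.
#' @return The model with a `pretrain_log` attribute: data frame
#'   (layer, epoch, cost) of per-epoch mean minibatch costs.
#' @export
sda_pretrain <- function(model, X, cfg = sda_train_config()) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty pre-training matrix")
  log_rows <- list()
  for (k in seq_along(model$layers)) {
    H <- sda_represent(model, X, k - 1L)
    layer <- model$layers[[k]]
    n <- nrow(H)
    for (epoch in seq_len(cfg$pretrain_epochs)) {
      perm <- sample.int(n)
      costs <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        xb <- H[idx, , drop = FALSE]
        xt <- corrupt(xb, layer$corruption)
        g <- da_grads(layer, xb, xt)
        layer$W <- layer$W - cfg$pretrain_lr * g$W
        layer$b <- layer$b - cfg$pretrain_lr * g$b
        layer$b_prime <- layer$b_prime - cfg$pretrain_lr * g$b_prime
        costs <- c(costs, g$cost)
      }
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(layer = k, epoch = epoch, cost = mean(costs))
    }
    model$layers[[k]] <- layer
  }
  attr(model, "pretrain_log") <- do.call(rbind, log_rows)
  model
}

# Full forward pass: hidden activations (list) and softmax class
# probabilities.
sda_forward_all <- function(model, X) {
  H <- as.matrix(X)
  acts <- vector("list", length(model$layers) + 1L)
  acts[[1L]] <- H
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    H <- sigmoid(sweep(H %*% l$W, 2L, l$b, "+"))
    acts[[i + 1L]] <- H
  }
  A <- sweep(H %*% model$top_W, 2L, model$top_b, "+")
  A <- A - apply(A, 1L, max)
  E <- exp(A)
  P <- E / rowSums(E)
  list(acts = acts, probs = P)
}

#' Class probabilities and predicted labels
#'
#' The top softmax layer gives one probability per class (rows sum to 1);
#' the predicted label is the argmax, with ties resolved to class 0.
#'
#' @param model A (fine-tuned) `SdAModel`.
#' @param X Row-matrix of scaled inputs.
#' @return `sda_predict_proba`: numeric matrix (n x classes).
#'   `sda_predict`: integer class labels (0-based).
#' @export
sda_predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$arch[1L]) stop("input dimension mismatch")
  sda_forward_all(model, X)$probs
}

#' @rdname sda_predict_proba
#' @export
sda_predict <- function(model, X) {
  P <- sda_predict_proba(model, X)
  max.col(P, ties.method = "first") - 1L
}

#' Supervised fine-tuning with a softmax top layer
#'
#' Minibatch gradient descent on the negative log-likelihood of the
#' softmax output, backpropagated through every hidden layer (one global
#' fine-tuning rate). After each epoch the zero-one error on the
#' validation set is measured; the parameters with the best validation
#' error seen so far are kept, and training stops after `cfg$patience`
#' epochs without improvement or at `cfg$max_finetune_epochs`.
#'
#' @param model A (pre-trained) `SdAModel`.
#' @param X,y Labeled training rows (`y` in 0-based class labels).
#' @param X_valid,y_valid Validation rows for early stopping.
#' @param cfg An `SdATrainConfig`.
#' @return The best-validation model, with attributes `finetune_log`
#'   (epoch, nll, valid_err) and `best_valid_err`.
#' @export
sda_finetune <- function(model, X, y, X_valid, y_valid,
                         cfg = sda_train_config()) {
  X <- as.matrix(X); X_valid <- as.matrix(X_valid)
  y <- as.integer(y); y_valid <- as.integer(y_valid)
  n_class <- model$arch[length(model$arch)]
  if (length(unique(y)) < 2L) stop("fine-tuning data has a single class")
  n <- nrow(X)
  best <- model
  best_err <- mean(sda_predict(model, X_valid) != y_valid)
  since <- 0L
  log_rows <- vector("list", cfg$max_finetune_epochs)
  for (epoch in seq_len(cfg$max_finetune_epochs)) {
    perm <- sample.int(n)
    nll <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      m <- length(idx)
      fw <- sda_forward_all(model, xb)
      P <- fw$probs
      Y1 <- matrix(0, m, n_class)
      Y1[cbind(seq_len(m), yb + 1L)] <- 1
      nll <- c(nll, -mean(log(pmax(P[cbind(seq_len(m), yb + 1L)], 1e-12))))
      dA <- (P - Y1) / m
      H_last <- fw$acts[[length(fw$acts)]]
      gW_top <- t(H_last) %*% dA
      gb_top <- colSums(dA)
      dH <- dA %*% t(model$top_W)
      for (i in rev(seq_along(model$layers))) {
        Hi <- fw$acts[[i + 1L]]
        dPre <- dH * Hi * (1 - Hi)
        gW <- t(fw$acts[[i]]) %*% dPre
        gb <- colSums(dPre)
        dH <- dPre %*% t(model$layers[[i]]$W)
        model$layers[[i]]$W <- model$layers[[i]]$W - cfg$finetune_lr * gW
        model$layers[[i]]$b <- model$layers[[i]]$b - cfg$finetune_lr * gb
      }
      model$top_W <- model$top_W - cfg$finetune_lr * gW_top
      model$top_b <- model$top_b - cfg$finetune_lr * gb_top
    }
    verr <- mean(sda_predict(model, X_valid) != y_valid)
    log_rows[[epoch]] <- data.frame(epoch = epoch, nll = mean(nll),
                                    valid_err = verr)
    if (verr < best_err) {
      best_err <- verr
      best <- model
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= cfg$patience) break
    }
  }
  attr(best, "finetune_log") <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1L))])
  attr(best, "best_valid_err") <- best_err
  best
}

#' Train a stacked denoising autoencoder end to end
#'
#' Seeds the RNG from `cfg$seed`, initialises the network, pre-trains on
#' the unlabeled matrix (defaulting to the training rows, labels unused)
#' and fine-tunes with early stopping.
#'
#' @param X,y Labeled training rows (0-based labels).
#' @param X_valid,y_valid Validation rows.
#' @param arch Layer sizes, e.g. `c(109, 100, 2)`.
#' @param X_pretrain Optional separate unlabeled pre-training matrix.
#' @param corruption Corruption level(s) for the hidden layers.
#' @param cfg An `SdATrainConfig`.
#' @return Fine-tuned `SdAModel`.
#' @export
train_sda <- function(X, y, X_valid, y_valid, arch,
                      X_pretrain = NULL, corruption = 0.1,
                      cfg = sda_train_config()) {
  set.seed(cfg$seed)
  model <- new_sda(arch, corruption)
  pre <- if (is.null(X_pretrain)) as.matrix(X) else as.matrix(X_pretrain)
  model <- sda_pretrain(model, pre, cfg)
  sda_finetune(model, X, y, X_valid, y_valid, cfg)
}

#' Serialize / restore an SdA model as portable JSON-able list
#'
#' @param model An `SdAModel`.
#' @param path File path.
#' @export
save_sda <- function(model, path) {
  obj <- list(arch = model$arch,
              corruption = vapply(model$layers, `[[`, numeric(1L), "corruption"),
              layers = lapply(model$layers, function(l)
                list(W = as.vector(l$W), b = l$b, b_prime = l$b_prime)),
              top_W = as.vector(model$top_W), top_b = model$top_b)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_sda
#' @export
load_sda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  arch <- as.integer(obj$arch)
  model <- structure(list(layers = list(), top_W = NULL, top_b = NULL,
                          arch = arch), class = "SdAModel")
  for (k in seq_len(length(arch) - 2L)) {
    model$layers[[k]] <- list(
      W = matrix(obj$layers[[k]]$W, arch[k], arch[k + 1L]),
      b = as.numeric(obj$layers[[k]]$b),
      b_prime = as.numeric(obj$layers[[k]]$b_prime),
      corruption = obj$corruption[k])
  }
  model$top_W <- matrix(obj$top_W, arch[length(arch) - 1L], arch[length(arch)])
  model$top_b <- as.numeric(obj$top_b)
  model
}
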
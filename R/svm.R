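#' SVM baseline configuration
#'
#' Scheme-1 default: polynomial kernel of degree 3 with trade-off C = 5.
#' Scheme-2 default: RBF kernel with gamma = 9 and the backend's default
#' C. The decision cutoff `mu` separates predicted classes on the
#' real-valued SVM output and is swept to build ROC curves.
#'
#' @param kernel `"polynomial"` or `"rbf"`.
#' @param C Error/margin trade-off; `NULL` uses the backend default (1).
#' @param degree Polynomial degree.
#' @param gamma RBF kernel width; `NULL` uses the backend default (1/d).
#' @param mu Decision cutoff (default 0).
#' @return List of class `SVMConfig`.
#' @export
svm_config <- function(kernel = c("polynomial", "rbf"), C = NULL,
                       degree = 3L, gamma = NULL, mu = 0) {
  kernel <- match.arg(kernel)
  if (is.null(C)) C <- if (kernel == "polynomial") 5 else 1
  stopifnot(C > 0, degree >= 1L, is.null(gamma) || gamma > 0)
  structure(list(kernel = kernel, C = C, degree = as.integer(degree),
                 gamma = gamma, mu = mu),
            class = "SVMConfig")
}

#' Train the SVM baseline
#'
#' Thin wrapper over the libsvm backend (package e1071) honouring the
#' scheme kernels: polynomial `(u.v + 1)^degree` or RBF
#' `exp(-gamma |u-v|^2)`. Labels are encoded so that positive decision
#' values correspond to the positive class (label 1).
#'
#' @param X Scaled feature matrix.
#' @param y Binary labels (0 = negative, 1 = positive).
#' @param cfg An `SVMConfig`.
#' @return Fitted model of class `MethSVM`.
#' @export
train_svm <- function(X, y, cfg = svm_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training data has a single class")
  yf <- factor(y, levels = c(1L, 0L))   # positive class first => decision > 0
  args <- list(x = X, y = yf, scale = FALSE, cost = cfg$C,
               fitted = FALSE)
  if (cfg$kernel == "polynomial") {
    args <- c(args, list(kernel = "polynomial", degree = cfg$degree,
                         gamma = 1, coef0 = 1))
  } else {
    args <- c(args, list(kernel = "radial",
                         gamma = if (is.null(cfg$gamma)) 1 / ncol(X) else cfg$gamma))
  }
  fit <- do.call(e1071::svm, args)
  model <- structure(list(fit = fit, cfg = cfg, sign = 1), class = "MethSVM")
  # the backend's decision-value sign follows the order classes appear in
  # the training data, not the factor levels; orient it so positive
  # values favour the positive class
  dv <- decision_values(model, X)
  if (mean(dv[y == 1L]) < mean(dv[y == 0L])) model$sign <- -1
  model
}

#' Real-valued SVM decision output
#'
#' @param model A `MethSVM`.
#' @param X Feature matrix on the training scale.
#' @return Numeric vector; positive values favour the positive class.
#' @export
decision_values <- function(model, X) {
  p <- stats::predict(model$fit, as.matrix(X), decision.values = TRUE)
  model$sign * as.numeric(attr(p, "decision.values"))
}

#' Cutoff classification of decision values
#'
#' @param values Real-valued decision outputs.
#' @param mu Cutoff: predicted positive iff `value > mu`.
#' @return Integer labels (0/1).
#' @export
classify <- function(values, mu = 0) {
  as.integer(values > mu)
}
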
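#' Compute the methylated-class threshold alpha balancing the classes
#'
#' Given the un-methylated threshold `beta` (sites with
#' `percent_meth < beta` are negatives), picks `alpha` so that the number
#' of positives (`percent_meth > alpha`) matches the number of negatives
#' as closely as possible. Candidates are the observed values (and
#' `beta` itself); ties in balance are broken toward fewer positives
#' (larger alpha), and the returned alpha is never below beta.
#'
#' @param values Numeric vector of percent-methylation values in `[0,1]`.
#' @param beta Un-methylated upper threshold (default 0.01).
#' @return The threshold alpha.
#' @export
compute_alpha <- function(values, beta = 0.01) {
  stopifnot(length(values) > 0)
  n_neg <- sum(values < beta)
  if (n_neg == 0L) stop("no value below beta = ", beta, "; cannot balance")
  cands <- sort(unique(c(beta, values)))
  n_pos <- vapply(cands, function(v) sum(values > v), integer(1L))
  diff <- abs(n_pos - n_neg)
  best <- which(diff == min(diff))
  # fewer positives = larger alpha; candidates sorted ascending, n_pos
  # non-increasing, so take the last tied candidate
  alpha <- cands[best[length(best)]]
  max(alpha, beta)
}

#' Labeling configuration
#'
#' Two labeling rules are supported. `b1_alpha_beta`: positive iff
#' `percent_meth > alpha`, negative iff `percent_meth < beta`, with alpha
#' chosen to balance the classes. `b2_fixed`: negative iff
#' `percent_meth == 0`, positive iff `percent_meth >= 0.9`.
#'
#' @param scheme `"b1_alpha_beta"` or `"b2_fixed"`.
#' @param beta Un-methylated threshold for scheme 1 (default 0.01).
#' @param alpha Methylated threshold for scheme 1; computed from the
#'   labeling population via [compute_alpha()] when `NULL`.
#' @return List of class `LabelConfig`.
#' @export
label_config <- function(scheme = c("b1_alpha_beta", "b2_fixed"),
                         beta = 0.01, alpha = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(alpha) && (alpha < beta || alpha > 1))
    stop("need beta <= alpha <= 1")
  structure(list(scheme = scheme, beta = beta, alpha = alpha),
            class = "LabelConfig")
}

#' Label CpG sites as methylated / un-methylated / unlabeled
#'
#' @param percent_meth Numeric vector of percent-methylation values.
#' @param cfg A `LabelConfig`. For scheme `b1_alpha_beta` with
#'   `alpha = NULL`, alpha is computed on `percent_meth` itself.
#' @return Factor with levels `positive`, `negative`, `unlabeled`; the
#'   computed alpha is attached as attribute `"alpha"` for scheme 1.
#' @export
label_sites <- function(percent_meth, cfg = label_config()) {
  if (cfg$scheme == "b1_alpha_beta") {
    alpha <- if (is.null(cfg$alpha)) compute_alpha(percent_meth, cfg$beta) else cfg$alpha
    lab <- ifelse(percent_meth > alpha, "positive",
                  ifelse(percent_meth < cfg$beta, "negative", "unlabeled"))
    out <- factor(lab, levels = c("positive", "negative", "unlabeled"))
    attr(out, "alpha") <- alpha
    out
  } else {
    lab <- ifelse(percent_meth == 0, "negative",
                  ifelse(percent_meth >= 0.9, "positive", "unlabeled"))
    factor(lab, levels = c("positive", "negative", "unlabeled"))
  }
}

#' Rebalance a labeled dataset by down- or up-sampling
#'
#' `downsample` removes uniformly-random majority-class rows until the
#' class counts are equal; `upsample` duplicates uniformly-random
#' minority-class rows (with replacement) until they are. Both are
#' deterministic for a fixed RNG state.
#'
#' @param y Binary label vector (two distinct values required).
#' @return Integer vector of retained row indices (with duplicates for
#'   `upsample`).
#' @export
downsample <- function(y) {
  tab <- table(y)
  tab <- tab[tab > 0]
  if (length(tab) != 2L) stop("need exactly two classes to balance")
  if (tab[[1L]] == tab[[2L]]) return(seq_along(y))
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  keep_min <- which(y == minority)
  maj <- which(y == majority)
  keep_maj <- sample(maj, size = tab[[minority]])
  sort(c(keep_min, keep_maj))
}

#' @rdname downsample
#' @export
upsample <- function(y) {
  tab <- table(y)
  tab <- tab[tab > 0]
  if (length(tab) != 2L) stop("need exactly two classes to balance")
  minority <- names(tab)[which.min(tab)]
  extra <- max(tab) - min(tab)
  mins <- which(y == minority)
  dup <- sample(mins, size = extra, replace = TRUE)
  c(seq_along(y), dup)
}
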
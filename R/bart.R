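# User-facing interface to the built-in probit BART classifier.

#' Bayesian additive regression trees for binary classification
#'
#' Fits a probit sum-of-trees model by Bayesian backfitting MCMC. Each of the
#' `m` trees is kept weak by a depth-penalizing structure prior
#' (split probability `alpha * (1 + depth)^(-beta)`) and a shrinking leaf
#' prior `N(0, tau^2)` with `tau = 3 / (k * sqrt(m))`, so the latent
#' function's prior mass sits within about +/-3 probit units. Binary
#' responses are handled by truncated-normal data augmentation; the fitted
#' probability of class 1 is the posterior mean of `pnorm(offset + f(x))`
#' over the kept draws, and central posterior intervals quantify the model's
#' predictive uncertainty.
#'
#' @param x Numeric feature matrix (rows = observations).
#' @param y Binary response (0/1 vector or two-level factor).
#' @param m Number of trees (default 50).
#' @param nskip Burn-in MCMC iterations discarded (default 200).
#' @param ndraw Kept posterior draws (default 800).
#' @param k Leaf-prior shrinkage constant (default 2).
#' @param alpha,beta Tree structure prior parameters (defaults 0.95, 2).
#' @param numcut Cutpoints per variable on a uniform grid (default 100).
#' @param seed Optional integer seed set before sampling.
#' @return An object of class `bart_fit` with stored tree ensembles; supports
#'   `predict()`, `print()` and `summary()`.
#' @export
bart <- function(x, y, m = 50L, nskip = 200L, ndraw = 800L, k = 2,
                 alpha = 0.95, beta = 2, numcut = 100L, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop_invalid("x rows must match length(y)")
  if (anyNA(x) || anyNA(y)) stop_invalid("missing values are not supported")
  if (!all(y %in% c(0L, 1L))) stop_invalid("y must be binary (0/1)")
  if (length(unique(y)) < 2L) stop_degenerate("y has a single class; nothing to learn")
  if (!is.null(seed)) set.seed(as.integer(seed))
  offset <- stats::qnorm(min(max(mean(y), 0.01), 0.99))
  tau <- 3 / (k * sqrt(m))
  fit <- .bart_mcmc(x, y, as.integer(m), as.integer(nskip), as.integer(ndraw),
                    alpha, beta, tau, as.integer(numcut), offset)
  structure(list(
    trees = fit$trees, m = as.integer(m), ndraw = as.integer(ndraw),
    nskip = as.integer(nskip), offset = offset, tau = tau,
    alpha = alpha, beta = beta,
    ftrain_mean = fit$ftrain_mean,
    prob_train = stats::pnorm(offset + fit$ftrain_mean),
    y = y, signature = colnames(x), n = nrow(x), p = ncol(x)
  ), class = "bart_fit")
}

check_signature <- function(signature, x) {
  if (is.null(signature)) return(x)
  if (!is.null(colnames(x))) {
    if (!identical(colnames(x), signature)) {
      if (all(signature %in% colnames(x))) return(x[, signature, drop = FALSE])
      stop_signature("feature columns do not match the training signature")
    }
    return(x)
  }
  if (ncol(x) != length(signature)) {
    stop_signature(sprintf("expected %d feature columns, got %d",
                           length(signature), ncol(x)))
  }
  x
}

#' Posterior draws of interaction probabilities from a BART fit
#'
#' @param object A `bart_fit`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Matrix (`ndraw` x `nrow(newdata)`) of per-draw probabilities.
#' @export
bart_posterior <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop_invalid("missing values are not supported")
  x <- check_signature(object$signature, x)
  if (ncol(x) != object$p) {
    stop_signature(sprintf("expected %d feature columns, got %d", object$p, ncol(x)))
  }
  f <- .bart_score(object$trees, object$ndraw, object$m, x)
  stats::pnorm(object$offset + f)
}

#' Predict method for BART fits
#'
#' @param object A `bart_fit`.
#' @param newdata Feature matrix.
#' @param level Width of the central posterior interval (default 0.95).
#' @param ... Unused.
#' @return Data frame with `prob` (posterior-mean probability), `lo`, `hi`
#'   (central posterior interval of the per-draw probabilities) and `label`
#'   (1 iff `prob > 0.5`).
#' @export
predict.bart_fit <- function(object, newdata, level = 0.95, ...) {
  draws <- bart_posterior(object, newdata)
  prob <- colMeans(draws)
  qs <- apply(draws, 2, stats::quantile, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
              names = FALSE)
  data.frame(prob = prob, lo = pmin(qs[1, ], prob), hi = pmax(qs[2, ], prob),
             label = as.integer(prob > 0.5))
}

#' @export
print.bart_fit <- function(x, ...) {
  cat(sprintf("Probit BART fit: %d trees, %d kept draws (%d burn-in)\n",
              x$m, x$ndraw, x$nskip))
  cat(sprintf("  n = %d observations, p = %d features\n", x$n, x$p))
  cat(sprintf("  leaf prior sd tau = %.4f, offset = %.4f\n", x$tau, x$offset))
  invisible(x)
}

#' @export
summary.bart_fit <- function(object, ...) {
  p <- object$prob_train
  cm <- confusion(object$y, as.integer(p > 0.5))
  out <- list(fit = object, train_metrics = classification_metrics(cm))
  class(out) <- "summary.bart_fit"
  out
}

#' @export
print.summary.bart_fit <- function(x, ...) {
  print(x$fit)
  m <- x$train_metrics
  cat(sprintf("  training accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              m$accuracy, m$sensitivity, m$specificity))
  invisible(x)
}
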
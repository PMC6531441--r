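# Uniform train/predict surface over the five classifiers: the built-in
# probit BART plus logistic regression, RBF-kernel SVM, a single decision
# tree, and a random forest. All five consume the same feature matrix; tree
# ensembles see raw features while logistic regression and the SVM see
# per-column standardized copies (standardization fitted on training data
# only).

CLASSIFIER_NAMES <- c("bart", "logistic", "svm", "decision_tree", "random_forest")

#' Classifier specification
#'
#' Defaults follow the pipeline's stated settings: essentially unpenalized
#' logistic regression; SVM with RBF kernel, `gamma = 1e-4`, `cost = 100`;
#' CART decision tree; 500-tree random forest; BART with 50 trees, 200
#' burn-in and 800 kept draws.
#'
#' @param name One of `"bart"`, `"logistic"`, `"svm"`, `"decision_tree"`,
#'   `"random_forest"`.
#' @param seed Integer seed used at training time.
#' @param ... Hyperparameter overrides (e.g. `m`, `ndraw`, `nskip` for BART;
#'   `gamma`, `cost` for the SVM; `num_trees` for the forest).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, seed = 1L, ...) {
  name <- match.arg(name, CLASSIFIER_NAMES)
  defaults <- switch(name,
    bart = list(m = 50L, nskip = 200L, ndraw = 800L, k = 2),
    logistic = list(),
    svm = list(gamma = 1e-4, cost = 100),
    # grown deep and unpruned, matching the common default of a fully
    # developed CART classifier
    decision_tree = list(cp = 1e-4, minsplit = 4L, maxdepth = 30L),
    random_forest = list(num_trees = 500L)
  )
  override <- list(...)
  defaults[names(override)] <- override
  structure(list(name = name, seed = as.integer(seed), params = defaults),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), vapply(x$params, format, character(1)), sep = "=", collapse = ", ")
  } else "defaults"
  cat(sprintf("classifier '%s' (%s), seed %d\n", x$name, ps, x$seed))
  invisible(x)
}

scale_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(x = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

scale_apply <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$center), 2, scaling$scale, "/")
}

#' Train a classifier
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric feature matrix.
#' @param y Binary labels (0/1).
#' @return Object of class `dti_model` recording the spec, the fitted
#'   backend and the feature-column signature.
#' @export
train_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop_invalid("X rows must match length(y)")
  if (anyNA(X) || anyNA(y)) stop_invalid("missing values are not supported")
  if (!all(y %in% c(0L, 1L))) stop_invalid("y must be binary (0/1)")
  if (length(unique(y)) < 2L) stop_degenerate("y has a single class; cannot train")
  p <- spec$params
  scaling <- NULL
  set.seed(spec$seed)
  fit <- switch(spec$name,
    bart = bart(X, y, m = p$m, nskip = p$nskip, ndraw = p$ndraw, k = p$k),
    logistic = {
      scaling <- scale_train(X)
      df <- as.data.frame(scaling$x)
      names(df) <- paste0("V", seq_len(ncol(df)))
      suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial()))
    },
    svm = {
      scaling <- scale_train(X)
      e1071::svm(scaling$x, factor(y, levels = c(0, 1)), kernel = "radial",
                 gamma = p$gamma, cost = p$cost, probability = TRUE, scale = FALSE)
    },
    decision_tree = {
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(df)))
      rpart::rpart(y ~ ., data = cbind(df, y = factor(y, levels = c(0, 1))),
                   method = "class",
                   control = rpart::rpart.control(cp = p$cp, minsplit = p$minsplit,
                                                  maxdepth = p$maxdepth, xval = 0L))
    },
    random_forest = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)), num.trees = p$num_trees,
      probability = TRUE, seed = spec$seed, num.threads = 1L
    )
  )
  structure(list(spec = spec, fit = fit, scaling = scaling,
                 signature = colnames(X), p = ncol(X)),
            class = "dti_model")
}

#' @export
print.dti_model <- function(x, ...) {
  cat("Fitted protein-ligand interaction classifier\n")
  print(x$spec)
  cat(sprintf("  %d feature columns\n", x$p))
  invisible(x)
}

#' Predict interaction probabilities
#'
#' @param model A `dti_model` from [train_classifier()].
#' @param X Feature matrix with the training columns.
#' @return Numeric vector of probabilities in \[0, 1\]. For BART models the
#'   central 95% posterior interval is attached as attribute `"interval"`
#'   (a two-row `lo`/`hi` matrix).
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "dti_model"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X <- check_signature(model$signature, X)
  if (ncol(X) != model$p) {
    stop_signature(sprintf("expected %d feature columns, got %d", model$p, ncol(X)))
  }
  name <- model$spec$name
  if (name == "bart") {
    pred <- predict(model$fit, X)
    out <- pred$prob
    attr(out, "interval") <- rbind(lo = pred$lo, hi = pred$hi)
    return(out)
  }
  if (!is.null(model$scaling)) X <- scale_apply(X, model$scaling)
  switch(name,
    logistic = {
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(df)))
      as.numeric(suppressWarnings(stats::predict(model$fit, newdata = df,
                                                 type = "response")))
    },
    svm = {
      pr <- attr(stats::predict(model$fit, X, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    decision_tree = {
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(df)))
      as.numeric(stats::predict(model$fit, newdata = df, type = "prob")[, "1"])
    },
    random_forest = as.numeric(stats::predict(model$fit, data = X,
                                              num.threads = 1L)$predictions[, "1"])
  )
}

#' Threshold probabilities into hard labels
#'
#' A pair is called an interaction only when its probability strictly
#' exceeds the threshold; a probability exactly at the threshold is a
#' non-interaction.
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  p <- as.numeric(probabilities)
  if (anyNA(p) || any(p < 0 | p > 1)) stop_invalid("probabilities must lie in [0, 1]")
  as.integer(p > threshold)
}

#' Save / load a fitted model with its spec and column signature
#' @param model A `dti_model`.
#' @param path Destination file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dti_model"))
  saveRDS(list(format = 1L, package_version = as.character(utils::packageVersion("bowdti")),
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$model)) stop_invalid("not a saved bowdti model archive")
  obj$model
}
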
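# The five-classifier surface and the built-in probit BART.

test_that("logistic regression separates a linearly separable toy problem", {
  d <- separable_xy()
  model <- train_classifier(classifier_spec("logistic", seed = 1), d$X, d$y)
  p <- predict_proba(model, d$X)
  expect_equal(as.integer(classify(p)), d$y)
})

test_that("single-class labels raise a degenerate-training error for every backend", {
  d <- separable_xy()
  for (nm in c("bart", "logistic", "svm", "decision_tree", "random_forest")) {
    expect_error(train_classifier(classifier_spec(nm, seed = 1), d$X, rep(1L, nrow(d$X))),
                 class = "bow_degenerate_training")
  }
})

test_that("training is seed-deterministic for the stochastic backends", {
  d <- separable_xy(n = 40)
  for (nm in c("random_forest", "bart")) {
    m1 <- train_classifier(classifier_spec(nm, seed = 11), d$X, d$y)
    m2 <- train_classifier(classifier_spec(nm, seed = 11), d$X, d$y)
    expect_equal(as.numeric(predict_proba(m1, d$X)),
                 as.numeric(predict_proba(m2, d$X)))
  }
})

test_that("column signatures are enforced at prediction time", {
  d <- separable_xy()
  model <- train_classifier(classifier_spec("random_forest", seed = 1), d$X, d$y)
  bad <- d$X[, 1, drop = FALSE]
  expect_error(predict_proba(model, bad), class = "bow_signature_error")
  renamed <- d$X
  colnames(renamed) <- c("a", "b")
  expect_error(predict_proba(model, renamed), class = "bow_signature_error")
  # reordered columns are realigned by name
  reord <- d$X[, c("x2", "x1")]
  expect_equal(as.numeric(predict_proba(model, reord)),
               as.numeric(predict_proba(model, d$X)))
})

test_that("probabilities are valid and the strict 0.5 rule sends ties to non-interaction", {
  expect_identical(classify(c(0.5, 0.51, 0.0, 1.0)), c(0L, 1L, 0L, 1L))
  expect_error(classify(c(-0.1, 0.5)), class = "bow_invalid_input")
  d <- separable_xy(n = 30)
  for (nm in c("logistic", "svm", "decision_tree", "random_forest")) {
    m <- train_classifier(classifier_spec(nm, seed = 2), d$X, d$y)
    p <- as.numeric(predict_proba(m, d$X))
    expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1))
  }
})

test_that("BART recovers near-extreme probabilities on clean structure with ordered intervals", {
  set.seed(31)
  n <- 120
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- as.integer(X[, "a"] > 0)  # noise-free threshold rule
  fit <- bart(X, y, m = 20, nskip = 100, ndraw = 300, seed = 5)
  pred <- predict(fit, X)
  clear_pos <- y == 1 & X[, "a"] > 0.5   # points far from the decision boundary
  clear_neg <- y == 0 & X[, "a"] < -0.5
  expect_gt(mean(pred$prob[clear_pos] > 0.9), 0.8)
  expect_gt(mean(pred$prob[clear_neg] < 0.1), 0.8)
  expect_true(all(pred$lo <= pred$prob & pred$prob <= pred$hi))
  expect_true(all(is.finite(pred$prob)))
})

test_that("BART posterior mean is invariant to the ordering of kept draws", {
  d <- separable_xy(n = 30)
  fit <- bart(d$X, d$y, m = 10, nskip = 50, ndraw = 100, seed = 3)
  draws <- bart_posterior(fit, d$X)
  expect_equal(dim(draws), c(100L, 30L))
  set.seed(1)
  shuffled <- draws[sample(nrow(draws)), ]
  expect_equal(colMeans(draws), colMeans(shuffled), tolerance = 1e-12)
})

test_that("model archives round-trip with spec and signature intact", {
  d <- separable_xy()
  model <- train_classifier(classifier_spec("decision_tree", seed = 1), d$X, d$y)
  f <- tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(back$signature, colnames(d$X))
  expect_equal(as.numeric(predict_proba(back, d$X)),
               as.numeric(predict_proba(model, d$X)))
})

test_that("all five classifiers exceed 0.9 AUC on directly separable data", {
  set.seed(17)
  n <- 300
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(n, 1, 0.5)
  X[, 1:2] <- X[, 1:2] + 2.5 * (y - 0.5)
  tr <- sample(n, 200)
  for (nm in c("bart", "logistic", "svm", "decision_tree", "random_forest")) {
    spec <- classifier_spec(nm, seed = 13)
    if (nm == "bart") spec <- classifier_spec(nm, seed = 13, nskip = 100L, ndraw = 300L)
    m <- train_classifier(spec, X[tr, ], y[tr])
    auc <- roc_auc(y[-tr], as.numeric(predict_proba(m, X[-tr, ])))$auc
    expect_gt(auc, 0.9)
  }
})
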
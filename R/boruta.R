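# All-relevant feature selection by shadow features around a random forest.
#
# Each iteration appends a freshly permuted ("shadow") copy of every column,
# fits a permutation-importance random forest, and scores a real feature a
# "hit" when its importance exceeds the maximum shadow importance. After
# max_iter iterations a two-sided binomial test of the hit count against
# chance (p = 0.5) classifies each feature: significantly above chance ->
# important, significantly below -> unimportant, otherwise tentative.

#' Shadow-feature all-relevant feature selection
#'
#' @param X Numeric feature matrix (at least two columns).
#' @param y Binary labels.
#' @param max_iter Number of shadow iterations (default 100).
#' @param alpha Significance level of the binomial test (default 0.05).
#' @param num_trees Trees per forest (default 500).
#' @param seed Integer seed; shadows are re-shuffled every iteration but the
#'   whole run is seed-deterministic.
#' @return Object of class `boruta_result`: per-feature `category`
#'   (`important` / `tentative` / `unimportant`), `hits`, `iterations`,
#'   `alpha`, `seed`.
#' @export
boruta_select <- function(X, y, max_iter = 100L, alpha = 0.05, num_trees = 500L,
                          seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (ncol(X) < 2L) stop_invalid("need at least 2 features")
  if (nrow(X) != length(y)) stop_invalid("X rows must match length(y)")
  if (length(unique(y)) < 2L) stop_degenerate("y has a single class; cannot select features")
  p <- ncol(X)
  nm <- colnames(X) %||% paste0("x", seq_len(p))
  yf <- factor(y, levels = c(0, 1))
  hits <- integer(p)
  set.seed(as.integer(seed))
  for (it in seq_len(max_iter)) {
    shadow <- apply(X, 2, sample)
    colnames(shadow) <- paste0(".shadow_", seq_len(p))
    Xs <- cbind(X, shadow)
    colnames(Xs) <- c(nm, colnames(shadow))
    rf <- ranger::ranger(x = Xs, y = yf, num.trees = num_trees,
                         importance = "permutation", num.threads = 1L,
                         seed = sample.int(2^31 - 1, 1))
    imp <- rf$variable.importance
    shadow_max <- max(imp[(p + 1):(2 * p)])
    hits <- hits + as.integer(imp[seq_len(p)] > shadow_max)
  }
  category <- vapply(hits, function(h) {
    pval <- stats::binom.test(h, max_iter, 0.5)$p.value
    if (pval < alpha) {
      if (h > max_iter / 2) "important" else "unimportant"
    } else "tentative"
  }, character(1))
  structure(list(
    category = stats::setNames(category, nm),
    hits = stats::setNames(hits, nm),
    iterations = as.integer(max_iter), alpha = alpha,
    num_trees = as.integer(num_trees), seed = as.integer(seed)
  ), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$category, levels = c("important", "tentative", "unimportant")))
  cat(sprintf("shadow-feature selection over %d iterations (alpha = %g):\n",
              x$iterations, x$alpha))
  cat(sprintf("  important %d | tentative %d | unimportant %d\n",
              tab[["important"]], tab[["tentative"]], tab[["unimportant"]]))
  invisible(x)
}

#' Derive the two feature subsets from a selection result
#'
#' `strict` keeps only confirmed-important features ("strictly selected");
#' `selected` also keeps tentative ones.
#'
#' @param result A [boruta_select()] result.
#' @return List with integer index vectors `strict` and `selected`.
#' @export
feature_subsets <- function(result) {
  stopifnot(inherits(result, "boruta_result"))
  list(strict = which(result$category == "important"),
       selected = which(result$category %in% c("important", "tentative")))
}

#' Count selected features per bow subspace
#'
#' @param result A [boruta_select()] result.
#' @param column_map Character vector assigning each feature column to a
#'   subspace (e.g. [bow_column_map()], values `protein` / `ligand` /
#'   `interaction`), aligned with the columns `result` was computed on.
#' @return Named integer vector of selected-feature counts per subspace;
#'   the counts sum to the number of selected features.
#' @export
subspace_attribution <- function(result, column_map) {
  stopifnot(inherits(result, "boruta_result"))
  if (length(column_map) != length(result$category) || anyNA(column_map)) {
    stop_invalid("column_map must assign every feature column to a subspace")
  }
  sel <- feature_subsets(result)$selected
  counts <- table(factor(column_map[sel], levels = unique(column_map)))
  stats::setNames(as.integer(counts), names(counts))
}

#' Serialize a selection result (JSON) and its subsets (plain index files)
#'
#' Writes `<path>` as JSON plus `<path>.strict.txt` / `<path>.selected.txt`
#' with one selected column name per line, consumable as a custom
#' featurization mask.
#'
#' @param result A [boruta_select()] result.
#' @param path Output JSON path.
#' @export
write_boruta_result <- function(result, path) {
  jsonlite::write_json(
    list(category = as.list(result$category), hits = as.list(result$hits),
         iterations = result$iterations, alpha = result$alpha,
         num_trees = result$num_trees, seed = result$seed),
    path, auto_unbox = TRUE, digits = NA)
  subsets <- feature_subsets(result)
  writeLines(names(result$category)[subsets$strict], paste0(path, ".strict.txt"))
  writeLines(names(result$category)[subsets$selected], paste0(path, ".selected.txt"))
  invisible(path)
}
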
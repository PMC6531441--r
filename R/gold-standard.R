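# Gold-standard dataset construction: positives from the interaction
# network, negatives sampled from entity pools disjoint from every positive,
# 70/30 train/test split and stratified k-fold assignment.

#' Positive labelled pairs from an interaction network
#'
#' One labelled pair per (unique) edge, label 1.
#'
#' @param network An [interaction_network()].
#' @return Data frame with columns `protein_id`, `ligand_id`, `label`.
#' @export
build_positive_set <- function(network) {
  data.frame(protein_id = network$protein_id, ligand_id = network$ligand_id,
             label = rep(1L, nrow(network)), stringsAsFactors = FALSE)
}

#' Sample negative (non-interacting) pairs from disjoint pools
#'
#' Draws `n` distinct protein-ligand pairs uniformly without replacement from
#' the cross product of the supplied pools, label 0. The pools are expected
#' to be disjoint from every entity occurring in a positive pair (supply
#' `positives` to enforce this). Pairs listed in `exclude` (e.g. background
#' known interactions) are never sampled.
#'
#' @param protein_pool,ligand_pool Character vectors of candidate ids.
#' @param n Number of negatives to draw.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param positives Optional positive pair data frame used to verify pool
#'   disjointness.
#' @param exclude Optional data frame/network of pairs that must not appear.
#' @return Data frame with columns `protein_id`, `ligand_id`, `label` (0).
#' @export
sample_negative_pairs <- function(protein_pool, ligand_pool, n, seed,
                                  positives = NULL, exclude = NULL) {
  protein_pool <- unique(as.character(protein_pool))
  ligand_pool <- unique(as.character(ligand_pool))
  n <- as.integer(n)
  if (n < 1L) stop_invalid("n must be >= 1")
  if (!is.null(positives) && nrow(positives) > 0L) {
    if (any(protein_pool %in% positives$protein_id) ||
        any(ligand_pool %in% positives$ligand_id)) {
      stop_invalid("negative pools must be disjoint from all entities in positive pairs")
    }
  }
  key <- function(p, l) paste(p, l, sep = "\r")
  banned <- character(0)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    banned <- key(as.character(exclude[[1]]), as.character(exclude[[2]]))
    banned <- banned[as.character(exclude[[1]]) %in% protein_pool &
                       as.character(exclude[[2]]) %in% ligand_pool]
  }
  total <- as.numeric(length(protein_pool)) * length(ligand_pool) - length(unique(banned))
  if (n > total) {
    stop_infeasible(sprintf("requested %d negatives but only %.0f candidate pairs exist",
                            n, total))
  }
  if (total > 2^31 - 1) {
    stop_infeasible("candidate pair space too large to enumerate; shrink the pools")
  }
  withr_seed(seed, {
    flat <- sample.int(length(protein_pool) * length(ligand_pool))
    pi <- ((flat - 1L) %% length(protein_pool)) + 1L
    li <- ((flat - 1L) %/% length(protein_pool)) + 1L
    keep <- !key(protein_pool[pi], ligand_pool[li]) %in% banned
    take <- which(keep)[seq_len(n)]
    data.frame(protein_id = protein_pool[pi[take]], ligand_id = ligand_pool[li[take]],
               label = rep(0L, n), stringsAsFactors = FALSE)
  })
}

# Run code under a local RNG state seeded deterministically.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Largest-remainder allocation of a total across strata, so the overall train
# size is round(fraction * n) and each stratum is within 1 of its exact share.
allocate_stratified <- function(sizes, fraction) {
  target <- round(fraction * sum(sizes))
  exact <- fraction * sizes
  base <- floor(exact)
  rem <- target - sum(base)
  if (rem > 0) {
    order_idx <- order(exact - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  } else if (rem < 0) {
    order_idx <- order(exact - base)
    k <- -rem
    base[order_idx[seq_len(k)]] <- base[order_idx[seq_len(k)]] - 1
  }
  pmin(pmax(base, 0), sizes)
}

#' Stratified train/test split
#'
#' Splits labelled pairs into a training and a test portion, stratified by
#' label so class balance is preserved within 1 pair per class.
#'
#' @param pairs Labelled pair data frame (column `label`).
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed.
#' @param stratify Set `FALSE` for a plain random split.
#' @return List of class `dataset_split`: `train` and `test` row indices,
#'   plus the seed and fraction.
#' @export
train_test_split <- function(pairs, train_fraction = 0.7, seed, stratify = TRUE) {
  n <- nrow(pairs)
  if (n < 2L) stop_invalid("need at least 2 pairs to split")
  if (train_fraction < 0 || train_fraction > 1) stop_invalid("train_fraction must be in [0, 1]")
  labs <- pairs$label
  if (stratify && length(unique(labs)) < 2L) {
    warning("single-class input: falling back to an unstratified split", call. = FALSE)
    stratify <- FALSE
  }
  train <- withr_seed(seed, {
    if (stratify) {
      strata <- split(seq_len(n), labs)
      sizes <- vapply(strata, length, integer(1))
      take <- allocate_stratified(sizes, train_fraction)
      unlist(lapply(seq_along(strata), function(s) sample(strata[[s]], take[s])),
             use.names = FALSE)
    } else {
      sample(seq_len(n), round(train_fraction * n))
    }
  })
  if (length(train) == n || length(train) == 0L) {
    warning("degenerate split: one side is empty", call. = FALSE)
  }
  structure(list(train = sort(train), test = sort(setdiff(seq_len(n), train)),
                 seed = seed, train_fraction = train_fraction, stratified = stratify),
            class = "dataset_split")
}

#' Stratified k-fold assignment
#'
#' Every pair lands in exactly one test fold; folds are label-stratified and
#' near-equal in size.
#'
#' @param pairs Labelled pair data frame.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param stratify Set `FALSE` to ignore labels.
#' @return Integer vector of fold ids (1..k), one per pair.
#' @export
kfold <- function(pairs, k = 10L, seed, stratify = TRUE) {
  n <- nrow(pairs)
  k <- as.integer(k)
  if (k < 2L) stop_invalid("k must be at least 2")
  if (k > n) stop_invalid(sprintf("k = %d exceeds the number of pairs (%d)", k, n))
  labs <- if (stratify) pairs$label else rep(1L, n)
  folds <- integer(n)
  withr_seed(seed, {
    for (s in split(seq_len(n), labs)) {
      folds[sample(s)] <- rep_len(seq_len(k), length(s))
    }
  })
  folds
}

#' Serialize a split or fold assignment as a JSON manifest
#' @param split A `dataset_split` or fold vector.
#' @param path Output path.
#' @param extra Named list merged into the manifest.
#' @export
write_split_manifest <- function(split, path, extra = list()) {
  obj <- if (inherits(split, "dataset_split")) unclass(split) else list(folds = split)
  jsonlite::write_json(c(obj, extra), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
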
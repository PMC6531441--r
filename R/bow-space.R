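# Interaction space and assembly of the full bow-pharmacological descriptor.
#
# The interaction-space descriptor of a protein (MACCSP) is the element-wise
# mean of the MACCS fingerprints of its known ligands in a supplied
# interaction network. A protein with no known ligands (an orphan) gets an
# all-zero MACCSP so that pairs involving unknown proteins remain
# predictable. The assembled pair descriptor is the fixed-order
# concatenation [protein block (107) | MACCSL (166) | MACCSP (166)],
# 439 dimensions in total.

#' Build an interaction network from an edge list
#'
#' @param edges Data frame (or two-column matrix) whose first two columns are
#'   protein id and ligand id. Duplicate edges collapse (set semantics).
#' @return Object of class `interaction_network`: a data frame with columns
#'   `protein_id`, `ligand_id` and unique rows.
#' @export
interaction_network <- function(edges) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop_invalid("edge list needs two columns (protein_id, ligand_id)")
  net <- data.frame(protein_id = as.character(edges[[1]]),
                    ligand_id = as.character(edges[[2]]),
                    stringsAsFactors = FALSE)
  if (anyNA(net) || any(!nzchar(unlist(net)))) stop_invalid("edge endpoints must be non-empty ids")
  net <- unique(net)
  rownames(net) <- NULL
  class(net) <- c("interaction_network", "data.frame")
  net
}

#' Read an interaction edge list from TSV
#'
#' Format: `protein_id<TAB>ligand_id`, one edge per line; lines starting
#' with `#` are comments.
#'
#' @param path Path to the TSV file.
#' @return An [interaction_network()] object.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  interaction_network(df)
}

#' Write an interaction network as a TSV edge list
#' @param network An [interaction_network()] object.
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interaction-space descriptor of one protein (MACCSP)
#'
#' Element-wise mean of the fingerprints of the protein's known ligands in
#' `network`. Orphan proteins yield a zero vector with a warning.
#'
#' @param protein_id Protein id.
#' @param network An [interaction_network()].
#' @param fps Fingerprint matrix (rows named by ligand id).
#' @return Named numeric vector of length 166 with entries in \[0, 1\].
#' @export
maccsp <- function(protein_id, network, fps) {
  ligs <- network$ligand_id[network$protein_id == protein_id]
  nm <- paste0("maccsp_", seq_len(N_MACCS))
  if (length(ligs) == 0L) {
    warning(sprintf("protein '%s' has no known ligands; MACCSP set to zero", protein_id),
            call. = FALSE)
    return(stats::setNames(numeric(N_MACCS), nm))
  }
  missing <- setdiff(ligs, rownames(fps))
  if (length(missing) > 0L) {
    stop_dangling(sprintf("network references ligand(s) missing from fingerprints: %s",
                          paste(utils::head(missing, 5L), collapse = ", ")))
  }
  stats::setNames(colMeans(fps[ligs, , drop = FALSE]), nm)
}

# MACCSP for many proteins at once (shared validation, no per-protein warning
# storm; returns count of orphans via attribute).
maccsp_matrix <- function(protein_ids, network, fps) {
  protein_ids <- unique(protein_ids)
  missing <- setdiff(network$ligand_id, rownames(fps))
  if (length(missing) > 0L) {
    stop_dangling(sprintf("network references ligand(s) missing from fingerprints: %s",
                          paste(utils::head(missing, 5L), collapse = ", ")))
  }
  out <- matrix(0, nrow = length(protein_ids), ncol = N_MACCS,
                dimnames = list(protein_ids, paste0("maccsp_", seq_len(N_MACCS))))
  idx <- split(network$ligand_id, network$protein_id)
  for (p in intersect(protein_ids, names(idx))) {
    out[p, ] <- colMeans(fps[idx[[p]], , drop = FALSE])
  }
  attr(out, "n_orphans") <- sum(!protein_ids %in% names(idx))
  out
}

#' Names of the 439 bow-space feature columns
#' @return Character vector: 107 protein + 166 `maccsl_*` + 166 `maccsp_*`.
#' @export
bow_feature_names <- function() {
  c(protein_feature_names(),
    paste0("maccsl_", seq_len(N_MACCS)),
    paste0("maccsp_", seq_len(N_MACCS)))
}

#' Subspace membership of each bow-space column
#' @return Character vector of length 439 with values `"protein"`,
#'   `"ligand"`, `"interaction"`, named by column.
#' @export
bow_column_map <- function() {
  stats::setNames(rep(c("protein", "ligand", "interaction"), c(107L, N_MACCS, N_MACCS)),
                  bow_feature_names())
}

resolve_mask <- function(subspace_mask) {
  nms <- bow_feature_names()
  if (is.null(subspace_mask)) stop_invalid("subspace mask must not be empty")
  if (is.character(subspace_mask) && length(subspace_mask) == 1L &&
      subspace_mask %in% c("all", "protein+ligand", "protein", "ligand", "interaction")) {
    map <- bow_column_map()
    keep <- switch(subspace_mask,
      "all" = rep(TRUE, length(nms)),
      "protein+ligand" = map %in% c("protein", "ligand"),
      "protein" = map == "protein",
      "ligand" = map == "ligand",
      "interaction" = map == "interaction")
    return(which(keep))
  }
  if (is.numeric(subspace_mask)) {
    idx <- as.integer(subspace_mask)
    if (length(idx) == 0L || anyNA(idx) || any(idx < 1L | idx > length(nms))) {
      stop_invalid("numeric mask must be non-empty column indices in 1..439")
    }
    return(idx)
  }
  idx <- match(subspace_mask, nms)
  if (length(idx) == 0L || anyNA(idx)) stop_invalid("mask names not all found in bow columns")
  idx
}

#' Assemble the 439-dimensional bow descriptor for one pair
#'
#' @param protein_id,ligand_id Pair identifiers.
#' @param blocks Protein feature matrix ([protein_feature_matrix()]).
#' @param fps Ligand fingerprint matrix.
#' @param network [interaction_network()] supplying the known interactions
#'   that define the interaction-space average.
#' @return Named numeric vector of length 439.
#' @export
assemble_bow <- function(protein_id, ligand_id, blocks, fps, network) {
  if (!protein_id %in% rownames(blocks)) {
    stop_dangling(sprintf("no protein feature block for '%s'", protein_id))
  }
  if (!ligand_id %in% rownames(fps)) {
    stop_dangling(sprintf("no fingerprint for ligand '%s'", ligand_id))
  }
  mp <- suppressWarnings(maccsp(protein_id, network, fps))
  out <- c(blocks[protein_id, ], stats::setNames(as.numeric(fps[ligand_id, ]),
                                                 paste0("maccsl_", seq_len(N_MACCS))), mp)
  names(out) <- bow_feature_names()
  out
}

#' Feature matrix for a set of protein-ligand pairs
#'
#' Rows follow the input pair order; columns are restricted by
#' `subspace_mask` (`"all"`, `"protein+ligand"`, `"protein"`, `"ligand"`,
#' `"interaction"`, or a custom index/name vector).
#'
#' @param pairs Data frame with columns `protein_id` and `ligand_id`.
#' @inheritParams assemble_bow
#' @param subspace_mask Column restriction (default `"all"`, 439 columns).
#' @param exclude_self When `TRUE`, a pair whose own edge is present in the
#'   network has that edge left out of its MACCSP average (leave-one-out),
#'   so a labelled pair's descriptor never encodes its own label. Pairs that
#'   are not network edges are unaffected.
#' @return Numeric matrix, `nrow(pairs)` rows.
#' @export
featurize_pairs <- function(pairs, blocks, fps, network, subspace_mask = "all",
                            exclude_self = FALSE) {
  idx <- resolve_mask(subspace_mask)
  missing_p <- setdiff(unique(pairs$protein_id), rownames(blocks))
  if (length(missing_p) > 0L) {
    stop_dangling(sprintf("no protein feature block for: %s",
                          paste(utils::head(missing_p, 5L), collapse = ", ")))
  }
  missing_l <- setdiff(unique(pairs$ligand_id), rownames(fps))
  if (length(missing_l) > 0L) {
    stop_dangling(sprintf("no fingerprint for ligand(s): %s",
                          paste(utils::head(missing_l, 5L), collapse = ", ")))
  }
  mp <- maccsp_matrix(unique(pairs$protein_id), network, fps)
  mp_rows <- mp[pairs$protein_id, , drop = FALSE]
  if (exclude_self) {
    deg <- table(network$protein_id)
    pair_deg <- as.numeric(deg[pairs$protein_id])
    pair_deg[is.na(pair_deg)] <- 0
    is_edge <- paste(pairs$protein_id, pairs$ligand_id, sep = "\r") %in%
      paste(network$protein_id, network$ligand_id, sep = "\r")
    loo <- which(is_edge)
    for (i in loo) {
      d <- pair_deg[i]
      mp_rows[i, ] <- if (d <= 1) 0 else {
        (mp_rows[i, ] * d - fps[pairs$ligand_id[i], ]) / (d - 1)
      }
    }
  }
  X <- cbind(blocks[pairs$protein_id, , drop = FALSE],
             fps[pairs$ligand_id, , drop = FALSE],
             mp_rows)
  colnames(X) <- bow_feature_names()
  rownames(X) <- paste(pairs$protein_id, pairs$ligand_id, sep = ":")
  X[, idx, drop = FALSE]
}

#' Write an assembled feature matrix (plus pair ids and labels) to CSV
#'
#' @param X Feature matrix from [featurize_pairs()].
#' @param pairs Matching pair data frame (may carry a `label` column).
#' @param path Output CSV path.
#' @export
write_bow_features <- function(X, pairs, path) {
  df <- data.frame(protein_id = pairs$protein_id, ligand_id = pairs$ligand_id,
                   stringsAsFactors = FALSE)
  if (!is.null(pairs$label)) df$label <- pairs$label
  utils::write.csv(cbind(df, as.data.frame(X, check.names = FALSE)), path, row.names = FALSE)
  invisible(path)
}
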
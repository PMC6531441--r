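# Protein space: ten sequence-derived feature sets (107 dimensions) computed
# from the raw amino-acid string.
#
# Layout of the 107-dimensional block, in fixed order:
#   cv    20  composition vector
#   cmv1  20  first-order composition moment vector
#   cmv2  20  second-order composition moment vector
#   bpc    7  basic physicochemical sums
#   npc    7  neighbourhood physicochemical contrasts
#   ipc    7  index-based (lagged squared-difference) correlations
#   rg     5  R-group composition
#   eleg   5  electronic-group composition (cysteine unassigned)
#   exg    6  exchange-group composition
#   hg     4  hydrophobicity-group composition
#   scg    6  side-chain-group composition (overlapping groups)

#' Validate a protein sequence
#'
#' Accepts only the 20 canonical one-letter residue codes (uppercased).
#' With `permissive = TRUE`, non-canonical letters (B, J, O, U, X, Z and
#' anything else) are dropped with a warning reporting the count; by default
#' they are rejected.
#'
#' @param residues Character scalar, the amino-acid string.
#' @param permissive Drop non-canonical residues instead of erroring.
#' @return The validated (possibly filtered) uppercase sequence string.
#' @export
validate_sequence <- function(residues, permissive = FALSE) {
  if (length(residues) != 1L || is.na(residues) || !nzchar(residues)) {
    stop_invalid("sequence must be a non-empty character scalar")
  }
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1]]
  ok <- chars %in% amino_acids()
  if (!all(ok)) {
    if (permissive) {
      warning(sprintf("dropped %d non-canonical residue(s)", sum(!ok)), call. = FALSE)
      chars <- chars[ok]
      if (length(chars) == 0L) stop_invalid("no canonical residues left after filtering")
    } else {
      stop_invalid(sprintf(
        "sequence contains %d non-canonical residue(s): %s",
        sum(!ok), paste(unique(chars[!ok]), collapse = ", ")
      ))
    }
  }
  paste(chars, collapse = "")
}

seq_chars <- function(residues) strsplit(residues, "", fixed = TRUE)[[1]]

#' Amino-acid composition vector (20 dimensions)
#'
#' Fraction of each canonical residue in the sequence, alphabetical residue
#' order; entries sum to 1.
#'
#' @param residues Validated sequence string.
#' @return Named numeric vector of length 20.
#' @export
composition_vector <- function(residues) {
  residues <- validate_sequence(residues)
  chars <- seq_chars(residues)
  counts <- table(factor(chars, levels = amino_acids()))
  stats::setNames(as.numeric(counts) / length(chars), paste0("cv_", amino_acids()))
}

#' Composition moment vector (20 dimensions per order)
#'
#' Order-k entry for residue type i is the sum of its (1-based) sequence
#' positions raised to the k-th power, normalized by N(N-1)...(N-k). Order 0
#' collapses to the plain composition vector.
#'
#' @param residues Validated sequence string.
#' @param order Moment order (0, 1 or 2).
#' @return Named numeric vector of length 20.
#' @export
composition_moment_vector <- function(residues, order = 1L) {
  residues <- validate_sequence(residues)
  order <- as.integer(order)
  if (!order %in% 0:2) stop_invalid("order must be 0, 1 or 2")
  chars <- seq_chars(residues)
  n <- length(chars)
  if (n <= order) {
    bow_stop(sprintf("sequence length %d too short for order-%d moment (normalizer is zero)",
                     n, order), "bow_degenerate_length")
  }
  norm <- prod(n - 0:order)
  pos_pow <- seq_len(n)^order
  sums <- vapply(amino_acids(), function(a) sum(pos_pow[chars == a]), numeric(1))
  stats::setNames(as.numeric(sums) / norm, paste0("cmv", order, "_", amino_acids()))
}

#' Basic physicochemical features (7 dimensions)
#'
#' Per property, the raw per-residue scale values summed along the sequence.
#' Note the sum is length-dependent by construction.
#'
#' @param residues Validated sequence string.
#' @param table 20 x 7 property table; defaults to [aa_property_table()].
#' @return Named numeric vector of length 7.
#' @export
basic_physicochemical <- function(residues, table = aa_property_table()) {
  residues <- validate_sequence(residues)
  table <- validate_property_table(table)
  chars <- seq_chars(residues)
  vals <- colSums(table[chars, , drop = FALSE])
  stats::setNames(as.numeric(vals), paste0("bpc_", colnames(table)))
}

#' Neighbourhood-based physicochemical features (7 dimensions)
#'
#' Per property, the sum over interior positions i = 2..N-1 of
#' |P_i^2 - P_{i-1} P_{i+1}| on the raw property values. Sequences shorter
#' than 3 have no interior positions and return zeros with a warning.
#'
#' @inheritParams basic_physicochemical
#' @return Named numeric vector of length 7.
#' @export
neighbourhood_physicochemical <- function(residues, table = aa_property_table()) {
  residues <- validate_sequence(residues)
  table <- validate_property_table(table)
  chars <- seq_chars(residues)
  n <- length(chars)
  nm <- paste0("npc_", colnames(table))
  if (n < 3L) {
    warning("sequence shorter than 3: no interior positions, NPC set to zero", call. = FALSE)
    return(stats::setNames(numeric(7), nm))
  }
  P <- table[chars, , drop = FALSE]
  i <- 2:(n - 1)
  vals <- colSums(abs(P[i, , drop = FALSE]^2 -
                        P[i - 1, , drop = FALSE] * P[i + 1, , drop = FALSE]))
  stats::setNames(as.numeric(vals), nm)
}

#' Index-based physicochemical features (7 dimensions)
#'
#' Sequence-order correlation descriptor. Per property: (1) standardize the
#' 20 residue scale values to mean 0, sd 1; (2) for every lag k = 1..N-1 take
#' the mean over i of the squared difference between the standardized values
#' at positions i and i+k (the k-th correlation factor); (3) average the
#' correlation factors over all lags. Always non-negative; exactly zero on
#' homopolymers.
#'
#' @inheritParams basic_physicochemical
#' @return Named numeric vector of length 7.
#' @export
index_physicochemical <- function(residues, table = aa_property_table()) {
  residues <- validate_sequence(residues)
  table <- validate_property_table(table)
  chars <- seq_chars(residues)
  n <- length(chars)
  nm <- paste0("ipc_", colnames(table))
  if (n < 2L) {
    warning("sequence of length 1: no residue pairs, IPC set to zero", call. = FALSE)
    return(stats::setNames(numeric(7), nm))
  }
  Z <- standardize_property_table(table)[chars, , drop = FALSE]
  vals <- vapply(seq_len(ncol(Z)), function(j) {
    z <- Z[, j]
    # delta_k = mean_i (z[i+k] - z[i])^2; vectorized over i for each lag.
    deltas <- vapply(seq_len(n - 1L), function(k) {
      d <- z[(1 + k):n] - z[1:(n - k)]
      mean(d * d)
    }, numeric(1))
    sum(deltas) / (n - 1L)
  }, numeric(1))
  stats::setNames(vals, nm)
}

#' Group-composition features
#'
#' Fraction of sequence residues falling in each group of a residue grouping
#' scheme. Overlapping groups (the side-chain scheme) count a residue once
#' per group it belongs to, so those entries need not sum to 1.
#'
#' @param residues Validated sequence string.
#' @param grouping Grouping name (`"rg"`, `"eleg"`, `"exg"`, `"hg"`, `"scg"`)
#'   or a named list of residue groups as returned by [aa_grouping()].
#' @return Named numeric vector, one entry per group.
#' @export
group_composition <- function(residues, grouping) {
  residues <- validate_sequence(residues)
  if (is.character(grouping)) grouping <- aa_grouping(grouping)
  chars <- seq_chars(residues)
  vals <- vapply(grouping, function(g) sum(chars %in% g) / length(chars), numeric(1))
  stats::setNames(vals, names(grouping))
}

#' Assemble the full 107-dimensional protein feature block
#'
#' Concatenates, in fixed order: composition vector, first- and second-order
#' composition moment vectors, basic/neighbourhood/index physicochemical
#' features, and the five group-composition sets.
#'
#' @inheritParams basic_physicochemical
#' @return Named numeric vector of length 107.
#' @export
protein_feature_block <- function(residues, table = aa_property_table()) {
  residues <- validate_sequence(residues)
  if (nchar(residues) < 3L) stop_invalid("protein feature block requires length >= 3")
  c(
    composition_vector(residues),
    composition_moment_vector(residues, 1L),
    composition_moment_vector(residues, 2L),
    basic_physicochemical(residues, table),
    neighbourhood_physicochemical(residues, table),
    index_physicochemical(residues, table),
    group_composition(residues, "rg"),
    group_composition(residues, "eleg"),
    group_composition(residues, "exg"),
    group_composition(residues, "hg"),
    group_composition(residues, "scg")
  )
}

#' Names of the 107 protein-space feature columns
#' @return Character vector of length 107.
#' @export
protein_feature_names <- function() {
  props <- colnames(aa_property_table())
  c(paste0("cv_", amino_acids()),
    paste0("cmv1_", amino_acids()),
    paste0("cmv2_", amino_acids()),
    paste0("bpc_", props), paste0("npc_", props), paste0("ipc_", props),
    paste0("rg_", 1:5), paste0("eleg_", 1:5), paste0("exg_", 1:6),
    paste0("hg_", 1:4), paste0("scg_", 1:6))
}

#' Protein feature blocks for a set of sequences
#'
#' @param sequences Named character vector (names are protein ids) or the
#'   data frame returned by [read_protein_fasta()].
#' @inheritParams basic_physicochemical
#' @return Numeric matrix, one row per protein, 107 named columns.
#' @export
protein_feature_matrix <- function(sequences, table = aa_property_table()) {
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$residues, sequences$id)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop_invalid("sequences must be uniquely named by protein id")
  }
  table <- validate_property_table(table)
  out <- t(vapply(sequences, protein_feature_block, numeric(107), table = table))
  rownames(out) <- names(sequences)
  out
}

#' Read protein sequences from a FASTA file
#'
#' The protein id is the first whitespace-delimited token of each header.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param permissive Passed to [validate_sequence()].
#' @return Data frame with columns `id` and `residues`.
#' @export
read_protein_fasta <- function(path, permissive = FALSE) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop_invalid("duplicate protein ids in FASTA")
  res <- vapply(as.character(set), validate_sequence, character(1),
                permissive = permissive, USE.NAMES = FALSE)
  data.frame(id = ids, residues = res, stringsAsFactors = FALSE)
}

#' Write protein feature blocks to CSV
#'
#' Stable 107-column header (`cv_A` ... `scg_6`) plus an `id` column.
#'
#' @param blocks Matrix from [protein_feature_matrix()].
#' @param path Output CSV path.
#' @export
write_protein_features <- function(blocks, path) {
  df <- data.frame(id = rownames(blocks), blocks, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
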
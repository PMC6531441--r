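# Ligand space: the 166-bit MACCS structural-key fingerprint per ligand.
#
# Keys are computed with the open MACCS SMARTS dictionary shipped with
# OpenBabel (via ChemmineOB). OpenBabel numbers the informative keys 1..166;
# we emit exactly those 166 bits, named maccs_1 ... maccs_166. Different
# MACCS dialects can disagree on individual substructure definitions; the
# pipeline consumes the bits generically, so the dictionary is a declared,
# fixed choice rather than a tunable.

N_MACCS <- 166L

maccs_names <- function() paste0("maccs_", seq_len(N_MACCS))

maccs_from_smiles <- function(smiles) {
  bits <- ChemmineOB::forEachMol("SMILES", smiles, function(mol) {
    ChemmineOB::fingerprint_OB(list(mol), "MACCS")
  })[[1]]
  as.integer(bits[seq_len(N_MACCS)])
}

#' MACCS fingerprint for one ligand
#'
#' Either computes the 166 informative MACCS keys from a SMILES string, or
#' validates and passes through a pre-computed bit vector.
#'
#' @param smiles SMILES string (ignored when `bits` is supplied).
#' @param bits Optional pre-computed fingerprint: 166 values in \{0, 1\}.
#' @return Named integer vector of 166 bits.
#' @export
maccs_fingerprint <- function(smiles = NULL, bits = NULL) {
  if (!is.null(bits)) {
    bits <- as.integer(bits)
    if (length(bits) != N_MACCS) {
      stop_invalid(sprintf("fingerprint must have %d bits, got %d", N_MACCS, length(bits)))
    }
    if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
      stop_invalid("fingerprint bits must all be 0 or 1")
    }
    return(stats::setNames(bits, maccs_names()))
  }
  if (is.null(smiles) || !nzchar(smiles)) {
    stop_invalid("either a SMILES structure or a bit vector must be supplied")
  }
  out <- tryCatch(maccs_from_smiles(smiles), error = function(e) {
    stop_invalid(sprintf("could not parse structure '%s': %s", smiles, conditionMessage(e)))
  })
  stats::setNames(out, maccs_names())
}

#' Fingerprint a collection of ligands
#'
#' Unparsable structures are collected in a rejects report, never silently
#' dropped.
#'
#' @param ligands Data frame with columns `id` and `smiles` (e.g. from
#'   [read_smiles()]), or a named character vector of SMILES.
#' @return List with `fingerprints` (n_valid x 166 binary matrix, rows named
#'   by ligand id) and `rejects` (data frame of id + error message).
#' @export
fingerprint_table <- function(ligands) {
  if (is.character(ligands)) {
    ligands <- data.frame(id = names(ligands) %||% as.character(seq_along(ligands)),
                          smiles = unname(ligands), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ligands$id)) stop_invalid("duplicate ligand ids")
  n <- nrow(ligands)
  fps <- matrix(0L, nrow = 0L, ncol = N_MACCS, dimnames = list(NULL, maccs_names()))
  rej <- data.frame(id = character(0), error = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(list(fingerprints = fps, rejects = rej))
  rows <- vector("list", n)
  ok <- logical(n)
  errs <- character(n)
  for (i in seq_len(n)) {
    r <- tryCatch(maccs_fingerprint(ligands$smiles[i]), error = function(e) e)
    if (inherits(r, "error")) {
      errs[i] <- conditionMessage(r)
    } else {
      rows[[i]] <- r
      ok[i] <- TRUE
    }
  }
  if (any(ok)) {
    fps <- do.call(rbind, rows[ok])
    rownames(fps) <- ligands$id[ok]
  }
  if (any(!ok)) {
    rej <- data.frame(id = ligands$id[!ok], error = errs[!ok], stringsAsFactors = FALSE)
  }
  list(fingerprints = fps, rejects = rej)
}

#' Read a SMILES file
#'
#' One record per line: `SMILES<TAB>id` (a single space also accepted).
#' Lines starting with `#` and blank lines are skipped.
#'
#' @param path Path to the SMILES file.
#' @return Data frame with columns `id` and `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "[\t ]+")
  smiles <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][2L] else sprintf("ligand_%d", i)
  }, character(1))
  if (anyDuplicated(ids)) stop_invalid("duplicate ligand ids in SMILES file")
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Read a pre-computed fingerprint table from CSV
#'
#' Expects an `id` column plus 166 bit columns named `maccs_1` ...
#' `maccs_166` (the format written by [write_fingerprints()]).
#'
#' @param path Path to the CSV file.
#' @return Binary matrix with rows named by ligand id.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop_invalid("fingerprint CSV must have an 'id' column")
  if (!all(maccs_names() %in% names(df))) {
    stop_invalid("fingerprint CSV must have columns maccs_1 ... maccs_166")
  }
  if (anyDuplicated(df$id)) stop_invalid("duplicate ligand ids in fingerprint CSV")
  m <- as.matrix(df[, maccs_names()])
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L))) stop_invalid("fingerprint bits must all be 0 or 1")
  rownames(m) <- df$id
  m
}

#' Write a fingerprint matrix to CSV
#' @param fps Binary matrix with rows named by ligand id.
#' @param path Output CSV path.
#' @export
write_fingerprints <- function(fps, path) {
  df <- data.frame(id = rownames(fps), fps, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
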
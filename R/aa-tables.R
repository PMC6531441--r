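# Reference tables for the protein space: the canonical residue alphabet, the
# default seven-property physicochemical scale table, and the five residue
# groupings used by the group-composition feature sets.

#' The 20 canonical amino acids, alphabetically by one-letter code
#'
#' All composition-style descriptors index residues in this fixed order
#' (A, C, D, E, ..., Y).
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Default physicochemical property scales
#'
#' A 20 x 7 table of per-residue values for the seven properties consumed by
#' the physicochemical descriptors (BPC, NPC, IPC): hydrophobicity
#' (Kyte-Doolittle), net side-chain charge at neutral pH, polarity (Grantham),
#' residue volume in cubic Angstroms (Zamyatnin), average chain flexibility
#' (Bhaskaran-Ponnuswamy), isoelectric point (Zimmerman), and molar
#' refractivity (Jones). Rows are the 20 canonical residues in alphabetical
#' order. These are widely used literature scales; any user-supplied table
#' with the same shape (see [read_property_table()]) may be substituted, and
#' descriptor values are reproducible only under a declared table.
#'
#' @return Numeric matrix, 20 rows (residues) x 7 named columns.
#' @export
aa_property_table <- function() {
  aa <- amino_acids()
  tab <- cbind(
    hydrophobicity = c( 1.8,  2.5, -3.5, -3.5,  2.8, -0.4, -3.2,  4.5, -3.9,  3.8,
                        1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7,  4.2, -0.9, -1.3),
    charge         = c( 0,    0,   -1,   -1,    0,    0,    0,    0,    1,    0,
                        0,    0,    0,    0,    1,    0,    0,    0,    0,    0),
    polarity       = c( 8.1,  5.5, 13.0, 12.3,  5.2,  9.0, 10.4,  5.2, 11.3,  4.9,
                        5.7, 11.6,  8.0, 10.5, 10.5,  9.2,  8.6,  5.9,  5.4,  6.2),
    volume         = c( 88.6, 108.5, 111.1, 138.4, 189.9, 60.1, 153.2, 166.7, 168.6, 166.7,
                       162.9, 114.1, 112.7, 143.8, 173.4, 89.0, 116.1, 140.0, 227.8, 193.6),
    flexibility    = c(0.357, 0.346, 0.511, 0.497, 0.314, 0.544, 0.323, 0.462, 0.466, 0.365,
                       0.295, 0.463, 0.509, 0.493, 0.529, 0.507, 0.444, 0.386, 0.305, 0.420),
    isoelectric    = c( 6.00, 5.05, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02, 9.74, 5.98,
                        5.74, 5.41, 6.30, 5.65, 10.76, 5.68, 5.66, 5.96, 5.89, 5.66),
    refractivity   = c( 4.34, 35.77, 12.00, 17.26, 29.40, 0.00, 21.81, 19.06, 21.29, 18.78,
                       21.64, 13.28, 10.93, 17.56, 26.66, 6.35, 11.01, 13.92, 42.53, 31.53)
  )
  rownames(tab) <- aa
  tab
}

#' Read a physicochemical property table from CSV
#'
#' The file must have a residue-letter column (named `residue` or the first
#' column) plus seven numeric property columns covering all 20 canonical
#' residues.
#'
#' @param path Path to a CSV file.
#' @return Numeric matrix, 20 x 7, rows ordered alphabetically by residue.
#' @export
read_property_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rescol <- if ("residue" %in% names(df)) "residue" else names(df)[1]
  res <- toupper(as.character(df[[rescol]]))
  df <- df[, setdiff(names(df), rescol), drop = FALSE]
  validate_property_table(as.matrix(df), res)
}

validate_property_table <- function(tab, residues = rownames(tab)) {
  aa <- amino_acids()
  if (is.null(residues) || !setequal(residues, aa)) {
    stop_invalid("property table must cover exactly the 20 canonical residues")
  }
  tab <- as.matrix(tab)
  if (ncol(tab) != 7L) {
    stop_invalid(sprintf("property table must have 7 property columns, got %d", ncol(tab)))
  }
  storage.mode(tab) <- "double"
  if (any(!is.finite(tab))) stop_invalid("property table contains non-finite values")
  rownames(tab) <- residues
  tab <- tab[aa, , drop = FALSE]
  if (any(apply(tab, 2, stats::sd) == 0)) {
    stop_invalid("each property must vary across residues (zero-variance column found)")
  }
  tab
}

# Standardized copy used by the index-based descriptor: per property, mean 0
# and (sample) standard deviation 1 across the 20 residues.
standardize_property_table <- function(tab) {
  scale(tab, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Residue grouping schemes for the group-composition feature sets
#'
#' Returns one of the five fixed groupings: `rg` (R-group chemistry, 5
#' groups), `eleg` (electronic donor/acceptor character, 5 groups; cysteine
#' belongs to none), `exg` (evolutionary exchange groups, 6), `hg`
#' (hydrophobicity classes, 4), `scg` (side-chain attribute groups, 6;
#' groups overlap so a residue may count in several).
#'
#' @param name One of `"rg"`, `"eleg"`, `"exg"`, `"hg"`, `"scg"`.
#' @return Named list of character vectors (the residue groups, in order).
#' @export
aa_grouping <- function(name) {
  groupings <- list(
    rg = list(
      rg_1 = c("A", "G", "I", "L", "M", "V"),   # non-polar aliphatic
      rg_2 = c("C", "N", "P", "Q", "S", "T"),   # polar uncharged
      rg_3 = c("H", "K", "R"),                  # positively charged
      rg_4 = c("D", "E"),                       # negatively charged
      rg_5 = c("F", "W", "Y")                   # aromatic
    ),
    eleg = list(
      eleg_1 = c("A", "D", "E", "P"),           # electron donor
      eleg_2 = c("I", "L", "V"),                # weak donor
      eleg_3 = c("K", "N", "R"),                # electron acceptor
      eleg_4 = c("F", "M", "Q", "T", "Y"),      # weak acceptor
      eleg_5 = c("G", "H", "S", "W")            # neutral; C unassigned
    ),
    exg = list(
      exg_1 = "C",
      exg_2 = c("A", "G", "P", "S", "T"),
      exg_3 = c("D", "E", "N", "Q"),
      exg_4 = c("H", "K", "R"),
      exg_5 = c("I", "L", "M", "V"),
      exg_6 = c("F", "W", "Y")
    ),
    hg = list(
      hg_1 = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y"),
      hg_2 = c("H", "K", "R"),
      hg_3 = c("D", "E"),
      hg_4 = c("N", "Q", "S", "T")
    ),
    scg = list(
      scg_1 = c("A", "G"),                                          # tiny
      scg_2 = c("F", "H", "R", "W", "Y"),                           # bulky
      scg_3 = c("D", "E"),                                          # polar uncharged
      scg_4 = c("D", "E", "H", "I", "K", "L", "R", "V"),            # charged
      scg_5 = c("D", "E", "K", "N", "Q", "R", "S", "T", "W", "Y"),  # polar
      scg_6 = c("F", "H", "W", "Y")                                 # aromatic
    )
  )
  if (!name %in% names(groupings)) {
    stop_invalid(sprintf("unknown grouping '%s' (expected rg/eleg/exg/hg/scg)", name))
  }
  groupings[[name]]
}
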
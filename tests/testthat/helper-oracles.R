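# Independent reference implementations and tiny fixture builders used
# across the suite. These deliberately use direct summation / enumeration,
# not the package's vectorized code paths.

# O(N^2) direct-summation reference for the index-based physicochemical
# descriptor: nested loops over lag and position on the standardized scales.
ipc_oracle <- function(residues, table = aa_property_table()) {
  z_tab <- scale(table)
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  out <- numeric(ncol(table))
  for (j in seq_len(ncol(table))) {
    z <- z_tab[chars, j]
    total <- 0
    for (k in seq_len(n - 1)) {
      dsum <- 0
      for (i in seq_len(n - k)) {
        dsum <- dsum + (z[i + k] - z[i])^2
      }
      total <- total + dsum / (n - k)
    }
    out[j] <- total / (n - 1)
  }
  out
}

# Rank-statistic (Wilcoxon-Mann-Whitney) reference for the AUC: probability
# that a random positive outranks a random negative, ties counted 1/2.
auc_oracle <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Per-bit direct summation reference for the interaction-space average.
maccsp_oracle <- function(protein_id, network, fps) {
  out <- numeric(ncol(fps))
  n <- 0
  for (e in seq_len(nrow(network))) {
    if (network$protein_id[e] == protein_id) {
      n <- n + 1
      for (j in seq_len(ncol(fps))) {
        out[j] <- out[j] + fps[network$ligand_id[e], j]
      }
    }
  }
  if (n > 0) out / n else out
}

random_sequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(amino_acids(), n, replace = TRUE), collapse = "")
}

# A tiny ligand universe with hand-set fingerprints.
tiny_fps <- function(n = 4L) {
  fps <- matrix(0L, nrow = n, ncol = 166,
                dimnames = list(paste0("L", seq_len(n)),
                                paste0("maccs_", 1:166)))
  set.seed(99)
  for (i in seq_len(n)) fps[i, sample(166, 30)] <- 1L
  fps
}

tiny_network <- function() {
  interaction_network(data.frame(
    protein_id = c("P1", "P1", "P2"),
    ligand_id = c("L1", "L2", "L3")
  ))
}

# Small linearly separable two-feature problem (classes gap-separated on x1).
separable_xy <- function(n = 20L, seed = 42L) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- cbind(x1 = 3 * y + runif(n, -1, 1), x2 = rnorm(n))
  list(X = X, y = y)
}
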
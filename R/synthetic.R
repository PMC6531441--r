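# Synthetic proteins, ligands and interaction networks with planted,
# tunable signal, so that every pipeline stage is testable without external
# databases.
#
# Signal is planted at the class/prototype level: protein classes have
# distinct residue-frequency profiles, ligands are bit-flipped copies of
# prototype fingerprints, and edges follow a random class x prototype
# compatibility table. Because a protein's partners concentrate on
# compatible prototypes, the interaction-space average (MACCSP) genuinely
# carries information -- the mechanism the bow space exploits. At signal 0
# the network is pure bipartite noise and positives/negatives become
# feature-exchangeable.
#
# Entities are split into a "gold" set (whose edges become labelled
# positives) and a disjoint "pool" set used for negative sampling. Pool
# entities keep their own background interactions -- a known interactome
# larger than the gold standard -- so that a pool protein's MACCSP is not
# trivially zero and the labels cannot be separated by orphan-ness alone.
#
# Crucially, every entity participates in exactly ONE labelled pair
# (positives form a matching over gold entities; negatives pair pool
# entities bijectively). Because negatives use entities disjoint from the
# positives, any entity appearing in several labelled pairs would make its
# identity -- recoverable from its near-unique descriptors -- a perfect
# label predictor under pair-level cross-validation, regardless of planted
# signal. One pair per entity removes that shortcut, so measured AUC
# reflects generalization over the planted compatibility structure alone.

#' Configuration for the synthetic benchmark generator
#'
#' @param n_proteins,n_ligands Entity counts (defaults 2200 and 2600: one
#'   labelled pair consumes one protein and one ligand, so ~1000 positives
#'   plus ~1000 negatives need ~2200 entities per side with headroom, and a
#'   little extra ligand supply keeps the positive matching on compatible
#'   pairs).
#' @param n_protein_classes Number of protein classes with distinct
#'   residue-frequency profiles (default 25).
#' @param n_ligand_prototypes Number of ligand scaffold prototypes
#'   (default 50). Keeping classes and prototypes numerous relative to the
#'   compatible fraction makes a random protein-ligand pairing unlikely to
#'   be compatible, which is what separates labelled positives from sampled
#'   negatives.
#' @param length_range Protein length range, uniform draw (default 80-300).
#' @param concentration Dirichlet concentration of class residue profiles;
#'   larger values make classes harder to tell apart (default 8).
#' @param bit_flip_rate Per-bit flip probability applied to a ligand's
#'   prototype fingerprint (default 0.08).
#' @param density Marginal edge probability (default 0.01, i.e. a mean
#'   interactome degree of about 22 partners per protein at the default
#'   sizes, independent of `signal`).
#' @param signal Strength of the planted compatibility signal in \[0, 1\]:
#'   edge probability is
#'   `density * ((1 - signal) + signal * compat / mean(compat))`, so
#'   `signal = 0` is pure bipartite noise at rate `density` and `signal = 1`
#'   confines edges to compatible class/prototype blocks (default 0.9).
#' @param n_positive Target number of labelled positive pairs (default 1000).
#' @param neg_ratio Negative:positive ratio (default 1, balanced).
#' @param gold_fraction Fraction of entities assigned to the gold set; the
#'   rest form the disjoint negative pools (default 0.52).
#' @param pair_mode How labelled pairs use entities. `"matched"` (default):
#'   every protein and every ligand occurs in at most one labelled pair, so
#'   cross-validated performance measures generalization over the planted
#'   compatibility structure only. `"pooled"`: entities are reused across
#'   pairs exactly as in the classical gold-standard protocol (positives
#'   reuse gold entities; negatives come from disjoint pools), in which case
#'   entity identity itself separates the labels and cross-validated
#'   performance includes a transductive entity-recognition component. See
#'   [pooled_benchmark_config()] for sizes suited to that mode.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return List of class `benchmark_config`.
#' @export
benchmark_config <- function(n_proteins = 2200L, n_ligands = 3200L,
                             n_protein_classes = 12L, n_ligand_prototypes = 12L,
                             length_range = c(80L, 300L), concentration = 4,
                             bit_flip_rate = 0.04, density = 0.015, signal = 0.9,
                             n_positive = 1000L, neg_ratio = 1,
                             gold_fraction = 0.52, pair_mode = c("matched", "pooled"),
                             seed = 1L) {
  pair_mode <- match.arg(pair_mode)
  cfg <- list(n_proteins = as.integer(n_proteins), n_ligands = as.integer(n_ligands),
              n_protein_classes = as.integer(n_protein_classes),
              n_ligand_prototypes = as.integer(n_ligand_prototypes),
              length_range = as.integer(length_range), concentration = concentration,
              bit_flip_rate = bit_flip_rate, density = density, signal = signal,
              n_positive = as.integer(n_positive), neg_ratio = neg_ratio,
              gold_fraction = gold_fraction, pair_mode = pair_mode,
              seed = as.integer(seed))
  counts <- c(cfg$n_proteins, cfg$n_ligands, cfg$n_protein_classes,
              cfg$n_ligand_prototypes, cfg$n_positive)
  if (any(counts < 1L)) stop_invalid("all counts must be >= 1")
  if (length(cfg$length_range) != 2L || cfg$length_range[1] > cfg$length_range[2]) {
    stop_invalid("length_range must be an increasing pair")
  }
  if (cfg$length_range[1] < 3L) stop_invalid("minimum protein length is 3")
  rates <- c(cfg$bit_flip_rate, cfg$density, cfg$signal, cfg$gold_fraction)
  if (any(rates < 0 | rates > 1)) stop_invalid("rates must lie in [0, 1]")
  if (cfg$concentration <= 0) stop_invalid("concentration must be positive")
  class(cfg) <- "benchmark_config"
  cfg
}

#' Configuration for a pooled-protocol benchmark
#'
#' Convenience wrapper around [benchmark_config()] with
#' `pair_mode = "pooled"` and sizes fitting the classical gold-standard
#' protocol: 100 proteins, 200 ligands, 4 protein classes, 8 ligand
#' prototypes, edge density 0.35, ~1000 positives with entity reuse.
#' Cross-validated performance under this protocol includes an
#' entity-recognition component (see [benchmark_config()]).
#'
#' @param ... Overrides passed on to [benchmark_config()].
#' @return List of class `benchmark_config`.
#' @export
pooled_benchmark_config <- function(...) {
  defaults <- list(n_proteins = 100L, n_ligands = 200L, n_protein_classes = 4L,
                   n_ligand_prototypes = 8L, density = 0.35,
                   gold_fraction = 0.5, pair_mode = "pooled")
  override <- list(...)
  defaults[names(override)] <- override
  do.call(benchmark_config, defaults)
}

rdirichlet1 <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration)
  g / sum(g)
}

#' Simulate class-structured protein sequences
#'
#' Each class draws a residue-frequency profile once from a symmetric
#' Dirichlet with the configured concentration; each protein samples its
#' residues i.i.d. from its class profile, with length uniform in the
#' configured range.
#'
#' @param config A [benchmark_config()].
#' @return Data frame with columns `id`, `residues`, `class`.
#' @export
simulate_proteins <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  withr_seed(derive_seed(config$seed, 1L), {
    profiles <- replicate(config$n_protein_classes,
                          rdirichlet1(20L, config$concentration))
    cls <- sample(rep_len(seq_len(config$n_protein_classes), config$n_proteins))
    lens <- sample(seq(config$length_range[1], config$length_range[2]),
                   config$n_proteins, replace = TRUE)
    res <- vapply(seq_len(config$n_proteins), function(i) {
      paste(sample(amino_acids(), lens[i], replace = TRUE, prob = profiles[, cls[i]]),
            collapse = "")
    }, character(1))
    data.frame(id = sprintf("P%04d", seq_len(config$n_proteins)),
               residues = res, class = cls, stringsAsFactors = FALSE)
  })
}

#' Simulate prototype-derived ligand fingerprints
#'
#' Each prototype's 166-bit pattern is the union of a small block of
#' signature keys exclusive to that prototype (chemical scaffolds light up
#' characteristic structural keys) and a random shared background at bit
#' density 0.12; each ligand copies its prototype's pattern and flips every
#' bit independently at the configured rate.
#'
#' @param config A [benchmark_config()].
#' @return List with `fingerprints` (n_ligands x 166 binary matrix, rows
#'   named by ligand id), `prototype` (integer vector) and `prototypes`
#'   (the prototype bit patterns).
#' @export
simulate_ligands <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  withr_seed(derive_seed(config$seed, 2L), {
    q <- config$n_ligand_prototypes
    protos <- matrix(stats::rbinom(q * N_MACCS, 1L, 0.12), nrow = q)
    # signature blocks use at most half the keys so fingerprints keep a
    # realistic shared background
    sig_width <- max(1L, (N_MACCS %/% 2L) %/% q)
    sig_bits <- sample.int(N_MACCS)   # disjoint signature blocks, random keys
    used_sig <- sig_bits[seq_len(min(q * sig_width, N_MACCS))]
    protos[, used_sig] <- 0L          # signature keys stay exclusive
    for (i in seq_len(q)) {
      lo <- (i - 1L) * sig_width + 1L
      if (lo > N_MACCS) break
      protos[i, sig_bits[lo:min(i * sig_width, N_MACCS)]] <- 1L
    }
    proto_of <- sample(rep_len(seq_len(q), config$n_ligands))
    flips <- matrix(stats::rbinom(config$n_ligands * N_MACCS, 1L, config$bit_flip_rate),
                    nrow = config$n_ligands)
    fps <- (protos[proto_of, , drop = FALSE] + flips) %% 2L
    dimnames(fps) <- list(sprintf("L%04d", seq_len(config$n_ligands)), maccs_names())
    list(fingerprints = fps, prototype = stats::setNames(proto_of, rownames(fps)),
         prototypes = protos)
  })
}

#' Simulate a compatibility-driven bipartite interaction network
#'
#' Compatibility between protein classes and ligand prototypes is
#' class-specific: prototypes are dealt round-robin to classes (so every
#' class owns a couple of scaffolds and every scaffold has a cognate
#' class), with additional sparse off-block compatibilities. The edge
#' (p, l) is then included independently with probability
#' `density * ((1 - signal) + signal * compat(class_p, proto_l) / mean(compat))`,
#' capped at 1. The `1/mean(compat)` normalization keeps the expected edge
#' count at `n_proteins * n_ligands * density` for every signal level, so
#' `signal = 0` yields pure bipartite noise at rate `density`, `signal = 1`
#' confines edges to compatible blocks, and in between a fraction `signal`
#' of edge mass concentrates on compatible cells.
#'
#' @param config A [benchmark_config()].
#' @param protein_classes Named integer vector (protein id -> class).
#' @param ligand_prototypes Named integer vector (ligand id -> prototype).
#' @return An [interaction_network()]; the compatibility table is attached
#'   as attribute `"compat"`.
#' @export
simulate_network <- function(config, protein_classes, ligand_prototypes) {
  stopifnot(inherits(config, "benchmark_config"))
  withr_seed(derive_seed(config$seed, 3L), {
    K <- config$n_protein_classes
    Q <- config$n_ligand_prototypes
    # class-specific compatibility: prototypes are dealt round-robin to
    # classes (each class owns a few scaffolds no other class prefers), plus
    # sparse off-block compatibilities for texture. Diverse per-class sets
    # keep a random pairing rarely compatible while leaving every class
    # enough compatible ligands to draw labelled positives from.
    owner <- rep_len(seq_len(K), Q)[sample.int(Q)]
    compat <- matrix(0L, nrow = K, ncol = Q)
    compat[cbind(owner, seq_len(Q))] <- 1L
    extra <- matrix(stats::runif(K * Q) < 0.02, nrow = K)
    compat[extra] <- 1L
    cell_prob <- config$density *
      ((1 - config$signal) + config$signal * compat / mean(compat))
    cell_prob <- pmin(cell_prob, 1)
    # edge probabilities over the full bipartite grid, one cell per pair
    P <- cell_prob[cbind(rep(protein_classes, times = length(ligand_prototypes)),
                         rep(ligand_prototypes, each = length(protein_classes)))]
    hit <- stats::runif(length(P)) < P
    pi <- ((seq_along(P) - 1L) %% length(protein_classes)) + 1L
    li <- ((seq_along(P) - 1L) %/% length(protein_classes)) + 1L
    net <- interaction_network(data.frame(
      protein_id = names(protein_classes)[pi[hit]],
      ligand_id = names(ligand_prototypes)[li[hit]],
      stringsAsFactors = FALSE))
    attr(net, "compat") <- compat
    net
  })
}

pair_key <- function(p, l) paste(p, l, sep = "\r")

#' Generate a complete labelled benchmark
#'
#' Runs the whole upstream pipeline: simulates entities and a network,
#' splits entities into a gold set and a disjoint negative pool, labels gold
#' edges as positives and samples pool non-edges as negatives, computes
#' protein feature blocks, assembles the bow feature matrix, and produces a
#' stratified 70/30 split plus 10-fold assignment.
#'
#' The interaction network used for the MACCSP average always includes the
#' background (non-labelled) interactions. With the default
#' `maccsp_edges = "loo"` every labelled pair's own edge is left out of its
#' own MACCSP average (leave-one-out), so no pair's descriptor encodes its
#' own label; because each entity occurs in exactly one labelled pair, this
#' also keeps train and held-out descriptors identically distributed.
#' `maccsp_edges = "train"` instead drops the test portion's positive edges
#' from the averaging network (so training rows keep their own edge), and
#' `maccsp_edges = "all"` is the permissive variant averaging every known
#' edge.
#'
#' @param config A [benchmark_config()].
#' @param maccsp_edges `"loo"` (default), `"train"` or `"all"`.
#' @return Object of class `bow_benchmark`: pairs, labels `y`, feature
#'   matrix `X` (439 columns), protein blocks, fingerprints, the full
#'   network, the labelled positives, split and folds.
#' @export
make_benchmark <- function(config = benchmark_config(),
                           maccsp_edges = c("loo", "train", "all")) {
  stopifnot(inherits(config, "benchmark_config"))
  maccsp_edges <- match.arg(maccsp_edges)
  prot <- simulate_proteins(config)
  lig <- simulate_ligands(config)
  net <- simulate_network(config,
                          stats::setNames(prot$class, prot$id),
                          lig$prototype)
  gold <- withr_seed(derive_seed(config$seed, 4L), {
    list(proteins = sample(prot$id, round(config$gold_fraction * nrow(prot))),
         ligands = sample(rownames(lig$fingerprints),
                          round(config$gold_fraction * nrow(lig$fingerprints))))
  })
  pool_proteins <- setdiff(prot$id, gold$proteins)
  pool_ligands <- setdiff(rownames(lig$fingerprints), gold$ligands)

  gold_edges <- net[net$protein_id %in% gold$proteins &
                      net$ligand_id %in% gold$ligands, , drop = FALSE]
  if (nrow(gold_edges) < 10L) {
    stop_infeasible("too few gold-set edges simulated; increase density or entity counts")
  }
  if (config$pair_mode == "matched") {
    # positives: a matching over gold entities (greedy on shuffled edges),
    # so no entity appears in more than one labelled pair
    positives <- withr_seed(derive_seed(config$seed, 5L), {
      ord <- sample(seq_len(nrow(gold_edges)))
      used_p <- new.env(hash = TRUE, parent = emptyenv())
      used_l <- new.env(hash = TRUE, parent = emptyenv())
      keep <- integer(0)
      for (i in ord) {
        p <- gold_edges$protein_id[i]
        l <- gold_edges$ligand_id[i]
        if (is.null(used_p[[p]]) && is.null(used_l[[l]])) {
          keep <- c(keep, i)
          used_p[[p]] <- TRUE
          used_l[[l]] <- TRUE
          if (length(keep) >= config$n_positive) break
        }
      }
      build_positive_set(interaction_network(gold_edges[sort(keep), , drop = FALSE]))
    })
    # negatives: pool proteins paired bijectively with pool ligands (one
    # pair per entity), dropping any pairing that is an interactome edge
    n_neg <- max(1L, round(config$neg_ratio * nrow(positives)))
    negatives <- withr_seed(derive_seed(config$seed, 6L), {
      np <- sample(pool_proteins)
      nl <- sample(pool_ligands)
      len <- min(length(np), length(nl))
      cand <- data.frame(protein_id = np[seq_len(len)], ligand_id = nl[seq_len(len)],
                         stringsAsFactors = FALSE)
      is_edge <- pair_key(cand$protein_id, cand$ligand_id) %in%
        pair_key(net$protein_id, net$ligand_id)
      cand <- cand[!is_edge, , drop = FALSE]
      if (nrow(cand) < n_neg) {
        stop_infeasible("negative pool too small for one-pair-per-entity sampling")
      }
      cand <- cand[seq_len(n_neg), , drop = FALSE]
      cand$label <- 0L
      cand
    })
  } else {
    # pooled protocol: positives subsample gold edges with entity reuse;
    # negatives are uniform draws from the disjoint pool cross product
    positives <- withr_seed(derive_seed(config$seed, 5L), {
      take <- if (nrow(gold_edges) > config$n_positive) {
        sort(sample(seq_len(nrow(gold_edges)), config$n_positive))
      } else seq_len(nrow(gold_edges))
      build_positive_set(interaction_network(gold_edges[take, , drop = FALSE]))
    })
    n_neg <- max(1L, round(config$neg_ratio * nrow(positives)))
    negatives <- sample_negative_pairs(pool_proteins, pool_ligands, n_neg,
                                       seed = derive_seed(config$seed, 6L),
                                       positives = positives, exclude = net)
  }
  pairs <- rbind(positives, negatives)
  rownames(pairs) <- NULL

  split <- train_test_split(pairs, 0.7, seed = derive_seed(config$seed, 7L))
  folds <- kfold(pairs, min(10L, nrow(pairs)), seed = derive_seed(config$seed, 8L))

  blocks <- protein_feature_matrix(
    stats::setNames(prot$residues, prot$id)[unique(pairs$protein_id)])
  network_for_maccsp <- if (maccsp_edges == "train") {
    test_pos <- intersect(split$test, seq_len(nrow(positives)))
    drop_keys <- pair_key(pairs$protein_id[test_pos], pairs$ligand_id[test_pos])
    keep <- !pair_key(net$protein_id, net$ligand_id) %in% drop_keys
    interaction_network(net[keep, , drop = FALSE])
  } else {
    net
  }
  X <- suppressWarnings(featurize_pairs(pairs, blocks, lig$fingerprints,
                                        network_for_maccsp,
                                        exclude_self = maccsp_edges == "loo"))
  structure(list(
    config = config, pairs = pairs, y = pairs$label, X = X,
    blocks = blocks, fingerprints = lig$fingerprints,
    network = net, positives = positives,
    split = split, folds = folds,
    protein_classes = stats::setNames(prot$class, prot$id),
    ligand_prototypes = lig$prototype,
    proteins = prot, maccsp_edges = maccsp_edges
  ), class = "bow_benchmark")
}

#' @export
print.bow_benchmark <- function(x, ...) {
  cat(sprintf("synthetic bow benchmark: %d pairs (%d positive / %d negative)\n",
              nrow(x$pairs), sum(x$y == 1), sum(x$y == 0)))
  cat(sprintf("  %d proteins, %d ligands, %d network edges, signal %.2f\n",
              x$config$n_proteins, x$config$n_ligands, nrow(x$network),
              x$config$signal))
  invisible(x)
}

#' Leakage-controlled k-fold cross-validation on a benchmark
#'
#' Features are assembled with leave-one-out MACCSP (each labelled pair's
#' own edge is excluded from its own interaction-space average, see
#' [featurize_pairs()]), so no descriptor encodes its own label and a
#' single featurization serves every fold. The classifier is trained on
#' each training fold and scored on the held-out fold; metrics pool the
#' out-of-fold scores.
#'
#' @param benchmark A [make_benchmark()] result.
#' @param spec A [classifier_spec()] or a (possibly named) list of specs;
#'   with a list, all classifiers share the fold assignment and the
#'   featurization.
#' @param k Number of folds (default 10).
#' @param subspace_mask Featurization mask (default `"all"`; e.g.
#'   `"protein+ligand"` ablates the interaction space).
#' @param seed Seed for the fold assignment (defaults to the benchmark's).
#' @return A `metrics_report` (see [crossval_report()]), or a named list of
#'   reports when `spec` is a list.
#' @export
crossval_bow <- function(benchmark, spec, k = 10L, subspace_mask = "all",
                         seed = NULL) {
  stopifnot(inherits(benchmark, "bow_benchmark"))
  specs <- if (inherits(spec, "classifier_spec")) list(spec) else spec
  stopifnot(all(vapply(specs, inherits, logical(1), "classifier_spec")))
  seed <- seed %||% derive_seed(benchmark$config$seed, 9L)
  folds <- kfold(benchmark$pairs, k, seed = seed)
  X <- suppressWarnings(featurize_pairs(benchmark$pairs, benchmark$blocks,
                                        benchmark$fingerprints, benchmark$network,
                                        subspace_mask, exclude_self = TRUE))
  reports <- lapply(specs, function(s) crossval_report(s, X, benchmark$y, folds))
  names(reports) <- vapply(specs, function(s) s$name, character(1))
  if (inherits(spec, "classifier_spec")) reports[[1]] else reports
}

#' Planted feature matrix for selection benchmarks
#'
#' Generates a binary outcome with `n_informative` columns shifted by
#' `effect` between the classes and `n_noise` pure-noise columns, the
#' standard planted design for validating all-relevant feature selection.
#'
#' @param n Number of rows (default 300).
#' @param n_informative,n_noise Column counts (defaults 5 and 50).
#' @param effect Mean shift between classes in the informative columns
#'   (default 1).
#' @param seed Integer seed.
#' @return List with `X` (columns `inf_1..`, `noise_1..`) and `y`.
#' @export
simulate_planted_features <- function(n = 300L, n_informative = 5L, n_noise = 50L,
                                      effect = 1, seed = 1L) {
  withr_seed(seed, {
    y <- stats::rbinom(n, 1L, 0.5)
    Xi <- matrix(stats::rnorm(n * n_informative), n) + effect * (y - 0.5)
    Xn <- matrix(stats::rnorm(n * n_noise), n)
    X <- cbind(Xi, Xn)
    colnames(X) <- c(paste0("inf_", seq_len(n_informative)),
                     paste0("noise_", seq_len(n_noise)))
    list(X = X, y = y)
  })
}

#' Write a benchmark's inputs in the pipeline's on-disk formats
#'
#' Emits `proteins.fasta`, `fingerprints.csv`, `edges.tsv` and `pairs.tsv`
#' under `dir`, so generated fixtures double as format round-trip tests.
#'
#' @param benchmark A [make_benchmark()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_benchmark_files <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::AAStringSet(stats::setNames(benchmark$proteins$residues,
                                                  benchmark$proteins$id))
  Biostrings::writeXStringSet(seqs, file.path(dir, "proteins.fasta"))
  write_fingerprints(benchmark$fingerprints, file.path(dir, "fingerprints.csv"))
  write_edge_list(benchmark$network, file.path(dir, "edges.tsv"))
  utils::write.table(benchmark$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
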
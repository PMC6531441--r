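# The synthetic benchmark generator.

small_cfg <- function(...) {
  defaults <- list(n_proteins = 60L, n_ligands = 90L, n_protein_classes = 3L,
                   n_ligand_prototypes = 6L, length_range = c(30L, 60L),
                   density = 0.05, n_positive = 15L)
  override <- list(...)
  defaults[names(override)] <- override
  do.call(benchmark_config, defaults)
}

test_that("configs validate counts, ranges and rates", {
  expect_error(benchmark_config(n_proteins = 0), class = "bow_invalid_input")
  expect_error(benchmark_config(length_range = c(2, 50)), class = "bow_invalid_input")
  expect_error(benchmark_config(length_range = c(50, 30)), class = "bow_invalid_input")
  expect_error(benchmark_config(signal = 1.2), class = "bow_invalid_input")
  expect_error(benchmark_config(concentration = 0), class = "bow_invalid_input")
  expect_equal(pooled_benchmark_config(seed = 3)$pair_mode, "pooled")
})

test_that("protein simulation is seed-deterministic with class structure", {
  cfg <- small_cfg(seed = 5L)
  p1 <- simulate_proteins(cfg)
  p2 <- simulate_proteins(cfg)
  expect_identical(p1, p2)
  expect_true(all(nchar(p1$residues) >= 30 & nchar(p1$residues) <= 60))
  expect_equal(sort(unique(p1$class)), 1:3)
  one_class <- simulate_proteins(small_cfg(n_protein_classes = 1L, seed = 5L))
  expect_equal(unique(one_class$class), 1L)
})

test_that("high concentration washes out class composition differences", {
  sharp <- simulate_proteins(small_cfg(concentration = 0.5, seed = 9L,
                                       n_proteins = 120L))
  flat <- simulate_proteins(small_cfg(concentration = 5000, seed = 9L,
                                      n_proteins = 120L))
  dist_between <- function(sim) {
    cv <- t(vapply(sim$residues, composition_vector, numeric(20)))
    centers <- apply(cv, 2, tapply, sim$class, mean)
    mean(dist(centers))
  }
  expect_gt(dist_between(sharp), 3 * dist_between(flat))
})

test_that("ligand simulation flips prototype bits at the configured rate", {
  cfg0 <- small_cfg(bit_flip_rate = 0, seed = 4L)
  lig0 <- simulate_ligands(cfg0)
  expect_identical(lig0$fingerprints[3, ],
                   stats::setNames(lig0$prototypes[lig0$prototype[3], ],
                                   colnames(lig0$fingerprints)))
  expect_identical(simulate_ligands(cfg0)$fingerprints, lig0$fingerprints)
  # at flip rate one half, bits are independent of the prototype
  cfg5 <- small_cfg(bit_flip_rate = 0.5, seed = 4L, n_ligands = 300L)
  lig5 <- simulate_ligands(cfg5)
  same_proto <- lig5$prototype[1] == lig5$prototype
  ham_to_proto <- rowMeans(lig5$fingerprints !=
    matrix(lig5$prototypes[lig5$prototype[1], ], nrow(lig5$fingerprints), 166,
           byrow = TRUE))
  expect_lt(abs(mean(ham_to_proto[same_proto]) - mean(ham_to_proto[!same_proto])), 0.05)
})

test_that("the network edge count follows the density at zero signal", {
  cfg <- small_cfg(signal = 0, seed = 8L, n_proteins = 100L, n_ligands = 100L)
  prot <- simulate_proteins(cfg)
  lig <- simulate_ligands(cfg)
  net <- simulate_network(cfg, setNames(prot$class, prot$id), lig$prototype)
  n_expected <- 100 * 100 * cfg$density
  sd3 <- 3 * sqrt(n_expected * (1 - cfg$density))
  expect_lt(abs(nrow(net) - n_expected), sd3)
  expect_identical(net, simulate_network(cfg, setNames(prot$class, prot$id),
                                         lig$prototype))
})

test_that("full signal confines edges to compatible blocks", {
  cfg <- small_cfg(signal = 1, seed = 12L)
  prot <- simulate_proteins(cfg)
  lig <- simulate_ligands(cfg)
  net <- simulate_network(cfg, setNames(prot$class, prot$id), lig$prototype)
  compat <- attr(net, "compat")
  cls <- setNames(prot$class, prot$id)
  expect_true(all(compat[cbind(cls[net$protein_id],
                               lig$prototype[net$ligand_id])] == 1L))
})

test_that("benchmarks deliver the 439-column contract with disjoint one-shot entities", {
  bm <- make_benchmark(small_cfg(seed = 2L))
  expect_equal(ncol(bm$X), 439L)
  expect_identical(colnames(bm$X), bow_feature_names())
  expect_equal(nrow(bm$X), nrow(bm$pairs))
  pos <- bm$pairs[bm$y == 1, ]
  neg <- bm$pairs[bm$y == 0, ]
  # negatives never share entities with positives
  expect_length(intersect(pos$protein_id, neg$protein_id), 0)
  expect_length(intersect(pos$ligand_id, neg$ligand_id), 0)
  # matched mode: every entity occurs exactly once
  expect_equal(anyDuplicated(bm$pairs$protein_id), 0L)
  expect_equal(anyDuplicated(bm$pairs$ligand_id), 0L)
  # negatives are non-edges
  expect_false(any(paste(neg$protein_id, neg$ligand_id) %in%
                     paste(bm$network$protein_id, bm$network$ligand_id)))
  # byte-identical regeneration from the same config
  bm2 <- make_benchmark(small_cfg(seed = 2L))
  expect_identical(bm$X, bm2$X)
  expect_identical(bm$pairs, bm2$pairs)
})

test_that("pooled benchmarks reuse gold entities but keep pools disjoint", {
  bm <- make_benchmark(pooled_benchmark_config(n_positive = 200L, seed = 6L))
  pos <- bm$pairs[bm$y == 1, ]
  neg <- bm$pairs[bm$y == 0, ]
  expect_gt(anyDuplicated(pos$protein_id), 0L)  # entity reuse in positives
  expect_length(intersect(pos$protein_id, neg$protein_id), 0)
  expect_length(intersect(pos$ligand_id, neg$ligand_id), 0)
})

test_that("planted feature sets have the documented shape and signal direction", {
  d <- simulate_planted_features(n = 120, n_informative = 3, n_noise = 7,
                                 effect = 2, seed = 13)
  expect_equal(dim(d$X), c(120L, 10L))
  expect_setequal(unique(d$y), c(0L, 1L))
  gap <- colMeans(d$X[d$y == 1, ]) - colMeans(d$X[d$y == 0, ])
  expect_true(all(gap[1:3] > 1))
  expect_true(all(abs(gap[4:10]) < 1))
  expect_identical(d, simulate_planted_features(n = 120, n_informative = 3,
                                                n_noise = 7, effect = 2, seed = 13))
})

test_that("benchmark files are emitted in the pipeline's own formats", {
  bm <- make_benchmark(small_cfg(seed = 2L))
  dir <- file.path(tempdir(), "bmfiles")
  write_benchmark_files(bm, dir)
  seqs <- read_protein_fasta(file.path(dir, "proteins.fasta"))
  expect_equal(nrow(seqs), 60L)
  fps <- read_fingerprints(file.path(dir, "fingerprints.csv"))
  expect_identical(unname(fps), unname(bm$fingerprints))
  net <- read_edge_list(file.path(dir, "edges.tsv"))
  expect_equal(nrow(net), nrow(bm$network))
})
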
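# Interaction-space averaging and assembly of the 439-dimensional pair
# descriptor.

test_that("MACCSP is the element-wise mean of the known ligands' fingerprints", {
  fps <- tiny_fps()
  net <- tiny_network()
  # one known ligand: the average IS that fingerprint
  expect_equal(unname(maccsp("P2", net, fps)), as.numeric(fps["L3", ]))
  # two known ligands: per-bit two-element mean
  expect_equal(unname(maccsp("P1", net, fps)),
               as.numeric((fps["L1", ] + fps["L2", ]) / 2))
  expect_warning(orphan <- maccsp("P9", net, fps), "no known ligands")
  expect_equal(unname(orphan), rep(0, 166))
})

test_that("MACCSP matches per-bit brute force, ignores duplicate edges, stays in bit bounds", {
  fps <- tiny_fps()
  net <- tiny_network()
  for (p in c("P1", "P2")) {
    expect_equal(unname(maccsp(p, net, fps)), maccsp_oracle(p, net, fps))
  }
  dup <- interaction_network(rbind(as.data.frame(net),
                                   data.frame(protein_id = "P1", ligand_id = "L1")))
  expect_equal(maccsp("P1", dup, fps), maccsp("P1", net, fps))
  mp <- maccsp("P1", net, fps)
  lo <- pmin(fps["L1", ], fps["L2", ])
  hi <- pmax(fps["L1", ], fps["L2", ])
  expect_true(all(mp >= lo & mp <= hi))
})

test_that("edges referencing unknown ligands raise a dangling-reference error", {
  fps <- tiny_fps()
  bad <- interaction_network(data.frame(protein_id = "P1", ligand_id = "L999"))
  expect_error(maccsp("P1", bad, fps), class = "bow_dangling_reference")
})

test_that("the assembled pair descriptor has 439 stable columns", {
  fps <- tiny_fps()
  net <- tiny_network()
  blocks <- protein_feature_matrix(c(P1 = random_sequence(40, seed = 1),
                                     P2 = random_sequence(50, seed = 2),
                                     P9 = random_sequence(60, seed = 3)))
  v <- assemble_bow("P1", "L1", blocks, fps, net)
  expect_length(v, 439)
  expect_identical(names(v), bow_feature_names())
  expect_identical(v, assemble_bow("P1", "L1", blocks, fps, net))
  orphan <- assemble_bow("P9", "L1", blocks, fps, net)
  expect_equal(unname(orphan[274:439]), rep(0, 166))
  expect_error(assemble_bow("PX", "L1", blocks, fps, net),
               class = "bow_dangling_reference")
  expect_error(assemble_bow("P1", "LX", blocks, fps, net),
               class = "bow_dangling_reference")
})

test_that("subspace masks restrict the feature matrix to documented widths", {
  fps <- tiny_fps()
  net <- tiny_network()
  blocks <- protein_feature_matrix(c(P1 = random_sequence(40, seed = 1),
                                     P2 = random_sequence(50, seed = 2)))
  pairs <- data.frame(protein_id = c("P1", "P2"), ligand_id = c("L1", "L3"))
  expect_equal(ncol(featurize_pairs(pairs, blocks, fps, net, "all")), 439L)
  expect_equal(ncol(featurize_pairs(pairs, blocks, fps, net, "protein+ligand")), 273L)
  expect_equal(ncol(featurize_pairs(pairs, blocks, fps, net, "protein")), 107L)
  expect_equal(ncol(featurize_pairs(pairs, blocks, fps, net, "ligand")), 166L)
  custom <- featurize_pairs(pairs, blocks, fps, net, c("cv_A", "maccsl_5"))
  expect_equal(colnames(custom), c("cv_A", "maccsl_5"))
  expect_error(featurize_pairs(pairs, blocks, fps, net, integer(0)),
               class = "bow_invalid_input")
  expect_equal(unname(table(bow_column_map())[c("protein", "ligand", "interaction")]),
               c(107L, 166L, 166L), ignore_attr = TRUE)
})

test_that("leave-one-out featurization removes only the pair's own edge", {
  fps <- tiny_fps()
  net <- tiny_network()
  blocks <- protein_feature_matrix(c(P1 = random_sequence(40, seed = 1),
                                     P2 = random_sequence(50, seed = 2)))
  pairs <- data.frame(protein_id = c("P1", "P1"), ligand_id = c("L1", "L4"))
  X <- featurize_pairs(pairs, blocks, fps, net, exclude_self = TRUE)
  mp_cols <- grep("^maccsp_", colnames(X))
  # (P1, L1) is an edge: average over the remaining partner L2 only
  expect_equal(unname(X[1, mp_cols]), as.numeric(fps["L2", ]))
  # (P1, L4) is not an edge: full two-ligand average is untouched
  expect_equal(unname(X[2, mp_cols]), as.numeric((fps["L1", ] + fps["L2", ]) / 2))
  # a single-ligand protein loses its only partner under leave-one-out
  p2 <- data.frame(protein_id = "P2", ligand_id = "L3")
  X2 <- featurize_pairs(p2, blocks, fps, net, exclude_self = TRUE)
  expect_equal(unname(X2[1, mp_cols]), rep(0, 166))
})

test_that("edge lists round-trip through TSV with comments and duplicates collapsed", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# known interactions", "P1\tL1", "P1\tL2", "P1\tL1"), f)
  net <- read_edge_list(f)
  expect_equal(nrow(net), 2L)
  out <- tempfile(fileext = ".tsv")
  write_edge_list(net, out)
  expect_equal(read_edge_list(out), net)
})
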
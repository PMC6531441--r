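# Protein-space descriptors: the ten sequence feature sets.

test_that("composition vector matches hand-computed fractions and sums to 1", {
  expect_equal(unname(composition_vector("AAAA")[1]), 1)
  expect_equal(sum(composition_vector("AAAA")), 1)
  cv <- composition_vector("ACDE")
  expect_equal(unname(cv[c("cv_A", "cv_C", "cv_D", "cv_E")]), rep(0.25, 4))
  expect_equal(sum(cv == 0), 16)
  cv2 <- composition_vector("ACA")
  expect_equal(unname(cv2["cv_A"]), 2 / 3)
  expect_equal(unname(cv2["cv_C"]), 1 / 3)
  for (i in 1:10) {
    expect_equal(sum(composition_vector(random_sequence(50, seed = i))), 1)
  }
})

test_that("sequence validation rejects bad input and permissive mode filters", {
  expect_error(composition_vector(""), class = "bow_invalid_input")
  expect_error(composition_vector("ACDX"), class = "bow_invalid_input")
  expect_warning(out <- validate_sequence("ACXDZ", permissive = TRUE), "2 non-canonical")
  expect_equal(out, "ACD")
  expect_equal(validate_sequence("acd"), "ACD")
})

test_that("composition moment vector matches 1-based position sums", {
  cmv1 <- composition_moment_vector("ACD", 1)
  expect_equal(unname(cmv1[c("cmv1_A", "cmv1_C", "cmv1_D")]), c(1, 2, 3) / 6)
  cmv2 <- composition_moment_vector("ACD", 2)
  expect_equal(unname(cmv2[c("cmv2_A", "cmv2_C", "cmv2_D")]), c(1, 4, 9) / 6)
  expect_error(composition_moment_vector("AA", 2), class = "bow_degenerate_length")
  expect_error(composition_moment_vector("A", 1), class = "bow_degenerate_length")
})

test_that("order-0 composition moment vector collapses to the composition vector", {
  for (i in 1:100) {
    s <- random_sequence(sample(5:80, 1), seed = 1000 + i)
    expect_equal(unname(composition_moment_vector(s, 0)),
                 unname(composition_vector(s)))
  }
})

test_that("basic physicochemical sums are additive over concatenation", {
  tab <- aa_property_table()
  expect_equal(unname(basic_physicochemical("AA")), unname(2 * tab["A", ]))
  s1 <- random_sequence(30, seed = 5)
  s2 <- random_sequence(40, seed = 6)
  expect_equal(basic_physicochemical(paste0(s1, s2)),
               basic_physicochemical(s1) + basic_physicochemical(s2))
  bad <- tab
  bad[1, 1] <- NA
  expect_error(basic_physicochemical("AC", bad), class = "bow_invalid_input")
})

test_that("neighbourhood descriptor is zero on homopolymers, interior-only otherwise", {
  expect_equal(unname(neighbourhood_physicochemical("AAA")), rep(0, 7))
  expect_equal(unname(neighbourhood_physicochemical(strrep("W", 25))), rep(0, 7))
  tab <- aa_property_table()
  expect_equal(unname(neighbourhood_physicochemical("ACA")),
               unname(abs(tab["C", ]^2 - tab["A", ] * tab["A", ])))
  expect_warning(out <- neighbourhood_physicochemical("AC"), "shorter than 3")
  expect_equal(unname(out), rep(0, 7))
})

test_that("index descriptor matches its closed form on two residues and is zero on homopolymers", {
  expect_equal(unname(index_physicochemical("GGGG")), rep(0, 7))
  z <- scale(aa_property_table())
  expect_equal(unname(index_physicochemical("AC")),
               unname((z["C", ] - z["A", ])^2))
  # non-negative; strictly positive exactly on properties where the two
  # residues differ (A and C share a zero charge, D and K differ everywhere)
  s <- random_sequence(40, seed = 11)
  expect_true(all(index_physicochemical(s) >= 0))
  expect_true(all(index_physicochemical("DKDKDK") > 0))
  tab <- aa_property_table()
  ac <- index_physicochemical("ACACAC")
  expect_equal(unname(ac > 0), unname(tab["A", ] != tab["C", ]))
})

test_that("index descriptor agrees with the direct-summation reference", {
  set.seed(123)
  for (i in 1:50) {
    s <- random_sequence(sample(4:200, 1))
    expect_equal(unname(index_physicochemical(s)), ipc_oracle(s), tolerance = 1e-10)
  }
})

test_that("group compositions match the printed group memberships", {
  rg <- group_composition("HKR", "rg")
  expect_equal(unname(rg["rg_3"]), 1)
  expect_equal(sum(rg), 1)
  exg <- group_composition("C", "exg")
  expect_equal(unname(exg["exg_1"]), 1)
  scg <- group_composition("DE", "scg")
  expect_equal(unname(scg[c("scg_3", "scg_4", "scg_5")]), c(1, 1, 1))
  expect_error(group_composition("AC", "nope"), class = "bow_invalid_input")
})

test_that("group sub-blocks sum correctly: rg/exg/hg to 1, eleg to 1 - cv_C", {
  for (i in 1:20) {
    s <- random_sequence(sample(10:100, 1), seed = 300 + i)
    expect_equal(sum(group_composition(s, "rg")), 1)
    expect_equal(sum(group_composition(s, "exg")), 1)
    expect_equal(sum(group_composition(s, "hg")), 1)
    expect_equal(sum(group_composition(s, "eleg")),
                 1 - unname(composition_vector(s)["cv_C"]))
  }
})

test_that("the assembled protein block has 107 named dimensions in fixed order", {
  s <- random_sequence(60, seed = 77)
  b <- protein_feature_block(s)
  expect_length(b, 107)
  expect_identical(names(b), protein_feature_names())
  expect_identical(b, protein_feature_block(s))  # deterministic
  h <- protein_feature_block(strrep("L", 30))
  expect_equal(unname(h[grep("^npc_|^ipc_", names(h))]), rep(0, 14))
  expect_error(protein_feature_block("AC"), class = "bow_invalid_input")
})

test_that("FASTA reading and the feature matrix round-trip through CSV", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">prot1 some description", "ACDEFGHIKL", ">prot2", "MNPQRSTVWY"), fa)
  seqs <- read_protein_fasta(fa)
  expect_equal(seqs$id, c("prot1", "prot2"))
  m <- protein_feature_matrix(seqs)
  expect_equal(dim(m), c(2L, 107L))
  out <- tempfile(fileext = ".csv")
  write_protein_features(m, out)
  back <- utils::read.csv(out, check.names = FALSE)
  expect_equal(back$id, c("prot1", "prot2"))
  expect_equal(as.numeric(back[1, -1]), unname(m[1, ]))
})

test_that("a user property table must cover 20 residues x 7 finite properties", {
  tab <- aa_property_table()
  expect_error(validate_property_table(tab[1:19, ]), class = "bow_invalid_input")
  expect_error(validate_property_table(tab[, 1:6]), class = "bow_invalid_input")
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(residue = rownames(tab), tab), f, row.names = FALSE)
  expect_equal(unname(read_property_table(f)), unname(tab))
})
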
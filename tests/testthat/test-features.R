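test_that("general features encode position and event size", {
  expect_equal(unname(general_features(indel_variant("P", 3, 4, "KL", ""),
                                       100)),
               c(0.03, 0, 2))
  expect_equal(unname(general_features(indel_variant("P", 50, 50, "", "QW"),
                                       100)),
               c(0.5, 2, 0))
  expect_equal(unname(general_features(indel_variant("P", 3, 5, "KLG", "WW"),
                                       5)),
               c(0.6, 2, 3))
})

test_that("window composition counts the flanking residues only", {
  polyA <- paste(rep("A", 30), collapse = "")
  f <- window_aa_frequency(indel_variant("P", 15, 15, "A", ""), polyA)
  expect_equal(unname(f["A"]), 1)
  expect_equal(sum(f), 1)

  # deletion of K2 from M KKKKKKKKKKK: window = {1} and {3..12}
  f <- window_aa_frequency(indel_variant("P", 2, 2, "K", ""),
                           "MKKKKKKKKKKK")
  expect_equal(unname(f["M"]), 1 / 11)
  expect_equal(unname(f["K"]), 10 / 11)

  # insertion after 10 of all 20 amino acids: full 20-residue window
  f <- window_aa_frequency(indel_variant("P", 10, 10, "", "Q"),
                           "ACDEFGHIKLMNPQRSTVWY")
  expect_true(all(abs(f - 0.05) < 1e-12))
})

test_that("composition ignores residues outside the 20-residue window", {
  set.seed(31)
  for (i in 1:20) {
    wt <- random_aa_sequence(60)
    v <- indel_variant("P", 30, 31, substr(wt, 30, 31), "",
                       sequence = wt)
    base <- window_aa_frequency(v, wt)
    # shuffle everything more than 10 residues away from the span
    far <- c(1:19, 42:60)
    chars <- strsplit(wt, "")[[1]]
    chars[far] <- sample(chars[far])
    expect_equal(window_aa_frequency(v, paste(chars, collapse = "")), base)
  }
})

test_that("repeat run length is the maximal run containing the site", {
  expect_equal(repeat_run_length(indel_variant("P", 3, 3, "K", ""),
                                 "MAKLG"), 1L)
  expect_equal(repeat_run_length(indel_variant("P", 3, 3, "A", ""),
                                 "MAAAKG"), 3L)
  # insertion between two A's of the run
  expect_equal(repeat_run_length(indel_variant("P", 2, 2, "", "Q"),
                                 "MAAAKG"), 3L)
  # deletion spanning two runs reports the longer
  expect_equal(repeat_run_length(indel_variant("P", 3, 4, "AA", ""),
                                 "MAAAKKKKG"), 3L)
  expect_equal(repeat_run_length(indel_variant("P", 4, 5, "AK", ""),
                                 "MAAAKKKKG"), 4L)
})

test_that("conservation aggregation takes the max over the variant window", {
  cons <- c(.1, .2, .9, .4, .3)
  expect_equal(conservation_feature(indel_variant("P", 3, 5, "KLG", ""),
                                    cons), 0.9)
  # insertion of 2 after 4: window {4, 5}
  expect_equal(conservation_feature(indel_variant("P", 4, 4, "", "QW"),
                                    c(.1, .2, .3, .4, .5)), 0.5)
  expect_equal(conservation_feature(indel_variant("P", 2, 3, "AK", ""),
                                    rep(0.7, 5)), 0.7)

  # brute-force oracle on random vectors and spans
  set.seed(32)
  for (i in 1:40) {
    L <- sample(10:30, 1)
    cons <- runif(L)
    wt <- random_aa_sequence(L)
    v <- random_variant(wt)
    expected <- if (variant_kind(v) == "insertion") {
      k <- nchar(v$inserted_seq)
      pos <- intersect(v$start:(v$start + k - 1), 1:L)
      if (!length(pos)) pos <- min(max(v$start, 1), L)
      max(cons[pos])
    } else {
      max(cons[v$start:v$end])
    }
    expect_equal(conservation_feature(v, cons), expected)
  }
})

test_that("homolog bins are cumulative counts at 50..95 by 5", {
  expect_equal(unname(homolog_count_features(numeric(0))), rep(0L, 10))
  expect_equal(unname(homolog_count_features(100)), rep(1L, 10))
  expect_equal(unname(homolog_count_features(c(52, 60, 97))),
               c(3L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
})

test_that("functional residue counts use windows 4, 20 and the whole protein", {
  L <- 100
  trk <- property_track("m", rep(1, L), 0.5)
  v <- indel_variant("P", 50, 50, "A", "")
  expect_equal(unname(functional_residue_counts(v, trk)),
               c(9L, 41L, 100L))
  trk0 <- property_track("m", rep(0, L), 0.5)
  expect_equal(unname(functional_residue_counts(v, trk0)), c(0L, 0L, 0L))
  # threshold above every score
  expect_equal(unname(functional_residue_counts(
    v, property_track("m", rep(0.99, L), 1))), c(0L, 0L, 0L))

  # monotone in window size, never out of range, on random inputs
  set.seed(33)
  for (i in 1:40) {
    L <- sample(10:60, 1)
    wt <- random_aa_sequence(L)
    trk <- property_track("m", runif(L), 0.6)
    v <- random_variant(wt)
    cnt <- functional_residue_counts(v, trk)
    expect_lte(cnt[["w4"]], cnt[["w20"]])
    expect_lte(cnt[["w20"]], cnt[["whole"]])
  }
})

test_that("feature vector assembly is deterministic with fixed layout", {
  set.seed(34)
  wt <- random_aa_sequence(40)
  p <- protein_record("P1", wt,
                      tracks = list(m1 = property_track("m1", runif(40), .5),
                                    m2 = property_track("m2", runif(40), .5)),
                      conservation = list(c1 = runif(40)),
                      homologs = list(human = c(60, 80), mouse = 55))
  cfg <- feature_config(mechanisms = c("m1", "m2"), conservation = "c1")
  v <- indel_variant("P1", 10, 12, substr(wt, 10, 12), "", sequence = wt)
  f <- assemble_feature_vector(v, p, cfg)
  # 3 general + 21 composition + 1 conservation + 20 homolog + 2 x 3 counts
  expect_length(f, 51)
  expect_identical(f, assemble_feature_vector(v, p, cfg))
  expect_equal(names(f), feature_layout(cfg)$name)

  # disabling a group removes exactly its features
  cfg2 <- feature_config(mechanisms = c("m1", "m2"), conservation = "c1",
                         homologs = FALSE)
  f2 <- assemble_feature_vector(v, p, cfg2)
  expect_length(f2, 31)
  expect_equal(setdiff(names(f), names(f2)),
               grep("^hom_", names(f), value = TRUE))

  # missing required track errors with its name
  cfg3 <- feature_config(mechanisms = c("m1", "m9"), conservation = "c1")
  expect_error(assemble_feature_vector(v, p, cfg3), "m9")
})

test_that("gene-score group is passed through with a presence flag", {
  wt <- "MAKLGWQRSTVYACDEFHIN"
  p1 <- protein_record("P1", wt, gene_scores = c(.1, .2, .3))
  p2 <- protein_record("P2", wt)
  cfg <- feature_config(homologs = FALSE, gene_scores = 3L)
  v <- indel_variant("P1", 3, 3, "K", "")
  f1 <- assemble_feature_vector(v, p1, cfg)
  expect_equal(unname(f1[c("gene_1", "gene_2", "gene_3", "gene_present")]),
               c(.1, .2, .3, 1))
  f2 <- assemble_feature_vector(v, p2, cfg)
  expect_equal(unname(f2["gene_present"]), 0)
})

test_that("feature computations never index outside the protein", {
  set.seed(35)
  for (i in 1:30) {
    L <- sample(8:15, 1)
    wt <- random_aa_sequence(L)
    p <- protein_record("P1", wt,
                        tracks = list(m1 = property_track("m1", runif(L), .5)),
                        conservation = list(c1 = runif(L)))
    cfg <- feature_config(mechanisms = "m1", conservation = "c1")
    # variants hugging the termini
    vs <- list(indel_variant("P1", 0, 0, "", "Q"),
               indel_variant("P1", L, L, "", "WW"),
               indel_variant("P1", 1, 1, substr(wt, 1, 1), ""),
               indel_variant("P1", L, L, substr(wt, L, L), ""))
    for (v in vs) {
      f <- assemble_feature_vector(v, p, cfg)
      expect_true(all(is.finite(f)))
    }
  }
})
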
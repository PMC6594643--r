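test_that("impact score counts confident residues in the impact window", {
  L <- 20
  scores <- rep(0, L); scores[c(5, 9)] <- 1
  trk <- property_track("m", scores, 0.5)
  del56 <- indel_variant("P", 5, 6, "AA", "")
  expect_equal(impact_score(del56, trk), 2L)           # window 2..9
  expect_equal(impact_score(del56, property_track("m", rep(0, L), .5)), 0L)
  expect_equal(impact_score(del56, property_track("m", rep(1, L), .5)), 8L)

  # brute-force oracle on random tracks and variants
  set.seed(81)
  for (i in 1:40) {
    L <- sample(10:40, 1)
    wt <- random_aa_sequence(L)
    trk <- property_track("m", runif(L), 0.6)
    v <- random_variant(wt)
    expected <- length(intersect(which(trk$scores >= 0.6),
                                 impacted_residues(v, L, "impact")))
    expect_equal(impact_score(v, trk), expected)
  }
})

test_that("empirical P is the literal exceedance fraction", {
  null <- c(1, 2, 3, 4)
  expect_equal(empirical_p(1, null), 1)
  expect_equal(empirical_p(3, null), 0.5)
  expect_equal(empirical_p(5, null), 0)
  expect_equal(empirical_p(5, null, add_one = TRUE), 1 / 5)
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("prior correction scales P by 1 - alpha", {
  expect_equal(prior_correct(0.04, 0), 0.04)
  expect_equal(prior_correct(0.04, 0.25), 0.03)
  expect_lt(prior_correct(0.5, 0.999), 0.001)
  expect_error(prior_correct(0.1, 1), "alpha")
  # ordering is preserved within a mechanism
  p <- sort(runif(20))
  expect_true(all(diff(prior_correct(p, 0.3)) >= 0))
})

test_that("FDR identity behaves at its algebraic anchors", {
  expect_equal(fdr_from_rates(0, 0.2, 0.9), 1)
  expect_equal(fdr_from_rates(0.3, 0.4, 0.4), 1 - 0.3)
  expect_equal(fdr_from_rates(0.5, 0.1, 0.8), 0.1 / 0.9)
  expect_error(fdr_from_rates(0.5, 0, 0), "denominator")
})

test_that("mechanism ranking keeps the top five significant, tie-stable", {
  set.seed(82)
  L <- 30
  wt <- random_aa_sequence(L)
  # 7 mechanisms, all confidently hit at the variant: all significant
  mechs <- paste0("m", 1:7)
  tracks <- lapply(mechs, function(m)
    property_track(m, rep(1, L), 0.5))
  names(tracks) <- mechs
  p <- protein_record("P1", wt, tracks = tracks)
  v <- indel_variant("P1", 10, 10, substr(wt, 10, 10), "")
  nulls <- stats::setNames(lapply(seq_along(mechs), function(i)
    c(rep(0, 1000 - i), rep(9, i))), mechs)  # distinct small tail masses
  res <- rank_mechanisms(v, p, nulls)
  expect_equal(nrow(res), 5L)
  expect_true(all(diff(res$p_prime) >= 0))
  expect_true(all(res$p_prime < 0.05))

  # none significant
  nulls9 <- stats::setNames(lapply(mechs, function(m) rep(9, 10)), mechs)
  expect_equal(nrow(rank_mechanisms(v, p, nulls9)), 0L)

  # invariant to mechanism input order; p' ties broken by score then name
  res2 <- rank_mechanisms(v, p, nulls[sample(7)])
  expect_equal(res2, res)
})

test_that("alpha defaults to zero and config alpha takes precedence", {
  L <- 10
  wt <- random_aa_sequence(L)
  p <- protein_record("P1", wt,
                      tracks = list(m1 = property_track("m1", rep(1, L), .5),
                                    m2 = property_track("m2", rep(1, L), .5,
                                                        alpha = 0.4)))
  v <- indel_variant("P1", 5, 5, substr(wt, 5, 5), "")
  nulls <- list(m1 = 0:9, m2 = 0:9)
  res <- impact_results(v, p, nulls)
  expect_equal(res$alpha[res$mechanism == "m1"], 0)
  expect_equal(res$p_prime[res$mechanism == "m1"],
               res$p_value[res$mechanism == "m1"])
  expect_equal(res$alpha[res$mechanism == "m2"], 0.4)
  res2 <- impact_results(v, p, nulls, alphas = c(m2 = 0.1))
  expect_equal(res2$alpha[res2$mechanism == "m2"], 0.1)
})

test_that("class-prior estimator recovers limiting and mixed cases", {
  set.seed(83)
  pos <- rnorm(3000, 4)
  # unlabeled identical to positives: estimate near 1 (capped)
  expect_gte(naive_alpha_estimate(rnorm(3000, 4), pos), 0.9)
  # unlabeled disjoint from positives: estimate near 0
  expect_lte(naive_alpha_estimate(rnorm(3000, -4), pos), 0.05)
  # 50/50 mixture at strong separation: 0.5 within 0.1 over 20 seeds
  ests <- vapply(1:20, function(i) {
    set.seed(830 + i)
    unl <- c(rnorm(1000, 4), rnorm(1000, 0))
    naive_alpha_estimate(unl, rnorm(2000, 4))
  }, 0)
  expect_true(all(abs(ests - 0.5) <= 0.1))
})

test_that("empirical P is calibrated on draws from the null itself", {
  d <- tiny_dataset(seed = 11, n_pathogenic = 30L, n_neutral = 400L)
  vl <- indelrisk:::as_variant_list(d$variants)
  neut <- vl[vapply(vl, `[[`, "", "label") == "neutral"]
  null1 <- null_distribution(neut, d$proteins, "mech1")
  # fresh neutral variants from the same generator act as null draws
  d2 <- tiny_dataset(seed = 12, n_pathogenic = 30L, n_neutral = 2000L)
  vl2 <- indelrisk:::as_variant_list(d2$variants)
  neut2 <- vl2[vapply(vl2, `[[`, "", "label") == "neutral"]
  draws <- vapply(neut2, function(v)
    impact_score(v, d2$proteins[[v$protein_id]]$tracks$mech1), 0L)
  pvals <- vapply(draws, empirical_p, 0, null = null1)
  expect_gte(mean(pvals <= 0.05), 0.03)
  expect_lte(mean(pvals <= 0.05), 0.07)
  # super-uniformity a bit up the scale as well
  expect_lte(mean(pvals <= 0.2), 0.25)
})

test_that("percentile rule and single-residue filter work as modes", {
  null <- c(rep(0, 95), rep(10, 5))
  expect_equal(predicted_by_percentile(c(0, 10), null), c(FALSE, TRUE))
  vs <- list(indel_variant("P", 3, 3, "K", ""),
             indel_variant("P", 3, 5, "KLM", ""),
             indel_variant("P", 3, 3, "", "Q"),
             indel_variant("P", 3, 3, "K", "WW"))
  expect_equal(single_residue_filter(vs), c(TRUE, FALSE, TRUE, FALSE))
})
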
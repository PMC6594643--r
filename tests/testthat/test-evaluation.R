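test_that("identity clustering links chains transitively", {
  s <- random_aa_sequence(80)
  expect_equal(unname(cluster_by_identity(c(A = s, B = s))), c(1L, 1L))

  # chain: A~B at ~75%, B~C at ~60%, A~C well below 50%
  set.seed(61)
  a <- random_aa_sequence(100)
  b <- generate_homolog_family(protein_record("A", a), 75)[[1]]$sequence
  cc <- generate_homolog_family(protein_record("B", b), 60)[[1]]$sequence
  cm <- cluster_by_identity(c(A = a, B = b, C = cc))
  expect_lt(percent_identity(a, cc), 50)
  expect_equal(length(unique(cm)), 1L)
})

test_that("random proteins fall into singleton clusters", {
  set.seed(62)
  seqs <- vapply(1:10, function(i) random_aa_sequence(200), "")
  names(seqs) <- paste0("P", 1:10)
  # brute-force check that no pair reaches 50% identity
  for (i in 1:9) for (j in (i + 1):10)
    expect_lt(percent_identity(seqs[i], seqs[j]), 50)
  cm <- cluster_by_identity(seqs)
  expect_equal(length(unique(cm)), 10L)
})

test_that("fold assignment respects grouping and the seed", {
  set.seed(63)
  vs <- list()
  for (p in paste0("P", 1:20)) {
    wt <- random_aa_sequence(30)
    for (j in 1:3) vs <- c(vs, list(random_variant(wt, p)))
  }
  f <- make_folds(vs, k = 10, grouping = "per_protein", seed = 4)
  pid <- vapply(vs, `[[`, "", "protein_id")
  expect_true(all(tapply(f, pid, function(x) length(unique(x))) == 1))
  expect_equal(sort(unique(f)), 1:10)
  expect_identical(f, make_folds(vs, k = 10, grouping = "per_protein",
                                 seed = 4))

  cm <- stats::setNames(rep(1:5, each = 4), paste0("P", 1:20))
  fc <- make_folds(vs, k = 5, grouping = "per_cluster", cluster_map = cm,
                   seed = 4)
  expect_true(all(tapply(fc, cm[pid], function(x) length(unique(x))) == 1))

  expect_error(make_folds(vs, k = 25, grouping = "per_protein", seed = 1),
               "fewer groups")
})

test_that("AUC matches brute-force pairwise concordance", {
  expect_equal(roc_auc(c(.1, .2, .8, .9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  # one tied positive/negative pair contributes one half
  expect_equal(roc_auc(c(.1, .4, .4, .8), c(0, 1, 0, 1)), 0.875)

  brute_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(64)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(round(runif(n), sample(1:3, 1)))  # force ties sometimes
    expect_equal(roc_auc(s, y), brute_auc(s, y))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("FPR-anchored threshold is the least cutoff meeting the bound", {
  s <- seq(0.05, 0.95, by = 0.1)  # 10 equally spaced values
  cut <- threshold_at_fpr(s, 0.10)
  expect_equal(cut, 0.95)               # exactly the top value stays above
  expect_equal(sum(s >= cut) / 10, 0.1)

  # constant scores: cutoff just above, nothing called
  cut <- threshold_at_fpr(rep(0.3, 20), 0.25)
  expect_gt(cut, 0.3)
  expect_equal(sum(rep(0.3, 20) >= cut), 0L)

  # permissive fpr drives the cutoff to the bottom of the score range
  expect_lte(threshold_at_fpr(s, 0.95), sort(s)[2])

  # least-cutoff property by enumeration on random score sets
  set.seed(65)
  for (i in 1:20) {
    sc <- round(runif(sample(5:50, 1)), 2)
    fpr <- runif(1, 0.02, 0.5)
    cut <- threshold_at_fpr(sc, fpr)
    expect_lte(mean(sc >= cut), fpr)
    smaller <- unique(sc[sc < cut])
    for (c2 in smaller) expect_gt(mean(sc >= c2), fpr)
  }
})

test_that("percentile mode returns the score percentile", {
  s <- 1:100 / 100
  expect_equal(threshold_at_fpr(s, 0.05, mode = "percentile"),
               unname(quantile(s, 0.95)))
})

test_that("confusion metrics follow their definitions", {
  expect_equal(unname(confusion_metrics(c(.9, .8, .1, .2), c(1, 1, 0, 0),
                                        0.5)),
               c(1, 1, 1, 1))
  # all-pathogenic prediction on a balanced set
  m <- confusion_metrics(rep(1, 10), rep(c(1, 0), 5), 0.5)
  expect_equal(unname(m[c("accuracy", "balanced_accuracy")]), c(0.5, 0.5))
  # TP=80 FN=20 TN=90 FP=10
  s <- c(rep(.9, 80), rep(.1, 20), rep(.1, 90), rep(.9, 10))
  y <- rep(c(1, 0), c(100, 100))
  m <- confusion_metrics(s, y, 0.5)
  expect_equal(unname(m), c(0.85, 0.85, 0.8, 0.9))
})

test_that("cross-validation refits the preprocessor per fold (no leakage)", {
  set.seed(66)
  d <- tiny_dataset(seed = 3)
  X <- feature_matrix(d$variants, d$proteins, d$feature_config)
  y <- attr(X, "label")
  folds <- make_folds(d$variants, k = 5, grouping = "per_protein", seed = 2)
  cv <- cross_validate(X, y, folds, seed = 9, n_networks = 5)
  expect_false(anyNA(cv$scores))
  # refitting fold 1 by hand reproduces its out-of-fold scores exactly
  tr <- which(folds != 1); te <- which(folds == 1)
  refit <- indel_ensemble(X[tr, ], indelrisk:::as_binary_label(y)[tr],
                          n_networks = 5, seed = 9 + 1000L)
  expect_equal(predict(refit, X[te, ]), cv$scores[te])
})
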
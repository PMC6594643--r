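test_that("preprocessor filters, normalises and projects as specified", {
  set.seed(41)
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  x <- matrix(rnorm(n * 6), n)
  x[, 1] <- x[, 1] + 2 * y        # informative
  x[, 2] <- 7                     # constant: dropped
  x[y == 1, 3] <- x[y == 0, 3]    # identical across classes (P = 1): dropped
  colnames(x) <- paste0("f", 1:6)
  pre <- fit_preprocessor(x, y)
  expect_true(pre$keep[["f1"]])
  expect_false(pre$keep[["f2"]])
  expect_false(pre$keep[["f3"]])
  expect_gte(pre$retained_variance, 0.99)

  # duplicated column does not raise the projection dimension
  x2 <- cbind(x, f7 = x[, 1])
  pre2 <- fit_preprocessor(x2, y)
  expect_equal(ncol(pre2$rotation), ncol(pre$rotation))

  expect_error(fit_preprocessor(x[y == 1, ], y[y == 1]), "class")
})

test_that("projection retains at least 99% variance (reconstruction oracle)", {
  set.seed(42)
  x <- matrix(rnorm(200 * 30), 200)
  y <- rbinom(200, 1, 0.5)
  pre <- fit_preprocessor(x, y, t_pvalue = 1.01)  # keep all, isolate the PCA
  z <- scale(x[, pre$keep], center = pre$means, scale = pre$sds)
  proj <- preprocess_features(pre, x)
  recon <- proj %*% t(pre$rotation)
  resid_var <- sum((z - recon)^2) / sum(z^2)
  expect_lte(resid_var, 0.01)
})

test_that("network gradients match numerical differentiation", {
  set.seed(43)
  X <- matrix(rnorm(12 * 3), 12)
  y <- rbinom(12, 1, 0.5)
  w <- indelrisk:::mlp_init(3, 4)
  g <- indelrisk:::mlp_grad(w, X, y)
  eps <- 1e-6
  for (nm in c("W1", "W2")) {
    for (k in sample(length(w[[nm]]), 5)) {
      wp <- w; wp[[nm]][k] <- wp[[nm]][k] + eps
      wm <- w; wm[[nm]][k] <- wm[[nm]][k] - eps
      num <- (indelrisk:::cross_entropy(indelrisk:::mlp_forward(wp, X)$p, y) -
              indelrisk:::cross_entropy(indelrisk:::mlp_forward(wm, X)$p, y)) /
        (2 * eps)
      expect_equal(g[[nm]][k], num, tolerance = 1e-5)
    }
  }
})

make_blobs <- function(n_pos, n_neg, sep = 4, d = 2) {
  x <- rbind(matrix(rnorm(n_pos * d), n_pos),
             matrix(rnorm(n_neg * d), n_neg))
  x[seq_len(n_pos), 1] <- x[seq_len(n_pos), 1] + sep
  list(x = cbind(x, matrix(rnorm((n_pos + n_neg) * 3), n_pos + n_neg)),
       y = rep(c(1L, 0L), c(n_pos, n_neg)))
}

test_that("ensemble bags are exactly class-balanced", {
  set.seed(44)
  b <- make_blobs(100, 300)
  fit <- indel_ensemble(b$x, b$y, n_networks = 8, seed = 5)
  for (bag in fit$bag_indices) {
    expect_length(bag, 200)
    expect_equal(as.vector(table(b$y[bag])), c(100L, 100L))
    expect_false(anyDuplicated(bag) > 0)  # undersampling w/o replacement
  }
})

test_that("ensemble training is deterministic given the seed", {
  set.seed(45)
  b <- make_blobs(40, 60)
  f1 <- indel_ensemble(b$x, b$y, n_networks = 5, seed = 7)
  f2 <- indel_ensemble(b$x, b$y, n_networks = 5, seed = 7)
  expect_identical(predict(f1, b$x), predict(f2, b$x))
  f3 <- indel_ensemble(b$x, b$y, n_networks = 5, seed = 8)
  expect_false(identical(predict(f1, b$x), predict(f3, b$x)))
})

test_that("ensemble separates linearly separable blobs", {
  set.seed(46)
  tr <- make_blobs(150, 250)
  te <- make_blobs(100, 100)
  fit <- indel_ensemble(tr$x, tr$y, n_networks = 20, seed = 9)
  expect_gt(roc_auc(predict(fit, te$x), te$y), 0.95)
})

test_that("ensemble scores are the mean of member outputs in [0, 1]", {
  set.seed(47)
  b <- make_blobs(40, 60)
  fit <- indel_ensemble(b$x, b$y, n_networks = 6, seed = 3)
  s <- predict(fit, b$x)
  expect_true(all(s >= 0 & s <= 1))
  Z <- preprocess_features(fit$preprocessor, b$x)
  manual <- rowMeans(sapply(fit$networks,
                            function(w) indelrisk:::mlp_forward(w, Z)$p))
  expect_equal(s, manual)
})

test_that("ensemble log-loss does not exceed mean member log-loss", {
  set.seed(48)
  tr <- make_blobs(80, 120, sep = 2)
  te <- make_blobs(80, 80, sep = 2)
  fit <- indel_ensemble(tr$x, tr$y, n_networks = 10, seed = 2)
  Z <- preprocess_features(fit$preprocessor, te$x)
  member_ll <- vapply(fit$networks, function(w)
    indelrisk:::cross_entropy(indelrisk:::mlp_forward(w, Z)$p, te$y), 0)
  ens_ll <- indelrisk:::cross_entropy(predict(fit, te$x), te$y)
  expect_lte(ens_ll, mean(member_ll) + 1e-12)
})

test_that("model-derived 10% FPR cutoff calibrates on fresh neutral data", {
  set.seed(49)
  tr <- make_blobs(400, 600, sep = 3)
  fit <- indel_ensemble(tr$x, tr$y, n_networks = 20, seed = 6)
  te <- make_blobs(4, 1000, sep = 3)
  neut_scores <- predict(fit, te$x)[te$y == 0L]
  frac <- mean(neut_scores >= fit$thresholds[["fpr10"]])
  expect_lte(frac, 0.12)
})

test_that("classification at published thresholds uses the >= convention", {
  expect_equal(classify_at_threshold(0.70, "fpr5"), "pathogenic")
  expect_equal(classify_at_threshold(0.60, "fpr1"), "neutral")
  expect_equal(classify_at_threshold(0.672, "fpr5"), "pathogenic")
  expect_equal(classify_at_threshold(0.546, "fpr10"), "pathogenic")
  expect_equal(classify_at_threshold(0.5, cutoff = 0.5), "pathogenic")
  expect_error(classify_at_threshold(0.5, "fpr42"), "unknown")
})

test_that("minority class below 4 examples is rejected", {
  set.seed(50)
  b <- make_blobs(3, 50)
  expect_error(indel_ensemble(b$x, b$y, n_networks = 2, seed = 1),
               "minority")
})

test_that("a saved model reloads and reproduces predictions", {
  set.seed(51)
  b <- make_blobs(40, 60)
  fit <- indel_ensemble(b$x, b$y, n_networks = 4, seed = 2)
  path <- tempfile(fileext = ".model")
  save_ensemble(fit, path)
  back <- load_ensemble(path)
  expect_s3_class(back, "indel_ensemble")
  expect_identical(predict(back, b$x), predict(fit, b$x))
  unlink(path)
})
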
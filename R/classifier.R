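# Pathogenicity model: minimal feature reduction (two-sample t-test at
# P < 0.5, z-score normalisation, PCA at 99% retained variance) feeding an
# ensemble of 100 bagged, class-balanced two-layer feed-forward networks
# trained by resilient propagation with a 25% validation split for early
# stopping.

#' Fit the feature preprocessor
#'
#' Performs the minimal feature reduction applied before network training:
#' constant features are dropped, a per-feature two-sample Welch t-test
#' between classes retains features with P below a minimally restrictive
#' threshold (default 0.5), retained features are z-score normalised, and a
#' principal-component projection keeping at least the requested fraction of
#' variance (default 99%) is fitted.
#'
#' @param x numeric feature matrix (rows = variants).
#' @param y labels: logical/0-1/factor, \code{TRUE}/1/"pathogenic" = positive.
#' @param t_pvalue t-test P-value threshold for retaining a feature.
#' @param var_retain minimum fraction of variance the projection keeps.
#' @return an object of class \code{"indel_preprocessor"} with the selection
#'   mask, normalisation parameters and rotation matrix.
#' @export
fit_preprocessor <- function(x, y, t_pvalue = 0.5, var_retain = 0.99) {
  y <- as_binary_label(y)
  if (length(unique(y)) < 2L) stop("both classes required to fit")
  if (min(table(y)) < 2L) stop("need at least 2 examples per class")
  if (any(!is.finite(x))) stop("non-finite feature values")
  sds0 <- apply(x, 2, stats::sd)
  keep <- sds0 > 0
  pvals <- rep(NA_real_, ncol(x))
  for (j in which(keep)) {
    a <- x[y == 1L, j]; b <- x[y == 0L, j]
    pvals[j] <- if (stats::sd(a) == 0 && stats::sd(b) == 0) 1
                else stats::t.test(a, b)$p.value
  }
  keep <- keep & !is.na(pvals) & pvals < t_pvalue
  if (!any(keep)) stop("no feature passed the t-test filter")
  xk <- x[, keep, drop = FALSE]
  mu <- colMeans(xk)
  sds <- apply(xk, 2, stats::sd)
  z <- scale(xk, center = mu, scale = sds)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- which(cum >= var_retain)[1]
  if (is.na(ncomp)) ncomp <- length(pc$sdev)
  structure(list(keep = keep, feature_names = colnames(x),
                 means = mu, sds = sds,
                 rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 retained_variance = cum[ncomp],
                 t_pvalue = t_pvalue, p_values = pvals),
            class = "indel_preprocessor")
}

#' Apply a fitted preprocessor
#'
#' @param pre an \code{indel_preprocessor}.
#' @param x feature matrix with the training columns (matched by name when
#'   column names are present).
#' @return projected matrix with \code{ncol(pre$rotation)} columns.
#' @export
preprocess_features <- function(pre, x) {
  if (!is.null(colnames(x)) && !is.null(pre$feature_names)) {
    if (!all(pre$feature_names %in% colnames(x)))
      stop("feature names do not match the training features")
    x <- x[, pre$feature_names, drop = FALSE]
  } else if (ncol(x) != length(pre$keep)) {
    stop("feature count mismatch: got ", ncol(x), ", expected ",
         length(pre$keep))
  }
  z <- scale(x[, pre$keep, drop = FALSE], center = pre$means,
             scale = pre$sds)
  z %*% pre$rotation
}

as_binary_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("pathogenic", "neutral"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    return(as.integer(y == "pathogenic"))
  }
  as.integer(as.logical(y))
}

## ---- two-layer feed-forward network trained with iRprop- ----

mlp_init <- function(d, h) {
  list(W1 = matrix(stats::runif((d + 1L) * h, -0.5, 0.5) / sqrt(d + 1L),
                   d + 1L, h),
       W2 = matrix(stats::runif(h + 1L, -0.5, 0.5) / sqrt(h + 1L), h + 1L, 1L))
}

mlp_forward <- function(w, X) {
  A <- tanh(cbind(1, X) %*% w$W1)
  p <- 1 / (1 + exp(-(cbind(1, A) %*% w$W2)))
  list(A = A, p = as.numeric(p))
}

mlp_grad <- function(w, X, y) {
  n <- length(y)
  f <- mlp_forward(w, X)
  d2 <- matrix((f$p - y) / n, ncol = 1)            # dCE/dz2 for sigmoid+CE
  gW2 <- crossprod(cbind(1, f$A), d2)
  dA <- (d2 %*% t(w$W2[-1L, , drop = FALSE])) * (1 - f$A^2)
  gW1 <- crossprod(cbind(1, X), dA)
  list(W1 = gW1, W2 = gW2)
}

cross_entropy <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# iRprop-: per-weight adaptive steps driven by gradient signs only; weights
# revisit no learning rate, making full-batch training cheap and robust.
mlp_train_rprop <- function(Xtr, ytr, Xval, yval, hidden = 10L,
                            max_epochs = 100L, patience = 10L,
                            eta_plus = 1.2, eta_minus = 0.5,
                            delta0 = 0.07, delta_min = 1e-6, delta_max = 50) {
  w <- mlp_init(ncol(Xtr), hidden)
  step <- lapply(w, function(m) array(delta0, dim(m)))
  prev_sign <- lapply(w, function(m) array(0, dim(m)))
  best <- w
  best_val <- Inf
  stall <- 0L
  for (epoch in seq_len(max_epochs)) {
    g <- mlp_grad(w, Xtr, ytr)
    for (nm in c("W1", "W2")) {
      s <- sign(g[[nm]])
      agree <- prev_sign[[nm]] * s
      step[[nm]] <- pmin(pmax(
        step[[nm]] * ifelse(agree > 0, eta_plus,
                            ifelse(agree < 0, eta_minus, 1)),
        delta_min), delta_max)
      s[agree < 0] <- 0          # iRprop-: skip update after a sign flip
      w[[nm]] <- w[[nm]] - s * step[[nm]]
      prev_sign[[nm]] <- s
    }
    val <- cross_entropy(mlp_forward(w, Xval)$p, yval)
    if (val < best_val - 1e-9) {
      best_val <- val; best <- w; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  best
}

#' Fit the bagged neural-network pathogenicity ensemble
#'
#' The core model: after preprocessing (\code{\link{fit_preprocessor}}), each
#' of \code{n_networks} member networks is trained on a class-balanced bag --
#' all minority-class examples plus a fresh uniform random undersample of the
#' majority class of the same size, drawn without replacement -- with 25% of
#' the bag held out as a validation set for early stopping of the resilient
#' propagation optimiser. The ensemble score of a variant is the mean of the
#' member outputs, in \code{[0, 1]}, higher meaning more likely pathogenic.
#' Score cutoffs anchored at 10/5/1% false-positive rate on the training
#' neutral scores are stored on the model.
#'
#' @param x numeric feature matrix (rows = variants).
#' @param y labels (\code{"pathogenic"}/\code{"neutral"}, logical, or 0/1).
#' @param n_networks number of ensemble members.
#' @param hidden hidden units per member network.
#' @param val_fraction fraction of each bag held out for early stopping.
#' @param t_pvalue,var_retain preprocessor settings.
#' @param max_epochs,patience optimiser budget and early-stopping patience
#'   (epochs without validation improvement).
#' @param seed integer seed; the fit is reproducible from (data, config,
#'   seed).
#' @return an object of class \code{"indel_ensemble"}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200 * 4), 200)
#' y <- rep(c(1, 0), each = 100)
#' x[y == 1, 1] <- x[y == 1, 1] + 2
#' fit <- indel_ensemble(x, y, n_networks = 5, seed = 1)
#' summary(fit)
#' @export
indel_ensemble <- function(x, y, n_networks = 100L, hidden = 10L,
                           val_fraction = 0.25, t_pvalue = 0.5,
                           var_retain = 0.99, max_epochs = 100L,
                           patience = 10L, seed = 1L) {
  y <- as_binary_label(y)
  x <- as.matrix(x)
  counts <- table(factor(y, levels = 0:1))
  if (min(counts) < 4L) stop("minority class has fewer than 4 examples")
  with_seed(seed, {
    pre <- fit_preprocessor(x, y, t_pvalue = t_pvalue,
                            var_retain = var_retain)
    Z <- preprocess_features(pre, x)
    idx_pos <- which(y == 1L); idx_neg <- which(y == 0L)
    m <- min(length(idx_pos), length(idx_neg))
    minority <- if (length(idx_pos) <= length(idx_neg)) idx_pos else idx_neg
    majority <- if (length(idx_pos) <= length(idx_neg)) idx_neg else idx_pos
    networks <- vector("list", n_networks)
    bag_indices <- vector("list", n_networks)
    for (b in seq_len(n_networks)) {
      bag <- c(minority, sample(majority, m))
      # stratified validation split keeps both classes in train and val
      val <- unlist(lapply(split(bag, y[bag]), function(ix)
        sample(ix, max(1L, round(val_fraction * length(ix))))))
      tr <- setdiff(bag, val)
      networks[[b]] <- mlp_train_rprop(Z[tr, , drop = FALSE], y[tr],
                                       Z[val, , drop = FALSE], y[val],
                                       hidden = hidden,
                                       max_epochs = max_epochs,
                                       patience = patience)
      bag_indices[[b]] <- bag
    }
    model <- structure(list(preprocessor = pre, networks = networks,
                            bag_indices = bag_indices,
                            config = list(n_networks = n_networks,
                                          hidden = hidden,
                                          val_fraction = val_fraction,
                                          t_pvalue = t_pvalue,
                                          var_retain = var_retain,
                                          max_epochs = max_epochs,
                                          patience = patience),
                            seed = seed, class_counts = as.integer(counts),
                            call = match.call()),
                       class = "indel_ensemble")
    train_scores <- predict(model, x)
    model$train_scores <- train_scores
    model$train_labels <- y
    neut <- train_scores[y == 0L]
    model$thresholds <- c(fpr10 = threshold_at_fpr(neut, 0.10),
                          fpr5  = threshold_at_fpr(neut, 0.05),
                          fpr1  = threshold_at_fpr(neut, 0.01))
    model
  })
}

#' Predict pathogenicity scores or class calls
#'
#' @param object an \code{indel_ensemble}.
#' @param newdata feature matrix with the training columns.
#' @param type \code{"score"} for the mean member output in \code{[0, 1]},
#'   \code{"class"} for calls at a false-positive-rate-anchored cutoff.
#' @param level FPR level for \code{type = "class"}: 0.10, 0.05 or 0.01.
#' @param ... unused.
#' @return numeric scores, or a character vector of
#'   \code{"pathogenic"}/\code{"neutral"} calls.
#' @export
predict.indel_ensemble <- function(object, newdata,
                                   type = c("score", "class"),
                                   level = 0.05, ...) {
  type <- match.arg(type)
  Z <- preprocess_features(object$preprocessor, as.matrix(newdata))
  s <- numeric(nrow(Z))
  for (w in object$networks) s <- s + mlp_forward(w, Z)$p
  s <- s / length(object$networks)
  if (type == "score") return(s)
  cutoff <- object$thresholds[[paste0("fpr", round(level * 100))]]
  if (is.null(cutoff)) stop("no threshold stored for level ", level)
  classify_at_threshold(s, cutoff = cutoff)
}

#' @export
print.indel_ensemble <- function(x, ...) {
  cat("Bagged neural-network indel pathogenicity ensemble\n")
  cat(sprintf("  %d networks, %d hidden units, %d -> %d features after projection\n",
              x$config$n_networks, x$config$hidden,
              length(x$preprocessor$keep), ncol(x$preprocessor$rotation)))
  cat(sprintf("  training: %d neutral, %d pathogenic; seed %d\n",
              x$class_counts[1], x$class_counts[2], x$seed))
  invisible(x)
}

#' @export
summary.indel_ensemble <- function(object, ...) {
  auc <- roc_auc(object$train_scores, object$train_labels)
  out <- list(config = object$config,
              class_counts = object$class_counts,
              retained_variance = object$preprocessor$retained_variance,
              n_projected = ncol(object$preprocessor$rotation),
              thresholds = object$thresholds,
              train_auc = auc)
  class(out) <- "summary.indel_ensemble"
  out
}

#' @export
print.summary.indel_ensemble <- function(x, ...) {
  cat("Indel pathogenicity ensemble\n")
  cat(sprintf("  networks: %d  hidden: %d  projected features: %d (%.1f%% variance)\n",
              x$config$n_networks, x$config$hidden, x$n_projected,
              100 * x$retained_variance))
  cat(sprintf("  training classes: %d neutral / %d pathogenic\n",
              x$class_counts[1], x$class_counts[2]))
  cat(sprintf("  apparent (in-sample) AUC: %.3f\n", x$train_auc))
  cat(sprintf("  score cutoffs: %.3f (10%% FPR)  %.3f (5%% FPR)  %.3f (1%% FPR)\n",
              x$thresholds["fpr10"], x$thresholds["fpr5"],
              x$thresholds["fpr1"]))
  invisible(x)
}

#' @export
plot.indel_ensemble <- function(x, ...) {
  s <- x$train_scores; y <- x$train_labels
  br <- seq(0, 1, by = 0.05)
  h1 <- graphics::hist(s[y == 1L], breaks = br, plot = FALSE)
  h0 <- graphics::hist(s[y == 0L], breaks = br, plot = FALSE)
  ylim <- c(0, max(h0$density, h1$density))
  graphics::plot(h0, freq = FALSE, col = grDevices::adjustcolor("steelblue", 0.5),
                 border = NA, xlim = c(0, 1), ylim = ylim,
                 main = "Training score distributions",
                 xlab = "pathogenicity score", ...)
  graphics::plot(h1, freq = FALSE, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, add = TRUE)
  graphics::abline(v = x$thresholds, lty = 2)
  graphics::legend("top", c("neutral", "pathogenic"), bty = "n",
                   fill = grDevices::adjustcolor(c("steelblue", "firebrick"), 0.5))
  invisible(x)
}

#' Published score thresholds
#'
#' FPR-anchored cutoffs of the reference model, kept as named constants for
#' compatibility reporting: 0.546 (10% FPR), 0.672 (5% FPR, recommended),
#' 0.85 (1% FPR). Retrained models derive their own cutoffs via
#' \code{\link{threshold_at_fpr}}.
#'
#' @return named numeric vector \code{fpr10}, \code{fpr5}, \code{fpr1}.
#' @export
published_thresholds <- function() {
  c(fpr10 = 0.546, fpr5 = 0.672, fpr1 = 0.85)
}

#' Call pathogenic/neutral at a score cutoff
#'
#' A variant is called pathogenic when its score is at or above the cutoff.
#' The cutoff may be given explicitly or as a published FPR level.
#'
#' @param score numeric scores in \code{[0, 1]}.
#' @param level one of \code{"fpr10"}, \code{"fpr5"}, \code{"fpr1"} selecting
#'   a \code{\link{published_thresholds}} cutoff; ignored when \code{cutoff}
#'   is given.
#' @param cutoff explicit score cutoff.
#' @return character vector of \code{"pathogenic"}/\code{"neutral"}.
#' @export
classify_at_threshold <- function(score, level = "fpr5", cutoff = NULL) {
  if (is.null(cutoff)) {
    th <- published_thresholds()
    if (!level %in% names(th)) stop("unknown FPR level: ", level)
    cutoff <- th[[level]]
  }
  ifelse(score >= cutoff, "pathogenic", "neutral")
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  expr
}
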
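# Cross-validation protocols (per-protein and per-cluster grouping), ROC/AUC,
# FPR-anchored score thresholds and confusion metrics.

#' Cluster proteins by global-alignment percent identity
#'
#' Pairwise percent identity is computed from a global alignment (match +1,
#' mismatch 0, zero gap penalties; identity = matches / alignment length) and
#' proteins are clustered by single-linkage transitive closure over pairs at
#' or above the threshold, so any chain of >= threshold pairs lands in one
#' cluster.
#'
#' @param proteins named list of \code{protein_record} objects, or a named
#'   character vector of sequences.
#' @param threshold percent-identity threshold (default 50).
#' @return named integer vector mapping protein id to cluster id.
#' @export
cluster_by_identity <- function(proteins, threshold = 50) {
  seqs <- if (is.character(proteins)) proteins
          else vapply(proteins, `[[`, "", "sequence")
  ids <- if (is.null(names(seqs))) vapply(proteins, `[[`, "", "id")
         else names(seqs)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    set <- Biostrings::AAStringSet(seqs)
    mat <- identity_submat()
    lens <- nchar(seqs)
    chars <- strsplit(seqs, "")
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      # ungapped identity is a lower bound on the gapped one: equal-length
      # pairs already at the threshold link without dynamic programming
      cheap <- rest[lens[rest] == lens[i]]
      for (j in cheap) {
        if (find(i) == find(j)) next
        if (100 * sum(chars[[i]] == chars[[j]]) / lens[i] >= threshold)
          parent[find(j)] <- find(i)
      }
      todo <- rest[vapply(rest, function(j) find(j) != find(i), TRUE)]
      if (!length(todo)) next
      pal <- Biostrings::pairwiseAlignment(set[todo], set[[i]],
                                           substitutionMatrix = mat,
                                           gapOpening = 0, gapExtension = 0,
                                           type = "global")
      alen <- Biostrings::width(Biostrings::alignedPattern(pal))
      pid <- 100 * Biostrings::nmatch(pal) / alen
      for (j in todo[pid >= threshold]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  stats::setNames(match(roots, unique(roots)), ids)
}

#' Percent identity of two protein sequences
#'
#' Global alignment with match score 1, mismatch 0 and zero gap penalties
#' (maximising the number of matched residues); identity is matches divided by
#' alignment length (gap columns included).
#'
#' @param a,b amino-acid strings.
#' @return percent identity in \code{[0, 100]}.
#' @export
percent_identity <- function(a, b) {
  if (a == b) return(100)
  mat <- identity_submat()
  pal <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                       Biostrings::AAString(b),
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 0,
                                       type = "global")
  aligned_len <- nchar(as.character(Biostrings::alignedPattern(pal)))
  100 * Biostrings::nmatch(pal) / aligned_len
}

identity_env <- new.env(parent = emptyenv())
identity_submat <- function() {
  if (is.null(identity_env$mat)) {
    letters <- c(AA20, "X")
    m <- matrix(0L, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- 1L
    identity_env$mat <- m
  }
  identity_env$mat
}

#' Assign variants to cross-validation folds by protein or cluster
#'
#' All variants of one protein (grouping \code{"per_protein"}) or of one
#' identity cluster (\code{"per_cluster"}) share a fold, so no homology
#' information leaks from training into test partitions. Groups are ordered
#' by variant count (ties shuffled with the seed) and dealt greedily to the
#' currently lightest fold to balance fold sizes.
#'
#' @param variants list of \code{indel_variant} objects or a variant
#'   data.frame.
#' @param k number of folds.
#' @param grouping \code{"per_protein"} or \code{"per_cluster"}.
#' @param cluster_map named protein-to-cluster vector from
#'   \code{\link{cluster_by_identity}} (required for \code{"per_cluster"}).
#' @param seed integer seed for the tie shuffle.
#' @return integer vector of fold indices in \code{1..k}, one per variant,
#'   with the grouping recorded in attribute \code{"grouping"}.
#' @export
make_folds <- function(variants, k = 10L, grouping = c("per_protein",
                                                       "per_cluster"),
                       cluster_map = NULL, seed = 1L) {
  grouping <- match.arg(grouping)
  variants <- as_variant_list(variants)
  pid <- vapply(variants, `[[`, "", "protein_id")
  key <- if (grouping == "per_protein") pid else {
    if (is.null(cluster_map)) stop("per_cluster grouping needs cluster_map")
    unknown <- setdiff(unique(pid), names(cluster_map))
    if (length(unknown)) stop("proteins missing from cluster_map: ",
                              paste(unknown, collapse = ", "))
    as.character(cluster_map[pid])
  }
  counts <- table(key)
  if (length(counts) < k)
    stop("fewer groups (", length(counts), ") than folds (", k, ")")
  with_seed(seed, {
    ord <- names(counts)[order(-as.integer(counts),
                               sample(length(counts)))]
    fold_of <- integer(0)
    load <- numeric(k)
    for (g in ord) {
      f <- which.min(load)
      fold_of[g] <- f
      load[f] <- load[f] + counts[[g]]
    }
    structure(unname(fold_of[key]), grouping = grouping)
  })
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; tied scores contribute one half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (1/\code{TRUE}/"pathogenic" = positive).
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param scores,labels as in \code{\link{roc_auc}}.
#' @return data.frame of (fpr, tpr) pairs swept over all score cutoffs,
#'   suitable for export or plotting.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_label(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  tpr <- cumsum(y[ord] == 1L) / sum(y == 1L)
  fpr <- cumsum(y[ord] == 0L) / sum(y == 0L)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # one point per distinct cutoff
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' Score cutoff anchored at a false-positive rate
#'
#' The smallest cutoff such that the fraction of neutral scores at or above
#' it does not exceed \code{fpr}. When even the largest score is too frequent
#' (e.g. constant scores), a cutoff just above the maximum is returned so no
#' neutral variant is called. \code{mode = "percentile"} instead returns the
#' requested percentile of the score distribution (the rule used to flag
#' variants scoring at or above the 95th percentile of a neutral cohort).
#'
#' @param neutral_scores scores of the neutral (negative) set.
#' @param fpr target false-positive rate in (0, 1); for
#'   \code{mode = "percentile"} the percentile is \code{1 - fpr}.
#' @param mode \code{"fpr"} or \code{"percentile"}.
#' @return numeric cutoff.
#' @export
threshold_at_fpr <- function(neutral_scores, fpr, mode = c("fpr",
                                                           "percentile")) {
  mode <- match.arg(mode)
  if (!length(neutral_scores)) stop("empty neutral score set")
  if (fpr <= 0 || fpr >= 1) stop("fpr must lie in (0, 1)")
  if (mode == "percentile")
    return(unname(stats::quantile(neutral_scores, 1 - fpr)))
  n <- length(neutral_scores)
  cand <- sort(unique(neutral_scores))
  frac_ge <- vapply(cand, function(c) sum(neutral_scores >= c) / n, 0)
  ok <- which(frac_ge <= fpr)
  if (length(ok)) cand[ok[1]]
  else max(neutral_scores) + max(1e-8, abs(max(neutral_scores)) * 1e-8)
}

#' Confusion-matrix metrics at a cutoff
#'
#' @param scores,labels as in \code{\link{roc_auc}}.
#' @param cutoff score at or above which a variant is called pathogenic.
#' @return named vector: accuracy, balanced accuracy (mean of sensitivity and
#'   specificity), sensitivity, specificity.
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2L) stop("both classes required")
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  c(accuracy = (tp + tn) / length(y),
    balanced_accuracy = (sens + spec) / 2,
    sensitivity = sens, specificity = spec)
}

#' Grouped cross-validation of the pathogenicity ensemble
#'
#' Fits an \code{\link{indel_ensemble}} on each training partition (the
#' preprocessor is refitted inside each fold, so no test information leaks)
#' and scores the held-out variants, yielding out-of-fold scores for every
#' variant plus per-fold and pooled AUC.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param folds fold assignment from \code{\link{make_folds}}.
#' @param seed integer seed; fold b trains with its own substream.
#' @param ... ensemble settings passed to \code{\link{indel_ensemble}}
#'   (e.g. \code{n_networks}).
#' @return list with \code{scores} (out-of-fold, aligned to rows of
#'   \code{x}), \code{auc} (pooled), \code{fold_auc}, and \code{folds}.
#' @export
cross_validate <- function(x, y, folds, seed = 1L, ...) {
  y <- as_binary_label(y)
  x <- as.matrix(x)
  k <- max(folds)
  oof <- rep(NA_real_, nrow(x))
  fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (!length(te)) next
    if (length(unique(y[tr])) < 2L)
      stop("training partition of fold ", f, " lacks a class")
    fit <- indel_ensemble(x[tr, , drop = FALSE], y[tr],
                          seed = seed + 1000L * f, ...)
    oof[te] <- predict(fit, x[te, , drop = FALSE])
    if (length(unique(y[te])) == 2L)
      fold_auc[f] <- roc_auc(oof[te], y[te])
  }
  list(scores = oof, auc = roc_auc(oof, y), fold_auc = fold_auc,
       folds = folds)
}
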
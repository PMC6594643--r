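# Per-variant, per-mechanism functional impact: confident-residue impact
# scores, empirical P-values against the neutral null, class-prior correction
# for positive-unlabeled nulls, and the top-5 mechanism report.

#' Functional impact score of a variant for one mechanism
#'
#' The number of residues impacted by the variant (deleted span plus three
#' flanking residues on either side, see
#' \code{\link{impacted_residues}} with \code{mode = "impact"}) that are
#' confidently predicted to exhibit the mechanism, i.e. whose track score is
#' at or above the track's confident threshold.
#'
#' @param v an \code{indel_variant}.
#' @param track a \code{\link{property_track}} on the variant's protein.
#' @return nonnegative integer count.
#' @export
impact_score <- function(v, track) {
  pos <- impacted_residues(v, length(track$scores), mode = "impact")
  sum(track$scores[pos] >= track$confident_threshold)
}

#' Null distribution of impact scores from a neutral cohort
#'
#' @param variants neutral variants (list or data.frame).
#' @param proteins named list of \code{protein_record} objects.
#' @param mechanism track name.
#' @return object of class \code{"impact_null"}: the multiset of impact
#'   scores of the neutral variants for that mechanism.
#' @export
null_distribution <- function(variants, proteins, mechanism) {
  variants <- as_variant_list(variants)
  scores <- vapply(variants, function(v) {
    p <- get_protein(proteins, v$protein_id)
    tr <- p$tracks[[mechanism]]
    if (is.null(tr)) stop("protein ", p$id, " lacks track ", mechanism)
    impact_score(v, tr)
  }, 0L)
  structure(list(mechanism = mechanism, scores = scores),
            class = "impact_null")
}

#' Empirical P-value against a null score multiset
#'
#' The fraction of null scores at least as high as the observed score --
#' a literal fraction that can be exactly zero. \code{add_one = TRUE}
#' switches to the (k+1)/(n+1) convention for users needing strictly
#' positive P-values.
#'
#' @param score observed impact score.
#' @param null an \code{impact_null} or numeric vector of null scores.
#' @param add_one logical, default \code{FALSE}.
#' @return P-value in \code{[0, 1]}.
#' @export
empirical_p <- function(score, null, add_one = FALSE) {
  ns <- if (inherits(null, "impact_null")) null$scores else null
  if (!length(ns)) stop("empty null distribution")
  k <- sum(ns >= score)
  if (add_one) (k + 1) / (length(ns) + 1) else k / length(ns)
}

#' Prior-corrected P-value
#'
#' Corrects the empirical P-value for the frequency alpha of the mechanism:
#' \code{P' = (1 - alpha) * P}. The correction is the numerator of the
#' false-discovery-rate identity (see \code{\link{fdr_from_rates}}) with the
#' P-value standing in for the false-positive rate, and makes P-values
#' comparable across mechanisms of different prevalence. With
#' \code{alpha = 0} it is the identity.
#'
#' @param p empirical P-value in \code{[0, 1]}.
#' @param alpha class prior (mechanism frequency) in \code{[0, 1)}.
#' @return corrected P-value \code{P'} with \code{P' <= P}.
#' @export
prior_correct <- function(p, alpha) {
  if (any(alpha < 0 | alpha >= 1)) stop("alpha must lie in [0, 1)")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  (1 - alpha) * p
}

#' False discovery rate from class prior and error rates
#'
#' \code{FDR = (1 - alpha) FPR / (alpha TPR + (1 - alpha) FPR)}: the rate at
#' which positive calls are false when a fraction \code{alpha} of the
#' population is truly positive. Dropping the denominator and reading the
#' P-value as the FPR yields the prior-corrected P-value of
#' \code{\link{prior_correct}}.
#'
#' @param alpha class prior in \code{[0, 1]}.
#' @param fpr,tpr false/true positive rates in \code{[0, 1]}.
#' @return FDR in \code{[0, 1]}.
#' @export
fdr_from_rates <- function(alpha, fpr, tpr) {
  den <- alpha * tpr + (1 - alpha) * fpr
  if (any(den == 0)) stop("zero denominator: alpha*TPR + (1-alpha)*FPR")
  (1 - alpha) * fpr / den
}

#' Impact results for one variant across mechanisms
#'
#' @param v an \code{indel_variant}.
#' @param protein its \code{protein_record} (tracks provide scores,
#'   thresholds and alphas).
#' @param nulls named list of \code{impact_null} objects (or numeric
#'   vectors), one per mechanism to test.
#' @param alphas optional named numeric vector of class priors; overrides the
#'   track alphas. Mechanisms with no alpha from either source use 0 (no
#'   correction).
#' @return data.frame with one row per mechanism: \code{mechanism},
#'   \code{impact_score}, \code{p_value}, \code{alpha}, \code{p_prime},
#'   \code{significant} (\code{p_prime < 0.05}).
#' @export
impact_results <- function(v, protein, nulls, alphas = NULL) {
  mechs <- names(nulls)
  if (!length(mechs)) stop("no mechanisms to test")
  rows <- lapply(mechs, function(m) {
    tr <- protein$tracks[[m]]
    if (is.null(tr)) stop("protein ", protein$id, " lacks track ", m)
    if (is.null(nulls[[m]])) stop("mechanism ", m, " has no null distribution")
    a <- if (!is.null(alphas) && m %in% names(alphas)) alphas[[m]]
         else if (!is.na(tr$alpha)) tr$alpha else 0
    s <- impact_score(v, tr)
    p <- empirical_p(s, nulls[[m]])
    pp <- prior_correct(p, a)
    data.frame(mechanism = m, impact_score = s, p_value = p, alpha = a,
               p_prime = pp, significant = pp < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Top significantly impacted mechanisms for a variant
#'
#' Computes \code{\link{impact_results}} and returns at most \code{top} rows
#' with prior-corrected P below 0.05, sorted by ascending \code{p_prime};
#' ties are broken by larger impact score, then mechanism name, so the output
#' does not depend on the input mechanism order.
#'
#' @inheritParams impact_results
#' @param top maximum number of mechanisms reported (default 5).
#' @return data.frame as in \code{\link{impact_results}}, possibly empty.
#' @export
rank_mechanisms <- function(v, protein, nulls, alphas = NULL, top = 5L) {
  res <- impact_results(v, protein, nulls, alphas)
  res <- res[res$significant, , drop = FALSE]
  if (!nrow(res)) return(res)
  ord <- order(res$p_prime, -res$impact_score, res$mechanism)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, top)
}

#' Conservative class-prior estimate from score samples
#'
#' Estimates the fraction alpha of an unlabeled sample drawn from the
#' positive component, given score samples from the unlabeled set and from
#' known positives. At upper-tail thresholds t (the 50th-90th percentiles of
#' the positive scores) the exceedance ratio
#' \code{Pr(unlabeled >= t) / Pr(positive >= t)} approaches alpha when
#' negatives rarely reach t (an Elkan-Noto-style ratio); the estimator
#' returns the median ratio over those thresholds, capped into
#' \code{[0, 0.99]}. Thresholds keeping fewer than \code{min_tail} positives
#' are skipped to control variance. The estimate is conservative (biased up)
#' when negatives overlap the positive tail; a directly configured alpha
#' should always take precedence over it.
#'
#' @param scores_unlabeled,scores_positive numeric score samples.
#' @param min_tail minimum positive-tail count per candidate threshold.
#' @return estimate in \code{[0, 0.99]}.
#' @export
naive_alpha_estimate <- function(scores_unlabeled, scores_positive,
                                 min_tail = 10L) {
  if (!length(scores_unlabeled) || !length(scores_positive))
    stop("both samples must be nonempty")
  cand <- unique(stats::quantile(scores_positive,
                                 probs = seq(0.5, 0.9, by = 0.1),
                                 names = FALSE))
  ratios <- numeric(0)
  for (t in cand) {
    np <- sum(scores_positive >= t)
    if (np < min_tail) next
    ratios <- c(ratios,
                (sum(scores_unlabeled >= t) / length(scores_unlabeled)) /
                  (np / length(scores_positive)))
  }
  if (!length(ratios)) return(0.99)
  min(max(stats::median(ratios), 0), 0.99)
}

#' Flag variants as predicted-impacting by the percentile rule
#'
#' Cohort-level analyses call a variant "predicted" to impact a mechanism
#' when its impact score is at or above the 95th percentile of the neutral
#' score distribution -- a rule distinct from the P < 0.05 significance call.
#'
#' @param scores numeric impact scores to flag.
#' @param null neutral scores (an \code{impact_null} or numeric vector).
#' @param percentile percentile of the null used as the cutoff (default 95).
#' @return logical vector.
#' @export
predicted_by_percentile <- function(scores, null, percentile = 95) {
  ns <- if (inherits(null, "impact_null")) null$scores else null
  scores >= stats::quantile(ns, percentile / 100)
}

#' Restrict a cohort to single-residue variants
#'
#' Cohort functional analyses exclude variants impacting more than one
#' residue, so that the greater footprint of long indels does not distort
#' mechanism comparisons: kept are single-residue deletions and
#' single-residue insertions/complex events (at most one residue deleted and
#' at most one inserted).
#'
#' @param variants list of \code{indel_variant} or a variant data.frame.
#' @return logical keep-vector aligned with the input.
#' @export
single_residue_filter <- function(variants) {
  variants <- as_variant_list(variants)
  vapply(variants, function(v)
    nchar(v$deleted_seq) <= 1L && nchar(v$inserted_seq) <= 1L, TRUE)
}
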
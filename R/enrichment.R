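# Cohort-level statistics: fraction of variants whose directly modified
# residues carry a confidently predicted mechanism, the trend/enrichment
# value E, Fisher's exact tests with Bonferroni correction, and recurrence
# stratification of somatic variants.

#' Fraction of variants impacting a mechanism
#'
#' A variant impacts the mechanism when at least one of its directly modified
#' residues (\code{\link{impacted_residues}} with \code{mode = "enrichment"}:
#' the deleted span, or the two residues either side of an insertion point)
#' scores at or above the track's confident threshold.
#'
#' @param variants cohort (list of \code{indel_variant} or data.frame);
#'   cohort-level analyses expect canonical-isoform variants.
#' @param proteins named list of \code{protein_record} objects.
#' @param mechanism track name.
#' @return list with \code{fraction}, \code{impacted} (count) and
#'   \code{total}.
#' @export
fraction_impacting <- function(variants, proteins, mechanism) {
  variants <- as_variant_list(variants)
  if (!length(variants)) stop("empty cohort")
  hit <- vapply(variants, function(v) {
    p <- get_protein(proteins, v$protein_id)
    tr <- p$tracks[[mechanism]]
    if (is.null(tr)) stop("protein ", p$id, " lacks track ", mechanism)
    pos <- impacted_residues(v, length(tr$scores), mode = "enrichment")
    any(tr$scores[pos] >= tr$confident_threshold)
  }, TRUE)
  list(fraction = mean(hit), impacted = sum(hit), total = length(hit))
}

#' Trend (enrichment) value E
#'
#' \code{E = (F_pathogenic - F_neutral) / (F_pathogenic + F_neutral)}, a
#' normalised difference of impacted fractions in \code{[-1, 1]}. Positive
#' values indicate an excess of functional impact among residues modified by
#' pathogenic variants; negative values an excess among neutral variants.
#' Undefined (NA) when both fractions are zero.
#'
#' @param f_pathogenic,f_neutral impacted fractions in \code{[0, 1]}.
#' @return E in \code{[-1, 1]}, or \code{NA} when both fractions are 0.
#' @export
enrichment_value <- function(f_pathogenic, f_neutral) {
  if (any(c(f_pathogenic, f_neutral) < 0 | c(f_pathogenic, f_neutral) > 1))
    stop("fractions must lie in [0, 1]")
  den <- f_pathogenic + f_neutral
  if (den == 0) return(NA_real_)
  (f_pathogenic - f_neutral) / den
}

#' Fisher's exact test with Bonferroni correction
#'
#' Two-sided Fisher's exact test (point-probability criterion) on a 2x2
#' count table, with the Bonferroni-corrected P for a family of
#' \code{n_tests} tests.
#'
#' @param table 2x2 matrix or length-4 vector
#'   \code{(a, b, c, d)} read row-wise: rows = cohorts (or gene classes),
#'   columns = impacted / not impacted.
#' @param n_tests number of tests in the family (default 1).
#' @return list with \code{p}, \code{p_bonferroni} (capped at 1),
#'   \code{significant} (\code{p_bonferroni < 0.05}) and \code{odds_ratio}.
#' @examples
#' # high-scoring variant counts in cancer vs other genes at the 10% FPR cutoff
#' fisher_enrichment(c(478, 1169 - 478, 3135, 11454 - 3135))
#' @export
fisher_enrichment <- function(table, n_tests = 1L) {
  m <- if (is.matrix(table)) table else matrix(as.numeric(table), 2L,
                                               byrow = TRUE)
  if (!all(dim(m) == c(2L, 2L))) stop("table must be 2x2")
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  if (n_tests < 1L) stop("n_tests must be >= 1")
  ft <- stats::fisher.test(m)
  p_b <- min(1, ft$p.value * n_tests)
  list(p = ft$p.value, p_bonferroni = p_b, significant = p_b < 0.05,
       odds_ratio = unname(ft$estimate))
}

#' Stratify variants by residue recurrence
#'
#' A variant's recurrence is the maximum observation count over its directly
#' modified residues, with counts supplied externally (e.g. missense plus
#' indel hits per residue across a somatic catalogue). Residues hit more
#' than once make a variant \code{"recurrent"}; residues hit at least 25
#' times make it \code{"highly_recurrent"}.
#'
#' @param variants cohort (list or data.frame).
#' @param hit_counts data.frame with columns \code{protein_id},
#'   \code{position}, \code{count}; unlisted residues count as 0.
#' @param proteins named list of \code{protein_record} (for protein lengths).
#' @param recurrent_min,highly_recurrent_min count cutoffs (2 and 25).
#' @return character vector per variant: \code{"non_recurrent"},
#'   \code{"recurrent"} or \code{"highly_recurrent"}, with the per-variant
#'   maximum count in attribute \code{"count"}.
#' @export
label_recurrence <- function(variants, hit_counts, proteins,
                             recurrent_min = 2L, highly_recurrent_min = 25L) {
  variants <- as_variant_list(variants)
  key <- paste(hit_counts$protein_id, hit_counts$position)
  lookup <- stats::setNames(hit_counts$count, key)
  counts <- vapply(variants, function(v) {
    L <- nchar(get_protein(proteins, v$protein_id)$sequence)
    pos <- impacted_residues(v, L, mode = "enrichment")
    k <- lookup[paste(v$protein_id, pos)]
    max(c(0, k), na.rm = TRUE)
  }, 0)
  lab <- ifelse(counts >= highly_recurrent_min, "highly_recurrent",
                ifelse(counts >= recurrent_min, "recurrent", "non_recurrent"))
  attr(lab, "count") <- counts
  lab
}

#' Cohort enrichment report across mechanisms
#'
#' For each mechanism: impacted fractions in the pathogenic and neutral
#' cohorts, the trend value E, and a two-sided Fisher's exact test on the
#' 2x2 impacted-by-cohort table, Bonferroni-corrected for the number of
#' mechanisms tested. Rows are sorted by decreasing \code{|E|}.
#'
#' @param path_variants,neut_variants pathogenic and neutral cohorts
#'   (canonical-isoform variants).
#' @param proteins named list of \code{protein_record} objects.
#' @param mechanisms character vector of track names; all are tested and
#'   \code{n_tests = length(mechanisms)}.
#' @return data.frame with columns \code{mechanism}, \code{f_pathogenic},
#'   \code{f_neutral}, \code{E}, \code{fisher_p}, \code{bonferroni_p},
#'   \code{significant}, plus the four table counts; the number of tests is
#'   in attribute \code{"n_tests"}.
#' @export
enrichment_report <- function(path_variants, neut_variants, proteins,
                              mechanisms) {
  if (!length(mechanisms)) stop("empty mechanism list")
  n_tests <- length(mechanisms)
  rows <- lapply(mechanisms, function(m) {
    fp <- fraction_impacting(path_variants, proteins, m)
    fn <- fraction_impacting(neut_variants, proteins, m)
    tab <- c(fp$impacted, fp$total - fp$impacted,
             fn$impacted, fn$total - fn$impacted)
    ft <- fisher_enrichment(tab, n_tests = n_tests)
    data.frame(mechanism = m, f_pathogenic = fp$fraction,
               f_neutral = fn$fraction,
               E = enrichment_value(fp$fraction, fn$fraction),
               fisher_p = ft$p, bonferroni_p = ft$p_bonferroni,
               significant = ft$significant,
               path_impacted = fp$impacted, path_total = fp$total,
               neut_impacted = fn$impacted, neut_total = fn$total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$E)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tests") <- n_tests
  out
}

#' Deduplicate a variant cohort for functional analyses
#'
#' Keeps one copy per distinct event, keyed by protein, span and the deleted
#' and inserted strings, optionally restricted to canonical proteins first.
#'
#' @param variants cohort (list or data.frame).
#' @param proteins named list of \code{protein_record}; when given, variants
#'   on non-canonical proteins are dropped before deduplication.
#' @return logical keep-vector aligned with the input.
#' @export
dedupe_filter <- function(variants, proteins = NULL) {
  variants <- as_variant_list(variants)
  keep <- rep(TRUE, length(variants))
  if (!is.null(proteins))
    keep <- vapply(variants, function(v)
      get_protein(proteins, v$protein_id)$canonical, TRUE)
  key <- vapply(variants, function(v)
    paste(v$protein_id, v$start, v$end, v$deleted_seq, v$inserted_seq),
    "")
  keep & !duplicated(key)
}
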
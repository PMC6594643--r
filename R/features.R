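# Per-variant feature engineering: general sequence features, local amino-acid
# composition, repeat runs, conservation aggregation, homolog-count bins and
# confident functional-residue counts at windows 4 / 20 / whole protein.

#' General variant features
#'
#' Relative position of the variant in the protein (start over length) and the
#' numbers of residues inserted and deleted.
#'
#' @param v an \code{indel_variant}.
#' @param L protein length.
#' @return named numeric vector \code{rel_pos}, \code{n_inserted},
#'   \code{n_deleted}.
#' @export
general_features <- function(v, L) {
  c(rel_pos = v$start / L,
    n_inserted = nchar(v$inserted_seq),
    n_deleted = nchar(v$deleted_seq))
}

#' Amino-acid frequencies in the flanking windows
#'
#' Frequencies of the 20 standard amino acids over the ten wildtype residues
#' on either side of the variant span (deleted residues excluded; for an
#' insertion, ten on each side of the insertion boundary). Windows shrink at
#' the termini and frequencies are normalised by the number of standard
#' residues actually present, so they always sum to one when the window is
#' nonempty.
#'
#' @param v an \code{indel_variant}.
#' @param sequence wildtype amino-acid string.
#' @return numeric vector of length 20 named by residue letter.
#' @export
window_aa_frequency <- function(v, sequence) {
  L <- nchar(sequence)
  if (variant_kind(v) == "insertion") {
    pos <- c(seq2(v$start - 9L, v$start), seq2(v$start + 1L, v$start + 10L))
  } else {
    pos <- c(seq2(v$start - 10L, v$start - 1L), seq2(v$end + 1L, v$end + 10L))
  }
  pos <- pos[pos >= 1L & pos <= L]
  out <- stats::setNames(numeric(20), AA20)
  if (!length(pos)) return(out)
  letters_here <- strsplit(sequence, "")[[1]][pos]
  tab <- table(factor(letters_here, levels = AA20))
  n <- sum(tab)  # X residues occupy the window but carry no composition bin
  if (n > 0) out[] <- as.numeric(tab) / n
  out
}

seq2 <- function(a, b) if (b < a) integer(0) else a:b

#' Length of the single amino-acid repeat at the variant site
#'
#' The maximal run of one repeated amino acid containing the variant site;
#' 1 when the site does not lie in a repeat. For deletions and complex indels
#' the maximum run over the deleted span is taken; for insertions the two
#' residues flanking the insertion point are examined and the longer
#' containing run reported.
#'
#' @param v an \code{indel_variant}.
#' @param sequence wildtype amino-acid string.
#' @return positive integer run length.
#' @export
repeat_run_length <- function(v, sequence) {
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  r <- rle(chars)
  run_id <- rep.int(seq_along(r$lengths), r$lengths)
  pos <- if (variant_kind(v) == "insertion") {
    c(v$start, v$start + 1L)
  } else {
    v$start:v$end
  }
  pos <- pos[pos >= 1L & pos <= L]
  if (!length(pos)) return(1L)
  max(r$lengths[unique(run_id[pos])])
}

#' Aggregate a conservation index over the variant site
#'
#' Deletions and complex indels take the maximum of the per-position index
#' over the deleted span. An insertion of k residues after position p takes
#' the maximum over the window p..p+k-1, i.e. starting from the first residue
#' prior to the insertion site with window size equal to the number of
#' inserted residues. Windows are clipped to the protein; a window clipped to
#' nothing (N-terminal single-residue insertion) falls back to the first
#' residue.
#'
#' @param v an \code{indel_variant}.
#' @param cons numeric per-position vector of protein length.
#' @return scalar maximum index value.
#' @export
conservation_feature <- function(v, cons) {
  L <- length(cons)
  if (variant_kind(v) == "insertion") {
    k <- nchar(v$inserted_seq)
    pos <- seq2(v$start, v$start + k - 1L)
  } else {
    pos <- v$start:v$end
  }
  pos <- pos[pos >= 1L & pos <= L]
  if (!length(pos)) pos <- min(max(v$start, 1L), L)
  max(cons[pos])
}

#' Homolog counts binned by percent identity
#'
#' Cumulative counts of homologs at identity thresholds 50, 55, ..., 95
#' percent: bin i holds the number of homologs with identity at or above the
#' i-th threshold (100% identity therefore falls in every bin).
#'
#' @param identities numeric vector of percent identities in \code{[0, 100]}.
#' @return integer vector of 10 counts named \code{ge50} ... \code{ge95}.
#' @export
homolog_count_features <- function(identities) {
  thr <- seq(50, 95, by = 5)
  stats::setNames(vapply(thr, function(t) sum(identities >= t), 0L),
                  paste0("ge", thr))
}

#' Confident functional-residue counts around the variant
#'
#' Number of residues whose track score meets the confident threshold within
#' 4 and within 20 residues of the variant span, and over the whole protein.
#' Windows are \code{[start - w, end + w]} clipped at the termini; deleted
#' residues are included.
#'
#' @param v an \code{indel_variant}.
#' @param track a \code{\link{property_track}}.
#' @return integer vector \code{w4}, \code{w20}, \code{whole}.
#' @export
functional_residue_counts <- function(v, track) {
  hits <- track$scores >= track$confident_threshold
  L <- length(hits)
  one <- function(w) {
    lo <- max(1L, v$start - w); hi <- min(L, v$end + w)
    if (hi < lo) 0L else sum(hits[lo:hi])
  }
  c(w4 = one(4L), w20 = one(20L), whole = sum(hits))
}

#' Feature configuration
#'
#' Declares which feature groups enter the per-variant vector and which named
#' inputs each group consumes. Groups: \code{general} (3 features),
#' \code{composition} (20 amino-acid frequencies + repeat length),
#' \code{conservation} (one max-over-site feature per named conservation
#' index; a PSSM-derived per-position vector may be attached under its own
#' name and is aggregated by the same rule), \code{homologs} (10 identity
#' bins x human/mouse), \code{functional} (3 window counts per mechanism) and
#' \code{gene} (gene-level scores passed through, plus one presence flag).
#'
#' @param mechanisms character vector of track names (functional group).
#' @param conservation character vector of conservation index names.
#' @param homologs logical; include homolog-count bins.
#' @param gene_scores integer; length of the gene-level score vector
#'   (0 disables the group).
#' @param general,composition logicals; include those groups.
#' @return an object of class \code{"feature_config"}.
#' @export
feature_config <- function(mechanisms = character(0),
                           conservation = character(0),
                           homologs = TRUE, gene_scores = 0L,
                           general = TRUE, composition = TRUE) {
  structure(list(mechanisms = mechanisms, conservation = conservation,
                 homologs = isTRUE(homologs),
                 gene_scores = as.integer(gene_scores),
                 general = isTRUE(general), composition = isTRUE(composition)),
            class = "feature_config")
}

#' Names and group labels of the configured feature vector
#'
#' @param config a \code{\link{feature_config}}.
#' @return data.frame with columns \code{name} and \code{group}, in the fixed
#'   vector order.
#' @export
feature_layout <- function(config) {
  nm <- character(0); gr <- character(0)
  add <- function(names, group) {
    nm <<- c(nm, names); gr <<- c(gr, rep(group, length(names)))
  }
  if (config$general) add(c("rel_pos", "n_inserted", "n_deleted"), "general")
  if (config$composition) add(c(paste0("comp_", AA20), "repeat_len"),
                              "composition")
  for (cn in config$conservation) add(paste0("cons_", cn), "conservation")
  if (config$homologs)
    add(c(paste0("hom_human_ge", seq(50, 95, 5)),
          paste0("hom_mouse_ge", seq(50, 95, 5))), "homologs")
  for (mech in config$mechanisms)
    add(paste0("fn_", mech, "_", c("w4", "w20", "whole")), "functional")
  if (config$gene_scores > 0L)
    add(c(paste0("gene_", seq_len(config$gene_scores)), "gene_present"),
        "gene")
  data.frame(name = nm, group = gr, stringsAsFactors = FALSE)
}

#' Assemble the feature vector for one variant
#'
#' Deterministic, fixed-order assembly of all configured feature groups from
#' the variant and its protein record. Required inputs (tracks, conservation
#' indexes) missing from the protein raise an error naming them; the optional
#' gene-score group is imputed as zeros with its presence flag set to 0 when
#' a protein carries no scores.
#'
#' @param v an \code{indel_variant}.
#' @param protein the matching \code{\link{protein_record}}.
#' @param config a \code{\link{feature_config}}.
#' @return named numeric vector following \code{\link{feature_layout}}, with
#'   the group labels in attribute \code{"group"}.
#' @export
assemble_feature_vector <- function(v, protein, config) {
  L <- nchar(protein$sequence)
  missing_tracks <- setdiff(config$mechanisms, names(protein$tracks))
  missing_cons <- setdiff(config$conservation, names(protein$conservation))
  if (length(missing_tracks) || length(missing_cons))
    stop("protein ", protein$id, " lacks required inputs: ",
         paste(c(missing_tracks, missing_cons), collapse = ", "))
  out <- numeric(0)
  if (config$general) out <- c(out, general_features(v, L))
  if (config$composition)
    out <- c(out, window_aa_frequency(v, protein$sequence),
             repeat_len = repeat_run_length(v, protein$sequence))
  for (cn in config$conservation)
    out <- c(out, conservation_feature(v, protein$conservation[[cn]]))
  if (config$homologs)
    out <- c(out, homolog_count_features(protein$homologs$human),
             homolog_count_features(protein$homologs$mouse))
  for (mech in config$mechanisms)
    out <- c(out, functional_residue_counts(v, protein$tracks[[mech]]))
  if (config$gene_scores > 0L) {
    g <- protein$gene_scores
    if (is.null(g)) {
      out <- c(out, rep(0, config$gene_scores), 0)
    } else {
      if (length(g) != config$gene_scores)
        stop("gene_scores of ", protein$id, " has length ", length(g),
             ", config expects ", config$gene_scores)
      out <- c(out, g, 1)
    }
  }
  layout <- feature_layout(config)
  names(out) <- layout$name
  if (anyNA(out) || any(!is.finite(out)))
    stop("non-finite feature value for variant on ", protein$id)
  attr(out, "group") <- layout$group
  out
}

#' Feature matrix for a variant cohort
#'
#' @param variants list of \code{indel_variant} objects (or a data.frame per
#'   \code{\link{read_variant_table}}, converted internally).
#' @param proteins named list of \code{protein_record} objects.
#' @param config a \code{\link{feature_config}}.
#' @return numeric matrix, one row per variant, columns per
#'   \code{\link{feature_layout}}; group labels in attribute \code{"group"},
#'   labels in attribute \code{"label"}.
#' @export
feature_matrix <- function(variants, proteins, config) {
  variants <- as_variant_list(variants)
  layout <- feature_layout(config)
  X <- matrix(0, nrow = length(variants), ncol = nrow(layout),
              dimnames = list(NULL, layout$name))
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    X[i, ] <- assemble_feature_vector(v, get_protein(proteins, v$protein_id),
                                      config)
  }
  attr(X, "group") <- layout$group
  attr(X, "label") <- vapply(variants, `[[`, "", "label")
  X
}

as_variant_list <- function(variants) {
  if (is.data.frame(variants)) return(variant_table_to_list(variants))
  if (inherits(variants, "indel_variant")) return(list(variants))
  variants
}
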
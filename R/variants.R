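#' Construct a non-frameshifting indel variant
#'
#' An indel variant lives on a protein sequence and is described by a 1-based
#' inclusive residue span plus the deleted and inserted amino-acid strings.
#' Pure insertions use the convention "insert after residue \code{p}" with
#' \code{start == end == p} and \code{p} in \code{[0, L]} (\code{p = 0} is an
#' N-terminal insertion); for them \code{deleted_seq} is empty. Pure deletions
#' have an empty \code{inserted_seq}; events with both strings nonempty are
#' complex indels (deletion-insertion at one locus).
#'
#' @param protein_id identifier of the protein the variant lies on.
#' @param start,end 1-based inclusive residue span (insertions: both equal the
#'   residue immediately preceding the insertion point, 0 allowed).
#' @param deleted_seq,inserted_seq amino-acid strings; at least one nonempty.
#' @param label one of \code{"pathogenic"}, \code{"neutral"},
#'   \code{"unlabeled"}.
#' @param allele_count optional nonnegative integer (population allele count).
#' @param recurrence_count optional nonnegative integer (times the impacted
#'   residue has been observed hit in a somatic catalogue).
#' @param sequence optional wildtype sequence; when given, coordinates and
#'   \code{deleted_seq} are validated against it.
#' @return an object of class \code{"indel_variant"}.
#' @examples
#' indel_variant("P1", 3, 4, "KL", "", sequence = "MAKLG")   # deletion
#' indel_variant("P1", 2, 2, "", "Q", sequence = "MAKLG")    # insertion after 2
#' @export
indel_variant <- function(protein_id, start, end, deleted_seq = "",
                          inserted_seq = "", label = "unlabeled",
                          allele_count = NA_integer_,
                          recurrence_count = NA_integer_,
                          sequence = NULL) {
  deleted_seq <- toupper(as.character(deleted_seq))
  inserted_seq <- toupper(as.character(inserted_seq))
  if (is.na(deleted_seq)) deleted_seq <- ""
  if (is.na(inserted_seq)) inserted_seq <- ""
  start <- as.integer(start); end <- as.integer(end)
  if (!nzchar(deleted_seq) && !nzchar(inserted_seq))
    stop("variant must delete and/or insert at least one residue")
  label <- match.arg(label, c("pathogenic", "neutral", "unlabeled"))
  if (nzchar(deleted_seq)) {
    if (start < 1L || end < start)
      stop("deletion span must satisfy 1 <= start <= end")
    if (nchar(deleted_seq) != end - start + 1L)
      stop("deleted_seq length does not match span ", start, "..", end)
  } else {
    if (start != end) stop("pure insertion must have start == end")
    if (start < 0L) stop("insertion point must be >= 0")
  }
  v <- structure(list(protein_id = as.character(protein_id),
                      start = start, end = end,
                      deleted_seq = deleted_seq, inserted_seq = inserted_seq,
                      label = label,
                      allele_count = as.integer(allele_count),
                      recurrence_count = as.integer(recurrence_count)),
                 class = "indel_variant")
  if (!is.null(sequence)) validate_variant(v, sequence)
  v
}

#' @export
print.indel_variant <- function(x, ...) {
  cat(sprintf("<indel_variant> %s %s %s [%s]\n", x$protein_id,
              format_variant(x), variant_kind(x), x$label))
  invisible(x)
}

format_variant <- function(v) {
  switch(variant_kind(v),
         insertion = sprintf("ins %s after %d", v$inserted_seq, v$start),
         deletion  = sprintf("del %d-%d (%s)", v$start, v$end, v$deleted_seq),
         complex   = sprintf("delins %d-%d %s>%s", v$start, v$end,
                             v$deleted_seq, v$inserted_seq))
}

#' Validate a variant against its wildtype sequence
#'
#' Checks that the span lies inside the sequence and that \code{deleted_seq},
#' when nonempty, equals the wildtype residues at \code{start..end}.
#'
#' @param v an \code{indel_variant}.
#' @param sequence wildtype amino-acid string.
#' @return \code{v}, invisibly; errors on mismatch.
#' @export
validate_variant <- function(v, sequence) {
  L <- nchar(sequence)
  if (nzchar(v$deleted_seq)) {
    if (v$end > L) stop("variant span ", v$start, "..", v$end,
                        " exceeds protein length ", L)
    ref <- substr(sequence, v$start, v$end)
    if (ref != v$deleted_seq)
      stop("reference mismatch at ", v$start, "..", v$end, ": sequence has '",
           ref, "', variant states '", v$deleted_seq, "'")
  } else if (v$start > L) {
    stop("insertion point ", v$start, " exceeds protein length ", L)
  }
  invisible(v)
}

#' Classify a variant as insertion, deletion or complex
#'
#' The kind is a pure function of the two sequences: insertion iff nothing is
#' deleted, deletion iff nothing is inserted, complex otherwise.
#'
#' @param v an \code{indel_variant}.
#' @return one of \code{"insertion"}, \code{"deletion"}, \code{"complex"}.
#' @export
variant_kind <- function(v) {
  if (!nzchar(v$deleted_seq)) "insertion"
  else if (!nzchar(v$inserted_seq)) "deletion"
  else "complex"
}

#' Parse HGVS-style protein indel notation
#'
#' Supports the three non-frameshifting grammars on one-letter amino-acid
#' codes: \code{p.K3del} / \code{p.K3_L4del}, \code{p.A2_K3insQ}, and
#' \code{p.K3delinsW} / \code{p.K3_G5delinsWW}. Stated residues are checked
#' against the sequence; insertions use the "insert after residue p"
#' convention, with p the left member of the flanking pair.
#'
#' @param text notation string (leading \code{"p."} optional).
#' @param sequence wildtype amino-acid string.
#' @param protein_id identifier recorded on the variant.
#' @param ... further arguments (e.g. \code{label}) passed to
#'   \code{\link{indel_variant}}.
#' @return an \code{indel_variant}.
#' @examples
#' parse_variant_notation("p.K3_L4del", "MAKLG", "P1")
#' @export
parse_variant_notation <- function(text, sequence, protein_id = "protein",
                                   ...) {
  s <- sub("^p\\.", "", trimws(text))
  aa <- "[A-Z]"
  m <- regmatches(s, regexec(paste0("^(", aa, ")(\\d+)(?:_(", aa,
                                    ")(\\d+))?delins(", aa, "+)$"), s))[[1]]
  if (length(m)) {  # delins: complex indel
    p1 <- as.integer(m[3])
    p2 <- if (nzchar(m[5])) as.integer(m[5]) else p1
    check_ref(sequence, p1, m[2], text)
    if (nzchar(m[4])) check_ref(sequence, p2, m[4], text)
    if (p2 < p1) stop("malformed notation (end before start): ", text)
    return(indel_variant(protein_id, p1, p2, substr(sequence, p1, p2), m[6],
                         sequence = sequence, ...))
  }
  m <- regmatches(s, regexec(paste0("^(", aa, ")(\\d+)(?:_(", aa,
                                    ")(\\d+))?del$"), s))[[1]]
  if (length(m)) {  # deletion
    p1 <- as.integer(m[3])
    p2 <- if (nzchar(m[5])) as.integer(m[5]) else p1
    check_ref(sequence, p1, m[2], text)
    if (nzchar(m[4])) check_ref(sequence, p2, m[4], text)
    if (p2 < p1) stop("malformed notation (end before start): ", text)
    return(indel_variant(protein_id, p1, p2, substr(sequence, p1, p2), "",
                         sequence = sequence, ...))
  }
  m <- regmatches(s, regexec(paste0("^(", aa, ")(\\d+)_(", aa, ")(\\d+)ins(",
                                    aa, "+)$"), s))[[1]]
  if (length(m)) {  # insertion between a flanking residue pair
    p1 <- as.integer(m[3]); p2 <- as.integer(m[5])
    if (p2 != p1 + 1L)
      stop("insertion flanks must be adjacent residues: ", text)
    check_ref(sequence, p1, m[2], text)
    check_ref(sequence, p2, m[4], text)
    return(indel_variant(protein_id, p1, p1, "", m[6],
                         sequence = sequence, ...))
  }
  stop("unrecognised protein indel notation: ", text)
}

check_ref <- function(sequence, pos, stated, text) {
  if (pos < 1L || pos > nchar(sequence))
    stop("position ", pos, " outside protein (", text, ")")
  actual <- substr(sequence, pos, pos)
  if (actual != stated)
    stop("reference mismatch in ", text, ": residue ", pos, " is ", actual,
         ", not ", stated)
}

#' Apply a variant to the wildtype sequence
#'
#' @param sequence wildtype amino-acid string.
#' @param v an \code{indel_variant} valid on \code{sequence}.
#' @return the mutant sequence; its length differs from the wildtype by
#'   \code{nchar(inserted_seq) - nchar(deleted_seq)}.
#' @examples
#' v <- indel_variant("P1", 3, 4, "KL", "")
#' apply_variant("MAKLG", v)  # "MAG"
#' @export
apply_variant <- function(sequence, v) {
  validate_variant(v, sequence)
  if (nzchar(v$deleted_seq)) {
    paste0(substr(sequence, 1L, v$start - 1L), v$inserted_seq,
           substr(sequence, v$end + 1L, nchar(sequence)))
  } else {
    paste0(substr(sequence, 1L, v$start), v$inserted_seq,
           substr(sequence, v$start + 1L, nchar(sequence)))
  }
}

#' Wildtype residues impacted by a variant
#'
#' Two window conventions are used by the downstream statistics.
#' \code{mode = "impact"} (per-variant functional impact): the deleted span
#' plus three flanking residues on either side; for insertions, three residues
#' on each side of the insertion boundary. \code{mode = "enrichment"}
#' (cohort-level trend value): only the deleted span for deletions and complex
#' indels, and the two residues on either side of the insertion point for
#' insertions. Positions are clipped to \code{[1, L]}; truncation at the
#' termini is silent.
#'
#' @param v an \code{indel_variant}.
#' @param L wildtype protein length.
#' @param mode \code{"impact"} or \code{"enrichment"}.
#' @return increasing integer vector of 1-based wildtype positions.
#' @examples
#' v <- indel_variant("P", 5, 6, "AA", "")
#' impacted_residues(v, 20, "impact")       # 2..9
#' impacted_residues(v, 20, "enrichment")   # 5..6
#' @export
impacted_residues <- function(v, L, mode = c("impact", "enrichment")) {
  mode <- match.arg(mode)
  ins <- variant_kind(v) == "insertion"
  if (mode == "impact") {
    rng <- if (ins) c(v$start - 2L, v$start + 3L)
           else c(v$start - 3L, v$end + 3L)
  } else {
    rng <- if (ins) c(v$start - 1L, v$start + 2L) else c(v$start, v$end)
  }
  lo <- max(1L, rng[1]); hi <- min(as.integer(L), rng[2])
  if (hi < lo) integer(0) else lo:hi
}
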
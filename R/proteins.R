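#' Protein record with attached per-residue tracks
#'
#' Bundles a wildtype sequence with the per-residue inputs the feature and
#' impact computations consume: property-score tracks (one per structural or
#' functional mechanism, each with its confident threshold at 10% upstream
#' false-positive rate and an optional class prior alpha), conservation-index
#' vectors, optional gene-level function scores, and homolog percent-identity
#' lists for human and mouse.
#'
#' @param id protein identifier.
#' @param sequence amino-acid string (20 standard letters, \code{X} allowed).
#' @param canonical logical; cohort-level analyses are restricted to canonical
#'   isoforms.
#' @param tracks named list of \code{\link{property_track}} objects.
#' @param conservation named list of numeric vectors, each of protein length.
#' @param gene_scores optional numeric vector of gene-level function scores.
#' @param homologs list with numeric elements \code{human} and \code{mouse}
#'   holding percent identities of homologs in each genome.
#' @return an object of class \code{"protein_record"}.
#' @export
protein_record <- function(id, sequence, canonical = TRUE, tracks = list(),
                           conservation = list(), gene_scores = NULL,
                           homologs = list(human = numeric(0),
                                           mouse = numeric(0))) {
  sequence <- toupper(sequence)
  if (grepl(paste0("[^", paste(AA20, collapse = ""), "X]"), sequence))
    stop("sequence of ", id, " contains non amino-acid characters")
  p <- structure(list(id = as.character(id), sequence = sequence,
                      canonical = isTRUE(canonical), tracks = tracks,
                      conservation = conservation, gene_scores = gene_scores,
                      homologs = homologs),
                 class = "protein_record")
  check_track_lengths(p)
  p
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

check_track_lengths <- function(p) {
  L <- nchar(p$sequence)
  for (nm in names(p$tracks))
    if (length(p$tracks[[nm]]$scores) != L)
      stop("track '", nm, "' of ", p$id, " has length ",
           length(p$tracks[[nm]]$scores), ", protein has ", L, " residues")
  for (nm in names(p$conservation))
    if (length(p$conservation[[nm]]) != L)
      stop("conservation '", nm, "' of ", p$id, " has wrong length")
  invisible(p)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  %d aa%s  %d track(s), %d conservation\n",
              x$id, nchar(x$sequence),
              if (x$canonical) " (canonical)" else "",
              length(x$tracks), length(x$conservation)))
  invisible(x)
}

#' Per-residue property-score track for one mechanism
#'
#' Scores are in \code{[0, 1]}; a residue is "confidently predicted" to
#' exhibit the mechanism when its score is at or above
#' \code{confident_threshold}, the cutoff calibrated upstream to a 10%
#' false-positive rate. \code{alpha} is the mechanism's class prior (the
#' frequency of the mechanism), used by the prior-corrected P-value.
#'
#' @param mechanism mechanism name.
#' @param scores numeric vector of per-residue scores in \code{[0, 1]}.
#' @param confident_threshold score cutoff in \code{[0, 1]}.
#' @param alpha optional class prior in \code{[0, 1)}.
#' @return an object of class \code{"property_track"}.
#' @export
property_track <- function(mechanism, scores, confident_threshold,
                           alpha = NA_real_) {
  scores <- as.numeric(scores)
  if (anyNA(scores) || any(scores < 0 | scores > 1))
    stop("track scores must lie in [0, 1]")
  if (confident_threshold < 0 || confident_threshold > 1)
    stop("confident_threshold must lie in [0, 1]")
  if (!is.na(alpha) && (alpha < 0 || alpha >= 1))
    stop("alpha must lie in [0, 1)")
  structure(list(mechanism = as.character(mechanism), scores = scores,
                 confident_threshold = as.numeric(confident_threshold),
                 alpha = as.numeric(alpha)),
            class = "property_track")
}

get_protein <- function(proteins, id) {
  p <- proteins[[id]]
  if (is.null(p)) stop("unknown protein_id: ", id)
  p
}
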
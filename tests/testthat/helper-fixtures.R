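# Shared fixtures, built in code.

# A protein with one mechanism track and one conservation index, fully
# controlled: track scores and threshold given explicitly.
toy_protein <- function(id = "P1", sequence = "MAKLGWQRSTVYACDEFHIN",
                        scores = NULL, threshold = 0.5, cons = NULL) {
  L <- nchar(sequence)
  if (is.null(scores)) scores <- rep(0, L)
  if (is.null(cons)) cons <- seq(0, 1, length.out = L)
  protein_record(id, sequence,
                 tracks = list(mech1 = property_track("mech1", scores,
                                                      threshold)),
                 conservation = list(cons1 = cons))
}

# Random valid variant on a sequence, exercising all three kinds and the
# termini; used by property-style tests.
random_variant <- function(sequence, pid = "P1") {
  L <- nchar(sequence)
  kind <- sample(c("deletion", "insertion", "complex"), 1)
  if (kind == "insertion") {
    p <- sample(0:L, 1)
    indel_variant(pid, p, p, "", paste(sample(indelrisk:::AA20,
                                              sample(1:4, 1), replace = TRUE),
                                       collapse = ""), sequence = sequence)
  } else {
    len <- sample(1:min(5L, L), 1)
    start <- sample(L - len + 1L, 1)
    ins <- if (kind == "complex")
      paste(sample(indelrisk:::AA20, sample(1:3, 1), replace = TRUE),
            collapse = "") else ""
    indel_variant(pid, start, start + len - 1L,
                  substr(sequence, start, start + len - 1L), ins,
                  sequence = sequence)
  }
}

random_aa_sequence <- function(L) {
  paste(sample(indelrisk:::AA20, L, replace = TRUE), collapse = "")
}

# Tiny dataset for fast end-to-end checks in unit tests; dots override the
# small defaults.
tiny_dataset <- function(seed = 1, ...) {
  args <- list(n_proteins = 25L, length_range = c(60L, 100L),
               n_pathogenic = 80L, n_neutral = 120L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_indel_dataset(do.call(simulate_indel_config, args))
}
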
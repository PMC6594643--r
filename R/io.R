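# Readers and writers for the interchange formats: FASTA sequences, TSV
# tables for variants, property tracks, conservation indexes, homolog
# identities and residue hit counts, the prediction output table, and a
# versioned model file. All residue positions in every format are 1-based
# inclusive.

#' Read protein sequences from FASTA
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are uppercased and validated (20 standard letters plus X).
#'
#' @param path FASTA file.
#' @return named list of \code{\link{protein_record}} objects (no tracks
#'   attached yet).
#' @export
read_protein_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  if (!length(aas)) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[[`, "", 1L)
  out <- lapply(seq_along(aas), function(i)
    protein_record(ids[i], as.character(aas[[i]])))
  stats::setNames(out, ids)
}

#' Write protein sequences to FASTA
#'
#' @param proteins named list of \code{protein_record} objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(vapply(proteins, `[[`, "", "sequence"))
  names(seqs) <- vapply(proteins, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

variant_list_to_table <- function(variants) {
  data.frame(protein_id = vapply(variants, `[[`, "", "protein_id"),
             start = vapply(variants, `[[`, 0L, "start"),
             end = vapply(variants, `[[`, 0L, "end"),
             deleted_seq = vapply(variants, `[[`, "", "deleted_seq"),
             inserted_seq = vapply(variants, `[[`, "", "inserted_seq"),
             label = vapply(variants, `[[`, "", "label"),
             allele_count = vapply(variants, `[[`, NA_integer_,
                                   "allele_count"),
             recurrence_count = vapply(variants, `[[`, NA_integer_,
                                       "recurrence_count"),
             stringsAsFactors = FALSE)
}

variant_table_to_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    indel_variant(df$protein_id[i], df$start[i], df$end[i],
                  df$deleted_seq[i], df$inserted_seq[i],
                  label = if ("label" %in% names(df)) df$label[i]
                          else "unlabeled",
                  allele_count = if ("allele_count" %in% names(df))
                    df$allele_count[i] else NA_integer_,
                  recurrence_count = if ("recurrence_count" %in% names(df))
                    df$recurrence_count[i] else NA_integer_))
}

#' Read a variant table
#'
#' Tab-separated with either an \code{hgvs_p} column (parsed against the
#' protein sequence) or explicit \code{start}, \code{end},
#' \code{deleted_seq}, \code{inserted_seq} columns; plus \code{protein_id}
#' and optional \code{label}, \code{allele_count}, \code{recurrence_count}.
#' Every row is validated against its protein; failing rows raise an error
#' naming the line. Allele-count filters reproduce the curation presets of
#' population cohorts: \code{"drop_zero"} removes AC = 0 rows (low-quality
#' calls), \code{"drop_singletons"} removes AC <= 1 (additionally dropping
#' variants seen in a single individual); \code{"none"} keeps everything.
#'
#' @param path TSV file.
#' @param proteins named list of \code{protein_record} objects.
#' @param ac_filter one of \code{"none"}, \code{"drop_zero"},
#'   \code{"drop_singletons"}; applied only to rows with a non-missing
#'   allele count.
#' @return variant data.frame in the explicit-column layout.
#' @export
read_variant_table <- function(path, proteins,
                               ac_filter = c("none", "drop_zero",
                                             "drop_singletons")) {
  ac_filter <- match.arg(ac_filter)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(df)) stop("variant table needs protein_id")
  rows <- lapply(seq_len(nrow(df)), function(i) {
    p <- tryCatch(get_protein(proteins, df$protein_id[i]),
                  error = function(e) stop("line ", i + 1L, ": ",
                                           conditionMessage(e), call. = FALSE))
    v <- tryCatch({
      if ("hgvs_p" %in% names(df) && nzchar(df$hgvs_p[i] %||% "")) {
        parse_variant_notation(df$hgvs_p[i], p$sequence, p$id,
                               label = df$label[i] %||% "unlabeled")
      } else {
        indel_variant(p$id, df$start[i], df$end[i],
                      df$deleted_seq[i] %||% "", df$inserted_seq[i] %||% "",
                      label = df$label[i] %||% "unlabeled",
                      sequence = p$sequence)
      }
    }, error = function(e) stop("line ", i + 1L, ": ",
                                conditionMessage(e), call. = FALSE))
    v$allele_count <- as.integer(df$allele_count[i] %||% NA)
    v$recurrence_count <- as.integer(df$recurrence_count[i] %||% NA)
    v
  })
  out <- variant_list_to_table(rows)
  keep <- switch(ac_filter,
                 none = rep(TRUE, nrow(out)),
                 drop_zero = is.na(out$allele_count) | out$allele_count > 0L,
                 drop_singletons = is.na(out$allele_count) |
                   out$allele_count > 1L)
  out[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Write a variant table
#'
#' @param variants list of \code{indel_variant} or a variant data.frame.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  df <- if (is.data.frame(variants)) variants
        else variant_list_to_table(as_variant_list(variants))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach property tracks from long-format TSV tables
#'
#' The track table has columns \code{protein_id}, \code{position},
#' \code{mechanism}, \code{score}; the threshold table has \code{mechanism},
#' \code{confident_threshold} and optionally \code{alpha}. Every protein
#' position must be covered exactly once per mechanism present for that
#' protein.
#'
#' @param proteins named list of \code{protein_record} objects.
#' @param track_path,threshold_path TSV files.
#' @return the protein list with tracks attached.
#' @export
read_tracks <- function(proteins, track_path, threshold_path) {
  tr <- utils::read.delim(track_path, stringsAsFactors = FALSE)
  th <- utils::read.delim(threshold_path, stringsAsFactors = FALSE)
  if (!"alpha" %in% names(th)) th$alpha <- NA_real_
  for (key in split(seq_len(nrow(tr)),
                    list(tr$protein_id, tr$mechanism), drop = TRUE)) {
    pid <- tr$protein_id[key[1]]
    mech <- tr$mechanism[key[1]]
    p <- get_protein(proteins, pid)
    L <- nchar(p$sequence)
    scores <- rep(NA_real_, L)
    scores[tr$position[key]] <- tr$score[key]
    if (anyNA(scores))
      stop("track ", mech, " does not cover every residue of ", pid)
    j <- match(mech, th$mechanism)
    if (is.na(j)) stop("no confident threshold for mechanism ", mech)
    p$tracks[[mech]] <- property_track(mech, scores,
                                       th$confident_threshold[j],
                                       th$alpha[j])
    proteins[[pid]] <- p
  }
  proteins
}

#' Attach conservation indexes from a long-format TSV
#'
#' Columns: \code{protein_id}, \code{position}, \code{alignment},
#' \code{value}; one conservation vector is attached per alignment name.
#'
#' @param proteins named list of \code{protein_record} objects.
#' @param path TSV file.
#' @return the protein list with conservation attached.
#' @export
read_conservation <- function(proteins, path) {
  cv <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (key in split(seq_len(nrow(cv)),
                    list(cv$protein_id, cv$alignment), drop = TRUE)) {
    pid <- cv$protein_id[key[1]]
    aln <- cv$alignment[key[1]]
    p <- get_protein(proteins, pid)
    vec <- rep(NA_real_, nchar(p$sequence))
    vec[cv$position[key]] <- cv$value[key]
    if (anyNA(vec))
      stop("conservation ", aln, " does not cover every residue of ", pid)
    p$conservation[[aln]] <- vec
    proteins[[pid]] <- p
  }
  proteins
}

#' Attach homolog percent identities from a TSV
#'
#' Columns: \code{protein_id}, \code{organism} (\code{human}/\code{mouse}),
#' \code{percent_identity}.
#'
#' @param proteins named list of \code{protein_record} objects.
#' @param path TSV file.
#' @return the protein list with homolog lists attached.
#' @export
read_homologs <- function(proteins, path) {
  hm <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (pid in unique(hm$protein_id)) {
    p <- get_protein(proteins, pid)
    sub <- hm[hm$protein_id == pid, ]
    p$homologs <- list(
      human = sub$percent_identity[sub$organism == "human"],
      mouse = sub$percent_identity[sub$organism == "mouse"])
    proteins[[pid]] <- p
  }
  proteins
}

#' Read residue hit counts
#'
#' @param path TSV with columns \code{protein_id}, \code{position},
#'   \code{count} (observations per residue across a somatic catalogue).
#' @return data.frame as read.
#' @export
read_hit_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write the per-variant prediction table
#'
#' One row per variant: coordinates, pathogenicity score (6 decimals), class
#' calls at the 10/5/1% FPR cutoffs, and up to five significant mechanisms
#' as semicolon-separated \code{mechanism:impact_score:p:p_prime} entries
#' (probabilities in 3-significant-figure scientific notation; empty when no
#' mechanism is significant).
#'
#' @param variants cohort (list or data.frame), aligned with \code{scores}.
#' @param scores numeric pathogenicity scores.
#' @param path output TSV.
#' @param thresholds named cutoffs \code{fpr10}, \code{fpr5}, \code{fpr1}
#'   (default the published ones).
#' @param impact_reports optional list (one element per variant) of
#'   \code{\link{rank_mechanisms}} data.frames.
#' @return the written data.frame, invisibly.
#' @export
write_predictions <- function(variants, scores, path,
                              thresholds = published_thresholds(),
                              impact_reports = NULL) {
  df <- if (is.data.frame(variants)) variants
        else variant_list_to_table(as_variant_list(variants))
  if (nrow(df) != length(scores)) stop("variants and scores length mismatch")
  if (!is.null(impact_reports) && length(impact_reports) != length(scores))
    stop("impact_reports length mismatch")
  fmt_mech <- function(r) {
    if (is.null(r) || !nrow(r)) return("")
    paste(sprintf("%s:%d:%s:%s", r$mechanism, r$impact_score,
                  format(r$p_value, digits = 3, scientific = TRUE),
                  format(r$p_prime, digits = 3, scientific = TRUE)),
          collapse = ";")
  }
  out <- data.frame(df[c("protein_id", "start", "end", "deleted_seq",
                         "inserted_seq")],
                    score = round(scores, 6),
                    call_fpr10 = classify_at_threshold(scores,
                                                       cutoff = thresholds[["fpr10"]]),
                    call_fpr5 = classify_at_threshold(scores,
                                                      cutoff = thresholds[["fpr5"]]),
                    call_fpr1 = classify_at_threshold(scores,
                                                      cutoff = thresholds[["fpr1"]]),
                    mechanisms = if (is.null(impact_reports)) ""
                                 else vapply(impact_reports, fmt_mech, ""),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a simulated dataset to interchange files
#'
#' Emits the exact formats the readers consume: FASTA sequences, variant
#' TSV, long-format track and threshold TSVs, conservation TSV, homolog TSV
#' and a ground-truth JSON.
#'
#' @param data result of \code{\link{simulate_indel_dataset}}.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             variants = file.path(dir, "variants.tsv"),
             tracks = file.path(dir, "tracks.tsv"),
             thresholds = file.path(dir, "thresholds.tsv"),
             conservation = file.path(dir, "conservation.tsv"),
             homologs = file.path(dir, "homologs.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_protein_fasta(data$proteins, paths["fasta"])
  write_variant_table(data$variants, paths["variants"])
  tr <- do.call(rbind, lapply(data$proteins, function(p)
    do.call(rbind, lapply(p$tracks, function(t)
      data.frame(protein_id = p$id, position = seq_along(t$scores),
                 mechanism = t$mechanism, score = t$scores)))))
  utils::write.table(tr, paths["tracks"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  first <- data$proteins[[1]]
  th <- data.frame(mechanism = names(first$tracks),
                   confident_threshold = vapply(first$tracks, `[[`, 0,
                                                "confident_threshold"),
                   alpha = vapply(first$tracks, `[[`, 0, "alpha"))
  utils::write.table(th, paths["thresholds"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cv <- do.call(rbind, lapply(data$proteins, function(p)
    do.call(rbind, lapply(names(p$conservation), function(a)
      data.frame(protein_id = p$id,
                 position = seq_along(p$conservation[[a]]),
                 alignment = a, value = p$conservation[[a]])))))
  utils::write.table(cv, paths["conservation"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hm <- do.call(rbind, lapply(data$proteins, function(p)
    do.call(rbind, lapply(c("human", "mouse"), function(org)
      if (length(p$homologs[[org]]))
        data.frame(protein_id = p$id, organism = org,
                   percent_identity = p$homologs[[org]])))))
  utils::write.table(hm, paths["homologs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(variants = data$ground_truth$variants,
                            confident_threshold =
                              data$ground_truth$confident_threshold,
                            seed = data$ground_truth$config$seed),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Save / load a fitted ensemble
#'
#' Single self-describing versioned file holding the preprocessor
#' parameters, member weights, thresholds, config and seed.
#'
#' @param model an \code{indel_ensemble}.
#' @param path file path.
#' @return \code{save_ensemble}: \code{path}, invisibly;
#'   \code{load_ensemble}: the model.
#' @export
save_ensemble <- function(model, path) {
  stopifnot(inherits(model, "indel_ensemble"))
  payload <- unclass(model)
  payload$format_version <- 1L
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  payload <- readRDS(path)
  if (is.null(payload$format_version) || payload$format_version != 1L)
    stop("unrecognised model file version")
  payload$format_version <- NULL
  structure(payload, class = "indel_ensemble")
}
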
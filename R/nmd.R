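# Nonsense-mediated decay (NMD) prediction for skipped exons.
#
# Two rules are exposed. The frame rule predicts NMD whenever the skipped
# exon's length is not a multiple of 3 (the frameshift necessarily creates
# a premature termination codon in almost all coding contexts). The full
# PTC rule re-translates a supplied transcript model without the exon and
# applies the classical 50-nt last-exon-junction rule.

.nmd_row <- function(exon_id, exon_length, frame_preserving, ptc_detected,
                     last_junction_rule_passed, nmd_predicted, rule_used) {
  data.frame(
    exon_id = exon_id,
    exon_length = as.integer(exon_length),
    frame_preserving = frame_preserving,
    ptc_detected = ptc_detected,
    last_junction_rule_passed = last_junction_rule_passed,
    nmd_predicted = nmd_predicted,
    rule_used = rule_used,
    stringsAsFactors = FALSE
  )
}

#' Frame-rule NMD prediction
#'
#' Predicts NMD for each exon purely from its length: skipping an exon
#' whose length is not divisible by 3 shifts the downstream reading frame.
#' `ptc_detected` and `last_junction_rule_passed` are not evaluated (NA)
#' under this rule.
#'
#' @param exons Exon `data.frame` with `exon_id` and either an
#'   `exon_length` column or `start`/`end` coordinates.
#' @return A `data.frame` of NMD calls (one row per exon).
#' @export
predict_nmd_frame <- function(exons) {
  len <- if ("exon_length" %in% names(exons)) {
    as.integer(exons$exon_length)
  } else {
    as.integer(exons$end - exons$start)
  }
  if (any(len <= 0L)) stop_data("exon length must be positive")
  frame_ok <- len %% 3L == 0L
  .nmd_row(exons$exon_id, len, frame_ok, NA, NA, !frame_ok, "frame_only")
}

.first_stop <- function(seq, from) {
  # 1-based position of the first in-frame stop codon at or after `from`,
  # NA if translation runs off the end without terminating.
  n <- nchar(seq)
  ncod <- (n - from + 1L) %/% 3L
  if (ncod < 1L) return(NA_integer_)
  cds <- substr(seq, from, from + 3L * ncod - 1L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  hit <- regexpr("*", aa, fixed = TRUE)
  if (hit < 0) return(NA_integer_)
  from + 3L * (as.integer(hit) - 1L)
}

.splice_transcript <- function(transcript_exons, genome) {
  strand <- unique(transcript_exons$strand)
  if (length(strand) != 1L) stop_data("transcript exons must share a strand")
  ord <- if (strand == "+") order(transcript_exons$start)
         else order(-transcript_exons$start)
  tx <- transcript_exons[ord, , drop = FALSE]
  seqs <- vapply(seq_len(nrow(tx)), function(i) {
    s <- as.character(Biostrings::subseq(genome[[tx$chrom[i]]],
                                         tx$start[i] + 1L, tx$end[i]))
    if (strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  list(exons = tx, seqs = seqs, seq = paste(seqs, collapse = ""))
}

#' Full PTC-rule NMD prediction for one skipped exon
#'
#' Re-translates the transcript without the exon. `ptc_detected` is TRUE
#' when a stop codon appears upstream of (the mapped position of) the
#' annotated stop; `last_junction_rule_passed` is TRUE when that premature
#' stop lies more than 50 nt upstream of the final exon-exon junction of
#' the skipped transcript; NMD is predicted when both hold.
#'
#' The supported case is an internal coding exon lying downstream of the
#' start codon and upstream of the annotated stop (the skiptic use case).
#' Skipping an exon at or after the annotated stop cannot create a PTC and
#' yields `nmd_predicted = FALSE`.
#'
#' @param exon_id ID of the exon to skip (must be in the transcript).
#' @param transcript_exons Ordered exon `data.frame` for one transcript
#'   (`chrom, start, end, strand, exon_id`).
#' @param genome A `DNAStringSet` or FASTA path (see [load_genome()]).
#' @param cds_start 1-based position of the first base of the start codon
#'   in spliced-transcript coordinates.
#' @return A one-row NMD call `data.frame` (same shape as
#'   [predict_nmd_frame()]).
#' @export
predict_nmd_full <- function(exon_id, transcript_exons, genome, cds_start) {
  if (missing(cds_start) || is.null(cds_start) || is.na(cds_start)) {
    stop_data("no annotated coding start; use predict_nmd_frame() for ",
              "frame-rule predictions")
  }
  genome <- load_genome(genome)
  tx <- .splice_transcript(transcript_exons, genome)
  pos <- match(exon_id, tx$exons$exon_id)
  if (is.na(pos)) stop_data("exon not in transcript: ", exon_id)
  lens <- nchar(tx$seqs)
  exon_len <- lens[pos]
  tx_start <- if (pos == 1L) 1L else sum(lens[seq_len(pos - 1L)]) + 1L
  tx_end <- tx_start + exon_len - 1L
  if (tx_start <= cds_start + 2L && tx_end >= cds_start) {
    stop_data("skipped exon overlaps the annotated start codon")
  }
  stop_full <- .first_stop(tx$seq, cds_start)
  if (is.na(stop_full)) stop_data("no stop codon in the annotated ORF")

  skip_seq <- paste(tx$seqs[-pos], collapse = "")
  cds_start2 <- if (tx_end < cds_start) cds_start - exon_len else cds_start
  frame_ok <- exon_len %% 3L == 0L

  if (tx_start > stop_full) {
    # Exon lies after the annotated stop codon's first base: no PTC.
    return(.nmd_row(exon_id, exon_len, frame_ok, FALSE, NA, FALSE,
                    "full_ptc_rule"))
  }
  mapped_stop <- stop_full - exon_len
  stop_skip <- .first_stop(skip_seq, cds_start2)
  ptc <- !is.na(stop_skip) && stop_skip < mapped_stop
  passed <- NA
  if (ptc) {
    lens2 <- lens[-pos]
    if (length(lens2) < 2L) {
      passed <- FALSE  # no downstream junction: NMD escape
    } else {
      last_junction <- sum(lens2) - lens2[length(lens2)]
      passed <- (last_junction - (stop_skip + 2L)) > 50L
    }
  }
  .nmd_row(exon_id, exon_len, frame_ok, ptc, passed,
           isTRUE(ptc) && isTRUE(passed), "full_ptc_rule")
}

#' Summarize NMD calls
#'
#' @param calls A `data.frame` of NMD calls with an `nmd_predicted` column.
#' @return A list with `n_nmd`, `n_total` and `fraction = n_nmd / n_total`.
#' @export
summarize_nmd <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) {
    stop_data("cannot summarize an empty NMD call set")
  }
  n_nmd <- sum(calls$nmd_predicted, na.rm = TRUE)
  n_total <- nrow(calls)
  list(n_nmd = n_nmd, n_total = n_total, fraction = n_nmd / n_total)
}

#' Write NMD calls and summary as TSV
#'
#' @param calls NMD call `data.frame`.
#' @param path Output path.
#' @export
write_nmd_tsv <- function(calls, path) {
  s <- summarize_nmd(calls)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# skipticr NMD calls: %d/%d predicted NMD (%.1f%%)",
                     s$n_nmd, s$n_total, 100 * s$fraction), con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
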
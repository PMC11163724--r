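# Skiptic-exon calling: classify exons as constitutive/alternative at
# steady state and call aberrant skipping under TDP-43 overexpression.
#
# An exon is treated as constitutive when its steady-state (control) PSI
# exceeds `constitutive_threshold` (default 0.90); a constitutive exon is
# called skiptic when its delta PSI drops by at least `skip_threshold`.

SKIPTIC_LABELS <- c("constitutive_unchanged", "skiptic", "alternative",
                    "low_coverage")

#' Classify exons from control/treated PSI
#'
#' Labels every delta-PSI record with exactly one of
#' `low_coverage` (coverage gate failed in either condition),
#' `alternative` (control PSI at or below the constitutive threshold),
#' `skiptic` (constitutive at baseline and `delta_psi <= -skip_threshold`),
#' or `constitutive_unchanged`.
#'
#' @param delta A delta-PSI table from [delta_psi()].
#' @param constitutive_threshold Steady-state PSI above which an exon is
#'   considered constitutive (default 0.90).
#' @param skip_threshold Minimum PSI drop calling a skiptic event
#'   (default 0.20).
#' @return The input with a `label` factor column appended.
#' @export
classify_exons <- function(delta, constitutive_threshold = 0.90,
                           skip_threshold = 0.20) {
  if (!(constitutive_threshold > 0 && constitutive_threshold < 1)) {
    stop_config("constitutive_threshold must be in (0, 1)")
  }
  if (!(skip_threshold > 0 && skip_threshold < 1)) {
    stop_config("skip_threshold must be in (0, 1)")
  }
  low <- !delta$covered_both | is.na(delta$psi_control) |
    is.na(delta$delta_psi)
  alt <- !low & delta$psi_control <= constitutive_threshold
  skp <- !low & !alt & delta$delta_psi <= -skip_threshold
  label <- rep("constitutive_unchanged", nrow(delta))
  label[low] <- "low_coverage"
  label[alt] <- "alternative"
  label[skp] <- "skiptic"
  delta$label <- factor(label, levels = SKIPTIC_LABELS)
  delta
}

#' Call skiptic exons over a delta-PSI table
#'
#' Applies [classify_exons()], logs per-label counts, and returns the call
#' table sorted by `delta_psi` ascending (strongest skipping first; records
#' with undefined delta last).
#'
#' @inheritParams classify_exons
#' @param verbose Emit a per-label summary message (default TRUE).
#' @return A `data.frame` of calls, class `skiptic_calls`.
#' @export
call_skiptics <- function(delta, constitutive_threshold = 0.90,
                          skip_threshold = 0.20, verbose = TRUE) {
  if (nrow(delta) == 0L) {
    warning("empty delta-PSI table; no calls made")
    delta$label <- factor(character(0), levels = SKIPTIC_LABELS)
    class(delta) <- c("skiptic_calls", class(delta))
    return(delta)
  }
  calls <- classify_exons(delta, constitutive_threshold, skip_threshold)
  calls <- calls[order(calls$delta_psi, na.last = TRUE), , drop = FALSE]
  rownames(calls) <- NULL
  if (verbose) {
    counts <- table(calls$label)
    message("skiptic calls: ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  class(calls) <- c("skiptic_calls", class(calls))
  calls
}

#' Compare skiptic calls between two species
#'
#' Overlap of skiptic calls across an explicit ortholog exon map
#' (no liftover is computed). Among mapped pairs, `shared` counts pairs
#' skiptic in both species; `a_only` / `b_only` count skiptic exons of one
#' species not shared (mapped to a non-skiptic partner, or unmapped).
#'
#' @param calls_a,calls_b Call tables from [call_skiptics()] produced with
#'   the same thresholds.
#' @param map A two-column `data.frame` of asserted-equivalent exon IDs
#'   (`exon_id_a`, `exon_id_b`).
#' @return A list with counts `shared`, `a_only`, `b_only`, `unmapped_a`,
#'   `unmapped_b` and a per-pair `data.frame` `pairs`.
#' @export
compare_species <- function(calls_a, calls_b, map) {
  ida <- map[[1]]
  idb <- map[[2]]
  unknown <- c(setdiff(ida, calls_a$exon_id), setdiff(idb, calls_b$exon_id))
  if (length(unknown)) {
    stop_data("ortholog map references unknown exon IDs: ",
              paste(unknown, collapse = ", "))
  }
  sk_a <- calls_a$exon_id[calls_a$label == "skiptic"]
  sk_b <- calls_b$exon_id[calls_b$label == "skiptic"]
  pairs <- data.frame(
    exon_id_a = ida, exon_id_b = idb,
    skiptic_a = ida %in% sk_a, skiptic_b = idb %in% sk_b,
    stringsAsFactors = FALSE
  )
  pairs$shared <- pairs$skiptic_a & pairs$skiptic_b
  shared <- sum(pairs$shared)
  list(
    shared = shared,
    a_only = length(sk_a) - shared,
    b_only = length(sk_b) - shared,
    unmapped_a = sum(!sk_a %in% ida),
    unmapped_b = sum(!sk_b %in% idb),
    pairs = pairs
  )
}

#' Write skiptic exons as a BED6 browser track
#'
#' One BED record per skiptic call with `name = gene:exon` and
#' `score = round(1000 * |delta_psi|)`, for genome-browser viewing.
#'
#' @param calls A call table from [call_skiptics()] carrying exon
#'   coordinates.
#' @param path Output path.
#' @export
write_skiptic_bed <- function(calls, path) {
  sk <- calls[calls$label == "skiptic", , drop = FALSE]
  out <- data.frame(
    sk$chrom, sk$start, sk$end,
    paste0(sk$gene_id, ":", sk$exon_id),
    round(1000 * abs(sk$delta_psi)), sk$strand
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a skiptic call table as TSV
#'
#' @param calls A call table from [call_skiptics()].
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# skipticr skiptic calls; coordinates 0-based half-open",
    "# delta_psi = treated - control"
  ), con)
  utils::write.table(as.data.frame(calls), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
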
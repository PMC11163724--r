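# Percent-spliced-in (PSI) quantification from junction read counts.
#
# For an exon, 5'PSI and 3'PSI are the ratios of inclusion-junction reads
# at the donor / acceptor splice site over inclusion plus exclusion reads,
# where exclusion junctions are those spanning the exon strictly. All
# coordinates are 0-based half-open; acceptor/donor assignment is
# strand-aware (on '-', the acceptor is the exon's higher-coordinate
# boundary).

#' Index a sample's junctions for PSI computation
#'
#' Builds a lookup structure over one sample's junctions supporting
#' acceptor-coordinate, donor-coordinate, and spanning-interval queries.
#' Duplicated identical intervals (same `chrom, start, end, strand`) are
#' merged with their read counts summed, with a warning.
#'
#' @param junctions A junction table from one sample (see
#'   [junction_table()]).
#' @return An object of class `junction_index`.
#' @export
index_junctions <- function(junctions) {
  validate_junctions(junctions)
  sample_id <- unique(junctions$sample_id)
  if (length(sample_id) > 1L) {
    stop_data("index_junctions expects junctions from a single sample, got: ",
              paste(sample_id, collapse = ", "))
  }
  key <- paste(junctions$chrom, junctions$start, junctions$end,
               junctions$strand, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning("merging ", ndup, " duplicated junction interval(s); ",
            "read counts summed")
    reads <- rowsum(junctions$reads, key, reorder = FALSE)
    first <- !duplicated(key)
    junctions <- junctions[first, , drop = FALSE]
    junctions$reads <- as.integer(reads[match(key[first], rownames(reads)), 1])
  }
  ord <- order(junctions$chrom, junctions$start, junctions$end,
               junctions$strand)
  junctions <- junctions[ord, , drop = FALSE]
  rownames(junctions) <- NULL
  structure(
    list(junctions = junctions,
         sample_id = if (length(sample_id)) sample_id else NA_character_),
    class = "junction_index"
  )
}

#' @export
print.junction_index <- function(x, ...) {
  cat("junction_index:", nrow(x$junctions), "junctions, sample",
      x$sample_id, "\n")
  invisible(x)
}

.strand_ok <- function(jstrand, strand, include_unstranded) {
  jstrand == strand | (include_unstranded & jstrand == ".")
}

# Reads of junctions whose `side` coordinate equals `coord`.
.site_reads <- function(index, chrom, coord, side, strand,
                        include_unstranded) {
  j <- index$junctions
  sel <- j$chrom == chrom & j[[side]] == coord &
    .strand_ok(j$strand, strand, include_unstranded)
  sum(j$reads[sel])
}

# Reads of junctions spanning [start, end) strictly.
.spanning_reads <- function(index, chrom, start, end, strand,
                            include_unstranded) {
  j <- index$junctions
  sel <- j$chrom == chrom & j$start < start & j$end > end &
    .strand_ok(j$strand, strand, include_unstranded)
  sum(j$reads[sel])
}

#' Compute 5'/3' PSI for one exon in one sample
#'
#' Inclusion reads at the 3' splice site (acceptor) are reads of junctions
#' whose downstream boundary coincides with the exon's acceptor coordinate;
#' inclusion reads at the 5' splice site (donor) are reads of junctions
#' whose upstream boundary coincides with the donor coordinate. Exclusion
#' reads are reads of junctions that start strictly before the exon start
#' and end strictly after the exon end on the matching strand; junctions
#' touching a boundary count as inclusion, never exclusion. Then
#' `psi3 = I3 / (I3 + E)`, `psi5 = I5 / (I5 + E)`, and `psi` is the mean of
#' the defined site values. PSI is undefined (NA) where the denominator is
#' zero. `covered` is TRUE when inclusion+exclusion totals at both sites
#' reach `min_reads`.
#'
#' @param exon A one-row exon `data.frame` (or list) with `chrom, start,
#'   end, strand, exon_id`.
#' @param index A [junction_index][index_junctions()].
#' @param min_reads Coverage gate: minimum informative reads per site
#'   (default 10).
#' @param include_unstranded If TRUE, unstranded (`.`) junctions may match
#'   exons on either strand; default FALSE (they are ignored).
#' @return A one-row `data.frame` with `exon_id, sample_id,
#'   inclusion_reads_3ss, inclusion_reads_5ss, exclusion_reads, psi3, psi5,
#'   psi, covered`.
#' @export
compute_psi <- function(exon, index, min_reads = 10,
                        include_unstranded = FALSE) {
  stopifnot(inherits(index, "junction_index"))
  chrom <- exon$chrom
  start <- exon$start
  end <- exon$end
  strand <- exon$strand
  if (!strand %in% c("+", "-")) stop_data("exon strand must be '+' or '-'")
  if (strand == "+") {
    i3 <- .site_reads(index, chrom, start, "end", strand, include_unstranded)
    i5 <- .site_reads(index, chrom, end, "start", strand, include_unstranded)
  } else {
    # On '-', the acceptor is the higher-coordinate boundary.
    i3 <- .site_reads(index, chrom, end, "start", strand, include_unstranded)
    i5 <- .site_reads(index, chrom, start, "end", strand, include_unstranded)
  }
  e <- .spanning_reads(index, chrom, start, end, strand, include_unstranded)
  psi3 <- if (i3 + e > 0) i3 / (i3 + e) else NA_real_
  psi5 <- if (i5 + e > 0) i5 / (i5 + e) else NA_real_
  psi <- if (!is.na(psi3) && !is.na(psi5)) {
    (psi3 + psi5) / 2
  } else if (!is.na(psi3)) psi3 else psi5
  data.frame(
    exon_id = exon$exon_id,
    sample_id = index$sample_id,
    inclusion_reads_3ss = i3,
    inclusion_reads_5ss = i5,
    exclusion_reads = e,
    psi3 = psi3, psi5 = psi5, psi = psi,
    covered = (i3 + e) >= min_reads && (i5 + e) >= min_reads,
    stringsAsFactors = FALSE
  )
}

#' PSI matrix over exons and samples
#'
#' One [compute_psi()] estimate per (exon, sample), with exon coordinates
#' carried through and deterministic row order
#' (`chrom, start, exon_id, sample_id`).
#'
#' @param exons Exon `data.frame` (see [read_exons_gtf()]).
#' @param samples Named list of [junction_index][index_junctions()] objects
#'   (or junction tables, which are indexed on the fly); names are sample
#'   ids.
#' @inheritParams compute_psi
#' @return A `data.frame` of PSI estimates, one row per exon x sample.
#' @export
psi_matrix <- function(exons, samples, min_reads = 10,
                       include_unstranded = FALSE) {
  if (!length(samples)) stop_data("no samples supplied")
  samples <- lapply(samples, function(s) {
    if (inherits(s, "junction_index")) s else index_junctions(s)
  })
  rows <- vector("list", nrow(exons) * length(samples))
  k <- 0L
  for (i in seq_len(nrow(exons))) {
    exon <- exons[i, ]
    for (s in samples) {
      k <- k + 1L
      est <- compute_psi(exon, s, min_reads = min_reads,
                         include_unstranded = include_unstranded)
      est$chrom <- exon$chrom
      est$start <- exon$start
      est$end <- exon$end
      est$strand <- exon$strand
      est$gene_id <- if ("gene_id" %in% names(exons)) exon$gene_id else NA_character_
      rows[[k]] <- est
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$exon_id, out$sample_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.aggregate_condition <- function(psi_tab, aggregator, min_reads) {
  sp <- split(psi_tab, psi_tab$exon_id)
  res <- lapply(sp, function(d) {
    if (aggregator == "pooled") {
      i3 <- sum(d$inclusion_reads_3ss)
      i5 <- sum(d$inclusion_reads_5ss)
      e <- sum(d$exclusion_reads)
      psi3 <- if (i3 + e > 0) i3 / (i3 + e) else NA_real_
      psi5 <- if (i5 + e > 0) i5 / (i5 + e) else NA_real_
      psi <- if (!is.na(psi3) && !is.na(psi5)) (psi3 + psi5) / 2
             else if (!is.na(psi3)) psi3 else psi5
      covered <- (i3 + e) >= min_reads && (i5 + e) >= min_reads
    } else {
      ok <- d$covered & !is.na(d$psi)
      psi <- if (any(ok)) mean(d$psi[ok]) else NA_real_
      covered <- any(ok)
    }
    data.frame(
      exon_id = d$exon_id[1], psi = psi, covered = covered,
      chrom = d$chrom[1], start = d$start[1], end = d$end[1],
      strand = d$strand[1], gene_id = d$gene_id[1],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Delta-PSI between two conditions
#'
#' Aggregates per-sample PSI estimates within each condition (pooled read
#' counts by default, or the mean of per-sample PSI over covered samples)
#' and reports per-exon `delta_psi = treated - control`. Exons failing the
#' coverage gate in either condition are emitted with
#' `covered_both = FALSE` and undefined delta.
#'
#' @param psi_control,psi_treated PSI tables from [psi_matrix()], one per
#'   condition, quantified over the same exon set.
#' @param aggregator `"pooled"` (sum counts, then ratio; default) or
#'   `"mean"` (mean of per-sample PSI over covered samples).
#' @param min_reads Coverage gate applied to pooled counts (default 10).
#' @return A `data.frame` with `exon_id, psi_control, psi_treated,
#'   delta_psi, covered_both` plus exon coordinates.
#' @export
delta_psi <- function(psi_control, psi_treated,
                      aggregator = c("pooled", "mean"), min_reads = 10) {
  aggregator <- match.arg(aggregator)
  ec <- unique(psi_control$exon_id)
  et <- unique(psi_treated$exon_id)
  miss <- c(setdiff(ec, et), setdiff(et, ec))
  if (length(miss)) {
    stop_data("conditions quantify different exon sets; missing IDs: ",
              paste(utils::head(miss, 10), collapse = ", "),
              if (length(miss) > 10) ", ..." else "")
  }
  ac <- .aggregate_condition(psi_control, aggregator, min_reads)
  at <- .aggregate_condition(psi_treated, aggregator, min_reads)
  at <- at[match(ac$exon_id, at$exon_id), , drop = FALSE]
  covered_both <- ac$covered & at$covered
  delta <- ifelse(covered_both & !is.na(ac$psi) & !is.na(at$psi),
                  at$psi - ac$psi, NA_real_)
  out <- data.frame(
    exon_id = ac$exon_id,
    psi_control = ac$psi,
    psi_treated = at$psi,
    delta_psi = delta,
    covered_both = covered_both,
    chrom = ac$chrom, start = ac$start, end = ac$end, strand = ac$strand,
    gene_id = ac$gene_id,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$exon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a PSI or delta-PSI table as TSV
#'
#' @param tab A table from [psi_matrix()] or [delta_psi()].
#' @param path Output path.
#' @export
write_psi_tsv <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# skipticr PSI table; coordinates 0-based half-open",
    "# psi3/psi5: inclusion fraction at acceptor/donor site; psi: mean of defined sites"
  ), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
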
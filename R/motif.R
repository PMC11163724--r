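# UG/GU dinucleotide repeat profiling around splice sites.
#
# TDP-43's consensus binding site is a UG repeat. The profiling algorithm:
# (i) mask every position participating in at least one UG or GU
# dinucleotide (overlaps allowed) as 'Y', everything else as 'N';
# (ii) score positions inside qualifying repeat runs (at least `min_len`
# Y characters, allowing up to `max_inner_N` single interior N insertions)
# as 1, everything else 0; (iii) average the per-position scores over all
# sequences aligned to the 3'SS or 5'SS.

#' Mask UG/GU dinucleotides in a sequence
#'
#' Every position participating in at least one `UG` or `GU` dinucleotide
#' (overlaps allowed, so `"TGT"` masks all three positions) becomes `Y`;
#' all other positions (including assembly `N`s and ambiguity codes, which
#' cannot support a UG dinucleotide) become `N`. `T` and `U` are treated
#' identically; case is ignored.
#'
#' @param sequence Character vector of nucleotide strings.
#' @return Character vector of same-length masks over `{Y, N}`.
#' @export
mask_ug <- function(sequence) {
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    chars <- strsplit(chartr("u", "T", toupper(s)), "", fixed = TRUE)[[1]]
    chars[chars == "U"] <- "T"
    if (n == 1L) return("N")
    a <- chars[-n]
    b <- chars[-1L]
    pair <- (a == "T" & b == "G") | (a == "G" & b == "T")
    y <- logical(n)
    hit <- which(pair)
    y[hit] <- TRUE
    y[hit + 1L] <- TRUE
    paste(ifelse(y, "Y", "N"), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Score qualifying repeat runs in a Y/N mask
#'
#' A stretch qualifies when it starts and ends with `Y`, contains at least
#' `min_len` `Y` characters, and at most `max_inner_N` interior `N`
#' characters, each a single isolated insertion flanked by `Y` on both
#' sides. Within qualifying stretches the `Y` positions score 1; interior
#' `N` insertions and everything outside qualifying stretches score 0.
#'
#' @param mask A mask string over `{Y, N}` (see [mask_ug()]).
#' @param min_len Minimum number of `Y`s in a qualifying run (default 5,
#'   i.e. pentamer and longer).
#' @param max_inner_N Maximum number of single interior `N` insertions
#'   (default 1).
#' @return Integer vector of 0/1 scores, one per mask position.
#' @export
find_repeat_runs <- function(mask, min_len = 5, max_inner_N = 1) {
  n <- nchar(mask)
  out <- integer(n)
  if (n == 0L) return(out)
  chars <- strsplit(mask, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("Y", "N"))) {
    stop_data("mask must contain only 'Y' and 'N'")
  }
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  yruns <- which(r$values == "Y")
  if (!length(yruns)) return(out)
  # A chain of consecutive Y-runs joined by single-N gaps qualifies when
  # its Y total reaches min_len using at most max_inner_N gaps. Marking a
  # run when any qualifying chain covers it reproduces the union over all
  # qualifying substrings.
  for (a in seq_along(yruns)) {
    total <- 0L
    for (b in a:length(yruns)) {
      if (b > a) {
        gap_run <- yruns[b - 1L] + 1L
        joined <- yruns[b] == yruns[b - 1L] + 2L && r$lengths[gap_run] == 1L
        if (!joined || (b - a) > max_inner_N) break
      }
      total <- total + r$lengths[yruns[b]]
      if (total >= min_len) {
        for (k in a:b) {
          out[starts[yruns[k]]:ends[yruns[k]]] <- 1L
        }
      }
    }
  }
  out
}

.anchor_coord <- function(exon, anchor) {
  # 0-based genomic coordinate of the anchor base: the first exonic base
  # for the 3'SS, the last exonic base for the 5'SS, on the sense strand.
  if (exon$strand == "+") {
    if (anchor == "3SS") exon$start else exon$end - 1L
  } else {
    if (anchor == "3SS") exon$end - 1L else exon$start
  }
}

#' Extract a sense-strand window around a splice site
#'
#' Returns the `2 * flank + 1`-base window centered on the chosen splice
#' site, reverse-complemented for `-`-strand exons so positions read 5'->3'
#' on the sense strand. Offset 0 is the first exonic base at the 3'SS
#' anchor and the last exonic base at the 5'SS anchor. Windows truncated at
#' contig ends are padded with `N` and flagged via the `truncated`
#' attribute.
#'
#' @param genome A named `Biostrings::DNAStringSet` (or path to an
#'   uncompressed FASTA file).
#' @param exon One exon record (`chrom, start, end, strand`).
#' @param anchor `"3SS"` (acceptor) or `"5SS"` (donor).
#' @param flank Half-window size in bases (default 400).
#' @return A character string of length `2 * flank + 1` with attribute
#'   `truncated`.
#' @export
extract_window <- function(genome, exon, anchor = c("3SS", "5SS"),
                           flank = 400) {
  anchor <- match.arg(anchor)
  genome <- load_genome(genome)
  if (!exon$chrom %in% names(genome)) {
    stop_data("contig missing from FASTA: ", exon$chrom)
  }
  chrom_seq <- genome[[exon$chrom]]
  w <- length(chrom_seq)
  a0 <- .anchor_coord(exon, anchor)
  lo <- a0 - flank
  hi <- a0 + flank
  from <- max(lo, 0L)
  to <- min(hi, w - 1L)
  if (from > to) stop_data("window entirely outside contig bounds")
  core <- as.character(Biostrings::subseq(chrom_seq, from + 1L, to + 1L))
  s <- paste0(strrep("N", from - lo), core, strrep("N", hi - to))
  if (exon$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  attr(s, "truncated") <- (lo < 0L) || (hi > w - 1L)
  s
}

#' Load a genome as a named DNAStringSet
#'
#' FASTA sequence names are trimmed to their first whitespace-delimited
#' token, matching common contig naming.
#'
#' @param genome A `DNAStringSet` (returned unchanged) or FASTA path.
#' @return A named `Biostrings::DNAStringSet`.
#' @export
load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (!file.exists(genome)) stop_data("FASTA file not found: ", genome)
  gs <- Biostrings::readDNAStringSet(genome)
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

#' Splice-site-aligned UG repeat metaprofile
#'
#' For each exon, extracts the sense-strand window around the chosen
#' splice site, masks UG/GU dinucleotides, scores qualifying repeat runs,
#' and averages the per-position scores over sequences: the repeat
#' frequency per nucleotide position relative to the splice site.
#'
#' @param exons Exon `data.frame` (at least one row).
#' @inheritParams extract_window
#' @inheritParams find_repeat_runs
#' @return A `data.frame` of class `repeat_profile` with columns
#'   `anchor, offset, frequency, n_sequences`.
#' @export
splice_site_profile <- function(exons, genome, anchor = c("3SS", "5SS"),
                                flank = 400, min_len = 5, max_inner_N = 1) {
  anchor <- match.arg(anchor)
  if (nrow(exons) == 0L) stop_data("splice_site_profile requires >= 1 exon")
  genome <- load_genome(genome)
  width <- 2L * flank + 1L
  q <- matrix(0L, nrow = nrow(exons), ncol = width)
  for (i in seq_len(nrow(exons))) {
    s <- extract_window(genome, exons[i, ], anchor = anchor, flank = flank)
    q[i, ] <- find_repeat_runs(mask_ug(s), min_len = min_len,
                               max_inner_N = max_inner_N)
  }
  out <- data.frame(
    anchor = anchor,
    offset = seq(-flank, flank),
    frequency = colMeans(q),
    n_sequences = nrow(exons),
    stringsAsFactors = FALSE
  )
  class(out) <- c("repeat_profile", class(out))
  out
}

#' Write a repeat profile as TSV
#'
#' @param profile A [splice_site_profile()] result.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# skipticr UG repeat metaprofile",
    "# offset 0 = first exonic base (3SS anchor) or last exonic base (5SS anchor), sense strand"
  ), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
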
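# Independent oracles and fixture builders used across the test files.
# The oracles deliberately take the slow, literal route (interval
# arithmetic per junction, substring enumeration per mask) so they share
# no code path with the implementation they check.

# ---- brute-force PSI classifier -------------------------------------------

brute_psi <- function(exon, junctions, min_reads = 10,
                      include_unstranded = FALSE) {
  i3 <- 0L; i5 <- 0L; e <- 0L
  for (k in seq_len(nrow(junctions))) {
    j <- junctions[k, ]
    if (j$chrom != exon$chrom) next
    if (!(j$strand == exon$strand ||
          (include_unstranded && j$strand == "."))) next
    acceptor_coord <- if (exon$strand == "+") exon$start else exon$end
    donor_coord <- if (exon$strand == "+") exon$end else exon$start
    if (exon$strand == "+") {
      if (j$end == acceptor_coord) i3 <- i3 + j$reads
      if (j$start == donor_coord) i5 <- i5 + j$reads
    } else {
      if (j$start == acceptor_coord) i3 <- i3 + j$reads
      if (j$end == donor_coord) i5 <- i5 + j$reads
    }
    if (j$start < exon$start && j$end > exon$end) e <- e + j$reads
  }
  psi3 <- if (i3 + e > 0) i3 / (i3 + e) else NA_real_
  psi5 <- if (i5 + e > 0) i5 / (i5 + e) else NA_real_
  psi <- if (!is.na(psi3) && !is.na(psi5)) (psi3 + psi5) / 2
         else if (!is.na(psi3)) psi3 else psi5
  list(i3 = i3, i5 = i5, e = e, psi3 = psi3, psi5 = psi5, psi = psi,
       covered = (i3 + e) >= min_reads && (i5 + e) >= min_reads)
}

# Random small instance: one exon plus junctions biased to hit exon
# boundaries so inclusion/exclusion classification is exercised.
random_psi_instance <- function(max_junctions = 20) {
  s <- sample(5:40, 1)
  e <- s + sample(3:15, 1)
  exon <- data.frame(chrom = "c1", start = s, end = e,
                     strand = sample(c("+", "-"), 1), exon_id = "x",
                     stringsAsFactors = FALSE)
  nj <- sample(1:max_junctions, 1)
  mk <- function() {
    kind <- sample(c("acc", "don", "span", "rand"), 1)
    if (kind == "acc") c(s - sample(1:10, 1), s)
    else if (kind == "don") c(e, e + sample(1:10, 1))
    else if (kind == "span") c(s - sample(1:10, 1), e + sample(1:10, 1))
    else sort(sample(0:60, 2))
  }
  coords <- t(replicate(nj, mk()))
  coords <- coords[coords[, 1] < coords[, 2], , drop = FALSE]
  coords <- coords[!duplicated(coords), , drop = FALSE]
  junctions <- data.frame(
    chrom = "c1", start = coords[, 1], end = coords[, 2],
    strand = sample(c("+", "-", "."), nrow(coords), replace = TRUE),
    reads = sample(0:100, nrow(coords), replace = TRUE),
    sample_id = "s1", stringsAsFactors = FALSE
  )
  # avoid duplicate (start,end,strand) triples so indexing never merges
  key <- paste(junctions$start, junctions$end, junctions$strand)
  junctions <- junctions[!duplicated(key), , drop = FALSE]
  list(exon = exon, junctions = junctions)
}

# ---- substring-enumeration repeat-run oracle ------------------------------

oracle_repeat_runs <- function(mask, min_len = 5, max_inner_N = 1) {
  n <- nchar(mask)
  out <- integer(n)
  if (n == 0L) return(out)
  chars <- strsplit(mask, "", fixed = TRUE)[[1]]
  isY <- chars == "Y"
  csY <- cumsum(isY)
  nn <- c(!isY[-n] & !isY[-1], FALSE)  # NN pair starting at each position
  csNN <- cumsum(nn)
  for (i in which(isY)) {
    for (j in which(isY)) {
      if (j < i) next
      ycount <- csY[j] - if (i > 1) csY[i - 1] else 0
      if (ycount < min_len) next
      ncount <- (j - i + 1) - ycount
      if (ncount > max_inner_N) next
      # no two adjacent interior Ns
      nn_inside <- 0
      if (j > i) {
        nn_inside <- csNN[j - 1] - (if (i > 1) csNN[i - 1] else 0)
      }
      if (nn_inside > 0) next
      out[i:j][isY[i:j]] <- 1L
    }
  }
  out
}

random_mask <- function(max_len = 30) {
  n <- sample(1:max_len, 1)
  paste(sample(c("Y", "N"), n, replace = TRUE, prob = c(0.6, 0.4)),
        collapse = "")
}

all_masks <- function(len) {
  grid <- expand.grid(rep(list(c("Y", "N")), len), stringsAsFactors = FALSE)
  apply(grid, 1, paste, collapse = "")
}

# ---- toy transcripts for the full PTC rule --------------------------------
#
# Four-exon '+' transcript on chrom "chrT"; coding starts at spliced
# position 10 (9-nt UTR then ATG). Exon "e2" is the skippable target.
# Variants (expected outcomes follow from the construction):
#   inframe : e2 = 96 nt of (GCA) codons; skipping keeps frame, the only
#             stop stays the annotated TAA -> no PTC.
#   ptc_far : e2 = 85 nt; the frameshifted reading of e3 hits a planted
#             TGA 54 nt upstream of the last junction -> NMD.
#   ptc_near: as ptc_far but the planted stop sits 27 nt upstream of the
#             last junction -> PTC detected, 50-nt rule fails.
make_toy_transcript <- function(variant = c("inframe", "ptc_far",
                                            "ptc_near")) {
  variant <- match.arg(variant)
  gct <- function(k) strrep("GCT", k)
  e1 <- paste0(strrep("C", 9), "ATG", gct(10))            # 42 nt
  if (variant == "inframe") {
    e2 <- strrep("GCA", 32)                                # 96 nt
    e3 <- gct(20)                                          # 60 nt
    e4 <- paste0(gct(30), "TAA", strrep("C", 27))          # 120 nt
  } else {
    e2 <- paste0(strrep("GCA", 28), "G")                   # 85 nt
    m <- if (variant == "ptc_far") 1 else 10
    # e3 = "CT" + 19 GCT units + "G", with units m, m+1 replaced by
    # ATG, ACT; in the shifted frame this reads ... TGA (stop).
    units <- rep("GCT", 19)
    units[m] <- "ATG"
    units[m + 1] <- "ACT"
    e3 <- paste0("CT", paste(units, collapse = ""), "G")   # 60 nt
    e4 <- paste0("CT", gct(30), "TAA", strrep("C", 25))    # 120 nt
  }
  exon_seqs <- c(e1 = e1, e2 = e2, e3 = e3, e4 = e4)
  intron <- strrep("C", 50)
  genome_seq <- paste(exon_seqs, collapse = intron)
  starts <- cumsum(c(0, head(nchar(exon_seqs), -1) + 50))
  exons <- data.frame(
    chrom = "chrT", start = starts, end = starts + nchar(exon_seqs),
    strand = "+", exon_id = names(exon_seqs),
    stringsAsFactors = FALSE
  )
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- "chrT"
  list(genome = genome, exons = exons, cds_start = 10, skip_id = "e2")
}

# Mirror a toy transcript onto the minus strand of a reflected contig.
mirror_toy <- function(toy) {
  glen <- Biostrings::width(toy$genome)[1]
  genome <- Biostrings::DNAStringSet(
    Biostrings::reverseComplement(toy$genome[[1]]))
  names(genome) <- "chrT"
  exons <- toy$exons
  new_start <- glen - exons$end
  exons$end <- glen - exons$start
  exons$start <- new_start
  exons$strand <- "-"
  list(genome = genome, exons = exons, cds_start = toy$cds_start,
       skip_id = toy$skip_id)
}

# ---- misc -----------------------------------------------------------------

sample_indexes <- function(sim, pattern) {
  lapply(sim$samples[grep(pattern, names(sim$samples))], index_junctions)
}
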
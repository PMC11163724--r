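# UG masking, repeat-run scoring, window extraction, and metaprofiles.

test_that("UG/GU masking marks every position in an overlapping pair", {
  expect_equal(mask_ug("TGTGTG"), "YYYYYY")
  expect_equal(mask_ug("ACTGAC"), "NNYYNN")
  expect_equal(mask_ug("AAAAAA"), "NNNNNN")
  expect_equal(mask_ug("TGT"), "YYY")     # overlap: all three positions
  expect_equal(mask_ug(""), "")
  expect_equal(mask_ug("G"), "N")
  # ambiguity codes and assembly Ns cannot support a UG pair
  expect_equal(mask_ug("TGNRGT"), "YYNNYY")
})

test_that("masking treats T and U (any case) identically", {
  expect_equal(mask_ug("ugugug"), mask_ug("TGTGTG"))
  expect_equal(mask_ug("acUGac"), mask_ug("ACTGAC"))
})

test_that("repeat-run scoring follows the pentamer-with-single-N rule", {
  expect_equal(find_repeat_runs("YYYYY"), rep(1L, 5))
  expect_equal(find_repeat_runs("YYYYNYYYY"),
               c(1L, 1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L))
  expect_equal(find_repeat_runs("YYNNYY"), rep(0L, 6))
  expect_equal(find_repeat_runs("YYYYN"), rep(0L, 5))
  expect_equal(find_repeat_runs("YYYY"), rep(0L, 4))
  # Y-count (not span) must reach min_len: 4 Y + N + 1 Y qualifies
  expect_equal(find_repeat_runs("YYYYNY"), c(1L, 1L, 1L, 1L, 0L, 1L))
})

test_that("repeat-run scoring matches the substring-enumeration oracle", {
  # exhaustive over short masks
  for (len in 1:8) {
    for (mask in all_masks(len)) {
      expect_identical(find_repeat_runs(mask), oracle_repeat_runs(mask),
                       label = mask)
    }
  }
  # random longer masks, including a stricter and looser parameterization
  set.seed(55)
  for (i in 1:300) {
    mask <- random_mask(30)
    expect_identical(find_repeat_runs(mask), oracle_repeat_runs(mask),
                     label = mask)
    expect_identical(find_repeat_runs(mask, min_len = 4, max_inner_N = 2),
                     oracle_repeat_runs(mask, min_len = 4, max_inner_N = 2),
                     label = paste(mask, "(4,2)"))
  }
})

toy_genome <- function(seq, chrom = "cG") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- chrom
  g
}

test_that("window extraction centers on the splice site, strand-aware", {
  # contig: 10 A, then CCGGG, then 10 A; exon = the CCGGG block [10, 15)
  g <- toy_genome(paste0(strrep("A", 10), "CCGGG", strrep("A", 10)))
  exon_plus <- data.frame(chrom = "cG", start = 10L, end = 15L,
                          strand = "+", stringsAsFactors = FALSE)
  w <- extract_window(g, exon_plus, "3SS", flank = 3)
  expect_equal(unclass(w)[1], "AAACCGG")  # offset 0 = first exonic base (C)
  expect_false(attr(w, "truncated"))
  w5 <- extract_window(g, exon_plus, "5SS", flank = 3)
  expect_equal(unclass(w5)[1], "CGGGAAA")  # offset 0 = last exonic base

  exon_minus <- exon_plus
  exon_minus$strand <- "-"
  wm <- extract_window(g, exon_minus, "3SS", flank = 3)
  # anchored on the exon END coordinate and reverse-complemented:
  # plus-strand window "CGGGAAA" -> sense "TTTCCCG"
  expect_equal(unclass(wm)[1], "TTTCCCG")
  expect_error(extract_window(g, transform(exon_plus, chrom = "missing"),
                              "3SS"), "contig missing")
})

test_that("windows truncated at contig ends are N-padded and flagged", {
  g <- toy_genome(strrep("A", 30))
  exon <- data.frame(chrom = "cG", start = 5L, end = 20L, strand = "+",
                     stringsAsFactors = FALSE)
  w <- extract_window(g, exon, "3SS", flank = 10)
  expect_equal(nchar(w), 21L)
  expect_true(attr(w, "truncated"))
  expect_true(substr(w, 1, 5) == "NNNNN")
})

test_that("profiles average qualifying indicators across sequences", {
  flank <- 20L
  # exon at [40, 60) with (TG)5 planted at 3'SS offsets +2..+11 in one of
  # two contigs; all-A background elsewhere
  base <- strrep("A", 100)
  planted <- paste0(substr(base, 1, 42), strrep("TG", 5),
                    substr(base, 53, 100))
  g <- Biostrings::DNAStringSet(c(planted, base))
  names(g) <- c("c1", "c2")
  exons <- data.frame(chrom = c("c1", "c2"), start = 40L, end = 60L,
                      strand = "+", stringsAsFactors = FALSE)
  p <- splice_site_profile(exons, g, "3SS", flank = flank)
  expect_equal(nrow(p), 2L * flank + 1L)
  expect_true(all(p$frequency >= 0 & p$frequency <= 1))
  expect_equal(unique(p$frequency[p$offset %in% 2:11]), 0.5)
  expect_equal(unique(p$frequency[!p$offset %in% 2:11]), 0)
  expect_equal(unique(p$n_sequences), 2L)
  # all-background input gives the all-zero profile
  p0 <- splice_site_profile(exons[2, , drop = FALSE], g, "3SS",
                            flank = flank)
  expect_true(all(p0$frequency == 0))
  expect_error(splice_site_profile(exons[0, ], g, "3SS"), ">= 1 exon")
})

test_that("profiles are identical for DNA and RNA spellings", {
  seq_dna <- "AATGTGTGTGTGAA"
  seq_rna <- chartr("T", "U", seq_dna)
  expect_identical(find_repeat_runs(mask_ug(seq_dna)),
                   find_repeat_runs(mask_ug(seq_rna)))
})

test_that("a minus-strand exon contributes the same profile as its sense-equivalent", {
  # plus-strand contig with a (TG)6 run inside the exon; the mirrored
  # contig carries the reverse complement with a '-' exon
  flank <- 15L
  fwd <- paste0(strrep("A", 30), strrep("TG", 6), strrep("A", 30))
  g_fwd <- toy_genome(fwd, "cF")
  exon_fwd <- data.frame(chrom = "cF", start = 28L, end = 50L,
                         strand = "+", stringsAsFactors = FALSE)
  rev <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  g_rev <- toy_genome(rev, "cR")
  glen <- nchar(fwd)
  exon_rev <- data.frame(chrom = "cR", start = glen - 50L,
                         end = glen - 28L, strand = "-",
                         stringsAsFactors = FALSE)
  p_fwd <- splice_site_profile(exon_fwd, g_fwd, "3SS", flank = flank)
  p_rev <- splice_site_profile(exon_rev, g_rev, "3SS", flank = flank)
  expect_equal(p_rev$frequency, p_fwd$frequency)
})
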
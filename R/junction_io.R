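# Readers and writers for splice-junction tables and exon annotation.
#
# Internal coordinate convention is uniformly 0-based half-open; every
# converter from a 1-based format lives here, at the I/O boundary.

#' Construct a validated splice-junction table
#'
#' A junction table is a plain `data.frame` with one row per intron
#' observation in one sample: `chrom`, `start` (0-based first intron base),
#' `end` (0-based exclusive past-last intron base), `strand` (one of
#' `+`, `-`, `.`), `reads` (non-negative unique-read count) and `sample_id`.
#'
#' @param chrom Character vector of contig names.
#' @param start,end Integer vectors, 0-based half-open intron span.
#' @param strand Character vector over `+`, `-`, `.`.
#' @param reads Non-negative integer read counts.
#' @param sample_id Sample label (scalar or vector).
#' @return A `data.frame` with the six junction columns, invariants checked.
#' @export
junction_table <- function(chrom, start, end, strand, reads, sample_id) {
  if (length(start) == 0L) return(empty_junction_table())
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    reads = as.integer(reads),
    sample_id = as.character(sample_id),
    stringsAsFactors = FALSE
  )
  validate_junctions(df)
  df
}

#' @rdname junction_table
#' @param junctions A candidate junction `data.frame`.
#' @export
validate_junctions <- function(junctions) {
  need <- c("chrom", "start", "end", "strand", "reads", "sample_id")
  miss <- setdiff(need, names(junctions))
  if (length(miss)) {
    stop_data("junction table missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(!(junctions$start < junctions$end))
  if (length(bad)) {
    stop_data("junction start must be < end (first bad row ", bad[1], ")")
  }
  bad <- which(junctions$reads < 0 | is.na(junctions$reads))
  if (length(bad)) {
    stop_data("junction read counts must be non-negative integers (first bad row ",
              bad[1], ")")
  }
  bad <- which(!junctions$strand %in% c("+", "-", "."))
  if (length(bad)) {
    stop_data("junction strand must be one of '+', '-', '.' (first bad row ",
              bad[1], ")")
  }
  invisible(junctions)
}

empty_junction_table <- function(sample_id = character(0)) {
  data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), reads = integer(0), sample_id = character(0),
    stringsAsFactors = FALSE
  )
}

.read_table_lines <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  list(lines = lines[keep], lineno = which(keep))
}

.check_integer_field <- function(values, lineno, what) {
  bad <- which(!grepl("^-?[0-9]+$", values))
  if (length(bad)) {
    stop_data("non-integer ", what, " '", values[bad[1]], "' at line ",
              lineno[bad[1]])
  }
  as.integer(values)
}

#' Read a STAR `SJ.out.tab` splice-junction file
#'
#' STAR reports 1-based inclusive intron coordinates and a numeric strand
#' code (0 undefined, 1 `+`, 2 `-`); column 7 holds the unique-mapping read
#' count. Coordinates are converted to the internal 0-based half-open
#' convention and strand codes to `.`/`+`/`-`. Unstranded (code 0)
#' junctions are retained; whether they may match exons is decided
#' downstream (see [compute_psi()]).
#'
#' @param path Path to an `SJ.out.tab`-style file.
#' @param sample_id Label recorded in the `sample_id` column.
#' @return A junction table (see [junction_table()]).
#' @export
read_star_sj <- function(path, sample_id) {
  got <- .read_table_lines(path)
  if (length(got$lines) == 0L) {
    warning("empty junction file: ", path)
    return(empty_junction_table())
  }
  fields <- strsplit(got$lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 9L)
  if (length(short)) {
    stop_data("malformed STAR junction row (expected >= 9 tab-separated ",
              "columns) at line ", got$lineno[short[1]])
  }
  m <- t(vapply(fields, function(f) f[1:9], character(9)))
  start1 <- .check_integer_field(m[, 2], got$lineno, "intron start")
  end1 <- .check_integer_field(m[, 3], got$lineno, "intron end")
  code <- .check_integer_field(m[, 4], got$lineno, "strand code")
  reads <- .check_integer_field(m[, 7], got$lineno, "read count")
  bad <- which(!code %in% 0:2)
  if (length(bad)) {
    stop_data("unknown STAR strand code '", code[bad[1]], "' at line ",
              got$lineno[bad[1]])
  }
  junction_table(
    chrom = m[, 1],
    start = start1 - 1L,   # 1-based inclusive -> 0-based half-open
    end = end1,
    strand = c(".", "+", "-")[code + 1L],
    reads = reads,
    sample_id = sample_id
  )
}

#' Read a 6-column junction BED file
#'
#' BED dialect: `chrom, start, end, name, score, strand` with a 0-based
#' half-open intron span; the score column is interpreted as the
#' unique-read count (no coordinate shift is applied).
#'
#' @inheritParams read_star_sj
#' @return A junction table.
#' @export
read_junction_bed <- function(path, sample_id) {
  got <- .read_table_lines(path)
  if (length(got$lines) == 0L) {
    warning("empty junction file: ", path)
    return(empty_junction_table())
  }
  fields <- strsplit(got$lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 6L)
  if (length(short)) {
    stop_data("malformed junction BED row (expected 6 columns) at line ",
              got$lineno[short[1]])
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  start <- .check_integer_field(m[, 2], got$lineno, "start coordinate")
  end <- .check_integer_field(m[, 3], got$lineno, "end coordinate")
  reads <- .check_integer_field(m[, 5], got$lineno, "read count (score)")
  bad <- which(start >= end)
  if (length(bad)) {
    stop_data("junction start >= end at line ", got$lineno[bad[1]])
  }
  bad <- which(reads < 0)
  if (length(bad)) {
    stop_data("negative read count at line ", got$lineno[bad[1]])
  }
  junction_table(
    chrom = m[, 1], start = start, end = end,
    strand = m[, 6], reads = reads, sample_id = sample_id
  )
}

#' Write a junction table to the BED6 dialect
#'
#' Inverse of [read_junction_bed()]: re-reading the written file
#' reproduces the junction collection exactly (the `name` column is
#' derived and carries no information).
#'
#' @param junctions A junction table.
#' @param path Output path.
#' @export
write_junction_bed <- function(junctions, path) {
  validate_junctions(junctions)
  out <- data.frame(
    junctions$chrom, junctions$start, junctions$end,
    paste0(junctions$chrom, ":", junctions$start, "-", junctions$end),
    junctions$reads, junctions$strand
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read the normalized junction TSV
#'
#' Plain tab-separated export of the internal junction model
#' (`chrom, start, end, strand, reads, sample_id`; 0-based half-open).
#'
#' @param junctions A junction table.
#' @param path File path.
#' @export
write_junction_tsv <- function(junctions, path) {
  validate_junctions(junctions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# skipticr junction table; coordinates 0-based half-open", con)
  utils::write.table(junctions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_junction_tsv
#' @export
read_junction_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_junctions(df)
  df
}

.parse_gtf_attributes <- function(s) {
  pieces <- strsplit(s, ";", fixed = TRUE)[[1]]
  pieces <- trimws(pieces)
  pieces <- pieces[nzchar(pieces)]
  # Accept both `key "value"` (GTF/GENCODE) and `key=value` (Ensembl-ish).
  m <- regmatches(pieces,
                  regexec("^([A-Za-z_][A-Za-z0-9_.]*)[ =]+\"?([^\"]*)\"?$",
                          pieces))
  ok <- lengths(m) == 3L
  vals <- vapply(m[ok], `[`, character(1), 3L)
  names(vals) <- vapply(m[ok], `[`, character(1), 2L)
  vals
}

#' Read exon records from a GTF annotation
#'
#' Parses a GENCODE-style GTF (1-based inclusive coordinates) into exon
#' records with 0-based half-open coordinates. Attribute fields in both the
#' `key "value";` and `key=value` dialects are accepted. Records lacking an
#' `exon_id` attribute get one synthesized deterministically as
#' `<transcript_id>:E<ordinal>` in file order within the transcript. The
#' reader is non-lossy: identical exon intervals appearing in several
#' transcripts yield several records (see [dedupe_exons()]).
#'
#' @param path Path to a GTF file.
#' @param feature Feature type to keep (column 3), default `"exon"`.
#' @return A `data.frame` with columns `chrom, start, end, strand, gene_id,
#'   exon_id, transcript_id` (0-based half-open coordinates).
#' @export
read_exons_gtf <- function(path, feature = "exon") {
  got <- .read_table_lines(path)
  if (length(got$lines) == 0L) {
    warning("no records in GTF file: ", path)
  }
  fields <- strsplit(got$lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 9L)
  if (length(short)) {
    stop_data("malformed GTF row (expected 9 columns) at line ",
              got$lineno[short[1]])
  }
  m <- t(vapply(fields, function(f) f[1:9], character(9)))
  keep <- m[, 3] == feature
  if (!any(keep)) {
    warning("no '", feature, "' features found in ", path)
    return(data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      strand = character(0), gene_id = character(0), exon_id = character(0),
      transcript_id = character(0), stringsAsFactors = FALSE
    ))
  }
  m <- m[keep, , drop = FALSE]
  lineno <- got$lineno[keep]
  start1 <- .check_integer_field(m[, 4], lineno, "start coordinate")
  end1 <- .check_integer_field(m[, 5], lineno, "end coordinate")
  strand <- m[, 7]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop_data("unknown strand symbol '", strand[bad[1]], "' at line ",
              lineno[bad[1]])
  }
  attrs <- lapply(m[, 9], .parse_gtf_attributes)
  get_attr <- function(key, required) {
    vals <- vapply(attrs, function(a) if (key %in% names(a)) a[[key]] else NA_character_,
                   character(1))
    if (required && anyNA(vals)) {
      stop_data("missing ", key, " attribute at line ", lineno[which(is.na(vals))[1]])
    }
    vals
  }
  gene_id <- get_attr("gene_id", required = TRUE)
  transcript_id <- get_attr("transcript_id", required = TRUE)
  exon_id <- get_attr("exon_id", required = FALSE)
  ord <- stats::ave(seq_along(transcript_id), transcript_id, FUN = seq_along)
  exon_id[is.na(exon_id)] <-
    paste0(transcript_id[is.na(exon_id)], ":E", ord[is.na(exon_id)])
  out <- data.frame(
    chrom = m[, 1],
    start = start1 - 1L,  # 1-based inclusive -> 0-based half-open
    end = end1,
    strand = strand,
    gene_id = gene_id,
    exon_id = exon_id,
    transcript_id = transcript_id,
    stringsAsFactors = FALSE
  )
  bad <- which(!(out$start < out$end))
  if (length(bad)) {
    stop_data("exon with non-positive length at line ", lineno[bad[1]])
  }
  out
}

#' Write exon records as a GTF annotation
#'
#' Inverse of [read_exons_gtf()] for the record fields the internal model
#' carries (source and score columns are fixed placeholders).
#'
#' @param exons Exon `data.frame` as returned by [read_exons_gtf()].
#' @param path Output path.
#' @export
write_gtf <- function(exons, path) {
  lines <- sprintf(
    '%s\tskipticr\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; exon_id "%s";',
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id, exons$exon_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Collapse duplicated exon intervals
#'
#' The GTF reader is non-lossy, so an exon shared by several transcripts
#' appears once per transcript. For interval-level analyses (PSI, motif
#' profiles) duplicates on `(chrom, start, end, strand)` are collapsed,
#' keeping the first record's identifiers.
#'
#' @param exons Exon `data.frame`.
#' @return The deduplicated `data.frame`.
#' @export
dedupe_exons <- function(exons) {
  key <- paste(exons$chrom, exons$start, exons$end, exons$strand, sep = "\r")
  exons[!duplicated(key), , drop = FALSE]
}
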
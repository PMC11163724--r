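# Seed-deterministic synthetic-data generators with truth tables.
#
# Three generators emulate the statistical structure the pipeline assumes:
# junction read counts under known inclusion levels for control vs.
# overexpression conditions, genomic sequence with UG repeat runs planted
# at known splice-site offsets, and dose-response observations generated
# under a known passive-diffusion fraction and monotone skipping curve.

.sim_defaults <- function() {
  list(
    seed = 1L,
    junctions = list(
      n_constitutive = 500L,   # constitutive exons unaffected by treatment
      n_skiptic = 78L,         # planted skipping events
      n_control = 2L,
      n_treated = 2L,
      read_depth = 1000,       # mean informative reads per splice site
      min_psi_constitutive = 0.92,
      skiptic_delta = c(-0.9, -0.5),  # planted delta-PSI range
      # Fraction of exon lengths divisible by 3 (frame-preserving); the
      # remainder frameshift on skipping.
      frame_preserving_prop = 39 / 69,
      flank_intron = 300L,     # inclusion-junction intron span
      spacing = 2500L,         # gap between consecutive exons
      chrom = "chrS1"
    ),
    genome = list(
      n_exons = 20L,
      exon_len = 1000L,        # > 2 * flank so the two anchors never overlap
      intron_len = 1000L,
      flank = 400L,
      repeat_spec = data.frame(anchor = "3SS", offset = 10L, units = 10L,
                               stringsAsFactors = FALSE),
      prop_planted = 1,
      # All-'+' exons by default: an {A,C} background is UG-free only on
      # the plus strand (its reverse complement is {G,T}). For mixed
      # strands use background = c("A","T"), which is UG-free on both.
      strands = "plus",        # or "both" (alternate '+'/'-')
      background = c("A", "C"),
      chrom = "chrM1"
    ),
    dose = list(
      # True response-curve knots: onset at ~1.1-1.5x, ~40% skipping at
      # 1.5x total nuclear TDP-43, ~90-95% saturation near 2-2.5x.
      knots = data.frame(fold = c(1, 1.5, 2, 2.5),
                         skipping = c(0, 40, 90, 95)),
      diffusion_fraction = 0.45,
      # Seven FACS-like expression bins per construct; WT levels are
      # chosen so sampled folds include the curve knots.
      wt_levels = c(0, 0.1, 0.25, 0.5, 0.75, 1, 1.5),
      nlsm_levels = c(0.5, 1, 1.5, 2, 2.5, 3, 3.3),
      endogenous = 1,
      noise_sd = 0.05          # multiplicative noise on responses
    )
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && !is.data.frame(base[[nm]]) &&
        is.list(override[[nm]]) && !is.data.frame(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Simulation configuration
#'
#' Builds the configuration for the synthetic-data generators. Defaults
#' describe the reference study conditions: 500 constitutive exons plus 78
#' planted skiptic events at delta-PSI between -0.9 and -0.5, ~1000
#' informative reads per splice site, (TG)10 runs planted 10 bases inside
#' the exon at the 3' splice site, and a dose design with true diffusion
#' fraction 0.45 and 5% multiplicative response noise.
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param junctions,genome,dose Named lists overriding individual defaults
#'   (see the package vignette for the full field list).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, junctions = list(), genome = list(),
                       dose = list()) {
  cfg <- .sim_defaults()
  cfg$seed <- as.integer(seed)
  cfg$junctions <- .merge_config(cfg$junctions, junctions)
  cfg$genome <- .merge_config(cfg$genome, genome)
  cfg$dose <- .merge_config(cfg$dose, dose)
  structure(cfg, class = "sim_config")
}

.sim_exon_lengths <- function(n, frame_prop) {
  # Base length drawn as a codon count; a +1/+2 offset frameshifts the
  # designated fraction of exons.
  codons <- sample(25:90, n, replace = TRUE)
  len <- 3L * codons
  shift <- stats::runif(n) >= frame_prop
  len[shift] <- len[shift] + sample(1:2, sum(shift), replace = TRUE)
  len
}

#' Simulate junction counts with known PSI
#'
#' Lays out one exon per gene along a synthetic contig and draws, for each
#' exon and sample, inclusion reads at the acceptor and donor sites and
#' exclusion reads on the single spanning junction as independent Poisson
#' counts (`I ~ Pois(depth * psi)`, `E ~ Pois(depth * (1 - psi))`). By
#' Poisson thinning this makes the site total `I + E ~ Pois(depth)` and
#' `I | (I + E) ~ Binomial(I + E, psi)` exactly at both splice sites
#' simultaneously. Zero-read junctions are omitted, as in real junction
#' files.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, per-sample junction BED
#'   files, the exon GTF and the truth table are written under it.
#' @return A list with `exons`, `samples` (named list of junction tables;
#'   control samples `ctrl_*`, treated `tdp_*`), `truth` and `config`.
#' @export
simulate_junctions <- function(config = sim_config(), dir = NULL) {
  p <- config$junctions
  set.seed(config$seed)
  n <- p$n_constitutive + p$n_skiptic
  len <- .sim_exon_lengths(n, p$frame_preserving_prop)
  start <- 1000L + cumsum(c(0L, utils::head(len, -1L) + p$spacing))
  strand <- rep(c("+", "-"), length.out = n)
  exons <- data.frame(
    chrom = p$chrom, start = start, end = start + len, strand = strand,
    gene_id = sprintf("g%04d", seq_len(n)),
    exon_id = sprintf("ex%04d", seq_len(n)),
    transcript_id = sprintf("t%04d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  psi_control <- stats::runif(n, p$min_psi_constitutive, 1)
  psi_treated <- psi_control
  is_skiptic <- logical(n)
  if (p$n_skiptic > 0L) {
    sk <- sample(n, p$n_skiptic)
    is_skiptic[sk] <- TRUE
    delta <- stats::runif(p$n_skiptic, min(p$skiptic_delta),
                          max(p$skiptic_delta))
    psi_treated[sk] <- pmax(0, psi_control[sk] + delta)
  }
  truth <- data.frame(
    exon_id = exons$exon_id, chrom = exons$chrom, start = exons$start,
    end = exons$end, strand = exons$strand,
    psi_control = psi_control, psi_treated = psi_treated,
    delta_true = psi_treated - psi_control, is_skiptic = is_skiptic,
    stringsAsFactors = FALSE
  )
  if (p$read_depth == 0) warning("read_depth is 0; junction files are empty")

  sample_names <- c(
    if (p$n_control > 0L) paste0("ctrl_", seq_len(p$n_control)),
    if (p$n_treated > 0L) paste0("tdp_", seq_len(p$n_treated))
  )
  sample_psi <- c(
    rep(list(psi_control), p$n_control),
    rep(list(psi_treated), p$n_treated)
  )
  fi <- p$flank_intron
  samples <- stats::setNames(vector("list", length(sample_names)),
                             sample_names)
  for (si in seq_along(sample_names)) {
    psi <- sample_psi[[si]]
    i3 <- stats::rpois(n, p$read_depth * psi)
    i5 <- stats::rpois(n, p$read_depth * psi)
    e <- stats::rpois(n, p$read_depth * (1 - psi))
    # Acceptor-side inclusion junction lies upstream of the exon for '+'
    # exons and downstream for '-' exons.
    up_reads <- ifelse(strand == "+", i3, i5)
    down_reads <- ifelse(strand == "+", i5, i3)
    jx <- data.frame(
      chrom = rep(p$chrom, 3L * n),
      start = c(exons$start - fi, exons$end, exons$start - fi),
      end = c(exons$start, exons$end + fi, exons$end + fi),
      strand = rep(strand, 3L),
      reads = c(up_reads, down_reads, e),
      sample_id = sample_names[si],
      stringsAsFactors = FALSE
    )
    jx <- jx[jx$reads > 0L, , drop = FALSE]
    rownames(jx) <- NULL
    samples[[si]] <- junction_table(jx$chrom, jx$start, jx$end, jx$strand,
                                    jx$reads, jx$sample_id)
  }
  out <- list(exons = exons, samples = samples, truth = truth,
              config = config)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "junctions"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    for (nm in names(samples)) {
      write_junction_bed(samples[[nm]],
                         file.path(dir, "junctions", paste0(nm, ".bed")))
    }
    write_gtf(exons, file.path(dir, "annotation.gtf"))
    utils::write.table(truth, file.path(dir, "truth", "junction_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

.plant_run <- function(chars, g_lo, g_hi, seq_chars, occupied) {
  if (g_lo < 1L || g_hi > length(chars)) {
    stop_data("planted repeat outside contig bounds")
  }
  if (any(occupied[g_lo:g_hi])) {
    stop_data("overlapping planted repeats")
  }
  chars[g_lo:g_hi] <- seq_chars
  occupied[g_lo:g_hi] <- TRUE
  list(chars = chars, occupied = occupied)
}

# Plant every repeat_spec row around one exon's splice sites; returns
# updated chars/occupied plus truth rows. The positions immediately
# flanking each run are set to a guard base that cannot extend the run's
# UG/GU mask on the exon's sense strand ('A' beside a TG run, 'T' beside
# its CA reverse complement), so planted offsets stay bit-exact.
.plant_exon_runs <- function(chars, occupied, exon, spec, flank) {
  rows <- list()
  for (r in seq_len(nrow(spec))) {
    anchor <- spec$anchor[r]
    o <- spec$offset[r]
    L <- 2L * spec$units[r]
    if (o < -flank || o + L - 1L > flank) {
      stop_config("planted repeat outside the +/-", flank, " window")
    }
    a0 <- .anchor_coord(exon, anchor)
    if (exon$strand == "+") {
      g_lo <- a0 + o
      g_hi <- a0 + o + L - 1L
      run <- rep(c("T", "G"), spec$units[r])
      guard <- "A"
    } else {
      g_hi <- a0 - o
      g_lo <- a0 - o - L + 1L
      run <- rep(c("C", "A"), spec$units[r])  # revcomp of (TG)k
      guard <- "T"
    }
    res <- .plant_run(chars, g_lo + 1L, g_hi + 1L, run, occupied)
    chars <- res$chars
    occupied <- res$occupied
    for (gpos in c(g_lo, g_hi + 2L)) {  # 1-based neighbors of the run
      if (gpos >= 1L && gpos <= length(chars) && !occupied[gpos]) {
        chars[gpos] <- guard
        occupied[gpos] <- TRUE
      }
    }
    rows[[r]] <- data.frame(
      exon_id = exon$exon_id, anchor = anchor, offset = o,
      units = spec$units[r], stringsAsFactors = FALSE
    )
  }
  list(chars = chars, occupied = occupied, truth = do.call(rbind, rows))
}

#' Simulate a genome with planted UG repeat runs
#'
#' Background sequence is drawn uniformly over `{A, C}`, which guarantees
#' zero spurious UG/GU dinucleotides, so the expected metaprofile is exact:
#' frequency `prop_planted` at planted offsets and 0 elsewhere. `(TG)k`
#' runs (sense strand; placed as `(CA)k` on the reference for `-` exons)
#' are planted at the configured splice-site offsets of the first
#' `round(prop_planted * n)` exons.
#'
#' @inheritParams simulate_junctions
#' @return A list with `genome` (a `DNAStringSet`), `exons`, `truth`
#'   (planted run per exon and spec row) and `config`.
#' @export
simulate_genome <- function(config = sim_config(), dir = NULL) {
  g <- config$genome
  set.seed(config$seed + 1L)
  n <- g$n_exons
  spacing <- g$exon_len + g$intron_len
  start <- g$intron_len + spacing * (seq_len(n) - 1L)
  exons <- data.frame(
    chrom = g$chrom, start = start, end = start + g$exon_len,
    strand = if (identical(g$strands, "plus")) rep("+", n)
             else rep(c("+", "-"), length.out = n),
    gene_id = sprintf("mg%03d", seq_len(n)),
    exon_id = sprintf("mex%03d", seq_len(n)),
    transcript_id = sprintf("mt%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  glen <- g$intron_len + spacing * n + g$flank
  chars <- sample(g$background, glen, replace = TRUE)
  occupied <- logical(glen)
  n_planted <- round(g$prop_planted * n)
  planted_rows <- list()
  spec <- g$repeat_spec
  for (i in seq_len(n_planted)) {
    res <- .plant_exon_runs(chars, occupied, exons[i, ], spec, g$flank)
    chars <- res$chars
    occupied <- res$occupied
    planted_rows[[i]] <- res$truth
  }
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- g$chrom
  truth <- if (length(planted_rows)) do.call(rbind, planted_rows)
           else data.frame(exon_id = character(0), anchor = character(0),
                           offset = integer(0), units = integer(0))
  out <- list(genome = genome, exons = exons, truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "truth"), recursive = TRUE,
               showWarnings = FALSE)
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    write_gtf(exons, file.path(dir, "motif_annotation.gtf"))
    utils::write.table(truth, file.path(dir, "truth", "repeat_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Simulate dose-response observations with known diffusion fraction
#'
#' WT observations respond at `curve(endogenous + level)`; NLSm
#' observations at `curve(endogenous + fraction * level)`, where `curve`
#' interpolates the configured monotone knots linearly (clamped outside).
#' Multiplicative Gaussian noise is applied to the responses and clamped
#' to `[0, 100]`.
#'
#' @inheritParams simulate_junctions
#' @return A list with `observations` (dose table) and `truth`
#'   (`diffusion_fraction`, `knots`).
#' @export
simulate_dose <- function(config = sim_config(), dir = NULL) {
  d <- config$dose
  set.seed(config$seed + 2L)
  k <- d$knots
  if (is.unsorted(k$fold, strictly = TRUE) ||
      is.unsorted(k$skipping, strictly = FALSE)) {
    stop_data("dose knots must have strictly increasing folds and ",
              "non-decreasing skipping")
  }
  curve_fun <- stats::approxfun(k$fold, k$skipping, rule = 2,
                                ties = "ordered")
  mk <- function(construct, levels, mult) {
    fold <- d$endogenous + mult * levels
    resp <- curve_fun(fold)
    if (d$noise_sd > 0) {
      resp <- resp * (1 + stats::rnorm(length(resp), 0, d$noise_sd))
      resp <- pmin(100, pmax(0, resp))
    }
    data.frame(
      construct = construct,
      fraction_id = paste0(construct, "_f", seq_along(levels)),
      construct_level = levels,
      endogenous_level = d$endogenous,
      skipping_percent = resp,
      stringsAsFactors = FALSE
    )
  }
  obs <- rbind(
    mk("WT", d$wt_levels, 1),
    mk("NLSm", d$nlsm_levels, d$diffusion_fraction)
  )
  rownames(obs) <- NULL
  out <- list(observations = obs,
              truth = list(diffusion_fraction = d$diffusion_fraction,
                           knots = k),
              config = config)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "truth"), recursive = TRUE,
               showWarnings = FALSE)
    write_dose_tsv(obs, file.path(dir, "dose.tsv"))
    utils::write.table(k, file.path(dir, "truth", "dose_knots.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate the full synthetic bundle
#'
#' Runs all three generators and writes a self-consistent input set under
#' `dir`: per-sample junction BED files, the exon annotation GTF, a genome
#' FASTA covering both the motif-fixture contig and the junction contig
#' (with UG runs planted around the planted skiptic exons, so the
#' end-to-end motif stage has signal to find), the dose TSV and truth
#' tables.
#'
#' @inheritParams simulate_junctions
#' @return Invisibly, a list with the three generator results.
#' @export
simulate_bundle <- function(config = sim_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jx <- simulate_junctions(config, dir = dir)
  gn <- simulate_genome(config, dir = NULL)
  ds <- simulate_dose(config, dir = dir)
  # Background sequence for the junction contig, with runs planted at the
  # planted skiptic exons. The junction exons alternate strands, so use
  # the {A,T} background, which is UG-free on both strands.
  set.seed(config$seed + 3L)
  jex <- jx$exons
  glen <- max(jex$end) + config$genome$flank + 1000L
  chars <- sample(c("A", "T"), glen, replace = TRUE)
  occupied <- logical(glen)
  spec <- config$genome$repeat_spec
  for (id in jx$truth$exon_id[jx$truth$is_skiptic]) {
    res <- .plant_exon_runs(chars, occupied,
                            jex[jex$exon_id == id, ], spec,
                            config$genome$flank)
    chars <- res$chars
    occupied <- res$occupied
  }
  jseq <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(jseq) <- unique(jex$chrom)
  genome <- c(gn$genome, jseq)
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  write_gtf(gn$exons, file.path(dir, "motif_annotation.gtf"))
  utils::write.table(gn$truth, file.path(dir, "truth", "repeat_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(junctions = jx, genome = gn, dose = ds))
}
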
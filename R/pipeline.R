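# End-to-end workflow: PSI -> delta-PSI -> skiptic calls -> UG metaprofiles
# of called exons -> NMD summary -> (optional) dose model fit, with a run
# manifest recording every tunable.

#' Build a validated run configuration
#'
#' @param junctions_control,junctions_treated Character vectors of junction
#'   file paths, one per sample; sample ids default to the file base names.
#' @param gtf Exon annotation (GTF path).
#' @param out_dir Output directory (created if needed).
#' @param fasta Optional genome FASTA; required for the motif stage.
#' @param dose Optional dose observation TSV; enables the dose stage.
#' @param format Junction file format: `"bed"` (BED6 dialect) or `"star"`
#'   (SJ.out.tab).
#' @param motif Run the motif stage? Default `NULL` = auto (TRUE when a
#'   FASTA is given). Requesting it without a FASTA is a config error.
#' @param min_reads,constitutive_threshold,skip_threshold,flank,
#'   detection_floor,diffusion_fraction,aggregator,include_unstranded
#'   Pipeline tunables, passed through to the stage functions.
#' @param verbose Verbosity level 0-2.
#' @return A list of class `run_config`.
#' @export
run_config <- function(junctions_control, junctions_treated, gtf, out_dir,
                       fasta = NULL, dose = NULL,
                       format = c("bed", "star"), motif = NULL,
                       min_reads = 10, constitutive_threshold = 0.90,
                       skip_threshold = 0.20, flank = 400,
                       detection_floor = 5, diffusion_fraction = 0.45,
                       aggregator = c("pooled", "mean"),
                       include_unstranded = FALSE, verbose = 1) {
  format <- match.arg(format)
  aggregator <- match.arg(aggregator)
  paths <- c(junctions_control, junctions_treated, gtf, fasta, dose)
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths)) {
    stop_config("input path(s) do not exist: ",
                paste(missing_paths, collapse = ", "))
  }
  if (is.null(motif)) motif <- !is.null(fasta)
  if (isTRUE(motif) && is.null(fasta)) {
    stop_config("motif stage: UG repeat profiles requested but no FASTA ",
                "was provided")
  }
  structure(list(
    junctions_control = junctions_control,
    junctions_treated = junctions_treated,
    gtf = gtf, fasta = fasta, dose = dose, out_dir = out_dir,
    format = format, motif = motif,
    min_reads = min_reads,
    constitutive_threshold = constitutive_threshold,
    skip_threshold = skip_threshold, flank = flank,
    detection_floor = detection_floor,
    diffusion_fraction = diffusion_fraction,
    aggregator = aggregator,
    include_unstranded = include_unstranded,
    verbose = verbose
  ), class = "run_config")
}

#' Read a run configuration from a key=value file
#'
#' Plain-text configuration: one `key=value` per line, `#` comments
#' allowed; list-valued keys (the junction paths) are comma-separated.
#' Keys mirror the arguments of [run_config()].
#'
#' @param path Configuration file path.
#' @param ... Overrides applied on top of the file values.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop_config("malformed config line: ", lines[bad[1]])
  vals <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
  numeric_keys <- c("min_reads", "constitutive_threshold", "skip_threshold",
                    "flank", "detection_floor", "diffusion_fraction",
                    "verbose")
  logical_keys <- c("include_unstranded", "motif")
  list_keys <- c("junctions_control", "junctions_treated")
  args <- lapply(stats::setNames(names(vals), names(vals)), function(k) {
    v <- vals[[k]]
    if (k %in% numeric_keys) as.numeric(v)
    else if (k %in% logical_keys) as.logical(v)
    else if (k %in% list_keys) trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    else v
  })
  args <- utils::modifyList(args, list(...))
  do.call(run_config, args)
}

.read_junction_samples <- function(paths, format) {
  reader <- if (format == "star") read_star_sj else read_junction_bed
  ids <- tools::file_path_sans_ext(basename(paths))
  stats::setNames(
    lapply(seq_along(paths), function(i) {
      index_junctions(reader(paths[i], ids[i]))
    }),
    ids
  )
}

#' Run the full pipeline
#'
#' Executes PSI quantification for both conditions, delta-PSI, skiptic
#' calling, UG repeat metaprofiles of the called skiptic exons (when a
#' FASTA is available), the frame-rule NMD summary over skiptic exons,
#' and, when a dose table is supplied, the dose-model fit. All tables are
#' written under `config$out_dir` together with `manifest.json` recording
#' every threshold and a hash of the configuration. Any stage error aborts
#' with a stage-named message after marking the manifest incomplete.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages_done <- character(0)
  manifest_path <- file.path(out, "manifest.json")
  write_manifest <- function(status) {
    m <- list(
      package = "skipticr",
      version = as.character(utils::packageVersion("skipticr")),
      status = status,
      stages = stages_done,
      inputs = list(
        junctions_control = config$junctions_control,
        junctions_treated = config$junctions_treated,
        gtf = config$gtf, fasta = config$fasta, dose = config$dose,
        format = config$format
      ),
      parameters = config[c("min_reads", "constitutive_threshold",
                            "skip_threshold", "flank", "detection_floor",
                            "diffusion_fraction", "aggregator",
                            "include_unstranded")],
      config_hash = config_hash(config)
    )
    jsonlite::write_json(m, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      write_manifest("incomplete")
      stop_data("stage ", name, ": ", conditionMessage(e))
    })
    stages_done <<- c(stages_done, name)
    vlog(config$verbose, 1, "stage ", name, ": done")
    res
  }

  psi <- stage("psi", {
    exons <- dedupe_exons(read_exons_gtf(config$gtf))
    ctrl <- .read_junction_samples(config$junctions_control, config$format)
    trt <- .read_junction_samples(config$junctions_treated, config$format)
    pc <- psi_matrix(exons, ctrl, min_reads = config$min_reads,
                     include_unstranded = config$include_unstranded)
    pt <- psi_matrix(exons, trt, min_reads = config$min_reads,
                     include_unstranded = config$include_unstranded)
    write_psi_tsv(pc, file.path(out, "psi_control.tsv"))
    write_psi_tsv(pt, file.path(out, "psi_treated.tsv"))
    list(exons = exons, control = pc, treated = pt)
  })

  delta <- stage("delta", {
    d <- delta_psi(psi$control, psi$treated, aggregator = config$aggregator,
                   min_reads = config$min_reads)
    write_psi_tsv(d, file.path(out, "delta_psi.tsv"))
    d
  })

  calls <- stage("call", {
    cl <- call_skiptics(delta,
                        constitutive_threshold = config$constitutive_threshold,
                        skip_threshold = config$skip_threshold,
                        verbose = config$verbose >= 2)
    write_calls_tsv(cl, file.path(out, "skiptic_calls.tsv"))
    write_skiptic_bed(cl, file.path(out, "skiptic_exons.bed"))
    cl
  })

  profiles <- NULL
  if (isTRUE(config$motif)) {
    profiles <- stage("motif", {
      if (is.null(config$fasta)) {
        stop("UG repeat profiles requested but no FASTA was provided")
      }
      sk <- calls[calls$label == "skiptic", , drop = FALSE]
      if (nrow(sk) == 0L) {
        vlog(config$verbose, 1, "motif: no skiptic exons called; skipping ",
             "profile computation")
        NULL
      } else {
        genome <- load_genome(config$fasta)
        pr <- lapply(c("3SS", "5SS"), function(a) {
          p <- splice_site_profile(sk, genome, anchor = a,
                                   flank = config$flank)
          write_profile_tsv(p, file.path(out, paste0(
            "repeat_profile_", tolower(a), ".tsv")))
          p
        })
        stats::setNames(pr, c("3SS", "5SS"))
      }
    })
  }

  nmd <- stage("nmd", {
    sk <- calls[calls$label == "skiptic", , drop = FALSE]
    if (nrow(sk) == 0L) {
      vlog(config$verbose, 1, "nmd: no skiptic exons called")
      NULL
    } else {
      calls_nmd <- predict_nmd_frame(sk)
      write_nmd_tsv(calls_nmd, file.path(out, "nmd_calls.tsv"))
      calls_nmd
    }
  })

  dose_fit <- NULL
  if (!is.null(config$dose)) {
    dose_fit <- stage("dose", {
      obs <- read_dose_tsv(config$dose)
      wt <- obs[obs$construct == "WT", , drop = FALSE]
      nlsm <- obs[obs$construct == "NLSm", , drop = FALSE]
      curve <- response_curve(wt$endogenous_level + wt$construct_level,
                              wt$skipping_percent)
      est <- if (nrow(nlsm)) estimate_diffusion_fraction(wt, nlsm) else NULL
      thr <- skipping_threshold(curve, config$detection_floor)
      summary <- list(
        threshold_fold = thr,
        detection_floor = config$detection_floor,
        diffusion_estimate = if (!is.null(est)) est$estimate else NULL,
        diffusion_range = if (!is.null(est)) est$range else NULL
      )
      jsonlite::write_json(summary, file.path(out, "dose_fit.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      utils::write.table(curve$knots, file.path(out, "dose_curve.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(curve = curve, estimate = est, threshold = thr)
    })
  }

  write_manifest("complete")
  invisible(list(psi = psi, delta = delta, calls = calls,
                 profiles = profiles, nmd = nmd, dose = dose_fit,
                 manifest = manifest_path))
}

#' Hash a run configuration
#'
#' MD5 of the canonical serialized configuration, recorded in the run
#' manifest so a results directory can be traced to its exact settings.
#'
#' @param config A [run_config()].
#' @return A hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(config),
                   vapply(config, function(x) paste(format(x), collapse = ","),
                          character(1)),
                   sep = "="), tmp)
  unname(tools::md5sum(tmp))
}
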
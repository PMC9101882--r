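#' Validate a pipeline configuration
#'
#' Collects and validates everything an end-to-end run needs: input
#' paths, sample labels, the reference sample for calibration and the
#' pair-order policy for variation statistics. All referenced input
#' files must exist at validation time.
#'
#' @param rmout RepeatMasker `.out` path.
#' @param counts Named character vector: sample label -> count TSV path.
#' @param totals Totals TSV path (`sample`, `total_mapped`).
#' @param busco BUSCO `full_table.tsv` path.
#' @param gene_panel Gene-panel TSV path (`gene`, `transcript_id`).
#' @param outdir Output directory for reports.
#' @param fasta Optional assembly FASTA (recorded in the log only).
#' @param reference Reference sample for calibration; default first
#'   sample lexicographically.
#' @param ordered_pairs Report all ordered condition pairs (default) or
#'   each unordered pair once.
#' @param class_map Optional path to a repeat class mapping TSV;
#'   defaults to the bundled table.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(rmout, counts, totals, busco, gene_panel,
                            outdir, fasta = NULL, reference = NULL,
                            ordered_pairs = TRUE, class_map = NULL) {
  samples <- names(counts)
  if (is.null(samples) || any(!nzchar(samples))) {
    config_error("counts must be a named vector (sample label -> path)")
  }
  if (anyDuplicated(samples)) {
    config_error("condition labels must be unique")
  }
  paths <- c(rmout = rmout, totals = totals, busco = busco,
             gene_panel = gene_panel, counts)
  if (!is.null(fasta)) paths <- c(paths, fasta = fasta)
  if (!is.null(class_map)) paths <- c(paths, class_map = class_map)
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0) {
    config_error("input file(s) not found: ",
                 paste(sprintf("%s (%s)", absent, names(absent)),
                       collapse = ", "))
  }
  if (!is.null(reference) && !reference %in% samples) {
    config_error("reference sample '", reference,
                 "' is not among the condition labels")
  }
  structure(list(rmout = rmout, counts = counts, totals = totals,
                 busco = busco, gene_panel = gene_panel, fasta = fasta,
                 outdir = outdir, reference = reference,
                 ordered_pairs = isTRUE(ordered_pairs),
                 class_map = class_map),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full TE-contribution and calibration pipeline
#'
#' Chains both analysis stages on one input bundle: parses and resolves
#' the RepeatMasker annotation, computes per-sample TE contributions
#' (percent of mapped reads per class) and pairwise percentage-variation
#' statistics, builds the BUSCO calibration set, derives scaling factors
#' and calibrates the gene panel. Four TSV reports and a run log are
#' written to `config$outdir`; the run is deterministic, so identical
#' inputs yield byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory reports
#'   (`assignments`, `contribution`, `variation`, `calibration`,
#'   `gene_expression`) and the written `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  say("tecontrib ", as.character(utils::packageVersion("tecontrib")),
      " | config hash ", config_hash(config))

  map <- if (is.null(config$class_map)) load_class_map() else
    load_class_map(config$class_map)

  hits <- parse_rmout(config$rmout)
  say("annotate: parsed ", nrow(hits), " RepeatMasker hits from ",
      config$rmout)
  assignments <- resolve_redundancy(hits, map)
  say("annotate: resolved to ", nrow(assignments),
      " TE assignments (one per transcript)")

  count_tables <- read_count_tables(config$counts, config$totals)
  say("quantify: loaded ", length(count_tables), " count tables")
  contribution <- te_contribution(assignments, count_tables)
  if (nrow(contribution) > 0 && all(contribution$pct_total == 0)) {
    warning("TE contribution is 0 in every sample: count-table transcript ",
            "ids may not match the RepeatMasker annotation", call. = FALSE)
    say("quantify: WARNING - all TE percents are 0")
  }
  variation <- if (nrow(contribution) >= 2) {
    contrast_conditions(contribution, ordered = config$ordered_pairs)
  } else {
    NULL
  }
  say("quantify: contribution rows ", nrow(contribution),
      ", variation pairs ", if (is.null(variation)) 0 else
        nrow(variation$pairs))

  records <- parse_busco_table(config$busco)
  calib_sets <- lapply(count_tables, function(ct) {
    build_calibration_set(records, ct)
  })
  factors <- compute_scaling_factors(calib_sets,
                                     reference = config$reference)
  say("calibrate: ", length(unique(records$busco_id)),
      " BUSCO orthologs, reference sample ", factors$reference)
  panel <- read_gene_panel(config$gene_panel)
  gene_expression <- apply_calibration(panel, count_tables, factors)
  say("calibrate: gene-panel rows ", nrow(gene_expression))

  paths <- list(
    assignments = file.path(config$outdir, "te_assignments.tsv"),
    contribution = file.path(config$outdir, "te_contribution.tsv"),
    variation = file.path(config$outdir, "te_variation.tsv"),
    calibration = file.path(config$outdir, "calibration.tsv"),
    gene_expression = file.path(config$outdir, "gene_panel_expression.tsv"),
    log = file.path(config$outdir, "run_log.txt")
  )
  write_assignments(assignments, paths$assignments)
  write_tsv(as.data.frame(contribution), paths$contribution)
  if (!is.null(variation)) write_tsv(variation$pairs, paths$variation)
  write_tsv(data.frame(sample = names(factors$cumulative),
                       cumulative = unname(factors$cumulative),
                       scaling_factor = unname(factors$factor),
                       reference = factors$reference),
            paths$calibration)
  write_tsv(as.data.frame(gene_expression), paths$gene_expression)
  writeLines(log_lines, paths$log)

  invisible(list(assignments = assignments, contribution = contribution,
                 variation = variation, factors = factors,
                 gene_expression = gene_expression, paths = paths))
}
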
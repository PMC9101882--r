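busco_statuses <- c("Complete", "Duplicated", "Fragmented", "Missing")

#' Parse a BUSCO `full_table.tsv`
#'
#' Reads the tab-separated BUSCO full table: `#`-prefixed comment lines
#' followed by one row per ortholog placement with columns busco id,
#' status, sequence (transcript id), score and length. `Missing`
#' orthologs have no sequence; a `Duplicated` busco id appears on one row
#' per copy.
#'
#' @param path Path to a `full_table.tsv`.
#' @return Data frame with columns `busco_id`, `status`, `sequence`
#'   (`NA` for Missing), `score`, `length`.
#' @export
parse_busco_table <- function(path) {
  if (!file.exists(path)) {
    input_error("BUSCO full table not found: ", path)
  }
  lines <- readLines(path)
  data_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(data_idx) == 0) {
    return(data.frame(busco_id = character(0), status = character(0),
                      sequence = character(0), score = numeric(0),
                      length = numeric(0), stringsAsFactors = FALSE))
  }
  toks <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(toks)
  bad <- which(nf < 2)
  if (length(bad) > 0) {
    parse_error("'", path, "' line ", data_idx[bad[1]],
                ": expected at least busco_id and status fields")
  }
  get <- function(i) {
    vapply(toks, function(t) if (length(t) >= i) t[[i]] else NA_character_,
           character(1))
  }
  status <- get(2)
  bad <- which(!status %in% busco_statuses)
  if (length(bad) > 0) {
    parse_error("'", path, "' line ", data_idx[bad[1]],
                ": unknown BUSCO status '", status[bad[1]], "' (expected ",
                paste(busco_statuses, collapse = "/"), ")")
  }
  sequence <- get(3)
  sequence[!is.na(sequence) & !nzchar(sequence)] <- NA_character_
  bad <- which(status == "Missing" & !is.na(sequence))
  if (length(bad) > 0) {
    parse_error("'", path, "' line ", data_idx[bad[1]],
                ": Missing BUSCO must not reference a transcript")
  }
  bad <- which(status != "Missing" & is.na(sequence))
  if (length(bad) > 0) {
    parse_error("'", path, "' line ", data_idx[bad[1]], ": status '",
                status[bad[1]], "' requires a sequence field")
  }
  data.frame(
    busco_id = get(1),
    status = status,
    sequence = sequence,
    score = suppressWarnings(as.numeric(get(4))),
    length = suppressWarnings(as.numeric(get(5))),
    stringsAsFactors = FALSE
  )
}

#' Serialize BUSCO records to `full_table.tsv` format
#'
#' @param records Data frame as returned by [parse_busco_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_busco_table <- function(records, path) {
  fmt <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE,
                                                 scientific = FALSE))
  rows <- ifelse(
    records$status == "Missing",
    paste(records$busco_id, records$status, sep = "\t"),
    paste(records$busco_id, records$status, records$sequence,
          fmt(records$score), fmt(records$length), sep = "\t")
  )
  writeLines(c(
    "# BUSCO full table",
    "# Busco id\tStatus\tSequence\tScore\tLength",
    rows
  ), path)
  invisible(path)
}

#' Build the BUSCO calibration set for one sample
#'
#' Calibration expression per ortholog: `Complete` (single copy) and
#' `Fragmented` orthologs keep the mapped-read count of their transcript;
#' `Duplicated` orthologs (typically transcriptional isoforms) take the
#' sum over all copies; `Missing` orthologs are set to 0. A referenced
#' transcript absent from the count table contributes 0 with a warning,
#' since assembly and mapping can disagree.
#'
#' @param records Data frame from [parse_busco_table()].
#' @param count_table A [count_table()].
#' @return Named numeric vector busco id -> calibration expression, one
#'   entry per distinct busco id, in the order of first appearance.
#' @export
build_calibration_set <- function(records, count_table) {
  stopifnot(inherits(count_table, "count_table"))
  by_id <- tapply(records$status, records$busco_id, unique, simplify = FALSE)
  multi <- names(by_id)[lengths(by_id) > 1]
  if (length(multi) > 0) {
    input_error("busco id(s) with conflicting statuses: ",
                paste(multi, collapse = ", "))
  }
  refs <- records$sequence[!is.na(records$sequence)]
  absent <- setdiff(unique(refs), names(count_table$counts))
  if (length(absent) > 0) {
    warning(length(absent), " BUSCO transcript(s) absent from count table '",
            count_table$sample, "' counted as 0 (e.g. ", absent[1], ")",
            call. = FALSE)
  }
  cnt <- count_table$counts[records$sequence]
  cnt[is.na(cnt)] <- 0  # Missing rows and absent transcripts
  ids <- unique(records$busco_id)
  expr <- tapply(cnt, factor(records$busco_id, levels = ids), sum)
  setNames(as.numeric(expr), ids)
}

#' Compute per-sample scaling factors from calibration sets
#'
#' The cumulative calibration expression of each sample (the sum over the
#' fixed ortholog set) measures its effective library depth. The scaling
#' factor of sample *s* is `cumulative(reference) / cumulative(s)`, so
#' the reference has factor 1 and `cumulative * factor` is identical
#' across samples after calibration.
#'
#' @param calibration_sets Named list of calibration sets (one per
#'   sample) from [build_calibration_set()], or a named numeric vector of
#'   per-sample cumulative expressions.
#' @param reference Reference sample label; defaults to the first sample
#'   in lexicographic order.
#' @return An object of class `calibration_factors` with components
#'   `cumulative` (named numeric), `factor` (named numeric) and
#'   `reference`.
#' @export
compute_scaling_factors <- function(calibration_sets, reference = NULL) {
  if (is.list(calibration_sets)) {
    cumulative <- vapply(calibration_sets, sum, numeric(1))
  } else {
    cumulative <- calibration_sets
  }
  samples <- names(cumulative)
  if (is.null(samples) || any(!nzchar(samples))) {
    input_error("calibration sets must be named by sample label")
  }
  if (is.null(reference)) {
    reference <- sort(samples, method = "radix")[1]
  }
  if (!reference %in% samples) {
    input_error("reference sample '", reference,
                "' is not among the calibrated samples")
  }
  zero <- samples[cumulative <= 0]
  if (length(zero) > 0) {
    input_error("cumulative calibration expression is 0 for sample(s): ",
                paste(zero, collapse = ", "))
  }
  factor <- cumulative[[reference]] / cumulative
  structure(list(cumulative = cumulative,
                 factor = factor,
                 reference = reference),
            class = "calibration_factors")
}

#' @export
print.calibration_factors <- function(x, ...) {
  cat("<calibration_factors> reference: ", x$reference, "\n", sep = "")
  print(data.frame(sample = names(x$cumulative),
                   cumulative = unname(x$cumulative),
                   factor = unname(x$factor)), row.names = FALSE)
  invisible(x)
}

#' Apply calibration factors to gene-panel expression
#'
#' Rescales the raw mapped-read count of each panel gene by the sample's
#' scaling factor so values are comparable across samples and species.
#' Internally the calibrated value is evaluated as
#' `(raw * cumulative(reference)) / cumulative(sample)` — one floating
#' point rounding after exact integer products — which makes calibration
#' exactly invariant to a uniform rescaling of any non-reference count
#' table. Genes absent from a sample's count table are reported with raw
#' and calibrated values of 0.
#'
#' @param panel Data frame with columns `gene` and `transcript_id`
#'   (see [read_gene_panel()]).
#' @param count_tables Named list of [count_table()] objects.
#' @param factors A `calibration_factors` object from
#'   [compute_scaling_factors()].
#' @return Data frame of class `gene_panel_expression`: `gene`,
#'   `transcript_id`, `sample`, `raw`, `calibrated`.
#' @export
apply_calibration <- function(panel, count_tables, factors) {
  stopifnot(inherits(factors, "calibration_factors"))
  if (anyDuplicated(panel$gene)) {
    input_error("duplicate gene name(s) in panel: ",
                paste(unique(panel$gene[duplicated(panel$gene)]),
                      collapse = ", "))
  }
  samples <- names(count_tables)
  missing <- setdiff(samples, names(factors$factor))
  if (length(missing) > 0) {
    input_error("no scaling factor for sample(s): ",
                paste(missing, collapse = ", "))
  }
  known <- unique(unlist(lapply(count_tables, function(ct) names(ct$counts))))
  orphan <- setdiff(panel$transcript_id, known)
  if (length(orphan) > 0) {
    warning("panel transcript(s) absent from every count table, reported ",
            "as 0: ", paste(orphan, collapse = ", "), call. = FALSE)
  }
  cum_ref <- factors$cumulative[[factors$reference]]
  out <- do.call(rbind, lapply(samples, function(s) {
    raw <- count_tables[[s]]$counts[panel$transcript_id]
    raw[is.na(raw)] <- 0
    data.frame(
      gene = panel$gene,
      transcript_id = panel$transcript_id,
      sample = s,
      raw = unname(raw),
      calibrated = unname((raw * cum_ref) / factors$cumulative[[s]]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("gene_panel_expression", "data.frame")
  out
}

#' The bundled TE-silencing gene panel
#'
#' The panel comprises 26 genes: 4 of the *Argonaute* subfamily, 6
#' involved in heterochromatin formation, 14 of the NuRD (nucleosome
#' remodeling deacetylase) complex, plus *TRIM33* and the actinopterygian
#' *KRAB-like* that are proposed to recruit the NuRD complex to TE
#' sequences in ray-finned fish. The loader asserts these category
#' counts, so the shipped configuration cannot drift silently.
#'
#' @return Data frame with columns `gene` and `category`.
#' @export
bundled_gene_panel <- function() {
  if (!is.null(.tecontrib_env$gene_panel)) {
    return(.tecontrib_env$gene_panel)
  }
  path <- system.file("extdata", "silencing_gene_panel.tsv",
                      package = "tecontrib", mustWork = TRUE)
  panel <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  counts <- table(panel$category)
  ok <- identical(unname(counts[["argonaute"]]), 4L) &&
    identical(unname(counts[["heterochromatin"]]), 6L) &&
    identical(unname(counts[["nurd"]]), 14L) &&
    setequal(panel$gene[panel$category == "recruiter"],
             c("TRIM33", "KRAB-like"))
  if (!ok) {
    invariant_error("bundled gene panel is corrupt: expected 4 argonaute, ",
                    "6 heterochromatin, 14 nurd genes plus TRIM33 and ",
                    "KRAB-like")
  }
  .tecontrib_env$gene_panel <- panel
  panel
}

#' Read a gene-panel table mapping gene names to transcript ids
#'
#' @param path TSV with columns `gene` and `transcript_id` (extra
#'   columns, e.g. `category`, are kept).
#' @return Data frame with at least `gene` and `transcript_id`.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) {
    input_error("gene panel not found: ", path)
  }
  panel <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  if (!all(c("gene", "transcript_id") %in% names(panel))) {
    parse_error("'", path,
                "' must have columns 'gene' and 'transcript_id'")
  }
  if (anyDuplicated(panel$gene)) {
    input_error("duplicate gene name(s) in panel '", path, "': ",
                paste(unique(panel$gene[duplicated(panel$gene)]),
                      collapse = ", "))
  }
  panel
}
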
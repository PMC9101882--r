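#' Construct a per-sample count table
#'
#' A count table holds the mapped-read count of each transcript in one
#' sample (library) together with the sample's total number of mapped
#' reads. Reads mapping to transcripts absent from `counts` are allowed:
#' the per-transcript counts may sum to less than `total_mapped`, and the
#' total — not the TE-assigned subset — is the denominator of all
#' percent-of-mapped-reads values.
#'
#' @param sample Sample label.
#' @param counts Named numeric vector, transcript id -> non-negative
#'   mapped-read count.
#' @param total_mapped Total mapped reads in the sample (positive).
#' @return An object of class `count_table`.
#' @export
count_table <- function(sample, counts, total_mapped) {
  if (!is.character(sample) || length(sample) != 1L || !nzchar(sample)) {
    input_error("'sample' must be a single non-empty label")
  }
  ids <- names(counts)
  if (length(counts) > 0 && (is.null(ids) || any(!nzchar(ids)))) {
    input_error("counts must be named by transcript id")
  }
  if (anyDuplicated(ids)) {
    input_error("duplicated transcript id(s) in count table '", sample,
                "': ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    input_error("counts for sample '", sample,
                "' must be non-negative integers")
  }
  if (!is_count(total_mapped)) {
    input_error("total_mapped for sample '", sample,
                "' must be a positive integer")
  }
  if (sum(counts) > total_mapped) {
    input_error("counts for sample '", sample, "' sum to ", sum(counts),
                " > total_mapped = ", total_mapped)
  }
  structure(list(sample = sample,
                 counts = counts,
                 total_mapped = as.numeric(total_mapped)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> sample '", x$sample, "': ", length(x$counts),
      " transcripts, ", format(x$total_mapped, big.mark = ","),
      " mapped reads\n", sep = "")
  invisible(x)
}

#' Read a per-sample count TSV
#'
#' Expects columns `transcript_id` and `count`.
#'
#' @param path Path to the TSV.
#' @param sample Sample label.
#' @param total_mapped Total mapped reads for this sample.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, sample, total_mapped) {
  if (!file.exists(path)) {
    input_error("count table not found: ", path)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "count") %in% names(df))) {
    parse_error("'", path, "' must have columns 'transcript_id' and 'count'")
  }
  count_table(sample, setNames(as.numeric(df$count), df$transcript_id),
              total_mapped)
}

#' Read a set of per-sample count tables plus their totals file
#'
#' @param count_paths Named character vector: sample label -> count TSV
#'   path.
#' @param totals_path TSV with columns `sample` and `total_mapped`.
#' @return Named list of [count_table()] objects, one per sample.
#' @export
read_count_tables <- function(count_paths, totals_path) {
  samples <- names(count_paths)
  if (is.null(samples) || any(!nzchar(samples))) {
    input_error("count_paths must be named by sample label")
  }
  if (anyDuplicated(samples)) {
    input_error("duplicate sample labels in count_paths")
  }
  if (!file.exists(totals_path)) {
    input_error("totals file not found: ", totals_path)
  }
  totals <- utils::read.delim(totals_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "total_mapped") %in% names(totals))) {
    parse_error("'", totals_path,
                "' must have columns 'sample' and 'total_mapped'")
  }
  missing <- setdiff(samples, totals$sample)
  if (length(missing) > 0) {
    input_error("totals file lacks sample(s): ",
                paste(missing, collapse = ", "))
  }
  tm <- setNames(totals$total_mapped, totals$sample)
  out <- lapply(samples, function(s) {
    read_count_table(count_paths[[s]], s, tm[[s]])
  })
  setNames(out, samples)
}

write_count_table <- function(ct, path) {
  write_tsv(data.frame(transcript_id = names(ct$counts),
                       count = unname(ct$counts)), path)
}
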
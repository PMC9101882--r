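#' Sum mapped-read counts per TE class
#'
#' The overall expression of each TE class is the sum of the mapped-read
#' counts of all transcripts assigned to that class. Transcripts assigned
#' a TE class but absent from the count table contribute 0.
#'
#' @param assignments Data frame from [resolve_redundancy()].
#' @param count_table A [count_table()].
#' @return Named numeric vector over [te_classes()], in reads.
#' @export
class_expression <- function(assignments, count_table) {
  stopifnot(inherits(count_table, "count_table"))
  cls <- te_classes()
  bad <- setdiff(unique(assignments$te_class), cls)
  if (length(bad) > 0) {
    input_error("assignments contain non-TE or unknown class(es): ",
                paste(bad, collapse = ", "))
  }
  cnt <- count_table$counts[assignments$query_id]
  cnt[is.na(cnt)] <- 0
  out <- setNames(numeric(length(cls)), cls)
  got <- tapply(cnt, factor(assignments$te_class, levels = cls), sum)
  got[is.na(got)] <- 0
  out[names(got)] <- got
  out
}

#' Convert per-class read counts to percent of mapped reads
#'
#' `pct_class = 100 * class_count / total_mapped`; the total TE
#' contribution is the sum over classes. Using total mapped reads (not
#' TE-assigned reads) as the denominator makes contributions comparable
#' across samples and species.
#'
#' @param class_counts Named numeric vector from [class_expression()].
#' @param total_mapped Total mapped reads (positive).
#' @param sample Sample label attached to the report.
#' @return A one-row data frame of class `te_contribution`: `sample`, one
#'   `pct_<class>` column per TE class, and `pct_total`.
#' @export
to_percent <- function(class_counts, total_mapped, sample = "sample") {
  if (!is.numeric(total_mapped) || length(total_mapped) != 1L ||
      !is.finite(total_mapped) || total_mapped <= 0) {
    input_error("total_mapped must be a single positive number")
  }
  cls <- te_classes()
  if (!all(cls %in% names(class_counts))) {
    input_error("class_counts must be named by the TE classes: ",
                paste(cls, collapse = ", "))
  }
  pct <- 100 * class_counts[cls] / total_mapped
  out <- data.frame(sample = sample, as.list(setNames(pct, paste0("pct_", cls))),
                    pct_total = sum(pct), stringsAsFactors = FALSE,
                    check.names = FALSE)
  class(out) <- c("te_contribution", "data.frame")
  out
}

#' Signed percentage variation between two contribution values
#'
#' `100 * (b - a) / a`: the relative change of `b` with respect to
#' baseline `a`, in percent. Undefined when the baseline is 0 while the
#' comparison value is not; reported as `NA` rather than infinity. Both
#' zero yields 0 (no change).
#'
#' @param a Baseline percent value(s).
#' @param b Comparison percent value(s).
#' @return Numeric vector of signed percentage variations.
#' @examples
#' pct_variation(2, 3)   # 50
#' pct_variation(10, 10) # 0
#' @export
pct_variation <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    input_error("percent values must be non-negative")
  }
  out <- 100 * (b - a) / a
  out[a == 0 & b == 0] <- 0
  out[a == 0 & b > 0] <- NA_real_
  out
}

#' Pairwise percentage-variation statistics across conditions
#'
#' Computes the signed percentage variation of the total TE contribution
#' and of every TE class for every pair of samples, and identifies the
#' maximum-magnitude variation for the total and across single classes.
#' Both orderings of each pair are reported by default so the direction
#' of any quoted variation is auditable.
#'
#' @param reports A `te_contribution` data frame with one row per sample
#'   (rbind of [to_percent()] outputs).
#' @param ordered If `TRUE` (default) all ordered pairs are reported
#'   (`n * (n - 1)` rows per class); otherwise each unordered pair appears
#'   once, in row order of `reports`.
#' @return A list of class `variation_report`: `pairs` (data frame with
#'   `sample_a`, `sample_b`, `class`, `pct_a`, `pct_b`, `variation`),
#'   `max_total` and `max_class` (one-row slices with the
#'   maximum-magnitude variation, `NA`s ignored).
#' @export
contrast_conditions <- function(reports, ordered = TRUE) {
  stopifnot(is.data.frame(reports))
  n <- nrow(reports)
  if (n < 2) {
    input_error("contrast_conditions needs at least 2 samples, got ", n)
  }
  if (anyDuplicated(reports$sample)) {
    input_error("duplicate sample labels in contribution reports")
  }
  cols <- c(paste0("pct_", te_classes()), "pct_total")
  labels <- c(te_classes(), "total")

  idx <- expand.grid(a = seq_len(n), b = seq_len(n))
  idx <- idx[idx$a != idx$b, , drop = FALSE]
  if (!ordered) idx <- idx[idx$a < idx$b, , drop = FALSE]

  pairs <- do.call(rbind, lapply(seq_along(cols), function(k) {
    a <- reports[[cols[k]]][idx$a]
    b <- reports[[cols[k]]][idx$b]
    data.frame(
      sample_a = reports$sample[idx$a],
      sample_b = reports$sample[idx$b],
      class = labels[k],
      pct_a = a,
      pct_b = b,
      variation = pct_variation(a, b),
      stringsAsFactors = FALSE
    )
  }))
  rownames(pairs) <- NULL

  pick_max <- function(df) {
    if (nrow(df) == 0 || all(is.na(df$variation))) {
      return(df[0, , drop = FALSE])
    }
    df[which.max(abs(df$variation)), , drop = FALSE]
  }
  structure(list(
    pairs = pairs,
    max_total = pick_max(pairs[pairs$class == "total", , drop = FALSE]),
    max_class = pick_max(pairs[pairs$class != "total", , drop = FALSE])
  ), class = "variation_report")
}

#' @export
print.variation_report <- function(x, ...) {
  cat("<variation_report> ", nrow(x$pairs), " pairwise comparisons\n",
      sep = "")
  if (nrow(x$max_total) == 1) {
    cat(sprintf("  max total TE variation: %.2f%% (%s vs. %s)\n",
                x$max_total$variation, x$max_total$sample_b,
                x$max_total$sample_a))
  }
  if (nrow(x$max_class) == 1) {
    cat(sprintf("  max single-class variation: %.2f%% (%s, %s vs. %s)\n",
                x$max_class$variation, x$max_class$class,
                x$max_class$sample_b, x$max_class$sample_a))
  }
  invisible(x)
}

#' TE contribution reports for a set of samples
#'
#' Convenience wrapper: applies [class_expression()] and [to_percent()]
#' to each sample's count table and stacks the per-sample reports.
#'
#' @param assignments Data frame from [resolve_redundancy()].
#' @param count_tables Named list of [count_table()] objects.
#' @return A `te_contribution` data frame, one row per sample.
#' @export
te_contribution <- function(assignments, count_tables) {
  rows <- lapply(count_tables, function(ct) {
    to_percent(class_expression(assignments, ct), ct$total_mapped, ct$sample)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("te_contribution", "data.frame")
  out
}
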
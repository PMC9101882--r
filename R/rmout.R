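#' Parse a RepeatMasker `.out` annotation file
#'
#' Reads the whitespace-aligned RepeatMasker output format: three header
#' lines (two column-name lines and a blank line) followed by one record
#' per repeat hit. Query coordinates are 1-based inclusive. The `C` strand
#' symbol is normalized to `-`; a trailing `*` (hit overlapped by a
#' higher-scoring match) is captured in `overlap_flag`. The
#' repeat-coordinate columns, whose layout depends on strand, are retained
#' verbatim so that [write_rmout()] round-trips records exactly.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A data frame with one row per hit and columns `sw_score`,
#'   `pct_div`, `pct_del`, `pct_ins`, `query_id`, `q_begin`, `q_end`,
#'   `q_left`, `strand`, `repeat_name`, `class_family`, `r_begin`, `r_end`,
#'   `r_left`, `hit_id`, `overlap_flag`.
#' @seealso [resolve_redundancy()], [classify_repeat()]
#' @export
parse_rmout <- function(path) {
  if (!file.exists(path)) {
    input_error("RepeatMasker .out file not found: ", path)
  }
  lines <- readLines(path)
  if (length(lines) < 3) {
    parse_error("'", path, "': expected the standard 3 RepeatMasker ",
                "header lines, found ", length(lines), " line(s)")
  }
  body <- lines[-(1:3)]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  lineno <- which(keep) + 3L  # original line numbers for error messages

  n <- length(body)
  empty <- data.frame(
    sw_score = integer(0), pct_div = numeric(0), pct_del = numeric(0),
    pct_ins = numeric(0), query_id = character(0), q_begin = integer(0),
    q_end = integer(0), q_left = character(0), strand = character(0),
    repeat_name = character(0), class_family = character(0),
    r_begin = character(0), r_end = character(0), r_left = character(0),
    hit_id = integer(0), overlap_flag = logical(0),
    stringsAsFactors = FALSE
  )
  if (n == 0) {
    return(empty)
  }

  toks <- strsplit(trimws(body), "[[:space:]]+")
  nf <- lengths(toks)
  bad <- which(nf < 15 | nf > 16)
  if (length(bad) > 0) {
    parse_error("'", path, "' line ", lineno[bad[1]], ": expected 15 or 16 ",
                "whitespace-separated fields, found ", nf[bad[1]])
  }

  field <- function(i) vapply(toks, `[[`, character(1), i)
  as_num <- function(x, what, integer = FALSE) {
    out <- suppressWarnings(if (integer) as.integer(x) else as.numeric(x))
    bad <- which(is.na(out))
    if (length(bad) > 0) {
      parse_error("'", path, "' line ", lineno[bad[1]], ": field '", what,
                  "' is not ", if (integer) "an integer" else "numeric",
                  ": '", x[bad[1]], "'")
    }
    out
  }

  strand <- field(9)
  bad <- which(!strand %in% c("+", "C", "-"))
  if (length(bad) > 0) {
    parse_error("'", path, "' line ", lineno[bad[1]],
                ": strand must be '+' or 'C', found '", strand[bad[1]], "'")
  }
  strand[strand == "C"] <- "-"

  hits <- data.frame(
    sw_score = as_num(field(1), "sw_score", integer = TRUE),
    pct_div = as_num(field(2), "pct_div"),
    pct_del = as_num(field(3), "pct_del"),
    pct_ins = as_num(field(4), "pct_ins"),
    query_id = field(5),
    q_begin = as_num(field(6), "q_begin", integer = TRUE),
    q_end = as_num(field(7), "q_end", integer = TRUE),
    q_left = field(8),
    strand = strand,
    repeat_name = field(10),
    class_family = field(11),
    r_begin = field(12),
    r_end = field(13),
    r_left = field(14),
    hit_id = as_num(field(15), "hit_id", integer = TRUE),
    overlap_flag = nf == 16,
    stringsAsFactors = FALSE
  )
  star <- which(hits$overlap_flag)
  bad <- star[vapply(toks[star], `[[`, character(1), 16) != "*"]
  if (length(bad) > 0) {
    parse_error("'", path, "' line ", lineno[bad[1]],
                ": 16th field must be '*'")
  }

  bad <- which(hits$q_begin < 1 | hits$q_end < hits$q_begin)
  if (length(bad) > 0) {
    parse_error("'", path, "' line ", lineno[bad[1]],
                ": query coordinates must satisfy 1 <= begin <= end, found ",
                hits$q_begin[bad[1]], "..", hits$q_end[bad[1]])
  }
  hits
}

#' Serialize repeat hits back to RepeatMasker `.out` format
#'
#' Writes the standard two column-name header lines plus a blank line,
#' then one space-aligned record per hit. The `-` strand is written back
#' as `C` and `overlap_flag` as a trailing `*`, so a
#' parse–serialize–parse cycle preserves every parsed field.
#'
#' @param hits Data frame of hits as returned by [parse_rmout()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rmout <- function(hits, path) {
  header <- c(
    paste0("   SW   perc perc perc  query                       position in query",
           "               matching         repeat                position in repeat"),
    paste0("score   div. del. ins.  sequence                    begin  end      (left)",
           "   repeat           class/family        begin  end   (left)      ID"),
    ""
  )
  fmt_pct <- function(x) formatC(x, format = "f", digits = 1)
  rows <- character(nrow(hits))
  if (nrow(hits) > 0) {
    rows <- paste(
      formatC(hits$sw_score, width = 5),
      formatC(fmt_pct(hits$pct_div), width = 5),
      formatC(fmt_pct(hits$pct_del), width = 4),
      formatC(fmt_pct(hits$pct_ins), width = 4),
      formatC(hits$query_id, width = -27),
      formatC(hits$q_begin, width = 6),
      formatC(hits$q_end, width = 6),
      formatC(hits$q_left, width = -9),
      ifelse(hits$strand == "-", "C", "+"),
      formatC(hits$repeat_name, width = -16),
      formatC(hits$class_family, width = -19),
      formatC(hits$r_begin, width = 5),
      formatC(hits$r_end, width = 5),
      formatC(hits$r_left, width = -7),
      formatC(hits$hit_id, width = 4),
      ifelse(hits$overlap_flag, "*", "")
    )
    rows <- sub("[[:space:]]+$", "", rows)
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Resolve redundant repeat hits to one TE assignment per transcript
#'
#' Drops hits whose repeat category is not a transposable element, then
#' keeps, for each transcript, the single hit with the highest
#' Smith-Waterman score, breaking score ties by the longer match. Exact
#' (score, length) ties are broken deterministically by repeat name
#' (ascending) then query start (ascending). The result assigns each
#' TE-containing transcript exactly one TE class, under which its whole
#' mapped-read count is later aggregated.
#'
#' @param hits Data frame from [parse_rmout()].
#' @param map Class mapping table, see [load_class_map()].
#' @return A data frame with one row per transcript that had at least one
#'   TE hit: `query_id`, `te_class`, `repeat_name`, `sw_score`,
#'   `length_bp`, `q_begin`, `q_end`, `strand`, `hit_id`.
#' @export
resolve_redundancy <- function(hits, map = load_class_map()) {
  te_class <- classify_repeat(hits$class_family, map)
  keep <- te_class != "NonTE"
  hits <- hits[keep, , drop = FALSE]
  te_class <- te_class[keep]
  length_bp <- hits$q_end - hits$q_begin + 1L

  # lexicographic best hit per transcript: max score, then max length,
  # then name/position for determinism; radix order is locale-independent
  ord <- order(hits$query_id, -hits$sw_score, -length_bp,
               hits$repeat_name, hits$q_begin, method = "radix")
  first <- ord[!duplicated(hits$query_id[ord])]
  first <- first[order(hits$query_id[first], method = "radix")]

  data.frame(
    query_id = hits$query_id[first],
    te_class = te_class[first],
    repeat_name = hits$repeat_name[first],
    sw_score = hits$sw_score[first],
    length_bp = length_bp[first],
    q_begin = hits$q_begin[first],
    q_end = hits$q_end[first],
    strand = hits$strand[first],
    hit_id = hits$hit_id[first],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write TE assignments as TSV
#'
#' @param assignments Data frame from [resolve_redundancy()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  write_tsv(assignments[, c("query_id", "te_class", "repeat_name",
                            "sw_score", "length_bp")], path)
}

#' Export TE assignments as BED6
#'
#' Converts the 1-based inclusive RepeatMasker query coordinates to
#' BED's 0-based half-open convention.
#'
#' @param assignments Data frame from [resolve_redundancy()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_assignments_bed <- function(assignments, path) {
  bed <- data.frame(
    chrom = assignments$query_id,
    start = assignments$q_begin - 1L,
    end = assignments$q_end,
    name = paste(assignments$te_class, assignments$repeat_name, sep = "|"),
    score = assignments$sw_score,
    strand = assignments$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
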
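# Shared fixture builders and independent oracles.

# a minimal RepeatMasker-style hit row (defaults are valid)
make_hit <- function(query_id = "tx1", sw_score = 500, repeat_name = "L2-1",
                     class_family = "LINE/L2", q_begin = 1L, q_end = 100L,
                     strand = "+", hit_id = 1L, overlap_flag = FALSE,
                     pct_div = 10, pct_del = 1, pct_ins = 1) {
  data.frame(
    sw_score = as.integer(sw_score), pct_div = pct_div, pct_del = pct_del,
    pct_ins = pct_ins, query_id = query_id, q_begin = as.integer(q_begin),
    q_end = as.integer(q_end), q_left = "(0)", strand = strand,
    repeat_name = repeat_name, class_family = class_family,
    r_begin = "1", r_end = as.character(q_end - q_begin + 1L),
    r_left = "(0)", hit_id = as.integer(hit_id),
    overlap_flag = overlap_flag, stringsAsFactors = FALSE
  )
}

make_hits <- function(...) {
  do.call(rbind, list(...))
}

# random hit sets over n_queries transcripts, <= max_hits TE hits each
random_hit_set <- function(n_queries = 50, max_hits = 10) {
  families <- c("LINE/L2", "SINE/tRNA", "LTR/Gypsy", "DNA/hAT",
                "RC/Helitron", "Retroposon", "Unknown")
  per_query <- sample.int(max_hits, n_queries, replace = TRUE)
  n <- sum(per_query)
  qb <- sample.int(400, n, replace = TRUE)
  qe <- qb + sample.int(300, n, replace = TRUE) - 1L
  data.frame(
    sw_score = sample.int(50, n, replace = TRUE) * 10L,  # frequent ties
    pct_div = 10, pct_del = 1, pct_ins = 1,
    query_id = rep(sprintf("q%03d", seq_len(n_queries)), times = per_query),
    q_begin = qb, q_end = qe, q_left = "(0)",
    strand = sample(c("+", "-"), n, replace = TRUE),
    repeat_name = sprintf("rep%02d", sample.int(20, n, replace = TRUE)),
    class_family = sample(families, n, replace = TRUE),
    r_begin = "1", r_end = as.character(qe - qb + 1L), r_left = "(0)",
    hit_id = seq_len(n), overlap_flag = FALSE,
    stringsAsFactors = FALSE
  )
}

# Independent oracle for redundancy resolution: per query, enumerate every
# TE hit and pick the best by explicit pairwise tuple comparison.
oracle_resolve <- function(hits, map = load_class_map()) {
  cls <- classify_repeat(hits$class_family, map)
  hits <- hits[cls != "NonTE", , drop = FALSE]
  cls <- cls[cls != "NonTE"]
  len <- hits$q_end - hits$q_begin + 1L
  better <- function(i, j) {
    # TRUE if hit i beats hit j under (score, length, name asc, q_begin asc)
    if (hits$sw_score[i] != hits$sw_score[j])
      return(hits$sw_score[i] > hits$sw_score[j])
    if (len[i] != len[j]) return(len[i] > len[j])
    if (hits$repeat_name[i] != hits$repeat_name[j])
      return(hits$repeat_name[i] < hits$repeat_name[j])
    hits$q_begin[i] < hits$q_begin[j]
  }
  winners <- vapply(sort(unique(hits$query_id), method = "radix"),
                    function(q) {
    idx <- which(hits$query_id == q)
    best <- idx[1]
    for (i in idx[-1]) if (better(i, best)) best <- i
    best
  }, integer(1))
  data.frame(query_id = hits$query_id[winners], te_class = cls[winners],
             repeat_name = hits$repeat_name[winners],
             sw_score = hits$sw_score[winners], length_bp = len[winners],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Brute-force oracle for the maximum-magnitude pairwise variation.
oracle_max_variation <- function(reports, ordered = TRUE) {
  cols <- c(paste0("pct_", te_classes()), "pct_total")
  best <- NULL
  n <- nrow(reports)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b || (!ordered && a > b)) next
      for (cn in cols) {
        va <- reports[[cn]][a]
        vb <- reports[[cn]][b]
        if (va == 0) next
        v <- 100 * (vb - va) / va
        if (is.null(best) || abs(v) > abs(best$v)) {
          best <- list(a = reports$sample[a], b = reports$sample[b],
                       class = sub("pct_", "", cn), v = v)
        }
      }
    }
  }
  best
}

# small deterministic synthetic bundle, regenerated per call
tiny_config <- function(seed = 42, ...) {
  args <- list(
    n_transcripts = 200,
    conditions = c("FW", "BW", "SW"),
    library_sizes = c(FW = 20000, BW = 24000, SW = 16000),
    n_busco = 20,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

make_count_table <- function(sample = "S1",
                             counts = c(tx1 = 10, tx2 = 20, tx3 = 30),
                             total_mapped = 1000) {
  count_table(sample, counts, total_mapped)
}
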
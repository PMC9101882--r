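#' Configuration for the synthetic dataset generator
#'
#' Defines the study design the generator emulates: a de novo
#' transcriptome whose transcripts are either TE transcripts (one of the
#' six TE classes) or non-TE transcripts, sequenced under several
#' salinity conditions with differing library sizes and condition-specific
#' TE expression shifts, annotated by RepeatMasker and BUSCO.
#'
#' Default values reproduce a three-condition freshwater / brackish /
#' salt-water (FW/BW/SW) design on a small assembly: TE transcripts make
#' up 12% of the assembly (DNA transposons dominant, LINEs second, as is
#' typical of teleost transcriptomes), libraries differ in depth, BW mildly
#' up-regulates all TE classes and SW down-regulates them except SINEs,
#' mimicking the eel-like pattern of a salinity-responsive TE load.
#'
#' @param n_transcripts Number of transcripts in the assembly.
#' @param class_fractions Named fractions over
#'   `c(te_classes(), "NonTE")`; must sum to 1.
#' @param conditions Sample labels.
#' @param library_sizes Named positive integers, total mapped reads per
#'   sample.
#' @param expression_shift Named list (per sample) of named multiplicative
#'   expression weights per class (> 0); unspecified classes default to 1.
#' @param n_busco Number of BUSCO orthologs to place.
#' @param busco_status_mix Named fractions over
#'   Complete/Duplicated/Fragmented/Missing; must sum to 1.
#' @param n_dup_copies Copies (isoform transcripts) per Duplicated BUSCO.
#' @param overlap_rate Fraction of TE transcripts given two or more
#'   competing RepeatMasker hits.
#' @param nonte_hit_rate Fraction of non-TE transcripts given a
#'   non-TE repeat hit (simple repeat / low complexity), exercising the
#'   TE filter.
#' @param force_score_ties If `TRUE`, competing hits tie the winner's
#'   Smith-Waterman score exactly (with shorter length), exercising the
#'   length tie-break; by default competing hits have strictly lower
#'   scores.
#' @param panel_overlaps_busco If `TRUE`, gene-panel transcripts may
#'   coincide with BUSCO-referenced transcripts; by default the two sets
#'   are disjoint.
#' @param seed Integer seed; identical configurations produce
#'   byte-identical output files.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_transcripts = 600,
                         class_fractions = c(SINE = 0.015, Retro = 0.01,
                                             LTR = 0.015, LINE = 0.03,
                                             DNA = 0.04, Unclear = 0.01,
                                             NonTE = 0.88),
                         conditions = c("FW", "BW", "SW"),
                         library_sizes = c(FW = 100000, BW = 120000,
                                           SW = 80000),
                         expression_shift = list(
                           FW = c(),
                           BW = c(SINE = 1.1, Retro = 1.1, LTR = 1.1,
                                  LINE = 1.1, DNA = 1.1, Unclear = 1.1),
                           SW = c(SINE = 1.3, Retro = 0.8, LTR = 0.8,
                                  LINE = 0.8, DNA = 0.8, Unclear = 0.8)
                         ),
                         n_busco = 50,
                         busco_status_mix = c(Complete = 0.7,
                                              Duplicated = 0.1,
                                              Fragmented = 0.1,
                                              Missing = 0.1),
                         n_dup_copies = 2,
                         overlap_rate = 0.2,
                         nonte_hit_rate = 0.1,
                         force_score_ties = FALSE,
                         panel_overlaps_busco = FALSE,
                         seed = 1) {
  if (!is_count(n_transcripts)) {
    config_error("n_transcripts must be a positive integer")
  }
  all_classes <- c(te_classes(), "NonTE")
  if (!setequal(names(class_fractions), all_classes)) {
    config_error("class_fractions must be named by ",
                 paste(all_classes, collapse = ", "))
  }
  class_fractions <- class_fractions[all_classes]
  if (any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-9) {
    config_error("class_fractions must be non-negative and sum to 1 ",
                 "(within 1e-9); got sum = ", sum(class_fractions))
  }
  if (length(conditions) < 1 || anyDuplicated(conditions)) {
    config_error("conditions must be a non-empty vector of unique labels")
  }
  if (!setequal(names(library_sizes), conditions)) {
    config_error("library_sizes must be named by the conditions")
  }
  library_sizes <- library_sizes[conditions]
  if (!all(vapply(library_sizes, is_count, logical(1)))) {
    config_error("library_sizes must all be positive integers")
  }
  missing_shift <- setdiff(conditions, names(expression_shift))
  if (length(missing_shift) > 0 && length(expression_shift) > 0 &&
      !is.null(names(expression_shift))) {
    # partially-specified list: missing samples default to all-1 weights
    for (s in missing_shift) expression_shift[[s]] <- c()
  } else if (is.null(names(expression_shift))) {
    config_error("expression_shift must be a named list (per condition)")
  }
  shift <- lapply(conditions, function(s) {
    w <- setNames(rep(1, length(all_classes)), all_classes)
    given <- expression_shift[[s]]
    if (length(given) > 0) {
      bad <- setdiff(names(given), all_classes)
      if (length(bad) > 0) {
        config_error("expression_shift[['", s, "']] has unknown class(es): ",
                     paste(bad, collapse = ", "))
      }
      if (any(given <= 0)) {
        config_error("expression_shift[['", s, "']] must be > 0")
      }
      w[names(given)] <- given
    }
    w
  })
  names(shift) <- conditions
  if (!is_count(n_busco)) {
    config_error("n_busco must be a positive integer")
  }
  if (!setequal(names(busco_status_mix), busco_statuses)) {
    config_error("busco_status_mix must be named by ",
                 paste(busco_statuses, collapse = ", "))
  }
  busco_status_mix <- busco_status_mix[busco_statuses]
  if (any(busco_status_mix < 0) ||
      abs(sum(busco_status_mix) - 1) > 1e-9) {
    config_error("busco_status_mix must be non-negative and sum to 1 ",
                 "(within 1e-9); got sum = ", sum(busco_status_mix))
  }
  if (!is_count(n_dup_copies) || n_dup_copies < 2) {
    config_error("n_dup_copies must be an integer >= 2")
  }
  for (nm in c("overlap_rate", "nonte_hit_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      config_error(nm, " must be a single value in [0, 1]")
    }
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    config_error("seed must be a single integer")
  }
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    class_fractions = class_fractions,
    conditions = as.character(conditions),
    library_sizes = library_sizes,
    expression_shift = shift,
    n_busco = as.integer(n_busco),
    busco_status_mix = busco_status_mix,
    n_dup_copies = as.integer(n_dup_copies),
    overlap_rate = overlap_rate,
    nonte_hit_rate = nonte_hit_rate,
    force_score_ties = isTRUE(force_score_ties),
    panel_overlaps_busco = isTRUE(panel_overlaps_busco),
    seed = as.integer(seed)
  ), class = "synth_config")
}

# repeat families the generator draws from, per TE class
.te_families <- list(
  SINE = c("SINE/tRNA-V", "SINE/5S-Deu-L2", "SINE/tRNA"),
  Retro = c("Retroposon", "Retroposon/R4"),
  LTR = c("LTR/Gypsy", "LTR/Copia", "LTR/ERV1", "LTR/DIRS"),
  LINE = c("LINE/L2", "LINE/L1", "LINE/Rex-Babar", "LINE/RTE-BovB"),
  DNA = c("DNA/TcMar-Tc1", "DNA/hAT-Charlie", "DNA/PiggyBac", "RC/Helitron"),
  Unclear = c("Unknown", "Unspecified"),
  NonTE = c("Simple_repeat", "Low_complexity", "Satellite")
)

#' Generate BUSCO table rows with a given status mix
#'
#' Status counts are allocated by largest-remainder rounding of the mix
#' (so a 50% Duplicated mix over 10 orthologs yields exactly 5 Duplicated
#' rows) and then assigned to busco ids in seeded random order.
#' `Complete` and `Fragmented` orthologs reference one transcript,
#' `Duplicated` ones reference `n_dup_copies` distinct transcripts and
#' `Missing` ones reference none.
#'
#' @param n_busco Number of orthologs.
#' @param status_mix Named fractions over
#'   Complete/Duplicated/Fragmented/Missing, summing to 1.
#' @param transcript_pool Candidate transcript ids (referenced transcripts
#'   are drawn without replacement).
#' @param n_dup_copies Copies per Duplicated ortholog.
#' @return Data frame of `full_table` rows: `busco_id`, `status`,
#'   `sequence`, `score`, `length`.
#' @export
generate_busco_copies <- function(n_busco, status_mix, transcript_pool,
                                  n_dup_copies = 2) {
  if (!setequal(names(status_mix), busco_statuses) ||
      any(status_mix < 0) || abs(sum(status_mix) - 1) > 1e-9) {
    config_error("status_mix must cover ",
                 paste(busco_statuses, collapse = "/"),
                 " with non-negative fractions summing to 1")
  }
  status_mix <- status_mix[busco_statuses]
  n_by_status <- setNames(apportion(n_busco, status_mix), busco_statuses)
  needed <- n_by_status[["Complete"]] + n_by_status[["Fragmented"]] +
    n_by_status[["Duplicated"]] * n_dup_copies
  if (length(transcript_pool) < needed) {
    config_error("transcript pool too small for BUSCO placement: need ",
                 needed, ", have ", length(transcript_pool))
  }
  ids <- sprintf("%06dat7898", seq_len(n_busco))
  status <- sample(rep(busco_statuses, times = n_by_status))
  pool <- sample(transcript_pool)
  rows <- vector("list", n_busco)
  used <- 0L
  for (i in seq_len(n_busco)) {
    st <- status[i]
    k <- switch(st, Complete = 1L, Fragmented = 1L,
                Duplicated = n_dup_copies, Missing = 0L)
    if (k == 0L) {
      rows[[i]] <- data.frame(busco_id = ids[i], status = st,
                              sequence = NA_character_, score = NA_real_,
                              length = NA_real_, stringsAsFactors = FALSE)
    } else {
      seqs <- pool[used + seq_len(k)]
      used <- used + k
      rows[[i]] <- data.frame(
        busco_id = ids[i], status = st, sequence = seqs,
        score = round(runif(k, 200, 1500), 1),
        length = round(runif(k, 150, 600)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

random_dna <- function(lens) {
  vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a full synthetic input bundle with ground truth
#'
#' Emits every file the pipeline consumes — transcriptome FASTA,
#' RepeatMasker `.out`, per-sample count TSVs plus a totals file, BUSCO
#' `full_table.tsv` and a gene-panel TSV — together with a JSON
#' ground-truth manifest.
#'
#' Each transcript carries a true class label (a TE class or non-TE),
#' allocated by largest-remainder rounding of `class_fractions`. Reads
#' for sample *s* are drawn once per sample as
#' `Multinomial(library_size[s], w)` with transcript weight
#' `w_t = expression_shift[s][class(t)]`, so the expected read fraction
#' of each class is available in closed form and recorded in the
#' manifest alongside the realized per-class counts. TE transcripts get
#' one RepeatMasker hit of their true class; a fraction `overlap_rate`
#' get additional competing hits that always lose the (score, length)
#' contest, so true classes are recoverable. All randomness flows from
#' `config$seed`: the same configuration yields byte-identical files.
#'
#' @param config A [synth_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `manifest` (the ground-truth list, also written as JSON).
#' @export
generate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  all_classes <- c(te_classes(), "NonTE")
  n <- config$n_transcripts

  # --- transcripts and true class labels -------------------------------
  ids <- sprintf("TRINITY_DN%04d_c0_g1_i1", seq_len(n))
  n_by_class <- apportion(n, config$class_fractions)
  labels <- sample(rep(all_classes, times = n_by_class))
  lens <- sample(200:500, n, replace = TRUE)

  fasta_path <- file.path(outdir, "transcriptome.fasta")
  seqs <- Biostrings::DNAStringSet(setNames(random_dna(lens), ids))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60L)

  # --- RepeatMasker hits ------------------------------------------------
  is_te <- labels != "NonTE"
  te_idx <- which(is_te)
  hit_list <- list()
  hid <- 0L
  mk_hit <- function(qid, qlen, fam_class, score, max_len, overlap) {
    hid <<- hid + 1L
    fam <- sample(.te_families[[fam_class]], 1)
    hlen <- sample(50:max(51, min(max_len, qlen - 1)), 1)
    qb <- sample(seq_len(qlen - hlen), 1)
    data.frame(
      sw_score = as.integer(score),
      pct_div = round(runif(1, 0.5, 35), 1),
      pct_del = round(runif(1, 0, 8), 1),
      pct_ins = round(runif(1, 0, 8), 1),
      query_id = qid,
      q_begin = as.integer(qb),
      q_end = as.integer(qb + hlen - 1L),
      q_left = sprintf("(%d)", qlen - (qb + hlen - 1L)),
      strand = sample(c("+", "-"), 1),
      repeat_name = paste0(sub(".*/", "", sub("/.*", "", fam)), "-",
                           sample(1:30, 1), "_Tc"),
      class_family = fam,
      r_begin = "1",
      r_end = as.character(hlen),
      r_left = "(0)",
      hit_id = hid,
      overlap_flag = overlap,
      stringsAsFactors = FALSE
    )
  }
  n_overlap <- floor(config$overlap_rate * length(te_idx))
  overlap_set <- if (n_overlap > 0) sample(te_idx, n_overlap) else integer(0)
  for (i in te_idx) {
    score <- sample(300:3000, 1)
    win <- mk_hit(ids[i], lens[i], labels[i], score, lens[i] - 1, FALSE)
    hit_list[[length(hit_list) + 1L]] <- win
    if (i %in% overlap_set) {
      n_comp <- sample(1:2, 1)
      for (k in seq_len(n_comp)) {
        comp_class <- sample(te_classes(), 1)
        if (config$force_score_ties) {
          # same score, strictly shorter match: length must break the tie
          win_len <- win$q_end - win$q_begin + 1L
          if (win_len > 51) {
            hit_list[[length(hit_list) + 1L]] <-
              mk_hit(ids[i], lens[i], comp_class, score, win_len - 1, TRUE)
          }
        } else {
          hit_list[[length(hit_list) + 1L]] <-
            mk_hit(ids[i], lens[i], comp_class,
                   score - sample(10:100, 1), lens[i] - 1, TRUE)
        }
      }
    }
  }
  # non-TE repeat hits on a fraction of non-TE transcripts
  nonte_idx <- which(!is_te)
  n_nonte_hits <- floor(config$nonte_hit_rate * length(nonte_idx))
  if (n_nonte_hits > 0) {
    for (i in sample(nonte_idx, n_nonte_hits)) {
      hit_list[[length(hit_list) + 1L]] <-
        mk_hit(ids[i], lens[i], "NonTE", sample(20:200, 1), lens[i] - 1,
               FALSE)
    }
  }
  hits <- do.call(rbind, hit_list)
  rmout_path <- file.path(outdir, "repeats.out")
  write_rmout(hits, rmout_path)

  # --- per-sample read counts ------------------------------------------
  weights <- lapply(config$conditions, function(s) {
    unname(config$expression_shift[[s]][labels])
  })
  names(weights) <- config$conditions
  count_paths <- character(0)
  realized <- list()
  counts_by_sample <- list()
  for (s in config$conditions) {
    L <- config$library_sizes[[s]]
    cnt <- as.numeric(rmultinom(1, L, weights[[s]] / sum(weights[[s]])))
    counts_by_sample[[s]] <- setNames(cnt, ids)
    p <- file.path(outdir, paste0("counts_", s, ".tsv"))
    write_count_table(count_table(s, setNames(cnt, ids), L), p)
    count_paths[s] <- p
    cls_counts <- vapply(te_classes(), function(cl) {
      sum(cnt[labels == cl])
    }, numeric(1))
    realized[[s]] <- list(
      class_counts = as.list(cls_counts),
      total_te_count = sum(cls_counts),
      class_pct = as.list(100 * cls_counts / L),
      total_te_pct = 100 * sum(cls_counts) / L
    )
  }
  totals_path <- file.path(outdir, "totals.tsv")
  write_tsv(data.frame(sample = config$conditions,
                       total_mapped = unname(unlist(
                         config$library_sizes[config$conditions]))),
            totals_path)

  # --- BUSCO table and gene panel --------------------------------------
  panel_genes <- bundled_gene_panel()
  pool <- ids[!is_te]
  panel_pool_n <- nrow(panel_genes)
  if (!config$panel_overlaps_busco) {
    if (length(pool) < panel_pool_n) {
      config_error("not enough non-TE transcripts for the gene panel")
    }
    panel_tx <- sample(pool, panel_pool_n)
    busco_pool <- setdiff(pool, panel_tx)
  } else {
    panel_tx <- sample(pool, panel_pool_n)
    busco_pool <- pool
  }
  busco_rows <- generate_busco_copies(config$n_busco,
                                      config$busco_status_mix,
                                      busco_pool, config$n_dup_copies)
  busco_path <- file.path(outdir, "full_table.tsv")
  write_busco_table(busco_rows, busco_path)

  panel <- data.frame(gene = panel_genes$gene,
                      transcript_id = panel_tx,
                      category = panel_genes$category,
                      stringsAsFactors = FALSE)
  panel_path <- file.path(outdir, "gene_panel.tsv")
  write_tsv(panel, panel_path)

  # --- ground-truth manifest -------------------------------------------
  busco_tx <- busco_rows$sequence[!is.na(busco_rows$sequence)]
  expected <- list()
  exp_cum <- numeric(0)
  for (s in config$conditions) {
    w <- weights[[s]]
    tot_w <- sum(w)
    cls_pct <- vapply(te_classes(), function(cl) {
      100 * sum(w[labels == cl]) / tot_w
    }, numeric(1))
    expected[[s]] <- list(class_pct = as.list(cls_pct),
                          total_te_pct = sum(cls_pct))
    w_named <- setNames(w, ids)
    exp_cum[s] <- config$library_sizes[[s]] * sum(w_named[busco_tx]) / tot_w
  }
  ref <- sort(config$conditions, method = "radix")[1]
  realized_cum <- vapply(config$conditions, function(s) {
    sum(counts_by_sample[[s]][busco_tx])
  }, numeric(1))
  manifest <- list(
    seed = config$seed,
    conditions = config$conditions,
    library_sizes = as.list(config$library_sizes),
    expected = expected,
    realized = realized,
    calibration = list(
      reference = ref,
      expected_cumulative = as.list(exp_cum),
      expected_factor = as.list(exp_cum[[ref]] / exp_cum),
      realized_cumulative = as.list(realized_cum),
      realized_factor = as.list(realized_cum[[ref]] / realized_cum)
    ),
    transcript_classes = as.list(setNames(labels, ids)),
    busco = lapply(split(busco_rows, busco_rows$busco_id), function(g) {
      list(status = g$status[1],
           transcripts = as.list(g$sequence[!is.na(g$sequence)]))
    }),
    gene_panel = as.list(setNames(panel$transcript_id, panel$gene))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    paths = list(fasta = fasta_path, rmout = rmout_path,
                 counts = count_paths, totals = totals_path,
                 busco = busco_path, gene_panel = panel_path,
                 manifest = manifest_path),
    manifest = manifest
  ))
}

#' Read a ground-truth manifest written by [generate_dataset()]
#'
#' @param path Path to `manifest.json`.
#' @return The manifest as a list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
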
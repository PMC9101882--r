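# Seeded synthetic input generator: determinism, config validation,
# closed-form expectations, format validity.

test_that("synth_config validates its fields and names the offender", {
  expect_s3_class(tiny_config(), "synth_config")
  expect_error(tiny_config(n_busco = 0), "n_busco",
               class = "tecontrib_config_error")
  expect_error(tiny_config(overlap_rate = 1.5), "overlap_rate",
               class = "tecontrib_config_error")
  expect_error(
    synth_config(class_fractions = c(SINE = 0.5, Retro = 0.1, LTR = 0.1,
                                     LINE = 0.1, DNA = 0.1, Unclear = 0.1,
                                     NonTE = 0.5)),
    "class_fractions", class = "tecontrib_config_error")
  expect_error(
    tiny_config(busco_status_mix = c(Complete = 0.9, Duplicated = 0.2,
                                     Fragmented = 0, Missing = 0)),
    "busco_status_mix", class = "tecontrib_config_error")
  expect_error(
    synth_config(conditions = c("A", "B"),
                 library_sizes = c(A = 1000, B = 0)),
    "library_sizes", class = "tecontrib_config_error")
})

test_that("the same seed yields byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(tiny_config(seed = 5), d1)
  generate_dataset(tiny_config(seed = 5), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 7)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # a different seed changes at least the counts
  d3 <- withr::local_tempdir()
  generate_dataset(tiny_config(seed = 6), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "counts_FW.tsv"))),
    unname(tools::md5sum(file.path(d3, "counts_FW.tsv")))))
})

test_that("overlap_rate = 0 gives at most one hit per transcript", {
  d <- withr::local_tempdir()
  out <- generate_dataset(tiny_config(overlap_rate = 0, nonte_hit_rate = 0),
                          d)
  hits <- parse_rmout(out$paths$rmout)
  expect_equal(anyDuplicated(hits$query_id), 0L)
  expect_false(any(hits$overlap_flag))
})

test_that("emitted files re-parse without loss (format round-trips)", {
  d <- withr::local_tempdir()
  out <- generate_dataset(tiny_config(), d)

  hits <- parse_rmout(out$paths$rmout)
  tmp <- withr::local_tempfile()
  write_rmout(hits, tmp)
  expect_equal(parse_rmout(tmp), hits)

  rec <- parse_busco_table(out$paths$busco)
  tmp2 <- withr::local_tempfile()
  write_busco_table(rec, tmp2)
  expect_equal(parse_busco_table(tmp2), rec)

  fa <- Biostrings::readDNAStringSet(out$paths$fasta)
  expect_equal(length(fa), 200)

  cts <- read_count_tables(out$paths$counts, out$paths$totals)
  expect_equal(unname(vapply(cts, function(ct) sum(ct$counts), 1)),
               c(20000, 24000, 16000))
})

test_that("a single-class config makes that class the whole TE total", {
  cfg <- synth_config(
    n_transcripts = 100,
    class_fractions = c(SINE = 0.5, Retro = 0, LTR = 0, LINE = 0,
                        DNA = 0, Unclear = 0, NonTE = 0.5),
    conditions = "S1", library_sizes = c(S1 = 10000),
    expression_shift = list(S1 = c()),  # uniform weights
    n_busco = 5, seed = 3
  )
  d <- withr::local_tempdir()
  out <- generate_dataset(cfg, d)
  exp <- out$manifest$expected$S1
  expect_equal(exp$class_pct$SINE, exp$total_te_pct)
  expect_equal(exp$total_te_pct, 50)  # closed form: 50 of 100 uniform weights
  expect_equal(exp$class_pct$LINE, 0)
})

test_that("manifest class percents sum to the total per sample", {
  d <- withr::local_tempdir()
  out <- generate_dataset(tiny_config(seed = 9), d)
  for (s in out$manifest$conditions) {
    for (kind in c("expected", "realized")) {
      m <- out$manifest[[kind]][[s]]
      expect_equal(sum(unlist(m$class_pct)), m$total_te_pct,
                   tolerance = 1e-9)
    }
  }
})

test_that("busco status allocation is exact and copies reference >= 2 transcripts", {
  set.seed(77)
  pool <- sprintf("tx%03d", 1:100)
  rows <- generate_busco_copies(
    10, c(Complete = 0.5, Duplicated = 0.5, Fragmented = 0, Missing = 0),
    pool, n_dup_copies = 2)
  # 5 Complete x1 + 5 Duplicated x2 = 15 transcript references
  expect_equal(sum(!is.na(rows$sequence)), 15)
  dup <- rows[rows$status == "Duplicated", ]
  per_id <- table(dup$busco_id)
  expect_true(all(per_id == 2))
  expect_equal(anyDuplicated(stats::na.omit(rows$sequence)), 0L)

  all_complete <- generate_busco_copies(
    8, c(Complete = 1, Duplicated = 0, Fragmented = 0, Missing = 0), pool)
  expect_equal(nrow(all_complete), 8)
  expect_true(all(table(all_complete$busco_id) == 1))

  all_missing <- generate_busco_copies(
    8, c(Complete = 0, Duplicated = 0, Fragmented = 0, Missing = 1), pool)
  expect_true(all(is.na(all_missing$sequence)))
  ct <- count_table("S", setNames(rep(5, 100), pool), 1000)
  expect_equal(sum(build_calibration_set(all_missing, ct)), 0)
})

test_that("empirical class fractions converge to manifest expectations", {
  cfg <- synth_config(n_transcripts = 300,
                      conditions = "S1",
                      library_sizes = c(S1 = 1e6),
                      expression_shift = list(S1 = c(SINE = 2, DNA = 0.5)),
                      n_busco = 10, seed = 21)
  d <- withr::local_tempdir()
  out <- generate_dataset(cfg, d)
  exp_pct <- unlist(out$manifest$expected$S1$class_pct)
  real_pct <- unlist(out$manifest$realized$S1$class_pct)
  p <- exp_pct / 100
  se_pct <- 100 * sqrt(p * (1 - p) / 1e6)
  expect_true(all(abs(real_pct - exp_pct) <= 3 * se_pct))
})

test_that("force_score_ties produces score ties resolved by length", {
  d <- withr::local_tempdir()
  out <- generate_dataset(tiny_config(overlap_rate = 1,
                                      force_score_ties = TRUE), d)
  hits <- parse_rmout(out$paths$rmout)
  te <- hits[classify_repeat(hits$class_family) != "NonTE", ]
  dup_q <- unique(te$query_id[duplicated(te$query_id)])
  expect_gt(length(dup_q), 0)
  ties <- vapply(dup_q, function(q) {
    s <- te$sw_score[te$query_id == q]
    any(duplicated(s))
  }, logical(1))
  expect_true(any(ties))
  # winners still carry the true class from the manifest
  asg <- resolve_redundancy(hits)
  truth <- unlist(out$manifest$transcript_classes)
  expect_equal(unname(truth[asg$query_id]), asg$te_class)
})

test_that("gene-panel transcripts are disjoint from BUSCO transcripts by default", {
  d <- withr::local_tempdir()
  out <- generate_dataset(tiny_config(seed = 15), d)
  busco_tx <- unlist(lapply(out$manifest$busco, function(b) b$transcripts))
  panel_tx <- unlist(out$manifest$gene_panel)
  expect_length(intersect(busco_tx, panel_tx), 0)
  # panel and BUSCO transcripts are never TE transcripts
  truth <- unlist(out$manifest$transcript_classes)
  expect_true(all(truth[c(busco_tx, panel_tx)] == "NonTE"))
})
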
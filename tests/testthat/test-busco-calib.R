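# BUSCO full_table parsing, calibration-set construction, scaling
# factors, gene-panel calibration.

busco_fixture <- c(
  "# BUSCO version is: 5.2.2",
  "# Busco id\tStatus\tSequence\tScore\tLength",
  "0001at7898\tComplete\ttxA\t850.2\t410",
  "0002at7898\tDuplicated\ttxB\t500.0\t300",
  "0002at7898\tDuplicated\ttxC\t480.0\t290",
  "0002at7898\tDuplicated\ttxD\t470.0\t280",
  "0003at7898\tFragmented\ttxE\t120.5\t90",
  "0004at7898\tMissing"
)

write_busco_fixture <- function(lines = busco_fixture) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("parse_busco_table reads records and validates statuses", {
  rec <- parse_busco_table(write_busco_fixture())
  expect_equal(nrow(rec), 6)  # rows minus comment lines
  expect_equal(sum(is.na(rec$sequence)), 1)
  expect_equal(rec$status[rec$busco_id == "0004at7898"], "Missing")
  # one Duplicated busco on 3 rows -> one id with 3 transcripts
  dup <- rec[rec$busco_id == "0002at7898", ]
  expect_equal(nrow(dup), 3)
  expect_setequal(dup$sequence, c("txB", "txC", "txD"))

  bad <- write_busco_fixture(c(busco_fixture, "0005at7898\tPartial\ttxF"))
  expect_error(parse_busco_table(bad), "line 9",
               class = "tecontrib_parse_error")
})

test_that("BUSCO table round-trips through write_busco_table", {
  rec <- parse_busco_table(write_busco_fixture())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_busco_table(rec, path)
  expect_equal(parse_busco_table(path), rec)
})

test_that("calibration set follows the status rules", {
  rec <- parse_busco_table(write_busco_fixture())
  ct <- count_table("S1",
                    c(txA = 50, txB = 30, txC = 20, txD = 0, txE = 7),
                    10000)
  cal <- build_calibration_set(rec, ct)
  expect_equal(length(cal), 4)  # one entry per busco id
  expect_equal(cal[["0001at7898"]], 50)   # Complete: mapped reads as-is
  expect_equal(cal[["0002at7898"]], 50)   # Duplicated: 30 + 20 + 0
  expect_equal(cal[["0003at7898"]], 7)    # Fragmented: mapped reads as-is
  expect_equal(cal[["0004at7898"]], 0)    # Missing: set to 0
})

test_that("duplicated copies 30 + 20 sum to 50 and missing transcripts warn", {
  rec <- data.frame(
    busco_id = c("b1", "b1", "b2"),
    status = c("Duplicated", "Duplicated", "Complete"),
    sequence = c("tx1", "tx2", "tx_gone"),
    score = NA_real_, length = NA_real_, stringsAsFactors = FALSE
  )
  ct <- count_table("S", c(tx1 = 30, tx2 = 20), 1000)
  expect_warning(cal <- build_calibration_set(rec, ct), "absent")
  expect_equal(cal[["b1"]], 50)
  expect_equal(cal[["b2"]], 0)
})

test_that("an all-Missing table yields zero cumulative expression", {
  rec <- data.frame(busco_id = c("b1", "b2"),
                    status = "Missing", sequence = NA_character_,
                    score = NA_real_, length = NA_real_,
                    stringsAsFactors = FALSE)
  ct <- count_table("S", c(tx1 = 5), 100)
  cal <- build_calibration_set(rec, ct)
  expect_equal(sum(cal), 0)
  expect_error(compute_scaling_factors(list(S = cal)), "S",
               class = "tecontrib_input_error")
})

test_that("scaling factors are cumulative ratios to the reference", {
  f <- compute_scaling_factors(c(A = 1000, B = 2000), reference = "A")
  expect_equal(unname(f$factor["A"]), 1)
  expect_equal(unname(f$factor["B"]), 0.5)
  expect_equal(unname(f$cumulative * f$factor),
               rep(1000, 2))  # equalized after calibration

  same <- compute_scaling_factors(c(A = 7, B = 7, C = 7))
  expect_true(all(same$factor == 1))
  expect_equal(same$reference, "A")  # first lexicographically

  single <- compute_scaling_factors(c(only = 123))
  expect_equal(unname(single$factor), 1)
})

test_that("calibrating already-calibrated cumulatives is idempotent", {
  f1 <- compute_scaling_factors(c(A = 1000, B = 4000, C = 250))
  again <- compute_scaling_factors(f1$cumulative * f1$factor)
  expect_true(all(again$factor == 1))
})

test_that("apply_calibration rescales raw counts per sample", {
  panel <- data.frame(gene = c("AGO1", "TRIM33"),
                      transcript_id = c("tx1", "tx2"),
                      stringsAsFactors = FALSE)
  cts <- list(A = count_table("A", c(tx1 = 40, tx2 = 10), 1000),
              B = count_table("B", c(tx1 = 80, tx2 = 20), 2000))
  f <- compute_scaling_factors(c(A = 500, B = 1000), reference = "A")
  out <- apply_calibration(panel, cts, f)
  expect_equal(nrow(out), 4)
  # raw 40, factor 0.5 -> 20
  expect_equal(out$calibrated[out$gene == "AGO1" & out$sample == "B"], 40)
  expect_equal(out$calibrated[out$gene == "AGO1" & out$sample == "A"], 40)
  expect_equal(out$raw[out$gene == "TRIM33" & out$sample == "B"], 20)
  expect_equal(out$calibrated[out$gene == "TRIM33" & out$sample == "B"], 10)

  # factor 1 -> calibrated equals raw
  f1 <- compute_scaling_factors(c(A = 500, B = 500), reference = "A")
  out1 <- apply_calibration(panel, cts, f1)
  expect_equal(out1$calibrated, out1$raw)

  # genes absent from a sample are 0/0, with a warning if absent everywhere
  panel2 <- rbind(panel, data.frame(gene = "GHOST",
                                    transcript_id = "tx_none"))
  expect_warning(out2 <- apply_calibration(panel2, cts, f), "GHOST|tx_none")
  expect_equal(out2$raw[out2$gene == "GHOST"], c(0, 0))
  expect_equal(out2$calibrated[out2$gene == "GHOST"], c(0, 0))

  dup_panel <- rbind(panel, panel[1, ])
  expect_error(apply_calibration(dup_panel, cts, f),
               class = "tecontrib_input_error")
})

test_that("calibrated values are bit-identical under library rescaling", {
  rec <- parse_busco_table(write_busco_fixture())
  panel <- data.frame(gene = c("g1", "g2"),
                      transcript_id = c("txP", "txQ"),
                      stringsAsFactors = FALSE)
  base <- c(txA = 53, txB = 31, txC = 17, txD = 5, txE = 7,
            txP = 211, txQ = 89)
  ref_ct <- count_table("REF", base, 1000)
  for (k in c(2, 10, 1000)) {
    cts_a <- list(REF = ref_ct, S = count_table("S", base, 1000))
    cts_b <- list(REF = ref_ct, S = count_table("S", base * k, 1000 * k))
    run <- function(cts) {
      cal <- lapply(cts, function(ct) build_calibration_set(rec, ct))
      apply_calibration(panel, cts,
                        compute_scaling_factors(cal, reference = "REF"))
    }
    expect_identical(run(cts_b)$calibrated, run(cts_a)$calibrated)
  }
})

test_that("row and sample order do not affect factors or calibrated values", {
  set.seed(31)
  rec <- parse_busco_table(write_busco_fixture())
  counts <- c(txA = 53, txB = 31, txC = 17, txD = 5, txE = 7, txP = 100)
  panel <- data.frame(gene = "g1", transcript_id = "txP",
                      stringsAsFactors = FALSE)
  cts <- list(A = count_table("A", counts, 1000),
              B = count_table("B", counts * 3, 3000))
  run <- function(records, tables) {
    cal <- lapply(tables, function(ct) build_calibration_set(records, ct))
    f <- compute_scaling_factors(cal, reference = "A")
    list(f = f, out = apply_calibration(panel, tables, f))
  }
  straight <- run(rec, cts)
  shuffled <- run(rec[sample(nrow(rec)), ], rev(cts))
  expect_equal(shuffled$f$factor[names(straight$f$factor)],
               straight$f$factor)
  m1 <- straight$out[order(straight$out$sample), ]
  m2 <- shuffled$out[order(shuffled$out$sample), ]
  expect_equal(m2$calibrated, m1$calibrated)
})

test_that("the bundled gene panel has the expected composition", {
  panel <- bundled_gene_panel()
  expect_equal(nrow(panel), 26)
  expect_equal(sum(panel$category == "argonaute"), 4)
  expect_equal(sum(panel$category == "heterochromatin"), 6)
  expect_equal(sum(panel$category == "nurd"), 14)
  expect_setequal(panel$gene[panel$category == "recruiter"],
                  c("TRIM33", "KRAB-like"))
  expect_true(all(c("AGO1", "AGO2", "AGO3", "AGO4") %in% panel$gene))
  expect_true(all(c("CHD3", "HDAC1", "MBD2", "MTA1", "RBBP4", "RBBP7")
                  %in% panel$gene))
})
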
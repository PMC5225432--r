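# SSR scanner, filters, canonical motifs and composition report.

test_that("read filters: dedup keeps first occurrence, length boundary is >=", {
  reads <- tibble::tibble(id = c("r1", "r2", "r3"),
                          sequence = c("ACGT", "ACGT", "ACGA"))
  expect_equal(deduplicate_reads(reads)$id, c("r1", "r3"))
  expect_equal(deduplicate_reads(reads[3, ])$id, "r3")
  expect_equal(nrow(deduplicate_reads(reads[0, ])), 0)

  lens <- c(100, 149, 150, 151, 300)
  reads <- tibble::tibble(id = paste0("r", seq_along(lens)),
                          sequence = vapply(lens, function(L) {
                            paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                  collapse = "")
                          }, character(1)))
  kept <- filter_reads_by_length(reads, 150)
  expect_equal(kept$id, c("r3", "r4", "r5"))  # 149 bp dropped, 150 bp kept
})

test_that("scanner honors the per-motif-length repeat thresholds", {
  h <- scan_read(paste0("TT", strrep("AC", 8), "GG"))
  expect_equal(nrow(h), 1)
  expect_equal(h$motif, "AC")
  expect_equal(h$repeat_count, 8L)
  expect_equal(c(h$start, h$end), c(2L, 18L))

  expect_equal(nrow(scan_read(paste0("TTGG", strrep("AC", 7), "TTGG"))), 0)

  h <- scan_read(paste0("G", strrep("ATT", 5), "C"))
  expect_equal(h$motif, "ATT")
  expect_equal(h$repeat_count, 5L)

  # shortest-period rule: (AT)x10 is one dinucleotide hit, never (ATAT)x5
  h <- scan_read(strrep("AT", 10))
  expect_equal(nrow(h), 1)
  expect_equal(h$motif_length, 2L)
  expect_equal(h$repeat_count, 10L)

  # homopolymers are never reported
  expect_equal(nrow(scan_read(strrep("A", 40))), 0)
  # N breaks a repeat
  expect_equal(nrow(scan_read(paste0(strrep("AC", 4), "NN", strrep("AC", 4)))), 0)
  expect_error(scan_read("ACGTX"), "ACGTN")
})

test_that("hits re-validate and are invariant to id and flanks", {
  set.seed(42)
  for (i in 1:20) {
    core <- strrep("AGC", sample(5:9, 1))
    left <- paste(sample(c("A", "C", "G", "T"), sample(0:30, 1), TRUE),
                  collapse = "")
    seq <- paste0(left, core, "TTTT")
    h <- scan_read(seq, read_id = paste0("read", i))
    for (r in seq_len(nrow(h))) {
      slice <- substr(seq, h$start[r] + 1, h$end[r])
      expect_identical(slice, strrep(h$motif[r], h$repeat_count[r]))
      expect_equal(h$end[r] - h$start[r], h$motif_length[r] * h$repeat_count[r])
    }
    agc <- h[h$canonical_motif == "AGC", ]
    expect_equal(nrow(agc), 1)
    # flanks may extend the planted run but never shrink it
    expect_gte(agc$repeat_count, nchar(core) / 3)
  }
})

test_that("canonical motif minimises over rotations and reverse complement", {
  expect_equal(canonical_motif("GA"), "AG")
  # brute-force enumeration of the 6 candidates for a trinucleotide
  bf_canon <- function(m) {
    rot <- function(x) vapply(seq_len(nchar(x)), function(i) {
      paste0(substr(x, i, nchar(x)), substr(x, 1, i - 1))
    }, character(1))
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(m, "")[[1]]), collapse = ""))
    min(c(rot(m), rot(rc)))
  }
  expect_equal(canonical_motif("TGC"), bf_canon("TGC"))
  set.seed(7)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    m <- paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = "")
    prim <- tryCatch(canonical_motif(m), error = function(e) NULL)
    if (is.null(prim)) next  # period-reducible draw
    expect_equal(prim, bf_canon(m))
    expect_equal(canonical_motif(prim), prim)  # idempotent
  }
  expect_error(canonical_motif("ATAT"), "period-reducible")
})

test_that("composition summary counts by motif length with unit frequencies", {
  hits <- dplyr::bind_rows(
    scan_read(strrep("AC", 9), read_id = "a"),
    scan_read(strrep("AC", 8), read_id = "b"),
    scan_read(strrep("TG", 8), read_id = "c"),
    scan_read(strrep("ATT", 6), read_id = "d"))
  comp <- composition_summary(hits)
  expect_equal(comp$n, c(3, 1, 0, 0, 0))
  expect_equal(comp$frequency[1:2], c(0.75, 0.25))
  expect_equal(sum(comp$frequency), 1, tolerance = 1e-12)
  empty <- composition_summary(scan_read("ACGT"))
  expect_true(all(empty$n == 0) && all(empty$frequency == 0))
})

test_that("composition recovers a planted class mix exactly", {
  set.seed(11)
  mix <- c(`2` = 20, `3` = 8, `4` = 4, `5` = 2, `6` = 1)
  units <- c(`2` = "AC", `3` = "AGG", `4` = "AAGC", `5` = "AACGT",
             `6` = "AACGTT")
  tag <- function(i) {  # unique repeat-free suffix so dedup keeps all reads
    digits <- c(i %% 4, (i %/% 4) %% 4, (i %/% 16) %% 4)
    paste(rbind(c("A", "C", "G", "T")[digits + 1], "T", "G"), collapse = "")
  }
  reads <- purrr::imap(mix, function(n, k) {
    tibble::tibble(
      id = paste0("k", k, "_", seq_len(n)),
      sequence = paste0(strrep("CGT", 3), strrep(units[[k]], 9),
                        strrep("TGA", 3),
                        vapply(seq_len(n), tag, character(1))))
  }) |> dplyr::bind_rows()
  hits <- mine_ssr(reads, mining_config(min_read_length = 1))
  comp <- composition_summary(hits)
  expect_equal(comp$n, unname(mix))
  expect_equal(comp$frequency, unname(mix) / sum(mix))
})

test_that("scanner agrees with the brute-force oracle on random reads", {
  set.seed(99)
  alphabet <- c("A", "C", "G", "T")
  for (i in 1:60) {
    # seed repeats into random background so hits actually occur
    bg <- sample(alphabet, 120, TRUE)
    unit <- paste(sample(alphabet, sample(2:6, 1), TRUE), collapse = "")
    ins <- strrep(unit, sample(4:10, 1))
    pos <- sample(110, 1)
    seq <- paste0(paste(bg[1:pos], collapse = ""), ins,
                  paste(bg[(pos + 1):120], collapse = ""))
    got <- scan_read(seq)
    want <- bf_scan(seq)
    expect_equal(nrow(got), nrow(want), info = seq)
    if (nrow(want)) {
      expect_equal(got$start, want$start, info = seq)
      expect_equal(got$end, want$end, info = seq)
      expect_equal(got$motif, want$motif, info = seq)
      expect_equal(got$repeat_count, want$repeat_count, info = seq)
    }
  }
})

test_that("mining funnel bookkeeping matches construction", {
  set.seed(3)
  mk <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  reads <- tibble::tibble(
    id = paste0("r", 1:10),
    sequence = c(mk(200), mk(200), mk(100), mk(100), mk(100), mk(100),
                 paste0(mk(140), strrep("AC", 8), mk(140)),
                 mk(160), mk(170), mk(180)))
  reads$sequence[2] <- reads$sequence[1]  # duplicate
  hits <- mine_ssr(reads, mining_config())
  funnel <- attr(hits, "funnel")
  expect_equal(unname(funnel["total"]), 10)
  expect_equal(unname(funnel["deduplicated"]), 9)
  expect_equal(unname(funnel["length_passed"]), 5)  # four 100 bp reads dropped
  expect_true(funnel["with_ssr"] >= 1)
  expect_true(all(hits$read_id %in% reads$id))
})
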
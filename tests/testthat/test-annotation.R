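test_that("per-call annotation variables follow their definitions", {
  expect_equal(normalized_coverage(500, 1000), 0.5)
  expect_equal(normalized_coverage(1000, 1000), 1)
  expect_error(normalized_coverage(10, 0), "positive")

  expect_equal(strand_ratio(500, 500), 1)
  expect_equal(strand_ratio(900, 100), 9)
  expect_warning(r <- strand_ratio(10, 0), "sentinel")
  expect_true(is.infinite(r))

  db1 <- data.frame(position = c(5L, 9L), count = c(3, 7))
  db2 <- data.frame(position = 5L, count = 1)
  expect_equal(numt_mean(5, db1, db2), 2)
  expect_equal(numt_mean(100, db1, db2), 0)
  expect_equal(numt_mean(5, db2, db1), 2)  # symmetric
  expect_equal(numt_mean(9, db1, db2), 3.5)
})

test_that("NUMT and LCR resources load from TSV/BED", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("position\tcount", "100\t4", "250\t1"), f)
  db <- read_numt_table(f)
  expect_equal(db$count[db$position == 100], 4)

  bed <- tempfile(fileext = ".bed")
  writeLines("chrM\t99\t200", bed)
  lcr <- read_lcr_bed(bed)
  expect_equal(lcr$start, 100)
  expect_equal(lcr$end, 200)
})

test_that("annotation records and per-class summaries are consistent", {
  ref <- full_ref(); panel <- full_panel(); haps <- full_haps()
  truth_vl <- data.frame(position = haps$H$variants$position,
                         ref = ref_base_at(ref, haps$H$variants$position),
                         alt = haps$H$variants$alt,
                         vl = haps$H$variants$vl,
                         expected_vl = haps$H$variants$vl)
  cnt <- simulate_counts(truth_vl, panel, ref, depth = 2000, err = 0.001,
                         seed = 77)
  numt_pos <- setdiff(seq(300, 16300, by = 800), blacklist_positions())
  numt_pos <- setdiff(numt_pos, truth_vl$position)
  cnt <- inject_numt_signal(cnt, numt_pos, level = 0.05, strand_skew = 0.9,
                            seed = 78)
  calls <- pass_calls(call_variants(cnt, threshold = 0.025))
  graded <- grade_variants(do.call(rbind, lapply(
    c("exome", "lowCov", "highCov"), function(r)
      data.frame(run = r, truth_vl[c("position", "alt", "vl")]))))
  out <- classify_test_calls(graded, calls)
  db1 <- data.frame(position = numt_pos, count = 2)
  db2 <- data.frame(position = numt_pos[1:3], count = 4)
  lcr <- data.frame(start = c(300L, 16000L), end = c(320L, 16100L))
  rec <- annotate_callset(calls, out, panel, lcr, db1, db2,
                          sample_mean_depth = mean(cnt$depth))
  expect_equal(nrow(rec), nrow(calls))
  expect_true(all(c("found", "novel") %in% rec$variant_class))

  # injected NUMT-like calls show the designed strand-bias signature
  novel <- rec[rec$variant_class == "novel" & rec$position %in% numt_pos, ]
  expect_gt(nrow(novel), 0)
  expect_equal(median(novel$strand_ratio), 9, tolerance = 0.25)
  found <- rec[rec$variant_class == "found", ]
  expect_equal(median(found$strand_ratio), 1, tolerance = 0.2)
  expect_true(all(novel$numt_mean > 0))

  # summary means recomputed by an independent brute-force pass
  s <- summarize_annotations(rec)
  for (cl in s$summary$variant_class) {
    g <- rec[rec$variant_class == cl, ]
    expect_equal(
      s$summary$normalized_coverage[s$summary$variant_class == cl],
      sum(g$normalized_coverage[is.finite(g$normalized_coverage)]) /
        sum(is.finite(g$normalized_coverage)))
    expect_equal(s$summary$lcr_prop[s$summary$variant_class == cl],
                 sum(g$lcr) / nrow(g))
  }
  # the strand-ratio contrast for novel variants is flagged upward
  eff <- s$effects
  expect_true(grepl("^up", eff$strand_ratio[eff$variant_class == "novel"]))
})

test_that("effect-direction binning reproduces the contrast encoding", {
  expect_equal(mitofold:::bin_effect(1.1, 1), "none")
  expect_equal(mitofold:::bin_effect(0.6, 1), "down-25-50")
  expect_equal(mitofold:::bin_effect(0.3, 1), "down-51-75")
  expect_equal(mitofold:::bin_effect(0.1, 1), "down-gt-75")
  expect_equal(mitofold:::bin_effect(1.4, 1), "up-25-50")
  expect_equal(mitofold:::bin_effect(9, 1), "up-gt-75")
  expect_true(is.na(mitofold:::bin_effect(1, 0)))
})

test_that("empty callsets annotate to empty records and summaries", {
  empty <- data.frame(position = integer(0), alt = character(0),
                      depth = integer(0), fwd_alt = integer(0),
                      rev_alt = integer(0))
  rec <- annotate_callset(empty, data.frame(position = integer(0),
                                            alt = character(0),
                                            outcome = character(0)),
                          full_panel(), data.frame(start = 1L, end = 2L),
                          data.frame(position = 1L, count = 1),
                          data.frame(position = 1L, count = 1), 100)
  expect_equal(nrow(rec), 0)
  s <- summarize_annotations(rec)
  expect_null(s$effects)
})
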
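test_that("the default design enumerates 15 named mixtures", {
  d <- default_design()
  expect_equal(nrow(d), 15)
  expect_equal(d$name[d$minor == "U" & d$fraction == 0.01], "U0.01H")
  expect_setequal(unique(paste(d$minor, d$major)), c("H T", "T U", "U H"))
  for (pair in split(d, paste(d$minor, d$major)))
    expect_false(is.unsorted(pair$fraction))
  expect_equal(sort(unique(d$fraction)), c(0.01, 0.02, 0.05, 0.10, 0.25))
})

test_that("expected mixture VLs follow linear allele accounting", {
  ref <- toy_ref()
  h_min <- haplotype("m", data.frame(position = c(2L, 5L), alt = c("G", "T"),
                                     vl = c(1, 1)))
  h_maj <- haplotype("M", data.frame(position = c(5L, 7L), alt = c("T", "A"),
                                     vl = c(1, 1)))
  tr <- mix_truth(h_min, h_maj, 0.05, ref)
  expect_equal(tr$expected_vl[tr$position == 2], 0.05)   # minor-only hom
  expect_equal(tr$expected_vl[tr$position == 5], 1.0)    # shared hom
  expect_equal(tr$expected_vl[tr$position == 7], 0.95)   # major-only hom
  expect_identical(tr$ref, c("C", "A", "G"))

  # brute-force genome-copy accounting agrees for arbitrary VLs
  for (vals in list(c(1, 0, 0.05), c(0.4, 0.7, 0.25), c(0.1, 0, 0.01))) {
    expect_equal(vals[1] * vals[3] + vals[2] * (1 - vals[3]),
                 brute_expected_vl(vals[1], vals[2], vals[3]))
  }
  expect_true(all(tr$expected_vl >= 0 & tr$expected_vl <= 1))
})

test_that("conflicting alternate bases are excluded as multi-allelic", {
  ref <- toy_ref()
  h1 <- haplotype("a", data.frame(position = 3L, alt = "A", vl = 1))
  h2 <- haplotype("b", data.frame(position = 3L, alt = "T", vl = 1))
  expect_warning(tr <- mix_truth(h1, h2, 0.1, ref), "multi-allelic")
  expect_equal(nrow(tr), 0)
})

test_that("synthetic haplotypes avoid the blacklist and share common sites", {
  haps <- full_haps()
  expect_named(haps, c("H", "T", "U"))
  shared <- Reduce(intersect, lapply(haps, function(h) h$variants$position))
  expect_gte(length(shared), 10)
  for (h in haps) {
    expect_false(any(is_blacklisted(h$variants$position)))
    expect_true(all(h$variants$alt != ref_base_at(full_ref(),
                                                  h$variants$position)))
    expect_equal(sum(h$variants$vl == 1), 30 + 10)  # private + shared hom
  }
})

test_that("simulated counts are seed-deterministic with coherent depths", {
  ref <- full_ref(); panel <- full_panel()
  tr <- data.frame(position = 1000L, ref = ref_base_at(ref, 1000),
                   alt = "A", expected_vl = 0.05)
  if (tr$ref == "A") tr$alt <- "C"
  c1 <- simulate_counts(tr, panel, ref, depth = 500, seed = 9)
  c2 <- simulate_counts(tr, panel, ref, depth = 500, seed = 9)
  expect_identical(c1, c2)
  base_cols <- paste0(rep(c("fwd_", "rev_"), each = 4), c("A", "C", "G", "T"))
  expect_equal(rowSums(c1[base_cols]), as.numeric(c1$depth))
})

test_that("error-free simulation of an empty truth is reference-only", {
  ref <- random_reference(1000, seed = 2)
  panel <- build_synthetic_panel(1000, 9, seed = 2)
  cnt <- simulate_counts(NULL, panel, ref, depth = 200, err = 0, seed = 3)
  refb <- strsplit(ref$sequence, "")[[1]]
  for (b in c("A", "C", "G", "T")) {
    tot <- cnt[[paste0("fwd_", b)]] + cnt[[paste0("rev_", b)]]
    expect_true(all(tot[refb != b] == 0))
    expect_true(all(tot[refb == b] == cnt$depth[refb == b]))
  }
})

test_that("simulated alternate fractions concentrate around the truth", {
  ref <- full_ref(); panel <- full_panel()
  pos <- seq(500, 16000, by = 500)
  refb <- ref_base_at(ref, pos)
  tr <- data.frame(position = pos, ref = refb,
                   alt = unname(c(A = "G", G = "A", C = "T", T = "C")[refb]),
                   expected_vl = 0.05)
  cnt <- simulate_counts(tr, panel, ref, depth = 5000, err = 0, seed = 21)
  i <- match(pos, cnt$position)
  n_alt <- mapply(function(row, b)
    cnt[[paste0("fwd_", b)]][row] + cnt[[paste0("rev_", b)]][row], i, tr$alt)
  frac <- n_alt / cnt$depth[i]
  se <- sqrt(0.05 * 0.95 / cnt$depth[i])
  expect_true(mean(abs(frac - 0.05) <= 3 * se) >= 0.95)
})

test_that("NUMT injection raises the alternate fraction with strand skew", {
  ref <- full_ref(); panel <- full_panel()
  cnt <- simulate_counts(NULL, panel, ref, depth = 5000, err = 0, seed = 4)
  pos <- seq(100, 16000, by = 400)
  out <- inject_numt_signal(cnt, pos, level = 0.05, strand_skew = 0.9,
                            seed = 5)
  refb <- ref_base_at(ref, pos)
  altb <- unname(c(A = "G", G = "A", C = "T", T = "C")[refb])
  i <- match(pos, out$position)
  fwd <- mapply(function(r, b) out[[paste0("fwd_", b)]][r], i, altb)
  rev <- mapply(function(r, b) out[[paste0("rev_", b)]][r], i, altb)
  frac <- (fwd + rev) / out$depth[i]
  expect_equal(mean(frac), 0.05, tolerance = 0.05)
  expect_equal(sum(fwd) / sum(rev), 9, tolerance = 0.15)

  # level 0 is the identity
  expect_identical(inject_numt_signal(cnt, pos, level = 0), cnt)

  # a 3% injection is callable at a 2.5% threshold (false positive by design)
  out3 <- inject_numt_signal(cnt, 1234, level = 0.03, seed = 6)
  calls <- call_variants(out3, threshold = 0.025)
  expect_true(1234 %in% pass_calls(calls)$position)
})

test_that("counts round-trip through TSV", {
  ref <- random_reference(500, seed = 8)
  panel <- build_synthetic_panel(500, 5, seed = 8)
  cnt <- simulate_counts(NULL, panel, ref, depth = 100, seed = 8)
  f <- tempfile(fileext = ".tsv")
  write_counts_tsv(cnt, f)
  back <- read_counts_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(cnt))
})
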
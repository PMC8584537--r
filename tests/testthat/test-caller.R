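test_that("site calling applies the threshold to allele fractions", {
  site <- simple_site(1000L, "A", "G", 950L, 50L)
  cs <- call_site(site, threshold = 0.025)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$alt, "G")
  expect_equal(cs$vl, 0.05)
  expect_equal(cs$filter, "PASS")

  expect_equal(nrow(call_site(site, threshold = 0.10)), 0)
})

test_that("blacklisted positions never yield PASS calls", {
  for (p in c(310L, 302L, 523L, 3110L)) {
    cs <- call_site(simple_site(p, "A", "G", 100L, 900L), threshold = 0.025)
    expect_true(all(cs$filter == "blacklist"))
  }
  # property: random counts at blacklisted positions, any threshold
  set.seed(13)
  for (i in 1:20) {
    p <- sample(blacklist_positions(), 1)
    cs <- call_site(simple_site(p, "C", "T", sample(1000, 1), sample(1000, 1)),
                    threshold = runif(1, 0.005, 0.2))
    expect_false(any(cs$filter == "PASS"))
  }
})

test_that("the strand rule flags single-strand support", {
  expect_true(strand_rule(25, 25))
  expect_false(strand_rule(50, 0))
  expect_true(strand_rule(50, 0, min_per_strand = 0))

  site <- site_row(50L, "A",
                   fwd = list(A = 450L, C = 0L, G = 50L, T = 0L),
                   rev = list(A = 500L, C = 0L, G = 0L, T = 0L))
  cs <- call_site(site, threshold = 0.025)
  expect_equal(cs$filter, "strand")
})

test_that("zero-depth and reference-N sites are uncallable", {
  z <- list(A = 0L, C = 0L, G = 0L, T = 0L)
  expect_equal(nrow(call_site(site_row(5L, "A", z, z))), 0)
  expect_equal(nrow(call_site(simple_site(5L, "N", "G", 10L, 90L))), 0)
})

test_that("at most the two most frequent alternates are reported", {
  site <- site_row(100L, "A",
                   fwd = list(A = 350L, C = 50L, G = 60L, T = 40L),
                   rev = list(A = 350L, C = 50L, G = 60L, T = 40L))
  cs <- call_site(site, threshold = 0.025)
  expect_equal(sort(cs$alt), c("C", "G"))  # T (lowest fraction) dropped

  # ties break alphabetically
  tie <- site_row(100L, "A",
                  fwd = list(A = 350L, C = 50L, G = 50L, T = 50L),
                  rev = list(A = 350L, C = 50L, G = 50L, T = 50L))
  ct <- call_site(tie, threshold = 0.025)
  expect_equal(sort(ct$alt), c("C", "G"))
})

test_that("the default grid has 21 thresholds spanning 0.4% to 10%", {
  g <- default_threshold_grid()
  expect_equal(length(g), 21)
  expect_equal(min(g), 0.004)
  expect_equal(max(g), 0.100)
  expect_false(is.unsorted(g, strictly = TRUE))
})

test_that("threshold sweeps produce nested callsets", {
  ref <- full_ref(); panel <- full_panel(); haps <- full_haps()
  tr <- mix_truth(haps$U, haps$H, 0.05, ref)
  cnt <- simulate_counts(tr, panel, ref, depth = 2000, err = 0.001,
                         seed = 31)
  sw <- sweep_thresholds(cnt)
  expect_equal(length(sw), 21)
  keys <- lapply(sw, function(cs) paste(cs$position, cs$alt))
  for (i in 2:length(keys))
    expect_true(all(keys[[i]] %in% keys[[i - 1]]))

  expect_error(sweep_thresholds(cnt, c(0.05, 0.01)), "sorted")
  expect_error(sweep_thresholds(cnt, c(0.01, 0.01)), "sorted")
  expect_error(sweep_thresholds(cnt, c(0, 0.5)), "\\(0, 1\\)")
})

test_that("a 2.5% sweep recovers minor-specific homoplasmies near 5%", {
  ref <- full_ref(); panel <- full_panel(); haps <- full_haps()
  tr <- mix_truth(haps$U, haps$H, 0.05, ref)
  cnt <- simulate_counts(tr, panel, ref, depth = 5000, err = 0.001,
                         seed = 17)
  cs <- pass_calls(sweep_thresholds(cnt, 0.025)[[1]])
  minor_hom <- tr[abs(tr$expected_vl - 0.05) < 1e-9, ]
  key <- paste(cs$position, cs$alt)
  expect_true(all(paste(minor_hom$position, minor_hom$alt) %in% key))
  got <- cs$vl[match(paste(minor_hom$position, minor_hom$alt), key)]
  se <- sqrt(0.05 * 0.95 / cs$depth[match(paste(minor_hom$position,
                                                minor_hom$alt), key)])
  expect_true(mean(abs(got - 0.05) <= 3 * se) >= 0.9)
})

test_that("error-free homoplasmic simulation is called back exactly", {
  ref <- random_reference(2000, seed = 51)
  panel <- build_synthetic_panel(2000, 18, seed = 51)
  pos <- c(100L, 700L, 1500L)
  refb <- ref_base_at(ref, pos)
  tr <- data.frame(position = pos, ref = refb,
                   alt = unname(c(A = "G", G = "A", C = "T", T = "C")[refb]),
                   expected_vl = 1)
  cnt <- simulate_counts(tr, panel, ref, depth = 1000, err = 0, seed = 52)
  cs <- pass_calls(call_variants(cnt, threshold = 0.025))
  expect_equal(cs$position, pos)
  expect_equal(cs$alt, tr$alt)
  expect_equal(cs$vl, c(1, 1, 1))
})

test_that("sensitivity falls and precision rises along the threshold grid", {
  ref <- full_ref(); panel <- full_panel(); haps <- full_haps()
  tr <- mix_truth(haps$T, haps$U, 0.05, ref)
  cnt <- simulate_counts(tr, panel, ref, depth = 3000, err = 0.002,
                         seed = 61)
  cnt <- inject_numt_signal(cnt, c(2000L, 6000L, 10000L), level = 0.01,
                            seed = 62)
  sw <- sweep_thresholds(cnt)
  truth_key <- paste(tr$position, tr$alt)
  sens <- fp <- numeric(length(sw))
  for (i in seq_along(sw)) {
    cs <- pass_calls(sw[[i]])
    key <- paste(cs$position, cs$alt)
    sens[i] <- mean(truth_key %in% key)
    fp[i] <- sum(!(key %in% truth_key))
  }
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(fp) <= 0))
})
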
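# Shared fixtures, built in code at test time.

# Small circular reference of known sequence.
toy_ref <- function() circular_reference("ACGTACGT", name = "toy")

# rCRS-sized random reference / panel, memoised per session.
fix_env <- new.env(parent = emptyenv())

full_ref <- function() {
  if (is.null(fix_env$ref)) fix_env$ref <- random_reference(16569, seed = 42)
  fix_env$ref
}

full_panel <- function() {
  if (is.null(fix_env$panel))
    fix_env$panel <- build_synthetic_panel(16569, 162, seed = 42)
  fix_env$panel
}

full_haps <- function() {
  if (is.null(fix_env$haps))
    fix_env$haps <- synthetic_haplotypes(full_ref(), seed = 42)
  fix_env$haps
}

# One-site strand-split counts row.
site_row <- function(position, ref, fwd, rev) {
  out <- data.frame(position = position, ref = ref)
  for (b in c("A", "C", "G", "T")) out[[paste0("fwd_", b)]] <- fwd[[b]]
  for (b in c("A", "C", "G", "T")) out[[paste0("rev_", b)]] <- rev[[b]]
  out$depth <- sum(unlist(fwd)) + sum(unlist(rev))
  class(out) <- c("site_counts", "data.frame")
  out
}

# Balanced-strand counts: ref base n_ref reads, one alt base n_alt reads.
simple_site <- function(position, ref, alt, n_ref, n_alt) {
  z <- list(A = 0L, C = 0L, G = 0L, T = 0L)
  fwd <- z; rev <- z
  fwd[[ref]] <- n_ref %/% 2L; rev[[ref]] <- n_ref - n_ref %/% 2L
  fwd[[alt]] <- n_alt %/% 2L; rev[[alt]] <- n_alt - n_alt %/% 2L
  site_row(position, ref, fwd, rev)
}

# Brute-force expected VL by discrete genome-copy accounting: N copies,
# m*N from the minor haplotype, each sub-population carrying the alternate
# allele in proportion to its VL.
brute_expected_vl <- function(vl_minor, vl_major, m, N = 1e6) {
  n_min <- m * N
  (n_min * vl_minor + (N - n_min) * vl_major) / N
}
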
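#' Default heteroplasmy threshold grid
#'
#' 21 thresholds spanning 0.4% to 10.0%: 0.004 followed by 0.005 to 0.100
#' in steps of 0.005.
#'
#' @return Sorted numeric vector of 21 fractions.
#' @export
default_threshold_grid <- function() {
  c(0.004, seq(0.005, 0.100, by = 0.005))
}

#' Call heteroplasmic SNVs from strand-split pileup counts
#'
#' A transparent frequency-based caller over per-site base counts: at each
#' site, every non-reference base whose allele fraction (VL) meets the
#' heteroplasmy threshold is emitted. Calls at blacklisted positions or
#' failing the per-strand support rule are retained with a non-PASS filter
#' status. Counts are assumed restricted to bases with quality >= 20 at
#' pileup construction (substitutions only; indels are out of scope). At
#' most the two most frequent non-reference bases are reported per site,
#' ties broken alphabetically. Reference-N sites never produce calls.
#'
#' @param counts A \code{site_counts} data.frame.
#' @param threshold Heteroplasmy threshold as a fraction (default 0.025).
#' @param blacklist A \code{position_blacklist}.
#' @param min_per_strand Minimum alternate reads required on each strand
#'   (default 1; 0 disables the rule).
#' @param max_alts Maximum non-reference bases reported per site (2).
#' @return A \code{callset} data.frame: \code{position}, \code{ref},
#'   \code{alt}, \code{vl}, \code{depth}, \code{fwd_alt}, \code{rev_alt},
#'   \code{fwd_total}, \code{rev_total}, \code{filter} (\code{"PASS"},
#'   \code{"blacklist"} or \code{"strand"}).
#' @export
call_variants <- function(counts, threshold = 0.025,
                          blacklist = position_blacklist(),
                          min_per_strand = 1L, max_alts = 2L) {
  stopifnot(inherits(counts, "data.frame"), threshold > 0, threshold < 1)
  bases <- c("A", "C", "G", "T")
  fwd <- as.matrix(counts[paste0("fwd_", bases)])
  rev <- as.matrix(counts[paste0("rev_", bases)])
  colnames(fwd) <- colnames(rev) <- bases
  depth <- counts$depth
  rows <- list()
  for (b in bases) {
    nonref <- counts$ref != b & counts$ref != "N" & depth > 0
    n_alt <- fwd[, b] + rev[, b]
    vl <- ifelse(depth > 0, n_alt / depth, 0)
    hit <- nonref & vl >= threshold
    if (!any(hit)) next
    rows[[b]] <- data.frame(
      position = counts$position[hit], ref = counts$ref[hit], alt = b,
      vl = vl[hit], depth = depth[hit],
      fwd_alt = fwd[hit, b], rev_alt = rev[hit, b],
      fwd_total = rowSums(fwd)[hit], rev_total = rowSums(rev)[hit])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), ref = character(0), alt = character(0),
               vl = numeric(0), depth = integer(0), fwd_alt = integer(0),
               rev_alt = integer(0), fwd_total = integer(0),
               rev_total = integer(0))
  out <- out[order(out$position, -out$vl, out$alt), , drop = FALSE]
  if (nrow(out)) {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$position),
                          function(i) i[seq_len(min(length(i), max_alts))]),
                   use.names = FALSE)
    out <- out[sort(keep), , drop = FALSE]
  }
  out$filter <- rep("PASS", nrow(out))
  out$filter[is_blacklisted(out$position, blacklist)] <- "blacklist"
  strand_ok <- strand_rule(out$fwd_alt, out$rev_alt, min_per_strand)
  out$filter[out$filter == "PASS" & !strand_ok] <- "strand"
  rownames(out) <- NULL
  class(out) <- c("callset", "data.frame")
  out
}

#' Call a single pileup site
#'
#' Single-site convenience wrapper around \code{\link{call_variants}}.
#'
#' @param site One-row \code{site_counts} data.frame.
#' @inheritParams call_variants
#' @return A \code{callset} with 0 or more rows for that site.
#' @export
call_site <- function(site, threshold = 0.025,
                      blacklist = position_blacklist(),
                      min_per_strand = 1L) {
  stopifnot(nrow(site) == 1L)
  call_variants(site, threshold = threshold, blacklist = blacklist,
                min_per_strand = min_per_strand)
}

#' Double-strand support rule
#'
#' TRUE when the alternate allele has at least \code{min_per_strand} reads
#' on each strand; single-strand support is the classic artifact signature.
#'
#' @param fwd_alt,rev_alt Alternate read counts per strand.
#' @param min_per_strand Minimum per-strand support; 0 disables the rule.
#' @return Logical vector.
#' @export
strand_rule <- function(fwd_alt, rev_alt, min_per_strand = 1L) {
  fwd_alt >= min_per_strand & rev_alt >= min_per_strand
}

#' Passing calls of a callset
#' @param calls A \code{callset}.
#' @return The subset with \code{filter == "PASS"}.
#' @export
pass_calls <- function(calls) {
  calls[calls$filter == "PASS", , drop = FALSE]
}

#' Sweep a threshold grid over one sample
#'
#' Calls are computed once at the smallest threshold and filtered upward,
#' so callsets are nested by construction: every call passing at threshold
#' t also passes at any t' < t.
#'
#' @param counts A \code{site_counts}.
#' @param grid Sorted vector of distinct thresholds in (0, 1); default
#'   \code{\link{default_threshold_grid}}.
#' @inheritParams call_variants
#' @return Named list (by threshold) of \code{callset}s.
#' @export
sweep_thresholds <- function(counts, grid = default_threshold_grid(),
                             blacklist = position_blacklist(),
                             min_per_strand = 1L) {
  if (!length(grid) || any(grid <= 0 | grid >= 1))
    stop("grid values must lie in (0, 1)")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be sorted and free of duplicates")
  base <- call_variants(counts, threshold = grid[1], blacklist = blacklist,
                        min_per_strand = min_per_strand)
  out <- lapply(grid, function(t) {
    cs <- base[base$vl >= t, , drop = FALSE]
    rownames(cs) <- NULL
    cs
  })
  names(out) <- format(grid, trim = TRUE, drop0trailing = TRUE)
  out
}
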
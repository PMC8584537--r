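#' Amplicon panel on the circular genome
#'
#' An amplicon panel is the set of "callable" regions — the interior segment
#' of each PCR amplicon within which variant calls are trusted after
#' primer/edge trimming. Real panel coordinates are vendor-proprietary; the
#' synthetic builder reproduces the published summary statistics (162
#' amplicons, callable lengths 73-137 bp) as a seed-deterministic,
#' non-overlapping circular tiling. Panels can also be loaded from BED.
#'
#' @param amplicons data.frame with columns \code{id}, \code{start},
#'   \code{end} (canonical 1-based inclusive; \code{start > end} denotes an
#'   amplicon wrapping the origin) and \code{callable_len}.
#' @param genome_len Circle length in bp.
#' @return An object of class \code{amplicon_panel}.
#' @export
amplicon_panel <- function(amplicons, genome_len) {
  stopifnot(is.data.frame(amplicons),
            all(c("id", "start", "end") %in% names(amplicons)))
  amplicons$start <- as.integer(amplicons$start)
  amplicons$end <- as.integer(amplicons$end)
  if (any(amplicons$start < 1L) || any(amplicons$end > genome_len))
    stop("amplicon coordinates outside [1, genome_len]")
  amplicons$callable_len <- ifelse(
    amplicons$start <= amplicons$end,
    amplicons$end - amplicons$start + 1L,
    genome_len - amplicons$start + 1L + amplicons$end)
  structure(list(amplicons = amplicons, genome_len = as.integer(genome_len)),
            class = "amplicon_panel")
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("<amplicon_panel> ", nrow(x$amplicons), " amplicons on a ",
      x$genome_len, "-bp circle; callable lengths ",
      min(x$amplicons$callable_len), "-", max(x$amplicons$callable_len),
      " bp (mean ", round(mean(x$amplicons$callable_len), 1), ")\n", sep = "")
  invisible(x)
}

#' Build a synthetic amplicon panel
#'
#' Draws callable lengths uniformly in \code{len_range}, then nudges them
#' (within the range) until they tile the circle exactly, and lays the
#' amplicons end-to-end from position 1. Deterministic for a fixed seed.
#' Defaults emulate the published panel summary: 162 amplicons covering the
#' 16,569-bp circle with callable lengths between 73 and 137 bp.
#'
#' @param genome_len Circle length (default 16,569).
#' @param n_amplicons Number of amplicons (default 162).
#' @param seed Integer seed.
#' @param len_range Allowed callable-length range, default \code{c(73, 137)}.
#' @return An \code{amplicon_panel} whose callable regions cover every
#'   position exactly once.
#' @export
build_synthetic_panel <- function(genome_len = 16569L, n_amplicons = 162L,
                                  seed = 1L, len_range = c(73L, 137L)) {
  genome_len <- as.integer(genome_len)
  n <- as.integer(n_amplicons)
  lo <- as.integer(len_range[1]); hi <- as.integer(len_range[2])
  if (n < 1L || n * lo > genome_len || n * hi < genome_len)
    stop("infeasible panel: need n*", lo, " <= genome_len <= n*", hi)
  len <- with_local_seed(seed, {
    len <- sample(seq.int(lo, hi), n, replace = TRUE)
    d <- genome_len - sum(len)
    while (d != 0L) {
      step <- sign(d)
      ok <- which(len + step >= lo & len + step <= hi)
      pick <- ok[sample.int(length(ok), min(length(ok), abs(d)))]
      len[pick] <- len[pick] + step
      d <- genome_len - sum(len)
    }
    len
  })
  start <- c(1L, 1L + cumsum(len)[-n])
  amplicon_panel(data.frame(id = seq_len(n), start = start,
                            end = start + len - 1L), genome_len)
}

# 1-based positions covered by a circular interval of given start/length.
circ_positions <- function(start, len, L) {
  ((start - 1L + seq_len(len) - 1L) %% L) + 1L
}

# Overlap (bp) between two circular intervals given as (start, len).
circ_overlap <- function(s1, l1, s2, l2, L) {
  length(intersect(circ_positions(s1, l1, L), circ_positions(s2, l2, L)))
}

#' Crop a read to the maximum usable length
#'
#' Reads longer than the cap are cropped; the default cap of 160 bp reflects
#' declining base quality toward read ends on this chemistry and the 73-137
#' bp callable amplicon sections.
#'
#' @param read_len Integer vector of read lengths (bp), all > 0.
#' @param max_len Crop length, default 160.
#' @return \code{pmin(read_len, max_len)}.
#' @export
crop_read <- function(read_len, max_len = 160L) {
  if (any(read_len <= 0)) stop("read lengths must be positive")
  pmin(as.integer(read_len), as.integer(max_len))
}

#' Assign a read to an amplicon and trim to its callable region
#'
#' The read is assigned to the amplicon whose callable region it overlaps
#' most (ties break toward the smaller amplicon id); the returned interval
#' is the intersection of the read with that callable region. Reads with no
#' callable overlap are dropped.
#'
#' @param read_start 1-based start position on the circle.
#' @param read_len Read length in bp.
#' @param panel An \code{amplicon_panel}.
#' @return A list with \code{amplicon} (id) and \code{positions} (sorted
#'   canonical positions of the trimmed interval), or \code{NULL} when the
#'   read overlaps no callable region.
#' @export
assign_and_trim <- function(read_start, read_len, panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  L <- panel$genome_len
  rp <- circ_positions(as.integer(read_start), as.integer(read_len), L)
  amp <- panel$amplicons
  ov <- vapply(seq_len(nrow(amp)), function(i) {
    length(intersect(rp, circ_positions(amp$start[i], amp$callable_len[i], L)))
  }, integer(1))
  if (max(ov) == 0L) return(NULL)
  i <- which(ov == max(ov))[1]  # ids are sorted, so first hit = smallest id
  list(amplicon = amp$id[i],
       positions = sort(intersect(
         rp, circ_positions(amp$start[i], amp$callable_len[i], L))))
}

#' Distance to the nearest callable amplicon extremity
#'
#' For each position, over all amplicons whose callable region covers it,
#' the minimum of the distances to either callable end (0 at an extremity).
#' Variants very close to a callable edge are enriched for artifacts.
#'
#' @param p Integer vector of canonical positions.
#' @param panel An \code{amplicon_panel}.
#' @return Integer vector of distances (bp). Positions covered by no
#'   amplicon raise an error.
#' @export
edge_distance <- function(p, panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  L <- panel$genome_len
  amp <- panel$amplicons
  vapply(as.integer(p), function(pos) {
    best <- NA_integer_
    for (i in seq_len(nrow(amp))) {
      off <- (pos - amp$start[i]) %% L
      if (off < amp$callable_len[i]) {
        d <- min(off, amp$callable_len[i] - 1L - off)
        if (is.na(best) || d < best) best <- d
      }
    }
    if (is.na(best)) stop("position ", pos, " covered by no amplicon")
    best
  }, integer(1))
}

# Amplicon id covering each position (first covering amplicon; a tiling
# covers each position exactly once).
position_amplicon <- function(panel) {
  L <- panel$genome_len
  amp <- panel$amplicons
  out <- integer(L)
  for (i in seq_len(nrow(amp))) {
    out[circ_positions(amp$start[i], amp$callable_len[i], L)] <- amp$id[i]
  }
  if (any(out == 0L)) stop("panel does not cover every position")
  out
}

#' Read / write amplicon panels as BED
#'
#' BED is 0-based half-open; conversion happens at this boundary only.
#' Amplicons wrapping the origin are split into two BED lines sharing a
#' name and re-joined on read.
#'
#' @param path BED file path.
#' @param genome_len Circle length (needed on read to re-join wrapped
#'   amplicons).
#' @return \code{read_panel_bed}: an \code{amplicon_panel}.
#' @export
read_panel_bed <- function(path, genome_len = 16569L) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed)[1:4] <- c("chrom", "start0", "end0", "name")
  parts <- split(bed, bed$name)
  rows <- lapply(parts, function(b) {
    b$start <- b$start0 + 1L
    b$end <- b$end0
    if (nrow(b) == 1L)
      return(data.frame(id = b$name, start = b$start, end = b$end))
    if (nrow(b) == 2L) {
      b <- b[order(b$start), ]
      # piece at origin (starts at 1) is the tail of the wrap
      if (b$start[1] != 1L || b$end[2] != genome_len)
        stop("cannot re-join wrapped amplicon ", b$name[1])
      return(data.frame(id = b$name[1], start = b$start[2], end = b$end[1]))
    }
    stop("amplicon ", b$name[1], " split into >2 BED lines")
  })
  amp <- do.call(rbind, rows)
  amp <- amp[order(amp$start), ]
  amp$id <- seq_len(nrow(amp))
  amplicon_panel(amp, genome_len)
}

#' @rdname read_panel_bed
#' @param panel An \code{amplicon_panel}.
#' @param chrom Contig name written in column 1.
#' @export
write_panel_bed <- function(panel, path, chrom = "chrM") {
  amp <- panel$amplicons
  L <- panel$genome_len
  lines <- character(0)
  for (i in seq_len(nrow(amp))) {
    nm <- paste0("amp", amp$id[i])
    if (amp$start[i] <= amp$end[i]) {
      lines <- c(lines, paste(chrom, amp$start[i] - 1L, amp$end[i], nm,
                              sep = "\t"))
    } else {
      lines <- c(lines,
                 paste(chrom, amp$start[i] - 1L, L, nm, sep = "\t"),
                 paste(chrom, 0L, amp$end[i], nm, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
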
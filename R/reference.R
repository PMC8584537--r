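#' Canonical circular mtDNA reference
#'
#' Construct a circular reference sequence object. The human mitochondrial
#' genome (rCRS) is a 16,569-bp circle; any circular sequence over the
#' alphabet A/C/G/T/N is accepted. Coordinates are 1-based inclusive
#' throughout the package.
#'
#' @param sequence Single character string of bases (A, C, G, T, N).
#' @param name Contig name used in VCF/BED output. Default \code{"chrM"}.
#' @return An object of class \code{circular_reference} with elements
#'   \code{name}, \code{sequence} and \code{length}.
#' @examples
#' ref <- circular_reference("ACGTACGT", name = "toy")
#' ref$length
#' @export
circular_reference <- function(sequence, name = "chrM") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("reference sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("reference sequence may only contain A, C, G, T, N")
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         circular = TRUE),
    class = "circular_reference"
  )
}

#' @export
print.circular_reference <- function(x, ...) {
  cat("<circular_reference> ", x$name, ": ", x$length, " bp (circular)\n",
      sep = "")
  invisible(x)
}

#' Random circular reference for simulation
#'
#' Draws a uniform random base sequence of the given length. Used as a
#' stand-in for the rCRS in synthetic benchmarks; any 16,569-base circular
#' sequence exercises the coordinate machinery identically.
#'
#' @param length Genome length in bp; default the rCRS length 16,569.
#' @param seed Integer seed; all randomness is local to the call.
#' @param name Contig name.
#' @return A \code{circular_reference}.
#' @export
random_reference <- function(length = 16569L, seed = 1L, name = "chrM") {
  stopifnot(length > 0)
  seq <- with_local_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
  circular_reference(seq, name = name)
}

#' Panel-style extended reference
#'
#' The amplicon panel's reference duplicates the first \code{dup_len} bases
#' of the circular genome at the end of the linear reference, so that the
#' final amplicon spanning the origin maps contiguously. For the rCRS with
#' the default \code{dup_len = 80} this yields the 16,649-bp extended
#' reference.
#'
#' @param ref A \code{circular_reference}.
#' @param dup_len Number of leading bases duplicated at the end (default 80).
#' @return An object of class \code{extended_reference} with elements
#'   \code{base} (the circular reference), \code{dup_len}, \code{sequence}
#'   and \code{length} (= L + dup_len).
#' @examples
#' ref <- circular_reference("ACGTACGT")
#' extend_reference(ref, 3)$sequence  # "ACGTACGTACG"
#' @export
extend_reference <- function(ref, dup_len = 80L) {
  stopifnot(inherits(ref, "circular_reference"))
  dup_len <- as.integer(dup_len)
  if (is.na(dup_len) || dup_len <= 0L || dup_len > ref$length)
    stop("dup_len must satisfy 0 < dup_len <= reference length")
  structure(
    list(base = ref, dup_len = dup_len,
         sequence = paste0(ref$sequence, substr(ref$sequence, 1L, dup_len)),
         length = ref$length + dup_len),
    class = "extended_reference"
  )
}

#' @export
print.extended_reference <- function(x, ...) {
  cat("<extended_reference> ", x$base$name, ": ", x$length, " bp (",
      x$base$length, " + ", x$dup_len, " duplicated)\n", sep = "")
  invisible(x)
}

#' Fold extended-reference positions onto the circle
#'
#' Positions called against the extended reference that fall beyond the
#' canonical length L are corrected back to the duplicated leading bases:
#' position p maps to p - L when p > L, and is unchanged otherwise.
#'
#' @param p Integer vector of 1-based extended-reference positions.
#' @param ref An \code{extended_reference}.
#' @return Integer vector of canonical positions in \code{[1, L]}.
#' @examples
#' ext <- extend_reference(random_reference(16569, seed = 1), 80)
#' fold_position(c(100L, 16570L, 16649L), ext)  # 100 1 80
#' @export
fold_position <- function(p, ref) {
  stopifnot(inherits(ref, "extended_reference"))
  p <- as.integer(p)
  if (any(is.na(p)) || any(p < 1L) || any(p > ref$length))
    stop("position out of extended-reference bounds [1, ", ref$length, "]")
  ifelse(p > ref$base$length, p - ref$base$length, p)
}

#' Extended positions mapping to a canonical position
#'
#' Inverse of \code{\link{fold_position}}: a canonical position within the
#' duplicated prefix has two images on the extended reference, all others
#' have one.
#'
#' @param p Single canonical 1-based position.
#' @param ref An \code{extended_reference}.
#' @return Sorted integer vector of extended positions whose fold equals
#'   \code{p}.
#' @export
extend_positions <- function(p, ref) {
  stopifnot(inherits(ref, "extended_reference"), length(p) == 1L)
  p <- as.integer(p)
  L <- ref$base$length
  if (is.na(p) || p < 1L || p > L)
    stop("position out of canonical bounds [1, ", L, "]")
  if (p <= ref$dup_len) c(p, p + L) else p
}

#' Position blacklist on the canonical reference
#'
#' Positions in homopolymeric / artifact-prone regions are excluded from
#' calling. The default intervals are 302-315, 523-524 and 3104-3110 on the
#' rCRS (1-based inclusive).
#'
#' @param ranges Two-column matrix or data.frame of interval start/end
#'   (1-based inclusive), or NULL for the default set.
#' @return An object of class \code{position_blacklist}.
#' @examples
#' bl <- position_blacklist()
#' is_blacklisted(310, bl)
#' @export
position_blacklist <- function(ranges = NULL) {
  if (is.null(ranges))
    ranges <- cbind(start = c(302L, 523L, 3104L), end = c(315L, 524L, 3110L))
  ranges <- as.matrix(ranges)
  storage.mode(ranges) <- "integer"
  colnames(ranges) <- c("start", "end")
  if (any(ranges[, "start"] > ranges[, "end"]) || any(ranges < 1L))
    stop("blacklist intervals must have 1 <= start <= end")
  structure(list(ranges = ranges), class = "position_blacklist")
}

#' @export
print.position_blacklist <- function(x, ...) {
  cat("<position_blacklist> ", nrow(x$ranges), " interval(s): ",
      paste(x$ranges[, 1], x$ranges[, 2], sep = "-", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Test canonical positions against a blacklist
#'
#' @param p Integer vector of canonical positions.
#' @param bl A \code{position_blacklist} (default set if missing).
#' @return Logical vector, TRUE where p lies in any blacklist interval.
#' @export
is_blacklisted <- function(p, bl = position_blacklist()) {
  stopifnot(inherits(bl, "position_blacklist"))
  p <- as.integer(p)
  out <- rep(FALSE, length(p))
  for (i in seq_len(nrow(bl$ranges)))
    out <- out | (p >= bl$ranges[i, 1] & p <= bl$ranges[i, 2])
  out
}

#' All blacklisted positions as a vector
#' @param bl A \code{position_blacklist}.
#' @return Sorted integer vector of blacklisted canonical positions.
#' @export
blacklist_positions <- function(bl = position_blacklist()) {
  sort(unique(unlist(lapply(seq_len(nrow(bl$ranges)), function(i)
    seq.int(bl$ranges[i, 1], bl$ranges[i, 2])))))
}

#' Read / write references as FASTA
#'
#' Thin wrappers over Biostrings. \code{read_reference_fasta} takes the
#' first record of the file as the circular reference;
#' \code{write_reference_fasta} accepts either a circular or an extended
#' reference.
#'
#' @param path FASTA file path.
#' @return \code{read_reference_fasta}: a \code{circular_reference}.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(ss)[1])
  circular_reference(as.character(ss[[1]]), name = nm)
}

#' @rdname read_reference_fasta
#' @param ref A \code{circular_reference} or \code{extended_reference}.
#' @export
write_reference_fasta <- function(ref, path) {
  if (inherits(ref, "extended_reference")) {
    nm <- paste0(ref$base$name, "_ext")
    seq <- ref$sequence
  } else {
    stopifnot(inherits(ref, "circular_reference"))
    nm <- ref$name
    seq <- ref$sequence
  }
  ss <- Biostrings::DNAStringSet(seq)
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a blacklist from BED
#'
#' BED input is 0-based half-open; intervals are converted to 1-based
#' inclusive at this boundary.
#'
#' @param path BED file (chrom, start, end).
#' @return A \code{position_blacklist}.
#' @export
read_blacklist_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  position_blacklist(cbind(start = bed[[2]] + 1L, end = bed[[3]]))
}

#' Reference base at canonical positions
#'
#' @param ref A \code{circular_reference}.
#' @param p Integer vector of 1-based canonical positions.
#' @return Character vector of bases.
#' @export
ref_base_at <- function(ref, p) {
  stopifnot(inherits(ref, "circular_reference"))
  if (!length(p)) return(character(0))
  substring(ref$sequence, p, p)
}

# Run code with a local, restored RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
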
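#' Merge duplicate records of the same variant
#'
#' Calls at the same canonical position and alternate base — one from each
#' copy of the duplicated leading region — are merged by taking the
#' arithmetic mean of their coverages and of their variant levels. The rule
#' extends associatively to more than two records (unweighted mean of all).
#'
#' @param ... Two or more call records, each a list/one-row data.frame with
#'   \code{position}, \code{ref}, \code{alt}, \code{coverage}, \code{vl}.
#' @return A single merged record (list).
#' @examples
#' merge_duplicates(list(position = 50, ref = "A", alt = "G",
#'                       coverage = 1000, vl = 0.90),
#'                  list(position = 50, ref = "A", alt = "G",
#'                       coverage = 800, vl = 0.80))
#' @export
merge_duplicates <- function(...) {
  recs <- list(...)
  if (length(recs) == 1L && is.list(recs[[1]]) && is.null(recs[[1]]$position))
    recs <- recs[[1]]
  stopifnot(length(recs) >= 1L)
  pos <- unique(vapply(recs, function(r) as.integer(r$position), integer(1)))
  alt <- unique(vapply(recs, function(r) as.character(r$alt), character(1)))
  if (length(pos) != 1L || length(alt) != 1L)
    stop("records with differing position/alt are not mergeable")
  list(position = pos, ref = recs[[1]]$ref, alt = alt,
       coverage = mean(vapply(recs, function(r) as.numeric(r$coverage),
                              numeric(1))),
       vl = mean(vapply(recs, function(r) as.numeric(r$vl), numeric(1))),
       merged_n = length(recs))
}

#' Fold an extended-reference callset onto canonical coordinates
#'
#' Positions above the canonical length L are corrected back into the
#' duplicated leading bases (p - L); records that land on the same
#' (canonical position, alternate base) are merged by
#' \code{\link{merge_duplicates}}. Non-SNV records are dropped first
#' (substitutions only). Folding is idempotent: a canonical callset passes
#' through unchanged.
#'
#' @param calls data.frame with columns \code{position} (extended or
#'   canonical 1-based), \code{ref}, \code{alt}, \code{coverage}, \code{vl}.
#' @param ref An \code{extended_reference}.
#' @return data.frame \code{position}, \code{ref}, \code{alt},
#'   \code{coverage}, \code{vl}, \code{merged_n}, sorted by position.
#' @export
fold_callset <- function(calls, ref) {
  stopifnot(inherits(ref, "extended_reference"), is.data.frame(calls))
  need <- c("position", "ref", "alt", "coverage", "vl")
  stopifnot(all(need %in% names(calls)))
  if (any(calls$position > ref$length))
    stop("position beyond extended reference length ", ref$length)
  snv <- nchar(calls$ref) == 1L & nchar(calls$alt) == 1L &
    calls$alt %in% c("A", "C", "G", "T")
  calls <- calls[snv, , drop = FALSE]
  if (!nrow(calls))
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), coverage = numeric(0),
                      vl = numeric(0), merged_n = integer(0)))
  calls$position <- fold_position(calls$position, ref)
  key <- paste(calls$position, calls$alt)
  groups <- split(seq_len(nrow(calls)), key)
  out <- do.call(rbind, lapply(groups, function(i) {
    m <- merge_duplicates(lapply(i, function(j) as.list(calls[j, ])))
    data.frame(position = m$position, ref = m$ref, alt = m$alt,
               coverage = m$coverage, vl = m$vl, merged_n = m$merged_n)
  }))
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genotype code from a variant level
#'
#' Variants at or above the homoplasmic genotype bound (default 90%) are
#' exported with the homoplasmic genotype code \code{"1/0"}; lower-level
#' variants are heteroplasmic, \code{"0/1"}. Distinct from the grading
#' homoplasmy bound of 95%.
#'
#' @param vl Variant level fraction(s) in [0, 1].
#' @param hom_gt_threshold Homoplasmic bound, inclusive (default 0.90).
#' @return Character vector of genotype codes.
#' @export
export_genotype <- function(vl, hom_gt_threshold = 0.90) {
  stopifnot(all(vl >= 0 & vl <= 1))
  ifelse(vl >= hom_gt_threshold, "1/0", "0/1")
}

#' Read a variant callset from VCF
#'
#' Reads a single-sample VCF (via vcfR) called against either the canonical
#' or the extended reference. The contig length declared in the header
#' selects folding behaviour downstream: a contig of length L + dup_len is
#' an extended-reference callset. Coverage is taken from INFO/DP (or
#' FORMAT/DP), the variant level from INFO/AF (or FORMAT/AF), as fractions.
#'
#' @param path VCF file (plain text or gzipped).
#' @return List with \code{calls} (data.frame position/ref/alt/coverage/vl)
#'   and \code{contig_len} (integer or NA when the header lacks it).
#' @export
read_callset_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  contig_len <- NA_integer_
  ctg <- grep("^##contig=", meta, value = TRUE)
  if (length(ctg)) {
    m <- regmatches(ctg[1], regexpr("length=[0-9]+", ctg[1]))
    if (length(m)) contig_len <- as.integer(sub("length=", "", m))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  calls <- data.frame(position = as.integer(fix$POS), ref = fix$REF,
                      alt = fix$ALT, coverage = dp, vl = af)
  list(calls = calls, contig_len = contig_len)
}

#' Write a callset as a single-sample VCF
#'
#' Emits VCFv4.2 with the canonical contig header, INFO fields DP (depth),
#' AF (variant level as a fraction) and MERGED_N (number of
#' duplicated-region records merged, when present), FORMAT/GT from
#' \code{\link{export_genotype}}, and the callset's filter codes. Strand
#' alternate counts, when present, are written as INFO SF/SR.
#'
#' @param calls data.frame with at least \code{position}, \code{ref},
#'   \code{alt}, \code{vl} and one of \code{coverage}/\code{depth}.
#' @param path Output path (plain text).
#' @param ref_name Contig name (default "chrM").
#' @param contig_len Contig length for the header (default 16,569).
#' @param sample Sample name.
#' @param hom_gt_threshold Passed to \code{\link{export_genotype}}.
#' @return The path, invisibly.
#' @export
write_callset_vcf <- function(calls, path, ref_name = "chrM",
                              contig_len = 16569L, sample = "SAMPLE",
                              hom_gt_threshold = 0.90) {
  depth <- if ("coverage" %in% names(calls)) calls$coverage else calls$depth
  filt <- if ("filter" %in% names(calls)) calls$filter else
    rep("PASS", nrow(calls))
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=mitofold-", as.character(utils::packageVersion("mitofold"))),
    paste0("##contig=<ID=", ref_name, ",length=", contig_len, ">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant level (fraction)\">",
    "##INFO=<ID=SF,Number=1,Type=Integer,Description=\"Forward-strand alternate reads\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Reverse-strand alternate reads\">",
    "##INFO=<ID=MERGED_N,Number=1,Type=Integer,Description=\"Duplicated-region records merged\">",
    "##FILTER=<ID=blacklist,Description=\"Blacklisted position\">",
    "##FILTER=<ID=strand,Description=\"Insufficient per-strand support\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  info <- paste0("DP=", round(depth), ";AF=", signif(calls$vl, 6))
  if ("fwd_alt" %in% names(calls))
    info <- paste0(info, ";SF=", calls$fwd_alt, ";SR=", calls$rev_alt)
  if ("merged_n" %in% names(calls))
    info <- paste0(info, ";MERGED_N=", calls$merged_n)
  body <- paste(ref_name, calls$position, ".", calls$ref, calls$alt, ".",
                filt, info, "GT",
                export_genotype(calls$vl, hom_gt_threshold), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
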
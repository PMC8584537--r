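#' Coverage normalized to the sample mean
#'
#' @param site_depth Site read depth(s).
#' @param sample_mean_depth Mean depth of the sample (> 0).
#' @return \code{site_depth / sample_mean_depth}.
#' @export
normalized_coverage <- function(site_depth, sample_mean_depth) {
  if (any(sample_mean_depth <= 0)) stop("sample mean depth must be positive")
  site_depth / sample_mean_depth
}

#' Forward/reverse strand coverage ratio
#'
#' Strand bias expressed as a coverage ratio. A zero reverse count yields
#' an infinite-bias sentinel (\code{Inf}) with a warning rather than an
#' error, so batch annotation can proceed.
#'
#' @param fwd,rev Read counts per strand.
#' @return \code{fwd / rev}, with \code{Inf} where \code{rev == 0}.
#' @export
strand_ratio <- function(fwd, rev) {
  if (any(rev == 0))
    warning("reverse-strand count 0: infinite strand ratio sentinel")
  ifelse(rev > 0, fwd / rev, Inf)
}

#' Mean NUMT count over two databases
#'
#' Per position, the mean of the counts of reported nuclear mitochondrial
#' insertions (NUMTs) in two databases; positions absent from a database
#' count 0.
#'
#' @param position Canonical position(s).
#' @param db1,db2 NUMT tables: data.frames with columns \code{position},
#'   \code{count} (as read by \code{\link{read_numt_table}}).
#' @return Numeric vector of mean counts.
#' @export
numt_mean <- function(position, db1, db2) {
  get_count <- function(db, p) {
    i <- match(p, db$position)
    ifelse(is.na(i), 0, db$count[i])
  }
  (get_count(db1, position) + get_count(db2, position)) / 2
}

#' Read a NUMT position-count table
#'
#' Two tab-separated columns: canonical 1-based position, count of
#' reported NUMTs at that position.
#'
#' @param path TSV path.
#' @return data.frame \code{position}, \code{count}.
#' @export
read_numt_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  names(d)[1:2] <- c("position", "count")
  d
}

#' Read low-complexity regions from BED
#'
#' @param path BED path (0-based half-open; converted here).
#' @return data.frame \code{start}, \code{end}, 1-based inclusive.
#' @export
read_lcr_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(start = bed[[2]] + 1L, end = bed[[3]])
}

# Membership of positions in a set of 1-based inclusive intervals.
in_intervals <- function(p, intervals) {
  out <- rep(FALSE, length(p))
  for (i in seq_len(nrow(intervals)))
    out <- out | (p >= intervals$start[i] & p <= intervals$end[i])
  out
}

#' Annotate a callset with the false-positive characterization battery
#'
#' One record per call: coverage normalized to the sample mean, strand
#' coverage ratio, mean NUMT count over two databases, low-complexity
#' region membership, and distance to the nearest callable amplicon
#' extremity; each call carries its classification from the found/lost/
#' novel ledger.
#'
#' @param calls A \code{callset} (needs \code{position}, \code{alt},
#'   \code{depth}, \code{fwd_total}, \code{rev_total}).
#' @param outcomes Ledger from \code{\link{classify_test_calls}}.
#' @param panel An \code{amplicon_panel}.
#' @param lcr LCR intervals (data.frame \code{start}, \code{end}).
#' @param numt_db1,numt_db2 NUMT tables (see \code{\link{numt_mean}}).
#' @param sample_mean_depth Sample mean depth (reads/bp).
#' @return data.frame of annotation records, one per call.
#' @export
annotate_callset <- function(calls, outcomes, panel, lcr, numt_db1,
                             numt_db2, sample_mean_depth) {
  for (nm in c("panel", "lcr", "numt_db1", "numt_db2"))
    if (is.null(get(nm))) stop("missing resource: ", nm)
  if (!nrow(calls))
    return(data.frame(position = integer(0), alt = character(0),
                      variant_class = character(0),
                      normalized_coverage = numeric(0),
                      strand_ratio = numeric(0), numt_mean = numeric(0),
                      lcr = logical(0), edge_distance = integer(0)))
  okey <- paste(outcomes$position, outcomes$alt)
  ckey <- paste(calls$position, calls$alt)
  cls <- outcomes$outcome[match(ckey, okey)]
  data.frame(
    position = calls$position, alt = calls$alt,
    variant_class = ifelse(is.na(cls), "novel", cls),
    normalized_coverage = normalized_coverage(calls$depth,
                                              sample_mean_depth),
    strand_ratio = strand_ratio(calls$fwd_alt, calls$rev_alt),
    numt_mean = numt_mean(calls$position, numt_db1, numt_db2),
    lcr = in_intervals(calls$position, lcr),
    edge_distance = edge_distance(calls$position, panel))
}

#' Per-class annotation summary with effect directions
#'
#' Means of the continuous annotation variables (and the LCR proportion)
#' per variant class, plus the effect direction of each class relative to
#' found variants (true positives), binned by the relative change:
#' |change| < 25% → \code{"none"}; 25-50% → \code{"down-25-50"} /
#' \code{"up-25-50"}; 51-75% → \code{"down-51-75"} / \code{"up-51-75"};
#' > 75% → \code{"down-gt-75"} / \code{"up-gt-75"}.
#'
#' @param records Annotation records from \code{\link{annotate_callset}}.
#' @return List with \code{summary} (per-class means) and \code{effects}
#'   (per class x variable direction bins vs the found class; NULL when no
#'   found variants exist).
#' @export
summarize_annotations <- function(records) {
  if (!nrow(records)) return(list(summary = records[0, ], effects = NULL))
  vars <- c("normalized_coverage", "strand_ratio", "numt_mean",
            "edge_distance")
  classes <- split(records, records$variant_class)
  summ <- do.call(rbind, lapply(names(classes), function(cl) {
    g <- classes[[cl]]
    row <- data.frame(variant_class = cl, n = nrow(g))
    for (v in vars) row[[v]] <- mean(g[[v]][is.finite(g[[v]])])
    row$lcr_prop <- mean(g$lcr)
    row
  }))
  effects <- NULL
  if ("found" %in% summ$variant_class) {
    base <- summ[summ$variant_class == "found", ]
    effects <- do.call(rbind, lapply(
      summ$variant_class[summ$variant_class != "found"], function(cl) {
        row <- data.frame(variant_class = cl)
        for (v in c(vars, "lcr_prop")) {
          row[[v]] <- bin_effect(summ[[v]][summ$variant_class == cl],
                                 base[[v]])
        }
        row
      }))
  }
  list(summary = summ, effects = effects)
}

# Direction bin of x relative to reference value base.
bin_effect <- function(x, base) {
  if (is.na(x) || is.na(base) || base == 0) return(NA_character_)
  pct <- (x - base) / base * 100
  dir <- if (pct < 0) "down" else "up"
  a <- abs(pct)
  if (a < 25) "none"
  else if (a <= 50) paste0(dir, "-25-50")
  else if (a <= 75) paste0(dir, "-51-75")
  else paste0(dir, "-gt-75")
}
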
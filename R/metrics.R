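#' Confusion-matrix metrics from a found/lost/novel ledger
#'
#' Counts: tp = found, fn = lost, fp = novel. The true-negative space is
#' the callable position-allele space — every non-blacklisted canonical
#' position times the 3 possible alternate alleles — minus tp + fn + fp.
#' Ratios with a zero denominator are reported as NA, never 0.
#'
#' @param outcomes Ledger from \code{\link{classify_test_calls}} (column
#'   \code{outcome}).
#' @param genome_len Canonical genome length (default 16,569).
#' @param blacklist A \code{position_blacklist}.
#' @param dataset Optional dataset label carried into the report.
#' @param threshold Optional threshold carried into the report.
#' @return One-row data.frame: \code{dataset}, \code{threshold}, \code{tp},
#'   \code{fp}, \code{fn}, \code{tn}, \code{sensitivity},
#'   \code{specificity}, \code{precision}, \code{f1}.
#' @export
compute_metrics <- function(outcomes, genome_len = 16569L,
                            blacklist = position_blacklist(),
                            dataset = NA_character_, threshold = NA_real_) {
  stopifnot("outcome" %in% names(outcomes))
  tp <- sum(outcomes$outcome == "found")
  fn <- sum(outcomes$outcome == "lost")
  fp <- sum(outcomes$outcome == "novel")
  space <- (genome_len - length(blacklist_positions(blacklist))) * 3
  tn <- space - (tp + fn + fp)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  prec <- div(tp, tp + fp)
  spec <- div(tn, tn + fp)
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * prec * sens / (prec + sens) else if (isTRUE(sens == 0) || isTRUE(prec == 0)) 0 else NA_real_
  data.frame(dataset = dataset, threshold = threshold, tp = tp, fp = fp,
             fn = fn, tn = tn, sensitivity = sens, specificity = spec,
             precision = prec, f1 = f1)
}

#' F1-optimal threshold across datasets
#'
#' Returns the grid threshold maximizing the unweighted mean F1 score
#' across datasets (e.g. primary/mixture x Grade A/B). Datasets with an
#' undefined F1 at a threshold are dropped from that mean with a warning.
#' Ties break toward the higher threshold.
#'
#' @param reports data.frame of per-dataset, per-threshold metric rows
#'   (columns \code{dataset}, \code{threshold}, \code{f1}).
#' @return List with \code{threshold} (the optimum) and \code{mean_f1}
#'   (data.frame of threshold vs mean F1).
#' @export
optimize_threshold <- function(reports) {
  stopifnot(all(c("dataset", "threshold", "f1") %in% names(reports)))
  if (any(is.na(reports$f1)))
    warning("datasets with undefined F1 dropped from the mean")
  agg <- stats::aggregate(f1 ~ threshold, data = reports, FUN = mean,
                          na.action = stats::na.omit)
  agg <- agg[order(agg$threshold), ]
  best <- max(agg$f1)
  thr <- max(agg$threshold[agg$f1 == best])  # tie -> higher threshold
  list(threshold = thr, mean_f1 = agg)
}

#' Paired comparison of per-sample metrics
#'
#' Two-sided paired t-test of matched per-sample values, with the 95%
#' confidence interval from the t distribution. Use
#' \code{\link{fdr_adjust}} to Benjamini-Hochberg-adjust p-values across a
#' batch of such comparisons. A zero-variance difference vector is
#' degenerate: flagged with NA p-value, not an error.
#'
#' @param a,b Numeric vectors of equal length >= 2, same sample order.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row data.frame: \code{mean_diff}, \code{ci_lo}, \code{ci_hi},
#'   \code{p}, \code{n}, \code{degenerate}.
#' @export
paired_compare <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    # no spread in the differences: identical vectors carry no evidence
    # against the null (p = 1); a constant non-zero shift is degenerate
    return(data.frame(mean_diff = mean(d), ci_lo = mean(d), ci_hi = mean(d),
                      p = if (isTRUE(all.equal(mean(d), 0))) 1 else NA_real_,
                      n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE, conf.level = conf_level)
  data.frame(mean_diff = unname(tt$estimate), ci_lo = tt$conf.int[1],
             ci_hi = tt$conf.int[2], p = tt$p.value, n = length(d),
             degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment across a batch of comparisons
#'
#' @param results data.frame with a \code{p} column (e.g. rows from
#'   \code{\link{paired_compare}}).
#' @return The data.frame with an added \code{adj_p} column.
#' @export
fdr_adjust <- function(results) {
  stopifnot("p" %in% names(results))
  results$adj_p <- stats::p.adjust(results$p, method = "BH")
  results
}

#' Mappability at coverage thresholds
#'
#' The fraction of genome positions readable at or above each coverage
#' threshold.
#'
#' @param depths Per-position depth vector over the whole canonical genome.
#' @param thresholds Coverage thresholds, default \code{c(1,10,50,100,500)}.
#' @return Named numeric vector of fractions, one per threshold.
#' @export
mappability <- function(depths, thresholds = c(1, 10, 50, 100, 500)) {
  vapply(thresholds, function(c) mean(depths >= c), numeric(1)) |>
    stats::setNames(as.character(thresholds))
}
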
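#' Cross-run variant reliability grading
#'
#' Variants observed across three independent reference sequencing runs of
#' the same sample (exome, lowCov, highCov) are graded by concordance:
#' \describe{
#'   \item{A}{homoplasmic (mean VL >= 95%) and present in both highCov and
#'     lowCov, regardless of exome;}
#'   \item{B}{present in both highCov and lowCov with mean VL below the
#'     homoplasmy bound, or present in exactly two runs one of which is the
#'     exome (highCov+exome or lowCov+exome);}
#'   \item{C}{present in a single reference run;}
#'   \item{novel}{absent from every reference run (seen only in the test
#'     platform).}
#' }
#' The mean VL is computed over the runs where the variant is observed
#' (absent runs contribute nothing, not zero). A reference-run detection
#' threshold of 0.4% is applied at ingestion. The A/B bound at exactly 95%
#' resolves to Grade A. A homoplasmic variant in a two-run pattern not
#' including both highCov and lowCov still grades B (two-run concordance
#' without the A-pattern), keeping the rules exhaustive.
#'
#' @param obs data.frame of reference-run observations: columns \code{run}
#'   (one of \code{"exome"}, \code{"lowCov"}, \code{"highCov"}),
#'   \code{position}, \code{alt}, \code{vl}.
#' @param hom_bound Homoplasmy bound for grading, default 0.95 (inclusive).
#' @param ref_threshold Reference-run VL threshold, default 0.004.
#' @return data.frame \code{position}, \code{alt}, \code{grade} (factor
#'   A/B/C), \code{mean_vl}, \code{n_runs}, \code{runs}.
#' @export
grade_variants <- function(obs, hom_bound = 0.95, ref_threshold = 0.004) {
  stopifnot(is.data.frame(obs),
            all(c("run", "position", "alt", "vl") %in% names(obs)))
  runs_ok <- c("exome", "lowCov", "highCov")
  if (!all(obs$run %in% runs_ok))
    stop("run must be one of ", paste(runs_ok, collapse = ", "))
  if (any(obs$vl < 0 | obs$vl > 1)) stop("VL must lie in [0, 1]")
  if (anyDuplicated(obs[c("run", "position", "alt")]))
    stop("one observation per (run, position, alt)")
  obs <- obs[obs$vl >= ref_threshold, , drop = FALSE]
  if (!nrow(obs))
    return(data.frame(position = integer(0), alt = character(0),
                      grade = character(0), mean_vl = numeric(0),
                      n_runs = integer(0), runs = character(0)))
  key <- paste(obs$position, obs$alt)
  groups <- split(seq_len(nrow(obs)), key)
  out <- do.call(rbind, lapply(groups, function(i) {
    g <- obs[i, ]
    data.frame(position = g$position[1], alt = g$alt[1],
               grade = grade_one(g$run, mean(g$vl), hom_bound),
               mean_vl = mean(g$vl), n_runs = nrow(g),
               runs = paste(sort(g$run), collapse = "+"))
  }))
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Grade from the set of observing runs and the mean VL.
grade_one <- function(runs, mean_vl, hom_bound = 0.95) {
  in_hc <- "highCov" %in% runs
  in_lc <- "lowCov" %in% runs
  if (in_hc && in_lc) {
    if (mean_vl >= hom_bound) return("A")
    return("B")
  }
  if (length(unique(runs)) >= 2L) return("B")
  "C"
}

#' Classify test-platform calls against graded truth
#'
#' Grade A/B variants called in the test run are \emph{found} (true
#' positives); Grade A/B variants not called are \emph{lost} (false
#' negatives); calls at (position, alt) pairs absent from the reference
#' runs at any grade are \emph{novel} (false positives). Grade C truth
#' entries are retained with outcome \code{"excluded"} and do not enter the
#' confusion counts.
#'
#' @param truth Graded truth from \code{\link{grade_variants}} (or any
#'   data.frame with \code{position}, \code{alt}, \code{grade}).
#' @param test_calls A \code{callset}; only PASS calls count.
#' @return data.frame \code{position}, \code{alt}, \code{grade},
#'   \code{outcome} in \{found, lost, novel, excluded\}, plus the observed
#'   \code{vl} for calls present in the test set.
#' @export
classify_test_calls <- function(truth, test_calls) {
  stopifnot(all(c("position", "alt", "grade") %in% names(truth)))
  calls <- pass_calls(test_calls)
  tkey <- paste(truth$position, truth$alt)
  ckey <- paste(calls$position, calls$alt)
  called <- tkey %in% ckey
  outcome <- ifelse(truth$grade %in% c("A", "B"),
                    ifelse(called, "found", "lost"), "excluded")
  out <- data.frame(position = truth$position, alt = truth$alt,
                    grade = as.character(truth$grade), outcome = outcome,
                    vl = calls$vl[match(tkey, ckey)])
  novel <- !(ckey %in% tkey)
  if (any(novel))
    out <- rbind(out, data.frame(position = calls$position[novel],
                                 alt = calls$alt[novel], grade = "novel",
                                 outcome = "novel", vl = calls$vl[novel]))
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
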
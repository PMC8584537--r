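#' Classify a mixture variant by component interaction
#'
#' A variant in a two-haplotype mixture is classified by the presence
#' pattern across the minor and major components: present only in the
#' minor → \code{minor-derived}; only in the major → \code{major-derived};
#' in both with the same alternate base → \code{shared}; in neither
#' reference component → \code{novel}. Components carrying \emph{different}
#' alternate bases at the same position are \code{mixed-status} and are
#' excluded from metric datasets (their origin cannot be determined under
#' the SNV-only scope). When both components carry the variant, the less
#' reliable grade prevails (A < B < C on the reliability lattice): a shared
#' variant graded A in one component and C in the other is effectively
#' Grade C.
#'
#' @param minor_grade,major_grade Component grades ("A", "B", "C") or NA
#'   when the component lacks the variant.
#' @param minor_alt,major_alt Alternate bases (NA when absent); used to
#'   detect mixed-status conflicts.
#' @return List with \code{macro} (one of minor-derived, major-derived,
#'   shared, novel, mixed-status) and \code{effective_grade} ("A", "B",
#'   "C", "novel", or NA for mixed-status).
#' @export
classify_mixture_variant <- function(minor_grade, major_grade,
                                     minor_alt = NA, major_alt = NA) {
  in_minor <- !is.na(minor_grade)
  in_major <- !is.na(major_grade)
  if (in_minor && in_major && !is.na(minor_alt) && !is.na(major_alt) &&
      minor_alt != major_alt)
    return(list(macro = "mixed-status", effective_grade = NA_character_))
  if (in_minor && in_major)
    return(list(macro = "shared",
                effective_grade = worst_grade(minor_grade, major_grade)))
  if (in_minor)
    return(list(macro = "minor-derived", effective_grade = minor_grade))
  if (in_major)
    return(list(macro = "major-derived", effective_grade = major_grade))
  list(macro = "novel", effective_grade = "novel")
}

# Lower (less reliable) of two grades; A best, C worst.
worst_grade <- function(a, b) {
  order <- c(A = 1L, B = 2L, C = 3L)
  c("A", "B", "C")[max(order[[a]], order[[b]])]
}

#' Build the graded truth set of a mixture sample
#'
#' Joins the graded truths of the minor and major components on position,
#' classifies each variant (\code{\link{classify_mixture_variant}}) and
#' attaches the externally expected VL (linear mixing of the component
#' reference-run mean VLs). Mixed-status rows are flagged, not dropped, so
#' callers can report them; metric datasets exclude them.
#'
#' @param minor_truth,major_truth Graded truths from
#'   \code{\link{grade_variants}} for the two unmixed components (columns
#'   \code{position}, \code{alt}, \code{grade}, \code{mean_vl}).
#' @param m Minor fraction in (0, 1).
#' @return data.frame \code{position}, \code{alt}, \code{macro},
#'   \code{grade} (effective), \code{expected_vl}.
#' @export
mixture_truth <- function(minor_truth, major_truth, m) {
  stopifnot(m > 0, m < 1)
  j <- merge(minor_truth[c("position", "alt", "grade", "mean_vl")],
             major_truth[c("position", "alt", "grade", "mean_vl")],
             by = "position", all = TRUE, suffixes = c("_minor", "_major"))
  out <- do.call(rbind, lapply(seq_len(nrow(j)), function(i) {
    r <- j[i, ]
    cls <- classify_mixture_variant(r$grade_minor, r$grade_major,
                                    r$alt_minor, r$alt_major)
    vmin <- if (is.na(r$mean_vl_minor)) 0 else r$mean_vl_minor
    vmaj <- if (is.na(r$mean_vl_major)) 0 else r$mean_vl_major
    data.frame(position = r$position,
               alt = if (is.na(r$alt_minor)) r$alt_major else r$alt_minor,
               macro = cls$macro, grade = cls$effective_grade,
               expected_vl = expected_vl(vmin, vmaj, m))
  }))
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected variant level in a mixture
#'
#' Ideal linear mixing: \code{m * minor_vl + (1 - m) * major_vl}. In the
#' \emph{external} comparison the component VLs are the reference-run
#' (cross-platform) mean VLs; in the \emph{internal} comparison they are
#' the VLs observed in the unmixed test-platform (primary) runs, which must
#' then be supplied.
#'
#' @param minor_vl,major_vl Component VLs (external mode); a component
#'   lacking the variant contributes 0.
#' @param m Minor fraction in (0, 1).
#' @param mode \code{"external"} (default) or \code{"internal"}.
#' @param primary_minor_vl,primary_major_vl Unmixed test-run VLs, required
#'   for internal mode.
#' @return Expected VL fraction(s).
#' @export
expected_vl <- function(minor_vl, major_vl, m,
                        mode = c("external", "internal"),
                        primary_minor_vl = NULL, primary_major_vl = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(m > 0 & m < 1))
  if (mode == "internal") {
    if (is.null(primary_minor_vl) || is.null(primary_major_vl))
      stop("internal comparison requires the unmixed test-run VLs")
    minor_vl <- primary_minor_vl
    major_vl <- primary_major_vl
  }
  m * minor_vl + (1 - m) * major_vl
}

#' Raw and relative VL differences
#'
#' The raw difference is observed minus expected; the relative difference
#' divides by the expected level, giving a percent variance per VL. A lost
#' variant (observed 0) has relative difference -1. Relative differences
#' are undefined (NA) when the expected level is 0.
#'
#' @param observed,expected VL fractions.
#' @return data.frame \code{raw}, \code{relative}.
#' @export
vl_differences <- function(observed, expected) {
  raw <- observed - expected
  relative <- ifelse(expected > 0, raw / expected, NA_real_)
  if (any(expected <= 0))
    warning("relative difference undefined where expected VL is 0")
  data.frame(raw = raw, relative = relative)
}

#' Correlation-strength indicator over expected/observed VL pairs
#'
#' Per group (typically one model per mixture x comparison x grade), an
#' ordinary least-squares fit of observed on expected VL is summarized by
#' its adjusted R-squared and model p-value; p-values are
#' Benjamini-Hochberg adjusted across all models of the batch, and the
#' indicator is \code{log10(adj_r2 / adj_p)} — larger means stronger
#' correlation. Degenerate groups (fewer than 3 pairs, or constant
#' expected VL) are flagged with NA.
#'
#' @param data data.frame with columns \code{expected}, \code{observed} and
#'   any grouping columns named in \code{by}.
#' @param by Character vector of grouping column names (default none: one
#'   model).
#' @return data.frame with one row per group: grouping columns,
#'   \code{n}, \code{adj_r2}, \code{p}, \code{adj_p}, \code{indicator}.
#' @export
correlation_indicator <- function(data, by = character(0)) {
  stopifnot(all(c("expected", "observed") %in% names(data)),
            all(by %in% names(data)))
  groups <- if (length(by)) split(data, data[by], drop = TRUE) else
    list(all = data)
  rows <- lapply(groups, function(g) {
    meta <- if (length(by)) g[1, by, drop = FALSE] else
      data.frame(row.names = 1)
    res <- data.frame(meta, n = nrow(g), adj_r2 = NA_real_, p = NA_real_,
                      adj_p = NA_real_, indicator = NA_real_,
                      row.names = NULL)
    if (nrow(g) < 3L || stats::var(g$expected) == 0) return(res)
    fit <- stats::lm(observed ~ expected, data = g)
    s <- summary(fit)
    res$adj_r2 <- s$adj.r.squared
    res$p <- stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                       lower.tail = FALSE)
    res
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  ok <- !is.na(out$adj_p) & !is.na(out$adj_r2) & out$adj_r2 > 0 &
    out$adj_p > 0
  out$indicator[ok] <- log10(out$adj_r2[ok] / out$adj_p[ok])
  rownames(out) <- NULL
  out
}
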
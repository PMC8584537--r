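#' Haplotype truth object
#'
#' A haplotype is a set of single-nucleotide differences from the canonical
#' reference, each with a true variant level (VL): 1.0 for homoplasmic
#' sites, a fraction in (0, 1) for intra-sample heteroplasmy.
#'
#' @param id Short identifier (e.g. "H", "T", "U").
#' @param variants data.frame with columns \code{position}, \code{alt} and
#'   \code{vl} (fractions in (0, 1]).
#' @return Object of class \code{haplotype}.
#' @export
haplotype <- function(id, variants) {
  stopifnot(is.data.frame(variants),
            all(c("position", "alt", "vl") %in% names(variants)))
  variants$position <- as.integer(variants$position)
  if (any(variants$vl <= 0 | variants$vl > 1))
    stop("haplotype VLs must lie in (0, 1]")
  if (anyDuplicated(variants$position))
    stop("one variant per position per haplotype")
  variants <- variants[order(variants$position), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(id = id, variants = variants), class = "haplotype")
}

#' @export
print.haplotype <- function(x, ...) {
  n_hom <- sum(x$variants$vl >= 0.95)
  cat("<haplotype> ", x$id, ": ", nrow(x$variants), " variants (",
      n_hom, " homoplasmic)\n", sep = "")
  invisible(x)
}

transition_of <- function(base) {
  c(A = "G", G = "A", C = "T", T = "C", N = "N")[base]
}

random_alt <- function(ref_base) {
  vapply(ref_base, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Generate three synthetic haplotypes
#'
#' Stand-in for three real samples sequenced on independent platforms: each
#' haplotype carries private homoplasmic variants, a few heteroplasmic ones,
#' and all three share a set of common homoplasmic sites (emulating shared
#' phylogeny). Blacklisted positions are never used.
#'
#' @param ref A \code{circular_reference}.
#' @param seed Integer seed.
#' @param ids Haplotype identifiers, default \code{c("H","T","U")}.
#' @param n_hom,n_het Private homoplasmic / heteroplasmic variants per
#'   haplotype (defaults 30 and 5).
#' @param n_shared Homoplasmic variants shared by all haplotypes (default 10).
#' @param blacklist A \code{position_blacklist}.
#' @return Named list of \code{haplotype} objects.
#' @export
synthetic_haplotypes <- function(ref, seed = 1L, ids = c("H", "T", "U"),
                                 n_hom = 30L, n_het = 5L, n_shared = 10L,
                                 blacklist = position_blacklist()) {
  stopifnot(inherits(ref, "circular_reference"))
  with_local_seed(seed, {
    usable <- setdiff(seq_len(ref$length), blacklist_positions(blacklist))
    n_each <- n_hom + n_het
    total <- n_shared + length(ids) * n_each
    pos <- sample(usable, total)
    shared_pos <- sort(pos[seq_len(n_shared)])
    shared_alt <- random_alt(ref_base_at(ref, shared_pos))
    rest <- pos[-seq_len(n_shared)]
    haps <- list()
    for (k in seq_along(ids)) {
      own <- sort(rest[((k - 1L) * n_each + 1L):(k * n_each)])
      alt <- random_alt(ref_base_at(ref, own))
      vl <- sample(c(rep(1, n_hom),
                     round(stats::runif(n_het, 0.10, 0.90), 3)))
      haps[[ids[k]]] <- haplotype(ids[k], data.frame(
        position = c(shared_pos, own),
        alt = c(shared_alt, alt),
        vl = c(rep(1, n_shared), vl)))
    }
    haps
  })
}

#' Default mixture design
#'
#' Three ordered haplotype pairs, each mixed at five minor fractions
#' (1, 2, 5, 10 and 25%), giving 15 mixtures. Names follow the convention
#' minor id + fraction with leading zero + major id, e.g. \code{"U0.01H"}
#' is haplotype U at 1% mixed with H at 99%.
#'
#' @param ids Three haplotype identifiers in design order; pairs are
#'   (1st minor, 2nd major), (2nd, 3rd), (3rd, 1st).
#' @param fractions Minor fractions, default \code{c(.01,.02,.05,.10,.25)}.
#' @return data.frame with columns \code{minor}, \code{major},
#'   \code{fraction}, \code{name}; fractions ascending within each pair.
#' @export
default_design <- function(ids = c("H", "T", "U"),
                           fractions = c(0.01, 0.02, 0.05, 0.10, 0.25)) {
  stopifnot(length(ids) == 3L, all(fractions > 0 & fractions <= 0.5),
            !is.unsorted(fractions))
  pairs <- data.frame(minor = ids, major = ids[c(2L, 3L, 1L)])
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    data.frame(minor = pairs$minor[i], major = pairs$major[i],
               fraction = fractions)))
  frac_lab <- vapply(out$fraction, function(f)
    format(f, trim = TRUE, drop0trailing = TRUE), character(1))
  out$name <- paste0(out$minor, frac_lab, out$major)
  rownames(out) <- NULL
  out
}

#' Expected variant levels of a two-haplotype mixture
#'
#' Ideal linear mixing: at each position the expected VL is
#' \code{m * VL_minor + (1 - m) * VL_major}, where a haplotype lacking the
#' variant contributes 0. Positions where the two haplotypes carry
#' different alternate bases are multi-allelic under the SNV-only scope and
#' are excluded from the truth with a warning.
#'
#' @param minor,major \code{haplotype} objects.
#' @param m Minor fraction in (0, 1).
#' @param ref A \code{circular_reference} (supplies the reference base).
#' @return data.frame \code{position}, \code{ref}, \code{alt},
#'   \code{expected_vl}; rows with expected VL 0 are omitted.
#' @export
mix_truth <- function(minor, major, m, ref) {
  stopifnot(inherits(minor, "haplotype"), inherits(major, "haplotype"),
            m > 0, m < 1)
  a <- minor$variants; b <- major$variants
  both <- merge(a, b, by = "position", all = TRUE,
                suffixes = c("_minor", "_major"))
  conflict <- !is.na(both$alt_minor) & !is.na(both$alt_major) &
    both$alt_minor != both$alt_major
  if (any(conflict)) {
    warning(sum(conflict), " multi-allelic position(s) excluded from truth")
    both <- both[!conflict, , drop = FALSE]
  }
  vl_minor <- ifelse(is.na(both$vl_minor), 0, both$vl_minor)
  vl_major <- ifelse(is.na(both$vl_major), 0, both$vl_major)
  evl <- m * vl_minor + (1 - m) * vl_major
  alt <- ifelse(is.na(both$alt_minor), both$alt_major, both$alt_minor)
  keep <- evl > 0
  data.frame(position = both$position[keep],
             ref = ref_base_at(ref, both$position[keep]),
             alt = alt[keep],
             expected_vl = evl[keep])
}

#' Simulate strand-split per-site base counts
#'
#' Emulates amplicon sequencing of a sample with known per-position expected
#' VLs: each amplicon receives a log-normal depth factor (coverage
#' heterogeneity), per-position depth is Poisson around the amplicon mean,
#' the alternate-base count is binomial with success probability
#' \code{VL*(1-err) + err/3}, the two remaining non-reference bases each
#' receive background errors at rate \code{err/3}, and every base count is
#' split between strands as Binomial(n, 0.5). Deterministic for a fixed
#' seed.
#'
#' @param truth Expected-VL truth (from \code{\link{mix_truth}}), or an
#'   empty/NULL truth for a variant-free sample.
#' @param panel An \code{amplicon_panel} covering the genome.
#' @param ref A \code{circular_reference}.
#' @param depth Mean depth (reads/bp), default 5000.
#' @param err Per-base substitution error rate, default 0.001.
#' @param seed Integer seed.
#' @param sigma_amplicon SD of the per-amplicon log-normal factor (0.3).
#' @return A \code{site_counts} data.frame: \code{position}, \code{ref},
#'   \code{fwd_A..fwd_T}, \code{rev_A..rev_T}, \code{depth}.
#' @export
simulate_counts <- function(truth, panel, ref, depth = 5000, err = 0.001,
                            seed = 1L, sigma_amplicon = 0.3) {
  stopifnot(inherits(panel, "amplicon_panel"),
            inherits(ref, "circular_reference"),
            depth > 0, err >= 0, err < 0.25)
  L <- ref$length
  bases <- c("A", "C", "G", "T")
  refb <- strsplit(ref$sequence, "")[[1]]
  vl <- numeric(L)
  altb <- rep(NA_character_, L)
  if (!is.null(truth) && nrow(truth)) {
    vl[truth$position] <- truth$expected_vl
    altb[truth$position] <- truth$alt
  }
  with_local_seed(seed, {
    amp_of <- position_amplicon(panel)
    fac <- stats::rlnorm(nrow(panel$amplicons),
                         meanlog = -sigma_amplicon^2 / 2,
                         sdlog = sigma_amplicon)
    site_depth <- stats::rpois(L, depth * fac[amp_of])
    counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, bases))
    # alt counts at truth sites
    has_alt <- !is.na(altb)
    n_alt <- integer(L)
    n_alt[has_alt] <- stats::rbinom(sum(has_alt), site_depth[has_alt],
                                    vl[has_alt] * (1 - err) + err / 3)
    # background errors on remaining depth for the other non-ref bases
    for (b in bases) {
      is_err <- refb != b & (!has_alt | altb != b) & refb != "N"
      n_err <- integer(L)
      if (err > 0 && any(is_err))
        n_err[is_err] <- stats::rbinom(sum(is_err), site_depth[is_err],
                                       err / 3)
      tot <- n_err
      tot[has_alt & altb == b] <- n_alt[has_alt & altb == b]
      counts[, b] <- counts[, b] + tot
    }
    nonref <- pmin(rowSums(counts), site_depth)
    not_n <- refb != "N"
    counts[cbind(which(not_n), match(refb[not_n], bases))] <-
      site_depth[not_n] - nonref[not_n]
    fwd <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, bases))
    for (b in bases) fwd[, b] <- stats::rbinom(L, counts[, b], 0.5)
    rev <- counts - fwd
    out <- data.frame(position = seq_len(L), ref = refb)
    for (b in bases) out[[paste0("fwd_", b)]] <- fwd[, b]
    for (b in bases) out[[paste0("rev_", b)]] <- rev[, b]
    out$depth <- as.integer(rowSums(counts))
    class(out) <- c("site_counts", "data.frame")
    out
  })
}

#' Inject NUMT-like contaminating signal
#'
#' Adds alternate-base counts at the given positions so that the resulting
#' alternate fraction approximates \code{level}, with a skewed strand split
#' (default 90% forward) reproducing the strand-bias signature of
#' co-amplified nuclear copies of mtDNA.
#'
#' @param counts A \code{site_counts} data.frame.
#' @param positions Canonical positions to contaminate.
#' @param level Target alternate fraction in (0, 0.5); 0 is a no-op.
#' @param strand_skew Forward-strand proportion of injected reads (0.9).
#' @param alt Optional alternate bases (recycled); default the transition
#'   of the reference base, the dominant artifact class.
#' @param seed Integer seed.
#' @return The modified \code{site_counts}.
#' @export
inject_numt_signal <- function(counts, positions, level = 0.03,
                               strand_skew = 0.9, alt = NULL, seed = 1L) {
  stopifnot(inherits(counts, "site_counts"), level >= 0, level < 0.5)
  if (level == 0 || length(positions) == 0L) return(counts)
  positions <- as.integer(positions)
  idx <- match(positions, counts$position)
  if (anyNA(idx)) stop("positions absent from counts")
  refb <- counts$ref[idx]
  if (is.null(alt)) alt <- unname(transition_of(refb))
  alt <- rep_len(alt, length(idx))
  with_local_seed(seed, {
    dep <- counts$depth[idx]
    n_add <- round(level * dep / (1 - level))
    n_fwd <- stats::rbinom(length(idx), n_add, strand_skew)
    n_rev <- n_add - n_fwd
    for (k in seq_along(idx)) {
      i <- idx[k]
      counts[[paste0("fwd_", alt[k])]][i] <-
        counts[[paste0("fwd_", alt[k])]][i] + n_fwd[k]
      counts[[paste0("rev_", alt[k])]][i] <-
        counts[[paste0("rev_", alt[k])]][i] + n_rev[k]
      counts$depth[i] <- counts$depth[i] + n_add[k]
    }
    counts
  })
}

#' Read / write site counts as TSV
#'
#' Plain tab-separated interchange: position, ref, forward and reverse
#' counts per base, depth.
#'
#' @param counts A \code{site_counts}.
#' @param path File path.
#' @return \code{read_counts_tsv}: a \code{site_counts}.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  class(out) <- c("site_counts", "data.frame")
  out
}
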
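#' End-to-end synthetic mixture benchmark
#'
#' Runs the whole evaluation on synthetic data: builds a circular
#' reference, an amplicon panel and three haplotypes; grades each
#' haplotype's variants against emulated reference runs (exome, lowCov,
#' highCov all observing the true VLs); simulates strand-split counts for
#' the three unmixed (primary) samples and for every mixture of the
#' design; sweeps the threshold grid; classifies calls against the graded
#' truths; and aggregates confusion metrics for the four datasets
#' (primary/mixture x Grade A/B) at every threshold, returning the
#' F1-optimal threshold.
#'
#' Novel calls carry no grade, so each dataset's false positives are all
#' novel calls of its samples; true positives and false negatives are
#' restricted to the dataset's grade.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param design Mixture design (default \code{\link{default_design}}).
#' @param n_amplicons Panel size (162).
#' @param genome_len Canonical genome length (16,569).
#' @param n_hom,n_het,n_shared Haplotype generator sizes (see
#'   \code{\link{synthetic_haplotypes}}).
#' @param numt_positions Optional canonical positions at which NUMT-like
#'   noise is injected into every simulated sample.
#' @param numt_level Injected alternate fraction (0 disables).
#' @param numt_strand_skew Forward-strand share of injected reads (0.9).
#' @return List: \code{reference}, \code{panel}, \code{haplotypes},
#'   \code{primary_truth} (per-haplotype graded truths),
#'   \code{mixture_truths}, \code{callsets} (per sample, at the default
#'   threshold), \code{reports} (dataset x threshold metric rows),
#'   \code{optimum} (from \code{\link{optimize_threshold}}).
#' @export
run_mixture_benchmark <- function(config = pipeline_config(),
                                  design = default_design(),
                                  n_amplicons = 162L, genome_len = 16569L,
                                  n_hom = 30L, n_het = 5L, n_shared = 10L,
                                  numt_positions = NULL, numt_level = 0,
                                  numt_strand_skew = 0.9) {
  seed <- config$seed
  ref <- random_reference(genome_len, seed = seed)
  panel <- build_synthetic_panel(genome_len, n_amplicons, seed = seed + 1L)
  haps <- synthetic_haplotypes(ref, seed = seed + 2L, n_hom = n_hom,
                               n_het = n_het, n_shared = n_shared,
                               blacklist = config$blacklist)
  # emulated reference runs: all three platforms observe the true VLs
  primary_truth <- lapply(haps, function(h) {
    obs <- do.call(rbind, lapply(c("exome", "lowCov", "highCov"),
      function(r) data.frame(run = r, h$variants[c("position", "alt", "vl")])))
    grade_variants(obs, hom_bound = config$hom_grade_bound)
  })

  simulate_sample <- function(truth, sample_seed) {
    cnt <- simulate_counts(truth, panel, ref, depth = config$depth,
                           err = config$err, seed = sample_seed)
    if (numt_level > 0 && length(numt_positions))
      cnt <- inject_numt_signal(cnt, numt_positions, level = numt_level,
                                strand_skew = numt_strand_skew,
                                seed = sample_seed + 500000L)
    cnt
  }

  samples <- list()   # per sample: truth (graded), counts, kind
  for (k in seq_along(haps)) {
    h <- haps[[k]]
    truth_vl <- data.frame(position = h$variants$position,
                           ref = ref_base_at(ref, h$variants$position),
                           alt = h$variants$alt,
                           expected_vl = h$variants$vl)
    samples[[h$id]] <- list(
      kind = "primary", name = h$id,
      truth = primary_truth[[h$id]],
      counts = simulate_sample(truth_vl, seed + 10L + k))
  }
  mixture_truths <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    tr <- mix_truth(haps[[d$minor]], haps[[d$major]], d$fraction, ref)
    mt <- mixture_truth(primary_truth[[d$minor]], primary_truth[[d$major]],
                        d$fraction)
    mt <- mt[mt$macro != "mixed-status", , drop = FALSE]
    mixture_truths[[d$name]] <- mt
    samples[[d$name]] <- list(
      kind = "mixture", name = d$name, truth = mt,
      counts = simulate_sample(tr, seed + 100L + i))
  }

  grid <- config$threshold_grid
  sweeps <- lapply(samples, function(s)
    sweep_thresholds(s$counts, grid, blacklist = config$blacklist,
                     min_per_strand = config$min_per_strand))
  reports <- list()
  for (t_idx in seq_along(grid)) {
    ledgers <- list(`primary-A` = list(), `primary-B` = list(),
                    `mixture-A` = list(), `mixture-B` = list())
    for (s in samples) {
      out <- classify_test_calls(s$truth, sweeps[[s$name]][[t_idx]])
      for (g in c("A", "B")) {
        ds <- paste0(s$kind, "-", g)
        keep <- (out$grade == g & out$outcome %in% c("found", "lost")) |
          out$outcome == "novel"
        ledgers[[ds]] <- c(ledgers[[ds]], list(out[keep, , drop = FALSE]))
      }
    }
    for (ds in names(ledgers)) {
      led <- do.call(rbind, ledgers[[ds]])
      reports[[length(reports) + 1L]] <- compute_metrics(
        led, genome_len = genome_len, blacklist = config$blacklist,
        dataset = ds, threshold = grid[t_idx])
    }
  }
  reports <- do.call(rbind, reports)
  optimum <- optimize_threshold(reports)
  t_def <- which.min(abs(grid - config$heteroplasmy_threshold))
  callsets <- lapply(sweeps, function(sw) sw[[t_def]])
  list(reference = ref, panel = panel, haplotypes = haps,
       primary_truth = primary_truth, mixture_truths = mixture_truths,
       callsets = callsets, reports = reports, optimum = optimum,
       config = config, design = design)
}
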
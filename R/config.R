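#' Pipeline configuration
#'
#' Bundles every tunable of the benchmarking pipeline with its default:
#' the heteroplasmy calling threshold (2.5%), the 21-value threshold grid,
#' the 160-bp read crop, the minimum base quality (20, applied at pileup
#' construction), the grading homoplasmy bound (95%), the genotype-export
#' homoplasmy bound (90%), the position blacklist, the extended-reference
#' duplication length (80) and the simulation seed. Round-trips losslessly
#' through YAML.
#'
#' @param heteroplasmy_threshold Calling threshold fraction (0.025).
#' @param threshold_grid Sweep grid (\code{\link{default_threshold_grid}}).
#' @param crop_len Read crop length in bp (160).
#' @param base_quality_min Minimum base quality (20).
#' @param hom_grade_bound Grading homoplasmy bound (0.95).
#' @param hom_gt_bound Genotype-export homoplasmy bound (0.90).
#' @param blacklist_ranges Blacklist intervals (list of c(start, end)).
#' @param dup_len Extended-reference duplication length (80).
#' @param seed Integer seed.
#' @param min_per_strand Strand-support minimum (1).
#' @param depth Simulation mean depth (5000).
#' @param err Simulation error rate (0.001).
#' @return Object of class \code{pipeline_config} (a named list).
#' @export
pipeline_config <- function(heteroplasmy_threshold = 0.025,
                            threshold_grid = default_threshold_grid(),
                            crop_len = 160L, base_quality_min = 20L,
                            hom_grade_bound = 0.95, hom_gt_bound = 0.90,
                            blacklist_ranges = NULL, dup_len = 80L,
                            seed = 1L, min_per_strand = 1L,
                            depth = 5000, err = 0.001) {
  bl <- position_blacklist(if (is.null(blacklist_ranges)) NULL else
    do.call(rbind, blacklist_ranges))
  structure(list(
    heteroplasmy_threshold = heteroplasmy_threshold,
    threshold_grid = threshold_grid, crop_len = as.integer(crop_len),
    base_quality_min = as.integer(base_quality_min),
    hom_grade_bound = hom_grade_bound, hom_gt_bound = hom_gt_bound,
    blacklist = bl, dup_len = as.integer(dup_len), seed = as.integer(seed),
    min_per_strand = as.integer(min_per_strand), depth = depth, err = err),
    class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  heteroplasmy threshold:", x$heteroplasmy_threshold, "\n")
  cat("  grid:", length(x$threshold_grid), "values in [",
      min(x$threshold_grid), ",", max(x$threshold_grid), "]\n")
  cat("  crop:", x$crop_len, "bp; BQ >=", x$base_quality_min,
      "; strands >=", x$min_per_strand, "\n")
  cat("  homoplasmy bounds: grade", x$hom_grade_bound, "/ GT",
      x$hom_gt_bound, "\n")
  cat("  dup_len:", x$dup_len, "; seed:", x$seed, "; depth:", x$depth,
      "; err:", x$err, "\n")
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A \code{pipeline_config}.
#' @param path YAML file path.
#' @return \code{read_config}: a \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$blacklist <- lapply(seq_len(nrow(config$blacklist$ranges)), function(i)
    as.integer(config$blacklist$ranges[i, ]))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  pipeline_config(
    heteroplasmy_threshold = lst$heteroplasmy_threshold,
    threshold_grid = as.numeric(lst$threshold_grid),
    crop_len = lst$crop_len, base_quality_min = lst$base_quality_min,
    hom_grade_bound = lst$hom_grade_bound, hom_gt_bound = lst$hom_gt_bound,
    blacklist_ranges = lst$blacklist, dup_len = lst$dup_len,
    seed = lst$seed, min_per_strand = lst$min_per_strand,
    depth = lst$depth, err = lst$err)
}
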
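## Run configuration, stable per-stage seed derivation, and the umbrella
## pipeline binding the three analyses (region outlier scan, iHS network
## test, ancient heterozygosity).

#' Build and validate a pipeline run configuration
#'
#' Defaults are the full-scale analysis constants: 99% genome-wide
#' threshold with up to 2,200,000 sampled SNPs, region flag level 1%,
#' 11,000 random 50-kb windows, per-region significance 0.05, 100,000
#' random iHS networks at 2-Mb spacing, and 500 x 2,500 heterozygosity
#' resampling. Reduce the replicate counts for desk-scale runs.
#'
#' @param vcf,sample_map,loci_bed,ihs_bedgraph,ancient_tsv Input paths
#'   (any may be `NULL`; stages lacking inputs are skipped).
#' @param comparisons Named list of two-element lists, each holding the
#'   two group selectors of one FST comparison, e.g.
#'   `list(EUR_EAS = list("EUR", "EAS"))`.
#' @param out_dir Output directory (created if absent).
#' @param q Threshold quantile (default 0.99).
#' @param flag_level Region flag level (default 0.01).
#' @param alpha Per-region significance level (default 0.05).
#' @param threshold_sample SNP subsample size for the threshold (default
#'   2,200,000).
#' @param n_random_regions Random windows per comparison (default 11,000).
#' @param n_random_networks Random iHS networks (default 100,000).
#' @param genotype_reps,read_reps Heterozygosity resampling depth
#'   (defaults 500 and 2,500).
#' @param window Analysis window width in bases (default 50,000).
#' @param min_spacing Same-chromosome spacing for random networks
#'   (default 2 Mb).
#' @param min_gap Locus-clustering gap (default 2 Mb).
#' @param collapse_clusters Collapse clustered loci in the iHS test.
#' @param signed_ihs Use signed instead of absolute iHS maxima.
#' @param seed Master seed; per-stage seeds are derived from it (see
#'   [derive_seed()]).
#' @return A validated `run_config` list.
#' @export
run_config <- function(vcf = NULL, sample_map = NULL, loci_bed = NULL,
                       ihs_bedgraph = NULL, ancient_tsv = NULL,
                       comparisons = list(), out_dir = tempfile("netsel_"),
                       q = 0.99, flag_level = 0.01, alpha = 0.05,
                       threshold_sample = 2200000,
                       n_random_regions = 11000,
                       n_random_networks = 100000,
                       genotype_reps = 500, read_reps = 2500,
                       window = 50000, min_spacing = 2e6, min_gap = 2e6,
                       collapse_clusters = FALSE, signed_ihs = FALSE,
                       seed = 1) {
  cfg <- list(vcf = vcf, sample_map = sample_map, loci_bed = loci_bed,
              ihs_bedgraph = ihs_bedgraph, ancient_tsv = ancient_tsv,
              comparisons = comparisons, out_dir = out_dir, q = q,
              flag_level = flag_level, alpha = alpha,
              threshold_sample = threshold_sample,
              n_random_regions = n_random_regions,
              n_random_networks = n_random_networks,
              genotype_reps = genotype_reps, read_reps = read_reps,
              window = window, min_spacing = min_spacing,
              min_gap = min_gap, collapse_clusters = collapse_clusters,
              signed_ihs = signed_ihs, seed = seed)
  counts <- c("threshold_sample", "n_random_regions", "n_random_networks",
              "genotype_reps", "read_reps", "window", "min_spacing",
              "min_gap")
  for (nm in counts)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(nm, " must be positive")
  for (nm in c("q", "alpha", "flag_level"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop(nm, " must lie in (0, 1)")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop("seed must be a single number")
  structure(cfg, class = "run_config")
}

#' Stable per-stage seed derivation
#'
#' Maps the master seed and a stage label to a deterministic 31-bit
#' integer seed via fixed integer offsets (no hashing), so any stage can
#' be re-run independently yet reproducibly.
#'
#' @param master Master seed (integer).
#' @param stage One of `"simulate"`, `"threshold"`, `"regions"`, `"ihs"`,
#'   `"ancient"`, or a comparison-qualified stage like `"regions:EUR_EAS"`
#'   (the comparison index is supplied via `index`).
#' @param index Optional non-negative integer distinguishing repeats of a
#'   stage (e.g. comparison number).
#' @return Integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  offsets <- c(simulate = 11L, threshold = 23L, regions = 37L,
               ihs = 53L, ancient = 67L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(master) + offsets[[stage]] * 1000003 +
                as.numeric(index) * 7919) %% 2147483647)
}

#' Run the configured analyses end to end
#'
#' Executes whichever stages the configuration provides inputs for:
#' FST scan + region outlier test per comparison (needs `vcf`,
#' `sample_map`, `loci_bed`, `comparisons`), the iHS network
#' randomization test (needs `ihs_bedgraph`, `loci_bed`), and the ancient
#' heterozygosity analysis (needs `ancient_tsv`; panel distributions are
#' added when a VCF panel is loaded). All result tables are written under
#' `out_dir`, every stage uses a seed derived from the master seed, and a
#' run summary JSON records seeds, skip counts and headline statistics.
#' The same configuration and seed reproduce byte-identical tables.
#'
#' @param config A [run_config()].
#' @return Result bundle: list with `regions`, `comparisons` (per
#'   comparison: threshold, scores, network test), `ihs`, `ancient`,
#'   `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) file.path(config$out_dir, name)
  bundle <- list(files = character(0))
  summary <- list(seed = config$seed)

  panel <- NULL
  if (!is.null(config$vcf)) {
    panel <- tryCatch(
      read_panel(config$vcf, config$sample_map),
      error = function(e) stop("[panel] ", conditionMessage(e),
                               call. = FALSE))
  }

  regions <- NULL
  if (!is.null(config$loci_bed)) {
    loci <- read_bed(config$loci_bed)
    loci <- cluster_loci(loci, min_gap = config$min_gap)
    regions <- tryCatch(
      build_windows(loci, window = config$window),
      error = function(e) stop("[regions] ", conditionMessage(e),
                               call. = FALSE))
    regions$cluster_id <-
      loci$cluster_id[match(regions$source_locus,
                            loci$name %||%
                              sprintf("locus_%d", seq_len(nrow(loci))))]
    write_bed(regions, out("analysis_windows.bed"))
    files <- c(files, out("analysis_windows.bed"))
    bundle$regions <- regions
  }

  if (!is.null(panel) && !is.null(regions) &&
      length(config$comparisons) > 0L) {
    bundle$comparisons <- list()
    for (i in seq_along(config$comparisons)) {
      cmp <- config$comparisons[[i]]
      label <- names(config$comparisons)[i] %||% paste0("cmp", i)
      res <- tryCatch({
        scan <- pairwise_scan(panel, cmp[[1]], cmp[[2]])
        thr <- genome_threshold(scan, q = config$q,
                                n_sample = config$threshold_sample,
                                seed = derive_seed(config$seed,
                                                   "threshold", i))
        scores <- region_fraction(regions, scan, thr,
                                  flag_level = config$flag_level)
        scores <- empirical_p(scores, scan, thr,
                              n_random = config$n_random_regions,
                              window = config$window,
                              seed = derive_seed(config$seed,
                                                 "regions", i))
        net <- network_test(scores, alpha = config$alpha)
        write_fst_tsv(scan, out(sprintf("fst_%s.tsv", label)))
        write_region_scores(scores,
                            out(sprintf("region_scores_%s.tsv", label)))
        list(threshold = thr, scores = scores, network = net,
             skip_log = attr(scan, "skip_log"))
      }, error = function(e) stop("[fst:", label, "] ",
                                  conditionMessage(e), call. = FALSE))
      files <- c(files, out(sprintf("fst_%s.tsv", label)),
                 out(sprintf("region_scores_%s.tsv", label)))
      bundle$comparisons[[label]] <- res
      summary[[paste0("network_P_", label)]] <- res$network$network_P
    }
  }

  if (!is.null(config$ihs_bedgraph) && !is.null(regions)) {
    track <- read_bedgraph(config$ihs_bedgraph)
    bundle$ihs <- tryCatch(
      randomization_p(regions, track,
                      n_random = config$n_random_networks,
                      window = config$window,
                      min_spacing = config$min_spacing,
                      signed = config$signed_ihs,
                      collapse_clusters = config$collapse_clusters,
                      seed = derive_seed(config$seed, "ihs")),
      error = function(e) stop("[ihs] ", conditionMessage(e),
                               call. = FALSE))
    maxima <- data.frame(regions[, c("chrom", "start", "end")],
                         max_ihs = region_max_ihs(regions, track,
                                                  signed = config$signed_ihs))
    write.table(maxima, out("ihs_region_maxima.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, out("ihs_region_maxima.tsv"))
    summary$ihs_p <- bundle$ihs$p_value
    summary$ihs_observed_mean <- bundle$ihs$observed_mean
  }

  if (!is.null(config$ancient_tsv)) {
    ancient <- read_ancient_sites(config$ancient_tsv)
    groups <- if (!is.null(panel)) unique(panel$samples$continent)
    bundle$ancient <- tryCatch(
      ancient_het_test(ancient, panel = panel, groups = groups,
                       n_genotype_reps = config$genotype_reps,
                       n_read_reps = config$read_reps,
                       seed = derive_seed(config$seed, "ancient")),
      error = function(e) stop("[ancient] ", conditionMessage(e),
                               call. = FALSE))
    write.table(bundle$ancient$summary, out("ancient_het_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, out("ancient_het_summary.tsv"))
    summary$ancient_observed_het <- bundle$ancient$observed
  }

  jsonlite::write_json(summary, out("run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle$files <- c(files, out("run_summary.json"))
  bundle$summary <- summary
  invisible(bundle)
}
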
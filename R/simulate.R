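## Synthetic data with known ground truth: Balding-Nichols genotype panels,
## iHS-like score tracks, and Poisson-coverage read pileups.

#' Describe one simulated population sample
#'
#' @param name Population label (e.g. `"POP1"`).
#' @param n_individuals Number of diploid individuals sampled (>= 1).
#' @param divergence_F Balding-Nichols drift parameter in `[0, 1)`. Each
#'   SNP's population allele frequency is drawn from a Beta distribution
#'   with mean equal to the ancestral frequency `p` and variance
#'   `F * p * (1 - p)`; `F = 0` means the population frequency equals `p`
#'   exactly.
#' @param continent Continental label used for pooled between-continent
#'   comparisons.
#' @return An object of class `pop_spec`.
#' @seealso [simulate_panel()]
#' @export
pop_spec <- function(name, n_individuals, divergence_F, continent = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L)
    stop("n_individuals must be a positive integer")
  if (!is.numeric(divergence_F) || length(divergence_F) != 1L ||
      is.na(divergence_F) || divergence_F < 0 || divergence_F >= 1)
    stop("divergence_F must lie in [0, 1)")
  structure(list(name = name, continent = continent,
                 n_individuals = n_individuals,
                 divergence_F = divergence_F),
            class = "pop_spec")
}

#' Describe a planted selection signal
#'
#' A sweep region either elevates the Balding-Nichols drift parameter for
#' SNPs falling inside it (`effect = "fst_shift"`, producing excess
#' allele-frequency differentiation) or adds a constant offset to iHS-like
#' scores inside it (`effect = "ihs_shift"`). Coordinates are 0-based,
#' half-open, the same convention as all regions in this package.
#'
#' @param chrom Chromosome label.
#' @param start,end Interval bounds (0-based, half-open; `end > start`).
#' @param effect `"fst_shift"` or `"ihs_shift"`.
#' @param divergence_F Elevated drift parameter (required for
#'   `"fst_shift"`); must exceed the background `divergence_F` of every
#'   population in the panel it is applied to.
#' @param offset Positive mean shift added to scores (required for
#'   `"ihs_shift"`).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(chrom, start, end,
                       effect = c("fst_shift", "ihs_shift"),
                       divergence_F = NULL, offset = NULL) {
  effect <- match.arg(effect)
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  if (!is.numeric(start) || !is.numeric(end) || start < 0 || end <= start)
    stop("sweep interval must satisfy 0 <= start < end")
  if (effect == "fst_shift") {
    if (is.null(divergence_F) || divergence_F <= 0 || divergence_F >= 1)
      stop("fst_shift sweeps need divergence_F in (0, 1)")
  } else {
    if (is.null(offset) || !is.numeric(offset) || offset <= 0)
      stop("ihs_shift sweeps need a positive offset")
  }
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 effect = effect, divergence_F = divergence_F,
                 offset = offset),
            class = "sweep_spec")
}

## Sweep list -> data.frame; checks effect type and same-chromosome overlap.
sweep_table <- function(sweeps, effect) {
  if (length(sweeps) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), divergence_F = numeric(),
                      offset = numeric()))
  stopifnot(all(vapply(sweeps, inherits, logical(1), "sweep_spec")))
  sweeps <- Filter(function(s) s$effect == effect, sweeps)
  df <- data.frame(chrom = vapply(sweeps, `[[`, character(1), "chrom"),
                   start = vapply(sweeps, `[[`, numeric(1), "start"),
                   end = vapply(sweeps, `[[`, numeric(1), "end"),
                   divergence_F = vapply(sweeps, function(s)
                     s$divergence_F %||% NA_real_, numeric(1)),
                   offset = vapply(sweeps, function(s)
                     s$offset %||% NA_real_, numeric(1)))
  if (nrow(df) > 1L) {
    o <- order(df$chrom, df$start)
    so <- df[o, ]
    same <- so$chrom[-1L] == so$chrom[-nrow(so)]
    if (any(same & so$start[-1L] < so$end[-nrow(so)]))
      stop("sweep regions overlap")
  }
  df
}

## Which of (chrom, pos) fall inside any row of a half-open interval table;
## returns the matching row index or NA.
match_interval <- function(chrom, pos, ivl) {
  hit <- rep(NA_integer_, length(pos))
  if (nrow(ivl) == 0L) return(hit)
  for (i in seq_len(nrow(ivl)))
    hit[chrom == ivl$chrom[i] & pos >= ivl$start[i] & pos < ivl$end[i]] <- i
  hit
}

#' Simulate a multi-population diploid genotype panel
#'
#' Genotypes are generated under the Balding-Nichols model: each SNP draws
#' an ancestral frequency `p` (Uniform over `ancestral_range` by default);
#' each population's frequency is a Beta draw with mean `p` and variance
#' `F p (1 - p)` where `F` is that population's drift parameter (`F = 0`
#' gives exactly `p`); individual genotypes are Binomial(2, population
#' frequency). SNPs inside an `"fst_shift"` sweep region use the sweep's
#' elevated `F` for every population, planting excess differentiation.
#'
#' @param pops List of [pop_spec()] objects (>= 1).
#' @param n_snps Number of biallelic SNPs to place (>= 1).
#' @param chrom_lengths Named vector of chromosome lengths in bases; SNP
#'   positions are uniform within chromosomes, allocated proportionally to
#'   length, strictly increasing, deduplicated.
#' @param sweeps List of [sweep_spec()] objects with effect `"fst_shift"`.
#' @param ancestral_range Length-2 range of the Uniform ancestral-frequency
#'   distribution (default `c(0.05, 0.95)`, keeping most sites segregating).
#' @param missing_rate Probability that any one genotype call is missing
#'   (default 0).
#' @param seed Integer seed; identical seeds give bit-identical panels.
#' @return A `genotype_panel`: list with `genotypes` (samples x SNPs integer
#'   matrix of 0/1/2 alternate-allele dosages, `NA` = missing), `sites`
#'   (data.frame: chrom, pos, id, ancestral_freq, sweep flag), `samples`
#'   (data.frame: sample_id, population, continent), `chrom_lengths`, and
#'   the `seed` used.
#' @examples
#' pops <- list(pop_spec("A", 10, 0.1), pop_spec("B", 10, 0.1))
#' panel <- simulate_panel(pops, n_snps = 100,
#'                         chrom_lengths = c(chr1 = 1e6), seed = 1)
#' dim(panel$genotypes)
#' @export
simulate_panel <- function(pops, n_snps,
                           chrom_lengths = c(chr1 = 25e6, chr2 = 25e6),
                           sweeps = list(),
                           ancestral_range = c(0.05, 0.95),
                           missing_rate = 0, seed = NULL) {
  stopifnot(all(vapply(pops, inherits, logical(1), "pop_spec")),
            length(pops) >= 1L)
  n_snps <- as.integer(n_snps)
  if (is.na(n_snps) || n_snps < 1L) stop("n_snps must be >= 1")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  stopifnot(length(ancestral_range) == 2L,
            ancestral_range[1] > 0, ancestral_range[2] < 1,
            ancestral_range[1] < ancestral_range[2])
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  sw <- sweep_table(sweeps, "fst_shift")
  bg_F <- vapply(pops, `[[`, numeric(1), "divergence_F")
  if (nrow(sw) > 0L && any(sw$divergence_F <= max(bg_F)))
    stop("sweep divergence_F must exceed every background divergence_F")

  with_seed(seed, {
    ## positions: counts proportional to length, then uniform without
    ## replacement within each chromosome
    n_per <- as.vector(stats::rmultinom(1, n_snps,
                                        chrom_lengths / sum(chrom_lengths)))
    chrom <- rep(names(chrom_lengths), n_per)
    pos <- unlist(lapply(seq_along(chrom_lengths), function(i) {
      if (n_per[i] == 0L) return(integer())
      sort(sample.int(chrom_lengths[i], n_per[i])) - 1L
    }), use.names = FALSE)

    p_anc <- runif(n_snps, ancestral_range[1], ancestral_range[2])
    sweep_hit <- match_interval(chrom, pos, sw)

    n_ind <- vapply(pops, `[[`, integer(1), "n_individuals")
    total <- sum(n_ind)
    G <- matrix(NA_integer_, nrow = total, ncol = n_snps)
    row0 <- 0L
    for (k in seq_along(pops)) {
      Fv <- rep(pops[[k]]$divergence_F, n_snps)
      Fv[!is.na(sweep_hit)] <- sw$divergence_F[sweep_hit[!is.na(sweep_hit)]]
      pk <- ifelse(Fv == 0, p_anc,
                   rbeta(n_snps, p_anc * (1 - Fv) / Fv,
                         (1 - p_anc) * (1 - Fv) / Fv))
      ## rbeta is degenerate only in the limit; force exact equality at F=0
      pk[Fv == 0] <- p_anc[Fv == 0]
      G[row0 + seq_len(n_ind[k]), ] <-
        rbinom(n_ind[k] * n_snps, 2L, rep(pk, each = n_ind[k]))
      row0 <- row0 + n_ind[k]
    }
    if (missing_rate > 0)
      G[runif(length(G)) < missing_rate] <- NA_integer_

    samples <- data.frame(
      sample_id = unlist(lapply(pops, function(p)
        sprintf("%s_%03d", p$name, seq_len(p$n_individuals)))),
      population = rep(vapply(pops, `[[`, character(1), "name"), n_ind),
      continent = rep(vapply(pops, `[[`, character(1), "continent"), n_ind),
      stringsAsFactors = FALSE)
    rownames(G) <- samples$sample_id
    sites <- data.frame(chrom = chrom, pos = pos,
                        id = sprintf("snp_%s_%d", chrom, pos),
                        ancestral_freq = p_anc,
                        in_sweep = !is.na(sweep_hit),
                        stringsAsFactors = FALSE)
    structure(list(genotypes = G, sites = sites, samples = samples,
                   chrom_lengths = chrom_lengths, seed = seed),
              class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(x$chrom_lengths)))
  tab <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  cat(sprintf("  missing genotype rate: %.4f\n", mean(is.na(x$genotypes))))
  invisible(x)
}

#' Simulate a genome-positioned normalized iHS-like score track
#'
#' Scores are standard-normal draws (the null for a normalized iHS track);
#' sites inside an `"ihs_shift"` sweep region get the sweep's offset added.
#' Site positions are uniform per chromosome at the requested density,
#' sorted and deduplicated.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bases).
#' @param density Expected scored sites per megabase (> 0).
#' @param sweeps List of [sweep_spec()] objects with effect `"ihs_shift"`.
#' @param seed Integer seed.
#' @return An `ihs_track` data.frame with columns `chrom`, `pos`, `score`,
#'   and an `in_sweep` flag; chromosome lengths kept as an attribute.
#' @export
simulate_ihs_track <- function(chrom_lengths, density = 200,
                               sweeps = list(), seed = NULL) {
  if (length(chrom_lengths) == 0L) stop("chrom_lengths must be non-empty")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  sw <- sweep_table(sweeps, "ihs_shift")
  with_seed(seed, {
    n_per <- pmax(1L, round(density * chrom_lengths / 1e6))
    chrom <- rep(names(chrom_lengths), n_per)
    pos <- unlist(lapply(seq_along(chrom_lengths), function(i)
      sort(sample.int(chrom_lengths[i], n_per[i])) - 1L),
      use.names = FALSE)
    score <- rnorm(length(pos))
    hit <- match_interval(chrom, pos, sw)
    score[!is.na(hit)] <- score[!is.na(hit)] + sw$offset[hit[!is.na(hit)]]
    track <- data.frame(chrom = chrom, pos = pos, score = score,
                        in_sweep = !is.na(hit), stringsAsFactors = FALSE)
    attr(track, "chrom_lengths") <- chrom_lengths
    class(track) <- c("ihs_track", "data.frame")
    track
  })
}

#' Simulate read pileups and genotype calls for an ancient individual
#'
#' Emulates low-coverage genotype calling with no sequencing error: per-site
#' read depth is Poisson(`mean_coverage`); each read copies one of the two
#' alleles of the true genotype with probability 1/2; the called genotype is
#' heterozygous iff both alleles are observed among the site's reads, else
#' homozygous for the observed allele. Depth-0 sites are flagged missing.
#' A true heterozygote at depth `c` is therefore called heterozygous with
#' probability `1 - 2^(1 - c)`.
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `pos`,
#'   `genotype` (true alternate-allele dosage 0/1/2) and optionally
#'   `derived_freq` (reference-population derived-allele frequency, carried
#'   through to the output).
#' @param mean_coverage Mean read depth (> 0).
#' @param depths Optional integer vector of fixed per-site depths,
#'   overriding the Poisson draw (used to condition on an observed depth
#'   profile).
#' @param seed Integer seed.
#' @return An `ancient_sites` data.frame: `site_id`, `chrom`, `pos`,
#'   `depth`, `call` (one of `"hom_ref"`, `"het"`, `"hom_alt"`,
#'   `"missing"`), `derived_freq`.
#' @export
simulate_pileup <- function(sites, mean_coverage, depths = NULL,
                            seed = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("site_id", "chrom", "pos", "genotype") %in% names(sites)))
  if (!all(sites$genotype %in% 0:2))
    stop("genotype must be biallelic dosage 0, 1 or 2")
  if (is.null(depths)) {
    if (!is.numeric(mean_coverage) || mean_coverage <= 0)
      stop("mean_coverage must be > 0")
  } else {
    stopifnot(length(depths) == nrow(sites), all(depths >= 0))
  }
  n <- nrow(sites)
  with_seed(seed, {
    depth <- if (is.null(depths)) rpois(n, mean_coverage)
             else as.integer(depths)
    ## alt-allele read count; het call iff both alleles seen
    alt_reads <- integer(n)
    het <- sites$genotype == 1L & depth > 0L
    alt_reads[het] <- rbinom(sum(het), depth[het], 0.5)
    alt_reads[sites$genotype == 2L] <- depth[sites$genotype == 2L]
    call <- rep("missing", n)
    pos_depth <- depth > 0L
    call[pos_depth & alt_reads == 0L] <- "hom_ref"
    call[pos_depth & alt_reads == depth] <- "hom_alt"
    call[pos_depth & alt_reads > 0L & alt_reads < depth] <- "het"
    out <- data.frame(site_id = sites$site_id, chrom = sites$chrom,
                      pos = sites$pos, depth = depth, call = call,
                      derived_freq = sites$derived_freq %||%
                        rep(NA_real_, n),
                      stringsAsFactors = FALSE)
    class(out) <- c("ancient_sites", "data.frame")
    out
  })
}
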
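## Low-coverage ancient-individual heterozygosity: observed multilocus
## heterozygosity, modern panel distributions, and the two-stage
## (genotype x read) resampling that corrects for depth-driven
## under-calling of heterozygotes.

## Accept genotype calls as character ("hom_ref"/"het"/"hom_alt"/
## "missing") or dosage (0/1/2/NA); return logical het with NA = missing.
as_het_indicator <- function(calls) {
  if (is.character(calls) || is.factor(calls)) {
    calls <- as.character(calls)
    bad <- !calls %in% c("hom_ref", "het", "hom_alt", "missing")
    if (any(bad)) stop("unrecognized genotype call: ", calls[bad][1L])
    ifelse(calls == "missing", NA, calls == "het")
  } else {
    if (!all(calls %in% c(0:2, NA))) stop("dosage calls must be 0/1/2/NA")
    calls == 1
  }
}

#' Mean observed heterozygosity across sites
#'
#' The fraction of non-missing genotype calls that are heterozygous - the
#' single-individual multilocus heterozygosity used to summarize
#' background-risk genotypes (e.g. 9 heterozygous calls among 49 sites
#' gives 0.1837).
#'
#' @param calls Genotype calls: character
#'   (`"hom_ref"`/`"het"`/`"hom_alt"`/`"missing"`), dosage (0/1/2, `NA`
#'   missing), or an `ancient_sites` data.frame (its `call` column is
#'   used).
#' @return Fraction of non-missing calls that are heterozygous.
#' @export
mean_observed_het <- function(calls) {
  if (is.data.frame(calls)) calls <- calls$call
  h <- as_het_indicator(calls)
  if (all(is.na(h))) stop("all calls are missing")
  mean(h, na.rm = TRUE)
}

## Constructor for labelled mean-heterozygosity distributions.
het_distribution <- function(values, label, n_genotype_reps = NA_integer_,
                             n_read_reps = NA_integer_) {
  stopifnot(all(values >= 0 & values <= 1))
  structure(list(values = values, label = label,
                 n_genotype_reps = n_genotype_reps,
                 n_read_reps = n_read_reps),
            class = "het_distribution")
}

#' @export
print.het_distribution <- function(x, ...) {
  cat(sprintf("het_distribution '%s': %d values, mean %.4f [%.4f, %.4f]\n",
              x$label, length(x$values), mean(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Per-individual heterozygosity distribution from a modern panel
#'
#' One mean-observed-heterozygosity value per individual of the selected
#' group, computed across the requested sites.
#'
#' @param panel A `genotype_panel`.
#' @param group Population and/or continent labels selecting individuals.
#' @param sites Optional data.frame (`chrom`, `pos`) of sites to use;
#'   sites absent from the panel are dropped with a message. Default: all
#'   panel sites.
#' @return A `het_distribution` whose values are per-individual means.
#' @export
panel_het_distribution <- function(panel, group, sites = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  rows <- group_rows(panel, group)
  cols <- seq_len(nrow(panel$sites))
  if (!is.null(sites)) {
    key <- paste(panel$sites$chrom, panel$sites$pos)
    want <- paste(sites$chrom, sites$pos)
    cols <- match(want, key)
    if (anyNA(cols)) {
      message(sum(is.na(cols)), " requested site(s) absent from panel; dropped")
      cols <- cols[!is.na(cols)]
    }
    if (length(cols) == 0L) stop("no requested site present in panel")
  }
  G <- panel$genotypes[rows, cols, drop = FALSE]
  values <- rowMeans(G == 1L, na.rm = TRUE)
  het_distribution(unname(values), paste(group, collapse = "+"))
}

#' Expected heterozygosity distribution from allele frequencies
#'
#' Per replicate, draws a genotype at every site under Hardy-Weinberg
#' equilibrium at the site's derived-allele frequency `q` (heterozygous
#' with probability `2 q (1 - q)`) and records the fraction of sites
#' heterozygous. This is the depth-free expectation an individual drawn
#' from the reference population would show.
#'
#' @param freqs Vector of per-site derived-allele frequencies in `[0, 1]`.
#' @param n_reps Number of genotype replicates (default 500).
#' @param seed Integer seed.
#' @return A `het_distribution` of `n_reps` values.
#' @export
simulate_expected_het <- function(freqs, n_reps = 500, seed = NULL) {
  stopifnot(all(freqs >= 0 & freqs <= 1), n_reps >= 1)
  S <- length(freqs)
  p_het <- 2 * freqs * (1 - freqs)
  with_seed(seed, {
    het <- matrix(rbinom(n_reps * S, 1L, rep(p_het, each = n_reps)),
                  nrow = n_reps)
    het_distribution(rowMeans(het), "expected (allele frequency)",
                     n_genotype_reps = n_reps, n_read_reps = 1L)
  })
}

#' Coverage-aware resampled heterozygosity distribution
#'
#' The two-stage resampling that measures how low read depth hides
#' heterozygotes: for each of `n_genotype_reps` genotype vectors (drawn
#' under Hardy-Weinberg from `freqs` as in [simulate_expected_het()]),
#' `n_read_reps` read-resampling replicates are generated. At site `s`
#' with observed depth `c_s`, each of `c_s` reads copies one of the
#' genotype's two alleles with probability 1/2; the site is scored
#' heterozygous iff both alleles appear among its reads (so a true
#' heterozygote is detected with probability `1 - 2^(1 - c_s)`). Each
#' replicate's value is its fraction of heterozygous-scored sites; the
#' output holds exactly `n_genotype_reps * n_read_reps` values (the
#' full-scale default is 500 x 2,500 = 1,250,000). Sites with depth 0
#' are excluded from the denominator.
#'
#' Called with the same `seed` and `n_genotype_reps` as
#' [simulate_expected_het()], the genotype stage reproduces that
#' function's genotype replicates exactly, so the depth effect is a
#' within-genotype comparison: every resampled value is bounded above by
#' its genotype replicate's true heterozygosity.
#'
#' @param freqs Per-site derived-allele frequencies.
#' @param depths Per-site read depths (non-negative integers), same length
#'   as `freqs`.
#' @param n_genotype_reps Genotype replicates (default 500).
#' @param n_read_reps Read-resampling replicates per genotype (default
#'   2,500).
#' @param seed Integer seed.
#' @return A `het_distribution` of `n_genotype_reps * n_read_reps` values.
#' @export
resample_reads_het <- function(freqs, depths, n_genotype_reps = 500,
                               n_read_reps = 2500, seed = NULL) {
  stopifnot(length(freqs) == length(depths),
            all(freqs >= 0 & freqs <= 1), all(depths >= 0),
            n_genotype_reps >= 1, n_read_reps >= 1)
  keep <- depths > 0
  if (!any(keep)) stop("all sites have depth 0")
  freqs <- freqs[keep]
  depths <- as.integer(depths[keep])
  S <- length(freqs)
  p_het <- 2 * freqs * (1 - freqs)
  with_seed(seed, {
    ## genotype stage drawn with the same layout as simulate_expected_het:
    ## calling both with one seed reproduces identical genotype replicates,
    ## so the coverage effect is a within-genotype comparison and the
    ## resampled mean can never exceed the expected mean
    het <- matrix(rbinom(n_genotype_reps * S, 1L,
                         rep(p_het, each = n_genotype_reps)),
                  nrow = n_genotype_reps)
    values <- numeric(n_genotype_reps * n_read_reps)
    for (g in seq_len(n_genotype_reps)) {
      het_sites <- which(het[g, ] == 1L)
      if (length(het_sites) == 0L) {
        v <- numeric(n_read_reps)
      } else {
        ## alt-read count per (replicate, het site); both alleles seen
        ## iff 0 < alt < depth
        c_s <- depths[het_sites]
        alt <- matrix(rbinom(n_read_reps * length(het_sites),
                             rep(c_s, each = n_read_reps), 0.5),
                      nrow = n_read_reps)
        seen_both <- alt > 0L &
          alt < matrix(c_s, n_read_reps, length(het_sites), byrow = TRUE)
        v <- rowSums(seen_both) / S
      }
      values[(g - 1L) * n_read_reps + seq_len(n_read_reps)] <- v
    }
    het_distribution(values, "resampled (allele frequency x coverage)",
                     n_genotype_reps = n_genotype_reps,
                     n_read_reps = n_read_reps)
  })
}

#' Percentile placement of a value within a panel distribution
#'
#' Rank of the value among the panel's values divided by the panel size,
#' with ties averaged: `(#below + (#equal + 1) / 2) / n`.
#'
#' @param value Single observed mean heterozygosity.
#' @param dist A `het_distribution` (or numeric vector of panel values).
#' @return Percentile in `(0, 1]`-ish range (may exceed 1 slightly when
#'   the value tops the whole panel; it is a rank ratio, not a
#'   probability).
#' @export
het_percentile <- function(value, dist) {
  values <- if (inherits(dist, "het_distribution")) dist$values else dist
  (sum(values < value) + (sum(values == value) + 1) / 2) / length(values)
}

#' Compare an ancient individual's heterozygosity to modern panels
#'
#' Convenience wrapper running the full ancient-heterozygosity analysis:
#' the observed mean heterozygosity of the ancient calls, per-group modern
#' panel distributions with the ancient individual's percentile placement,
#' the depth-free expected distribution, and the coverage-aware resampled
#' distribution.
#'
#' @param ancient An `ancient_sites` data.frame (columns `depth`, `call`,
#'   `derived_freq`; see [simulate_pileup()] or [read_ancient_sites()]).
#' @param panel Optional `genotype_panel` of modern individuals.
#' @param groups List (or character vector) of group selectors for panel
#'   distributions.
#' @param n_genotype_reps,n_read_reps Resampling depth (defaults 500 and
#'   2,500).
#' @param seed Integer seed.
#' @return An `ancient_het_test` list: `observed`, `expected`,
#'   `resampled` (both `het_distribution`s), `panel_groups` (named list),
#'   `percentiles`, `summary` data.frame.
#' @export
ancient_het_test <- function(ancient, panel = NULL, groups = NULL,
                             n_genotype_reps = 500, n_read_reps = 2500,
                             seed = NULL) {
  stopifnot(is.data.frame(ancient),
            all(c("depth", "call", "derived_freq") %in% names(ancient)))
  usable <- ancient$depth > 0 & ancient$call != "missing" &
    !is.na(ancient$derived_freq)
  if (!any(usable)) stop("no usable ancient sites")
  a <- ancient[usable, ]
  observed <- mean_observed_het(a$call)
  ## shared seed: both stages draw the identical genotype replicates
  expected <- simulate_expected_het(a$derived_freq, n_reps = n_genotype_reps,
                                    seed = seed)
  resampled <- resample_reads_het(a$derived_freq, a$depth,
                                  n_genotype_reps = n_genotype_reps,
                                  n_read_reps = n_read_reps, seed = seed)
  panel_groups <- list()
  percentiles <- numeric(0)
  if (!is.null(panel)) {
    if (is.null(groups)) groups <- unique(panel$samples$population)
    if (!is.list(groups)) groups <- as.list(groups)
    names(groups) <- vapply(groups, paste, character(1), collapse = "+")
    panel_groups <- lapply(groups, function(g)
      tryCatch(panel_het_distribution(panel, g,
                                      sites = a[, c("chrom", "pos")]),
               error = function(e) {
                 warning("panel group ", paste(g, collapse = "+"),
                         " skipped: ", conditionMessage(e), call. = FALSE)
                 NULL
               }))
    panel_groups <- Filter(Negate(is.null), panel_groups)
    percentiles <- vapply(panel_groups, function(d)
      het_percentile(observed, d), numeric(1))
  }
  summary <- data.frame(
    distribution = c("expected", "resampled", names(panel_groups)),
    mean = c(mean(expected$values), mean(resampled$values),
             vapply(panel_groups, function(d) mean(d$values), numeric(1))),
    min = c(min(expected$values), min(resampled$values),
            vapply(panel_groups, function(d) min(d$values), numeric(1))),
    stringsAsFactors = FALSE)
  structure(list(observed = observed, expected = expected,
                 resampled = resampled, panel_groups = panel_groups,
                 percentiles = percentiles, summary = summary,
                 n_sites = nrow(a), mean_depth = mean(a$depth)),
            class = "ancient_het_test")
}

#' @export
print.ancient_het_test <- function(x, ...) {
  cat(sprintf(
    "ancient het test: observed mean heterozygosity %.4f over %d sites (mean depth %.2f)\n",
    x$observed, x$n_sites, x$mean_depth))
  cat(sprintf("  expected (frequency only): mean %.4f\n",
              mean(x$expected$values)))
  cat(sprintf("  resampled (with coverage): mean %.4f\n",
              mean(x$resampled$values)))
  for (nm in names(x$panel_groups))
    cat(sprintf("  panel %s: mean %.4f, min %.4f; ancient percentile %.3f\n",
                nm, mean(x$panel_groups[[nm]]$values),
                min(x$panel_groups[[nm]]$values), x$percentiles[[nm]]))
  invisible(x)
}
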
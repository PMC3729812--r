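## Region outlier scan: genome-wide high-FST threshold, per-region
## high-FST fractions, empirical P-values from random genomic windows,
## and the binomial network-level excess test.

#' Genome-wide empirical high-FST threshold
#'
#' The 99% upper boundary of a sample of qualifying FST values: the
#' inverse-ECDF (type-1) quantile, i.e. the smallest sampled value `v`
#' such that at least a fraction `q` of the sample is `<= v`. Downstream
#' "outliers" are values strictly greater than the boundary, so at most
#' `1 - q` of the estimation sample itself is an outlier. The full-scale
#' default is a sample of 2,200,000 random SNPs; `n_sample` scales this
#' down by subsampling.
#'
#' @param fst_values Numeric vector of qualifying FST values (an
#'   `fst_scan` is accepted and its qualifying values used).
#' @param q Quantile level (default 0.99).
#' @param n_sample Optional subsample size drawn without replacement.
#' @param seed Seed for the subsample.
#' @return An `fst_threshold` list: `t99`, `q`, `n_sampled`.
#' @export
genome_threshold <- function(fst_values, q = 0.99, n_sample = NULL,
                             seed = NULL) {
  if (inherits(fst_values, "fst_scan"))
    fst_values <- fst_values$fst[fst_values$qualifying]
  fst_values <- fst_values[!is.na(fst_values)]
  if (length(fst_values) == 0L) stop("empty FST sample")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (!is.null(n_sample) && n_sample < length(fst_values))
    fst_values <- with_seed(seed,
                            sample(fst_values, n_sample, replace = FALSE))
  t99 <- unname(quantile(fst_values, q, type = 1, names = FALSE))
  structure(list(t99 = t99, q = q, n_sampled = length(fst_values)),
            class = "fst_threshold")
}

## Count qualifying and high-FST SNPs in half-open windows, vectorized via
## per-chromosome cumulative counts over the scan's qualifying sites.
count_in_windows <- function(scan, threshold, chrom, start, end) {
  qs <- scan[scan$qualifying, c("chrom", "pos", "fst")]
  high <- qs$fst > threshold$t99
  n_q <- integer(length(start))
  n_h <- integer(length(start))
  for (ch in unique(chrom)) {
    w <- which(chrom == ch)
    cp <- qs$pos[qs$chrom == ch]
    hh <- high[qs$chrom == ch]
    if (length(cp) == 0L) next
    cumh <- c(0L, cumsum(hh))
    lo <- findInterval(start[w] - 0.5, cp)
    hi <- findInterval(end[w] - 0.5, cp)   # pos < end (half-open)
    n_q[w] <- hi - lo
    n_h[w] <- cumh[hi + 1L] - cumh[lo + 1L]
  }
  list(n_qualifying = n_q, n_high = n_h)
}

#' Score regions by their fraction of high-FST SNPs
#'
#' For each region, counts the qualifying SNPs it contains and how many of
#' them exceed the genome-wide threshold; the region is flagged as
#' excessively differentiated when that fraction exceeds `flag_level`
#' (more than 1% of its SNPs by default). Regions containing zero
#' qualifying SNPs are unevaluable: their fraction is `NA` and they are
#' excluded from network counts.
#'
#' @param regions A `regions` data.frame (see [build_windows()]), or any
#'   data.frame with `chrom`, `start`, `end`.
#' @param scan An `fst_scan` from [pairwise_scan()].
#' @param threshold An `fst_threshold` from [genome_threshold()] computed
#'   on the same comparison.
#' @param flag_level Fraction above which a region is flagged (default
#'   0.01).
#' @return A `region_scores` data.frame: region columns plus
#'   `n_qualifying`, `n_high`, `fraction`, `flagged`, `evaluable`.
#' @export
region_fraction <- function(regions, scan, threshold, flag_level = 0.01) {
  stopifnot(inherits(scan, "fst_scan"),
            inherits(threshold, "fst_threshold"),
            all(c("chrom", "start", "end") %in% names(regions)))
  cnt <- count_in_windows(scan, threshold, regions$chrom, regions$start,
                          regions$end)
  out <- regions
  out$n_qualifying <- cnt$n_qualifying
  out$n_high <- cnt$n_high
  out$fraction <- ifelse(cnt$n_qualifying > 0,
                         cnt$n_high / cnt$n_qualifying, NA_real_)
  out$flagged <- !is.na(out$fraction) & out$fraction > flag_level
  out$evaluable <- cnt$n_qualifying > 0
  attr(out, "flag_level") <- flag_level
  class(out) <- c("region_scores", "data.frame")
  out
}

## Draw n random half-open windows uniform over the covered genome
## (chromosomes weighted by placeable length); windows may overlap.
draw_random_windows <- function(chrom_lengths, n, window) {
  placeable <- chrom_lengths - window
  if (all(placeable <= 0)) stop("covered genome smaller than one window")
  keep <- placeable > 0
  ch <- sample(names(chrom_lengths)[keep], n, replace = TRUE,
               prob = placeable[keep])
  start <- floor(runif(n, 0, placeable[ch]))
  data.frame(chrom = ch, start = start, end = start + window,
             stringsAsFactors = FALSE)
}

#' Draw random genomic windows
#'
#' Windows of fixed width drawn uniformly over the genome (chromosomes
#' weighted by placeable length; windows may overlap one another). Used
#' for null calibration studies and as the randomization background of
#' [empirical_p()].
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n Number of windows.
#' @param window Window width (default 50,000).
#' @param seed Integer seed.
#' @return A `regions` data.frame (`chrom`, `start`, `end`).
#' @export
random_regions <- function(chrom_lengths, n, window = 50000, seed = NULL) {
  out <- with_seed(seed, draw_random_windows(chrom_lengths, n, window))
  class(out) <- c("regions", "data.frame")
  out
}

#' Attach empirical P-values from random genomic windows
#'
#' Draws `n_random` windows of the analysis width uniformly over the
#' genome covered by the scan, scores each by the identical
#' [region_fraction()] procedure, and assigns each candidate region the
#' fraction of random windows whose high-FST fraction is greater than or
#' equal to the candidate's (a one-tailed empirical P; ties count, and P
#' may be exactly 0). Random windows containing zero qualifying SNPs are
#' redrawn; the same random-window set is reused for every region of the
#' comparison. Full scale is 11,000 windows; reduce `n_random` for desk
#' scale.
#'
#' @param scores A `region_scores` data.frame from [region_fraction()].
#' @param scan,threshold The same scan and threshold the scores were built
#'   from.
#' @param n_random Number of random windows (default 11,000).
#' @param window Window width (default 50,000).
#' @param seed Integer seed for the window draw.
#' @param max_redraws Redraw rounds allowed for empty windows before
#'   erroring.
#' @return `scores` with an `empirical_P` column (`NA` for unevaluable
#'   regions); the random-window fractions are kept in attribute
#'   `random_fractions`.
#' @export
empirical_p <- function(scores, scan, threshold, n_random = 11000,
                        window = 50000, seed = NULL, max_redraws = 100) {
  stopifnot(inherits(scores, "region_scores"),
            inherits(scan, "fst_scan"))
  chrom_lengths <- attr(scan, "chrom_lengths")
  if (is.null(chrom_lengths)) stop("scan carries no chromosome lengths")
  rand_frac <- with_seed(seed, {
    rw <- draw_random_windows(chrom_lengths, n_random, window)
    cnt <- count_in_windows(scan, threshold, rw$chrom, rw$start, rw$end)
    frac <- ifelse(cnt$n_qualifying > 0,
                   cnt$n_high / cnt$n_qualifying, NA_real_)
    tries <- 0L
    while (anyNA(frac)) {            # redraw windows with no qualifying SNP
      tries <- tries + 1L
      if (tries > max_redraws)
        stop("could not place non-empty random windows after ",
             max_redraws, " redraw rounds")
      i <- which(is.na(frac))
      rw2 <- draw_random_windows(chrom_lengths, length(i), window)
      cnt2 <- count_in_windows(scan, threshold, rw2$chrom, rw2$start,
                               rw2$end)
      frac[i] <- ifelse(cnt2$n_qualifying > 0,
                        cnt2$n_high / cnt2$n_qualifying, NA_real_)
    }
    frac
  })
  scores$empirical_P <- vapply(scores$fraction, function(f) {
    if (is.na(f)) NA_real_ else mean(rand_frac >= f)
  }, numeric(1))
  attr(scores, "random_fractions") <- rand_frac
  attr(scores, "n_random") <- n_random
  scores
}

#' Binomial test for an excess of significant regions in a network
#'
#' Given per-region empirical P-values, counts the regions significant at
#' `alpha` and computes the upper-tail binomial probability
#' `P(X >= k)` for `X ~ Binomial(m, alpha)` - the probability that at
#' least as many of `m` regions would reach `alpha` if regions were
#' exchangeable with random genomic windows. One-tailed by construction
#' (the scan screens only for an *excess* of high-FST SNPs). When a
#' `cluster_id` column is present (see [cluster_loci()]), overlapping
#' windows of clustered loci are collapsed to one unit per cluster
#' (counted significant if any member region is), so that physically
#' linked regions are not counted twice.
#'
#' @param scores A `region_scores` data.frame with `empirical_P` (see
#'   [empirical_p()]). Unevaluable regions are excluded.
#' @param alpha Per-region significance level (default 0.05).
#' @param collapse_clusters Collapse regions sharing a `cluster_id` before
#'   counting (default `TRUE` when the column is present).
#' @return A `network_test` list: `m` units tested, `k` significant,
#'   `alpha`, `network_P`.
#' @examples
#' ## 13 of 54 regions significant at 0.05
#' sc <- data.frame(chrom = "chr1", start = 0, end = 5e4,
#'                  fraction = 0.02, evaluable = TRUE,
#'                  empirical_P = c(rep(0.01, 13), rep(0.5, 41)))
#' class(sc) <- c("region_scores", "data.frame")
#' network_test(sc)$network_P
#' @export
network_test <- function(scores, alpha = 0.05,
                         collapse_clusters = "cluster_id" %in%
                           names(scores)) {
  stopifnot(is.data.frame(scores), "empirical_P" %in% names(scores))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  ev <- scores[!is.na(scores$empirical_P), ]
  if (nrow(ev) == 0L) stop("no evaluable regions")
  if (isTRUE(collapse_clusters) && "cluster_id" %in% names(ev)) {
    sig <- tapply(ev$empirical_P < alpha, ev$cluster_id, any)
  } else {
    sig <- ev$empirical_P < alpha
  }
  m <- length(sig)
  k <- sum(sig)
  structure(list(m = m, k = k, alpha = alpha,
                 network_P = pbinom(k - 1, m, alpha,
                                    lower.tail = FALSE)),
            class = "network_test")
}

#' @export
print.network_test <- function(x, ...) {
  cat(sprintf(
    "network excess test: %d of %d regions significant at %.3g; P(X >= %d) = %.4g\n",
    x$k, x$m, x$alpha, x$k, x$network_P))
  invisible(x)
}
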
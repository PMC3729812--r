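## Per-SNP sample-weighted FST (mean-squares form) and genome scans.

#' Per-site allele counts for an FST comparison
#'
#' Bundles, for one biallelic site and `r >= 2` population samples, the
#' sampled chromosome counts `n_i` (2 x non-missing diploid individuals)
#' and alternate-allele counts `a_i`. Populations with `n_i < 2` are
#' dropped; if fewer than two remain the site cannot be evaluated.
#'
#' @param n Integer vector of sampled chromosome counts per population.
#' @param a Integer vector of alternate-allele counts, `0 <= a_i <= n_i`.
#' @return An object of class `site_counts`.
#' @export
site_counts <- function(n, a) {
  stopifnot(length(n) == length(a), length(n) >= 2L)
  if (any(a < 0 | a > n)) stop("allele counts must satisfy 0 <= a <= n")
  keep <- n >= 2L
  if (sum(keep) < 2L)
    stop("fewer than two populations with n >= 2 chromosomes")
  structure(list(n = as.numeric(n[keep]), a = as.numeric(a[keep]),
                 n_dropped = sum(!keep)),
            class = "site_counts")
}

#' Sample-weighted FST for one site
#'
#' Computes the mean-squares estimator
#' \deqn{\hat F_{ST} = \frac{MSP - MSG}{MSP + (n_c - 1)\, MSG}}
#' with \eqn{MSP = \sum_i n_i (p_i - \bar p)^2 / (r - 1)},
#' \eqn{MSG = \sum_i n_i p_i (1 - p_i) / \sum_i (n_i - 1)} and
#' \eqn{n_c = (\sum_i n_i - \sum_i n_i^2 / \sum_i n_i) / (r - 1)}, where
#' \eqn{p_i = a_i / n_i} and \eqn{\bar p} is the chromosome-count-weighted
#' mean frequency. The estimator is bounded above by 1 (attained iff
#' `MSG = 0` with `MSP > 0`, a fixed difference) and may be negative
#' (identical sample frequencies give `-1 / (n_c - 1)`).
#'
#' A *qualifying* value is one from a site segregating within at least one
#' sample and with a strictly positive estimate; only qualifying sites
#' enter downstream high-FST fractions. Sites monomorphic in every sample
#' (both mean squares zero) return `NA` flagged `monomorphic`.
#'
#' @param counts A [site_counts()] object.
#' @return List with `value`, `qualifying`, `monomorphic`, and the
#'   components `MSP`, `MSG`, `n_c`.
#' @examples
#' weighted_fst(site_counts(n = c(10, 10), a = c(8, 2)))$value  # 0.4771
#' @export
weighted_fst <- function(counts) {
  stopifnot(inherits(counts, "site_counts"))
  n <- counts$n; a <- counts$a
  r <- length(n)
  p <- a / n
  N <- sum(n)
  pbar <- sum(n * p) / N
  MSP <- sum(n * (p - pbar)^2) / (r - 1)
  MSG <- sum(n * p * (1 - p)) / sum(n - 1)
  n_c <- (N - sum(n^2) / N) / (r - 1)
  if (MSP == 0 && MSG == 0) {
    return(list(value = NA_real_, qualifying = FALSE, monomorphic = TRUE,
                MSP = MSP, MSG = MSG, n_c = n_c))
  }
  value <- (MSP - MSG) / (MSP + (n_c - 1) * MSG)
  segregating <- any(p > 0 & p < 1)
  list(value = value, qualifying = segregating && value > 0,
       monomorphic = FALSE, MSP = MSP, MSG = MSG, n_c = n_c)
}

## Vectorized two-group engine on chromosome/allele count vectors.
## Returns one row per site; sites with n < 2 in either group are marked
## skipped (value NA) so callers can log them.
fst_two_groups <- function(n_a, a_a, n_b, a_b) {
  skipped <- n_a < 2 | n_b < 2
  p_a <- ifelse(n_a > 0, a_a / n_a, NA_real_)
  p_b <- ifelse(n_b > 0, a_b / n_b, NA_real_)
  N <- n_a + n_b
  pbar <- (a_a + a_b) / N
  MSP <- n_a * (p_a - pbar)^2 + n_b * (p_b - pbar)^2          # r - 1 = 1
  MSG <- (n_a * p_a * (1 - p_a) + n_b * p_b * (1 - p_b)) / (N - 2)
  n_c <- N - (n_a^2 + n_b^2) / N
  mono <- !skipped & MSP == 0 & MSG == 0
  fst <- ifelse(skipped | mono, NA_real_,
                (MSP - MSG) / (MSP + (n_c - 1) * MSG))
  segregating <- (p_a > 0 & p_a < 1) | (p_b > 0 & p_b < 1)
  data.frame(n_a = n_a, n_b = n_b, p_a = p_a, p_b = p_b,
             fst = fst,
             qualifying = !skipped & !mono & segregating & !is.na(fst) &
               fst > 0,
             monomorphic = mono, skipped = skipped,
             msp = MSP, msg = MSG, n_c = n_c)
}

## Resolve a group selector (population and/or continent labels) to row
## indices of panel$samples.
group_rows <- function(panel, group) {
  hit <- panel$samples$population %in% group |
    panel$samples$continent %in% group
  if (!any(hit))
    stop("group matches no population or continent label: ",
         paste(group, collapse = ", "))
  which(hit)
}

#' Per-SNP weighted FST scan between two pooled groups
#'
#' Pools each group's samples into one population sample (the two-sample
#' comparison the region scan consumes; pooling a continent means the union
#' of its population samples). Per-site chromosome counts reflect only
#' non-missing genotypes. Sites where either pooled sample retains fewer
#' than 2 chromosomes are skipped and counted in the skip log. Output
#' preserves genome order.
#'
#' @param panel A `genotype_panel` (from [simulate_panel()] or
#'   [read_panel()]).
#' @param group_a,group_b Disjoint character vectors of population and/or
#'   continent labels to pool.
#' @param sites Optional data.frame of half-open intervals (`chrom`,
#'   `start`, `end`) restricting the scan.
#' @return An `fst_scan` data.frame (one row per evaluated site): `chrom`,
#'   `pos`, `id`, `n_a`, `n_b`, `p_a`, `p_b`, `fst`, `qualifying`,
#'   `monomorphic`, plus mean-square components `msp`, `msg`, `n_c` used by
#'   [panel_fst()]. Attributes: `groups`, `skip_log` (named counts),
#'   `chrom_lengths`.
#' @export
pairwise_scan <- function(panel, group_a, group_b, sites = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(intersect(group_a, group_b)) > 0L)
    stop("groups must be disjoint")
  ra <- group_rows(panel, group_a)
  rb <- group_rows(panel, group_b)
  if (length(intersect(ra, rb)) > 0L)
    stop("groups must select disjoint sample sets")

  keep <- rep(TRUE, nrow(panel$sites))
  if (!is.null(sites)) {
    keep <- !is.na(match_interval(panel$sites$chrom, panel$sites$pos,
                                  sites))
  }
  idx <- which(keep)
  GA <- panel$genotypes[ra, idx, drop = FALSE]
  GB <- panel$genotypes[rb, idx, drop = FALSE]
  n_a <- 2 * colSums(!is.na(GA))
  n_b <- 2 * colSums(!is.na(GB))
  a_a <- colSums(GA, na.rm = TRUE)
  a_b <- colSums(GB, na.rm = TRUE)
  res <- fst_two_groups(n_a, a_a, n_b, a_b)
  out <- cbind(panel$sites[idx, c("chrom", "pos", "id")], res)
  skip_log <- c(low_count = sum(res$skipped),
                monomorphic = sum(res$monomorphic))
  out <- out[!out$skipped, setdiff(names(out), "skipped")]
  rownames(out) <- NULL
  attr(out, "groups") <- list(a = group_a, b = group_b)
  attr(out, "skip_log") <- skip_log
  attr(out, "chrom_lengths") <- panel$chrom_lengths
  class(out) <- c("fst_scan", "data.frame")
  out
}

#' Multilocus FST as a ratio of summed mean squares
#'
#' Combines per-site mean squares across loci as
#' `sum(MSP - MSG) / sum(MSP + (n_c - 1) MSG)` (the standard
#' ratio-of-averages convention for multilocus estimates). Under the
#' Balding-Nichols model its expectation is the drift parameter `F`, which
#' makes it the parameter-recovery statistic for simulated panels; the
#' arithmetic mean of per-site values is biased for this purpose (see the
#' methods vignette).
#'
#' @param scan An `fst_scan` from [pairwise_scan()].
#' @param which Sites to combine: `"segregating"` (default; segregating in
#'   at least one sample), `"qualifying"`, or `"all"` evaluated sites.
#' @return Single numeric multilocus FST estimate.
#' @export
panel_fst <- function(scan, which = c("segregating", "qualifying", "all")) {
  which <- match.arg(which)
  stopifnot(inherits(scan, "fst_scan"))
  seg <- (scan$p_a > 0 & scan$p_a < 1) | (scan$p_b > 0 & scan$p_b < 1)
  use <- switch(which,
                segregating = seg,
                qualifying = scan$qualifying,
                all = !scan$monomorphic)
  s <- scan[use, ]
  if (nrow(s) == 0L) stop("no usable sites")
  sum(s$msp - s$msg) / sum(s$msp + (s$n_c - 1) * s$msg)
}
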
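## Network randomization test on precomputed normalized iHS score tracks:
## mean of per-region maximum scores versus random, spacing-constrained
## locus sets.

## ---- track indexing -------------------------------------------------------

## Per-chromosome sorted positions + sparse table over |score| (or signed
## score), giving O(1) vectorized range-max queries for window scoring.
index_track <- function(track, signed = FALSE) {
  stopifnot(is.data.frame(track),
            all(c("chrom", "pos", "score") %in% names(track)))
  if (any(!is.finite(track$score))) stop("track scores must be finite")
  chroms <- unique(track$chrom)
  idx <- lapply(chroms, function(ch) {
    t2 <- track[track$chrom == ch, ]
    o <- order(t2$pos)
    x <- if (signed) t2$score[o] else abs(t2$score[o])
    n <- length(x)
    K <- max(1L, floor(log2(n)) + 1L)
    M <- matrix(-Inf, K, n)
    M[1L, ] <- x
    len <- 1L
    k <- 1L
    while (2L * len <= n) {
      i <- seq_len(n - 2L * len + 1L)
      M[k + 1L, i] <- pmax(M[k, i], M[k, i + len])
      len <- 2L * len
      k <- k + 1L
    }
    list(pos = t2$pos[o], tab = M)
  })
  names(idx) <- chroms
  cl <- attr(track, "chrom_lengths")
  if (is.null(cl)) {
    cl <- vapply(idx, function(z) max(z$pos) + 1, numeric(1))
    names(cl) <- chroms
  }
  list(chroms = chroms, idx = idx, chrom_lengths = cl)
}

## Vectorized range max over inclusive index ranges lo..hi (lo <= hi).
range_max <- function(tab, lo, hi) {
  len <- hi - lo + 1L
  k <- floor(log2(len))
  pmax(tab[cbind(k + 1, lo)], tab[cbind(k + 1, hi - 2^k + 1)])
}

## Max (abs) score inside half-open windows on one indexed chromosome;
## NA where the window holds no scored site.
window_max <- function(ti, chrom, start, end) {
  out <- rep(NA_real_, length(start))
  for (ch in unique(chrom)) {
    z <- ti$idx[[ch]]
    w <- which(chrom == ch)
    if (is.null(z)) next
    lo <- findInterval(start[w] - 0.5, z$pos) + 1L
    hi <- findInterval(end[w] - 0.5, z$pos)
    ok <- hi >= lo
    out[w[ok]] <- range_max(z$tab, lo[ok], hi[ok])
  }
  out
}

#' Highest iHS score in each region
#'
#' Extracts, for each region, the maximum normalized iHS score among the
#' track sites it contains. By default the maximum of absolute scores is
#' used (extreme normalized iHS of either sign indicates a sweep);
#' `signed = TRUE` takes the literal signed maximum instead. Regions
#' overlapping no scored site are unevaluable and return `NA`.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (half-open).
#' @param track An `ihs_track` (see [simulate_ihs_track()] or
#'   [read_bedgraph()]).
#' @param signed Use signed scores instead of absolute values.
#' @return Numeric vector of per-region maxima (`NA` = unevaluable).
#' @export
region_max_ihs <- function(regions, track, signed = FALSE) {
  ti <- index_track(track, signed = signed)
  window_max(ti, regions$chrom, regions$start, regions$end)
}

## ---- random network sampling ---------------------------------------------

## Draw n_networks random networks of n_regions windows each, sequentially
## per slot and vectorized across networks: a draw that violates the
## min_spacing constraint against any already-accepted same-chromosome
## window of its network, or holds no scored site, is rejected and
## redrawn. Returns list(chrom index matrix, start matrix) and the
## networks' mean per-region maxima.
sample_network_batch <- function(ti, n_networks, n_regions, window,
                                 min_spacing, max_attempts = 10000) {
  cl <- ti$chrom_lengths
  placeable <- cl - window
  if (all(placeable <= 0)) stop("no chromosome can hold one window")
  chrom_names <- names(cl)
  keep <- which(placeable > 0)
  chm <- matrix(NA_integer_, n_networks, n_regions)
  stm <- matrix(NA_real_, n_networks, n_regions)
  for (j in seq_len(n_regions)) {
    need <- rep(TRUE, n_networks)
    attempts <- 0L
    while (any(need)) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", n_regions, " windows at spacing ",
             min_spacing, " after ", max_attempts,
             " rejection rounds (genome too small?)")
      m <- sum(need)
      ci <- keep[sample.int(length(keep), m, replace = TRUE,
                            prob = placeable[keep])]
      st <- floor(runif(m, 0, placeable[ci]))
      ok <- rep(TRUE, m)
      if (j > 1L) {
        prev_ch <- chm[need, seq_len(j - 1L), drop = FALSE]
        prev_st <- stm[need, seq_len(j - 1L), drop = FALSE]
        conflict <- (prev_ch == ci) & (abs(prev_st - st) < min_spacing)
        ok <- rowSums(conflict) == 0L
      }
      ## require >= 1 scored site
      mx <- window_max(ti, chrom_names[ci], st, st + window)
      ok <- ok & !is.na(mx)
      wrows <- which(need)[ok]
      chm[wrows, j] <- ci[ok]
      stm[wrows, j] <- st[ok]
      need[wrows] <- FALSE
    }
  }
  means <- rowMeans(matrix(window_max(ti, chrom_names[as.vector(chm)],
                                      as.vector(stm),
                                      as.vector(stm) + window),
                           n_networks, n_regions))
  list(chrom = matrix(chrom_names[chm], n_networks, n_regions),
       start = stm, means = means)
}

#' Sample one random spacing-constrained network of windows
#'
#' Draws `n_regions` windows uniformly over the track's chromosomes
#' (weighted by placeable length). A draw is rejected and redrawn if it
#' comes within `min_spacing` bases (start-to-start) of an
#' already-accepted window on the same chromosome, or if it contains no
#' scored site. Errors with a diagnostic if placement is infeasible
#' within the attempt budget.
#'
#' @param track An `ihs_track`.
#' @param n_regions Number of windows.
#' @param window Window width (default 50,000).
#' @param min_spacing Minimum same-chromosome distance between window
#'   starts (default 2 Mb, the physical-independence spacing).
#' @param seed Integer seed.
#' @param max_attempts Rejection budget per window.
#' @return A `regions` data.frame of the accepted windows.
#' @export
sample_random_network <- function(track, n_regions, window = 50000,
                                  min_spacing = 2e6, seed = NULL,
                                  max_attempts = 10000) {
  ti <- index_track(track)
  b <- with_seed(seed,
                 sample_network_batch(ti, 1L, n_regions, window,
                                      min_spacing, max_attempts))
  out <- data.frame(chrom = b$chrom[1L, ], start = b$start[1L, ],
                    end = b$start[1L, ] + window,
                    stringsAsFactors = FALSE)
  class(out) <- c("regions", "data.frame")
  out
}

#' Network randomization test on an iHS track
#'
#' Computes the candidate network's mean per-region maximum iHS score and
#' compares it against `n_random` random networks of the same region
#' count, each drawn with the same window width and same-chromosome
#' spacing constraint. The P-value is the fraction of random networks
#' whose mean is as high or higher than the candidate's (ties count; no
#' pseudo-count). With `collapse_clusters = TRUE`, physically linked
#' candidate regions (sharing `cluster_id`) contribute one region drawn
#' uniformly per cluster, the network mean is averaged over
#' `n_cluster_draws` such draws, and random networks match the collapsed
#' region count. Unevaluable candidate regions (no scored site) are
#' dropped, shrinking both the observed and the random networks.
#'
#' @param regions Candidate regions (`chrom`, `start`, `end`, optionally
#'   `cluster_id`).
#' @param track An `ihs_track`.
#' @param n_random Number of random networks (full scale 100,000; reduce
#'   for desk scale).
#' @param window,min_spacing Window width and same-chromosome spacing for
#'   random networks.
#' @param signed Use signed scores (default absolute).
#' @param collapse_clusters Draw one region per cluster (requires a
#'   `cluster_id` column).
#' @param n_cluster_draws Cluster draws averaged into the observed mean.
#' @param seed Integer seed.
#' @return A `network_score` list: `observed_mean`, `region_max`
#'   (per evaluable candidate region), `n_regions`, `n_random`,
#'   `p_value`, `null_means`.
#' @export
randomization_p <- function(regions, track, n_random = 100000,
                            window = 50000, min_spacing = 2e6,
                            signed = FALSE, collapse_clusters = FALSE,
                            n_cluster_draws = 10, seed = NULL) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)))
  ti <- index_track(track, signed = signed)
  mx <- window_max(ti, regions$chrom, regions$start, regions$end)
  ev <- !is.na(mx)
  if (!any(ev)) stop("no candidate region overlaps a scored site")
  n_dropped <- sum(!ev)
  regions <- regions[ev, , drop = FALSE]
  mx <- mx[ev]
  with_seed(seed, {
    if (collapse_clusters) {
      if (!"cluster_id" %in% names(regions))
        stop("collapse_clusters needs a cluster_id column")
      cl <- split(seq_along(mx), regions$cluster_id)
      draws <- vapply(seq_len(n_cluster_draws), function(d)
        mean(vapply(cl, function(i)
          mx[i[sample.int(length(i), 1L)]], numeric(1))),
        numeric(1))
      observed <- mean(draws)
      n_regions <- length(cl)
    } else {
      observed <- mean(mx)
      n_regions <- length(mx)
    }
    nulls <- sample_network_batch(ti, n_random, n_regions, window,
                                  min_spacing)$means
    structure(list(observed_mean = observed, region_max = mx,
                   n_regions = n_regions, n_random = n_random,
                   n_dropped = n_dropped,
                   p_value = mean(nulls >= observed),
                   null_means = nulls),
              class = "network_score")
  })
}

#' @export
print.network_score <- function(x, ...) {
  cat(sprintf(
    "iHS network test: mean of %d per-region maxima = %.3f; p = %.4g (%d random networks)\n",
    x$n_regions, x$observed_mean, x$p_value, x$n_random))
  invisible(x)
}
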
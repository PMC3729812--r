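## Candidate loci -> fixed 50-kb analysis windows, and physical clustering
## of nearby loci. All coordinates 0-based, half-open (BED convention).

#' Build fixed-width analysis windows from candidate loci
#'
#' A locus no longer than the window width yields one window of exactly
#' that width centered on the locus midpoint (25 kb up- and downstream for
#' the default 50-kb window). A longer locus is tiled with
#' `floor(L / window)` consecutive non-overlapping windows anchored at the
#' locus start; the trailing remainder (< one window) is dropped. Windows
#' of *different* loci may overlap; such windows are flagged rather than
#' merged.
#'
#' @param loci data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open) and optionally `name`.
#' @param window Window width in bases (default 50,000).
#' @return A `regions` data.frame: `chrom`, `start`, `end`,
#'   `source_locus`, `window_id`, `overlaps_other_locus`.
#' @examples
#' build_windows(data.frame(chrom = "chr1", start = 1e6, end = 1.02e6))
#' @export
build_windows <- function(loci, window = 50000) {
  stopifnot(is.data.frame(loci),
            all(c("chrom", "start", "end") %in% names(loci)))
  if (any(loci$end <= loci$start))
    stop("locus intervals must satisfy end > start")
  nm <- loci$name %||% sprintf("locus_%d", seq_len(nrow(loci)))
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    L <- loci$end[i] - loci$start[i]
    if (L <= window) {
      center <- floor((loci$start[i] + loci$end[i]) / 2)
      s <- center - window / 2
      if (s < 0)
        stop("window for locus ", nm[i], " would extend below position 0")
      data.frame(chrom = loci$chrom[i], start = s, end = s + window,
                 source_locus = nm[i], stringsAsFactors = FALSE)
    } else {
      k <- floor(L / window)
      s <- loci$start[i] + window * (seq_len(k) - 1)
      data.frame(chrom = loci$chrom[i], start = s, end = s + window,
                 source_locus = nm[i], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$window_id <- sprintf("%s_w%d", out$source_locus,
                           as.integer(stats::ave(seq_len(nrow(out)),
                                                 out$source_locus,
                                                 FUN = seq_along)))
  out$overlaps_other_locus <- vapply(seq_len(nrow(out)), function(i) {
    other <- out$source_locus != out$source_locus[i] &
      out$chrom == out$chrom[i]
    any(other & out$start < out$end[i] & out$end > out$start[i])
  }, logical(1))
  rownames(out) <- NULL
  class(out) <- c("regions", "data.frame")
  out
}

#' Cluster loci that are not physically independent
#'
#' Single-linkage clustering of loci on physical distance: two loci on the
#' same chromosome whose gap is smaller than `min_gap` share a cluster
#' (transitively); loci on different chromosomes never share. The gap
#' between intervals is `start_j - end_i` for the sorted pair (0 for
#' overlapping loci). Cluster assignment is invariant to input order.
#'
#' @param loci data.frame with `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param min_gap Minimum physical gap (bases) for independence; default
#'   2 Mb.
#' @return `loci` with a `cluster_id` column (`"cl1"`, `"cl2"`, ... in
#'   genome order).
#' @export
cluster_loci <- function(loci, min_gap = 2e6) {
  stopifnot(is.data.frame(loci),
            all(c("chrom", "start", "end") %in% names(loci)))
  o <- order(loci$chrom, loci$start, loci$end)
  cl <- integer(nrow(loci))
  cur <- 0L
  prev_chrom <- ""
  prev_end <- -Inf
  for (i in o) {
    new_cluster <- loci$chrom[i] != prev_chrom ||
      (loci$start[i] - prev_end) >= min_gap
    if (new_cluster) {
      cur <- cur + 1L
      prev_end <- loci$end[i]
    } else {
      prev_end <- max(prev_end, loci$end[i])
    }
    cl[i] <- cur
    prev_chrom <- loci$chrom[i]
  }
  loci$cluster_id <- sprintf("cl%d", cl)
  loci
}
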
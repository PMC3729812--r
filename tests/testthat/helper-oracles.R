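## Independent brute-force evaluation of the sample-weighted FST mean
## squares, written with explicit loops so it shares no code with the
## package implementation.
oracle_fst <- function(n, a) {
  r <- length(n)
  p <- numeric(r)
  for (i in 1:r) p[i] <- a[i] / n[i]
  tot <- 0
  for (i in 1:r) tot <- tot + n[i]
  pbar <- 0
  for (i in 1:r) pbar <- pbar + n[i] * p[i] / tot
  msp <- 0
  for (i in 1:r) msp <- msp + n[i] * (p[i] - pbar)^2
  msp <- msp / (r - 1)
  num <- 0
  den <- 0
  for (i in 1:r) {
    num <- num + n[i] * p[i] * (1 - p[i])
    den <- den + (n[i] - 1)
  }
  msg <- num / den
  sq <- 0
  for (i in 1:r) sq <- sq + n[i]^2
  nc <- (tot - sq / tot) / (r - 1)
  (msp - msg) / (msp + (nc - 1) * msg)
}

## Small two-population Balding-Nichols panel.
make_panel <- function(F = 0.1, n_ind = 50, n_snps = 2000,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       sweeps = list(), missing_rate = 0, seed = 1) {
  simulate_panel(list(pop_spec("A", n_ind, F, continent = "West"),
                      pop_spec("B", n_ind, F, continent = "East")),
                 n_snps, chrom_lengths = chrom_lengths, sweeps = sweeps,
                 missing_rate = missing_rate, seed = seed)
}

## Hand-built fst_scan for tests that need exact site configurations.
fake_scan <- function(chrom, pos, fst, qualifying,
                      chrom_lengths = c(chr1 = 1e6)) {
  df <- data.frame(chrom = chrom, pos = pos,
                   id = sprintf("s%d", seq_along(pos)),
                   n_a = 100, n_b = 100, p_a = 0.5, p_b = 0.5,
                   fst = fst, qualifying = qualifying,
                   monomorphic = FALSE,
                   msp = NA_real_, msg = NA_real_, n_c = NA_real_,
                   stringsAsFactors = FALSE)
  attr(df, "chrom_lengths") <- chrom_lengths
  class(df) <- c("fst_scan", "data.frame")
  df
}

fake_threshold <- function(t99, q = 0.99) {
  structure(list(t99 = t99, q = q, n_sampled = NA_integer_),
            class = "fst_threshold")
}
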
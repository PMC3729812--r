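test_that("parameter validation rejects malformed specs", {
  expect_error(pop_spec("A", 0, 0.1), "positive integer")
  expect_error(pop_spec("A", 10, 1), "\\[0, 1\\)")
  expect_error(pop_spec("A", 10, -0.1), "\\[0, 1\\)")
  expect_error(sweep_spec("chr1", 100, 50, "fst_shift", divergence_F = 0.4),
               "start < end")
  expect_error(sweep_spec("chr1", 0, 100, "ihs_shift", offset = -1),
               "positive offset")
  sw <- list(sweep_spec("chr1", 0, 1e5, "fst_shift", divergence_F = 0.4),
             sweep_spec("chr1", 5e4, 2e5, "fst_shift", divergence_F = 0.4))
  expect_error(simulate_panel(list(pop_spec("A", 5, 0.05),
                                   pop_spec("B", 5, 0.05)),
                              100, c(chr1 = 1e6), sweeps = sw),
               "overlap")
  expect_error(simulate_panel(list(pop_spec("A", 5, 0.05),
                                   pop_spec("B", 5, 0.05)), 100,
                              c(chr1 = 1e6),
                              sweeps = list(sweep_spec("chr1", 0, 1e5,
                                                       "fst_shift",
                                                       divergence_F = 0.03))),
               "exceed every background")
})

test_that("identical seeds give bit-identical panels, tracks and pileups", {
  pops <- list(pop_spec("A", 10, 0.1), pop_spec("B", 10, 0.2))
  p1 <- simulate_panel(pops, 300, c(chr1 = 1e6), missing_rate = 0.02,
                       seed = 5)
  p2 <- simulate_panel(pops, 300, c(chr1 = 1e6), missing_rate = 0.02,
                       seed = 5)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$sites, p2$sites)

  t1 <- simulate_ihs_track(c(chr1 = 1e7), density = 100, seed = 6)
  t2 <- simulate_ihs_track(c(chr1 = 1e7), density = 100, seed = 6)
  expect_identical(t1, t2)

  sites <- data.frame(site_id = "s1", chrom = "chr1", pos = 100L,
                      genotype = 1L, derived_freq = 0.5)
  expect_identical(simulate_pileup(sites, 3, seed = 7),
                   simulate_pileup(sites, 3, seed = 7))
})

test_that("panel geometry and coding invariants hold", {
  panel <- make_panel(F = 0.1, n_ind = 10, n_snps = 800,
                      missing_rate = 0.05, seed = 21)
  g <- panel$genotypes
  expect_true(all(g[!is.na(g)] %in% 0:2))
  expect_gt(mean(is.na(g)), 0.03)
  for (ch in names(panel$chrom_lengths)) {
    p <- panel$sites$pos[panel$sites$chrom == ch]
    expect_true(all(diff(p) > 0))        # strictly increasing, deduplicated
  }
  expect_equal(nrow(g), 20L)
  expect_equal(ncol(g), 800L)
})

test_that("F = 0 populations draw frequencies equal to the ancestral", {
  ## both populations then share one binomial frequency per SNP, so the
  ## multilocus estimate sits at zero
  panel <- make_panel(F = 0, n_snps = 5000, seed = 31)
  est <- panel_fst(pairwise_scan(panel, "A", "B"))
  expect_lt(abs(est), 0.01)
})

test_that("allele-frequency variance across SNPs matches F p (1 - p)", {
  ## near-degenerate ancestral distribution pins p at 0.5; the sample
  ## frequency variance is F p q plus binomial noise pq(1-F)/n_chrom
  F <- 0.2
  n_ind <- 50
  panel <- simulate_panel(list(pop_spec("A", n_ind, F),
                               pop_spec("B", n_ind, F)),
                          20000, c(chr1 = 5e6),
                          ancestral_range = c(0.4999, 0.5001), seed = 41)
  a_rows <- panel$samples$population == "A"
  phat <- colMeans(panel$genotypes[a_rows, ]) / 2
  expected_var <- F * 0.25 + 0.25 * (1 - F) / (2 * n_ind)
  expect_equal(var(phat), expected_var, tolerance = 0.05)
})

test_that("fst_shift sweeps plant recoverable excess differentiation", {
  sweep <- sweep_spec("chr1", 2e6, 2.05e6, "fst_shift", divergence_F = 0.4)
  panel <- make_panel(F = 0.05, n_snps = 20000, sweeps = list(sweep),
                      seed = 51)
  expect_true(any(panel$sites$in_sweep))
  scan <- pairwise_scan(panel, "A", "B")
  inside <- data.frame(chrom = "chr1", start = 2e6, end = 2.05e6)
  est_in <- panel_fst(pairwise_scan(panel, "A", "B", sites = inside))
  est_all <- panel_fst(scan)
  expect_gt(est_in, 0.25)
  expect_lt(est_all, 0.1)
})

test_that("iHS tracks are standard normal off sweeps with planted offsets", {
  glen <- c(chr1 = 2.5e7, chr2 = 2.5e7)
  track0 <- simulate_ihs_track(glen, density = 200, seed = 61)
  n <- nrow(track0)
  expect_equal(n, 10000L)
  expect_lt(abs(mean(track0$score)), 4 / sqrt(n))   # 4 standard errors

  sweep <- sweep_spec("chr1", 1e6, 1.5e6, "ihs_shift", offset = 3)
  track <- simulate_ihs_track(glen, density = 200,
                              sweeps = list(sweep), seed = 61)
  inside <- track$in_sweep
  expect_gt(sum(inside), 30)
  expect_equal(mean(track$score[inside]) - mean(track$score[!inside]), 3,
               tolerance = 0.6)
  for (ch in names(glen))
    expect_true(all(diff(track$pos[track$chrom == ch]) > 0))
})

test_that("pileup calls follow the no-error read-sampling model", {
  ## all-homozygous truth can never yield a heterozygous call
  hom <- data.frame(site_id = sprintf("s%d", 1:2000), chrom = "chr1",
                    pos = 1:2000, genotype = rep(c(0L, 2L), 1000),
                    derived_freq = 0.5)
  ph <- simulate_pileup(hom, mean_coverage = 4, seed = 71)
  expect_false(any(ph$call == "het"))
  expect_true(all(ph$call[ph$depth == 0] == "missing"))
  expect_true(all(ph$call[hom$genotype == 0L & ph$depth > 0] == "hom_ref"))

  ## heterozygous truth at fixed depth c is called het w.p. 1 - 2^(1-c)
  S <- 100000
  het <- data.frame(site_id = sprintf("s%d", 1:S), chrom = "chr1",
                    pos = 1:S, genotype = 1L, derived_freq = 0.5)
  for (cc in c(2L, 5L)) {
    pc <- simulate_pileup(het, mean_coverage = cc,
                          depths = rep(cc, S), seed = 72 + cc)
    expect_equal(mean(pc$call == "het"), 1 - 2^(1 - cc),
                 tolerance = 0.006)
  }
  expect_error(simulate_pileup(het, mean_coverage = 0), "> 0")
})

test_that("pileup depths are Poisson distributed", {
  S <- 100000
  lambda <- 3.5
  truth <- data.frame(site_id = sprintf("s%d", 1:S), chrom = "chr1",
                      pos = 1:S, genotype = 1L, derived_freq = 0.5)
  pile <- simulate_pileup(truth, mean_coverage = lambda, seed = 81)
  cap <- 12L
  obs <- tabulate(pmin(pile$depth, cap) + 1L, nbins = cap + 1L)
  p <- dpois(0:(cap - 1), lambda)
  p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})
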
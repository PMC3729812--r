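test_that("mean observed heterozygosity is the het fraction of calls", {
  calls <- rep(c("het", "hom_ref"), c(9, 40))        # 9 of 49
  expect_equal(mean_observed_het(calls), 9 / 49)
  expect_equal(round(mean_observed_het(calls), 3), 0.184)

  expect_equal(mean_observed_het(rep("hom_alt", 10)), 0)
  expect_equal(mean_observed_het(rep("het", 7)), 1)
  expect_equal(mean_observed_het(c(1L, 0L, NA, 2L, 1L)), 0.5)
  expect_equal(mean_observed_het(c("het", "missing", "hom_ref")), 0.5)
  expect_error(mean_observed_het(rep("missing", 3)), "all calls")
  expect_error(mean_observed_het("hetero"), "unrecognized")
})

test_that("panel distributions give one value per individual", {
  panel <- make_panel(F = 0.05, n_ind = 12, n_snps = 400, seed = 8)
  d <- panel_het_distribution(panel, "A")
  expect_length(d$values, 12L)
  expect_true(all(d$values >= 0 & d$values <= 1))

  ## all-heterozygous panel
  panel$genotypes[] <- 1L
  expect_true(all(panel_het_distribution(panel, "A")$values == 1))

  ## single individual reduces to mean_observed_het
  one <- simulate_panel(list(pop_spec("solo", 1, 0.1),
                             pop_spec("other", 2, 0.1)),
                        200, c(chr1 = 1e6), seed = 9)
  d1 <- panel_het_distribution(one, "solo")
  g <- one$genotypes["solo_001", ]
  expect_equal(d1$values, mean_observed_het(unname(g)))
})

test_that("HWE panels match the closed-form expected heterozygosity", {
  ## under HWE at frequency q each site is het w.p. 2q(1-q)
  panel <- make_panel(F = 0, n_ind = 60, n_snps = 3000, seed = 18)
  d <- panel_het_distribution(panel, c("A", "B"))
  q <- panel$sites$ancestral_freq
  expect_equal(mean(d$values), mean(2 * q * (1 - q)), tolerance = 0.01)
})

test_that("expected-het simulation follows binomial moments", {
  expect_true(all(simulate_expected_het(rep(0, 20), seed = 1)$values == 0))
  expect_true(all(simulate_expected_het(rep(1, 20), seed = 1)$values == 0))

  d <- simulate_expected_het(rep(0.5, 49), n_reps = 2000, seed = 2)
  expect_length(d$values, 2000L)
  expect_equal(mean(d$values), 0.5, tolerance = 0.01)
  expect_equal(var(d$values), 0.25 / 49, tolerance = 0.1)
})

test_that("identical seeds reproduce identical distributions", {
  q <- withr::with_seed(4, runif(30, 0.1, 0.9))
  a <- simulate_expected_het(q, n_reps = 100, seed = 5)
  b <- simulate_expected_het(q, n_reps = 100, seed = 5)
  expect_identical(a$values, b$values)
  depths <- withr::with_seed(6, rpois(30, 5) + 1L)
  r1 <- resample_reads_het(q, depths, 20, 50, seed = 7)
  r2 <- resample_reads_het(q, depths, 20, 50, seed = 7)
  expect_identical(r1$values, r2$values)
})

test_that("single reads can never reveal a heterozygote", {
  q <- rep(0.5, 25)
  r <- resample_reads_het(q, rep(1L, 25), 50, 40, seed = 11)
  expect_true(all(r$values == 0))
  expect_length(r$values, 50L * 40L)     # exactly genotype x read reps
  expect_error(resample_reads_het(q, rep(0L, 25), 5, 5, seed = 1),
               "depth 0")
})

test_that("resampled mean matches the closed form 2q(1-q)(1 - 2^(1-c))", {
  q <- withr::with_seed(21, runif(40, 0.1, 0.9))
  depths <- withr::with_seed(22, rpois(40, 5) + 1L)
  r <- resample_reads_het(q, depths, 400, 200, seed = 23)
  closed <- mean(2 * q * (1 - q) * (1 - 2^(1 - depths)))
  expect_equal(mean(r$values), closed, tolerance = 0.01)
})

test_that("coverage can only hide heterozygotes (shared-seed dominance)", {
  for (s in 1:5) {
    q <- withr::with_seed(30 + s, runif(49, 0.05, 0.95))
    depths <- withr::with_seed(40 + s, rpois(49, 5.6))
    depths[depths == 0] <- 1L
    e <- simulate_expected_het(q, n_reps = 100, seed = 50 + s)
    r <- resample_reads_het(q, depths, 100, 50, seed = 50 + s)
    expect_lte(mean(r$values), mean(e$values))
    ## per-genotype bound: every read replicate <= its genotype's true het
    expect_lte(max(r$values), max(e$values))
  }
})

test_that("high depth converges to the depth-free expectation", {
  q <- withr::with_seed(61, runif(49, 0.1, 0.9))
  e <- simulate_expected_het(q, n_reps = 300, seed = 62)
  r <- resample_reads_het(q, rep(30L, 49), 300, 10, seed = 62)
  ks <- suppressWarnings(ks.test(e$values, r$values))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(e$values), mean(r$values), tolerance = 0.005)
})

test_that("percentile placement averages ties", {
  panel_vals <- c(0.1, 0.2, 0.2, 0.3, 0.4)
  expect_equal(het_percentile(0.2, panel_vals), (1 + 1.5) / 5)
  expect_equal(het_percentile(0.05, panel_vals), 0.5 / 5)
  expect_equal(het_percentile(0.9, panel_vals), 5.5 / 5)
})

test_that("the full ancient comparison bundles all distributions", {
  panel <- make_panel(F = 0.05, n_ind = 20, n_snps = 300, seed = 71)
  idx <- withr::with_seed(72, sort(sample.int(300, 49)))
  truth <- data.frame(site_id = sprintf("s%02d", 1:49),
                      chrom = panel$sites$chrom[idx],
                      pos = panel$sites$pos[idx],
                      genotype = withr::with_seed(73, rbinom(49, 2, 0.5)),
                      derived_freq = panel$sites$ancestral_freq[idx])
  pile <- simulate_pileup(truth, mean_coverage = 5.6, seed = 74)
  at <- ancient_het_test(pile, panel = panel,
                         groups = list("A", c("A", "B")),
                         n_genotype_reps = 60, n_read_reps = 40,
                         seed = 75)
  expect_length(at$resampled$values, 60L * 40L)
  expect_length(at$expected$values, 60L)
  expect_lte(mean(at$resampled$values), mean(at$expected$values))
  expect_named(at$panel_groups, c("A", "A+B"))
  expect_length(at$percentiles, 2L)
  expect_output(print(at), "observed mean heterozygosity")
})
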
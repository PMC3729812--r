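make_track <- function(chrom, pos, score) {
  tr <- data.frame(chrom = chrom, pos = pos, score = score,
                   stringsAsFactors = FALSE)
  class(tr) <- c("ihs_track", "data.frame")
  tr
}

test_that("region maximum takes the largest absolute score", {
  tr <- make_track("chr1", c(100, 200, 300), c(-3.1, 0.2, 1.4))
  region <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_equal(region_max_ihs(region, tr), 3.1)
  expect_equal(region_max_ihs(region, tr, signed = TRUE), 1.4)

  single <- data.frame(chrom = "chr1", start = 150, end = 250)
  expect_equal(region_max_ihs(single, tr), 0.2)    # |s| of the only site

  off <- data.frame(chrom = "chr1", start = 5000, end = 6000)
  expect_true(is.na(region_max_ihs(off, tr)))      # unevaluable
})

test_that("range-max indexing agrees with direct window maxima", {
  set.seed(12)
  tr <- simulate_ihs_track(c(chr1 = 5e6, chr2 = 5e6), density = 300,
                           seed = 12)
  starts <- seq(0, 4.9e6, by = 9e4)
  regions <- data.frame(chrom = rep(c("chr1", "chr2"),
                                    each = length(starts)),
                        start = rep(starts, 2))
  regions$end <- regions$start + 5e4
  got <- region_max_ihs(regions, tr)
  naive <- vapply(seq_len(nrow(regions)), function(i) {
    s <- tr$score[tr$chrom == regions$chrom[i] &
                    tr$pos >= regions$start[i] & tr$pos < regions$end[i]]
    if (length(s) == 0) NA_real_ else max(abs(s))
  }, numeric(1))
  expect_equal(got, naive)
})

test_that("random networks satisfy the same-chromosome spacing", {
  tr <- simulate_ihs_track(c(chrA = 3e6), density = 500, seed = 33)
  net <- sample_random_network(tr, 2, min_spacing = 2e6, seed = 34)
  expect_equal(nrow(net), 2L)
  expect_gte(abs(diff(net$start)), 2e6)

  ## more windows than a 3 Mb chromosome can hold 2 Mb apart
  expect_error(sample_random_network(tr, 5, min_spacing = 2e6, seed = 35,
                                     max_attempts = 50),
               "could not place")
})

test_that("every audited random window pair respects spacing", {
  tr <- simulate_ihs_track(setNames(rep(3e7, 4), paste0("chr", 1:4)),
                           density = 100, seed = 36)
  for (s in 1:25) {
    net <- sample_random_network(tr, 8, min_spacing = 2e6, seed = 100 + s)
    for (ch in unique(net$chrom)) {
      st <- sort(net$start[net$chrom == ch])
      if (length(st) > 1) expect_true(all(diff(st) >= 2e6))
    }
    expect_false(any(is.na(region_max_ihs(net, tr))))
  }
})

test_that("window starts are uniform across and within chromosomes", {
  ## chromosomes large enough that spacing rejections are rare, so the
  ## accepted marginal stays near the placeable-length weights
  glen <- c(chr1 = 2e7, chr2 = 4e7)
  tr <- simulate_ihs_track(glen, density = 300, seed = 37)
  nets <- lapply(1:400, function(s)
    sample_random_network(tr, 3, min_spacing = 2e6, seed = 1000 + s))
  all_ch <- unlist(lapply(nets, `[[`, "chrom"))
  all_st <- unlist(lapply(nets, `[[`, "start"))
  placeable <- glen - 5e4
  gof <- suppressWarnings(
    chisq.test(table(factor(all_ch, names(glen))),
               p = placeable / sum(placeable)))
  expect_gt(gof$p.value, 0.01)
  ## within-chromosome uniformity of start positions
  u <- all_st[all_ch == "chr2"] / placeable["chr2"]
  expect_gt(suppressWarnings(ks.test(u, "punif")$p.value), 0.01)
})

test_that("a constant track forces p = 1 by the tie rule", {
  pos <- seq(1000, 2e7, by = 4000)
  tr <- make_track("chr1", pos, rep(1.7, length(pos)))
  regions <- data.frame(chrom = "chr1", start = c(0, 5e6, 1.2e7))
  regions$end <- regions$start + 5e4
  ns <- randomization_p(regions, tr, n_random = 200, seed = 44)
  expect_equal(ns$observed_mean, 1.7)
  expect_equal(ns$p_value, 1)
})

test_that("p is invariant under a global sign flip of the track", {
  tr <- simulate_ihs_track(c(chr1 = 2e7, chr2 = 2e7), density = 200,
                           seed = 55)
  flipped <- tr
  flipped$score <- -flipped$score
  regions <- sample_random_network(tr, 6, seed = 56)
  a <- randomization_p(regions, tr, n_random = 300, seed = 57)
  b <- randomization_p(regions, flipped, n_random = 300, seed = 57)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$observed_mean, b$observed_mean)
})

test_that("boosting candidate scores can only shrink p", {
  tr <- simulate_ihs_track(c(chr1 = 2e7, chr2 = 2e7), density = 200,
                           seed = 65)
  regions <- sample_random_network(tr, 6, seed = 66)
  boosted <- tr
  hit <- !is.na(netsel:::match_interval(tr$chrom, tr$pos, regions))
  boosted$score[hit] <- boosted$score[hit] + 1.5
  p0 <- randomization_p(regions, tr, n_random = 400, seed = 67)$p_value
  p1 <- randomization_p(regions, boosted, n_random = 400, seed = 67)$p_value
  expect_lte(p1, p0)
})

test_that("cluster collapse averages draws over one region per cluster", {
  tr <- simulate_ihs_track(c(chr1 = 3e7), density = 300, seed = 75)
  regions <- data.frame(chrom = "chr1",
                        start = c(1e6, 1.5e6, 1e7),
                        cluster_id = c("cl1", "cl1", "cl2"))
  regions$end <- regions$start + 5e4
  ns <- randomization_p(regions, tr, n_random = 100,
                        collapse_clusters = TRUE, n_cluster_draws = 10,
                        seed = 76)
  expect_equal(ns$n_regions, 2L)       # clusters, not regions
  mx <- region_max_ihs(regions, tr)
  expect_gte(ns$observed_mean, mean(c(min(mx[1:2]), mx[3])))
  expect_lte(ns$observed_mean, mean(c(max(mx[1:2]), mx[3])))
  expect_error(randomization_p(regions[, c("chrom", "start", "end")], tr,
                               n_random = 10, collapse_clusters = TRUE,
                               seed = 1),
               "cluster_id")
})

test_that("unevaluable regions drop symmetrically from the network", {
  tr <- make_track("chr1", seq(1e6, 2e6, by = 1000), rnorm(1001))
  regions <- data.frame(chrom = "chr1", start = c(1.2e6, 9e6))
  regions$end <- regions$start + 5e4
  ns <- randomization_p(regions, tr, n_random = 100, seed = 86)
  expect_equal(ns$n_regions, 1L)
  expect_equal(ns$n_dropped, 1L)
  far <- data.frame(chrom = "chr1", start = 9e6, end = 9.05e6)
  expect_error(randomization_p(far, tr, n_random = 10, seed = 1),
               "no candidate region")
})
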
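Package: netsel
Title: Differentiation and Selection Tests for Candidate Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests for natural selection acting on a network of candidate
    gene loci, built around three complementary analyses: a per-SNP
    sample-weighted FST outlier scan over fixed 50-kb windows with
    empirical P-values from randomly drawn genomic windows and a binomial
    network-level test; a randomization test comparing the mean per-region
    maximum of normalized integrated haplotype scores (iHS) against random
    spacing-constrained locus sets; and coverage-aware resampling of an
    ancient individual's multilocus heterozygosity that corrects for
    under-calling of heterozygotes at low read depth. A synthetic-data
    module (Balding-Nichols genotype panels, iHS-like score tracks, and
    Poisson-coverage read pileups with planted selection signals) makes
    every stage testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
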
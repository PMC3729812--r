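---
title: "Selection tests on candidate gene networks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection tests on candidate gene networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsel)
```

`netsel` asks one question three ways: has a *set* of candidate gene
regions — a "network", such as the non-HLA autosomal loci associated with
a disease by GWAS — evolved differently from the genome-wide background?
All three analyses are empirical randomization tests: rather than fitting
a demographic model (human population history is too heterogeneous and
too poorly known for that to be safe), each candidate statistic is ranked
against the same statistic computed on randomly drawn genomic units.
Demography moves the whole genome; a candidate set that stands out
against random draws from that same genome cannot be explained by
demography alone. The price of this design is conservatism: whatever
fraction of the genome truly was selected sits inside the null sample.

## The per-SNP F_ST estimator

For one biallelic SNP and r population samples with chromosome counts
$n_i$ (twice the non-missing diploid individuals) and sample frequencies
$p_i$, the sample-weighted estimator is

$$\hat F_{ST} = \frac{MSP - MSG}{MSP + (n_c - 1)\,MSG},$$

with $MSP = \sum_i n_i(p_i-\bar p)^2/(r-1)$,
$MSG = \sum_i n_i p_i(1-p_i)/\sum_i(n_i-1)$ and
$n_c = (\sum_i n_i - \sum_i n_i^2/\sum_i n_i)/(r-1)$. It equals 1 exactly
at a fixed difference ($MSG=0$), and is *negative* whenever the
between-sample mean square falls below the within-sample one — identical
sample frequencies give exactly $-1/(n_c-1)$. Comparisons are always two
pooled samples ($r = 2$): continents are pooled unions of their
population samples, while within-continent comparisons should use single
population pairs, since continental regions are represented by unequal
numbers of populations with unknown histories and a weighted average
would dilute the signal.

Design choices worth stating:

* **Chromosome counts, not individuals.** The mean-squares formulas are
  ambiguous between the two conventions at this level; allele counts are
  the sufficient statistic for a frequency comparison, so $n_i$ counts
  chromosomes.
* **Qualifying SNPs.** Downstream fractions use only SNPs segregating in
  at least one sample with $\hat F_{ST} > 0$. Sites monomorphic in both
  samples are a flagged non-value (0/0 mean squares), not a zero.
  Populations reduced below 2 chromosomes by missingness drop out; if
  fewer than two samples remain the site is skipped and logged.
* **Multilocus combination.** `panel_fst()` combines loci as a ratio of
  summed mean squares, $\sum(MSP-MSG)/\sum(MSP+(n_c-1)MSG)$. Under the
  Balding–Nichols model (below) this recovers the drift parameter F
  within Monte-Carlo error. The arithmetic mean of per-SNP values does
  *not*: averaging the ratios is biased downward (each SNP's denominator
  is noisy), and averaging only qualifying values truncates the negative
  tail and is biased upward. We measured both effects at several F
  before settling on the ratio-of-sums form, which is the standard
  convention for multilocus estimates. Per-SNP values are still what the
  outlier scan consumes — there the ranking, not the level, matters.

## Windows, thresholds and empirical P-values

Candidate loci become fixed 50-kb windows: a locus ≤ 50 kb yields one
window centered on its midpoint (±25 kb — GWAS index SNPs are not
necessarily causal, so flanking sequence is deliberately included); a
longer locus is tiled with ⌊L/50kb⌋ non-overlapping windows anchored at
its start, dropping the trailing remainder. Anchoring at the start is an
arbitrary but deterministic choice. Windows of *different* nearby loci
may overlap; they are flagged, and the network test collapses clustered
loci (single-linkage, < 2 Mb gap) to one unit so linked regions are not
counted twice.

The genome-wide significance boundary is the inverse-ECDF (type-1) 99%
quantile of a large sample of qualifying F_ST values (2,200,000 SNPs at
full scale); "outliers" are strictly above it, so by construction at
most 1% of the estimation sample is an outlier. A window is flagged when
more than 1% of its qualifying SNPs are outliers, and its empirical P is
the fraction of 11,000 random same-width genomic windows with an equal
or larger outlier fraction. Ties count toward the numerator and there is
no pseudo-count, so P can be exactly 0 — users who need strictly
positive P-values should add (k+1)/(n+1) themselves, at the cost of
departing from the literal fraction definition. Random windows are drawn
uniformly (chromosomes weighted by placeable length), may overlap one
another, and are redrawn if they contain no qualifying SNP; one window
set is reused for every region of a comparison, which preserves the
between-region ranking. The network test is the exact binomial upper
tail $P(X \ge k)$, $X \sim \mathrm{Bin}(m, 0.05)$, on the number of
significant units — one-tailed only, since the scan screens for an
*excess* of differentiation; a deficit is not evidence against
selection elsewhere.

Because the outlier fraction is discrete (a window holds finitely many
SNPs), the empirical P is conservative: ties inflate P-values slightly
above uniform. The calibration checks therefore bound the rejection
rate from above rather than pinning it exactly.

## The iHS network test

Normalized iHS is consumed as a precomputed position-scored track
(computing it from haplotypes is out of scope). Each candidate region
contributes its maximum |iHS|; "highest score" on a signed statistic is
ambiguous, and since extreme values of either sign indicate sweeps we
default to absolute values, with `signed = TRUE` preserving the literal
reading. The candidate network's mean of per-region maxima is ranked
against 100,000 random networks of the same region count, drawn window
by window with rejection: a draw landing within 2 Mb (start-to-start;
the windows are tiny relative to the spacing) of an accepted
same-chromosome window, or containing no scored site, is redrawn.
Physical distance stands in for genetic distance purely for efficiency.
Ties count ("as high or higher") and unevaluable candidate regions
shrink observed and random networks symmetrically. When candidate loci
cluster, one region per cluster is drawn and the observed mean averaged
over ten draws before ranking.

## Ancient heterozygosity under low coverage

A single ancient individual's mean observed heterozygosity across S risk
sites (e.g. 9 heterozygous calls of 49 sites = 0.184) is compared to
per-individual values in modern panels. Low coverage biases this
comparison: with no sequencing error, a true heterozygote at depth c is
called heterozygous only when both alleles are sampled, probability
$1 - 2^{1-c}$. The two-stage resampling measures the bias under the
modern allele frequencies: 500 genotype vectors drawn per site under
Hardy–Weinberg at the reference-population derived-allele frequency
(strict HWE is assumed; the alternative — resampling observed genotype
frequencies — was rejected as it would fold population structure into
the null), then 2,500 read-resampling replicates per genotype at the
ancient individual's observed depths, each read copying one of the two
alleles with probability 1/2. The 1,250,000 resampled values quantify
how far coverage alone drags the distribution down.

Two implementation details matter. Reads are resampled as independent
allele choices (physical read identity is not reconstructible from a
site table). And the resampling shares its genotype stage with the
depth-free expectation when given the same seed, making the coverage
effect a within-genotype comparison: every resampled value is bounded by
its genotype's true heterozygosity, so the resampled mean can never
exceed the expected mean, matching the statistic's logic exactly rather
than only in expectation. Depth-0 sites are excluded, not imputed.
Percentile placement within a modern group is the tie-averaged rank of
the ancient value divided by group size.

## The synthetic-data generator

The generator exists to give every stage ground truth:

* **Genotype panels** follow the Balding–Nichols model: ancestral
  frequency p ~ Uniform(0.05, 0.95) (keeping most sites segregating;
  configurable), population frequency ~ Beta with mean p and variance
  F·p(1−p), genotypes Binomial(2, frequency). The model was chosen
  because the estimator's expectation under it is the drift parameter F,
  giving a parameter-recovery target; no claim is made that it mimics
  human demography. `fst_shift` sweep regions elevate F locally;
  `ihs_shift` sweeps add a positive offset to track scores. Missing
  genotypes are injected at a configurable rate (default 0).
* **iHS-like tracks** are standard normal (the null of a normalized
  score) at a chosen site density.
* **Read pileups** draw per-site depth ~ Poisson(mean coverage) and
  sample alleles error-free, exactly the model the resampling correction
  inverts.

What the generator does *not* emulate — linkage disequilibrium between
SNPs, realistic site-frequency spectra, haplotype structure behind iHS,
sequencing error, reference bias, ancient DNA damage — bounds what
passing tests show: they validate the statistical machinery
(estimators, thresholds, randomization, calibration, power on planted
signals), not robustness to real-data artifacts. In particular,
adjacent windows on real data are correlated through LD, while
simulated SNPs are independent, so real-data network P-values are
"noisier" than the simulated calibration suggests — which is exactly
why the cluster-collapse step exists.

## Scales, seeds and numerical choices

Full-scale defaults match the analysis constants above (2,200,000
threshold SNPs; 11,000 random windows; 100,000 random networks;
500 × 2,500 resampling). The test suite and acceptance script run at
desk scale, a deliberate study-size choice: two populations of 50
diploids; genomes of 10 Mb with 20,000–600,000 SNPs (the densest panels
put thousands of qualifying SNPs in each 50-kb window, so the discrete
outlier fraction is fine-grained enough for uniformity checks); iHS
tracks of 200 sites/Mb over 200 Mb; 1,000 random windows and 2,000
random networks. Calibration claims at these sizes transfer to full
scale because every statistic is a fraction or rank whose resolution
only improves with more randomization draws.

All randomness is seed-controlled. `derive_seed()` maps a master seed
and stage label to a 31-bit integer via fixed offsets (no hashing), so
stages re-run independently yet reproducibly; simulators restore the
caller's RNG state. Range-maximum queries over tracks use a per
chromosome sparse table, making the 100,000-network randomization
linear-ish rather than quadratic. Infeasible spacing requests fail with
a diagnostic after a bounded rejection budget rather than looping
forever.

## Known limitations

* The empirical null inherits whatever selection the genome background
  contains; all tests are conservative in that direction.
* No model-based outlier detection, no low-F_ST (balancing-selection)
  scan — the one-tailed excess test is the design.
* VCF handling assumes diploid GT fields and one ALT allele per record;
  multi-allelic records are dropped, not decomposed.
* The ancient-heterozygosity module starts from a called site table;
  genotype calling from BAMs, contamination and damage modeling are
  upstream of this package.
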
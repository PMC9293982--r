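---
title: "Methods: haplotype-based selection scans and the expression association"
author: "desertsweep developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based selection scans and the expression association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes, which
knobs matter, what the synthetic-data generator does and does not emulate,
and where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Marker quality control

Three per-SNP filters are applied to the pooled sample set, each with
strict "less than" removal semantics:

* call rate `< 0.90` — fraction of non-missing genotypes;
* minor allele frequency `< 0.05` — `min(p, 1-p)` of the alternate-allele
  frequency among non-missing calls;
* Hardy–Weinberg exact p `< 1e-6`.

The HWE test is the exact conditional test: given the observed allele
totals, the p-value sums the probabilities of all heterozygote counts
(same parity, same allele totals) whose conditional probability does not
exceed the observed one. We chose the exact test over the chi-square
approximation because it is the established chip-QC practice and is
well-behaved at the rare-allele margin where the asymptotic test is not.
Probabilities are computed by a two-step recurrence anchored at the
distribution mode (numerically stable; no factorials of large numbers),
and the test suite checks it against a direct log-multinomial enumeration
for every configuration with up to 50 samples at 1e-12.

One consequence worth knowing: at the 1e-6 threshold the exact test
*cannot* reject with fewer than ~22 diploid samples — the most extreme
table at n = 20, a complete heterozygote deficit at frequency 0.5, still
has p ≈ 1.3e-6. The QC fixture generator therefore refuses sample sizes
below 24.

Filters are evaluated on the full sample set pooled across populations,
and the pipeline applies QC once, before haplotype expansion; haplotype
construction treats any remaining missing or unphased genotype as an
error rather than imputing.

## 2. Population structure

**PCA.** Genotype columns are mean-imputed, centred by `2p` and scaled by
`sqrt(2p(1-p))` (Patterson scaling), and the scores are SVD projections;
by construction the score covariance equals the eigenvalue diagonal,
which the tests assert numerically. Monomorphic SNPs are dropped with a
message — they carry no variance and would divide by zero.

**p-distance and neighbor joining.** The p-distance between two
individuals is the mean over co-observed SNPs of `|g_i - g_j|/2`
(pairwise deletion for missing data). Trees come from the Saitou–Nei
agglomeration on `Q(i,j) = (n-2) d(i,j) - R_i - R_j`; branch lengths use
the standard formulas, and a negative length is clamped to zero with the
deficit moved to its sibling so the joined pair's distance is preserved.
NJ is exact on additive matrices, which the acceptance suite verifies to
1e-9 on 100 random trees. Newick output uses fixed 6-decimal branch
lengths.

**LD.** Two r² modes exist because chip pipelines use both: haplotype r²
(`D²/(p_A p_a p_B p_b)` from phased frequencies) and the composite
squared Pearson correlation of genotype dosages. Pruning follows the
PLINK `--indep-pairwise 50 10 0.1` scheme on composite r²: within each
50-SNP window, while any retained pair exceeds 0.1, the worst pair loses
its lower-MAF member (equal MAF: the later-positioned SNP, for
determinism). The post-condition — no retained pair above the threshold
in any window the pruner visited — is re-checked exhaustively by a
brute-force scan in the tests. LD decay bins all intra-chromosome pairs
by physical distance (defaults 1-kb bins to 500 kb; the bin width is a
reporting choice, not an inference choice); pair counts include pairs
whose r² is undefined (monomorphic member), while bin means average only
defined values.

## 3. The four selection statistics

All haplotype statistics are built on one primitive: the probability that
two randomly drawn haplotypes from some set are identical over the
interval from a core SNP out to a flanking SNP,
`sum_k n_k(n_k-1) / (n(n-1))` over the distinct extended haplotypes. A
small C++ core refines the haplotype partition one SNP at a time, so a
whole-genome scan is linear in (haplotypes × extension length).

* **EHH / iHS.** EHH is that probability over the carriers of one core
  allele; it is 1 at the core and non-increasing outward. Extension stops
  when EHH drops below `ehh_cutoff` (default 0.05) or the chromosome
  ends. iHH is the trapezoid integral of the two-sided curve over
  physical distance, linearly interpolated to the exact cutoff crossing.
  Raw iHS is `ln(iHH_ancestral / iHH_derived)`; standardization is by
  z-score within derived-allele-frequency bins (20 equal-width bins,
  small bins merged with their nearest neighbour until each holds at
  least 10 scores), because the unstandardized ratio depends strongly on
  allele frequency.
* **EHHS / Rsb / xp-EHH.** The site versions pool all haplotypes,
  partitioned by core allele. The core-normalized variant (EHHS, used by
  Rsb) and the unnormalized site homozygosity (used by xp-EHH) share the
  same extension and the same stopping rule (applied to the normalized
  curve); their integrals are iES and inES. Raw cross-population scores
  are `ln(iES_A/iES_B)` and `ln(inES_A/inES_B)`, standardized
  genome-wide by z-score (Rsb also offers median centring). The two
  statistics coincide up to the per-SNP core-homozygosity factor; we keep
  both because the normalized form needs no polarization while the
  unnormalized form weights cores by their own homozygosity — the same
  division of labour the established EHH tooling uses.
* **Integration is over physical distance** (bp) because chip panels come
  without a genetic map; the units cancel in every log-ratio.
* **Edges and degeneracies.** A core whose curve never reaches the cutoff
  before the chromosome end is flagged `edge_truncated` and excluded from
  standardization under the default `edge_policy = "discard"`
  (`"truncate"` keeps the partial integral instead). Cores failing the
  MAF filter (default 0.05) are excluded from iHS only: the site-based
  integrals are computed for *all* cores, because a sweep drives the
  focal population toward fixation and a MAF filter there would mask
  precisely the xp-EHH/Rsb signal.
* **FST.** Per-SNP Weir–Cockerham variance components for two
  (possibly pooled) populations; `theta = a/(a+b+c)`, undefined (flagged)
  when the denominator is zero or a population has fewer than two
  genotyped samples; the panel average is the ratio of sums `Σa/Σ(a+b+c)`
  rather than the mean of ratios. Note the estimator's small-sample
  behaviour: identical genotype tables in both populations give a
  slightly *negative* theta unless all heterozygosity sits within
  individuals — the tests assert this against an independently coded
  textbook calculator rather than pretending the value is zero.

Thresholding of any score table takes the `ceiling(f·n_valid)` most
extreme standardized scores (|z| for two-sided; one-sided for FST's upper
tail), ties included; the fraction is multiplied with a 1e-9 guard so
that `0.07 × 100` is 7, not 8, despite floating point.

## 4. Candidate genes and the expression association

Genes are annotated to selected SNPs when `[start - flank, end + flank]`
(1-based, inclusive) contains a selected position; the default flank of
50 kb reflects typical chip marker spacing — on a ~50k-marker genome a
swept haplotype's nearest chip SNP is tens of kb from the causal gene.
The search uses an interval tree; tests compare it against an all-pairs
oracle. Per-test gene sets at 1% and 5% feed UpSet-style exclusive
intersections (sizes sum to the union), and the candidate gene set (CGS)
defaults to the *union* of the per-test 1% sets, with intersection mode
first-class for the stricter any-test-agrees construction at 5%.

The expression arm takes FPKM (`1e6·C/(N·L/1e3)`) either precomputed or
from counts + gene lengths. Stage specificity is the least-squares
t-statistic of the focal-stage indicator in `X = [indicator, intercept]`:
`t = beta[0] / sqrt(MSE · [(X'X)^{-1}]_{00})` with `MSE = RSS/N`. Two
deliberate choices here:

* `MSE` divides by `N`, not `N-2`. That is the contract this package
  implements; algebraically it *inflates* t relative to the classic
  pooled two-sample statistic by `sqrt(N/(N-2))`, and the tests assert
  exactly that identity. Since every gene's t is inflated by the same
  factor within a stage, rankings — and hence SEGS membership — are
  unaffected.
* Genes are ranked by *signed* t, descending, so "top 7%" means
  up-regulation in the focal stage; values enter untransformed (no log),
  and per-stage replicate groups are the default contrast unit (a
  per-sample leave-one-in mode is available behind `by = "sample"`).

The association intersects the CGS with each stage's SEGS and reports the
contribution `|CGS ∩ SEGS_s| / |∪_s (CGS ∩ SEGS_s)|`, zero when the union
is empty. qPCR arithmetic is the standard `2^-((dCt_sample)-(dCt_calibrator))`.

## 5. The synthetic world

The generator is a *stated world*, not a tuned one: its defaults are the
conditions the tests run under, chosen once.

* Two populations × 50 diploid samples, 5,000 SNPs on a 10-Mb chromosome
  (2-kb spacing — a chip-density panel scaled down to desk size).
* Founder allele frequencies from a U-shaped Beta(0.2, 0.2) clipped to
  [0.05, 0.95]; per-population frequencies drawn Balding–Nichols around
  them. The founder *pool* (50 haplotypes per population) adds roughly
  `1/n_founders` of extra drift on top of the Beta variance, so the Beta
  parameter is set to `drift_fst_target - 1/n_founders`; the acceptance
  calibration checks the realized Weir–Cockerham mean lands within ±0.05
  of the 0.10 target.
* Haplotypes are founder mosaics with geometric segment lengths (mean
  20 kb), which yields monotonically decaying LD over tens of kb.
* Hard sweeps are implanted mechanically: a donor haplotype overwrites
  `carrier_fraction` (0.8 in the acceptance runs — a strong,
  near-complete hard sweep) of the focal population's haplotypes across a
  200-kb window. This reproduces the two features the statistics detect —
  a long shared haplotype and elevated site homozygosity — without
  claiming coalescent realism: no mutation/recombination process, no soft
  sweeps, no demographic history. A green sweep-recovery test therefore
  establishes that the statistics detect the *signature*, not that they
  would have a particular power on real data.
* Expression: 4 stages × 3 replicates, 1,000 genes, log-normal baselines,
  4-fold focal-stage effects on 20 genes per stage, 10% multiplicative
  noise. Counts are generated first and the FPKM matrix is *defined* as
  `fpkm_matrix()` of those counts, making the count/FPKM round trip exact
  rather than approximate.
* Every generator is a pure function of `(config, seed)`; the fixture
  bundle is byte-stable under a fixed seed, which the tests check by
  hashing.

The neutral-calibration check on iHS ("about 5% of |z| above 2") uses the
band [0.030, 0.065] around the Gaussian 4.55%, fixed a priori: at the
pooled test size the binomial noise is below 0.2%, so the band width is
an explicit allowance for residual non-normality of the log-ratio within
frequency bins, not a fitted tolerance.

## 6. Known limitations

* Phasing is an input contract: the package consumes phased VCFs and
  never phases or imputes.
* Cross-population scans assume the same SNP panel in both populations
  and error out otherwise; no panel harmonization is attempted.
* The PLINK text dialect carries no allele labels, so allele orientation
  on read follows a "first allele seen is the reference" convention; the
  synthetic writer orients its output accordingly, but external .ped
  files round-trip only up to that convention.
* No statistical significance is attached to scan thresholds: top-1%/5%
  tails are selection heuristics, as in the scan literature, not
  calibrated p-values.
* ADMIXTURE-style ancestry modelling, enrichment analysis against
  external databases, read alignment/quantification and figure rendering
  are out of scope; outputs are plain TSV/JSON designed to be plotted or
  post-processed elsewhere.
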
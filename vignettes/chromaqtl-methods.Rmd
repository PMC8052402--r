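---
title: "Models and design choices in chromaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in chromaqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chromaqtl maps genetic effects on chromatin phenotypes across genotyped
donor cohorts and follows them through allele-specific signals, chromatin
contacts and disease associations. This vignette documents the statistical
models, the parameters that matter, the synthetic-data generator that
stands in for controlled-access cohort data, and the places where the
design was genuinely open and a choice had to be made.

## Phenotype normalisation

Raw per-donor read counts under consensus features are transformed in a
fixed order, tracked by a machine-checked `stage` field so mis-ordered
pipelines fail rather than silently producing shifted results:

1. **log2RPM**: `log2((count + 0.5) * 1e6 / library_size)`. The pseudocount
   of 0.5 keeps zero counts finite while preserving the "log2RPM > 0 iff
   RPM > 1" semantics of the downstream filter for non-zero counts.
2. **Presence filter**: a feature is kept when log2RPM exceeds 0 in at
   least `ceiling(0.5 * n_donors)` donors. At exactly half the donors the
   rule is inclusive (the `>=`/ceiling reading of "at least 50%").
3. **Latent-factor correction**: confounders are estimated as principal
   components of the feature-standardised matrix and removed by linear
   residualisation. Principal components are a deliberate stand-in for
   factor-analysis style confounder estimation: for dense molecular
   matrices the two track each other closely, and the residualisation step
   is identical. The number of factors defaults to a permutation choice
   (below) rather than a fixed K; a fixed K (e.g. 10, a common choice for
   cohort ChIP studies) can be configured. With desk-scale feature counts
   (hundreds rather than tens of thousands) a fixed large K is risky:
   when a third of features carry planted genetic effects, extra
   components align with true signal and absorb it, which is why the
   permutation default is used throughout the tests.
4. **Quantile normalisation**: each donor column is mapped onto the
   row-wise mean of sorted columns (`limma::normalizeQuantiles`,
   ties = average rank). Applying it twice equals applying it once. We
   implement the standard across-donor column form; the per-donor
   alternative is not offered.

**Choosing the factor count by permutation.** Explained variances of the
observed components are compared against matrices whose rows are permuted
independently (per-feature distributions preserved, cross-feature
structure destroyed). `k` is the largest N such that components 1..N all
exceed the permutation envelope, summarised at the 95th percentile of the
permuted explained variances. The percentile (rather than the mean) keeps
the false-positive rate of the first component near 5% on pure noise.

**Consensus peaks** merge per-sample peak calls by single-linkage union
with a strictly positive (>= 1 bp) overlap — abutting intervals are not
merged — and keep merged intervals supported by at least 3 samples
(configurable). Sex chromosomes are excluded, mirroring their exclusion
from the QTL analysis. Broad repressive-mark domains are tiled into
2500-bp windows; the final window is truncated at the peak end so windows
never extend past called enrichment.

## cis-QTL mapping

For each feature, all variants within 1 Mb of either feature edge are
tested under

$$y = \mu + g\beta + u + e, \qquad u \sim N(0, \sigma_g^2 K), \quad
e \sim N(0, \sigma_e^2 I),$$

with $K$ the standardised realised-relatedness matrix
($K = ZZ^\top/m$ over centred, scaled dosages). The implementation is the
standard two-stage approximation: eigendecompose $K$ once, fit the
heritability ratio per feature by maximum likelihood under the null
(intercept-only) model on the rotated data, then score every cis variant
with a Wald t-test on the weighted (generalised) least-squares fit. With
`kinship = NULL` the fit is OLS; with an identity kinship the two paths
agree to machine precision, which the tests assert at 1e-6.

Numerical details: the heritability ratio is optimised on (1e-4, 0.9999)
so weights stay finite even when $K$ has near-zero eigenvalues (the
centred dosage construction always produces one); missing dosages are
mean-imputed for testing only; variants with no genotype variance among
tested donors are skipped and counted.

**Two-step multiple testing.** The minimum p per feature is
Bonferroni-adjusted by that feature's number of tested variants, and the
adjusted minima are passed across features to the Storey q-value
procedure, declaring QTLs at q < 0.05. Whether the adjusted or raw minima
enter the q-value step is not fully pinned down by common usage; we use
the adjusted minima — the cited two-step standard — and note that using
raw minima would make the second step anti-conservative.

**Storey pi0.** pi0 is estimated on the grid `lambda = 0.05..0.95` as
`mean(p > lambda)/(1 - lambda)`, smoothed by a cubic spline (df = 3) and
read off as the mean prediction over `lambda in [0.4, 0.6]`. The classical
endpoint evaluation at `lambda = 0.95` is unbiased under diffuse
alternatives but has standard error ~0.04-0.06 at m = 2000, which is too
noisy to certify pi0 to ±0.05; the mid-grid evaluation cuts that to
~0.01-0.02 at the cost of a small upward bias when alternatives have mass
above 0.5. For QTL-style look-ups, where true signals are concentrated
near zero, the trade is clearly favourable. Below 100 p-values the
estimate falls back to the fixed point `lambda = 0.5`.

**Leads and clumping.** Per significant feature the minimum-p variant is
the lead (ties: smallest p, then largest |beta|, then smallest position —
fully deterministic). Greedy clumping by ascending p absorbs a lead into
an earlier-kept one at dosage r^2 >= 0.8; survivors are the independent
QTLs. Distance is measured to the nearest feature edge (not the midpoint),
0 inside the feature, and the proximal/distal boundary is strict:
|distance| < 2500 bp is proximal.

## Allele-specific analysis

Read-count filters follow the field's conventions exactly: a
(variant, donor) observation needs >= 10 reads and non-zero counts on both
alleles; a variant needs >= 2 qualifying rows. Rows are the filtering unit,
so one donor measured in two cell types can satisfy the requirement — the
cross-sample consistency filter (below) is where single-sample evidence is
restricted.

The imbalance test is a beta-binomial likelihood-ratio test of a shared
reference fraction of 0.5 against a free fraction, with the intra-class
correlation rho shared across donors. rho = 0 collapses to the exact
binomial test on pooled counts. When `rho = "estimate"`, a method-of-moments
estimator pools all sites of an assay; the within-site residual sums carry
a k/(k-1) correction for the degree of freedom absorbed by the pooled site
fraction — without it rho is biased low by ~(k-1)/k and the null type-I
rate at 5% drifts to ~7%. A full joint model of total and allelic counts
with genotype-error and reference-mapping-bias terms is out of scope here:
the generator's counts are mapping-bias-free by construction, so the
beta-binomial test carries the same validation logic (do QTL leads show
allelic imbalance?) without modelling artefacts it cannot see.

Promoter-contact (PCHi-C-style) calls work per (variant, donor, cell
type): reference fractions outside (1%, 99%) are removed as extreme bias —
a fraction cannot exceed 100%, so the upper bound of the conventional
"<1% or >100%" phrasing is read as 99%, and both bounds are parameters —
and remaining observations are biased at <= 40% or >= 60% (inclusive).
"Allele bias" is interpreted as the signed reference-read fraction; the
two-sided 40/60 window only makes sense for a signed fraction. The
consistency filter retains a variant observed in >= 2 samples, or in one
sample but both cell types, provided all observations fall on the same
side of 0.5 (exact 0.5 observations carry no direction and are ignored
for the direction check). Donor identity is verified by genotype
concordance over shared sites, matching at > 90%.

## Sharing and PIR enrichment

Sharing between molecular layers uses three complementary views: LD
overlap of leads (identical variant or r^2 >= 0.8; one best partner per
lead, ties to the nearest position), pi1 = 1 - pi0 on look-up p-values
(each layer-A lead looked up on its nearest layer-B feature within 1 Mb —
the look-up rule is our choice, as cross-layer look-ups are rarely spelled
out further), and direction-of-effect concordance with zero products
counted positive and logged (determinism over silent drops).

PIR membership counts other-end fragments of interactions with score
strictly above 5; bait-only overlap never counts, because the
promoter-interacting region is by definition the non-bait end. Enrichment
is tested per sample with Fisher's exact test on the
(significant QTL) x (in PIR) table — implemented as the exact conditional
hypergeometric p with the same two-sided definition `stats::fisher.test`
uses, verified against it in the tests — and summarised as the
cross-sample mean ± sd of odds ratios (sample cross-product ratio; zero
margins are flagged rather than patched). The combined approach flags
variants where at least N samples fall in a PIR and at least N carry a
significant QTL, for N = 1..4.

The genomic permutation null re-places query intervals uniformly within
their chromosome, preserving lengths, with the empirical p
`(1 + #null >= observed)/(n_perm + 1)` at 50 permutations by default. This
is the simplest null consistent with randomising genomic regions;
rank-preserving or gap-aware randomisations are not implemented.
Expression binning assigns PIRs to four near-equal bins (sizes differ by
at most one) by their bait gene's expression, ties to the lower bin; the
alternative of binning over genes rather than PIRs would weight
multi-PIR genes differently. The distance-matched effect comparison
excludes records within 25 kb of the TSS, greedily matches each in-PIR
record to the nearest-|distance| out-of-PIR record without replacement
(ties to the lower position), and compares |beta| with a two-sided
rank-sum test.

## Colocalisation

Wakefield log approximate Bayes factors are computed in log space with
prior effect variance w = 0.15^2 for quantitative traits (0.2^2 suggested
for case-control log-odds effects); when only (p, MAF, N) are available,
the standard error is reconstructed from the standard approximation.
Per-hypothesis evidence is assembled by log-sum-exp over single-variant
configurations (H1, H2, shared H4) and ordered variant pairs i != j
(distinct H3), all variants carrying equal prior probability; the prior
mass of the null configuration is the leftover
`1 - n p1 - n p2 - n p12 - n(n-1) p1 p2`, so the five posteriors sum to
one exactly. Output labels follow the community convention (H3 =
distinct, H4 = shared); because the same four-alternative-model scheme is
sometimes numbered with the shared model third, every result carries a
`model_numbering` field recording the mapping. Loci with one shared
variant leave H3 undefined and emit a classed warning.

Per-locus maximum-likelihood priors maximise the locus marginal
likelihood over log10 priors in `p1, p2 in [1e-6, 1e-2]`,
`p12 in [1e-8, min(p1, p2)]`, by a coarse feasible grid followed by
Nelder-Mead with the constraint enforced by clamping inside the
objective; configurations whose leftover null mass is non-positive score
-Inf. We optimise all three priors jointly (a p12-only search is a
trivial restriction of the same objective). Priors estimated from a
single locus are prone to overestimation; results carry a
`single_locus_warning` flag rather than silently standing in for
multi-locus estimates. The catalogue pre-selects QTL-GWAS pairs whose
leads are identical or in r^2 >= 0.8, tests each over the shared variant
list, and emits pairs with shared-signal PP strictly above 0.9.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known ground truth. What it emulates:

- **Genotypes**: biallelic dosages in LD blocks via block-haplotype
  copying — each block owns a small founder pool (8 haplotypes) and each
  donor chromosome is a Markov mosaic over the pool (switch probability
  0.05 per variant), giving r^2 that decays within blocks and vanishes
  across them without coalescent machinery. Related pairs share a full
  chromosome (expected kinship ~1/4). The founder pool introduces drift,
  so a variant's realised MAF can differ from its nominal frequency —
  occasionally to fixation; consumers select on empirical MAF.
- **Signal**: latent log2 abundance = baseline + beta x dosage + latent
  confounders + Gaussian noise (sd 1), observed through a
  negative-binomial count layer (log link) with per-donor log-normal
  library sizes. Across-donor count dispersion is not a published
  quantity for ChIP cohorts; it is exposed as a parameter with default
  0.05, a mid-range value for biological replicates. Planted effects are
  expressed per alternate allele on the latent log2 scale, i.e. in units
  of the residual phenotype SD.
- **Allelic counts**: Poisson depths (floored at 1) and beta-binomial
  reference counts at donor-heterozygous sites; unbiased sites have
  reference fraction 0.5.
- **Interactions**: candidate other-ends receive scores above 5 (planted
  PIR fraction) or uniform on [0, 5], attached to random non-overlapping
  baits.
- **Locus summary statistics**: marginal z-scores drawn from
  MVN(R lambda, R) with R the panel dosage correlation and lambda the
  causal non-centrality (default 8), under five scenarios (null, single
  trait x2, distinct causal pair with r^2 below a cap, shared causal);
  beta = z/sqrt(n) on the standardised scale.

What it does not emulate — and what passing tests therefore do not show
about real data: read-level artefacts (mapping bias, duplicates, peak
mis-calling), genotype uncertainty and imputation error, population
structure beyond simple relatedness, trans effects, and case-control
ascertainment. All generators are bit-deterministic for a fixed seed;
per-stage sub-seeds are derived from one master seed so stages can be
re-run in isolation.

## Study conditions used by the packaged experiments

The test-suite and acceptance experiments run at desk scale, chosen once
as a realistic miniature of a cohort study: null-calibration cohorts of
100 donors, 200 features and 20,000 variants at ~1 kb spacing (20
replicates); recovery cohorts of 100 donors, 200 features with 60 planted
proximal effects of one phenotype SD at MAF >= 0.2, over a 3000-variant
panel at ~10 kb spacing (an LD-pruned-panel density); allelic experiments
at depth 50-60 over 20-30 donors with 1000+ null and 200 biased sites;
colocalisation recovery over 100 loci per scenario with 50 variants on a
shared 400-donor LD panel. The end-to-end pipeline default is 60 donors,
4000 variants, 100 features with 20 planted effects of 1.5 SD.

## Known limitations

- Single-variant association only: no conditional or stepwise secondary
  signals, no trans scans, no fine-mapping beyond single-variant ABFs.
- The colocalisation model assumes one causal variant per trait per
  locus; with two causal variants in high LD it has limited power to
  separate shared from distinct signals, which is why scenario-recovery
  expectations are lower for the distinct-pair case.
- The latent-factor correction is linear; non-linear batch structure is
  not captured.
- BAM-level read processing (base/mapping quality filters, re-mapping for
  reference bias) is out of scope; the allelic filters operate on count
  tables produced elsewhere.
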
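# chromaqtl

Integrative mapping of genetic effects on chromatin phenotypes in
multi-donor cohorts: transcription-factor binding QTLs (tfQTLs),
histone-mark QTLs (hQTLs), allele-specific binding and promoter-contact
imbalance, sharing between molecular layers, enrichment in
promoter-interacting regions (PIRs), and Bayesian colocalisation with GWAS
traits.

## Who this is for

Groups that quantify a molecular phenotype (ChIP-seq read counts under
peaks, promoter-capture Hi-C contacts, expression) across tens to hundreds
of genotyped donors and want to ask, stage by stage: which variants shift
the phenotype in *cis*; whether those effects replicate across assays and
cell types; whether they concentrate in the enhancer side of
promoter-enhancer contacts; and whether they share causal variants with
disease associations. Every stage is also exercised by a synthetic-data
generator with known ground truth, so the full pipeline is testable without
any controlled-access data.

## The models at the core

**cis-QTL mapping.** For each feature (peak, window, gene) with normalised
phenotype vector *y* over donors, every variant with dosage *g* within 1 Mb
of a feature edge is scored with the single-random-effect linear mixed
model

  y = mu + g beta + u + e,  u ~ N(0, sigma_g^2 K),  e ~ N(0, sigma_e^2 I)

where *K* is the realised relatedness matrix from genome-wide dosages. The
variance components are fitted once per feature under the null on
eigen-rotated data; each variant is then a Wald t-test on the
generalised-least-squares fit (kinship = identity reduces exactly to OLS).
Multiple testing is controlled in two steps: Bonferroni across variants
within each feature, then Storey q-values across features, with QTLs
declared at q < 0.05. Leads in mutual LD (r^2 >= 0.8) are clumped to
independent QTLs and classified proximal (< 2.5 kb from the peak edge) or
distal.

**Phenotype normalisation.** Raw counts become log2 reads-per-million,
features must exceed log2RPM > 0 in at least half the donors, latent
confounders (principal-component factors, count chosen by a permutation
null) are residualised out, and donors are quantile-normalised to a common
distribution.

**Allelic imbalance.** At donor-heterozygous sites with >= 10 reads,
non-zero counts on both alleles and >= 2 qualifying rows, the reference
fraction is tested against 0.5 with a beta-binomial likelihood-ratio test
(dispersion estimated by method of moments; rho = 0 collapses to the exact
binomial). Promoter-contact reads use the 40%/60% bias windows after
removing extreme bias outside (1%, 99%), with cross-sample consistency
rules.

**Sharing and enrichment.** Cross-layer sharing is quantified by pi1 = 1 -
pi0 on look-up p-values and by direction-of-effect concordance of shared
leads. PIR enrichment uses per-sample Fisher exact tests
(2x2: significant QTL x in-PIR) and genomic permutation nulls (50
random placements preserving interval lengths within chromosomes).

**Colocalisation.** Per locus, Wakefield log approximate Bayes factors

  log ABF = 0.5 log(se^2/(se^2+w)) + 0.5 (w/(se^2+w)) (beta/se)^2

are combined over single-variant and variant-pair configurations into
posterior probabilities of five hypotheses (no signal; trait-1 only;
trait-2 only; two distinct causal variants; one shared causal variant),
with per-variant priors (p1, p2, p12) optionally estimated per locus by
maximum likelihood. Shared-signal pairs at PP > 0.9 form the catalogue.

## Worked example

```r
library(chromaqtl)
library(dplyr)

# synthetic cohort: 100 donors, 3000 variants in LD blocks, 150 peaks,
# 30 planted proximal effects of one phenotype SD per alternate allele
g <- simulate_genotypes(100, 3000, ld_block_len = 10, spacing = 10000, seed = 42)
eligible <- filter(g$variants, maf >= 0.2)
effects <- withr::with_seed(43, tibble::tibble(
  variant_id = sample(eligible$variant_id, 30),
  beta = sample(c(-1, 1), 30, TRUE), proximity = "proximal"))
sim <- simulate_signal(g, n_features = 150, effects = effects, k_conf = 2, seed = 44)

# normalise: log2RPM -> presence filter -> factor correction -> quantile
l2  <- filter_features(compute_log2rpm(sim$signal))
k   <- select_k_by_permutation(l2, n_perm = 20, seed = 45)   # k = 2
sig <- quantile_normalize(correct_confounders(l2, k = k))

# mixed-model cis scan, two-step FDR, LD clumping
rec   <- map_cis_qtl(sig, g, kinship = g$kinship)            # 25384 tested pairs
leads <- correct_multiple_testing(rec, fdr = 0.05)           # 30 significant features
indep <- clump_leads(filter(leads, significant), g, r2_min = 0.8)
filter(indep, is_independent) |>
  select(feature_id, variant_id, beta, se, p, q, distance, proximity) |>
  head(3)
#>   feature_id variant_id  beta    se        p            q distance proximity
#> 1 feat0014   var00804   -1.10 0.133 7.76e-13 0.0000000179        0 proximal
#> 2 feat0027   var00590    1.18 0.146 1.45e-12 0.0000000179        0 proximal
#> 3 feat0022   var01994   -1.03 0.137 3.01e-11 0.000000177         0 proximal
```

The scan declares 30 significant features, all of them independent after
clumping, and 28 of the 30 planted effects are recovered with the causal
variant in the lead's r^2 >= 0.8 set; the estimated betas sit near the
planted +/-1 with standard errors around 0.14, and every lead falls inside
its peak (distance 0, proximal).

Colocalising a simulated shared-causal-variant locus:

```r
loc <- simulate_gwas_locus("H4", n_snps = 50, effect_size = 8, seed = 46)
res <- coloc_pp(loc$trait1, loc$trait2)
res
#> <coloc_result> 50 variants | PP0-4: 0.000 0.000 0.000 0.000 1.000
glance(res)[, c("pp3", "pp4", "lead1", "lead2")]
#>   pp3        pp4   lead1    lead2
#>   1.02e-11   1.00  var00038 var00038
```

The shared-variant posterior is ~1 and both traits point at the same lead
variant, as planted.

A full pipeline run (`run_pipeline(default_config(), "out/")`, or the
command-line wrapper `inst/cli/chromaqtl.R all --seed 7 --out out/`) writes
VCF genotypes, BED peaks, the normalised signal matrix, QTL lead tables,
allelic-imbalance calls, sharing summaries, PIR enrichment and a
colocalisation catalogue, plus a provenance record; identical
configurations reproduce byte-identical outputs.

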
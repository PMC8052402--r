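test_that("variant QC filters match a naive re-application oracle", {
  g <- tiny_geno(60, 120, seed = 13)
  # inject missingness and a monomorphic variant
  G <- g$dosage
  withr::with_seed(14, {
    G[sample(length(G), 200)] <- NA
  })
  G[, 5] <- 0L
  g2 <- geno_matrix(G, g$variants)
  got <- filter_variants(g2, maf_min = 0.05, hwe_p_min = 1e-6,
                         miss_max = 0.05, info_min = 0.8)
  # oracle: each filter independently
  keep <- logical(ncol(G))
  for (j in seq_len(ncol(G))) {
    x <- G[, j]
    miss <- mean(is.na(x))
    af <- mean(x, na.rm = TRUE) / 2
    maf <- min(af, 1 - af)
    if (is.nan(maf)) maf <- 0
    hwe <- chromaqtl:::hwe_exact_p(sum(x == 2, na.rm = TRUE),
                                   sum(x == 1, na.rm = TRUE),
                                   sum(x == 0, na.rm = TRUE))
    keep[j] <- maf >= 0.05 && hwe >= 1e-6 && miss <= 0.05 &&
      g$variants$info[j] >= 0.8
  }
  expect_equal(got$variants$variant_id, g$variants$variant_id[keep])
  expect_false("var00005" %in% got$variants$variant_id)  # monomorphic out
})

test_that("exact HWE test agrees with direct multinomial enumeration", {
  # spot-check against hand-enumerated probabilities
  p_obs <- chromaqtl:::hwe_exact_p(1, 0, 1)  # all homozygous, na = nb = 2
  # configurations with na=nb=2, n=2: het in {0, 2}; P(h=2) = 2/3, P(h=0) = 1/3
  expect_equal(p_obs, 1 / 3)
  expect_equal(chromaqtl:::hwe_exact_p(0, 2, 0), 1)
  expect_equal(chromaqtl:::hwe_exact_p(5, 0, 0), 1)  # monomorphic
})

test_that("cis mapping respects the window and collapses to OLS at identity kinship", {
  g <- tiny_geno(50, 40, seed = 23, spacing = 100000)  # ~4 Mb span
  sim <- simulate_signal(g, 6, effects = NULL, k_conf = 0, seed = 24)
  sig <- quantile_normalize(correct_confounders(
    filter_features(compute_log2rpm(sim$signal)), k = 0))
  rec <- map_cis_qtl(sig, g, window = 1e6)
  # no tested pair further than 1 Mb from the feature edge
  expect_true(all(abs(rec$distance) <= 1e6))
  # some variants on the same chromosome were excluded by the window
  expect_lt(nrow(rec), 6 * 40)
  rec_id <- map_cis_qtl(sig, g, kinship = diag(50), window = 1e6)
  expect_lt(max(abs(rec_id$p - rec$p)), 1e-6)
  expect_lt(max(abs(rec_id$beta - rec$beta)), 1e-8)
  # OLS agreement with lm on a spot-checked pair
  row <- rec[17, ]
  fit <- summary(lm(sig$values[row$feature_id, ] ~
                      g$dosage[, row$variant_id]))$coefficients
  expect_equal(row$beta, unname(fit[2, 1]), tolerance = 1e-10)
  expect_equal(row$p, unname(fit[2, 4]), tolerance = 1e-10)
  expect_error(map_cis_qtl(sig, tiny_geno(10, 5, seed = 1)),
               class = "chromaqtl_invalid_argument")
})

test_that("a planted effect is mapped with correct effect size and power", {
  # phenotype with a unit effect per alt allele on the mapped scale
  hits <- vapply(1:20, function(s) {
    g <- simulate_genotypes(100, 200, ld_block_len = 1,
                            maf_range = c(0.29, 0.31), seed = 400 + s)
    vpick <- g$variants$variant_id[g$variants$maf >= 0.25][15]
    withr::with_seed(500 + s, {
      vals <- matrix(rnorm(10 * 100), 10, 100)
      vals[1, ] <- g$dosage[, vpick] + rnorm(100)
    })
    colnames(vals) <- rownames(g$dosage)
    sig <- manual_signal(vals, stage = "quantile_normalised",
                         start_pos = g$variants$pos[
                           match(vpick, g$variants$variant_id)])
    rec <- map_cis_qtl(sig, g)
    row <- rec[rec$feature_id == "feat0001" & rec$variant_id == vpick, ]
    c(abs(row$beta - 1) <= 3 * row$se, row$p < 1e-5)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.9)   # beta-hat within 3 SE of truth
  expect_gte(mean(hits[2, ]), 0.9)   # power at p < 1e-5
})

test_that("q-values follow the Storey construction", {
  expect_equal(qvalue_storey(0.03, pi0 = 1)$qvalues, 0.03)
  expect_error(qvalue_storey(c(0.5, 0)), class = "chromaqtl_invalid_argument")
  # null p-values: pi0 close to 1
  withr::with_seed(31, p <- runif(5000))
  pi0 <- qvalue_storey(p)$pi0
  expect_gte(pi0, 0.9)
  expect_lte(pi0, 1)
  # 25% strong alternatives: pi0 within 0.05 of 0.75
  withr::with_seed(32, pm <- c(10^-runif(500, 6, 10), runif(1500)))
  expect_lt(abs(qvalue_storey(pm)$pi0 - 0.75), 0.05)
  # q monotone non-decreasing in p
  q <- qvalue_storey(pm)$qvalues
  ord <- order(pm)
  expect_true(all(diff(q[ord]) >= -1e-12))
})

test_that("two-step correction matches closed form and a two-loop oracle", {
  rec1 <- tibble::tibble(
    feature_id = "f1",
    variant_id = paste0("v", 1:10), chrom = "chr1", pos = 1:10 * 100,
    beta = rnorm(10), se = 1, p = c(1e-6, runif(9, 0.2, 1)),
    distance = 0, proximity = "proximal", n = 50)
  leads <- correct_multiple_testing(rec1)
  expect_equal(leads$bonf_p, 1e-5)  # 1e-6 * 10
  expect_equal(leads$variant_id, "v1")
  # fuzzed records against a naive oracle
  withr::with_seed(33, {
    rec <- tibble::tibble(
      feature_id = rep(sprintf("f%02d", 1:30), each = 20),
      variant_id = rep(sprintf("v%03d", 1:20), times = 30),
      chrom = "chr1", pos = rep(1:20 * 50, 30),
      beta = rnorm(600), se = 1, p = runif(600)^3,
      distance = 0, proximity = "proximal", n = 80)
  })
  got <- correct_multiple_testing(rec, fdr = 0.05)
  # oracle: per-feature min and Bonferroni by explicit loops
  feats <- unique(rec$feature_id)
  bonf <- numeric(length(feats))
  lead_v <- character(length(feats))
  for (i in seq_along(feats)) {
    sub <- rec[rec$feature_id == feats[i], ]
    j <- which.min(sub$p)
    bonf[i] <- min(1, sub$p[j] * nrow(sub))
    lead_v[i] <- sub$variant_id[j]
  }
  got <- got[match(feats, got$feature_id), ]
  expect_equal(got$bonf_p, bonf)
  expect_equal(got$variant_id, lead_v)
  qo <- qvalue_storey(bonf)
  expect_equal(got$q, qo$qvalues)
  expect_equal(got$significant, qo$qvalues < 0.05)
})

test_that("LD r2 handles identity, flips and degenerate input", {
  g <- tiny_geno(50, 10, seed = 43, maf_range = c(0.3, 0.5))
  x <- g$dosage[, which.max(g$variants$maf)]
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 2 - x), 1)
  expect_warning(r <- ld_r2(x, rep(1, 50)), class = "chromaqtl_ld_undefined")
  expect_true(is.na(r))
  # independent variants are near-uncorrelated
  gi <- simulate_genotypes(500, 40, ld_block_len = 1,
                           maf_range = c(0.4, 0.5), seed = 44)
  r2s <- vapply(seq(2, 40, 2), function(j)
    ld_r2(gi$dosage[, j - 1], gi$dosage[, j]), numeric(1))
  expect_gte(mean(r2s < 0.05), 0.9)
})

test_that("greedy clumping matches the enumeration oracle and ignores input order", {
  # construct three dosage vectors with controlled correlations:
  # A-B high, B-C high, A-C low
  withr::with_seed(45, {
    a <- rbinom(200, 2, 0.5)
    b <- a
    flip <- sample(200, 12)
    b[flip] <- rbinom(12, 2, 0.5)
    cc <- b
    flip2 <- sample(200, 12)
    cc[flip2] <- rbinom(12, 2, 0.5)
  })
  G <- cbind(A = a, B = b, C = cc)
  rownames(G) <- sprintf("donor%03d", 1:200)
  r_ab <- ld_r2(a, b); r_bc <- ld_r2(b, cc); r_ac <- ld_r2(a, cc)
  expect_gt(r_ab, 0.8); expect_gt(r_bc, 0.8)
  variants <- tibble::tibble(variant_id = c("A", "B", "C"), chrom = "chr1",
                             pos = c(100L, 200L, 300L), ref = "A", alt = "G",
                             maf = 0.5, info = 1)
  g <- geno_matrix(G, variants)
  leads <- tibble::tibble(feature_id = c("f1", "f2", "f3"),
                          variant_id = c("A", "B", "C"),
                          chrom = "chr1", pos = c(100L, 200L, 300L),
                          beta = c(2, 1.5, 1), se = 1,
                          p = c(1e-10, 1e-8, 1e-6),
                          distance = 0, proximity = "proximal", n = 200)
  got <- clump_leads(leads, g, r2_min = 0.8)
  kept <- got$variant_id[got$is_independent]
  if (r_ac < 0.8) {
    expect_setequal(kept, c("A", "C"))  # B absorbed by A; C survives via low A-C LD
  } else {
    expect_setequal(kept, "A")
  }
  # two identical leads collapse to one; independent ones stay
  two <- leads[c(1, 1), ]
  two$feature_id <- c("f1", "f2")
  expect_equal(sum(clump_leads(two, g)$is_independent), 1)
  # order invariance
  got_rev <- clump_leads(leads[3:1, ], g, r2_min = 0.8)
  expect_setequal(got_rev$variant_id[got_rev$is_independent], kept)
})

test_that("proximity classification follows the 2.5 kb edge rule", {
  inside <- classify_proximity(pos = 150, start = 100, end = 200)
  expect_equal(inside$distance, 0)
  expect_equal(inside$proximity, "proximal")
  near <- classify_proximity(pos = 200 + 264, start = 100, end = 200)
  expect_equal(near$distance, 264)
  expect_equal(near$proximity, "proximal")
  far <- classify_proximity(pos = 200 + 23000, start = 100, end = 200)
  expect_equal(far$distance, 23000)
  expect_equal(far$proximity, "distal")
  # boundary: exactly 2500 bp is distal (strict <)
  edge <- classify_proximity(pos = 200 + 2500, start = 100, end = 200)
  expect_equal(edge$proximity, "distal")
  left <- classify_proximity(pos = 50, start = 100, end = 200)
  expect_equal(left$distance, -51)
  expect_equal(left$proximity, "proximal")
})

test_that("distance profiles recover means, t-intervals and decaying trends", {
  # all pairs in one bin: mean equals the arithmetic mean; CI matches formula
  anchors <- tibble::tibble(variant_id = paste0("v", 1:20), pos = 1:20)
  withr::with_seed(46, betas <- rnorm(20, 1, 0.3))
  partners <- tibble::tibble(variant_id = paste0("v", 1:20),
                             feature_id = paste0("g", 1:20),
                             beta = betas, distance = 5000)
  res <- effect_distance_profile(anchors, partners, bins = c(0, 1e4))
  expect_equal(res$profile$n, 20)
  expect_equal(res$profile$mean_abs_beta, mean(abs(betas)))
  half <- qt(0.975, 19) * sd(abs(betas)) / sqrt(20)
  expect_equal(res$profile$ci_hi - res$profile$mean_abs_beta, half,
               tolerance = 1e-10)
  # planted decay: slope negative with small p
  withr::with_seed(47, {
    d <- runif(500, 0, 2e5)
    b <- pmax(0, 1 - d / 1e5) + rnorm(500, 0, 0.1)
  })
  partners2 <- tibble::tibble(variant_id = paste0("w", 1:500),
                              feature_id = paste0("h", 1:500),
                              beta = b, distance = d)
  anchors2 <- tibble::tibble(variant_id = paste0("w", 1:500), pos = 1:500)
  res2 <- effect_distance_profile(anchors2, partners2)
  expect_lt(res2$trend$slope, 0)
  expect_lt(res2$trend$p, 0.01)
})

test_that("genotype-stratified trends behave on degenerate and exact signals", {
  g <- tiny_geno(40, 10, seed = 48)
  vals <- matrix(rep(g$dosage[, 3], each = 2), nrow = 2, byrow = FALSE)
  dimnames(vals) <- list(c("feat0001", "feat0002"), rownames(g$dosage))
  sm <- manual_signal(vals, stage = "raw")
  sites <- tibble::tibble(feature_id = c("feat0001", "feat0002"),
                          variant_id = c("var00003", "var00003"),
                          group = "proximal")
  res <- suppressWarnings(genotype_stratified_trend(sm, g, sites))
  expect_equal(res$slope, 1, tolerance = 1e-10)
  expect_lt(res$p, 1e-10)
  # constant signal: slope 0, p = 1
  vals2 <- matrix(5, nrow = 2, ncol = 40,
                  dimnames = dimnames(vals))
  res2 <- genotype_stratified_trend(manual_signal(vals2, stage = "raw"),
                                    g, sites)
  expect_equal(res2$slope, 0)
  expect_equal(res2$p, 1)
})
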
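# Paired locus summary statistics under the five colocalisation scenarios.
# Marginal z-scores follow the standard LD propagation: z ~ MVN(R lambda, R)
# with lambda carrying the causal non-centrality, R the dosage correlation.

#' Simulate paired locus summary statistics under a causal scenario
#'
#' Scenarios: `H0` no association in either trait; `H1`/`H2` a single causal
#' variant in trait 1 / trait 2 only; `H3` two distinct causal variants (one
#' per trait) with pairwise r^2 below `r2_cap`; `H4` one shared causal
#' variant. Per-variant `beta = z * se` with `se = 1 / sqrt(n)` on the
#' standardised scale.
#'
#' @param scenario One of `"H0" ... "H4"`.
#' @param n_snps Number of variants at the locus.
#' @param ld Optional [geno_matrix()] (or dosage matrix) supplying the LD
#'   structure; when `NULL` a reference panel is simulated internally.
#' @param effect_size Causal non-centrality on the z scale (default 8).
#' @param n_trait1,n_trait2 GWAS sample sizes for the two traits.
#' @param r2_cap Maximum r^2 allowed between the two `H3` causal variants.
#' @param seed Integer seed.
#' @return List with `trait1` and `trait2` summary-stat tibbles
#'   (`variant_id`, `beta`, `se`, `p`, `maf`, `n`) and `truth`
#'   (`scenario`, `causal1`, `causal2`).
#' @export
simulate_gwas_locus <- function(scenario = c("H0", "H1", "H2", "H3", "H4"),
                                n_snps = 50, ld = NULL, effect_size = 8,
                                n_trait1 = 10000, n_trait2 = 10000,
                                r2_cap = 0.1, seed = 1) {
  scenario <- match.arg(scenario)
  n_snps <- check_count(n_snps, "n_snps")
  if (scenario == "H3" && n_snps < 2) {
    abort_invalid("H3 requires at least 2 variants.")
  }
  if (is.null(ld)) {
    ld <- simulate_genotypes(400, n_snps, ld_block_len = 10,
                             seed = derive_seed(seed, "ld_panel"))
  }
  dos <- if (inherits(ld, "geno_matrix")) ld$dosage else ld
  dos <- dos[, seq_len(min(n_snps, ncol(dos))), drop = FALSE]
  if (ncol(dos) < n_snps) {
    abort_invalid("LD panel has fewer variants than `n_snps`.")
  }
  maf <- pmin(colMeans(dos, na.rm = TRUE) / 2, 1 - colMeans(dos, na.rm = TRUE) / 2)
  R <- suppressWarnings(cor(dos, use = "pairwise.complete.obs"))
  R[is.na(R)] <- 0
  diag(R) <- 1
  L <- chol(R + diag(1e-4, n_snps))
  vids <- colnames(dos) %||% sprintf("var%05d", seq_len(n_snps))
  withr::with_seed(derive_seed(seed, paste0("gwas_", scenario)), {
    pick_causal <- function() sample.int(n_snps, 1)
    causal1 <- NA_integer_; causal2 <- NA_integer_
    lam1 <- numeric(n_snps); lam2 <- numeric(n_snps)
    if (scenario %in% c("H1", "H3", "H4")) {
      causal1 <- pick_causal()
      lam1[causal1] <- effect_size
    }
    if (scenario == "H2") {
      causal2 <- pick_causal()
      lam2[causal2] <- effect_size
    }
    if (scenario == "H4") {
      causal2 <- causal1
      lam2 <- lam1
    }
    if (scenario == "H3") {
      r2_with_c1 <- R[causal1, ]^2
      cand <- setdiff(which(r2_with_c1 < r2_cap), causal1)
      if (length(cand) == 0) cand <- setdiff(order(r2_with_c1)[1:2], causal1)
      causal2 <- cand[sample.int(length(cand), 1)]
      lam2[causal2] <- effect_size
    }
    z1 <- as.numeric(R %*% lam1 + crossprod(L, rnorm(n_snps)))
    z2 <- as.numeric(R %*% lam2 + crossprod(L, rnorm(n_snps)))
    mk <- function(z, n) {
      se <- rep(1 / sqrt(n), n_snps)
      tibble(variant_id = vids, beta = z * se, se = se,
             p = 2 * pnorm(-abs(z)), maf = maf, n = n)
    }
    list(trait1 = mk(z1, n_trait1), trait2 = mk(z2, n_trait2),
         truth = tibble(scenario = scenario,
                        causal1 = ifelse(is.na(causal1), NA_character_,
                                         vids[causal1]),
                        causal2 = ifelse(is.na(causal2), NA_character_,
                                         vids[causal2])))
  })
}
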
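#' Genotype container
#'
#' A light container for a donors x variants dosage matrix together with the
#' variant annotation table and the realised relatedness (kinship) matrix.
#' Dosages count copies of the alternate allele (0/1/2, `NA` for missing).
#'
#' @param dosage Integer matrix, donors in rows, variants in columns; dimnames
#'   must carry donor and variant ids.
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `maf`, `info`.
#' @param kinship Symmetric donors x donors matrix, or `NULL`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, variants, kinship = NULL) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)), !is.null(colnames(dosage)))
  if (!all(colnames(dosage) == variants$variant_id)) {
    abort_invalid("dosage column names must match `variants$variant_id`.")
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) {
    abort_invalid("dosages must be 0, 1, 2 or missing.")
  }
  if (!is.null(kinship)) {
    stopifnot(is.matrix(kinship), nrow(kinship) == nrow(dosage))
  }
  structure(
    list(dosage = dosage, variants = as_tibble(variants), kinship = kinship,
         donors = rownames(dosage)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d donors x %d variants (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$variants$chrom), collapse = ",")))
  invisible(x)
}

#' @export
tidy.geno_matrix <- function(x, ...) x$variants

#' Realised relatedness matrix from dosages
#'
#' Standardised genomic relationship matrix: dosages are centred at twice the
#' allele frequency and scaled by the binomial standard deviation, and the
#' cross-product is averaged over variants. Monomorphic variants are dropped;
#' missing dosages are mean-imputed for this computation only.
#'
#' @param geno A [geno_matrix()].
#' @return Donors x donors symmetric positive semi-definite matrix.
#' @export
realized_relatedness <- function(geno) {
  G <- geno$dosage
  G <- apply(G, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  p <- colMeans(G) / 2
  keep <- p > 0 & p < 1
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(geno$dosage), rownames(geno$dosage))
  K
}

#' Simulate LD-structured biallelic genotypes
#'
#' Generates donor genotypes by block-haplotype copying: each LD block owns a
#' small pool of founder haplotypes and every donor chromosome is a mosaic of
#' pool haplotypes with a per-variant switch probability, so pairwise r^2
#' decays with index distance inside a block and vanishes across blocks.
#' Optionally, pairs of donors share one full chromosome to create elevated
#' kinship entries.
#'
#' @param n_donors,n_variants Counts (donors >= 2).
#' @param maf_range Interval within (0, 0.5] for founder allele frequencies.
#' @param ld_block_len Variants per LD block (1 = independent variants).
#' @param related_pairs Number of donor pairs sharing a chromosome.
#' @param chrom Chromosome label for all variants.
#' @param spacing Mean base-pair spacing between adjacent variants.
#' @param n_haplotypes Founder haplotypes per block.
#' @param switch_prob Per-variant probability of switching founder haplotype.
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @return A [geno_matrix()] with kinship attached.
#' @export
simulate_genotypes <- function(n_donors, n_variants,
                               maf_range = c(0.05, 0.5),
                               ld_block_len = 10,
                               related_pairs = 0,
                               chrom = "chr1",
                               spacing = 1000,
                               n_haplotypes = 8,
                               switch_prob = 0.05,
                               seed = 1) {
  n_donors <- check_count(n_donors, "n_donors", min = 2L)
  n_variants <- check_count(n_variants, "n_variants")
  ld_block_len <- check_count(ld_block_len, "ld_block_len")
  related_pairs <- check_count(related_pairs, "related_pairs", min = 0L)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort_invalid("`maf_range` must be an interval within (0, 0.5].")
  }
  withr::with_seed(derive_seed(seed, "genotypes"), {
    n_hap_chrom <- 2L * n_donors
    blocks <- split(seq_len(n_variants),
                    ceiling(seq_len(n_variants) / ld_block_len))
    H <- matrix(0L, nrow = n_hap_chrom, ncol = n_variants)
    for (idx in blocks) {
      freq <- runif(length(idx), maf_range[1], maf_range[2])
      pool <- matrix(rbinom(n_haplotypes * length(idx), 1L, rep(freq, each = n_haplotypes)),
                     nrow = n_haplotypes)
      # mosaic copying: per chromosome, a Markov chain over pool haplotypes
      pick <- matrix(0L, nrow = n_hap_chrom, ncol = length(idx))
      cur <- sample.int(n_haplotypes, n_hap_chrom, replace = TRUE)
      pick[, 1] <- cur
      if (length(idx) > 1) {
        for (j in 2:length(idx)) {
          sw <- runif(n_hap_chrom) < switch_prob
          cur[sw] <- sample.int(n_haplotypes, sum(sw), replace = TRUE)
          pick[, j] <- cur
        }
      }
      for (j in seq_along(idx)) H[, idx[j]] <- pool[pick[, j], j]
    }
    hap1 <- H[seq_len(n_donors), , drop = FALSE]
    hap2 <- H[n_donors + seq_len(n_donors), , drop = FALSE]
    if (related_pairs > 0) {
      for (k in seq_len(min(related_pairs, floor(n_donors / 2)))) {
        a <- 2L * k - 1L
        b <- 2L * k
        hap1[b, ] <- hap1[a, ]  # pair shares one chromosome: expected kinship 1/4
      }
    }
    dosage <- hap1 + hap2
    pos <- cumsum(pmax(1L, rpois(n_variants, spacing)))
    alleles <- matrix(replicate(n_variants, sample(c("A", "C", "G", "T"), 2)),
                      nrow = 2)
    maf_emp <- pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2)
    variants <- tibble(
      variant_id = sprintf("var%05d", seq_len(n_variants)),
      chrom = chrom,
      pos = as.integer(pos),
      ref = alleles[1, ],
      alt = alleles[2, ],
      maf = maf_emp,
      info = round(runif(n_variants, 0.8, 1), 4)
    )
    dimnames(dosage) <- list(sprintf("donor%03d", seq_len(n_donors)),
                             variants$variant_id)
    g <- geno_matrix(dosage, variants)
    g$kinship <- realized_relatedness(g)
    g
  })
}

#' Squared-correlation linkage disequilibrium between two dosage vectors
#'
#' @param g1,g2 Numeric dosage vectors over the same donors; entries missing
#'   in either vector are excluded pairwise.
#' @return r^2 in `[0, 1]`, or `NA` (with a warning) when either vector has
#'   zero variance among complete pairs.
#' @export
ld_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < 2 || var(g1) == 0 || var(g2) == 0) {
    rlang::warn("ld_r2 undefined: zero variance in a dosage vector.",
                class = "chromaqtl_ld_undefined")
    return(NA_real_)
  }
  cor(g1, g2)^2
}

# Exact Hardy-Weinberg test on genotype counts (two-sided, plain exact test,
# no mid-p correction): probability of the observed heterozygote count plus
# all configurations with probability <= it, conditional on allele counts.
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  het_vals <- seq(rare %% 2, rare, by = 2)
  # P(h) = n! / (hom_r! h! hom_c!) * 2^h * na! nb! / (2n)!
  hom_r <- (rare - het_vals) / 2
  hom_c <- n - het_vals - hom_r
  logp <- lfactorial(n) - lfactorial(hom_r) - lfactorial(het_vals) -
    lfactorial(hom_c) + het_vals * log(2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  p_obs <- logp[match(n_ab, het_vals)]
  if (is.na(p_obs)) return(1)
  sum(exp(logp[logp <= p_obs + 1e-12]))
}

#' Genotype quality-control filters
#'
#' Retains biallelic single-nucleotide variants passing minor allele
#' frequency, exact Hardy-Weinberg, per-variant missingness and imputation
#' INFO thresholds (defaults: MAF >= 5%, HWE p >= 1e-6, missingness <= 5%,
#' INFO >= 0.8).
#'
#' @param geno A [geno_matrix()].
#' @param maf_min,hwe_p_min,miss_max,info_min Filter thresholds.
#' @return A filtered [geno_matrix()]; kinship is carried over unchanged.
#' @export
filter_variants <- function(geno, maf_min = 0.05, hwe_p_min = 1e-6,
                            miss_max = 0.05, info_min = 0.8) {
  G <- geno$dosage
  v <- geno$variants
  snv <- nchar(v$ref) == 1 & nchar(v$alt) == 1 &
    v$ref %in% c("A", "C", "G", "T") & v$alt %in% c("A", "C", "G", "T") &
    v$ref != v$alt
  miss <- colMeans(is.na(G))
  afreq <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(afreq, 1 - afreq)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    hwe_exact_p(sum(g == 2, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                sum(g == 0, na.rm = TRUE))
  }, numeric(1))
  info <- if ("info" %in% names(v)) v$info else rep(1, ncol(G))
  keep <- snv & maf >= maf_min & hwe >= hwe_p_min & miss <= miss_max &
    info >= info_min
  out <- geno_matrix(G[, keep, drop = FALSE], v[keep, , drop = FALSE],
                     kinship = geno$kinship)
  out
}
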
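# Overdispersed binomial allelic counts at donor-heterozygous sites.

#' Draw one beta-binomial sample per (n, prob) pair
#'
#' `rho = 0` collapses to the plain binomial; otherwise the per-draw success
#' probability is Beta-distributed with mean `prob` and intra-class
#' correlation `rho`.
#' @param n Vector of trial counts.
#' @param prob Success probabilities.
#' @param rho Intra-class correlation in `[0, 1)`.
#' @return Integer vector of successes.
#' @export
rbetabinom <- function(n, prob, rho = 0) {
  if (rho < 0 || rho >= 1) abort_invalid("`rho` must lie in [0, 1).")
  if (rho == 0) return(rbinom(length(n), n, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- rbeta(length(n), a, b)
  rbinom(length(n), n, p)
}

#' Simulate allelic read counts at heterozygous sites
#'
#' For every donor heterozygous at a site, a sequencing depth is drawn as
#' `Poisson(depth_mean)` (floored at 1) and the reference read count as an
#' overdispersed binomial with the site's true reference fraction. Sites not
#' listed in `sites` are unbiased (reference fraction 0.5).
#'
#' @param geno A [geno_matrix()]; heterozygosity is dosage == 1.
#' @param sites Tibble with `variant_id` and `ref_fraction` in (0, 1); when
#'   `NULL`, all variants are unbiased.
#' @param variant_ids Variants to emit counts for (default: all in `sites`,
#'   or all variants when `sites` is `NULL`).
#' @param depth_mean Mean read depth per site and donor.
#' @param overdispersion Beta-binomial intra-class correlation in `[0, 1)`.
#' @param assay,cell_type Labels attached to every row.
#' @param seed Integer seed.
#' @return Tibble with `variant_id`, `donor_id`, `assay`, `cell_type`,
#'   `ref_count`, `alt_count`.
#' @export
simulate_allelic_counts <- function(geno, sites = NULL, variant_ids = NULL,
                                    depth_mean = 50, overdispersion = 0,
                                    assay = "TF", cell_type = "neutrophil",
                                    seed = 1) {
  if (overdispersion < 0 || overdispersion >= 1) {
    abort_invalid("`overdispersion` must lie in [0, 1).")
  }
  if (!is.null(sites)) {
    sites <- as_tibble(sites)
    if (any(sites$ref_fraction <= 0 | sites$ref_fraction >= 1)) {
      abort_invalid("`ref_fraction` must lie strictly in (0, 1).")
    }
  }
  variant_ids <- variant_ids %||% (if (!is.null(sites)) sites$variant_id
                                   else geno$variants$variant_id)
  missing_v <- setdiff(variant_ids, geno$variants$variant_id)
  if (length(missing_v)) abort_invalid("unknown variant ids in `variant_ids`.")
  withr::with_seed(derive_seed(seed, "allelic"), {
    rows <- purrr::map_dfr(variant_ids, function(vid) {
      g <- geno$dosage[, vid]
      het <- names(g)[!is.na(g) & g == 1]
      if (length(het) == 0) return(NULL)
      frac <- 0.5
      if (!is.null(sites)) {
        hit <- match(vid, sites$variant_id)
        if (!is.na(hit)) frac <- sites$ref_fraction[hit]
      }
      depth <- pmax(1L, rpois(length(het), depth_mean))
      ref <- rbetabinom(depth, frac, overdispersion)
      tibble(variant_id = vid, donor_id = het, assay = assay,
             cell_type = cell_type, ref_count = as.integer(ref),
             alt_count = as.integer(depth - ref))
    })
    rows
  })
}
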
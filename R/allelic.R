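# Allele-specific imbalance at heterozygous sites: read-count filters,
# beta-binomial imbalance test, contact-bias windows, cross-sample
# consistency and donor-identity checks.

#' Filter heterozygous-site allelic counts
#'
#' A (variant, donor) row is kept when `ref + alt >= min_reads` and both
#' allele counts are non-zero; a variant is kept when at least `min_donors`
#' of its rows survive.
#'
#' @param counts Tibble with `variant_id`, `donor_id`, `ref_count`,
#'   `alt_count` (one row per heterozygous donor and site).
#' @param min_reads Minimum total reads per row (default 10).
#' @param min_donors Minimum surviving donors per variant (default 2).
#' @return The filtered tibble.
#' @export
filter_het_sites <- function(counts, min_reads = 10, min_donors = 2) {
  counts <- as_tibble(counts)
  counts |>
    filter(.data$ref_count + .data$alt_count >= min_reads,
           .data$ref_count > 0, .data$alt_count > 0) |>
    group_by(.data$variant_id) |>
    filter(n() >= min_donors) |>
    ungroup()
}

# beta-binomial log density with mean prob and intra-class correlation rho
dbetabinom_log <- function(x, n, prob, rho) {
  if (rho <= 0) return(dbinom(x, n, prob, log = TRUE))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

#' Method-of-moments beta-binomial dispersion estimate
#'
#' Pools all rows of an allelic-count table: per-site reference fractions are
#' compared with the binomial sampling variance around the pooled site
#' fraction, and the excess is attributed to the beta-binomial intra-class
#' correlation.
#'
#' @param counts Filtered allelic-count tibble.
#' @return rho clamped to `[0, 0.95]`.
#' @export
estimate_allelic_dispersion <- function(counts) {
  counts <- as_tibble(counts)
  per_site <- counts |>
    group_by(.data$variant_id) |>
    filter(n() >= 2) |>
    mutate(site_pi = sum(.data$ref_count) /
             sum(.data$ref_count + .data$alt_count)) |>
    ungroup() |>
    mutate(total = .data$ref_count + .data$alt_count,
           frac = .data$ref_count / .data$total)
  per_site <- filter(per_site, .data$site_pi > 0, .data$site_pi < 1)
  if (nrow(per_site) < 2) return(0)
  # within-site residual sums carry a Bessel-style k/(k-1) correction for
  # the degree of freedom absorbed by the pooled site fraction
  site_stats <- per_site |>
    group_by(.data$variant_id) |>
    summarise(
      k = n(),
      num = (n() / (n() - 1)) * sum((.data$frac - .data$site_pi)^2) -
        sum(.data$site_pi * (1 - .data$site_pi) / .data$total),
      den = sum(.data$site_pi * (1 - .data$site_pi) *
                  (.data$total - 1) / .data$total),
      .groups = "drop")
  max(0, min(0.95, sum(site_stats$num) / sum(site_stats$den)))
}

#' Test a variant for allelic imbalance
#'
#' Likelihood-ratio test of a shared reference fraction of 0.5 against a
#' free shared fraction, under a beta-binomial observation model with
#' intra-class correlation `rho` across the donors' counts. `rho = 0`
#' collapses to the exact binomial test on the pooled counts.
#'
#' @param rows Allelic-count rows for one variant (post
#'   [filter_het_sites()]).
#' @param rho Dispersion in `[0, 1)`, or `"estimate"` to plug in a
#'   pre-computed estimate via the `rho_estimate` argument.
#' @param rho_estimate Dispersion used when `rho = "estimate"`.
#' @param bias_low,bias_high Reference-fraction windows declaring a biased
#'   call (defaults 0.40 / 0.60).
#' @return One-row tibble: `variant_id`, `n_donors`, `ref_fraction`,
#'   `effect` (log2 ref/alt), `p`, `status`.
#' @export
test_allelic_imbalance <- function(rows, rho = 0, rho_estimate = 0,
                                   bias_low = 0.40, bias_high = 0.60) {
  rows <- as_tibble(rows)
  tot <- rows$ref_count + rows$alt_count
  if (all(tot == 0)) abort_invalid("all-zero read totals.")
  if (identical(rho, "estimate")) rho <- rho_estimate
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    abort_invalid("`rho` must lie in [0, 1) or be \"estimate\".")
  }
  ref <- sum(rows$ref_count)
  alt <- sum(rows$alt_count)
  frac <- ref / (ref + alt)
  if (rho == 0) {
    p <- binom.test(ref, ref + alt, p = 0.5)$p.value
  } else {
    pi_hat <- min(max(frac, 1e-6), 1 - 1e-6)
    l1 <- sum(dbetabinom_log(rows$ref_count, tot, pi_hat, rho))
    l0 <- sum(dbetabinom_log(rows$ref_count, tot, 0.5, rho))
    stat <- max(0, 2 * (l1 - l0))
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble(
    variant_id = rows$variant_id[1],
    n_donors = nrow(rows),
    ref_fraction = frac,
    effect = log2((ref + 0.5) / (alt + 0.5)),
    p = p,
    status = ifelse(frac <= bias_low | frac >= bias_high, "biased", "unbiased")
  )
}

#' Imbalance calls for every variant in a count table
#'
#' Applies [filter_het_sites()] and [test_allelic_imbalance()] across a
#' table, estimating the beta-binomial dispersion per assay when requested.
#'
#' @param counts Allelic-count tibble.
#' @param rho Numeric dispersion, or `"estimate"` for a per-assay
#'   method-of-moments estimate.
#' @param min_reads,min_donors Filter thresholds.
#' @return Tibble of per-variant calls with an `assay` column; the
#'   dispersion used per assay is attached as attribute `"rho"`.
#' @export
call_allelic_imbalance <- function(counts, rho = "estimate", min_reads = 10,
                                   min_donors = 2) {
  counts <- filter_het_sites(counts, min_reads, min_donors)
  if (!"assay" %in% names(counts)) counts$assay <- "all"
  rhos <- list()
  out <- counts |>
    group_by(.data$assay) |>
    dplyr::group_modify(function(df, key) {
      r <- if (identical(rho, "estimate")) estimate_allelic_dispersion(df) else rho
      rhos[[key$assay]] <<- r
      df |>
        group_by(.data$variant_id) |>
        dplyr::group_modify(function(rows, k2) {
          select(test_allelic_imbalance(mutate(rows, variant_id = k2$variant_id),
                                        rho = r), -"variant_id")
        }) |>
        ungroup()
    }) |>
    ungroup()
  attr(out, "rho") <- unlist(rhos)
  out
}

#' Allele-bias calls for promoter-contact reads
#'
#' Per (variant, donor, cell type) observation: reference fractions outside
#' `(extreme_low, extreme_high)` are removed as extreme bias; remaining
#' observations are flagged biased when the fraction is at most `low` or at
#' least `high`.
#'
#' @param counts Allelic-count tibble (typically PCHi-C reads), with
#'   `cell_type`.
#' @param low,high Bias windows (defaults 0.40 and 0.60).
#' @param extreme_low,extreme_high Extreme-bias removal bounds (defaults
#'   0.01 and 0.99).
#' @return Tibble of per-observation calls with `ref_fraction` and `status`
#'   in `biased` / `unbiased` / `removed_extreme`.
#' @export
call_pchic_allelic_bias <- function(counts, low = 0.40, high = 0.60,
                                    extreme_low = 0.01, extreme_high = 0.99) {
  if (low >= high) abort_invalid("`low` must be smaller than `high`.")
  counts <- as_tibble(counts)
  counts |>
    mutate(ref_fraction = .data$ref_count /
             (.data$ref_count + .data$alt_count),
           status = dplyr::case_when(
             .data$ref_fraction < extreme_low |
               .data$ref_fraction > extreme_high ~ "removed_extreme",
             .data$ref_fraction <= low | .data$ref_fraction >= high ~ "biased",
             TRUE ~ "unbiased"
           ))
}

#' Cross-sample consistency filter for allelic calls
#'
#' A variant is retained when it is observed in at least `min_obs` samples,
#' or in a single sample but in both cell types, and all its observations
#' fall on the same side of a reference fraction of 0.5 (observations at
#' exactly 0.5 carry no direction and are ignored for the direction check).
#'
#' @param calls Tibble with `variant_id`, `donor_id`, `cell_type`,
#'   `ref_fraction` (rows with status `removed_extreme` should be dropped
#'   beforehand).
#' @param min_obs Minimum number of samples (default 2).
#' @return Character vector of retained variant ids.
#' @export
consistency_filter <- function(calls, min_obs = 2) {
  calls <- as_tibble(calls)
  keep <- calls |>
    group_by(.data$variant_id) |>
    summarise(
      n_samples = dplyr::n_distinct(.data$donor_id),
      n_cells = dplyr::n_distinct(.data$cell_type),
      n_sides = dplyr::n_distinct(sign(.data$ref_fraction - 0.5)[
        .data$ref_fraction != 0.5]),
      .groups = "drop"
    ) |>
    filter((.data$n_samples >= min_obs |
              (.data$n_samples == 1 & .data$n_cells >= 2)),
           .data$n_sides <= 1)
  keep$variant_id
}

#' Genotype concordance between two call sets
#'
#' Fraction of shared sites with identical genotype; two samples are declared
#' a match when the rate exceeds `threshold`.
#'
#' @param called,reference Named vectors (or two-column tibbles with
#'   `variant_id`, `genotype`) of genotype calls.
#' @param threshold Match threshold (default 0.9, i.e. the >90% rule).
#' @return Tibble with `n_shared`, `rate`, `match`.
#' @export
genotype_concordance <- function(called, reference, threshold = 0.9) {
  as_map <- function(x) {
    if (is.data.frame(x)) setNames(x$genotype, x$variant_id) else x
  }
  called <- as_map(called)
  reference <- as_map(reference)
  shared <- intersect(names(called), names(reference))
  if (length(shared) == 0) abort_invalid("no shared sites between call sets.")
  rate <- mean(called[shared] == reference[shared])
  tibble(n_shared = length(shared), rate = rate, match = rate > threshold)
}
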
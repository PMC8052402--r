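# Shared genetic effects across molecular layers: LD overlap of leads,
# pi1 replication, direction-of-effect concordance, effect-size contrasts.

#' Overlap two lead sets by LD
#'
#' A pair is emitted when the two leads are the same variant (r^2 = 1) or
#' their dosage r^2 reaches `r2_min`; each layer-A lead keeps its single
#' best partner (largest r^2, ties broken by nearest position).
#'
#' @param leads_a,leads_b Lead tibbles (`variant_id`, `beta`, `pos`,
#'   optionally an assay label in `layer`).
#' @param geno A [geno_matrix()] containing all lead variants.
#' @param r2_min LD threshold (default 0.8).
#' @return Tibble of shared pairs: `lead_a`, `lead_b`, `r2`, `beta_a`,
#'   `beta_b`, `direction`.
#' @export
overlap_by_ld <- function(leads_a, leads_b, geno, r2_min = 0.8) {
  leads_a <- as_tibble(leads_a)
  leads_b <- as_tibble(leads_b)
  if (nrow(leads_a) == 0 || nrow(leads_b) == 0) {
    return(tibble(lead_a = character(), lead_b = character(), r2 = numeric(),
                  beta_a = numeric(), beta_b = numeric(),
                  direction = character()))
  }
  dos <- geno$dosage
  purrr::pmap_dfr(
    list(leads_a$variant_id, leads_a$beta, leads_a$pos),
    function(va, ba, pa) {
      r2 <- vapply(seq_len(nrow(leads_b)), function(j) {
        vb <- leads_b$variant_id[j]
        if (vb == va) return(1)
        suppressWarnings(ld_r2(dos[, va], dos[, vb]))
      }, numeric(1))
      ok <- which(!is.na(r2) & r2 >= r2_min)
      if (length(ok) == 0) return(NULL)
      best <- ok[order(-r2[ok], abs(leads_b$pos[ok] - pa))][1]
      bb <- leads_b$beta[best]
      tibble(lead_a = va, lead_b = leads_b$variant_id[best], r2 = r2[best],
             beta_a = ba, beta_b = bb,
             direction = ifelse(ba * bb >= 0, "positive", "negative"))
    })
}

#' Direction-of-effect concordance of shared pairs
#'
#' Pairs are partitioned by the sign of `beta_a * beta_b` (zero products are
#' counted positive and reported) and the Pearson correlation of the two
#' effect vectors is returned.
#'
#' @param pairs Tibble from [overlap_by_ld()].
#' @return Tibble with `n_positive`, `n_negative`, `n_zero_ties`,
#'   `pearson_r`.
#' @export
direction_concordance <- function(pairs) {
  pairs <- as_tibble(pairs)
  prod <- pairs$beta_a * pairs$beta_b
  n_zero <- sum(prod == 0)
  if (n_zero > 0) {
    rlang::inform(sprintf("%d zero-effect pairs counted as positive.", n_zero))
  }
  tibble(
    n_positive = sum(prod >= 0),
    n_negative = sum(prod < 0),
    n_zero_ties = n_zero,
    pearson_r = if (nrow(pairs) >= 3) cor(pairs$beta_a, pairs$beta_b)
                else NA_real_
  )
}

#' Welch two-sided t comparison of two |beta| groups
#'
#' @param values_a,values_b Numeric vectors (size >= 2 each).
#' @return Tibble with `t`, `df` (Satterthwaite) and `p`.
#' @export
compare_effect_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort_invalid("both groups need at least 2 values.")
  }
  if (sd(values_a) == 0 && sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    return(tibble(t = 0, df = NA_real_, p = 1))
  }
  ht <- t.test(values_a, values_b, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Cross-layer look-up p-values for pi1
#'
#' For each layer-A lead variant, finds the nearest layer-B feature within
#' `window` bp and returns the p-value of that (variant, feature) record in
#' layer B — the look-up vector fed to [estimate_pi1()].
#'
#' @param leads_a Layer-A lead records (`variant_id`, `pos`).
#' @param records_b Layer-B association records (`variant_id`, `feature_id`,
#'   `p`, `distance`).
#' @param window Maximum |distance| in bp (default 1 Mb).
#' @return Numeric vector of look-up p-values (leads without a partner are
#'   dropped).
#' @export
lookup_secondary_p <- function(leads_a, records_b, window = 1e6) {
  records_b |>
    filter(.data$variant_id %in% leads_a$variant_id,
           abs(.data$distance) <= window) |>
    group_by(.data$variant_id) |>
    arrange(abs(.data$distance), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    dplyr::pull(.data$p)
}
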
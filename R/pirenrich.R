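# Enrichment of QTL variants and annotations in promoter-interacting
# regions (PIRs): Fisher tests per sample, combined-N tests, genomic
# permutation enrichment, expression-quartile binning and distance-matched
# effect-size comparison.

#' Flag variants inside promoter-interacting regions
#'
#' A variant is inside a PIR when it falls in the other-end interval of an
#' interaction with score strictly greater than `score_min`; overlap with a
#' bait fragment alone does not count (baits are promoters by construction,
#' PIRs are the non-bait ends).
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos` (1-based).
#' @param interactions Interaction tibble (`oe_chr`, `oe_start`, `oe_end`,
#'   `score`).
#' @param score_min Significance threshold on the interaction score
#'   (default 5).
#' @return `variants` with a logical `in_pir` column.
#' @export
assign_to_pirs <- function(variants, interactions, score_min = 5) {
  variants <- as_tibble(variants)
  pirs <- filter(as_tibble(interactions), .data$score > score_min)
  in_pir <- rep(FALSE, nrow(variants))
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    pi_ <- pirs[pirs$oe_chr == ch, ]
    if (nrow(pi_) == 0 || length(vi) == 0) next
    vr <- IRanges::IRanges(start = variants$pos[vi], width = 1)
    pr <- IRanges::IRanges(start = pi_$oe_start + 1L, end = pi_$oe_end)
    in_pir[vi] <- IRanges::overlapsAny(vr, pr)
  }
  mutate(variants, in_pir = in_pir)
}

# Exact conditional (Fisher) two-sided p for a 2x2 table: the sum of
# hypergeometric probabilities not exceeding that of the observed table
# (relative tolerance 1e-7, the stats::fisher.test convention).
fisher_exact_p <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10
  c1 <- n11 + n01
  n <- n11 + n10 + n01 + n00
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  min(1, sum(probs[probs <= dhyper(n11, c1, n - c1, r1) * (1 + 1e-7)]))
}

# Full per-table record; the odds ratio is the sample cross-product ratio.
fisher_2x2 <- function(n11, n10, n01, n00) {
  tab <- matrix(c(n11, n10, n01, n00), nrow = 2, byrow = TRUE)
  zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- if (n10 * n01 == 0) {
    if (n11 * n00 == 0) NA_real_ else Inf
  } else n11 * n00 / (n10 * n01)
  p <- fisher_exact_p(n11, n10, n01, n00)
  tibble(n_sig_pir = n11, n_sig_nopir = n10, n_nonsig_pir = n01,
         n_nonsig_nopir = n00,
         odds_ratio = or, or_undefined = zero_margin || !is.finite(or),
         p = p)
}

#' Per-sample Fisher enrichment of significant QTLs in PIRs
#'
#' For every sample, a two-sided Fisher exact test on the 2x2 table of
#' (significant QTL yes/no) x (in PIR yes/no); the cross-sample mean and
#' standard deviation of the odds ratios are appended as a `summary` row.
#' The odds ratio reported is the sample cross-product ratio.
#'
#' @param observations Long tibble with one row per (variant, sample):
#'   `variant_id`, `sample_id`, `in_pir`, `significant`.
#' @return Tibble with one row per sample plus a `summary` row carrying
#'   `or_mean` / `or_sd` across samples.
#' @export
fisher_pir_enrichment <- function(observations) {
  observations <- as_tibble(observations)
  per_sample <- observations |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      fisher_2x2(sum(df$significant & df$in_pir),
                 sum(df$significant & !df$in_pir),
                 sum(!df$significant & df$in_pir),
                 sum(!df$significant & !df$in_pir))
    }) |>
    ungroup()
  ors <- per_sample$odds_ratio[!per_sample$or_undefined]
  summary_row <- tibble(sample_id = "summary", or_mean = mean(ors),
                        or_sd = if (length(ors) > 1) sd(ors) else NA_real_)
  bind_rows(mutate(per_sample, or_mean = NA_real_, or_sd = NA_real_),
            summary_row)
}

#' Combined-sample PIR enrichment for increasing support N
#'
#' Variants observed across samples are flagged when at least N samples
#' place them in a PIR and at least N samples carry a significant QTL; one
#' Fisher test per N is run on the combined variant set.
#'
#' @param observations Long tibble as in [fisher_pir_enrichment()].
#' @param n_values Values of N to test (default 1:4).
#' @return Tibble with one row per N (`n_required`, counts, `odds_ratio`,
#'   `p`, `skipped`).
#' @export
combined_sample_enrichment <- function(observations, n_values = 1:4) {
  if (any(n_values < 1)) abort_invalid("N must be at least 1.")
  observations <- as_tibble(observations)
  per_variant <- observations |>
    group_by(.data$variant_id) |>
    summarise(n_pir = sum(.data$in_pir), n_sig = sum(.data$significant),
              .groups = "drop")
  purrr::map_dfr(n_values, function(N) {
    pir_flag <- per_variant$n_pir >= N
    sig_flag <- per_variant$n_sig >= N
    if (!any(pir_flag) || !any(sig_flag)) {
      return(tibble(n_required = N, n_sig_pir = NA_integer_,
                    n_sig_nopir = NA_integer_, n_nonsig_pir = NA_integer_,
                    n_nonsig_nopir = NA_integer_, odds_ratio = NA_real_,
                    or_undefined = TRUE, p = NA_real_, skipped = TRUE))
    }
    mutate(fisher_2x2(sum(sig_flag & pir_flag), sum(sig_flag & !pir_flag),
                      sum(!sig_flag & pir_flag), sum(!sig_flag & !pir_flag)),
           n_required = N, skipped = FALSE)
  })
}

#' Permutation enrichment of query intervals in an annotation
#'
#' The null distribution re-places every query interval uniformly within its
#' chromosome (lengths preserved) and counts how many land in the
#' annotation; the empirical p-value is `(1 + #null >= observed) /
#' (n_perm + 1)`.
#'
#' @param query,annotation Interval tibbles (`chrom`, `start`, `end`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_perm Number of permutations (default 50).
#' @param seed Integer seed.
#' @return Tibble with `observed`, `null_mean`, `null_sd`, `fold`, `z`
#'   (`NA` when the null is degenerate) and `p_empirical`.
#' @export
region_permutation_enrichment <- function(query, annotation, chrom_sizes,
                                          n_perm = 50, seed = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  query <- as_tibble(query)
  annotation <- as_tibble(annotation)
  widths <- query$end - query$start
  if (any(widths > chrom_sizes[query$chrom])) {
    abort_invalid("a query interval is longer than its chromosome.")
  }
  count_overlaps <- function(q) {
    total <- 0L
    for (ch in unique(q$chrom)) {
      qi <- q[q$chrom == ch, ]
      ai <- annotation[annotation$chrom == ch, ]
      if (nrow(ai) == 0) next
      qr <- IRanges::IRanges(start = qi$start + 1L, end = qi$end)
      ar <- IRanges::IRanges(start = ai$start + 1L, end = ai$end)
      total <- total + sum(IRanges::overlapsAny(qr, ar))
    }
    total
  }
  observed <- count_overlaps(query)
  withr::with_seed(derive_seed(seed, "region_perm"), {
    null_counts <- vapply(seq_len(n_perm), function(b) {
      max_start <- chrom_sizes[query$chrom] - widths
      new_start <- floor(runif(nrow(query)) * (max_start + 1))
      stopifnot(all(new_start >= 0), all(new_start + widths <=
                                           chrom_sizes[query$chrom]))
      count_overlaps(tibble(chrom = query$chrom, start = new_start,
                            end = new_start + widths))
    }, numeric(1))
  })
  null_sd <- sd(null_counts)
  tibble(
    observed = observed,
    null_mean = mean(null_counts),
    null_sd = null_sd,
    fold = observed / max(mean(null_counts), .Machine$double.eps),
    z = if (null_sd > 0) (observed - mean(null_counts)) / null_sd else NA_real_,
    p_empirical = (1 + sum(null_counts >= observed)) / (n_perm + 1)
  )
}

#' Annotation enrichment of PIRs binned by target-gene expression
#'
#' PIRs (other ends of interactions above the score threshold) are ranked
#' into `n_bins` near-equal bins by the expression of their bait gene (ties
#' fall into the lower bin); each bin is tested against each annotation with
#' [region_permutation_enrichment()] and the observed/null-mean fold change
#' is reported.
#'
#' @param interactions Interaction tibble with `gene_id` on the bait.
#' @param expression Tibble with `gene_id`, `expression`.
#' @param annotations Named list of interval tibbles.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_bins Number of expression bins (default 4).
#' @param score_min PIR score threshold (default 5).
#' @param n_perm Permutations per test (default 50).
#' @param seed Integer seed.
#' @return List with `folds` (bins x annotations tibble) and `n_skipped`
#'   (PIRs whose bait gene has no expression value).
#' @export
expression_bin_enrichment <- function(interactions, expression, annotations,
                                      chrom_sizes, n_bins = 4, score_min = 5,
                                      n_perm = 50, seed = 1) {
  pirs <- as_tibble(interactions) |>
    filter(.data$score > score_min) |>
    dplyr::distinct(.data$oe_chr, .data$oe_start, .data$oe_end,
                    .keep_all = TRUE) |>
    left_join(as_tibble(expression), by = "gene_id")
  n_skipped <- sum(is.na(pirs$expression))
  pirs <- filter(pirs, !is.na(.data$expression))
  n <- nrow(pirs)
  ord <- order(pirs$expression)  # stable: ties keep input order -> lower bin
  sizes <- diff(floor(seq(0, n, length.out = n_bins + 1)))
  bin_of_sorted <- rep(seq_len(n_bins), times = sizes)
  pirs$bin <- NA_integer_
  pirs$bin[ord] <- bin_of_sorted
  folds <- purrr::map_dfr(seq_len(n_bins), function(b) {
    q <- pirs |>
      filter(.data$bin == b) |>
      dplyr::transmute(chrom = .data$oe_chr, start = .data$oe_start,
                       end = .data$oe_end)
    row <- purrr::map_dbl(annotations, function(ann) {
      region_permutation_enrichment(q, ann, chrom_sizes, n_perm = n_perm,
                                    seed = derive_seed(seed, paste0("bin", b)))$fold
    })
    tibble(bin = b, n_pirs = nrow(q), !!!as.list(row))
  })
  list(folds = folds, n_skipped = n_skipped)
}

#' Compare eQTL effect sizes inside vs outside PIRs, distance-matched
#'
#' Records closer than `tss_min` bp to the transcription start site are
#' excluded; every in-PIR record is then greedily matched (without
#' replacement, nearest |distance|, ties to the lower position) to an
#' out-of-PIR record, and the two |beta| samples are compared with a
#' two-sided rank-sum test.
#'
#' @param eqtl_records Tibble with `beta`, `distance` (bp to TSS), `pos` and
#'   a logical `in_pir` column.
#' @param tss_min TSS exclusion radius in bp (default 25000).
#' @return List with `matched` (tibble of pairs), `in_beta`, `out_beta`,
#'   `statistic`, `p`, `n_unmatched`.
#' @export
pir_vs_matched_effect <- function(eqtl_records, tss_min = 25000) {
  rec <- as_tibble(eqtl_records) |>
    filter(abs(.data$distance) >= tss_min)
  inside <- rec |> filter(.data$in_pir) |>
    arrange(abs(.data$distance), .data$pos)
  outside <- rec |> filter(!.data$in_pir) |>
    arrange(abs(.data$distance), .data$pos)
  available <- rep(TRUE, nrow(outside))
  match_idx <- integer(nrow(inside))
  for (i in seq_len(nrow(inside))) {
    cand <- which(available)
    if (length(cand) == 0) { match_idx[i] <- NA_integer_; next }
    gaps <- abs(abs(outside$distance[cand]) - abs(inside$distance[i]))
    best <- cand[order(gaps, outside$pos[cand])][1]
    match_idx[i] <- best
    available[best] <- FALSE
  }
  ok <- !is.na(match_idx)
  n_unmatched <- sum(!ok)
  in_beta <- abs(inside$beta[ok])
  out_beta <- abs(outside$beta[match_idx[ok]])
  if (length(in_beta) < 2) {
    return(list(matched = tibble(), in_beta = in_beta, out_beta = out_beta,
                statistic = NA_real_, p = NA_real_,
                n_unmatched = n_unmatched))
  }
  wt <- suppressWarnings(wilcox.test(in_beta, out_beta, exact = FALSE))
  list(
    matched = tibble(in_distance = abs(inside$distance[ok]),
                     out_distance = abs(outside$distance[match_idx[ok]]),
                     in_beta = in_beta, out_beta = out_beta),
    in_beta = in_beta, out_beta = out_beta,
    statistic = unname(wt$statistic), p = wt$p.value,
    n_unmatched = n_unmatched
  )
}
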
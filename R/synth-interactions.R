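# Promoter-capture interaction tables with planted promoter-interacting
# regions (PIRs). Interaction scores are consumed downstream exactly as
# significance scores from an interaction caller would be: score > 5 marks
# a significant contact and its other end a PIR.

#' Simulate a promoter-interaction table with planted PIRs
#'
#' Each candidate other-end fragment is linked to a random bait; a planted
#' fraction of fragments receives a score above the significance threshold
#' (5 + Gamma-distributed excess) and the remainder scores uniform on
#' [0, 5]. Baits overlapping their own other end are rejected.
#'
#' @param fragments Tibble of candidate other-end intervals
#'   (`chrom`, `start`, `end`).
#' @param baits Tibble of bait intervals (`chrom`, `start`, `end`,
#'   optionally `gene_id`).
#' @param pir_fraction Fraction of fragments planted as PIRs.
#' @param cell_type Label attached to every interaction.
#' @param seed Integer seed.
#' @return List with `interactions` (tibble `bait_chr`, `bait_start`,
#'   `bait_end`, `gene_id`, `oe_chr`, `oe_start`, `oe_end`, `score`,
#'   `cell_type`) and `truth` (per-fragment `is_pir` flags).
#' @export
simulate_interactions <- function(fragments, baits, pir_fraction = 0.3,
                                  cell_type = "neutrophil", seed = 1) {
  check_prob(pir_fraction, "pir_fraction")
  fragments <- as_tibble(fragments)
  baits <- as_tibble(baits)
  if (!"gene_id" %in% names(baits)) {
    baits$gene_id <- sprintf("gene%04d", seq_len(nrow(baits)))
  }
  withr::with_seed(derive_seed(seed, "interactions"), {
    n <- nrow(fragments)
    is_pir <- runif(n) < pir_fraction
    score <- ifelse(is_pir, 5 + stats::rgamma(n, shape = 2, scale = 3),
                    runif(n, 0, 5))
    bait_idx <- sample.int(nrow(baits), n, replace = TRUE)
    overlap <- baits$chrom[bait_idx] == fragments$chrom &
      baits$start[bait_idx] < fragments$end &
      baits$end[bait_idx] > fragments$start
    if (any(overlap)) {
      # re-draw clashing baits once; error out if a clash persists
      bait_idx[overlap] <- sample.int(nrow(baits), sum(overlap), replace = TRUE)
      overlap <- baits$chrom[bait_idx] == fragments$chrom &
        baits$start[bait_idx] < fragments$end &
        baits$end[bait_idx] > fragments$start
      if (any(overlap)) {
        abort_invalid("bait and other-end intervals overlap on the same fragment.")
      }
    }
    interactions <- tibble(
      bait_chr = baits$chrom[bait_idx],
      bait_start = baits$start[bait_idx],
      bait_end = baits$end[bait_idx],
      gene_id = baits$gene_id[bait_idx],
      oe_chr = fragments$chrom,
      oe_start = fragments$start,
      oe_end = fragments$end,
      score = score,
      cell_type = cell_type
    )
    truth <- mutate(fragments, is_pir = is_pir)
    list(interactions = interactions, truth = truth)
  })
}
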
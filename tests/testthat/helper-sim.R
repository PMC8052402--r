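# Shared fixture builders and independent oracles used across test files.
# Oracles are deliberately naive (loops, direct formulas) and never call the
# code paths they check.

# small genotype panel for structural tests
tiny_geno <- function(n_donors = 30, n_variants = 60, seed = 1, ...) {
  simulate_genotypes(n_donors, n_variants, seed = seed, ...)
}

# a raw signal matrix straight from counts, bypassing the generator
manual_signal <- function(values, start_pos = 1000, stage = "raw",
                          library_sizes = NULL) {
  n <- nrow(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("feat%04d", seq_len(n))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("donor%03d", seq_len(ncol(values)))
  }
  features <- tibble::tibble(
    feature_id = rownames(values), chrom = "chr1",
    start = start_pos + (seq_len(n) - 1) * 10000L,
    end = start_pos + (seq_len(n) - 1) * 10000L + 500L
  )
  signal_matrix(values, features, stage = stage,
                library_sizes = library_sizes)
}

# naive interval merge + support count (single linkage, >= 1 bp overlap)
oracle_consensus <- function(peaks_df, min_samples) {
  out <- list()
  for (ch in unique(peaks_df$chrom)) {
    df <- peaks_df[peaks_df$chrom == ch, ]
    df <- df[order(df$start), ]
    cur_s <- df$start[1]; cur_e <- df$end[1]; members <- df$sample_id[1]
    flush <- function(s, e, mem) {
      list(chrom = ch, start = s, end = e,
           support = length(unique(mem)))
    }
    res <- list()
    if (nrow(df) > 1) {
      for (i in 2:nrow(df)) {
        if (df$start[i] < cur_e) {
          cur_e <- max(cur_e, df$end[i]); members <- c(members, df$sample_id[i])
        } else {
          res[[length(res) + 1]] <- flush(cur_s, cur_e, members)
          cur_s <- df$start[i]; cur_e <- df$end[i]; members <- df$sample_id[i]
        }
      }
    }
    res[[length(res) + 1]] <- flush(cur_s, cur_e, members)
    out <- c(out, res)
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  df <- df[df$support >= min_samples, ]
  df[order(df$chrom, df$start), ]
}

# exact two-sided binomial p at p0 = 0.5 by direct enumeration
oracle_binom_p <- function(x, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# hypergeometric two-sided p for a 2x2 table, by enumeration
oracle_fisher_p <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10; c1 <- n11 + n01; n <- n11 + n10 + n01 + n00
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  obs <- dhyper(n11, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# direct-sum colocalisation posterior for a small locus
oracle_coloc_pp <- function(l1, l2, p1, p2, p12) {
  n <- length(l1); b1 <- exp(l1); b2 <- exp(l2)
  w0 <- 1 - n * p1 - n * p2 - n * p12 - n * (n - 1) * p1 * p2
  w3 <- 0
  if (n >= 2) {
    for (i in 1:n) for (j in 1:n) if (i != j) w3 <- w3 + p1 * p2 * b1[i] * b2[j]
  }
  ws <- c(w0, p1 * sum(b1), p2 * sum(b2), w3, p12 * sum(b1 * b2))
  ws / sum(ws)
}

oracle_coloc_loglik <- function(l1, l2, p1, p2, p12) {
  n <- length(l1); b1 <- exp(l1); b2 <- exp(l2)
  w0 <- 1 - n * p1 - n * p2 - n * p12 - n * (n - 1) * p1 * p2
  if (w0 <= 0) return(-Inf)
  w3 <- 0
  if (n >= 2) for (i in 1:n) for (j in 1:n) if (i != j)
    w3 <- w3 + p1 * p2 * b1[i] * b2[j]
  log(w0 + p1 * sum(b1) + p2 * sum(b2) + w3 + p12 * sum(b1 * b2))
}

random_locus_stats <- function(n, seed) {
  withr::with_seed(seed, {
    list(
      s1 = tibble::tibble(variant_id = paste0("v", seq_len(n)),
                          beta = rnorm(n, 0, 0.2),
                          se = runif(n, 0.05, 0.2)),
      s2 = tibble::tibble(variant_id = paste0("v", seq_len(n)),
                          beta = rnorm(n, 0, 0.2),
                          se = runif(n, 0.05, 0.2))
    )
  })
}

fixture_counts <- function() {
  readr::read_tsv(system.file("extdata", "allelic_counts_synthetic.tsv",
                              package = "chromaqtl"),
                  show_col_types = FALSE)
}
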
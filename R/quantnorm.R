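# Consensus peak construction and the count-normalisation pipeline:
# log2RPM -> presence filter -> latent-factor correction -> quantile
# normalisation. Matrices move through `signal_matrix` stages so the order
# is machine-checked.

#' Build a consensus peak set across samples
#'
#' Overlapping peaks from different samples are merged into maximal connected
#' unions (single-linkage, >= 1 bp overlap) and a merged interval is retained
#' when at least `min_samples` distinct samples contribute an overlapping
#' peak. Sex chromosomes are excluded, as they are left out of the QTL
#' analysis altogether.
#'
#' @param peak_sets Named list of per-sample peak tibbles
#'   (`chrom`, `start`, `end`; 0-based half-open).
#' @param min_samples Minimum number of contributing samples (default 3).
#' @param drop_chroms Chromosome labels removed before merging.
#' @return Tibble of consensus intervals with a `support` column.
#' @export
build_consensus_peaks <- function(peak_sets, min_samples = 3,
                                  drop_chroms = c("chrX", "chrY", "X", "Y")) {
  if (!is.list(peak_sets) || length(peak_sets) == 0) {
    abort_invalid("`peak_sets` must be a non-empty list of peak tables.")
  }
  min_samples <- check_count(min_samples, "min_samples")
  if (length(peak_sets) < min_samples) {
    abort_invalid("need at least `min_samples` input peak sets.")
  }
  if (is.null(names(peak_sets))) {
    names(peak_sets) <- sprintf("sample%02d", seq_along(peak_sets))
  }
  all_peaks <- purrr::imap_dfr(peak_sets, function(df, nm) {
    mutate(as_tibble(df), sample_id = nm)
  })
  all_peaks <- filter(all_peaks, !.data$chrom %in% drop_chroms)
  if (nrow(all_peaks) == 0) return(tibble(chrom = character(), start = integer(),
                                          end = integer(), support = integer()))
  out <- all_peaks |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      ir <- IRanges::IRanges(start = df$start + 1L, end = df$end)
      merged <- IRanges::reduce(ir, min.gapwidth = 0L)  # >= 1 bp overlap
      hits <- IRanges::findOverlaps(merged, ir)
      support <- vapply(seq_along(merged), function(i) {
        length(unique(df$sample_id[S4Vectors::subjectHits(hits)[
          S4Vectors::queryHits(hits) == i]]))
      }, integer(1))
      tibble(start = IRanges::start(merged) - 1L,
             end = IRanges::end(merged),
             support = support)
    }) |>
    ungroup() |>
    filter(.data$support >= min_samples) |>
    arrange(.data$chrom, .data$start)
  out
}

#' Tile broad peaks into fixed-width windows
#'
#' Each peak is tiled left to right with windows of `width` base pairs; the
#' final window is truncated at the peak end so windows never extend past the
#' called enrichment. Peaks shorter than `width` yield a single window equal
#' to the peak.
#'
#' @param peaks Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param width Window width in bp (default 2500, the convention for broad
#'   repressive-mark domains).
#' @return Tibble of windows with a `source` column indexing the parent peak.
#' @export
window_broad_peaks <- function(peaks, width = 2500) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0) {
    abort_invalid("`width` must be a positive number.")
  }
  peaks <- as_tibble(peaks)
  purrr::pmap_dfr(
    list(peaks$chrom, peaks$start, peaks$end, seq_len(nrow(peaks))),
    function(chrom, start, end, i) {
      starts <- seq(start, end - 1, by = width)
      tibble(chrom = chrom, start = starts,
             end = pmin(starts + width, end), source = i)
    })
}

#' Convert raw counts to log2 reads per million
#'
#' `log2((count + pseudocount) * 1e6 / library_size)` per feature and donor.
#' The pseudocount (default 0.5) keeps zero counts finite while preserving
#' the `log2RPM > 0 <=> RPM > 1` semantics of the downstream presence filter
#' for non-zero counts.
#'
#' @param counts A `signal_matrix` at stage `raw`.
#' @param library_sizes Named per-donor totals; defaults to the library sizes
#'   stored on `counts`.
#' @param pseudocount Added to every count before the log transform.
#' @return A `signal_matrix` at stage `log2rpm`.
#' @export
compute_log2rpm <- function(counts, library_sizes = NULL, pseudocount = 0.5) {
  check_stage(counts, "raw", "compute_log2rpm")
  library_sizes <- library_sizes %||% counts$library_sizes
  if (is.null(library_sizes)) abort_invalid("library sizes are required.")
  library_sizes <- library_sizes[counts$donors]
  if (anyNA(library_sizes) || any(library_sizes <= 0)) {
    abort_invalid("`library_sizes` must be positive for every donor.")
  }
  if (any(counts$values < 0, na.rm = TRUE)) {
    abort_invalid("counts must be non-negative.")
  }
  vals <- log2(sweep(counts$values + pseudocount, 2, library_sizes / 1e6, "/"))
  signal_matrix(vals, counts$features, stage = "log2rpm",
                library_sizes = library_sizes)
}

#' Presence filter on normalised signal
#'
#' A feature is kept when its value exceeds `threshold` in at least
#' `ceiling(min_frac * n_donors)` donors (default: log2RPM > 0 in at least
#' half of the donors). Feature order is preserved.
#'
#' @param signal A `signal_matrix` at stage `log2rpm`.
#' @param min_frac Minimum fraction of donors (default 0.5).
#' @param threshold Strict lower bound on the signal value (default 0).
#' @return A `signal_matrix` at stage `filtered`.
#' @export
filter_features <- function(signal, min_frac = 0.5, threshold = 0) {
  check_stage(signal, "log2rpm", "filter_features")
  need <- ceiling(min_frac * ncol(signal$values))
  keep <- rowSums(signal$values > threshold) >= need
  signal_matrix(signal$values[keep, , drop = FALSE],
                signal$features[keep, , drop = FALSE],
                stage = "filtered", library_sizes = signal$library_sizes)
}

#' Choose the number of latent factors by permutation
#'
#' Principal components are computed on the feature-standardised matrix and
#' compared with components of matrices whose rows are independently
#' permuted (destroying cross-feature structure while preserving per-feature
#' distributions). `k` is the largest N such that the observed explained
#' variance of every component 1..N exceeds the permutation null, summarised
#' at the `null_quantile` level.
#'
#' @param signal A `signal_matrix` (any post-log stage).
#' @param n_perm Number of permutations (>= 1).
#' @param null_quantile Quantile of the permuted explained variances used as
#'   the null envelope (default 0.95).
#' @param seed Integer seed.
#' @return Integer `k >= 0`.
#' @export
select_k_by_permutation <- function(signal, n_perm = 50, null_quantile = 0.95,
                                    seed = 1) {
  check_stage(signal, c("log2rpm", "filtered"), "select_k_by_permutation")
  n_perm <- check_count(n_perm, "n_perm")
  X <- standardise_rows(signal$values)
  d_obs <- svd(X, nu = 0, nv = 0)$d^2
  d_obs <- d_obs / sum(d_obs)
  k_max <- length(d_obs)
  withr::with_seed(derive_seed(seed, "select_k"), {
    null_d <- matrix(NA_real_, nrow = n_perm, ncol = k_max)
    for (b in seq_len(n_perm)) {
      Xp <- t(apply(X, 1, sample))
      dp <- svd(Xp, nu = 0, nv = 0)$d^2
      null_d[b, ] <- dp / sum(dp)
    }
  })
  env <- apply(null_d, 2, quantile, probs = null_quantile, names = FALSE)
  above <- d_obs > env
  k <- 0L
  while (k < k_max && above[k + 1L]) k <- k + 1L
  k
}

standardise_rows <- function(values) {
  mu <- rowMeans(values)
  s <- apply(values, 1, sd)
  s[s == 0] <- 1
  (values - mu) / s
}

#' Remove latent confounding factors
#'
#' Latent factors are estimated as the top-`k` principal components of the
#' feature-standardised matrix (a principal-component stand-in for
#' factor-analysis confounder estimation) and removed from every feature by
#' linear residualisation; the residual matrix is orthogonal to the retained
#' factor scores.
#'
#' @param signal A `signal_matrix` at stage `filtered` (or `log2rpm`).
#' @param k Number of factors to remove (default 10); `k = 0` returns the
#'   input unchanged apart from the stage label.
#' @return A `signal_matrix` at stage `factor_corrected`, with the factor
#'   score matrix attached as attribute `"factors"`.
#' @export
correct_confounders <- function(signal, k = 10) {
  check_stage(signal, c("log2rpm", "filtered"), "correct_confounders")
  k <- check_count(k, "k", min = 0L)
  n_donors <- ncol(signal$values)
  if (k >= n_donors) abort_invalid("`k` must be smaller than the number of donors.")
  vals <- signal$values
  if (k == 0) {
    out <- signal_matrix(vals, signal$features, stage = "factor_corrected",
                         library_sizes = signal$library_sizes)
    attr(out, "factors") <- matrix(numeric(0), nrow = n_donors, ncol = 0)
    return(out)
  }
  X <- standardise_rows(vals)
  sv <- svd(X, nu = 0, nv = k)
  scores <- sv$v[, seq_len(k), drop = FALSE]  # donors x k
  design <- cbind(1, scores)
  fit <- lm.fit(design, t(vals))
  resid <- t(fit$residuals)
  dimnames(resid) <- dimnames(vals)
  out <- signal_matrix(resid, signal$features, stage = "factor_corrected",
                       library_sizes = signal$library_sizes)
  attr(out, "factors") <- scores
  out
}

#' Quantile-normalise donors to a common distribution
#'
#' Every donor column is mapped onto the row-wise mean of the sorted input
#' columns; ties receive the average of the reference values at the tied
#' ranks. Applying the transform twice equals applying it once.
#'
#' @param signal A `signal_matrix` at stage `factor_corrected` (re-application
#'   at stage `quantile_normalised` is allowed, and is a no-op).
#' @return A `signal_matrix` at stage `quantile_normalised`.
#' @export
quantile_normalize <- function(signal) {
  check_stage(signal, c("factor_corrected", "quantile_normalised"),
              "quantile_normalize")
  vals <- limma::normalizeQuantiles(signal$values, ties = TRUE)
  dimnames(vals) <- dimnames(signal$values)
  signal_matrix(vals, signal$features, stage = "quantile_normalised",
                library_sizes = signal$library_sizes)
}
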
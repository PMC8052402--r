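# Generative mirror of the QTL model: latent per-feature log2 abundance with
# additive cis genotype effects and latent confounders, observed through a
# negative-binomial count layer (log link) plus per-donor library sizes.

#' Simulate a raw ChIP-style count matrix with planted cis effects
#'
#' The latent log2 abundance of feature *f* in donor *j* is
#' `mu + beta_f * g_j + sum_k lambda_fk u_kj + e_fj`, with
#' `e ~ N(0, noise_sd^2)`; counts are drawn from a negative binomial with
#' mean `2^latent * library_size / 1e6` and dispersion `dispersion`
#' (`dispersion = 0` gives Poisson counts). Planted features are placed so
#' the causal variant respects the requested proximity class: inside the
#' peak for `proximal`, 10-200 kb from the nearest edge for `distal`.
#'
#' @param geno A [geno_matrix()].
#' @param n_features Number of features (>= number of planted effects).
#' @param effects Tibble with `variant_id`, `beta` (log2 units per alternate
#'   allele, i.e. phenotype standard deviations when `noise_sd = 1`) and
#'   `proximity` (`"proximal"` or `"distal"`), or `NULL` for a null dataset.
#' @param k_conf Number of latent confounders.
#' @param conf_sd Standard deviation of confounder loadings.
#' @param noise_sd Residual latent standard deviation.
#' @param baseline Mean log2RPM of features.
#' @param dispersion Negative-binomial dispersion (variance
#'   `m + dispersion * m^2`); 0 for Poisson.
#' @param feature_width Peak width in bp.
#' @param library_size_mean Mean per-donor library size (log-normal, cv 0.2).
#' @param assay,cell_type Labels carried on the feature table.
#' @param seed Integer seed.
#' @return A list with `signal` (a `signal_matrix` at stage `raw`, library
#'   sizes attached), and `truth` (tibble `feature_id`, `variant_id`, `beta`,
#'   `proximity` for planted effects).
#' @export
simulate_signal <- function(geno, n_features, effects = NULL, k_conf = 0,
                            conf_sd = 1, noise_sd = 1, baseline = 5,
                            dispersion = 0.05, feature_width = 500,
                            library_size_mean = 2e7,
                            assay = "TF", cell_type = "neutrophil", seed = 1) {
  n_features <- check_count(n_features, "n_features")
  k_conf <- check_count(k_conf, "k_conf", min = 0L)
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    missing_v <- setdiff(effects$variant_id, geno$variants$variant_id)
    if (length(missing_v)) {
      abort_invalid(sprintf("effect variants absent from genotypes: %s",
                            paste(head(missing_v, 3), collapse = ", ")))
    }
    if (nrow(effects) > n_features) {
      abort_invalid("more planted effects than features.")
    }
  }
  n_donors <- nrow(geno$dosage)
  span <- max(geno$variants$pos) + 1e4
  withr::with_seed(derive_seed(seed, "signal"), {
    starts <- sort(sample.int(span, n_features))
    features <- tibble(
      feature_id = sprintf("feat%04d", seq_len(n_features)),
      chrom = geno$variants$chrom[1],
      start = starts,
      end = starts + as.integer(feature_width),
      assay = assay, cell_type = cell_type
    )
    truth <- tibble(feature_id = character(), variant_id = character(),
                    beta = numeric(), proximity = character())
    latent <- matrix(rnorm(n_features * n_donors, sd = noise_sd),
                     nrow = n_features,
                     dimnames = list(features$feature_id, rownames(geno$dosage)))
    if (k_conf > 0) {
      loadings <- matrix(rnorm(n_features * k_conf, sd = conf_sd), n_features)
      factors <- matrix(rnorm(k_conf * n_donors), k_conf)
      latent <- latent + loadings %*% factors
    }
    if (!is.null(effects) && nrow(effects) > 0) {
      planted_rows <- seq_len(nrow(effects))
      for (i in planted_rows) {
        vid <- effects$variant_id[i]
        vpos <- geno$variants$pos[match(vid, geno$variants$variant_id)]
        prox <- effects$proximity[i]
        if (identical(prox, "proximal")) {
          fstart <- max(0L, as.integer(vpos - feature_width %/% 2))
        } else {
          gap <- sample(10000:200000, 1)
          fstart <- max(0L, as.integer(vpos + gap))
        }
        features$start[i] <- fstart
        features$end[i] <- fstart + as.integer(feature_width)
        g <- geno$dosage[, vid]
        g[is.na(g)] <- mean(g, na.rm = TRUE)
        latent[i, ] <- latent[i, ] + effects$beta[i] * g
      }
      truth <- tibble(feature_id = features$feature_id[planted_rows],
                      variant_id = effects$variant_id,
                      beta = effects$beta,
                      proximity = effects$proximity)
    }
    latent <- latent + baseline
    lib <- stats::rlnorm(n_donors, log(library_size_mean) - 0.02, 0.2)
    lib <- setNames(round(lib), rownames(geno$dosage))
    mu <- sweep(2^latent, 2, lib / 1e6, "*")
    counts <- if (dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), nrow(mu))
    } else {
      matrix(rpois(length(mu), mu), nrow(mu))
    }
    dimnames(counts) <- dimnames(latent)
    sig <- signal_matrix(counts, features, stage = "raw", library_sizes = lib)
    list(signal = sig, truth = truth)
  })
}
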
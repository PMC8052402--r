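# cis-QTL mapping with a single-variance-component linear mixed model,
# two-step multiple-testing control, LD clumping and distance
# characterisation of lead variants.

#' Map cis QTLs for a normalised molecular phenotype
#'
#' For every feature, all variants whose position lies within `window` bp of
#' either feature edge are tested for association. With a kinship matrix the
#' model is `y = mu + g beta + u + e`, `u ~ N(0, sigma_g^2 K)`: the variance
#' components are estimated once per feature under the null (no variant) by
#' maximum likelihood on the eigen-rotated data, phenotype and genotypes are
#' decorrelated by the fitted covariance, and each variant is then scored by
#' a Wald t-test on the generalised-least-squares fit. Without kinship the
#' fit is ordinary least squares; with `kinship = identity` the two paths
#' coincide exactly.
#'
#' Missing dosages are mean-imputed for testing. Variants without genotype
#' variance among the tested donors are skipped and counted in the
#' `"n_skipped"` attribute.
#'
#' @param signal A `signal_matrix` at stage `quantile_normalised`.
#' @param geno A [geno_matrix()] over the same donors.
#' @param kinship Donor x donor relatedness matrix, or `NULL` for OLS.
#' @param window cis window in bp on each side of the feature (default 1 Mb).
#' @param proximity_cutoff Boundary between proximal and distal leads in bp.
#' @return Tibble with one row per tested (feature, variant) pair:
#'   `feature_id`, `variant_id`, `chrom`, `pos`, `beta`, `se`, `p`,
#'   `distance` (signed bp to the nearest feature edge, 0 inside),
#'   `proximity` and `n` (donors).
#' @export
map_cis_qtl <- function(signal, geno, kinship = NULL, window = 1e6,
                        proximity_cutoff = 2500) {
  check_stage(signal, "quantile_normalised", "map_cis_qtl")
  donors <- signal$donors
  if (!setequal(donors, rownames(geno$dosage))) {
    abort_invalid("signal and genotype donors do not match.")
  }
  G <- geno$dosage[donors, , drop = FALSE]
  G <- apply(G, 2, function(g) {
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  n <- length(donors)
  variants <- geno$variants
  # eigen-rotation for the mixed model; identity rotation for OLS
  if (!is.null(kinship)) {
    K <- if (is.null(dimnames(kinship))) kinship else kinship[donors, donors]
    eig <- eigen(K, symmetric = TRUE)
    U <- eig$vectors
    d <- pmax(eig$values, 0)
    Gt <- crossprod(U, G)
    onet <- as.numeric(crossprod(U, rep(1, n)))
  } else {
    Gt <- G
    onet <- rep(1, n)
    d <- rep(1, n)
    U <- NULL
  }
  feats <- signal$features
  n_skipped <- 0L
  res <- vector("list", nrow(feats))
  for (f in seq_len(nrow(feats))) {
    on_chrom <- variants$chrom == feats$chrom[f]
    dist_all <- interval_distance(variants$pos,
                                  rep(feats$start[f], nrow(variants)),
                                  rep(feats$end[f], nrow(variants)))
    idx <- which(on_chrom & abs(dist_all) <= window)
    if (length(idx) == 0) next
    y <- signal$values[f, ]
    yt <- if (is.null(U)) y else as.numeric(crossprod(U, y))
    if (!is.null(kinship)) {
      h <- optimize(function(h) null_ml_loglik(h, yt, onet, d),
                    interval = c(1e-4, 0.9999), maximum = TRUE)$maximum
      w <- 1 / (h * d + (1 - h))
    } else {
      w <- rep(1, n)
    }
    # weighted 2x2 normal equations for design (rotated intercept, variant),
    # vectorised over all cis variants
    X <- Gt[, idx, drop = FALSE]
    a11 <- sum(w * onet^2)
    b1 <- sum(w * onet * yt)
    a12 <- as.numeric(crossprod(X, w * onet))
    a22 <- as.numeric(crossprod(X^2, w))
    b2 <- as.numeric(crossprod(X, w * yt))
    syy <- sum(w * yt^2)
    det <- a11 * a22 - a12^2
    ok <- det > 1e-10 * a11 * pmax(a22, 1e-12) & (a22 - a12^2 / a11) > 1e-10
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    beta <- (a11 * b2[ok] - a12[ok] * b1) / det[ok]
    alpha <- (b1 - a12[ok] * beta) / a11
    rss <- pmax(syy - alpha * b1 - beta * b2[ok], 0)
    sigma2 <- rss / (n - 2)
    se <- sqrt(sigma2 * a11 / det[ok])
    tstat <- beta / se
    p <- 2 * pt(-abs(tstat), df = n - 2)
    dist_f <- dist_all[idx][ok]
    res[[f]] <- tibble(
      feature_id = feats$feature_id[f],
      variant_id = variants$variant_id[idx][ok],
      chrom = variants$chrom[idx][ok],
      pos = variants$pos[idx][ok],
      beta = beta, se = se, p = pmax(p, .Machine$double.xmin),
      distance = dist_f,
      proximity = ifelse(abs(dist_f) < proximity_cutoff, "proximal", "distal"),
      n = n
    )
  }
  out <- bind_rows(res)
  attr(out, "n_skipped") <- n_skipped
  out
}

# profile log-likelihood of the intercept-only mixed model at heritability h,
# on eigen-rotated data (yt = U'y, xt = U'1, d = eigenvalues of K)
null_ml_loglik <- function(h, yt, xt, d) {
  v <- h * d + (1 - h)
  w <- 1 / v
  b0 <- sum(w * xt * yt) / sum(w * xt^2)
  r <- yt - xt * b0
  n <- length(yt)
  s2 <- sum(w * r^2) / n
  -0.5 * (n * log(s2) + sum(log(v)) + n)
}

#' Two-step multiple-testing correction and lead selection
#'
#' Step one corrects across variants within each feature: the feature's
#' minimum p-value is Bonferroni-adjusted by the number of variants tested
#' for that feature. Step two feeds the adjusted minima across features to
#' the Storey q-value procedure; features with `q < fdr` are flagged
#' significant and their minimum-p variant becomes the lead (ties broken by
#' smallest p, then largest |beta|, then smallest position).
#'
#' @param records Tibble from [map_cis_qtl()].
#' @param fdr Study-wide false discovery rate (default 0.05).
#' @return One row per feature (its lead variant) with `n_tested`, `bonf_p`,
#'   `q`, `significant` and `is_lead` columns; the pi0 estimate is attached
#'   as attribute `"pi0"`.
#' @export
correct_multiple_testing <- function(records, fdr = 0.05) {
  leads <- records |>
    group_by(.data$feature_id) |>
    mutate(n_tested = n()) |>
    arrange(.data$p, desc(abs(.data$beta)), .data$pos, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(bonf_p = pmin(1, .data$p * .data$n_tested))
  qv <- qvalue_storey(leads$bonf_p)
  leads <- leads |>
    mutate(q = qv$qvalues, significant = .data$q < fdr, is_lead = TRUE)
  attr(leads, "pi0") <- qv$pi0
  leads
}

#' Collapse leads in mutual LD to independent QTLs
#'
#' Greedy clumping by ascending p-value (ties: largest |beta|, smallest
#' position): a lead is absorbed into an earlier-kept lead when their dosage
#' r^2 is at least `r2_min`; survivors are flagged `is_independent`.
#'
#' @param leads Lead records (typically significant rows from
#'   [correct_multiple_testing()]).
#' @param geno A [geno_matrix()] containing the lead variants.
#' @param r2_min LD threshold for absorption (default 0.8).
#' @return `leads` with an `is_independent` flag, independent leads first in
#'   the greedy order.
#' @export
clump_leads <- function(leads, geno, r2_min = 0.8) {
  if (nrow(leads) == 0) return(mutate(leads, is_independent = logical(0)))
  ord <- order(leads$p, -abs(leads$beta), leads$pos)
  leads <- leads[ord, ]
  dos <- geno$dosage[, leads$variant_id, drop = FALSE]
  kept <- integer(0)
  indep <- logical(nrow(leads))
  for (i in seq_len(nrow(leads))) {
    absorbed <- FALSE
    for (k in kept) {
      r2 <- suppressWarnings(ld_r2(dos[, i], dos[, k]))
      if (!is.na(r2) && r2 >= r2_min) { absorbed <- TRUE; break }
    }
    if (!absorbed) {
      kept <- c(kept, i)
      indep[i] <- TRUE
    }
  }
  mutate(leads, is_independent = indep)
}

#' Classify a lead variant as proximal or distal
#'
#' Distance is the signed base-pair offset from the variant to the nearest
#' feature edge (0 when the variant lies inside the feature); variants
#' strictly closer than `cutoff` are proximal.
#'
#' @param pos Variant position(s), 1-based.
#' @param start,end Feature interval, 0-based half-open.
#' @param cutoff Proximal/distal boundary in bp (default 2500).
#' @return Tibble with `distance` and `proximity`.
#' @export
classify_proximity <- function(pos, start, end, cutoff = 2500) {
  d <- interval_distance(pos, rep(start, length.out = length(pos)),
                         rep(end, length.out = length(pos)))
  tibble(distance = d,
         proximity = ifelse(abs(d) < cutoff, "proximal", "distal"))
}

#' Effect size of anchor leads on a partner phenotype, by distance
#'
#' Each anchor lead is paired with the nearest partner feature carrying a
#' record for the anchor variant; |beta| on the partner phenotype is binned
#' by the distance between the anchor variant and the partner feature.
#' Returns per-bin mean |beta| with a t-interval, and the slope of a linear
#' model of |beta| on distance.
#'
#' @param anchor_leads Lead records of the anchor layer (need `variant_id`,
#'   `pos`).
#' @param partner_records Full association records of the partner layer
#'   (need `variant_id`, `feature_id`, `beta`, `distance`).
#' @param bins Distance bin edges in bp.
#' @return List with `profile` (per-bin tibble: `bin`, `n`, `mean_abs_beta`,
#'   `ci_lo`, `ci_hi`) and `trend` (tibble: `slope`, `se`, `p`).
#' @export
effect_distance_profile <- function(anchor_leads, partner_records,
                                    bins = c(0, 1e4, 2.5e4, 5e4, 1e5, 2.5e5,
                                             5e5, 1e6)) {
  pairs <- partner_records |>
    filter(.data$variant_id %in% anchor_leads$variant_id) |>
    group_by(.data$variant_id) |>
    arrange(abs(.data$distance), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(abs_beta = abs(.data$beta), abs_dist = abs(.data$distance))
  profile <- pairs |>
    mutate(bin = cut(.data$abs_dist, breaks = bins, include.lowest = TRUE,
                     right = FALSE)) |>
    group_by(.data$bin, .drop = FALSE) |>
    summarise(n = n(),
              mean_abs_beta = ifelse(n() > 0, mean(.data$abs_beta), NA_real_),
              sd_abs_beta = ifelse(n() > 1, sd(.data$abs_beta), NA_real_),
              .groups = "drop") |>
    mutate(half = stats::qt(0.975, df = pmax(.data$n - 1, 1)) *
             .data$sd_abs_beta / sqrt(.data$n),
           ci_lo = .data$mean_abs_beta - .data$half,
           ci_hi = .data$mean_abs_beta + .data$half) |>
    select(-"half")
  trend <- if (nrow(pairs) >= 3 && length(unique(pairs$abs_dist)) > 1) {
    fit <- summary(lm(abs_beta ~ abs_dist, data = pairs))$coefficients
    tibble(slope = fit["abs_dist", 1], se = fit["abs_dist", 2],
           p = fit["abs_dist", 4])
  } else {
    tibble(slope = NA_real_, se = NA_real_, p = NA_real_)
  }
  list(profile = profile, trend = trend, pairs = pairs)
}

#' Pooled genotype-stratified signal trend per site group
#'
#' Pools (donor, site) observations across all sites of a group and fits one
#' linear regression of signal on dosage per group and per cell type,
#' mirroring genotype-stratified cross-cell-type sharing analyses.
#'
#' @param signal A `signal_matrix` (any stage past raw).
#' @param geno A [geno_matrix()].
#' @param sites Tibble with `feature_id`, `variant_id` and a `group` column
#'   (e.g. `"proximal"` / `"distal"`).
#' @return Tibble with one row per (group, cell_type): `slope`, `se`, `p`,
#'   `n_obs`.
#' @export
genotype_stratified_trend <- function(signal, geno, sites) {
  sites <- as_tibble(sites)
  donors <- intersect(signal$donors, rownames(geno$dosage))
  long <- purrr::pmap_dfr(
    list(sites$feature_id, sites$variant_id, sites$group),
    function(fid, vid, grp) {
      fi <- match(fid, signal$features$feature_id)
      if (is.na(fi) || !vid %in% colnames(geno$dosage)) return(NULL)
      ct <- if ("cell_type" %in% names(signal$features)) {
        signal$features$cell_type[fi]
      } else "all"
      tibble(group = grp,
             cell_type = ct,
             donor_id = donors,
             value = signal$values[fi, donors],
             dosage = geno$dosage[donors, vid])
    })
  long |>
    filter(!is.na(.data$dosage)) |>
    group_by(.data$group, .data$cell_type) |>
    dplyr::group_modify(function(df, key) {
      if (length(unique(df$dosage)) < 2) {
        rlang::warn("a site group has a single genotype class; trend undefined.",
                    class = "chromaqtl_trend_undefined")
        return(tibble(slope = NA_real_, se = NA_real_, p = NA_real_,
                      n_obs = nrow(df)))
      }
      if (var(df$value) == 0) {
        return(tibble(slope = 0, se = 0, p = 1, n_obs = nrow(df)))
      }
      fit <- summary(lm(value ~ dosage, data = df))$coefficients
      tibble(slope = fit["dosage", 1], se = fit["dosage", 2],
             p = fit["dosage", 4], n_obs = nrow(df))
    }) |>
    ungroup()
}
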
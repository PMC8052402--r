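peaks_tbl <- function(...) tibble::tibble(chrom = "chr1", ...)

test_that("consensus peaks follow the merge-then-count rule", {
  three_same <- list(a = peaks_tbl(start = 100, end = 200),
                     b = peaks_tbl(start = 100, end = 200),
                     c = peaks_tbl(start = 100, end = 200))
  res <- build_consensus_peaks(three_same, min_samples = 3)
  expect_equal(nrow(res), 1)
  expect_equal(res$start, 100)
  expect_equal(res$end, 200)
  expect_equal(res$support, 3)
  # present in 2 of 5 samples with min 3 -> dropped
  five <- c(list(a = peaks_tbl(start = 100, end = 200),
                 b = peaks_tbl(start = 120, end = 220)),
            lapply(1:3, function(i) peaks_tbl(start = 5000, end = 5100)))
  names(five)[3:5] <- c("c", "d", "e")
  res2 <- build_consensus_peaks(five, min_samples = 3)
  expect_false(any(res2$start < 1000))
  expect_true(any(res2$start == 5000 & res2$support == 3))
  # chained overlaps merge into one union
  chain <- list(a = peaks_tbl(start = 0, end = 150),
                b = peaks_tbl(start = 100, end = 250),
                c = peaks_tbl(start = 200, end = 300))
  res3 <- build_consensus_peaks(chain, min_samples = 3)
  expect_equal(nrow(res3), 1)
  expect_equal(c(res3$start, res3$end, res3$support), c(0, 300, 3))
  # sex chromosomes excluded
  sexy <- lapply(1:3, function(i)
    tibble::tibble(chrom = c("chr1", "chrX"), start = c(0, 0),
                   end = c(100, 100)))
  names(sexy) <- letters[1:3]
  expect_false("chrX" %in% build_consensus_peaks(sexy, 3)$chrom)
  expect_error(build_consensus_peaks(list(), 3),
               class = "chromaqtl_invalid_argument")
})

test_that("consensus peaks match an interval-sweep oracle on fuzzed inputs", {
  for (s in 1:5) {
    withr::with_seed(s, {
      sets <- lapply(1:4, function(i) {
        st <- sort(sample.int(5000, 15)) * 10
        peaks_tbl(start = st, end = st + sample(50:400, 15, replace = TRUE))
      })
      names(sets) <- paste0("s", 1:4)
    })
    got <- build_consensus_peaks(sets, min_samples = 2)
    all_peaks <- dplyr::bind_rows(lapply(names(sets), function(nm)
      dplyr::mutate(sets[[nm]], sample_id = nm)))
    want <- oracle_consensus(all_peaks, 2)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$support, want$support)
    # support conservation: never more supporters than overlapping peaks
    for (i in seq_len(nrow(got))) {
      n_olap <- sum(all_peaks$start < got$end[i] & all_peaks$end > got$start[i])
      expect_gte(n_olap, got$support[i])
    }
  }
})

test_that("broad peaks tile into truncated windows", {
  w <- window_broad_peaks(peaks_tbl(start = 0, end = 5000), 2500)
  expect_equal(w$start, c(0, 2500))
  expect_equal(w$end, c(2500, 5000))
  w2 <- window_broad_peaks(peaks_tbl(start = 0, end = 6000), 2500)
  expect_equal(nrow(w2), 3)
  expect_equal(w2$end[3], 6000)
  expect_equal(w2$start[3], 5000)
  w3 <- window_broad_peaks(peaks_tbl(start = 100, end = 900), 2500)
  expect_equal(nrow(w3), 1)
  expect_equal(c(w3$start, w3$end), c(100, 900))
  expect_error(window_broad_peaks(peaks_tbl(start = 0, end = 10), width = 0),
               class = "chromaqtl_invalid_argument")
})

test_that("log2RPM matches the closed form and an element-wise oracle", {
  m <- matrix(c(2, 0), nrow = 2, ncol = 1,
              dimnames = list(c("f1", "f2"), "d1"))
  feats <- tibble::tibble(feature_id = c("f1", "f2"), chrom = "chr1",
                          start = c(0, 1000), end = c(500, 1500))
  sm <- signal_matrix(m, feats, stage = "raw")
  out <- compute_log2rpm(sm, library_sizes = c(d1 = 1e6), pseudocount = 0)
  expect_equal(out$values["f1", "d1"], 1)
  out2 <- compute_log2rpm(sm, library_sizes = c(d1 = 1e6), pseudocount = 0.5)
  expect_equal(out2$values["f2", "d1"], log2(0.5))
  withr::with_seed(9, {
    counts <- matrix(rpois(200, 40), 20, 10)
    libs <- setNames(runif(10, 5e6, 2e7), sprintf("donor%03d", 1:10))
  })
  sm2 <- manual_signal(counts)
  got <- compute_log2rpm(sm2, library_sizes = libs)$values
  want <- counts
  for (i in 1:20) for (j in 1:10) {
    want[i, j] <- log2((counts[i, j] + 0.5) * 1e6 / libs[j])
  }
  expect_lt(max(abs(got - want)), 1e-12)
  neg <- manual_signal(matrix(-1, 1, 2))
  expect_error(compute_log2rpm(neg, library_sizes = c(donor001 = 1, donor002 = 1)),
               class = "chromaqtl_invalid_argument")
})

test_that("the presence filter keeps features by the ceil rule", {
  vals <- rbind(c(1, 1, -1, -1), c(-1, -1, -1, -1), c(1, -1, -1, -1))
  sm <- manual_signal(vals, stage = "log2rpm")
  kept <- filter_features(sm, min_frac = 0.5, threshold = 0)
  expect_equal(rownames(kept$values), "feat0001")  # 2 of 4 meets ceil(2)
  # fuzzed matrices against a per-row counting oracle
  for (s in 1:5) {
    withr::with_seed(s, m <- matrix(rnorm(300), 30, 10))
    got <- rownames(filter_features(manual_signal(m, stage = "log2rpm"))$values)
    want <- rownames(manual_signal(m, stage = "log2rpm")$values)[
      sapply(seq_len(30), function(i) sum(m[i, ] > 0) >= 5)]
    expect_equal(got, want)
  }
})

test_that("permutation-based factor count finds planted structure, not noise", {
  noise_k <- vapply(1:30, function(s) {
    withr::with_seed(s, m <- matrix(rnorm(100 * 30), 100, 30))
    select_k_by_permutation(manual_signal(m, stage = "log2rpm"),
                            n_perm = 25, seed = s)
  }, integer(1))
  expect_gte(mean(noise_k <= 1), 0.9)
  planted_k <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      u <- rnorm(100, sd = 3); v <- rnorm(30)
      m <- u %o% v + matrix(rnorm(100 * 30), 100, 30)
    })
    select_k_by_permutation(manual_signal(m, stage = "log2rpm"),
                            n_perm = 25, seed = s)
  }, integer(1))
  expect_true(all(planted_k >= 1))
  sm <- manual_signal(matrix(rnorm(100), 10, 10), stage = "log2rpm")
  expect_identical(select_k_by_permutation(sm, 10, seed = 4),
                   select_k_by_permutation(sm, 10, seed = 4))
  expect_error(select_k_by_permutation(sm, n_perm = 0),
               class = "chromaqtl_invalid_argument")
})

test_that("confounder correction removes planted factors and is orthogonal", {
  sm <- manual_signal(matrix(rnorm(50 * 20), 50, 20), stage = "filtered")
  same <- correct_confounders(sm, k = 0)
  expect_equal(same$values, sm$values)
  # pure rank-1 structure vanishes with k = 1
  withr::with_seed(2, {
    u <- rnorm(50, sd = 2); v <- rnorm(20)
    m <- u %o% v + matrix(rnorm(50 * 20, sd = 0.05), 50, 20)
  })
  cc <- correct_confounders(manual_signal(m, stage = "filtered"), k = 1)
  expect_lt(var(as.numeric(cc$values)) / var(as.numeric(m)), 0.01)
  # residuals orthogonal to retained factor scores
  scores <- attr(cc, "factors")
  cors <- abs(cor(t(cc$values), scores))
  expect_lt(max(cors), 1e-8)
  expect_error(correct_confounders(sm, k = 20),
               class = "chromaqtl_invalid_argument")
})

test_that("confounder correction preserves orthogonal genotype effects", {
  g <- simulate_genotypes(120, 20, ld_block_len = 1, maf_range = c(0.3, 0.5),
                          seed = 71)
  x <- g$dosage[, 5]
  withr::with_seed(72, {
    factors <- matrix(rnorm(2 * 120), 2, 120)
    load <- matrix(rnorm(120 * 2, sd = 2), 120, 2)
    base <- matrix(rnorm(120 * 120), 120, 120)
    m_conf <- base + load %*% factors
    m_conf[1, ] <- m_conf[1, ] + 1 * x
    m_free <- base
    m_free[1, ] <- m_free[1, ] + 1 * x
  })
  b_conf <- coef(lm(correct_confounders(
    manual_signal(m_conf, stage = "filtered"), k = 2)$values[1, ] ~ x))[2]
  b_free <- coef(lm(m_free[1, ] ~ x))[2]
  expect_lt(abs(b_conf - b_free) / abs(b_free), 0.1)
})

test_that("quantile normalisation matches the rank oracle and is idempotent", {
  m <- matrix(c(1, 2, 10, 20), 2, 2, dimnames = list(c("f1", "f2"), c("a", "b")))
  feats <- tibble::tibble(feature_id = c("f1", "f2"), chrom = "chr1",
                          start = c(0, 1000), end = c(500, 1500))
  qn <- quantile_normalize(signal_matrix(m, feats, stage = "factor_corrected"))
  ref <- unname(rowMeans(apply(m, 2, sort)))  # mean of sorted columns
  expect_equal(unname(qn$values[, 1]), ref)
  expect_equal(unname(qn$values[, 2]), ref)
  # columns already permutations of a common vector stay a permutation of it
  withr::with_seed(5, {
    base <- rnorm(30)
    m2 <- sapply(1:8, function(j) sample(base))
  })
  qn2 <- quantile_normalize(manual_signal(m2, stage = "factor_corrected"))
  for (j in 1:8) expect_equal(unname(sort(qn2$values[, j])), sort(base))
  # idempotence
  qn3 <- quantile_normalize(qn2)
  expect_lt(max(abs(qn3$values - qn2$values)), 1e-12)
  # constant column collapses to the mean reference value
  m3 <- cbind(rnorm(10), rep(1, 10))
  qn4 <- quantile_normalize(manual_signal(m3, stage = "factor_corrected"))
  expect_equal(length(unique(qn4$values[, 2])), 1)
  # tied ranks map to the reference value at the average rank (mid-quantile)
  ref3 <- sort(rowMeans(apply(m3, 2, sort)))
  expect_equal(unname(unique(qn4$values[, 2])), mean(ref3[5:6]))
})

test_that("pipeline stages advance only in order", {
  raw <- manual_signal(matrix(rpois(40, 30), 10, 4), stage = "raw")
  expect_error(filter_features(raw), class = "chromaqtl_invalid_argument")
  expect_error(quantile_normalize(raw), class = "chromaqtl_invalid_argument")
  l2 <- compute_log2rpm(raw, library_sizes = setNames(rep(1e6, 4),
                                                      colnames(raw$values)))
  expect_error(compute_log2rpm(l2, library_sizes = setNames(rep(1e6, 4),
                                                            colnames(raw$values))),
               class = "chromaqtl_invalid_argument")
  expect_equal(quantile_normalize(correct_confounders(filter_features(l2),
                                                      k = 1))$stage,
               "quantile_normalised")
})
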
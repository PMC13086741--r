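test_that("low-count filter keeps exactly the genes at or above the threshold", {
  m <- tiny_counts(c(3L, 5L, 0L, 6L, 5L, 0L), 3, 2)  # row sums 9, 10, 0
  out <- filter_low_counts(m)
  expect_identical(rownames(out), "g02")
  expect_identical(retention(out)$n_retained, 1L)

  expect_error(filter_low_counts(tiny_counts(rep(0L, 4), 2, 2)),
               "empty dataset")
})

test_that("retention percentages reproduce half-away-from-zero integer rounding", {
  expect_identical(retention_summary(17908, 22642)$percent, 79L)
  expect_identical(retention_summary(17624, 22642)$percent, 78L)
  expect_identical(retention_summary(17043, 22642)$percent, 75L)
  expect_identical(retention_summary(159, 200)$percent, 80L)  # 79.5 rounds up
})

test_that("median-of-ratios size factors match hand calculation and DESeq2", {
  # identical columns -> all size factors 1
  m <- tiny_counts(rep(c(5L, 9L), 3), 2, 3)
  expect_equal(unname(estimate_size_factors(m)), rep(1, 3))

  # hand-evaluated 2x2 example
  m2 <- tiny_counts(c(2L, 6L, 4L, 12L), 2, 2)
  expect_equal(unname(estimate_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # doubling one column doubles its size factor relative to the others
  m3 <- m2
  m3[, 2] <- m3[, 2] * 2L
  s2 <- estimate_size_factors(m2)
  s3 <- estimate_size_factors(m3)
  expect_equal(unname(s3[2] / s3[1]), unname(2 * s2[2] / s2[1]),
               tolerance = 1e-12)

  # independent oracle: DESeq2's median-of-ratios, rescaled to geomean 1
  set.seed(15)
  m4 <- matrix(stats::rnbinom(800, mu = 60, size = 2), 80, 10,
               dimnames = list(sprintf("g%02d", 1:80),
                               sprintf("s%02d", 1:10)))
  s_pkg <- estimate_size_factors(m4)
  s_ref <- DESeq2::estimateSizeFactorsForMatrix(m4)
  s_ref <- s_ref / exp(mean(log(s_ref)))
  expect_equal(unname(s_pkg), unname(s_ref), tolerance = 1e-10)

  # geometric mean is 1 and an all-zero-containing matrix needs the flag
  expect_equal(exp(mean(log(s_pkg))), 1, tolerance = 1e-9)
  m5 <- tiny_counts(c(0L, 4L, 5L, 0L), 2, 2)
  expect_error(estimate_size_factors(m5), "pseudo_reference")
  expect_length(estimate_size_factors(m5, pseudo_reference = TRUE), 2)
})

test_that("dispersion estimates recover generative values and handle degeneracy", {
  n <- 500
  sf <- stats::setNames(rep(1, n), sprintf("s%03d", 1:n))

  set.seed(31)
  pois <- matrix(stats::rpois(2 * n, 100), 2, n,
                 dimnames = list(c("g01", "g02"), names(sf)))
  a0 <- estimate_dispersions(pois, sf, trend_weight = 0)
  expect_true(all(a0 < 0.05))

  set.seed(32)
  nb <- matrix(stats::rnbinom(2 * n, mu = 100, size = 1), 2, n,
               dimnames = list(c("g01", "g02"), names(sf)))
  a1 <- estimate_dispersions(nb, sf, trend_weight = 0)
  expect_true(all(abs(a1 - 1) < 0.25))

  const <- matrix(7L, 2, 4, dimnames = list(c("g01", "g02"),
                                            sprintf("s%02d", 1:4)))
  expect_equal(unname(estimate_dispersions(const, rep(1, 4))), c(0, 0))

  # trend shrinkage keeps estimates non-negative and moves them toward
  # the pooled mean-dispersion trend
  d <- quick_dataset(n_genes = 300, dispersion = 0.4, seed = 33)
  a_raw <- estimate_dispersions(d$counts, d$norm$size_factors,
                                trend_weight = 0)
  a_shr <- estimate_dispersions(d$counts, d$norm$size_factors,
                                trend_weight = 0.5)
  expect_true(all(a_shr >= 0))
  expect_lt(stats::sd(a_shr), stats::sd(a_raw))
})

test_that("NB Wald fits match symmetry and closed-form two-group cases", {
  # identical counts in all treatments -> zero LFC, p ~ 1
  m <- tiny_counts(rep(20L, 6), 1, 6)
  design <- balanced_design(2)
  norm <- list(size_factors = stats::setNames(rep(1, 6), colnames(m)),
               dispersions = 0.1)
  res <- fit_contrasts(m, design, norm)
  expect_equal(res$log2FC, rep(0, 3), tolerance = 1e-8)
  expect_equal(res$pvalue, rep(1, 3), tolerance = 1e-6)

  # 10,10,10 naive vs 40,40,40 positive: log2 ratio of group means is the MLE
  m2 <- tiny_counts(c(10L, 10L, 10L, 40L, 40L, 40L, 20L, 20L, 20L), 1, 9)
  design2 <- balanced_design(3)
  norm2 <- list(size_factors = stats::setNames(rep(1, 9), colnames(m2)),
                dispersions = 1e-8)
  res2 <- fit_contrasts(m2, design2, norm2)
  expect_equal(res2$log2FC[res2$contrast == "pos_vs_naive"], 2,
               tolerance = 1e-6)
})

test_that("NB Wald fits match the brute-force likelihood oracle", {
  set.seed(41)
  design <- balanced_design(2)
  group <- rep(1:3, each = 2)
  n_checked <- 0
  while (n_checked < 50) {
    y <- stats::rnbinom(6, mu = exp(stats::runif(1, 2, 5)), size = 1 / 0.3)
    if (any(tapply(y, group, sum) == 0)) next
    s <- exp(stats::runif(6, -0.3, 0.3))
    s <- s / exp(mean(log(s)))
    m <- tiny_counts(as.integer(y), 1, 6)
    norm <- list(size_factors = stats::setNames(s, colnames(m)),
                 dispersions = 0.3)
    res <- fit_contrasts(m, design, norm)
    oracle <- oracle_fit_one_gene(y, s, 0.3, group)
    for (ct in c("pos_vs_naive", "neg_vs_naive", "neg_vs_pos")) {
      row <- res[res$contrast == ct, ]
      # absolute agreement: coefficients within 1e-4, p within 1e-6
      expect_lt(abs(row$log2FC - oracle[[ct]]["lfc2"]), 1e-4)
      expect_lt(abs(row$pvalue - oracle[[ct]]["p"]), 1e-6)
    }
    n_checked <- n_checked + 1
  }
})

test_that("contrasts are internally consistent and p-values calibrate under the null", {
  d <- quick_dataset(n_genes = 2000, dispersion = 0.5, seed = 51)
  res <- fit_contrasts(d$counts, d$design, d$norm)
  lfc <- matrix(res$log2FC, ncol = 3)
  # neg_vs_pos = neg_vs_naive - pos_vs_naive within the same fitted model
  expect_equal(lfc[, 3], lfc[, 2] - lfc[, 1], tolerance = 1e-6)
  # sign(W) = sign(log2FC)
  ok <- !is.na(res$wald) & res$log2FC != 0
  expect_true(all(sign(res$wald[ok]) == sign(res$log2FC[ok])))
  # null calibration: raw Wald p approximately uniform
  p <- res$pvalue[!is.na(res$pvalue)]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("planted effects are detected with high power at raw p < 0.01", {
  d <- quick_dataset(n_genes = 1000, dispersion = 0.2, effect_lfc = 2,
                     frac_unique_pos = 0.1, seed = 52)
  res <- fit_contrasts(d$counts, d$design, d$norm)
  p_pos <- res$pvalue[res$contrast == "pos_vs_naive"]
  planted <- d$truth$class == "unique_pos"
  expect_gte(mean(p_pos[planted] < 0.01, na.rm = TRUE), 0.9)
})

test_that("LFC shrinkage is zero-preserving, SE-monotone and likelihood-dominated", {
  res <- data.frame(gene_id = "g", contrast = "pos_vs_naive",
                    log2FC = 0, log2FC_shrunk = NA_real_, SE = 0.5,
                    wald = 0, pvalue = 1, stringsAsFactors = FALSE)
  expect_equal(shrink_lfc(res)$log2FC_shrunk, 0)

  # SE -> 0 with fixed log2FC = 1: shrunk -> 1
  res$log2FC <- 1
  res$SE <- 1e-6
  expect_equal(shrink_lfc(res)$log2FC_shrunk, 1, tolerance = 1e-3)

  # monotone non-increasing in SE; always between 0 and the raw estimate
  ses <- seq(0.01, 3, length.out = 40)
  shrunk <- vapply(ses, function(se) {
    res$SE <- se
    shrink_lfc(res)$log2FC_shrunk
  }, numeric(1))
  expect_true(all(diff(shrunk) <= 1e-10))
  expect_true(all(shrunk >= 0 & shrunk <= 1))

  # direct posterior-mode oracle at a few SEs
  for (se in c(0.1, 0.5, 1)) {
    grid <- seq(0, 1, by = 1e-5)
    post <- (grid - 1)^2 / (2 * se^2) + log(1 + grid^2)
    res$SE <- se
    expect_equal(shrink_lfc(res)$log2FC_shrunk, grid[which.min(post)],
                 tolerance = 1e-4)
  }

  expect_error(shrink_lfc(res, prior_scale = 0), "prior_scale")
})

test_that("vst_zscore standardizes rows and is scale invariant", {
  d <- quick_dataset(n_genes = 50, n_reps_per_treatment = 3, seed = 61)
  z <- vst_zscore(d$counts, d$norm)
  expect_equal(unname(rowMeans(z)), rep(0, nrow(z)), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, stats::sd)), rep(1, nrow(z)),
               tolerance = 1e-9)

  # doubling all counts and all size factors leaves the output unchanged
  norm2 <- d$norm
  norm2$size_factors <- norm2$size_factors * 2
  z2 <- vst_zscore(d$counts * 2L, norm2)
  expect_equal(z2, z, tolerance = 1e-12, ignore_attr = TRUE)

  # constant gene (unit size factors): all-zero row plus a warning
  m <- rbind(d$counts[1:3, ],
             gflat = rep(5L, ncol(d$counts)))
  unit <- list(size_factors = stats::setNames(rep(1, ncol(m)), colnames(m)))
  expect_warning(zf <- vst_zscore(m, unit), "zero-variance")
  expect_equal(unname(zf["gflat", ]), rep(0, ncol(m)))
})
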
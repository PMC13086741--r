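#' Filter genes with low total counts
#'
#' Drops genes whose total read count across all samples is below
#' `min_total` (default 10), preserving gene order. The retention summary
#' (number retained, number annotated, integer percentage with halves
#' rounded away from zero) is attached as the `"retention"` attribute and
#' retrievable with [retention()].
#'
#' @param counts integer count matrix, genes x samples.
#' @param min_total minimum total count for a gene to be retained.
#' @param n_annotated denominator for the retention percentage; defaults to
#'   the number of genes in `counts` (pass the annotated-genome size when
#'   `counts` is already restricted to expressed genes).
#' @return the filtered count matrix with a `"retention"` attribute.
#' @export
filter_low_counts <- function(counts, min_total = 10,
                              n_annotated = nrow(counts)) {
  check_counts(counts)
  keep <- rowSums(counts) >= min_total
  if (!any(keep)) {
    stop("empty dataset: all genes fall below the minimum total count of ",
         min_total, call. = FALSE)
  }
  out <- counts[keep, , drop = FALSE]
  attr(out, "retention") <- retention_summary(sum(keep), n_annotated)
  out
}

#' Retention summary arithmetic
#'
#' @param n_retained genes passing the filter.
#' @param n_annotated annotated genes (denominator).
#' @return list with `n_retained`, `n_annotated` and `percent` (integer,
#'   half away from zero).
#' @export
retention_summary <- function(n_retained, n_annotated) {
  list(n_retained = as.integer(n_retained),
       n_annotated = as.integer(n_annotated),
       percent = as.integer(round_half_away(100 * n_retained / n_annotated)))
}

#' @rdname filter_low_counts
#' @param x a matrix returned by [filter_low_counts()].
#' @export
retention <- function(x) attr(x, "retention")

#' Median-of-ratios size factors
#'
#' Computes per-sample size factors as the median, over genes positive in
#' every sample, of the ratio of the sample's count to the gene's geometric
#' mean, then rescales so the size factors have geometric mean 1.
#'
#' @param counts count matrix.
#' @param pseudo_reference if no gene is positive in all samples, set TRUE
#'   to compute gene geometric means over positive counts only (a
#'   pseudo-reference in the spirit of DESeq2's `poscounts`).
#' @return named numeric vector of size factors (geometric mean 1).
#' @export
estimate_size_factors <- function(counts, pseudo_reference = FALSE) {
  check_counts(counts)
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos) && !pseudo_reference) {
    stop(paste(
      "no gene has positive counts in every sample;",
      "rerun with pseudo_reference = TRUE to use a positive-count pseudo-reference"
    ), call. = FALSE)
  }
  if (any(all_pos) && !pseudo_reference) {
    sub <- counts[all_pos, , drop = FALSE]
    log_geo <- rowMeans(log(sub))
    s <- apply(log(sub) - log_geo, 2, stats::median)
  } else {
    lc <- log(counts)
    lc[!is.finite(lc)] <- NA
    log_geo <- rowMeans(lc, na.rm = TRUE)
    ratios <- log(counts) - log_geo
    s <- apply(ratios, 2, function(r) stats::median(r[is.finite(r)]))
  }
  s <- exp(s - mean(s))  # rescale to geometric mean 1
  stats::setNames(s, colnames(counts))
}

#' Per-gene dispersion by method of moments with trend shrinkage
#'
#' For each gene, normalized counts `y_ij / s_j` give a method-of-moments
#' dispersion `alpha_mom = max(0, (var - mean) / mean^2)` under
#' `Var = mu + alpha mu^2`. A mean-dispersion trend
#' `alpha_tr(mu) = a0 + a1 / mu` is fit by least squares over genes with
#' positive `alpha_mom` (coefficients clamped at 0, as in the common
#' parametric trend), and the returned estimate is the convex combination
#' `(1 - w) alpha_mom + w alpha_tr` with weight `trend_weight`.
#' Degenerate genes (zero mean or zero variance) get `alpha = 0`.
#'
#' @param counts count matrix (already filtered).
#' @param size_factors per-sample size factors.
#' @param trend_weight shrinkage weight toward the trend, in `[0, 1]`;
#'   0 returns the raw gene-wise method-of-moments estimates.
#' @return named numeric vector of per-gene dispersions (>= 0).
#' @export
estimate_dispersions <- function(counts, size_factors, trend_weight = 0.5) {
  check_counts(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  if (trend_weight < 0 || trend_weight > 1) {
    stop("trend_weight must lie in [0, 1]", call. = FALSE)
  }
  norm <- sweep(counts, 2, size_factors, "/")
  m <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  mom <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)

  alpha <- mom
  if (trend_weight > 0) {
    use <- mom > 0 & m > 0
    if (sum(use) >= 2) {
      fit <- stats::lm.fit(cbind(1, 1 / m[use]), mom[use])
      a <- pmax(fit$coefficients, 0)
      trend <- pmax(0, a[1] + a[2] / pmax(m, .Machine$double.eps))
    } else {
      trend <- mom
    }
    alpha <- (1 - trend_weight) * mom + trend_weight * trend
  }
  alpha[m == 0 | v == 0] <- 0
  stats::setNames(pmax(alpha, 0), rownames(counts))
}

#' Bundle normalization quantities for the NB model
#'
#' Convenience wrapper running [estimate_size_factors()] and
#' [estimate_dispersions()] on a filtered count matrix.
#'
#' @inheritParams estimate_dispersions
#' @inheritParams estimate_size_factors
#' @return list with `size_factors` and `dispersions`.
#' @export
normalization_model <- function(counts, trend_weight = 0.5,
                                pseudo_reference = FALSE) {
  s <- estimate_size_factors(counts, pseudo_reference = pseudo_reference)
  list(size_factors = s,
       dispersions = estimate_dispersions(counts, s,
                                          trend_weight = trend_weight))
}

# ---------------------------------------------------------------------------
# NB GLM fitting. The model y ~ treatment with a log link and offset
# log(s_j) separates across treatment groups, so maximum likelihood reduces
# to one concave 1-D problem per gene per group, solved by damped Newton
# iterations vectorized across genes (ridge 1e-6 on the information,
# steps clipped to +/-5, convergence |step| < 1e-8, max 100 iterations).
# Standard errors use the observed information at the MLE.
# ---------------------------------------------------------------------------

# Fit group log-means for all genes. Returns beta (G x 3, natural log),
# observed information (G x 3) and a converged flag per gene.
fit_group_means <- function(counts, size_factors, dispersions, treatment,
                            tol = 1e-8, max_iter = 100, ridge = 1e-6) {
  G <- nrow(counts)
  beta <- matrix(NA_real_, G, 3, dimnames = list(rownames(counts), TREATMENTS))
  info <- beta
  converged <- matrix(FALSE, G, 3)
  alpha <- rep_len(dispersions, G)

  for (t in seq_along(TREATMENTS)) {
    idx <- which(treatment == TREATMENTS[t])
    yt <- counts[, idx, drop = FALSE]
    st <- size_factors[idx]
    rs <- rowSums(yt)
    b <- ifelse(rs > 0, log(rs / sum(st)), NA_real_)
    ok <- rs > 0
    active <- which(ok)
    for (it in seq_len(max_iter)) {
      if (length(active) == 0) break
      mu <- exp(b[active]) %o% st
      denom <- 1 + alpha[active] * mu
      U <- rowSums((yt[active, , drop = FALSE] - mu) / denom)
      I_exp <- rowSums(mu / denom)
      step <- U / (I_exp + ridge)
      step <- pmin(pmax(step, -5), 5)
      b[active] <- b[active] + step
      done <- abs(step) < tol
      if (any(done)) {
        converged[active[done], t] <- TRUE
        active <- active[!done]
      }
    }
    # observed information at the final estimate
    fin <- which(ok)
    if (length(fin) > 0) {
      mu <- exp(b[fin]) %o% st
      denom <- 1 + alpha[fin] * mu
      info[fin, t] <- rowSums(mu * (1 + alpha[fin] * yt[fin, , drop = FALSE]) /
                                denom^2)
    }
    beta[, t] <- b
  }
  list(beta = beta, info = info,
       converged = converged[, 1] & converged[, 2] & converged[, 3])
}

# p-value / LFC matrices for the three contrasts from a fit_group_means()
# result. Returns list of G x 3 matrices (columns = CONTRASTS).
contrast_stats <- function(fit) {
  b <- fit$beta / log(2)          # log2 scale
  se <- sqrt(1 / fit$info) / log(2)
  lfc <- cbind(pos_vs_naive = b[, "positive"] - b[, "naive"],
               neg_vs_naive = b[, "negative"] - b[, "naive"],
               neg_vs_pos = b[, "negative"] - b[, "positive"])
  sem <- cbind(pos_vs_naive = sqrt(se[, "positive"]^2 + se[, "naive"]^2),
               neg_vs_naive = sqrt(se[, "negative"]^2 + se[, "naive"]^2),
               neg_vs_pos = sqrt(se[, "negative"]^2 + se[, "positive"]^2))
  wald <- lfc / sem
  p <- 2 * stats::pnorm(-abs(wald))
  p[!fit$converged, ] <- NA_real_
  lfc[!fit$converged, ] <- NA_real_
  list(lfc = lfc, se = sem, wald = wald, p = p)
}

#' Fit the three pairwise treatment contrasts per gene
#'
#' Fits, for every gene, the negative-binomial log-link GLM
#' `y ~ treatment` with offset `log(size factor)` at fixed per-gene
#' dispersion, and extracts Wald statistics for the contrasts
#' positive-vs-naive, negative-vs-naive and negative-vs-positive (label on
#' the right is the reference). P-values are two-sided against the standard
#' normal. Genes whose fit does not converge (including genes with a
#' zero-count treatment group, whose group mean has no finite MLE) are
#' returned with `NA` statistics and `converged = FALSE`; they are never
#' called differentially expressed downstream.
#'
#' @param counts filtered count matrix.
#' @param design design data.frame (single tissue, all three treatments).
#' @param norm normalization model from [normalization_model()].
#' @return data.frame with one row per gene per contrast: `gene_id`,
#'   `contrast`, `log2FC`, `log2FC_shrunk` (NA until [shrink_lfc()]),
#'   `SE`, `wald`, `pvalue`, `converged`.
#' @export
fit_contrasts <- function(counts, design, norm) {
  check_counts(counts)
  design <- check_design(design, counts)
  if (!setequal(unique(design$treatment), TREATMENTS)) {
    stop("all three treatments must be present for model fitting",
         call. = FALSE)
  }
  if (any(rowSums(counts) == 0)) {
    stop("all-zero gene present; run filter_low_counts() first",
         call. = FALSE)
  }
  design <- design_in_counts_order(design, counts)
  s <- norm$size_factors[colnames(counts)]
  fit <- fit_group_means(counts, s, norm$dispersions, design$treatment)
  st <- contrast_stats(fit)
  G <- nrow(counts)
  out <- data.frame(
    gene_id = rep(rownames(counts), times = 3),
    contrast = rep(CONTRASTS, each = G),
    log2FC = as.vector(st$lfc),
    log2FC_shrunk = NA_real_,
    SE = as.vector(st$se),
    wald = as.vector(st$wald),
    pvalue = as.vector(st$p),
    converged = rep(fit$converged, times = 3),
    stringsAsFactors = FALSE
  )
  attr(out, "n_nonconverged") <- sum(!fit$converged)
  out
}

#' Shrink log2 fold changes toward zero with a heavy-tailed prior
#'
#' Replaces each raw contrast estimate by the posterior mode under a
#' zero-centered Cauchy prior on the log2 fold change, with the likelihood
#' approximated as normal at the Wald estimate and standard error. The
#' shrunken estimate always lies between 0 and the raw estimate, and
#' shrinkage vanishes as the standard error goes to 0.
#'
#' @param results data.frame from [fit_contrasts()].
#' @param prior_scale Cauchy prior scale in log2 units (default 1).
#' @return `results` with the `log2FC_shrunk` column filled in.
#' @export
shrink_lfc <- function(results, prior_scale = 1) {
  if (!is.numeric(prior_scale) || prior_scale <= 0) {
    stop("configuration error: prior_scale must be positive", call. = FALSE)
  }
  results$log2FC_shrunk <- mapply(function(l, se) {
    if (is.na(l) || is.na(se)) return(NA_real_)
    posterior_mode_cauchy(l, se, prior_scale)
  }, results$log2FC, results$SE)
  results
}

# Posterior mode of N(lfc, se^2) likelihood x Cauchy(0, scale) prior.
posterior_mode_cauchy <- function(lfc, se, scale) {
  if (lfc == 0) return(0)
  if (se <= 0) return(lfc)
  obj <- function(b) (b - lfc)^2 / (2 * se^2) + log(1 + (b / scale)^2)
  interval <- sort(c(0, lfc))
  opt <- stats::optimize(obj, interval = interval, tol = 1e-10)
  # the mode can sit at the MLE end when shrinkage is negligible
  cand <- c(opt$minimum, lfc)
  cand[which.min(vapply(cand, obj, numeric(1)))]
}

#' Variance-stabilized, Z-scored expression matrix
#'
#' Transforms counts to `log2(count / size_factor + 1)` and standardizes
#' each gene across samples to mean 0 and standard deviation 1, the form
#' used for expression heatmaps. Zero-variance genes get all-zero rows and
#' a warning.
#'
#' @param counts filtered count matrix.
#' @param norm normalization model (only `size_factors` is used).
#' @return numeric matrix, genes x samples.
#' @export
vst_zscore <- function(counts, norm) {
  check_counts(counts)
  x <- log2(sweep(counts, 2, norm$size_factors[colnames(counts)], "/") + 1)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) set to all-zero rows")
    sd[flat] <- 1
  }
  z <- (x - mu) / sd
  z[flat, ] <- 0
  z
}
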
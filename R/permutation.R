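#' Permutation configuration
#'
#' @param K number of label permutations (the production analysis this
#'   mirrors used 1000; 200 is a desk-scale default).
#' @param alpha_tail empirical tail used for the per-gene threshold
#'   (default 0.01, "the 1% tail").
#' @param seed integer seed for the permutation stream.
#' @return object of class `perm_config`.
#' @export
perm_config <- function(K = 1000, alpha_tail = 0.01, seed = 1L) {
  if (alpha_tail <= 0 || alpha_tail >= 1) {
    stop("configuration error: alpha_tail must lie in (0, 1)", call. = FALSE)
  }
  if (K < 1 / alpha_tail) {
    stop("configuration error: K must be at least 1/alpha_tail so the ",
         "empirical tail is non-empty", call. = FALSE)
  }
  structure(list(K = as.integer(K), alpha_tail = alpha_tail,
                 seed = as.integer(seed)),
            class = "perm_config")
}

#' Permute treatment labels within a tissue
#'
#' Returns the design with treatment labels uniformly permuted across all
#' samples of the (single) tissue: the multiset of labels is preserved, so
#' the 10/10/10 balance of the emulated design is preserved by
#' construction. Deterministic given `(seed, iteration)`.
#'
#' @param design single-tissue design data.frame.
#' @param seed base seed.
#' @param iteration permutation index (1..K).
#' @return design data.frame with permuted `treatment` column.
#' @export
permute_labels <- function(design, seed, iteration) {
  if (length(unique(design$tissue)) > 1) {
    stop("design spans multiple tissues; permute each tissue separately",
         call. = FALSE)
  }
  perm <- with_seed(stream_seed(seed, iteration),
                    sample.int(nrow(design)))
  out <- design
  out$treatment <- design$treatment[perm]
  out
}

#' Build per-gene null p-value distributions by label permutation
#'
#' Refits the NB Wald contrasts on `K` label-permuted designs, reusing the
#' observed normalization (size factors are label-free) and dispersions,
#' and records every gene x contrast p-value. Permutation fits that fail to
#' converge contribute a null p-value of 1.0 (counted in the
#' `n_imputed` attribute). The per-gene, per-contrast empirical threshold is
#' the `ceiling(alpha_tail * K)`-th smallest null p-value.
#'
#' @param counts filtered count matrix.
#' @param design single-tissue design.
#' @param norm normalization model from [normalization_model()].
#' @param config a [perm_config()].
#' @return object of class `perm_null`: list with `null_p` (list of three
#'   genes x K matrices of sorted null p-values, one per contrast),
#'   `threshold` (genes x 3 matrix), `K`, `alpha_tail`, `gene_id`.
#' @export
build_null <- function(counts, design, norm, config) {
  if (!inherits(config, "perm_config")) config <- do.call(perm_config, config)
  check_counts(counts)
  design <- check_design(design, counts)
  design <- design_in_counts_order(design, counts)
  s <- norm$size_factors[colnames(counts)]
  G <- nrow(counts)
  K <- config$K

  null_p <- lapply(CONTRASTS, function(x) matrix(NA_real_, G, K))
  names(null_p) <- CONTRASTS
  n_imputed <- 0L
  for (k in seq_len(K)) {
    d_k <- permute_labels(design, config$seed, k)
    fit <- fit_group_means(counts, s, norm$dispersions, d_k$treatment)
    p <- contrast_stats(fit)$p
    miss <- is.na(p)
    if (any(miss)) {
      n_imputed <- n_imputed + sum(miss)
      p[miss] <- 1.0
    }
    for (ct in CONTRASTS) null_p[[ct]][, k] <- p[, ct]
  }
  for (ct in CONTRASTS) {
    null_p[[ct]] <- t(apply(null_p[[ct]], 1, sort))
    rownames(null_p[[ct]]) <- rownames(counts)
  }
  rank <- as.integer(ceiling(config$alpha_tail * K))
  threshold <- vapply(CONTRASTS, function(ct) null_p[[ct]][, rank],
                      numeric(G))
  if (G == 1) threshold <- matrix(threshold, 1, 3,
                                  dimnames = list(rownames(counts), CONTRASTS))
  structure(list(null_p = null_p, threshold = threshold,
                 K = K, alpha_tail = config$alpha_tail,
                 gene_id = rownames(counts), n_imputed = n_imputed),
            class = "perm_null")
}

#' Call differentially expressed genes against the permutation null
#'
#' A gene is flagged for a contrast when its observed p-value falls
#' strictly below the per-gene empirical threshold (the
#' `ceiling(alpha_tail * K)`-th smallest of its K null p-values); ties with
#' the threshold resolve to not-DEG, and genes with `NA` observed p-values
#' are never flagged.
#'
#' @param observed data.frame from [fit_contrasts()].
#' @param null a `perm_null` object from [build_null()].
#' @return data.frame with `gene_id`, `contrast`, `observed_p`,
#'   `threshold`, `deg_flag`.
#' @export
call_degs <- function(observed, null) {
  missing <- setdiff(unique(observed$gene_id), null$gene_id)
  if (length(missing) > 0) {
    stop("gene(s) present in observed results but missing from the ",
         "permutation null, e.g. '", missing[1], "'", call. = FALSE)
  }
  thr <- null$threshold[cbind(match(observed$gene_id, null$gene_id),
                              match(observed$contrast, CONTRASTS))]
  flag <- !is.na(observed$pvalue) & observed$pvalue < thr
  data.frame(gene_id = observed$gene_id,
             contrast = observed$contrast,
             observed_p = observed$pvalue,
             threshold = thr,
             deg_flag = flag,
             stringsAsFactors = FALSE)
}

#' Reshape long DEG flags to a genes x contrasts logical matrix
#'
#' @param flags data.frame from [call_degs()].
#' @return logical matrix, genes x 3 contrasts.
#' @export
flags_matrix <- function(flags) {
  genes <- unique(flags$gene_id)
  m <- matrix(FALSE, length(genes), 3,
              dimnames = list(genes, CONTRASTS))
  m[cbind(match(flags$gene_id, genes), match(flags$contrast, CONTRASTS))] <-
    flags$deg_flag
  m
}
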
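#' Simulation configuration for planted-truth count datasets
#'
#' Describes a single-tissue three-treatment experiment (naive reference,
#' positive training, negative training) with negative-binomial counts and a
#' configurable mixture of planted gene classes:
#'
#' * `null` — no treatment effect;
#' * `unique_pos` / `unique_neg` — effect in one training context only;
#' * `shared_learning` — same-sign effect in both training contexts
#'   (valence-independent learning genes);
#' * `antagonistic` — opposite-sign effects in the two training contexts
#'   (valence-associated genes).
#'
#' Counts for gene g in sample j are drawn
#' `NB(mean = baseline_g * 2^lfc(g, treatment_j) * depth_j, dispersion = alpha)`
#' with the DESeq2-style parameterization `Var = mu + alpha * mu^2`.
#'
#' @param n_genes number of simulated genes.
#' @param n_reps_per_treatment biological replicates per treatment (the study
#'   design this emulates used 10).
#' @param treatments treatment labels; must be exactly `naive`, `positive`,
#'   `negative` with `naive` first (the reference level).
#' @param tissue tissue label recorded in the design table.
#' @param baseline_mean_log_range range (natural-log scale) from which
#'   per-gene baseline means are drawn log-uniformly.
#' @param dispersion NB dispersion `alpha` (scalar or per-gene vector),
#'   `Var = mu + alpha mu^2`; must be > 0.
#' @param frac_null,frac_unique_pos,frac_unique_neg,frac_shared_learning,frac_antagonistic
#'   class fractions, each in `[0, 1]`, summing to at most 1; genes not
#'   covered by the explicit fractions are null.
#' @param effect_lfc planted absolute log2 fold change for non-null classes.
#' @param depth_factor_range range for per-sample depth factors, drawn
#'   log-uniformly, to exercise normalization.
#' @param seed integer RNG seed; identical seeds give bit-identical counts.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_reps_per_treatment = 10,
                       treatments = c("naive", "positive", "negative"),
                       tissue = "antennae",
                       baseline_mean_log_range = c(log(10), log(1000)),
                       dispersion = 0.5,
                       frac_null = NULL,
                       frac_unique_pos = 0,
                       frac_unique_neg = 0,
                       frac_shared_learning = 0,
                       frac_antagonistic = 0,
                       effect_lfc = 2,
                       depth_factor_range = c(0.7, 1.4),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_reps_per_treatment = as.integer(n_reps_per_treatment),
    treatments = treatments,
    tissue = tissue,
    baseline_mean_log_range = baseline_mean_log_range,
    dispersion = dispersion,
    frac_unique_pos = frac_unique_pos,
    frac_unique_neg = frac_unique_neg,
    frac_shared_learning = frac_shared_learning,
    frac_antagonistic = frac_antagonistic,
    effect_lfc = effect_lfc,
    depth_factor_range = depth_factor_range,
    seed = as.integer(seed)
  )
  fracs <- c(cfg$frac_unique_pos, cfg$frac_unique_neg,
             cfg$frac_shared_learning, cfg$frac_antagonistic)
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("configuration error: class fractions must lie in [0, 1]",
         call. = FALSE)
  }
  tol <- 1e-12
  if (!is.null(frac_null)) {
    if (frac_null < 0 || sum(fracs) + frac_null > 1 + tol) {
      stop("configuration error: class fractions must sum to at most 1",
           call. = FALSE)
    }
  }
  if (sum(fracs) > 1 + tol) {
    stop("configuration error: class fractions must sum to at most 1",
         call. = FALSE)
  }
  if (any(cfg$dispersion <= 0)) {
    stop("configuration error: dispersion must be positive", call. = FALSE)
  }
  if (!(length(cfg$dispersion) %in% c(1L, cfg$n_genes))) {
    stop("configuration error: dispersion must be scalar or one per gene",
         call. = FALSE)
  }
  if (cfg$n_reps_per_treatment < 2) {
    stop("configuration error: need at least 2 replicates per treatment",
         call. = FALSE)
  }
  if (cfg$n_genes < 1) {
    stop("configuration error: n_genes must be positive", call. = FALSE)
  }
  if (length(cfg$treatments) != 3 || cfg$treatments[1] != "naive" ||
      !setequal(cfg$treatments, TREATMENTS)) {
    stop("configuration error: treatments must be naive, positive, negative with naive first",
         call. = FALSE)
  }
  if (cfg$effect_lfc < 0) {
    stop("configuration error: effect_lfc must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Largest-remainder apportionment of n genes to the planted classes;
# remaining genes are null. Deterministic: ties broken in class order.
apportion_classes <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  target <- min(n, round_half_away(sum(raw)))
  leftover <- as.integer(target - sum(base))
  counts <- base
  if (leftover > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    counts[ord[seq_len(leftover)]] <- counts[ord[seq_len(leftover)]] + 1
  }
  as.integer(counts)
}

#' Simulate a planted-truth count dataset
#'
#' Draws a gene-by-sample integer count matrix under the configuration's
#' generative model, together with the sample design table and the per-gene
#' ground truth (class label and planted log2 fold changes relative to
#' naive). Class labels are assigned to genes in deterministic id order:
#' first `unique_pos`, then `unique_neg`, `shared_learning`, `antagonistic`,
#' and the remainder `null`. Within each planted class the effect sign
#' alternates deterministically so both directions are exercised
#' (antagonistic genes get mirrored signs in the two training contexts).
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `counts` (integer matrix, genes x samples),
#'   `design` (data.frame: sample_id, tissue, treatment) and `truth`
#'   (data.frame: gene_id, class, lfc_pos, lfc_neg).
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  G <- config$n_genes
  nrep <- config$n_reps_per_treatment
  N <- 3L * nrep

  gene_id <- sprintf("gene_%05d", seq_len(G))
  treatment <- rep(config$treatments, each = nrep)
  sample_id <- sprintf("%s_%s_%02d", config$tissue, treatment,
                       rep(seq_len(nrep), times = 3))
  design <- data.frame(sample_id = sample_id, tissue = config$tissue,
                       treatment = treatment, stringsAsFactors = FALSE)

  fracs <- c(unique_pos = config$frac_unique_pos,
             unique_neg = config$frac_unique_neg,
             shared_learning = config$frac_shared_learning,
             antagonistic = config$frac_antagonistic)
  counts_per_class <- apportion_classes(G, fracs)
  class <- rep(c(names(fracs), "null"),
               times = c(counts_per_class, G - sum(counts_per_class)))

  e <- config$effect_lfc
  lfc_pos <- numeric(G)
  lfc_neg <- numeric(G)
  for (cl in names(fracs)) {
    idx <- which(class == cl)
    if (length(idx) == 0) next
    sgn <- ifelse(seq_along(idx) %% 2 == 1, 1, -1)
    if (cl == "unique_pos") {
      lfc_pos[idx] <- sgn * e
    } else if (cl == "unique_neg") {
      lfc_neg[idx] <- sgn * e
    } else if (cl == "shared_learning") {
      lfc_pos[idx] <- sgn * e
      lfc_neg[idx] <- sgn * e
    } else if (cl == "antagonistic") {
      lfc_pos[idx] <- sgn * e
      lfc_neg[idx] <- -sgn * e
    }
  }

  alpha <- rep_len(config$dispersion, G)
  lr <- config$baseline_mean_log_range
  dr <- log(config$depth_factor_range)

  counts <- with_seed(config$seed, {
    baseline <- exp(stats::runif(G, lr[1], lr[2]))
    depth <- exp(stats::runif(N, dr[1], dr[2]))
    lfc_by_treatment <- cbind(naive = numeric(G), positive = lfc_pos,
                              negative = lfc_neg)
    mu <- (baseline * 2^lfc_by_treatment[, treatment, drop = FALSE]) *
      rep(depth, each = G)
    m <- matrix(
      stats::rnbinom(G * N, mu = as.vector(mu), size = rep(1 / alpha, N)),
      nrow = G, ncol = N
    )
    storage.mode(m) <- "integer"
    dimnames(m) <- list(gene_id, sample_id)
    m
  })

  truth <- data.frame(gene_id = gene_id, class = class,
                      lfc_pos = lfc_pos, lfc_neg = lfc_neg,
                      stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth)
}
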
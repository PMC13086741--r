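# Small fixtures shared across test files. Everything is generated in code.

# A tiny named count matrix.
tiny_counts <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# A single-tissue design with n replicates per treatment, sample ids s01..
balanced_design <- function(n = 2, tissue = "antennae") {
  treatment <- rep(c("naive", "positive", "negative"), each = n)
  data.frame(sample_id = sprintf("s%02d", seq_along(treatment)),
             tissue = tissue, treatment = treatment,
             stringsAsFactors = FALSE)
}

# Simulate, filter and normalize in one call; returns the pieces most tests
# need. Keeps per-test simulation settings explicit at the call site.
quick_dataset <- function(..., min_total = 10, trend_weight = 0.5) {
  sim <- simulate_counts(sim_config(...))
  filtered <- filter_low_counts(sim$counts, min_total = min_total)
  norm <- normalization_model(filtered, trend_weight = trend_weight)
  list(sim = sim, counts = filtered, design = sim$design,
       truth = sim$truth[match(rownames(filtered), sim$truth$gene_id), ],
       norm = norm)
}

# Brute-force NB log-likelihood oracle for one gene: maximizes the joint
# likelihood over the three group log-means with optim (BFGS) and derives
# Wald p-values from the numerical Hessian. Independent of the package's
# Newton solver.
oracle_fit_one_gene <- function(y, s, alpha, group) {
  nll <- function(b) {
    mu <- s * exp(b[group])
    -sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
  o <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
                    control = list(reltol = 1e-14), hessian = TRUE)
  vc <- solve(o$hessian)
  contrast <- function(a, b) {
    est <- o$par[a] - o$par[b]
    se <- sqrt(vc[a, a] + vc[b, b])
    c(lfc2 = est / log(2), p = 2 * stats::pnorm(-abs(est / se)))
  }
  list(beta = o$par,
       pos_vs_naive = contrast(2, 1),
       neg_vs_naive = contrast(3, 1),
       neg_vs_pos = contrast(3, 2))
}
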
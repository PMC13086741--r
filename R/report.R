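#' Run the full per-tissue analysis pipeline
#'
#' Orchestrates filter -> normalize -> fit -> shrink -> permute -> call ->
#' classify -> report for one tissue, from either a dataset directory or a
#' simulation configuration, writing all tables and a machine-readable run
#' manifest. Outputs are deterministic given the configuration (including
#' seeds): re-running with an unchanged configuration reproduces the same
#' bytes.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{dataset_dir}{directory with `counts.tsv` + `design.csv`, or}
#'     \item{simulation}{argument list for [sim_config()];}
#'     \item{out_dir}{output directory (required);}
#'     \item{K, alpha_tail, seed}{permutation settings (defaults 200, 0.01, 1);}
#'     \item{min_total}{low-count filter threshold (default 10);}
#'     \item{n_annotated}{denominator for the retention percentage;}
#'     \item{prior_scale}{LFC shrinkage prior scale (default 1);}
#'     \item{trend_weight}{dispersion trend shrinkage weight (default 0.5);}
#'     \item{naive_window, antagonistic_threshold}{valence rule (0.075, 0.5);}
#'     \item{annotation}{optional path to a gene_id<TAB>group TSV.}
#'   }
#' @return the run manifest, invisibly; all artifacts are written under
#'   `out_dir` (`results.tsv`, `flags.tsv`, `classification.tsv`,
#'   `heatmap.tsv` when at least two DEGs exist, `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config must set out_dir", call. = FALSE)
  pcfg <- perm_config(K = config$K %||% 200,
                      alpha_tail = config$alpha_tail %||% 0.01,
                      seed = config$seed %||% 1L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (!is.null(config$dataset_dir)) {
    dataset <- stage("load", read_dataset(config$dataset_dir))
  } else if (!is.null(config$simulation)) {
    dataset <- stage("simulate",
                     simulate_counts(do.call(sim_config, config$simulation)))
  } else {
    stop("config must provide dataset_dir or simulation", call. = FALSE)
  }

  min_total <- config$min_total %||% 10
  filtered <- stage("filter", filter_low_counts(
    dataset$counts, min_total = min_total,
    n_annotated = config$n_annotated %||% nrow(dataset$counts)
  ))
  ret <- retention(filtered)

  norm <- stage("normalize", normalization_model(
    filtered, trend_weight = config$trend_weight %||% 0.5
  ))
  results <- stage("fit", fit_contrasts(filtered, dataset$design, norm))
  results <- stage("shrink", shrink_lfc(results,
                                        prior_scale = config$prior_scale %||% 1))
  null <- stage("permute", build_null(filtered, dataset$design, norm, pcfg))
  flags <- stage("call", call_degs(results, null))

  params <- valence_params(
    naive_window = config$naive_window %||% 0.075,
    antagonistic_threshold = config$antagonistic_threshold %||% 0.5
  )
  trel <- stage("classify", treatment_relative_lfc(filtered, dataset$design,
                                                   norm))
  annotation <- NULL
  if (!is.null(config$annotation)) {
    annotation <- stage("classify",
                        utils::read.delim(config$annotation,
                                          stringsAsFactors = FALSE))
  }
  classification <- stage("classify",
                          classify_genes(flags, results, trel, params,
                                         annotation))

  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  stage("report", {
    write_tsv(results, "results.tsv")
    write_tsv(flags, "flags.tsv")
    write_tsv(classification, "classification.tsv")
  })

  fm <- flags_matrix(flags)
  deg_genes <- rownames(fm)[rowSums(fm) > 0]
  z <- stage("report", vst_zscore(filtered, norm))
  hm <- stage("report", render_heatmap_matrix(z, deg_genes,
                                              classification = classification))
  if (!is.null(hm)) {
    hm_df <- data.frame(gene_id = rownames(hm$matrix), group = hm$group,
                        hm$matrix, check.names = FALSE,
                        stringsAsFactors = FALSE)
    write_tsv(hm_df, "heatmap.tsv")
  }

  part <- partition_deg_sets(fm)
  manifest <- list(
    package_version = as.character(utils::packageVersion("valenceDE")),
    config_hash = config_hash(config),
    seed = pcfg$seed,
    K = pcfg$K,
    alpha_tail = pcfg$alpha_tail,
    min_total = min_total,
    prior_scale = config$prior_scale %||% 1,
    trend_weight = config$trend_weight %||% 0.5,
    naive_window = params$naive_window,
    antagonistic_threshold = params$antagonistic_threshold,
    retention = ret,
    n_nonconverged = attr(results, "n_nonconverged"),
    n_null_imputed = null$n_imputed,
    deg_counts = as.list(colSums(fm)),
    partition_cells = as.list(part$counts),
    n_learning = sum(classification$learning_flag),
    n_valence = sum(classification$valence_flag)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Stable hash of the configuration (md5 of its canonical serialization).
# The output location is not part of the analysis identity, so identical
# configurations written to different directories hash identically.
config_hash <- function(config) {
  config$out_dir <- NULL
  config <- config[order(names(config))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Order a Z-scored DEG matrix for heatmap display
#'
#' Restricts the Z-score matrix to the DEG rows and orders rows and columns
#' by hierarchical clustering (average linkage on Euclidean distances).
#' Values are only re-ordered, never altered.
#'
#' @param z Z-score matrix from [vst_zscore()].
#' @param deg_genes character vector of DEG ids (rows to keep).
#' @param classification optional classification table supplying per-gene
#'   `group` labels.
#' @return list with `matrix` (re-ordered), `row_order`, `col_order`,
#'   `group` (per retained gene), or NULL (with a warning) when fewer than
#'   two DEGs are available.
#' @export
render_heatmap_matrix <- function(z, deg_genes, classification = NULL) {
  deg_genes <- intersect(rownames(z), deg_genes)
  if (length(deg_genes) < 2) {
    warning("fewer than 2 DEGs; heatmap matrix skipped")
    return(NULL)
  }
  sub <- z[deg_genes, , drop = FALSE]
  row_order <- stats::hclust(stats::dist(sub), method = "average")$order
  col_order <- stats::hclust(stats::dist(t(sub)), method = "average")$order
  ordered <- sub[row_order, col_order, drop = FALSE]
  group <- rep("uncharacterised", nrow(ordered))
  if (!is.null(classification) && "group" %in% names(classification)) {
    idx <- match(rownames(ordered), classification$gene_id)
    group <- ifelse(is.na(idx), "uncharacterised",
                    classification$group[idx])
  }
  list(matrix = ordered, row_order = row_order, col_order = col_order,
       group = group)
}
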
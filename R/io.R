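#' Write a dataset to plain-text files
#'
#' Writes `counts.tsv` (gene_id column then one tab-separated integer column
#' per sample), `design.csv` (sample_id,tissue,treatment) and, when ground
#' truth is present, `truth.tsv` (gene_id, class, lfc_pos, lfc_neg).
#'
#' @param dataset list with `counts`, `design` and optionally `truth`, as
#'   returned by [simulate_counts()].
#' @param dir output directory (created if missing).
#' @return named character vector of the files written.
#' @export
write_dataset <- function(dataset, dir) {
  check_counts(dataset$counts)
  check_design(dataset$design, dataset$counts, single_tissue = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  counts_path <- file.path(dir, "counts.tsv")
  df <- data.frame(gene_id = rownames(dataset$counts),
                   dataset$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  design_path <- file.path(dir, "design.csv")
  utils::write.table(dataset$design, design_path, sep = ",", quote = FALSE,
                     row.names = FALSE)

  paths <- c(counts = counts_path, design = design_path)
  if (!is.null(dataset$truth)) {
    truth_path <- file.path(dir, "truth.tsv")
    utils::write.table(dataset$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, truth = truth_path)
  }
  paths
}

#' Read a dataset written by [write_dataset()]
#'
#' Parsing is strict: counts must be non-negative integers (the offending
#' gene and sample are named otherwise), treatment labels must match the
#' vocabulary `naive` / `positive` / `negative` exactly (no case folding or
#' whitespace trimming), and sample ids must agree between the two files.
#'
#' @param dir directory containing `counts.tsv` and `design.csv`
#'   (and optionally `truth.tsv`).
#' @return list with `counts` (integer matrix), `design` (data.frame) and
#'   `truth` (data.frame or NULL).
#' @export
read_dataset <- function(dir) {
  counts_path <- file.path(dir, "counts.tsv")
  design_path <- file.path(dir, "design.csv")
  if (!file.exists(counts_path)) stop("missing counts.tsv in ", dir, call. = FALSE)
  if (!file.exists(design_path)) stop("missing design.csv in ", dir, call. = FALSE)

  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (names(raw)[1] != "gene_id") {
    stop("malformed counts header: first column must be 'gene_id', got '",
         names(raw)[1], "'", call. = FALSE)
  }
  if (ncol(raw) < 2) stop("counts.tsv has no sample columns", call. = FALSE)
  gene_id <- raw[[1]]
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene id '", gene_id[anyDuplicated(gene_id)],
         "' in counts.tsv", call. = FALSE)
  }
  sample_ids <- names(raw)[-1]
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                dimnames = list(gene_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad) > 0) {
      stop(sprintf(
        "parse error in counts.tsv: value '%s' for gene '%s', sample '%s' is not a non-negative integer",
        col[bad[1]], gene_id[bad[1]], sample_ids[j]
      ), call. = FALSE)
    }
    mat[, j] <- num
  }
  storage.mode(mat) <- "integer"

  design <- utils::read.csv(design_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  required <- c("sample_id", "tissue", "treatment")
  if (!all(required %in% names(design))) {
    stop("parse error in design.csv: need columns sample_id, tissue, treatment",
         call. = FALSE)
  }
  bad <- which(!design$treatment %in% TREATMENTS)
  if (length(bad) > 0) {
    stop(sprintf(
      "parse error in design.csv: unknown treatment label '%s' for sample '%s'",
      design$treatment[bad[1]], design$sample_id[bad[1]]
    ), call. = FALSE)
  }
  if (!setequal(design$sample_id, sample_ids) ||
      nrow(design) != length(sample_ids)) {
    stop("design.csv samples do not match counts.tsv columns", call. = FALSE)
  }

  truth_path <- file.path(dir, "truth.tsv")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
  }
  list(counts = mat, design = design, truth = truth)
}
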
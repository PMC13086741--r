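#' Valence-rule parameters
#'
#' @param naive_window symmetric bound `w` on the naive treatment-relative
#'   log2 expression (default 0.075 log2 units, inclusive).
#' @param antagonistic_threshold magnitude `m` the positive and negative
#'   treatment-relative log2 values must exceed, in opposite directions
#'   (default 0.5 log2 units, strict).
#' @return object of class `valence_params`.
#' @export
valence_params <- function(naive_window = 0.075,
                           antagonistic_threshold = 0.5) {
  if (!(naive_window > 0 && naive_window < antagonistic_threshold)) {
    stop("configuration error: need 0 < naive_window < antagonistic_threshold",
         call. = FALSE)
  }
  structure(list(naive_window = naive_window,
                 antagonistic_threshold = antagonistic_threshold),
            class = "valence_params")
}

#' Treatment-relative log2 expression
#'
#' For each gene, the mean of `log2(normalized count + 1)` within each
#' treatment, centered by the equal-weight grand mean of the three
#' treatment means. This gives each treatment — including naive — a
#' relative log2 value, and the three values sum to zero by construction.
#'
#' @param counts filtered count matrix.
#' @param design single-tissue design.
#' @param norm normalization model (size factors).
#' @return data.frame with `gene_id`, `naive_lfc`, `pos_lfc`, `neg_lfc`.
#' @export
treatment_relative_lfc <- function(counts, design, norm) {
  check_counts(counts)
  design <- check_design(design, counts)
  design <- design_in_counts_order(design, counts)
  x <- log2(sweep(counts, 2, norm$size_factors[colnames(counts)], "/") + 1)
  means <- vapply(TREATMENTS, function(t) {
    rowMeans(x[, design$treatment == t, drop = FALSE])
  }, numeric(nrow(counts)))
  grand <- rowMeans(means)
  data.frame(gene_id = rownames(counts),
             naive_lfc = means[, "naive"] - grand,
             pos_lfc = means[, "positive"] - grand,
             neg_lfc = means[, "negative"] - grand,
             stringsAsFactors = FALSE)
}

#' Partition flagged genes into unique/shared contrast cells
#'
#' Assigns every gene flagged in at least one contrast to exactly one of
#' the seven non-empty cells of the three-contrast Venn diagram
#' (`unique_pos`, `unique_neg`, `unique_negpos`, `shared_pos_neg`,
#' `shared_pos_negpos`, `shared_neg_negpos`, `shared_all`); unflagged genes
#' get `none`.
#'
#' @param flags logical genes x contrasts matrix ([flags_matrix()]) or a
#'   long flags data.frame from [call_degs()].
#' @return list with `cells` (named character vector per gene) and
#'   `counts` (named integer vector over the 8 cells).
#' @export
partition_deg_sets <- function(flags) {
  if (is.data.frame(flags)) flags <- flags_matrix(flags)
  stopifnot(identical(colnames(flags), CONTRASTS))
  pattern <- flags[, 1] + 2 * flags[, 2] + 4 * flags[, 3]
  cell_names <- c("none",                # 0 0 0
                  "unique_pos",          # 1 0 0
                  "unique_neg",          # 0 1 0
                  "shared_pos_neg",      # 1 1 0
                  "unique_negpos",       # 0 0 1
                  "shared_pos_negpos",   # 1 0 1
                  "shared_neg_negpos",   # 0 1 1
                  "shared_all")          # 1 1 1
  cells <- stats::setNames(cell_names[pattern + 1], rownames(flags))
  counts <- vapply(cell_names[-1], function(cl) sum(cells == cl), integer(1))
  list(cells = cells,
       counts = c(counts, none = sum(cells == "none")))
}

#' Shared same-direction (valence-independent learning) genes
#'
#' Genes flagged in both training-vs-naive contrasts whose shrunken log2
#' fold changes agree in sign — the operationalization of "similar
#' expression patterns in both training contexts". Genes with a zero
#' shrunken fold change in either contrast are excluded.
#'
#' @param flags logical genes x contrasts matrix or long flags data.frame.
#' @param results data.frame from [fit_contrasts()] after [shrink_lfc()].
#' @return character vector of gene ids.
#' @export
shared_learning_genes <- function(flags, results) {
  if (is.data.frame(flags)) flags <- flags_matrix(flags)
  lfc <- lfc_matrix(results, "log2FC_shrunk")
  genes <- rownames(flags)[flags[, "pos_vs_naive"] & flags[, "neg_vs_naive"]]
  keep <- vapply(genes, function(g) {
    a <- lfc[g, "pos_vs_naive"]
    b <- lfc[g, "neg_vs_naive"]
    !is.na(a) && !is.na(b) && a != 0 && b != 0 && sign(a) == sign(b)
  }, logical(1))
  genes[keep]
}

# genes x contrasts matrix of a results column
lfc_matrix <- function(results, column = "log2FC_shrunk") {
  genes <- unique(results$gene_id)
  m <- matrix(NA_real_, length(genes), 3, dimnames = list(genes, CONTRASTS))
  m[cbind(match(results$gene_id, genes),
          match(results$contrast, CONTRASTS))] <- results[[column]]
  m
}

#' Valence-associated (antagonistic) genes
#'
#' Applies the threshold rule for valence-associated expression: the naive
#' treatment-relative value must lie inside the window `[-w, w]`
#' (inclusive), the positive and negative values must exceed the
#' antagonism threshold `m` in opposite directions (strictly:
#' `pos < -m & neg > m`, or `neg < -m & pos > m`), and the gene must be a
#' DEG in the negative-vs-positive contrast.
#'
#' @param trel data.frame from [treatment_relative_lfc()].
#' @param flags logical genes x contrasts matrix or long flags data.frame.
#' @param params a [valence_params()] object.
#' @return character vector of gene ids.
#' @export
valence_genes <- function(trel, flags, params = valence_params()) {
  if (is.data.frame(flags)) flags <- flags_matrix(flags)
  flagged <- rownames(flags)[flags[, "neg_vs_pos"]]
  missing <- setdiff(flagged, trel$gene_id)
  if (length(missing) > 0) {
    stop("treatment-relative values missing for flagged gene(s), e.g. '",
         missing[1], "'", call. = FALSE)
  }
  w <- params$naive_window
  m <- params$antagonistic_threshold
  i <- match(flagged, trel$gene_id)
  naive <- trel$naive_lfc[i]
  pos <- trel$pos_lfc[i]
  neg <- trel$neg_lfc[i]
  sel <- (naive >= -w & naive <= w) &
    ((pos < -m & neg > m) | (neg < -m & pos > m))
  flagged[sel]
}

#' Join functional-group annotations onto a gene classification
#'
#' Left-joins a `gene_id -> group` annotation table; genes absent from the
#' table are labeled `"uncharacterised"`. Duplicate annotation rows with
#' conflicting labels are an error; consistent duplicates are collapsed.
#'
#' @param classification data.frame with a `gene_id` column.
#' @param annotation data.frame with columns `gene_id` and `group`
#'   (or NULL for no annotation).
#' @return `classification` with a `group` column; group counts are
#'   attached as the `"group_counts"` attribute.
#' @export
annotate_groups <- function(classification, annotation = NULL) {
  if (is.null(annotation) || nrow(annotation) == 0) {
    classification$group <- "uncharacterised"
  } else {
    if (!all(c("gene_id", "group") %in% names(annotation))) {
      stop("annotation must have columns gene_id and group", call. = FALSE)
    }
    ann <- unique(annotation[, c("gene_id", "group")])
    dup <- ann$gene_id[duplicated(ann$gene_id)]
    if (length(dup) > 0) {
      stop("conflicting annotation labels for gene(s): ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
    idx <- match(classification$gene_id, ann$gene_id)
    classification$group <- ifelse(is.na(idx), "uncharacterised",
                                   ann$group[idx])
  }
  attr(classification, "group_counts") <-
    table(classification$group, dnn = NULL)
  classification
}

#' Full per-gene classification table
#'
#' Combines the Venn-cell partition, the learning-gene rule and the
#' valence rule into one per-gene table, optionally annotated with
#' functional groups.
#'
#' @param flags long flags data.frame from [call_degs()].
#' @param results shrunken results from [shrink_lfc()].
#' @param trel treatment-relative values from [treatment_relative_lfc()].
#' @param params [valence_params()].
#' @param annotation optional annotation data.frame (`gene_id`, `group`).
#' @return data.frame: `gene_id`, per-contrast flags, `cell`,
#'   `learning_flag`, `valence_flag`, `group`.
#' @export
classify_genes <- function(flags, results, trel,
                           params = valence_params(), annotation = NULL) {
  fm <- flags_matrix(flags)
  part <- partition_deg_sets(fm)
  learning <- shared_learning_genes(fm, results)
  valence <- valence_genes(trel, fm, params)
  out <- data.frame(
    gene_id = rownames(fm),
    deg_pos_vs_naive = fm[, "pos_vs_naive"],
    deg_neg_vs_naive = fm[, "neg_vs_naive"],
    deg_neg_vs_pos = fm[, "neg_vs_pos"],
    cell = unname(part$cells),
    learning_flag = rownames(fm) %in% learning,
    valence_flag = rownames(fm) %in% valence,
    stringsAsFactors = FALSE
  )
  annotate_groups(out, annotation)
}
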
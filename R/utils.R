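# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's
#' RNG state, so package functions are reproducible without clobbering the
#' user's random stream.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a 32-bit-safe stream seed from a base seed and an iteration index.
# Distinct iterations of one base seed must map to distinct stream seeds.
stream_seed <- function(seed, iteration) {
  base <- as.numeric(seed) %% 599999999
  as.integer((base + as.numeric(iteration)) %% 2147483647L)
}

# Round half away from zero (so 79.5 -> 80, not banker's 80/79 ambiguity).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical treatment vocabulary; naive is always the reference level.
TREATMENTS <- c("naive", "positive", "negative")
CONTRASTS <- c("pos_vs_naive", "neg_vs_naive", "neg_vs_pos")

# Validate a counts matrix: integer, non-negative, unique dimnames.
check_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids in counts matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids in counts matrix", call. = FALSE)
  }
  bad <- which(counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "counts must be non-negative integers; first offender gene '%s', sample '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]
    ), call. = FALSE)
  }
  invisible(counts)
}

# Validate a design data.frame against a counts matrix (single tissue).
check_design <- function(design, counts = NULL, single_tissue = TRUE) {
  required <- c("sample_id", "tissue", "treatment")
  if (!all(required %in% names(design))) {
    stop("design must have columns sample_id, tissue, treatment", call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  bad <- setdiff(unique(design$treatment), TREATMENTS)
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown treatment label '%s' (allowed: %s)",
      bad[1], paste(TREATMENTS, collapse = ", ")
    ), call. = FALSE)
  }
  if (single_tissue && length(unique(design$tissue)) > 1) {
    stop("design spans multiple tissues; analyse one tissue at a time",
         call. = FALSE)
  }
  if (!is.null(counts)) {
    if (!setequal(design$sample_id, colnames(counts)) ||
        nrow(design) != ncol(counts)) {
      stop("design samples do not match counts columns exactly", call. = FALSE)
    }
  }
  invisible(design)
}

# design rows in counts-column order
design_in_counts_order <- function(design, counts) {
  design[match(colnames(counts), design$sample_id), , drop = FALSE]
}
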
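#' Construct an expression dataset
#'
#' The universal input container of the package: a nonnegative gene-by-sample
#' expression matrix (RPKM/TPM/count-like units) with optional per-sample
#' metadata. All downstream machinery consumes only within-sample ranks, so
#' the normalization unit of `values` is irrelevant as long as it is a
#' per-sample monotone transform of abundance.
#'
#' @param values numeric matrix, genes as rows and samples as columns, with
#'   unique non-empty `rownames` (gene identifiers) and `colnames` (sample
#'   identifiers). All entries must be finite and `>= 0`.
#' @param dataset_id single character label identifying the dataset.
#' @param sample_meta optional `data.frame` of per-sample metadata. Must
#'   contain a `sample` column (or rownames) covering exactly the sample set.
#'   Recognized columns: `time` (numeric differentiation time), `group`,
#'   `state` (trajectory state label), `csc` (logical cancer-stem-cell flag).
#' @return an object of class `ExpressionDataset`: a list with elements
#'   `dataset_id`, `values`, and `sample_meta` (NULL or a data.frame aligned
#'   with the columns of `values`).
#' @examples
#' x <- matrix(c(5, 1, 2, 6, 2, 1), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' ds <- expression_dataset(x, dataset_id = "toy")
#' ds
#' @export
expression_dataset <- function(values, dataset_id = "dataset", sample_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite (found NA/NaN/Inf)")
  if (any(values < 0))
    stop("expression values must be nonnegative; found ", sum(values < 0),
         " negative entries")
  if (!is.character(dataset_id) || length(dataset_id) != 1L || !nzchar(dataset_id))
    stop("`dataset_id` must be a single non-empty string")
  sample_meta <- check_sample_meta(sample_meta, colnames(values), dataset_id)
  structure(list(dataset_id = dataset_id, values = values,
                 sample_meta = sample_meta),
            class = "ExpressionDataset")
}

check_sample_meta <- function(sample_meta, samples, dataset_id) {
  if (is.null(sample_meta)) return(NULL)
  if (!is.data.frame(sample_meta))
    stop("`sample_meta` must be a data.frame")
  if (!"sample" %in% names(sample_meta)) {
    if (is.null(rownames(sample_meta)))
      stop("`sample_meta` needs a 'sample' column or rownames")
    sample_meta$sample <- rownames(sample_meta)
  }
  sample_meta$sample <- as.character(sample_meta$sample)
  if (anyDuplicated(sample_meta$sample))
    stop("duplicate samples in `sample_meta` for dataset '", dataset_id, "'")
  if (!setequal(sample_meta$sample, samples))
    stop("`sample_meta` must cover exactly the samples of dataset '",
         dataset_id, "'")
  # align meta rows with matrix columns
  sample_meta <- sample_meta[match(samples, sample_meta$sample), , drop = FALSE]
  rownames(sample_meta) <- NULL
  sample_meta
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d genes x %d samples\n",
              x$dataset_id, nrow(x$values), ncol(x$values)))
  if (!is.null(x$sample_meta))
    cat("  sample_meta columns:",
        paste(setdiff(names(x$sample_meta), "sample"), collapse = ", "), "\n")
  invisible(x)
}

#' Gene and sample identifiers of a dataset
#' @param x an `ExpressionDataset`.
#' @return character vector of identifiers.
#' @export
dataset_genes <- function(x) rownames(x$values)

#' @rdname dataset_genes
#' @export
dataset_samples <- function(x) colnames(x$values)

# Coerce inputs (dataset or plain named matrix) to ExpressionDataset.
as_expression_dataset <- function(x, dataset_id = "dataset") {
  if (inherits(x, "ExpressionDataset")) return(x)
  if (is.matrix(x)) return(expression_dataset(x, dataset_id = dataset_id))
  stop("expected an ExpressionDataset or a named numeric matrix")
}

# Deterministic, locale-independent lexicographic sort.
lex_sort <- function(x) sort(x, method = "radix")

lex_order <- function(...) order(..., method = "radix")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed that stays inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629)
}
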
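#' Spearman correlation of every gene with differentiation time
#'
#' Computes, for each gene, the Spearman rank correlation (average ranks for
#' ties) between its expression and the per-sample differentiation time
#' stored in `sample_meta$time`, together with a two-sided p-value from the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom. Genes with zero expression variance carry no rank information:
#' they are emitted with `rho = NA`, `p = 1` and `q = NA`, and are excluded
#' from significance selection downstream.
#'
#' Benjamini-Hochberg adjusted values (`q`) are computed within the dataset
#' over the genes with a defined correlation.
#'
#' @param dataset an `ExpressionDataset` whose `sample_meta` has a numeric
#'   `time` column covering every sample (rows with `NA` time are dropped).
#' @return data.frame with columns `dataset_id`, `gene`, `rho`, `p`, `q`,
#'   one row per gene, in the dataset's gene order.
#' @export
spearman_time_correlation <- function(dataset) {
  dataset <- as_expression_dataset(dataset)
  meta <- dataset$sample_meta
  if (is.null(meta) || !"time" %in% names(meta))
    stop("dataset '", dataset$dataset_id,
         "' has no 'time' column in sample_meta")
  time <- as.numeric(meta$time)
  keep <- !is.na(time)
  if (sum(keep) < 4L)
    stop("dataset '", dataset$dataset_id,
         "' has fewer than 4 time-bearing samples")
  X <- dataset$values[, keep, drop = FALSE]
  time <- time[keep]
  if (length(unique(time)) < 2L)
    stop("dataset '", dataset$dataset_id, "' has constant time")
  n <- ncol(X)
  rt <- rank(time)
  rt_c <- rt - mean(rt)
  R <- t(apply(X, 1L, rank))          # average ranks within each gene
  Rc <- R - rowMeans(R)
  ssg <- rowSums(Rc^2)
  sst <- sum(rt_c^2)
  rho <- as.vector(Rc %*% rt_c) / sqrt(ssg * sst)
  rho[ssg == 0] <- NA_real_
  rho <- pmin(1, pmax(-1, rho))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.na(rho) & abs(rho) == 1] <- 0
  p[is.na(rho)] <- 1
  q <- rep(NA_real_, length(p))
  defined <- !is.na(rho)
  if (any(defined)) q[defined] <- bh_fdr(p[defined])
  data.frame(dataset_id = dataset$dataset_id, gene = rownames(X),
             rho = rho, p = p, q = q, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped to \[0, 1\] and returned in
#' the input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\] (no `NA`).
#' @return adjusted values, same length and order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(pvalues)
  o <- order(pvalues)
  adj <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Select stemness-related genes from differentiation time courses
#'
#' A gene belongs to the panel when its Spearman correlation with
#' differentiation time is significant (BH FDR below `fdr_threshold`,
#' controlled within each dataset) in *every* supplied dataset. Sign
#' agreement across datasets is not required by default, matching the
#' selection on significance alone; set `require_sign_concordance = TRUE`
#' to additionally demand a common correlation sign.
#'
#' @param time_datasets list of at least two `ExpressionDataset`s with time
#'   metadata (see [spearman_time_correlation()]).
#' @param fdr_threshold per-dataset BH FDR cutoff (default 0.05).
#' @param require_sign_concordance if `TRUE`, keep only genes whose rho has
#'   the same sign in all datasets.
#' @return a `StemnessGenePanel`: list with `genes` (sorted identifiers),
#'   `evidence` (row-bound per-dataset correlation tables) and
#'   `fdr_threshold`. An empty panel triggers a warning, not an error.
#' @export
select_stemness_genes <- function(time_datasets, fdr_threshold = 0.05,
                                  require_sign_concordance = FALSE) {
  if (!is.list(time_datasets) || length(time_datasets) < 2L)
    stop("at least two time-course datasets are required")
  tabs <- lapply(time_datasets, spearman_time_correlation)
  sig_sets <- lapply(tabs, function(tb)
    tb$gene[!is.na(tb$rho) & !is.na(tb$q) & tb$q < fdr_threshold])
  panel <- lex_sort(Reduce(intersect, sig_sets))
  if (require_sign_concordance && length(panel)) {
    signs <- sapply(tabs, function(tb) sign(tb$rho[match(panel, tb$gene)]))
    signs <- matrix(signs, nrow = length(panel))
    keep <- apply(signs, 1L, function(s) length(unique(s)) == 1L)
    panel <- panel[keep]
  }
  if (length(panel) == 0L)
    warning("no gene is significant in every dataset: empty panel")
  structure(list(genes = panel, evidence = do.call(rbind, tabs),
                 fdr_threshold = fdr_threshold),
            class = "StemnessGenePanel")
}

#' @export
print.StemnessGenePanel <- function(x, ...) {
  cat(sprintf("StemnessGenePanel: %d genes (FDR < %g in every dataset)\n",
              length(x$genes), x$fdr_threshold))
  invisible(x)
}

#' Build the reference REO signature from ESC pools
#'
#' Pools all single-cell ESC samples into one collection and all bulk ESC
#' samples into another, identifies the stable REOs among panel genes in
#' each pool, and retains the unordered pairs that are stable in *both*
#' pools with the *same* direction. Those directed pairs constitute the
#' reference signature against which any sample is scored; shared pairs
#' whose directions disagree between the pools are dropped.
#'
#' @param sc_datasets list of single-cell `ExpressionDataset`s.
#' @param bulk_datasets list of bulk `ExpressionDataset`s.
#' @param panel a `StemnessGenePanel` (or plain character vector of genes).
#' @param min_samples forwarded to [identify_stable_reos()].
#' @return a `ReferenceSignature`: list with `pairs` (data.frame
#'   `gene_high`/`gene_low`, meaning gene_high > gene_low in the ESC state),
#'   `provenance` (counts: `n_sc_stable`, `n_bulk_stable`, `n_shared`,
#'   `n_concordant`) and `panel_genes`.
#' @export
build_reference_signature <- function(sc_datasets, bulk_datasets, panel,
                                      min_samples = 4L) {
  panel_genes <- if (inherits(panel, "StemnessGenePanel")) panel$genes
                 else as.character(panel)
  if (length(panel_genes) < 2L)
    stop("the stemness gene panel must contain at least two genes")
  if (!length(sc_datasets) || !length(bulk_datasets))
    stop("both the single-cell and the bulk pool must be nonempty")
  pool <- function(datasets, id) {
    datasets <- lapply(datasets, as_expression_dataset)
    genes <- Reduce(intersect, lapply(datasets, dataset_genes))
    genes <- intersect(genes, panel_genes)
    if (length(genes) < 2L)
      stop("fewer than two panel genes shared across the ", id, " pool")
    mats <- lapply(datasets, function(d) {
      m <- d$values[genes, , drop = FALSE]
      colnames(m) <- paste(d$dataset_id, colnames(m), sep = ".")
      m
    })
    expression_dataset(do.call(cbind, mats), dataset_id = id)
  }
  sc_set <- identify_stable_reos(pool(sc_datasets, "sc_pool"),
                                 min_samples = min_samples)
  bulk_set <- identify_stable_reos(pool(bulk_datasets, "bulk_pool"),
                                   min_samples = min_samples)
  ks <- pair_key(sc_set$pairs$gene_high, sc_set$pairs$gene_low)
  kb <- pair_key(bulk_set$pairs$gene_high, bulk_set$pairs$gene_low)
  ds <- pair_dir(sc_set$pairs$gene_high, sc_set$pairs$gene_low)
  db <- pair_dir(bulk_set$pairs$gene_high, bulk_set$pairs$gene_low)
  hit <- match(ks, kb)
  shared <- !is.na(hit)
  concord <- shared
  concord[shared] <- ds[shared] == db[hit[shared]]
  pairs <- sc_set$pairs[concord, , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0L)
    stop("empty reference signature: no concordant stable pair shared by ",
         "the two pools")
  structure(list(
    pairs = pairs,
    provenance = c(n_sc_stable = nrow(sc_set$pairs),
                   n_bulk_stable = nrow(bulk_set$pairs),
                   n_shared = sum(shared),
                   n_concordant = sum(concord)),
    panel_genes = panel_genes),
    class = "ReferenceSignature")
}

#' @export
print.ReferenceSignature <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf(paste0(
    "ReferenceSignature: %d directed pairs over %d panel genes\n",
    "  stable in sc pool: %d; bulk pool: %d; shared: %d; concordant: %d\n"),
    nrow(x$pairs), length(x$panel_genes),
    pv["n_sc_stable"], pv["n_bulk_stable"], pv["n_shared"], pv["n_concordant"]))
  invisible(x)
}

#' Assemble a reference signature from a directed pair table
#'
#' @param pairs data.frame with `gene_high`, `gene_low` columns.
#' @param provenance optional named counts carried along.
#' @return a `ReferenceSignature`.
#' @export
reference_signature <- function(pairs, provenance = NULL) {
  set <- stable_reo_set(pairs, source_id = "reference")
  if (is.null(provenance))
    provenance <- c(n_sc_stable = NA_integer_, n_bulk_stable = NA_integer_,
                    n_shared = NA_integer_, n_concordant = nrow(set$pairs))
  structure(list(pairs = set$pairs, provenance = provenance,
                 panel_genes = lex_sort(unique(c(set$pairs$gene_high,
                                                 set$pairs$gene_low)))),
            class = "ReferenceSignature")
}
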
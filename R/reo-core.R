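#' Identify stable relative expression orderings (REOs) in a dataset
#'
#' A gene pair (Gi, Gj) has a *stable REO* in a dataset when the strict
#' ordering of its two expression values is identical in every sample:
#' either Gi > Gj in all samples or Gi < Gj in all samples. A tie in any
#' sample (equal values, including two dropout zeros) disqualifies the pair,
#' because only strict orderings are preserved under arbitrary strictly
#' increasing per-sample transforms.
#'
#' @param dataset an [expression_dataset()] (or a named numeric matrix).
#' @param gene_subset optional character vector restricting the pair universe
#'   to these genes; must all be present in the dataset.
#' @param min_samples minimum number of samples required (default 4, i.e.
#'   datasets with more than three samples).
#' @param chunk_size number of candidate pairs compared per block; purely a
#'   memory/time trade-off.
#' @return a `StableREOSet`: list with `pairs` (data.frame with columns
#'   `gene_high`, `gene_low`, in deterministic lexicographic order of the
#'   unordered pair), `source_id`, and `n_samples_used`.
#' @examples
#' x <- rbind(g1 = c(5, 6, 7, 8), g2 = c(1, 2, 3, 4), g3 = c(3, 1, 5, 2))
#' colnames(x) <- paste0("s", 1:4)
#' identify_stable_reos(x)$pairs
#' @export
identify_stable_reos <- function(dataset, gene_subset = NULL, min_samples = 4L,
                                 chunk_size = 200000L) {
  dataset <- as_expression_dataset(dataset)
  X <- dataset$values
  if (ncol(X) < min_samples)
    stop("dataset '", dataset$dataset_id, "' has ", ncol(X),
         " samples; at least ", min_samples, " required")
  genes <- rownames(X)
  if (!is.null(gene_subset)) {
    unknown <- setdiff(gene_subset, genes)
    if (length(unknown))
      stop("gene_subset contains identifiers absent from dataset '",
           dataset$dataset_id, "': ", paste(lex_sort(unknown), collapse = ", "))
    X <- X[genes %in% gene_subset, , drop = FALSE]
  }
  # canonical gene order: pairs are enumerated with gene_a < gene_b
  # lexicographically, so the output order is deterministic
  X <- X[lex_order(rownames(X)), , drop = FALSE]
  g <- rownames(X)
  m <- length(g)
  ns <- ncol(X)
  if (m < 2L)
    return(stable_reo_set(data.frame(gene_high = character(), gene_low = character()),
                          source_id = dataset$dataset_id, n_samples_used = ns))
  idx_a <- rep.int(seq_len(m - 1L), times = rev(seq_len(m - 1L)))
  idx_b <- sequence(rev(seq_len(m - 1L)), from = seq_len(m - 1L) + 1L)
  npairs <- length(idx_a)
  out_high <- character(0)
  out_low <- character(0)
  for (start in seq(1L, npairs, by = chunk_size)) {
    end <- min(start + chunk_size - 1L, npairs)
    ia <- idx_a[start:end]; ib <- idx_b[start:end]
    A <- X[ia, , drop = FALSE]
    B <- X[ib, , drop = FALSE]
    n_gt <- rowSums(A > B)
    n_lt <- rowSums(A < B)
    a_high <- n_gt == ns
    b_high <- n_lt == ns
    out_high <- c(out_high, g[ia[a_high]], g[ib[b_high]])
    out_low <- c(out_low, g[ib[a_high]], g[ia[b_high]])
  }
  pairs <- data.frame(gene_high = out_high, gene_low = out_low,
                      stringsAsFactors = FALSE)
  pairs <- pairs[lex_order(pmin(pairs$gene_high, pairs$gene_low),
                           pmax(pairs$gene_high, pairs$gene_low)), , drop = FALSE]
  rownames(pairs) <- NULL
  stable_reo_set(pairs, source_id = dataset$dataset_id, n_samples_used = ns)
}

#' Construct a stable-REO set
#'
#' Low-level constructor; most users obtain these from
#' [identify_stable_reos()] or [read_reo_set()].
#'
#' @param pairs data.frame with character columns `gene_high`, `gene_low`;
#'   `gene_high` is the gene with the larger expression value.
#' @param source_id label of the originating dataset.
#' @param n_samples_used number of samples the stability was asserted over.
#' @return a `StableREOSet` object.
#' @export
stable_reo_set <- function(pairs, source_id = "set", n_samples_used = NA_integer_) {
  stopifnot(is.data.frame(pairs),
            all(c("gene_high", "gene_low") %in% names(pairs)))
  pairs$gene_high <- as.character(pairs$gene_high)
  pairs$gene_low <- as.character(pairs$gene_low)
  if (any(pairs$gene_high == pairs$gene_low))
    stop("self-pairs (gene_high == gene_low) are not allowed")
  key <- pair_key(pairs$gene_high, pairs$gene_low)
  if (anyDuplicated(key))
    stop("a gene pair appears more than once (possibly with both directions)")
  structure(list(pairs = pairs[, c("gene_high", "gene_low")],
                 source_id = source_id,
                 n_samples_used = as.integer(n_samples_used)),
            class = "StableREOSet")
}

#' @export
print.StableREOSet <- function(x, ...) {
  cat(sprintf("StableREOSet '%s': %d stable pairs over %s samples\n",
              x$source_id, nrow(x$pairs),
              ifelse(is.na(x$n_samples_used), "?", x$n_samples_used)))
  invisible(x)
}

# Canonical unordered key for a directed pair; direction flag is TRUE when
# the lexicographically smaller gene is the high one.
pair_key <- function(gene_high, gene_low) {
  paste(pmin(gene_high, gene_low), pmax(gene_high, gene_low), sep = "\r")
}

pair_dir <- function(gene_high, gene_low) {
  gene_high < gene_low
}

#' Upper-tail cumulative binomial p-value for REO concordance
#'
#' Significance of observing at least `s` concordant orderings among `n`
#' shared gene pairs when each pair agrees by chance with probability `p0`:
#' `P = 1 - sum_{i=0}^{s-1} choose(n, i) p0^i (1-p0)^(n-i)`, i.e. the
#' survival function `P(X >= s)` of a Binomial(n, p0) variable. Evaluated
#' through [stats::pbinom()]'s survival tail, which is numerically stable
#' for `n` well beyond 1e6.
#'
#' @param s integer number of concordant pairs, `0 <= s <= n`.
#' @param n integer number of shared pairs.
#' @param p0 chance agreement probability (default 0.5: two orderings are
#'   equally likely a priori).
#' @return p-value in \[0, 1\].
#' @examples
#' binomial_consistency_pvalue(8, 10)   # 0.0546875
#' @export
binomial_consistency_pvalue <- function(s, n, p0 = 0.5) {
  if (length(s) != 1L || length(n) != 1L || is.na(s) || is.na(n))
    stop("`s` and `n` must be single non-missing numbers")
  if (s != round(s) || n != round(n)) stop("`s` and `n` must be integers")
  if (s < 0 || s > n) stop("require 0 <= s <= n; got s = ", s, ", n = ", n)
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop("`p0` must lie strictly between 0 and 1")
  stats::pbinom(s - 1, size = n, prob = p0, lower.tail = FALSE)
}

#' Cross-dataset consistency of two stable-REO sets
#'
#' The consistency of stable REOs between two datasets is `s/n`, where `n`
#' counts the unordered gene pairs stable in both sets and `s` counts those
#' with the same ordering direction. Significance comes from
#' [binomial_consistency_pvalue()] with chance probability `p0 = 0.5`.
#'
#' @param set_a,set_b `StableREOSet` objects.
#' @param p0 chance agreement probability for the binomial model.
#' @return a `ConsistencyResult`: list with `n_shared`, `s_concordant`,
#'   `consistency` (`s/n`, `NA` when `n == 0`), `p_value` (`NA` when
#'   `n == 0`), and `p0`.
#' @export
consistency <- function(set_a, set_b, p0 = 0.5) {
  stopifnot(inherits(set_a, "StableREOSet"), inherits(set_b, "StableREOSet"))
  ka <- pair_key(set_a$pairs$gene_high, set_a$pairs$gene_low)
  kb <- pair_key(set_b$pairs$gene_high, set_b$pairs$gene_low)
  da <- pair_dir(set_a$pairs$gene_high, set_a$pairs$gene_low)
  db <- pair_dir(set_b$pairs$gene_high, set_b$pairs$gene_low)
  hit <- match(ka, kb)
  shared <- !is.na(hit)
  n <- sum(shared)
  s <- sum(da[shared] == db[hit[shared]])
  structure(list(
    n_shared = n,
    s_concordant = s,
    consistency = if (n > 0) s / n else NA_real_,
    p_value = if (n > 0) binomial_consistency_pvalue(s, n, p0) else NA_real_,
    p0 = p0), class = "ConsistencyResult")
}

#' @export
print.ConsistencyResult <- function(x, ...) {
  if (is.na(x$consistency)) {
    cat("ConsistencyResult: no shared stable pairs (consistency undefined)\n")
  } else {
    cat(sprintf("ConsistencyResult: s/n = %d/%d = %.4f, P = %.3g (p0 = %g)\n",
                x$s_concordant, x$n_shared, x$consistency, x$p_value, x$p0))
  }
  invisible(x)
}

#' Recovery rate of merged-training stable REOs in a holdout dataset
#'
#' Pools the samples of all training datasets (restricted to their common
#' gene universe) into one merged collection, identifies the stable REOs of
#' the merged collection, and returns the fraction of those pairs that are
#' also stable, with the same direction, in the holdout dataset. Merging
#' more datasets can only shrink the merged stable set, so the surviving
#' pairs are increasingly robust and the recovery rate tends to rise with
#' the number of merged datasets.
#'
#' @param training_sets list of one or more `ExpressionDataset`s.
#' @param holdout the independent `ExpressionDataset`.
#' @param gene_subset optional gene restriction applied to all datasets.
#' @param min_samples forwarded to [identify_stable_reos()].
#' @return fraction in \[0, 1\], or `NA` when the merged stable set is empty.
#' @export
recovery_rate <- function(training_sets, holdout, gene_subset = NULL,
                          min_samples = 4L) {
  if (!is.list(training_sets) || length(training_sets) < 1L)
    stop("`training_sets` must be a non-empty list of datasets")
  training_sets <- lapply(training_sets, as_expression_dataset)
  holdout <- as_expression_dataset(holdout)
  shared_genes <- Reduce(intersect, c(lapply(training_sets, dataset_genes),
                                      list(dataset_genes(holdout))))
  if (!is.null(gene_subset)) shared_genes <- intersect(shared_genes, gene_subset)
  if (length(shared_genes) < 2L)
    stop("datasets share fewer than 2 genes after subsetting")
  mats <- lapply(training_sets, function(d) {
    m <- d$values[shared_genes, , drop = FALSE]
    colnames(m) <- paste(d$dataset_id, colnames(m), sep = ".")
    m
  })
  merged <- expression_dataset(do.call(cbind, mats), dataset_id = "merged_training")
  merged_set <- identify_stable_reos(merged, min_samples = min_samples)
  if (nrow(merged_set$pairs) == 0L) return(NA_real_)
  hold_set <- identify_stable_reos(holdout, gene_subset = shared_genes,
                                   min_samples = min_samples)
  km <- pair_key(merged_set$pairs$gene_high, merged_set$pairs$gene_low)
  kh <- pair_key(hold_set$pairs$gene_high, hold_set$pairs$gene_low)
  dm <- pair_dir(merged_set$pairs$gene_high, merged_set$pairs$gene_low)
  dh <- pair_dir(hold_set$pairs$gene_high, hold_set$pairs$gene_low)
  hit <- match(km, kh)
  ok <- !is.na(hit)
  ok[ok] <- dm[ok] == dh[hit[ok]]
  sum(ok) / nrow(merged_set$pairs)
}
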
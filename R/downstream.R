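#' Rank genes by their correlation with the stemness score
#'
#' Spearman correlation of each gene's expression with the per-sample
#' stemness scores, sorted descending. Genes with zero expression variance
#' have no defined correlation and sink to the bottom of the table.
#'
#' @param dataset an `ExpressionDataset`.
#' @param scores a `StemSCScores` table aligned with the dataset samples
#'   (same identifiers in the same order); undefined scores are dropped
#'   before correlating, at least 4 defined scores are required.
#' @return data.frame of class `RankedGeneTable` with columns `gene`, `rho`,
#'   `p`, sorted by decreasing `rho` (ties by gene identifier, `NA` last).
#' @export
rank_genes_by_score_correlation <- function(dataset, scores) {
  dataset <- as_expression_dataset(dataset)
  if (is.data.frame(scores) && "sample" %in% names(scores) &&
      !identical(as.character(scores$sample), dataset_samples(dataset)))
    stop("`scores` are not aligned with the samples of dataset '",
         dataset$dataset_id, "'")
  v <- score_values(scores)
  keep <- !is.na(v)
  if (sum(keep) < 4L) stop("need at least 4 defined scores")
  X <- dataset$values[, keep, drop = FALSE]
  v <- v[keep]
  n <- length(v)
  rv <- rank(v); rv_c <- rv - mean(rv)
  R <- t(apply(X, 1L, rank))
  Rc <- R - rowMeans(R)
  ssg <- rowSums(Rc^2)
  rho <- as.vector(Rc %*% rv_c) / sqrt(ssg * sum(rv_c^2))
  rho[ssg == 0] <- NA_real_
  rho <- pmin(1, pmax(-1, rho))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.na(rho) & abs(rho) == 1] <- 0
  tab <- data.frame(gene = rownames(X), rho = rho, p = p,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$rho, tab$gene, method = "radix", na.last = TRUE), ,
             drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("RankedGeneTable", "data.frame")
  tab
}

#' Pre-ranked gene-set enrichment (weighted Kolmogorov-Smirnov running sum)
#'
#' Walks down the list of genes ranked by a statistic (descending). Genes in
#' `gene_set` increment the running sum proportionally to `|stat|` (weight
#' exponent 1, normalized so hits total +1); other genes decrement it by a
#' uniform `1 / (N - N_hit)`. The enrichment score ES is the signed extreme
#' deviation of the running sum. The null distribution comes from `n_perm`
#' random relabelings of the gene set (same size, labels drawn uniformly
#' from the ranked universe): `NES = ES / mean(|null ES of the same sign|)`
#' and `p = (1 + #{same-sign nulls at least as extreme}) / (1 + #{same-sign
#' nulls})`. In the degenerate case where the gene set exhausts the universe
#' there are no misses and no contrast: ES is defined as 0 with `p = 1`.
#'
#' @param ranked_stats named numeric vector (gene -> ranking statistic).
#'   Ties are ordered deterministically by gene identifier.
#' @param gene_set character vector; its overlap with the ranked universe
#'   must be nonempty.
#' @param n_perm number of permutations, at least 100 (default 1000).
#' @param seed integer seed for the permutation null (mandatory).
#' @return an `EnrichmentResult`: list with `es`, `nes`, `p`, `n_perm`,
#'   `seed`, `n_hits`.
#' @export
preranked_enrichment <- function(ranked_stats, gene_set, n_perm = 1000L, seed) {
  if (!is.numeric(ranked_stats) || is.null(names(ranked_stats)))
    stop("`ranked_stats` must be a named numeric vector")
  if (missing(seed)) stop("`seed` is required for the permutation null")
  if (n_perm < 100L) stop("`n_perm` must be at least 100")
  ord <- order(-ranked_stats, names(ranked_stats), method = "radix")
  stat <- ranked_stats[ord]
  genes <- names(stat)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stop("`gene_set` does not overlap the ranked gene universe")
  N <- length(genes)
  w <- abs(stat)
  es_of <- function(hit) {
    if (all(hit)) return(0)                      # no misses: no contrast
    tw <- sum(w[hit])
    inc <- if (tw > 0) ifelse(hit, w / tw, 0) else ifelse(hit, 1 / sum(hit), 0)
    dec <- ifelse(hit, 0, 1 / (N - sum(hit)))
    dev <- cumsum(inc - dec)
    dev[which.max(abs(dev))]
  }
  es <- es_of(hit)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    h <- logical(N)
    h[sample.int(N, nh)] <- TRUE
    es_of(h)
  }, numeric(1)))
  if (es == 0) {
    nes <- 0; p <- 1
  } else {
    same <- sign(null_es) == sign(es)
    denom <- mean(abs(null_es[same]))
    nes <- if (sum(same) > 0L && denom > 0) es / denom else NA_real_
    p <- (1 + sum(same & abs(null_es) >= abs(es))) / (1 + sum(same))
  }
  structure(list(es = es, nes = nes, p = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), n_hits = nh),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: ES = %.4f, NES = %.3f, p = %.4g (%d hits, %d perms)\n",
              x$es, x$nes, x$p, x$n_hits, x$n_perm))
  invisible(x)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of drawing at least `overlap_k` members of a
#' `set_size_K`-gene set when selecting `selected_n` genes without
#' replacement from a universe of `universe_N` genes.
#'
#' @param overlap_k observed overlap.
#' @param set_size_K size of the gene set in the universe.
#' @param selected_n number of selected genes.
#' @param universe_N universe size.
#' @return `P(X >= k)` for X ~ Hypergeometric(N, K, n).
#' @examples
#' hypergeometric_enrichment(4, 5, 4, 10)  # 5/210
#' @export
hypergeometric_enrichment <- function(overlap_k, set_size_K, selected_n,
                                      universe_N) {
  v <- c(overlap_k, set_size_K, selected_n, universe_N)
  if (any(v != round(v)) || any(v < 0))
    stop("all counts must be nonnegative integers")
  if (set_size_K > universe_N || selected_n > universe_N ||
      overlap_k > min(set_size_K, selected_n))
    stop("inconsistent counts: require k <= min(K, n) and K, n <= N")
  stats::phyper(overlap_k - 1, m = set_size_K, n = universe_N - set_size_K,
                k = selected_n, lower.tail = FALSE)
}

#' Calibrate a stem-like threshold from validated CSC labels
#'
#' Scans every distinct observed score as a candidate lower limit `t`. For
#' each, the stem-like group is the set of samples with `score >= t` (kept
#' only when it has at least `min_group` members) and its precision is the
#' fraction of experimentally validated CSCs in the group. The decision is
#' the *smallest* threshold attaining the maximal precision, which on ties
#' yields the largest qualifying stem-like group. `criterion = "recall"`
#' instead maximizes the fraction of all CSCs captured by the group (its
#' maximum is always attained at the smallest candidate; exposed for
#' completeness).
#'
#' @param scores `StemSCScores` table or numeric vector; undefined scores
#'   are dropped with a warning.
#' @param csc_flags logical vector aligned with `scores`; both classes must
#'   be present.
#' @param min_group minimal stem-like group size (default 1).
#' @param criterion `"precision"` (default) or `"recall"`.
#' @return a `ThresholdDecision`: list with `threshold`,
#'   `precision_at_threshold`, `group_sizes` (stem-like, other),
#'   `candidates_examined`.
#' @export
select_stem_threshold <- function(scores, csc_flags, min_group = 1L,
                                  criterion = c("precision", "recall")) {
  criterion <- match.arg(criterion)
  v <- score_values(scores)
  if (length(v) != length(csc_flags))
    stop("`scores` and `csc_flags` lengths differ")
  csc_flags <- as.logical(csc_flags)
  keep <- !is.na(v) & !is.na(csc_flags)
  if (any(is.na(v))) {
    warning(sum(is.na(v)), " undefined scores dropped")
  }
  v <- v[keep]; csc <- csc_flags[keep]
  if (!any(csc) || all(csc))
    stop("both CSC and non-CSC samples must be present")
  cands <- sort(unique(v))
  best_t <- NA_real_; best_val <- -Inf; examined <- 0L
  for (t in cands) {
    grp <- v >= t
    if (sum(grp) < min_group) next
    examined <- examined + 1L
    val <- switch(criterion,
                  precision = mean(csc[grp]),
                  recall = sum(csc[grp]) / sum(csc))
    if (val > best_val + 1e-15) { best_val <- val; best_t <- t }
  }
  if (!is.finite(best_val)) stop("no candidate threshold admits a group of size ",
                                 min_group)
  grp <- v >= best_t
  structure(list(threshold = best_t,
                 precision_at_threshold = mean(csc[grp]),
                 group_sizes = c(stem_like = sum(grp), other = sum(!grp)),
                 candidates_examined = examined),
            class = "ThresholdDecision")
}

#' @export
print.ThresholdDecision <- function(x, ...) {
  cat(sprintf(paste0("ThresholdDecision: threshold = %.4f, precision = %.3f, ",
                     "groups = %d stem-like / %d other (%d candidates)\n"),
              x$threshold, x$precision_at_threshold,
              x$group_sizes["stem_like"], x$group_sizes["other"],
              x$candidates_examined))
  invisible(x)
}

#' Classify samples as stem-like by a score threshold
#'
#' @param scores `StemSCScores` table or numeric vector.
#' @param threshold lower limit in \[0, 1\]; `score >= threshold` is called
#'   stem-like. Undefined scores are labeled "other" with a warning.
#' @return character vector of labels `"stem-like"`/`"other"`, named by
#'   sample when names are available.
#' @export
classify_stem_like <- function(scores, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("`threshold` must be a single value in [0, 1]")
  v <- score_values(scores)
  out <- ifelse(!is.na(v) & v >= threshold, "stem-like", "other")
  if (any(is.na(v)))
    warning(sum(is.na(v)), " undefined scores labeled 'other'")
  out
}

#' Select the trajectory root state by mean stemness
#'
#' Given trajectory state labels (e.g. from an external branch-detection
#' tool) the differentiation root is the state with the highest mean
#' stemness score: the most stem-like state is where the process starts.
#' Exact ties are broken toward the lexicographically smallest label, with
#' a warning.
#'
#' @param scores `StemSCScores` table or numeric vector.
#' @param state_labels character vector aligned with `scores`; at least two
#'   states, each with at least one defined score.
#' @return a `RootCall`: list with `root_state` and `state_means` (named,
#'   sorted decreasing).
#' @export
select_root_state <- function(scores, state_labels) {
  v <- score_values(scores)
  state_labels <- as.character(state_labels)
  if (length(v) != length(state_labels))
    stop("`scores` and `state_labels` lengths differ")
  states <- lex_sort(unique(state_labels))
  if (length(states) < 2L) stop("at least two states are required")
  means <- vapply(states, function(st) {
    x <- v[state_labels == st & !is.na(v)]
    if (!length(x)) stop("state '", st, "' has no defined score")
    mean(x)
  }, numeric(1))
  winners <- states[means == max(means)]
  if (length(winners) > 1L)
    warning("tie between states ", paste(winners, collapse = ", "),
            "; choosing '", winners[1L], "'")
  structure(list(root_state = winners[1L],
                 state_means = sort(means, decreasing = TRUE)),
            class = "RootCall")
}

#' @export
print.RootCall <- function(x, ...) {
  cat("RootCall: root =", x$root_state, "\n  state means:",
      paste(sprintf("%s=%.3f", names(x$state_means), x$state_means),
            collapse = ", "), "\n")
  invisible(x)
}

#' Highly variable gene selection for trajectory inference
#'
#' Removes genes detected (value > 0) in fewer than `min_cells` cells, then
#' ranks the survivors by the product of squared coefficient of variation
#' and mean — algebraically the variance-to-mean ratio, with the sample
#' (n-1) variance — and returns the `top_n` genes. Zero-mean genes are
#' excluded.
#'
#' @param dataset an `ExpressionDataset`.
#' @param min_cells detection floor (default 10).
#' @param top_n number of genes returned (default 5000; all if fewer pass).
#' @return character vector of gene identifiers, ranked by decreasing
#'   statistic (ties by identifier).
#' @export
select_hvg <- function(dataset, min_cells = 10L, top_n = 5000L) {
  dataset <- as_expression_dataset(dataset)
  X <- dataset$values
  detected <- rowSums(X > 0)
  X <- X[detected >= min_cells, , drop = FALSE]
  if (nrow(X) == 0L) return(character(0))
  mu <- rowMeans(X)
  keep <- mu > 0
  X <- X[keep, , drop = FALSE]; mu <- mu[keep]
  if (nrow(X) == 0L) return(character(0))
  v <- rowSums((X - mu)^2) / (ncol(X) - 1L)
  stat <- v / mu                     # (cv^2) * mean == var / mean
  ord <- order(-stat, rownames(X), method = "radix")
  head(rownames(X)[ord], top_n)
}

#' Two-sample t-test on stemness scores
#'
#' Pooled-variance Student t-test by default; set `equal_variance = FALSE`
#' for the Welch form. The degenerate case of zero variance in both groups
#' with equal means yields `t = 0, p = 1` rather than an error.
#'
#' @param scores_a,scores_b numeric vectors (at least 2 values each; `NA`
#'   dropped).
#' @param equal_variance pooled (TRUE, default) or Welch (FALSE).
#' @return list with `statistic` (t), `p_value` (two-sided), `df`,
#'   `mean_a`, `mean_b`.
#' @export
compare_groups <- function(scores_a, scores_b, equal_variance = TRUE) {
  a <- scores_a[!is.na(scores_a)]; b <- scores_b[!is.na(scores_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two defined values")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (equal_variance) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    tt <- if (ma == mb) 0 else sign(ma - mb) * Inf
    p <- if (ma == mb) 1 else 0
    if (!equal_variance || (va == 0 && vb == 0)) df <- na + nb - 2
  } else {
    tt <- (ma - mb) / se
    p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  }
  list(statistic = tt, p_value = p, df = df, mean_a = ma, mean_b = mb)
}
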
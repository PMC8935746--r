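#' Score one sample against a reference REO signature
#'
#' The stemness index of a sample is `k/n`: `n` is the number of reference
#' pairs *contained* in the sample — both genes measured in the sample's
#' gene universe and their values strictly different — and `k` is the number
#' of contained pairs whose observed ordering matches the reference
#' direction. Tied pairs (including two dropout zeros) carry no ordering
#' evidence and are excluded from `n`; a (positive, zero) pair is evaluable.
#' When no pair is evaluable the score is undefined and flagged, never
#' coerced to 0 or 1.
#'
#' The score depends only on within-sample ranks, so it is exactly invariant
#' to any strictly increasing transform of the sample's values (RPKM vs TPM
#' vs log, per-sample batch distortions).
#'
#' @param sample_expression named numeric vector: expression values of one
#'   sample, names are gene identifiers. Values must be finite and `>= 0`.
#' @param signature a `ReferenceSignature` (or `StableREOSet`).
#' @param sample_id label stored in the result.
#' @param ties `"exclude"` (default): tied pairs are dropped from `n`;
#'   `"discordant"`: tied pairs count in `n` but never in `k`. The original
#'   method leaves this unstated; exclusion is the default because a tie
#'   carries no ordering evidence.
#' @return one-row data.frame with columns `sample`, `n_evaluable`,
#'   `k_concordant`, `stemsc` (`NA` when undefined).
#' @examples
#' sig <- reference_signature(data.frame(gene_high = c("a", "c"),
#'                                       gene_low  = c("b", "d")))
#' score_sample(c(a = 5, b = 1, c = 2, d = 7), sig)  # n = 2, k = 1
#' @export
score_sample <- function(sample_expression, signature, sample_id = "sample",
                         ties = c("exclude", "discordant")) {
  ties <- match.arg(ties)
  if (!is.numeric(sample_expression) || is.null(names(sample_expression)))
    stop("`sample_expression` must be a named numeric vector")
  if (any(!is.finite(sample_expression)) || any(sample_expression < 0))
    stop("sample expression values must be finite and nonnegative")
  pr <- signature_pairs(signature)
  hi <- match(pr$gene_high, names(sample_expression))
  lo <- match(pr$gene_low, names(sample_expression))
  present <- !is.na(hi) & !is.na(lo)
  vh <- sample_expression[hi[present]]
  vl <- sample_expression[lo[present]]
  evaluable <- if (ties == "exclude") vh != vl else rep(TRUE, length(vh))
  n <- sum(evaluable)
  k <- sum(vh > vl)
  data.frame(sample = sample_id, n_evaluable = n, k_concordant = k,
             stemsc = if (n > 0) k / n else NA_real_,
             stringsAsFactors = FALSE)
}

#' Score every sample of a dataset
#'
#' Vectorized equivalent of mapping [score_sample()] over the columns of the
#' expression matrix. The evaluable-pair universe is determined per sample
#' (ties differ between samples even though the gene universe is shared).
#'
#' @param dataset an `ExpressionDataset` (or named numeric matrix).
#' @param signature a `ReferenceSignature` (or `StableREOSet`).
#' @param ties tie handling, see [score_sample()].
#' @return data.frame of class `StemSCScores` with one row per sample, in
#'   dataset sample order: `sample`, `n_evaluable`, `k_concordant`, `stemsc`.
#' @export
score_dataset <- function(dataset, signature,
                          ties = c("exclude", "discordant")) {
  ties <- match.arg(ties)
  dataset <- as_expression_dataset(dataset)
  X <- dataset$values
  pr <- signature_pairs(signature)
  hi <- match(pr$gene_high, rownames(X))
  lo <- match(pr$gene_low, rownames(X))
  present <- !is.na(hi) & !is.na(lo)
  if (!any(present)) {
    res <- data.frame(sample = colnames(X), n_evaluable = 0L,
                      k_concordant = 0L, stemsc = NA_real_,
                      stringsAsFactors = FALSE)
    class(res) <- c("StemSCScores", "data.frame")
    return(res)
  }
  H <- X[hi[present], , drop = FALSE]
  L <- X[lo[present], , drop = FALSE]
  evaluable <- if (ties == "exclude") H != L else
    matrix(TRUE, nrow(H), ncol(H))
  n <- colSums(evaluable)
  k <- colSums(H > L)
  res <- data.frame(sample = colnames(X), n_evaluable = as.integer(n),
                    k_concordant = as.integer(k),
                    stemsc = ifelse(n > 0, k / n, NA_real_),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("StemSCScores", "data.frame")
  res
}

# Accept a ReferenceSignature or StableREOSet and return its pair table.
signature_pairs <- function(signature) {
  if (inherits(signature, "ReferenceSignature") ||
      inherits(signature, "StableREOSet")) return(signature$pairs)
  if (is.data.frame(signature) &&
      all(c("gene_high", "gene_low") %in% names(signature))) return(signature)
  stop("`signature` must be a ReferenceSignature, StableREOSet, or a ",
       "data.frame with gene_high/gene_low columns")
}

# Pull a numeric score vector (with NA for undefined) out of a score table.
score_values <- function(scores) {
  if (inherits(scores, "StemSCScores") ||
      (is.data.frame(scores) && "stemsc" %in% names(scores)))
    return(stats::setNames(scores$stemsc, scores$sample))
  if (is.numeric(scores)) return(scores)
  stop("`scores` must be a StemSCScores table or a numeric vector")
}
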
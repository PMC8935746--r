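# Shared fixture builders. All randomness is seeded at the call site.

# small random nonnegative matrix with unique gene/sample names
random_matrix <- function(n_genes, n_samples, sparsity = 0) {
  x <- matrix(rexp(n_genes * n_samples, rate = 0.2), n_genes, n_samples)
  if (sparsity > 0) x[matrix(runif(length(x)), n_genes) < sparsity] <- 0
  dimnames(x) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n_samples)))
  x
}

# independent brute-force oracle for stable REOs: explicit double loop over
# gene pairs and samples, no shared code with identify_stable_reos()
oracle_stable_reos <- function(x) {
  g <- sort(rownames(x), method = "radix")
  x <- x[g, , drop = FALSE]
  high <- character(0); low <- character(0)
  for (i in seq_len(nrow(x) - 1L)) {
    for (j in (i + 1L):nrow(x)) {
      gt <- TRUE; lt <- TRUE
      for (s in seq_len(ncol(x))) {
        if (x[i, s] <= x[j, s]) gt <- FALSE
        if (x[i, s] >= x[j, s]) lt <- FALSE
      }
      if (gt) { high <- c(high, g[i]); low <- c(low, g[j]) }
      if (lt) { high <- c(high, g[j]); low <- c(low, g[i]) }
    }
  }
  data.frame(gene_high = high, gene_low = low, stringsAsFactors = FALSE)
}

# brute-force k/n scoring oracle: per-pair loop
oracle_score <- function(values, pairs) {
  n <- 0L; k <- 0L
  for (r in seq_len(nrow(pairs))) {
    hi <- pairs$gene_high[r]; lo <- pairs$gene_low[r]
    if (!hi %in% names(values) || !lo %in% names(values)) next
    if (values[hi] == values[lo]) next
    n <- n + 1L
    if (values[hi] > values[lo]) k <- k + 1L
  }
  list(n = n, k = k, score = if (n > 0) k / n else NA_real_)
}

# tiny deterministic signature over genes a > b, c > d
toy_signature <- function() {
  reference_signature(data.frame(gene_high = c("a", "c"),
                                 gene_low = c("b", "d"),
                                 stringsAsFactors = FALSE))
}
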
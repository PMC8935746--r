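test_that("rank_genes_by_score_correlation orders genes by rho", {
  set.seed(29)
  n <- 12
  sc <- runif(n)
  x <- rbind(hit = sc, anti = max(sc) + 1 - sc, flat = rep(1, n),
             matrix(runif(4 * n), 4, dimnames = list(paste0("r", 1:4), NULL)))
  colnames(x) <- paste0("s", 1:n)
  ds <- expression_dataset(x, "d")
  scores <- data.frame(sample = colnames(x), n_evaluable = 10L,
                       k_concordant = 5L, stemsc = sc)
  tab <- rank_genes_by_score_correlation(ds, scores)
  expect_identical(tab$gene[1], "hit")
  expect_equal(tab$rho[1], 1)
  defined <- tab[!is.na(tab$rho), ]
  expect_identical(defined$gene[nrow(defined)], "anti")
  expect_equal(defined$rho[nrow(defined)], -1)
  expect_true(is.na(tab$rho[nrow(tab)]))        # flat gene sinks to bottom
  # per-gene loop oracle
  for (g in c("r1", "r2", "r3", "r4"))
    expect_equal(tab$rho[tab$gene == g],
                 cor(x[g, ], sc, method = "spearman"), tolerance = 1e-12)
  # misalignment is rejected
  bad <- scores; bad$sample <- rev(bad$sample)
  expect_error(rank_genes_by_score_correlation(ds, bad), "not aligned")
})

test_that("preranked_enrichment reproduces the hand-computed running sum", {
  st <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2)
  res <- preranked_enrichment(st, c("g1", "g2"), n_perm = 100, seed = 1)
  expect_identical(res$es, 1)          # peaks 0.6 then 1.0, misses -1/3 each
  expect_identical(res$n_hits, 2L)
  expect_gte(res$p, 1 / 101)
  # bottom of the ranking: negative ES
  res_bot <- preranked_enrichment(st, c("g4", "g5"), n_perm = 100, seed = 1)
  expect_lt(res_bot$es, 0)
  # full universe as the gene set: no contrast, ES defined as 0
  res_full <- preranked_enrichment(st, names(st), n_perm = 100, seed = 1)
  expect_identical(res_full$es, 0)
  expect_identical(res_full$p, 1)
  expect_error(preranked_enrichment(st, c("zz"), n_perm = 100, seed = 1),
               "overlap")
  expect_error(preranked_enrichment(st, "g1", n_perm = 10, seed = 1),
               "at least 100")
  # deterministic in the seed
  expect_identical(res$p,
                   preranked_enrichment(st, c("g1", "g2"), n_perm = 100,
                                        seed = 1)$p)
})

test_that("hypergeometric_enrichment matches enumeration", {
  expect_identical(hypergeometric_enrichment(0, 5, 4, 10), 1)
  expect_equal(hypergeometric_enrichment(4, 5, 4, 10), 5 / 210)
  expect_identical(hypergeometric_enrichment(4, 4, 4, 4), 1)
  expect_error(hypergeometric_enrichment(5, 4, 4, 10), "inconsistent")
  # enumeration oracle over a grid
  for (N in c(8, 15)) for (K in c(3, 6)) for (n in c(2, 5)) {
    for (k in 0:min(K, n)) {
      oracle <- sum(choose(K, k:min(K, n)) * choose(N - K, n - (k:min(K, n)))) /
        choose(N, n)
      expect_equal(hypergeometric_enrichment(k, K, n, N), oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("select_stem_threshold maximizes precision at the smallest t", {
  dec <- select_stem_threshold(c(0.90, 0.95, 0.50, 0.88),
                               c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(dec$threshold, 0.90)
  expect_identical(dec$precision_at_threshold, 1)
  expect_identical(unname(dec$group_sizes), c(2L, 2L))
  expect_identical(dec$candidates_examined, 4L)
  # perfectly separated classes: threshold = min CSC score
  dec2 <- select_stem_threshold(c(0.99, 0.93, 0.2, 0.4), c(T, T, F, F))
  expect_identical(dec2$threshold, 0.93)
  expect_error(select_stem_threshold(c(0.9, 0.8), c(TRUE, TRUE)),
               "both CSC and non-CSC")
})

test_that("threshold precision is the true maximum over all candidates", {
  set.seed(37)
  for (rep in 1:20) {
    v <- round(runif(30), 2)
    csc <- runif(30) < 0.3
    if (!any(csc) || all(csc)) next
    dec <- select_stem_threshold(v, csc)
    oracle_best <- max(sapply(unique(v), function(t) mean(csc[v >= t])))
    expect_equal(dec$precision_at_threshold, oracle_best, tolerance = 1e-12)
    # classify_stem_like reproduces the recorded group sizes
    lab <- classify_stem_like(v, dec$threshold)
    expect_identical(sum(lab == "stem-like"),
                     unname(dec$group_sizes["stem_like"]))
  }
})

test_that("classify_stem_like applies the boundary and NA rules", {
  expect_identical(classify_stem_like(c(0.90, 0.50), 0.862),
                   c("stem-like", "other"))
  expect_identical(unname(classify_stem_like(c(0.3, 0.9), 0)),
                   c("stem-like", "stem-like"))
  expect_identical(unname(classify_stem_like(c(0.3, 0.99), 1)),
                   c("other", "other"))
  expect_warning(lab <- classify_stem_like(c(NA, 0.9), 0.5), "undefined")
  expect_identical(unname(lab), c("other", "stem-like"))
  expect_error(classify_stem_like(c(0.5), 1.5), "\\[0, 1\\]")
})

test_that("select_root_state picks the highest-mean state", {
  sc <- c(0.9, 0.85, 0.3, 0.35, 0.5, 0.55)
  st <- c("S1", "S1", "S2", "S2", "S3", "S3")
  rc <- select_root_state(sc, st)
  expect_identical(rc$root_state, "S1")
  expect_equal(unname(rc$state_means["S2"]), 0.325)
  # exact tie: lexicographically smallest label, with a warning
  expect_warning(rc2 <- select_root_state(c(0.5, 0.5, 0.1), c("B", "A", "C")),
                 "tie")
  expect_identical(rc2$root_state, "A")
  expect_error(select_root_state(c(0.5, NA), c("A", "B")), "'B'")
  expect_error(select_root_state(c(0.5, 0.4), c("A", "A")), "two states")
})

test_that("select_hvg applies detection filter and var/mean ranking", {
  set.seed(41)
  x <- matrix(runif(20 * 12, 1, 10), 20, 12,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:12)))
  x["g01", ] <- c(rep(0, 3), runif(9, 1, 10))   # detected in 9 < 10 cells
  x["g02", ] <- rep(2, 12)                       # zero variance
  x["g03", ] <- rep(c(1, 3), 6)                  # var 2.1818../mean 2
  ds <- expression_dataset(x, "d")
  hv <- select_hvg(ds, min_cells = 10, top_n = 50)
  expect_false("g01" %in% hv)
  expect_true(all(c("g02", "g03") %in% hv))
  # full-sort oracle
  keep <- rowSums(x > 0) >= 10
  stat <- apply(x[keep, ], 1, var) / rowMeans(x[keep, ])
  oracle <- names(sort(stat, decreasing = TRUE))
  expect_identical(hv, oracle[seq_along(hv)])
  # top_n truncation and gene-order invariance
  expect_identical(select_hvg(ds, 10, 5), oracle[1:5])
  ds_perm <- expression_dataset(x[sample(nrow(x)), ], "p")
  expect_identical(select_hvg(ds_perm, 10, 5), oracle[1:5])
  # the [1,3] gene outranks the constant gene
  expect_lt(match("g03", hv), match("g02", hv))
})

test_that("compare_groups matches the pooled and Welch references", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674235, tolerance = 1e-6)
  expect_identical(res$df, 4)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # swap negates t, p unchanged
  swap <- compare_groups(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$statistic, -res$statistic)
  expect_equal(swap$p_value, res$p_value)
  # identical groups
  same <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  # Welch oracle on unequal variances
  set.seed(43)
  a <- rnorm(10); b <- rnorm(15, sd = 3)
  w <- compare_groups(a, b, equal_variance = FALSE)
  refw <- t.test(a, b)
  expect_equal(w$statistic, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(w$p_value, refw$p.value, tolerance = 1e-12)
  expect_equal(w$df, unname(refw$parameter), tolerance = 1e-9)
  expect_error(compare_groups(1, c(1, 2)), "at least two")
})
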
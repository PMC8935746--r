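make_time_dataset <- function(values, id = "tc") {
  meta <- data.frame(sample = colnames(values),
                     time = seq_len(ncol(values)) - 1)
  expression_dataset(values, dataset_id = id, sample_meta = meta)
}

test_that("spearman_time_correlation handles monotone and degenerate genes", {
  x <- rbind(up = 1:6, down = 6:1, flat = rep(2, 6),
             noisy = c(2, 1, 4, 3, 6, 5))
  colnames(x) <- paste0("s", 1:6)
  tab <- spearman_time_correlation(make_time_dataset(x))
  expect_identical(tab$gene, rownames(x))
  expect_equal(tab$rho[tab$gene == "up"], 1)
  expect_equal(tab$p[tab$gene == "up"], 0)
  expect_equal(tab$rho[tab$gene == "down"], -1)
  expect_true(is.na(tab$rho[tab$gene == "flat"]))
  expect_identical(tab$p[tab$gene == "flat"], 1)
  expect_true(is.na(tab$q[tab$gene == "flat"]))
  # agreement with the base-R reference on a tied, noisy gene
  ref <- suppressWarnings(
    cor.test(x["noisy", ], 0:5, method = "spearman"))
  expect_equal(tab$rho[tab$gene == "noisy"], unname(ref$estimate),
               tolerance = 1e-12)
  # missing time metadata is a rejection
  expect_error(spearman_time_correlation(expression_dataset(x, "no_time")),
               "no_time")
})

test_that("bh_fdr matches step-up enumeration and validates input", {
  expect_identical(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.01, 1.0)), c(0.02, 1.0))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, NA)), "\\[0, 1\\]")
  # independent step-up oracle: q_i = min over j with p_j >= p_i of p_j*m/j
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(sample(1:100, 1))
    m <- length(p)
    oracle <- vapply(seq_len(m), function(i) {
      r <- rank(p, ties.method = "max")
      min(pmin(1, (p * m / r)[p >= p[i]]))
    }, numeric(1))
    expect_equal(bh_fdr(p), oracle, tolerance = 1e-12)
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("select_stemness_genes intersects per-dataset significant genes", {
  set.seed(9)
  noise <- function() matrix(rnorm(8 * 10, 5, 0.1), 8, 10)
  base <- function(id, strong = TRUE) {
    x <- 2^(noise())
    rownames(x) <- paste0("g", 1:8)
    colnames(x) <- paste0(id, "_s", 1:10)
    if (strong) x["g1", ] <- 2^(5 + (0:9))          # strongly increasing
    make_time_dataset(x, id)
  }
  d1 <- base("a"); d2 <- base("b"); d3 <- base("c", strong = FALSE)
  panel_all <- select_stemness_genes(list(d1, d2))
  expect_true("g1" %in% panel_all$genes)
  # significant in only a subset of datasets: excluded
  panel_part <- suppressWarnings(select_stemness_genes(list(d1, d2, d3)))
  expect_false("g1" %in% panel_part$genes)
  # invariant to dataset ordering
  expect_identical(select_stemness_genes(list(d2, d1))$genes, panel_all$genes)
})

test_that("planted monotone genes are recovered across seeds", {
  recalls <- fps <- numeric(10)
  for (s in 1:10) {
    cfg <- synthetic_config(seed = s, n_genes = 120, n_stemness_genes = 20)
    courses <- lapply(1:5, function(k)
      generate_differentiation_course(cfg, paste0("tc", k),
                                      seed = 100 * s + k))
    panel <- select_stemness_genes(courses)
    roles <- courses[[1]]$truth$roles
    planted <- names(roles)[roles != "null"]
    recalls[s] <- mean(planted %in% panel$genes)
    fps[s] <- sum(!panel$genes %in% planted)
  }
  expect_gte(mean(recalls), 0.95)
  # with FDR 0.05 in each of 5 datasets, null genes essentially never pass all
  expect_lte(mean(fps), 1)
})

test_that("disjoint significant sets give an empty panel with a warning", {
  set.seed(2)
  mk <- function(id, sig_gene) {
    x <- 2^matrix(rnorm(4 * 10, 5, 0.1), 4, 10)
    x[sig_gene, ] <- 2^(5 + (0:9))
    rownames(x) <- paste0("g", 1:4)
    colnames(x) <- paste0(id, "_s", 1:10)
    make_time_dataset(x, id)
  }
  expect_warning(panel <- select_stemness_genes(list(mk("a", 1), mk("b", 2))),
                 "empty panel")
  expect_length(panel$genes, 0)
})

test_that("build_reference_signature applies intersection and concordance", {
  # noiseless pools from one latent ordering: signature = all panel pairs
  cfg <- synthetic_config(seed = 4, n_genes = 30, n_stemness_genes = 10,
                          noise_sd = 0, dropout_rate = 0)
  pool <- generate_esc_pool(cfg, n_cells_sc = 6, n_cells_bulk = 6)
  roles <- pool$sc[[1]]$truth$roles
  panel <- names(roles)[roles != "null"]
  sig <- build_reference_signature(pool$sc, pool$bulk, panel)
  expect_identical(nrow(sig$pairs), as.integer(choose(10, 2)))
  expect_identical(sig$provenance[["n_shared"]],
                   sig$provenance[["n_concordant"]])
  expect_true(all(c(sig$pairs$gene_high, sig$pairs$gene_low) %in% panel))

  # hand-built pools: one pair sc-only, one discordant, one concordant
  mk <- function(id, a, b, c, d) {
    x <- rbind(a = a, b = b, c = c, d = d)
    colnames(x) <- paste0(id, "_s", 1:4)
    expression_dataset(x, id)
  }
  sc <- list(mk("sc", a = c(9, 9, 9, 9), b = c(1, 1, 1, 1),
                c = c(5, 5, 5, 5), d = c(3, 3, 3, 3)))
  # bulk: a>b concordant; c<d discordant
  bulk <- list(mk("bk", a = c(8, 8, 8, 8), b = c(2, 2, 2, 2),
                  c = c(3, 3, 3, 3), d = c(5, 5, 5, 5)))
  sig2 <- build_reference_signature(sc, bulk, c("a", "b", "c", "d"))
  expect_identical(sig2$provenance[["n_shared"]] -
                   sig2$provenance[["n_concordant"]], 1L)
  key <- paste(sig2$pairs$gene_high, sig2$pairs$gene_low)
  expect_true("a b" %in% key)
  expect_false(any(grepl("^c|^d", sig2$pairs$gene_high)) &&
               "c d" %in% key)

  # fully discordant pools cannot yield a signature
  bulk_rev <- list(mk("rev", a = c(1, 1, 1, 1), b = c(7, 7, 7, 7),
                      c = c(2, 2, 2, 2), d = c(6, 6, 6, 6)))
  expect_error(build_reference_signature(sc, bulk_rev, c("a", "b", "c", "d")),
               "empty reference signature")
})

test_that("end-to-end training recovers the planted stemness axis", {
  cfg <- synthetic_config(seed = 31)
  courses <- lapply(1:5, function(k)
    generate_differentiation_course(cfg, paste0("tc", k), seed = 300 + k))
  panel <- select_stemness_genes(courses)
  pool <- generate_esc_pool(cfg, seed = 400)
  sig <- build_reference_signature(pool$sc, pool$bulk, panel)
  held <- generate_differentiation_course(cfg, "held", seed = 500)
  scores <- score_dataset(held, sig)
  rho <- cor(scores$stemsc, held$sample_meta$time, method = "spearman")
  expect_lte(rho, -0.8)
})
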
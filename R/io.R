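#' Read an expression matrix from disk
#'
#' Supported formats: dense TSV/CSV with genes as rows (first column `gene`,
#' remaining columns samples) and Matrix-Market coordinate triplets with
#' `genes.tsv` / `barcodes.tsv` sidecar files (one identifier per line,
#' 1-based indices, genes as rows).
#'
#' @param path file path; for `mtx-triplet`, the `.mtx` file whose directory
#'   also holds the sidecars.
#' @param format one of `"dense-tsv"`, `"dense-csv"`, `"mtx-triplet"`.
#' @param dataset_id label of the resulting dataset (defaults to the file
#'   name without extension).
#' @param sample_meta optional path of a sample metadata TSV (see
#'   [read_sample_meta()]).
#' @param genes_file,barcodes_file sidecar paths for `mtx-triplet`
#'   (defaults: `genes.tsv` and `barcodes.tsv` next to the matrix).
#' @return an `ExpressionDataset`.
#' @export
read_expression <- function(path,
                            format = c("dense-tsv", "dense-csv", "mtx-triplet"),
                            dataset_id = NULL, sample_meta = NULL,
                            genes_file = NULL, barcodes_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  X <- switch(format,
    "dense-tsv" = read_dense(path, sep = "\t"),
    "dense-csv" = read_dense(path, sep = ","),
    "mtx-triplet" = read_mtx_triplet(path, genes_file, barcodes_file))
  meta <- if (!is.null(sample_meta)) read_sample_meta(sample_meta) else NULL
  expression_dataset(X, dataset_id = dataset_id, sample_meta = meta)
}

read_dense <- function(path, sep) {
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (ncol(tab) < 2L || tolower(names(tab)[1L]) != "gene")
    stop("malformed header in ", path,
         ": expected a leading 'gene' column followed by sample columns")
  genes <- as.character(tab[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene rows in ", path, ": ", paste(dup, collapse = ", "))
  X <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- which(apply(tab[, -1L, drop = FALSE], 2, function(col)
      any(is.na(suppressWarnings(as.numeric(col))))))
    stop("non-numeric expression values in ", path, " (columns: ",
         paste(names(bad), collapse = ", "), ")")
  }
  neg <- which(X < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative expression values in ", path, " at data line(s) ",
         paste(utils::head(sort(unique(neg[, 1L])) + 1L, 5L), collapse = ", "))
  rownames(X) <- genes
  X
}

read_mtx_triplet <- function(path, genes_file = NULL, barcodes_file = NULL) {
  if (is.null(genes_file)) genes_file <- file.path(dirname(path), "genes.tsv")
  if (is.null(barcodes_file))
    barcodes_file <- file.path(dirname(path), "barcodes.tsv")
  for (f in c(genes_file, barcodes_file))
    if (!file.exists(f)) stop("sidecar file not found: ", f)
  M <- as.matrix(Matrix::readMM(path))
  genes <- readLines(genes_file)
  genes <- sub("\t.*$", "", genes[nzchar(genes)])
  barcodes <- readLines(barcodes_file)
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(genes) != nrow(M))
    stop("genes sidecar has ", length(genes), " entries but matrix has ",
         nrow(M), " rows")
  if (length(barcodes) != ncol(M))
    stop("barcodes sidecar has ", length(barcodes), " entries but matrix has ",
         ncol(M), " columns")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene identifiers in ", genes_file, ": ",
         paste(dup, collapse = ", "))
  dimnames(M) <- list(genes, barcodes)
  M
}

#' Write an expression dataset to disk
#'
#' @param dataset an `ExpressionDataset`.
#' @param path output path (`.mtx` file for the triplet format).
#' @param format as in [read_expression()].
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset,
                             path,
                             format = c("dense-tsv", "dense-csv", "mtx-triplet")) {
  format <- match.arg(format)
  dataset <- as_expression_dataset(dataset)
  X <- dataset$values
  if (format == "mtx-triplet") {
    Matrix::writeMM(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(X), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(X), file.path(dirname(path), "barcodes.tsv"))
  } else {
    sep <- if (format == "dense-tsv") "\t" else ","
    tab <- data.frame(gene = rownames(X), X, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-sample metadata
#'
#' TSV with a mandatory `sample` column; `time` is coerced to numeric and
#' `csc` to logical when present.
#'
#' @param path metadata TSV path.
#' @return data.frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "", quote = "\"")
  if (!"sample" %in% names(meta))
    stop("metadata file ", path, " lacks a 'sample' column")
  meta$sample <- as.character(meta$sample)
  if ("time" %in% names(meta)) meta$time <- as.numeric(meta$time)
  if ("csc" %in% names(meta)) meta$csc <- as.logical(meta$csc)
  meta
}

#' Serialize / deserialize stable-REO sets and reference signatures
#'
#' TSV with header `gene_high<TAB>gene_low`, one directed pair per line,
#' UTF-8, deterministic lexicographic order of the unordered pair. For
#' signatures, provenance counts go to a `key: value` sidecar at
#' `<path>.provenance`.
#'
#' @param x a `StableREOSet` or `ReferenceSignature`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_reo_set <- function(x, path) {
  pairs <- signature_pairs(x)
  pairs <- pairs[lex_order(pmin(pairs$gene_high, pairs$gene_low),
                           pmax(pairs$gene_high, pairs$gene_low)), ,
                 drop = FALSE]
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (inherits(x, "ReferenceSignature")) {
    writeLines(sprintf("%s: %s", names(x$provenance), x$provenance),
               paste0(path, ".provenance"))
  }
  invisible(path)
}

#' @rdname write_reo_set
#' @param source_id label for the deserialized set.
#' @export
read_reo_set <- function(path, source_id = NULL) {
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  if (!all(c("gene_high", "gene_low") %in% names(tab)))
    stop("file ", path, " lacks gene_high/gene_low columns")
  stable_reo_set(tab, source_id = source_id)
}

#' @rdname write_reo_set
#' @export
read_signature <- function(path) {
  set <- read_reo_set(path)
  prov_path <- paste0(path, ".provenance")
  prov <- NULL
  if (file.exists(prov_path)) {
    lines <- readLines(prov_path)
    kv <- strsplit(lines[nzchar(lines)], ":\\s*")
    prov <- stats::setNames(as.integer(vapply(kv, `[`, "", 2L)),
                            vapply(kv, `[`, "", 1L))
  }
  reference_signature(set$pairs, provenance = prov)
}

#' Read / write a gene panel (one identifier per line)
#'
#' @param path file path.
#' @return character vector of identifiers.
#' @export
read_panel <- function(path) {
  g <- readLines(path)
  g[nzchar(g)]
}

#' @rdname read_panel
#' @param genes character vector (or `StemnessGenePanel`).
#' @export
write_panel <- function(genes, path) {
  if (inherits(genes, "StemnessGenePanel")) genes <- genes$genes
  writeLines(genes, path)
  invisible(path)
}

#' Read / write stemness score tables
#'
#' TSV with header `sample  n_evaluable  k_concordant  stemsc`; undefined
#' scores are serialized as `NA`.
#'
#' @param scores a `StemSCScores` table.
#' @param path file path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  needed <- c("sample", "n_evaluable", "k_concordant", "stemsc")
  if (!all(needed %in% names(tab)))
    stop("file ", path, " lacks score columns: ",
         paste(setdiff(needed, names(tab)), collapse = ", "))
  tab$sample <- as.character(tab$sample)
  class(tab) <- c("StemSCScores", "data.frame")
  tab
}

#' Remove low-quality cells by detected-gene count
#'
#' Detection is `value > 0`; cells with strictly fewer than `min_detected`
#' detected genes are removed (the boundary cell with exactly `min_detected`
#' is kept). A removal log is emitted as a message.
#'
#' @param dataset an `ExpressionDataset`.
#' @param min_detected detection floor (default 2000).
#' @return the filtered `ExpressionDataset`.
#' @export
qc_filter_cells <- function(dataset, min_detected = 2000L) {
  dataset <- as_expression_dataset(dataset)
  detected <- colSums(dataset$values > 0)
  keep <- detected >= min_detected
  if (!any(keep))
    stop("all ", length(keep), " cells fall below ", min_detected,
         " detected genes (max detected: ", max(detected), ")")
  message("qc_filter_cells: removed ", sum(!keep), " of ", length(keep),
          " cells with < ", min_detected, " detected genes")
  out <- dataset
  out$values <- dataset$values[, keep, drop = FALSE]
  if (!is.null(dataset$sample_meta))
    out$sample_meta <- dataset$sample_meta[keep, , drop = FALSE]
  out
}

#' Read a two-column gene identifier map
#'
#' Whitespace rows and rows with empty fields are dropped; exact duplicate
#' rows are collapsed. A source identifier mapping to two different targets
#' is an error.
#'
#' @param path TSV with two columns: source identifier, target identifier.
#'   A header line is detected and skipped when its first field is `source`.
#' @return a `GeneIdMap` data.frame with columns `source`, `target`.
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "", col.names = c("source", "target"))
  if (nrow(tab) && tolower(tab$source[1L]) == "source")
    tab <- tab[-1L, , drop = FALSE]
  tab <- tab[nzchar(tab$source) & nzchar(tab$target) &
             !is.na(tab$source) & !is.na(tab$target), , drop = FALSE]
  tab <- unique(tab)
  dup <- unique(tab$source[duplicated(tab$source)])
  if (length(dup))
    stop("source identifiers mapping to multiple targets: ",
         paste(dup, collapse = ", "))
  rownames(tab) <- NULL
  class(tab) <- c("GeneIdMap", "data.frame")
  tab
}

#' Map gene identifiers of a dataset
#'
#' Unmapped genes are dropped (count logged). When several source genes map
#' to the same target, the row with the highest mean expression is kept —
#' the common convention for many-to-one identifier collapses.
#'
#' @param dataset an `ExpressionDataset`.
#' @param id_map a `GeneIdMap` (see [read_gene_map()]) or a data.frame with
#'   `source`/`target` columns.
#' @return the renamed `ExpressionDataset`, rows sorted by target
#'   identifier.
#' @export
map_gene_ids <- function(dataset, id_map) {
  dataset <- as_expression_dataset(dataset)
  if (!is.data.frame(id_map) || !all(c("source", "target") %in% names(id_map)))
    stop("`id_map` must have 'source' and 'target' columns")
  if (anyDuplicated(id_map$source))
    stop("`id_map` is not cleaned: duplicated source identifiers")
  X <- dataset$values
  target <- id_map$target[match(rownames(X), id_map$source)]
  mapped <- !is.na(target)
  message("map_gene_ids: ", sum(!mapped), " of ", nrow(X),
          " genes unmapped and dropped")
  if (!any(mapped)) stop("no gene could be mapped")
  X <- X[mapped, , drop = FALSE]
  target <- target[mapped]
  # many-to-one collapse: keep the highest-mean source row per target
  mu <- rowMeans(X)
  ord <- order(target, -mu, rownames(X), method = "radix")
  X <- X[ord, , drop = FALSE]
  target <- target[ord]
  keep <- !duplicated(target)
  dropped <- sum(!keep)
  if (dropped)
    message("map_gene_ids: collapsed ", dropped,
            " lower-mean rows in many-to-one mappings")
  X <- X[keep, , drop = FALSE]
  rownames(X) <- target[keep]
  out <- dataset
  out$values <- X[lex_order(rownames(X)), , drop = FALSE]
  out
}
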
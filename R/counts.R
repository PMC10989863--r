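#' Sparse gene-by-cell count container
#'
#' Bundles a sparse non-negative integer count matrix (genes in rows, cells in
#' columns) with its gene and cell annotation tables. This is the unit every
#' pipeline stage consumes: one object per replicate, or per analysis after
#' pooling replicates.
#'
#' @param counts A matrix or [Matrix::sparseMatrix()] of non-negative integer
#'   counts, genes in rows.
#' @param genes A data frame with one row per gene: columns `gene_id`,
#'   `symbol`, `class` and logical `mito`.
#' @param cells A data frame with one row per cell: columns `barcode`,
#'   `replicate` and `analysis`.
#'
#' @return An object of class `germ_counts`: a list with elements `counts`
#'   (a `dgCMatrix`), `genes` and `cells` (tibbles).
#' @export
germ_counts <- function(counts, genes, cells) {
  if (!methods::is(counts, "sparseMatrix")) {
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  genes <- as_tibble(genes)
  cells <- as_tibble(cells)
  need_g <- c("gene_id", "symbol", "class", "mito")
  if (!all(need_g %in% names(genes))) {
    abort(paste0("`genes` must have columns: ", paste(need_g, collapse = ", ")))
  }
  if (!"barcode" %in% names(cells)) {
    abort("`cells` must have a `barcode` column")
  }
  if (nrow(counts) != nrow(genes)) {
    abort(sprintf("matrix has %d rows but gene table has %d rows",
                  nrow(counts), nrow(genes)))
  }
  if (ncol(counts) != nrow(cells)) {
    abort(sprintf("matrix has %d columns but cell table has %d rows",
                  ncol(counts), nrow(cells)))
  }
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != round(counts@x)))) {
    abort("counts must be non-negative integers")
  }
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$barcode
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "germ_counts")
}

#' @export
print.germ_counts <- function(x, ...) {
  cat(sprintf("<germ_counts> %d genes x %d cells (%d non-zero entries)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  reps <- unique(paste(x$cells$analysis, x$cells$replicate, sep = "/"))
  cat("  replicates:", paste(head(reps, 6), collapse = ", "),
      if (length(reps) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.germ_counts <- function(x) dim(x$counts)

#' Pool several count objects column-wise
#'
#' Concatenates the cells of multiple [germ_counts] objects that share an
#' identical gene table. Used to pool the replicates of one analysis before
#' labeling and differential expression.
#'
#' @param x A list of `germ_counts` objects.
#' @return A single [germ_counts] with all cells.
#' @export
pool_counts <- function(x) {
  stopifnot(length(x) >= 1)
  g0 <- x[[1]]$genes
  for (m in x) {
    if (!identical(m$genes$gene_id, g0$gene_id)) {
      abort("cannot pool count objects with different gene tables")
    }
  }
  germ_counts(do.call(cbind, lapply(x, function(m) m$counts)),
              g0, bind_rows(lapply(x, function(m) m$cells)))
}
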
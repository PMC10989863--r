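#' Per-cell mitochondrial count fraction
#'
#' Fraction of each cell's total counts that falls on genes flagged
#' mitochondrial. Cells with zero total counts get fraction 0 and are flagged
#' in the `zero_total` attribute.
#'
#' @param x A [germ_counts].
#' @return A numeric vector, one value per cell, named by barcode.
#' @export
mito_fraction <- function(x) {
  stopifnot(inherits(x, "germ_counts"))
  tot <- Matrix::colSums(x$counts)
  mito <- if (any(x$genes$mito)) {
    Matrix::colSums(x$counts[x$genes$mito, , drop = FALSE])
  } else {
    numeric(ncol(x$counts))
  }
  frac <- unname(ifelse(tot > 0, mito / pmax(tot, 1), 0))
  names(frac) <- x$cells$barcode
  attr(frac, "zero_total") <- unname(tot == 0)
  frac
}

#' QC thresholds for cell filtering
#'
#' @param min_genes,max_genes Bounds (inclusive) on the number of genes
#'   detected per cell (count > 0).
#' @param max_mito_fraction Maximum allowed mitochondrial count fraction.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 0, max_genes = Inf, max_mito_fraction = 1) {
  if (min_genes > max_genes) abort("`min_genes` must not exceed `max_genes`")
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    abort("`max_mito_fraction` must lie in [0, 1]")
  }
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Derive QC thresholds from a replicate's own distributions
#'
#' The replicate-specific rule: bounds at median +/- `n_mads` MADs on
#' log10(genes detected), and a fixed mitochondrial-fraction ceiling. This
#' reproduces the procedure of deriving cutoffs from each replicate's
#' genes-expressed and mitochondrial distributions when the numeric cutoffs
#' themselves are not published.
#'
#' @param x A [germ_counts] (one replicate).
#' @param n_mads Number of MADs around the median (default 3).
#' @param max_mito_fraction Mitochondrial ceiling (default 0.2).
#' @return A [qc_thresholds()].
#' @export
auto_qc_thresholds <- function(x, n_mads = 3, max_mito_fraction = 0.2) {
  stopifnot(inherits(x, "germ_counts"))
  detected <- Matrix::colSums(x$counts > 0)
  lg <- log10(pmax(detected, 1))
  ctr <- stats::median(lg)
  dev <- stats::mad(lg)
  qc_thresholds(min_genes = floor(10^(ctr - n_mads * dev)),
                max_genes = ceiling(10^(ctr + n_mads * dev)),
                max_mito_fraction = max_mito_fraction)
}

#' Filter cells on genes-detected and mitochondrial fraction
#'
#' Keeps cells with `min_genes <= genes detected <= max_genes` and
#' mitochondrial fraction `<= max_mito_fraction`. Genes are never removed and
#' the order of surviving cells is preserved, so the filter is idempotent.
#'
#' @param x A [germ_counts].
#' @param thresholds A [qc_thresholds()].
#' @return The filtered [germ_counts], with a `qc_report` attribute (a tibble
#'   of cells in/out per replicate).
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "germ_counts"), inherits(thresholds, "qc_thresholds"))
  detected <- Matrix::colSums(x$counts > 0)
  mf <- mito_fraction(x)
  keep <- detected >= thresholds$min_genes & detected <= thresholds$max_genes &
    mf <= thresholds$max_mito_fraction
  if (!any(keep)) {
    abort(sprintf("QC removed every cell of replicate %s",
                  paste(unique(paste(x$cells$analysis, x$cells$replicate, sep = "/")),
                        collapse = ",")))
  }
  report <- tibble(analysis = x$cells$analysis, replicate = x$cells$replicate,
                   keep = keep) |>
    group_by(.data$analysis, .data$replicate) |>
    summarise(cells_in = dplyr::n(), cells_kept = sum(.data$keep), .groups = "drop")
  out <- germ_counts(x$counts[, keep, drop = FALSE], x$genes, x$cells[keep, ])
  attr(out, "qc_report") <- report
  out
}

#' Log-normalized expression (counts per 10k, natural log)
#'
#' Per-cell depth normalization followed by a log transform:
#' `value = ln(1 + 1e4 * count / cell_total)`. Zero counts stay exactly zero
#' (the sparse pattern is preserved). This is the monotone per-cell
#' normalization behind marker scores, dot-plot means and fold-changes.
#'
#' @param x A [germ_counts] with no zero-total cells (run [qc_filter()] first).
#' @return A `germ_norm` object: list of `values` (sparse, natural-log scale),
#'   `genes`, `cells` and `method = "log_cp10k"`.
#' @export
normalize_cp10k <- function(x) {
  stopifnot(inherits(x, "germ_counts"))
  tot <- Matrix::colSums(x$counts)
  if (any(tot == 0)) {
    abort("cells with zero total counts present; apply qc_filter() before normalizing")
  }
  v <- x$counts
  per_entry <- rep.int(tot, diff(v@p))
  v@x <- log1p(1e4 * v@x / per_entry)
  structure(list(values = v, genes = x$genes, cells = x$cells,
                 method = "log_cp10k"),
            class = "germ_norm")
}

#' @export
print.germ_norm <- function(x, ...) {
  cat(sprintf("<germ_norm> %s, %d genes x %d cells\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}
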
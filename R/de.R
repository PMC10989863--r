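#' Natural-log fold-change between two groups of normalized values
#'
#' Back-transforms the natural-log normalized values to the linear scale
#' (`expm1`), averages per group, re-applies a pseudocount of 1 and takes the
#' natural-log ratio:
#' `lnFC = ln((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`.
#'
#' @param norm_in,norm_out Numeric vectors of normalized (natural-log scale)
#'   values for the two groups.
#' @return The natural-log fold-change (antisymmetric under group swap).
#' @export
log_fold_change <- function(norm_in, norm_out) {
  if (!length(norm_in) || !length(norm_out)) abort("both groups must be non-empty")
  log((mean(expm1(norm_in)) + 1) / (mean(expm1(norm_out)) + 1))
}

#' Differential expression of germline vs all other cells
#'
#' One tie-corrected Wilcoxon rank-sum test per gene (germline vs soma, on
#' normalized values), Bonferroni adjustment over the number of genes tested,
#' and the natural-log fold-change of mean depth-normalized expression. A gene
#' is flagged significant when `p_adj < 0.05` **and** `lnFC > 0` (the
#' positive-gene filter). Genes expressed in no cell get `p = 1`, `lnFC = 0`.
#' P-values are floored at 1e-300 to keep downstream ranking finite.
#'
#' @param norm A `germ_norm`.
#' @param labeling A `germ_labeling` covering the same cells.
#' @param analysis Analysis identifier recorded in the result.
#' @param alpha Adjusted-p threshold for the significance flag.
#' @return A tibble (class `germ_de`): `analysis`, `gene_id`, `symbol`, `U`,
#'   `z`, `p`, `p_adj`, `lnfc`, `n_in`, `n_out`, `significant`.
#' @export
de_table <- function(norm, labeling, analysis = "1", alpha = 0.05) {
  stopifnot(inherits(norm, "germ_norm"))
  if (nrow(labeling) != ncol(norm$values)) {
    abort("labeling does not cover the cells of the matrix")
  }
  in_cells <- labeling$label == "germline"
  n1 <- sum(in_cells); n2 <- sum(!in_cells)
  if (n1 == 0 || n2 == 0) abort("both classes must be non-empty for DE")

  dense <- as.matrix(norm$values)
  cp10k <- expm1(dense)
  mean_in <- rowMeans(cp10k[, in_cells, drop = FALSE])
  mean_out <- rowMeans(cp10k[, !in_cells, drop = FALSE])
  lnfc <- log((mean_in + 1) / (mean_out + 1))

  n <- n1 + n2
  mu0 <- n1 * n2 / 2
  stats <- vapply(seq_len(nrow(dense)), function(i) {
    x <- dense[i, ]
    r <- rank(x)
    U <- sum(r[in_cells]) - n1 * (n1 + 1) / 2
    tl <- rle(sort(x))$lengths
    v <- n1 * n2 / 12 * ((n + 1) - sum(tl^3 - tl) / (n * (n - 1)))
    if (v <= 0) return(c(U = U, z = 0, p = 1))
    d <- U - mu0
    z <- (d - sign(d) * 0.5 * (abs(d) >= 0.5)) / sqrt(v)
    c(U = U, z = z, p = max(min(2 * pnorm(-abs(z)), 1), 1e-300))
  }, c(U = 0, z = 0, p = 0))

  expressed <- unname(Matrix::rowSums(norm$values != 0) > 0)
  p <- unname(ifelse(expressed, stats["p", ], 1))
  z <- unname(ifelse(expressed, stats["z", ], 0))
  lnfc <- unname(ifelse(expressed, lnfc, 0))
  p_adj <- bonferroni(p, nrow(dense))
  out <- tibble(analysis = analysis,
                gene_id = norm$genes$gene_id,
                symbol = norm$genes$symbol,
                U = stats["U", ], z = z, p = p, p_adj = p_adj, lnfc = lnfc,
                n_in = n1, n_out = n2,
                significant = p_adj < alpha & lnfc > 0)
  structure(out, class = c("germ_de", class(out)))
}

#' @export
tidy.germ_de <- function(x, ...) as_tibble(x)

#' @export
glance.germ_de <- function(x, ...) {
  tibble(analysis = x$analysis[1], n_genes = nrow(x),
         n_significant = sum(x$significant),
         n_in = x$n_in[1], n_out = x$n_out[1])
}
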
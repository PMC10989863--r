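#' Per-cell marker score
#'
#' Unweighted mean of the normalized expression of the marker genes
#' (vasa plus the three synaptonemal-complex genes, by default) in each cell.
#'
#' @param norm A `germ_norm` from [normalize_cp10k()].
#' @param markers Character vector of marker gene symbols or ids.
#' @return Named numeric vector of scores, one per cell.
#' @export
marker_score <- function(norm, markers = c("vas", "c(3)G", "cona", "corolla")) {
  stopifnot(inherits(norm, "germ_norm"))
  idx <- match(markers, norm$genes$symbol)
  idx[is.na(idx)] <- match(markers[is.na(idx)], norm$genes$gene_id)
  if (anyNA(idx)) {
    abort(sprintf("marker gene(s) not found: %s",
                  paste(markers[is.na(idx)], collapse = ", ")))
  }
  sc <- Matrix::colMeans(norm$values[idx, , drop = FALSE])
  names(sc) <- norm$cells$barcode
  sc
}

#' Otsu threshold of a score distribution
#'
#' Exhaustively scans the cuts between consecutive sorted scores and returns
#' the one maximizing the between-class variance `w0 * w1 * (m0 - m1)^2`.
#'
#' @param scores Numeric vector (non-constant).
#' @return The threshold (midpoint between the two scores straddling the
#'   optimal cut).
#' @export
otsu_threshold <- function(scores) {
  ss <- sort(scores)
  n <- length(ss)
  if (n < 2 || ss[1] == ss[n]) {
    abort("degenerate score distribution: all scores equal")
  }
  cs <- cumsum(ss)
  i <- seq_len(n - 1)
  w0 <- i / n
  bv <- w0 * (1 - w0) * (cs[i] / i - (cs[n] - cs[i]) / (n - i))^2
  bv[ss[i] == ss[i + 1]] <- -Inf      # cuts inside a tie group are not real cuts
  k <- which.max(bv)
  (ss[k] + ss[k + 1]) / 2
}

#' Partition cells into germline and soma by marker score
#'
#' Thresholds the per-cell marker score with Otsu's criterion; cells strictly
#' above the threshold are labeled germline (ties at the threshold go to
#' soma). An externally supplied threshold or label vector can be used
#' instead, e.g. when cluster assignments come from a different tool.
#'
#' @param scores Named numeric vector from [marker_score()] (>= 10 cells).
#' @param threshold Optional manual threshold overriding Otsu.
#' @param labels Optional externally computed labels (`"germline"`/`"soma"`),
#'   bypassing the scores entirely.
#' @return A tibble (class `germ_labeling`) with `barcode`, `score`, `label`;
#'   attributes `method` and `threshold`.
#' @export
assign_germline <- function(scores, threshold = NULL, labels = NULL) {
  if (!is.null(labels)) {
    out <- tibble(barcode = names(scores) %||% as.character(seq_along(labels)),
                  score = as.numeric(scores), label = labels)
    return(structure(out, class = c("germ_labeling", class(out)),
                     method = "external", threshold = NA_real_))
  }
  if (length(scores) < 10) abort("need at least 10 cells to threshold scores")
  method <- if (is.null(threshold)) "otsu" else "manual"
  if (is.null(threshold)) threshold <- otsu_threshold(scores)
  label <- unname(ifelse(scores > threshold, "germline", "soma"))
  if (method == "otsu" && length(unique(label)) < 2) {
    abort("thresholding left one class empty; supply a manual threshold")
  }
  out <- tibble(barcode = names(scores) %||% as.character(seq_along(scores)),
                score = as.numeric(scores), label = label)
  structure(out, class = c("germ_labeling", class(out)),
            method = method, threshold = threshold)
}

#' Dot-plot summary statistics per group and gene
#'
#' For every (group, gene) pair: the mean normalized expression, and the
#' fraction of the group's cells with raw count > 0 — the two quantities a
#' cluster dot plot encodes as color and diameter.
#'
#' @param norm A `germ_norm`.
#' @param counts The matching [germ_counts].
#' @param labeling A `germ_labeling` from [assign_germline()].
#' @param genes Character vector of gene symbols or ids to summarize.
#' @return A tibble (class `germ_dotplot`): `group`, `gene`, `mean_norm`,
#'   `frac_expressing`.
#' @export
dotplot_stats <- function(norm, counts, labeling, genes) {
  stopifnot(inherits(norm, "germ_norm"), inherits(counts, "germ_counts"))
  idx <- match(genes, norm$genes$symbol)
  idx[is.na(idx)] <- match(genes[is.na(idx)], norm$genes$gene_id)
  if (anyNA(idx)) {
    abort(sprintf("gene(s) not found: %s", paste(genes[is.na(idx)], collapse = ", ")))
  }
  groups <- split(seq_len(ncol(norm$values)), labeling$label)
  if (any(lengths(groups) == 0)) abort("empty group in labeling")
  out <- purrr::imap(groups, function(cols, grp) {
    nv <- norm$values[idx, cols, drop = FALSE]
    cv <- counts$counts[idx, cols, drop = FALSE]
    tibble(group = grp, gene = genes,
           mean_norm = as.numeric(Matrix::rowMeans(nv)),
           frac_expressing = as.numeric(Matrix::rowMeans(cv > 0)))
  })
  out <- bind_rows(out)
  structure(out, class = c("germ_dotplot", class(out)))
}

#' @rdname dotplot_stats
#' @param object A `germ_dotplot`.
#' @param ... Unused.
#' @export
autoplot.germ_dotplot <- function(object, ...) {
  ggplot(object, aes(x = .data$group, y = .data$gene,
                     size = .data$frac_expressing, colour = .data$mean_norm)) +
    geom_point() +
    scale_size_area(max_size = 8, limits = c(0, 1)) +
    labs(x = NULL, y = NULL, size = "Fraction expressing",
         colour = "Mean normalized\nexpression") +
    theme_minimal()
}
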
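#' Write a count object as a 10x-style MatrixMarket triplet
#'
#' Emits `matrix.mtx` (MatrixMarket `coordinate integer general`, 1-based
#' indices, genes as rows), `features.tsv` (gene id, symbol, class,
#' mitochondrial flag) and `barcodes.tsv` (barcode, replicate, analysis) into
#' `directory`. [read_tenx()] on the result reproduces the object exactly.
#'
#' @param x A [germ_counts].
#' @param directory Output directory; created if missing.
#' @return Invisibly, the paths of the three files written.
#' @export
write_tenx <- function(x, directory) {
  stopifnot(inherits(x, "germ_counts"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(directory, "matrix.mtx")
  m <- x$counts
  tm <- methods::as(m, "TsparseMatrix")
  ord <- order(tm@j, tm@i)            # column-major body, conventional for 10x
  body <- sprintf("%d %d %d", tm@i[ord] + 1L, tm@j[ord] + 1L, as.integer(tm@x[ord]))
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             sprintf("%d %d %d", nrow(m), ncol(m), length(tm@x)),
             body)
  tryCatch(writeLines(lines, mtx),
           error = function(e) abort(sprintf("failed to write %s: %s", mtx, conditionMessage(e))))
  feat <- file.path(directory, "features.tsv")
  readr::write_tsv(x$genes[c("gene_id", "symbol", "class", "mito")], feat,
                   col_names = FALSE, progress = FALSE)
  bc <- file.path(directory, "barcodes.tsv")
  readr::write_tsv(x$cells[c("barcode", "replicate", "analysis")], bc,
                   col_names = FALSE, progress = FALSE)
  invisible(c(matrix = mtx, features = feat, barcodes = bc))
}

#' Read a 10x-style MatrixMarket triplet
#'
#' Reads `matrix.mtx` + `features.tsv` + `barcodes.tsv` from a directory and
#' returns a [germ_counts]. The 1-based MatrixMarket coordinates are mapped to
#' the internal sparse representation. `features.tsv` may carry 2-4 columns
#' (id, symbol, class, mito); missing columns are filled with defaults.
#'
#' @param directory Directory holding the three files.
#' @return A [germ_counts].
#' @export
read_tenx <- function(directory) {
  mtx <- file.path(directory, "matrix.mtx")
  feat <- file.path(directory, "features.tsv")
  bc <- file.path(directory, "barcodes.tsv")
  for (f in c(mtx, feat, bc)) {
    if (!file.exists(f)) abort(sprintf("missing file: %s", f))
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- readr::read_tsv(feat, col_names = FALSE, progress = FALSE,
                           show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  cells <- readr::read_tsv(bc, col_names = FALSE, progress = FALSE,
                           show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (nrow(genes) != nrow(m)) {
    abort(sprintf("matrix.mtx declares %d genes but features.tsv has %d lines",
                  nrow(m), nrow(genes)))
  }
  if (nrow(cells) != ncol(m)) {
    abort(sprintf("matrix.mtx declares %d cells but barcodes.tsv has %d lines",
                  ncol(m), nrow(cells)))
  }
  gene_tab <- tibble(
    gene_id = genes[[1]],
    symbol = if (ncol(genes) >= 2) genes[[2]] else genes[[1]],
    class = if (ncol(genes) >= 3) genes[[3]] else "unknown",
    mito = if (ncol(genes) >= 4) as.logical(genes[[4]])
           else grepl("^mt:", genes[[min(2L, ncol(genes))]]))
  cell_tab <- tibble(
    barcode = cells[[1]],
    replicate = if (ncol(cells) >= 2) cells[[2]] else "1",
    analysis = if (ncol(cells) >= 3) cells[[3]] else "1")
  germ_counts(m, gene_tab, cell_tab)
}

#' Write a full simulated study as 10x triplets
#'
#' Lays out one triplet directory per replicate under
#' `<out>/<analysis>/<replicate>/`, the cell and gene truth tables as TSV, and
#' a JSON manifest recording the configuration and derived seeds.
#'
#' @param study Result of [simulate_study()].
#' @param out Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_study <- function(study, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  reps <- study$replicates
  for (i in seq_len(nrow(reps))) {
    d <- file.path(out, reps$analysis[i], reps$replicate[i])
    write_tenx(reps$counts[[i]], d)
    readr::write_tsv(reps$cell_truth[[i]], file.path(d, "cell_truth.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(study$genes, file.path(out, "gene_truth.tsv"), progress = FALSE)
  cfg <- unclass(study$config)
  manifest <- list(
    config = cfg,
    replicate_seeds = with(reps, setNames(
      map2(analysis, replicate, function(a, r) replicate_seed(cfg$seed, a, r)),
      paste(analysis, replicate, sep = "/"))))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(mp)
}
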
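# Small in-code fixtures shared across test files.

# a germ_counts from a dense integer matrix, with optional mito flags
toy_counts <- function(mat, mito = rep(FALSE, nrow(mat)),
                       symbols = sprintf("Gene%d", seq_len(nrow(mat))),
                       class = ifelse(mito, "mitochondrial", "protein_coding")) {
  germ_counts(mat,
              genes = tibble::tibble(gene_id = sprintf("g%03d", seq_len(nrow(mat))),
                                     symbol = symbols, class = class, mito = mito),
              cells = tibble::tibble(barcode = sprintf("c%03d", seq_len(ncol(mat))),
                                     replicate = "1", analysis = "1"))
}

# a germ_norm with given dense values (bypasses normalization, for arithmetic tests)
toy_norm <- function(values, symbols = sprintf("Gene%d", seq_len(nrow(values)))) {
  structure(list(values = Matrix::Matrix(values, sparse = TRUE),
                 genes = tibble::tibble(gene_id = sprintf("g%03d", seq_len(nrow(values))),
                                        symbol = symbols,
                                        class = "protein_coding",
                                        mito = FALSE),
                 cells = tibble::tibble(barcode = sprintf("c%03d", seq_len(ncol(values))),
                                        replicate = "1", analysis = "1"),
                 method = "log_cp10k"),
            class = "germ_norm")
}

# labeling object from an explicit label vector
toy_labeling <- function(labels) {
  germscreen::assign_germline(stats::setNames(numeric(length(labels)),
                                              sprintf("c%03d", seq_along(labels))),
                              labels = labels)
}

# independent brute-force two-sided Wilcoxon p by enumerating group assignments
oracle_wilcoxon_p <- function(x_in, x_out) {
  n1 <- length(x_in); n <- n1 + length(x_out)
  r <- rank(c(x_in, x_out))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu0 <- n1 * (n - n1) / 2
  us <- apply(utils::combn(n, n1), 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu0) >= abs(u_obs - mu0) - 1e-9)
}

# a wild-type germarium record
wt_germarium <- function(line_id = "L1", germarium_id = 1) {
  tibble::tibble(line_id = line_id, germarium_id = germarium_id,
                 underdeveloped_ovary = FALSE, orb_status = "normal",
                 sc_2a = "full_length", sc_region3 = "full_length",
                 polycomplex_present = FALSE, gh2av_2a_present = TRUE,
                 gh2av_region3_foci = 0L)
}
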
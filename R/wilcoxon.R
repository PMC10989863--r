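#' Wilcoxon rank-sum test (tie-corrected, with exact small-sample path)
#'
#' Computes the Mann-Whitney U statistic from midranks of the pooled sample.
#' The two-sided p-value comes from the normal approximation with
#' tie-corrected variance and a continuity correction of 0.5, or — when
#' `n_in * n_out <= 64` and `choose(n_in + n_out, n_in) <= 1e5` — from full
#' enumeration of all group assignments (which handles ties exactly, using the
#' symmetry of the null distribution of U around `n_in * n_out / 2`).
#'
#' @param x_in,x_out Numeric vectors for the two groups (both non-empty).
#' @param method `"auto"` (exact when enumerable), `"exact"`, or `"normal"`.
#' @return A list with `U`, `z` (NA on the exact path), `p` (two-sided) and
#'   `method` used.
#' @export
wilcoxon_rank_sum <- function(x_in, x_out, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  n1 <- length(x_in); n2 <- length(x_out)
  if (n1 < 1 || n2 < 1) abort("both groups must be non-empty")
  pooled <- c(x_in, x_out)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  enumerable <- n1 * n2 <= 64 && choose(n1 + n2, n1) <= 1e5
  use_exact <- method == "exact" || (method == "auto" && enumerable)
  if (method == "exact" && !enumerable) {
    abort("exact enumeration not feasible for these group sizes")
  }
  if (use_exact) {
    p <- exact_u_pvalue(r, n1, n2, U)
    return(list(U = U, z = NA_real_, p = max(p, 1e-300), method = "exact"))
  }
  z <- u_zscore(U, r, n1, n2)
  p <- min(2 * pnorm(-abs(z)), 1)
  list(U = U, z = z, p = max(p, 1e-300), method = "normal")
}

# normal approximation z for U given pooled midranks
u_zscore <- function(U, r, n1, n2) {
  n <- n1 + n2
  tie_lengths <- tabulate(match(r, unique(r)))
  v <- n1 * n2 / 12 * ((n + 1) - sum(tie_lengths^3 - tie_lengths) / (n * (n - 1)))
  mu0 <- n1 * n2 / 2
  if (v <= 0) return(0)
  d <- U - mu0
  (d - sign(d) * 0.5 * (abs(d) >= 0.5)) / sqrt(v)
}

# exact two-sided p by enumerating all C(n, n1) assignments of the observed
# midranks to the "in" group; two-sided tail by symmetry about n1*n2/2
exact_u_pvalue <- function(r, n1, n2, U) {
  n <- n1 + n2
  subsets <- utils::combn(n, n1)
  Us <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
  mu0 <- n1 * n2 / 2
  mean(abs(Us - mu0) >= abs(U - mu0) - 1e-9)
}

#' Bonferroni adjustment
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param m Number of tests (the number of genes tested in the analysis).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni <- function(p, m) {
  if (m < 1) abort("`m` must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  pmin(1, p * m)
}
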
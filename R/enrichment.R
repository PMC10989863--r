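#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for a hypergeometric draw of `n` from a population of `N` with
#' `K` successes: `sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`, computed
#' in log space for stability. Vectorized over `k`.
#'
#' @param k Observed overlap (candidates in the term).
#' @param K Background genes in the term.
#' @param n Candidates tested.
#' @param N Background size.
#' @return The upper-tail probability (1 exactly when `k = 0`).
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (K < 0 || n < 0 || K > N || n > N) abort("inconsistent counts: need 0 <= K, n <= N")
  if (any(k < 0 | k > pmin(K, n))) abort("inconsistent counts: need 0 <= k <= min(K, n)")
  vapply(k, function(kk) {
    if (kk == 0) return(1)
    i <- kk:min(K, n)
    lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    mx <- max(lt)
    min(exp(mx + log(sum(exp(lt - mx)))), 1)
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved. Thin wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' GO over-representation of a candidate list
#'
#' One hypergeometric upper-tail test per annotation term against the
#' expressed-gene background, BH-adjusted. Term gene sets are taken as given
#' (no ontology-graph propagation) and are restricted to the background
#' before testing; terms outside the size bounds are dropped.
#'
#' @param candidates Character vector of candidate gene ids (must be a subset
#'   of `background`).
#' @param background Character vector of background (expressed) gene ids.
#' @param annotation A data frame mapping genes to terms: columns `gene_id`,
#'   `term_id`, and optionally `term_name`. Annotated genes absent from the
#'   background are ignored (their count is reported in the
#'   `n_ignored_annotations` attribute).
#' @param min_term_size,max_term_size Bounds on the in-background term size.
#' @return A tibble (class `germ_enrichment`) sorted by ascending p: `term_id`,
#'   `term_name`, `k`, `n`, `K`, `N`, `p`, `q`, `neg_log10_p`.
#' @export
go_overrepresentation <- function(candidates, background, annotation,
                                  min_term_size = 10, max_term_size = 500) {
  candidates <- unique(candidates)
  background <- unique(background)
  missing <- setdiff(candidates, background)
  if (length(missing)) {
    abort(sprintf("candidate gene(s) not in background: %s%s",
                  paste(head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) ", ..." else ""))
  }
  annotation <- as_tibble(annotation)
  if (!"term_name" %in% names(annotation)) annotation$term_name <- annotation$term_id
  in_bg <- annotation$gene_id %in% background
  n_ignored <- sum(!in_bg)
  annotation <- annotation[in_bg, ]
  terms <- split(annotation$gene_id, annotation$term_id)
  term_names <- annotation$term_name[match(names(terms), annotation$term_id)]
  N <- length(background)
  n <- length(candidates)
  rows <- purrr::map2(terms, term_names, function(gset, nm) {
    gset <- unique(gset)
    K <- length(gset)
    if (K < min_term_size || K > max_term_size) return(NULL)
    k <- length(intersect(gset, candidates))
    tibble(term_name = nm, k = k, n = n, K = K, N = N,
           p = hypergeom_upper(k, K, n, N))
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- bind_rows(rows[keep], .id = NULL)
  if (nrow(out) == 0) {
    out <- tibble(term_id = character(), term_name = character(),
                  k = integer(), n = integer(), K = integer(), N = integer(),
                  p = numeric(), q = numeric(), neg_log10_p = numeric())
    return(structure(out, class = c("germ_enrichment", class(out)),
                     n_ignored_annotations = n_ignored))
  }
  out$term_id <- names(terms)[keep]
  out$q <- bh_adjust(out$p)
  out$neg_log10_p <- -log10(out$p)
  out <- out[order(out$p, out$term_id),
             c("term_id", "term_name", "k", "n", "K", "N", "p", "q", "neg_log10_p")]
  structure(out, class = c("germ_enrichment", class(out)),
            n_ignored_annotations = n_ignored)
}

#' @export
autoplot.germ_enrichment <- function(object, n = 10, ...) {
  d <- head(object, n)
  d$term <- factor(d$term_name, levels = rev(d$term_name))
  ggplot(d, aes(x = .data$neg_log10_p, y = .data$term)) +
    geom_col() +
    labs(x = expression(-log[10](p)), y = NULL) +
    theme_minimal()
}
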
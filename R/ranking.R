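#' Rank significant genes within one analysis
#'
#' Keeps only the genes flagged significant (positively enriched at Bonferroni
#' `p_adj < 0.05`) and ranks them by ascending adjusted p-value, ties getting
#' the average rank. A companion lnFC rank (1 = largest lnFC, descending,
#' average for ties) over the same gene set is carried along for the
#' aggregate tie-break.
#'
#' @param de A `germ_de` from [de_table()].
#' @return A tibble (class `germ_ranks`): `analysis`, `gene_id`, `p_rank`,
#'   `lnfc`, `lnfc_rank`.
#' @export
rank_within_analysis <- function(de) {
  sig <- de[de$significant, ]
  if (nrow(sig) == 0) {
    abort(sprintf("no significant genes in analysis %s", de$analysis[1]))
  }
  out <- tibble(analysis = sig$analysis,
                gene_id = sig$gene_id,
                p_rank = rank(sig$p_adj, ties.method = "average"),
                lnfc = sig$lnfc,
                lnfc_rank = rank(-sig$lnfc, ties.method = "average"))
  structure(out, class = c("germ_ranks", class(out)))
}

#' Intersect the significant gene sets of several analyses
#'
#' Only genes significant in every analysis survive; disjoint sets produce a
#' warning and an empty result rather than an error.
#'
#' @param ranks_list List of `germ_ranks`.
#' @return Character vector of gene ids.
#' @export
intersect_analyses <- function(ranks_list) {
  stopifnot(length(ranks_list) >= 1)
  out <- reduce(map(ranks_list, function(r) unique(r$gene_id)), intersect)
  if (length(out) == 0) warn("no gene is significant in all analyses")
  out
}

#' Aggregate per-analysis ranks into one ordered candidate list
#'
#' Orders the cross-analysis intersection by ascending mean p-value rank.
#' Genes tied on mean rank are ordered by ascending mean lnFC rank (lnFC rank
#' 1 = largest lnFC within its analysis); remaining ties break alphabetically
#' by gene id, making the ordering total and deterministic.
#'
#' @param ranks_list List of `germ_ranks`, one per analysis.
#' @param genes Optional gene set to aggregate; defaults to
#'   [intersect_analyses()] of the list.
#' @return A tibble (class `germ_ranking`): `gene_id`, one `rank_<analysis>`
#'   column per analysis, `mean_rank`, `mean_lnfc_rank`, `position`.
#' @export
aggregate_rank <- function(ranks_list, genes = NULL) {
  if (is.null(genes)) genes <- intersect_analyses(ranks_list)
  if (length(genes) == 0) {
    out <- tibble(gene_id = character(), mean_rank = numeric(),
                  mean_lnfc_rank = numeric(), position = integer())
    return(structure(out, class = c("germ_ranking", class(out))))
  }
  per <- map(ranks_list, function(r) {
    i <- match(genes, r$gene_id)
    if (anyNA(i)) {
      abort(sprintf("gene(s) in the intersection missing from analysis %s: %s",
                    r$analysis[1], paste(genes[is.na(i)][1:min(3, sum(is.na(i)))],
                                         collapse = ", ")))
    }
    tibble(analysis = r$analysis[1], gene_id = genes,
           p_rank = r$p_rank[i], lnfc_rank = r$lnfc_rank[i])
  })
  wide <- bind_rows(per) |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "analysis",
                       values_from = "p_rank", names_prefix = "rank_")
  agg <- bind_rows(per) |>
    group_by(.data$gene_id) |>
    summarise(mean_rank = mean(.data$p_rank),
              mean_lnfc_rank = mean(.data$lnfc_rank), .groups = "drop")
  out <- left_join(wide, agg, by = "gene_id") |>
    arrange(.data$mean_rank, .data$mean_lnfc_rank, .data$gene_id) |>
    mutate(position = row_number())
  structure(out, class = c("germ_ranking", class(out)))
}

#' Flag genes of untestable or ubiquitous classes
#'
#' Applies the cull rules (first match wins) to each ranked gene, using the
#' gene table's class label when a rule targets a class and the symbol
#' otherwise. Flagged genes keep their row — with the matching rule recorded
#' in `cull_reason` — so the full ranked audit trail survives; they are
#' dropped by [top_candidates()].
#'
#' @param ranking A `germ_ranking`.
#' @param gene_table Gene table with `gene_id`, `symbol`, `class`.
#' @param rules A rules tibble from [default_cull_rules()] or
#'   [read_cull_rules()].
#' @return The ranking with `symbol`, `class` and `cull_reason` columns
#'   (`NA` = retained).
#' @export
cull_genes <- function(ranking, gene_table, rules = default_cull_rules()) {
  stopifnot(all(c("gene_id", "symbol", "class") %in% names(gene_table)))
  out <- left_join(ranking, gene_table[c("gene_id", "symbol", "class")],
                   by = "gene_id")
  reason <- rep(NA_character_, nrow(out))
  for (i in seq_len(nrow(rules))) {
    field <- if (rules$target[i] == "class") out$class else out$symbol
    hit <- is.na(reason) & grepl(rules$pattern[i], field)
    reason[hit] <- rules$rule[i]
  }
  out$cull_reason <- reason
  out <- as_tibble(out)
  structure(out, class = c("germ_ranking", class(out)))
}

#' Default cull rules
#'
#' The gene classes removed before top-N selection because they cannot be
#' targeted by the RNAi screen (mitochondrial genes, CR-designated
#' pseudogenes, non-coding RNA classes) or are ubiquitously expressed
#' (ribosomal structural proteins). First match wins; order is fixed.
#'
#' @return A tibble with columns `rule`, `target` (`"class"` or `"symbol"`)
#'   and `pattern` (a regular expression).
#' @export
default_cull_rules <- function() {
  tibble(
    rule = c("mitochondrial", "mitochondrial_symbol", "CR_designation",
             "asRNA", "hpRNA", "snRNA", "snRNP", "snmRNA", "snoRNA",
             "lncRNA", "sisRNA", "pre_rRNA", "ribosomal_structural",
             "ribosomal_symbol"),
    target = c("class", "symbol", "symbol",
               "class", "class", "class", "class", "class", "class",
               "class", "class", "class", "class", "symbol"),
    pattern = c("^mitochondrial$", "^mt:", "^CR[0-9]+$",
                "^asRNA$", "^hpRNA$", "^snRNA$", "^snRNP$", "^snmRNA$",
                "^snoRNA$", "^lncRNA$", "^sisRNA$", "^pre_rRNA$",
                "^ribosomal_protein$", "^Rp[LS][0-9]"))
}

#' Read cull rules from a YAML file
#'
#' The file format is a list of `{rule, target, pattern}` entries, as shipped
#' in `system.file("extdata", "cull_rules.yaml", package = "germscreen")`.
#'
#' @param path Path to the YAML file.
#' @return A rules tibble as in [default_cull_rules()].
#' @export
read_cull_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  bind_rows(lapply(raw, as_tibble))
}

#' Select the top-N candidate genes
#'
#' Drops culled genes, takes the first `n` of the remaining ordered list and
#' renumbers positions 1..n.
#'
#' @param ranking A culled `germ_ranking`.
#' @param n Number of candidates (default 500).
#' @return A tibble of the candidates with `position` 1..n.
#' @export
top_candidates <- function(ranking, n = 500) {
  kept <- if ("cull_reason" %in% names(ranking)) {
    ranking[is.na(ranking$cull_reason), ]
  } else ranking
  out <- head(kept, n)
  out$position <- seq_len(nrow(out))
  out
}

#' @export
tidy.germ_ranking <- function(x, ...) as_tibble(x)

#' @export
glance.germ_ranking <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_culled = if ("cull_reason" %in% names(x)) sum(!is.na(x$cull_reason)) else 0L,
         n_analyses = sum(grepl("^rank_", names(x))))
}

#' @export
autoplot.germ_ranking <- function(object, n = 30, ...) {
  d <- head(object, n)
  lab <- if ("symbol" %in% names(d)) d$symbol else d$gene_id
  d$label <- factor(lab, levels = rev(lab))
  ggplot(d, aes(x = .data$mean_rank, y = .data$label)) +
    geom_point() +
    labs(x = "Mean rank across analyses", y = NULL) +
    theme_minimal()
}
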
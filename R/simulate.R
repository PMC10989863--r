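#' Configuration of the synthetic ovary-transcriptome study
#'
#' Defines the study layout (analyses, replicates, cells) and the statistical
#' structure of the simulated counts: two cell populations (a minority
#' germline and a majority soma), four abundant marker genes strongly elevated
#' in germline cells, a configurable set of truly germline-enriched genes with
#' known natural-log fold-changes, mitochondrial genes, genes carrying
#' cull-class labels, and negative-binomial noise with
#' `Var = mu + mu^2 / nb_dispersion`.
#'
#' @param n_analyses Number of independent analyses (datasets).
#' @param replicates_per_analysis Replicates simulated per analysis.
#' @param cells_per_replicate Cells per replicate.
#' @param germline_fraction Proportion of germline cells, in the open
#'   interval (0, 1). The germline cell count per replicate is
#'   `floor(germline_fraction * cells_per_replicate)`.
#' @param n_genes Total number of genes.
#' @param marker_gene_ids Symbols of the 4 marker genes.
#' @param n_enriched Number of truly germline-enriched non-marker genes.
#' @param lnfc_low,lnfc_high Bounds of the uniform natural-log fold-change of
#'   enriched genes. Marker genes are simulated as the strongest enriched
#'   genes, with lnFC fixed at `lnfc_high`. When `n_enriched = 0` the
#'   simulation is a global null and the markers are not enriched either.
#' @param base_mean_low,base_mean_high Bounds of the uniform per-gene baseline
#'   negative-binomial mean.
#' @param marker_base_mean Baseline mean of the 4 marker genes. Markers are
#'   modeled at vasa-class abundance, far above the typical gene, so that the
#'   per-cell marker score carries the information it carries in real data.
#' @param nb_dispersion Negative-binomial size parameter theta
#'   (`Var = mu + mu^2 / theta`).
#' @param n_mito_genes Number of mitochondrial genes.
#' @param mito_mean Negative-binomial mean of mitochondrial genes (both
#'   lineages).
#' @param cull_class_fraction Fraction of plain background genes tagged with a
#'   cull-class label (CR-designated, ribosomal-protein, non-coding RNA
#'   classes) to exercise the culling stage.
#' @param seed Integer seed; gene-level parameters derive from it directly and
#'   per-replicate draws from a stable hash of (seed, analysis, replicate).
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_analyses = 4,
                       replicates_per_analysis = 3,
                       cells_per_replicate = 800,
                       germline_fraction = 0.25,
                       n_genes = 3000,
                       marker_gene_ids = c("vas", "c(3)G", "cona", "corolla"),
                       n_enriched = 150,
                       lnfc_low = log(2),
                       lnfc_high = log(4),
                       base_mean_low = 0.1,
                       base_mean_high = 2,
                       marker_base_mean = 20,
                       nb_dispersion = 2,
                       n_mito_genes = 10,
                       mito_mean = 5,
                       cull_class_fraction = 0.05,
                       seed = 1L) {
  cfg <- list(n_analyses = n_analyses,
              replicates_per_analysis = replicates_per_analysis,
              cells_per_replicate = cells_per_replicate,
              germline_fraction = germline_fraction,
              n_genes = n_genes,
              marker_gene_ids = marker_gene_ids,
              n_enriched = n_enriched,
              lnfc_low = lnfc_low, lnfc_high = lnfc_high,
              base_mean_low = base_mean_low, base_mean_high = base_mean_high,
              marker_base_mean = marker_base_mean,
              nb_dispersion = nb_dispersion,
              n_mito_genes = n_mito_genes, mito_mean = mito_mean,
              cull_class_fraction = cull_class_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min || v != round(v)) {
      abort(sprintf("invalid configuration: `%s` must be an integer >= %d", field, min))
    }
  }
  chk_count("n_analyses"); chk_count("replicates_per_analysis")
  chk_count("cells_per_replicate"); chk_count("n_genes")
  chk_count("n_enriched", 0); chk_count("n_mito_genes", 0)
  gf <- cfg$germline_fraction
  if (!is.numeric(gf) || length(gf) != 1 || is.na(gf) || gf <= 0 || gf >= 1) {
    abort("invalid configuration: `germline_fraction` must lie in (0, 1)")
  }
  if (length(cfg$marker_gene_ids) != 4 || anyDuplicated(cfg$marker_gene_ids)) {
    abort("invalid configuration: `marker_gene_ids` must be 4 distinct ids")
  }
  for (field in c("base_mean_low", "base_mean_high", "marker_base_mean",
                  "nb_dispersion", "mito_mean")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      abort(sprintf("invalid configuration: `%s` must be positive", field))
    }
  }
  if (cfg$lnfc_low > cfg$lnfc_high) {
    abort("invalid configuration: `lnfc_low` must not exceed `lnfc_high`")
  }
  if (cfg$lnfc_low < 0) {
    abort("invalid configuration: `lnfc_low` must be non-negative")
  }
  if (cfg$base_mean_low > cfg$base_mean_high) {
    abort("invalid configuration: `base_mean_low` must not exceed `base_mean_high`")
  }
  if (cfg$cull_class_fraction < 0 || cfg$cull_class_fraction > 1) {
    abort("invalid configuration: `cull_class_fraction` must lie in [0, 1]")
  }
  if (cfg$n_enriched + 4 + cfg$n_mito_genes > cfg$n_genes) {
    abort("invalid configuration: `n_genes` must cover markers, enriched and mito genes")
  }
  invisible(cfg)
}

# Stable polynomial string hash; keeps derived seeds within 32-bit range.
stable_hash <- function(...) {
  s <- paste(..., sep = "|")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 1000003
  h
}

replicate_seed <- function(seed, analysis_id, replicate_id) {
  as.integer(((seed %% 100000) * 10007 + stable_hash(analysis_id, replicate_id)) %%
               2147483647)
}

#' Gene-level ground truth of a simulation configuration
#'
#' Gene identities, baseline means, enrichment flags and true lnFC are a
#' deterministic function of the configuration (and its seed) alone, so every
#' replicate of every analysis shares the same gene table.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per gene: `gene_id`, `symbol`, `class`,
#'   `mito`, `marker`, `enriched`, `culled_class`, `base_mean`, `lnfc`.
#' @export
gene_truth <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  out <- local_seed_eval(config$seed, {
    base_mean <- runif(n, config$base_mean_low, config$base_mean_high)
    gene_id <- sprintf("SG%06d", seq_len(n))
    symbol <- sprintf("CG2%05d", seq_len(n))
    class <- rep("protein_coding", n)
    mito <- rep(FALSE, n)
    lnfc <- numeric(n)
    marker <- enriched <- culled <- rep(FALSE, n)

    marker_idx <- 1:4
    symbol[marker_idx] <- config$marker_gene_ids
    marker[marker_idx] <- TRUE
    base_mean[marker_idx] <- config$marker_base_mean

    mito_idx <- integer(0)
    if (config$n_mito_genes > 0) {
      mito_idx <- 4 + seq_len(config$n_mito_genes)
      symbol[mito_idx] <- sprintf("mt:Mito%d", seq_along(mito_idx))
      class[mito_idx] <- "mitochondrial"
      mito[mito_idx] <- TRUE
      base_mean[mito_idx] <- config$mito_mean
      culled[mito_idx] <- TRUE
    }

    pool <- setdiff(seq_len(n), c(marker_idx, mito_idx))
    enr_idx <- integer(0)
    if (config$n_enriched > 0) {
      enr_idx <- sort(sample(pool, config$n_enriched))
      enriched[enr_idx] <- TRUE
      lnfc[enr_idx] <- runif(config$n_enriched, config$lnfc_low, config$lnfc_high)
      marker_lnfc <- config$lnfc_high
    } else {
      marker_lnfc <- 0
    }
    lnfc[marker_idx] <- marker_lnfc

    # tag a fraction of the remaining background genes with cull classes
    bg <- setdiff(pool, enr_idx)
    n_cull <- floor(config$cull_class_fraction * length(bg))
    if (n_cull > 0) {
      cull_idx <- sort(sample(bg, n_cull))
      cls <- rep(c("pseudogene", "ribosomal_protein", "lncRNA", "snoRNA",
                   "asRNA", "snRNA"), length.out = n_cull)
      class[cull_idx] <- cls
      symbol[cull_idx] <- ifelse(
        cls == "pseudogene", sprintf("CR4%04d", seq_len(n_cull)),
        ifelse(cls == "ribosomal_protein", sprintf("RpL%d", seq_len(n_cull)),
               symbol[cull_idx]))
      culled[cull_idx] <- TRUE
    }
    tibble(gene_id = gene_id, symbol = symbol, class = class, mito = mito,
           marker = marker, enriched = enriched, culled_class = culled,
           base_mean = base_mean, lnfc = lnfc)
  })
  out
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed_eval <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one replicate of single-cell counts
#'
#' Draws a gene-by-cell negative-binomial count matrix for one replicate.
#' Germline cells (the first `floor(germline_fraction * cells)` columns) use
#' mean `base_mean * exp(lnfc)` for enriched and marker genes; soma cells use
#' the baseline means everywhere. Deterministic given
#' (config seed, analysis id, replicate id).
#'
#' @param config A [sim_config()].
#' @param analysis_id,replicate_id Identifiers of the analysis and replicate.
#' @return A list with elements `counts` (a [germ_counts]) and `truth` (a
#'   tibble of per-cell `barcode` and `lineage`, `"germline"` or `"soma"`).
#' @export
simulate_replicate <- function(config, analysis_id = 1L, replicate_id = 1L) {
  validate_sim_config(config)
  genes <- gene_truth(config)
  n_cells <- config$cells_per_replicate
  n_germ <- floor(config$germline_fraction * n_cells)
  lineage <- c(rep("germline", n_germ), rep("soma", n_cells - n_germ))
  mat <- local_seed_eval(replicate_seed(config$seed, analysis_id, replicate_id), {
    mu <- matrix(genes$base_mean, config$n_genes, n_cells)
    bump <- genes$lnfc > 0
    if (n_germ > 0 && any(bump)) {
      mu[bump, seq_len(n_germ)] <- genes$base_mean[bump] * exp(genes$lnfc[bump])
    }
    matrix(rnbinom(length(mu), size = config$nb_dispersion, mu = mu),
           config$n_genes, n_cells)
  })
  barcode <- sprintf("A%s-R%s-C%04d", analysis_id, replicate_id, seq_len(n_cells))
  cells <- tibble(barcode = barcode,
                  replicate = as.character(replicate_id),
                  analysis = as.character(analysis_id))
  list(counts = germ_counts(mat, genes[c("gene_id", "symbol", "class", "mito")], cells),
       truth = tibble(barcode = barcode, lineage = lineage))
}

#' Simulate the full multi-analysis study
#'
#' Runs [simulate_replicate()] for every (analysis, replicate) pair of the
#' configuration.
#'
#' @param config A [sim_config()].
#' @return A list with `replicates` (a tibble with columns `analysis`,
#'   `replicate`, and list-columns `counts` and `cell_truth`), `genes`
#'   (the [gene_truth()] table) and `config`.
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  grid <- tidyr::expand_grid(analysis = as.character(seq_len(config$n_analyses)),
                             replicate = as.character(seq_len(config$replicates_per_analysis)))
  sims <- map2(grid$analysis, grid$replicate,
               function(a, r) simulate_replicate(config, a, r))
  grid$counts <- map(sims, "counts")
  grid$cell_truth <- map(sims, "truth")
  list(replicates = grid, genes = gene_truth(config), config = config)
}
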
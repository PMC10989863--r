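#' Pipeline configuration
#'
#' One object holding every stage's options: the simulation (or an input
#' directory of 10x triplets laid out `<dir>/<analysis>/<replicate>/`), QC,
#' marker genes, top-N size, cull rules and optional enrichment annotation.
#'
#' @param sim A [sim_config()] used when `input_dir` is `NULL`.
#' @param input_dir Optional directory of existing triplet data.
#' @param markers Marker gene symbols used for labeling.
#' @param qc_n_mads,qc_max_mito MAD multiplier and mitochondrial ceiling for
#'   the per-replicate automatic QC rule.
#' @param qc_thresholds Optional named list mapping `"analysis/replicate"` to
#'   a [qc_thresholds()], overriding the automatic rule for those replicates.
#' @param n_top Candidate list size (default 500).
#' @param cull_rules A rules tibble ([default_cull_rules()]).
#' @param annotation Optional gene-to-term annotation data frame; when given,
#'   the enrichment stage runs.
#' @param min_term_size,max_term_size Term-size bounds for enrichment.
#' @param out_dir Optional directory; when given, stage outputs and a JSON run
#'   manifest are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            input_dir = NULL,
                            markers = sim$marker_gene_ids,
                            qc_n_mads = 3, qc_max_mito = 0.2,
                            qc_thresholds = NULL,
                            n_top = 500,
                            cull_rules = default_cull_rules(),
                            annotation = NULL,
                            min_term_size = 10, max_term_size = 500,
                            out_dir = NULL) {
  if (n_top < 0) abort("`n_top` must be >= 0")
  structure(list(sim = sim, input_dir = input_dir, markers = markers,
                 qc_n_mads = qc_n_mads, qc_max_mito = qc_max_mito,
                 qc_thresholds = qc_thresholds,
                 n_top = n_top, cull_rules = cull_rules,
                 annotation = annotation,
                 min_term_size = min_term_size, max_term_size = max_term_size,
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
  })
}

#' Run the whole prioritization pipeline
#'
#' Executes simulate (or read) -> per-replicate QC -> per-analysis pooling,
#' normalization and marker labeling -> per-analysis differential expression
#' -> cross-analysis intersection and mean-rank aggregation -> culling and
#' top-N selection -> optional GO over-representation, and assembles a run
#' manifest. Deterministic given the configuration (and its seed).
#'
#' @param config A [pipeline_config()].
#' @return A list (class `germ_run`) with elements `qc_report`, `labelings`,
#'   `de` (one `germ_de` per analysis), `ranking` (culled `germ_ranking`),
#'   `candidates`, `enrichment` (or `NULL`), `truth` (simulation only) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  replicates <- stage("input", {
    if (is.null(config$input_dir)) {
      study <- simulate_study(config$sim)
      study$replicates
    } else {
      dirs <- list.dirs(config$input_dir, recursive = TRUE, full.names = TRUE)
      dirs <- dirs[file.exists(file.path(dirs, "matrix.mtx"))]
      if (!length(dirs)) abort(sprintf("no triplet directories under %s", config$input_dir))
      tibble(analysis = basename(dirname(dirs)), replicate = basename(dirs),
             counts = map(dirs, read_tenx), cell_truth = list(NULL))
    }
  })

  qc_out <- stage("qc", {
    purrr::pmap(replicates, function(analysis, replicate, counts, cell_truth) {
      key <- paste(analysis, replicate, sep = "/")
      thr <- config$qc_thresholds[[key]] %||%
        auto_qc_thresholds(counts, config$qc_n_mads, config$qc_max_mito)
      qc_filter(counts, thr)
    })
  })
  qc_report <- bind_rows(map(qc_out, attr, "qc_report"))

  analyses <- unique(replicates$analysis)
  pooled <- stage("pool", {
    setNames(map(analyses, function(a) pool_counts(qc_out[replicates$analysis == a])),
             analyses)
  })

  norms <- stage("normalize", map(pooled, normalize_cp10k))

  labelings <- stage("label", {
    map(norms, function(nm) assign_germline(marker_score(nm, config$markers)))
  })

  de <- stage("de", {
    purrr::imap(norms, function(nm, a) de_table(nm, labelings[[a]], analysis = a))
  })

  ranking <- stage("rank", {
    ranks <- map(de, rank_within_analysis)
    agg <- aggregate_rank(ranks)
    cull_genes(agg, pooled[[1]]$genes, config$cull_rules)
  })
  candidates <- stage("top_n", top_candidates(ranking, config$n_top))

  enrichment <- NULL
  if (!is.null(config$annotation)) {
    enrichment <- stage("enrich", {
      expressed <- pooled[[1]]$genes$gene_id[
        Matrix::rowSums(do.call(cbind, map(pooled, function(p) p$counts))) > 0]
      go_overrepresentation(intersect(candidates$gene_id, expressed), expressed,
                            config$annotation,
                            config$min_term_size, config$max_term_size)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("germscreen")),
    seed = if (is.null(config$input_dir)) config$sim$seed else NA,
    n_analyses = length(analyses),
    de_tables = map_int(de, nrow),
    n_significant = map_int(de, function(d) sum(d$significant)),
    n_intersection = nrow(ranking),
    n_culled = sum(!is.na(ranking$cull_reason)),
    n_candidates = nrow(candidates))

  run <- structure(list(config = config, qc_report = qc_report,
                        labelings = labelings, de = de, ranking = ranking,
                        candidates = candidates, enrichment = enrichment,
                        truth = if (is.null(config$input_dir))
                          list(genes = gene_truth(config$sim),
                               cells = setNames(replicates$cell_truth,
                                                paste(replicates$analysis,
                                                      replicates$replicate, sep = "/")))
                        else NULL,
                        manifest = manifest),
                   class = "germ_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$qc_report, file.path(out_dir, "qc_report.tsv"), progress = FALSE)
  for (a in names(run$de)) {
    readr::write_tsv(run$de[[a]], file.path(out_dir, sprintf("de_%s.tsv", a)),
                     progress = FALSE)
  }
  readr::write_tsv(run$ranking, file.path(out_dir, "ranking.tsv"), progress = FALSE)
  readr::write_tsv(run$candidates, file.path(out_dir, "candidates.tsv"), progress = FALSE)
  if (!is.null(run$enrichment)) {
    readr::write_tsv(run$enrichment, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.germ_run <- function(x, ...) {
  cat("<germ_run>\n")
  cat(sprintf("  analyses: %d | DE genes per analysis: %s\n",
              x$manifest$n_analyses,
              paste(x$manifest$de_tables, collapse = ", ")))
  cat(sprintf("  significant per analysis: %s\n",
              paste(x$manifest$n_significant, collapse = ", ")))
  cat(sprintf("  intersection: %d genes (%d culled) -> %d candidates\n",
              x$manifest$n_intersection, x$manifest$n_culled,
              x$manifest$n_candidates))
  invisible(x)
}

#' @export
glance.germ_run <- function(x, ...) {
  tibble(n_analyses = x$manifest$n_analyses,
         n_intersection = x$manifest$n_intersection,
         n_culled = x$manifest$n_culled,
         n_candidates = x$manifest$n_candidates)
}
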
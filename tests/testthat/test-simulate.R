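test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(germline_fraction = 0), "germline_fraction")
  expect_error(sim_config(germline_fraction = 1), "germline_fraction")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(n_genes = 10, n_enriched = 20), "n_genes")
  expect_error(sim_config(lnfc_low = 1, lnfc_high = 0.5), "lnfc_low")
  expect_error(sim_config(marker_gene_ids = c("a", "b")), "marker_gene_ids")
})

test_that("germline cell count is floor(fraction * cells)", {
  cfg <- sim_config(cells_per_replicate = 800, germline_fraction = 0.25,
                    n_genes = 50, n_enriched = 5, n_mito_genes = 2)
  sim <- simulate_replicate(cfg, 1, 1)
  expect_identical(sum(sim$truth$lineage == "germline"), 200L)
  expect_identical(nrow(sim$truth), 800L)
  # truth labels partition the cells
  expect_setequal(unique(sim$truth$lineage), c("germline", "soma"))

  cfg2 <- sim_config(cells_per_replicate = 7, germline_fraction = 0.5,
                     n_genes = 50, n_enriched = 5)
  expect_identical(sum(simulate_replicate(cfg2)$truth$lineage == "germline"), 3L)
})

test_that("counts are non-negative integers and reproducible under the seed", {
  cfg <- sim_config(cells_per_replicate = 60, n_genes = 80, n_enriched = 10,
                    seed = 42)
  a <- simulate_replicate(cfg, "1", "2")
  b <- simulate_replicate(cfg, "1", "2")
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_true(all(a$counts$counts@x >= 0))
  expect_true(all(a$counts$counts@x == round(a$counts$counts@x)))
  # different replicate id, different draw; same gene table
  c <- simulate_replicate(cfg, "1", "3")
  expect_false(identical(as.matrix(a$counts$counts), as.matrix(c$counts$counts)))
  expect_identical(a$counts$genes, c$counts$genes)
})

test_that("gene-level truth is shared across replicates and marks 4 markers", {
  cfg <- sim_config(n_genes = 100, n_enriched = 10, cells_per_replicate = 20)
  tr <- gene_truth(cfg)
  expect_identical(sum(tr$marker), 4L)
  expect_identical(sum(tr$enriched), 10L)
  expect_true(all(tr$lnfc[tr$enriched] > 0))
  expect_true(all(tr$lnfc[!tr$enriched & !tr$marker] == 0))
  expect_identical(tr, gene_truth(cfg))
})

test_that("a null simulation shows no germline/soma separation", {
  cfg <- sim_config(n_analyses = 1, replicates_per_analysis = 1,
                    cells_per_replicate = 2000, germline_fraction = 0.25,
                    n_genes = 300, n_enriched = 0, n_mito_genes = 0, seed = 3)
  sim <- simulate_replicate(cfg)
  m <- as.matrix(sim$counts$counts)
  germ <- sim$truth$lineage == "germline"
  n1 <- sum(germ); n2 <- sum(!germ)
  diff_se <- abs(rowMeans(m[, germ]) - rowMeans(m[, !germ])) /
    sqrt(apply(m[, germ], 1, var) / n1 + apply(m[, !germ], 1, var) / n2)
  expect_gte(mean(diff_se < 4), 0.99)
})

test_that("the Poisson limit of the dispersion recovers Var = mu", {
  # theta = 1e6 makes the NB practically Poisson; for mu = 5 and 999 cells the
  # central 99.9% chi-square interval for the sample variance is well inside
  # [4.0, 6.0]: 5 * qchisq(c(5e-4, 1 - 5e-4), 998) / 998 = [4.29, 5.76]
  cfg <- sim_config(n_analyses = 1, replicates_per_analysis = 1,
                    cells_per_replicate = 1000, germline_fraction = 0.001,
                    n_genes = 20, n_enriched = 0, n_mito_genes = 0,
                    base_mean_low = 5, base_mean_high = 5,
                    nb_dispersion = 1e6, seed = 11)
  sim <- simulate_replicate(cfg)
  soma <- sim$truth$lineage == "soma"
  x <- as.numeric(sim$counts$counts[10, soma])
  expect_gte(var(x), 4.0)
  expect_lte(var(x), 6.0)
})

test_that("soma sample means recover the configured base means", {
  cfg <- sim_config(n_analyses = 1, replicates_per_analysis = 1,
                    cells_per_replicate = 5000, germline_fraction = 0.2,
                    n_genes = 30, n_enriched = 0, n_mito_genes = 0,
                    base_mean_low = 1, base_mean_high = 3, seed = 5)
  sim <- simulate_replicate(cfg)
  tr <- gene_truth(cfg)
  soma <- sim$truth$lineage == "soma"
  keep <- which(!tr$marker & tr$base_mean >= 1)[1:20]
  obs <- Matrix::rowMeans(sim$counts$counts[keep, soma])
  expect_true(all(abs(obs - tr$base_mean[keep]) / tr$base_mean[keep] < 0.05))
})

test_that("a fraction of background genes carries cull-class labels", {
  cfg <- sim_config(n_genes = 400, n_enriched = 20, cells_per_replicate = 20,
                    cull_class_fraction = 0.1)
  tr <- gene_truth(cfg)
  expect_gt(sum(tr$culled_class), 0)
  # enriched genes and markers are never cull-class
  expect_false(any(tr$culled_class & (tr$enriched | tr$marker)))
  # mito genes always are
  expect_true(all(tr$culled_class[tr$mito]))
})
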
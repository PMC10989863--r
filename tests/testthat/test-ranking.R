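# minimal DE-like table for ranking tests
fake_de <- function(analysis, gene_id, p_adj, lnfc, significant = rep(TRUE, length(gene_id))) {
  tibble::tibble(analysis = analysis, gene_id = gene_id, p_adj = p_adj,
                 lnfc = lnfc, significant = significant)
}

test_that("within-analysis ranks follow ascending adjusted p with average ties", {
  de <- fake_de("a", c("g1", "g2", "g3"), c(0.01, 0.001, 0.04), c(1, 2, 3))
  r <- rank_within_analysis(de)
  expect_equal(r$p_rank, c(2, 1, 3))
  de2 <- fake_de("a", c("g1", "g2", "g3"), c(0.01, 0.01, 0.04), c(1, 2, 3))
  expect_equal(rank_within_analysis(de2)$p_rank, c(1.5, 1.5, 3))
  de3 <- fake_de("a", "solo", 0.01, 1)
  expect_equal(rank_within_analysis(de3)$p_rank, 1)
  # lnFC rank is descending: largest lnFC gets rank 1
  expect_equal(rank_within_analysis(de)$lnfc_rank, c(3, 2, 1))
  # only significant genes are ranked
  de4 <- fake_de("a", c("g1", "g2"), c(0.01, 0.2), c(1, 1), c(TRUE, FALSE))
  expect_identical(rank_within_analysis(de4)$gene_id, "g1")
  expect_error(rank_within_analysis(fake_de("a4", "g", 0.5, 1, FALSE)), "a4")
})

test_that("the intersection keeps genes significant in every analysis", {
  rl <- list(rank_within_analysis(fake_de("1", c("A", "B", "C"), c(.01, .02, .03), 1:3)),
             rank_within_analysis(fake_de("2", c("B", "C"), c(.01, .02), 1:2)),
             rank_within_analysis(fake_de("3", c("B", "C", "D"), c(.01, .02, .03), 1:3)))
  expect_setequal(intersect_analyses(rl), c("B", "C"))
  expect_setequal(intersect_analyses(rl[1]), c("A", "B", "C"))
  disjoint <- list(rank_within_analysis(fake_de("1", "A", .01, 1)),
                   rank_within_analysis(fake_de("2", "B", .01, 1)))
  expect_warning(out <- intersect_analyses(disjoint), "no gene")
  expect_length(out, 0)
})

test_that("mean-rank ties break by mean lnFC rank, then alphabetically", {
  # A ranks (2,2), B ranks (1,3): both mean 2; A's lnFC always larger
  rl <- list(
    rank_within_analysis(fake_de("1", c("A", "B", "C"), c(.02, .01, .03), c(1.5, 0.5, 0.1))),
    rank_within_analysis(fake_de("2", c("A", "B", "C"), c(.02, .03, .01), c(1.5, 0.5, 0.1))))
  agg <- aggregate_rank(rl)
  expect_identical(agg$gene_id[1:2], c("A", "B"))
  expect_equal(agg$mean_rank[1:2], c(2, 2))
  expect_equal(agg$mean_lnfc_rank[1:2], c(1, 2))
  # gene id breaks full ties deterministically
  rl2 <- list(rank_within_analysis(fake_de("1", c("zz", "aa"), c(.01, .01), c(1, 1))))
  expect_identical(aggregate_rank(rl2)$gene_id, c("aa", "zz"))
})

test_that("aggregate order matches a brute-force mean-rank computation", {
  set.seed(5)
  genes <- sprintf("g%02d", 1:12)
  des <- lapply(1:3, function(a) {
    fake_de(as.character(a), genes, round(runif(12), 3), round(runif(12), 3))
  })
  rl <- lapply(des, rank_within_analysis)
  agg <- aggregate_rank(rl)
  # oracle: explicit per-analysis ranks, averaged
  mr <- rowMeans(sapply(des, function(d) rank(d$p_adj)))
  mfr <- rowMeans(sapply(des, function(d) rank(-d$lnfc)))
  oracle <- genes[order(mr, mfr, genes)]
  expect_identical(agg$gene_id, oracle)
  # single analysis: aggregate order equals the analysis's own order
  one <- aggregate_rank(rl[1])
  expect_identical(one$gene_id, rl[[1]]$gene_id[order(rl[[1]]$p_rank,
                                                      rl[[1]]$lnfc_rank,
                                                      rl[[1]]$gene_id)])
})

test_that("aggregation is invariant to the order of analyses", {
  set.seed(6)
  genes <- sprintf("g%02d", 1:10)
  rl <- lapply(1:4, function(a) {
    rank_within_analysis(fake_de(as.character(a), genes,
                                 round(runif(10), 2), round(runif(10), 2)))
  })
  a1 <- aggregate_rank(rl)
  a2 <- aggregate_rank(rev(rl))
  expect_identical(a1$gene_id, a2$gene_id)
  expect_equal(a1$mean_rank, a2$mean_rank)
})

test_that("an intersection gene missing from one analysis is an internal error", {
  rl <- list(rank_within_analysis(fake_de("1", c("A", "B"), c(.01, .02), 1:2)),
             rank_within_analysis(fake_de("2", "A", .01, 1)))
  expect_error(aggregate_rank(rl, genes = c("A", "B")), "missing from analysis 2")
})

test_that("cull rules flag untestable and ribosomal genes, first match wins", {
  ranking <- aggregate_rank(list(rank_within_analysis(
    fake_de("1", sprintf("g%d", 1:5), seq(.01, .05, .01), 5:1))))
  gene_table <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5),
    symbol = c("CR43242", "mt:CoI", "RpL3", "CG8142", "vas"),
    class = c("pseudogene", "mitochondrial", "ribosomal_protein",
              "protein_coding", "protein_coding"))
  culled <- cull_genes(ranking, gene_table)
  reason <- setNames(culled$cull_reason, culled$symbol)
  expect_identical(unname(reason["CR43242"]), "CR_designation")
  expect_identical(unname(reason["mt:CoI"]), "mitochondrial")
  expect_identical(unname(reason["RpL3"]), "ribosomal_structural")
  expect_true(is.na(reason["CG8142"]))
  expect_true(is.na(reason["vas"]))
  # culled genes keep their rows (audit trail) but drop out of the top-N
  expect_identical(nrow(culled), 5L)
  expect_setequal(top_candidates(culled, 500)$symbol, c("CG8142", "vas"))
})

test_that("top_candidates truncates, renumbers and honors n = 0", {
  ranking <- aggregate_rank(list(rank_within_analysis(
    fake_de("1", sprintf("g%02d", 1:9), seq(.01, .09, .01), 9:1))))
  ranking$cull_reason <- NA_character_
  expect_identical(nrow(top_candidates(ranking, 500)), 9L)
  expect_identical(nrow(top_candidates(ranking, 0)), 0L)
  top5 <- top_candidates(ranking, 5)
  expect_identical(top5$position, 1:5)
  expect_false("g06" %in% top5$gene_id)
})

test_that("rules round-trip through the shipped YAML file", {
  path <- system.file("extdata", "cull_rules.yaml", package = "germscreen")
  expect_true(nzchar(path))
  rules <- read_cull_rules(path)
  expect_identical(as.data.frame(rules), as.data.frame(default_cull_rules()))
})
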
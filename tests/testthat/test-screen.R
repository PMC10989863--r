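test_that("germarium-level rules flag each phenotype category", {
  g <- wt_germarium()
  expect_false(any(unlist(classify_germarium(g)[germscreen:::.defect_categories])))
  # DSB repair: 2 or more region-3 foci, not 1
  g2 <- dplyr::mutate(g, gh2av_region3_foci = 2L)
  expect_true(classify_germarium(g2)$dsb_repair)
  g1 <- dplyr::mutate(g, gh2av_region3_foci = 1L)
  expect_false(classify_germarium(g1)$dsb_repair)
  # fragmented region-3 SC is a maintenance defect
  gm <- dplyr::mutate(g, sc_region3 = "fragmented")
  expect_true(classify_germarium(gm)$sc_maintenance)
  # absent 2A SC is an assembly defect; absent 2A foci a DSB-initiation defect
  expect_true(classify_germarium(dplyr::mutate(g, sc_2a = "absent_or_punctate"))$sc_assembly)
  expect_true(classify_germarium(dplyr::mutate(g, gh2av_2a_present = FALSE))$dsb_initiation)
  # abnormal Orb states are developmental
  expect_true(classify_germarium(dplyr::mutate(g, orb_status = "weak_2A"))$developmental)
})

test_that("malformed records are rejected naming the field", {
  g <- wt_germarium()
  expect_error(classify_germarium(dplyr::select(g, -orb_status)), "orb_status")
  expect_error(classify_germarium(dplyr::mutate(g, sc_2a = "sideways")), "sc_2a")
  expect_error(classify_germarium(dplyr::mutate(g, gh2av_region3_foci = -1L)),
               "gh2av_region3_foci")
})

test_that("a line is called defective at the inclusive 50% boundary with >= 10 germaria", {
  mk_line <- function(n_defect, n_total, defect = "orb") {
    g <- dplyr::bind_rows(lapply(seq_len(n_total), function(i) wt_germarium("L", i)))
    if (n_defect > 0 && defect == "orb") {
      g$orb_status[seq_len(n_defect)] <- "too_few_cysts"
    }
    g
  }
  # 7 of 12 developmental-defect germaria: a developmental call
  cl <- classify_line(mk_line(7, 12), gene = "CG8173")
  expect_identical(cl$category, "developmental")
  expect_equal(cl$defect_fraction, 7 / 12)
  # exactly 5 of 10: still defective ("at least 50%")
  expect_identical(classify_line(mk_line(5, 10))$category, "developmental")
  # 4 of 10: below the rule
  expect_identical(classify_line(mk_line(4, 10))$category, "wild_type")
  # clean line
  cl_wt <- classify_line(mk_line(0, 15))
  expect_identical(cl_wt$category, "wild_type")
  expect_identical(cl_wt$n_germaria, 15L)
  # defects present but fewer than 10 germaria: no call
  short <- classify_line(mk_line(5, 8))
  expect_identical(short$status, "insufficient_germaria")
  expect_true(is.na(short$category))
})

test_that("underdeveloped ovaries dominate and developmental precedes SC/DSB", {
  g <- dplyr::bind_rows(lapply(1:10, function(i) wt_germarium("L", i)))
  g$underdeveloped_ovary <- TRUE
  g$sc_region3 <- "absent"
  expect_identical(classify_line(g)$category, "underdeveloped")
  # developmental and SC maintenance both >= 50%: developmental wins
  g2 <- dplyr::bind_rows(lapply(1:10, function(i) wt_germarium("L", i)))
  g2$orb_status[1:6] <- "absent"
  g2$sc_region3[1:8] <- "fragmented"
  expect_identical(classify_line(g2)$category, "developmental")
  # SC maintenance alone
  g3 <- dplyr::bind_rows(lapply(1:10, function(i) wt_germarium("L", i)))
  g3$sc_region3[1:8] <- "fragmented"
  expect_identical(classify_line(g3)$category, "sc_maintenance")
})

test_that("line classification ignores germarium record order", {
  g <- dplyr::bind_rows(lapply(1:12, function(i) wt_germarium("L", i)))
  g$orb_status[1:7] <- "absent"
  shuffled <- g[sample(nrow(g)), ]
  expect_identical(classify_line(g)$category, classify_line(shuffled)$category)
  expect_error(classify_line(dplyr::mutate(g, line_id = c("A", rep("B", 11)))),
               "one line id")
})

test_that("classify_lines maps lines to genes and processes a whole screen", {
  g1 <- dplyr::bind_rows(lapply(1:10, function(i) wt_germarium("L1", i)))
  g2 <- dplyr::bind_rows(lapply(1:10, function(i) wt_germarium("L2", i)))
  g2$gh2av_region3_foci <- 3L
  out <- classify_lines(dplyr::bind_rows(g1, g2),
                        line_genes = tibble::tibble(line_id = c("L1", "L2"),
                                                    gene = c("geneA", "geneB")))
  expect_identical(out$category[out$line_id == "L1"], "wild_type")
  expect_identical(out$category[out$line_id == "L2"], "dsb_repair")
  expect_identical(out$gene, c("geneA", "geneB"))
})

test_that("line categories partition the screen and genes roll up once", {
  cl <- synthetic_screen_classifications()
  t <- tally_screen(cl)
  cnt <- function(section, metric) {
    t$count[t$section == section & t$metric == metric]
  }
  expect_identical(cnt("lines", "underdeveloped_ovaries") +
                     cnt("lines", "germaria_phenotype") +
                     cnt("lines", "wild_type"),
                   cnt("lines", "total"))
  # a gene with one wild-type and one defective line counts once as defective
  two <- tibble::tibble(line_id = c("A", "B"), gene = "g",
                        category = c("wild_type", "sc_assembly"),
                        n_germaria = 12L, status = "ok")
  t2 <- tally_screen(two)
  expect_identical(t2$count[t2$section == "genes" &
                              t2$metric == "with_germaria_phenotype_line"], 1L)
  expect_identical(t2$count[t2$section == "genes" &
                              t2$metric == "all_lines_wild_type"], 0L)
  # empty screen: all-zero tally
  t0 <- tally_screen(cl[0, ])
  expect_true(all(t0$count == 0))
  expect_error(tally_screen(dplyr::mutate(two, gene = NA)), "gene")
})

test_that("percentages round half away from zero", {
  expect_identical(percent_of_genes(51, 331), 15L)
  expect_identical(percent_of_genes(0, 100), 0L)
  expect_identical(percent_of_genes(1, 3), 33L)
  expect_identical(percent_of_genes(1, 40), 3L)   # 2.5 rounds up
  expect_error(percent_of_genes(1, 0), "total")
})
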
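#' Classify the defects observed in one or more germaria
#'
#' Turns raw per-germarium cytology observations into one boolean defect flag
#' per phenotype category, applying the scoring rules: a developmental defect
#' is any abnormal Orb state (absent, weak in region 2A, too few cysts, no
#' single focus, abnormal cysts); an SC assembly defect is the absence of
#' full-length synaptonemal complex in region 2A; an SC maintenance defect is
#' fragmented or absent SC in the region 3 oocyte; a DSB initiation defect is
#' the absence of gamma-H2AV foci in region 2A; a DSB repair defect is 2 or
#' more gamma-H2AV foci in the region 3 oocyte.
#'
#' @param scores A data frame with one row per germarium: `line_id`,
#'   `germarium_id`, logical `underdeveloped_ovary`, `orb_status` (one of
#'   `"absent"`, `"weak_2A"`, `"too_few_cysts"`, `"no_single_focus"`,
#'   `"abnormal_cyst"`, `"normal"`), `sc_2a` (`"full_length"`,
#'   `"too_few_nuclei"`, `"absent_or_punctate"`), `sc_region3`
#'   (`"full_length"`, `"fragmented"`, `"absent"`), logical
#'   `polycomplex_present`, logical `gh2av_2a_present`, integer
#'   `gh2av_region3_foci`.
#' @return The input with added logical columns `underdeveloped`,
#'   `developmental`, `sc_assembly`, `sc_maintenance`, `polycomplex`,
#'   `dsb_initiation`, `dsb_repair`.
#' @export
classify_germarium <- function(scores) {
  scores <- as_tibble(scores)
  need <- c("line_id", "germarium_id", "underdeveloped_ovary", "orb_status",
            "sc_2a", "sc_region3", "polycomplex_present", "gh2av_2a_present",
            "gh2av_region3_foci")
  miss <- setdiff(need, names(scores))
  if (length(miss)) abort(paste0("missing field(s): ", paste(miss, collapse = ", ")))
  chk_levels <- function(field, levels) {
    bad <- setdiff(unique(scores[[field]]), levels)
    if (length(bad)) {
      abort(sprintf("invalid value(s) in `%s`: %s", field, paste(bad, collapse = ", ")))
    }
  }
  chk_levels("orb_status", c("absent", "weak_2A", "too_few_cysts",
                             "no_single_focus", "abnormal_cyst", "normal"))
  chk_levels("sc_2a", c("full_length", "too_few_nuclei", "absent_or_punctate"))
  chk_levels("sc_region3", c("full_length", "fragmented", "absent"))
  if (any(scores$gh2av_region3_foci < 0)) {
    abort("invalid value(s) in `gh2av_region3_foci`: focus counts must be >= 0")
  }
  scores |>
    mutate(underdeveloped = .data$underdeveloped_ovary,
           developmental = .data$orb_status != "normal",
           sc_assembly = .data$sc_2a != "full_length",
           sc_maintenance = .data$sc_region3 != "full_length",
           polycomplex = .data$polycomplex_present,
           dsb_initiation = !.data$gh2av_2a_present,
           dsb_repair = .data$gh2av_region3_foci >= 2)
}

.defect_categories <- c("underdeveloped", "developmental", "sc_assembly",
                        "sc_maintenance", "polycomplex", "dsb_initiation",
                        "dsb_repair")

#' Classify one RNAi line from its scored germaria
#'
#' A line is called defective in a category when at least 50% (inclusive) of
#' its scored germaria show that defect. Underdeveloped ovaries dominate every
#' other call (such ovaries cannot be staged, so it needs no minimum germaria
#' count); among germarium phenotypes at least 10 scored germaria are required
#' and developmental defects take precedence over SC and DSB categories, which
#' follow in the fixed order assembly, maintenance, polycomplex, DSB
#' initiation, DSB repair. Lines with fewer than 10 scorable germaria and any
#' defect observed get status `"insufficient_germaria"` and no call.
#'
#' @param scores Germarium score rows of a single line (see
#'   [classify_germarium()] for the columns).
#' @param gene Gene targeted by the line (recorded in the output).
#' @return A one-row tibble: `line_id`, `gene`, `category`, `defect_fraction`,
#'   `n_germaria`, `status`, plus one `frac_*` column per category.
#' @export
classify_line <- function(scores, gene = NA_character_) {
  flags <- classify_germarium(scores)
  if (length(unique(flags$line_id)) != 1) {
    abort("all scores passed to classify_line() must share one line id")
  }
  n <- nrow(flags)
  fracs <- vapply(.defect_categories, function(cat) mean(flags[[cat]]), numeric(1))
  names(fracs) <- .defect_categories
  category <- "wild_type"; status <- "ok"
  if (fracs["underdeveloped"] >= 0.5) {
    category <- "underdeveloped"
  } else {
    germ_cats <- setdiff(.defect_categories, "underdeveloped")
    hit <- germ_cats[fracs[germ_cats] >= 0.5]
    if (length(hit) && n < 10) {
      category <- NA_character_; status <- "insufficient_germaria"
    } else if (length(hit)) {
      category <- hit[1]                 # precedence = fixed category order
    }
  }
  out <- tibble(line_id = flags$line_id[1], gene = gene,
                category = category,
                defect_fraction = if (!is.na(category) && category != "wild_type")
                  unname(fracs[category]) else 0,
                n_germaria = n, status = status)
  for (cat in .defect_categories) out[[paste0("frac_", cat)]] <- unname(fracs[cat])
  out
}

#' Classify every line of a screen
#'
#' @param scores Germarium score rows for any number of lines.
#' @param line_genes Optional data frame mapping `line_id` to `gene`.
#' @return One row per line, as in [classify_line()].
#' @export
classify_lines <- function(scores, line_genes = NULL) {
  scores <- as_tibble(scores)
  out <- scores |>
    group_by(.data$line_id) |>
    dplyr::group_map(function(d, key) {
      g <- if (!is.null(line_genes)) {
        line_genes$gene[match(key$line_id, line_genes$line_id)]
      } else NA_character_
      classify_line(mutate(d, line_id = key$line_id), gene = g)
    }) |>
    bind_rows()
  out
}

.germaria_categories <- c("developmental", "sc_assembly", "sc_maintenance",
                          "polycomplex", "dsb_initiation", "dsb_repair")

#' Tally a screen into a summary table
#'
#' Line-level counts per top-level category (underdeveloped ovaries, any
#' germarium phenotype, wild type — a partition of the lines), a gene-level
#' rollup in which a gene counts in a category when at least one of its lines
#' does, the overlap count (genes with lines in both defect categories), and
#' sub-tallies of CG-designated (uncharacterized) genes.
#'
#' @param classifications Line classifications from [classify_lines()]; the
#'   `gene` column must be filled.
#' @param cg_pattern Regular expression identifying CG-designated gene
#'   symbols.
#' @return A tibble (class `germ_tally`) with columns `section`, `metric`,
#'   `count`.
#' @export
tally_screen <- function(classifications, cg_pattern = "^CG[0-9]+$") {
  cl <- as_tibble(classifications)
  if (anyNA(cl$gene)) abort("every line must map to a gene")
  cl$germaria_phenotype <- cl$category %in% .germaria_categories
  cl$wild_type <- cl$category == "wild_type"
  cl$underdev <- cl$category == "underdeveloped"

  by_gene <- cl |>
    group_by(.data$gene) |>
    summarise(underdev = any(.data$underdev),
              germaria = any(.data$germaria_phenotype),
              all_wt = all(.data$wild_type), .groups = "drop")
  cg <- grepl(cg_pattern, by_gene$gene)

  out <- tibble(
    section = c(rep("lines", 4), rep("genes", 5), rep("cg_genes", 3)),
    metric = c("underdeveloped_ovaries", "germaria_phenotype", "wild_type",
               "total",
               "with_underdeveloped_line", "with_germaria_phenotype_line",
               "all_lines_wild_type", "overlap_both_defect_categories",
               "total",
               "tested", "with_underdeveloped_line",
               "with_germaria_phenotype_line"),
    count = c(sum(cl$underdev), sum(cl$germaria_phenotype), sum(cl$wild_type),
              nrow(cl),
              sum(by_gene$underdev), sum(by_gene$germaria),
              sum(by_gene$all_wt), sum(by_gene$underdev & by_gene$germaria),
              nrow(by_gene),
              sum(cg), sum(by_gene$underdev[cg]), sum(by_gene$germaria[cg])))
  structure(out, class = c("germ_tally", class(out)))
}

#' Rounded percentage of genes
#'
#' `round(100 * count / total)` to the nearest integer, halves away from zero.
#'
#' @param count Numerator.
#' @param total Denominator (> 0).
#' @return Integer percent.
#' @export
percent_of_genes <- function(count, total) {
  if (total <= 0) abort("`total` must be > 0")
  x <- 100 * count / total
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Synthetic Table-1-style screen classification fixture
#'
#' A synthetic line-level classification table whose margins reproduce the
#' published screen summary: 74 lines with underdeveloped ovaries, 84 lines
#' with a germarium phenotype, 368 wild-type lines (526 lines in total) over
#' 331 tested genes, of which 51 have an underdeveloped line, 61 a
#' germarium-phenotype line (2 genes in both categories), with 61
#' CG-designated genes among which 1 underdeveloped and 5 germarium-phenotype.
#' The per-line category assignment within those margins is synthetic; only
#' the margins are meaningful.
#'
#' @return A classification tibble as produced by [classify_lines()]
#'   (columns `line_id`, `gene`, `category`, `n_germaria`, `status`).
#' @export
synthetic_screen_classifications <- function() {
  genes <- sprintf("Gene%03d", seq_len(331))
  # 61 CG-designated genes among the tested set
  genes[271:331] <- sprintf("CG1%04d", 271:331)
  underdev_genes <- c(genes[1:50], genes[271])           # 51, incl. 1 CG gene
  # 61 genes: 2 overlapping the underdeveloped set, 5 of them CG-designated
  germ_genes <- c(genes[49:50], genes[52:105], genes[272:276])
  rows <- list()
  # 74 underdeveloped lines over the 51 genes
  ud_lines <- underdev_genes[c(seq_len(51), rep(1:23, length.out = 23))]
  rows$ud <- tibble(gene = ud_lines, category = "underdeveloped")
  # 84 germarium-phenotype lines over the 61 genes, categories cycled
  gp_lines <- germ_genes[c(seq_len(61), rep(1:23, length.out = 23))]
  rows$gp <- tibble(gene = gp_lines,
                    category = rep(c("developmental", "sc_assembly",
                                     "sc_maintenance", "polycomplex",
                                     "dsb_initiation", "dsb_repair"),
                                   length.out = 84))
  # 368 wild-type lines: every remaining gene once, the rest recycled
  wt_genes <- setdiff(genes, c(underdev_genes, germ_genes))
  rows$wt <- tibble(gene = c(wt_genes, rep(wt_genes, length.out = 368 - length(wt_genes))),
                    category = "wild_type")
  out <- bind_rows(rows)
  out$line_id <- sprintf("TRiP%04d", seq_len(nrow(out)))
  out$n_germaria <- 12L
  out$status <- "ok"
  out[c("line_id", "gene", "category", "n_germaria", "status")]
}
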
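---
title: "Marker-anchored candidate prioritization: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-anchored candidate prioritization: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germscreen)
```

## What the pipeline computes

`germscreen` ranks genes by how specifically they are expressed in early
meiotic germline cells of the *Drosophila* ovary, using several independent
single-cell analyses, and summarizes the cytological RNAi screen that such a
ranking feeds. The chain is:

QC → normalization → marker-based germline labeling → per-analysis Wilcoxon
differential expression with Bonferroni correction (positive genes only) →
cross-analysis intersection → mean-rank aggregation with lnFC-rank tie-break
→ gene-class culling → top-N candidates → GO over-representation.

The statistical logic: a gene that is *independently* called
germline-enriched in every analysis, and sits near the top of each analysis's
p-value ranking, is co-expressed with the marker program in a way that is
robust to dataset-specific technical structure. The aggregation deliberately
uses ranks, not p-values, so analyses with different cell numbers (hence
incomparable p-value scales) contribute equally.

### Assumptions

* A germline/soma *partition* is all the downstream procedure needs — no
  embedding, graph clustering or batch integration is required for the
  statistics. Labeling here scores each cell by the unweighted mean
  normalized expression of the four markers and thresholds the score with
  Otsu's criterion (maximizing between-class variance over all candidate
  cuts). Cells strictly above the threshold are germline; a tie at the
  threshold goes to soma, for determinism. External cluster labels can be
  substituted via `assign_germline(labels = ...)`.
* The Wilcoxon rank-sum test only needs a per-cell monotone normalization,
  so log-CP10K (`ln(1 + 1e4·count/total)`) stands in for variance-stabilizing
  regression-based normalizations: every rank-based statistic, the sign of
  the fold-change and the dot-plot summaries are unchanged by any monotone
  per-cell transform. The *magnitude* of lnFC does depend on this choice,
  which matters only for tie-breaking among equally significant genes.
* Genes are tested marginally; no covariates, pseudobulk or gene-gene
  dependence modeling.

## The test, exactly

For each gene, with `n_in` germline and `n_out` other cells, the
Mann–Whitney U is computed from midranks. The two-sided p-value uses the
normal approximation with tie-corrected variance

```
Var(U) = n_in·n_out/12 · [(n+1) − Σ(t³−t)/(n(n−1))]
```

(`t` the tie-group sizes) and a continuity correction of 0.5 toward the null
mean. When `n_in·n_out ≤ 64` and `choose(n, n_in) ≤ 1e5` the p-value comes
instead from full enumeration of all group assignments, which is exact under
ties as well (the null distribution of U is symmetric about `n_in·n_out/2`,
which the enumeration exploits for the two-sided tail). P-values are floored
at 1e-300 so Bonferroni adjustment and ranking stay finite.

A note on accuracy: the suite measures the worst-case deviation between the
prescribed normal approximation and the exact distribution over *all*
tie-free inputs with 3–8 observations per group. The worst cases sit at the
smallest sizes (3 vs 3) in the middle of the distribution, where the
approximation is several percentage points off; this is a property of the
approximation itself, not of the implementation, and is immaterial in
practice because the function switches to the exact path at exactly those
sizes. The acceptance report prints the measured worst-case deviation rather
than hiding it.

`lnFC = ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))` — i.e. the
log ratio of mean depth-normalized expression with a pseudocount of 1, the
convention of the single-cell tool family this pipeline mirrors. The log base
is natural throughout. Significance is `p_adj < 0.05` *and* `lnFC > 0`: the
screen only wants genes elevated in the germline, and a two-sided p with a
positive-lnFC filter implements that without changing the test.

## Ranking and tie policy

Within an analysis only significant genes are ranked (ascending `p_adj`,
average ranks for ties). Aggregation keeps the intersection of all analyses'
significant sets, orders by mean rank, breaks ties by mean lnFC rank (lnFC
rank 1 = largest lnFC within its analysis, computed over the same significant
set), and breaks any remaining ties alphabetically by gene id. All three
levels are deterministic, so identical inputs give byte-identical output.

With large cell numbers many p-values underflow to the 1e-300 floor and tie;
the lnFC tie-break then does the real ordering work near the top of the list.
This mirrors how abundant, specific genes (the markers themselves included —
they are *not* exempted from ranking) rise to the top.

Culling happens after aggregation and before top-N selection, so the full
ranked list with cull reasons survives as an audit trail. Rules are ordered,
first-match-wins, each a regex against the gene table's class label or the
symbol (`inst/extdata/cull_rules.yaml` ships the defaults): mitochondrial
genes, CR-designated pseudogenes, asRNA/hpRNA/snRNA/snRNP/snmRNA/snoRNA/
lncRNA/sisRNA/pre-rRNA classes, and ribosomal structural proteins
(`RpL*`/`RpS*`).

## GO over-representation

One hypergeometric upper-tail test per term against the expressed-gene
background, computed in log space (log-sum-exp over `lchoose` terms) for
stability, BH-adjusted. Term gene sets are used as given — no ontology-graph
propagation — so results are exactly as good as the annotation table
supplied; term-size bounds default to [10, 500]. This is a deliberate
limitation: propagation belongs to the annotation-preparation step, not the
statistics.

## The synthetic study

The generator emulates *post-alignment* 10x count data with the structure the
analysis assumes, and nothing more:

* counts are negative-binomial, `Var = μ + μ²/θ`, with a single global
  dispersion `θ = 2` — a typical UMI-data overdispersion;
* baseline per-gene means are uniform on [0.1, 2];
* a germline minority (default 25%, `floor(fraction · cells)` cells per
  replicate, for determinism) has `n_enriched = 150` genes elevated by
  lnFC uniform on [ln 2, ln 4];
* the four markers are simulated as the strongest enriched genes
  (lnFC = upper bound) at a baseline mean of 20 — vasa-class markers are
  among the most abundant germline transcripts, and at typical-gene abundance
  the Poisson component of counting noise would make a 4-gene score far less
  informative than marker genes are in real data;
* mitochondrial genes (default 10 at mean 5) and a 5% sprinkling of
  cull-class symbols/classes over background genes exercise QC and culling;
* per-replicate seeds derive from the configured seed plus a stable
  polynomial string hash of (analysis id, replicate id), so replicates differ
  but every byte is reproducible; gene-level truth derives from the seed
  alone and is shared across replicates.

Not emulated: ambient RNA, doublets, batch effects beyond sampling noise,
per-gene dispersions, zero inflation beyond NB zeros, and read-level
artifacts. Passing recovery tests on this generator therefore shows the
*procedure* is correct and well-calibrated under its own assumptions — not
that any particular real dataset satisfies those assumptions.

On the default configuration the acceptance script measures germline-labeling
accuracy against the simulated truth. Under the default dispersion and the
4-fold marker enrichment, the 4-marker score distributions of the two
populations overlap enough that accuracies sit in the low-to-mid 90s rather
than arbitrarily close to 100%: the per-marker log-scale noise floor is about
`sqrt(ln(1 + 1/θ))` regardless of abundance, and Otsu's criterion places its
cut slightly off the accuracy-optimal point for unbalanced classes. The
property suite asserts ≥ 90%. Mislabeled cells act as diluted noise in the
rank-sum test, which is why marker and strong-enriched-gene recovery remain
essentially perfect at that labeling accuracy.

## QC defaults

The replicate-specific rule (median ± 3 MADs on log10 genes-detected,
mitochondrial fraction ≤ 0.2) reproduces the *procedure* of deriving cutoffs
from each replicate's own distributions when published numeric cutoffs are
unavailable; explicit per-replicate thresholds can be supplied through
`pipeline_config(qc_thresholds = ...)`. Genes-detected uses `count > 0`, and
the mitochondrial criterion is a fraction of counts (not a raw count) —
flagged here because either convention exists in the wild. QC never removes
genes, preserves cell order, and is idempotent.

## Screen classification rules

Per germarium: any abnormal Orb state is a developmental defect; absence of
full-length SC in region 2A an assembly defect; fragmented/absent SC in the
region-3 oocyte a maintenance defect; absent region-2A γH2AV a DSB-initiation
defect; **≥ 2** γH2AV foci in the region-3 oocyte a DSB-repair defect.

Per line: "at least 50%" is inclusive (5 defective of 10 scored ⇒ defective),
read literally. Underdeveloped ovaries dominate every other call and are
exempt from the 10-germarium minimum (such ovaries cannot be staged at all);
among germarium phenotypes, ≥ 10 scored germaria are required and
developmental calls take precedence over SC/DSB calls — when cyst development
is broken, downstream SC/DSB abnormalities are uninterpretable as primary
phenotypes. The remaining precedence (assembly > maintenance > polycomplex >
DSB initiation > DSB repair) is fixed and documented rather than meaningful.
Gene-level tallies roll a gene into a category if ≥ 1 of its lines is in it,
and genes with lines in both defect categories are tracked as an explicit
overlap count rather than forced into one.

The bundled `synthetic_screen_classifications()` fixture reproduces the
published screen's *margins* (74/84/368 lines over 331 genes, with the CG
sub-tallies); its per-line assignments within those margins are synthetic.
One caveat a user of the real table should know: the published gene-level
margins are internally inconsistent by one (51 + 61 − 2 overlapping + the
printed wild-type-only count exceeds the printed genes-tested total by one),
so the fixture reproduces the line margins and the tested-gene total exactly
and lets the wild-type-only count follow arithmetically.

## Problem sizes and runtime

The validation suite uses the default synthetic study (4 analyses × 3
replicates × 800 cells, 3,000 genes) for recovery, 100 null replicates of
200 genes × 400 cells for type-I error, and exhaustive enumerations for the
Wilcoxon (group sizes 3–8) and hypergeometric (populations ≤ 30) oracles —
sizes chosen so the whole suite runs in a couple of minutes on one core while
still giving each stochastic check thousands of effective trials.

## Known limitations

* Otsu labeling assumes a bimodal marker score; for cell types without
  abundant specific markers, supply external labels.
* No gene pre-filter before testing (every gene is tested and counted in the
  Bonferroni `m`); a detection-fraction pre-filter is a common alternative
  and would shrink `m`.
* The lnFC magnitude depends on the normalization stand-in; only its sign and
  rank are used by the pipeline's decisions.
* GO results are annotation-version-dependent by nature; the package performs
  no id mapping.
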
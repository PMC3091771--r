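---
title: "Comparing sequence conservation around imprinted and autosomal genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sequence conservation around imprinted and autosomal genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the approach

Imprinted genes are expressed from only one parental allele, under the
control of germline differentially methylated regions. If monoallelic
regulation constrains the surrounding DNA, the conserved elements near
imprinted genes should differ from those near biallelically expressed
genes — in their density, their placement relative to exons, their G+C
and CpG composition, and in how strongly historical CpG methylation has
eroded their CpG dinucleotides.

`imprintcons` implements that comparison as a reusable pipeline over
standard annotation tracks:

1. **Gene models** (`merge_transcripts()`): all transcripts of a gene are
   collapsed to the longest possible transcription unit — the most 5'
   start to the most 3' termination site — with exons and coding
   intervals merged to the largest possible sets, and introns defined as
   the span minus the merged exons.
2. **Region partition** (`partition_intergenic()`, `promoter_of()`): the
   DNA between two genes is halved at the midpoint and each half assigned
   to the nearer gene; promoters are the 1000 bp upstream of the most
   upstream TSS, strand-aware and clipped only at chromosome ends.
3. **Conserved elements** (`filter_elements()`, `classify_elements()`):
   scored conserved segments (phastCons-style "most conserved" tracks)
   shorter than 20 bp are dropped; the rest are classified coding
   (≥ 1 bp overlap with merged coding sequence), UTR (exon but not
   coding overlap), intronic (inside a span, no exon overlap), or
   intergenic (assigned to the owner of the containing intergenic
   region). Feature possession (`annotate_overlaps()`) means ≥ 1 bp
   overlap with the track.
4. **Composition** (`composition()`): G+C content; normalized CpG
   content CpG~obs~/CpG~exp~ = n~CpG~·L/(n~C~·n~G~) (the Gardiner–Garden
   convention, the same normalization that underlies the UCSC CpG-island
   track); and the deamination index (TpG+CpA)/(2·CpG). Methylated CpG
   deaminates to TpG on one strand and CpA on the other, so a high index
   marks accumulated CpG decay and a low index CpG preservation.
5. **Statistics** (`compare_continuous()`, `compare_counts()`,
   `calibrate_with_random_sets()`): two-sided Wilcoxon rank-sum tests for
   distributional features, chi-square (or Fisher's exact) tests for
   proportions and relative element counts, raw p values interpreted in
   tiers, and a background calibration that re-runs a comparison on 100
   random autosomal gene sets of the labeled set's size.
6. **Motifs** (`concatenate_by_gene()`, `enriched_motifs()`): element
   sequences concatenated per gene with six-`N` separators (so no window
   spans a junction), strand-specific 6-mer counting, and a binomial
   z-score against both a genomic background and a comparison collection,
   with a pass threshold on both scores.

All interval tables are tibbles in 0-based half-open (BED) coordinates;
GTF input is converted on read. Everything chains with the pipe, and
`analyze_bundle()` runs the whole pipeline on a track bundle.

## Significance tiers

Raw p values are reported, never adjusted. The tier labels encode a
Bonferroni-style reading of the raw values: **highly** significant below
0.005, **moderately** significant from 0.005 to 0.01, a **trend** from
0.01 to 0.05, and `ns` above. `significance_tier()` applies the mapping;
reports annotate it with stars.

The Wilcoxon implementation enumerates exactly for two untied groups of
at most 20 and otherwise uses the tie-corrected normal approximation with
continuity correction. `compare_counts()` uses the chi-square test
without continuity correction and falls back to Fisher's exact test
whenever an expected cell is below 5 — the switching rule is ours, chosen
so that the exact test covers precisely the tables where the chi-square
approximation is unreliable.

For the random-set calibration, sets are drawn without replacement and
excluded from their comparison pool, so a random set is never compared
against itself; the reported frequency is the fraction of random sets
whose comparison reaches at least the tier observed for the labeled set.

## The synthetic-genome generator

Real conserved-element tracks are genome-scale; the generator
(`synth_genome()`) builds internally consistent toy genomes where every
downstream quantity has a planted ground truth. The defaults encode the
contrasts under study, so the default bundle behaves like the study
system:

* **58 labeled genes** (29 maternally, 29 paternally expressed) among a
  larger autosomal background — `paper_shaped_fixture()` uses 942
  autosomal genes for 1000 in total, our desk-scale stand-in for a full
  autosomal gene set.
* **Longer intergenic regions** around labeled genes (flank allowance
  ×2): each gene draws a log-normal flank (median 2.5 kb), consecutive
  flanks average into the gap between genes.
* **Reduced CpG deamination** in labeled territories: each CpG of the
  ancestral sequence deaminates with probability *d* (0.25 maternal,
  0.20 paternal, 0.50 autosomal) outside CpG islands and with a much
  lower island rate — emulating territories methylated outside their
  islands but protected at them. *d* is a surrogate for germline
  methylation exposure, not a calibrated evolutionary rate; only the
  ordering and separation of groups matter to the analysis.
* **Denser intronic conserved elements near exons** for labeled genes
  (1.2 vs 0.6 per intron kb; exponential exon-proximity decay with mean
  300 vs 800 bp).
* **More intronic CpG islands**, a **larger ancient-L1M fraction** among
  L1 repeats (0.8 vs 0.4), **more CTCF/YY1 sites**, and a CpG-containing
  6-mer (`TGCGTA`) planted into the labeled genes' intronic elements at
  5-fold enrichment.

The background sequence is i.i.d. at G+C 0.42 with region-specific
adjustments (CpG-rich islands planted as dinucleotides, then deaminated)
rather than a full Markov chain: every statistic the pipeline computes
depends only on mono- and dinucleotide composition, so an i.i.d. model
with planted CpGs is sufficient and much easier to reason about.
Conservation scores are drawn from per-class gamma distributions; the
absolute scale is arbitrary because only within-run comparisons are ever
made. `synth_config_null()` flattens every per-group knob, giving the
null condition for calibration tests.

What the generator does **not** emulate: real repeat sequence content
(repeats are intervals with names, not transposon sequence), isoform
structure beyond a single transcript per gene, alignment artefacts in
conserved-element calls, and the long-range correlation structure of
real genomes. Tests passing on synthetic data therefore validate the
*bookkeeping and the statistics* — interval arithmetic, composition
accounting, calibration — not biological conclusions about real
imprinted loci.

## Numerical conventions and edge cases

* Odd-length gaps split at `floor((a+b)/2)`, so the extra base goes to
  the downstream gene; any fixed rule would do, this one is documented
  and tested.
* Overlapping gene spans leave an empty gap — no intergenic base is
  assigned twice. Elements overlapping several spans go to the gene with
  the larger overlap, ties to the lower-coordinate gene.
* `N` bases never contribute: they are excluded from effective length,
  from dinucleotide windows, and from k-mer windows, so repeat-to-`N`
  masking cannot dilute a ratio or fabricate a motif.
* No dinucleotide window spans an interval boundary when pooling
  discontiguous intervals (e.g. a gene's introns).
* Ratios with zero denominators (CpG~obs~/CpG~exp~ without C or G, the
  deamination index without CpG) are `NA`, with `has_cpg`/`valid` flags.
* An intronic element's exon distance is the gap to the *nearest* exon
  boundary of its host gene (either side); exon-overlapping elements get
  negative distances — penetration depth past the crossed boundary, or
  distance to the nearer boundary when fully inside an exon. Profile
  elements beyond 10 kb are dropped.
* A zero reference count in motif scoring yields an infinite score,
  flagged rather than hidden; a pseudocount option is available.
* The motif score is a binomial z-score. It is **not** numerically
  comparable to scores of the published K-Factor tool, whose internal
  normalization is not public; only motif identities, rankings, and
  threshold-passing behavior on synthetic data are asserted.

## Problem sizes used by the test suite

The acceptance tests run at sizes chosen to finish in minutes on one
CPU while keeping each check statistically meaningful: 200 random
≤ 10 kb chromosomes for the per-base oracle equivalence; 100 kb
sequences across 20 seeds for deamination monotonicity; 10⁴ null
simulations for type-I calibration; 100 generator runs with 58 labeled
versus 442 autosomal genes (and 50 null runs) for planted-contrast
recovery; 50 seeds of 50 × 600 bp targets for motif recovery; and the
1000-gene `paper_shaped_fixture()` for the end-to-end determinism check.

Two statistical design points deserve a note. For the planted
element-density contrast we use the count-based chi-square comparison
(element counts versus summed intron length) rather than the per-gene
Wilcoxon: rate contrasts between pooled regions are exactly what the
proportion-test family is for, and per-gene counts at desk scale are
dominated by zeros. And for the motif null: the two enrichment scores of
one k-mer share the same observed target count, so the joint pass rate
is governed by the (Poisson) tail of that single count — roughly the
single-score tail — and not by the product of two independent tails.
The null acceptance check therefore asserts consistency with that
correct expectation, a fraction of a percent of all 4096 k-mers.

## Known limitations

* Distance conventions for exon-equidistant intronic elements take the
  minimum; the source convention is unknowable from published methods.
* Repeat categories come from a name-prefix mapping
  (`repeat_category()`); unknown families fall into `other`.
* `mask_lowercase` requires character input for interval extraction,
  since `DNAStringSet` storage uppercases soft-masked sequence.
* The pipeline analyzes one genome per run; cross-species replication is
  emulated by running two bundles (two seeds) and intersecting motif
  lists with `shared_motifs()`.
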
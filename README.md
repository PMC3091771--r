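# imprintcons

Comparative sequence-conservation analysis of imprinted versus autosomal
genes, as a tidyverse-native R package.

## What it does, and for whom

Imprinted genes — expressed from a single parental allele under the
control of germline differentially methylated regions — may leave a
signature in the conserved DNA around them. This package is for
computational biologists who want to quantify that signature from
standard annotation tracks: gene models (GTF/BED12), a scored
conserved-element track (phastCons-style "most conserved" BED), CpG
islands, RepeatMasker repeats, transcription-factor binding sites, a
genome FASTA, and a two-column gene→group file
(maternal/paternal/autosomal).

The pipeline:

* merges each gene's transcripts into the longest possible transcription
  unit (most 5' TSS to most 3' termination site, exons and CDS unioned),
  halves the DNA between genes at the midpoint and assigns each half to
  the nearer gene, and takes promoters as the 1000 bp upstream of the
  most upstream TSS;
* filters conserved elements (PCSs) shorter than 20 bp, classifies the
  rest as coding / UTR / intronic / intergenic (coding wins with ≥ 1 bp
  CDS overlap), flags ≥ 1 bp overlaps with CpG islands, repeats and
  binding sites, attributes each repeat-overlapping element to its first
  overlapping repeat, and marks "unique" elements overlapping no exon,
  repeat, or island;
* computes composition statistics per sequence or interval set: G+C,
  normalized CpG content CpG_obs/CpG_exp = n_CpG·L/(n_C·n_G), and the
  deamination index **(TpG+CpA)/(2·CpG)** — methylated CpG deaminates to
  TpG/CpA, so a low index means preserved CpGs;
* compares groups with two-sided Wilcoxon rank-sum tests (distributions)
  and chi-square/Fisher tests (proportions), reports raw p values with
  significance tiers (p < 0.005 highly; 0.005–0.01 moderate; 0.01–0.05
  trend), and calibrates any comparison against 100 random autosomal
  gene sets of the same size as the labeled set;
* finds 6-mers enriched in per-gene-concatenated element sequences
  (six-`N` separators, optional repeat masking) against both a genomic
  background and a comparison collection, passing only motifs with both
  binomial z-scores ≥ 3.5.

A full synthetic-genome generator (`synth_genome()`) emits consistent
FASTA + GTF + BED bundles with planted group effects (intergenic-length
ratio, per-group deamination probability, element densities and
exon-proximity decay, L1M fractions, a planted motif) so that every
stage can be validated against ground truth; `paper_shaped_fixture()`
is the deterministic 58-labeled-gene study-shaped instance.

## Worked example

```r
library(imprintcons)
library(dplyr)

bundle <- paper_shaped_fixture(seed = 1)   # 58 labeled + 942 autosomal genes
analysis <- analyze_bundle(bundle)
analysis
#> <imprintcons_analysis>
#>   genes: 1000 | elements: 3014
#>   groups: autosomal, maternal, paternal
#>   passing motifs: 51 (top: TGCGTA)

analysis$table1 |>
  filter(feature %in% c("intergenic_bp", "deamination_index"),
         group %in% c("imprinted", "autosomal"))
#> # A tibble: 4 × 7
#>   feature           group         n  median     p_raw tier   stars
#>   <chr>             <chr>     <int>   <dbl>     <dbl> <chr>  <chr>
#> 1 intergenic_bp     autosomal   942 2764.   NA        <NA>   <NA>
#> 2 intergenic_bp     imprinted    58 3938.    6.86e-13 highly ***
#> 3 deamination_index autosomal   941    2.06 NA        <NA>   <NA>
#> 4 deamination_index imprinted    58    1.22  1.90e-14 highly ***
```

Read: imprinted genes sit in intergenic regions with a larger median
length (planted ×2 flank effect; Wilcoxon vs autosomal, raw
p ≈ 7·10⁻¹³, "highly" tier), and their territories show a much lower
deamination index (1.22 vs 2.06) — the planted reduced CpG-decay
contrast — again at the "highly" tier. The top enriched 6-mer in
intronic elements of labeled genes is the planted, CpG-containing
`TGCGTA`, passing both the genomic-background and the
autosomal-comparison score thresholds.

`autoplot(analysis$profile)` draws the exon-distance density profile,
`plot_repeat_attribution(analysis$repeat_attribution)` the
first-overlapping-repeat histogram, and `plot_motif_scores()` the motif
score plane. `tidy()`/`glance()` methods cover the comparison and
calibration objects.

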
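# crenrich

Tools for two linked questions about open-chromatin peak sets (for
example scATAC-seq peaks) in regulatory genomics:

1. **Are the peaks enriched inside LD blocks around trait-associated
   GWAS variants?**  `crenrich` builds linkage-disequilibrium blocks
   around genome-wide-significant SNPs (P < 5×10⁻⁸) from phased
   haplotype panels — nearest panel variants act as proxies for SNPs
   absent from the panel, and a block runs from the most upstream to the
   most downstream variant with r² ≥ 0.8 to either proxy inside a 500-kb
   window — then tests peak overlap against background region sets
   matched on the joint GC-content × genomic-annotation distribution by
   stratified sampling without replacement from a 500-bp genome tiling.
2. **Are the peaks' regulatory functions conserved across species?**
   Synteny projection scores are classified as directly conserved
   (score > 0.98), indirectly conserved (> 0.84) or nonconserved;
   differentially accessible regions (DARs) are called functionally
   conserved when a conserved projection lands on a DAR in the other
   species, with tissue-level rate contrasts (ectoderm vs mesenchyme)
   tested by Fisher's exact test.

The statistics: for an observed peak set and `N` matched background
sets, the overlap frequency is the number of peaks touching ≥ 1 block
(each peak counted once) and the peak density is that count per megabase
of merged block length; the empirical p-value is

```
p = #{ background sets with a statistic ≥ observed } / N
```

with a reported bound `< 1/N` when no background set reaches the
observed value, and the fold estimate is `observed / mean(null)`.

A first-class synthetic-data module generates every input the pipeline
consumes — haplotype panels with block-structured LD of tunable
within-segment r², annotated genomes with heterogeneous GC, peak sets
with a planted enrichment factor, GWAS tables with planted significance
counts, and projection-score tables drawn from class-proportion
mixtures — so the whole pipeline is testable with no downloads.

## Worked example

The default configuration runs the full synthetic study: a 2 × 400-kb
genome, 200-haplotype panels for two population groups, 2400 GWAS SNP
records (1687 genome-wide significant), 500 peaks planted at enrichment
factor λ = 5 inside trait blocks covering ~2% of the genome, and 200
matched background sets.

```r
library(crenrich)

res <- run_pipeline(cre_config(), out_dir = "cre_run", seed = 42)

res$enrichment
#> <cre_enrichment> 200 background sets
#>   overlap_frequency  observed 52  null 13.76 +/- 2.88  fold 3.78  empirical P < 0.005
#>   peak_density       observed 2697  null 713.3 +/- 149  fold 3.78  empirical P < 0.005
```

52 of the 500 peaks touch an LD block, against a matched-background
expectation of 13.8, a 3.8-fold enrichment that no background set
reaches (empirical P below the 1/200 resolution) — the planted λ = 5 is
recovered up to the expected edge effects.  The conservation stage
classifies the simulated projections and contrasts the tissues:

```r
res$conservation$classes
#> # A tibble: 3 × 3
#>   class            n fraction
#> 1 direct          57    0.142
#> 2 indirect       165    0.412
#> 3 nonconserved   178    0.445

res$conservation$tissue_rate_ratio
#> # A tibble: 1 × 6
#>   ratio  p_value ect_conserved ect_total mes_conserved mes_total
#> 1  4.38 6.94e-16            93       201            21       199
```

The class split matches the planted 14.3/41.1/44.4% mixture, and the
ectodermal conservation rate exceeds the mesenchymal one 4.4-fold
(planted rates 0.44 vs 0.10).  Each stage is also callable on its own —
`filter_gwas()`, `build_ld_blocks()`, `annotate_regions()`,
`build_pool()` + `sample_background()`, `run_enrichment()`,
`functional_conservation()` — with tibbles in and out,
`tidy()`/`glance()` methods and `autoplot()` for enrichment results,
and every result written as plain TSV/BED with a JSON run manifest.
A thin CLI lives at `inst/scripts/cre-enrich.R`.

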
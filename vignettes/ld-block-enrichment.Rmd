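---
title: "Methods: LD-block enrichment of open chromatin and cross-species conservation of regulatory regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD-block enrichment and regulatory conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crenrich)
```

# The question

Open-chromatin peaks from single-cell ATAC experiments are candidates for
cis-regulatory elements.  Two recurring questions about such peak sets are:

1. **Trait relevance.**  Do the peaks fall inside linkage-disequilibrium
   (LD) blocks around trait-associated GWAS variants more often than
   expected for regions of the same sequence composition and genomic
   context?
2. **Evolutionary conservation.**  When peaks are projected onto another
   species through synteny, how many land on accessible chromatin there,
   and does that rate differ between tissues?

`crenrich` implements both analyses as a reusable, tested pipeline, and
ships a synthetic-data generator that emulates every input, so all stages
are verifiable on a desk without any external download.

# LD blocks from phased haplotypes

**Significance filter.**  GWAS SNP records with association p-value
strictly below `p_threshold` (default `5e-8`, the genome-wide significance
convention) seed blocks.  SNPs are processed within their population
group, using that group's haplotype panel, and the resulting blocks are
pooled and merged across groups.

**Haplotype r².**  For phased biallelic variants with allele frequencies
$p_x$, $p_y$ and haplotype frequency $p_{xy}$,

$$ D = p_{xy} - p_x p_y, \qquad
   r^2 = \frac{D^2}{p_x(1-p_x)\,p_y(1-p_y)}. $$

r² with a monomorphic variant is undefined; the block builder treats it as
*not linked* rather than an error, since a monomorphic site carries no LD
information.

**Proxies and the block span.**  A GWAS SNP need not be present in the
panel; the nearest panel variants at or below and at or above its position
act as downstream/upstream proxies (a SNP present in the panel is its own
proxy; a one-sided neighbourhood uses the single available variant for
both).  Every panel variant within the search window is marked *linked*
when its r² with either proxy reaches `r2_min` (default 0.8); the block
runs from the most upstream to the most downstream linked variant.
Overlapping blocks are merged, with provenance (source SNP ids, groups)
pooled; abutting half-open blocks are deliberately left separate.

Choices worth noting:

* **Window.**  "A 500-kb window around the SNP" is read as
  `pos ± window/2` (centred), with `window` a configuration knob.
* **No proxy in the window.**  The SNP yields a degenerate 1-bp block with
  a warning (configurable to drop), so genome-wide hits are never silently
  lost.
* **Coordinates.**  All internal coordinates are 0-based half-open (BED
  convention); VCF and GFF3 positions are converted at the reader
  boundary.  One convention internally eliminates off-by-one drift, and
  overlap is always "at least one shared base".

# Matched background sets

Testing raw peak counts against random genomic intervals conflates
enrichment with sequence composition: peaks are GC-rich and
promoter-biased.  The null therefore resamples regions matched on the
joint distribution of GC content and genomic annotation.

1. **Tiling.**  The genome is tiled into fixed 500-bp half-open tiles
   (terminal partial tiles kept with their true width).
2. **Annotation.**  Each tile and each peak receives exactly one class by
   any-overlap with fixed priority
   `promoter > 5'UTR > 3'UTR > exon > intron > intergenic`.  The promoter
   is a strand-aware `TSS − 2000 / + 200` bp window; both numbers are
   configuration knobs, declared rather than inferred, since "promoter"
   has no universal definition.
3. **GC strata.**  GC content is `(G+C)/(A+C+G+T)` with ambiguous bases
   excluded from numerator and denominator; 10 equal-width bins on
   $[0,1]$ (GC = 1 in the top bin) crossed with the annotation class give
   the sampling strata.
4. **Sampling.**  Each of `n_sets` background sets draws, per stratum,
   exactly the foreground's count, uniformly *without replacement* from
   the eligible tiles.  Per-set seeds are derived deterministically from
   (master seed, set index), so any single set is independently
   reproducible and the result does not depend on iteration order.
   If a stratum is exhausted the sampler borrows deterministically from
   the nearest GC bin with the same annotation, then from the same GC bin
   with priority-adjacent annotation, logging every substitution; a set
   always reaches the full foreground size, and a pool globally smaller
   than the foreground is a hard error with a demand/supply table.

Two deliberate width decisions: background units are 500-bp tiles while
real peaks vary in width; the synthetic generator fixes peak width at
500 bp (the tile width), which makes foreground and background
geometrically exchangeable — a peak and a tile have identical probability
of touching a block of given length — so the permutation test is exactly
calibrated in the simulations.  With variable-width real peaks the width
mismatch is accepted and documented, as the statistic counts peaks rather
than bases.

Excluding foreground-overlapping tiles from the pool (so the null cannot
contain the signal itself) is supported and is the `build_pool()` default.
The default *pipeline* configuration disables it: on a desk-scale
synthetic genome an enriched foreground covers most in-block tiles, and
excluding them would empty exactly the strata the null must sample from.
At genome scale, where peaks cover a few percent of tiles, exclusion is
the better default and costs nothing.

# Enrichment statistics and the empirical p-value

Two statistics are computed on the observed peaks and on every background
set against the same merged blocks:

* **Overlap frequency** — the number of peaks intersecting, partially or
  fully, any block; each peak counts at most once, so the statistic is
  invariant to merging or splitting blocks.
* **Peak density** — overlapping-peak count per megabase of merged block
  length.  A base-pair ratio alternative (`bp_ratio`) is available behind
  a flag; the count-based form matches the per-peak counting style of the
  overlap statistic.

The empirical p-value is the proportion of background sets with a value
**equal to or greater than** the observed one — no add-one correction —
so attainable values are $0, 1/N, \dots, 1$, and a reported 0 carries the
resolution bound "< 1/N".  Both statistics use all $N$ background sets as
the control distribution; a single background set cannot form a
distribution of the test statistic, so the test is one-sided
(enrichment direction) against the full set.  The fold estimate is
`observed / mean(null)`, reported as undefined when the null mean is 0.

# Cross-species conservation

Synteny projection scores in $[0,1]$ (higher = closer to conserved
anchors) are consumed, not computed.  Classification uses strict
thresholds: **direct** above 0.98, **indirect** above 0.84, otherwise
**nonconserved**; exact-boundary scores fall in the lower class,
consistent with the strict inequalities, and both thresholds are
configuration knobs.  The classes partition $[0,1]$ and the mapping is
monotone in the score.

A source differentially accessible region (DAR) is **functionally
conserved** iff, in order:

1. its projection is conserved (direct or indirect) — the gate comes
   first, so a nonconserved projection never yields a call even if its
   coordinates happen to overlap a target DAR;
2. the projection carries target coordinates — a conserved score without
   them (anchor-interpolated) is counted as not functionally conserved;
3. the target interval overlaps ≥ 1 bp of a DAR in the other species,
   irrespective of cell-type correspondence.

Source DARs without a projection record are counted as nonconserved and
logged.  The direction matters: source→target and target→source are
computed separately, never assumed symmetric.

**Identity retention** is the fraction of functionally conserved DARs
whose best-overlapping target DAR (largest overlap, ties to the leftmost
target) shares the source tissue class.  The **tissue rate ratio**
contrasts per-tissue conservation rates
(ectoderm/mesenchyme), with a two-sided Fisher exact test on the 2×2
conserved-by-tissue table — the exact test is a declared choice recorded
in the output, made because small per-tissue counts are common.  A zero
mesenchyme rate yields an infinite ratio with the table attached.

# The synthetic-data generator

The generator is a pure function of (configuration, seed): every source
of randomness flows from one master seed through named substreams, so
outputs are byte-identical across runs and platforms, and each component
(a single background set, a single panel) is independently reproducible.

* **Genome.**  Per-kilobase GC is drawn from a Beta distribution
  (default Beta(42, 58), mean 0.42), with bases i.i.d. within a window
  given its GC — no dinucleotide structure, which no consumer needs.
  Genes are placed uniformly without overlap; each has a strand, exons,
  and 5'/3' UTRs, so every annotation class is realizable.
* **Haplotype panel.**  Chromosomes are partitioned into latent LD
  segments (exponential lengths, default mean 20 kb).  Per segment, two
  complementary ancestral haplotypes are drawn; each present-day
  haplotype inherits one of them for the whole segment with probability
  $\rho$ (orientation Bernoulli(1/2)) and otherwise draws i.i.d.
  alleles.  Between segregating variants this gives expected within-
  segment $r^2 \approx \rho^2$ and cross-segment $r^2 \approx 0$, so the
  default $\rho = 0.95$ puts the within-segment median safely above the
  0.8 block threshold while segment boundaries stay sharp.  This mosaic
  model was chosen over per-site founder copying (which makes sites
  conditionally independent and cannot sustain high r²) and over
  coalescent simulation (more realism than any consumer uses); it gives
  direct, tunable control of the one LD property the pipeline consumes.
  Variant positions and segments are shared across population groups;
  alleles are drawn independently per group.
* **GWAS table.**  2400 SNP records, of which 1687 receive p-values
  strictly below 5e-8 (drawn log-uniformly) and are placed at panel
  positions inside the designated trait blocks; the remainder are
  non-significant and placed anywhere.  Records may share positions, as
  several studies can report the same locus.
* **Peaks.**  Start positions follow a two-level density — baseline
  outside trait blocks, $\lambda \times$ baseline inside — so the
  expected in-block fraction is $\lambda b / (\lambda b + 1 - b)$ for
  block genome-fraction $b$.  Default $\lambda = 5$ with blocks covering
  2% of the genome; widths fixed at 500 bp (see above).
* **DARs and projections.**  DARs are non-overlapping fixed-width
  regions (disjoint, like real peak calls), labelled with cell
  populations mapped to ectoderm/mesenchyme.  Projection classes follow
  the configured mixture (default 14.3% / 41.1% / 44.4%
  direct/indirect/nonconserved, renormalised exactly) by
  largest-remainder allocation, so planted proportions are exact up to
  rounding; scores are uniform within each class band.  Conserved
  regions receive target coordinates that hit a target DAR with
  tissue-dependent probability calibrated to functional-conservation
  rates of 0.44 (ectoderm) and 0.10 (mesenchyme) — a 4.4-fold contrast —
  choosing a same-tissue anchor with probability 0.8 (identity
  retention).  Hit targets are roughly centred on their anchor DAR
  (jitter ≤ w/4), so the anchor is unambiguously the best-overlapping
  DAR; misses are placed in DAR-free sequence.

## What the simulations do and do not show

The generator reproduces the *statistical structure* the analysis
assumes: block-wise LD, GC/annotation heterogeneity, planted enrichment,
mixture-distributed projection scores.  Passing tests therefore
demonstrate that the procedures are correctly implemented and correctly
calibrated under that structure.  They do not certify behaviour on real
data, which additionally has recombination-rate variation, allele
frequency spectra, repeat content, variable peak widths, assembly gaps,
and projection-score error correlated with genomic context — none of
which is modelled.

# Problem sizes and numerical choices

The shipped simulation studies use a 2 × 400-kb genome (1600 tiles),
200-haplotype panels, 500 peaks, and 200 background sets per test, with
200 replicates for the type-I study and 100 for power/fold recovery —
sizes at which the permutation distributions are well resolved while a
full study runs in minutes on one core.  The paper-scale defaults
(1000 background sets) remain the `sample_background()` default.

Other numerical decisions, all surfaced as arguments:

* strict `<` at the significance threshold and strict `>` at both
  conservation thresholds (boundaries fall in the lower class);
* equal-or-greater counting in the empirical p (ties count toward the
  null), no add-one correction;
* proxy distance ties cannot occur (panel positions are strictly
  increasing); equidistant flanking variants resolve down/up
  deterministically by construction;
* class mixtures that sum to 1 within 0.01 (published rounded
  percentages) are accepted and renormalised exactly;
* fold reported as undefined (`NA`) when the null mean is zero rather
  than clamped or inflated.

# Known limitations

* The density statistic in its default count-per-Mb form is a monotone
  transform of the overlap count for a fixed block set, so its empirical
  p equals the overlap p; the `bp_ratio` mode breaks that tie.
* The sampler matches GC and annotation only; distance to TSS,
  mappability, or replication timing are out of scope.
* Projection computation (synteny anchors, bridging genomes) is consumed
  as a score table, never reimplemented.
* Degenerate 1-bp blocks from proxy-less SNPs slightly deflate density
  denominators; they are flagged so callers can drop them.
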
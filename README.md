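# reachmap

Chromatin-associated enzymes that act as rigid molecular bridges — the
cullin scaffolds of cullin-RING ubiquitin ligases are the motivating case —
do not only influence the base pairs their ChIP peaks cover. A scaffold
that spans ~100 Å can reach substrates across neighbouring chromatin, and
on the compacted fibre that physical distance corresponds to kilobases of
linear DNA. `reachmap` implements the analysis built around this idea for
ChIP-seq peak sets: it converts physical reach into a genomic flank,
extends peaks into putative *control domains*, and then asks the questions
such a study needs answered:

- **Co-localization.** Do the domains coincide with another genomic
  landscape (active/repressive histone marks, protein-degradation sites,
  a co-factor's peaks)? Observed overlap is calibrated against an
  *intra-chromosomal permutation null* — peaks are relocated uniformly
  within their own chromosomes, preserving count and lengths — giving a
  fold enrichment `observed / E[null]` and an add-one empirical p-value
  `(1 + #{null ≥ obs}) / (N + 1)`. 2×2 associations are tested with the
  chi-squared test with Yates' continuity correction.
- **Promoter geometry.** Feature distribution of peak anchors
  (promoter / gene body / downstream / intergenic, with the genome-wide
  bp prevalence as baseline) and TSS-relative density profiles.
- **Target genes.** A gene is a target when a peak anchor lies strictly
  within 1 kb of its TSS; target sets can be intersected with a
  co-factor's targets and tested for association.
- **Expression linkage.** Wilcoxon rank-sum tests of log2 fold-change
  shifts in target-gene sets (exact by enumeration for small tie-free
  samples, tie-corrected normal approximation otherwise), ΔΔCt
  quantification of qPCR panels (fold = 2^−ΔΔCt against a reference
  transcript and control condition), and pooled-variance t tests.
- **Motifs.** IUPAC consensus scanning (e.g. the palindromic E-box
  `CACGTG` of the c-MYC/MAX heterodimer) on both strands, with enrichment
  judged against the same relocation null.

A first-class synthetic-data layer (`simulateStudy()` and the individual
generators) produces genomes, gene models, peak sets with planted TSS
proximity, co-occurring peak sets with an *exactly* planted overlap
fraction, sequences with planted motifs, and expression/Ct tables with
planted shifts — so the whole pipeline is testable end to end with known
ground truth and no external downloads.

## Worked example

```r
library(reachmap)

reachToBp(reach_angstrom = 100, rise_nm_per_bp = 0.34, packing_ratio = 102)
#> [1] 3000

cfg   <- syntheticConfig(seed = 42, n_peaks = 120L)
study <- simulateStudy(cfg)                      # planted overlap q = 0.5917
dir   <- file.path(tempdir(), "demo"); writeStudy(study, dir)
p     <- function(f) file.path(dir, f)

report <- runPipeline(list(
  genome     = p("genome.chrom.sizes"),
  peaks_rep1 = p("peaksA.bed"), peaks_rep2 = p("peaksA.bed"),
  genes      = p("genes.bed"),
  landscapes = list(degradation = p("peaksB.bed")),
  cofactor   = p("peaksB.bed"),
  expr       = p("expr.tsv"), fasta = p("genome.fa"),
  seed = 7, n_perm = 200))
```

The report is a plain nested list; the headline numbers it prints for this
fixture are:

```
consensus peaks:     120
extended domains:    92 (650651 bp)
peak overlap:        59.17%
fold enrichment:     2.88 (p = 0.004975)
promoter share:      44.2% of peaks vs 29.9% of genome
target genes:        70
shift test p:        2.33e-19
motif fold / p:      30.17 / 0.004975
```

Reading them: the 120 consensus peaks, extended by the default 3 kb reach
flank, merge into 92 domains; 59.17% of peaks overlap the simulated
degradation landscape — exactly the fraction the generator planted
(`round(0.5917 × 120)/120 = 71/120`); the domains are 2.9-fold enriched
for that landscape relative to the permutation null at the smallest
empirical p attainable with 200 permutations; peak anchors concentrate in
promoters relative to the genomic baseline; the 70 TSS-proximal target
genes carry the planted expression shift (one-sided rank-sum p ≈ 2e−19);
and the E-box planted in every peak is recovered as a 30-fold motif
enrichment.

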
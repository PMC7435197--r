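---
title: "Reach-based chromatin co-localization: models, nulls and design choices"
author: "reachmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reach-based chromatin co-localization: models, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachmap)
library(GenomicRanges)
```

# The model

Chromatin immunoprecipitation localises a DNA-associated factor to peaks,
but a rigid bridging enzyme influences more DNA than it touches. The
package's central conversion treats the factor's physical reach $R$ (in
ångström) as a straight line through the compacted chromatin fibre. With
a B-DNA rise of $r$ nm/bp and a fibre packing ratio $\kappa$ (the fold
compaction of linear DNA inside the fibre), the genomic flank is

$$F \;=\; \mathrm{round}\!\left( \frac{R \times 0.1\,\mathrm{nm/\text{Å}} \times \kappa}{r} \right)\ \mathrm{bp}.$$

Defaults are $R = 100$ Å, $r = 0.34$ nm/bp and $\kappa = 102$, giving
$F = 3000$ bp exactly. The packing ratio is the one genuinely soft
parameter: estimates for the solenoid fibre vary widely with salt,
nucleosome repeat length and method. We expose it explicitly and choose
102 as the default so that the canonical 100 Å reach maps onto the round
3 kb flank used in practice; users modelling looser or tighter fibres
should set it themselves. Rounding is to the nearest base pair because
flanks are whole bases. `extendIntervals()` widens each peak by $F$ on
both sides, clips at chromosome boundaries, and by default merges the
result (abutting counts as mergeable), so that downstream fractions have
unambiguous region denominators.

# Coordinates and containers

Intervals live in `GRanges` (1-based, closed), genomes in `Seqinfo`,
sequences in `DNAStringSet` — the standard Bioconductor containers. BED
input/output converts to and from the 0-based half-open convention at the
file boundary, and round-trips are coordinate-exact. The overlap
predicate everywhere is "at least one shared base"; abutting intervals do
not overlap but do merge. Motif hit positions are reported 1-based, in
line with the rest of the Bioconductor ecosystem.

Two replicate-consensus rules are provided because peak-level Venn
intersections are ambiguous: `"anchored"` keeps the replicate-1 peaks
touched by replicate 2 (peak-anchored, preserves peak identity and
metadata), `"intersect"` takes the base-wise intersection of the merged
sets. `"anchored"` is the default; analyses should record which rule they
used, since counts differ between them.

# The permutation null

All enrichment statements are calibrated against an intra-chromosomal
permutation null: each query interval is relocated to a uniform position
within its own chromosome, preserving per-chromosome interval counts and
the multiset of lengths. The landscape set is held fixed. With $N$
permutations and observed statistic $s$, we report

* fold enrichment $s / \bar{s}_{\mathrm{null}}$, and
* the add-one empirical p-value $(1 + \#\{s_{\mathrm{null}} \ge s\})/(N+1)$
  (or $\le$ for the depletion tail), which is never zero and is the
  standard permutation-test estimator.

Design choices worth knowing:

* **Relocated intervals may overlap each other** by default. That is the
  plainest reading of "randomised peaks of equal number and size", and it
  makes the null exchangeable with the (possibly overlapping) query set.
  A non-overlapping variant is available for sensitivity analysis; it
  places intervals sequentially (largest first, with restarts), which is
  uniform enough for that purpose but is *not* exactly the uniform
  distribution conditional on disjointness.
* **Degenerate cases are flagged, not hidden**: a zero null mean with a
  positive observation reports fold `Inf` with a `"zero-null"` flag; zero
  signal everywhere reports fold 1 with `"zero-signal"`.
* For the interval-hit statistics the null is computed vectorised (all
  $N$ relocations drawn at once, one overlap query), which keeps
  $N = 1000$ permutations on hundreds of peaks in the tens of
  milliseconds; base-pair statistics fall back to a per-permutation loop.
* No GC-, mappability- or distance-matched nulls are attempted; that is
  deliberate scope, and claims should be read accordingly.

The null is verified two ways in the test suite: conservation (counts and
length multisets invariant under permutation) and calibration — for
independently placed query and landscape sets, the mean fold enrichment
over 200 replicates sits within Monte-Carlo error of 1 and the empirical
p-values are uniform (the fraction below 0.05 falls in the binomial 99%
band [0.02, 0.09] at 200 replicates).

2×2 associations (e.g. regions hit by an active mark versus a repressive
mark) use the chi-squared test with Yates' continuity correction,

$$\chi^2 = \frac{n\,\bigl(\max(|ad-bc| - n/2,\,0)\bigr)^2}{(a{+}b)(c{+}d)(a{+}c)(b{+}d)},$$

with the corrected deviation clamped at zero. The implementation is the
closed formula (cross-checked in tests against `chisq.test(correct =
TRUE)` on random tables); both the permutation p and the contingency p
are reported side by side where both apply, since they answer subtly
different questions.

# TSS annotation

The TSS is the strand-dependent 5′ end of a gene model (BED start on
`+`, end−1 on `-` in file coordinates). Peaks are reduced to a single
anchor — the midpoint by default, a `summit` metadata column when one is
provided — and signed distances are oriented in gene coordinates
(negative = upstream). A gene is a *target* when some anchor satisfies
$|d| < 1000$ bp, strictly; the bound is symmetric about the TSS because
nothing in the biology forces upstream-only proximity, but an
`upstream_only` switch restricts it for users who prefer the promoter
reading. Target sets are nested in the distance bound, and are invariant
under mirroring the genome (a property test).

Feature distribution classifies anchors with precedence
promoter > gene body > downstream > intergenic. The promoter window is
3 kb upstream / 0 bp downstream of the TSS — a conventional
promoter-annotation default; the "downstream" window is 3 kb past the 3′
end. The genome-wide bp share of each category is reported as the
baseline against which peak shares are judged. TSS profiles histogram the
signed distance to the *nearest* TSS (ties broken toward the gene earlier
in sorted order) over half-open bins in $[-w, w)$ and normalise to unit
in-window mass.

# Expression linkage

`geneSetShiftTest()` compares target-gene log2 fold changes against all
measured non-target genes by default (an explicit background set can be
given instead, e.g. one ontology against another). The rank-sum p-value
is exact by enumeration when the samples are tie-free and
$\binom{n_x+n_y}{n_x} \le 200{,}000$, otherwise a normal approximation
with tie-corrected variance and 0.5 continuity correction; the cutoff and
correction are fixed constants so results are identical across platforms.
Multiple gene-set tests run through `shiftTestBattery()` report raw and
Benjamini–Hochberg adjusted p-values side by side, labelled; nothing is
silently adjusted.

ΔΔCt quantification references each gene's Ct to the reference transcript
within the same replicate and condition, averages replicate ΔCt within
condition, and references to the control condition: fold
$= 2^{-\Delta\Delta Ct}$. Replicates are paired to the reference within a
replicate ID but conditions are treated as unpaired; dispersion is the SD
of replicate ΔCt. Adding a constant to every Ct of a condition (a plate
effect hitting target and reference alike) provably leaves all folds
unchanged, and the noiseless simulator inverts exactly through `ddct()`.
The two-sample comparisons reported alongside qPCR panels use the
two-sided pooled-variance t test.

# Motif scanning

Motifs are IUPAC consensus strings matched exactly (no PWMs — the E-box
claim rests on the consensus; PWM support would be an extension point).
`N` in the subject never matches. Both strands are scanned; palindromic
consensi (such as `CACGTG`) match both strands at the same position and
are counted once. Enrichment reuses the relocation null: relocated peaks
are re-scanned against the same genome sequence. Dinucleotide shuffling
is *not* used; relocation keeps the motif framework consistent with the
interval framework. An optional `window` recentres peaks to a fixed width
around their anchors before scanning, for peak sets with very
heterogeneous widths.

# The synthetic study

The generators define the conditions every statistical claim is tested
under; they are parameters of the study, not tuning knobs. Defaults: 3
chromosomes × 1 Mb, i.i.d. sequence at GC 0.41 (human-like), 300
non-overlapping genes (2–10 kb, gaps-method uniform placement, random
strands), 120–200 disjoint peaks of 200 bp, half of them with anchors
planted strictly within 1 kb of a random TSS, a co-occurring peak set
with planted overlap fraction q = 0.5917, expression shifts of +0.5 log2
units at noise SD 0.5 in 100 targets against 900 background genes, and
guaranteed motif planting. The planted-overlap construction is exact:
hit peaks are placed inside distinct (disjoint) base intervals and the
remainder rejection-sampled to avoid the base set, so the recovered
fraction equals $\mathrm{round}(q n)/n$ with no sampling error. A single
master seed fans out to fixed per-generator sub-seeds, so adding a
generator never perturbs existing fixtures.

What the synthetic data deliberately does **not** emulate: read-level
noise, fragment-size effects, GC and mappability bias, peak-width
heterogeneity of real callers, correlated gene placement (clusters,
bidirectional promoters), and realistic expression covariance. Passing
tests therefore demonstrate the *statistical machinery* — exact
recoveries, calibrated nulls, power at planted effect sizes — not
robustness to real-data artefacts. On real data the undocumented choices
(consensus rule, merged vs unmerged denominators, symmetric vs upstream
windows) move headline percentages by several points, which is why the
pipeline reports its configuration inside every report.

# Problem sizes and numerical choices

Simulations in the tests and the acceptance script use the toy scale
above (per-base oracle checks run on ≤100 kb genomes; null calibration
uses 200 replicates of 99 permutations; type-I checks 500 simulations),
chosen so the whole suite completes in a few minutes while keeping
binomial tolerance bands meaningful. Fractions are compared exactly where
the construction is exact, and within explicit tolerance bands (3 SE, or
binomial 99% bands) where they are stochastic. Empty sets, zero margins,
genes on unknown chromosomes, motifs absent from the genome and
single-placement permutations all have defined behaviour (error, flag or
warning — never silence).

# Limitations

* The reach model is geometric, not polymeric: no persistence length, no
  looping probabilities, one κ for the whole genome.
* The permutation null ignores sequence composition and chromatin
  accessibility; enrichment against marks that track GC will be
  optimistic.
* Consensus motif matching has no mismatch tolerance.
* CEAS-style exon/intron subclassification and transcript isoforms are
  out of scope; gene models are single intervals.
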
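---
title: "Methods: models, parameters, and design choices in stemchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in stemchrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and rules behind each stage, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the places where the design was genuinely open
and a choice had to be made.

## The biological question

Planarian neoblasts are the only dividing somatic cells of the animal, and
the genes specifically expressed in them turn out not to be regulated like
tissue-specific genes. Tissue-specific promoters carry a nucleosome-free,
accessible region roughly 200 bp upstream of the TSS, enriched for
transcription-factor motifs and AT trinucleotide tandem repeats.
Stem-cell-specific and constitutive promoters instead show only a mild,
TSS-centered accessibility gain flanked by firmly positioned -1/+1
nucleosomes, an Initiator-like element at the TSS, and an extreme sequence
signature: over 90% AT in the ~200 bp before the TSS, a T-over-A strand
bias, and repeated poly(dT) tracts — homopolymeric dA:dT runs that lower
nucleosome affinity. `stemchrom` operationalizes each observation as a
testable computation, and ships a generator that plants all of these
signals so the whole chain can be verified against known truth.

## Expression classification

**Model.** Counts are TPM-normalized (`tpm = 1e6 * rate / sum(rate)` with
`rate = count / length`). All unordered pairs of the five isolations
(brain, epidermis, intestine, pharynx, neoblast) are contrasted, and genes
are labeled by rules on the contrast table:

* specific to isolation X: `log2FC > 1` and `p_adj < 0.05` versus every
  other isolation (strict inequalities; a gene at exactly `log2FC = 1` in
  one required contrast is not called);
* constitutive: mean TPM > 10 in every isolation and **no** contrast with
  `|log2FC| > 1` and `p_adj < 0.05`;
* otherwise unclassified.

The published definition of "constitutive" is internally inconsistent in
its source ("expressed in all the samples and all P_adj < 0.05" cannot
describe genes expressed at similar levels everywhere); we implement the
concept as stated in words — expressed everywhere, no significant pairwise
difference.

**The contrast engine is pluggable.** The default engine fits one
negative-binomial GLM across all isolations with DESeq2 and extracts Wald
contrasts per pair; fold changes are therefore median-of-ratios
normalized. This matters for two reasons. First, with three replicates per
isolation a per-gene Welch t-test has ~4 degrees of freedom; its p-values
cannot support a rule that demands four simultaneously significant
contrasts, and classification sensitivity collapses. Dispersion sharing
across genes (DESeq2's shrinkage) is the standard remedy at this replicate
count. Second, TPM-based fold changes carry a composition bias: an
isolation with no up-regulated gene set of its own (the pharynx here) has
a smaller total signal, which inflates its TPMs and shifts every fold
change against it by a constant; median-of-ratios normalization removes
this. A self-contained `engine = "welch"` (two-sided Welch on
`log2(TPM + 1)`, BH within each contrast, fold change from mean TPMs with
pseudocount 1) is retained for transparency and for data without raw
counts, and externally computed contrast tables in the package's TSV
schema are accepted directly, so users with their own DESeq2 runs can keep
them.

**Expression bins.** >30 TPM high, <10 weak, and the closed interval
[10, 30] "expressed": the published bin edges are open on both sides, so
boundary values are assigned to the middle bin to keep the bins
exhaustive. A gene's reported bin uses its best (highest mean TPM)
isolation.

## Chromatin profiling

All fragment-window statistics count a fragment when it overlaps the
window by at least 1 bp (read-coverage semantics, matching the profiling
tools the field uses) and scale as
`RPKM = count * 1e9 / (window_bp * library_size)`. Metaprofiles average
binned RPKM across the genes of a class in a strand-oriented +/-1 kb
window; the bin size (10 bp default) is a free parameter with no published
value. Per-gene promoter architecture is summarized by the argmax of the
binned signal, ties broken toward the TSS — the same tie rule used by
`max_signal_region()`, which reports the maximum-signal bin in the 2-kb
upstream promoter only when it exceeds 10 RPKM (strictly).

**Consensus peaks** require a peak present (>= 1 bp mutual overlap) in all
replicates (3 by default) with every member's `-log10 p` strictly above 4.
The score is interpreted as `-log10` because that is the convention of the
peak caller that produces the column. Consensus coordinates are the union
of the member intervals; union versus intersection is not specified
anywhere, and union is the conservative choice for downstream feature
assignment by summit. Summit-based feature assignment uses the fixed
priority promoter > exon > intron > TE > intergenic with the promoter
defined as the strand-aware 2 kb upstream of the TSS.

**Nucleosome occupancy proxy.** Model-based occupancy callers infer
nucleosome positions from the joint distribution of insertion sites and
fragment sizes; reimplementing one is out of scope here. The package's
proxy is deliberately simple and fully specified: the density of midpoints
of nucleosome-sized fragments (150-250 bp), Gaussian-smoothed with
sigma = 20 bp, normalized to the mean over the distal flanks
(|position| in [800, 1000] bp). Against planted phased nucleosomes the
proxy recovers modes within a few bp of truth; on real data it should be
read as relative positioning signal, not absolute occupancy.

## Promoter sequence statistics

Promoters are extracted strand-aware (minus-strand genes
reverse-complemented) so position -1 always abuts the TSS; windows that
run off a contig are N-padded and flagged. Composition, T-stretch, k-mer,
and tandem-repeat statistics are computed on the coding strand only,
because the T-over-A bias they measure is strand-asymmetric; genomic motif
scans for accessibility profiles scan both strands.

* **T-stretches** are maximal runs (a run of 7 T's counts once); the
  minimum length (default 5) is configurable since no published minimum
  exists. Class comparisons use two-sided rank-sum tests with Bonferroni
  correction.
* **k-mer enrichment** compares overlapping k-mer counts (default k = 9)
  against a background sequence set: expected counts from background
  frequencies, `log2((obs + 0.5) / (exp + 0.5))` enrichment, and an upper
  binomial tail p-value (positions treated as independent — an
  approximation that ignores overlap dependence; exact overlap-aware nulls
  are out of scope). The background frequency used in the p-value is
  floored at half a count so k-mers absent from the background cannot
  claim p = 0. Results are ranked by significance, then enrichment: with
  a pseudocount, a k-mer seen 30 times against an expectation of zero
  would otherwise outrank one seen 600 times against an expectation of 9.
* **Tandem arrays** are maximal stretches where the sequence repeats with
  the requested period (>= 3 full units by default); the maximal extent
  may include a partial trailing unit, and `n_units` counts full units.
  Arrays whose unit is all A/T are flagged, since AT trinucleotide repeats
  are the tissue-promoter signature.
* **PWM scanning** scores log2 odds against the motif's background, with
  zero cells floored at 1e-3 before the log. Hit thresholds come either
  directly as scores or from a p-value via exact enumeration of the score
  distribution under the background model. The enumeration accumulates on
  a rounded grid; numerically split ties are merged (gap < 1e-5) so a tie
  group is never cut in half, and the returned threshold carries a 5e-6
  margin so boundary instances scored without rounding still qualify. The
  Inr and TATA matrices shipped under `inst/extdata/pwm/` are editable
  placeholders with the right qualitative shape (pyrimidine-purine
  Inr-like; TATAWAWR-like), not empirically derived motifs; the planted
  tissue TF matrix is a synthetic information-rich 8-mer fixture.

## Hi-C compartments

Compartments are called per contig at 50-kb resolution: low-coverage bins
are removed, the matrix is balanced, distance decay is divided out, and
the compartment signal is the leading eigenvector of the Pearson
correlation matrix of the observed/expected rows (equivalently the first
principal component), reallocated to original bin coordinates with `NA` at
the dropped bins.

Numerical choices worth stating:

* **White strips.** The drop rule is: all zero-coverage bins, plus bins
  whose row sum falls below 5% of the median nonzero row sum. A
  quantile-based rule would unconditionally discard its quantile's worth
  of bins even in a fully covered matrix; the fraction-of-median form
  drops nothing when nothing is wrong and cleanly separates near-zero
  strips, which sit orders of magnitude below the median.
* **Balancing** uses the symmetric fixed-point iteration
  `x <- x / sqrt(rowsums)` to the Knight-Ruiz target (all row sums of
  `DMD` equal), converging when the row-sum coefficient of variation
  falls below 1e-6; non-convergence is an error that reports the
  iteration count rather than returning a half-balanced matrix.
* **Orientation.** The eigenvector's sign is arbitrary, so the track is
  oriented per contig such that the positive side has the higher mean
  accessibility (the A compartment is the more accessible one); when
  accessibility is missing for most bins, gene density is the documented
  fallback. Whether the source analysis took the correlation of O/E or of
  raw balanced counts is not stated; the O/E-correlation convention is
  adopted because it removes the distance decay that otherwise dominates
  the leading component.
* **Feature enrichment** for family f in compartment C is (fraction of
  f's bases in C) / (C's share of labeled bins), so a uniformly
  distributed feature scores exactly 1.0 — the genome-wide reference.

## Colony quantification

The detection chain mirrors automated nucleus-counting plugins: a
contrast-enhancing "Laplacian of size n" — implemented as center minus
neighborhood mean with in-plane radius `n`, extended along z with the
radius scaled by voxel anisotropy (`round(n * voxel_x / voxel_z)`) in 3D
mode — followed by a threshold at `mean + f * sd` of the filtered image
and connected-component labeling (8-connectivity per slice in 2D,
26-connectivity in 3D), with a minimum object size (default 8 voxels).
Whether the published threshold factor multiplies the mean, the standard
deviation, or an absolute level is not stated; `mean + f * sd` is the
choice here, isolated in one function. The count-normalized mean makes
the filter's response to a constant image exactly zero, including at the
edges, so segmentation is invariant to adding a constant to the raw
image, and the whole chain is invariant to affine intensity rescaling —
which is also why stacks can be stored as [0, 1]-scaled 32-bit TIFF
without affecting detection.

Centroids are intensity-unweighted voxel means scaled by the per-axis
calibration (defaults: the 10x objective, 2.76 x 2.76 x 7 um). Colonies
are the connected components of the graph joining centroids at Euclidean
distance strictly below 50 um; the closure is transitive (chains merge)
and a pair at exactly 50.0 um stays split.

## The synthetic-data generator

Every generator is a pure function of a `simulation_plan`; identical plans
produce byte-identical artifacts because each stage seeds its own RNG from
the plan seed plus a fixed offset (so artifacts do not depend on call
order).

What is emulated, and the defaults chosen for it:

* **Genome**: i.i.d. bases at 70% AT (the genome-wide level), because the
  analyses measure composition, not higher-order sequence structure.
  Genes sit in fixed slots wide enough that no promoter or profile window
  can touch a neighboring gene, on random strands, two exons each.
* **Constitutive/stem promoters**: the [-200, -1] window is rewritten to
  exactly ceil(200 x 0.92) AT bases (T with probability 0.65), with 2-3
  poly(dT) runs of 6-12 nt separated by planted `A` flanks so each run
  stays a distinct maximal run, and an Inr instance across the TSS.
* **Tissue promoters**: one TF-motif instance placed in [-300, -100] and
  two AT trinucleotide tandem arrays (4-8 units) further upstream; 10% of
  tissue promoters also get an Inr. Planted motif instances are sampled
  from the PWM conditional on a log-odds score at least as high as a
  stringent scan threshold (p = 1e-4) — planted sites emulate functional,
  high-affinity instances, and a scan at that stringency recovers them
  all.
* **Counts**: negative-binomial, dispersion 0.1, three replicates of five
  isolations; class genes are 4-fold up in their matching isolation;
  base means are log-normal around class-typical levels (specific ~80,
  constitutive ~200, unclassified ~0.5 expected counts — the last chosen
  to keep unclassified genes clearly below the 10-TPM "expressed" line
  rather than hovering at the threshold). Library sizes per isolation are
  not published; depth is free.
* **Fragments**: Poisson counts around per-promoter class templates
  (tissue: a strong sub-nucleosomal enrichment at -200 +/- 50 bp in the
  matching isolation only; constitutive/stem: a milder TSS-centered
  enrichment plus nucleosome-sized fragments with midpoints at -180 and
  +120 +/- 20 bp; H3K4me3 downstream of the TSS, stronger for
  constitutive/stem), over a uniform genomic background. Template
  intensities are printed by `fragment_templates()`.
* **Hi-C**: power-law distance decay (exponent 1) times a 2x boost for
  same-compartment pairs on an alternating 10-bin checkerboard; 10% of
  bins become near-zero "white strips" (expected counts scaled by 0.02);
  per-bin accessibility is log-normal and twice as high in A; genic bases
  are uniform across compartments — deliberately reproducing the negative
  result that compartments carry no genic enrichment.
* **Image stacks**: Gaussian blobs (sigma 6 um, peak amplitude `snr`
  times the total background SD) over Gaussian detector noise plus sparse
  (1%) single-voxel hot pixels at 15x the detector SD. The hot pixels are
  deliberate: real detector backgrounds are heavy-tailed, the resulting
  global SD keeps the `mean + f * sd` threshold above the Gaussian bulk,
  and the spikes themselves are removed by the minimum object size. With
  a purely Gaussian i.i.d. background the threshold would always pass a
  fixed ~Phi(-f) fraction of voxels, whose 26-connected clusters are not
  separable from dim blobs by any size filter — no parameter setting can
  make that noise model behave like confocal data. The default colony
  field places cells on a jittered 26-um grid per colony: adjacent cells
  chain at well under the 50-um cutoff, no two cells sit so close that
  their segmented objects merge, and colony centers are far enough apart
  that distinct colonies never approach the cutoff.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level sequencing artifacts (the generator
emits fragments, not FASTQ), mappability and alignment error, GC and
length biases in counts, between-replicate batch structure, higher-order
genome sequence structure (beyond planted motifs and repeats), distance-
dependent Hi-C noise beyond Poisson, TADs or loops, optical PSF blur and
depth-dependent attenuation in stacks, and touching or overlapping
nuclei. Results on real libraries depend on upstream processing choices
that are out of scope here (trimming, alignment, deduplication, peak
calling).

## Problem sizes and determinism

The shipped tests and the acceptance script run at sizes chosen to
exercise the statistics without waste: 1,000-gene count simulations for
classification (one effect run plus ten null runs), 200 planted promoters
per architecture for profile recovery, 1,000 random sequences for each
brute-force oracle comparison, ten 100-bin contact maps, one hundred
random centroid sets of up to 500 points for the clustering oracle, five
SNR-5 image stacks, and two complete pipeline runs compared byte for
byte. The pipeline writes a timestamped log, but every analysis artifact
(including `report.md`) is a pure function of the resolved configuration,
which is itself written beside the outputs.

## Known limitations

* The Welch engine is underpowered at three replicates by construction;
  it exists for transparency and for TPM-only inputs, not as the
  recommended default.
* The k-mer p-values ignore overlap dependence between positions and
  should be read comparatively (rankings), not as calibrated tail
  probabilities for low-complexity k-mers.
* The nucleosome proxy reports relative midpoint density, not occupancy
  probability; flank normalization fails gracefully (with a warning) when
  a class has no distal nucleosomal fragments.
* Compartment calling assumes each contig is long enough for a meaningful
  correlation matrix (tens of bins); very short contigs should be
  excluded by the caller.
* Colony assignment operates on centroids only; two touching cells merged
  by segmentation are counted once, which is why the generator keeps
  planted cells at least ~20 um apart and why very dense real colonies
  will undercount.
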
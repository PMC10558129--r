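# stemchrom

Regulatory-genomics toolkit for asking how adult pluripotent stem cells
(planarian neoblasts), differentiated tissues, and constitutively expressed
genes differ in promoter architecture — and for quantifying the cellular
readout of that regulation in imaging data.

Planarian gene regulation poses an unusual problem: tissue-specific genes
carry a classic architecture (a nucleosome-free accessible region ~200 bp
upstream of the TSS harboring transcription-factor motifs, plus AT
trinucleotide tandem repeats further upstream), whereas stem-cell-specific
and constitutive genes show only a mild TSS-centered accessibility gain,
firmly phased -1/+1 nucleosomes, an Initiator-like motif at the TSS, and
promoters whose AT content exceeds 90% with a T-over-A bias and repeated
poly(dT) tracts. `stemchrom` implements the full analysis chain that
distinguishes these regimes:

* **Expression classification** — TPM normalization, all pairwise
  differential contrasts between five cell isolations (brain, epidermis,
  intestine, pharynx, neoblast; DESeq2 engine by default, a self-contained
  Welch engine and external contrast tables as alternatives), and the rule
  set: a gene is *specific* to an isolation if `log2FC > 1` and
  `p_adj < 0.05` against **every** other isolation; *constitutive* if
  expressed (>10 TPM) everywhere with no significant contrast; otherwise
  *unclassified*. Expression bins: >30 TPM high, 10-30 expressed, <10 weak.
* **Chromatin profiling** — strand-aware TSS metaprofiles (RPKM, +/-1 kb),
  per-gene position-of-maximum signal in the 2-kb promoter,
  `log2(ATAC / H3K4me3)` over the TSS-centered 2-kb window,
  replicate-consensus peak filtering (present in all replicates,
  `-log10 p > 4`), peak-to-feature assignment
  (promoter > exon > intron > TE > intergenic), and a fragment-midpoint
  nucleosome-occupancy proxy (150-250 bp fragments, Gaussian-smoothed,
  flank-normalized).
* **Promoter sequence statistics** — positional base composition, maximal
  poly(dT) run counting, nonamer enrichment against a background set with
  binomial tails, perfect tandem-repeat scanning, and log-odds PWM scanning
  with exact p-value thresholds (Inr/TATA fixtures included).
* **Hi-C A/B compartments** — white-strip removal, KR balancing,
  observed/expected, the leading eigenvector of the Pearson correlation
  matrix with reallocation of dropped bins, orientation by accessibility,
  and per-family feature enrichment normalized so a uniform feature scores
  1.0.
* **Colony quantification** — Laplacian (center-minus-neighborhood-mean)
  contrast enhancement of calibrated image stacks, `mean + f*sd`
  thresholding with 26-connected 3D labeling, physical centroids, and
  colony assignment as the transitive closure of centroid pairs closer
  than 50 um.
* **Synthetic data with planted truth** — a [simulation_plan()]-driven
  generator for every input (genome + annotation, replicated counts,
  ATAC/H3K4me3 fragments, checkerboard Hi-C with coverage strips, blob
  image stacks), so each stage is testable end to end without downloads.

## Worked example

```r
library(stemchrom)

plan <- simulation_plan(
  seed = 1,
  n_genes_per_class = c(brain = 40, epidermis = 40, intestine = 40,
                        neoblast = 40, constitutive = 60,
                        unclassified = 40))

counts <- simulate_counts(plan)
fit <- classify_expression(counts, engine = "deseq2")
glance(fit)
#> # A tibble: 1 x 8
#>   n_genes engine brain epidermis intestine neoblast constitutive unclassified
#> 1     260 deseq2    39        39        40       36           58           48
```

Of 260 simulated genes, the contrast rules call 39/40 brain, 39/40
epidermis, 40/40 intestine, 36/40 neoblast, and 58/60 constitutive genes
correctly; the few misses land in `unclassified`, never in a wrong class.

```r
bundle <- simulate_genome(plan)
atac <- simulate_fragments(plan, bundle, "ATAC")
tissue <- tss_argmax(atac[atac$isolation == "brain", ],
                     bundle$genes[bundle$genes$class == "brain", ])
mean(tissue$argmax_position >= -300 & tissue$argmax_position <= -100)
#> [1] 1
stem <- tss_argmax(atac[atac$isolation == "neoblast", ],
                   bundle$genes[bundle$genes$class == "constitutive", ])
mean(abs(stem$argmax_position) <= 50)
#> [1] 1
```

Every brain-specific promoter has its accessibility maximum in the
upstream [-300, -100] window, and every constitutive promoter is
TSS-centered — the two planted architectures separate perfectly.

```r
prom <- extract_promoters(bundle$genome, bundle$genes,
                          upstream = 500, downstream = 500)
at_content(prom, from = -200, to = -1, by = "class")
#>   constitutive 0.911 | neoblast 0.911 | tissue classes ~0.69
```

Constitutive and neoblast promoters reach 91% AT in the 200 bp before the
TSS against a ~70% AT genome, as planted.

```r
cc <- simulate_contacts(plan)
track <- call_compartments(cc)
oriented <- orient_and_enrich(track, cc$accessibility)
table(oriented$track$label, useNA = "ifany")
#>    A    B <NA>
#>   44   46   10
```

The 100-bin contact map resolves into A and B compartments with `NA`
exactly at the ten planted low-coverage strips.

A complete run of all stages (`simulate` through `report`) is one call:

```r
run_pipeline(list(seed = 7), outdir = "out")
```

or, from a shell, via the thin wrapper `inst/cli/stemchrom`:

```sh
Rscript inst/cli/stemchrom all --seed 7 --outdir out
```

Both write per-stage TSV artifacts, the resolved configuration, and a
deterministic `report.md`.

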
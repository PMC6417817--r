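---
title: "Calling KIR gene copy number from short-read cohorts"
author: "kircn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling KIR gene copy number from short-read cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The killer immunoglobulin-like receptor (KIR) locus on chromosome 19q13.4
holds up to 16 genes that regulate natural-killer-cell activity through
interactions with MHC class I. The genes are recent paralogs with very
high sequence identity, and individuals differ both in which genes they
carry and in how many copies. Short reads from the locus map ambiguously
across paralogs, so depth-of-coverage copy-number callers, which assume
reads can be assigned to a locus, break down here.

`kircn` sidesteps read mapping entirely. It works with substrings: a
**unique k-mer** of gene $g$ is a length-$k$ sequence that (as itself or
its reverse complement) occurs in *every* allele of $g$ and in *no*
allele of any other gene in the reference. Occurrences of such k-mers in
a sample's reads can only come from copies of $g$, whatever the allele,
so their abundance measures the gene's copy number directly.

## The model

For each sample $s$ and gene $g$ with unique k-mer set $U_g$, the
pipeline counts canonical-space occurrences $c_{s,u}$ of every
$u \in U_g$ across every read window (overlaps included) and aggregates

$$a_{s,g} = \frac{1}{|U_g|}\sum_{u \in U_g} c_{s,u},$$

the mean per-k-mer count. The mean, not the sum, keeps genes with
different k-mer richness on one comparable axis. Sequencing-depth
differences are removed with a background panel of unrelated genes
(default: up to 100 unique 30-mers from each of a set of random genes):

$$f_{s,g} = a_{s,g} / N_s, \qquad
  N_s = \operatorname{mean}_b\; a_{s,b} \text{ over background genes } b.$$

$f_{s,g}$ is proportional to the copy number of $g$ in $s$ and is, by
construction, invariant to uniform scaling of a sample's counts.

Four normalizer variants exist (mean or median over background genes, of
per-gene mean k-mer counts or of reads-with-≥1-hit);
`evaluate_normalization()` scores all of them at every candidate $k$ by
the residual variance of the anchor gene KIR3DL3, which is diploid in
nearly everyone, so any variance left after normalization is error. Two
details matter:

* the four methods put $f$ on different absolute scales, so the score is
  the variance of the *mean-scaled* frequency (a squared coefficient of
  variation), which is scale-free;
* a sample variance over $n$ samples has relative standard error about
  $\sqrt{2/n}$, so candidates within 10% of the minimum are treated as
  tied and resolved toward larger $k$ (better coverage of low-frequency
  genes), then toward the (mean, k-mer occurrences) method. The shipped
  default is $k = 30$ with that method.

## From population densities to copy numbers

Copy number is *not* callable per sample: the frequency scale of each
gene is learned from the cohort. For each gene the per-sample
frequencies are pooled into a Gaussian kernel density (Silverman
bandwidth, 512-point grid on $[0, 1.1\max f]$, reflected at zero so a
copy-0 mass at $f=0$ keeps its weight). Peaks are prominence-filtered
local maxima (floor: 2% of the maximum density; boundary maxima count,
with one-sided prominence). Genes fall into three documented categories:

* **anchor** (diploid in nearly everyone): the highest peak is copy 2;
  its extent — where density drops below 10% of the peak height — bounds
  the copy-2 interval, one peak-width further left separates copy 0 from
  copy 1, and beyond the right edge is 3+;
* **high-frequency non-anchor**: three peaks map left-to-right to
  copies 0/1/2, with the inter-peak valleys as cutoffs and the right
  extent of the third peak opening the 3+ interval;
* **low-frequency non-anchor**: two peaks map to copies 0/1; the valley
  between them is the 0/1 cutoff and hypothetical higher-copy peaks are
  extrapolated at multiples of the inter-peak distance $d$ beyond the
  copy-1 peak, with cutoffs at the midpoints (peak$_1$ + $d/2$,
  peak$_1$ + $3d/2$).

Samples closer to any cutoff than the exclusion margin — the 1/2 cutoff
divided by 50 — are excluded for that gene rather than guessed.

Genes with no unique k-mers co-segregate with indexed genes and are
inferred: KIR2DS1 = KIR3DS1, KIR2DL2 = KIR2DS2, KIR3DL1 = KIR2DS4,
KIR2DL5A = KIR2DS3 + KIR2DS5, and KIR2DL3 = 2 − KIR2DS2 (inverse
co-segregation; results below 0 are clamped and flagged, sums above 3
are reported as "3+"). A target is excluded wherever a source is.

```{r pipeline}
library(kircn)

lib <- read_allele_library("kir_alleles.fasta")        # IPD-style headers
idx <- extract_unique_kmers(lib, k = 30)
bg  <- select_background_kmers(bg_lib, lib, idx, k = 30, seed = 1)

counts <- lapply(sample_files, function(f)
  count_kmers(read_sample_reads(f), idx, bg))
freqs <- cohort_frequency_matrix(counts, idx, bg)
cn <- call_copy_numbers(freqs, kir_default_config())
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 30 | k-mer length (bases); the selection sweep supports 10–40 |
| `max_per_gene` | 100 | background k-mers kept per background gene |
| `min_prominence` | 0.02 | peak floor, fraction of maximum density |
| `anchor_edge_fraction` | 0.1 | peak-extent cutoff, fraction of peak height |
| `exclusion_divisor` | 50 | margin = (1/2 cutoff) / divisor |
| `min_samples` | 50 | cohort floor for density estimation |
| `random_gene_min`, `kir_min` | 40000, 20000 | coverage filters (total k-mer counts; cohort-scale values for a 100-gene panel at exome depth) |

The coverage filters retain a sample only when both totals reach their
threshold (strictly-below excludes). The defaults are full-cohort-scale
numbers; desk-scale simulated cohorts need proportionally smaller ones.

## What the simulator emulates — and what it does not

`simulation_config()` generates the structure the caller relies on: a
gene family sharing a common backbone (75% of an 800 bp allele by
default, so most k-mers are non-unique), three alleles per gene differing
by point substitutions, diploid genotypes drawn per haplotype (anchors at
frequency 1, high-frequency genes at 0.7, low-frequency at 0.15), one
gene (KIR2DS1) built as a truncation of KIR3DS1 so it has zero unique
k-mers while its source keeps a private segment, a diploid 20-gene
background panel, lognormal per-sample depth (mean 30× per copy, CV 0.3
— roughly a four-fold range across a cohort), both strands equiprobable,
and 0.1% base error. Truth tables carry the co-segregation targets
computed from the simulated sources, so inferred calls can be checked.

It does **not** emulate capture-kit batch structure, GC or probe bias,
paired-end fragment geometry, quality-score error profiles, partial or
truncated reference alleles, or somatic copy-number change. Passing
tests therefore demonstrate the correctness of the algorithmic chain —
index, counting, normalization, thresholding, inference — under the
population structure the method assumes, not robustness to every exome
artifact; on real cohorts the t-SNE-style diagnostics and coverage
filters exist precisely because those artifacts appear. Like the
method itself, thresholds must be re-learned per cohort; single samples
and small cohorts (below ~50) are refused.

## Numerical choices

* Canonical k-mers are the lexicographic minimum of a k-mer and its
  reverse complement; counting packs bases 2 bits each for $k \le 32$
  (packing preserves lexicographic order), with a string fallback above.
* Windows containing non-ACGT characters are never candidates and never
  match.
* Variances are unbiased sample variances.
* Density grids always start at 0; when all frequencies are equal the
  Silverman bandwidth degenerates and a small fallback bandwidth
  (10⁻³ of the typical scale) keeps the density a sharp point mass.
* Peak-count mismatches with a gene's declared category (e.g., one peak
  for a high-frequency gene) raise an error advising a category
  override; extra minor peaks beyond the expected count are dropped by
  prominence with a warning.
* Ties in the normalization sweep resolve toward larger $k$, then the
  mean statistic, then the k-mer-occurrence unit.
* Seeded selections (background k-mers, simulation stages) restore the
  caller's RNG state; every stage is a pure function of (inputs, seed).

## Validation shipped with the package

The test suite regenerates everything it checks: extraction and counting
are compared exactly against brute-force enumeration oracles on
randomized toy libraries; thresholds are checked against constructed
Gaussian mixtures with known component means; and the full pipeline runs
on the default simulated study (500 samples, 13 called genes) where it
must recover ≥95% of non-excluded measured calls, exclude ≤10% of
cells, match every inferred call whose sources are correct, and
reproduce population gene frequencies with $r^2 \ge 0.99$. The
normalization sweep runs on ten replicate 100-sample cohorts and must
always beat raw counts and pick a stable winner. `scripts/acceptance.R`
re-runs the same computations from scratch and reports the measured
numbers as JSON.

## Known limitations

* Allele-level genotypes are out of scope; the method calls gene copy
  number only.
* The "3+" state is not resolved further, and enters downstream means
  and burdens as 3.
* Co-segregation rules are population heuristics; in individuals whose
  haplotypes violate them the inferred genes are simply wrong, and the
  package cannot detect it.
* The inhibitory-gene list used for burden analysis is configuration,
  not inference; review it for the cohort at hand.
* Real-data accuracy depends on cohort homogeneity (one capture kit) and
  on the coverage filters having removed degenerate samples.
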
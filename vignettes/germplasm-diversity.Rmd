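---
title: "Diversity and differentiation analysis of germplasm SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity and differentiation analysis of germplasm SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsdiv)
library(dplyr)
```

## The analysis this package implements

Gene banks hold large collections of crop accessions — landraces, synthetic
hexaploids, elite lines — whose value for breeding depends on how much
genetic variation they carry and how that variation is distributed among
sets. `gbsdiv` implements the standard marker-based characterization of such
a collection from a biallelic SNP panel (GBS/DArTseq-style scores):

1. **Read and marker QC** — Phred-threshold read filtering, then marker
   filters on missing data, minor allele frequency, call rate, map position
   and technical-replicate reproducibility.
2. **Diversity** — Nei's gene diversity (DI) and polymorphic information
   content (PIC) per locus, summarized by linkage group, subgenome and
   panel; within-group mean genetic distance; equal-size resampling.
3. **Differentiation** — Nei's partitioning of total diversity into
   within- and between-group components (`Ht`, `Hs`, `Gst`) with the
   island-model gene-flow estimate `Nm`.
4. **Relationships** — Euclidean distance matrices, neighbor-joining
   dendrograms, locus-bootstrap support, cluster composition by group.
5. **Gene-specific markers** — frequency tables for allele-specific
   STS/KASP assays, gene-based diversity, and flagging of PCR bands whose
   size departs from the expected amplicon (putative novel indel alleles).
6. **Allele characterization** — exact reference-coordinate description of
   the indel carried by a novel allele, from an affix comparison or a
   global alignment, plus interval comparison against known alleles and
   signature-catalog classification.

All tabular results are tibbles; trees are `ape::phylo`; the genotype
container is a plain integer matrix of 0/1/`NA` calls with accession and
marker ids (`geno_matrix`). Accessions are treated as fully inbred — one
homozygous call per locus, no heterozygote state — which is the right model
for self-pollinated wheat landraces and breeding lines scored with binary
SNP sheets.

## Statistical model and formulas

For a biallelic locus with alternate-allele frequency $p$:

* gene diversity $DI = 1 - p^2 - (1-p)^2 = 2p(1-p)$, maximal 0.5;
* $PIC = 1 - p^2 - q^2 - 2p^2q^2$, $q = 1-p$, maximal 0.375, always
  $\le DI$.

For $k$ groups with within-group frequencies $p_1,\dots,p_k$, per locus
$\bar p = \tfrac1k\sum_g p_g$, $h_t = 2\bar p(1-\bar p)$ and
$h_s = \tfrac1k\sum_g 2p_g(1-p_g)$; `Ht` and `Hs` average $h_t$, $h_s$ over
loci, and

$$G_{st} = 1 - H_s/H_t, \qquad N_m = \tfrac12\,(1-G_{st})/G_{st}.$$

Pooling is *unweighted* across groups by default (each group counts once).
This is the classical convention and the defensible choice when group sizes
are very unequal, as they are in germplasm sets of a few hundred versus
several hundred accessions; a sample-size-weighted pooling is available via
`weighted = TRUE`. Frequencies always use called cells only, and a locus
with zero calls in any group is dropped from `Ht`/`Hs` (and counted), never
imputed.

### Why `estimate_fst()` exists alongside `gst()`

Raw $G_{st}$ depends on the number of groups. If group frequencies scatter
around an ancestral frequency with variance $F\,p_0(1-p_0)$ (the
Balding–Nichols model the simulator uses), then with $k$ groups
$\mathrm{E}[G_{st}] \approx F\,(k-1)/(k-F)$ — at $k = 4$ and $F = 0.15$
that is roughly 0.117, not 0.15, because $\bar p$ is itself estimated from
only $k$ draws. `estimate_fst()` inverts this moment relation,
$\hat F = k\,G_{st}/(k-1+G_{st})$, and is the right quantity for recovering
a simulated differentiation parameter or comparing groupings with
different $k$. `gst()` stays exactly the definitional $1 - H_s/H_t$, which
is what published differentiation tables print.

```{r}
gst(0.360, 0.301)   # definitional Gst from a published Ht/Hs pair
nm(gst(0.360, 0.301))
```

## The synthetic-data generator

No public genotype deposit accompanies panels like the one this pipeline
targets, so the package ships a first-class simulator whose defaults encode
the study design it emulates: four germplasm sets of 280, 281, 651 and 211
accessions, 11,874 mapped markers on the 21 wheat linkage groups, and a
differentiation parameter `fst = 0.15` chosen to sit inside the observed
range of published wheat germplasm `Gst` values. Per locus an ancestral
frequency is drawn uniformly on [0.05, 0.95] (kept off 0/1 so loci stay
informative), each group draws its frequency from the Balding–Nichols Beta
distribution with mean $p_0$ and variance $F p_0(1-p_0)$, inbred calls are
Bernoulli draws, and cells are masked missing independently (default 5%,
the level of a panel that has already passed a 20%-missing filter).

```{r}
sim <- simulate_structured_snp_panel(
  n_per_group = c(FD = 30, AH = 30, SH = 30, E = 30),
  n_loci = 600, fst = 0.15, missing_rate = 0.05, seed = 1)
filtered <- filter_markers(sim$geno, sim$map)
differentiation_stats(filtered, sim$groups, grouping_label = "sets")
estimate_fst(sim$geno, sim$groups)
```

What the simulator deliberately does **not** model: linkage disequilibrium
along chromosomes (loci are independent), site-frequency spectra estimated
from real data (the ancestral law is a free knob), selection, pedigree, or
genotyping error beyond missingness. Passing parameter-recovery tests
therefore demonstrates correctness of the estimators under the stated
model, not robustness to every property of real GBS panels.

Companion generators produce presence/absence gene-marker tables at target
frequencies, reference/query sequence pairs carrying one planted indel plus
optional substitutions, and 77-bp FASTQ reads with class-structured quality
profiles (class counts are apportioned deterministically, so threshold
pass/fail counts are exact ground truth). `simulate_indel_pair()`
resamples the bases flanking a planted event so it cannot slide through a
repeat; generator truth then coincides with the left-normalized call, which
is what makes exact-coordinate tests meaningful. Every generator is
byte-deterministic given `seed` (one `set.seed()` at entry).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `max_missing` | 0.20 | drop markers with > 20% missing calls |
| `min_maf` | 0.05 | drop markers with minor allele frequency < 0.05; exactly 0.05 is kept |
| `min_call_rate` | 0.50 | drop markers scored in < 50% of accessions |
| `min_reproducibility` | 0.995 | technical-replicate concordance floor |
| read body rule | Q30 on ≥ 50% of bases | read-level Phred filter |
| barcode rule | Q10 on ≥ 75% of first 8 bases | barcode length is configurable; 8 bp is a typical inline-barcode length |
| `n_reps` (bootstrap) | 1000 | locus bootstrap replicates for NJ support |
| `n` (resampling) | 211 | equal-size subsample, the smallest set in the emulated design |
| gel `tolerance` | 0.10 | relative band-size tolerance before a band is called novel |

Filters are conjunctive; the filter log records, for every dropped marker,
the first rule (in the order no-calls, call rate, missing, MAF, unmapped,
reproducibility) that removed it, so survivors plus log always partition
the input panel.

## Numerical and design choices

* **Genotype coding.** 0 = major/reference, 1 = alternate, `NA` = missing;
  the missing state is never conflated with 0. Parsers refuse any other
  cell value with row/column coordinates rather than coercing.
* **Within-group mean genetic distance** defaults to the allele-sharing
  distance (mismatch proportion over co-called loci), which lives on the
  proportion scale typical of published within-group distances; Euclidean
  distance is reserved for tree building, where it is conventional. Both
  are exposed.
* **Missing data in distances.** The Euclidean distance rescales each
  pair's squared mismatch count by total loci over co-called loci, making
  the expected squared distance invariant to loci missing at random. A pair
  sharing no called locus is an error, not a guess.
* **No small-sample correction by default.** DI is reported as $2p(1-p)$
  without the $n/(n-1)$ factor; a toggle exists. At germplasm-set sample
  sizes the factor is below half a percent.
* **Neighbor joining** delegates the core agglomeration to `ape::nj`
  (exact on additive matrices) and post-processes: negative branch lengths
  are clamped to zero and counted, never silently. Bootstrap support is
  counted for the bipartitions of the fixed full-data tree (the annotated
  dendrogram convention), not via a consensus tree.
* **Resampling is subsampling.** Equal-size diversity comparisons draw
  without replacement — the point is equal $n$, not a bootstrap.
* **Indel coordinates.** 1-based; a deletion "between a and b" means last
  retained base `a`, last deleted base `b`, length `b - a`. This is the
  only convention under which a deletion spanning 1807–7804 has length
  5997, and it makes nested-interval arithmetic
  (`additional = upstream + downstream`) exact.
* **Left normalization.** Both the affix detector and the alignment caller
  shift indels to the smallest valid reference anchor, stopping at the
  previous variant; classification and cross-method agreement rely on this
  canonical form.
* **Alignment scoring** defaults to match +1, mismatch −1, gap open 10,
  gap extend 0.5 (affine), which keeps a long indel as one block instead
  of fragmenting it; fully configurable. Global alignment is quadratic, so
  the caller is meant for allele-sized sequences (≤ ~20 kb), not contigs.
* **Ties.** NJ tie-breaking follows the implementation's deterministic
  order; combined with seeded resampling this makes bootstrap runs
  byte-reproducible.

## Problem sizes used by the test suite

The suite exercises parameter recovery at 4 groups × 100 accessions × 2000
loci over 20 seeds, NJ exactness on 200 random additive trees of up to 12
leaves, the read filter against a brute-force oracle on 10,000 reads, and
bootstrap support (500 replicates, 500 loci) for the true split of two
clusters simulated at `fst = 0.4` — sizes at which the Monte-Carlo answers
are stable while the whole suite runs in well under a minute.

## Known limitations

* Diversity statistics assume biallelic, effectively haploid (inbred)
  calls; heterozygote or multi-allelic data are out of scope.
* `Gst`-based gene-flow (`Nm`) inherits all caveats of the island model;
  it is reported because it is the field's conventional companion
  statistic, not because migration is being estimated.
* The alignment caller reports one best global alignment; in low-complexity
  regions different gap placements with equal score exist, and only the
  left-normalized representative is returned.
* Published group-level tables can rarely be reproduced to the digit from
  printed summaries alone (inputs are rounded); the package keeps full
  precision internally and rounds only at output.
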
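---
title: "Methods: coding-potential classification and isoform co-expression analysis"
author: "codewise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coding-potential classification and isoform co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codewise)
```

## Scope

`codewise` characterizes transcript isoforms from developmental RNA-Seq
experiments along two axes: *what a transcript is* (protein-coding or long
noncoding, decided by a weighted support vector machine over a
twelve-feature vector) and *how it behaves over time* (temporal k-means
clusters and super-clusters, a correlation-threshold co-expression
network with hub detection, and a sense-antisense correlation screen).
The package operates downstream of read mapping and assembly: its inputs
are transcript sequences (FASTA), parsed conserved-domain hit tables,
optional annotation/CPC tables, and transcript-by-timepoint FPKM
matrices.

## The coding-potential classifier

### Feature vector

Each transcript is summarized by up to twelve features, assembled by
`buildFeatureTable()`:

| feature | meaning | units / range |
|---|---|---|
| `transcript_len` | sequence length | nt |
| `orf_ratio` | longest-ORF length / transcript length | [0, 1] |
| `utr5_ratio` | 5'-UTR length / transcript length | [0, 1] |
| `protein_len` | translated protein length (stop excluded) | aa |
| `gc_content` | (G+C) / non-N length | [0, 1] |
| `ta_ratio` | #T / #A | >= 0 |
| `gc_ratio` | #G / #C | >= 0 |
| `n_domains` | conserved-domain hits | count |
| `truncation_ratio` | truncated hits / total hits | [0, 1] |
| `mfe` | structure (pseudo-)energy | model units, <= 0 |
| `in_mapman_bin` | functional-bin membership (optional) | {0, 1} |
| `cpc_score` | external coding-potential score (optional) | real |

The two optional features may be absent; a model records the schema it
was trained with and refuses prediction on mismatched tables, so a model
trained with `cpc_score` is never silently applied to a table without
it.

Zero denominators in the content ratios (a sequence with no A, or no C)
are clamped to 1 and flagged rather than propagated as `NaN`, so the
scaler and the SVM never see non-finite values. This biases the ratio
for such degenerate sequences, which are vanishingly rare in real
transcripts.

### Longest-ORF translator

`findLongestOrf()` scans the given strand only (transcripts are already
stranded) for spans that begin `ATG` and end at the *first* in-frame
stop codon downstream; the longest such span wins and ties go to the
5'-most start. Three choices deserve note:

* Run-off ORFs with no in-frame stop are not counted; a qualifying ORF
  must terminate at a stop codon.
* `orf_len` includes the stop codon while the protein excludes it, so a
  transcript that is exactly one ORF attains `orf_ratio = 1`.
* A codon containing `N` encountered before any stop invalidates that
  candidate span — ambiguity is handled conservatively rather than
  translated through.

### Structure energy backends

The minimum free energy of RNA secondary structure separates coding from
noncoding transcripts strongly, so it is a first-class feature with a
pluggable backend. The `external` backend adapts the ViennaRNA `RNAfold`
command-line folder (thermodynamic nearest-neighbor model, kcal/mol).
The `builtin` backend is a Nussinov-style base-pair maximization dynamic
programme (pair scores GC = -3, AU = -2, GU = -1, minimum hairpin loop
of 3 unpaired bases; implemented in C++, cubic in sequence length). Its
value is a pseudo-energy, not a thermodynamic quantity, but it preserves
the discriminative *ordering* — more and stronger pairing scores lower —
which is all the classifier consumes. Throughout the package energies
are treated as opaque model units; no unit conversion is attempted
between backends.

### Training procedure

`codewiseTrain()` follows the standard imbalanced-SVM recipe:

1. Min-max scale every feature to $[-1, +1]$ using *training-set*
   minima and maxima (`fitScaler()`/`applyScaler()`); test data reuse
   the training bounds and may fall outside the interval. A constant
   feature maps to 0.
2. Fit a support vector machine (libsvm via **e1071**) with a class
   weight of 3 on the noncoding minority class — mirroring the 3:1
   coding:noncoding imbalance of the training compendium the method was
   designed around — and cost parameter 1 (library default; exposed).
   Linear, RBF and polynomial kernels are supported.
3. Calibrate probabilities by sigmoid fitting on the decision values
   (libsvm's Platt procedure); per-transcript coding and noncoding
   probabilities sum to 1, and transcripts near 0.45/0.55 are readily
   identified as ambiguous.

The weight direction (which class gets the factor 3) is configurable;
the default weights the minority class because that is what "preventing
unbalanced training" requires when noncoding examples are scarce.
Splitting is stratified (`stratifiedSplit()`, default 75% training) so
both partitions keep the 3:1 class ratio within rounding.

`codewiseEvaluate()` reports accuracy, the confusion counts with coding
as the positive class, per-class rates, and AUC computed by trapezoidal
integration of the ROC of the coding-class probabilities (equivalently
the rank-sum statistic, ties averaged). `assessFeatures()` adds PCA on
the scaled features and an LDA baseline evaluated on a held-out
stratified split.

## Co-expression analysis

### Preprocessing and clustering

A transcript counts as *expressed* when its FPKM sum across the time
course is strictly greater than 1 (`filterExpressed()`; the boundary sum
of exactly 1 is dropped). `centerNormalize()` applies the GeneCluster
convention — rows are mean-centered, then scaled to unit sum of squares;
the tool that popularized this preprocessing names it without stating
the formula, and this is the conventional reading. Constant rows become
all-zero and are flagged.

`kmeansCluster()` reads "k-means with 500 iterations" as 500 random
restarts keeping the best within-cluster sum of squares (GeneCluster
semantics), with Lloyd iterations run to convergence (cap 300) inside
each restart; `stats::kmeans(algorithm = "Lloyd", nstart = ...)`
implements exactly this. Cluster ids are 1-based as is idiomatic in R.
The mapping of clusters to developmental super-clusters (early
maturation, mid-to-late maturation, desiccation/DT) is user-supplied via
`assignSuperclusters()`: the biology decides which profiles belong
together, not the algorithm.

### Network, connectivity, hubs

`buildNetwork()` computes all-pairs Pearson correlations and joins two
transcripts when $r_{ij} \ge 0.9$ (default `signed_positive` rule) or
$|r_{ij}| \ge 0.9$ (`absolute`). Whether the upstream tool's 0.9
edge-adjacency threshold applies to signed or absolute correlation is
not documented; co-expression language implies positive association, so
signed-positive is the default and the absolute rule is provided. No
additional significance filtering is layered on top of the threshold.
Constant profiles cannot form edges and are kept as isolated nodes with
a warning.

For a node $x$ with $m$ neighbors inside super-cluster $sc$ of $n$
nodes,

$$\mathrm{degree}_{x,\,sc} = m / n,$$

and a super-cluster is summarized by the *median* member degree (the
degree distribution is not normal). `findHubs()` ranks members by
degree, breaking ties lexicographically by transcript id (the tie rule
is unstated upstream, so a deterministic one was fixed); per-gene
deduplication — keeping only the best-connected isoform of each gene —
is a switch, because in practice hubs from the same gene are redundant
observations rather than distinct network actors. `nearestNeighbors()`
returns the induced sub-network of a node and its direct neighbors.

### Sense-antisense screen

`senseAntisenseScreen()` computes Pearson $r$ per pair and a two-sided
p-value via the t transform with `timepoints - 2` degrees of freedom;
a pair is significant iff $p < 0.05$. A constant member leaves $r$
undefined; the pair is flagged not-significant with a reason rather than
dropped, preserving row conservation.

### Splice-variant domain categorization

`categorizeSvDomains()` compares domain-accession *sets* across the
isoforms of one gene: any member without hits makes the group
`no_known_domain`; identical sets (hit counts may differ — a repeated
domain does not change the type composition) make it `similar`;
otherwise `disparate`.

## The synthetic benchmark generator

`generatorConfig()` defines the study conditions under which the
framework is exercised without external downloads. It emulates:

* the class separations observed between coding and noncoding
  transcripts — structure energies Normal(-371, 80) vs Normal(-134, 50)
  model units (clamped at 0), lengths lognormal with medians ~1,500 vs
  ~600 nt, ORF ratios Beta-distributed around 0.7 vs 0.2, 5'-UTR ratios
  around 0.1 vs 0.45, 1-4 domains vs none with probability 0.95 — with
  GC content drawn from one shared distribution, so the classifier
  cannot lean on nucleotide content;
* a CPC-like score that is a noisy monotone function of ORF ratio and
  protein length, reproducing the redundancy that makes the optional
  feature uninfluential;
* three temporal archetypes over 10 time points (early-maturation
  decline, mid-to-late plateau, final-timepoint desiccation spike) with
  multiplicative lognormal noise and optional correlated sense-antisense
  partners;
* sequence-level realism sufficient for the translator: coding
  sequences embed a designed `ATG`...stop ORF of target length inside an
  ATG-free 5'-UTR and a stop-seeded 3' region, verified to be the
  realized longest ORF.

Distribution families (lognormal lengths, Beta ratios, Gaussian
energies) are the package's own modelling choices; only the orderings
and the two energy means are externally anchored. What the generator
does **not** emulate: real codon usage and compositional biases,
splice-graph structure, genomic coordinates, read-level sampling noise,
and the heavy tails of real expression data. Tests passing on this
benchmark therefore demonstrate the *machinery* — correct feature
algebra, correct weighted training, correct network arithmetic — not
field performance on real transcriptomes, which depends on training
compendia this package deliberately does not download.

## Numerical choices and degenerate inputs

* Strictly-greater-than expressed filter; boundary rows are dropped.
* Zero-denominator content ratios clamped to the numerator, flagged.
* Constant features scale to 0; constant profiles are flagged and
  isolated.
* ORF ties break 5'-most; hub ties break lexicographically.
* All stochastic steps (splits, k-means restarts, probability
  calibration, generators) take explicit integer seeds; reruns are
  bit-identical, and pipeline runs record their configuration and seed
  in a manifest.

## Problem sizes used in the checks

The shipped test suite and acceptance script exercise the classifier on
3,000 coding + 1,000 noncoding generated feature rows (75/25 split,
medians over five run seeds), the ORF finder against a brute-force
enumerator on 1,000 random 300-nt sequences, the folding DP against an
independent memoized implementation on 40-nt sequences, the network
builder against all-pairs brute force on 30-row matrices, and the
antisense screen's type-I error on 1,000 independent pairs at 10 time
points. These sizes were chosen as the smallest at which the statistical
checks are stable.

## Known limitations

* The builtin pseudo-energy is not a thermodynamic MFE; absolute values
  are not comparable across backends, only orderings.
* Antisense orientation is inferred from class codes (`x`, `s`) alone;
  genomic coordinates are out of scope.
* The cluster-to-super-cluster mapping is user-supplied.
* Headline classifier metrics obtained on the synthetic benchmark
  characterize the implementation under the generator's separations, not
  performance on any real transcript compendium.
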
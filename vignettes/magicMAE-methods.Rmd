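---
title: "Inferring mosaic monoallelic expression from gene-body chromatin: methods and design"
author: "magicMAE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mosaic monoallelic expression from gene-body chromatin: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magicMAE)
```

# The biological model

Mosaic monoallelic expression (MAE) is the mitotically stable, cell-autonomous
expression of an autosomal gene from predominantly one allele, with the active
allele varying between cells of one individual. In a mosaic cell population
the silenced allele of an MAE gene carries the repressive mark H3K27me3 while
the active allele carries the transcription-coupled mark H3K36me3 over the
gene body. Averaged over the population, an MAE gene is therefore enriched for
*both* marks simultaneously — a signature that expressed biallelic (BAE) genes
(K36-high, K27-low) and silent genes (K27-high, K36-low) do not show. This
package infers MAE from that signature and provides the downstream analyses
that make the inference useful: validation against allele-specific RNA-Seq,
a cross-species conservation test, MAE-profile clustering across tissues, and
a correction of multi-sample MAE counts for classifier accuracy.

The direct measurement the chromatin inference is benchmarked against is
allele-specific RNA-Seq in *clonal* cell lines: in a clone, all cells share
the same active allele, so allelic read imbalance at transcribed SNPs reveals
MAE. In non-clonal populations opposite biases cancel, which is precisely why
a chromatin-based proxy is needed.

# From coverage tracks to classifier features

For each autosomal gene the gene body is the genomic span of its longest
transcript, introns included (tie on span length broken by the
lexicographically smallest transcript id). Coverage of each assay (H3K27me3,
H3K36me3, input control, RNA) is summed base-wise over this span. Mark sums
are normalized to the input sum over the same span or, when no input control
exists, to the span length; genes with an input track but zero input signal
are removed, while genes with zero *mark* signal are kept and take the lowest
ranks. Replicates are averaged on the normalized-signal scale, before
ranking, so that ranks stay well-defined when replicates disagree. RNA
abundance is integrated by the same pipeline and normalized to length, or
supplied externally as an FPKM-like column.

Each normalized signal is then converted to a quantile rank: the value's
average 1-based rank (ties share the average) divided by the number of genes,
giving values in $(0, 1]$. Quantile ranks are invariant under any strictly
monotone transform of the signal, so a classifier trained on one dataset's
ranks transfers to another dataset regardless of absolute scale — this is the
property the whole design leans on, and it is asserted as a property test.
The package stamps the rank scale into both feature tables and model files
and refuses to mix scales, because any monotone rank scale works *provided
training and application use the same one*.

Coordinates are handled throughout in the Bioconductor convention (1-based,
closed `GRanges`), with `rtracklayer` converting GTF, BED12, bedGraph and
wiggle inputs on read. Maintaining a single convention inside the battle-
tested container library eliminates the usual off-by-one bug class more
reliably than a hand-maintained half-open convention would; the equivalence
of the file conventions is itself covered by a round-trip test. Chromosome
names are matched by exact string comparison — no `chr` aliasing — because
silent aliasing hides real input mismatches; `ioCheck()` reports the name-set
overlap up front. Autosomes are recognized by a configurable regular
expression (default excludes `X`, `Y`, `M`/`MT`, with or without the `chr`
prefix).

# The alternating decision tree classifier

The classifier is an alternating decision tree (ADTree) over the two features
`k27_qrank` and `k36_qrank`. An ADTree is a sum-of-paths model: a root
prediction plus, for every splitter node whose precondition path is
satisfied, one of two prediction values depending on the node's threshold
condition. The score is the sum over all satisfied paths; its sign is the
call.

Training follows the boosting construction: instance weights start uniform;
the root prediction is $\frac{1}{2}\log\frac{W_+ + 1}{W_- + 1}$; each round
adds the (precondition, `feature <= t`) pair minimizing

$$Z = 2\left(\sqrt{W_+(P \wedge c)W_-(P \wedge c)} +
\sqrt{W_+(P \wedge \neg c)W_-(P \wedge \neg c)}\right) + W(\neg P)$$

with thresholds $t$ ranging over midpoints of consecutive distinct feature
values; branch predictions use the same smoothed half log-odds; and weights
update as $w \leftarrow w\,e^{-y\,r(x)}$ ($y = +1$ for MAE). Design choices
worth making explicit:

* **Equal class costs.** The classifier is "neutral": no misclassification
  cost asymmetry and no class reweighting. MAE calls are then driven purely
  by the training geometry.
* **$+1$ smoothing** inside the prediction log-odds (the original ADTree
  formulation) bounds predictions on pure partitions. With this smoothing
  the total training weight is still non-increasing every round, which the
  implementation records (`weightTrace`) and the tests assert.
* **Ten boosting rounds** by default — the conventional ADTree default; the
  planted-rule benchmark reaches its accuracy plateau well before that.
* **Score exactly 0 is called BAE**: an MAE call requires strictly positive
  evidence.
* **Early stop**: if no candidate split improves on not splitting, training
  stops with a message rather than adding vacuous nodes.
* **No shipped model.** Training data is user-supplied;
  `simulateTrainingTable()` provides a stand-in with the MAE-in-the-
  high/high-corner geometry for testing and experimentation.

Model files are versioned JSON with numerics at 17 significant digits, so a
write/read round trip scores bit-identically.

# Filters and dataset QC

After classification (never before), two filters set genes aside: bodies
shorter than 2.5 kb (the signature is unreliable on short genes) and genes
below the dataset's median expression (expression quantile rank < 0.5;
exactly 0.5 is kept). The span, not the exonic length, of the longest
transcript is compared against the 2.5 kb cutoff, consistent with the
gene-body definition used everywhere else. Filtered genes keep their raw
call but a final call of `not_assessed`.

A dataset is only informative if the two marks actually separate genes.
The dynamic-range QC splits genes into four quadrants at the median
normalized enrichment of each mark and requires the two anti-correlated
quadrants (low-K27/high-K36 and high-K27/low-K36) to hold at least 50% more
genes than the two others ($n_1 + n_2 \ge 1.5\,(n_3 + n_4)$, boundary
passing). `runMagic()` refuses failing datasets unless forced, and the
refusal message names the four counts.

# Allelic-expression calling

SNP-level maternal/paternal counts are summed per gene (per-SNP testing with
gene-level combination would require modeling per-SNP overdispersion; plain
summation is transparent and symmetric, at the cost of ignoring
isoform-specific SNPs). A gene with at least `minTotal` (default 20) reads
is tested two ways:

* **Monoallelic**: two-sided exact binomial p-value against 0.5 — computed by
  doubling the smaller tail, capped at 1, which is reproducible and
  order-stable where the "minimum-likelihood" two-sided construction is not —
  passed through Benjamini–Hochberg across all tested genes, requiring
  $q < 0.05$ *and* a major-allele fraction of at least $2/3$ (the 2:1 bias).
* **Biallelic**: a positive equivalence test, realized as a binomial TOST
  with bounds $(1/3, 2/3)$ mirroring the 2:1 monoallelic bias, both one-sided
  tests at $\alpha$. The bounds are configurable since other choices are
  defensible.

Everything else is indeterminate, including all genes under the read floor.
The floor value of 20 reads gives the binomial test its first usable
resolution (at 19 reads even a 16:3 split cannot reach $q < 0.05$ after any
correction) while discarding little data at typical depths. The procedure is
symmetric in the parental labels by construction, which the tests assert.

Calls from several clones aggregate by the benchmark rule: MAE if
monoallelic in at least one clone; else BAE if biallelic in at least one
clone; else indeterminate. Concordance of chromatin calls with the benchmark
is summarized as the 2×2 table, Fisher's exact two-sided p, per-class
confirmation rates, and the *sample* odds ratio $(tp \cdot tn)/(fp \cdot fn)$
— not the conditional-MLE odds ratio `fisher.test` reports, which differs
slightly; a zero margin leaves the odds ratio `NA` while p remains defined.

# Conservation, clustering, and the accuracy correction

**Conservation.** Over one-to-one ortholog pairs (every gene appearing in
more than one orthology row is dropped) with a determinate call in both
species, the expected shared-MAE count under independence is
$p_A\,p_B\,N$ and the significance is the *inclusive* hypergeometric upper
tail $P(X \ge \mathrm{observed})$ — the standard enrichment convention —
evaluated via `phyper(log.p = TRUE)` because realistic tails underflow
double precision by a hundred orders of magnitude. Exclusion of
indeterminate pairs happens *before* $N$ is counted. A brute-force pmf
summation over small universes serves as the test oracle.

**Profile clustering.** Across samples, MAE/BAE profiles are compared by
Gower distance, which for symmetric binary traits reduces to the mismatch
fraction over genes informative in *both* samples of a pair — missingness is
handled pairwise, not by global complete-case reduction, and "informative"
means a determinate final call (the expression filter is therefore already
inside it). Trees are built with size-weighted (textbook) UPGMA, merge
heights at $d/2$, ties broken on the lexicographically smallest pair of
cluster labels so results are reproducible; `hclust(..., "average")` is the
cross-check oracle in the tests, and both the similarity matrix and the
Newick tree are emitted. The expression-breadth binning groups genes by the
number of samples expressing them and reports the per-sample MAE proportion
per bin with quartiles.

**Accuracy correction.** The MAE prediction accuracy $a$ (default 0.73,
the precision measured for the clonal lymphoblast benchmark) is treated as
the probability that any single MAE call is truly MAE, independently across
samples. A gene predicted MAE in $k$ of $n$ samples is truly MAE in $m$
samples with probability $\binom{k}{m}a^m(1-a)^{k-m}$; BAE calls are taken
at face value (a generalized mode with a BAE-specificity parameter was
considered and rejected as default, because only the single MAE-precision
figure is well estimated). Summing over genes gives expected counts per
$m$, which conserve total mass exactly; an expected count below 1 is
reported as 0 ("no gene"). Only the *count* of MAE samples is modeled, not
their identity — the two formulations agree for the summed output.

# What the simulator emulates — and what it does not

`simulateMagicDataset()` generates every input the pipeline consumes from a
single seed (fanned out to per-generator substreams, so each input can be
regenerated independently):

* **Annotation**: non-overlapping genes of 1–50 kb with 1–3 transcripts,
  ~10% under the 2.5 kb filter, a few chrX genes to exercise the autosome
  restriction.
* **Tracks**: per-gene lognormal levels by class — MAE high in both marks
  (the population-mixture signature), expressed BAE K36-high/K27-low, silent
  K27-high/K36-low — Poisson noise per 1 kb bin, near-uniform input. Default
  mixture: 15% MAE (the upper end of reported autosomal MAE prevalence),
  45% silent (roughly the fraction of genes not expressed in a given cell
  type), the rest expressed BAE.
* **Allele counts**: 1–20 SNPs per expressed gene, Poisson depth around 20
  reads per SNP, maternal fraction 0.95 or 0.05 for MAE genes (clone-fixed
  allele) and 0.5 for BAE genes.
* **Profiles**: per-gene root state Bernoulli(0.15) flipped along each
  lineage-tree branch with probability 0.05.
* **Orthologs**: exact planted counts of species-specific and shared MAE.

The simulator deliberately omits several features of real data: mappability
and GC artifacts, peak-shaped (rather than uniform-within-gene) mark
deposition, overdispersed and reference-biased allelic counts, correlated
replicates, dynamic or cell-subset-specific expression that mimics the MAE
signature, and imprinted genes (parent-of-origin monoallelic expression,
which the chromatin signature cannot distinguish from mosaic MAE). Passing
tests on simulated data therefore demonstrate that the implementation is
correct and internally consistent — the classifier recovers planted
structure, the caller is calibrated, the correction is conservative — not
that a given real dataset satisfies the model's assumptions; the
dynamic-range QC exists exactly because some real datasets do not.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use 2 000 genes for the
end-to-end run and the profile/lineage recovery, 1 000 genes for caller
calibration, 10 000 genes for correction recovery, and 1 000 random
instances for the hypergeometric and UPGMA oracles — sizes at which the
stochastic checks are comfortably stable while the whole suite stays fast.
Other numerics: quantile ranks use average ties; the two-sided binomial
doubles the smaller tail (capped at 1); BH runs once across all tested
genes; hypergeometric tails are computed in log space; Newick branch lengths
are written with 17 significant digits; UPGMA and training tie-breaks are
deterministic as described above.

# A short worked example

```{r example, eval = FALSE}
d <- simulateMagicDataset(simConfig(n_genes = 2000L), seed = 1)
ft <- buildFeatureTable(d$transcripts, d$tracks$k27, d$tracks$k36,
                        d$tracks$input, d$tracks$rna)
model <- trainADTree(d$training, d$training$label)
res <- runMagic(ft, model)
res

# validate against allele-specific counts from the same simulated clone
allelic <- callAllelic(aggregateSnpCounts(d$snps))
bench <- aggregateClones(list(allelic))
concordanceTable(res, bench)
```

# Known limitations

* The classifier uses two marks only; MAE genes whose signature involves
  other marks are invisible to it, and population-level mixtures of
  cell-type-specific expression can mimic the signature.
* Gene-level aggregation of SNP counts ignores isoform-specific allelic
  behavior.
* The accuracy correction models MAE-call precision only and assumes
  independence across samples.
* The equivalence-test bounds, the 20-read floor, and the autosome regex are
  conventions, exposed as parameters rather than hidden.
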
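# magicMAE

Inference of mosaic monoallelic expression (MAE) of autosomal genes from the
H3K27me3/H3K36me3 gene-body chromatin signature — the MaGIC procedure — with
the validation and downstream analyses that make the inference usable:
allele-specific RNA-Seq calling and benchmarking, a cross-species
conservation test over one-to-one orthologs, MAE-profile clustering across
tissues, and a correction of multi-sample MAE counts for classifier
accuracy. Everything is testable offline through built-in simulators for
every input.

**Who it is for:** epigenomics and regulatory-genomics researchers who have
gene-body ChIP-Seq coverage (H3K27me3, H3K36me3, input) plus an RNA
abundance measure, and want per-gene MAE/BAE calls without clonal
allele-specific RNA-Seq — or who have SNP-level allelic counts from clones
and want to benchmark or train against them.

## The method

In a mosaic population an MAE gene silences one allele (H3K27me3) while
transcribing the other (H3K36me3), so at the population level it is enriched
for **both** marks over its gene body; expressed biallelic genes are
K36-high/K27-low and silent genes K27-high/K36-low. The pipeline:

1. **Features.** For each autosomal gene, sum each track over the span of
   the longest transcript; normalize marks to input (or length); average
   replicates; convert to quantile ranks
   `qrank(x) = avg_rank(x) / n ∈ (0, 1]` (average ties). Quantile ranks are
   invariant under monotone transforms, so a trained classifier ports
   across datasets.
2. **Classifier.** An alternating decision tree (ADTree) over
   `(k27_qrank, k36_qrank)`: score = root prediction `½·ln((W₊+1)/(W₋+1))`
   plus prediction values of every splitter node whose precondition path is
   satisfied; each boosting round adds the node minimizing
   `Z = 2(√(W₊W₋)|c + √(W₊W₋)|¬c) + W(¬P)`; call = MAE iff score > 0.
3. **Filters & QC.** After classification, drop genes < 2.5 kb and genes
   below median expression (qrank < 0.5). A dataset passes the
   dynamic-range QC iff the two anti-correlated mark quadrants (split at
   each mark's median) hold ≥ 50% more genes than the other two.
4. **Allelic benchmark.** Per gene, summed maternal/paternal SNP counts:
   monoallelic iff BH-corrected exact binomial `q < 0.05` **and** major
   fraction ≥ 2/3; biallelic iff a binomial TOST shows the fraction inside
   (1/3, 2/3); MAE across clones iff monoallelic in ≥ 1 clone. Concordance
   is reported as a 2×2 table with Fisher's exact p and the sample odds
   ratio `(tp·tn)/(fp·fn)`.
5. **Downstream.** Conservation over N one-to-one orthologs: expected
   shared MAE `p_A·p_B·N` vs the inclusive hypergeometric tail
   `P(X ≥ observed)` in log space. Profile clustering: Gower distance
   (mismatch fraction over genes informative in both samples) + UPGMA.
   Accuracy correction: gene predicted MAE in `k` of `n` samples is truly
   MAE in `m` with probability `C(k,m)·aᵐ·(1−a)^(k−m)` (a = 0.73); expected
   counts below 1 report as 0.

## Worked example

```r
library(magicMAE)

# a complete simulated input set: annotation, 4 coverage tracks,
# SNP allele counts, and a labelled training table
d  <- simulateMagicDataset(simConfig(n_genes = 2000L), seed = 1)
ft <- buildFeatureTable(d$transcripts, d$tracks$k27, d$tracks$k36,
                        d$tracks$input, d$tracks$rna)
model <- trainADTree(d$training, d$training$label)
res <- runMagic(ft, model)
res
#> MagicResult
#>   genes assessed : 2000
#>   MAE / BAE      : 140 / 759
#>   filtered       : 210 short, 891 low expression
#>   QC quadrants   : 819 / 819 / 181 / 181 -> passed
```

Of 2000 simulated genes, 210 are set aside as shorter than 2.5 kb and 891 as
below median expression; among the 899 assessed genes the classifier calls
140 MAE. The QC quadrant counts (819 + 819 anti-correlated vs 181 + 181)
show the dataset has the dynamic range the signature needs.

Benchmarking those chromatin calls against allelic calls from the simulated
clone's SNP counts:

```r
allelic <- callAllelic(aggregateSnpCounts(d$snps))
bench   <- aggregateClones(list(allelic))
cc <- concordanceTable(res, bench)
cc[c("tp", "fp", "fn", "tn", "odds_ratio", "mae_confirmation")]
#> $tp: 128   $fp: 7   $fn: 65   $tn: 620
#> $odds_ratio: 174.3
#> $mae_confirmation: 0.948
```

128 of 135 determinate MAE calls are confirmed monoallelic by the simulated
RNA-Seq (precision 0.95); the odds ratio of 174 reflects how cleanly the
planted signature separates under the default simulation.

The conservation test on a planted two-species ortholog set sized like a
real mouse/human comparison:

```r
sim <- simulateOrthologs(7429, 563/7429, 580/7429, 240, seed = 1)
conservationTest(sim$pairs, sim$callsA, sim$callsB)
#> $expected_overlap: 43.95   $observed_overlap: 240
#> $hyper_p: 1.15e-131
```

240 shared MAE orthologs where independence predicts 44 — conservation at
log10 p ≈ −131.

A command-line front end wrapping the same functions (subcommands
`io-check`, `simulate`, `signal`, `train`, `classify`, `qc`, `allelic`,
`benchmark`, `conserve`, `cluster`, `bins`, `correct`) is installed at
`system.file("cli", "magic", package = "magicMAE")`.

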
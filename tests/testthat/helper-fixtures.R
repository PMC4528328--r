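# In-code fixtures and independent reference implementations used as oracles.

toyTrack <- function(chrom, start, end, score) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$score <- score
  gr
}

toyTx <- function(chrom, start, end, gene_id, tx_id) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$tx_id <- tx_id
  gr
}

writeTempGtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

gtfLine <- function(chrom, type, start, end, gene, tx) {
  paste(chrom, "test", type, start, end, ".", "+", ".",
        sprintf('gene_id "%s"; transcript_id "%s";', gene, tx), sep = "\t")
}

# brute-force inclusive hypergeometric upper tail, direct pmf summation via
# log binomial coefficients (independent of phyper)
bruteHyperUpper <- function(N, K, n, obs) {
  hi <- min(K, n)
  if (obs > hi) return(0)
  i <- max(0, obs):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# brute-force Benjamini-Hochberg step-up q-values
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[ord[r]] * m / r)
    q[ord[r]] <- val
    prev <- val
  }
  q
}

# UPGMA reference: cophenetic distances from hclust average linkage
refUpgmaCophenetic <- function(d) {
  as.matrix(stats::cophenetic(stats::hclust(d, method = "average")))
}

# cophenetic distances of an ultrametric phylo, labelled matrix
treeCophenetic <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m))]
}

# balanced 6-leaf lineage tree used for profile recovery checks
balancedTree6 <- "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);"
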
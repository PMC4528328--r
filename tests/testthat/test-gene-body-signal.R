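test_that("longestTranscript picks the maximal span with a stable tie-break", {
  tx <- toyTx("chr1", c(1, 1), c(100, 250), c("g1", "g1"), c("t1", "t2"))
  lt <- longestTranscript(tx)
  expect_equal(GenomicRanges::width(lt), 250L)
  expect_equal(lt$tx_id, "t2")

  single <- toyTx("chr1", 10, 60, "g1", "t1")
  expect_equal(GenomicRanges::width(longestTranscript(single)), 51L)

  tie <- toyTx("chr1", c(1, 201), c(100, 300), c("g1", "g1"),
               c("tx_b", "tx_a"))
  expect_equal(longestTranscript(tie)$tx_id, "tx_a")
  expect_error(longestTranscript(tie[0]), "no transcripts")
})

test_that("geneBodySum integrates coverage over the body", {
  # constant coverage 2.0 over a 10 bp gene
  expect_equal(unname(geneBodySum(toyTrack("chr1", 1, 100, 2),
                                  GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(21, 30)))), 20)
  # track covering bases 1..10 at 3 against gene 6..15: 5 bases overlap
  expect_equal(unname(geneBodySum(toyTrack("chr1", 1, 10, 3),
                                  GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(6, 15)))), 15)
  # empty track
  expect_equal(unname(geneBodySum(toyTrack("chr1", 1, 10, 3)[0],
                                  GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(1, 10)))), 0)
  # chromosome absent from track: zero with warning
  expect_warning(
    s <- geneBodySum(toyTrack("chr1", 1, 10, 3),
                     GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10))),
    "chr9")
  expect_equal(unname(s), 0)
})

test_that("geneBodySum is additive over a partition of the body", {
  set.seed(7)
  track <- toyTrack("chr1", seq(1, 991, 10), seq(10, 1000, 10),
                    runif(100, 0, 5))
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 700))
  cut <- sample(102:699, 1)
  parts <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, cut + 1), c(cut, 700)))
  expect_equal(unname(geneBodySum(track, whole)),
               sum(geneBodySum(track, parts)))
})

test_that("normalizeSignal uses input when present, length otherwise", {
  expect_equal(normalizeSignal(20, 10, 1000), 2)
  expect_equal(normalizeSignal(20, NULL, 1000), 0.02)
  expect_equal(normalizeSignal(0, 10, 1000), 0)
  expect_error(normalizeSignal(1, 0, 1000), "input")
})

test_that("replicates average on the normalized scale", {
  expect_equal(averageReplicates(c(2, 1), c(4, 3)), c(3, 2))
  expect_equal(averageReplicates(5), 5)
  expect_equal(averageReplicates(matrix(rep(c(1.5, 2.5), 4), 2)), c(1.5, 2.5))
})

test_that("quantileRank matches the average-rank definition", {
  expect_equal(quantileRank(c(0.5, 2, 2, 7)), c(0.25, 0.625, 0.625, 1))
  expect_equal(quantileRank(rep(3, 4)), rep(0.625, 4))  # mean rank 2.5 / 4
  n <- 17
  expect_equal(quantileRank(seq_len(n) * 1.3), seq_len(n) / n)
  expect_error(quantileRank(numeric()), "empty")
})

test_that("quantile ranks are invariant under strictly monotone transforms", {
  set.seed(3)
  for (i in 1:20) {
    x <- rlnorm(50)
    x[sample(50, 5)] <- x[1]               # inject ties
    expect_equal(quantileRank(x), quantileRank(log2(x)))
    expect_equal(quantileRank(x), quantileRank(x^3 + 2))
  }
  # mean qrank of a tie-free vector is (n+1)/(2n)
  y <- rnorm(31)
  expect_equal(mean(quantileRank(y)), (31 + 1) / (2 * 31))
})

test_that("buildFeatureTable reproduces a hand-computed 4-gene toy", {
  # four 1 kb genes, constant per-gene coverage
  tx <- toyTx("chr1", c(1, 2001, 4001, 6001), c(1000, 3000, 5000, 7000),
              paste0("g", 1:4), paste0("g", 1:4, ".t1"))
  span <- function(v) toyTrack("chr1",
                               c(1, 2001, 4001, 6001),
                               c(1000, 3000, 5000, 7000), v)
  k27 <- span(c(2, 1, 4, 3))
  k36 <- span(c(1, 2, 3, 4))
  rna <- span(c(4, 3, 2, 1))
  input <- toyTrack("chr1", 1, 7000, 2)

  ft <- buildFeatureTable(tx, k27, k36, input = input, rna = rna)
  expect_equal(rownames(ft), paste0("g", 1:4))
  expect_equal(ft$length_bp, rep(1000L, 4))
  # mark sum = value * 1000; input sum = 2 * 1000; norm = value / 2
  expect_equal(ft$k27_norm, c(1, 0.5, 2, 1.5))
  expect_equal(ft$k36_norm, c(0.5, 1, 1.5, 2))
  # expression = rna sum / length = value
  expect_equal(ft$expr_norm, c(4, 3, 2, 1))
  expect_equal(ft$k27_qrank, c(0.5, 0.25, 1, 0.75))
  expect_equal(ft$k36_qrank, c(0.25, 0.5, 0.75, 1))
  expect_equal(ft$expr_qrank, c(1, 0.75, 0.5, 0.25))

  # input order of transcripts does not matter
  ft2 <- buildFeatureTable(tx[c(3, 1, 4, 2)], k27, k36, input = input,
                           rna = rna)
  expect_equal(as.data.frame(ft), as.data.frame(ft2))
})

test_that("non-autosomal genes and zero-input genes leave the table", {
  tx <- toyTx(c("chr1", "chrX", "chr1"), c(1, 1, 5001),
              c(1000, 1000, 6000), c("g1", "gx", "g3"),
              c("g1.t1", "gx.t1", "g3.t1"))
  k <- toyTrack(c("chr1", "chrX", "chr1"), c(1, 1, 5001),
                c(1000, 1000, 6000), c(2, 2, 2))
  input <- toyTrack(c("chr1", "chrX"), c(1, 1), c(1000, 1000), c(1, 1))
  # g3 has no input signal -> dropped; gx is X-linked -> excluded
  ft <- suppressMessages(suppressWarnings(
    buildFeatureTable(tx, k, k, input = input, rna = k)))
  expect_equal(rownames(ft), "g1")

  # zero mark signal is kept with the lowest rank
  k0 <- toyTrack("chr1", 5001, 6000, 2)   # nothing over g1
  input2 <- toyTrack("chr1", 1, 6000, 1)
  tx2 <- toyTx("chr1", c(1, 5001), c(1000, 6000), c("g1", "g3"),
               c("g1.t1", "g3.t1"))
  ft2 <- buildFeatureTable(tx2, k0, k0, input = input2, rna = k0)
  expect_equal(ft2["g1", "k27_norm"], 0)
  expect_lt(ft2["g1", "k27_qrank"], ft2["g3", "k27_qrank"])
})

test_that("an external abundance table can replace the RNA track", {
  tx <- toyTx("chr1", c(1, 2001), c(1000, 3000), c("g1", "g2"),
              c("g1.t1", "g2.t1"))
  k <- toyTrack("chr1", c(1, 2001), c(1000, 3000), c(2, 4))
  ft <- buildFeatureTable(tx, k, k, abundance = c(g1 = 7.5, g2 = 1.5))
  expect_equal(ft$expr_norm, c(7.5, 1.5))
  expect_equal(ft$expr_qrank, c(1, 0.5))
})
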
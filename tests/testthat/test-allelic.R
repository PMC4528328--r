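test_that("maskReference replaces exactly the listed positions with N", {
  seqs <- Biostrings::DNAStringSet(c(r1 = "ACGT", r2 = "GGGG"))
  out <- maskReference(seqs, list(r1 = 2))
  expect_equal(as.character(out), c(r1 = "ANGT", r2 = "GGGG"))

  expect_equal(as.character(maskReference(seqs, list())),
               as.character(seqs))                       # identity

  all4 <- maskReference(seqs, list(r1 = 1:4))
  expect_equal(as.character(all4[["r1"]]), "NNNN")

  expect_error(maskReference(seqs, list(r1 = 5)), "out of range.*r1")
  expect_error(maskReference(seqs, list(zz = 1)), "unknown")
})

test_that("SNP counts aggregate to genes by summation", {
  snps <- data.frame(gene_id = c("g1", "g1", "g2"),
                     chrom = "chr1", pos = c(10, 20, 30),
                     maternal_count = c(10L, 20L, 5L),
                     paternal_count = c(2L, 0L, 5L))
  agg <- aggregateSnpCounts(snps)
  expect_equal(agg$mat[agg$gene_id == "g1"], 30)
  expect_equal(agg$pat[agg$gene_id == "g1"], 2)
  expect_equal(agg$mat[agg$gene_id == "g2"], 5)
  expect_false("g3" %in% agg$gene_id)     # no SNPs, absent from output
})

test_that("allelic calls follow the binomial + bias + equivalence rules", {
  counts <- data.frame(gene_id = c("mono", "bal", "few"),
                       mat = c(30L, 50L, 6L), pat = c(2L, 50L, 4L))
  tab <- callAllelic(counts, minTotal = 10L)
  # exact doubled binomial tail: 2 * P(X <= 2 | 32, 1/2) = 2 * 529 / 2^32
  expect_equal(tab["mono", "p_binom"], 2 * 529 / 2^32, tolerance = 1e-12)
  expect_equal(tab["mono", "major_fraction"], 30 / 32)
  expect_equal(tab["mono", "call"], "monoallelic")

  # 50/50 at depth 100: both TOST tails significant
  expect_equal(tab["bal", "p_eq_low"], pbinom(50, 100, 2 / 3))
  expect_lt(tab["bal", "p_eq_low"], 0.05)
  expect_lt(tab["bal", "p_eq_high"], 0.05)
  expect_equal(tab["bal", "call"], "biallelic")

  # 6/4: no significance either way
  expect_equal(tab["few", "call"], "indeterminate")

  # below the read-depth floor everything is indeterminate
  tab20 <- callAllelic(counts[3, , drop = FALSE], minTotal = 20L)
  expect_equal(tab20$call, "indeterminate")
  expect_true(is.na(tab20$q_value))

  expect_error(callAllelic(counts, alpha = 1.5), "alpha")
})

test_that("allelic calling is symmetric in the parental labels", {
  set.seed(31)
  counts <- data.frame(gene_id = sprintf("g%03d", 1:200),
                       mat = rbinom(200, 80, runif(200)),
                       pat = rbinom(200, 80, 0.5))
  a <- callAllelic(counts)
  b <- callAllelic(transform(counts, mat = pat, pat = mat))
  expect_equal(a$call, b$call)
  expect_equal(a$p_binom, b$p_binom)
  expect_equal(a$major_fraction, b$major_fraction)
  expect_equal(a$p_eq_low, b$p_eq_high)
  expect_equal(a$p_eq_high, b$p_eq_low)
})

test_that("BH q-values match a brute-force step-up reference", {
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bruteBH(p), tolerance = 1e-12)
  }
  # and the caller's q column is that BH over tested genes
  counts <- data.frame(gene_id = paste0("g", 1:50),
                       mat = rbinom(50, 100, 0.6), pat = rbinom(50, 100, 0.4))
  counts$pat <- 100 - counts$mat
  tab <- callAllelic(counts)
  expect_equal(unname(tab$q_value), bruteBH(tab$p_binom), tolerance = 1e-12)
})

test_that("the caller is calibrated and powered at depth 100", {
  set.seed(77)
  nm <- 1000
  balanced <- data.frame(gene_id = sprintf("b%04d", 1:nm),
                         mat = rbinom(nm, 100, 0.5))
  balanced$pat <- 100L - balanced$mat
  calls <- callAllelic(balanced)
  expect_lte(mean(calls$call == "monoallelic"), 0.05)   # type-I control
  expect_gte(mean(calls$call == "biallelic"), 0.90)     # TOST power

  skewed <- data.frame(gene_id = sprintf("s%04d", 1:nm),
                       mat = rbinom(nm, 100, 0.95))
  skewed$pat <- 100L - skewed$mat
  expect_gte(mean(callAllelic(skewed)$call == "monoallelic"), 0.95)
})

test_that("clone aggregation follows the any-MAE-wins benchmark rule", {
  mk <- function(...) setNames(c(...), paste0("g", seq_along(c(...))))
  # per gene across two clones
  c1 <- c(g1 = "monoallelic", g2 = "biallelic", g3 = "indeterminate",
          g4 = "biallelic")
  c2 <- c(g1 = "biallelic", g2 = "indeterminate", g3 = "indeterminate",
          g4 = "monoallelic")
  agg <- aggregateClones(list(c1, c2))
  expect_equal(unname(agg[c("g1", "g2", "g3", "g4")]),
               c("MAE", "BAE", "indeterminate", "MAE"))
  # genes present in only one clone still aggregate
  agg2 <- aggregateClones(list(c(g1 = "monoallelic"), c(g9 = "biallelic")))
  expect_equal(unname(agg2[c("g1", "g9")]), c("MAE", "BAE"))
  expect_error(aggregateClones(list()), "clone")
})

test_that("concordance tables give Fisher p, sample OR and confirmation rates", {
  mkCalls <- function(tp, fp, fn, tn) {
    n <- tp + fp + fn + tn
    g <- sprintf("g%05d", seq_len(n))
    magic <- setNames(rep(c("MAE", "MAE", "BAE", "BAE"), c(tp, fp, fn, tn)), g)
    bench <- setNames(rep(c("MAE", "BAE", "MAE", "BAE"), c(tp, fp, fn, tn)), g)
    list(magic = magic, bench = bench)
  }
  x <- mkCalls(10, 2, 5, 40)
  cc <- concordanceTable(x$magic, x$bench)
  expect_equal(cc$odds_ratio, 40)
  expect_equal(cc$mae_confirmation, 10 / 12)

  ind <- mkCalls(25, 25, 25, 25)
  ci <- concordanceTable(ind$magic, ind$bench)
  expect_equal(ci$odds_ratio, 1)
  expect_equal(ci$fisher_p, 1)

  # counts reconstructed from published-style confirmation rates:
  # 492 MAE calls at 73% confirmed, 3585 BAE calls at 75% confirmed
  big <- mkCalls(359, 133, 896, 2689)
  cb <- concordanceTable(big$magic, big$bench)
  expect_equal(cb$odds_ratio, (359 * 2689) / (133 * 896))
  expect_equal(round(cb$odds_ratio, 2), 8.10)
  expect_lt(cb$fisher_p, 2.2e-16)
  expect_equal(cb$mae_confirmation, 359 / 492)

  # a zero margin leaves the odds ratio undefined but p computable
  z <- mkCalls(10, 0, 5, 40)
  cz <- concordanceTable(z$magic, z$bench)
  expect_true(is.na(cz$odds_ratio))
  expect_true(is.finite(cz$fisher_p))

  # indeterminate genes are excluded before counting
  m2 <- c(x$magic, gx = "not_assessed")
  b2 <- c(x$bench, gx = "MAE")
  expect_equal(concordanceTable(m2, b2)$n, cc$n)
})
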
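# minimal two-point training set: one of each class, fully separable
tinyTrain <- function() {
  data.frame(k27_qrank = c(0.25, 0.75, 0.3, 0.8),
             k36_qrank = c(0.25, 0.75, 0.2, 0.9),
             label = c("BAE", "MAE", "BAE", "MAE"))
}

test_that("root prediction is the smoothed half log-odds of the classes", {
  bal <- data.frame(k27_qrank = runif(12), k36_qrank = runif(12))
  lab <- rep(c("MAE", "BAE"), each = 6)
  m <- trainADTree(bal, lab, nBoost = 1L)
  expect_equal(m@rootPrediction, 0.5 * log(7 / 7))  # = 0

  skew <- data.frame(k27_qrank = runif(10), k36_qrank = runif(10))
  m2 <- suppressMessages(trainADTree(skew, rep(c("MAE", "BAE"), c(8, 2)),
                                     nBoost = 1L))
  expect_equal(m2@rootPrediction, 0.5 * log(9 / 3), tolerance = 1e-12)
})

test_that("degenerate training inputs are rejected", {
  f <- data.frame(k27_qrank = runif(5), k36_qrank = runif(5))
  expect_error(trainADTree(f, rep("MAE", 5)), "both")
  expect_error(trainADTree(f, rep(c("MAE", "BAE"), c(3, 2)), nBoost = 0),
               "nBoost")
  expect_error(trainADTree(f, c("MAE", "BAE", "other", "MAE", "BAE")),
               "label")
})

test_that("scoring follows the satisfied-path sum and breaks ties to BAE", {
  # empty node list: every gene scores the root prediction
  m <- new("ADTreeModel", rootPrediction = -0.3,
           nodes = data.frame(node_id = integer(), precondition = character(),
                              feature = character(), threshold = numeric(),
                              pred_true = numeric(), pred_false = numeric()),
           nBoost = 1L, featureScaleTag = "qrank-average-rank-over-n",
           weightTrace = numeric())
  f <- S4Vectors::DataFrame(k27_qrank = c(0.1, 0.9), k36_qrank = c(0.2, 0.8),
                            row.names = c("a", "b"))
  calls <- classifyGenes(m, f)
  expect_equal(calls$score, c(-0.3, -0.3))
  expect_equal(calls$call, c("BAE", "BAE"))

  # single unconditioned node: k36_qrank <= 0.5 ? -1 : +1, root 0
  m1 <- new("ADTreeModel", rootPrediction = 0,
            nodes = data.frame(node_id = 1L, precondition = "",
                               feature = "k36_qrank", threshold = 0.5,
                               pred_true = -1, pred_false = 1),
            nBoost = 1L, featureScaleTag = "qrank-average-rank-over-n",
            weightTrace = numeric())
  expect_equal(adtreeScore(m1, data.frame(k27_qrank = 0.5, k36_qrank = 0.8)),
               1)
  c1 <- classifyGenes(m1, S4Vectors::DataFrame(k27_qrank = 0.5,
                                               k36_qrank = 0.8,
                                               row.names = "g"))
  expect_equal(c1$call, "MAE")

  # score exactly zero is BAE (MAE requires strictly positive evidence)
  m0 <- m; m0@rootPrediction <- 0
  expect_equal(classifyGenes(m0, f)$call, c("BAE", "BAE"))

  # a node under an unsatisfied precondition contributes nothing
  m2 <- m1
  m2@nodes <- rbind(m1@nodes,
                    data.frame(node_id = 2L, precondition = "1:TRUE",
                               feature = "k27_qrank", threshold = 0.5,
                               pred_true = 100, pred_false = 100))
  expect_equal(adtreeScore(m2, data.frame(k27_qrank = 0.5, k36_qrank = 0.8)),
               1)   # precondition 1:TRUE fails for k36 = 0.8
})

test_that("classification is order-independent and skips missing features", {
  m <- trainADTree(tinyTrain(), tinyTrain()$label, nBoost = 3L)
  set.seed(5)
  f <- S4Vectors::DataFrame(k27_qrank = runif(30), k36_qrank = runif(30),
                            row.names = sprintf("g%02d", 1:30))
  a <- classifyGenes(m, f)
  b <- classifyGenes(m, f[sample(30), ])
  expect_equal(as.data.frame(a)[rownames(a), ],
               as.data.frame(b)[rownames(a), ])

  f2 <- f
  f2$k36_qrank[3] <- NA
  expect_warning(c2 <- classifyGenes(m, f2), "missing")
  expect_equal(nrow(c2), 29L)
})

test_that("a model refuses features computed on a different rank scale", {
  m <- trainADTree(tinyTrain(), tinyTrain()$label, nBoost = 2L,
                   featureScaleTag = "qrank-average-rank-over-n")
  f <- S4Vectors::DataFrame(k27_qrank = 0.5, k36_qrank = 0.5,
                            row.names = "g1")
  S4Vectors::metadata(f)$feature_scale_tag <- "log2-normalized"
  expect_error(classifyGenes(m, f), "scale")
})

test_that("training weight is non-increasing and separable data is learned", {
  set.seed(21)
  n <- 600
  f <- data.frame(k27_qrank = quantileRank(runif(n)),
                  k36_qrank = quantileRank(runif(n)))
  lab <- ifelse(f$k27_qrank > 0.6 & f$k36_qrank > 0.6, "MAE", "BAE")
  m <- suppressMessages(trainADTree(f, lab, nBoost = 8L))
  expect_true(all(diff(m@weightTrace) <= 1e-9))
  acc <- mean(ifelse(adtreeScore(m, f) > 0, "MAE", "BAE") == lab)
  expect_gte(acc, 0.95)
})

test_that("the planted two-feature rule is recovered on held-out data", {
  set.seed(1234)
  n <- 4000
  f <- data.frame(k27_qrank = quantileRank(runif(n)),
                  k36_qrank = quantileRank(runif(n)))
  lab <- ifelse(f$k27_qrank > 0.6 & f$k36_qrank > 0.6, "MAE", "BAE")
  flip <- runif(n) < 0.05
  lab[flip] <- ifelse(lab[flip] == "MAE", "BAE", "MAE")
  tr <- seq_len(2000); te <- setdiff(seq_len(n), tr)
  m <- trainADTree(f[tr, ], lab[tr], nBoost = 10L)
  acc <- mean(ifelse(adtreeScore(m, f[te, ]) > 0, "MAE", "BAE") == lab[te])
  expect_gte(acc, 0.90)
})

test_that("serialization round-trips to bit-identical scores", {
  set.seed(8)
  f <- data.frame(k27_qrank = quantileRank(runif(200)),
                  k36_qrank = quantileRank(runif(200)))
  lab <- ifelse(f$k27_qrank * f$k36_qrank > 0.3, "MAE", "BAE")
  m <- suppressMessages(trainADTree(f, lab, nBoost = 6L))
  p <- tempfile(fileext = ".json")
  writeADTreeModel(m, p)
  m2 <- readADTreeModel(p)
  expect_identical(adtreeScore(m2, f), adtreeScore(m, f))
  expect_identical(m2@nodes$threshold, m@nodes$threshold)
  expect_identical(m2@featureScaleTag, m@featureScaleTag)
})
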
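test_that("confusion counts and metrics match hand-enumerated toys", {
  ids <- sprintf("s%d", 1:20)
  truth <- structure(rep(c("target", "contaminant"), each = 10), names = ids)
  perfect <- truth
  cc <- confusionCounts(perfect, truth)
  expect_equal(cc, c(TP = 10, FP = 0, TN = 10, FN = 0))
  allT <- structure(rep("target", 20), names = ids)
  expect_equal(confusionCounts(allT, truth), c(TP = 10, FP = 10, TN = 0, FN = 0))

  # 8-row toy with 2 flips: truth tttt/cccc, predictions flip s4 and c4
  t8 <- structure(rep(c("target", "contaminant"), each = 4),
                  names = paste0("r", 1:8))
  p8 <- t8
  p8["r4"] <- "contaminant"
  p8["r8"] <- "target"
  c8 <- confusionCounts(p8, t8)
  expect_equal(c8, c(TP = 3, FP = 1, TN = 3, FN = 1))
  m8 <- classMetrics(c8)
  expect_equal(m8$accuracy, 0.75)
  expect_equal(m8$sensitivity, 0.75)
  expect_equal(m8$specificity, 0.75)
  expect_equal(m8$error, 0.25)

  expect_equal(classMetrics(c(TP = 99, FP = 0, TN = 0, FN = 1))$sensitivity, 0.99)
  expect_equal(classMetrics(c(TP = 0, FP = 2, TN = 98, FN = 0))$specificity, 0.98)
  # zero-denominator metrics are NA, never silent zeros
  noNeg <- classMetrics(c(TP = 5, FP = 0, TN = 0, FN = 0))
  expect_true(is.na(noNeg$specificity))
  expect_equal(noNeg$accuracy, 1)
  expect_error(classMetrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "empty")
  # id mismatch errors
  expect_error(confusionCounts(structure("target", names = "zz"),
                               structure("target", names = "s1")),
               "differ")
})

test_that("metrics are invariant to row permutation and accuracy + error = 1", {
  set.seed(3)
  ids <- sprintf("x%d", 1:50)
  truth <- structure(sample(c("target", "contaminant"), 50, TRUE), names = ids)
  pred <- structure(sample(c("target", "contaminant"), 50, TRUE), names = ids)
  m1 <- classMetrics(confusionCounts(pred, truth))
  perm <- sample(ids)
  m2 <- classMetrics(confusionCounts(pred[perm], truth))
  expect_identical(m1, m2)
  expect_identical(m1$accuracy + m1$error, 1)
})

sweepFixture <- function(n = 150, seed = 8) {
  sim <- simulatePredictorTable("separable", seed = seed,
                                nTarget = n, nContam = n %/% 2)
  list(table = sim$table,
       labeled = LabeledScaffolds(truthVector(sim)))
}

test_that("training-fraction sweep aggregates replicate metrics reproducibly", {
  fx <- sweepFixture()
  spec <- list(kind = "bagging", B = 5L)
  rep1 <- trainingFractionSweep(fx$labeled, fx$table,
                                fractions = c(0.05, 0.5), replicates = 4,
                                modelSpec = spec, seed = 31)
  expect_s4_class(rep1, "SweepReport")
  tb <- rep1@table
  expect_setequal(unique(tb$metric),
                  c("error", "accuracy", "sensitivity", "specificity"))
  expect_true(all(tb$std >= 0))
  # determinism from the master seed
  rep2 <- trainingFractionSweep(fx$labeled, fx$table,
                                fractions = c(0.05, 0.5), replicates = 4,
                                modelSpec = spec, seed = 31)
  expect_identical(rep1@table, rep2@table)
  # aggregates equal recomputation from the stored per-replicate records
  pr <- rep1@perReplicate
  acc50 <- pr$accuracy[pr$fraction == 0.5 & pr$ok]
  expect_equal(tb$mean[tb$fraction == 0.5 & tb$metric == "accuracy"],
               mean(acc50))
  expect_equal(tb$std[tb$fraction == 0.5 & tb$metric == "accuracy"],
               sd(acc50))
  # more training helps on this regime
  accs <- tb[tb$metric == "accuracy", ]
  expect_gte(accs$mean[accs$fraction == 0.5], accs$mean[accs$fraction == 0.05])
  # single replicate: std 0 by convention
  r1 <- trainingFractionSweep(fx$labeled, fx$table, fractions = 0.5,
                              replicates = 1, modelSpec = spec, seed = 2)
  expect_true(all(r1@table$std == 0))
})

test_that("predictor-subset sweep ranks by importance and grows with k", {
  fx <- sweepFixture(n = 200)
  spec <- list(kind = "bagging", B = 10L)
  rep1 <- predictorSubsetSweep(fx$labeled, fx$table, replicates = 3,
                               modelSpec = spec, sizes = c(2, 4, 8),
                               seed = 17)
  ord <- attr(rep1@table, "ordering")
  expect_setequal(ord, colnames(predictorMatrix(fx$table)))
  acc <- rep1@table[rep1@table$metric == "accuracy", ]
  # monotone non-decrease within one std on this preset
  expect_gte(acc$mean[acc$n_predictors == 8] + acc$std[acc$n_predictors == 8],
             acc$mean[acc$n_predictors == 2])
  # an explicit ordering is respected
  rep2 <- predictorSubsetSweep(fx$labeled, fx$table, replicates = 2,
                               modelSpec = spec, sizes = 2,
                               ordering = c("gc", "length", "dna_mean_depth",
                                            "rna_mean_depth", "dna_breadth",
                                            "rna_breadth", "dna_read_gc",
                                            "rna_read_gc"),
                               seed = 17)
  expect_equal(attr(rep2@table, "ordering")[1:2], c("gc", "length"))
  expect_error(predictorSubsetSweep(fx$labeled, fx$table, replicates = 1,
                                    ordering = c("gc", "bogus"), seed = 1),
               "bogus")
  # TSV export round-trips the summary table
  p <- tempfile(fileext = ".tsv")
  writeSweepReport(rep1, p)
  back <- read.delim(p)
  expect_equal(back$mean, rep1@table$mean)
})

test_that("the k = 8 subset point equals a plain full-predictor run at equal seeds", {
  fx <- sweepFixture(n = 120)
  spec <- list(kind = "bagging", B = 5L)
  repK <- predictorSubsetSweep(fx$labeled, fx$table, replicates = 3,
                               modelSpec = spec, sizes = 8, seed = 23)
  # reproduce by hand with the same derived seeds and all predictors
  accs <- vapply(1:3, function(r) {
    rseed <- deriveSeed(23, r)
    sp <- splitTraining(fx$labeled, 0.5, seed = rseed)
    x <- predictorMatrix(fx$table)
    lab <- scaffoldClasses(fx$labeled)
    m <- fitModel(x[sp@trainIds, , drop = FALSE], lab[sp@trainIds],
                  spec = spec, seed = rseed)
    pred <- predict(m, x[sp@testIds, , drop = FALSE])
    names(pred) <- sp@testIds
    classMetrics(confusionCounts(pred, lab[sp@testIds]))$accuracy
  }, 0)
  acc <- repK@table[repK@table$metric == "accuracy", ]
  expect_equal(acc$mean, mean(accs))
})
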
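test_that("entropy, information gain and Gini reproduce hand-derived values", {
  expect_equal(entropyBits(c(target = 5, contaminant = 5)), 1.0)
  expect_equal(entropyBits(c(10, 0)), 0.0)
  expect_equal(entropyBits(c(3, 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(entropyBits(c(0, 0)), 0.0)
  expect_error(entropyBits(c(-1, 2)), "non-negative")

  expect_equal(informationGain(c(2, 2), list(c(2, 0), c(0, 2))), 1.0)
  expect_equal(informationGain(c(4, 4), list(c(2, 2), c(2, 2))), 0.0)
  expect_equal(informationGain(c(3, 1), list(c(2, 0), c(1, 1))),
               entropyBits(c(3, 1)) - 0.5 * 1.0)
  expect_error(informationGain(c(3, 1), list(c(2, 0), c(2, 1))), "sum")

  expect_equal(giniIndex(c(1, 0)), 0.0)
  expect_equal(giniIndex(c(0.5, 0.5)), 0.5)
  expect_equal(giniIndex(c(0.75, 0.25)), 0.375)
  expect_error(giniIndex(c(0.7, 0.2)), "sum to 1")
  expect_error(giniIndex(c(-0.5, 1.5)), "non-negative")
})

test_that("bestSplit finds the separating midpoint and honors tie-breaks", {
  x <- cbind(v = c(1, 2, 9, 10))
  y <- c("target", "target", "contaminant", "contaminant")
  sp <- bestSplit(x, y)
  expect_equal(sp$predictor, "v")
  expect_equal(sp$threshold, 5.5)
  expect_equal(unname(sp$left), c(2, 0))
  expect_equal(unname(sp$right), c(0, 2))
  expect_equal(sp$gain, 1.0)
  # pure input: nothing to gain
  expect_null(bestSplit(x, rep("target", 4)))
  # identical rows with mixed labels: no split exists
  expect_null(bestSplit(cbind(v = rep(1, 4)), y))
  # equal-quality splits prefer the earlier (canonical) predictor
  x2 <- cbind(p1 = c(0, 0, 1, 1), p2 = c(0, 0, 1, 1))
  expect_equal(bestSplit(x2, y)$predictor, "p1")
  # minLeaf constrains the candidate set
  x3 <- cbind(v = c(1, 2, 3, 4))
  y3 <- c("target", "target", "target", "contaminant")
  expect_equal(bestSplit(x3, y3, minLeaf = 1)$threshold, 3.5)
  expect_equal(bestSplit(x3, y3, minLeaf = 2)$threshold, 2.5)
  expect_null(bestSplit(x3, y3, minLeaf = 3))
  # entropy criterion agrees on the clean separation
  expect_equal(bestSplit(x, y, criterion = "entropy")$threshold, 5.5)
})

test_that("fitTree grows to purity on consistent data and respects budgets", {
  x <- cbind(v = c(1, 2, 9, 10))
  y <- c("target", "target", "contaminant", "contaminant")
  tr <- fitTree(x, y)
  expect_equal(nSplits(tr), 1)           # one split suffices
  expect_identical(predict(tr, x), y)
  # XOR pattern: no single split works, >= 3 splits reach purity
  xx <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  yy <- c("target", "contaminant", "contaminant", "target")
  expect_null(bestSplit(xx, yy, predictors = "a"))
  txor <- fitTree(xx, yy)
  expect_gte(nSplits(txor), 3)
  expect_identical(predict(txor, xx), yy)
  # training error is 0 on consistent random data with no budget
  set.seed(42)
  xr <- cbind(p1 = runif(40), p2 = runif(40), p3 = runif(40))
  yr <- sample(c("target", "contaminant"), 40, replace = TRUE)
  trr <- fitTree(xr, yr)
  expect_identical(predict(trr, xr), yr)
  # maxSplits = 0 gives a majority stump
  stump <- fitTree(x, c("target", "target", "target", "contaminant"),
                   maxSplits = 0)
  expect_equal(nSplits(stump), 0)
  expect_equal(unique(predict(stump, x)), "target")
})

test_that("cost-sensitive prediction minimizes expected cost with target ties", {
  x <- cbind(v = c(1, 10))
  # leaf proportions (0.4, 0.6): uniform costs pick contaminant...
  tr <- fitTree(cbind(v = rep(1, 5)), rep(c("target", "contaminant"), c(2, 3)),
                maxSplits = 0)
  expect_equal(unique(predict(tr, x)), "contaminant")
  # ...but asymmetric costs flip the call: with leaf (0.4, 0.6),
  # C(target|contam) = 10, C(contam|target) = 1:
  # cost(target) = 0.6 * 10 = 6; cost(contam) = 0.4 * 1 = 0.4
  costs <- matrix(c(0, 1, 10, 0), 2, 2,
                  dimnames = list(c("target", "contaminant"),
                                  c("target", "contaminant")))
  expect_equal(unique(predict(tr, x, costs = costs)), "contaminant")
  costs2 <- matrix(c(0, 10, 1, 0), 2, 2)  # now mistakes on targets cost 10
  expect_equal(unique(predict(tr, x, costs = costs2)), "target")
  # exact 50/50 leaf, uniform costs: canonical class 1 (target) wins
  tie <- fitTree(cbind(v = rep(1, 4)), rep(c("target", "contaminant"), 2),
                 maxSplits = 0)
  expect_equal(unique(predict(tie, x)), "target")
  # rows at the threshold route left
  tsplit <- fitTree(cbind(v = c(1, 2, 9, 10)),
                    c("target", "target", "contaminant", "contaminant"))
  expect_equal(predict(tsplit, cbind(v = 5.5)), "target")
  # missing predictor errors (no surrogates)
  expect_error(predict(tsplit, cbind(w = 1)), "v")
  expect_error(predict(tsplit, cbind(v = NA_real_)), "missing")
})

test_that("tree Gini importance accumulates weighted impurity decreases", {
  x <- cbind(p1 = c(1, 2, 9, 10), p2 = c(5, 6, 5, 6))
  y <- c("target", "target", "contaminant", "contaminant")
  tr <- fitTree(x, y)
  imp <- giniImportance(tr)
  # single perfect split from a (0.5, 0.5) root: delta G = 0.5
  expect_equal(unname(imp["p1"]), 0.5)
  expect_equal(unname(imp["p2"]), 0)
  # stump: all zeros
  stump <- fitTree(x, y, maxSplits = 0)
  expect_true(all(giniImportance(stump) == 0))
  # row order (scaffold relabeling) leaves importances unchanged
  perm <- c(3, 1, 4, 2)
  expect_equal(giniImportance(fitTree(x[perm, ], y[perm])), imp)
  # literal unweighted mode exists and differs in general
  deep <- fitTree(cbind(p1 = c(1, 2, 3, 4, 5, 6), p2 = c(1, 1, 2, 2, 1, 1)),
                  c("target", "target", "contaminant", "target",
                    "contaminant", "contaminant"))
  expect_length(giniImportance(deep, weighted = FALSE), 2)
})

test_that("tree serialization round-trips exactly", {
  set.seed(7)
  x <- cbind(p1 = runif(30), p2 = runif(30))
  y <- sample(c("target", "contaminant"), 30, replace = TRUE)
  tr <- fitTree(x, y)
  p <- tempfile(fileext = ".json")
  writeModel(tr, p)
  tr2 <- readModel(p)
  expect_equal(tr2@root, tr@root, tolerance = 0)
  expect_identical(tr2@config, tr@config)
  expect_identical(predict(tr2, x), predict(tr, x))
  # rewriting the restored model is byte-identical
  p2 <- tempfile(fileext = ".json")
  writeModel(tr2, p2)
  expect_identical(readLines(p), readLines(p2))
})
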
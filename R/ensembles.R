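# Bagged, random-forest and boosted tree ensembles.
#
# Per-tree seeds are derived from the master seed with deriveSeed(seed, b),
# so bagging and a forest fitted with the same master seed draw identical
# bootstrap samples ("shared bootstrap streams"), and any single tree can be
# re-fit in isolation.

#' Fit a bagged (bootstrap-aggregated) tree model
#'
#' Draws `B` bootstrap resamples of the training rows (size n, with
#' replacement) and fits one unpruned classification tree to each. The
#' ensemble target score of a row is the mean over trees of the leaf
#' posterior P(target | x), and classification thresholds that score.
#'
#' @param x Predictor matrix or [PredictorTable-class].
#' @param y Class labels aligned with rows of `x`.
#' @param B Number of bootstrap trees (default 100).
#' @param criterion,minLeaf,maxSplits Tree-level parameters, see [fitTree()].
#' @param predictors Candidate predictor names (default: all columns).
#' @param threshold Decision threshold on the target score (default 0.5;
#'   a score equal to the threshold is called target).
#' @param seed Integer master seed.
#' @param identityResample If `TRUE`, every "bootstrap" is the identity
#'   resample (each row once). Intended for degenerate-case verification:
#'   with `B = 1` the model then reproduces a single [fitTree()] fit.
#' @return An [EnsembleModel-class] of kind `"bagging"`.
#' @export
fitBagging <- function(x, y, B = 100L, criterion = "gini", minLeaf = 1L,
                       maxSplits = Inf, predictors = NULL, threshold = 0.5,
                       seed = 1L, identityResample = FALSE) {
  fitResampledTrees(x, y, kind = "bagging", B = B, m = NULL,
                    criterion = criterion, minLeaf = minLeaf,
                    maxSplits = maxSplits, predictors = predictors,
                    threshold = threshold, seed = seed,
                    identityResample = identityResample)
}

#' Fit a random forest model
#'
#' Bagging in which each split considers only a fresh uniform draw of `m`
#' of the `p` candidate predictors. With `m = p` no drawing is performed and
#' the forest is identical, tree for tree, to [fitBagging()] at the same
#' seed. Set `mtryPerTree = TRUE` to draw the subset once per tree instead
#' of at each split.
#'
#' @inheritParams fitBagging
#' @param nTrees Number of trees (default 5000).
#' @param m Predictors considered per split (default 4).
#' @param mtryPerTree Draw the predictor subset per tree rather than per
#'   split.
#' @return An [EnsembleModel-class] of kind `"random_forest"`.
#' @export
fitRandomForest <- function(x, y, nTrees = 5000L, m = 4L, criterion = "gini",
                            minLeaf = 1L, maxSplits = Inf, predictors = NULL,
                            threshold = 0.5, seed = 1L, mtryPerTree = FALSE,
                            identityResample = FALSE) {
  fitResampledTrees(x, y, kind = "random_forest", B = nTrees, m = m,
                    criterion = criterion, minLeaf = minLeaf,
                    maxSplits = maxSplits, predictors = predictors,
                    threshold = threshold, seed = seed,
                    mtryPerTree = mtryPerTree,
                    identityResample = identityResample)
}

fitResampledTrees <- function(x, y, kind, B, m, criterion, minLeaf, maxSplits,
                              predictors, threshold, seed,
                              mtryPerTree = FALSE, identityResample = FALSE) {
  if (is(x, "PredictorTable")) x <- predictorMatrix(x)
  predictors <- predictors %||% colnames(x)
  if (B < 1L) stopf("the number of trees must be >= 1")
  p <- length(predictors)
  if (!is.null(m) && (m < 1L || m > p))
    stopf("m must be in [1, %d], got %s", p, format(m))
  yc <- classCodes(y)
  n <- nrow(x)
  trees <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(deriveSeed(seed, b))
    idx <- if (identityResample) seq_len(n) else sample.int(n, n, replace = TRUE)
    trees[[b]] <- fitTree(x[idx, , drop = FALSE], yc[idx],
                          criterion = criterion, minLeaf = minLeaf,
                          maxSplits = maxSplits, predictors = predictors,
                          mtry = m, mtryPerTree = mtryPerTree)
  }
  new("EnsembleModel", kind = kind, trees = trees, B = as.integer(B),
      m = as.integer(m %||% p), shrinkage = NA_real_, f0 = NA_real_,
      threshold = threshold,
      config = list(criterion = criterion, minLeaf = as.integer(minLeaf),
                    maxSplits = maxSplits, mtryPerTree = mtryPerTree,
                    identityResample = identityResample),
      predictors = predictors, classes = CLASS_NAMES, seed = as.integer(seed))
}

#' Fit a boosted shallow-tree model
#'
#' Residual boosting of the 0/1 target indicator: starting from the training
#' base rate F0 = mean(y), each stage fits a regression tree with at most
#' `maxSplits` splits (squared-error splitting) to the current residuals
#' r = y - F(x) and updates F by `shrinkage` times the tree's prediction.
#' The target score of a row is F(x) clipped to [0, 1].
#'
#' @inheritParams fitBagging
#' @param nTrees Number of boosting stages (default 10).
#' @param maxSplits Split budget per stage tree (default 2).
#' @param shrinkage Learning rate in (0, 1] (default 0.01); 0 is accepted
#'   and yields the base-rate model.
#' @return An [EnsembleModel-class] of kind `"boosted"`.
#' @export
fitBoosted <- function(x, y, nTrees = 10L, maxSplits = 2L, shrinkage = 0.01,
                       minLeaf = 1L, predictors = NULL, threshold = 0.5,
                       seed = 1L) {
  if (is(x, "PredictorTable")) x <- predictorMatrix(x)
  predictors <- predictors %||% colnames(x)
  if (nTrees < 1L) stopf("nTrees must be >= 1")
  if (shrinkage < 0 || shrinkage > 1) stopf("shrinkage must be in [0, 1]")
  y01 <- as.numeric(classCodes(y) == 1L)
  f0 <- mean(y01)
  Fcur <- rep(f0, length(y01))
  trees <- vector("list", nTrees)
  for (b in seq_len(nTrees)) {
    r <- y01 - Fcur
    tr <- fitRegTree(x, r, maxSplits = maxSplits, minLeaf = minLeaf,
                     predictors = predictors)
    trees[[b]] <- tr
    Fcur <- Fcur + shrinkage * regTreeScore(tr, x)
  }
  new("EnsembleModel", kind = "boosted", trees = trees,
      B = as.integer(nTrees), m = length(predictors),
      shrinkage = shrinkage, f0 = f0, threshold = threshold,
      config = list(maxSplits = as.integer(maxSplits),
                    minLeaf = as.integer(minLeaf)),
      predictors = predictors, classes = CLASS_NAMES, seed = as.integer(seed))
}

# Target score in [0, 1] for every row.
ensembleScore <- function(model, x) {
  if (model@kind == "boosted") {
    f <- rep(model@f0, nrow(x))
    for (tr in model@trees) f <- f + model@shrinkage * regTreeScore(tr, x)
    return(pmin(pmax(f, 0), 1))
  }
  acc <- numeric(nrow(x))
  for (tr in model@trees) acc <- acc + treeScore(tr@root, x)
  acc / length(model@trees)
}

#' Predict from an ensemble model
#'
#' Bagging and random forests average the per-tree leaf posteriors
#' P(target | x); boosted models evaluate the clipped additive score. The
#' predicted class is target when the score is greater than or equal to the
#' model's decision threshold (default 0.5).
#'
#' @param object An [EnsembleModel-class].
#' @param newdata [PredictorTable-class], matrix or data.frame.
#' @param type `"class"` (default) or `"prob"` for the target score.
#' @return Character classes or numeric scores.
#' @export
setMethod("predict", "EnsembleModel",
  function(object, newdata, type = c("class", "prob")) {
    type <- match.arg(type)
    x <- rowsForModel(newdata, object@predictors)
    sc <- ensembleScore(object, x)
    if (type == "prob") return(sc)
    ifelse(sc >= object@threshold, CLASS_NAMES[1L], CLASS_NAMES[2L])
  })

#' @describeIn giniImportance Ensemble importance: the mean of per-tree
#'   importances, normalized to sum to 1 (all-zero stays all-zero). Boosted
#'   models use the analogous variance-reduction importance of their
#'   regression stages.
#' @export
setMethod("giniImportance", "EnsembleModel", function(object, weighted = TRUE) {
  imp <- structure(numeric(length(object@predictors)),
                   names = object@predictors)
  for (tr in object@trees) {
    imp <- imp + if (object@kind == "boosted")
      regTreeImportance(tr, object@predictors)
    else giniImportance(tr, weighted = weighted)
  }
  imp <- imp / length(object@trees)
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  imp
})

#' @describeIn nSplits Total splits across an ensemble's trees.
#' @export
setMethod("nSplits", "EnsembleModel", function(object) {
  sum(vapply(object@trees, function(tr) {
    if (is(tr, "DecisionTreeModel")) countSplits(tr@root) else countSplits(tr)
  }, integer(1)))
})

setMethod("show", "EnsembleModel", function(object) {
  extra <- switch(object@kind,
    random_forest = sprintf(", m = %d", object@m),
    boosted = sprintf(", shrinkage = %g", object@shrinkage),
    "")
  cat(sprintf("EnsembleModel: %s with B = %d tree(s)%s, threshold = %g, seed = %d\n",
              object@kind, object@B, extra, object@threshold, object@seed))
})

## ---- Model-spec dispatcher (used by sweeps and the pipeline) ------------

#' Fit a model from a declarative specification
#'
#' Convenience dispatcher used by the sweep experiments and the pipeline.
#' `spec` is a list with `kind` in `"tree"`, `"bagging"`, `"random_forest"`
#' or `"boosted"` plus the matching hyperparameters (`B`, `m`, `nTrees`,
#' `shrinkage`, `maxSplits`, `criterion`, `minLeaf`, `threshold`).
#'
#' @param x Predictor matrix or [PredictorTable-class].
#' @param y Class labels.
#' @param spec Model specification list; `list(kind = "bagging", B = 100)`
#'   is the default.
#' @param predictors Candidate predictors.
#' @param seed Integer seed.
#' @return A fitted [DecisionTreeModel-class] or [EnsembleModel-class].
#' @export
fitModel <- function(x, y, spec = list(kind = "bagging"), predictors = NULL,
                     seed = 1L) {
  kind <- spec$kind %||% "bagging"
  criterion <- spec$criterion %||% "gini"
  minLeaf <- spec$minLeaf %||% 1L
  threshold <- spec$threshold %||% 0.5
  switch(kind,
    tree = fitTree(x, y, criterion = criterion, minLeaf = minLeaf,
                   maxSplits = spec$maxSplits %||% Inf,
                   predictors = predictors),
    bagging = fitBagging(x, y, B = spec$B %||% 100L, criterion = criterion,
                         minLeaf = minLeaf,
                         maxSplits = spec$maxSplits %||% Inf,
                         predictors = predictors, threshold = threshold,
                         seed = seed),
    random_forest = fitRandomForest(x, y, nTrees = spec$nTrees %||% 5000L,
                                    m = spec$m %||% 4L, criterion = criterion,
                                    minLeaf = minLeaf,
                                    maxSplits = spec$maxSplits %||% Inf,
                                    predictors = predictors,
                                    threshold = threshold, seed = seed),
    boosted = fitBoosted(x, y, nTrees = spec$nTrees %||% 10L,
                         maxSplits = spec$maxSplits %||% 2L,
                         shrinkage = spec$shrinkage %||% 0.01,
                         minLeaf = minLeaf, predictors = predictors,
                         threshold = threshold, seed = seed),
    stopf("unknown model kind '%s'", kind))
}
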
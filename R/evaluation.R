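# Confusion-matrix metrics and the two replicate sweep experiments
# (training fraction; predictor subsets ranked by Gini importance).

#' Confusion counts of predictions against truth
#'
#' Target scaffolds are the positives, contaminants the negatives. Truth
#' must contain no unknowns — scaffolds without a database label are
#' excluded upstream.
#'
#' @param predictions Named character vector of predicted classes, or an
#'   unnamed vector aligned with `truth`.
#' @param truth Named character vector of true classes.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusionCounts <- function(predictions, truth) {
  if (!is.null(names(predictions)) && !is.null(names(truth))) {
    if (!setequal(names(predictions), names(truth)))
      stopf("prediction and truth scaffold id sets differ")
    predictions <- predictions[names(truth)]
  } else if (length(predictions) != length(truth)) {
    stopf("predictions and truth lengths differ")
  }
  p <- classCodes(predictions)
  t <- classCodes(truth)
  c(TP = sum(p == 1L & t == 1L), FP = sum(p == 1L & t == 2L),
    TN = sum(p == 2L & t == 2L), FN = sum(p == 2L & t == 1L))
}

#' Classification metrics from confusion counts
#'
#' error = (FP + FN) / total, accuracy = 1 - error,
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP). A metric with
#' a zero denominator is returned as `NA` (flagged undefined), never as a
#' silent 0.
#'
#' @param counts Named vector `c(TP, FP, TN, FN)` from [confusionCounts()].
#' @return Named list with `error`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
classMetrics <- function(counts) {
  total <- sum(counts)
  if (total == 0) stopf("empty test set: no metrics")
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  err <- (fp + fn) / total
  list(error = err, accuracy = 1 - err,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Fit on the train side of a split, return metrics on the test side.
fitAndScore <- function(ptable, labels, trainIds, testIds, modelSpec,
                        predictors, seed) {
  x <- predictorMatrix(ptable)
  yTr <- labels[trainIds]
  if (length(unique(yTr)) < 2) return(NULL)  # single-class draw: no model
  model <- fitModel(x[trainIds, , drop = FALSE], yTr, spec = modelSpec,
                    predictors = predictors, seed = seed)
  pred <- predict(model, x[testIds, , drop = FALSE])
  names(pred) <- testIds
  classMetrics(confusionCounts(pred, labels[testIds]))
}

aggregateSweep <- function(rec, axisName, replicates, seed) {
  metricCols <- c("error", "accuracy", "sensitivity", "specificity")
  pts <- unique(rec[[axisName]])
  rows <- do.call(rbind, lapply(pts, function(v) {
    sub <- rec[rec[[axisName]] == v, ]
    okRows <- sub[sub$ok, ]
    do.call(rbind, lapply(metricCols, function(m) {
      vals <- okRows[[m]]
      data.frame(axis = v, metric = m,
                 mean = if (length(vals)) mean(vals, na.rm = TRUE) else NA_real_,
                 std = if (sum(!is.na(vals)) > 1) stats::sd(vals, na.rm = TRUE)
                       else 0,
                 n_ok = nrow(okRows), n_failed = sum(!sub$ok))
    }))
  }))
  names(rows)[1] <- axisName
  rownames(rows) <- NULL
  new("SweepReport", axis = axisName, table = rows,
      replicates = as.integer(replicates), seed = as.integer(seed),
      perReplicate = rec)
}

#' Training-fraction sweep
#'
#' For each training fraction and replicate, draws a fresh random split of
#' the labeled scaffolds (replicate seeds derived from the master seed via
#' [deriveSeed()]), fits the model and scores the held-out labeled
#' scaffolds; reports mean and standard deviation of accuracy, sensitivity
#' and specificity per fraction. Replicates whose training draw contains a
#' single class are recorded as failed and excluded from the aggregates.
#'
#' @param labeled A [LabeledScaffolds-class].
#' @param ptable A [PredictorTable-class] covering the labeled ids.
#' @param fractions Numeric vector of training fractions in (0, 1)
#'   (default 0.01 to 0.99 by 0.01 — the 1-99 percent sweep).
#' @param replicates Replicates per fraction (default 100).
#' @param modelSpec Model specification, see [fitModel()].
#' @param predictors Predictor subset to use (default all eight).
#' @param seed Master seed.
#' @return A [SweepReport-class] with axis `"fraction"`.
#' @export
trainingFractionSweep <- function(labeled, ptable,
                                  fractions = seq(0.01, 0.99, by = 0.01),
                                  replicates = 100L,
                                  modelSpec = list(kind = "bagging", B = 100L),
                                  predictors = NULL, seed = 1L) {
  if (any(fractions <= 0 | fractions >= 1))
    stopf("fractions must lie in (0, 1)")
  if (replicates < 1) stopf("replicates must be >= 1")
  rec <- expand.grid(fraction = fractions, replicate = seq_len(replicates))
  rec <- rec[order(rec$fraction, rec$replicate), ]
  rownames(rec) <- NULL
  out <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    rseed <- deriveSeed(seed, (match(rec$fraction[i], fractions) - 1L) *
                                replicates + rec$replicate[i])
    sp <- splitTraining(labeled, rec$fraction[i], seed = rseed)
    m <- fitAndScore(ptable, scaffoldClasses(labeled), sp@trainIds,
                     sp@testIds, modelSpec, predictors, seed = rseed)
    out[[i]] <- m
  }
  rec$ok <- !vapply(out, is.null, TRUE)
  for (m in c("error", "accuracy", "sensitivity", "specificity"))
    rec[[m]] <- vapply(out, function(r) if (is.null(r)) NA_real_ else r[[m]],
                       0)
  if (any(!rec$ok))
    message(sprintf("%d replicate(s) failed (single-class training draw)",
                    sum(!rec$ok)))
  aggregateSweep(rec, "fraction", replicates, seed)
}

#' Predictor-subset sweep
#'
#' Ranks the eight predictors once, by the Gini importance of a bagged model
#' fitted on a seed-fixed 50 percent split, then for each k = 2..8 fits
#' replicate models restricted to the top-k predictors and reports mean and
#' standard deviation of the metrics per k. A user-supplied `ordering`
#' (vector of predictor names, most important first) replaces the automatic
#' ranking.
#'
#' @inheritParams trainingFractionSweep
#' @param replicates Replicates per subset size (default 1000).
#' @param fraction Training fraction for every replicate (default 0.5).
#' @param ordering Optional explicit predictor ordering.
#' @param sizes Subset sizes (default 2:8).
#' @return A [SweepReport-class] with axis `"n_predictors"`; the ranking
#'   used is attached as attribute `ordering` of the report table.
#' @export
predictorSubsetSweep <- function(labeled, ptable, replicates = 1000L,
                                 fraction = 0.5,
                                 modelSpec = list(kind = "bagging", B = 100L),
                                 ordering = NULL, sizes = 2:8, seed = 1L) {
  if (is.null(ordering)) {
    sp0 <- splitTraining(labeled, 0.5, seed = deriveSeed(seed, 0L))
    x <- predictorMatrix(ptable)
    base <- fitModel(x[sp0@trainIds, , drop = FALSE],
                     scaffoldClasses(labeled)[sp0@trainIds],
                     spec = modelSpec, seed = deriveSeed(seed, 0L))
    imp <- giniImportance(base)
    ordering <- names(sort(imp, decreasing = TRUE))
  }
  bad <- setdiff(ordering, PREDICTOR_NAMES)
  if (length(bad) > 0)
    stopf("unknown predictor(s) in ordering: %s", paste(bad, collapse = ", "))
  if (max(sizes) > length(ordering))
    stopf("subset size exceeds the number of ranked predictors")
  rec <- expand.grid(n_predictors = sizes, replicate = seq_len(replicates))
  rec <- rec[order(rec$n_predictors, rec$replicate), ]
  rownames(rec) <- NULL
  out <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    # one seed per replicate index: all subset sizes see the same splits
    rseed <- deriveSeed(seed, rec$replicate[i])
    sp <- splitTraining(labeled, fraction, seed = rseed)
    preds <- ordering[seq_len(rec$n_predictors[i])]
    out[[i]] <- fitAndScore(ptable, scaffoldClasses(labeled), sp@trainIds,
                            sp@testIds, modelSpec, preds, seed = rseed)
  }
  rec$ok <- !vapply(out, is.null, TRUE)
  for (m in c("error", "accuracy", "sensitivity", "specificity"))
    rec[[m]] <- vapply(out, function(r) if (is.null(r)) NA_real_ else r[[m]],
                       0)
  rep0 <- aggregateSweep(rec, "n_predictors", replicates, seed)
  attr(rep0@table, "ordering") <- ordering
  rep0
}

#' Write a sweep report as TSV
#' @param report A [SweepReport-class].
#' @param path Output TSV path.
#' @param perReplicate Also write the per-replicate log next to `path`
#'   (suffix `.replicates.tsv`).
#' @return `path`, invisibly.
#' @export
writeSweepReport <- function(report, path, perReplicate = FALSE) {
  utils::write.table(report@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (perReplicate)
    utils::write.table(report@perReplicate,
                       sub("(\\.tsv)?$", ".replicates.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "SweepReport", function(object) {
  cat(sprintf("SweepReport over %s (%d replicates, seed %d)\n",
              object@axis, object@replicates, object@seed))
  acc <- object@table[object@table$metric == "accuracy", ]
  print(utils::head(acc, 10), row.names = FALSE)
})
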
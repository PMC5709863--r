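#' @import methods
NULL

#' PredictorTable: per-scaffold predictor variables
#'
#' One row per scaffold with the eight predictor variables used for
#' contaminant classification: scaffold length (bp), scaffold GC fraction,
#' mean per-base depth, breadth of coverage (fraction of positions with
#' depth >= 1) and aligned-read GC fraction for the DNA and the RNA
#' libraries.
#'
#' @slot table `data.frame` with column `scaffold_id` followed by the eight
#'   canonical predictor columns `length`, `gc`, `dna_mean_depth`,
#'   `rna_mean_depth`, `dna_breadth`, `rna_breadth`, `dna_read_gc`,
#'   `rna_read_gc`.
#' @slot noData `data.frame` with columns `scaffold_id`, `dna`, `rna`
#'   (logical): whether a scaffold had no aligned reads in a library, in
#'   which case its depth/breadth/read-GC entries are 0 by convention.
#' @export
setClass("PredictorTable",
  representation(table = "data.frame", noData = "data.frame"))

setValidity("PredictorTable", function(object) {
  tb <- object@table
  want <- c("scaffold_id", PREDICTOR_NAMES)
  if (!identical(colnames(tb), want))
    return(sprintf("columns must be exactly: %s", paste(want, collapse = ", ")))
  if (anyDuplicated(tb$scaffold_id))
    return("duplicate scaffold_id")
  for (col in PREDICTOR_NAMES) {
    if (!is.numeric(tb[[col]])) return(sprintf("column '%s' must be numeric", col))
    if (anyNA(tb[[col]])) return(sprintf("column '%s' has NA", col))
  }
  if (any(tb$length < 1)) return("length must be >= 1")
  for (col in FRACTION_COLS) {
    if (any(tb[[col]] < -1e-9 | tb[[col]] > 1 + 1e-9))
      return(sprintf("column '%s' must lie in [0, 1]", col))
  }
  if (any(tb$dna_mean_depth < 0) || any(tb$rna_mean_depth < 0))
    return("mean depths must be >= 0")
  TRUE
})

#' LabeledScaffolds: training labels derived from BLAST results
#'
#' Scaffolds with a database-assigned class (target or contaminant) plus the
#' set of scaffolds with no hit ("unknown"), which are excluded from
#' training and testing but still classified by fitted models.
#'
#' @slot labels Named character vector; names are scaffold ids, values are
#'   `"target"` or `"contaminant"`.
#' @slot unknownIds Character vector of scaffold ids with no BLAST hit.
#' @export
setClass("LabeledScaffolds",
  representation(labels = "character", unknownIds = "character"))

setValidity("LabeledScaffolds", function(object) {
  if (is.null(names(object@labels)) && length(object@labels) > 0)
    return("labels must be named by scaffold_id")
  if (!all(object@labels %in% CLASS_NAMES))
    return(sprintf("labels must be one of: %s", paste(CLASS_NAMES, collapse = ", ")))
  if (anyDuplicated(names(object@labels))) return("duplicate labeled scaffold_id")
  if (anyDuplicated(object@unknownIds)) return("duplicate unknown scaffold_id")
  if (length(intersect(names(object@labels), object@unknownIds)) > 0)
    return("labeled and unknown scaffold sets must be disjoint")
  TRUE
})

#' TrainTestSplit: a random partition of the labeled scaffolds
#'
#' @slot trainIds,testIds Disjoint character vectors covering the labeled
#'   scaffold ids.
#' @slot fraction Training fraction in (0, 1).
#' @slot seed Integer seed the partition was drawn with.
#' @export
setClass("TrainTestSplit",
  representation(trainIds = "character", testIds = "character",
                 fraction = "numeric", seed = "integer"))

setValidity("TrainTestSplit", function(object) {
  if (length(intersect(object@trainIds, object@testIds)) > 0)
    return("train and test ids must be disjoint")
  if (object@fraction <= 0 || object@fraction >= 1)
    return("fraction must be in (0, 1)")
  TRUE
})

#' DecisionTreeModel: a single binary classification tree
#'
#' Binary CART tree grown by exhaustive threshold search, splitting on the
#' Gini diversity index (default) or on information gain in bits. Leaves
#' store class proportions used as posterior probabilities; prediction
#' minimizes expected misclassification cost.
#'
#' @slot root Nested list of nodes (internal representation; use
#'   [writeModel()] for a stable serialized form).
#' @slot config List of fitting parameters (criterion, minLeaf, maxSplits).
#' @slot predictors Character vector of predictor names the tree may use.
#' @slot classes Character vector of class names, canonical order.
#' @export
setClass("DecisionTreeModel",
  representation(root = "list", config = "list", predictors = "character",
                 classes = "character"))

#' EnsembleModel: bagged, random-forest or boosted tree model
#'
#' @slot kind `"bagging"`, `"random_forest"` or `"boosted"`.
#' @slot trees List of fitted trees (classification trees for bagging and
#'   forests; regression trees on the class indicator for boosting).
#' @slot B Number of trees.
#' @slot m Predictors sampled per split (forests; equals `length(predictors)`
#'   for bagging).
#' @slot shrinkage Boosting shrinkage (learning rate); `NA` otherwise.
#' @slot f0 Boosting intercept (training base rate of the target class);
#'   `NA` otherwise.
#' @slot threshold Target-score decision threshold (default 0.5; ties go to
#'   the target class).
#' @slot config List of tree-level fitting parameters.
#' @slot predictors,classes Character vectors as in [DecisionTreeModel-class].
#' @slot seed Master seed the model was fitted with.
#' @export
setClass("EnsembleModel",
  representation(kind = "character", trees = "list", B = "integer",
                 m = "integer", shrinkage = "numeric", f0 = "numeric",
                 threshold = "numeric", config = "list",
                 predictors = "character", classes = "character",
                 seed = "integer"))

setValidity("EnsembleModel", function(object) {
  if (!object@kind %in% c("bagging", "random_forest", "boosted"))
    return("kind must be bagging, random_forest or boosted")
  if (length(object@trees) != object@B)
    return("number of trees must equal B")
  if (object@kind == "random_forest" &&
      (object@m < 1 || object@m > length(object@predictors)))
    return("m must be in [1, number of predictors]")
  if (object@kind == "boosted" &&
      (is.na(object@shrinkage) || object@shrinkage < 0 || object@shrinkage > 1))
    return("shrinkage must be in [0, 1] for boosted models")
  TRUE
})

#' SweepReport: replicate-sweep summary
#'
#' Mean and standard deviation of accuracy, sensitivity and specificity per
#' sweep point (training fraction, or number of predictors), across
#' replicate random training draws.
#'
#' @slot axis Name of the sweep axis (`"fraction"` or `"n_predictors"`).
#' @slot table `data.frame` with columns axis value, `metric`, `mean`,
#'   `std`, `n_ok`, `n_failed`.
#' @slot replicates Replicates attempted per sweep point.
#' @slot seed Master seed.
#' @slot perReplicate `data.frame` of per-replicate metric records, from
#'   which `table` is recomputable.
#' @export
setClass("SweepReport",
  representation(axis = "character", table = "data.frame",
                 replicates = "integer", seed = "integer",
                 perReplicate = "data.frame"))

#' ClassificationReport: end-to-end decontamination result
#'
#' @slot table Per-scaffold `data.frame`: the eight predictors, label source
#'   (`blast-target`, `blast-contaminant`, `no-hit`), predicted class and
#'   target score.
#' @slot summary List with kept/removed counts and megabases.
#' @slot metrics Named list of test-set metrics (error, accuracy,
#'   sensitivity, specificity) or `NULL`-like empty list before evaluation.
#' @export
setClass("ClassificationReport",
  representation(table = "data.frame", summary = "list", metrics = "list"))
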
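#' Scaffold ids of an object
#' @param x A decontree object.
#' @return Character vector of scaffold ids.
#' @export
setGeneric("scaffoldIds", function(x) standardGeneric("scaffoldIds"))

#' Per-predictor Gini importance
#'
#' Importance of each predictor as the total impurity decrease attributed to
#' its splits. For a single tree each split contributes its node-weighted
#' Gini decrease; for an ensemble, tree importances are averaged and
#' normalized to sum to 1 (an all-stump model yields all zeros).
#'
#' @param object A [DecisionTreeModel-class] or [EnsembleModel-class].
#' @param weighted Use child-size-weighted impurity decrease (default). With
#'   `weighted = FALSE` the literal unweighted difference
#'   G_parent - G_left - G_right is summed instead; it can be negative and
#'   is provided for comparison only.
#' @return Named numeric vector over the model's predictors.
#' @export
setGeneric("giniImportance",
           function(object, weighted = TRUE) standardGeneric("giniImportance"))

#' Number of splits in a tree model
#' @param object A fitted tree model.
#' @return Integer number of internal nodes.
#' @export
setGeneric("nSplits", function(object) standardGeneric("nSplits"))
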
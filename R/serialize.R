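# Human-readable JSON serialization of fitted models. Numbers are written
# at full precision (digits = NA) so a read/write round trip reproduces the
# model exactly and reruns with the same seed are byte-identical.

nodeToList <- function(nd, regression = FALSE) {
  if (nd$leaf) {
    if (regression)
      list(type = "leaf", n = nd$n, value = nd$value, sse = nd$sse)
    else
      list(type = "leaf", n = nd$n, prop = as.list(nd$prop), gini = nd$gini)
  } else {
    base <- list(type = "split", predictor = nd$predictor,
                 threshold = nd$threshold, n = nd$n)
    if (regression) base$sse <- nd$sse
    else { base$gini <- nd$gini; base$gain <- nd$gain }
    base$left <- nodeToList(nd$left, regression)
    base$right <- nodeToList(nd$right, regression)
    base
  }
}

listToNode <- function(l, regression = FALSE) {
  if (l$type == "leaf") {
    if (regression)
      list(leaf = TRUE, n = as.integer(l$n), value = as.numeric(l$value),
           sse = as.numeric(l$sse))
    else
      list(leaf = TRUE, n = as.integer(l$n),
           prop = structure(as.numeric(unlist(l$prop)), names = names(l$prop)),
           gini = as.numeric(l$gini))
  } else {
    nd <- list(leaf = FALSE, predictor = l$predictor,
               threshold = as.numeric(l$threshold), n = as.integer(l$n))
    if (regression) nd$sse <- as.numeric(l$sse)
    else { nd$gini <- as.numeric(l$gini); nd$gain <- as.numeric(l$gain) }
    nd$left <- listToNode(l$left, regression)
    nd$right <- listToNode(l$right, regression)
    nd
  }
}

modelToList <- function(model) {
  if (is(model, "DecisionTreeModel")) {
    list(model = "tree",
         config = model@config,
         predictors = as.list(model@predictors),
         classes = as.list(model@classes),
         root = nodeToList(model@root))
  } else if (is(model, "EnsembleModel")) {
    reg <- model@kind == "boosted"
    list(model = "ensemble", kind = model@kind, B = model@B, m = model@m,
         shrinkage = model@shrinkage, f0 = model@f0,
         threshold = model@threshold, seed = model@seed,
         config = model@config,
         predictors = as.list(model@predictors),
         classes = as.list(model@classes),
         trees = lapply(model@trees, function(tr) {
           if (reg) nodeToList(tr, regression = TRUE)
           else nodeToList(tr@root)
         }))
  } else stopf("not a serializable model")
}

#' Serialize a fitted model to JSON
#'
#' Writes a single tree or an ensemble (all trees plus hyperparameters and
#' seed) as human-readable JSON at full numeric precision; [readModel()]
#' restores an identical model, and rewriting a model produces byte-identical
#' output.
#'
#' @param model A [DecisionTreeModel-class] or [EnsembleModel-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path) {
  writeLines(emitJson(modelToList(model)), path, useBytes = TRUE)
  invisible(path)
}

# Minimal JSON emitter: doubles at %.17g so that readModel(writeModel(m))
# restores every numeric bit-exactly (jsonlite prints 15 significant digits).
emitJson <- function(x, indent = 0) {
  pad <- strrep("  ", indent)
  padIn <- strrep("  ", indent + 1)
  scalar <- function(v) {
    if (is.null(v)) return("null")
    if (is.na(v)) return("null")
    if (is.logical(v)) return(if (v) "true" else "false")
    if (is.character(v)) {
      v <- gsub("\\", "\\\\", v, fixed = TRUE)
      v <- gsub("\"", "\\\"", v, fixed = TRUE)
      return(paste0("\"", v, "\""))
    }
    if (is.infinite(v)) return(if (v > 0) "\"Inf\"" else "\"-Inf\"")
    if (is.integer(v)) return(as.character(v))
    s <- sprintf("%.17g", v)
    s
  }
  if (is.list(x)) {
    if (length(x) == 0)
      return(if (is.null(names(x))) "[]" else "{}")
    items <- vapply(x, emitJson, "", indent = indent + 1)
    if (is.null(names(x))) {
      paste0("[\n", paste0(padIn, items, collapse = ",\n"), "\n", pad, "]")
    } else {
      keys <- vapply(names(x), function(k) scalar(k), "")
      paste0("{\n", paste0(padIn, keys, ": ", items, collapse = ",\n"),
             "\n", pad, "}")
    }
  } else if (length(x) == 1) {
    scalar(x)
  } else if (is.null(x)) {
    "null"
  } else {
    items <- vapply(x, function(v) scalar(v), "")
    paste0("[", paste0(items, collapse = ", "), "]")
  }
}

#' Read a serialized model
#' @param path Path written by [writeModel()].
#' @return The restored model object.
#' @export
readModel <- function(path) {
  l <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fixConfig <- function(cf) {
    if (!is.null(cf$maxSplits) && is.character(cf$maxSplits))
      cf$maxSplits <- Inf
    if (is.null(cf$maxSplits)) cf["maxSplits"] <- list(Inf)
    if (!is.null(cf$minLeaf)) cf$minLeaf <- as.integer(cf$minLeaf)
    cf
  }
  if (identical(l$model, "tree")) {
    cf <- l$config
    cf <- fixConfig(cf)
    if (is.null(cf$mtry)) cf["mtry"] <- list(NULL)
    new("DecisionTreeModel", root = listToNode(l$root), config = cf,
        predictors = unlist(l$predictors), classes = unlist(l$classes))
  } else if (identical(l$model, "ensemble")) {
    reg <- identical(l$kind, "boosted")
    trees <- lapply(l$trees, function(tl) {
      nd <- listToNode(tl, regression = reg)
      if (reg) nd
      else new("DecisionTreeModel", root = nd,
               config = fixConfig(l$config),
               predictors = unlist(l$predictors), classes = unlist(l$classes))
    })
    new("EnsembleModel", kind = l$kind, trees = trees, B = as.integer(l$B),
        m = as.integer(l$m),
        shrinkage = if (is.null(l$shrinkage)) NA_real_ else l$shrinkage,
        f0 = if (is.null(l$f0)) NA_real_ else l$f0,
        threshold = l$threshold, config = fixConfig(l$config),
        predictors = unlist(l$predictors), classes = unlist(l$classes),
        seed = as.integer(l$seed))
  } else stopf("unrecognized model file: %s", path)
}
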
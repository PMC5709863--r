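# Classification and regression tree core.
#
# Trees are nested lists. Classification leaf:
#   list(leaf = TRUE, n, prop = c(target, contaminant), gini)
# Classification split:
#   list(leaf = FALSE, predictor, threshold, n, gini, gain, left, right)
# Regression nodes replace prop/gini with value (leaf mean).
# Values equal to a threshold route to the left (<=) child.

SPLIT_EPS <- 1e-12

#' Shannon entropy of class counts, in bits
#'
#' H(S) = -sum_x p_x log2 p_x over the classes of S, with 0 log2 0 = 0 and
#' H = 0 for an empty set.
#'
#' @param counts Non-negative numeric vector of per-class counts.
#' @return Entropy in bits.
#' @examples
#' entropyBits(c(target = 5, contaminant = 5))  # 1
#' entropyBits(c(10, 0))                        # 0
#' @export
entropyBits <- function(counts) {
  if (any(counts < 0)) stopf("class counts must be non-negative")
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Information gain of a candidate partition, in bits
#'
#' IG(A, S) = H(S) - sum_t p(t) H(t), where the subsets t partition S and
#' p(t) is the fraction of S falling in t.
#'
#' @param parent Non-negative per-class counts of the parent set.
#' @param children List of per-class count vectors that partition the parent.
#' @return Information gain in bits (>= 0 up to rounding).
#' @examples
#' informationGain(c(2, 2), list(c(2, 0), c(0, 2)))  # 1
#' @export
informationGain <- function(parent, children) {
  tot <- Reduce(`+`, children)
  if (!isTRUE(all.equal(as.numeric(tot), as.numeric(parent), tolerance = 0)))
    stopf("children counts do not sum to parent counts")
  n <- sum(parent)
  if (n == 0) return(0)
  child <- sum(vapply(children, function(cc) sum(cc) / n * entropyBits(cc), 0))
  entropyBits(parent) - child
}

#' Gini diversity index
#'
#' G = sum_i p_i (1 - p_i) over class proportions p_i.
#'
#' @param proportions Per-class proportions summing to 1 (tolerance 1e-9).
#' @return Gini index in `[0, 1 - 1/n_c]`.
#' @examples
#' giniIndex(c(0.5, 0.5))    # 0.5
#' giniIndex(c(0.75, 0.25))  # 0.375
#' @export
giniIndex <- function(proportions) {
  if (any(proportions < 0)) stopf("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9)
    stopf("proportions must sum to 1 (got %.12g)", sum(proportions))
  sum(proportions * (1 - proportions))
}

# Gini impurity from binary counts c1, c2 (vectorized over candidates).
giniFromCounts <- function(c1, c2) {
  n <- c1 + c2
  g <- 1 - (c1 / n)^2 - (c2 / n)^2
  g[n == 0] <- 0
  g
}

# Entropy (bits) from binary counts (vectorized); 0 log 0 = 0.
entropyFromCounts <- function(c1, c2) {
  n <- c1 + c2
  p1 <- ifelse(n > 0, c1 / n, 0)
  p2 <- ifelse(n > 0, c2 / n, 0)
  t1 <- ifelse(p1 > 0, p1 * log2(p1), 0)
  t2 <- ifelse(p2 > 0, p2 * log2(p2), 0)
  -(t1 + t2)
}

#' Exhaustive best binary split of a labeled predictor matrix
#'
#' Scans every candidate predictor and every threshold midway between
#' consecutive distinct sorted values, scoring candidates by n-weighted
#' child Gini impurity (`criterion = "gini"`, minimized) or by information
#' gain (`criterion = "entropy"`, maximized). Ties are broken by lower
#' canonical predictor index, then lower threshold; a competing candidate
#' must be better by more than 1e-12 to displace an earlier one.
#'
#' @param x Numeric matrix of predictors (columns named).
#' @param y Class labels (`"target"`/`"contaminant"`, or integer codes 1/2).
#' @param predictors Candidate predictor names (default: all columns), kept
#'   in canonical column order for tie-breaking.
#' @param criterion `"gini"` or `"entropy"`.
#' @param minLeaf Minimum rows in each child (default 1).
#' @param allowZeroGain Accept the best valid split even when it does not
#'   reduce the parent impurity (used internally during tree growth so that
#'   interaction-only structure, e.g. an XOR pattern, can still be
#'   resolved by deeper splits; the default requires strict improvement).
#' @return A list with elements `predictor`, `threshold`, `score` (weighted
#'   child impurity in the criterion's units), `gain` (information gain,
#'   bits), `left` and `right` class counts — or `NULL` when no split
#'   improves on the parent (pure node, all candidate values constant, or
#'   `minLeaf` unsatisfiable).
#' @export
bestSplit <- function(x, y, predictors = colnames(x),
                      criterion = c("gini", "entropy"), minLeaf = 1L,
                      allowZeroGain = FALSE) {
  criterion <- match.arg(criterion)
  if (nrow(x) < 2L) return(NULL)
  yc <- if (is.numeric(y)) as.integer(y) else classCodes(y)
  # candidate order = column order of x (canonical tie-break order)
  predictors <- intersect(colnames(x), predictors)
  n <- nrow(x)
  n1 <- sum(yc == 1L)
  n2 <- n - n1
  if (n1 == 0L || n2 == 0L) return(NULL)
  parentScore <- if (criterion == "gini") giniFromCounts(n1, n2)
                 else entropyFromCounts(n1, n2)
  best <- NULL
  for (j in predictors) {
    xj <- unname(x[, j])
    o <- order(xj, method = "radix")
    xs <- xj[o]
    ys <- yc[o]
    i <- seq_len(n - 1L)
    ok <- xs[i] < xs[i + 1L] & i >= minLeaf & (n - i) >= minLeaf
    idx <- i[ok]
    if (length(idx) == 0L) next
    cum1 <- cumsum(ys == 1L)
    l1 <- cum1[idx]
    nl <- idx
    l2 <- nl - l1
    r1 <- n1 - l1
    nr <- n - nl
    r2 <- nr - r1
    if (criterion == "gini") {
      score <- (nl * giniFromCounts(l1, l2) + nr * giniFromCounts(r1, r2)) / n
    } else {
      score <- (nl * entropyFromCounts(l1, l2) + nr * entropyFromCounts(r1, r2)) / n
    }
    k <- which(score == min(score))[1L]  # lowest threshold among exact ties
    if (!allowZeroGain && parentScore - score[k] <= SPLIT_EPS) next
    if (is.null(best) || score[k] < best$score - SPLIT_EPS) {
      thr <- (xs[idx[k]] + xs[idx[k] + 1L]) / 2
      best <- list(predictor = j, threshold = thr, score = score[k],
                   left = c(target = l1[k], contaminant = l2[k]),
                   right = c(target = r1[k], contaminant = r2[k]))
    }
  }
  if (is.null(best)) return(NULL)
  best$gain <- informationGain(c(n1, n2),
                               list(unname(best$left), unname(best$right)))
  best
}

classLeaf <- function(yc) {
  n <- length(yc)
  n1 <- sum(yc == 1L)
  prop <- c(n1, n - n1) / n
  names(prop) <- CLASS_NAMES
  list(leaf = TRUE, n = n, prop = prop, gini = giniFromCounts(n1, n - n1))
}

#' Fit a binary classification tree
#'
#' Grows a CART tree by recursive exhaustive split search, expanding nodes
#' breadth-first until every node is pure, no valid split exists (all
#' candidate values constant, or `minLeaf` binds), or the whole-tree split
#' budget `maxSplits` is exhausted. Impure nodes split on the best
#' candidate even when its immediate impurity gain is zero, so
#' interaction-only structure (an XOR pattern) is resolved by deeper
#' splits. No pruning is performed; leaves store class proportions used as
#' posterior probabilities at prediction time.
#'
#' @param x Numeric predictor matrix with named columns (or a
#'   [PredictorTable-class]).
#' @param y Class labels aligned with the rows of `x`.
#' @param criterion Split criterion, `"gini"` (default) or `"entropy"`.
#' @param minLeaf Minimum rows per child node (default 1).
#' @param maxSplits Whole-tree split budget, counted breadth-first
#'   (default unlimited). `maxSplits = 0` yields a single majority leaf.
#' @param predictors Candidate predictor names (default: all columns).
#' @param mtry If non-NULL, the number of predictors drawn uniformly at
#'   random (without replacement) as candidates at each split — the random
#'   forest device. `mtry` equal to the number of predictors disables
#'   drawing entirely so the tree is identical to an unrestricted one.
#' @param mtryPerTree If `TRUE`, draw the `mtry` subset once per tree rather
#'   than at each split.
#' @return A [DecisionTreeModel-class].
#' @examples
#' x <- cbind(gc = c(1, 2, 9, 10))
#' y <- c("target", "target", "contaminant", "contaminant")
#' fitTree(x, y)
#' @export
fitTree <- function(x, y, criterion = c("gini", "entropy"), minLeaf = 1L,
                    maxSplits = Inf, predictors = NULL, mtry = NULL,
                    mtryPerTree = FALSE) {
  criterion <- match.arg(criterion)
  if (is(x, "PredictorTable")) x <- predictorMatrix(x)
  if (nrow(x) == 0L) stopf("cannot fit a tree on an empty training set")
  if (minLeaf < 1L) stopf("minLeaf must be >= 1")
  predictors <- predictors %||% colnames(x)
  missing <- setdiff(predictors, colnames(x))
  if (length(missing) > 0)
    stopf("predictor(s) not in x: %s", paste(missing, collapse = ", "))
  yc <- if (is.numeric(y)) as.integer(y) else classCodes(y)
  if (length(yc) != nrow(x)) stopf("x and y lengths differ")
  p <- length(predictors)
  if (!is.null(mtry)) {
    if (mtry < 1L || mtry > p)
      stopf("mtry must be in [1, %d], got %s", p, format(mtry))
    if (mtry == p) mtry <- NULL  # no drawing: identical to the full search
  }
  treeCands <- predictors
  if (!is.null(mtry) && mtryPerTree)
    treeCands <- predictors[sort(sample.int(p, mtry))]

  grow <- function(idx) classLeaf(yc[idx])  # placeholder leaf
  nodes <- list()     # flat store; children referenced by index
  rowsets <- list()
  queue <- integer(0) # node ids pending a split attempt, FIFO
  newNode <- function(idx) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- grow(idx)
    rowsets[[id]] <<- idx
    queue <<- c(queue, id)
    id
  }
  rootId <- newNode(seq_along(yc))
  splitsUsed <- 0L
  while (length(queue) > 0L) {
    id <- queue[1L]
    queue <- queue[-1L]
    if (splitsUsed >= maxSplits) next
    idx <- rowsets[[id]]
    if (nodes[[id]]$gini == 0) next
    cands <- treeCands
    if (!is.null(mtry) && !mtryPerTree)
      cands <- treeCands[sort(sample.int(length(treeCands), mtry))]
    sp <- bestSplit(x[idx, , drop = FALSE], yc[idx], predictors = cands,
                    criterion = criterion, minLeaf = minLeaf,
                    allowZeroGain = TRUE)
    if (is.null(sp)) next
    goLeft <- x[idx, sp$predictor] <= sp$threshold
    leftId <- newNode(idx[goLeft])
    rightId <- newNode(idx[!goLeft])
    node <- nodes[[id]]
    nodes[[id]] <- list(leaf = FALSE, predictor = sp$predictor,
                        threshold = sp$threshold, n = node$n,
                        gini = node$gini, gain = sp$gain,
                        left = leftId, right = rightId)
    splitsUsed <- splitsUsed + 1L
  }
  assemble <- function(id) {
    nd <- nodes[[id]]
    if (nd$leaf) return(nd)
    nd$left <- assemble(nd$left)
    nd$right <- assemble(nd$right)
    nd
  }
  new("DecisionTreeModel", root = assemble(rootId),
      config = list(criterion = criterion, minLeaf = as.integer(minLeaf),
                    maxSplits = maxSplits, mtry = mtry,
                    mtryPerTree = mtryPerTree),
      predictors = predictors, classes = CLASS_NAMES)
}

# Route rows to leaves; returns P(target | x) per row.
treeScore <- function(node, x) {
  out <- numeric(nrow(x))
  recurse <- function(nd, idx) {
    if (length(idx) == 0L) return(invisible())
    if (nd$leaf) {
      out[idx] <<- nd$prop[1L]
      return(invisible())
    }
    v <- x[idx, nd$predictor]
    if (anyNA(v)) stopf("missing value for predictor '%s'", nd$predictor)
    go <- v <= nd$threshold
    recurse(nd$left, idx[go])
    recurse(nd$right, idx[!go])
  }
  recurse(node, seq_len(nrow(x)))
  out
}

# Expected-cost classification from target posteriors. costs is a K x K
# matrix, rows = predicted class y, cols = true class k, canonical order.
costClassify <- function(pTarget, costs = NULL) {
  if (is.null(costs)) costs <- defaultCosts()
  checkCosts(costs)
  # expected cost of predicting y: p1 * C[y,1] + p2 * C[y,2]
  e1 <- pTarget * costs[1L, 1L] + (1 - pTarget) * costs[1L, 2L]
  e2 <- pTarget * costs[2L, 1L] + (1 - pTarget) * costs[2L, 2L]
  # arg min; ties to the lower canonical index (target)
  ifelse(e1 <= e2, CLASS_NAMES[1L], CLASS_NAMES[2L])
}

#' Default (uniform) misclassification costs
#'
#' Zero on the diagonal, one off it: expected-cost classification then
#' reduces to the majority (maximum-posterior) class.
#' @return 2x2 numeric cost matrix `C[y, k]`, canonical class order.
#' @export
defaultCosts <- function() {
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(CLASS_NAMES, CLASS_NAMES))
  m
}

checkCosts <- function(costs) {
  if (!is.matrix(costs) || any(dim(costs) != 2L))
    stopf("costs must be a 2x2 matrix C[y, k]")
  if (any(diag(costs) != 0)) stopf("costs must be zero on the diagonal")
  if (any(costs < 0)) stopf("costs must be non-negative")
  invisible(TRUE)
}

rowsForModel <- function(newdata, predictors) {
  if (is(newdata, "PredictorTable")) newdata <- predictorMatrix(newdata)
  if (is.data.frame(newdata)) {
    keep <- intersect(colnames(newdata), PREDICTOR_NAMES)
    newdata <- as.matrix(newdata[, keep, drop = FALSE])
  }
  missing <- setdiff(predictors, colnames(newdata))
  if (length(missing) > 0)
    stopf("newdata lacks predictor(s): %s", paste(missing, collapse = ", "))
  newdata
}

#' Predict from a single classification tree
#'
#' Rows are routed down the tree (values equal to a threshold go left); the
#' leaf's class proportions act as posterior probabilities and the class
#' minimizing expected misclassification cost is returned. With the default
#' uniform costs this is the majority class; posterior ties go to the
#' target class.
#'
#' @param object A [DecisionTreeModel-class].
#' @param newdata [PredictorTable-class], matrix or data.frame of predictor
#'   columns.
#' @param type `"class"` (default) or `"prob"` for P(target | x).
#' @param costs Optional 2x2 cost matrix `C[y, k]` (predicted y, true k);
#'   see [defaultCosts()].
#' @return Character vector of classes, or numeric target posteriors.
#' @export
setMethod("predict", "DecisionTreeModel",
  function(object, newdata, type = c("class", "prob"), costs = NULL) {
    type <- match.arg(type)
    x <- rowsForModel(newdata, object@predictors)
    sc <- treeScore(object@root, x)
    if (type == "prob") return(sc)
    costClassify(sc, costs)
  })

#' @describeIn giniImportance Importance of each predictor in a single tree:
#'   sum over that predictor's splits of the node-fraction-scaled Gini
#'   decrease (n_node / n_root) * (G_parent - w_L G_L - w_R G_R).
#' @export
setMethod("giniImportance", "DecisionTreeModel", function(object, weighted = TRUE) {
  imp <- structure(numeric(length(object@predictors)),
                   names = object@predictors)
  rootN <- object@root$n
  walk <- function(nd) {
    if (nd$leaf) return(invisible())
    gl <- nd$left$gini; gr <- nd$right$gini
    nl <- nd$left$n; nr <- nd$right$n
    dG <- if (weighted) nd$gini - (nl * gl + nr * gr) / nd$n
          else nd$gini - gl - gr
    contrib <- if (weighted) (nd$n / rootN) * dG else dG
    imp[nd$predictor] <<- imp[nd$predictor] + contrib
    walk(nd$left)
    walk(nd$right)
  }
  walk(object@root)
  imp
})

countSplits <- function(nd) {
  if (nd$leaf) return(0L)
  1L + countSplits(nd$left) + countSplits(nd$right)
}

#' @describeIn nSplits Splits in a single tree.
#' @export
setMethod("nSplits", "DecisionTreeModel", function(object) countSplits(object@root))

setMethod("show", "DecisionTreeModel", function(object) {
  cat(sprintf("DecisionTreeModel (criterion = %s): %d split(s), root n = %d\n",
              object@config$criterion, nSplits(object), object@root$n))
})

## ---- Regression trees (boosting stages) -------------------------------

# Best squared-error split of response r. Returns NULL when no split
# reduces the sum of squared errors.
bestRegSplit <- function(x, r, predictors = colnames(x), minLeaf = 1L) {
  n <- nrow(x)
  if (n < 2L) return(NULL)
  parentSSE <- sum(r^2) - sum(r)^2 / n
  best <- NULL
  for (j in predictors) {
    xj <- unname(x[, j])
    o <- order(xj, method = "radix")
    xs <- xj[o]
    rs <- r[o]
    i <- seq_len(n - 1L)
    ok <- xs[i] < xs[i + 1L] & i >= minLeaf & (n - i) >= minLeaf
    idx <- i[ok]
    if (length(idx) == 0L) next
    cs <- cumsum(rs)[idx]
    cs2 <- cumsum(rs^2)[idx]
    nl <- idx
    nr <- n - nl
    sseL <- cs2 - cs^2 / nl
    sseR <- (sum(rs^2) - cs2) - (sum(rs) - cs)^2 / nr
    score <- sseL + sseR
    k <- which(score == min(score))[1L]
    if (parentSSE - score[k] <= SPLIT_EPS) next
    if (is.null(best) || score[k] < best$score - SPLIT_EPS) {
      best <- list(predictor = j, threshold = (xs[idx[k]] + xs[idx[k] + 1L]) / 2,
                   score = score[k])
    }
  }
  best
}

# Shallow regression tree fit breadth-first under a whole-tree split budget.
fitRegTree <- function(x, r, maxSplits = 2L, minLeaf = 1L,
                       predictors = colnames(x)) {
  nodes <- list()
  rowsets <- list()
  queue <- integer(0)
  newNode <- function(idx) {
    id <- length(nodes) + 1L
    ri <- r[idx]
    nodes[[id]] <<- list(leaf = TRUE, n = length(idx), value = mean(ri),
                         sse = sum(ri^2) - sum(ri)^2 / length(idx))
    rowsets[[id]] <<- idx
    queue <<- c(queue, id)
    id
  }
  rootId <- newNode(seq_along(r))
  used <- 0L
  while (length(queue) > 0L) {
    id <- queue[1L]
    queue <- queue[-1L]
    if (used >= maxSplits) next
    idx <- rowsets[[id]]
    sp <- bestRegSplit(x[idx, , drop = FALSE], r[idx], predictors, minLeaf)
    if (is.null(sp)) next
    goLeft <- x[idx, sp$predictor] <= sp$threshold
    leftId <- newNode(idx[goLeft])
    rightId <- newNode(idx[!goLeft])
    nd <- nodes[[id]]
    nodes[[id]] <- list(leaf = FALSE, predictor = sp$predictor,
                        threshold = sp$threshold, n = nd$n, sse = nd$sse,
                        left = leftId, right = rightId)
    used <- used + 1L
  }
  assemble <- function(id) {
    nd <- nodes[[id]]
    if (nd$leaf) return(nd)
    nd$left <- assemble(nd$left)
    nd$right <- assemble(nd$right)
    nd
  }
  assemble(rootId)
}

regTreeScore <- function(node, x) {
  out <- numeric(nrow(x))
  recurse <- function(nd, idx) {
    if (length(idx) == 0L) return(invisible())
    if (nd$leaf) {
      out[idx] <<- nd$value
      return(invisible())
    }
    v <- x[idx, nd$predictor]
    if (anyNA(v)) stopf("missing value for predictor '%s'", nd$predictor)
    go <- v <= nd$threshold
    recurse(nd$left, idx[go])
    recurse(nd$right, idx[!go])
  }
  recurse(node, seq_len(nrow(x)))
  out
}

# Variance-reduction importance for a regression tree, scaled by root SSE
# so stages are comparable; returns a vector over `predictors`.
regTreeImportance <- function(node, predictors) {
  imp <- structure(numeric(length(predictors)), names = predictors)
  rootSSE <- node$sse
  if (is.null(rootSSE) || rootSSE <= 0) return(imp)
  walk <- function(nd) {
    if (nd$leaf) return(invisible())
    dS <- nd$sse - (nd$left$sse + nd$right$sse)
    imp[nd$predictor] <<- imp[nd$predictor] + dS / rootSSE
    walk(nd$left)
    walk(nd$right)
  }
  walk(node)
  imp
}
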
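# Fixtures built in code: tiny FASTA / SAM files and brute-force oracles.

writeTempFasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# Minimal SAM writer. Each alignment: list(qname, flag, rname, pos, cigar,
# seq). Proper-paired primary reads use flag 99 unless stated.
writeTempSam <- function(refs, alignments) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6",
           vapply(names(refs), function(r)
             sprintf("@SQ\tSN:%s\tLN:%d", r, refs[[r]]), ""))
  recs <- vapply(alignments, function(a) {
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t0\t%s\t%s",
            a$qname, a$flag %||% 99L, a$rname, a$pos, a$cigar,
            a$pos, a$seq, strrep("I", nchar(a$seq)))
  }, "")
  writeLines(c(hdr, recs), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct-summation oracles, deliberately written as elementwise loops.
oracleEntropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  h <- 0
  for (ci in counts) {
    p <- ci / n
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

oracleGini <- function(props) {
  g <- 0
  for (p in props) g <- g + p * (1 - p)
  g
}

oracleIG <- function(parent, children) {
  n <- sum(parent)
  h <- oracleEntropy(parent)
  for (ch in children) h <- h - sum(ch) / n * oracleEntropy(ch)
  h
}

# Brute-force best split: double loop over predictors and midpoints, same
# tie rule as the implementation (candidate must be better by > 1e-12 to
# displace an earlier predictor; within a predictor, first = lowest
# threshold among exact ties).
oracleBestSplit <- function(x, y, minLeaf = 1L) {
  yc <- ifelse(y == "target", 1L, ifelse(y == "contaminant", 2L, y))
  yc <- as.integer(yc)
  n <- nrow(x)
  n1 <- sum(yc == 1L)
  if (n1 == 0L || n1 == n) return(NULL)
  gini2 <- function(c1, c2) {
    m <- c1 + c2
    if (m == 0) return(0)
    1 - (c1 / m)^2 - (c2 / m)^2
  }
  parent <- gini2(n1, n - n1)
  best <- NULL
  for (j in colnames(x)) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2) next
    for (v in seq_len(length(vals) - 1)) {
      thr <- (vals[v] + vals[v + 1]) / 2
      left <- x[, j] <= thr
      nl <- sum(left)
      if (nl < minLeaf || n - nl < minLeaf) next
      l1 <- sum(yc[left] == 1L)
      r1 <- n1 - l1
      score <- (nl * gini2(l1, nl - l1) + (n - nl) * gini2(r1, n - nl - r1)) / n
      if (parent - score <= 1e-12) next
      if (is.null(best) || score < best$score - 1e-12)
        best <- list(predictor = j, threshold = thr, score = score)
    }
  }
  best
}

# Truth labels of a simulated dataset as a named vector.
truthVector <- function(sim) {
  structure(sim$truth$class, names = sim$truth$scaffold_id)
}
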
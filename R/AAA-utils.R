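# Internal constants and helpers shared across modules.

# Canonical predictor order; tie-breaks in split search use this index.
PREDICTOR_NAMES <- c("length", "gc", "dna_mean_depth", "rna_mean_depth",
                     "dna_breadth", "rna_breadth", "dna_read_gc", "rna_read_gc")

# Canonical class order; class 1 (target) wins prediction ties.
CLASS_NAMES <- c("target", "contaminant")

# Fraction-valued predictor columns (must lie in [0, 1]).
FRACTION_COLS <- c("gc", "dna_breadth", "rna_breadth", "dna_read_gc", "rna_read_gc")

#' Derive a reproducible child seed from a master seed and a counter
#'
#' Linear-congruential style derivation keeping results in 32-bit integer
#' range, so any replicate of a sweep or any tree of an ensemble can be
#' re-fit individually from the master seed and its position.
#'
#' @param seed Integer master seed.
#' @param counter Non-negative integer counter (replicate, tree or stage
#'   index).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, counter) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  v <- (s * 48271 + as.numeric(counter) * 9739) %% m
  as.integer(v + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Coerce labels (character/factor with values in CLASS_NAMES) to integer
# codes 1 = target, 2 = contaminant.
classCodes <- function(labels) {
  codes <- match(as.character(labels), CLASS_NAMES)
  if (anyNA(codes)) {
    bad <- unique(as.character(labels)[is.na(codes)])
    stopf("unknown class label(s): %s", paste(bad, collapse = ", "))
  }
  codes
}
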
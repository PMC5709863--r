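# Per-scaffold predictor computation: scaffold length and GC from FASTA,
# and depth / breadth / aligned-read GC from DNA and RNA alignments
# (SAM/BAM via Rsamtools + GenomicAlignments, or pre-computed TSV).

#' Compute scaffold length and GC content from a FASTA assembly
#'
#' Length counts all residues (including N); the GC fraction is
#' (G + C) / (A + C + G + T), i.e. ambiguous bases are excluded from both
#' numerator and denominator. A scaffold consisting only of ambiguous bases
#' gets `gc = 0` with `gc_defined = FALSE` and a warning.
#'
#' @param assembly Path to a FASTA file (case-insensitive sequences,
#'   multi-line records), or a [Biostrings::DNAStringSet].
#' @return `data.frame` with columns `scaffold_id`, `length`, `gc`,
#'   `gc_defined`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ATGC", ">s2", "AAAA"), fa)
#' computeScaffoldStats(fa)
#' @export
computeScaffoldStats <- function(assembly) {
  seqs <- if (is(assembly, "DNAStringSet")) assembly
          else Biostrings::readDNAStringSet(assembly)
  if (length(seqs) == 0) stopf("no sequences in assembly input")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stopf("duplicate scaffold id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  len <- Biostrings::width(seqs)
  if (any(len == 0))
    stopf("zero-length sequence(s): %s", paste(ids[len == 0], collapse = ", "))
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = FALSE)
  acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
  denom <- rowSums(acgt)
  gc <- ifelse(denom > 0, (acgt[, "G"] + acgt[, "C"]) / denom, 0)
  if (any(denom == 0))
    warnf("scaffold(s) with no unambiguous base, gc set to 0: %s",
          paste(ids[denom == 0], collapse = ", "))
  data.frame(scaffold_id = ids, length = as.numeric(len), gc = gc,
             gc_defined = denom > 0, row.names = NULL)
}

# Flags excluded from coverage: unmapped, secondary, QC fail, duplicate,
# supplementary; proper pair required by default.
alignmentFlagFilter <- function(requireProperPair = TRUE) {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                         isNotPassingQualityControls = FALSE,
                         isSupplementaryAlignment = FALSE,
                         isProperPair = if (requireProperPair) TRUE else NA)
}

summarizeOneBam <- function(path, scaffolds, requireProperPair = TRUE,
                            readGcMode = c("read", "aligned")) {
  readGcMode <- match.arg(readGcMode)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, destination = sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(flag = alignmentFlagFilter(requireProperPair),
                                   what = "seq")
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  refs <- as.character(GenomicAlignments::seqnames(ga))
  unknown <- setdiff(unique(refs), scaffolds$scaffold_id)
  if (length(unknown) > 0)
    stopf("alignment reference(s) not in assembly: %s",
          paste(unknown, collapse = ", "))
  lens <- structure(scaffolds$length, names = scaffolds$scaffold_id)

  # Per-base depth over CIGAR-consumed reference positions: M/=/X count as
  # covered; D consumes and counts as covered; N consumes without covering;
  # insertions and clips consume nothing.
  covRanges <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(ga), pos = GenomicRanges::start(ga),
    ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
  gr <- GenomicRanges::GRanges(rep(refs, lengths(covRanges)),
                               unlist(covRanges, use.names = FALSE))
  GenomeInfoDb::seqlevels(gr) <- scaffolds$scaffold_id
  GenomeInfoDb::seqlengths(gr) <- as.integer(lens)
  cov <- GenomicRanges::coverage(gr)

  depthSum <- vapply(cov, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                          S4Vectors::runLength(r)), 0)
  covered <- vapply(cov, function(r) sum(as.numeric(S4Vectors::runLength(r)[
                                          S4Vectors::runValue(r) >= 1L])), 0)

  # Aligned-read GC: full read sequences by default, or only the bases
  # consumed on the reference (soft-clipped and inserted bases dropped).
  seqdat <- S4Vectors::mcols(ga)$seq
  if (readGcMode == "aligned") {
    qr <- GenomicAlignments::cigarRangesAlongQuerySpace(
      GenomicAlignments::cigar(ga), ops = c("M", "=", "X"))
    seqdat <- unlist(Biostrings::extractAt(seqdat, qr), use.names = FALSE)
    refs2 <- rep(refs, lengths(qr))
  } else {
    refs2 <- refs
  }
  af <- Biostrings::alphabetFrequency(seqdat, baseOnly = TRUE)
  gcb <- rowsum(af[, "G"] + af[, "C"], group = refs2)
  allb <- rowsum(af[, "A"] + af[, "C"] + af[, "G"] + af[, "T"], group = refs2)
  gcBases <- structure(numeric(length(lens)), names = names(lens))
  totBases <- gcBases
  gcBases[rownames(gcb)] <- gcb[, 1]
  totBases[rownames(allb)] <- allb[, 1]

  ids <- scaffolds$scaffold_id
  list(depth_sum = depthSum[ids], covered = covered[ids],
       gc_bases = gcBases[ids], total_bases = totBases[ids])
}

readDepthTsv <- function(path, scaffolds) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  summaryCols <- c("scaffold_id", "mean_depth", "breadth", "aligned_read_gc")
  perBaseCols <- c("scaffold_id", "pos", "depth")
  lens <- structure(scaffolds$length, names = scaffolds$scaffold_id)
  unknown <- setdiff(unique(tb$scaffold_id), names(lens))
  if (length(unknown) > 0)
    stopf("depth TSV references unknown scaffold(s): %s",
          paste(unknown, collapse = ", "))
  if (all(summaryCols %in% colnames(tb))) {
    for (col in summaryCols[-1]) if (!is.numeric(tb[[col]]))
      stopf("column '%s' in %s must be numeric", col, path)
    out <- data.frame(scaffold_id = names(lens), mean_depth = 0, breadth = 0,
                      aligned_read_gc = 0, no_data = TRUE)
    i <- match(tb$scaffold_id, out$scaffold_id)
    out$mean_depth[i] <- tb$mean_depth
    out$breadth[i] <- tb$breadth
    out$aligned_read_gc[i] <- tb$aligned_read_gc
    out$no_data[i] <- tb$mean_depth == 0
    return(out)
  }
  if (all(perBaseCols %in% colnames(tb))) {
    bad <- tb$pos < 1 | tb$pos > lens[tb$scaffold_id]
    if (any(bad))
      stopf("depth TSV position(s) outside [1, length] for scaffold(s): %s",
            paste(unique(tb$scaffold_id[bad]), collapse = ", "))
    ds <- rowsum(as.numeric(tb$depth), group = tb$scaffold_id)
    cv <- rowsum(as.numeric(tb$depth >= 1), group = tb$scaffold_id)
    out <- data.frame(scaffold_id = names(lens), mean_depth = 0, breadth = 0,
                      aligned_read_gc = 0, no_data = TRUE)
    i <- match(rownames(ds), out$scaffold_id)
    out$mean_depth[i] <- ds[, 1] / lens[rownames(ds)]
    out$breadth[i] <- cv[, 1] / lens[rownames(ds)]
    if ("aligned_read_gc" %in% colnames(tb)) {
      gc1 <- tapply(tb$aligned_read_gc, tb$scaffold_id, function(v) v[1])
      out$aligned_read_gc[match(names(gc1), out$scaffold_id)] <- as.numeric(gc1)
    }
    out$no_data <- out$mean_depth == 0
    return(out)
  }
  stopf("unrecognized depth TSV schema in %s (need %s, or %s)", path,
        paste(summaryCols, collapse = "/"), paste(perBaseCols, collapse = "/"))
}

#' Summarize read alignments per scaffold
#'
#' Computes, for each scaffold of the assembly, the mean per-base depth, the
#' breadth of coverage (fraction of positions with depth >= 1) and the GC
#' fraction of aligned read bases. Inputs may be one or more SAM/BAM files
#' (only primary, properly paired alignments passing QC are counted;
#' secondary, supplementary, unmapped, QC-fail and duplicate records are
#' excluded) and/or pre-computed TSVs (either per-scaffold summaries with
#' columns `scaffold_id`, `mean_depth`, `breadth`, `aligned_read_gc`, or
#' per-base records with columns `scaffold_id`, `pos`, `depth` and an
#' optional `aligned_read_gc`). Files flagged in `exclude` (e.g. mate-pair
#' libraries, whose chimeric artifacts distort coverage) are skipped
#' entirely.
#'
#' @param paths Character vector of SAM/BAM/TSV paths.
#' @param scaffolds Scaffold records from [computeScaffoldStats()].
#' @param exclude Logical vector along `paths`: `TRUE` marks a library
#'   excluded from coverage (default all `FALSE`).
#' @param requireProperPair Keep only properly paired alignments
#'   (default `TRUE`).
#' @param readGcMode `"read"` (default): GC over full read sequences of
#'   retained alignments; `"aligned"`: only read bases consumed on the
#'   reference.
#' @return `data.frame` with columns `scaffold_id`, `mean_depth`, `breadth`,
#'   `aligned_read_gc`, `no_data` (logical: no reads aligned, values are 0
#'   by convention).
#' @export
summarizeAlignments <- function(paths, scaffolds, exclude = NULL,
                                requireProperPair = TRUE,
                                readGcMode = c("read", "aligned")) {
  readGcMode <- match.arg(readGcMode)
  exclude <- exclude %||% rep(FALSE, length(paths))
  if (length(exclude) != length(paths))
    stopf("exclude must have one flag per path")
  paths <- paths[!exclude]
  ids <- scaffolds$scaffold_id
  lens <- structure(scaffolds$length, names = ids)
  tsv <- grepl("\\.(tsv|txt)$", paths, ignore.case = TRUE)
  if (any(tsv) && any(!tsv))
    stopf("cannot mix SAM/BAM and TSV alignment inputs in one library")
  if (length(paths) == 0) {
    return(data.frame(scaffold_id = ids, mean_depth = 0, breadth = 0,
                      aligned_read_gc = 0, no_data = TRUE))
  }
  if (all(tsv)) {
    if (length(paths) > 1)
      stopf("a single TSV per library is supported")
    return(readDepthTsv(paths, scaffolds))
  }
  depthSum <- structure(numeric(length(ids)), names = ids)
  covered <- depthSum  # upper bound by union not tracked across files:
  gcBases <- depthSum
  totBases <- depthSum
  if (length(paths) > 1) {
    # exact multi-file breadth needs a merged depth vector; merge BAMs first
    stopf("multiple SAM/BAM files per library are not supported; merge them first")
  }
  s <- summarizeOneBam(paths, scaffolds, requireProperPair, readGcMode)
  depthSum <- s$depth_sum
  covered <- s$covered
  gcBases <- s$gc_bases
  totBases <- s$total_bases
  noData <- totBases == 0 & depthSum == 0
  data.frame(scaffold_id = ids,
             mean_depth = unname(depthSum / lens),
             breadth = unname(covered / lens),
             aligned_read_gc = unname(ifelse(totBases > 0,
                                             gcBases / totBases, 0)),
             no_data = unname(noData))
}

#' Assemble the eight-predictor table
#'
#' Joins scaffold statistics with DNA and RNA alignment summaries into the
#' canonical predictor table. A scaffold absent from an alignment summary is
#' treated as zero-evidence (depth, breadth and read GC of 0) — for RNA this
#' is a valid biological signal (the scaffold expressed no mRNA), not
#' missing data.
#'
#' @param stats Output of [computeScaffoldStats()].
#' @param dna,rna Outputs of [summarizeAlignments()] for the DNA and RNA
#'   libraries (either may be `NULL` for zero evidence).
#' @return A [PredictorTable-class] with the eight canonical columns.
#' @export
buildPredictorTable <- function(stats, dna = NULL, rna = NULL) {
  if (anyDuplicated(stats$scaffold_id))
    stopf("duplicate scaffold_id in scaffold stats")
  ids <- stats$scaffold_id
  zero <- data.frame(scaffold_id = ids, mean_depth = 0, breadth = 0,
                     aligned_read_gc = 0, no_data = TRUE)
  fill <- function(s) {
    if (is.null(s)) return(zero)
    if (anyDuplicated(s$scaffold_id))
      stopf("duplicate scaffold_id in alignment summary")
    extra <- setdiff(s$scaffold_id, ids)
    if (length(extra) > 0)
      stopf("alignment summary references unknown scaffold(s): %s",
            paste(extra, collapse = ", "))
    out <- zero
    i <- match(s$scaffold_id, ids)
    out$mean_depth[i] <- s$mean_depth
    out$breadth[i] <- s$breadth
    out$aligned_read_gc[i] <- s$aligned_read_gc
    out$no_data[i] <- if ("no_data" %in% colnames(s)) s$no_data
                      else s$mean_depth == 0
    out
  }
  d <- fill(dna)
  r <- fill(rna)
  tb <- data.frame(scaffold_id = ids,
                   length = as.numeric(stats$length),
                   gc = stats$gc,
                   dna_mean_depth = d$mean_depth,
                   rna_mean_depth = r$mean_depth,
                   dna_breadth = d$breadth,
                   rna_breadth = r$breadth,
                   dna_read_gc = d$aligned_read_gc,
                   rna_read_gc = r$aligned_read_gc,
                   row.names = NULL)
  new("PredictorTable", table = tb,
      noData = data.frame(scaffold_id = ids, dna = d$no_data, rna = r$no_data))
}

#' Construct a PredictorTable from a data.frame
#'
#' @param df `data.frame` with `scaffold_id` and the eight canonical
#'   predictor columns.
#' @return A [PredictorTable-class].
#' @export
PredictorTable <- function(df) {
  df <- as.data.frame(df)[, c("scaffold_id", PREDICTOR_NAMES)]
  df$scaffold_id <- as.character(df$scaffold_id)
  for (col in PREDICTOR_NAMES) df[[col]] <- as.numeric(df[[col]])
  rownames(df) <- NULL
  new("PredictorTable", table = df,
      noData = data.frame(scaffold_id = df$scaffold_id,
                          dna = df$dna_mean_depth == 0,
                          rna = df$rna_mean_depth == 0))
}

#' @describeIn PredictorTable Scaffold ids, in table order.
#' @param x A [PredictorTable-class].
#' @export
setMethod("scaffoldIds", "PredictorTable", function(x) x@table$scaffold_id)

#' Numeric predictor matrix of a PredictorTable
#' @param x A [PredictorTable-class].
#' @return Numeric matrix, rownames scaffold ids, the eight canonical
#'   columns.
#' @export
predictorMatrix <- function(x) {
  m <- as.matrix(x@table[, PREDICTOR_NAMES])
  rownames(m) <- x@table$scaffold_id
  m
}

#' @export
#' @describeIn PredictorTable Coerce to `data.frame`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
as.data.frame.PredictorTable <- function(x, row.names = NULL,
                                         optional = FALSE, ...) x@table

setMethod("show", "PredictorTable", function(object) {
  cat(sprintf("PredictorTable: %d scaffold(s) x %d predictors\n",
              nrow(object@table), length(PREDICTOR_NAMES)))
  print(utils::head(object@table, 5))
  if (nrow(object@table) > 5) cat("...\n")
})

#' Write / read a predictor table as TSV
#' @param x A [PredictorTable-class].
#' @param path TSV path.
#' @return `path` (write) or a [PredictorTable-class] (read).
#' @export
writePredictorTable <- function(x, path) {
  utils::write.table(x@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictorTable
#' @export
readPredictorTable <- function(path) {
  PredictorTable(utils::read.delim(path, stringsAsFactors = FALSE))
}
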
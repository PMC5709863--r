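# End-to-end decontamination: predictors -> labels -> model -> classify all
# scaffolds (including those without a BLAST hit) -> kept FASTA + report.

REPORT_COLS <- c("scaffold_id", PREDICTOR_NAMES, "label_source",
                 "predicted_class", "target_score")

#' Assemble a run configuration
#'
#' @param fasta Assembly FASTA path.
#' @param dna,rna Character vectors of DNA / RNA alignment inputs (SAM/BAM
#'   or TSV, see [summarizeAlignments()]); `NULL` means no evidence.
#' @param blast BLAST tabular path (outfmt 6, optional 13th subject-taxon
#'   column).
#' @param outDir Output directory.
#' @param targetGenus Genus of the sequencing target.
#' @param contaminantOverrides,targetOverrides Curated taxon substrings, see
#'   [assignLabels()].
#' @param trainFraction Training fraction of the labeled scaffolds
#'   (default 0.5).
#' @param modelSpec Model specification (default bagging with B = 100), see
#'   [fitModel()].
#' @param dnaExclude,rnaExclude Logical flags along `dna` / `rna` marking
#'   libraries excluded from coverage (mate-pair libraries).
#' @param seed Integer master seed.
#' @return A validated run-configuration list.
#' @export
runConfig <- function(fasta, dna = NULL, rna = NULL, blast, outDir,
                      targetGenus, contaminantOverrides = character(),
                      targetOverrides = character(), trainFraction = 0.5,
                      modelSpec = list(kind = "bagging", B = 100L),
                      dnaExclude = NULL, rnaExclude = NULL, seed = 1L) {
  cfg <- list(fasta = fasta, dna = dna, rna = rna, blast = blast,
              outDir = outDir, targetGenus = targetGenus,
              contaminantOverrides = contaminantOverrides,
              targetOverrides = targetOverrides,
              trainFraction = trainFraction, modelSpec = modelSpec,
              dnaExclude = dnaExclude, rnaExclude = rnaExclude,
              seed = as.integer(seed))
  for (p in c(fasta, dna, rna, blast))
    if (!file.exists(p)) stopf("input does not exist: %s", p)
  if (trainFraction <= 0 || trainFraction >= 1)
    stopf("trainFraction must be in (0, 1)")
  cfg
}

#' Run the decontamination pipeline
#'
#' Builds the eight-predictor table from the assembly and alignments,
#' assigns labels from the BLAST results, splits the labeled scaffolds at
#' the training fraction, fits the model, reports held-out test metrics,
#' classifies every scaffold (labeled and unknown alike), and writes to the
#' output directory: `kept.fasta` (predicted target scaffolds),
#' `removed_ids.txt`, `report.tsv`, the serialized model (`model.json`) and
#' a machine-readable run manifest (`manifest.json`). Reruns with the same
#' configuration are byte-identical.
#'
#' @param config List from [runConfig()].
#' @return A [ClassificationReport-class], invisibly; side effects on disk.
#' @export
runDecontam <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::readDNAStringSet(config$fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  stats <- computeScaffoldStats(seqs)
  dna <- if (is.null(config$dna)) NULL
         else summarizeAlignments(config$dna, stats, exclude = config$dnaExclude)
  rna <- if (is.null(config$rna)) NULL
         else summarizeAlignments(config$rna, stats, exclude = config$rnaExclude)
  ptable <- buildPredictorTable(stats, dna, rna)

  hits <- readBlastHits(config$blast)
  best <- bestHitPerScaffold(hits, stats$scaffold_id)
  labeled <- assignLabels(best, config$targetGenus,
                          config$contaminantOverrides, config$targetOverrides)
  if (length(scaffoldClasses(labeled)) == 0)
    stopf("empty labeled set: no scaffold has a BLAST-assigned origin")

  sp <- splitTraining(labeled, config$trainFraction,
                      seed = deriveSeed(config$seed, 1L))
  x <- predictorMatrix(ptable)
  lab <- scaffoldClasses(labeled)
  model <- fitModel(x[sp@trainIds, , drop = FALSE], lab[sp@trainIds],
                    spec = config$modelSpec, seed = deriveSeed(config$seed, 2L))
  testPred <- predict(model, x[sp@testIds, , drop = FALSE])
  names(testPred) <- sp@testIds
  metrics <- classMetrics(confusionCounts(testPred, lab[sp@testIds]))

  score <- if (is(model, "EnsembleModel")) predict(model, x, type = "prob")
           else predict(model, x, type = "prob")
  thr <- if (is(model, "EnsembleModel")) model@threshold
         else config$modelSpec$threshold %||% 0.5
  predicted <- ifelse(score >= thr, CLASS_NAMES[1L], CLASS_NAMES[2L])
  source <- ifelse(stats$scaffold_id %in% unknownIds(labeled), "no-hit",
                   paste0("blast-", lab[stats$scaffold_id]))
  tb <- cbind(ptable@table,
              data.frame(label_source = source, predicted_class = predicted,
                         target_score = score))
  keep <- tb$predicted_class == "target"
  summary <- list(
    total_scaffolds = nrow(tb),
    kept_scaffolds = sum(keep),
    removed_scaffolds = sum(!keep),
    total_mb = round(sum(tb$length) / 1e6, 2),
    kept_mb = round(sum(tb$length[keep]) / 1e6, 2),
    removed_mb = round(sum(tb$length[!keep]) / 1e6, 2))

  report <- new("ClassificationReport", table = tb, summary = summary,
                metrics = metrics)
  Biostrings::writeXStringSet(seqs[tb$scaffold_id[keep]],
                              file.path(config$outDir, "kept.fasta"))
  writeLines(tb$scaffold_id[!keep],
             file.path(config$outDir, "removed_ids.txt"))
  writeReport(report, file.path(config$outDir, "report.tsv"))
  writeModel(model, file.path(config$outDir, "model.json"))
  manifest <- list(
    package = "decontree",
    version = as.character(utils::packageVersion("decontree")),
    config = config[c("fasta", "dna", "rna", "blast", "targetGenus",
                      "contaminantOverrides", "targetOverrides",
                      "trainFraction", "modelSpec", "seed")],
    n_train = length(sp@trainIds), n_test = length(sp@testIds),
    n_unknown = length(unknownIds(labeled)),
    metrics = metrics, summary = summary)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(config$outDir, "manifest.json"), useBytes = TRUE)
  invisible(report)
}

#' Write / read a classification report TSV
#'
#' Lossless round trip with a fixed column order; the summary and test
#' metrics are stored as `#`-prefixed JSON header lines.
#'
#' @param report A [ClassificationReport-class].
#' @param path TSV path.
#' @return `path` (write) or the restored report (read).
#' @export
writeReport <- function(report, path) {
  hdr <- c(
    paste0("# summary=", jsonlite::toJSON(report@summary, auto_unbox = TRUE,
                                          digits = NA)),
    paste0("# metrics=", jsonlite::toJSON(report@metrics, auto_unbox = TRUE,
                                          digits = NA, na = "null")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(report@table[, REPORT_COLS], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  lines <- readLines(path, n = 10)
  hdr <- lines[startsWith(lines, "# ")]
  parseHdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    if (length(ln) == 0) stopf("report lacks '%s' header: %s", key, path)
    jsonlite::fromJSON(sub(paste0("^# ", key, "="), "", ln))
  }
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(REPORT_COLS, colnames(tb))
  if (length(missing) > 0)
    stopf("report schema mismatch, missing column(s): %s",
          paste(missing, collapse = ", "))
  tb <- tb[, REPORT_COLS]
  metrics <- parseHdr("metrics")
  metrics <- lapply(metrics, function(v) if (is.null(v)) NA_real_ else v)
  new("ClassificationReport", table = tb, summary = parseHdr("summary"),
      metrics = metrics)
}

setMethod("show", "ClassificationReport", function(object) {
  s <- object@summary
  cat(sprintf("ClassificationReport: %d scaffolds (%.2f Mb); kept %d (%.2f Mb), removed %d (%.2f Mb)\n",
              s$total_scaffolds, s$total_mb, s$kept_scaffolds, s$kept_mb,
              s$removed_scaffolds, s$removed_mb))
  if (length(object@metrics) > 0) {
    m <- object@metrics
    cat(sprintf("Test metrics: accuracy %.4f, sensitivity %.4f, specificity %.4f\n",
                m$accuracy, m$sensitivity, m$specificity))
  }
})

#' @describeIn runDecontam Scaffold ids in a report.
#' @param x A [ClassificationReport-class].
#' @export
setMethod("scaffoldIds", "ClassificationReport", function(x) x@table$scaffold_id)
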
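# BLAST tabular results -> target / contaminant / unknown training labels,
# and random train/test partitions of the labeled scaffolds.

#' Read BLAST tabular (outfmt 6) results
#'
#' Reads the default 12 tab-separated columns, plus an optional appended
#' subject-title/taxonomy column used as the subject taxon text. Without a
#' 13th column the subject sequence id is used as the taxon string.
#'
#' @param path Tabular BLAST output (no header).
#' @return `data.frame` with columns `scaffold_id`, `subject_taxon`,
#'   `bitscore`, `evalue` (one row per hit, input order preserved).
#' @export
readBlastHits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(scaffold_id = character(), subject_taxon = character(),
                      bitscore = numeric(), evalue = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12))
    stopf("malformed BLAST tabular line %d: expected >= 12 fields, got %d",
          which(nf < 12)[1], nf[which(nf < 12)[1]])
  getcol <- function(i) vapply(parts, `[[`, "", i)
  evalue <- suppressWarnings(as.numeric(getcol(11)))
  bitscore <- suppressWarnings(as.numeric(getcol(12)))
  if (anyNA(evalue))
    stopf("malformed numeric evalue at line %d", which(is.na(evalue))[1])
  if (anyNA(bitscore))
    stopf("malformed numeric bitscore at line %d", which(is.na(bitscore))[1])
  taxon <- ifelse(nf >= 13, vapply(parts, function(p)
    if (length(p) >= 13) p[[13]] else "", ""), getcol(2))
  data.frame(scaffold_id = getcol(1), subject_taxon = taxon,
             bitscore = bitscore, evalue = evalue, row.names = NULL)
}

#' Select the single best BLAST hit of one scaffold
#'
#' The best hit maximizes the bitscore; ties are broken by the smaller
#' e-value, then by input order.
#'
#' @param hits `data.frame` of hits for one scaffold (columns
#'   `subject_taxon`, `bitscore`, `evalue`).
#' @return The best-hit row as a one-row `data.frame`, or `NULL` for an
#'   empty hit list ("No BLAST hit").
#' @export
selectBestHit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  if (length(unique(hits$scaffold_id %||% "x")) > 1)
    stopf("selectBestHit expects hits of a single scaffold")
  o <- order(-hits$bitscore, hits$evalue)  # stable: input order breaks ties
  hits[o[1], , drop = FALSE]
}

#' Best hit per scaffold over a full BLAST table
#'
#' @param hits `data.frame` from [readBlastHits()].
#' @param scaffoldIds All assembly scaffold ids; ids without any hit map to
#'   `NA` ("No BLAST hit").
#' @return Named character vector of best-hit subject taxa over
#'   `scaffoldIds`, `NA` where no hit exists.
#' @export
bestHitPerScaffold <- function(hits, scaffoldIds) {
  out <- structure(rep(NA_character_, length(scaffoldIds)),
                   names = scaffoldIds)
  if (nrow(hits) > 0) {
    extra <- setdiff(unique(hits$scaffold_id), scaffoldIds)
    if (length(extra) > 0)
      stopf("BLAST hits reference unknown scaffold(s): %s",
            paste(extra, collapse = ", "))
    o <- order(match(hits$scaffold_id, scaffoldIds), -hits$bitscore,
               hits$evalue)
    h <- hits[o, ]
    first <- !duplicated(h$scaffold_id)
    out[h$scaffold_id[first]] <- h$subject_taxon[first]
  }
  out
}

genusToken <- function(taxon) {
  tolower(sub("^\\s*(\\S+).*$", "\\1", taxon))
}

matchesAny <- function(taxon, patterns) {
  if (length(patterns) == 0) return(rep(FALSE, length(taxon)))
  hit <- rep(FALSE, length(taxon))
  lt <- tolower(taxon)
  for (p in patterns) hit <- hit | grepl(tolower(p), lt, fixed = TRUE)
  hit
}

#' Assign target/contaminant/unknown labels from best hits
#'
#' A scaffold with no hit is unknown ("No BLAST hit"). Otherwise the match
#' precedence is: a contaminant override (curated taxa labeled contaminant
#' regardless of genus, e.g. suspect strains) beats a target override (e.g.
#' an "Other Animalia" grouping) beats the genus rule, under which a hit
#' whose first whitespace-delimited taxon token equals the target genus
#' (case-insensitively) is target and anything else is contaminant.
#' Overrides are case-insensitive substring matches on the full subject
#' taxon text; a hit matching overrides on both lists is an error
#' (ambiguous curation).
#'
#' @param bestHits Named character vector (scaffold id -> subject taxon,
#'   `NA` = no hit), as from [bestHitPerScaffold()].
#' @param targetGenus Genus of the sequencing target (non-empty).
#' @param contaminantOverrides,targetOverrides Character vectors of taxon
#'   substrings.
#' @return A [LabeledScaffolds-class].
#' @export
assignLabels <- function(bestHits, targetGenus,
                         contaminantOverrides = character(),
                         targetOverrides = character()) {
  if (is.null(targetGenus) || !nzchar(targetGenus))
    stopf("targetGenus must be non-empty")
  ids <- names(bestHits)
  if (is.null(ids)) stopf("bestHits must be named by scaffold_id")
  hasHit <- !is.na(bestHits)
  taxa <- bestHits[hasHit]
  isContam <- matchesAny(taxa, contaminantOverrides)
  isTargOv <- matchesAny(taxa, targetOverrides)
  both <- isContam & isTargOv
  if (any(both))
    stopf("ambiguous curation: taxon matches both override lists: %s",
          paste(unique(taxa[both]), collapse = "; "))
  lab <- ifelse(isContam, "contaminant",
         ifelse(isTargOv, "target",
         ifelse(genusToken(taxa) == tolower(targetGenus),
                "target", "contaminant")))
  names(lab) <- ids[hasHit]
  new("LabeledScaffolds", labels = lab, unknownIds = ids[!hasHit])
}

#' Construct LabeledScaffolds directly
#' @param labels Named character vector (`"target"`/`"contaminant"`).
#' @param unknownIds Character vector of no-hit scaffold ids.
#' @return A [LabeledScaffolds-class].
#' @export
LabeledScaffolds <- function(labels, unknownIds = character()) {
  new("LabeledScaffolds", labels = labels, unknownIds = unknownIds)
}

#' @describeIn LabeledScaffolds All scaffold ids (labeled then unknown).
#' @param x A [LabeledScaffolds-class].
#' @export
setMethod("scaffoldIds", "LabeledScaffolds",
          function(x) c(names(x@labels), x@unknownIds))

#' Accessors for LabeledScaffolds
#' @param x A [LabeledScaffolds-class].
#' @return `scaffoldClasses`: named character vector of labels;
#'   `unknownIds`: character vector; `labeledIds`: character vector.
#' @export
scaffoldClasses <- function(x) x@labels

#' @rdname scaffoldClasses
#' @export
unknownIds <- function(x) x@unknownIds

#' @rdname scaffoldClasses
#' @export
labeledIds <- function(x) names(x@labels)

setMethod("show", "LabeledScaffolds", function(object) {
  tab <- table(factor(object@labels, levels = CLASS_NAMES))
  cat(sprintf("LabeledScaffolds: %d target, %d contaminant, %d unknown (no hit)\n",
              tab["target"], tab["contaminant"], length(object@unknownIds)))
})

#' Randomly split labeled scaffolds into training and test sets
#'
#' Uniform sampling without replacement of `round(fraction * n)` labeled ids
#' (unknown scaffolds are never sampled); the remainder is the test set.
#' Deterministic for a fixed seed. The split is not class-stratified by
#' default; `stratify = TRUE` samples the same fraction within each class.
#'
#' @param labeled A [LabeledScaffolds-class].
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratify Stratify by class (default `FALSE`).
#' @return A [TrainTestSplit-class].
#' @export
splitTraining <- function(labeled, fraction, seed = 1L, stratify = FALSE) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  lab <- labeled@labels
  present <- CLASS_NAMES %in% lab
  if (!all(present))
    stopf("class '%s' absent from labeled scaffolds: untrainable",
          CLASS_NAMES[!present][1])
  ids <- names(lab)
  set.seed(seed)
  if (stratify) {
    train <- unlist(lapply(CLASS_NAMES, function(cl) {
      clIds <- ids[lab == cl]
      sample(clIds, round(fraction * length(clIds)))
    }), use.names = FALSE)
  } else {
    train <- sample(ids, round(fraction * length(ids)))
  }
  new("TrainTestSplit", trainIds = train, testIds = setdiff(ids, train),
      fraction = fraction, seed = as.integer(seed))
}

setMethod("show", "TrainTestSplit", function(object) {
  cat(sprintf("TrainTestSplit: %d train / %d test (fraction %.3g, seed %d)\n",
              length(object@trainIds), length(object@testIds),
              object@fraction, object@seed))
})
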
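# Synthetic contaminated-assembly generator. Rather than simulating reads
# and re-assembling, the generator draws the eight per-scaffold predictors
# from class-conditional distributions chosen to emulate the structure of
# contaminated assemblies: GC ranges per class, gamma-distributed DNA depth,
# beta-distributed RNA breadth reflecting gene density, and saturating
# DNA breadth as a function of depth. A toy file bundle (FASTA + depth TSVs
# + BLAST-like hits) exercises the real parsers end to end.

#' Regime presets for the synthetic generator
#'
#' Three study regimes:
#' \describe{
#'   \item{separable}{GC-rich microbial contaminants (GC 0.50-0.69) in an
#'     AT-skewed eukaryotic assembly (GC 0.24-0.48), with well-separated DNA
#'     depth (contaminants sequenced at ~20x vs ~100x for the target): GC
#'     and depth alone suffice.}
#'   \item{overlapping}{A yeast-like contaminant whose GC range (0.23-0.53)
#'     falls inside the target's (0.24-0.72) and whose DNA depth
#'     distribution broadly overlaps the target's: discrimination requires
#'     the RNA-derived predictors (gene density differs sharply between a
#'     compact fungal genome and a metazoan one).}
#'   \item{empirical_like}{Contaminants are a mixture of low-coverage
#'     scaffolds of broad GC and moderate-coverage high-GC scaffolds,
#'     mirroring the structure seen in real nematode assemblies.}
#' }
#'
#' @param name Preset name.
#' @return A list of generator parameters with class `"RegimePreset"`:
#'   per-class `n`, `gc_range`, `dna_depth` (mean, shape), `rna_depth`
#'   (mean, shape), `rna_breadth` (alpha, beta), `p_no_rna`, `length`
#'   (meanlog, sdlog), plus `label_noise` and `unknown_fraction`.
#' @export
regimePreset <- function(name = c("separable", "overlapping", "empirical_like")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    label_noise = 0,
    unknown_fraction = 0.1,
    target = list(
      n = 3000L, gc_range = c(0.24, 0.48),
      dna_depth = c(mean = 100, shape = 8),
      rna_depth = c(mean = 30, shape = 4),
      rna_breadth = c(alpha = 2.5, beta = 9),  # ~22% of a metazoan scaffold genic
      p_no_rna = 0.02,
      length = c(meanlog = log(5000), sdlog = 1.0)),
    contaminant = list(
      n = 1000L, gc_range = c(0.50, 0.69),
      dna_depth = c(mean = 20, shape = 8),
      rna_depth = c(mean = 10, shape = 4),
      rna_breadth = c(alpha = 18, beta = 3.6),  # gene-dense microbe, ~83%
      p_no_rna = 0.002,
      length = c(meanlog = log(2000), sdlog = 1.0)))
  if (name == "overlapping") {
    base$target$n <- 1000L
    base$target$gc_range <- c(0.24, 0.72)
    base$target$dna_depth <- c(mean = 100, shape = 1.2)  # heavy-tailed coverage
    base$contaminant$gc_range <- c(0.23, 0.53)
    base$contaminant$dna_depth <- c(mean = 80, shape = 1.0)
  } else if (name == "empirical_like") {
    base$target$gc_range <- c(0.30, 0.50)
    base$target$dna_depth <- c(mean = 100, shape = 4)
    # mixture weight of the low-coverage contaminant component
    base$contaminant$mixture <- list(
      p_low = 0.7,
      low = list(gc_range = c(0.35, 0.70), dna_depth = c(mean = 5, shape = 2)),
      high = list(gc_range = c(0.60, 0.70), dna_depth = c(mean = 100, shape = 4)))
    base$contaminant$rna_breadth <- c(alpha = 8, beta = 3)
  }
  structure(base, class = "RegimePreset")
}

drawClass <- function(par, n, cls) {
  len <- pmax(200, round(stats::rlnorm(n, par$length["meanlog"],
                                       par$length["sdlog"])))
  if (!is.null(par$mixture)) {
    low <- stats::runif(n) < par$mixture$p_low
    gc <- numeric(n)
    depth <- numeric(n)
    for (side in c("low", "high")) {
      sel <- if (side == "low") low else !low
      cmp <- par$mixture[[side]]
      gc[sel] <- stats::runif(sum(sel), cmp$gc_range[1], cmp$gc_range[2])
      depth[sel] <- stats::rgamma(sum(sel), shape = cmp$dna_depth["shape"],
                                  rate = cmp$dna_depth["shape"] /
                                         cmp$dna_depth["mean"])
    }
  } else {
    gc <- stats::runif(n, par$gc_range[1], par$gc_range[2])
    depth <- stats::rgamma(n, shape = par$dna_depth["shape"],
                           rate = par$dna_depth["shape"] /
                                  par$dna_depth["mean"])
  }
  # Breadth saturates with depth (Poisson-style coverage of positions),
  # bounded above by mean depth so a per-base depth vector can realize it.
  dnaBreadth <- (1 - exp(-0.8 * depth)) * stats::runif(n, 0.95, 1)
  dnaBreadth <- pmin(dnaBreadth, depth)
  dnaBreadth[depth == 0] <- 0
  rnaBr <- stats::rbeta(n, par$rna_breadth["alpha"], par$rna_breadth["beta"])
  noRna <- stats::runif(n) < par$p_no_rna
  rnaBr[noRna] <- 0
  rnaDepthLocal <- stats::rgamma(n, shape = par$rna_depth["shape"],
                                 rate = par$rna_depth["shape"] /
                                        par$rna_depth["mean"])
  rnaDepth <- rnaBr * rnaDepthLocal
  rnaDepth <- pmax(rnaDepth, rnaBr)  # covered positions have depth >= 1
  rnaDepth[rnaBr == 0] <- 0
  dnaReadGc <- pmin(pmax(gc + stats::rnorm(n, 0, 0.01), 0), 1)
  dnaReadGc[depth == 0] <- 0
  rnaReadGc <- pmin(pmax(gc + stats::rnorm(n, 0, 0.02), 0), 1)
  rnaReadGc[rnaBr == 0] <- 0
  data.frame(length = as.numeric(len), gc = gc, dna_mean_depth = depth,
             rna_mean_depth = rnaDepth, dna_breadth = dnaBreadth,
             rna_breadth = rnaBr, dna_read_gc = dnaReadGc,
             rna_read_gc = rnaReadGc, class = cls)
}

#' Simulate a predictor table with ground truth
#'
#' Draws per-scaffold predictors from the preset's class-conditional
#' distributions: length log-normal, GC uniform on the class range, DNA
#' depth gamma, RNA breadth beta (reflecting the class's gene density,
#' with a per-class probability of no mRNA expression at all), and the
#' remaining columns derived from the same latent class parameters with
#' noise. Deterministic for a fixed seed.
#'
#' @param preset A `"RegimePreset"` from [regimePreset()], or a preset name.
#' @param seed Integer seed.
#' @param nTarget,nContam Optional overrides of the preset's per-class
#'   scaffold counts.
#' @return List with `table` (a [PredictorTable-class]), `truth`
#'   (`data.frame` of `scaffold_id`, `class`, with the preset snapshot and
#'   seed as attributes).
#' @export
simulatePredictorTable <- function(preset, seed = 1L, nTarget = NULL,
                                   nContam = NULL) {
  if (is.character(preset)) preset <- regimePreset(preset)
  nT <- as.integer(nTarget %||% preset$target$n)
  nC <- as.integer(nContam %||% preset$contaminant$n)
  if (nT < 1 || nC < 1) stopf("both classes need at least one scaffold")
  set.seed(seed)
  tg <- drawClass(preset$target, nT, "target")
  ct <- drawClass(preset$contaminant, nC, "contaminant")
  df <- rbind(tg, ct)
  df$scaffold_id <- sprintf("scaffold_%05d", seq_len(nrow(df)))
  truth <- data.frame(scaffold_id = df$scaffold_id, class = df$class)
  attr(truth, "preset") <- preset
  attr(truth, "seed") <- as.integer(seed)
  list(table = PredictorTable(df[, c("scaffold_id", PREDICTOR_NAMES)]),
       truth = truth)
}

#' Simulate the BLAST labeling process over ground truth
#'
#' Each scaffold independently becomes unknown ("No BLAST hit") with
#' probability `unknownFraction`; surviving labels are flipped with
#' probability `mislabelRate` (database-contamination noise).
#'
#' @param truth Truth `data.frame` from [simulatePredictorTable()].
#' @param unknownFraction,mislabelRate Rates in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [LabeledScaffolds-class].
#' @export
simulateBlastLabels <- function(truth, unknownFraction = 0,
                                mislabelRate = 0, seed = 1L) {
  if (unknownFraction < 0 || unknownFraction >= 1 ||
      mislabelRate < 0 || mislabelRate >= 1)
    stopf("rates must lie in [0, 1)")
  set.seed(seed)
  n <- nrow(truth)
  unk <- stats::runif(n) < unknownFraction
  flip <- stats::runif(n) < mislabelRate
  if (all(unk)) stopf("all scaffolds unknown: nothing to train on")
  lab <- truth$class
  lab[flip] <- ifelse(lab[flip] == "target", "contaminant", "target")
  new("LabeledScaffolds",
      labels = structure(lab[!unk], names = truth$scaffold_id[!unk]),
      unknownIds = truth$scaffold_id[unk])
}

# A random sequence of given length with an exact count of G+C bases.
sequenceWithGc <- function(len, gc) {
  nGc <- round(gc * len)
  bases <- c(sample(c("G", "C"), nGc, replace = TRUE),
             sample(c("A", "T"), len - nGc, replace = TRUE))
  paste(bases[sample.int(len)], collapse = "")
}

#' Write a toy contaminated-assembly file bundle
#'
#' Draws a small predictor table from the preset and writes a consistent
#' file bundle: `assembly.fasta` (sequences matching the drawn lengths and
#' GC), `dna.depth.tsv` / `rna.depth.tsv` (per-scaffold alignment summaries
#' matching the drawn depth, breadth and read GC), `hits.tsv` (BLAST outfmt
#' 6 plus a subject-taxon column, realizing the simulated labeling process)
#' and `truth.tsv`. Running [computeScaffoldStats()],
#' [summarizeAlignments()] and [buildPredictorTable()] on the bundle
#' reproduces the drawn table up to FASTA GC quantization. Target hits use
#' the genus `Targetus`; contaminant hits use `Contamina`.
#'
#' @param preset Preset or preset name (see [regimePreset()]).
#' @param seed Integer seed; the same seed yields a byte-identical bundle.
#' @param outDir Output directory (created if needed).
#' @param nTarget,nContam Scaffolds per class (defaults 30 and 20; toy
#'   scale).
#' @param maxLength Cap on scaffold length so the bundle stays small
#'   (default 3000 bp).
#' @return Named list of file paths (`fasta`, `dna`, `rna`, `hits`,
#'   `truth`) plus `target_genus` and the drawn `table` and `truth_table`.
#' @export
simulateToyAssembly <- function(preset, seed = 1L, outDir = tempfile("toy_"),
                                nTarget = 30L, nContam = 20L,
                                maxLength = 3000L) {
  if (is.character(preset)) preset <- regimePreset(preset)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulatePredictorTable(preset, seed = seed, nTarget = nTarget,
                                nContam = nContam)
  tb <- sim$table@table
  tb$length <- pmin(tb$length, maxLength)
  labels <- simulateBlastLabels(sim$truth,
                                unknownFraction = preset$unknown_fraction,
                                mislabelRate = preset$label_noise,
                                seed = deriveSeed(seed, 1L))
  set.seed(deriveSeed(seed, 2L))
  seqs <- vapply(seq_len(nrow(tb)),
                 function(i) sequenceWithGc(tb$length[i], tb$gc[i]), "")
  paths <- list(
    fasta = file.path(outDir, "assembly.fasta"),
    dna = file.path(outDir, "dna.depth.tsv"),
    rna = file.path(outDir, "rna.depth.tsv"),
    hits = file.path(outDir, "hits.tsv"),
    truth = file.path(outDir, "truth.tsv"))
  writeLines(paste0(">", tb$scaffold_id, "\n", seqs), paths$fasta)
  writeSummary <- function(path, prefix) {
    df <- data.frame(scaffold_id = tb$scaffold_id,
                     mean_depth = tb[[paste0(prefix, "_mean_depth")]],
                     breadth = tb[[paste0(prefix, "_breadth")]],
                     aligned_read_gc = tb[[paste0(prefix, "_read_gc")]])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeSummary(paths$dna, "dna")
  writeSummary(paths$rna, "rna")
  lab <- scaffoldClasses(labels)
  taxa <- ifelse(lab == "target", "Targetus simulatus",
                 "Contamina albicans")
  hitRows <- sprintf(
    "%s\tsubj_%s\t98.5\t500\t5\t0\t1\t500\t1\t500\t1e-100\t900\t%s",
    names(lab), ifelse(lab == "target", "tgt", "ctm"), taxa)
  writeLines(hitRows, paths$hits)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, list(target_genus = "Targetus",
                table = PredictorTable(tb), truth_table = sim$truth))
}
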
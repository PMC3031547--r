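# End-to-end orchestration: simulate/ingest -> align per preset -> metrics +
# saturation -> trees + support -> RF vs reference -> rank -> optional
# selection suite -> report tables.

#' Build a pipeline configuration
#'
#' @param simulate A [FamilySimConfig-class], or NULL when providing input
#'   files.
#' @param aaFasta,ntFasta Paths to unaligned amino-acid / in-frame coding
#'   FASTA files (used when \code{simulate} is NULL; \code{ntFasta} is
#'   required only for the selection stage).
#' @param presets Character vector of built-in preset names (see
#'   [builtinPresets()]) and/or a list of [AlignerPreset-class] objects.
#' @param externalAlignments Named character vector of aligned-FASTA paths
#'   ingested alongside the presets (names become method labels).
#' @param reference \code{"truth"} (the simulator's tree/alignment) or a path
#'   to a Newick file used as the ranking anchor.
#' @param doSelection Run the codon selection suite.
#' @param foreground Leaf ids of the foreground clade for branch tests; when
#'   NULL and simulating, the expansion clade is used.
#' @param search \code{"nni"} for the ML topology search, \code{"bionj"} for
#'   distance trees with ML branch lengths only.
#' @param nniStarts,bootstrapReps,nRestarts Stage effort knobs.
#' @param seed Master seed.
#' @param outputDir Where artifacts are written.
#' @return A validated config list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(simulate = familySimConfig(), aaFasta = NULL,
                           ntFasta = NULL,
                           presets = c("strict62-nj", "loose62-nj",
                                       "loose45-kmer"),
                           externalAlignments = NULL, reference = "truth",
                           doSelection = TRUE, foreground = NULL,
                           search = c("bionj", "nni"), nniStarts = 2L,
                           bootstrapReps = 50L, nRestarts = 1L, seed = 1L,
                           outputDir = tempfile("alnsens-run")) {
  search <- match.arg(search)
  if (is.null(simulate) && is.null(aaFasta)) {
    stop("need either a simulation config or an input FASTA")
  }
  if (is.null(simulate) && identical(reference, "truth")) {
    stop("reference 'truth' requires simulated input")
  }
  if (is.character(presets)) {
    all <- builtinPresets()
    bad <- setdiff(presets, names(all))
    if (length(bad)) stop("unknown preset(s): ", paste(bad, collapse = ", "))
    presets <- all[presets]
  }
  if (length(presets) + length(externalAlignments) < 1L) {
    stop("need at least one alignment source")
  }
  structure(list(simulate = simulate, aaFasta = aaFasta, ntFasta = ntFasta,
                 presets = presets, externalAlignments = externalAlignments,
                 reference = reference, doSelection = doSelection,
                 foreground = foreground, search = search,
                 nniStarts = as.integer(nniStarts),
                 bootstrapReps = as.integer(bootstrapReps),
                 nRestarts = as.integer(nRestarts), seed = as.integer(seed),
                 outputDir = outputDir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; the
#' \code{simulate} block holds [familySimConfig()] fields.
#'
#' @param path YAML file.
#' @return A \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim <- do.call(familySimConfig, y$simulate)
  }
  args <- y[setdiff(names(y), "simulate")]
  do.call(pipelineConfig, c(list(simulate = sim), args))
}

#' Run the full sensitivity analysis
#'
#' Executes every stage in order and writes the report artifacts into the
#' configured output directory: \code{table2.tsv} (per-alignment metric
#' battery ranked by RF to the reference), \code{table3.tsv} plus
#' \code{site_overlap.tsv} (selection suite), \code{uncertainty.tsv}
#' (per-column congruence profile), \code{trees/*.nwk} (midpoint-rooted
#' per-method ML trees plus the reference), and \code{log.txt}. Reruns with
#' the same config are reproducible.
#'
#' @param config A \code{"PipelineConfig"} from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return Invisibly, a list with \code{battery} (ranked table),
#'   \code{selection} (report or NULL), \code{uncertainty}, \code{trees},
#'   \code{alignments}, \code{family}, \code{outputDir}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$outputDir, "trees"), showWarnings = FALSE)
  logf <- file.path(config$outputDir, "log.txt")
  logc <- file(logf, "w")
  on.exit(close(logc))
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, logc)
  }
  say("seed: ", config$seed)

  # stage 1: simulate or ingest
  family <- NULL
  if (!is.null(config$simulate)) {
    say("simulate: ", config$simulate@nConserved, "+",
        config$simulate@nExpansion, " lineages, seed ",
        config$simulate@seed)
    family <- simulateFamily(config$simulate)
    aaSeqs <- family@unalignedAa
    ntSeqs <- family@unalignedNt
  } else {
    say("ingest: ", config$aaFasta)
    aaSeqs <- .as_seqvec(readFasta(config$aaFasta, "aa"), "aa")
    ntSeqs <- if (!is.null(config$ntFasta)) {
      .as_seqvec(readFasta(config$ntFasta, "nt"), "nt")
    } else NULL
  }

  # stage 2: alignments
  alignments <- lapply(config$presets, function(p) {
    say("align: preset ", p@name)
    progressiveAlign(aaSeqs, p)
  })
  for (nm in names(config$externalAlignments)) {
    say("ingest alignment: ", nm)
    alignments[[nm]] <- readAlignment(config$externalAlignments[[nm]],
                                      "aa", nm)
  }
  names(alignments) <- vapply(alignments, methodLabel, "")

  # reference tree / alignment
  if (identical(config$reference, "truth")) {
    refTree <- family@trueTree
    refAln <- family@alignmentAa
  } else {
    refTree <- readNewick(config$reference)
    refAln <- NULL
  }
  writeNewick(refTree, file.path(config$outputDir, "trees",
                                 "reference.nwk"))

  # stages 3-5: metrics, trees, concordance
  say("metrics + trees (search = ", config$search, ")")
  rows <- list()
  trees <- list()
  for (nm in names(alignments)) {
    aln <- alignments[[nm]]
    model <- proteinModel(freqs = empiricalFreqs(aln))
    if (config$search == "nni") {
      fit <- nniSearch(aln, model, nStarts = config$nniStarts,
                       seed = .derive_seed(config$seed, nm))
      fit <- optimizeBranchLengths(fit$tree, aln, fit$model,
                                   optAlpha = TRUE, optPInv = TRUE,
                                   maxCycles = 5L)
    } else {
      tr0 <- bionjTree(proteinDistance(aln, "poisson"))
      fit <- optimizeBranchLengths(tr0, aln, model, optAlpha = TRUE,
                                   optPInv = TRUE, maxCycles = 5L)
    }
    bs <- bootstrapSupport(fit$tree, aln, nReps = config$bootstrapReps,
                           seed = .derive_seed(config$seed, paste0("bs-", nm)))
    sat <- saturationTest(aln, nReps = 200L,
                          seed = .derive_seed(config$seed,
                                              paste0("sat-", nm)))
    cmp <- rfDistance(fit$tree, refTree)
    trees[[nm]] <- midpointRoot(bs$tree)
    writeNewick(trees[[nm]], file.path(config$outputDir, "trees",
                                       paste0(nm, ".nwk")))
    rows[[nm]] <- data.frame(
      method = nm,
      length = nCols(aln),
      coreLength = coreLength(aln),
      pctIdentity = percentIdentity(aln),
      parsInformative = parsimonyInformativeCount(aln),
      lnL = fit$lnL,
      parsimony = fitchParsimony(fit$tree, aln),
      treeSize = treeSize(fit$tree),
      meanSupport = if (is.null(bs$support)) NA_real_ else
        mean(bs$support, na.rm = TRUE),
      saturationIss = sat$iss,
      saturated = sat$saturated,
      rf = cmp$rf,
      normalizedRf = cmp$normalizedRf,
      stringsAsFactors = FALSE)
    say("  ", nm, ": length ", nCols(aln), ", lnL ", round(fit$lnL, 2),
        ", RF ", cmp$rf)
  }
  battery <- rankAlignments(do.call(rbind, rows))
  writeReportTable(battery, file.path(config$outputDir, "table2.tsv"))

  # uncertainty profile against the reference alignment
  uncertainty <- NULL
  if (!is.null(refAln)) {
    prof <- uncertaintyProfile(c(list(truth = refAln), alignments),
                               refIndex = 1L)
    uncertainty <- data.frame(column = seq_along(prof$perColumnScore),
                              score = prof$perColumnScore)
    writeReportTable(uncertainty,
                     file.path(config$outputDir, "uncertainty.tsv"))
    say("uncertainty: overall ", round(prof$overall, 4))
  }

  # stage: selection
  selection <- NULL
  if (config$doSelection) {
    if (is.null(ntSeqs)) {
      stop("selection stage requires in-frame coding sequences")
    }
    say("selection suite")
    codonAlns <- lapply(alignments, codonBackmap, ntRecords = ntSeqs)
    selTrees <- trees[names(alignments)]
    selection <- selectionReport(codonAlns, selTrees,
                                 nRestarts = config$nRestarts,
                                 seed = config$seed)
    writeReportTable(selection, file.path(config$outputDir, "table3.tsv"))
    ov <- attr(selection, "siteOverlap")
    writeReportTable(data.frame(method = rownames(ov), ov,
                                check.names = FALSE),
                     file.path(config$outputDir, "site_overlap.tsv"))
  }
  say("done")
  invisible(list(battery = battery, selection = selection,
                 uncertainty = uncertainty, trees = trees,
                 alignments = alignments, family = family,
                 outputDir = config$outputDir))
}
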
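#' Published per-threshold key active protein lists
#'
#' The six ordered 22-protein key lists of the Shewanella oneidensis MR-1
#' active protein networks, one per interaction-confidence threshold
#' (CS_0.4 to CS_0.9), shipped as a plain-text fixture. These are the inputs
#' to frequency aggregation across the network series.
#'
#' @return named list of six ordered character vectors
#' @export
shewanellaKeyProteins <- function() {
  path <- system.file("extdata", "shewanella_key_proteins.tsv",
                      package = "ShewEETNet", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as.list(df[, -1])
}

#' Default pipeline configuration
#'
#' Desk-scale study conditions for the end-to-end synthetic run: the
#' proteomics generator plants the four expression archetypes plus flat and
#' never-expressed proteins, the interactome/regulon emulate a heavy-tailed
#' scored background and a sparse TF-target layer, and the analysis stages
#' use the canonical parameters (c = 4, m = 1.5, thresholds 0.4-0.9, top 2
#' percent, quorum 5 of 6, 1000 motif randomizations).
#'
#' @return named list of parameters; any element can be overridden via the
#'   \code{config} argument of \code{\link{runPipeline}}
#' @export
defaultConfig <- function() {
  list(
    nPerPattern = c(sharp_decrease = 250, sharp_increase = 200,
                    fast_then_slow_decrease = 200, late_increase = 150,
                    flat = 100, all_zero = 50),
    noiseSd = 0.2,
    meanDegree = 6,
    nTfs = 30, nTargetsPerTf = 8,
    thresholds = seq(0.4, 0.9, by = 0.1),
    c = 4, m = 1.5, sharpRatio = 2,
    percent = 0.02, topN = 20,
    nRandom = 1000, quorum = 5, zThr = 2, pThr = 0.05,
    conserved = c("Co-regulated PPI", "Protein Clique",
                  "Co-regulated Proteins", "PPI Regulating"),
    plantedMotifs = c("Bi-feedforward Loop" = 25,
                      "Regulatory Cascade with a Feedback" = 25,
                      "Feedback with a PPI" = 25,
                      "Co-regulated PPI" = 25),
    nTerms = 25, plantedTermSize = 40, plantedOverlap = 38,
    fdr = 0.05
  )
}

## Independent sub-seeds per stage, derived from the master seed and kept
## below 2^31.
stageSeeds <- function(seed) {
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max %/% 2, 7)
  stats::setNames(as.list(s), c("proteomics", "interactome", "regulon",
                                "cluster", "motifs", "modules",
                                "annotations"))
}

#' Run the full analysis on synthetic data
#'
#' Orchestrates simulate, cluster, network, centrality, motifs, modules and
#' enrichment in order, from one configuration and one master seed. Every
#' source of randomness flows through per-stage seeds derived from
#' \code{seed}, so a re-run with identical arguments reproduces the report
#' exactly. When \code{outdir} is given, the stage outputs (expression,
#' edges, arcs, active sets, centralities, frequency table, motif calls,
#' module assignment, enrichment) are written as TSV/JSON files.
#'
#' @param config named list overriding entries of \code{\link{defaultConfig}}
#' @param seed master integer seed
#' @param outdir optional output directory
#' @return a run-report list: parameter echo, per-stage counts, ground-truth
#'   recovery metrics and the main result tables
#' @export
runPipeline <- function(config = list(), seed = 1L, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$nPerPattern))
    config$nPerPattern <- unlist(config$nPerPattern)
  cfg <- utils::modifyList(defaultConfig(), config)
  if (any(cfg$thresholds < 0 | cfg$thresholds > 1) ||
      is.unsorted(cfg$thresholds))
    stop("thresholds must be sorted and lie in [0, 1]")
  seeds <- stageSeeds(seed)

  ## simulate
  se <- generateProteomics(cfg$nPerPattern, cfg$noiseSd, seeds$proteomics)
  expressed <- filterUnexpressed(se)
  ids <- rownames(expressed)
  edges <- generateInteractome(length(ids), cfg$meanDegree,
                               seeds$interactome, ids = ids)
  arcs <- generateRegulon(cfg$nTfs, cfg$nTargetsPerTf, ids, seeds$regulon)
  truthPat <- SummarizedExperiment::rowData(expressed)$pattern
  motifTruth <- list()
  if (length(cfg$plantedMotifs)) {
    sharpIds <- ids[truthPat %in% c("sharp_decrease", "sharp_increase")]
    for (i in seq_along(cfg$plantedMotifs)) {
      cl <- names(cfg$plantedMotifs)[i]
      pl <- plantMotifTriples(edges, arcs, sharpIds, cl,
                              cfg$plantedMotifs[[i]],
                              seed = seeds$interactome + i)
      edges <- pl$edges; arcs <- pl$arcs
      motifTruth[[cl]] <- pl$truth
      sharpIds <- setdiff(sharpIds, pl$truth$nodes)  # keep triples disjoint
    }
  }

  ## cluster -> active proteins
  std <- standardizeProfiles(expressed)
  fit <- fuzzyCMeans(std, c = cfg$c, m = cfg$m, seed = seeds$cluster)
  active <- identifyActiveClusters(fit, sharpRatio = cfg$sharpRatio)
  truth <- stats::setNames(truthPat, rownames(expressed))
  recovery <- patternRecovery(active, truth)

  ## thresholded integrated networks
  nets <- buildNetworkSeries(edges, arcs, active, cfg$thresholds)
  statsTab <- do.call(rbind, lapply(nets, networkStats))
  statsTab <- cbind(network = names(nets), statsTab)

  ## centrality and frequency ranking
  k <- selectionSize(min(statsTab$nProteinsWithIsolates), cfg$percent)
  keyLists <- lapply(nets, function(net)
    rankAndSelect(computeCentralities(net), k))
  freqTab <- aggregateFrequencies(keyLists, cfg$topN)

  ## motifs
  motifStats <- lapply(seq_along(nets), function(i)
    motifSignificance(nets[[i]], nRandom = cfg$nRandom,
                      seed = seeds$motifs + i))
  names(motifStats) <- names(nets)
  calls <- callMotifs(motifStats, cfg$conserved, quorum = cfg$quorum,
                      zThr = cfg$zThr, pThr = cfg$pThr)

  ## modules on the motif-protein PPI subnetwork (densest network)
  modClasses <- if (length(calls$exclusive)) calls$exclusive else calls$active
  modPartition <- NULL
  if (length(modClasses)) {
    motProt <- motifProteins(nets[[1]], modClasses)
    sub <- nets[[1]]@ppi
    sub <- sub[sub$a %in% motProt & sub$b %in% motProt, , drop = FALSE]
    if (nrow(sub)) {
      lcc <- largestComponent(sub)
      modPartition <- annealModules(lcc, seed = seeds$modules)
    }
  }

  ## enrichment on a planted annotation collection
  ann <- generateAnnotations(cfg$nTerms, cfg$plantedTermSize,
                             cfg$plantedOverlap, background = ids,
                             query = activeProteins(active),
                             seed = seeds$annotations)
  enr <- hypergeomEnrich(activeProteins(active), ann$terms, ids)

  report <- list(
    parameters = cfg,
    seed = as.integer(seed), stageSeeds = seeds,
    counts = list(
      proteinsSimulated = nrow(se),
      proteinsExpressed = nrow(expressed),
      activeDown = length(downSet(active)),
      activeUp = length(upSet(active)),
      activeTotal = length(activeProteins(active)),
      keyProteinsPerNetwork = k,
      enrichedTerms = sum(enr$fdr < cfg$fdr, na.rm = TRUE),
      modules = if (is.null(modPartition)) 0L
                else length(unique(moduleAssignments(modPartition)))),
    patternRecovery = recovery,
    networkStats = statsTab,
    keyLists = keyLists,
    frequencyRanking = freqTab,
    motifStats = motifStats,
    motifCalls = calls,
    modulePartition = modPartition,
    enrichment = enr,
    motifTruth = motifTruth,
    annotationTruth = ann$truth
  )
  if (!is.null(outdir)) writeRunOutputs(report, se, edges, arcs, outdir)
  report
}

## Fraction of truly sharp_decrease / sharp_increase proteins recovered in
## the down / up set, and the overall active-label agreement.
patternRecovery <- function(active, truth) {
  dn <- names(truth)[truth == "sharp_decrease"]
  up <- names(truth)[truth == "sharp_increase"]
  down <- downSet(active); upS <- upSet(active)
  agree <- (sum(dn %in% down) + sum(up %in% upS) +
            sum(!(setdiff(names(truth), c(dn, up)) %in%
                  c(down, upS)))) / length(truth)
  list(downRecall = if (length(dn)) mean(dn %in% down) else NA_real_,
       upRecall = if (length(up)) mean(up %in% upS) else NA_real_,
       overallAgreement = agree)
}

writeRunOutputs <- function(report, se, edges, arcs, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeExpressionTSV(se, file.path(outdir, "expression.tsv"))
  utils::write.table(edges, file.path(outdir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(arcs, file.path(outdir, "arcs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$networkStats,
                     file.path(outdir, "network_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$frequencyRanking,
                     file.path(outdir, "frequency_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$enrichment,
                     file.path(outdir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$modulePartition)) {
    mp <- moduleAssignments(report$modulePartition)
    utils::write.table(data.frame(node = names(mp), module = mp),
                       file.path(outdir, "modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  summary <- report[c("seed", "counts", "patternRecovery")]
  summary$motifCalls <- report$motifCalls[c("active", "exclusive")]
  jsonlite::write_json(summary, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
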
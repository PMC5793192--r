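## Pre-noise trajectory templates over the six ordered samples (S1-S3
## high-O2, S4-S6 low-O2). The S3->S4 step dominates only for the two
## "sharp" archetypes.
patternTemplates <- list(
  sharp_decrease          = c( 1,    1,   1,  -1,   -1,   -1),
  sharp_increase          = c(-1,   -1,  -1,   1,    1,    1),
  fast_then_slow_decrease = c( 1.5, 0.5,  0,  -0.2, -0.4, -0.5),
  late_increase           = c( 0,    0,   0,   0,    0.2,  1.5),
  flat                    = c( 0,    0,   0,   0,    0,    0),
  all_zero                = c( 0,    0,   0,   0,    0,    0)
)

## Abundances are copy numbers and cannot be negative, so templates are
## shifted by a fixed baseline; rare negative noise excursions are truncated.
.abundanceBaseline <- 2

#' Generate a synthetic six-sample proteomics matrix
#'
#' Draws protein trajectories as archetype template plus iid Gaussian noise,
#' emulating the four expression patterns seen across the aerobic-to-anaerobic
#' transition (sharp decrease/increase at S3 to S4, fast-then-slow decrease,
#' late increase), plus flat and never-expressed (all-zero) proteins. The true
#' pattern of every protein is recorded in \code{rowData(se)$pattern}.
#'
#' @param nPerPattern named integer vector; names from
#'   \code{names(patternTemplates)}: \code{sharp_decrease},
#'   \code{sharp_increase}, \code{fast_then_slow_decrease},
#'   \code{late_increase}, \code{flat}, \code{all_zero}
#' @param noiseSd non-negative Gaussian noise standard deviation (abundance
#'   units; the archetype step has magnitude 2)
#' @param seed integer seed
#' @return \code{SummarizedExperiment} with assay \code{abundance}
#'   (proteins x 6), \code{colData$phase} (\code{high_O2}/\code{low_O2}) and
#'   the ground-truth \code{rowData$pattern}
#' @examples
#' se <- generateProteomics(c(sharp_decrease = 5, all_zero = 2),
#'                          noiseSd = 0, seed = 1)
#' SummarizedExperiment::assay(se)
#' @export
generateProteomics <- function(nPerPattern, noiseSd = 0.2, seed = 1L) {
  if (is.null(names(nPerPattern)) ||
      !all(names(nPerPattern) %in% names(patternTemplates)))
    stop("nPerPattern must be named with known pattern labels")
  if (any(nPerPattern < 0) || any(nPerPattern != round(nPerPattern)))
    stop("pattern counts must be non-negative integers")
  stopifnot(length(noiseSd) == 1L, noiseSd >= 0)
  set.seed(as.integer(seed))
  labels <- rep(names(nPerPattern), times = nPerPattern)
  n <- length(labels)
  mat <- matrix(0, nrow = n, ncol = 6,
                dimnames = list(NULL, paste0("S", 1:6)))
  for (i in seq_len(n)) {
    if (labels[i] == "all_zero") next          # exactly zero, no noise
    tmpl <- patternTemplates[[labels[i]]] + .abundanceBaseline
    mat[i, ] <- pmax(0, tmpl + stats::rnorm(6, sd = noiseSd))
  }
  rownames(mat) <- sprintf("P%04d", seq_len(n))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = mat),
    rowData = S4Vectors::DataFrame(pattern = labels),
    colData = S4Vectors::DataFrame(
      phase = rep(c("high_O2", "low_O2"), each = 3),
      row.names = colnames(mat)),
    metadata = list(seed = as.integer(seed), noiseSd = noiseSd)
  )
}

#' Generate a scored random interactome
#'
#' Erdos-Renyi background with edge probability \code{meanDegree/(nNodes-1)}
#' and Beta(2, 2) confidence scores, so every conventional cutoff between 0.4
#' and 0.9 keeps an informative subset. If by chance no edge reaches 0.9, the
#' strongest edge is redrawn uniformly from (0.9, 1) so the full threshold
#' series stays non-degenerate.
#'
#' @param nNodes number of proteins (>= 2)
#' @param meanDegree expected degree; must not exceed \code{nNodes - 1}
#' @param seed integer seed
#' @param ids optional node ids (default \code{N0001...})
#' @return data.frame with columns \code{a}, \code{b}, \code{confidence}
#' @export
generateInteractome <- function(nNodes, meanDegree, seed = 1L, ids = NULL) {
  stopifnot(nNodes >= 2)
  if (meanDegree > nNodes - 1)
    stop("meanDegree must not exceed nNodes - 1")
  set.seed(as.integer(seed))
  if (is.null(ids)) ids <- sprintf("N%04d", seq_len(nNodes))
  stopifnot(length(ids) == nNodes)
  pairs <- utils::combn(nNodes, 2)
  p <- meanDegree / (nNodes - 1)
  keep <- stats::runif(ncol(pairs)) < p
  a <- ids[pairs[1, keep]]
  b <- ids[pairs[2, keep]]
  conf <- stats::rbeta(length(a), 2, 2)
  if (length(conf) && max(conf) < 0.9)
    conf[which.max(conf)] <- stats::runif(1, 0.9, 1)
  data.frame(a = a, b = b, confidence = conf)
}

#' Generate a sparse TF-to-target regulon
#'
#' Transcription factors are drawn from the node pool; each regulates a fixed
#' number of distinct targets (never itself). Arcs are unique by construction.
#'
#' @param nTfs number of transcription factors
#' @param nTargetsPerTf targets per TF
#' @param nodePool character vector of candidate ids
#' @param seed integer seed
#' @return data.frame with columns \code{tf}, \code{target}
#' @export
generateRegulon <- function(nTfs, nTargetsPerTf, nodePool, seed = 1L) {
  if (nTfs == 0) return(data.frame(tf = character(), target = character()))
  if (length(nodePool) == 0) stop("empty node pool")
  if (nTfs > length(nodePool) || nTargetsPerTf > length(nodePool) - 1)
    stop("node pool too small for the requested regulon")
  set.seed(as.integer(seed))
  tfs <- sample(nodePool, nTfs)
  arcs <- lapply(tfs, function(tf) {
    data.frame(tf = tf,
               target = sample(setdiff(nodePool, tf), nTargetsPerTf))
  })
  out <- do.call(rbind, arcs)
  rownames(out) <- NULL
  out
}

#' Plant disjoint motif instances into a network
#'
#' Embeds \code{extraCount} fresh instances of a named triad class on brand
#' new nodes (no connection to the rest of the graph), guaranteeing the triad
#' census of that class rises by at least \code{extraCount}. Used for
#' z-score-recovery benchmarks of the motif-significance machinery.
#'
#' @param network an \linkS4class{IntegratedNetwork}
#' @param triadClass a display name or canonical code from
#'   \code{\link{triadClassNames}}
#' @param extraCount number of instances to embed (>= 0)
#' @param idPrefix prefix for the fresh node ids
#' @return list with the augmented \code{network} and a \code{truth} list
#'   (class id and planted count)
#' @export
plantMotifs <- function(network, triadClass, extraCount, idPrefix = "MOT") {
  stopifnot(methods::is(network, "IntegratedNetwork"), extraCount >= 0)
  pat <- triadPattern(triadClass)     # errors on unknown class
  if (extraCount == 0)
    return(list(network = network, truth = list(class = pat$name, planted = 0L)))
  ppiAdd <- NULL; regAdd <- NULL
  for (k in seq_len(extraCount)) {
    nodes <- sprintf("%s%03d_%d", idPrefix, k, 1:3)
    if (nrow(pat$ppi))
      ppiAdd <- rbind(ppiAdd, data.frame(a = nodes[pat$ppi$a],
                                         b = nodes[pat$ppi$b],
                                         confidence = 1))
    if (nrow(pat$reg))
      regAdd <- rbind(regAdd, data.frame(tf = nodes[pat$reg$tf],
                                         target = nodes[pat$reg$target]))
  }
  out <- integratedNetwork(ppi = rbind(network@ppi, ppiAdd),
                           reg = rbind(network@reg, regAdd),
                           isolated = network@isolated,
                           threshold = network@threshold)
  list(network = out,
       truth = list(class = pat$name, planted = as.integer(extraCount)))
}

#' Plant motif instances into background edge/arc lists
#'
#' Embeds \code{count} instances of a triad class on disjoint triples drawn
#' from \code{candidates}, directly into the background PPI edge list (with
#' high confidence, so the instances survive every threshold) and the
#' regulatory arc list. Pre-existing interactions on the planted pairs are
#' replaced.
#'
#' @param edges background scored edge data.frame (\code{a}, \code{b},
#'   \code{confidence})
#' @param arcs regulatory arc data.frame (\code{tf}, \code{target})
#' @param candidates node ids eligible for planting (needs
#'   \code{3 * count})
#' @param class triad class display name or canonical code
#' @param count number of disjoint instances
#' @param confidence confidence score of planted PPI edges (default 0.97)
#' @param seed integer seed for triple sampling
#' @return list with updated \code{edges}, \code{arcs} and a \code{truth}
#'   record (class, count, nodes used)
#' @export
plantMotifTriples <- function(edges, arcs, candidates, class, count,
                              confidence = 0.97, seed = 1L) {
  pat <- triadPattern(class)
  if (count == 0)
    return(list(edges = edges, arcs = arcs,
                truth = list(class = pat$name, planted = 0L,
                             nodes = character())))
  if (length(candidates) < 3 * count)
    stop("need at least ", 3 * count, " candidate nodes")
  set.seed(as.integer(seed))
  picked <- sample(candidates, 3 * count)
  triples <- matrix(picked, ncol = 3, byrow = TRUE)
  ppiAdd <- NULL; regAdd <- NULL
  for (k in seq_len(count)) {
    nodes <- triples[k, ]
    if (nrow(pat$ppi))
      ppiAdd <- rbind(ppiAdd, data.frame(a = nodes[pat$ppi$a],
                                         b = nodes[pat$ppi$b],
                                         confidence = confidence))
    if (nrow(pat$reg))
      regAdd <- rbind(regAdd, data.frame(tf = nodes[pat$reg$tf],
                                         target = nodes[pat$reg$target]))
  }
  pairKey <- function(x, y) paste(pmin(x, y), pmax(x, y))
  usedPairs <- unique(c(if (!is.null(ppiAdd)) pairKey(ppiAdd$a, ppiAdd$b),
                        if (!is.null(regAdd)) pairKey(regAdd$tf, regAdd$target)))
  edges <- edges[!(pairKey(edges$a, edges$b) %in% usedPairs), , drop = FALSE]
  arcs <- arcs[!(pairKey(arcs$tf, arcs$target) %in% usedPairs), , drop = FALSE]
  list(edges = rbind(edges, ppiAdd),
       arcs = if (is.null(regAdd)) arcs else rbind(arcs, regAdd),
       truth = list(class = pat$name, planted = as.integer(count),
                    nodes = picked))
}

#' Generate annotation sets with one planted enriched term
#'
#' Builds a GMT-style term-to-members map in which one term
#' (\code{planted_term}) overlaps a designated query set by construction;
#' all other terms are drawn uniformly from the background.
#'
#' @param nTerms total number of terms (>= 1; includes the planted one)
#' @param plantedTermSize size of the planted term
#' @param plantedOverlap members of the planted term drawn from \code{query}
#' @param background character vector of all ids
#' @param query character vector, the query set (subset of background)
#' @param termSize size of the non-planted terms (default
#'   \code{plantedTermSize})
#' @param seed integer seed
#' @return list with \code{terms} (named list of id vectors) and \code{truth}
#'   (the planted term name)
#' @export
generateAnnotations <- function(nTerms, plantedTermSize, plantedOverlap,
                                background, query, termSize = plantedTermSize,
                                seed = 1L) {
  stopifnot(nTerms >= 1, all(query %in% background))
  if (plantedOverlap > plantedTermSize || plantedTermSize > length(background)
      || plantedOverlap > length(query)
      || plantedTermSize - plantedOverlap > length(setdiff(background, query)))
    stop("impossible planted term/overlap sizes")
  set.seed(as.integer(seed))
  planted <- c(sample(query, plantedOverlap),
               sample(setdiff(background, query),
                      plantedTermSize - plantedOverlap))
  terms <- list(planted_term = planted)
  if (nTerms > 1) {
    others <- lapply(seq_len(nTerms - 1), function(i)
      sample(background, min(termSize, length(background))))
    names(others) <- sprintf("term_%03d", seq_len(nTerms - 1))
    terms <- c(terms, others)
  }
  list(terms = terms, truth = list(plantedTerm = "planted_term"))
}
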
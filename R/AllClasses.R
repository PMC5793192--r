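#' Fuzzy c-means clustering result
#'
#' Soft cluster memberships of standardized six-sample protein trajectories,
#' together with the cluster centroids, the per-iteration objective trace and
#' the hard (argmax) assignment. Produced by \code{\link{fuzzyCMeans}}.
#'
#' @slot memberships numeric matrix, proteins x clusters; rows sum to 1
#' @slot centroids numeric matrix, clusters x 6 standardized sample profiles
#' @slot hardLabels named integer vector, argmax cluster per protein (ties
#'   broken towards the lowest cluster index)
#' @slot objective numeric vector of the weighted within-cluster squared
#'   distance after each iteration (non-increasing)
#' @slot m numeric, the fuzzifier used
#' @slot converged logical, whether the tolerance was met before maxIter
#' @slot seed integer seed used for centroid initialization
#'
#' @aliases memberships centroids hardLabels
#' @export
setClass("FuzzyClustering",
  representation(
    memberships = "matrix",
    centroids   = "matrix",
    hardLabels  = "integer",
    objective   = "numeric",
    m           = "numeric",
    converged   = "logical",
    seed        = "integer"
  )
)

setValidity("FuzzyClustering", function(object) {
  msg <- character()
  rs <- rowSums(object@memberships)
  if (any(abs(rs - 1) > 1e-9))
    msg <- c(msg, "membership rows must sum to 1 (tolerance 1e-9)")
  if (any(object@memberships < -1e-12 | object@memberships > 1 + 1e-12))
    msg <- c(msg, "memberships must lie in [0, 1]")
  if (ncol(object@centroids) != 6L)
    msg <- c(msg, "centroids must have 6 sample columns")
  if (nrow(object@centroids) != ncol(object@memberships))
    msg <- c(msg, "centroid count must equal the number of clusters")
  if (length(object@hardLabels) != nrow(object@memberships))
    msg <- c(msg, "one hard label per protein required")
  if (length(msg)) msg else TRUE
})

#' Active protein set
#'
#' Proteins in the sharply decreasing (\code{downSet}) and sharply increasing
#' (\code{upSet}) clusters across the high-oxygen to low-oxygen transition.
#' Produced by \code{\link{identifyActiveClusters}}.
#'
#' @slot downSet character, proteins with a sharp S3 to S4 decrease
#' @slot upSet character, proteins with a sharp S3 to S4 increase
#'
#' @aliases activeProteins downSet upSet
#' @export
setClass("ActiveProteinSet",
  representation(downSet = "character", upSet = "character")
)

setValidity("ActiveProteinSet", function(object) {
  msg <- character()
  if (length(intersect(object@downSet, object@upSet)))
    msg <- c(msg, "downSet and upSet must be disjoint")
  if (anyDuplicated(object@downSet) || anyDuplicated(object@upSet))
    msg <- c(msg, "sets must not contain duplicate ids")
  if (length(msg)) msg else TRUE
})

#' Integrated mixed network
#'
#' A mixed graph over one node set: undirected, confidence-scored
#' protein-protein interaction (PPI) edges plus directed transcription-factor
#' to target regulatory arcs. In arc accounting a PPI edge counts as two
#' directed arcs and a regulatory arc as one, so
#' \code{totalArcs = 2 * nPPI + nReg}. Isolated active proteins (members of
#' the active set with no retained interaction) are tracked separately.
#'
#' @slot nodes character, connected node ids
#' @slot ppi data.frame with columns \code{a}, \code{b}, \code{confidence};
#'   unordered pairs unique, no self-loops
#' @slot reg data.frame with columns \code{tf}, \code{target}; ordered pairs
#'   unique, no self-loops
#' @slot isolated character, active proteins with no incident edge or arc
#' @slot threshold numeric, the confidence cutoff this network was built at
#'   (\code{NA} if not applicable)
#'
#' @aliases totalArcs,IntegratedNetwork-method
#'   networkStats,IntegratedNetwork-method
#' @export
setClass("IntegratedNetwork",
  representation(
    nodes     = "character",
    ppi       = "data.frame",
    reg       = "data.frame",
    isolated  = "character",
    threshold = "numeric"
  ),
  prototype(
    nodes = character(),
    ppi = data.frame(a = character(), b = character(),
                     confidence = numeric()),
    reg = data.frame(tf = character(), target = character()),
    isolated = character(),
    threshold = NA_real_
  )
)

setValidity("IntegratedNetwork", function(object) {
  msg <- character()
  p <- object@ppi; r <- object@reg
  if (!all(c("a", "b", "confidence") %in% names(p)))
    msg <- c(msg, "ppi needs columns a, b, confidence")
  if (!all(c("tf", "target") %in% names(r)))
    msg <- c(msg, "reg needs columns tf, target")
  if (nrow(p)) {
    if (any(p$a == p$b)) msg <- c(msg, "PPI self-loops are not allowed")
    key <- paste(pmin(p$a, p$b), pmax(p$a, p$b))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate PPI pairs")
    if (any(p$confidence < 0 | p$confidence > 1))
      msg <- c(msg, "confidences must lie in [0, 1]")
    if (!all(c(p$a, p$b) %in% object@nodes))
      msg <- c(msg, "PPI endpoints must be members of nodes")
  }
  if (nrow(r)) {
    if (any(r$tf == r$target)) msg <- c(msg, "regulatory self-loops are not allowed")
    if (anyDuplicated(paste(r$tf, r$target))) msg <- c(msg, "duplicate arcs")
    if (!all(c(r$tf, r$target) %in% object@nodes))
      msg <- c(msg, "arc endpoints must be members of nodes")
  }
  if (length(intersect(object@isolated, object@nodes)))
    msg <- c(msg, "isolated ids must not also be connected nodes")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
  if (length(msg)) msg else TRUE
})

#' Module partition of an undirected graph
#'
#' Node-to-module assignment with its Newman-Girvan modularity
#' \eqn{M = \sum_i (e_{ii} - a_i^2)}, where \eqn{e_{ii}} is the fraction of
#' edges inside module \eqn{i} and \eqn{a_i} the fraction of edge ends in it.
#' Produced by \code{\link{annealModules}}.
#'
#' @slot assignment named integer vector, module index per node
#' @slot M numeric, Newman-Girvan modularity of the assignment
#' @slot schedule list of annealing-schedule metadata (T0, cooling, proposals
#'   per temperature, stop rule, seed)
#'
#' @aliases moduleAssignments modularityValue
#' @export
setClass("ModulePartition",
  representation(assignment = "integer", M = "numeric", schedule = "list")
)

setValidity("ModulePartition", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)) || anyDuplicated(names(object@assignment)))
    msg <- c(msg, "assignment must be named with unique node ids")
  if (object@M < -1 - 1e-12 || object@M > 1 + 1e-12)
    msg <- c(msg, "modularity must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @rdname FuzzyClustering-class
#' @param x object
#' @export
setMethod("memberships", "FuzzyClustering", function(x) x@memberships)

#' @rdname FuzzyClustering-class
#' @export
setMethod("centroids", "FuzzyClustering", function(x) x@centroids)

#' @rdname FuzzyClustering-class
#' @export
setMethod("hardLabels", "FuzzyClustering", function(x) x@hardLabels)

#' @rdname ActiveProteinSet-class
#' @param x object
#' @export
setMethod("downSet", "ActiveProteinSet", function(x) x@downSet)

#' @rdname ActiveProteinSet-class
#' @export
setMethod("upSet", "ActiveProteinSet", function(x) x@upSet)

#' @rdname ActiveProteinSet-class
#' @export
setMethod("activeProteins", "ActiveProteinSet",
          function(x) union(x@downSet, x@upSet))

#' @rdname IntegratedNetwork-class
#' @param x object
#' @export
setMethod("totalArcs", "IntegratedNetwork",
          function(x) 2L * nrow(x@ppi) + nrow(x@reg))

#' @rdname IntegratedNetwork-class
#' @export
setMethod("networkStats", "IntegratedNetwork", function(x) {
  ppiNodes <- unique(c(x@ppi$a, x@ppi$b))
  regNodes <- unique(c(x@reg$tf, x@reg$target))
  stats <- data.frame(
    nProteinsConnected    = length(ppiNodes),
    nProteinsWithIsolates = length(ppiNodes) + length(x@isolated),
    nPPIEdges             = nrow(x@ppi),
    nRegGenes             = length(regNodes),
    nRegArcs              = nrow(x@reg),
    nNodesTotal           = length(x@nodes),
    nArcsTotal            = totalArcs(x)
  )
  stopifnot(stats$nArcsTotal == 2L * stats$nPPIEdges + stats$nRegArcs)
  stats
})

#' @rdname ModulePartition-class
#' @param x object
#' @export
setMethod("moduleAssignments", "ModulePartition", function(x) x@assignment)

#' @rdname ModulePartition-class
#' @export
setMethod("modularityValue", "ModulePartition", function(x) x@M)

## ---- show ----

setMethod("show", "FuzzyClustering", function(object) {
  cat("FuzzyClustering:", nrow(object@memberships), "proteins,",
      ncol(object@memberships), "clusters (m =", object@m, ")\n")
  cat("  objective:", signif(utils::tail(object@objective, 1), 6),
      "after", length(object@objective), "iterations",
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  cluster sizes:", paste(tabulate(object@hardLabels,
      nbins = ncol(object@memberships)), collapse = ", "), "\n")
})

setMethod("show", "ActiveProteinSet", function(object) {
  cat("ActiveProteinSet:", length(object@downSet), "down +",
      length(object@upSet), "up =",
      length(activeProteins(object)), "active proteins\n")
})

setMethod("show", "IntegratedNetwork", function(object) {
  cat("IntegratedNetwork",
      if (!is.na(object@threshold)) sprintf("(threshold %.2g)", object@threshold),
      "\n")
  cat(" ", length(object@nodes), "nodes (+", length(object@isolated),
      "isolated),", nrow(object@ppi), "PPI edges,", nrow(object@reg),
      "regulatory arcs;", totalArcs(object), "arcs total\n")
})

setMethod("show", "ModulePartition", function(object) {
  cat("ModulePartition:", length(object@assignment), "nodes in",
      length(unique(object@assignment)), "modules; M =",
      signif(object@M, 6), "\n")
})
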
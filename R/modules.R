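## Coerce edges (data.frame a/b, IntegratedNetwork PPI layer, or igraph) to
## an undirected simple igraph.
asUndirectedGraph <- function(x, nodes = NULL) {
  if (igraph::is_igraph(x)) return(x)
  if (methods::is(x, "IntegratedNetwork")) {
    nodes <- unique(c(x@nodes, nodes))
    x <- x@ppi
  }
  edges <- as.data.frame(x)[, 1:2]
  names(edges) <- c("a", "b")
  verts <- unique(c(edges$a, edges$b, as.character(nodes)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  igraph::simplify(g)
}

#' Largest connected component
#'
#' Node-induced subgraph of the maximum-cardinality connected component;
#' among equal-sized components the one containing the smallest node id wins.
#'
#' @param x edge data.frame (\code{a}, \code{b}), \linkS4class{IntegratedNetwork}
#'   (PPI layer) or igraph
#' @param nodes optional extra (possibly isolated) node ids
#' @return igraph subgraph
#' @export
largestComponent <- function(x, nodes = NULL) {
  g <- asUndirectedGraph(x, nodes)
  if (igraph::vcount(g) == 0) stop("empty graph")
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    minIds <- vapply(best, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), character(1))
    best <- best[order(minIds)[1]]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Newman-Girvan modularity of a partition
#'
#' Direct evaluation of \eqn{M = \sum_i (e_{ii} - a_i^2)} on an undirected
#' unweighted graph: \eqn{e_{ii}} is the fraction of edges with both ends in
#' module \eqn{i} and \eqn{a_i} the fraction of edge ends attached to it.
#'
#' @param graph igraph (or anything \code{\link{largestComponent}} accepts)
#' @param assignment named integer/character vector, module per node; must
#'   cover every node of the graph
#' @return numeric M
#' @export
modularityScore <- function(graph, assignment) {
  g <- asUndirectedGraph(graph)
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(assignment)))
    stop("assignment must cover every node: missing ",
         paste(utils::head(setdiff(nodes, names(assignment)), 5), collapse = ", "))
  comm <- assignment[nodes]
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  el <- igraph::as_edgelist(g)
  mods <- sort(unique(comm))
  inside <- vapply(mods, function(cc) {
    sum(comm[el[, 1]] == cc & comm[el[, 2]] == cc)
  }, numeric(1))
  degSum <- vapply(mods, function(cc) {
    sum(igraph::degree(g)[comm == cc])
  }, numeric(1))
  sum(inside / m - (degSum / (2 * m))^2)
}

#' Functional-module detection by simulated-annealing modularity maximization
#'
#' Stochastic search over partitions: single-node moves (including moves into
#' a fresh module) plus occasional pairwise module merges and random splits,
#' with Metropolis acceptance \eqn{\exp(\Delta M / T)} of worsening moves and
#' geometric cooling. The search starts from singleton modules; T0 is
#' calibrated so that about half of the initially worsening moves are
#' accepted. Returns the best partition seen, whose M is recomputed exactly
#' before return and is never below the one-module baseline of 0.
#'
#' @param graph connected undirected igraph (or edges acceptable to
#'   \code{\link{largestComponent}})
#' @param seed integer seed
#' @param cooling geometric cooling factor (default 0.995)
#' @param movesPerT node-move proposals per temperature (default
#'   \code{n^2}, capped at 20000)
#' @param stagnation stop after this many temperatures without improvement
#'   of the best M (default 50)
#' @param maxTemps hard cap on temperature steps (default 3000)
#' @return a \linkS4class{ModulePartition}
#' @export
annealModules <- function(graph, seed = 1L, cooling = 0.995,
                          movesPerT = NULL, stagnation = 50L,
                          maxTemps = 3000L) {
  g <- asUndirectedGraph(graph)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  if (n == 0) stop("empty graph")
  set.seed(as.integer(seed))
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  deg <- vapply(adj, length, integer(1))
  m <- igraph::ecount(g)
  if (is.null(movesPerT)) movesPerT <- min(n^2, 20000L)

  comm <- seq_len(n)                 # singleton start
  Lc <- numeric(2L * n)              # internal edges per module id
  Dc <- numeric(2L * n); Dc[seq_len(n)] <- deg
  M <- sum(Lc[seq_len(n)] / m) - sum((Dc / (2 * m))^2)

  linksTo <- function(v, cc) sum(comm[adj[[v]]] == cc)
  deltaMove <- function(v, c1, c2) {
    k1 <- linksTo(v, c1); k2 <- linksTo(v, c2)
    (k2 - k1) / m - deg[v] * (Dc[c2] - Dc[c1] + deg[v]) / (2 * m^2)
  }
  applyMove <- function(v, c1, c2) {
    k1 <- linksTo(v, c1); k2 <- linksTo(v, c2)
    Lc[c1] <<- Lc[c1] - k1; Lc[c2] <<- Lc[c2] + k2
    Dc[c1] <<- Dc[c1] - deg[v]; Dc[c2] <<- Dc[c2] + deg[v]
    comm[v] <<- c2
  }
  freeModule <- function() {
    empty <- which(Dc == 0)
    if (length(empty)) empty[1] else stop("module table exhausted")
  }

  # T0: accept about half of the worsening single-node moves at the start
  probes <- replicate(200, {
    v <- sample.int(n, 1)
    tgt <- comm[sample.int(n, 1)]
    if (tgt == comm[v]) NA_real_ else deltaMove(v, comm[v], tgt)
  })
  worsening <- probes[!is.na(probes) & probes < 0]
  T0 <- if (length(worsening)) mean(-worsening) / log(2) else 0.05
  Temp <- max(T0, 1e-8)

  best <- list(comm = comm, M = M)
  stagnant <- 0L
  for (step in seq_len(maxTemps)) {
    improvedAt <- best$M
    for (p in seq_len(movesPerT)) {
      v <- sample.int(n, 1)
      c1 <- comm[v]
      c2 <- if (stats::runif(1) < 0.1) freeModule() else comm[sample.int(n, 1)]
      if (c2 == c1) next
      dM <- deltaMove(v, c1, c2)
      if (dM >= 0 || stats::runif(1) < exp(dM / Temp)) {
        applyMove(v, c1, c2)
        M <- M + dM
      }
    }
    # occasional collective moves: merges and random splits
    mods <- which(Dc > 0)
    for (p in seq_len(max(2L, n %/% 2L))) {
      mods <- which(Dc > 0)
      if (stats::runif(1) < 0.5 && length(mods) >= 2) {      # merge
        pick <- sample(mods, 2)
        c1 <- pick[1]; c2 <- pick[2]
        members2 <- which(comm == c2)
        cross <- sum(vapply(members2, function(v) linksTo(v, c1), numeric(1)))
        dM <- cross / m - Dc[c1] * Dc[c2] / (2 * m^2)
        if (dM >= 0 || stats::runif(1) < exp(dM / Temp)) {
          Lc[c1] <- Lc[c1] + Lc[c2] + cross
          Dc[c1] <- Dc[c1] + Dc[c2]
          Lc[c2] <- 0; Dc[c2] <- 0
          comm[members2] <- c1
          M <- M + dM
        }
      } else {                                               # random split
        c1 <- if (length(mods) == 1) mods else sample(mods, 1)
        members <- which(comm == c1)
        if (length(members) < 2) next
        half <- sample(members, max(1, length(members) %/% 2))
        c2 <- freeModule()
        oldM <- M
        oldState <- list(comm = comm, Lc = Lc, Dc = Dc)
        for (v in half) applyMove(v, comm[v], c2)
        newM <- sum(Lc[Dc > 0] / m) - sum((Dc[Dc > 0] / (2 * m))^2)
        dM <- newM - oldM
        if (dM >= 0 || stats::runif(1) < exp(dM / Temp)) {
          M <- newM
        } else {
          comm <- oldState$comm; Lc <- oldState$Lc; Dc <- oldState$Dc
        }
      }
    }
    if (M > best$M + 1e-12) best <- list(comm = comm, M = M)
    stagnant <- if (best$M > improvedAt + 1e-12) 0L else stagnant + 1L
    if (stagnant >= stagnation || Temp < 1e-6) break
    Temp <- Temp * cooling
  }

  assignment <- stats::setNames(match(best$comm, sort(unique(best$comm))),
                                nodes)
  Mexact <- modularityScore(g, assignment)
  if (Mexact < 0) {                        # never worse than one module
    assignment[] <- 1L
    Mexact <- 0
  }
  methods::new("ModulePartition", assignment = as.integer(assignment) |>
                 stats::setNames(nodes), M = Mexact,
               schedule = list(T0 = T0, cooling = cooling,
                               movesPerT = movesPerT,
                               stagnation = stagnation, maxTemps = maxTemps,
                               seed = as.integer(seed)))
}
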
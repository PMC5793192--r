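## igraph view of the undirected PPI layer (connected nodes only).
ppiGraph <- function(network) {
  stopifnot(methods::is(network, "IntegratedNetwork"))
  edges <- network@ppi
  igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                vertices = unique(c(edges$a, edges$b)))
}

#' Degree and betweenness centrality of the active PPI layer
#'
#' Hubs are captured by degree (incident-edge count) and bottlenecks by
#' unweighted shortest-path betweenness (each unordered pair counted once,
#' endpoints excluded). Both are ranked with fractional (average) ranks, 1 =
#' most central, and combined as their mean -- the average-rank statistic used
#' to order candidate key proteins. Isolated nodes carry no centrality signal
#' and are excluded.
#'
#' @param network an \linkS4class{IntegratedNetwork} (the undirected PPI
#'   layer is used)
#' @return data.frame with columns \code{id}, \code{degree},
#'   \code{betweenness}, \code{degreeRank}, \code{betweennessRank},
#'   \code{avgRank}, ordered by \code{avgRank} (ties by id)
#' @export
computeCentralities <- function(network) {
  if (nrow(network@ppi) == 0) stop("network has no PPI edges")
  g <- ppiGraph(network)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  rec <- data.frame(id = names(deg), degree = as.integer(deg),
                    betweenness = as.numeric(btw))
  rec$degreeRank <- rank(-rec$degree, ties.method = "average")
  rec$betweennessRank <- rank(-rec$betweenness, ties.method = "average")
  rec$avgRank <- (rec$degreeRank + rec$betweennessRank) / 2
  rec <- rec[order(rec$avgRank, rec$id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Key-protein selection size from the top-percent rule
#'
#' \code{k = round(percent * nMin)}, floored at 1, where \code{nMin} is the
#' smallest node count (isolates included) across the thresholded network
#' series -- one k for all networks, for comparability.
#'
#' @param nMin smallest network size across the series
#' @param percent fraction selected (default 0.02)
#' @return integer k
#' @examples
#' selectionSize(1118)  # 22
#' @export
selectionSize <- function(nMin, percent = 0.02) {
  stopifnot(percent > 0, percent < 1, nMin >= 1)
  max(1L, as.integer(round(percent * nMin)))
}

#' Select the top-ranked key proteins of one network
#'
#' Orders the centrality records by average rank (ascending; residual ties by
#' id) and returns the first \code{k} ids.
#'
#' @param records output of \code{\link{computeCentralities}}
#' @param k number of key proteins; supply the shared
#'   \code{\link{selectionSize}} when comparing across networks
#' @return character vector of \code{k} ids in rank order
#' @export
rankAndSelect <- function(records, k) {
  if (k > nrow(records)) stop("k exceeds the number of ranked proteins")
  records <- records[order(records$avgRank, records$id), , drop = FALSE]
  utils::head(records$id, k)
}

#' Aggregate key proteins across the network series by frequency
#'
#' A protein's frequency is the number of per-network key lists containing
#' it. The table is sorted by frequency (descending), then mean within-list
#' rank (ascending), then id, and truncated to \code{topN}.
#'
#' @param keyLists named list of ordered key-protein character vectors, one
#'   per network
#' @param topN rows to keep (default all)
#' @return data.frame with \code{id}, \code{frequency}, \code{meanRank},
#'   \code{finalRank}
#' @export
aggregateFrequencies <- function(keyLists, topN = Inf) {
  stopifnot(length(keyLists) >= 1)
  ids <- sort(unique(unlist(keyLists)))
  if (!length(ids))
    return(data.frame(id = character(), frequency = integer(),
                      meanRank = numeric(), finalRank = integer()))
  freq <- vapply(ids, function(p)
    sum(vapply(keyLists, function(l) p %in% l, logical(1))), integer(1))
  meanRank <- vapply(ids, function(p) {
    pos <- unlist(lapply(keyLists, function(l) match(p, l)))
    mean(pos, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(id = ids, frequency = freq, meanRank = meanRank)
  out <- out[order(-out$frequency, out$meanRank, out$id), , drop = FALSE]
  if (is.finite(topN)) out <- utils::head(out, topN)
  out$finalRank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
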
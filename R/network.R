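#' Construct an integrated mixed network
#'
#' Low-level constructor used by the pipeline stages. Connected nodes are the
#' union of all edge/arc endpoints plus any ids in \code{nodes}; ids passed in
#' \code{isolated} that turn out to be endpoints are silently promoted to
#' connected nodes.
#'
#' @param ppi data.frame with columns \code{a}, \code{b}, \code{confidence}
#'   (confidence defaults to 1 when absent)
#' @param reg data.frame with columns \code{tf}, \code{target}
#' @param nodes additional connected node ids
#' @param isolated active proteins with no incident interaction
#' @param threshold confidence cutoff this network was built at
#' @return an \linkS4class{IntegratedNetwork}
#' @examples
#' net <- integratedNetwork(
#'   ppi = data.frame(a = "p1", b = "p2", confidence = 0.9),
#'   reg = data.frame(tf = "p1", target = "p3"))
#' totalArcs(net)  # 3
#' @export
integratedNetwork <- function(ppi = NULL, reg = NULL, nodes = character(),
                              isolated = character(), threshold = NA_real_) {
  if (is.null(ppi))
    ppi <- data.frame(a = character(), b = character(), confidence = numeric())
  if (is.null(reg))
    reg <- data.frame(tf = character(), target = character())
  ppi <- as.data.frame(ppi, stringsAsFactors = FALSE)
  reg <- as.data.frame(reg, stringsAsFactors = FALSE)
  if (!"confidence" %in% names(ppi) && nrow(ppi))
    ppi$confidence <- 1
  if (nrow(ppi)) {
    ppi$a <- as.character(ppi$a); ppi$b <- as.character(ppi$b)
    ppi <- dedupEdges(ppi)
  }
  if (nrow(reg)) {
    reg$tf <- as.character(reg$tf); reg$target <- as.character(reg$target)
    dup <- duplicated(paste(reg$tf, reg$target), fromLast = TRUE)
    if (any(dup)) {
      warning(sum(dup), " duplicate regulatory arc(s) dropped (last kept)")
      reg <- reg[!dup, , drop = FALSE]
    }
  }
  endpoints <- unique(c(ppi$a, ppi$b, reg$tf, reg$target))
  allNodes <- unique(c(endpoints, as.character(nodes)))
  isolated <- setdiff(unique(as.character(isolated)), allNodes)
  rownames(ppi) <- NULL; rownames(reg) <- NULL
  methods::new("IntegratedNetwork", nodes = allNodes, ppi = ppi, reg = reg,
               isolated = isolated, threshold = as.numeric(threshold))
}

## Last occurrence of a duplicated unordered pair wins.
dedupEdges <- function(edges) {
  key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate PPI pair(s) dropped (last kept)")
    edges <- edges[!dup, , drop = FALSE]
  }
  loops <- edges$a == edges$b
  if (any(loops)) {
    warning(sum(loops), " self-interaction(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  edges
}

#' Filter scored interactions by confidence
#'
#' Keeps edges whose confidence is greater than or equal to the threshold
#' (inclusive cutoff, matching the medium/high/highest STRING convention of
#' 0.4/0.7/0.9). Results at a higher threshold are always a subset of results
#' at a lower one.
#'
#' @param edges data.frame with columns \code{a}, \code{b}, \code{confidence}
#' @param threshold numeric in [0, 1]
#' @return the retained rows of \code{edges}
#' @examples
#' e <- data.frame(a = c("x", "x"), b = c("y", "z"), confidence = c(0.3, 0.8))
#' filterByConfidence(e, 0.5)
#' @export
filterByConfidence <- function(edges, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  out <- edges[edges$confidence >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Induce the active-protein subnetwork
#'
#' Restricts a background interaction list to edges whose both endpoints are
#' active. Active proteins left without any retained interaction are recorded
#' as isolates rather than dropped, so network size can be reported with and
#' without them.
#'
#' @param background data.frame of scored edges (\code{a}, \code{b},
#'   \code{confidence})
#' @param active an \linkS4class{ActiveProteinSet} or a character vector of ids
#' @param threshold recorded on the result for bookkeeping
#' @return an \linkS4class{IntegratedNetwork} holding only the PPI layer
#' @export
induceActiveSubnetwork <- function(background, active, threshold = NA_real_) {
  if (methods::is(active, "ActiveProteinSet"))
    active <- activeProteins(active)
  active <- unique(as.character(active))
  if (methods::is(background, "IntegratedNetwork"))
    background <- background@ppi
  keep <- background$a %in% active & background$b %in% active
  edges <- background[keep, , drop = FALSE]
  connected <- unique(c(edges$a, edges$b))
  integratedNetwork(ppi = edges, isolated = setdiff(active, connected),
                    threshold = threshold)
}

#' Extract the active regulatory arcs
#'
#' Keeps regulatory arcs whose TF and target are both members of the active
#' network (connected nodes plus isolated actives). The both-endpoints rule is
#' the default; \code{rule = "either"} keeps arcs with at least one member
#' endpoint.
#'
#' @param arcs data.frame with columns \code{tf}, \code{target}
#' @param network an \linkS4class{IntegratedNetwork} or a character vector of
#'   node ids
#' @param rule \code{"both"} (default) or \code{"either"}
#' @return the retained rows of \code{arcs}
#' @export
extractActiveRegulon <- function(arcs, network, rule = c("both", "either")) {
  rule <- match.arg(rule)
  ids <- if (methods::is(network, "IntegratedNetwork"))
    c(network@nodes, network@isolated) else as.character(network)
  inTf <- arcs$tf %in% ids
  inTg <- arcs$target %in% ids
  keep <- if (rule == "both") inTf & inTg else inTf | inTg
  out <- arcs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integrate the PPI and regulatory layers
#'
#' Merges an active PPI network with its active regulatory arcs over a shared
#' node set. The layers are kept distinct: a pair connected in both layers is
#' not deduplicated, and the arc accounting is
#' \code{totalArcs = 2 * nPPI + nReg} (each undirected interaction counts as
#' two directed arcs).
#'
#' @param ppiNet an \linkS4class{IntegratedNetwork} (PPI layer)
#' @param arcs data.frame of regulatory arcs (\code{tf}, \code{target})
#' @return an \linkS4class{IntegratedNetwork}
#' @examples
#' ppi <- integratedNetwork(ppi = data.frame(a = "p1", b = "p2",
#'                                           confidence = 0.7))
#' net <- integrateNetworks(ppi, data.frame(tf = "p3", target = "p1"))
#' totalArcs(net)  # 2 * 1 + 1
#' @export
integrateNetworks <- function(ppiNet, arcs) {
  stopifnot(methods::is(ppiNet, "IntegratedNetwork"))
  integratedNetwork(ppi = ppiNet@ppi, reg = arcs,
                    isolated = ppiNet@isolated, threshold = ppiNet@threshold)
}

#' Build the thresholded active network series
#'
#' Convenience wrapper running confidence filtering, active-subnetwork
#' induction, active-regulon extraction and layer integration for each
#' threshold, as done across the 0.4-0.9 confidence series.
#'
#' @param edges background scored edge data.frame
#' @param arcs regulatory arc data.frame
#' @param active \linkS4class{ActiveProteinSet} or character vector
#' @param thresholds numeric vector of confidence cutoffs
#' @return named list of \linkS4class{IntegratedNetwork}, one per threshold
#' @export
buildNetworkSeries <- function(edges, arcs, active,
                               thresholds = seq(0.4, 0.9, by = 0.1)) {
  stopifnot(all(thresholds >= 0 & thresholds <= 1))
  nets <- lapply(thresholds, function(t) {
    bg <- filterByConfidence(edges, t)
    net <- induceActiveSubnetwork(bg, active, threshold = t)
    activeArcs <- extractActiveRegulon(arcs, net)
    integrateNetworks(net, activeArcs)
  })
  names(nets) <- sprintf("CS_%.1f", thresholds)
  nets
}
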
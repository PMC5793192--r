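## Structural definitions of the named 3-node classes of the mixed graph
## (PPI edge = mutual arc pair, regulatory arc = single arc). Local node ids
## 1..3. Covers all 13 connected mixed triad classes.
triadPatterns <- list(
  "Co-regulated PPI" = list(
    ppi = data.frame(a = 2L, b = 3L),
    reg = data.frame(tf = c(1L, 1L), target = c(2L, 3L))),
  "Protein Clique" = list(
    ppi = data.frame(a = c(1L, 1L, 2L), b = c(2L, 3L, 3L)),
    reg = data.frame(tf = integer(), target = integer())),
  "Co-regulated Proteins" = list(
    ppi = data.frame(a = integer(), b = integer()),
    reg = data.frame(tf = c(1L, 1L), target = c(2L, 3L))),
  "PPI Regulating" = list(
    ppi = data.frame(a = 1L, b = 2L),
    reg = data.frame(tf = 1L, target = 3L)),
  "Bi-feedforward Loop" = list(
    ppi = data.frame(a = 1L, b = 2L),
    reg = data.frame(tf = c(1L, 2L), target = c(3L, 3L))),
  "Regulatory Cascade with a Feedback" = list(
    ppi = data.frame(a = integer(), b = integer()),
    reg = data.frame(tf = c(1L, 2L, 3L), target = c(2L, 3L, 1L))),
  "Regulated PPI" = list(
    ppi = data.frame(a = 2L, b = 3L),
    reg = data.frame(tf = 1L, target = 2L)),
  "Feedback with a PPI" = list(
    ppi = data.frame(a = 1L, b = 2L),
    reg = data.frame(tf = c(2L, 3L), target = c(3L, 1L))),
  "Bi-regulated Protein" = list(
    ppi = data.frame(a = integer(), b = integer()),
    reg = data.frame(tf = c(1L, 2L), target = c(3L, 3L))),
  "Regulatory Cascade" = list(
    ppi = data.frame(a = integer(), b = integer()),
    reg = data.frame(tf = c(1L, 2L), target = c(2L, 3L))),
  "PPI Path" = list(
    ppi = data.frame(a = c(1L, 2L), b = c(2L, 3L)),
    reg = data.frame(tf = integer(), target = integer())),
  "PPI Path with Regulation" = list(
    ppi = data.frame(a = c(1L, 1L), b = c(2L, 3L)),
    reg = data.frame(tf = 2L, target = 3L)),
  "Feedforward Loop" = list(
    ppi = data.frame(a = integer(), b = integer()),
    reg = data.frame(tf = c(1L, 1L, 2L), target = c(2L, 3L, 3L)))
)

## Pair states (ab, ac, bc) of a 3-node pattern given its local edges/arcs.
patternStates <- function(pat) {
  pairIdx <- rbind(c(1, 2), c(1, 3), c(2, 3))
  vapply(seq_len(3), function(k) {
    u <- pairIdx[k, 1]; v <- pairIdx[k, 2]
    mutual <- any(pmin(pat$ppi$a, pat$ppi$b) == u &
                  pmax(pat$ppi$a, pat$ppi$b) == v)
    fwd <- any(pat$reg$tf == u & pat$reg$target == v)
    bwd <- any(pat$reg$tf == v & pat$reg$target == u)
    if (mutual || (fwd && bwd)) 3L else if (fwd) 1L else if (bwd) 2L else 0L
  }, integer(1))
}

triadCodeCache <- new.env(parent = emptyenv())

triadCodeTable <- function() {
  if (!is.null(triadCodeCache$table)) return(triadCodeCache$table)
  codes <- vapply(triadPatterns, function(pat) {
    s <- patternStates(pat)
    cpp_canonical_code(s[1], s[2], s[3])
  }, integer(1))
  stopifnot(!anyDuplicated(codes))
  tab <- data.frame(code = unname(codes), name = names(codes))
  triadCodeCache$table <- tab
  tab
}

#' Canonical codes and display names of the connected mixed triad classes
#'
#' The 13 isomorphism classes of connected 3-node mixed graphs, where a PPI
#' edge is a mutual arc pair and a regulatory arc a single arc. The canonical
#' code is the minimum, over vertex orderings, of the base-4 encoding of the
#' three pair states (0 none / 1 forward / 2 backward / 3 mutual).
#'
#' @return data.frame with columns \code{code} and \code{name}
#' @export
triadClassNames <- function() triadCodeTable()

## Resolve a class given by display name or canonical code.
triadPattern <- function(class) {
  tab <- triadCodeTable()
  if (is.character(class) && class %in% tab$name)
    return(c(triadPatterns[[class]], list(name = class)))
  if (is.numeric(class) && class %in% tab$code) {
    nm <- tab$name[match(class, tab$code)]
    return(c(triadPatterns[[nm]], list(name = nm)))
  }
  stop("unknown triad class: ", class)
}

## Integer-indexed mixed-layer view of an IntegratedNetwork for the C++
## kernels. Hybrid pairs (PPI and regulatory on the same pair) keep the PPI
## edge and drop the arc(s) (logged); opposing arc pairs are promoted to the
## mutual layer.
asMixedIndices <- function(network, quiet = TRUE) {
  nodes <- network@nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  ea <- idx[network@ppi$a]; eb <- idx[network@ppi$b]
  at <- idx[network@reg$tf]; ah <- idx[network@reg$target]
  ppiKey <- paste(pmin(ea, eb), pmax(ea, eb))
  arcKey <- paste(pmin(at, ah), pmax(at, ah))
  hybrid <- arcKey %in% ppiKey
  if (any(hybrid)) {
    if (!quiet)
      message(sum(hybrid), " regulatory arc(s) on PPI-connected pairs ",
              "treated as PPI (", signif(mean(hybrid), 3), " of arcs)")
    at <- at[!hybrid]; ah <- ah[!hybrid]; arcKey <- arcKey[!hybrid]
  }
  opposing <- arcKey %in% arcKey[duplicated(arcKey)]
  if (any(opposing)) {
    pairKeys <- unique(arcKey[opposing])
    for (k in pairKeys) {
      w <- which(arcKey == k)
      ea <- c(ea, at[w[1]]); eb <- c(eb, ah[w[1]])
    }
    at <- at[!opposing]; ah <- ah[!opposing]
  }
  list(ea = unname(ea), eb = unname(eb), at = unname(at), ah = unname(ah),
       n = length(nodes), nodes = nodes,
       nHybrid = sum(hybrid))
}

#' Classify one 3-node mixed subgraph
#'
#' @param network an \linkS4class{IntegratedNetwork} with exactly 3 nodes
#' @return list with \code{code} (canonical) and \code{name} (display name)
#' @examples
#' tri <- integratedNetwork(
#'   ppi = data.frame(a = "y", b = "z", confidence = 1),
#'   reg = data.frame(tf = c("x", "x"), target = c("y", "z")))
#' classifyTriad(tri)$name  # "Co-regulated PPI"
#' @export
classifyTriad <- function(network) {
  stopifnot(methods::is(network, "IntegratedNetwork"))
  if (length(network@nodes) != 3L)
    stop("classifyTriad expects exactly 3 nodes")
  m <- asMixedIndices(network)
  state <- function(u, v) {
    mut <- any((m$ea == u & m$eb == v) | (m$ea == v & m$eb == u))
    fwd <- any(m$at == u & m$ah == v)
    bwd <- any(m$at == v & m$ah == u)
    if (mut || (fwd && bwd)) 3L else if (fwd) 1L else if (bwd) 2L else 0L
  }
  s <- c(state(1, 2), state(1, 3), state(2, 3))
  if (sum(s > 0) < 2) stop("triad is disconnected")
  code <- cpp_canonical_code(s[1], s[2], s[3])
  tab <- triadCodeTable()
  list(code = code,
       name = if (code %in% tab$code) tab$name[match(code, tab$code)]
              else sprintf("Triad_%02d", code))
}

#' Census of connected 3-node subgraphs
#'
#' Enumerates every connected induced 3-node subgraph of the mixed graph
#' exactly once and tallies it by canonical triad class.
#'
#' @param network an \linkS4class{IntegratedNetwork}
#' @return data.frame with \code{code}, \code{name}, \code{count}, sorted by
#'   decreasing count; the number of hybrid pairs resolved to the PPI layer
#'   is attached as attribute \code{nHybrid}
#' @export
triadCensus <- function(network) {
  m <- asMixedIndices(network, quiet = FALSE)
  res <- cpp_triad_census(m$ea, m$eb, m$at, m$ah, m$n)
  tab <- triadCodeTable()
  nm <- ifelse(res$code %in% tab$code,
               tab$name[match(res$code, tab$code)],
               sprintf("Triad_%02d", res$code))
  out <- data.frame(code = res$code, name = nm, count = as.numeric(res$count))
  out <- out[order(-out$count, out$code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nHybrid") <- m$nHybrid
  out
}

#' Degree-preserving switching randomization of a mixed graph
#'
#' Regulatory arcs are switched only with regulatory arcs and PPI edges only
#' with PPI edges, so every node keeps its exact (single-in, single-out,
#' mutual) degree triple; proposals creating self-loops, duplicates, or
#' merging the two layers on one pair are skipped.
#'
#' @param network an \linkS4class{IntegratedNetwork}
#' @param nAttempts number of swap attempts (default
#'   \code{100 * (nPPI + nReg)})
#' @return a rewired \linkS4class{IntegratedNetwork}
#' @export
randomizeNetwork <- function(network, nAttempts = NULL) {
  m <- asMixedIndices(network)
  if (is.null(nAttempts))
    nAttempts <- 100L * (length(m$ea) + length(m$at))
  res <- cpp_rewire_mixed(m$ea, m$eb, m$at, m$ah, m$n, as.integer(nAttempts))
  integratedNetwork(
    ppi = data.frame(a = m$nodes[res$ea], b = m$nodes[res$eb],
                     confidence = rep(1, length(res$ea))),
    reg = data.frame(tf = m$nodes[res$at], target = m$nodes[res$ah]),
    nodes = m$nodes, isolated = network@isolated,
    threshold = network@threshold)
}

#' Proteins involved in instances of given motif classes
#'
#' Collects the nodes participating in at least one connected 3-node induced
#' subgraph of any of the given classes (e.g. the exclusive active motifs).
#'
#' @param network an \linkS4class{IntegratedNetwork}
#' @param classes display names or canonical codes
#' @return character vector of node ids
#' @export
motifProteins <- function(network, classes) {
  tab <- triadCodeTable()
  codes <- vapply(classes, function(cl) {
    if (is.character(cl) && cl %in% tab$name) tab$code[match(cl, tab$name)]
    else if (suppressWarnings(!is.na(as.numeric(cl)))) as.integer(cl)
    else stop("unknown triad class: ", cl)
  }, integer(1))
  m <- asMixedIndices(network)
  idx <- cpp_triad_members(m$ea, m$eb, m$at, m$ah, m$n, codes)
  m$nodes[idx]
}

#' Motif significance against switching nulls
#'
#' Runs the triad census on the real network and on \code{nRandom}
#' independent switching randomizations, then scores each class by
#' \eqn{z = (real - mean_{null}) / sd_{null}} and the one-sided empirical
#' over-representation p-value (fraction of null counts >= real). Classes
#' absent from the real network and every null are omitted.
#'
#' @param network an \linkS4class{IntegratedNetwork}
#' @param nRandom number of randomizations (>= 2; default 1000)
#' @param nAttempts swap attempts per randomization (default
#'   \code{100 * (nPPI + nReg)})
#' @param seed integer seed
#' @return data.frame with \code{code}, \code{name}, \code{realCount},
#'   \code{nullMean}, \code{nullSd}, \code{z}, \code{pOver}, \code{pUnder},
#'   \code{nRandom}; \code{z} is \code{Inf}/\code{-Inf} when
#'   \code{nullSd = 0} and the real count differs from the null mean
#' @export
motifSignificance <- function(network, nRandom = 1000L, nAttempts = NULL,
                              seed = 1L) {
  stopifnot(nRandom >= 2)
  set.seed(as.integer(seed))
  m <- asMixedIndices(network)
  if (is.null(nAttempts))
    nAttempts <- 100L * (length(m$ea) + length(m$at))
  real <- cpp_triad_census(m$ea, m$eb, m$at, m$ah, m$n)
  nullCounts <- vector("list", nRandom)
  for (r in seq_len(nRandom)) {
    rw <- cpp_rewire_mixed(m$ea, m$eb, m$at, m$ah, m$n,
                           as.integer(nAttempts))
    nullCounts[[r]] <- cpp_triad_census(rw$ea, rw$eb, rw$at, rw$ah, m$n)
  }
  codes <- sort(unique(c(real$code,
                         unlist(lapply(nullCounts, `[[`, "code")))))
  nullMat <- vapply(nullCounts, function(cc) {
    out <- numeric(length(codes))
    out[match(cc$code, codes)] <- cc$count
    out
  }, numeric(length(codes)))
  nullMat <- matrix(nullMat, nrow = length(codes))
  realCount <- numeric(length(codes))
  realCount[match(real$code, codes)] <- real$count
  nullMean <- rowMeans(nullMat)
  nullSd <- apply(nullMat, 1, stats::sd)
  z <- ifelse(nullSd > 0, (realCount - nullMean) / nullSd,
              ifelse(realCount == nullMean, 0, Inf * sign(realCount - nullMean)))
  pOver <- rowMeans(nullMat >= realCount)
  pUnder <- rowMeans(nullMat <= realCount)
  tab <- triadCodeTable()
  nm <- ifelse(codes %in% tab$code, tab$name[match(codes, tab$code)],
               sprintf("Triad_%02d", codes))
  out <- data.frame(code = codes, name = nm, realCount = realCount,
                    nullMean = nullMean, nullSd = nullSd, z = z,
                    pOver = pOver, pUnder = pUnder, nRandom = nRandom)
  out <- out[order(-out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call active and exclusive motifs across the network series
#'
#' A class is an active motif when it is significant (z above \code{zThr},
#' over-representation p below \code{pThr}) in at least \code{quorum} of the
#' thresholded networks; exclusive motifs are the active ones not on the
#' supplied conserved-class list.
#'
#' @param statsList list of \code{\link{motifSignificance}} tables (or of
#'   character vectors of already-significant class identifiers), one per
#'   network
#' @param conserved character/numeric vector of conserved class identifiers
#' @param quorum minimum number of networks (default 5 of 6)
#' @param zThr,pThr significance cutoffs (defaults 2 and 0.05)
#' @return list with \code{active}, \code{conserved}, \code{exclusive} and
#'   the per-class significance count \code{times}
#' @export
callMotifs <- function(statsList, conserved, quorum = 5L, zThr = 2,
                       pThr = 0.05) {
  stopifnot(quorum <= length(statsList))
  sigSets <- lapply(statsList, function(s) {
    if (is.data.frame(s)) {
      key <- if ("name" %in% names(s)) s$name else s$code
      as.character(key[s$z > zThr & s$pOver < pThr])
    } else as.character(s)
  })
  all <- sort(unique(unlist(sigSets)))
  times <- vapply(all, function(cl)
    sum(vapply(sigSets, function(s) cl %in% s, logical(1))), integer(1))
  active <- all[times >= quorum]
  conserved <- as.character(conserved)
  list(active = active, conserved = conserved,
       exclusive = setdiff(active, conserved), times = times)
}
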
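#' Hypergeometric over-representation test
#'
#' For each annotation term, tests whether the query set contains more term
#' members than expected from sampling without replacement from the
#' background: \eqn{p = P[X \ge k]} with \eqn{X \sim}
#' Hypergeom(\eqn{N, K, n}). Term membership is intersected with the
#' background first. Terms smaller than \code{minSize} or larger than
#' \code{maxFrac} of the background are skipped (reported with
#' \code{skipped = TRUE}).
#'
#' @param query character vector, must be a subset of \code{background}
#' @param annotations named list of term member id vectors (GMT-style)
#' @param background character vector, the statistical universe
#' @param minSize,maxFrac term-size guards (defaults 2 and 0.8)
#' @return data.frame with \code{term}, \code{k}, \code{K}, \code{n},
#'   \code{N}, \code{p}, \code{fdr}, \code{skipped}, sorted by \code{fdr}
#'   then \code{p} (skipped terms last, with \code{NA} statistics)
#' @export
hypergeomEnrich <- function(query, annotations, background,
                            minSize = 2L, maxFrac = 0.8) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  bad <- setdiff(query, background)
  if (length(bad))
    stop("query ids missing from background: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...")
  N <- length(background); n <- length(query)
  rows <- lapply(names(annotations), function(term) {
    members <- intersect(unique(annotations[[term]]), background)
    K <- length(members)
    if (K < minSize || K > maxFrac * N)
      return(data.frame(term = term, k = NA_integer_, K = K, n = n, N = N,
                        p = NA_real_, skipped = TRUE))
    k <- length(intersect(query, members))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  tested <- !out$skipped
  if (any(tested)) out$fdr[tested] <- bhFdr(out$p[tested])
  out <- out[order(out$skipped, out$fdr, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH FDR: \code{adj_j = min_{i >= j} p_(i) * m / i}, capped at 1,
#' returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted values, same length and order
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Category proportion in a query set versus the genome
#'
#' Compares the share of a category (say, EET proteins or signal proteins)
#' within a query set to its share in the whole-genome background.
#'
#' @param query character vector of ids
#' @param categoryMembers character vector, subset of \code{genome}
#' @param genome character vector, the background universe
#' @param label category label carried through to the output
#' @return one-row data.frame with counts, the two proportions and their
#'   ratio (\code{NaN} when the genome proportion is 0)
#' @export
proportionCompare <- function(query, categoryMembers, genome,
                              label = "category") {
  query <- unique(as.character(query))
  genome <- unique(as.character(genome))
  categoryMembers <- unique(as.character(categoryMembers))
  if (!length(query) || !length(genome)) stop("empty query or genome")
  if (length(setdiff(categoryMembers, genome)))
    stop("categoryMembers must be a subset of genome")
  qHit <- length(intersect(query, categoryMembers))
  qProp <- qHit / length(query)
  gProp <- length(categoryMembers) / length(genome)
  data.frame(label = label,
             queryCount = qHit, querySize = length(query),
             queryProportion = qProp,
             genomeCount = length(categoryMembers),
             genomeSize = length(genome),
             genomeProportion = gProp,
             ratio = qProp / gProp)
}
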
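## Coerce an expression container to a plain matrix (proteins x 6 samples).
asAbundanceMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x)
  x <- as.matrix(x)
  if (ncol(x) != 6L)
    stop("expression matrix must have exactly 6 sample columns")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("P%04d", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("protein ids must be unique")
  x
}

#' Remove never-expressed proteins
#'
#' Drops rows whose abundance is exactly zero in all six samples (protein
#' copies = 0 throughout); row order of the remainder is preserved.
#'
#' @param x \code{SummarizedExperiment} or matrix, proteins x 6 samples
#' @return object of the same class with all-zero rows removed
#' @examples
#' m <- rbind(p1 = rep(0, 6), p2 = c(0, 0, 0, 0, 0, 1))
#' filterUnexpressed(m)  # keeps p2 only
#' @export
filterUnexpressed <- function(x) {
  mat <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x) else as.matrix(x)
  keep <- rowSums(mat != 0) > 0
  x[keep, , drop = FALSE]
}

#' Row-standardize expression trajectories
#'
#' Scales every trajectory to mean 0 and standard deviation 1, the canonical
#' preprocessing of soft clustering on expression profiles (shape, not level,
#' drives the clusters). Constant rows cannot be standardized and are dropped
#' with a warning.
#'
#' @param x \code{SummarizedExperiment} or matrix with no all-zero rows
#' @return matrix of standardized trajectories
#' @export
standardizeProfiles <- function(x) {
  mat <- asAbundanceMatrix(x)
  sds <- apply(mat, 1, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) dropped before standardization")
    mat <- mat[!const, , drop = FALSE]
    sds <- sds[!const]
  }
  (mat - rowMeans(mat)) / sds
}

## k-means++-style seeding: spread the initial centroids out by sampling
## points with probability proportional to squared distance from the
## nearest centre chosen so far.
kmeansppInit <- function(mat, c) {
  n <- nrow(mat)
  centers <- matrix(NA_real_, c, ncol(mat))
  centers[1, ] <- mat[sample.int(n, 1), ]
  d2 <- colSums((t(mat) - centers[1, ])^2)
  for (k in seq_len(c - 1) + 1) {
    prob <- d2 / sum(d2)
    centers[k, ] <- mat[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, colSums((t(mat) - centers[k, ])^2))
  }
  centers
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means on Euclidean distance: memberships
#' \eqn{u_{ij} \propto (1/d_{ij}^2)^{1/(m-1)}} normalized per protein,
#' centroids as \eqn{u^m}-weighted means, alternated until the objective
#' \eqn{J = \sum_{ij} u_{ij}^m d_{ij}^2} changes by less than \code{tol}.
#' Defaults (\code{c = 4}, \code{m = 1.5}) match the standard soft-clustering
#' settings for six-sample expression trajectories.
#'
#' @param x standardized matrix (or \code{SummarizedExperiment}; rows are
#'   standardized internally when their sd is not already 1)
#' @param c number of clusters (>= 2)
#' @param m fuzzifier (> 1)
#' @param maxIter iteration cap
#' @param tol convergence tolerance on the objective decrease
#' @param seed integer seed for the k-means++-style initialization
#' @param nstart independent restarts; the run with the lowest final
#'   objective is returned (default 5)
#' @return a \linkS4class{FuzzyClustering}
#' @export
fuzzyCMeans <- function(x, c = 4, m = 1.5, maxIter = 1000L, tol = 1e-6,
                        seed = 1L, nstart = 5L) {
  stopifnot(nstart >= 1)
  fits <- lapply(seq_len(nstart), function(i)
    fuzzyCMeansOnce(x, c = c, m = m, maxIter = maxIter, tol = tol,
                    seed = as.integer(seed) + (i - 1L) * 1009L))
  objs <- vapply(fits, function(f) utils::tail(f@objective, 1), numeric(1))
  fits[[which.min(objs)]]
}

fuzzyCMeansOnce <- function(x, c, m, maxIter, tol, seed) {
  stopifnot(c >= 2, m > 1)
  mat <- if (is.matrix(x)) x else asAbundanceMatrix(x)
  if (c > nrow(mat)) stop("more clusters than proteins")
  set.seed(as.integer(seed))
  centers <- kmeansppInit(mat, c)
  expo <- 1 / (m - 1)
  objective <- numeric(0)
  u <- NULL
  for (iter in seq_len(maxIter)) {
    d2 <- vapply(seq_len(c),
                 function(k) colSums((t(mat) - centers[k, ])^2),
                 numeric(nrow(mat)))                    # n x c
    w <- (1 / pmax(d2, 1e-12))^expo
    u <- w / rowSums(w)
    exact <- d2 < 1e-12                     # point sits on a centroid
    hit <- rowSums(exact) > 0
    if (any(hit))
      u[hit, ] <- exact[hit, , drop = FALSE] / rowSums(exact)[hit]
    um <- u^m
    objective <- c(objective, sum(um * d2))
    centers <- (t(um) %*% mat) / colSums(um)
    if (iter > 1 &&
        abs(objective[iter - 1] - objective[iter]) < tol) break
  }
  converged <- iter < maxIter ||
    (iter > 1 && abs(objective[iter - 1] - objective[iter]) < tol)
  if (!converged) warning("fuzzy c-means did not converge in ", maxIter,
                          " iterations")
  hard <- apply(u, 1, which.max)   # which.max takes the lowest index on ties
  colnames(centers) <- colnames(mat)
  rownames(centers) <- paste0("cluster", seq_len(c))
  dimnames(u) <- list(rownames(mat), rownames(centers))
  methods::new("FuzzyClustering", memberships = u, centroids = centers,
               hardLabels = stats::setNames(as.integer(hard), rownames(mat)),
               objective = objective, m = m, converged = converged,
               seed = as.integer(seed))
}

#' Identify the sharp-transition (active) clusters
#'
#' A cluster is "sharp" when the S3 to S4 step of its centroid is both its
#' largest consecutive step and at least \code{sharpRatio} times larger than
#' any other consecutive step -- the signature of the aerobic-to-anaerobic
#' transition between the last high-O2 and the first low-O2 sample. Proteins
#' of sharp clusters with a negative step form the down set, positive the up
#' set (hard labels).
#'
#' @param fit a \linkS4class{FuzzyClustering}
#' @param sharpRatio multiple by which the S3 to S4 step must exceed the
#'   largest other consecutive step (default 2)
#' @return an \linkS4class{ActiveProteinSet}
#' @export
identifyActiveClusters <- function(fit, sharpRatio = 2) {
  cen <- centroids(fit)
  steps <- t(apply(cen, 1, diff))          # c x 5 consecutive steps
  s34 <- steps[, 3]
  maxOther <- apply(abs(steps[, -3, drop = FALSE]), 1, max)
  sharp <- abs(s34) >= maxOther & abs(s34) > sharpRatio * maxOther
  if (!any(sharp & s34 < 0) || !any(sharp & s34 > 0)) {
    stepTxt <- paste(sprintf("cluster %d: S3->S4 %.3f, max other %.3f",
                             seq_len(nrow(cen)), s34, maxOther),
                     collapse = "; ")
    stop("no sharp decreasing and/or increasing cluster found (",
         stepTxt, "); consider lowering sharpRatio")
  }
  labels <- hardLabels(fit)
  downCl <- which(sharp & s34 < 0)
  upCl <- which(sharp & s34 > 0)
  methods::new("ActiveProteinSet",
               downSet = names(labels)[labels %in% downCl],
               upSet = names(labels)[labels %in% upCl])
}
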
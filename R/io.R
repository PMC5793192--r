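#' Read a six-sample expression table
#'
#' Tab-separated with header \code{protein_id, S1..S6}; returns the standard
#' expression container with high/low-oxygen phase labels on the columns.
#'
#' @param path TSV file
#' @return \code{SummarizedExperiment} with assay \code{abundance}
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "protein_id") || ncol(df) != 7L)
    stop("expected columns: protein_id, S1..S6")
  mat <- as.matrix(df[, -1])
  rownames(mat) <- df$protein_id
  if (anyDuplicated(df$protein_id)) stop("duplicate protein ids")
  if (any(mat < 0)) stop("abundances must be non-negative")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = mat),
    colData = S4Vectors::DataFrame(
      phase = rep(c("high_O2", "low_O2"), each = 3),
      row.names = colnames(mat)))
}

#' @rdname readExpressionTSV
#' @param se \code{SummarizedExperiment} or matrix
#' @export
writeExpressionTSV <- function(se, path) {
  mat <- asAbundanceMatrix(se)
  df <- data.frame(protein_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scored interaction edge list
#'
#' Tab-separated \code{protein_a, protein_b, confidence}. Both score dialects
#' are accepted: real scores in [0, 1], or STRING-style integer combined
#' scores in 0-999 which are divided by 1000 (auto-detected per file from the
#' score range).
#'
#' @param path TSV file
#' @return data.frame with columns \code{a}, \code{b}, \code{confidence}
#' @export
readEdgeTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("a", "b", "confidence")
  conf <- as.numeric(df$confidence)
  if (any(conf > 1)) {
    if (any(conf != round(conf)) || any(conf > 999))
      stop("scores must be either reals in [0,1] or integers in 0-999")
    conf <- conf / 1000
  }
  if (any(conf < 0 | conf > 1)) stop("confidence out of range")
  df$confidence <- conf
  df[, c("a", "b", "confidence")]
}

#' Read / write a directed regulatory arc list
#'
#' Tab-separated \code{tf, target}.
#'
#' @param path TSV file
#' @return data.frame with columns \code{tf}, \code{target}
#' @export
readArcTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("tf", "target")
  df[, c("tf", "target")]
}

#' Read a GMT annotation file
#'
#' Standard GMT: one term per line, tab-separated name, description, members.
#'
#' @param path GMT file
#' @return named list of member id vectors
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname readGMT
#' @param terms named list of member id vectors
#' @param description second-column text (recycled)
#' @export
writeGMT <- function(terms, path, description = "na") {
  lines <- vapply(names(terms), function(nm)
    paste(c(nm, description, terms[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-id-per-line protein list
#'
#' @param path text file
#' @return character vector
#' @export
readIdList <- function(path) {
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}
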
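#' @import methods
NULL

#' Total arc count of an integrated network
#'
#' An undirected protein-protein interaction edge contributes two directed
#' arcs; a regulatory interaction contributes one.
#'
#' @param x an \linkS4class{IntegratedNetwork}
#' @return integer, \code{2 * nPPI + nReg}
#' @export
setGeneric("totalArcs", function(x) standardGeneric("totalArcs"))

#' Summary statistics of an integrated network
#'
#' @param x an \linkS4class{IntegratedNetwork}
#' @return one-row \code{data.frame} with columns \code{nProteinsConnected},
#'   \code{nProteinsWithIsolates}, \code{nPPIEdges}, \code{nRegGenes},
#'   \code{nRegArcs}, \code{nNodesTotal}, \code{nArcsTotal}
#' @export
setGeneric("networkStats", function(x) standardGeneric("networkStats"))

#' @rdname FuzzyClustering-class
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname FuzzyClustering-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname FuzzyClustering-class
#' @export
setGeneric("hardLabels", function(x) standardGeneric("hardLabels"))

#' @rdname ActiveProteinSet-class
#' @export
setGeneric("activeProteins", function(x) standardGeneric("activeProteins"))

#' @rdname ActiveProteinSet-class
#' @export
setGeneric("downSet", function(x) standardGeneric("downSet"))

#' @rdname ActiveProteinSet-class
#' @export
setGeneric("upSet", function(x) standardGeneric("upSet"))

#' @rdname ModulePartition-class
#' @export
setGeneric("moduleAssignments", function(x) standardGeneric("moduleAssignments"))

#' @rdname ModulePartition-class
#' @export
setGeneric("modularityValue", function(x) standardGeneric("modularityValue"))
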
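#' Accessors for fitted mixture objects and annotated experiments
#'
#' \code{alphaParams} returns the component-by-gene probability matrix,
#' \code{mixWeights} the mixing weights, \code{debrisIndex} the index of the
#' debris component, \code{posteriorProbs} the droplet-by-component posterior
#' matrix, and \code{emTrace} the per-iteration log-likelihood trace of a
#' \linkS4class{MultinomMixture}.  On a \linkS4class{DebrisExperiment},
#' \code{clusterAssignments}, \code{debrisScores} and \code{keptBarcodes}
#' return the hard component labels, the normalized debris scores, and the
#' barcodes called clean by the last filtering step.
#'
#' @param object,x a \linkS4class{MultinomMixture} or
#'   \linkS4class{DebrisExperiment}.
#' @return See the description of each accessor.
#' @name accessors
#' @examples
#' sim <- simulateDroplets(makeProfiles(nGenes = 50, nTypes = 2, seed = 1),
#'                         nEmpty = 100, nPerType = 20, seed = 1)
#' dropletStats(sim$experiment)[1:3, ]
NULL

#' @rdname accessors
#' @export
setGeneric("alphaParams", function(object) standardGeneric("alphaParams"))
#' @rdname accessors
#' @export
setGeneric("mixWeights", function(object) standardGeneric("mixWeights"))
#' @rdname accessors
#' @export
setGeneric("debrisIndex", function(object) standardGeneric("debrisIndex"))
#' @rdname accessors
#' @export
setGeneric("posteriorProbs", function(object) standardGeneric("posteriorProbs"))
#' @rdname accessors
#' @export
setGeneric("emTrace", function(object) standardGeneric("emTrace"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setGeneric("debrisScores", function(x) standardGeneric("debrisScores"))
#' @rdname accessors
#' @export
setGeneric("keptBarcodes", function(x) standardGeneric("keptBarcodes"))
#' @rdname accessors
#' @export
setGeneric("dropletStats", function(x) standardGeneric("dropletStats"))

#' @rdname accessors
#' @export
setMethod("alphaParams", "MultinomMixture", function(object) object@alpha)
#' @rdname accessors
#' @export
setMethod("mixWeights", "MultinomMixture", function(object) object@pi)
#' @rdname accessors
#' @export
setMethod("debrisIndex", "MultinomMixture",
          function(object) object@debrisIndex)
#' @rdname accessors
#' @export
setMethod("posteriorProbs", "MultinomMixture",
          function(object) object@posterior)
#' @rdname accessors
#' @export
setMethod("emTrace", "MultinomMixture", function(object) object@trace)

.colDataColumn <- function(x, col) {
    cd <- SummarizedExperiment::colData(x)
    if (!col %in% colnames(cd))
        stop("column '", col, "' not present; run the corresponding step")
    out <- cd[[col]]
    names(out) <- rownames(cd)
    out
}

#' @rdname accessors
#' @export
setMethod("clusterAssignments", "DebrisExperiment",
          function(x) .colDataColumn(x, "cluster"))
#' @rdname accessors
#' @export
setMethod("debrisScores", "DebrisExperiment",
          function(x) .colDataColumn(x, "debris_score_norm"))
#' @rdname accessors
#' @export
setMethod("keptBarcodes", "DebrisExperiment",
          function(x) names(which(.colDataColumn(x, "keep"))))
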
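#' DebrisExperiment: droplet counts with debris-filtering annotations
#'
#' A thin extension of \linkS4class{SingleCellExperiment} holding a
#' gene-by-droplet UMI count matrix together with the per-droplet summaries
#' and debris-filtering results accumulated by the pipeline.  Rows are
#' genes, columns are droplet barcodes.  On construction the per-droplet
#' totals (\code{total_counts}) and number of genes with at least one count
#' (\code{genes_detected}) are computed into \code{colData}.
#'
#' Downstream steps add further \code{colData} columns:
#' \describe{
#'   \item{\code{droplet_set}}{\code{"fixed_debris"} or \code{"test"}
#'     (\code{\link{splitSets}}).}
#'   \item{\code{in_cluster_set}}{logical; used for k-means initialization.}
#'   \item{\code{init_cluster}, \code{cluster}}{integer component labels,
#'     1 = debris component.}
#'   \item{\code{debris_score}, \code{debris_score_norm}, \code{keep}}{the
#'     per-droplet debris score, its cluster-anchored normalization, and the
#'     final keep/remove call.}
#' }
#' Fit artifacts (the \linkS4class{MultinomMixture}, the debris-enriched
#' gene table, the configuration) live in \code{metadata()}.
#'
#' @param counts gene-by-droplet matrix of non-negative integer counts
#'   (dense or any \pkg{Matrix} sparse form).
#' @param geneIds character vector of unique gene identifiers (rownames of
#'   \code{counts} used when missing).
#' @param geneNames character vector of gene symbols, same length as
#'   \code{geneIds}; defaults to \code{geneIds}.
#' @param barcodes character vector of unique droplet barcodes (colnames of
#'   \code{counts} used when missing).
#'
#' @return A \code{DebrisExperiment} object.
#' @examples
#' m <- matrix(c(5, 0, 0, 0, 0, 2), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("AAA", "CCC")))
#' de <- DebrisExperiment(m)
#' dropletStats(de)
#' @export
#' @import SingleCellExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
setClass("DebrisExperiment", contains = "SingleCellExperiment")

#' @rdname DebrisExperiment-class
#' @aliases DebrisExperiment
#' @export
DebrisExperiment <- function(counts, geneIds = NULL, geneNames = NULL,
                             barcodes = NULL) {
    counts <- asCountMatrix(counts)
    if (!is.null(geneIds)) rownames(counts) <- geneIds
    if (!is.null(barcodes)) colnames(counts) <- barcodes
    if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
        (ncol(counts) > 0 && is.null(colnames(counts))))
        stop("gene ids and barcodes are required (as names or arguments)")
    if (is.null(colnames(counts))) colnames(counts) <- character(0)
    if (is.null(geneNames)) geneNames <- rownames(counts)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_id = rownames(counts),
                                       gene_name = geneNames),
        colData = S4Vectors::DataFrame(
            barcode = colnames(counts),
            total_counts = unname(Matrix::colSums(counts)),
            genes_detected = unname(Matrix::colSums(counts > 0)),
            row.names = colnames(counts)))
    new("DebrisExperiment", sce)
}

setValidity("DebrisExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (is(m, "sparseMatrix")) {
            v <- m@x
            if (length(v) && (any(v < 0) || any(v != floor(v))))
                msg <- c(msg, "counts must be non-negative integers")
        }
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "barcodes must be unique")
    if (length(msg)) msg else TRUE
})

#' MultinomMixture: parameters and posteriors of the droplet mixture model
#'
#' Holds the fitted (or initial) parameters of the (K+1)-component
#' multinomial mixture over droplet expression: one debris component
#' (always component 1) plus K cell-type components.  Row k of \code{alpha}
#' is the gene-probability vector of component k; \code{pi} are the mixing
#' weights.  After \code{\link{runEM}} the object also carries the
#' per-droplet posterior membership probabilities, the fixed-label mask of
#' the semi-supervised fit, and the iteration trace.
#'
#' @slot alpha numeric matrix, components by genes; each row a probability
#'   vector (sums to 1, all entries positive).
#' @slot pi numeric vector of mixing weights (non-negative, sums to 1).
#' @slot debrisIndex integer; index of the debris component (1).
#' @slot posterior numeric matrix, droplets by components (may have 0 rows
#'   before fitting); each row sums to 1, fixed rows one-hot at
#'   \code{debrisIndex}.
#' @slot fixed logical vector marking the droplets whose labels were held
#'   at the debris component.
#' @slot trace data.frame with one row per EM iteration: \code{iter},
#'   \code{logLik} (semi-supervised observed-data log-likelihood) and
#'   \code{delta} (max absolute parameter change).
#' @slot converged logical.
#'
#' @aliases MultinomMixture
#' @export
setClass("MultinomMixture",
    representation(alpha = "matrix", pi = "numeric", debrisIndex = "integer",
                   posterior = "matrix", fixed = "logical",
                   trace = "data.frame", converged = "logical"),
    prototype(debrisIndex = 1L, posterior = matrix(0, 0, 0),
              fixed = logical(0),
              trace = data.frame(iter = integer(), logLik = numeric(),
                                 delta = numeric()),
              converged = NA))

MultinomMixture <- function(alpha, pi, debrisIndex = 1L,
                            posterior = matrix(0, 0, length(pi)),
                            fixed = logical(0),
                            trace = data.frame(iter = integer(),
                                               logLik = numeric(),
                                               delta = numeric()),
                            converged = NA) {
    new("MultinomMixture", alpha = alpha, pi = pi,
        debrisIndex = as.integer(debrisIndex), posterior = posterior,
        fixed = fixed, trace = trace, converged = converged)
}

setValidity("MultinomMixture", function(object) {
    msg <- character()
    a <- object@alpha
    if (nrow(a) != length(object@pi))
        msg <- c(msg, "nrow(alpha) must equal length(pi)")
    if (nrow(a) && any(abs(rowSums(a) - 1) > 1e-10))
        msg <- c(msg, "alpha rows must sum to 1 (tol 1e-10)")
    if (nrow(a) && any(a <= 0))
        msg <- c(msg, "alpha entries must be positive")
    if (any(object@pi < 0) || abs(sum(object@pi) - 1) > 1e-10)
        msg <- c(msg, "pi must be non-negative and sum to 1 (tol 1e-10)")
    if (object@debrisIndex < 1L || object@debrisIndex > length(object@pi))
        msg <- c(msg, "debrisIndex out of range")
    p <- object@posterior
    if (nrow(p)) {
        if (ncol(p) != length(object@pi))
            msg <- c(msg, "posterior columns must match components")
        if (any(abs(rowSums(p) - 1) > 1e-10))
            msg <- c(msg, "posterior rows must sum to 1 (tol 1e-10)")
    }
    if (length(msg)) msg else TRUE
})

#' MidpointFit: two-Gaussian model of the percent-spliced distribution
#'
#' The percent of reads spliced across droplets is typically bimodal:
#' nuclear droplets sit low, ambient/background droplets sit high.  This
#' class stores the two-component univariate Gaussian mixture fitted by EM
#' and the midpoint -- the point between the two means where the weighted
#' probability densities are equal -- used to classify droplets.
#'
#' @slot mean,sd,weight numeric length-2 vectors of component parameters,
#'   ordered so \code{mean[1] <= mean[2]}; weights sum to 1.
#' @slot midpoint numeric; the equal-density point between the means.
#' @slot converged logical.
#'
#' @aliases MidpointFit
#' @export
setClass("MidpointFit",
    representation(mean = "numeric", sd = "numeric", weight = "numeric",
                   midpoint = "numeric", converged = "logical"))

MidpointFit <- function(mean, sd, weight, midpoint, converged = TRUE) {
    new("MidpointFit", mean = mean, sd = sd, weight = weight,
        midpoint = midpoint, converged = converged)
}

setValidity("MidpointFit", function(object) {
    msg <- character()
    if (length(object@mean) != 2L || length(object@sd) != 2L ||
        length(object@weight) != 2L)
        msg <- c(msg, "mean, sd, weight must have length 2")
    if (abs(sum(object@weight) - 1) > 1e-8)
        msg <- c(msg, "weights must sum to 1")
    if (any(object@sd <= 0))
        msg <- c(msg, "sds must be positive")
    if (length(msg)) msg else TRUE
})

#' @export
#' @rdname MultinomMixture-class
setMethod("show", "MultinomMixture", function(object) {
    cat("MultinomMixture with", nrow(object@alpha), "components over",
        ncol(object@alpha), "genes\n")
    cat("  debris component:", object@debrisIndex, "\n")
    cat("  pi:", paste(signif(object@pi, 3), collapse = " "), "\n")
    if (nrow(object@posterior))
        cat("  posteriors:", nrow(object@posterior), "droplets (",
            sum(object@fixed), "fixed )\n")
    if (nrow(object@trace))
        cat("  EM: ", nrow(object@trace), " iterations, converged = ",
            object@converged, ", logLik = ",
            format(object@trace$logLik[nrow(object@trace)]), "\n", sep = "")
    invisible(NULL)
})

#' @export
#' @rdname MidpointFit-class
setMethod("show", "MidpointFit", function(object) {
    cat("MidpointFit: two-Gaussian mixture of percent spliced\n")
    cat(sprintf("  means %.4f / %.4f, sds %.4f / %.4f, weights %.3f / %.3f\n",
                object@mean[1], object@mean[2], object@sd[1], object@sd[2],
                object@weight[1], object@weight[2]))
    cat(sprintf("  midpoint: %.4f (converged: %s)\n", object@midpoint,
                object@converged))
    invisible(NULL)
})
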
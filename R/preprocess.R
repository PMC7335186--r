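#' Restrict to expressed genes
#'
#' Keeps genes with a nonzero total count across all droplets (equivalent
#' to counts-per-million > 0).  All model fitting operates on this subset.
#'
#' @param x a \linkS4class{DebrisExperiment} or count matrix.
#' @return The input subset to expressed genes (same class).
#' @export
filterExpressedGenes <- function(x) {
    m <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else asCountMatrix(x)
    keep <- Matrix::rowSums(m) > 0
    if (!any(keep)) stop("no expressed genes")
    x[keep, ]
}

#' Split droplets into the fixed debris set and the test set
#'
#' Droplets with fewer than \code{fixedThreshold} total counts are assumed
#' to contain ambient RNA and form the fixed debris set: their mixture
#' component labels are held at the debris component throughout EM.  The
#' remaining droplets form the test set, whose membership the model infers.
#' Droplets with at least \code{clusterSetMinGenes} genes detected
#' additionally form the cluster set used for k-means initialization, so
#' that initial clusters are not driven by near-empty droplets.
#'
#' @param x a \linkS4class{DebrisExperiment}.
#' @param fixedThreshold total-count threshold below which droplets are
#'   fixed debris (default 100).
#' @param clusterSetMinGenes genes-detected threshold for the cluster set
#'   (default 200).
#' @return \code{x} with \code{colData} columns \code{droplet_set}
#'   (\code{"fixed_debris"}/\code{"test"}) and \code{in_cluster_set}.
#' @export
splitSets <- function(x, fixedThreshold = 100, clusterSetMinGenes = 200) {
    if (fixedThreshold < 0 || clusterSetMinGenes < 0)
        stop("thresholds must be >= 0")
    cd <- SummarizedExperiment::colData(x)
    test <- cd$total_counts >= fixedThreshold
    if (!any(test)) stop("no droplets above fixed threshold")
    cd$droplet_set <- ifelse(test, "test", "fixed_debris")
    cd$in_cluster_set <- test & cd$genes_detected >= clusterSetMinGenes
    SummarizedExperiment::colData(x) <- cd
    x
}

#' Median-depth normalization for initialization
#'
#' Scales each droplet's counts to sum to the median total count of the
#' included droplets, then applies \code{log(scaled + 1)}.
#'
#' @param counts gene-by-droplet sparse count matrix (droplets with zero
#'   totals must already be excluded).
#' @return A sparse real-valued matrix of the same shape.
#' @export
normalizeForInit <- function(counts) {
    counts <- asCountMatrix(counts)
    tot <- Matrix::colSums(counts)
    if (any(tot == 0)) stop("droplets with zero totals must be excluded")
    med <- median(tot)
    sf <- med / tot
    out <- counts %*% Matrix::Diagonal(x = sf)
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
    out
}

#' Select highly variable genes with a mean-variance trend correction
#'
#' The per-gene mean and variance of the raw counts are computed and
#' log-transformed; a LOESS curve of log variance on log mean (span
#' \code{span}, degree 2) captures the expected mean-variance relationship,
#' and the standardized variance of a gene is its observed log variance
#' minus the fitted value.  The top \code{nGenes} genes by standardized
#' variance are flagged as variable.  Genes with zero counts are excluded
#' from the trend fit (their log mean is undefined).
#'
#' @param counts gene-by-droplet raw count matrix (typically restricted to
#'   the cluster-set droplets).
#' @param nGenes number of variable genes to select (default 2000).
#' @param span LOESS span (default 0.3).
#' @return A data.frame with one row per analyzed gene: \code{gene_id},
#'   \code{log_mean}, \code{log_variance}, \code{fitted_variance},
#'   \code{standardized_variance}, \code{rank} and \code{selected}; ordered
#'   by rank (ties broken by gene id for determinism).
#' @export
selectVariableGenes <- function(counts, nGenes = 2000, span = 0.3) {
    counts <- asCountMatrix(counts)
    mv <- sparseRowMeanVar(counts)
    keep <- mv$mean > 0 & mv$var > 0
    if (sum(keep) < 2) stop("need at least 2 genes with positive variance")
    ids <- rownames(counts)[keep]
    lm_ <- log(mv$mean[keep])
    lv <- log(mv$var[keep])
    fit <- loess(lv ~ lm_, span = span, degree = 2,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct"))
    fitted <- as.numeric(stats::predict(fit, lm_))
    std <- lv - fitted
    ord <- order(-std, ids)
    tab <- data.frame(gene_id = ids, log_mean = lm_, log_variance = lv,
                      fitted_variance = fitted, standardized_variance = std,
                      stringsAsFactors = FALSE)[ord, ]
    tab$rank <- seq_len(nrow(tab))
    if (nrow(tab) < nGenes)
        warning("only ", nrow(tab), " genes available; returning all")
    tab$selected <- tab$rank <= nGenes
    rownames(tab) <- NULL
    tab
}

#' PCA embedding of normalized expression
#'
#' Principal components of the gene-centered normalized expression over the
#' selected variable genes; droplets are observations.  Genes are centered
#' but not scaled to unit variance.  Components are deterministic up to
#' sign.
#'
#' @param normalized normalized gene-by-droplet matrix (from
#'   \code{\link{normalizeForInit}}).
#' @param varGenes character vector of variable gene ids.
#' @param nPCs number of components to return (default 30; reduced with a
#'   warning if the data have lower rank).
#' @return A droplets-by-components numeric matrix.
#' @export
pcaEmbed <- function(normalized, varGenes, nPCs = 30) {
    varGenes <- intersect(varGenes, rownames(normalized))
    m <- t(as.matrix(normalized[varGenes, , drop = FALSE]))
    maxPC <- min(dim(m)) - 1L
    if (nPCs > maxPC) {
        warning("nPCs reduced from ", nPCs, " to ", maxPC)
        nPCs <- maxPC
    }
    pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = nPCs)
    pc$x[, seq_len(nPCs), drop = FALSE]
}

#' Seeded k-means on the PC embedding
#'
#' Runs \code{\link[stats]{kmeans}} (Hartigan-Wong, 10 random restarts)
#' under the given seed to produce the initial cell-type clustering of the
#' cluster-set droplets.
#'
#' @param embedding droplets-by-PCs matrix from \code{\link{pcaEmbed}}.
#' @param k number of cell-type clusters (default 20).
#' @param seed integer seed; the same seed reproduces identical labels.
#' @param nstart number of random restarts.
#' @return Integer vector of labels in \code{1..k}, named by droplet.
#' @export
kmeansInit <- function(embedding, k = 20, seed = 1, nstart = 10) {
    if (k < 1) stop("k must be >= 1")
    if (k > nrow(embedding))
        stop("k (", k, ") exceeds the number of cluster-set droplets (",
             nrow(embedding), ")")
    km <- withSeed(seed,
                   kmeans(embedding, centers = k, nstart = nstart,
                          iter.max = 100))
    labels <- km$cluster
    names(labels) <- rownames(embedding)
    labels
}

#' Initial mixture parameters from the k-means labeling
#'
#' Builds the (K+1)-component starting point for EM: component 1 (debris)
#' pools the counts of the fixed debris droplets; components 2..K+1 pool
#' the counts of each k-means cluster.  A pseudocount keeps every gene
#' probability positive.  Mixing weights are the labeled-droplet fractions.
#' Empty k-means clusters are dropped with a message.
#'
#' @param x a \linkS4class{DebrisExperiment} after \code{\link{splitSets}},
#'   restricted to expressed genes.
#' @param kmLabels named integer labels from \code{\link{kmeansInit}}.
#' @param pseudocount added to every pooled gene count (default 1e-10).
#' @return A \linkS4class{MultinomMixture} with K+1 components.
#' @export
initialParameters <- function(x, kmLabels, pseudocount = 1e-10) {
    counts <- SummarizedExperiment::assay(x, "counts")
    cd <- SummarizedExperiment::colData(x)
    if (!"droplet_set" %in% colnames(cd)) stop("run splitSets() first")
    fixed <- cd$droplet_set == "fixed_debris"
    ks <- sort(unique(kmLabels))
    present <- ks[vapply(ks, function(k) sum(kmLabels == k) > 0, logical(1))]
    if (length(present) < length(ks))
        message("dropping ", length(ks) - length(present),
                " empty k-means cluster(s)")
    groups <- c(list(colnames(counts)[fixed]),
                lapply(present, function(k) names(kmLabels)[kmLabels == k]))
    G <- nrow(counts)
    alpha <- matrix(0, length(groups), G,
                    dimnames = list(NULL, rownames(counts)))
    sizes <- numeric(length(groups))
    for (j in seq_along(groups)) {
        cols <- groups[[j]]
        pooled <- if (length(cols))
            Matrix::rowSums(counts[, cols, drop = FALSE]) else numeric(G)
        a <- as.numeric(pooled) + pseudocount
        alpha[j, ] <- a / sum(a)
        sizes[j] <- length(cols)
    }
    MultinomMixture(alpha = alpha, pi = sizes / sum(sizes), debrisIndex = 1L)
}
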
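#' Identify debris clusters
#'
#' The debris cluster set is the fixed (debris) component plus any
#' component whose assigned droplets have a mean number of genes detected
#' below \code{d}; clusters of genuine nuclei are expected to exceed it.
#' All remaining components form the cell-type set.
#'
#' @param clusters integer component labels over droplets (1 = debris).
#' @param genesDetected per-droplet genes-detected counts, aligned with
#'   \code{clusters}.
#' @param d mean genes-detected threshold (default 200).
#' @param debrisIdx index of the fixed debris component (default 1).
#' @return Sorted integer vector of debris component indices.
#' @export
defineDebrisClusters <- function(clusters, genesDetected, d = 200,
                                 debrisIdx = 1L) {
    ks <- sort(unique(clusters))
    means <- vapply(ks, function(k) mean(genesDetected[clusters == k]),
                    numeric(1))
    debris <- union(debrisIdx, ks[means < d])
    if (all(ks %in% debris))
        stop("no cell-type clusters; cannot score")
    sort(as.integer(debris))
}

#' Proportion-based log normalization for DE and scoring
#'
#' Each droplet's counts are scaled to sum to 1 (proportions) and then
#' \code{log(p + 1)} transformed.  Output is invariant to droplet depth.
#'
#' @param counts gene-by-droplet sparse count matrix; zero-total droplets
#'   yield all-zero columns.
#' @return A sparse real-valued matrix of the same shape.
#' @export
normalizeForDE <- function(counts) {
    counts <- asCountMatrix(counts)
    tot <- Matrix::colSums(counts)
    sf <- ifelse(tot > 0, 1 / tot, 0)
    out <- counts %*% Matrix::Diagonal(x = sf)
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
    out
}

#' Debris-enriched genes by Welch's t-test
#'
#' For every gene, a Welch (unequal-variance) two-sample t-test of the
#' normalized expression in the debris-cluster droplets against the
#' cell-type-cluster droplets (test-set droplets only), with two-sided
#' p-values and Benjamini-Hochberg q-values.  The log fold change is the
#' difference of group means on the log-normalized scale.  A gene is
#' debris-enriched when \code{log_fold_change > 0} and \code{q_value <
#' 0.05}.  Genes constant in both groups get a p-value of 1.
#'
#' @param normalized normalized matrix from \code{\link{normalizeForDE}}.
#' @param debrisCells,cellCells character vectors (or indices) of the two
#'   droplet groups; each needs at least 2 droplets.
#' @param fdr enrichment q-value cutoff (default 0.05).
#' @return A data.frame with \code{gene_id}, \code{log_fold_change},
#'   \code{t_statistic}, \code{df}, \code{p_value}, \code{q_value},
#'   \code{enriched}.
#' @export
debrisDE <- function(normalized, debrisCells, cellCells, fdr = 0.05) {
    if (length(debrisCells) < 2 || length(cellCells) < 2)
        stop("each group needs at least 2 droplets")
    a <- normalized[, debrisCells, drop = FALSE]
    b <- normalized[, cellCells, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    mva <- sparseRowMeanVar(a)
    mvb <- sparseRowMeanVar(b)
    lfc <- mva$mean - mvb$mean
    se2 <- mva$var / na + mvb$var / nb
    stat <- lfc / sqrt(se2)
    df <- se2^2 / ((mva$var / na)^2 / (na - 1) + (mvb$var / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(stat), df)
    degen <- se2 == 0
    if (any(degen)) {
        stat[degen] <- ifelse(lfc[degen] == 0, 0, Inf * sign(lfc[degen]))
        df[degen] <- NA_real_
        p[degen] <- ifelse(lfc[degen] == 0, 1, 0)
    }
    q <- p.adjust(p, method = "BH")
    data.frame(gene_id = rownames(normalized),
               log_fold_change = lfc, t_statistic = stat, df = df,
               p_value = p, q_value = q,
               enriched = lfc > 0 & q < fdr,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Raw per-droplet debris score
#'
#' The sum of a droplet's normalized expression over the debris-enriched
#' gene set.  Defined for every droplet, including the fixed debris set.
#'
#' @param normalized matrix from \code{\link{normalizeForDE}}.
#' @param enrichedGenes non-empty character vector of debris-enriched
#'   gene ids.
#' @return Named numeric vector of raw scores, one per droplet.
#' @export
scoreDroplets <- function(normalized, enrichedGenes) {
    if (length(enrichedGenes) == 0)
        stop("no debris-enriched genes; scoring unreliable")
    missing <- setdiff(enrichedGenes, rownames(normalized))
    if (length(missing))
        stop("unknown gene ids: ", paste(missing, collapse = ", "))
    Matrix::colSums(normalized[enrichedGenes, , drop = FALSE])
}

#' Cluster-anchored score normalization
#'
#' Rescales raw debris scores so the lowest-mean cluster averages 0 and
#' the debris clusters average 1:
#' \code{(raw - m_low) / (m_deb - m_low)}, where \code{m_low} is the
#' smallest per-cluster mean raw score (cluster means over test-set
#' droplets) and \code{m_deb} the mean raw score over all droplets in the
#' debris clusters (the fixed set included, since it constitutes the fixed
#' cluster).  \code{method = "literal"} instead divides the centered scores
#' by the debris-cluster mean alone, which anchors the debris average at 1
#' only when \code{m_low} is 0.
#'
#' @param raw named raw scores over all droplets.
#' @param clusters component labels aligned with \code{raw}.
#' @param debrisSet debris component indices from
#'   \code{\link{defineDebrisClusters}}.
#' @param testSet logical vector marking test-set droplets (default all).
#' @param method \code{"anchored"} (default) or \code{"literal"}.
#' @return Named numeric vector of normalized scores.
#' @export
normalizeScores <- function(raw, clusters, debrisSet,
                            testSet = rep(TRUE, length(raw)),
                            method = c("anchored", "literal")) {
    method <- match.arg(method)
    ks <- sort(unique(clusters))
    clMeans <- vapply(ks, function(k) {
        sel <- clusters == k & (testSet | k %in% debrisSet)
        if (!any(sel)) return(NA_real_)
        mean(raw[sel])
    }, numeric(1))
    mLow <- min(clMeans, na.rm = TRUE)
    inDebris <- clusters %in% debrisSet
    if (!any(inDebris)) stop("no droplets in debris clusters")
    mDeb <- mean(raw[inDebris])
    if (mDeb <= mLow)
        stop("debris clusters do not have elevated scores; ",
             "debris-enrichment DE likely failed")
    if (method == "anchored") (raw - mLow) / (mDeb - mLow)
    else (raw - mLow) / mDeb
}

#' Filter droplets by debris score or cluster membership
#'
#' In score mode a test-set droplet is kept when its normalized debris
#' score is below \code{t}; in cluster mode when its component is not in
#' the debris set.  Fixed debris droplets are always removed.
#'
#' @param scores normalized debris scores over all droplets.
#' @param clusters component labels aligned with \code{scores}.
#' @param debrisSet debris component indices.
#' @param testSet logical vector marking test-set droplets.
#' @param t score cutoff (default 0.5).
#' @param mode \code{"score"} (default) or \code{"cluster"}.
#' @return Logical keep vector aligned with \code{scores}.
#' @export
filterDroplets <- function(scores, clusters, debrisSet,
                           testSet = rep(TRUE, length(scores)),
                           t = 0.5, mode = c("score", "cluster")) {
    mode <- match.arg(mode)
    keep <- if (mode == "score") scores < t
            else !(clusters %in% debrisSet)
    keep & testSet
}
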
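#' Read a per-droplet or per-gene splice count table
#'
#' Accepts a headered TSV in either of two layouts: per-gene rows
#' (\code{barcode, gene_id, spliced, unspliced, ambiguous}) as emitted by
#' per-gene splice quantifiers, or pre-aggregated per-droplet rows
#' (\code{barcode, spliced, unspliced, ambiguous}).
#'
#' @param path TSV file path (optionally gzipped).
#' @return A data.frame in the layout found in the file.
#' @export
readSpliceTable <- function(path) {
    if (!file.exists(path)) stop("splice table not found: ", path)
    tab <- tryCatch(read.delim(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE),
                    error = function(e)
                        stop("malformed splice TSV '", path, "': ",
                             conditionMessage(e)))
    need <- c("barcode", "spliced", "unspliced")
    if (!all(need %in% colnames(tab)))
        stop("splice TSV must have columns: ",
             paste(need, collapse = ", "))
    bad <- which(!vapply(tab$spliced + tab$unspliced, is.finite, logical(1)))
    if (length(bad))
        stop("malformed splice TSV at line ", bad[1] + 1L)
    tab
}

#' Per-droplet percent of reads spliced
#'
#' Aggregates spliced/unspliced counts per droplet -- excluding
#' mitochondrial genes first, since MT transcripts have no introns and
#' would bias the estimate -- and computes
#' \code{spliced / (spliced + unspliced)}.  Ambiguous reads never enter
#' the ratio.  Droplets with a zero denominator get \code{NA} (undefined,
#' never silently 0) and are excluded from midpoint fitting.
#'
#' @param spliceTable data.frame from \code{\link{readSpliceTable}}; MT
#'   exclusion requires the per-gene layout (with pre-aggregated input the
#'   caller is assumed to have excluded MT already).
#' @param mtGenes character vector of mitochondrial gene ids (matched
#'   against \code{gene_id}); alternatively a regular expression via
#'   \code{mtPattern}.
#' @param mtPattern regex applied to \code{gene_id} when \code{mtGenes} is
#'   NULL (default matches the conventional "MT-"/"mt-" symbol prefix).
#' @return A data.frame with \code{barcode}, \code{spliced},
#'   \code{unspliced}, \code{ambiguous}, \code{pct_spliced}.
#' @export
percentSpliced <- function(spliceTable, mtGenes = NULL,
                           mtPattern = "^(MT|mt)-") {
    if (!"ambiguous" %in% colnames(spliceTable)) spliceTable$ambiguous <- 0
    if ("gene_id" %in% colnames(spliceTable)) {
        drop <- if (!is.null(mtGenes)) spliceTable$gene_id %in% mtGenes
                else grepl(mtPattern, spliceTable$gene_id)
        spliceTable <- spliceTable[!drop, , drop = FALSE]
        agg <- stats::aggregate(
            spliceTable[, c("spliced", "unspliced", "ambiguous")],
            by = list(barcode = spliceTable$barcode), FUN = sum)
    } else {
        agg <- spliceTable[, c("barcode", "spliced", "unspliced",
                               "ambiguous")]
    }
    den <- agg$spliced + agg$unspliced
    agg$pct_spliced <- ifelse(den > 0, agg$spliced / den, NA_real_)
    agg
}

#' Per-droplet fraction of counts on a gene set
#'
#' The fraction of each droplet's total UMIs falling on the given genes,
#' e.g. the mitochondrial fraction (MT\%) or the MALAT1 fraction.
#' Zero-total droplets get \code{NA}.
#'
#' @param x a \linkS4class{DebrisExperiment} or gene-by-droplet count
#'   matrix.
#' @param geneIds non-empty character vector of gene ids; unknown ids are
#'   an error naming them.
#' @return Named numeric vector of fractions in [0, 1] (or \code{NA}).
#' @export
fractionOfCounts <- function(x, geneIds) {
    m <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else asCountMatrix(x)
    if (length(geneIds) == 0) stop("gene set is empty")
    missing <- setdiff(geneIds, rownames(m))
    if (length(missing))
        stop("unknown gene ids: ", paste(missing, collapse = ", "))
    tot <- Matrix::colSums(m)
    sub <- Matrix::colSums(m[geneIds, , drop = FALSE])
    ifelse(tot > 0, sub / tot, NA_real_)
}

# Equal-weighted-density point between the two component means of a
# univariate Gaussian mixture: solve w1*phi1(x) = w2*phi2(x), a quadratic
# in x; prefer the root strictly between the means.
.equalDensityPoint <- function(mu, sigma, w) {
    A <- 1 / (2 * sigma[2]^2) - 1 / (2 * sigma[1]^2)
    B <- mu[1] / sigma[1]^2 - mu[2] / sigma[2]^2
    C <- mu[2]^2 / (2 * sigma[2]^2) - mu[1]^2 / (2 * sigma[1]^2) +
        log((w[1] * sigma[2]) / (w[2] * sigma[1]))
    mid <- mean(mu)
    if (abs(A) < 1e-12) {
        if (abs(B) < 1e-12) return(mid)
        return(-C / B)
    }
    disc <- B^2 - 4 * A * C
    if (disc < 0) {
        warning("no real equal-density point; using the means' midpoint")
        return(mid)
    }
    roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    inside <- roots > min(mu) & roots < max(mu)
    if (any(inside)) return(roots[inside][1])
    warning("no equal-density root between the means; ",
            "using the root closest to their midpoint")
    roots[which.min(abs(roots - mid))]
}

#' Fit the two-Gaussian midpoint model of percent spliced
#'
#' Fits a two-component univariate Gaussian mixture to the per-droplet
#' percent-spliced values by EM, with a deterministic initialization
#' anchored at the 25th/75th percentiles of the data, and computes the
#' midpoint: the value between the two means at which the two weighted
#' component densities are equal (a quadratic in x; the root between the
#' means is taken, with a documented fallback to the root nearest the
#' means' midpoint).  Near-unimodal data trigger a warning and a midpoint
#' at the overall mean.
#'
#' @param values numeric vector of defined percent-spliced values (NAs
#'   dropped); at least 20 values with nontrivial spread are required.
#' @param seed optional seed (the quantile-anchored initialization is
#'   already deterministic; kept for API symmetry with restart schemes).
#' @param maxIter,tol EM iteration cap and log-likelihood tolerance.
#' @return A \linkS4class{MidpointFit}.
#' @examples
#' v <- c(rnorm(200, 0.3, 0.05), rnorm(200, 0.7, 0.05))
#' fitMidpoint(v)
#' @export
fitMidpoint <- function(values, seed = NULL, maxIter = 500, tol = 1e-8) {
    values <- values[is.finite(values)]
    n <- length(values)
    if (n < 20) stop("need at least 20 defined values")
    if (sd(values) < 1e-8) stop("values have no spread")
    mu <- unname(quantile(values, c(0.25, 0.75)))
    sigma <- rep(max(sd(values) / 2, 1e-4), 2)
    w <- c(0.5, 0.5)
    ll0 <- -Inf
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        d1 <- w[1] * stats::dnorm(values, mu[1], sigma[1])
        d2 <- w[2] * stats::dnorm(values, mu[2], sigma[2])
        tot <- d1 + d2
        tot[tot == 0] <- .Machine$double.xmin
        r <- d1 / tot
        ll <- sum(log(tot))
        if (is.finite(ll0) && abs(ll - ll0) < tol * (abs(ll0) + 1)) {
            converged <- TRUE
            break
        }
        ll0 <- ll
        n1 <- sum(r); n2 <- n - n1
        w <- c(n1, n2) / n
        mu <- c(sum(r * values) / n1, sum((1 - r) * values) / n2)
        sigma <- sqrt(c(sum(r * (values - mu[1])^2) / n1,
                        sum((1 - r) * (values - mu[2])^2) / n2))
        sigma <- pmax(sigma, 1e-6)
    }
    ord <- order(mu)
    mu <- mu[ord]; sigma <- sigma[ord]; w <- w[ord]
    if (abs(mu[2] - mu[1]) < 2 * sd(values) / sqrt(n) ||
        min(w) < 1e-3) {
        warning("percent-spliced distribution looks unimodal; ",
                "midpoint set to the overall mean")
        mid <- mean(values)
    } else {
        mid <- .equalDensityPoint(mu, sigma, w)
    }
    MidpointFit(mean = mu, sd = sigma, weight = w, midpoint = mid,
                converged = converged)
}

#' Classify droplets as background or nuclear
#'
#' Droplets with a percent of reads spliced above the midpoint are called
#' background (ambient-dominated); at or below, nuclear (values exactly at
#' the midpoint resolve to background).  Undefined values give
#' \code{"unclassified"}.
#'
#' @param pct numeric vector of percent-spliced values (NA = undefined).
#' @param midpoint a number in (0, 1) or a \linkS4class{MidpointFit}.
#' @return Character vector: \code{"background"}, \code{"nuclear"} or
#'   \code{"unclassified"}.
#' @export
classifyDroplets <- function(pct, midpoint) {
    if (is(midpoint, "MidpointFit")) midpoint <- midpoint@midpoint
    out <- ifelse(is.na(pct), "unclassified",
                  ifelse(pct >= midpoint, "background", "nuclear"))
    out
}

#' Classify clusters as debris or cell type by mean percent spliced
#'
#' A cluster whose droplets average at least \code{cutoff} percent spliced
#' is called debris; below, cell type.  Clusters with no defined values
#' are unclassified with a warning.
#'
#' @param clusters component labels over droplets.
#' @param pct percent-spliced values aligned with \code{clusters}.
#' @param cutoff mean percent-spliced cutoff (default 0.5, inclusive on
#'   the debris side).
#' @return Named character vector over clusters: \code{"debris"},
#'   \code{"cell_type"} or \code{"unclassified"}.
#' @export
classifyClusters <- function(clusters, pct, cutoff = 0.5) {
    ks <- sort(unique(clusters))
    out <- vapply(ks, function(k) {
        v <- pct[clusters == k]
        v <- v[is.finite(v)]
        if (!length(v)) {
            warning("cluster ", k, " has no defined percent-spliced values")
            return("unclassified")
        }
        if (mean(v) >= cutoff) "debris" else "cell_type"
    }, character(1))
    names(out) <- ks
    out
}
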
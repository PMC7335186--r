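#' Pipeline configuration
#'
#' Collects every tunable of the filtering pipeline with its default.
#' Unknown keys are rejected; the full configuration is echoed into the
#' run manifest so a run can be reproduced exactly.
#'
#' @param fixedThreshold total-count threshold of the fixed debris set
#'   (default 100).
#' @param k number of cell-type mixture components (default 20).
#' @param eps EM convergence tolerance on the max parameter change
#'   (default 1e-4).
#' @param pseudocount M-step pseudocount (default 1e-10).
#' @param clusterSetMinGenes genes-detected floor of the k-means cluster
#'   set (default 200).
#' @param debrisClusterMinGenes mean genes-detected threshold below which
#'   a cluster is called debris (default 200).
#' @param scoreCutoff debris-score keep threshold t (default 0.5).
#' @param variableGenes number of variable genes for the init PCA
#'   (default 2000).
#' @param loessSpan mean-variance trend span (default 0.3).
#' @param nPCs principal components for k-means (default 30).
#' @param quantileTopC,quantileQ,quantileDivisor parameters of the
#'   barcode-rank baseline threshold (defaults 3000, 0.99, 10).
#' @param maxIter EM iteration cap (default 1000).
#' @param filterMode \code{"score"} or \code{"cluster"}.
#' @param scoreNormMethod \code{"anchored"} or \code{"literal"} (see
#'   \code{\link{normalizeScores}}).
#' @param fdr debris-enrichment q-value cutoff (default 0.05).
#' @param seed integer seed for k-means initialization.
#' @param ... rejected; catches misspelled keys.
#' @return A named list of class \code{"debris_config"}.
#' @export
debrisConfig <- function(fixedThreshold = 100, k = 20, eps = 1e-4,
                         pseudocount = 1e-10, clusterSetMinGenes = 200,
                         debrisClusterMinGenes = 200, scoreCutoff = 0.5,
                         variableGenes = 2000, loessSpan = 0.3, nPCs = 30,
                         quantileTopC = 3000, quantileQ = 0.99,
                         quantileDivisor = 10, maxIter = 1000,
                         filterMode = c("score", "cluster"),
                         scoreNormMethod = c("anchored", "literal"),
                         fdr = 0.05, seed = 1, ...) {
    extra <- list(...)
    if (length(extra))
        stop("unknown configuration keys: ",
             paste(names(extra), collapse = ", "))
    cfg <- list(fixedThreshold = fixedThreshold, k = k, eps = eps,
                pseudocount = pseudocount,
                clusterSetMinGenes = clusterSetMinGenes,
                debrisClusterMinGenes = debrisClusterMinGenes,
                scoreCutoff = scoreCutoff, variableGenes = variableGenes,
                loessSpan = loessSpan, nPCs = nPCs,
                quantileTopC = quantileTopC, quantileQ = quantileQ,
                quantileDivisor = quantileDivisor, maxIter = maxIter,
                filterMode = match.arg(filterMode),
                scoreNormMethod = match.arg(scoreNormMethod),
                fdr = fdr, seed = seed)
    class(cfg) <- "debris_config"
    cfg
}

#' Run the full debris-filtering pipeline
#'
#' Executes the whole procedure on a raw count matrix: restrict to
#' expressed genes; fix low-count droplets as debris; normalize, select
#' variable genes, embed with PCA and run k-means on the cluster set to
#' initialize the mixture; fit the semi-supervised multinomial mixture by
#' EM; assign droplets to components; identify debris clusters; find
#' debris-enriched genes by Welch's t-test; score, normalize and filter
#' droplets.
#'
#' @param x a \linkS4class{DebrisExperiment} (e.g. from
#'   \code{\link{readTenX}} or \code{\link{simulateDroplets}}).
#' @param config a \code{\link{debrisConfig}} list.
#' @param verbose emit stage messages.
#' @return \code{x} restricted to expressed genes, with per-droplet
#'   results in \code{colData} (\code{cluster}, \code{debris_score},
#'   \code{debris_score_norm}, \code{keep}, ...) and fit artifacts in
#'   \code{metadata()}: \code{mixture} (\linkS4class{MultinomMixture}),
#'   \code{debris_genes}, \code{debris_clusters}, \code{var_genes},
#'   \code{config} and \code{manifest}.
#' @examples
#' sim <- simulateDroplets(
#'     makeProfiles(nGenes = 120, nTypes = 2, seed = 7),
#'     nEmpty = 400, nPerType = 60, seed = 7)
#' cfg <- debrisConfig(k = 3, variableGenes = 100, nPCs = 10, seed = 7)
#' res <- runDebrisPipeline(sim$experiment, cfg, verbose = FALSE)
#' table(SummarizedExperiment::colData(res)$keep)
#' @export
runDebrisPipeline <- function(x, config = debrisConfig(), verbose = TRUE) {
    say <- function(...) if (verbose) message("[debrisEM] ", ...)
    stage <- "expressed-genes"
    out <- tryCatch({
        x <- filterExpressedGenes(x)
        stage <- "split-sets"
        x <- splitSets(x, config$fixedThreshold, config$clusterSetMinGenes)
        cd <- SummarizedExperiment::colData(x)
        counts <- SummarizedExperiment::assay(x, "counts")
        fixed <- cd$droplet_set == "fixed_debris"
        say(sum(fixed), " fixed debris droplets, ", sum(!fixed),
            " test droplets, ", sum(cd$in_cluster_set), " in cluster set")

        stage <- "initialization"
        cs <- cd$in_cluster_set
        if (sum(cs) < config$k)
            stop("cluster set smaller than k")
        norm <- normalizeForInit(counts[, cs, drop = FALSE])
        vg <- selectVariableGenes(counts[, cs, drop = FALSE],
                                  nGenes = config$variableGenes,
                                  span = config$loessSpan)
        emb <- pcaEmbed(norm, vg$gene_id[vg$selected], nPCs = config$nPCs)
        km <- kmeansInit(emb, k = config$k, seed = config$seed)
        init <- initialParameters(x, km, pseudocount = config$pseudocount)
        say("initialized ", length(init@pi), " components")

        stage <- "EM"
        fit <- runEM(counts, init, fixed, eps = config$eps,
                     maxIter = config$maxIter,
                     pseudocount = config$pseudocount)
        say("EM: ", nrow(fit@trace), " iterations, converged = ",
            fit@converged)
        clusters <- assignClusters(fit)

        stage <- "debris-clusters"
        debrisSet <- defineDebrisClusters(clusters, cd$genes_detected,
                                          d = config$debrisClusterMinGenes,
                                          debrisIdx = fit@debrisIndex)
        say("debris clusters: ", paste(debrisSet, collapse = ", "))

        stage <- "differential-expression"
        normDE <- normalizeForDE(counts)
        test <- !fixed
        inDeb <- clusters %in% debrisSet
        de <- debrisDE(normDE, colnames(x)[test & inDeb],
                       colnames(x)[test & !inDeb], fdr = config$fdr)
        say(sum(de$enriched), " debris-enriched genes")

        stage <- "scoring"
        raw <- scoreDroplets(normDE, de$gene_id[de$enriched])
        normScore <- normalizeScores(raw, clusters, debrisSet,
                                     testSet = test,
                                     method = config$scoreNormMethod)
        keep <- filterDroplets(normScore, clusters, debrisSet,
                               testSet = test, t = config$scoreCutoff,
                               mode = config$filterMode)
        say(sum(keep), " droplets kept of ", sum(test), " in the test set")

        cd$cluster <- unname(clusters)
        cd$debris_score <- unname(raw)
        cd$debris_score_norm <- unname(normScore)
        cd$keep <- unname(keep)
        SummarizedExperiment::colData(x) <- cd
        md <- S4Vectors::metadata(x)
        md$mixture <- fit
        md$debris_genes <- de
        md$debris_clusters <- debrisSet
        md$var_genes <- vg
        md$config <- config
        md$manifest <- list(
            config = unclass(config),
            n_droplets = ncol(x), n_genes = nrow(x),
            n_fixed = sum(fixed), n_kept = sum(keep),
            em_iterations = nrow(fit@trace), em_converged = fit@converged,
            rng = RNGkind()[1], timestamp = format(Sys.time()))
        S4Vectors::metadata(x) <- md
        x
    }, error = function(e) {
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
    })
    out
}

#' Quantile-threshold baseline filter
#'
#' Runs the barcode-rank quantile baseline alone: derives the count
#' threshold and partitions the droplets by it.
#'
#' @inheritParams runDebrisPipeline
#' @return A list with \code{threshold}, \code{kept}, \code{removed}.
#' @export
quantileBaseline <- function(x, config = debrisConfig()) {
    st <- dropletStats(x)
    thr <- quantileThreshold(st, topC = config$quantileTopC,
                             q = config$quantileQ,
                             divisor = config$quantileDivisor)
    c(list(threshold = thr), filterByCount(st, thr))
}

#' Contamination metrics table
#'
#' Computes the per-droplet contamination metrics: MT\% and MALAT1\% from
#' the count matrix, and, when a splice table is supplied, the percent of
#' reads spliced with the two-Gaussian midpoint model and the resulting
#' background/nuclear classification.
#'
#' @param x a \linkS4class{DebrisExperiment}.
#' @param spliceTable optional data.frame from
#'   \code{\link{readSpliceTable}} / \code{\link{simulateSplice}}.
#' @param mtGenes mitochondrial gene ids in \code{x} (NULL = match gene
#'   names against \code{mtPattern}).
#' @param malat1 MALAT1 gene id (NULL = look for a gene named MALAT1;
#'   skipped if absent).
#' @param mtPattern regex for mitochondrial gene names.
#' @return A list with \code{metrics} (data.frame: barcode, mt_frac,
#'   malat1_frac, and when available pct_spliced and class) and
#'   \code{midpoint} (a \linkS4class{MidpointFit} or NULL).
#' @export
contaminationMetrics <- function(x, spliceTable = NULL, mtGenes = NULL,
                                 malat1 = NULL, mtPattern = "^(MT|mt)-") {
    rd <- SummarizedExperiment::rowData(x)
    if (is.null(mtGenes))
        mtGenes <- rd$gene_id[grepl(mtPattern, rd$gene_name)]
    tab <- data.frame(barcode = colnames(x), stringsAsFactors = FALSE)
    tab$mt_frac <- if (length(mtGenes)) fractionOfCounts(x, mtGenes)
                   else NA_real_
    if (is.null(malat1)) {
        hit <- rd$gene_id[rd$gene_name %in% c("MALAT1", "Malat1")]
        malat1 <- if (length(hit)) hit[1] else NULL
    }
    tab$malat1_frac <- if (!is.null(malat1)) fractionOfCounts(x, malat1)
                       else NA_real_
    midpoint <- NULL
    if (!is.null(spliceTable)) {
        ps <- percentSpliced(spliceTable, mtGenes = mtGenes)
        tab <- merge(tab, ps[, c("barcode", "pct_spliced")],
                     by = "barcode", all.x = TRUE, sort = FALSE)
        midpoint <- fitMidpoint(tab$pct_spliced)
        tab$class <- classifyDroplets(tab$pct_spliced, midpoint)
    }
    list(metrics = tab, midpoint = midpoint)
}

#' Write pipeline outputs to a directory
#'
#' Emits the kept-barcode list, the filtered count triplet, the score and
#' gene tables, the mixture parameters and the manifest of a finished
#' \code{\link{runDebrisPipeline}} run.
#'
#' @param x the annotated \linkS4class{DebrisExperiment} returned by
#'   \code{\link{runDebrisPipeline}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeResults <- function(x, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    cd <- SummarizedExperiment::colData(x)
    md <- S4Vectors::metadata(x)
    writeLines(keptBarcodes(x), file.path(dir, "kept_barcodes.txt"))
    writeTenX(x[, cd$keep], file.path(dir, "filtered_counts"))
    write.table(as.data.frame(cd), file.path(dir, "droplet_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(md$debris_genes, file.path(dir, "debris_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fit <- md$mixture
    write.table(data.frame(component = seq_along(fit@pi), pi = fit@pi),
                file.path(dir, "mixture_weights.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fit@trace, file.path(dir, "em_trace.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- md$manifest
    writeLines(
        vapply(names(manifest), function(k)
            paste0(k, "=", paste(deparse(manifest[[k]]), collapse = "")),
            character(1)),
        file.path(dir, "manifest.txt"))
    invisible(dir)
}
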
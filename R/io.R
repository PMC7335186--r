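.findTriplet <- function(dir, stems) {
    for (stem in stems) {
        for (f in c(stem, paste0(stem, ".gz"))) {
            p <- file.path(dir, f)
            if (file.exists(p)) return(p)
        }
    }
    NULL
}

.readTsvCols <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    read.delim(con, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character")
}

#' Read a CellRanger-style MatrixMarket triplet
#'
#' Reads a raw gene-by-droplet UMI count matrix from a directory holding a
#' MatrixMarket file plus barcode and gene/feature TSVs.  Both the v2
#' dialect (\code{matrix.mtx}, \code{barcodes.tsv}, \code{genes.tsv} with 2
#' columns) and the v3 dialect (\code{matrix.mtx.gz}, \code{barcodes.tsv.gz},
#' \code{features.tsv.gz} with 3 columns) are accepted, gzipped or plain.
#'
#' @param dir path to the directory holding the triplet.
#' @return A \linkS4class{DebrisExperiment} with the counts and identifiers.
#' @seealso \code{\link{writeTenX}}
#' @examples
#' td <- tempfile(); dir.create(td)
#' m <- matrix(c(5, 0, 0, 0, 0, 2), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("AAA", "CCC")))
#' writeTenX(DebrisExperiment(m), td)
#' readTenX(td)
#' @export
readTenX <- function(dir) {
    if (!dir.exists(dir)) stop("directory not found: ", dir)
    mtx <- .findTriplet(dir, "matrix.mtx")
    if (is.null(mtx))
        stop("format error: no matrix.mtx[.gz] in ", dir)
    bc <- .findTriplet(dir, "barcodes.tsv")
    if (is.null(bc))
        stop("format error: no barcodes.tsv[.gz] in ", dir)
    feat <- .findTriplet(dir, c("features.tsv", "genes.tsv"))
    if (is.null(feat))
        stop("format error: no features.tsv[.gz] or genes.tsv[.gz] in ", dir)

    counts <- Matrix::readMM(mtx)
    barcodes <- .readTsvCols(bc)[[1]]
    ft <- .readTsvCols(feat)
    if (nrow(counts) != nrow(ft))
        stop("integrity error: matrix has ", nrow(counts),
             " rows but ", basename(feat), " lists ", nrow(ft), " genes")
    if (ncol(counts) != length(barcodes))
        stop("integrity error: matrix has ", ncol(counts),
             " columns but ", basename(bc), " lists ", length(barcodes),
             " barcodes")
    geneNames <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
    DebrisExperiment(counts, geneIds = ft[[1]], geneNames = geneNames,
                     barcodes = barcodes)
}

#' Write a count matrix as a CellRanger-style triplet
#'
#' @param x a \linkS4class{DebrisExperiment} (or SingleCellExperiment with a
#'   \code{counts} assay).
#' @param dir output directory (created if absent).
#' @param version \code{"v2"} (plain \code{genes.tsv}, 2 columns) or
#'   \code{"v3"} (gzipped \code{features.tsv.gz}, 3 columns with a
#'   \code{"Gene Expression"} feature type).
#' @return \code{dir}, invisibly.
#' @export
writeTenX <- function(x, dir, version = c("v2", "v3")) {
    version <- match.arg(version)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    counts <- SummarizedExperiment::assay(x, "counts")
    rd <- SummarizedExperiment::rowData(x)
    geneNames <- if ("gene_name" %in% colnames(rd)) rd$gene_name
                 else rownames(x)
    gz <- version == "v3"
    sfx <- if (gz) ".gz" else ""
    mtxPath <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(as(counts, "CsparseMatrix"), mtxPath)
    if (gz) {
        lines <- readLines(mtxPath)
        con <- gzfile(paste0(mtxPath, ".gz"), "wt")
        writeLines(lines, con); close(con)
        unlink(mtxPath)
    }
    .writeTsv <- function(df, name) {
        path <- file.path(dir, paste0(name, sfx))
        con <- if (gz) gzfile(path, "wt") else file(path, "wt")
        write.table(df, con, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        close(con)
    }
    .writeTsv(data.frame(colnames(counts)), "barcodes.tsv")
    if (version == "v2") {
        .writeTsv(data.frame(rownames(counts), geneNames), "genes.tsv")
    } else {
        .writeTsv(data.frame(rownames(counts), geneNames,
                             "Gene Expression"), "features.tsv")
    }
    invisible(dir)
}

#' @rdname accessors
#' @export
setMethod("dropletStats", "DebrisExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(barcode = cd$barcode,
               total_counts = cd$total_counts,
               genes_detected = cd$genes_detected,
               row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("dropletStats", "ANY", function(x) {
    m <- asCountMatrix(x)
    data.frame(barcode = colnames(m),
               total_counts = Matrix::colSums(m),
               genes_detected = Matrix::colSums(m > 0),
               row.names = NULL, stringsAsFactors = FALSE)
})

#' Barcode-rank quantile count threshold
#'
#' The baseline hard-count filter used by CellRanger-style pipelines:
#' droplets are ranked in decreasing order of total UMI counts, the stated
#' quantile (default the 99th percentile) of the top \code{topC} totals is
#' computed, and divided by \code{divisor} to give the count threshold.
#' Using a high quantile rather than the maximum avoids anchoring the
#' threshold on doublets.  The quantile uses linear interpolation between
#' order statistics (R's default type-7 convention).
#'
#' @param totals numeric vector of per-droplet total counts (or a
#'   data.frame from \code{\link{dropletStats}}).
#' @param topC number of top barcodes used to derive the threshold.
#' @param q quantile level of the top totals.
#' @param divisor divisor applied to the quantile.
#' @return The count threshold (a single number).
#' @examples
#' quantileThreshold(rep(100, 4000))  # 10
#' @export
quantileThreshold <- function(totals, topC = 3000, q = 0.99, divisor = 10) {
    if (is.data.frame(totals)) totals <- totals$total_counts
    if (length(totals) < 1L) stop("at least one droplet is required")
    if (topC < 1L) stop("topC must be >= 1")
    if (length(totals) < topC) {
        warning("fewer droplets (", length(totals), ") than topC (", topC,
                "); using all droplets")
        topC <- length(totals)
    }
    top <- sort(totals, decreasing = TRUE)[seq_len(topC)]
    unname(quantile(top, probs = q, type = 7)) / divisor
}

#' Partition droplets by a count threshold
#'
#' Droplets with total counts greater than or equal to the threshold are
#' kept (putative nuclei); the rest are removed.
#'
#' @param x a \linkS4class{DebrisExperiment} or a
#'   \code{\link{dropletStats}} data.frame.
#' @param threshold count threshold (inclusive on the kept side).
#' @return A list with character vectors \code{kept} and \code{removed};
#'   together they partition the barcodes.
#' @export
filterByCount <- function(x, threshold) {
    if (threshold < 0) stop("threshold must be >= 0")
    st <- if (is.data.frame(x)) x else dropletStats(x)
    keep <- st$total_counts >= threshold
    list(kept = st$barcode[keep], removed = st$barcode[!keep])
}
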
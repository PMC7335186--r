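#' Generate ambient and cell-type expression profiles
#'
#' Draws cell-type gene-probability vectors from a symmetric Dirichlet and
#' builds the ambient profile from its own base draw by boosting a random
#' subset of debris-marker genes by \code{markerBoost} and renormalizing.
#' A moderately large \code{concentration} keeps the profiles correlated,
#' as real cell types are (they share most of the transcriptome and differ
#' in a minority of genes); the marker boost makes the ambient pool
#' recognizably distinct, mirroring the strong compositional differences
#' observed between debris and nuclear RNA.
#'
#' @param nGenes number of genes (default 1000).
#' @param nTypes number of cell types (default 3).
#' @param concentration symmetric Dirichlet concentration per gene
#'   (default 5).
#' @param nDebrisMarkers number of genes boosted in the ambient profile
#'   (default 50; must be < \code{nGenes}).
#' @param markerBoost multiplicative boost of marker genes in the ambient
#'   profile (default 5; must be >= 1, 1 = no boost).
#' @param seed integer seed.
#' @return A list with \code{ambient} (named probability vector),
#'   \code{types} (type-by-gene probability matrix), \code{markers}
#'   (marker gene ids) and \code{geneIds}.
#' @export
makeProfiles <- function(nGenes = 1000, nTypes = 3, concentration = 5,
                         nDebrisMarkers = 50, markerBoost = 5, seed = 1) {
    if (nDebrisMarkers >= nGenes)
        stop("nDebrisMarkers must be < nGenes")
    if (markerBoost < 1) stop("markerBoost must be >= 1")
    if (nTypes < 1 || nGenes < 2 || concentration <= 0)
        stop("invalid profile parameters")
    withSeed(seed, {
        geneIds <- sprintf("gene%04d", seq_len(nGenes))
        rdirichlet1 <- function() {
            g <- rgamma(nGenes, shape = concentration)
            g / sum(g)
        }
        types <- t(vapply(seq_len(nTypes), function(i) rdirichlet1(),
                          numeric(nGenes)))
        colnames(types) <- geneIds
        rownames(types) <- paste0("type", seq_len(nTypes))
        ambient <- rdirichlet1()
        markers <- sort(sample(nGenes, nDebrisMarkers))
        ambient[markers] <- ambient[markers] * markerBoost
        ambient <- ambient / sum(ambient)
        names(ambient) <- geneIds
        list(ambient = ambient, types = types,
             markers = geneIds[markers], geneIds = geneIds)
    })
}

# Integer totals drawn log-uniformly over [lo, hi).
.logUniformSizes <- function(n, lo, hi) {
    pmax(1L, as.integer(floor(exp(runif(n, log(lo), log(hi))))))
}

#' Simulate a droplet count matrix with known ambient structure
#'
#' Emulates the generative picture behind debris filtering: a long tail of
#' empty droplets drawing counts from the ambient profile alone, and
#' nucleus droplets whose counts mix their cell-type profile with the
#' ambient profile according to a per-droplet contamination fraction
#' \eqn{\rho \sim \mathrm{Beta}(a, b)}.  Each nucleus draws its total
#' \eqn{u} log-uniformly from \code{nucleusSizeRange}, the number of
#' ambient molecules as \eqn{\mathrm{Binomial}(u, \rho)}, and gene counts
#' from the corresponding multinomials (marginally a multinomial with
#' mixed probabilities \eqn{(1-\rho)\,p_{type} + \rho\,p_{amb}}).  Empty
#' droplet totals are drawn log-uniformly from \code{emptySizeRange},
#' whose default keeps most (about two thirds) of them below 100 counts
#' while leaving an ambient tail at higher depth -- the regime in which
#' hard count thresholds fail.  Droplet order is shuffled.
#'
#' @param profiles output of \code{\link{makeProfiles}}.
#' @param nEmpty number of empty (ambient-only) droplets (default 5000).
#' @param nPerType nuclei per cell type (default 300).
#' @param emptySizeRange,nucleusSizeRange total-count ranges, log-uniform
#'   (defaults \code{c(1, 1000)} and \code{c(150, 5000)}).
#' @param contaminationBeta length-2 shape parameters of the Beta
#'   contamination-fraction distribution (default \code{c(1, 9)}, mean
#'   0.1).
#' @param seed integer seed; the same seed and parameters reproduce the
#'   counts exactly (R's default Mersenne-Twister generator).
#' @return A list with \code{experiment} (a
#'   \linkS4class{DebrisExperiment}) and \code{truth}, a data.frame with
#'   per-droplet \code{barcode}, \code{origin} (\code{"empty"} /
#'   \code{"nucleus"}), \code{cell_type} (NA for empties),
#'   \code{ambient_fraction} (the drawn \eqn{\rho}; 1 for empties),
#'   \code{ambient_molecules}, \code{total_count}, plus the seed and
#'   parameter record as attributes.
#' @export
simulateDroplets <- function(profiles, nEmpty = 5000, nPerType = 300,
                             emptySizeRange = c(1, 1000),
                             nucleusSizeRange = c(150, 5000),
                             contaminationBeta = c(1, 9), seed = 1) {
    stopifnot(length(emptySizeRange) == 2, length(nucleusSizeRange) == 2,
              all(emptySizeRange > 0), all(nucleusSizeRange > 0),
              length(contaminationBeta) == 2, all(contaminationBeta > 0))
    nTypes <- nrow(profiles$types)
    nNuc <- nTypes * nPerType
    withSeed(seed, {
        uEmpty <- .logUniformSizes(nEmpty, emptySizeRange[1],
                                   emptySizeRange[2])
        uNuc <- .logUniformSizes(nNuc, nucleusSizeRange[1],
                                 nucleusSizeRange[2])
        type <- rep(seq_len(nTypes), each = nPerType)
        rho <- rbeta(nNuc, contaminationBeta[1], contaminationBeta[2])
        nAmb <- rbinom(nNuc, uNuc, rho)

        G <- length(profiles$geneIds)
        counts <- matrix(0L, G, nEmpty + nNuc)
        for (i in seq_len(nEmpty))
            counts[, i] <- rmultinom(1, uEmpty[i], profiles$ambient)
        for (j in seq_len(nNuc)) {
            cj <- rmultinom(1, nAmb[j], profiles$ambient) +
                rmultinom(1, uNuc[j] - nAmb[j], profiles$types[type[j], ])
            counts[, nEmpty + j] <- cj
        }
        barcodes <- sprintf("BC%06d", seq_len(nEmpty + nNuc))
        truth <- data.frame(
            barcode = barcodes,
            origin = rep(c("empty", "nucleus"), c(nEmpty, nNuc)),
            cell_type = c(rep(NA_integer_, nEmpty), type),
            ambient_fraction = c(rep(1, nEmpty), rho),
            ambient_molecules = c(uEmpty, nAmb),
            total_count = c(uEmpty, uNuc),
            stringsAsFactors = FALSE)
        perm <- sample(nEmpty + nNuc)
        counts <- counts[, perm, drop = FALSE]
        truth <- truth[perm, , drop = FALSE]
        rownames(truth) <- NULL
        rownames(counts) <- profiles$geneIds
        colnames(counts) <- truth$barcode
        attr(truth, "seed") <- seed
        attr(truth, "rng") <- RNGkind()[1]
        attr(truth, "params") <- list(
            nEmpty = nEmpty, nPerType = nPerType,
            emptySizeRange = emptySizeRange,
            nucleusSizeRange = nucleusSizeRange,
            contaminationBeta = contaminationBeta)
        list(experiment = DebrisExperiment(counts), truth = truth)
    })
}

#' Simulate per-droplet spliced/unspliced counts
#'
#' Labels each molecule spliced by a Bernoulli draw whose probability
#' depends on the molecule's origin within the droplet: ambient molecules
#' (cytoplasmic, mostly mature mRNA) are spliced with probability
#' \code{pSplicedAmbient}, nuclear molecules (rich in unspliced pre-mRNA)
#' with probability \code{pSplicedNuclear}.  Aggregated per droplet in the
#' layout consumed by \code{\link{percentSpliced}}.
#'
#' @param truth truth table from \code{\link{simulateDroplets}}.
#' @param pSplicedAmbient,pSplicedNuclear splice probabilities in [0, 1]
#'   (defaults 0.8 and 0.25).
#' @param seed integer seed.
#' @return A data.frame with \code{barcode}, \code{spliced},
#'   \code{unspliced}, \code{ambiguous} (0).
#' @export
simulateSplice <- function(truth, pSplicedAmbient = 0.8,
                           pSplicedNuclear = 0.25, seed = 1) {
    stopifnot(pSplicedAmbient >= 0, pSplicedAmbient <= 1,
              pSplicedNuclear >= 0, pSplicedNuclear <= 1)
    withSeed(seed, {
        nAmb <- truth$ambient_molecules
        nNuc <- truth$total_count - nAmb
        spliced <- rbinom(nrow(truth), nAmb, pSplicedAmbient) +
            rbinom(nrow(truth), nNuc, pSplicedNuclear)
        data.frame(barcode = truth$barcode,
                   spliced = spliced,
                   unspliced = truth$total_count - spliced,
                   ambiguous = 0L,
                   stringsAsFactors = FALSE)
    })
}
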
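suppressPackageStartupMessages({
    library(Matrix)
    library(SummarizedExperiment)
})

# Tiny deterministic count matrix with named genes/barcodes.
tinyCounts <- function(values, nGenes, nDroplets) {
    m <- matrix(as.numeric(values), nGenes, nDroplets)
    dimnames(m) <- list(sprintf("g%02d", seq_len(nGenes)),
                        sprintf("bc%02d", seq_len(nDroplets)))
    m
}

# Random sparse count matrix for property-style loops.
randomCounts <- function(nGenes, nDroplets, lambda = 2) {
    m <- matrix(as.numeric(rpois(nGenes * nDroplets, lambda)),
                nGenes, nDroplets)
    dimnames(m) <- list(sprintf("g%03d", seq_len(nGenes)),
                        sprintf("bc%03d", seq_len(nDroplets)))
    m
}

# Random valid mixture parameters.
randomParams <- function(K, G) {
    a <- matrix(rgamma(K * G, 1) + 1e-8, K, G)
    a <- a / rowSums(a)
    p <- rgamma(K, 1) + 1e-8
    debrisEM:::MultinomMixture(alpha = a, pi = p / sum(p))
}

# Direct-Bayes posterior oracle: full multinomial pmf per component.
bayesPosteriorOracle <- function(counts, alpha, pi) {
    t(apply(counts, 2L, function(x) {
        lp <- vapply(seq_len(nrow(alpha)), function(k) {
            log(pi[k]) + lgamma(sum(x) + 1) - sum(lgamma(x + 1)) +
                sum(ifelse(x > 0, x * log(alpha[k, ]), 0))
        }, numeric(1))
        w <- exp(lp - max(lp))
        w / sum(w)
    }))
}

# Brute-force Benjamini-Hochberg step-up.
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

# Independent sort-and-index quantile oracle (type-7 linear interpolation).
quantileOracle <- function(totals, topC, q) {
    top <- sort(totals, decreasing = TRUE)[seq_len(topC)]
    v <- sort(top)
    h <- (length(v) - 1) * q
    lo <- floor(h)
    v[lo + 1] + (h - lo) * (v[min(lo + 2, length(v))] - v[lo + 1])
}

# Total-variation distance between probability vectors.
tvDist <- function(p, q) 0.5 * sum(abs(p - q))

# Analytic equal-density point of a two-Gaussian mixture.
analyticMidpoint <- function(mu, sigma, w) {
    f <- function(x) w[1] * dnorm(x, mu[1], sigma[1]) -
        w[2] * dnorm(x, mu[2], sigma[2])
    uniroot(f, interval = mu, tol = 1e-12)$root
}

# Small shared simulation for module-level tests.
smallSim <- function(seed = 42, nGenes = 200, nTypes = 2,
                     nEmpty = 600, nPerType = 80) {
    prof <- makeProfiles(nGenes = nGenes, nTypes = nTypes, seed = seed)
    sim <- simulateDroplets(prof, nEmpty = nEmpty, nPerType = nPerType,
                            seed = seed)
    sim$profiles <- prof
    sim
}
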
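#' @importFrom methods is new validObject
#' @importFrom stats kmeans loess median p.adjust pnorm prcomp pt quantile
#'   rbeta rbinom rgamma rmultinom runif sd var
#' @importFrom utils read.delim write.table
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic entry points route
# through this so a user-visible seed argument is sufficient for exact
# reproducibility.
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old))
                rm(".Random.seed", envir = globalenv())
            else
                assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(code)
}

# Row-wise log(sum(exp(x))) with max subtraction; x is a dense matrix.
rowLogSumExp <- function(x) {
    m <- apply(x, 1L, max)
    finite <- is.finite(m)
    out <- m
    if (any(finite)) {
        xs <- x[finite, , drop = FALSE] - m[finite]
        out[finite] <- m[finite] + log(rowSums(exp(xs)))
    }
    out
}

# Coerce any matrix-like input to a column-sparse dgCMatrix of counts,
# validating non-negativity and integrality.
asCountMatrix <- function(x) {
    x <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    v <- x@x
    if (length(v) && (any(v < 0) || any(v != floor(v))))
        stop("counts must be non-negative integers")
    x
}

# Per-gene mean and variance across the columns of a sparse matrix,
# without densifying.
sparseRowMeanVar <- function(x) {
    n <- ncol(x)
    mu <- Matrix::rowSums(x) / n
    ex2 <- Matrix::rowSums(x^2) / n
    v <- (ex2 - mu^2) * n / (n - 1)
    v[v < 0] <- 0
    list(mean = mu, var = v)
}
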
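#' Multinomial log-probability of a droplet's counts
#'
#' Computes \eqn{\sum_g x_g \log \alpha_{kg}}, the multinomial
#' log-probability of a count vector up to the multinomial coefficient.
#' The coefficient depends only on the counts, cancels in the component
#' posteriors, and is therefore omitted by default throughout the mixture
#' fit; set \code{includeCoef = TRUE} for the full log pmf.  Reported
#' log-likelihoods are consequently comparable only within a run computed
#' under the same convention.
#'
#' @param x non-negative integer count vector.
#' @param alphaK probability vector over genes (same length).
#' @param includeCoef include the multinomial coefficient
#'   \eqn{\log u! - \sum_g \log x_g!}.
#' @return A single number (may be \code{-Inf} if a zero-probability gene
#'   has a positive count).
#' @examples
#' multinomLogProb(c(1, 0), c(0.5, 0.5))  # log(0.5)
#' @export
multinomLogProb <- function(x, alphaK, includeCoef = FALSE) {
    pos <- x > 0
    lp <- sum(x[pos] * log(alphaK[pos]))
    if (includeCoef)
        lp <- lp + lgamma(sum(x) + 1) - sum(lgamma(x[pos] + 1))
    lp
}

# Droplet-by-component matrix of sum_g x_g log(alpha_kg).
.logProbMatrix <- function(counts, alpha) {
    as.matrix(Matrix::crossprod(counts, t(log(alpha))))
}

#' E-step: posterior component membership
#'
#' Computes, in log space with max subtraction for numerical stability,
#' the posterior probability that each droplet belongs to each mixture
#' component given current parameters.  Droplets flagged in \code{fixed}
#' are the semi-supervised debris set: their posteriors are overwritten
#' with a one-hot vector at the debris component regardless of their
#' counts.
#'
#' @param counts gene-by-droplet sparse count matrix (expressed genes).
#' @param params a \linkS4class{MultinomMixture}.
#' @param fixed logical vector over droplets (default none fixed).
#' @return Droplet-by-component posterior matrix; rows sum to 1.
#' @export
eStep <- function(counts, params, fixed = NULL) {
    counts <- asCountMatrix(counts)
    if (is.null(fixed)) fixed <- rep(FALSE, ncol(counts))
    lp <- sweep(.logProbMatrix(counts, params@alpha), 2L,
                log(params@pi), "+")
    m <- apply(lp, 1L, max)
    if (any(!is.finite(m)))
        stop("a droplet has -Inf likelihood in every component")
    post <- exp(lp - m)
    post <- post / rowSums(post)
    if (any(fixed)) {
        post[fixed, ] <- 0
        post[fixed, params@debrisIndex] <- 1
    }
    rownames(post) <- colnames(counts)
    post
}

#' M-step: maximum-likelihood parameter updates
#'
#' Gene probabilities of component k are the posterior-weighted mean of the
#' droplet counts plus a pseudocount (which prevents the likelihood from
#' collapsing to zero on unseen genes), renormalized; mixing weights are
#' the mean posterior membership.
#'
#' @param counts gene-by-droplet sparse count matrix.
#' @param posterior droplet-by-component posterior matrix.
#' @param pseudocount added per gene to the weighted counts (default 1e-10).
#' @param debrisIndex index of the debris component carried into the
#'   returned object.
#' @return A \linkS4class{MultinomMixture} with updated \code{alpha} and
#'   \code{pi}.
#' @export
mStep <- function(counts, posterior, pseudocount = 1e-10, debrisIndex = 1L) {
    counts <- asCountMatrix(counts)
    w <- t(as.matrix(counts %*% posterior))   # components x genes
    if (any(rowSums(w) == 0))
        warning("component(s) with zero posterior mass; ",
                "pseudocount yields a uniform profile")
    w <- w + pseudocount
    alpha <- w / rowSums(w)
    colnames(alpha) <- rownames(counts)
    MultinomMixture(alpha = alpha,
                    pi = colSums(posterior) / nrow(posterior),
                    debrisIndex = as.integer(debrisIndex))
}

#' Observed-data log-likelihood
#'
#' For unconstrained droplets the mixture log-likelihood
#' \eqn{\sum_i \log \sum_k \pi_k \mathrm{Mult}(x_i \mid \alpha_k)}; droplets
#' in the fixed debris set contribute their debris-component term
#' \eqn{\log \pi_{deb} + \log \mathrm{Mult}(x_i \mid \alpha_{deb})} instead,
#' since their labels are observed under the semi-supervised model.  This
#' is the objective that EM increases monotonically.  The multinomial
#' coefficient is omitted unless \code{includeCoef = TRUE} (same convention
#' as \code{\link{multinomLogProb}}).
#'
#' @inheritParams eStep
#' @param includeCoef include the count-only multinomial coefficient.
#' @return A single number.
#' @export
observedLogLik <- function(counts, params, fixed = NULL,
                           includeCoef = FALSE) {
    counts <- asCountMatrix(counts)
    if (is.null(fixed)) fixed <- rep(FALSE, ncol(counts))
    lp <- sweep(.logProbMatrix(counts, params@alpha), 2L,
                log(params@pi), "+")
    per <- rowLogSumExp(lp)
    if (any(fixed)) per[fixed] <- lp[fixed, params@debrisIndex]
    ll <- sum(per)
    if (includeCoef) {
        u <- Matrix::colSums(counts)
        v <- counts@x
        ll <- ll + sum(lgamma(u + 1)) - sum(lgamma(v + 1))
    }
    ll
}

#' Fit the semi-supervised multinomial mixture by EM
#'
#' Alternates \code{\link{eStep}} and \code{\link{mStep}} from the given
#' starting parameters until the maximum absolute change over all entries
#' of \code{alpha} and \code{pi} falls below \code{eps}, or \code{maxIter}
#' is reached.  Droplets in \code{fixed} keep a one-hot debris posterior
#' at every iteration.  The run is deterministic given the initialization.
#'
#' @inheritParams eStep
#' @param init a \linkS4class{MultinomMixture} starting point (see
#'   \code{\link{initialParameters}}).
#' @param eps convergence tolerance on the parameter change (default 1e-4).
#' @param maxIter iteration cap (default 1000).
#' @param pseudocount M-step pseudocount (default 1e-10).
#' @return A \linkS4class{MultinomMixture} with final parameters, the
#'   per-droplet posterior matrix, the fixed mask, the iteration trace
#'   (semi-supervised log-likelihood and parameter delta), and the
#'   convergence flag.
#' @export
runEM <- function(counts, init, fixed = NULL, eps = 1e-4, maxIter = 1000,
                  pseudocount = 1e-10) {
    counts <- asCountMatrix(counts)
    if (is.null(fixed)) fixed <- rep(FALSE, ncol(counts))
    stopifnot(length(fixed) == ncol(counts))
    params <- init
    trace <- vector("list", maxIter)
    converged <- FALSE
    iter <- 0L
    post <- NULL
    while (iter < maxIter) {
        iter <- iter + 1L
        post <- eStep(counts, params, fixed)
        newp <- mStep(counts, post, pseudocount = pseudocount,
                      debrisIndex = params@debrisIndex)
        delta <- max(max(abs(newp@alpha - params@alpha)),
                     max(abs(newp@pi - params@pi)))
        params <- newp
        trace[[iter]] <- data.frame(
            iter = iter,
            logLik = observedLogLik(counts, params, fixed),
            delta = delta)
        if (delta < eps) { converged <- TRUE; break }
    }
    if (!converged)
        warning("EM did not converge in ", maxIter, " iterations")
    post <- eStep(counts, params, fixed)
    MultinomMixture(alpha = params@alpha, pi = params@pi,
                    debrisIndex = params@debrisIndex, posterior = post,
                    fixed = fixed,
                    trace = do.call(rbind, trace[seq_len(iter)]),
                    converged = converged)
}

#' Hard component assignment from posteriors
#'
#' Each droplet is assigned to the component with the maximum posterior
#' probability; exact ties go to the lowest component index (so a tie with
#' the debris component resolves to debris).
#'
#' @param posterior droplet-by-component posterior matrix, or a fitted
#'   \linkS4class{MultinomMixture}.
#' @return Integer component labels (1 = debris), named by droplet.
#' @export
assignClusters <- function(posterior) {
    if (is(posterior, "MultinomMixture")) posterior <- posterior@posterior
    lab <- max.col(posterior, ties.method = "first")
    names(lab) <- rownames(posterior)
    lab
}
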
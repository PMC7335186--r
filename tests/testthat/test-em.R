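test_that("multinomial log-probability matches enumerated pmfs", {
    expect_equal(multinomLogProb(c(1, 0), c(0.5, 0.5)), log(0.5))
    # x=(2,1), alpha=(2/3,1/3) with coefficient: 3 * (2/3)^2 * (1/3) = 4/9
    expect_equal(multinomLogProb(c(2, 1), c(2/3, 1/3), includeCoef = TRUE),
                 log(4/9))
    # adding a zero-count gene changes nothing
    expect_equal(multinomLogProb(c(2, 1, 0), c(0.6, 0.3, 0.1)),
                 multinomLogProb(c(2, 1), c(0.6, 0.3)) + 0)
})

test_that("E-step equals direct Bayes computation on enumerable toys", {
    # 2-gene, 2-component toy, hand-checkable
    alpha <- rbind(c(0.9, 0.1), c(0.1, 0.9))
    params <- debrisEM:::MultinomMixture(alpha = alpha, pi = c(0.4, 0.6))
    x <- tinyCounts(c(3, 1), 2, 1)
    post <- eStep(x, params)
    num <- c(0.4 * 0.9^3 * 0.1, 0.6 * 0.1^3 * 0.9)
    expect_equal(as.numeric(post), num / sum(num), tolerance = 1e-12)
    # random toys against the full-pmf oracle (coefficient cancels)
    set.seed(11)
    for (i in 1:10) {
        cnt <- randomCounts(5, 8)
        pr <- randomParams(3, 5)
        expect_equal(unname(eStep(cnt, pr)),
                     unname(bayesPosteriorOracle(cnt, pr@alpha, pr@pi)),
                     tolerance = 1e-12)
    }
})

test_that("E-step symmetry and the semi-supervision contract hold", {
    alpha <- rbind(c(0.3, 0.7), c(0.3, 0.7))
    params <- debrisEM:::MultinomMixture(alpha = alpha, pi = c(0.5, 0.5))
    cnt <- randomCounts(2, 6)
    post <- eStep(cnt, params)
    expect_equal(unname(post), matrix(0.5, 6, 2), tolerance = 1e-12)
    fixed <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
    postf <- eStep(cnt, params, fixed)
    expect_equal(unname(postf[fixed, ]),
                 matrix(c(1, 1, 0, 0), 2, 2))
    expect_equal(rowSums(postf), rep(1, 6), ignore_attr = TRUE)
})

test_that("M-step recovers pooled proportions under one-hot posteriors", {
    set.seed(12)
    cnt <- randomCounts(6, 20)
    lab <- sample(1:3, 20, replace = TRUE)
    post <- diag(3)[lab, ]
    p <- mStep(cnt, post)
    for (k in 1:3) {
        pooled <- rowSums(cnt[, lab == k, drop = FALSE])
        expect_equal(unname(alphaParams(p)[k, ]),
                     unname(pooled / sum(pooled)), tolerance = 1e-8)
    }
    expect_equal(mixWeights(p), as.numeric(table(lab)) / 20)
    expect_warning(mStep(cnt, cbind(post, 0)), "zero posterior mass")
})

test_that("a converged fit is a fixed point of the EM map", {
    set.seed(13)
    cnt <- randomCounts(8, 60, lambda = 4)
    fixed <- colSums(cnt) < quantile(colSums(cnt), 0.3)
    fit <- runEM(cnt, randomParams(3, 8), fixed, eps = 1e-10,
                 maxIter = 3000)
    p2 <- mStep(cnt, eStep(cnt, fit, fixed))
    expect_lt(max(abs(alphaParams(p2) - alphaParams(fit))), 1e-8)
    expect_lt(max(abs(mixWeights(p2) - mixWeights(fit))), 1e-8)
})

test_that("K=1 with no fixed droplets converges to the closed-form MLE", {
    set.seed(14)
    cnt <- randomCounts(10, 40)
    fit <- runEM(cnt, randomParams(1, 10), eps = 1e-10)
    pooled <- rowSums(cnt) / sum(cnt)
    expect_equal(unname(alphaParams(fit)[1, ]), unname(pooled),
                 tolerance = 1e-8)
    expect_equal(mixWeights(fit), 1)
})

test_that("the EM fit is invariant to droplet order", {
    set.seed(15)
    cnt <- randomCounts(6, 50)
    fixed <- colSums(cnt) < median(colSums(cnt))
    init <- randomParams(3, 6)
    fit1 <- runEM(cnt, init, fixed)
    perm <- sample(50)
    fit2 <- runEM(cnt[, perm], init, fixed[perm])
    expect_equal(alphaParams(fit2), alphaParams(fit1), tolerance = 1e-10)
    expect_equal(posteriorProbs(fit2),
                 posteriorProbs(fit1)[perm, ], tolerance = 1e-10)
})

test_that("semi-supervised log-likelihood never decreases across EM", {
    set.seed(16)
    for (i in 1:15) {
        G <- sample(4:20, 1); N <- sample(20:200, 1); K <- sample(1:4, 1)
        cnt <- randomCounts(G, N)
        fixed <- runif(N) < 0.3
        fit <- runEM(cnt, randomParams(K + 1, G), fixed, eps = 1e-6,
                     maxIter = 300)
        ll <- emTrace(fit)$logLik
        if (length(ll) > 1) {
            d <- diff(ll)
            expect_true(all(d >= -1e-8 * abs(ll[-length(ll)])))
        }
        # fixed posteriors one-hot at the debris component
        post <- posteriorProbs(fit)
        expect_equal(unname(post[fixed, 1]), rep(1, sum(fixed)))
    }
})

test_that("posteriors are unaffected by the multinomial coefficient", {
    set.seed(17)
    cnt <- randomCounts(5, 10)
    pr <- randomParams(3, 5)
    # oracle includes the coefficient; eStep omits it
    expect_equal(unname(eStep(cnt, pr)),
                 unname(bayesPosteriorOracle(cnt, pr@alpha, pr@pi)),
                 tolerance = 1e-12)
    # observed log-likelihood differs exactly by the count-only constant
    base <- observedLogLik(cnt, pr)
    full <- observedLogLik(cnt, pr, includeCoef = TRUE)
    const <- sum(vapply(seq_len(ncol(cnt)), function(i) {
        x <- cnt[, i]
        lgamma(sum(x) + 1) - sum(lgamma(x + 1))
    }, numeric(1)))
    expect_equal(full - base, const, tolerance = 1e-10)
})

test_that("observed log-likelihood matches brute-force summation", {
    alpha <- rbind(c(0.8, 0.2), c(0.3, 0.7))
    params <- debrisEM:::MultinomMixture(alpha = alpha, pi = c(0.25, 0.75))
    cnt <- tinyCounts(c(2, 0, 1, 3, 0, 4), 2, 3)
    brute <- sum(apply(cnt, 2, function(x)
        log(sum(params@pi * c(exp(sum(x * log(alpha[1, ]))),
                              exp(sum(x * log(alpha[2, ]))))))))
    expect_equal(observedLogLik(cnt, params), brute, tolerance = 1e-12)
    # one droplet, one component: just that droplet's log pmf term
    p1 <- debrisEM:::MultinomMixture(alpha = alpha[1, , drop = FALSE],
                                     pi = 1)
    x1 <- tinyCounts(c(2, 5), 2, 1)
    expect_equal(observedLogLik(x1, p1),
                 multinomLogProb(c(2, 5), alpha[1, ]))
})

test_that("hard assignment takes the argmax with ties to lowest index", {
    post <- rbind(c(0.7, 0.3), c(0.5, 0.5), c(0.2, 0.8))
    rownames(post) <- paste0("b", 1:3)
    expect_equal(unname(assignClusters(post)), c(1L, 1L, 2L))
})
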
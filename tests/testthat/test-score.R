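test_that("debris-cluster definition applies the mean-genes rule", {
    clusters <- rep(1:3, each = 4)
    genes <- c(rep(500, 4), c(199, 200, 199, 200),  # cluster 2 mean 199.5
               rep(200, 4))                          # cluster 3 mean 200
    expect_equal(defineDebrisClusters(clusters, genes, d = 200),
                 c(1L, 2L))
    # fixed cluster always debris, even with a high mean
    expect_equal(defineDebrisClusters(clusters, rep(1000, 12), d = 200), 1L)
    expect_equal(defineDebrisClusters(clusters, genes, d = 0), 1L)
    expect_error(defineDebrisClusters(rep(1L, 5), rep(10, 5), d = 200),
                 "no cell-type clusters")
})

test_that("DE normalization gives depth-invariant log proportions", {
    m <- tinyCounts(c(2, 2), 2, 1)
    nm <- normalizeForDE(m)
    expect_equal(as.numeric(nm), rep(log(1.5), 2))
    m2 <- tinyCounts(c(0, 4), 2, 1)
    expect_equal(as.numeric(normalizeForDE(m2)), c(0, log(2)))
    set.seed(21)
    r <- randomCounts(10, 5)
    expect_equal(as.matrix(normalizeForDE(r)),
                 as.matrix(normalizeForDE(r * 3L)), tolerance = 1e-12)
})

test_that("Welch t, df and BH q-values match brute-force oracles", {
    set.seed(22)
    m <- randomCounts(40, 10, lambda = 5)
    nm <- normalizeForDE(m)
    deb <- colnames(m)[1:5]; cel <- colnames(m)[6:10]
    de <- debrisDE(nm, deb, cel)
    dn <- as.matrix(nm)
    for (g in sample(nrow(m), 10)) {
        a <- dn[g, deb]; b <- dn[g, cel]
        if (sd(a) == 0 && sd(b) == 0) next
        tt <- t.test(a, b, var.equal = FALSE)
        expect_equal(de$t_statistic[g], unname(tt$statistic),
                     tolerance = 1e-10)
        expect_equal(de$df[g], unname(tt$parameter), tolerance = 1e-10)
        expect_equal(de$p_value[g], tt$p.value, tolerance = 1e-10)
        expect_equal(de$log_fold_change[g], mean(a) - mean(b),
                     tolerance = 1e-12)
    }
    expect_equal(de$q_value, bhOracle(de$p_value), tolerance = 1e-12)
    expect_equal(de$enriched, de$log_fold_change > 0 & de$q_value < 0.05)
    expect_error(debrisDE(nm, deb[1], cel), "at least 2")
})

test_that("degenerate genes get p = 1 and DE keeps sign contracts", {
    m <- tinyCounts(0, 3, 8)
    m[1, ] <- 5                      # constant everywhere
    m[2, 1:4] <- c(1, 2, 1, 2)       # expressed only in debris group
    m[3, ] <- rep(c(1, 3), 4)
    nm <- normalizeForDE(m)
    de <- debrisDE(nm, colnames(m)[1:4], colnames(m)[5:8])
    expect_equal(de$p_value[2] < 1, TRUE)
    expect_gt(de$log_fold_change[2], 0)
    # gene 1: proportions differ between groups only via totals; make a
    # truly constant normalized gene instead
    m2 <- tinyCounts(rep(c(2, 2), 8), 2, 8)
    de2 <- debrisDE(normalizeForDE(m2), paste0("bc0", 1:4),
                    paste0("bc0", 5:8))
    expect_equal(de2$t_statistic, c(0, 0))
    expect_equal(de2$p_value, c(1, 1))
    expect_false(any(de2$enriched))
})

test_that("raw scores sum normalized expression over the gene set", {
    m <- tinyCounts(c(1, 1, 2, 0, 0, 4, 2, 2, 0), 3, 3)
    nm <- normalizeForDE(m)
    sc <- scoreDroplets(nm, c("g01", "g02"))
    expect_equal(unname(sc), colSums(as.matrix(nm)[c(1, 2), ]),
                 ignore_attr = TRUE)
    # droplet expressing none of the enriched genes scores 0
    expect_equal(unname(scoreDroplets(nm, "g01")[2]), 0)
    # adding an enriched gene with positive expression raises the score
    expect_true(all(scoreDroplets(nm, c("g01", "g03")) >=
                    scoreDroplets(nm, "g01")))
    expect_error(scoreDroplets(nm, character(0)), "no debris-enriched")
    expect_error(scoreDroplets(nm, "nope"), "unknown gene ids")
})

test_that("score normalization anchors cluster means at 0 and 1", {
    set.seed(23)
    clusters <- c(rep(1L, 30), rep(2L, 40), rep(3L, 30))
    raw <- c(rnorm(30, 10), rnorm(40, 2), rnorm(30, 5))
    ns <- normalizeScores(raw, clusters, debrisSet = 1L)
    expect_equal(mean(ns[clusters == 2]), 0, tolerance = 1e-10)
    expect_equal(mean(ns[clusters == 1]), 1, tolerance = 1e-10)
    # affine invariance
    ns2 <- normalizeScores(3 * raw + 7, clusters, debrisSet = 1L)
    expect_equal(ns2, ns, tolerance = 1e-9)
    # midway droplet
    mLow <- mean(raw[clusters == 2]); mDeb <- mean(raw[clusters == 1])
    raw2 <- c(raw, (mLow + mDeb) / 2)
    ns3 <- normalizeScores(raw2, c(clusters, 3L), debrisSet = 1L)
    expect_equal(unname(ns3[101]), 0.5, tolerance = 1e-10)
    # debris clusters must score above the cleanest cluster
    expect_error(normalizeScores(raw, clusters, debrisSet = 2L),
                 "elevated")
})

test_that("literal normalization variant divides by the debris mean", {
    clusters <- rep(1:2, each = 5)
    raw <- c(rep(4, 5), rep(1, 5))
    lit <- normalizeScores(raw, clusters, debrisSet = 1L,
                           method = "literal")
    expect_equal(unname(lit), (raw - 1) / 4)
})

test_that("filtering is monotone in t and respects modes", {
    set.seed(24)
    scores <- runif(50, -0.2, 1.5)
    clusters <- sample(1:3, 50, replace = TRUE)
    test <- rep(c(TRUE, FALSE), c(40, 10))
    k1 <- filterDroplets(scores, clusters, 1L, test, t = 0.3)
    k2 <- filterDroplets(scores, clusters, 1L, test, t = 0.8)
    expect_true(all(k2[k1]))          # raising t never removes a kept one
    expect_false(any(k1[!test]))      # fixed droplets always removed
    expect_equal(filterDroplets(scores, clusters, 1L, test, t = 0),
                 (scores < 0) & test)
    expect_equal(filterDroplets(scores, clusters, 1L, test, t = Inf), test)
    kc <- filterDroplets(scores, clusters, c(1L, 3L), test,
                         mode = "cluster")
    expect_equal(kc, !(clusters %in% c(1L, 3L)) & test)
})
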
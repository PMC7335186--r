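test_that("profiles are simplex vectors with boosted ambient markers", {
    prof <- makeProfiles(nGenes = 100, nTypes = 3, nDebrisMarkers = 10,
                         markerBoost = 4, seed = 3)
    expect_equal(sum(prof$ambient), 1, tolerance = 1e-12)
    expect_equal(unname(rowSums(prof$types)), rep(1, 3),
                 tolerance = 1e-12)
    expect_length(prof$markers, 10)
    # markers carry more ambient mass than the average non-marker
    expect_gt(mean(prof$ambient[prof$markers]),
              3 * mean(prof$ambient[setdiff(prof$geneIds, prof$markers)]))
    expect_error(makeProfiles(nGenes = 5, nDebrisMarkers = 5),
                 "nDebrisMarkers")
    expect_error(makeProfiles(markerBoost = 0.5), "markerBoost")
})

test_that("simulation is exactly reproducible under a fixed seed", {
    prof <- makeProfiles(nGenes = 80, nTypes = 2, seed = 9)
    s1 <- simulateDroplets(prof, nEmpty = 150, nPerType = 30, seed = 77)
    s2 <- simulateDroplets(prof, nEmpty = 150, nPerType = 30, seed = 77)
    expect_identical(as.matrix(counts(s1$experiment)),
                     as.matrix(counts(s2$experiment)))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateDroplets(prof, nEmpty = 150, nPerType = 30, seed = 78)
    expect_false(identical(as.matrix(counts(s1$experiment)),
                           as.matrix(counts(s3$experiment))))
    # truth invariants
    expect_true(all(s1$truth$ambient_fraction[s1$truth$origin == "empty"]
                    == 1))
    expect_equal(unname(colSums(as.matrix(counts(s1$experiment)))),
                 s1$truth$total_count[match(colnames(s1$experiment),
                                            s1$truth$barcode)])
})

test_that("droplet means match the analytic mixed-multinomial expectation", {
    # many small replicate droplets at a forced contamination fraction
    prof <- makeProfiles(nGenes = 30, nTypes = 1, nDebrisMarkers = 5,
                         markerBoost = 6, seed = 13)
    rho <- 0.3; u <- 50; nrep <- 1000
    set.seed(13)
    cnt <- vapply(seq_len(nrep), function(i) {
        na <- rbinom(1, u, rho)
        rmultinom(1, na, prof$ambient)[, 1] +
            rmultinom(1, u - na, prof$types[1, ])[, 1]
    }, numeric(30))
    expected <- u * ((1 - rho) * prof$types[1, ] + rho * prof$ambient)
    se <- sqrt(apply(cnt, 1, var) / nrep)
    dev <- abs(rowMeans(cnt) - expected)
    # all gene means within 3 standard errors up to a small slack
    expect_true(all(dev <= 3 * se + 1e-8))
})

test_that("zero and full contamination produce the degenerate regimes", {
    prof <- makeProfiles(nGenes = 60, nTypes = 2, seed = 21)
    s0 <- simulateDroplets(prof, nEmpty = 50, nPerType = 40,
                           contaminationBeta = c(1e-6, 1), seed = 21)
    nuc <- s0$truth$origin == "nucleus"
    expect_true(all(s0$truth$ambient_fraction[nuc] < 1e-3))
    expect_true(all(s0$truth$ambient_molecules[nuc] == 0 |
                    s0$truth$ambient_fraction[nuc] > 0))
    s1 <- simulateDroplets(prof, nEmpty = 50, nPerType = 40,
                           contaminationBeta = c(1, 1e-6), seed = 21)
    nuc1 <- s1$truth$origin == "nucleus"
    expect_true(all(s1$truth$ambient_fraction[nuc1] > 1 - 1e-3))
    expect_true(all(s1$truth$ambient_molecules[nuc1] ==
                    s1$truth$total_count[nuc1]))
})

test_that("splice simulation respects origin-conditional probabilities", {
    prof <- makeProfiles(nGenes = 40, nTypes = 1, nDebrisMarkers = 8,
                         seed = 5)
    sim <- simulateDroplets(prof, nEmpty = 100, nPerType = 50, seed = 5)
    # deterministic labels: ambient always spliced, nuclear never
    sp <- simulateSplice(sim$truth, pSplicedAmbient = 1,
                         pSplicedNuclear = 0, seed = 5)
    expect_identical(sp$spliced, as.integer(sim$truth$ambient_molecules))
    # per-droplet binomial variance matches the closed form
    rep <- vapply(1:400, function(i)
        simulateSplice(sim$truth[1, , drop = FALSE], 0.8, 0.25,
                       seed = i)$spliced, numeric(1))
    n <- sim$truth$ambient_molecules[1]
    m <- sim$truth$total_count[1] - n
    vTrue <- n * 0.8 * 0.2 + m * 0.25 * 0.75
    expect_equal(var(rep), vTrue, tolerance = 0.25 * vTrue + 1)
    # same seed, same table
    expect_identical(simulateSplice(sim$truth, seed = 2),
                     simulateSplice(sim$truth, seed = 2))
})

test_that("midpoint separates simulated ambient and nuclear populations", {
    sim <- smallSim(seed = 6, nEmpty = 800, nPerType = 150)
    sp <- simulateSplice(sim$truth, pSplicedAmbient = 0.8,
                         pSplicedNuclear = 0.25, seed = 6)
    ps <- percentSpliced(sp)
    tr <- merge(ps, sim$truth, by = "barcode")
    ok <- is.finite(tr$pct_spliced)
    fit <- fitMidpoint(tr$pct_spliced[ok])
    called <- classifyDroplets(tr$pct_spliced[ok], fit)
    truthLab <- ifelse(tr$origin[ok] == "empty", "background", "nuclear")
    # restrict to droplets whose expected percent spliced sits away from
    # the decision boundary relative to its binomial noise: enough reads,
    # and for nuclei a contamination fraction below the ambiguous range
    # (a nucleus that is half ambient is background-like by construction)
    denom <- tr$spliced[ok] + tr$unspliced[ok]
    clear <- denom >= 20 &
        (tr$origin[ok] == "empty" | tr$ambient_fraction[ok] < 0.4)
    agreement <- mean(called[clear] == truthLab[clear])
    expect_gte(agreement, 0.95)
})

test_that("equal splice probabilities yield a unimodal distribution", {
    sim <- smallSim(seed = 8, nEmpty = 400, nPerType = 50)
    sp <- simulateSplice(sim$truth, pSplicedAmbient = 0.5,
                         pSplicedNuclear = 0.5, seed = 8)
    ps <- percentSpliced(sp)
    expect_warning(fitMidpoint(ps$pct_spliced[is.finite(ps$pct_spliced)]),
                   "unimodal")
})
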
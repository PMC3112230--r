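structuredObs <- function(nChains = 5, seed = 10) {
    truth <- randomFA(nChains, seed = seed)
    list(obs = asObserved(peakDistributionIID(truth)),
         support = chainLabels(truth))
}

test_that("fold partitions are valid: disjoint, exhaustive, balanced", {
    for (seed in 1:20) {
        fold <- clremodel:::.withSeed(seed, clremodel:::.makeFolds(23, 4))
        expect_length(fold, 23)
        sizes <- tabulate(fold, 4)
        expect_true(all(sizes >= 1))
        expect_lte(diff(range(sizes)), 1)
    }
})

test_that("cross-validation of a noise-free IID profile predicts held-out peaks", {
    s <- structuredObs(6, seed = 12)
    expect_gte(length(s$obs@values), 40)   # rich peak set
    cv <- crossValidateCL(s$obs, s$support, seed = 4)
    expect_gt(mean(cvCorrelations(cv)), 0.99)
    expect_length(cvCorrelations(cv), 3)
})

test_that("four peaks with four folds is a working boundary case", {
    obs <- CLProfile(c("72:4" = 0.1, "72:5" = 0.3, "72:6" = 0.4,
                       "72:7" = 0.2))
    cv <- crossValidateCL(obs, c("18:1", "18:2"), folds = 4, seed = 2)
    expect_length(cvCorrelations(cv), 3)
    expect_error(crossValidateCL(obs, c("18:1", "18:2"), folds = 5,
                                 seed = 2), "exceeds")
})

test_that("identical seeds reproduce cross-validation exactly", {
    s <- structuredObs(5, seed = 30)
    r1 <- cvCorrelations(crossValidateCL(s$obs, s$support, seed = 9))
    r2 <- cvCorrelations(crossValidateCL(s$obs, s$support, seed = 9))
    r3 <- cvCorrelations(crossValidateCL(s$obs, s$support, seed = 10))
    expect_identical(r1, r2)
    expect_false(identical(r1, r3))
})

test_that("label permutation separates structured data from noise", {
    s <- structuredObs(5, seed = 14)
    res <- labelPermutationTest(s$obs, s$support, seed = 3)
    expect_lt(pValue(res), 0.05)
    expect_gt(mean(res@observed), mean(res@null))
})

test_that("all-equal concentrations make the label test degenerate", {
    obs <- CLProfile(rep(0.25, 4),
                     labels = c("72:4", "72:5", "72:6", "72:7"))
    expect_error(labelPermutationTest(obs, c("18:1", "18:2"), seed = 1),
                 class = "clremodel_degenerate")
})

test_that("donor permutation p-values honour the empirical bounds", {
    pools <- sampleDonorPools(8, nClasses = 3, seed = 40)
    # self-explaining composition: CL equals the PG pool
    res <- donorPermutationTest(pools$PG, pools, nPerm = 199, seed = 5)
    expect_gte(pValue(res), 1 / 200)
    expect_lte(pValue(res), 0.05)

    # uniform pools: permutation is the identity, p must be 1
    unif <- lapply(pools[1:2], function(p)
        FADistribution(rep(1 / 8, 8), labels = chainLabels(p)))
    names(unif) <- c("PG", "PC_sn2")
    res <- donorPermutationTest(unif$PG, unif, nPerm = 50, seed = 6)
    expect_equal(pValue(res), 1)

    expect_error(donorPermutationTest(pools$PG, pools, nPerm = 0,
                                      seed = 1), "nPerm")
})

test_that("donor permutation is reproducible under a fixed seed", {
    pools <- sampleDonorPools(6, nClasses = 3, seed = 41)
    cl <- randomFA(6, seed = 42)
    p1 <- pValue(suppressWarnings(
        donorPermutationTest(cl, pools, nPerm = 99, seed = 8)))
    p2 <- pValue(suppressWarnings(
        donorPermutationTest(cl, pools, nPerm = 99, seed = 8)))
    expect_identical(p1, p2)
})

test_that("IDD-vs-IID comparison flags differential truths and not IID truths", {
    sn1 <- FADistribution(c("16:0" = 0.7, "18:0" = 0.3))
    sn2 <- FADistribution(c("20:4" = 0.6, "22:6" = 0.4))
    obs <- asObserved(peakDistributionIDD(sn1, sn2))
    support <- c("16:0", "18:0", "20:4", "22:6")
    cmp <- compareIDDvsIID(obs, support, seed = 11)
    expect_lt(cmp$pValue, 0.05)
    expect_gt(mean(cvCorrelations(cmp$cvIDD)),
              mean(cvCorrelations(cmp$cvIID)))

    # a two-chain binomial profile is fit exactly by both models:
    # identical score sets give p = 1
    two <- asObserved(peakDistributionIID(
        FADistribution(c("18:1" = 0.5, "18:2" = 0.5))))
    cmp <- compareIDDvsIID(two, c("18:1", "18:2"), seed = 12)
    expect_equal(cmp$pValue, 1)
})
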
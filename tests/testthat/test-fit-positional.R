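test_that("a single-chain support fits a single observed peak perfectly", {
    obs <- CLProfile(c("72:4" = 1))
    fit <- fitIID(obs, "18:1")
    expect_equal(unname(probs(faDistributions(fit)[[1]])), 1)
    expect_lt(fitError(fit), 1e-20)
    expect_equal(pearsonR(fit), 1)  # perfect single-point fit convention
})

test_that("IID fit recovers noise-free truths on the full reachable peak set", {
    for (i in 1:3) {
        truth <- randomFA(5, seed = 400 + i)
        obs <- asObserved(peakDistributionIID(truth))
        fit <- fitIID(obs, chainLabels(truth))
        expect_lt(fitError(fit), 1e-10)
        expect_lt(faL1(faDistributions(fit)[[1]], truth), 1e-4)
        p <- probs(faDistributions(fit)[[1]])
        expect_true(all(p >= 0))
        expect_lt(abs(sum(p) - 1), 1e-9)
    }
})

test_that("fit metrics follow the squared-error and Pearson definitions", {
    m <- fitMetrics(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5))
    expect_equal(m$error, 0)
    expect_equal(m$pearsonR, 1)

    obs <- c(0.1, 0.2, 0.7)
    m <- fitMetrics(obs + 0.05, obs)
    expect_equal(m$error, 3 * 0.05^2)
    expect_equal(m$pearsonR, 1)  # shift invariance

    set.seed(9)
    a <- runif(10); b <- runif(10)
    m <- fitMetrics(a, b)
    expect_equal(m$error, sum((a - b)^2))
    expect_equal(m$pearsonR, cor(a, b))

    expect_error(fitMetrics(1:3, 1:4), "length mismatch")
    expect_true(is.na(fitMetrics(c(1, 1), c(0.5, 1))$pearsonR))
})

test_that("IDD recovers differential truths and beats IID on them", {
    sn1 <- FADistribution(c("16:0" = 1))
    sn2 <- FADistribution(c("18:1" = 1))
    obs <- asObserved(peakDistributionIDD(sn1, sn2))
    support <- c("16:0", "18:1")
    idd <- fitIDD(obs, support)
    iid <- fitIID(obs, support)
    expect_lt(fitError(idd), 1e-10)
    expect_gt(fitError(iid), fitError(idd) + 1e-3)
    # pools recovered up to the sn1/sn2 swap
    got <- faDistributions(idd)
    d1 <- faL1(got$sn1, sn1) + faL1(got$sn2, sn2)
    d2 <- faL1(got$sn1, sn2) + faL1(got$sn2, sn1)
    expect_lt(min(d1, d2), 1e-4)
})

test_that("IDD is never worse than IID (nesting) and is swap-symmetric", {
    truth <- randomFA(4, seed = 31)
    obs <- asObserved(peakDistributionIID(truth))
    iid <- fitIID(obs, chainLabels(truth))
    idd <- fitIDD(obs, chainLabels(truth))
    expect_lte(fitError(idd), fitError(iid) + 1e-8)

    # swapping the returned pools leaves the predicted profile unchanged
    got <- faDistributions(idd)
    straight <- peakDistributionIDD(got$sn1, got$sn2)
    swapped <- peakDistributionIDD(got$sn2, got$sn1)
    expect_equal(peakValues(straight), peakValues(swapped),
                 tolerance = 1e-12)
})

test_that("fits are deterministic and feasible under noise", {
    pools <- sampleDonorPools(6, seed = 21)
    tr <- syntheticTruth(pools, weights = c(PG = 1/3, PC_sn2 = 1/3,
                                            PE_sn2 = 1/3),
                         sigma = 0.01, seed = 21)
    ds <- generateDataset(tr, mode = "iid")
    obs <- clProfile(buildSample(ds$table))
    support <- chainSupport(donorPools(buildSample(ds$table)))
    f1 <- suppressWarnings(fitIID(obs, support))
    f2 <- suppressWarnings(fitIID(obs, support))
    expect_identical(probs(faDistributions(f1)[[1]]),
                     probs(faDistributions(f2)[[1]]))
    expect_identical(fitError(f1), fitError(f2))
    p <- probs(faDistributions(f1)[[1]])
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-9)
})

test_that("unreachable observed peaks warn and contribute their squared value", {
    obs <- CLProfile(c("72:4" = 0.9, "70:3" = 0.1))  # 70:3 unreachable from 18:1
    expect_warning(fit <- fitIID(obs, "18:1"), "unreachable")
    expect_identical(fit@unreachablePeaks, "70:3")
    expect_equal(fitError(fit), (1 - 0.9)^2 + 0.1^2, tolerance = 1e-6)
})

test_that("multi-start fitting is reproducible given a seed", {
    truth <- randomFA(4, seed = 55)
    obs <- asObserved(peakDistributionIID(truth))
    f1 <- fitIID(obs, chainLabels(truth), restarts = 3, seed = 7)
    f2 <- fitIID(obs, chainLabels(truth), restarts = 3, seed = 7)
    expect_identical(probs(faDistributions(f1)[[1]]),
                     probs(faDistributions(f2)[[1]]))
    expect_error(fitIID(obs, chainLabels(truth), restarts = 2), "seed")
})
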
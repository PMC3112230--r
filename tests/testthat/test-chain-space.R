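test_that("chain labels parse with ASCII and Unicode separators and round-trip", {
    expect_equal(parseChainLabel("18:1"), list(carbons = 18L, doubleBonds = 1L))
    expect_equal(parseChainLabel("18∶1"),
                 list(carbons = 18L, doubleBonds = 1L))
    expect_equal(parseChainLabel("22:6"), list(carbons = 22L, doubleBonds = 6L))
    labs <- c("14:0", "18:1", "22:6")
    expect_identical(formatChainLabel(parseChainLabel(labs)), labs)
    expect_error(parseChainLabel("18-1"), "18-1")
    expect_error(parseChainLabel("banana"), "banana")
    expect_error(parseChainLabel("18:20"), "double bonds")
})

test_that("chain support is the sorted union of positive-probability donor chains", {
    a <- FADistribution(c("18:1" = 1))
    b <- FADistribution(c("18:2" = 1))
    expect_identical(chainSupport(list(a, b)), c("18:1", "18:2"))

    withZero <- FADistribution(c("16:0" = 0.5, "18:1" = 0.5, "20:4" = 0))
    expect_identical(chainSupport(list(withZero)), c("16:0", "18:1"))

    labs <- c("14:0", "16:0", "18:1", "18:2", "20:4", "22:6")
    pools <- lapply(1:3, function(i) {
        g <- clremodel:::.withSeed(i, rgamma(6, 1))
        FADistribution(g / sum(g), labels = sample(labs))
    })
    expect_identical(chainSupport(pools), labs)

    allZero <- new("FADistribution", carbons = 18L, doubleBonds = 1L,
                   probs = 1)
    allZero@probs <- 0  # bypass validity to exercise the empty-union error
    expect_error(chainSupport(list(allZero)), "no candidate chain types")
})

test_that("IID peak distribution matches closed forms", {
    single <- FADistribution(c("18:1" = 1))
    expect_equal(peakValues(peakDistributionIID(single)), c("72:4" = 1))

    two <- FADistribution(c("18:1" = 0.5, "18:2" = 0.5))
    pv <- peakValues(peakDistributionIID(two))
    expect_equal(unname(pv["72:6"]), 0.375)
    expect_equal(unname(pv["72:4"]), 0.0625)
    expect_equal(unname(pv["72:5"]), 0.25)
    expect_equal(pv, dbinom(0:4, 4, 0.5) |>
                     setNames(paste0("72:", 4:8)))
})

test_that("convolution equals brute-force enumeration and conserves mass", {
    for (i in 1:12) {
        fa <- randomFA(sample(2:6, 1), seed = 100 + i)
        conv <- peakDistributionIID(fa)
        brute <- bruteForcePeakDistribution(fa)
        expect_identical(peakLabels(conv), peakLabels(brute))
        expect_lt(max(abs(conv@values - brute@values)), 1e-12)
        expect_lt(abs(sum(conv@values) - 1), 1e-9)
    }
})

test_that("IDD reduces to IID with equal pools and matches brute force otherwise", {
    fa <- randomFA(4, seed = 5)
    expect_equal(peakValues(peakDistributionIDD(fa, fa)),
                 peakValues(peakDistributionIID(fa)), tolerance = 1e-12)

    p16 <- FADistribution(c("16:0" = 1))
    p18 <- FADistribution(c("18:1" = 1))
    expect_equal(peakValues(peakDistributionIDD(p16, p18)), c("68:2" = 1))

    for (i in 1:6) {
        a <- randomFA(3, seed = 200 + i)
        b <- randomFA(3, seed = 300 + i)
        conv <- peakDistributionIDD(a, b)
        brute <- bruteForcePeakDistribution(a, b)
        expect_identical(peakLabels(conv), peakLabels(brute))
        expect_lt(max(abs(conv@values - brute@values)), 1e-12)
    }
})

test_that("peak distributions are invariant under support reordering", {
    labs <- c("16:0", "18:1", "20:4", "22:6")
    p <- c(0.1, 0.4, 0.3, 0.2)
    f1 <- FADistribution(p, labels = labs)
    shuf <- c(3, 1, 4, 2)
    f2 <- FADistribution(p[shuf], labels = labs[shuf])
    expect_identical(peakValues(peakDistributionIID(f1)),
                     peakValues(peakDistributionIID(f2)))
})

test_that("brute force refuses oversized supports and normalizes by construction", {
    big <- FADistribution(rep(1 / 12, 12), labels = defaultChainCatalog())
    tiny <- FADistribution(c("24:1" = 1))  # outside the catalog: union 13
    expect_error(bruteForcePeakDistribution(big, tiny), "too large")
    fa <- randomFA(4, seed = 77)
    expect_lt(abs(sum(bruteForcePeakDistribution(fa)@values) - 1), 1e-12)
})

test_that("FADistribution and CLProfile enforce their invariants", {
    expect_error(FADistribution(c("18:1" = 0.6, "18:2" = 0.6)), "sum to 1")
    expect_error(FADistribution(c("18:1" = 1.2, "18:2" = -0.2)),
                 "nonnegative")
    expect_error(FADistribution(c("18:1" = 0.5, "18:1" = 0.5)),
                 "duplicated")
    expect_error(CLProfile(c("72:8" = 0.5)), "sum to 1")
    expect_silent(CLProfile(c("72:8" = 0.5), kind = "predicted"))
    expect_error(CLProfile(c("72:8" = 0.9, "72:7" = 0.4),
                           kind = "predicted"), "exceeds 1")
})
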
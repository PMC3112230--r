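propFitFor <- function(cl, pools) suppressWarnings(fitProportional(cl, pools))

cohortFits <- function(nSamples, excess = NULL, noise = 0, seed = 1) {
    # proportional-model cohort with optional constructed per-chain excess;
    # fixed support so the boosted chain is always present
    labs <- c("16:0", "18:1", "18:2", "20:4", "22:5", "22:6")
    clremodel:::.withSeed(seed, {
        pools <- lapply(c(PG = 1, PC_sn2 = 2, PE_sn2 = 3), function(.) {
            g <- rgamma(length(labs), 1)
            FADistribution(g / sum(g), labels = labs)
        })
        lapply(seq_len(nSamples), function(i) {
            g <- rgamma(3, 1); w <- g / sum(g); names(w) <- names(pools)
            truth <- syntheticTruth(pools, weights = w)
            y <- probs(truth@clFA)
            if (!is.null(excess)) {
                y[excess] <- y[excess] + 0.05
            }
            y <- pmax(y + rnorm(length(y), 0, noise), 0)
            cl <- FADistribution(y / sum(y), labels = names(y))
            propFitFor(cl, pools)
        }) |> setNames(paste0("s", seq_len(nSamples)))
    })
}

test_that("the residual matrix stacks per-sample residuals on the union support", {
    fits <- cohortFits(2, seed = 3)
    fits$s2 <- fits$s1
    mat <- residualMatrix(fits)
    expect_identical(mat["s1", ], mat["s2", ])
    expect_true(all(abs(rowSums(mat, na.rm = TRUE)) < 1e-9))
    expect_error(residualMatrix(fits["s1"]), "at least 2")
})

test_that("a constructed excess of 18:2 appears as a uniformly positive column", {
    fits <- cohortFits(6, excess = "18:2", seed = 4)
    mat <- residualMatrix(fits)
    expect_true(all(mat[, "18:2"] > 0))
})

test_that("a zero-noise proportional cohort leaves no residual signal", {
    fits <- cohortFits(4, seed = 5)
    mat <- residualMatrix(fits)
    expect_lt(max(abs(mat), na.rm = TRUE), 1e-8)
})

test_that("chain residual correlations are squared, symmetric and bounded", {
    set.seed(8)
    mat <- matrix(rnorm(60), nrow = 10,
                  dimnames = list(NULL, defaultChainCatalog()[1:6]))
    mat <- mat - rowMeans(mat)   # rows sum to 0 like real residuals
    r2 <- chainResidualCorrelation(mat)
    expect_equal(r2, t(r2))
    expect_true(all(diag(r2) == 1))
    expect_true(all(r2 >= 0 & r2 <= 1))

    # perfect linear relation and constructed orthogonality
    a <- rnorm(10); b <- 2 * a
    o <- rnorm(10); o <- o - a * sum(o * (a - mean(a))) /
        sum((a - mean(a))^2)   # not exactly orthogonal to centered a
    o <- residuals(lm(o ~ a))  # orthogonalize properly
    m2 <- cbind("16:0" = a, "18:1" = b, "22:4" = as.vector(o))
    r2 <- chainResidualCorrelation(m2)
    expect_equal(r2["16:0", "18:1"], 1, tolerance = 1e-12)
    expect_lt(r2["16:0", "22:4"], 1e-20)
})

test_that("pairs sharing fewer than 3 samples are marked missing", {
    mat <- matrix(rnorm(12), nrow = 4,
                  dimnames = list(NULL, c("16:0", "18:1", "18:2")))
    mat[1:2, 3] <- NA
    r2 <- chainResidualCorrelation(mat)
    expect_true(is.na(r2["16:0", "18:2"]))
    expect_false(is.na(r2["16:0", "18:1"]))
})

test_that("clustering merges the most correlated chains first", {
    labs <- c("16:0", "18:1", "22:4")
    r2 <- matrix(0.1, 3, 3, dimnames = list(labs, labs))
    diag(r2) <- 1
    r2["16:0", "18:1"] <- r2["18:1", "16:0"] <- 0.99
    tree <- clusterChains(r2)
    expect_setequal(tree$tip.label, labs)
    coph <- ape::cophenetic.phylo(tree)
    expect_lt(coph["16:0", "18:1"], coph["16:0", "22:4"])
    expect_lt(coph["16:0", "18:1"], coph["18:1", "22:4"])
})

test_that("identical residual columns merge at height zero and trees serialize", {
    labs <- c("16:0", "18:1", "22:4", "22:6")
    r2 <- matrix(1, 4, 4, dimnames = list(labs, labs))
    tree <- clusterChains(r2)
    expect_true(all(tree$edge.length < 1e-12))

    tf <- withr::local_tempfile(fileext = ".nwk")
    writeChainTree(tree, tf)
    back <- ape::read.tree(tf)
    expect_setequal(back$tip.label, gsub(":", "_", labs))  # Newick reserves ':'

    single <- clusterChains(matrix(1, 1, 1,
                                   dimnames = list("18:2", "18:2")))
    expect_identical(single$tip.label, "18:2")
})

test_that("box statistics use the inclusive quartile convention", {
    mat <- cbind("18:2" = c(1, 2, 3, 4, 100))
    bs <- residualBoxStats(mat)
    expect_equal(bs$median, 3)
    expect_equal(bs$q25, quantile(c(1, 2, 3, 4, 100), 0.25, type = 7,
                                  names = FALSE))
    expect_equal(bs$n, 5L)
})
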
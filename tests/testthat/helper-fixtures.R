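# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# Random normalized FA distribution over n chains from the default catalog.
randomFA <- function(n, seed = NULL, catalog = defaultChainCatalog()) {
    draw <- function() {
        labs <- sort(sample(catalog, n))
        g <- rgamma(n, shape = 1)
        FADistribution(g / sum(g), labels = labs)
    }
    if (is.null(seed)) draw() else clremodel:::.withSeed(seed, draw())
}

# Treat a model-generated peak distribution as an observed profile.
asObserved <- function(profile) {
    profile@kind <- "observed"
    validObject(profile)
    profile
}

# Euclidean projection onto the probability simplex (Duchi et al.),
# used by the independent projected-gradient QP oracle.
projectSimplex <- function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    tau <- (1 - css[rho]) / rho
    pmax(v + tau, 0)
}

# Independent projected-gradient solver for min ||D w - y||^2 on the
# simplex; oracle for the exact active-set QP.
pgSimplexLsq <- function(D, y, w0, iters = 20000) {
    H <- 2 * crossprod(D)
    g0 <- -2 * crossprod(D, y)
    step <- 1 / (2 * max(abs(eigen(H, only.values = TRUE)$values)))
    w <- w0
    for (i in seq_len(iters)) {
        w <- projectSimplex(w - step * as.vector(H %*% w + g0))
    }
    w
}

# L1 distance between two FADistributions on the union support.
faL1 <- function(a, b) {
    pa <- probs(a); pb <- probs(b)
    labs <- union(names(pa), names(pb))
    va <- ifelse(labs %in% names(pa), pa[labs], 0)
    vb <- ifelse(labs %in% names(pb), pb[labs], 0)
    sum(abs(va - vb), na.rm = TRUE)
}
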
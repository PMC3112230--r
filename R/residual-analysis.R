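## Cross-sample residual analysis: assemble per-chain residuals from
## proportional fits across samples, summarize them (box statistics),
## correlate residual profiles between chains (R^2) and hierarchically
## cluster chain types.

#' Assemble a cross-sample residual matrix
#'
#' Stacks the per-chain residuals of several samples' proportional fits
#' into a samples x chains matrix on the union chain set. Chains absent
#' from a sample's aligned support are marked \code{NA} (missing), not
#' zero. Each row sums to 0 over its non-missing entries.
#'
#' @param fits named list (>= 2) of [PropFitResult-class] objects, one per
#'   sample; names become row names.
#' @return A numeric matrix, rows = samples, columns = chain labels
#'   (sorted by carbons then double bonds).
#' @examples
#' pg <- FADistribution(c("16:0" = 0.6, "18:1" = 0.4))
#' pc <- FADistribution(c("18:2" = 0.8, "20:4" = 0.2))
#' cl <- FADistribution(c("16:0" = 0.3, "18:1" = 0.25, "18:2" = 0.35,
#'                        "20:4" = 0.1))
#' f <- fitProportional(cl, list(PG = pg, PC_sn2 = pc))
#' residualMatrix(list(a = f, b = f))
#' @export
residualMatrix <- function(fits) {
    if (length(fits) < 2L)
        stop("at least 2 samples are required")
    stopifnot(all(vapply(fits, is, TRUE, "PropFitResult")))
    if (is.null(names(fits)))
        names(fits) <- paste0("sample", seq_along(fits))
    chainsPer <- lapply(fits, function(f) names(residuals(f)))
    common <- Reduce(intersect, chainsPer)
    if (length(common) == 0L)
        stop("no common chains across samples")
    allChains <- unique(unlist(chainsPer))
    ch <- parseChainLabel(allChains)
    allChains <- allChains[order(ch$carbons, ch$doubleBonds)]
    mat <- matrix(NA_real_, nrow = length(fits), ncol = length(allChains),
                  dimnames = list(names(fits), allChains))
    for (i in seq_along(fits)) {
        r <- residuals(fits[[i]])
        mat[i, names(r)] <- r
    }
    mat
}

#' Pairwise squared correlation of chain residual profiles
#'
#' For each pair of chains, the squared Pearson correlation (R^2) of their
#' residual values across samples, computed over the samples where both
#' chains are present. Pairs sharing fewer than 3 samples (or with zero
#' variance) are marked \code{NA}; the diagonal is 1. High R^2 between two
#' chains suggests they respond to the same selective remodeling process.
#'
#' @param mat residual matrix from [residualMatrix()] (>= 3 samples).
#' @return A symmetric chains x chains matrix of values in [0, 1].
#' @export
chainResidualCorrelation <- function(mat) {
    stopifnot(is.matrix(mat))
    if (nrow(mat) < 3L)
        stop("at least 3 samples are required")
    nChain <- ncol(mat)
    r2 <- matrix(NA_real_, nChain, nChain,
                 dimnames = list(colnames(mat), colnames(mat)))
    for (a in seq_len(nChain)) {
        r2[a, a] <- 1
        for (b in seq_len(nChain)[-seq_len(a)]) {
            ok <- !is.na(mat[, a]) & !is.na(mat[, b])
            if (sum(ok) < 3L) next
            r <- .pearson(mat[ok, a], mat[ok, b])
            r2[a, b] <- r2[b, a] <- if (is.na(r)) NA_real_ else r^2
        }
    }
    r2
}

#' Hierarchically cluster chain types by residual co-variation
#'
#' Agglomeratively clusters chains with distance \code{1 - R^2} from
#' [chainResidualCorrelation()]. Missing entries are imputed with the mean
#' off-diagonal R^2 before clustering. The default average linkage is the
#' conventional choice for similarity-derived distances; complete and
#' single linkage are available.
#'
#' @param r2 symmetric R^2 matrix.
#' @param linkage \code{"average"} (default), \code{"complete"} or
#'   \code{"single"}.
#' @return An [ape::phylo] tree over the chains (one-leaf supports give a
#'   trivial single-tip tree); serialize with [writeChainTree()].
#' @examples
#' r2 <- diag(3); r2[1, 2] <- r2[2, 1] <- 0.99
#' dimnames(r2) <- list(c("16:0", "18:1", "22:4"), c("16:0", "18:1", "22:4"))
#' clusterChains(r2)
#' @export
clusterChains <- function(r2, linkage = c("average", "complete", "single")) {
    linkage <- match.arg(linkage)
    stopifnot(is.matrix(r2), nrow(r2) == ncol(r2))
    if (nrow(r2) == 1L) {
        tree <- list(edge = matrix(c(2L, 1L), 1, 2),
                     tip.label = rownames(r2),
                     edge.length = 0, Nnode = 1L)
        class(tree) <- "phylo"
        return(tree)
    }
    off <- r2[upper.tri(r2)]
    if (anyNA(r2))
        r2[is.na(r2)] <- mean(off, na.rm = TRUE)
    d <- stats::as.dist(1 - r2)
    hc <- stats::hclust(d, method = linkage)
    ape::as.phylo(hc)
}

#' Write a chain dendrogram in Newick format
#'
#' The colon is reserved in Newick (it introduces branch lengths), so tip
#' labels are written as \code{"C_D"} (e.g. \code{18_1}) instead of the
#' usual \code{"C:D"}.
#'
#' @param tree [ape::phylo] from [clusterChains()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeChainTree <- function(tree, path) {
    tree$tip.label <- gsub(":", "_", tree$tip.label, fixed = TRUE)
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' Box statistics of per-chain residuals across samples
#'
#' Median and 25th/75th percentiles (inclusive quartile convention) of
#' each chain's residuals across samples, ignoring missing entries.
#'
#' @param mat residual matrix from [residualMatrix()].
#' @return A data.frame with columns \code{chain}, \code{median},
#'   \code{q25}, \code{q75}, \code{n}.
#' @export
residualBoxStats <- function(mat) {
    stopifnot(is.matrix(mat))
    stats <- t(apply(mat, 2L, function(v) {
        v <- v[!is.na(v)]
        c(stats::median(v),
          stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE),
          length(v))
    }))
    data.frame(chain = colnames(mat), median = stats[, 1L],
               q25 = stats[, 2L], q75 = stats[, 3L], n = as.integer(stats[, 4L]),
               row.names = NULL)
}
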
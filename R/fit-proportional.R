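## Proportional-incorporation model: express the CL fatty-acid composition
## as a simplex-weighted mixture of donor-pool compositions. The weights
## solve the convex quadratic program
##   min_w || D w - y ||^2   s.t.  w >= 0,  sum(w) = 1,
## with D the chains x donor-classes matrix and y the CL FA probabilities,
## both aligned on the union chain support with zeros imputed. With at
## most 4 donor classes the QP is solved exactly by enumerating active
## sets: for every nonempty subset of classes allowed to be nonzero, solve
## the equality-constrained least-squares KKT system and keep the best
## feasible candidate. The global optimum of a convex QP is attained at
## one of these candidates.

## Align a CL FA distribution and donor pools on the union chain support.
.alignChains <- function(clFA, donors) {
    allC <- clFA@carbons; allD <- clFA@doubleBonds
    for (pool in donors) {
        allC <- c(allC, pool@carbons)
        allD <- c(allD, pool@doubleBonds)
    }
    key <- .cdKey(allC, allD)
    u <- !duplicated(key)
    allC <- allC[u]; allD <- allD[u]
    ord <- order(allC, allD)
    allC <- allC[ord]; allD <- allD[ord]
    ukey <- .cdKey(allC, allD)
    take <- function(fa) {
        v <- numeric(length(ukey))
        v[match(.cdKey(fa@carbons, fa@doubleBonds), ukey)] <- fa@probs
        v
    }
    D <- vapply(donors, take, numeric(length(ukey)))
    list(chains = .cdLabel(allC, allD), y = take(clFA),
         D = matrix(D, ncol = length(donors),
                    dimnames = list(.cdLabel(allC, allD), names(donors))))
}

## Exact simplex-constrained least squares by active-set enumeration.
.simplexLsq <- function(D, y) {
    K <- ncol(D)
    best <- NULL
    candidates <- list()
    for (m in seq_len(2^K - 1L)) {
        act <- which(bitwAnd(m, bitwShiftL(1L, seq_len(K) - 1L)) != 0L)
        k <- length(act)
        Da <- D[, act, drop = FALSE]
        A <- rbind(cbind(2 * crossprod(Da), 1), c(rep(1, k), 0))
        b <- c(2 * crossprod(Da, y), 1)
        sol <- tryCatch(solve(A, b), error = function(e) NULL)
        if (is.null(sol)) next
        w <- sol[seq_len(k)]
        if (any(w < -1e-9)) next
        w <- pmax(w, 0); w <- w / sum(w)
        full <- numeric(K); full[act] <- w
        obj <- sum((D %*% full - y)^2)
        candidates[[length(candidates) + 1L]] <- list(w = full, obj = obj)
        if (is.null(best) || obj < best$obj - 1e-15) best <- candidates[[length(candidates)]]
    }
    if (is.null(best))
        stop("no feasible active set found (numerically degenerate donors)")
    ## non-uniqueness: another candidate attains the optimum with
    ## different weights (affinely dependent donor vectors)
    nonUnique <- any(vapply(candidates, function(cand)
        cand$obj <= best$obj + 1e-12 &&
            sum(abs(cand$w - best$w)) > 1e-6, TRUE))
    list(w = best$w, nonUnique = nonUnique)
}

#' Fit the proportional-incorporation model
#'
#' Models the CL fatty-acid composition as a weighted sum of the donor
#' class compositions (PG, PC sn-2, PE sn-2, optionally acyl CoA), with
#' nonnegative weights summing to 1. The weights express what fraction of
#' the acyl chains in CL originates from each donor class under
#' head-group-determined, chain-blind donation. The CL composition passed
#' in is typically the IID-fitted chain distribution, since per-position
#' CL chain compositions are not directly measured. Chains are aligned on
#' the union support with zeros imputed, and every chain is weighted
#' equally in the regression.
#'
#' Per-chain residuals (CL value minus fitted mixture) sum to zero by
#' construction; a positive residual means the chain is in excess in CL
#' over proportional donation (a remodeling enzyme may favor it).
#'
#' @param clFA [FADistribution-class]: the CL chain composition (e.g.
#'   \code{faDistributions(fitIID(...))[[1]]}).
#' @param donors named list of at least two donor [FADistribution-class]
#'   pools; names among \code{PG}, \code{PC_sn2}, \code{PE_sn2}, \code{AC}.
#' @return A [PropFitResult-class]; \code{weights()}, \code{residuals()},
#'   \code{fitted()}, \code{fitError()} and \code{pearsonR()} access the
#'   components. When the donor compositions are affinely dependent the
#'   optimum is not unique and the result is flagged (\code{@nonUnique}).
#' @examples
#' pg <- FADistribution(c("16:0" = 0.6, "18:1" = 0.4))
#' pc <- FADistribution(c("18:2" = 0.8, "20:4" = 0.2))
#' pe <- FADistribution(c("18:1" = 0.3, "22:6" = 0.7))
#' ## CL composition = 0.25 PG + 0.5 PC + 0.25 PE
#' cl <- FADistribution(c("16:0" = 0.15, "18:1" = 0.175, "18:2" = 0.4,
#'                        "20:4" = 0.1, "22:6" = 0.175))
#' weights(fitProportional(cl, list(PG = pg, PC_sn2 = pc, PE_sn2 = pe)))
#' @seealso [donorPermutationTest()], [residualMatrix()]
#' @export
fitProportional <- function(clFA, donors) {
    stopifnot(is(clFA, "FADistribution"))
    if (length(donors) < 2L)
        stop("at least 2 donor classes are required")
    if (is.null(names(donors)) || !all(names(donors) %in% .DONOR_CLASSES))
        stop("donor names must be among: ",
             paste(.DONOR_CLASSES, collapse = ", "))
    al <- .alignChains(clFA, donors)
    sol <- .simplexLsq(al$D, al$y)
    if (sol$nonUnique)
        warning("donor compositions are affinely dependent; ",
                "optimal weights are not unique", call. = FALSE)
    w <- sol$w
    names(w) <- names(donors)
    fit <- as.vector(al$D %*% w)
    names(fit) <- al$chains
    res <- al$y - fit
    names(res) <- al$chains
    new("PropFitResult",
        weights = w, clFA = clFA, donorMatrix = al$D,
        target = stats::setNames(al$y, al$chains),
        fitted = fit, residuals = res,
        error = sum(res^2),
        pearsonR = .pearson(fit, al$y),
        nonUnique = sol$nonUnique)
}
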
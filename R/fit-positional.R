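## Simplex-constrained least-squares inversion of the positional models:
## find the per-position chain distribution(s) whose 4-fold convolution
## best matches an observed CL mass-peak profile.
##
## The simplex constraints (p >= 0, sum p = 1) are enforced by the squared
## reparameterisation p_i = x_i^2 / sum_j x_j^2, optimized with L-BFGS-B
## and analytic gradients. The chain rule for the reparameterisation is
##   dE/dx_j = (2 x_j / S) * (g_j - sum_i g_i p_i),   S = sum x^2,
## where g = dE/dp. The gradient of a predicted peak value with respect to
## a chain probability is a 3-fold convolution evaluated at the peak key
## minus the chain key (4x for IID; for IDD, 2x the cross convolution of
## one position pair's distribution with the other pair's
## self-convolution).

## Objective/gradient environment for a fixed observed profile + support.
.positionalProblem <- function(observed, support) {
    sup <- .asSupport(support)
    n <- length(sup$carbons)
    chainKey <- .cdKey(sup$carbons, sup$doubleBonds)
    obsKey <- .cdKey(observed@totalCarbons, observed@totalDoubleBonds)
    obs <- observed@values

    ## reachability: peaks attainable by some ordered 4-tuple from support
    ones <- list(c = sup$carbons, d = sup$doubleBonds, p = rep(1, n))
    r2 <- .convCD(ones, ones)
    reach <- .convCD(r2, r2)
    reachable <- obsKey %in% (reach$c * 64L + reach$d)

    list(sup = sup, n = n, chainKey = chainKey, obsKey = obsKey, obs = obs,
         reachable = reachable)
}

## value/gradient of E(p) = sum_s (pred_s - obs_s)^2 for the IID model
.iidValGrad <- function(p, prob) {
    f <- list(c = prob$sup$carbons, d = prob$sup$doubleBonds, p = p)
    f2 <- .convCD(f, f)
    f3 <- .convCD(f2, f)
    f4 <- .convCD(f2, f2)
    k4 <- f4$c * 64L + f4$d
    pred <- f4$p[match(prob$obsKey, k4)]
    pred[is.na(pred)] <- 0
    r <- pred - prob$obs
    ## lookup conv3 at (peak key - chain key); impossible differences miss
    k3 <- f3$c * 64L + f3$d
    M <- outer(prob$obsKey, prob$chainKey, "-")
    V <- f3$p[match(M, k3)]
    V[is.na(V)] <- 0
    dim(V) <- dim(M)
    g <- 4 * as.vector(crossprod(V, 2 * r))
    list(value = sum(r * r), grad = g, pred = pred)
}

## value/gradient for the IDD model; p = c(pa, pb)
.iddValGrad <- function(pa, pb, prob) {
    a <- list(c = prob$sup$carbons, d = prob$sup$doubleBonds, p = pa)
    b <- list(c = prob$sup$carbons, d = prob$sup$doubleBonds, p = pb)
    a2 <- .convCD(a, a); b2 <- .convCD(b, b)
    f4 <- .convCD(a2, b2)
    k4 <- f4$c * 64L + f4$d
    pred <- f4$p[match(prob$obsKey, k4)]
    pred[is.na(pred)] <- 0
    r <- pred - prob$obs
    ab2 <- .convCD(a, b2)   # d pred / d a_i = 2 * ab2(key_s - akey_i)
    ba2 <- .convCD(b, a2)
    kab <- ab2$c * 64L + ab2$d
    kba <- ba2$c * 64L + ba2$d
    M <- outer(prob$obsKey, prob$chainKey, "-")
    Va <- ab2$p[match(M, kab)]; Va[is.na(Va)] <- 0; dim(Va) <- dim(M)
    Vb <- ba2$p[match(M, kba)]; Vb[is.na(Vb)] <- 0; dim(Vb) <- dim(M)
    ga <- 2 * as.vector(crossprod(Va, 2 * r))
    gb <- 2 * as.vector(crossprod(Vb, 2 * r))
    list(value = sum(r * r), grad = c(ga, gb), pred = pred)
}

## One L-BFGS-B solve over the reparameterised simplex (or product of two
## simplexes when blocks = 2). init is a probability vector (per block).
.solveSimplexLS <- function(prob, model, initP, maxit, factr) {
    nblk <- if (model == "IID") 1L else 2L
    n <- prob$n
    x0 <- sqrt(initP)
    blockIdx <- rep(seq_len(nblk), each = n)

    toP <- function(x) {
        unlist(lapply(seq_len(nblk), function(b) {
            xb <- x[blockIdx == b]
            xb^2 / sum(xb^2)
        }), use.names = FALSE)
    }
    valGrad <- function(p) {
        if (model == "IID") .iidValGrad(p, prob)
        else .iddValGrad(p[seq_len(n)], p[n + seq_len(n)], prob)
    }
    fn <- function(x) valGrad(toP(x))$value
    gr <- function(x) {
        p <- toP(x)
        g <- valGrad(p)$grad
        out <- numeric(length(x))
        for (b in seq_len(nblk)) {
            i <- blockIdx == b
            S <- sum(x[i]^2)
            out[i] <- (2 * x[i] / S) * (g[i] - sum(g[i] * p[i]))
        }
        out
    }
    opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = factr))
    ## a failed line search at machine-precision factr means no further
    ## progress is possible: the iterate is the converged solution
    lnsrchStall <- opt$convergence == 52 &&
        grepl("ABNORMAL_TERMINATION_IN_LNSRCH", opt$message %||% "")
    if (opt$convergence != 0 && !lnsrchStall)
        stop(sprintf(
            "positional-model optimizer did not converge (code %d, %d function / %d gradient evaluations): %s",
            opt$convergence, opt$counts[1L], opt$counts[2L],
            if (nzchar(opt$message %||% "")) opt$message else "no message"),
            call. = FALSE)
    p <- toP(opt$par)
    if (any(!is.finite(p)))
        stop("positional-model optimizer produced non-finite parameters",
             call. = FALSE)
    ## exact simplex cleanup per block
    for (b in seq_len(nblk)) {
        i <- blockIdx == b
        pb <- p[i]
        pb[pb < 0] <- 0
        p[i] <- pb / sum(pb)
    }
    vg <- valGrad(p)
    list(p = p, value = vg$value, pred = vg$pred,
         counts = opt$counts, message = opt$message %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.supportFA <- function(sup, p) {
    new("FADistribution", carbons = sup$carbons,
        doubleBonds = sup$doubleBonds, probs = p / sum(p))
}

.positionalFit <- function(observed, support, model, restarts, seed,
                           maxit, factr, extraInits = list()) {
    stopifnot(is(observed, "CLProfile"))
    prob <- .positionalProblem(observed, support)
    if (any(!prob$reachable)) {
        bad <- .cdLabel(observed@totalCarbons[!prob$reachable],
                        observed@totalDoubleBonds[!prob$reachable])
        warning(sprintf(
            "%d observed peak(s) unreachable from the chain support: %s",
            length(bad), paste(bad, collapse = ", ")), call. = FALSE)
    }
    n <- prob$n
    nblk <- if (model == "IID") 1L else 2L
    inits <- c(list(rep(1 / n, n * nblk)), extraInits)
    if (model == "IDD" && n > 1L) {
        ## the uniform (and IID-duplicated) starts are symmetric in the two
        ## position pairs, which are stationary under the symmetric
        ## gradient; add a deterministic antisymmetric tilt so genuinely
        ## differential optima are reachable
        z <- scale(seq_len(n))[, 1L]
        pa <- exp(z) / sum(exp(z))
        pb <- exp(-z) / sum(exp(-z))
        inits <- c(inits, list(c(pa, pb)))
    }
    if (restarts > 0) {
        rand <- .withSeed(seed, lapply(seq_len(restarts), function(i) {
            unlist(lapply(seq_len(nblk), function(b) {
                g <- stats::rgamma(n, shape = 1)
                g / sum(g)
            }))
        }))
        inits <- c(inits, rand)
    }
    best <- NULL
    for (initP in inits) {
        fit <- .solveSimplexLS(prob, model, initP, maxit, factr)
        if (is.null(best) || fit$value < best$value) best <- fit
    }
    fa <- if (model == "IID") list(.supportFA(prob$sup, best$p))
          else list(sn1 = .supportFA(prob$sup, best$p[seq_len(n)]),
                    sn2 = .supportFA(prob$sup, best$p[n + seq_len(n)]))
    predicted <- new("CLProfile",
                     totalCarbons = observed@totalCarbons,
                     totalDoubleBonds = observed@totalDoubleBonds,
                     values = best$pred, kind = "predicted")
    new("CLFitResult",
        model = model, fa = fa, observed = observed, predicted = predicted,
        error = best$value,
        pearsonR = .pearson(best$pred, prob$obs),
        unassignedMass = max(0, 1 - sum(best$pred)),
        unreachablePeaks = .cdLabel(
            observed@totalCarbons[!prob$reachable],
            observed@totalDoubleBonds[!prob$reachable]),
        convergence = list(counts = best$counts, message = best$message,
                           starts = length(inits)))
}

#' Fit the IID positional model to an observed CL profile
#'
#' Finds the chain distribution on the simplex that minimizes the sum of
#' squared deviations between the model peak distribution
#' ([peakDistributionIID()]) and the observed peak values, over the
#' observed peak set. Under a Gaussian measurement-error model with equal
#' variance across peaks this least-squares fit is the maximum-likelihood
#' estimate. Initialization is the uniform distribution; optional random
#' multi-starts probe local minima. Model mass falling on peaks absent
#' from the observed set is reported as \code{unassignedMass} and never
#' renormalized away. Observed peaks unreachable from the support raise a
#' warning, are listed in the result, and contribute their squared
#' observed value to the error.
#'
#' @param observed a [CLProfile-class]; typically observed (normalized),
#'   but any nonnegative peak values are accepted (used internally on
#'   cross-validation subsets).
#' @param support candidate chain types: character labels, a list as
#'   returned by [parseChainLabel()], an [FADistribution-class], or the
#'   output of [chainSupport()].
#' @param restarts number of additional random (Dirichlet(1)) starts;
#'   default 0 keeps the single uniform start.
#' @param seed integer seed for the random starts (required when
#'   \code{restarts > 0}).
#' @param maxit maximum optimizer iterations (default 2000).
#' @param factr L-BFGS-B objective-convergence factor (default 10, i.e.
#'   about 2e-15 relative objective tolerance).
#' @return A [CLFitResult-class].
#' @examples
#' fa <- FADistribution(c("16:0" = 0.3, "18:1" = 0.5, "18:2" = 0.2))
#' obs <- peakDistributionIID(fa)
#' obs@kind <- "observed"
#' fit <- fitIID(obs, chainLabels(fa))
#' fitError(fit)          # ~0
#' probs(faDistributions(fit)[[1]])
#' @seealso [fitIDD()], [fitMetrics()], [crossValidateCL()]
#' @export
fitIID <- function(observed, support, restarts = 0, seed = NULL,
                   maxit = 2000, factr = 10) {
    if (restarts > 0 && is.null(seed))
        stop("'seed' is required when restarts > 0")
    .positionalFit(observed, support, "IID", restarts, seed, maxit, factr)
}

#' Fit the IDD positional model to an observed CL profile
#'
#' Like [fitIID()] but with distinct chain distributions for the sn-1/sn-1'
#' and sn-2/sn-2' position pairs ([peakDistributionIDD()]). Because the IID
#' model is the special case of equal pair distributions, the IDD optimum
#' can never be worse; to guarantee this against local minima the solver
#' polishes from two deterministic starts — the uniform distribution and
#' the IID solution duplicated at both position pairs — and keeps the
#' better optimum (disable the second start with \code{initFromIID =
#' FALSE} to reproduce a pure uniform-start protocol). The two returned
#' distributions are exchangeable: the objective is symmetric under
#' swapping the position pairs.
#'
#' @inheritParams fitIID
#' @param initFromIID logical; also start from the IID fit (default
#'   \code{TRUE}).
#' @return A [CLFitResult-class] with \code{faDistributions()} of length
#'   two (\code{sn1}, \code{sn2}).
#' @examples
#' p1 <- FADistribution(c("16:0" = 1))
#' p2 <- FADistribution(c("18:1" = 1))
#' obs <- peakDistributionIDD(p1, p2)
#' obs@kind <- "observed"
#' fit <- fitIDD(obs, c("16:0", "18:1"))
#' fitError(fit)
#' @export
fitIDD <- function(observed, support, restarts = 0, seed = NULL,
                   maxit = 2000, factr = 10, initFromIID = TRUE) {
    if (restarts > 0 && is.null(seed))
        stop("'seed' is required when restarts > 0")
    extra <- list()
    if (initFromIID) {
        iid <- suppressWarnings(
            fitIID(observed, support, maxit = maxit, factr = factr))
        p <- faDistributions(iid)[[1]]@probs
        n <- length(p)
        ## nudge off exact zeros so reparameterised coordinates can move
        p <- 0.99 * p + 0.01 / n
        extra <- list(c(p, p))
    }
    .positionalFit(observed, support, "IDD", restarts, seed, maxit, factr,
                   extraInits = extra)
}

#' Squared error and Pearson correlation between two peak profiles
#'
#' @param pred predicted [CLProfile-class] (or bare numeric vector).
#' @param observed observed [CLProfile-class] (or bare numeric vector) on
#'   the same peak set in the same order.
#' @return A list with \code{error} (sum of squared deviations) and
#'   \code{pearsonR}. The correlation of identical vectors is 1; otherwise
#'   zero variance in either vector yields \code{NA} (undefined).
#' @examples
#' fitMetrics(c(0.5, 0.5), c(0.6, 0.4))
#' @export
fitMetrics <- function(pred, observed) {
    if (is(pred, "CLProfile") && is(observed, "CLProfile")) {
        if (!identical(peakLabels(pred), peakLabels(observed)))
            stop("profiles must share the same peak set in the same order")
        pred <- pred@values
        observed <- observed@values
    }
    if (length(pred) != length(observed))
        stop("length mismatch between predicted and observed values")
    list(error = sum((pred - observed)^2),
         pearsonR = .pearson(pred, observed))
}
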
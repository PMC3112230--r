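## Dynamic remodeling model and its steady-state reduction. The per-chain
## dynamics under head-group-determined donation are linear:
##   dA(alpha)/dt = sum_c k_c * f_c(alpha) - gamma * A(alpha),
## with k_c the transfer rate constant of donor class c, f_c its chain
## fractions, and gamma the CL chain degradation rate. The normalized
## fixed point of the chain fractions is sum_c W_c f_c with
## W_c = k_c / sum k — exactly the proportional-incorporation mixture;
## gamma cancels at the normalized fixed point and only shapes the
## trajectory.

.alignPools <- function(pools) {
    stopifnot(length(pools) >= 1L,
              all(vapply(pools, is, TRUE, "FADistribution")))
    cs <- integer(0); ds <- integer(0)
    for (pool in pools) {
        cs <- c(cs, pool@carbons); ds <- c(ds, pool@doubleBonds)
    }
    key <- .cdKey(cs, ds)
    u <- !duplicated(key)
    cs <- cs[u]; ds <- ds[u]
    ord <- order(cs, ds)
    cs <- cs[ord]; ds <- ds[ord]
    ukey <- .cdKey(cs, ds)
    F <- vapply(pools, function(pool) {
        v <- numeric(length(ukey))
        v[match(.cdKey(pool@carbons, pool@doubleBonds), ukey)] <- pool@probs
        v
    }, numeric(length(ukey)))
    matrix(F, ncol = length(pools),
           dimnames = list(.cdLabel(cs, ds), names(pools)))
}

#' Steady-state donor weights implied by transfer rate constants
#'
#' At the steady state of the dynamic remodeling model the fraction of CL
#' chains donated by class \code{c} is \code{W_c = k_c / sum(k)}, so the
#' steady-state CL chain composition is the proportional-incorporation
#' mixture \code{sum_c W_c f_c} of the donor pools.
#'
#' @param rates named numeric vector of nonnegative transfer rate
#'   constants (1/time), at least one positive.
#' @return Named numeric weight vector on the simplex.
#' @examples
#' steadyStateWeights(c(PC_sn2 = 2, PE_sn2 = 1, PG = 1))
#' @export
steadyStateWeights <- function(rates) {
    if (any(rates < 0)) stop("transfer rates must be >= 0")
    if (sum(rates) <= 0) stop("at least one transfer rate must be positive")
    rates / sum(rates)
}

#' Simulate the dynamic remodeling model
#'
#' Numerically integrates the linear chain dynamics (donation from each
#' donor class at rate \code{k_c} proportional to its chain fractions,
#' first-order degradation at rate \code{gamma}) and reports the CL chain
#' fractions along the trajectory. The total CL chain amount is held at
#' steady state, so fractions are obtained by normalizing the integrated
#' amounts. The trajectory approaches the unique fixed point
#' \code{sum_c W_c f_c} with \code{W = steadyStateWeights(rates)}.
#'
#' @param rates named numeric vector of transfer rate constants, one per
#'   donor class; nonnegative, at least one positive.
#' @param pools named list of donor [FADistribution-class] pools matching
#'   \code{names(rates)}.
#' @param init [FADistribution-class], the initial CL chain composition;
#'   default uniform over the union pool support.
#' @param gamma degradation rate constant (1/time), default 1; it cancels
#'   at the normalized fixed point.
#' @param tEnd end time of the integration.
#' @param nSteps number of output time points (default 100).
#' @param tol relative/absolute integrator tolerance (default 1e-10).
#' @return A list with \code{times}, \code{fractions} (time x chains
#'   matrix of CL chain fractions, rows summing to 1) and
#'   \code{steadyState} (the closed-form fixed point for reference).
#' @examples
#' pc <- FADistribution(c("18:2" = 0.8, "20:4" = 0.2))
#' pg <- FADistribution(c("16:0" = 0.6, "18:1" = 0.4))
#' out <- simulateDynamics(c(PC_sn2 = 2, PG = 1), list(PC_sn2 = pc, PG = pg),
#'                         tEnd = 40)
#' out$fractions[nrow(out$fractions), ]
#' @export
simulateDynamics <- function(rates, pools, init = NULL, gamma = 1,
                             tEnd = 50, nSteps = 100, tol = 1e-10) {
    if (any(rates < 0) || sum(rates) <= 0)
        stop("rates must be nonnegative with at least one positive")
    if (gamma < 0) stop("gamma must be >= 0")
    if (tEnd <= 0) stop("tEnd must be positive")
    if (is.null(names(rates)) || !setequal(names(rates), names(pools)))
        stop("'rates' and 'pools' must share the same donor class names")
    F <- .alignPools(pools)
    F <- F[, names(rates), drop = FALSE]
    influx <- as.vector(F %*% rates)
    chains <- rownames(F)
    n <- length(chains)
    if (is.null(init)) {
        a0 <- rep(1 / n, n)
    } else {
        stopifnot(is(init, "FADistribution"))
        a0 <- numeric(n)
        idx <- match(.cdLabel(init@carbons, init@doubleBonds), chains)
        if (anyNA(idx))
            stop("initial composition contains chains outside the pool support")
        a0[idx] <- init@probs
    }
    deriv <- function(t, A, parms) list(influx - gamma * A)
    times <- seq(0, tEnd, length.out = nSteps + 1L)
    sol <- deSolve::ode(y = a0, times = times, func = deriv, parms = NULL,
                        rtol = tol, atol = tol)
    if (any(!is.finite(sol)))
        stop("integration produced non-finite state; check rates and tEnd")
    A <- sol[, -1L, drop = FALSE]
    frac <- A / rowSums(A)
    colnames(frac) <- chains
    w <- steadyStateWeights(rates)
    ss <- as.vector(F %*% w)
    names(ss) <- chains
    list(times = sol[, 1L], fractions = frac, steadyState = ss)
}
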
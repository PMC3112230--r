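## Acyl-chain combinatorics: label parsing, chain-type support, and forward
## computation of CL mass-peak distributions from per-position FA
## distributions by sparse self-convolution over (carbons, double-bonds)
## keys.

## Labels accept the ASCII colon and the Unicode ratio character U+2236
## that lipidomics literature often uses (e.g. "18∶1").
.CHAIN_LABEL_RE <- "^\\s*([0-9]+)\\s*[:∶]\\s*([0-9]+)\\s*$"

.parseCDLabel <- function(label, what) {
    label <- as.character(label)
    m <- regmatches(label, regexec(.CHAIN_LABEL_RE, label))
    bad <- vapply(m, length, 0L) != 3L
    if (any(bad))
        stop(sprintf("malformed %s label(s): %s", what,
                     paste(sQuote(label[bad]), collapse = ", ")),
             call. = FALSE)
    list(carbons = vapply(m, function(x) as.integer(x[2L]), 0L),
         doubleBonds = vapply(m, function(x) as.integer(x[3L]), 0L))
}

#' Parse acyl chain labels
#'
#' Parses chain labels of the form \code{"C:D"} (carbons : double bonds),
#' accepting either the ASCII colon or the Unicode ratio separator, into
#' integer carbon and double-bond counts. Chains must satisfy
#' \code{carbons >= 1} and \code{0 <= doubleBonds < carbons}.
#'
#' @param label character vector of chain labels, e.g. \code{"18:1"}.
#' @return A list with integer vectors \code{carbons} and \code{doubleBonds}.
#' @examples
#' parseChainLabel(c("18:1", "22:6"))
#' @export
parseChainLabel <- function(label) {
    ch <- .parseCDLabel(label, "chain")
    if (any(ch$carbons < 1L))
        stop("chain carbons must be >= 1", call. = FALSE)
    if (any(ch$doubleBonds >= ch$carbons))
        stop("chain double bonds must be < carbons", call. = FALSE)
    ch
}

.parsePeakLabel <- function(label) .parseCDLabel(label, "CL peak")

#' Format chains as ASCII "C:D" labels
#'
#' @param carbons integer vector (or a list with \code{carbons} and
#'   \code{doubleBonds} as returned by [parseChainLabel()]).
#' @param doubleBonds integer vector, ignored when \code{carbons} is a list.
#' @return Character vector of ASCII \code{"C:D"} labels; parsing and
#'   formatting round-trip.
#' @examples
#' formatChainLabel(18, 1)
#' @export
formatChainLabel <- function(carbons, doubleBonds) {
    if (is.list(carbons)) {
        doubleBonds <- carbons$doubleBonds
        carbons <- carbons$carbons
    }
    .cdLabel(carbons, doubleBonds)
}

#' Candidate chain-type support from donor pools
#'
#' The chain types allowed at CL positions are those observed (with
#' strictly positive probability) in any acyl donor pool. Returns the
#' sorted union.
#'
#' @param donorPools a list of [FADistribution-class] donor pools (or a
#'   single one).
#' @return Character vector of chain labels sorted by carbons, then double
#'   bonds.
#' @examples
#' pg <- FADistribution(c("16:0" = 0.5, "18:1" = 0.5))
#' pc <- FADistribution(c("18:2" = 1))
#' chainSupport(list(pg, pc))
#' @export
chainSupport <- function(donorPools) {
    if (is(donorPools, "FADistribution"))
        donorPools <- list(donorPools)
    if (length(donorPools) == 0L)
        stop("at least one donor pool is required")
    cs <- integer(0); ds <- integer(0)
    for (pool in donorPools) {
        stopifnot(is(pool, "FADistribution"))
        keep <- pool@probs > 0
        cs <- c(cs, pool@carbons[keep])
        ds <- c(ds, pool@doubleBonds[keep])
    }
    key <- .cdKey(cs, ds)
    u <- !duplicated(key)
    cs <- cs[u]; ds <- ds[u]
    if (length(cs) == 0L)
        stop("no candidate chain types (all donor probabilities are zero)")
    ord <- order(cs, ds)
    .cdLabel(cs[ord], ds[ord])
}

## ---- sparse (c, d) convolution ------------------------------------------

## A "cd" object is list(c = integer, d = integer, p = numeric), sparse over
## (carbons, double-bonds) keys.

.asCD <- function(fa, dropZero = TRUE) {
    keep <- if (dropZero) fa@probs > 0 else rep(TRUE, length(fa@probs))
    list(c = fa@carbons[keep], d = fa@doubleBonds[keep], p = fa@probs[keep])
}

.convCD <- function(a, b) {
    cc <- outer(a$c, b$c, "+")
    dd <- outer(a$d, b$d, "+")
    pp <- outer(a$p, b$p)
    key <- as.vector(cc) * 64L + as.vector(dd)
    agg <- rowsum(as.vector(pp), key)     # sorted by key
    k <- as.integer(rownames(agg))
    list(c = k %/% 64L, d = k %% 64L, p = as.vector(agg))
}

.cdToProfile <- function(cd, kind = "predicted") {
    ord <- order(cd$c, cd$d)
    new("CLProfile",
        totalCarbons = as.integer(cd$c[ord]),
        totalDoubleBonds = as.integer(cd$d[ord]),
        values = cd$p[ord],
        kind = kind)
}

.checkNormalized <- function(fa, arg) {
    if (abs(sum(fa@probs) - 1) > .TOL_NORM)
        stop(sprintf("'%s' is not normalized (sum %.12g)", arg, sum(fa@probs)),
             call. = FALSE)
}

#' CL peak distribution under the IID positional model
#'
#' Under the independent-and-identical distribution (IID) model the four CL
#' chain positions (sn-1, sn-1', sn-2, sn-2') draw independently from one
#' chain distribution; the probability of an isomer is the product of its
#' four chain probabilities and the probability of a mass peak
#' \code{(c, d)} is the sum over all ordered 4-tuples with total carbons
#' \code{c} and total double bonds \code{d}. Computed as the 4-fold sparse
#' self-convolution of the (carbons, double-bonds) chain distribution,
#' which enumerating all ordered tuples confirms (see
#' [bruteForcePeakDistribution()]).
#'
#' @param fa a normalized [FADistribution-class].
#' @return A [CLProfile-class] over all reachable peaks, summing to 1.
#' @examples
#' fa <- FADistribution(c("18:1" = 0.5, "18:2" = 0.5))
#' peakDistributionIID(fa)  # binomial(4, 0.5) over double bonds 4..8
#' @export
peakDistributionIID <- function(fa) {
    stopifnot(is(fa, "FADistribution"))
    .checkNormalized(fa, "fa")
    f <- .asCD(fa)
    f2 <- .convCD(f, f)
    .cdToProfile(.convCD(f2, f2))
}

#' CL peak distribution under the IDD positional model
#'
#' The independent-and-differential distribution (IDD) model keeps the four
#' positions independent but lets the sn-1/sn-1' pair draw from one chain
#' distribution and the sn-2/sn-2' pair from another. The peak distribution
#' is the convolution of the two pairwise self-convolutions; with equal
#' distributions it reduces exactly to [peakDistributionIID()].
#'
#' @param faSn1 normalized [FADistribution-class] for the sn-1/sn-1'
#'   positions.
#' @param faSn2 normalized [FADistribution-class] for the sn-2/sn-2'
#'   positions.
#' @return A [CLProfile-class] over all reachable peaks, summing to 1.
#' @examples
#' p1 <- FADistribution(c("16:0" = 1))
#' p2 <- FADistribution(c("18:1" = 1))
#' peakDistributionIDD(p1, p2)  # single peak 68:2
#' @export
peakDistributionIDD <- function(faSn1, faSn2) {
    stopifnot(is(faSn1, "FADistribution"), is(faSn2, "FADistribution"))
    .checkNormalized(faSn1, "faSn1")
    .checkNormalized(faSn2, "faSn2")
    a <- .asCD(faSn1); b <- .asCD(faSn2)
    .cdToProfile(.convCD(.convCD(a, a), .convCD(b, b)))
}

#' Brute-force CL peak distribution (test oracle)
#'
#' Explicitly enumerates all \code{N^4} ordered assignments of chains to
#' the four CL positions and accumulates isomer probabilities into
#' \code{(total carbons, total double bonds)} peaks. Exponentially slower
#' than the convolution route but independent of it; used as the reference
#' in tests. Refuses combined supports larger than 12 chains.
#'
#' @param faSn1 normalized [FADistribution-class] for sn-1/sn-1'.
#' @param faSn2 normalized [FADistribution-class] for sn-2/sn-2'; defaults
#'   to \code{faSn1} (IID).
#' @return A [CLProfile-class] over all reachable peaks.
#' @examples
#' fa <- FADistribution(c("18:1" = 0.5, "18:2" = 0.5))
#' bruteForcePeakDistribution(fa)
#' @export
bruteForcePeakDistribution <- function(faSn1, faSn2 = faSn1) {
    stopifnot(is(faSn1, "FADistribution"), is(faSn2, "FADistribution"))
    .checkNormalized(faSn1, "faSn1")
    .checkNormalized(faSn2, "faSn2")
    a <- .asCD(faSn1); b <- .asCD(faSn2)
    n <- length(unique(c(.cdKey(a$c, a$d), .cdKey(b$c, b$d))))
    if (n > 12L)
        stop(sprintf(
            "combined support of %d chains is too large for brute-force %s",
            n, "enumeration (limit 12)"), call. = FALSE)
    na <- length(a$p); nb <- length(b$p)
    idx <- expand.grid(i = seq_len(na), j = seq_len(na),
                       k = seq_len(nb), h = seq_len(nb))
    cc <- a$c[idx$i] + a$c[idx$j] + b$c[idx$k] + b$c[idx$h]
    dd <- a$d[idx$i] + a$d[idx$j] + b$d[idx$k] + b$d[idx$h]
    pp <- a$p[idx$i] * a$p[idx$j] * b$p[idx$k] * b$p[idx$h]
    agg <- rowsum(pp, .cdKey(cc, dd))
    k <- as.integer(rownames(agg))
    .cdToProfile(list(c = k %/% 64L, d = k %% 64L, p = as.vector(agg)))
}
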
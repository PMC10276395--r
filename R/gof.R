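#' Aggregate matrix entries by nearest estimated rate
#'
#' Selects the \code{m} entries of the rate matrix whose estimated Poisson
#' rates are closest to the target \eqn{\lambda_0} (default 200 entries, a
#' pool large enough to assess Poissoneity without spanning too wide a
#' range of underlying rates). Their observed counts are then treated as an
#' approximately i.i.d. Poisson(\eqn{\lambda_0}) sample by the tests below.
#' Ties in \eqn{|\hat\lambda - \lambda_0|} are broken deterministically by
#' lower gene index, then lower cell index.
#'
#' @param x dense count matrix (or a [CountMatrix-class]).
#' @param lambdaHat estimated rate matrix of the same shape.
#' @param lambda0 positive target rate.
#' @param m number of entries, at most \code{G * C}.
#' @return an [EntryAggregate-class].
#' @export
aggregateEntries <- function(x, lambdaHat, lambda0, m = 200L) {
    if (is(x, "CountMatrix")) x <- as.matrix(x@values)
    stopifnot(identical(dim(x), dim(lambdaHat)))
    if (lambda0 <= 0) stop("lambda0 must be positive")
    if (m > length(x)) stop("m exceeds the number of matrix entries")
    d <- abs(lambdaHat - lambda0)
    rows <- as.vector(row(x))
    cols <- as.vector(col(x))
    ord <- order(as.vector(d), rows, cols)[seq_len(m)]
    new("EntryAggregate", targetLambda = lambda0,
        genes = rows[ord], cells = cols[ord],
        counts = as.numeric(x[ord]), lambdas = as.numeric(lambdaHat[ord]))
}

setMethod("show", "EntryAggregate", function(object) {
    cat(sprintf("EntryAggregate: %d entries near lambda0 = %g\n",
                length(object@counts), object@targetLambda))
    cat(sprintf("  rate range [%.4g, %.4g]; mean count %.3f\n",
                min(object@lambdas), max(object@lambdas),
                mean(object@counts)))
})

#' Kolmogorov-Smirnov distance to the Poisson
#'
#' Maximum vertical distance between the empirical CDF of the aggregated
#' counts and the theoretical Poisson(\eqn{\lambda_0}) CDF, evaluated over
#' the full integer support (both step functions only jump at integers).
#' The p-value uses the standard one-sample asymptotic Kolmogorov null,
#' which is conservative for discrete data; it is reported as such and no
#' bootstrap is attempted.
#'
#' @param agg an [EntryAggregate-class].
#' @return list with \code{stat} (the KS distance D) and \code{p}.
#' @export
ksPoisson <- function(agg) {
    stopifnot(is(agg, "EntryAggregate"))
    y <- agg@counts
    n <- length(y)
    l0 <- agg@targetLambda
    xmax <- max(max(y), stats::qpois(1 - 1e-12, l0))
    grid <- 0:xmax
    ec <- stats::ecdf(y)(grid)
    D <- max(abs(ec - stats::ppois(grid, l0)))
    list(stat = D, p = .kolmogorovP(sqrt(n) * D))
}

# upper-tail of the Kolmogorov distribution, Q(t) = 2 sum (-1)^{k-1} e^{-2k^2 t^2}
.kolmogorovP <- function(t) {
    if (t < 0.2) return(1)
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
    min(max(p, 0), 1)
}

#' Over-dispersion score test
#'
#' Cameron-Trivedi auxiliary regression test of the Poisson null
#' \eqn{\mathrm{Var}(X) = \lambda} against the over-dispersion alternative
#' \eqn{\mathrm{Var}(X) = (1+\alpha)\lambda}, \eqn{\alpha > 0}: the
#' quantities \eqn{(x_i - \hat\mu_i)^2 - x_i} are regressed on
#' \eqn{\hat\mu_i} without intercept and the slope's standardized statistic
#' is referred to the asymptotic normal null, one-sided. By default each
#' entry contributes its own estimated rate \eqn{\hat\mu_i = \hat\lambda_i}
#' (heterogeneous null); \code{pooled = TRUE} replaces all means by the
#' sample mean for comparability with the classical single-sample test.
#'
#' @param agg an [EntryAggregate-class] with at least 30 entries.
#' @param pooled use the pooled sample mean instead of per-entry rates.
#' @return list with \code{z}, one-sided \code{p}, and \code{alphaHat},
#'   the estimated dispersion coefficient (negative under
#'   under-dispersion).
#' @export
dispersionTest <- function(agg, pooled = FALSE) {
    stopifnot(is(agg, "EntryAggregate"))
    y <- agg@counts
    n <- length(y)
    if (n < 30L) stop("dispersion test requires at least 30 entries")
    mu <- if (pooled) rep(mean(y), n) else agg@lambdas
    zaux <- (y - mu)^2 - y
    slope <- sum(zaux * mu) / sum(mu^2)
    resid <- zaux - slope * mu
    se <- sqrt(sum(resid^2) / (n - 1) / sum(mu^2))
    # a degenerate residual (e.g. constant sample) leaves the sign of the
    # slope as the only information
    z <- if (se > 0) slope / se else sign(slope) * Inf
    list(z = z, p = stats::pnorm(z, lower.tail = FALSE), alphaHat = slope)
}

#' Zero-inflation test
#'
#' Compares the observed proportion of zeros
#' \eqn{\Pi = \frac{1}{m}\sum_i I\{x_i = 0\}} with the model-implied
#' proportion \eqn{\frac{1}{m}\sum_i e^{-\hat\lambda_i}}. Each indicator is
#' Bernoulli\eqn{(e^{-\hat\lambda_i})} under the null, giving
#' \eqn{\mathrm{var}(\Pi) = \frac{1}{m^2}\sum_i
#' e^{-\hat\lambda_i}(1 - e^{-\hat\lambda_i})} and a one-sided Gaussian
#' test for excess zeros. When every rate is so large that the null
#' variance underflows to zero, the null is degenerate at zero observed
#' zeros and \code{p = 1} is reported with a flag.
#'
#' @param agg an [EntryAggregate-class].
#' @return list with \code{pi} (observed zero proportion), \code{expected},
#'   \code{varPi}, \code{z}, one-sided \code{p}, and \code{degenerate}.
#' @export
zeroInflationTest <- function(agg) {
    stopifnot(is(agg, "EntryAggregate"))
    y <- agg@counts
    m <- length(y)
    p0 <- exp(-agg@lambdas)
    Pi <- mean(y == 0)
    expected <- mean(p0)
    varPi <- sum(p0 * (1 - p0)) / m^2
    if (varPi == 0)
        return(list(pi = Pi, expected = expected, varPi = 0, z = NA_real_,
                    p = 1, degenerate = TRUE))
    z <- (Pi - expected) / sqrt(varPi)
    list(pi = Pi, expected = expected, varPi = varPi, z = z,
         p = stats::pnorm(z, lower.tail = FALSE), degenerate = FALSE)
}

#' Q-Q simulation envelope against the Poisson
#'
#' Pairs the sorted observed counts against the theoretical mid-quantiles
#' \eqn{F^{-1}((i - 0.5)/m)} of Poisson(\eqn{\lambda_0}) (mid-positions
#' chosen for symmetry with the averaged CDF) and surrounds them with the
#' pointwise band of sorted values over \code{nSim} simulated
#' Poisson(\eqn{\lambda_0}) samples of the same size, by default the
#' [2.5\%, 97.5\%] percentile band. Zero-inflation shows as points leaving
#' the band below on the left, over-dispersion as points leaving above on
#' the right.
#'
#' @param agg an [EntryAggregate-class].
#' @param nSim number of simulated samples, at least 20.
#' @param seed RNG seed.
#' @param band lower/upper percentiles of the envelope.
#' @return list with \code{observed}, \code{theoretical}, \code{lower},
#'   \code{upper}, \code{fractionInside} and the verdict \code{inside}
#'   (at least 95\% of order statistics within the band).
#' @export
qqEnvelope <- function(agg, nSim = 500L, seed = 1L, band = c(0.025, 0.975)) {
    stopifnot(is(agg, "EntryAggregate"))
    if (nSim < 20L) stop("nSim must be at least 20")
    m <- length(agg@counts)
    l0 <- agg@targetLambda
    set.seed(seed)
    sims <- matrix(stats::rpois(nSim * m, l0), nSim, m)
    sims <- t(apply(sims, 1L, sort))
    lower <- apply(sims, 2L, stats::quantile, probs = band[1L])
    upper <- apply(sims, 2L, stats::quantile, probs = band[2L])
    obs <- sort(agg@counts)
    fin <- mean(obs >= lower & obs <= upper)
    list(observed = obs,
         theoretical = stats::qpois((seq_len(m) - 0.5) / m, l0),
         lower = unname(lower), upper = unname(upper),
         fractionInside = fin, inside = fin >= 0.95)
}

#' Full Poissoneity report for one target rate
#'
#' Runs the KS, over-dispersion and zero-inflation tests, plus the Q-Q
#' envelope, on the entries aggregated nearest to \code{lambda0}.
#'
#' @param x dense count matrix or [CountMatrix-class].
#' @param lambdaHat estimated rate matrix.
#' @param lambda0 target rate.
#' @param m entries per aggregate.
#' @param nSim envelope simulations (0 to skip the envelope).
#' @param seed RNG seed for the envelope.
#' @return a [GofReport-class].
#' @export
poissoneityReport <- function(x, lambdaHat, lambda0, m = 200L,
                              nSim = 500L, seed = 1L) {
    agg <- aggregateEntries(x, lambdaHat, lambda0, m)
    env <- if (nSim >= 20L) qqEnvelope(agg, nSim, seed) else list()
    new("GofReport", targetLambda = lambda0,
        ks = ksPoisson(agg),
        dispersion = if (length(agg@counts) >= 30L) dispersionTest(agg)
                     else list(),
        zeroInflation = zeroInflationTest(agg),
        envelope = env)
}

setMethod("show", "GofReport", function(object) {
    cat(sprintf("GofReport at lambda0 = %g\n", object@targetLambda))
    cat(sprintf("  KS:             D = %.4f, p = %.4f\n",
                object@ks$stat, object@ks$p))
    if (length(object@dispersion))
        cat(sprintf("  over-dispersion: z = %.3f, p = %.4f (alpha-hat %.3f)\n",
                    object@dispersion$z, object@dispersion$p,
                    object@dispersion$alphaHat))
    cat(sprintf("  zero-inflation:  Pi = %.3f vs %.3f, p = %.4f\n",
                object@zeroInflation$pi, object@zeroInflation$expected,
                object@zeroInflation$p))
    if (length(object@envelope))
        cat(sprintf("  Q-Q envelope:    %.0f%% of points inside (%s)\n",
                    100 * object@envelope$fractionInside,
                    if (object@envelope$inside) "inside" else "outside"))
})
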
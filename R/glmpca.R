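#' Minimal Poisson GLM-PCA
#'
#' Fits the latent-factor Poisson rate model
#' \deqn{\log\lambda_{gc} = \log n_c + \alpha_g + \sum_{l=1}^L \xi_{gl}\rho_{cl}}
#' by blockwise Newton (Fisher-scoring) ascent of the Poisson
#' log-likelihood with the offsets fixed at the log cell totals: per-gene
#' updates of \eqn{(\alpha_g, \xi_{g\cdot})} given the loadings, then
#' per-cell updates of \eqn{\rho_{c\cdot}} given the scores, each step
#' halved until the deviance does not increase, so the deviance trace is
#' monotone non-increasing by construction. Used here to estimate per-entry
#' rates for Poissoneity validation, not for embedding; the factorization
#' \eqn{\xi\rho^\top} is rotation-invariant and no identifiability
#' normalization is applied.
#'
#' With \code{L = 0} the model reduces to the analytic per-gene
#' offset-intercept MLE \eqn{\hat\alpha_g = \log(\sum_c x_{gc} / \sum_c n_c)}
#' and no iteration is run.
#'
#' @param m a filtered [CountMatrix-class].
#' @param L latent dimension, \code{0 <= L < min(G, C)}.
#' @param maxIter maximum number of full update sweeps.
#' @param tol relative deviance change declaring convergence.
#' @param seed seed for the small Gaussian initialization (sd 1e-3) of the
#'   scores and loadings, so the ascent starts near the null model.
#' @return a [GlmPcaFit-class]; non-convergence at \code{maxIter} is
#'   recorded in the fit (and warned about), not an error.
#' @export
fitGlmPca <- function(m, L, maxIter = 200L, tol = 1e-6, seed = 1L) {
    stopifnot(is(m, "CountMatrix"))
    x <- as.matrix(m@values)
    G <- nrow(x); C <- ncol(x)
    if (L >= min(G, C)) stop("L must be smaller than min(G, C)")
    n <- colSums(x)
    if (any(n == 0) || any(rowSums(x) == 0))
        stop("zero margins present; apply filterCounts() first")
    off <- log(n)
    alpha <- log(rowSums(x) / sum(n))

    if (L == 0L) {
        lam <- exp(alpha) %o% n
        fit <- new("GlmPcaFit", geneIntercepts = unname(alpha),
                   scores = matrix(numeric(0), G, 0),
                   loadings = matrix(numeric(0), C, 0),
                   offsets = unname(off), L = 0L,
                   devianceTrace = .poisDeviance(x, lam), converged = TRUE,
                   geneIds = m@geneIds, cellIds = m@cellIds)
        return(fit)
    }

    set.seed(seed)
    xi <- matrix(stats::rnorm(G * L, sd = 1e-3), G, L)
    rho <- matrix(stats::rnorm(C * L, sd = 1e-3), C, L)

    lam <- exp(outer(alpha, off, "+") + tcrossprod(xi, rho))
    dev <- .poisDeviance(x, lam)
    trace <- dev
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        # gene block: coefficients (alpha_g, xi_g.) with design (1, rho)
        Z <- cbind(1, rho)
        for (g in seq_len(G)) {
            b <- .newtonStep(x[g, ], Z, off, c(alpha[g], xi[g, ]))
            alpha[g] <- b[1L]; xi[g, ] <- b[-1L]
        }
        # cell block: coefficients rho_c. with design xi, offset log n_c + alpha
        for (c_ in seq_len(C)) {
            rho[c_, ] <- .newtonStep(x[, c_], xi, off[c_] + alpha, rho[c_, ])
        }
        lam <- exp(outer(alpha, off, "+") + tcrossprod(xi, rho))
        devNew <- .poisDeviance(x, lam)
        trace <- c(trace, devNew)
        if (dev - devNew < tol * abs(dev)) {
            converged <- TRUE
            dev <- devNew
            break
        }
        dev <- devNew
    }
    if (!converged)
        warning("GLM-PCA did not reach the deviance tolerance in ",
                maxIter, " sweeps")
    new("GlmPcaFit", geneIntercepts = unname(alpha), scores = xi,
        loadings = rho, offsets = unname(off), L = as.integer(L),
        devianceTrace = trace, converged = converged,
        geneIds = m@geneIds, cellIds = m@cellIds)
}

# one damped Newton step for a Poisson regression block:
# maximize sum(y * eta - exp(eta)), eta = off + Z b. The per-block
# log-likelihood is concave in b, and the step is halved until it does not
# decrease, so each block update is monotone.
.newtonStep <- function(y, Z, off, b) {
    eta <- off + drop(Z %*% b)
    mu <- exp(eta)
    ll0 <- sum(y * eta - mu)
    gr <- crossprod(Z, y - mu)
    H <- crossprod(Z, Z * mu)
    diag(H) <- diag(H) + 1e-10
    delta <- tryCatch(solve(H, gr), error = function(e) gr * 0)
    step <- 1
    for (h in 1:30) {
        bNew <- b + step * drop(delta)
        etaNew <- off + drop(Z %*% bNew)
        if (max(etaNew) < 700) {           # overflow guard
            llNew <- sum(y * etaNew - exp(etaNew))
            if (llNew >= ll0) return(bNew)
        }
        step <- step / 2
    }
    b
}

.poisDeviance <- function(x, lam) {
    t1 <- ifelse(x > 0, x * log(x / lam), 0)
    2 * sum(t1 - (x - lam))
}

#' @rdname accessors
#' @export
setMethod("lambdaHat", "GlmPcaFit", function(object) {
    eta <- outer(object@geneIntercepts, object@offsets, "+")
    if (object@L > 0L)
        eta <- eta + tcrossprod(object@scores, object@loadings)
    lam <- exp(eta)
    dimnames(lam) <- list(object@geneIds, object@cellIds)
    lam
})

setMethod("show", "GlmPcaFit", function(object) {
    cat(sprintf("GlmPcaFit: %d genes x %d cells, L = %d\n",
                length(object@geneIntercepts), length(object@offsets),
                object@L))
    cat(sprintf("  deviance %.2f after %d sweep(s); converged: %s\n",
                utils::tail(object@devianceTrace, 1),
                length(object@devianceTrace) - 1L, object@converged))
})

#' Select the latent dimension by goodness of fit
#'
#' Fits each candidate \code{L} in turn and runs a Poissoneity battery on
#' entries aggregated by nearest estimated rate; returns the smallest
#' \code{L} whose battery reports no rejection, or \code{NA} if every
#' candidate is rejected. This encodes the trial-and-error principle for
#' choosing the latent dimension: too small an \code{L} leaves biological
#' structure in the residual rates (rejected as over-dispersion / zero
#' inflation), too large an \code{L} overfits; any accepted \code{L}
#' validates the per-entry Poisson description.
#'
#' @param m a filtered [CountMatrix-class].
#' @param candidates integer vector of latent dimensions to try, in the
#'   order given (conventionally increasing).
#' @param gof battery callable with signature
#'   \code{function(counts, lambdaHat)} returning \code{TRUE} to accept;
#'   defaults to [poissoneityAccept()].
#' @param ... passed to [fitGlmPca()].
#' @return the accepted latent dimension, or \code{NA_integer_} when all
#'   candidates fail.
#' @export
selectL <- function(m, candidates, gof = poissoneityAccept, ...) {
    stopifnot(length(candidates) >= 1L)
    x <- as.matrix(m@values)
    for (L in candidates) {
        fit <- fitGlmPca(m, L = L, ...)
        if (isTRUE(gof(x, lambdaHat(fit))))
            return(as.integer(L))
    }
    NA_integer_
}

#' Default Poissoneity acceptance battery
#'
#' Accepts a rate model when, at every target rate in \code{lambda0} (a
#' grid spanning the informative range of UMI rates), the over-dispersion,
#' zero-inflation and KS tests on the entries aggregated by nearest
#' estimated rate are all non-significant at \code{level}. An aggregate is
#' only meaningful if its rates are nearly constant: selection is
#' restricted to entries with estimated rates within 25\% of
#' \eqn{\lambda_0}, shrinking the aggregate below \code{m} where the rate
#' range is sparsely populated (the standard remedy for the sampling
#' artifact in the upper rate range, where the nearest entries otherwise
#' form a genuine rate mixture and every battery would reject a correct
#' model); a target with fewer than 30 such entries is skipped.
#'
#' @param x dense count matrix.
#' @param lambdaHat estimated rate matrix of the same shape.
#' @param lambda0 target rates for aggregation.
#' @param m entries per aggregate.
#' @param level significance level per test.
#' @return logical: \code{TRUE} when no test rejects.
#' @export
poissoneityAccept <- function(x, lambdaHat, lambda0 = c(0.1, 0.5, 2, 20),
                              m = 200L, level = 0.05) {
    for (l0 in lambda0) {
        inWin <- lambdaHat >= l0 / 1.25 & lambdaHat <= l0 * 1.25
        mUse <- min(m, sum(inWin), length(x))
        if (mUse < 30L) next
        lamMasked <- lambdaHat
        lamMasked[!inWin] <- Inf
        agg <- aggregateEntries(x, lamMasked, l0, mUse)
        if (ksPoisson(agg)$p < level) return(FALSE)
        if (dispersionTest(agg)$p < level) return(FALSE)
        if (zeroInflationTest(agg)$p < level) return(FALSE)
    }
    TRUE
}
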
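#' Fit the two-way Poisson approximation
#'
#' Maximum-likelihood fit of the purely additive log-linear rate model
#' \deqn{\tilde\lambda_{gc} = e^{\mu + \alpha_g + \beta_c}}
#' under the identifiability constraints \eqn{\sum_g e^{\alpha_g} = G},
#' \eqn{\sum_c e^{\beta_c} = C}. The MLE has the closed form
#' \deqn{\hat\mu = \log\frac{\sum_{g,c} x_{gc}}{GC},\qquad
#'   \hat\alpha_g = \log\Big(\frac{\sum_c x_{gc}}{C}\Big) - \hat\mu,\qquad
#'   \hat\beta_c = \log\Big(\frac{\sum_g x_{gc}}{G}\Big) - \hat\mu,}
#' i.e. log row means and log column means centred at the log grand mean;
#' the score equations vanish exactly at these values. The model captures
#' gene-level abundance and cell-level library-size effects only; anything
#' beyond it (cell clusters in particular) surfaces as departure, see
#' [dipd()].
#'
#' All computation is in log space. Every gene row total and cell column
#' total must be positive (otherwise the corresponding effect estimate is
#' \eqn{-\infty}); call [filterCounts()] first.
#'
#' @param m a filtered [CountMatrix-class].
#' @return a [TwoWayFit-class].
#' @examples
#' m <- CountMatrix(matrix(c(1, 2, 3, 4), 2, 2))
#' f <- fitTwoWay(m)
#' lambdaTilde(f)
#' @export
fitTwoWay <- function(m) {
    stopifnot(is(m, "CountMatrix"))
    G <- nrow(m@values); C <- ncol(m@values)
    rowTot <- Matrix::rowSums(m@values)
    colTot <- Matrix::colSums(m@values)
    if (any(rowTot == 0) || any(colTot == 0))
        stop("zero row/column totals present; apply filterCounts() first")
    mu <- log(sum(rowTot) / (G * C))
    alpha <- log(rowTot / C) - mu
    beta <- log(colTot / G) - mu
    new("TwoWayFit", mu = mu, alpha = unname(alpha), beta = unname(beta),
        geneIds = m@geneIds, cellIds = m@cellIds)
}

#' @rdname accessors
#' @export
setMethod("lambdaTilde", "TwoWayFit", function(object) {
    lam <- exp(object@mu) * (exp(object@alpha) %o% exp(object@beta))
    dimnames(lam) <- list(object@geneIds, object@cellIds)
    lam
})

#' @rdname accessors
#' @export
setMethod("geneIds", "TwoWayFit", function(object) object@geneIds)

#' @rdname accessors
#' @export
setMethod("cellIds", "TwoWayFit", function(object) object@cellIds)

setMethod("show", "TwoWayFit", function(object) {
    cat(sprintf("TwoWayFit: %d genes x %d cells\n",
                length(object@alpha), length(object@beta)))
    cat(sprintf("  mu = %.4f  (grand-mean rate %.4f)\n",
                object@mu, exp(object@mu)))
    cat(sprintf("  alpha range [%.3f, %.3f], beta range [%.3f, %.3f]\n",
                min(object@alpha), max(object@alpha),
                min(object@beta), max(object@beta)))
})

#' Poisson log-likelihood of a rate matrix
#'
#' Convenience helper used by tests and model comparison:
#' \eqn{\sum_{g,c} (x_{gc}\log\lambda_{gc} - \lambda_{gc})} up to the
#' additive \eqn{-\log x!} constant.
#'
#' @param x count matrix.
#' @param lambda positive rate matrix of the same shape.
#' @export
poissonLogLik <- function(x, lambda) {
    sum(x * log(lambda) - lambda)
}
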
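# clamp bounds for the averaged CDF before the logit; 1e-10 is small with
# respect to double precision while keeping the logit finite (~ +/- 23.03)
.F_EPS <- 1e-10

#' Averaged (mid-distribution) Poisson CDF
#'
#' \deqn{\tilde F(x;\lambda) = \frac{P(X \le x) + P(X < x)}{2}}
#' under Poisson(\eqn{\lambda}), with \eqn{P(X < 0) = 0}. The conventional
#' CDF \eqn{P(X \le x)} is bounded below by \eqn{e^{-\lambda} \approx 1}
#' for the tiny rates typical of UMI data, and \eqn{P(X < x)} goes too far
#' the other way; the average treats the discrete mass at \eqn{x}
#' symmetrically and has mean exactly 0.5 under the true model. Strictly
#' inside (0, 1) for any finite \eqn{\lambda > 0}.
#'
#' Evaluated through [stats::ppois()] (regularized incomplete gamma), so it
#' is accurate for rates up to ~1e5 where naive pmf summation is not.
#'
#' @param x non-negative integer count(s).
#' @param lam positive Poisson rate(s), recycled against \code{x}.
#' @return probabilities in (0, 1).
#' @examples
#' avgCdf(0, log(2))  # exactly 0.25
#' @export
avgCdf <- function(x, lam) {
    if (any(lam <= 0)) stop("lam must be positive")
    if (any(x < 0) || any(x != round(x))) stop("x must be non-negative integers")
    (stats::ppois(x, lam) + stats::ppois(x - 1, lam)) / 2
}

#' Departure-from-Poisson (DIPD) representation
#'
#' Replaces each count by
#' \eqn{D_{gc} = \mathrm{logit}(\tilde F(x_{gc}; \tilde\lambda_{gc}))},
#' the logit of the averaged Poisson CDF under the two-way approximation,
#' with \eqn{\tilde F} clamped to \eqn{[10^{-10}, 1-10^{-10}]} before the
#' logit so all entries are finite. Counts far below their two-way
#' expectation map to large negative values, counts far above to large
#' positive values; entries well explained by the model sit near zero.
#' The result is dense: near-zero counts carry informative negative values,
#' so the sparsity of the input is intentionally destroyed.
#'
#' @param m a [CountMatrix-class].
#' @param fit the [TwoWayFit-class] for the same genes and cells.
#' @return a [DepartureMatrix-class] of the same shape.
#' @export
dipd <- function(m, fit) {
    stopifnot(is(m, "CountMatrix"), is(fit, "TwoWayFit"))
    if (!identical(m@geneIds, fit@geneIds) ||
        !identical(m@cellIds, fit@cellIds))
        stop("counts and fit disagree in genes/cells")
    x <- as.matrix(m@values)
    lam <- exp(fit@mu) * (exp(fit@alpha) %o% exp(fit@beta))
    Ft <- (stats::ppois(x, lam) + stats::ppois(x - 1, lam)) / 2
    Ft <- pmin(pmax(Ft, .F_EPS), 1 - .F_EPS)
    D <- stats::qlogis(Ft)
    dim(D) <- dim(x)
    new("DepartureMatrix", values = D,
        geneIds = m@geneIds, cellIds = m@cellIds)
}

#' @rdname accessors
#' @export
setMethod("departures", "DepartureMatrix", function(object) {
    d <- object@values
    dimnames(d) <- list(object@geneIds, object@cellIds)
    d
})

#' @rdname accessors
#' @export
setMethod("geneIds", "DepartureMatrix", function(object) object@geneIds)

#' @rdname accessors
#' @export
setMethod("cellIds", "DepartureMatrix", function(object) object@cellIds)

#' @export
setMethod("dim", "DepartureMatrix", function(x) dim(x@values))

setMethod("show", "DepartureMatrix", function(object) {
    cat(sprintf("DepartureMatrix: %d genes x %d cells\n",
                nrow(object@values), ncol(object@values)))
    cat(sprintf("  departure range [%.3f, %.3f], mean %.3f\n",
                min(object@values), max(object@values), mean(object@values)))
})

#' Write a departure matrix as dense CSV
#'
#' Gene ids in the first column, cell ids in the header; the format
#' external tools (e.g. graph-based community detection on the departure
#' representation) consume.
#'
#' @param d a [DepartureMatrix-class].
#' @param path output file.
#' @export
writeDepartures <- function(d, path) {
    stopifnot(is(d, "DepartureMatrix"))
    df <- data.frame(gene = d@geneIds, d@values, check.names = FALSE)
    colnames(df) <- c("gene", d@cellIds)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(NULL)
}
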
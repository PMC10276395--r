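#' @import methods
#' @importFrom Matrix Matrix colSums rowSums readMM writeMM t
NULL

#' CountMatrix: genes-by-cells UMI counts
#'
#' An S4 container for a genes \eqn{\times} cells matrix of non-negative
#' integer UMI counts with unique gene and cell identifiers. Counts are
#' stored sparsely (a \code{dgCMatrix}) but every operation in this package
#' is defined on the logical dense matrix: zeros are data, not missingness.
#'
#' @slot values sparse \code{dgCMatrix} of counts, genes in rows.
#' @slot geneIds character vector of unique gene identifiers (length G).
#' @slot cellIds character vector of unique cell identifiers (length C).
#'
#' @seealso [readCounts()], [filterCounts()], [fitTwoWay()]
#' @export
setClass("CountMatrix",
         representation(values = "dgCMatrix",
                        geneIds = "character",
                        cellIds = "character"))

setValidity("CountMatrix", function(object) {
    v <- object@values
    if (nrow(v) != length(object@geneIds))
        return("number of rows does not match length of geneIds")
    if (ncol(v) != length(object@cellIds))
        return("number of columns does not match length of cellIds")
    if (anyDuplicated(object@geneIds))
        return("duplicate gene identifiers (refusing to merge silently)")
    if (anyDuplicated(object@cellIds))
        return("duplicate cell identifiers (refusing to merge silently)")
    bad <- which(v@x < 0 | v@x != round(v@x))
    if (length(bad)) {
        ij <- .sparseCoord(v, bad[1L])
        return(sprintf(
            "counts must be non-negative integers; offending entry at gene %d, cell %d (value %g)",
            ij[1L], ij[2L], v@x[bad[1L]]))
    }
    TRUE
})

# recover (row, col) of the k-th stored element of a dgCMatrix
.sparseCoord <- function(v, k) {
    col <- findInterval(k - 1L, v@p[-1L]) + 1L
    c(v@i[k] + 1L, col)
}

#' TwoWayFit: closed-form two-way Poisson approximation
#'
#' Maximum-likelihood fit of the log-linear rate model
#' \eqn{\tilde\lambda_{gc} = e^{\mu + \alpha_g + \beta_c}} under the
#' identifiability constraints \eqn{\sum_g e^{\alpha_g} = G} and
#' \eqn{\sum_c e^{\beta_c} = C}. The implied rate matrix is recomputed on
#' demand by [lambdaTilde()] rather than stored.
#'
#' @slot mu grand-mean log rate.
#' @slot alpha gene effects (length G).
#' @slot beta cell effects (length C).
#' @slot geneIds,cellIds identifiers carried from the source counts.
#' @export
setClass("TwoWayFit",
         representation(mu = "numeric", alpha = "numeric", beta = "numeric",
                        geneIds = "character", cellIds = "character"))

setValidity("TwoWayFit", function(object) {
    if (length(object@mu) != 1L) return("mu must be a scalar")
    if (length(object@alpha) != length(object@geneIds))
        return("alpha and geneIds lengths differ")
    if (length(object@beta) != length(object@cellIds))
        return("beta and cellIds lengths differ")
    if (abs(sum(exp(object@alpha)) - length(object@alpha)) > 1e-8 * max(1, length(object@alpha)))
        return("identifiability violated: sum(exp(alpha)) != G")
    if (abs(sum(exp(object@beta)) - length(object@beta)) > 1e-8 * max(1, length(object@beta)))
        return("identifiability violated: sum(exp(beta)) != C")
    TRUE
})

#' DepartureMatrix: model-departure (DIPD) data representation
#'
#' Dense genes-by-cells matrix of departures
#' \eqn{D_{gc} = \mathrm{logit}(\tilde F(x_{gc}; \tilde\lambda_{gc}))},
#' where \eqn{\tilde F} is the averaged (mid-distribution) Poisson CDF,
#' clamped to \eqn{[10^{-10}, 1 - 10^{-10}]} before the logit. Unexpectedly
#' small counts map to large negative values, unexpectedly large counts to
#' large positive values; sparsity of the source counts is intentionally
#' destroyed.
#'
#' @slot values dense numeric matrix of departures.
#' @slot geneIds,cellIds identifiers carried from the source counts.
#' @export
setClass("DepartureMatrix",
         representation(values = "matrix",
                        geneIds = "character", cellIds = "character"))

setValidity("DepartureMatrix", function(object) {
    if (nrow(object@values) != length(object@geneIds) ||
        ncol(object@values) != length(object@cellIds))
        return("dimensions do not match identifier lengths")
    if (any(!is.finite(object@values)))
        return("departures must be finite")
    bound <- stats::qlogis(1 - 1e-10) + 1e-6
    if (any(abs(object@values) > bound))
        return("departures exceed the logit clamp bounds")
    TRUE
})

#' GlmPcaFit: Poisson GLM-PCA rate model
#'
#' Latent-factor Poisson model
#' \eqn{\log\lambda_{gc} = \log n_c + \alpha_g + \sum_l \xi_{gl}\rho_{cl}}
#' fitted by blockwise Newton ascent. Only the implied per-entry rates
#' (see [lambdaHat()]) are consumed downstream; the factorization
#' \eqn{\xi\rho^\top} is rotation-invariant and is reported as-is.
#'
#' @slot geneIntercepts per-gene intercepts (length G).
#' @slot scores G x L factor scores.
#' @slot loadings C x L factor loadings.
#' @slot offsets per-cell offsets, \code{log} of cell totals.
#' @slot L latent dimension.
#' @slot devianceTrace Poisson deviance after each full update sweep.
#' @slot converged whether the relative-deviance tolerance was reached.
#' @slot geneIds,cellIds identifiers.
#' @export
setClass("GlmPcaFit",
         representation(geneIntercepts = "numeric",
                        scores = "matrix", loadings = "matrix",
                        offsets = "numeric", L = "integer",
                        devianceTrace = "numeric", converged = "logical",
                        geneIds = "character", cellIds = "character"))

#' EntryAggregate: matrix entries pooled by nearest estimated rate
#'
#' The \code{m} matrix entries whose estimated Poisson rates are closest to
#' a target rate \eqn{\lambda_0}, treated as an i.i.d. sample from
#' Poisson(\eqn{\lambda_0}) for goodness-of-fit testing. Ties in
#' \eqn{|\hat\lambda - \lambda_0|} are broken by lower (gene, cell) index,
#' lexicographically.
#'
#' @slot targetLambda the target rate \eqn{\lambda_0}.
#' @slot genes,cells integer coordinates of the selected entries.
#' @slot counts observed counts at the selected entries.
#' @slot lambdas estimated rates at the selected entries.
#' @export
setClass("EntryAggregate",
         representation(targetLambda = "numeric",
                        genes = "integer", cells = "integer",
                        counts = "numeric", lambdas = "numeric"))

setValidity("EntryAggregate", function(object) {
    n <- length(object@counts)
    if (length(object@genes) != n || length(object@cells) != n ||
        length(object@lambdas) != n)
        return("component lengths differ")
    if (n < 1L) return("aggregate is empty")
    TRUE
})

#' GofReport: Poissoneity diagnostics for one entry aggregate
#'
#' @slot targetLambda aggregation target rate.
#' @slot ks list with the KS statistic and (conservative) asymptotic p-value.
#' @slot dispersion list with the over-dispersion z, p and alpha-hat.
#' @slot zeroInflation list with observed/expected zero proportion, variance,
#'   z and p.
#' @slot envelope Q-Q envelope bundle (list), possibly empty.
#' @export
setClass("GofReport",
         representation(targetLambda = "numeric", ks = "list",
                        dispersion = "list", zeroInflation = "list",
                        envelope = "list"))

#' ClusterTree: recursive significance-gated bisection of cells
#'
#' Binary tree produced by [hclustDeparture()]. Each node records its cells,
#' depth, Monte-Carlo split p-value (where a split was tested) and the
#' reason recursion stopped. Leaves are labelled by their binary path string
#' ("0" for the root, then "0"/"1" appended per split).
#'
#' @slot root nested-list representation of the tree.
#' @slot alpha significance level gating each split.
#' @slot J maximum depth (at most \eqn{2^J} leaves).
#' @slot S minimum cluster size eligible for further splitting.
#' @slot nMc Monte-Carlo replicates per split test.
#' @slot seed RNG seed used for the whole recursion.
#' @slot cellIds all cell identifiers, in input order.
#' @export
setClass("ClusterTree",
         representation(root = "list", alpha = "numeric", J = "integer",
                        S = "integer", nMc = "integer", seed = "integer",
                        cellIds = "character"))

#' PerturbedData: a crafted-experiment perturbation of a count matrix
#'
#' @slot counts the perturbed [CountMatrix-class].
#' @slot F signal strength; \code{F = 0} leaves the counts unchanged.
#' @slot mode "library" (library-size magnification) or "cluster"
#'   (planted artificial cluster).
#' @slot perturbedGenes,perturbedCells index sets touched by the
#'   perturbation (cluster mode; empty means all, library mode).
#' @slot truthLabels planted per-cell labels for evaluation (cluster mode).
#' @slot seed RNG seed used.
#' @export
setClass("PerturbedData",
         representation(counts = "CountMatrix", F = "numeric",
                        mode = "character",
                        perturbedGenes = "integer", perturbedCells = "integer",
                        truthLabels = "character", seed = "integer"))

#' SyntheticSpec: recipe for a synthetic UMI count matrix
#'
#' Describes Poisson (or over-dispersed / zero-inflated) counts whose
#' log-rates are a grand mean plus gene effects plus cell effects plus
#' optional cluster-specific gene offsets. Effects are drawn Gaussian and
#' recentred so the identifiability constraints of the two-way model hold
#' exactly, making the true parameters directly comparable with
#' [fitTwoWay()] estimates.
#'
#' @slot G,C matrix dimensions.
#' @slot mu grand-mean log rate.
#' @slot alphaSd,betaSd standard deviations of the gene and cell effects.
#' @slot clusters list of planted clusters, each a list with elements
#'   \code{fraction}, \code{delta} (log-fold offset added to the affected
#'   genes' log-rates in that cluster) and either \code{genes} (explicit
#'   integer indices) or \code{rankGenes} (abundance ranks: 1 is the gene
#'   with the largest drawn gene effect).
#' @slot noise one of "poisson", "negbin", "zip".
#' @slot noiseParam NB size parameter or ZIP structural-zero probability
#'   (\code{NA} for Poisson noise).
#' @slot seed RNG seed.
#' @export
setClass("SyntheticSpec",
         representation(G = "integer", C = "integer", mu = "numeric",
                        alphaSd = "numeric", betaSd = "numeric",
                        clusters = "list", noise = "character",
                        noiseParam = "numeric", seed = "integer"),
         prototype(G = 1L, C = 1L, mu = 0, alphaSd = 1, betaSd = 1,
                   clusters = list(), noise = "poisson",
                   noiseParam = NA_real_, seed = 1L))

setValidity("SyntheticSpec", function(object) {
    if (object@G < 1L || object@C < 1L) return("G and C must be positive")
    if (!object@noise %in% c("poisson", "negbin", "zip"))
        return("noise must be one of poisson, negbin, zip")
    if (object@noise != "poisson" &&
        (is.na(object@noiseParam) || object@noiseParam <= 0))
        return("negbin/zip noise requires a positive noiseParam")
    if (length(object@clusters)) {
        fr <- vapply(object@clusters, function(k) k$fraction, numeric(1))
        if (abs(sum(fr) - 1) > 1e-8) return("cluster fractions must sum to 1")
        for (k in object@clusters) {
            idx <- c(k$genes, k$rankGenes)
            if (any(idx < 1L | idx > object@G))
                return("cluster gene indices/ranks out of range")
        }
    }
    TRUE
})
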
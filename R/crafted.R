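#' Magnify library-size effects
#'
#' Crafted-experiment perturbation that makes cells with a large (small)
#' library even larger (smaller), leaving everything else alone. After the
#' two-way fit, each entry receives a random count
#' \eqn{p_{gc} \sim \mathrm{Poisson}(|e^{\hat\mu + \hat\alpha_g +
#' (1+F)\hat\beta_c} - \tilde\lambda_{gc}|)}
#' added with the sign of \eqn{\hat\beta_c} and truncated at zero:
#' \eqn{(x_{gc} + \mathrm{sign}(\hat\beta_c)\, p_{gc})_+}. \code{F = 0}
#' collapses every Poisson rate to zero and returns the input unchanged.
#' \code{sign(0)} is taken as +1 (inert: a zero cell effect gives a zero
#' rate).
#'
#' @param m a filtered [CountMatrix-class].
#' @param F signal strength, \code{F >= 0}.
#' @param seed RNG seed.
#' @return a [PerturbedData-class] (mode "library"; no planted labels).
#' @export
magnifyLibrary <- function(m, F, seed = 1L) {
    stopifnot(is(m, "CountMatrix"), F >= 0)
    fit <- fitTwoWay(m)
    lam <- exp(fit@mu) * (exp(fit@alpha) %o% exp(fit@beta))
    # |e^{mu+alpha+(1+F)beta} - lambda~| = lambda~ * |e^{F beta} - 1|
    rate <- sweep(lam, 2L, abs(exp(F * fit@beta) - 1), `*`)
    set.seed(seed)
    p <- matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate))
    sgn <- ifelse(fit@beta >= 0, 1, -1)
    x <- as.matrix(m@values) + sweep(p, 2L, sgn, `*`)
    x[x < 0] <- 0
    new("PerturbedData",
        counts = CountMatrix(x, m@geneIds, m@cellIds),
        F = F, mode = "library",
        perturbedGenes = integer(0), perturbedCells = integer(0),
        truthLabels = character(0), seed = as.integer(seed))
}

#' Plant an artificial cell cluster
#'
#' Crafted-experiment perturbation that overlays a cluster signal on real
#' or synthetic counts: on the sub-matrix of the \code{nGenes} genes with
#' the largest total counts (ties broken by original row order) and
#' \code{nCells} cells sampled uniformly without replacement, independent
#' \eqn{\mathrm{Poisson}(F \tilde\lambda_{gc})} draws are added to the
#' observed counts. The perturbed cells form a planted cluster whose
#' recovery should improve as \code{F} grows; \code{F = 0} adds nothing
#' but still records the labels.
#'
#' @param m a filtered [CountMatrix-class].
#' @param F signal strength, \code{F >= 0}.
#' @param nGenes,nCells sub-matrix dimensions (defaults 500 and 250).
#' @param seed RNG seed (governs both the cell sample and the added
#'   counts).
#' @return a [PerturbedData-class] (mode "cluster") with
#'   \code{truthLabels} "perturbed"/"unperturbed" per cell.
#' @export
plantCluster <- function(m, F, nGenes = 500L, nCells = 250L, seed = 1L) {
    stopifnot(is(m, "CountMatrix"), F >= 0)
    G <- nrow(m@values); C <- ncol(m@values)
    if (nGenes > G) stop("nGenes exceeds the number of genes")
    if (nCells > C) stop("nCells exceeds the number of cells")
    tot <- Matrix::rowSums(m@values)
    genes <- sort(order(-tot)[seq_len(nGenes)])   # order() is stable in ties
    set.seed(seed)
    cells <- sort(sample.int(C, nCells))
    fit <- fitTwoWay(m)
    lam <- exp(fit@mu) * (exp(fit@alpha[genes]) %o% exp(fit@beta[cells]))
    add <- matrix(stats::rpois(length(lam), F * lam), nrow(lam), ncol(lam))
    x <- as.matrix(m@values)
    x[genes, cells] <- x[genes, cells] + add
    truth <- rep("unperturbed", C)
    truth[cells] <- "perturbed"
    new("PerturbedData",
        counts = CountMatrix(x, m@geneIds, m@cellIds),
        F = F, mode = "cluster",
        perturbedGenes = as.integer(genes), perturbedCells = as.integer(cells),
        truthLabels = truth, seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("counts", "PerturbedData", function(object) counts(object@counts))

setMethod("show", "PerturbedData", function(object) {
    cat(sprintf("PerturbedData (%s mode): F = %g, seed = %d\n",
                object@mode, object@F, object@seed))
    if (object@mode == "cluster")
        cat(sprintf("  planted cluster: %d genes x %d cells\n",
                    length(object@perturbedGenes),
                    length(object@perturbedCells)))
})

#' Adjusted Rand index
#'
#' Permutation-model chance-corrected agreement between two labelings,
#' computed from the contingency table; 1 for identical partitions, ~0 for
#' independent ones, negative for worse-than-chance agreement.
#'
#' @param a,b label vectors of equal length (>= 2 items).
#' @return ARI in [-1, 1].
#' @export
adjustedRandIndex <- function(a, b) {
    if (length(a) != length(b)) stop("labelings differ in length")
    n <- length(a)
    if (n < 2L) stop("need at least 2 items")
    tab <- table(a, b)
    sumij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    expected <- ai * bj / choose(n, 2)
    maxidx <- (ai + bj) / 2
    if (maxidx == expected) return(0)
    (sumij - expected) / (maxidx - expected)
}

#' Cluster purity
#'
#' \eqn{\frac{1}{N}\sum_k \max_j |C_k \cap T_j|}: each predicted cluster
#' votes for its majority truth class. Note the documented pathology that
#' all-singleton predictions score 1 regardless of the truth.
#'
#' @param pred,truth label vectors of equal length.
#' @return purity in (0, 1].
#' @export
purity <- function(pred, truth) {
    if (length(pred) != length(truth)) stop("labelings differ in length")
    tab <- table(pred, truth)
    sum(apply(tab, 1L, max)) / length(pred)
}

#' Perturbation sweep with clustering evaluation
#'
#' For each signal strength in \code{FGrid} and each replicate: perturb
#' the counts ([plantCluster()] or [magnifyLibrary()]), run the supplied
#' clustering pipeline (any callable \code{CountMatrix -> labels}, so
#' external methods can be benchmarked), and score ARI and purity against
#' the truth (the planted labels in cluster mode, the supplied
#' \code{truth} in library mode). Replicates use one derived RNG stream
#' per (seed, replicate), so they are independent but reproducible.
#'
#' @param m a filtered [CountMatrix-class].
#' @param mode "cluster" or "library".
#' @param FGrid signal strengths to sweep.
#' @param nRep replicates per strength.
#' @param pipeline callable mapping a [CountMatrix-class] to per-cell
#'   labels.
#' @param seed base seed.
#' @param truth per-cell truth labels, required in library mode.
#' @param ... passed to the perturbation generator (e.g. \code{nGenes},
#'   \code{nCells}).
#' @return list with \code{results} (one row per F x replicate) and
#'   \code{summary} (mean and sd of ARI and purity per F).
#' @export
sweepPerturbations <- function(m, mode = c("cluster", "library"), FGrid,
                               nRep = 10L, pipeline, seed = 1L,
                               truth = NULL, ...) {
    mode <- match.arg(mode)
    stopifnot(length(FGrid) >= 1L, is.function(pipeline))
    if (mode == "library" && is.null(truth))
        stop("library mode requires truth labels to score against")
    rows <- list()
    for (fi in seq_along(FGrid)) {
        for (r in seq_len(nRep)) {
            subSeed <- (seed + 7919L * r + 104729L * fi) %% .Machine$integer.max
            pd <- if (mode == "cluster")
                plantCluster(m, FGrid[fi], seed = subSeed, ...)
            else magnifyLibrary(m, FGrid[fi], seed = subSeed, ...)
            labels <- pipeline(pd@counts)
            tl <- if (mode == "cluster") pd@truthLabels else truth
            rows[[length(rows) + 1L]] <- data.frame(
                F = FGrid[fi], rep = r,
                ari = adjustedRandIndex(labels, tl),
                purity = purity(labels, tl))
        }
    }
    results <- do.call(rbind, rows)
    summary <- do.call(rbind, lapply(split(results, results$F), function(d)
        data.frame(F = d$F[1L], meanARI = mean(d$ari), sdARI = stats::sd(d$ari),
                   meanPurity = mean(d$purity),
                   sdPurity = stats::sd(d$purity))))
    rownames(summary) <- NULL
    list(results = results, summary = summary)
}
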
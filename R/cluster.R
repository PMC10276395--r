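#' One Ward bisection of cells in departure space
#'
#' Agglomerative hierarchical clustering of the cell vectors (columns of
#' the departure matrix) with Euclidean distance and Ward's linkage, cut at
#' \code{k = 2}. Deterministic. If all cell vectors are identical the split
#' is arbitrary-but-deterministic (first cell vs the rest) and flagged
#' degenerate.
#'
#' @param D a [DepartureMatrix-class] or dense genes x cells matrix with at
#'   least two columns.
#' @return list with \code{labels} (1/2 per cell, label 1 containing the
#'   first cell), \code{height} (top merge height) and \code{degenerate}.
#' @export
splitOnce <- function(D) {
    V <- if (is(D, "DepartureMatrix")) D@values else as.matrix(D)
    n <- ncol(V)
    if (n < 2L) stop("need at least two cells to split")
    dd <- stats::dist(t(V))
    if (all(dd == 0)) {
        return(list(labels = c(1L, rep(2L, n - 1L)), height = 0,
                    degenerate = TRUE))
    }
    hc <- stats::hclust(dd, method = "ward.D2")
    labels <- stats::cutree(hc, k = 2L)
    if (labels[1L] != 1L) labels <- 3L - labels
    list(labels = unname(labels), height = max(hc$height),
         degenerate = FALSE)
}

# two-cluster index: within-split sum of squares / total sum of squares
.clusterIndex <- function(V, labels) {
    ctr <- rowMeans(V)
    tot <- sum((V - ctr)^2)
    if (tot == 0) return(1)
    w <- 0
    for (k in unique(labels)) {
        Vk <- V[, labels == k, drop = FALSE]
        w <- w + sum((Vk - rowMeans(Vk))^2)
    }
    w / tot
}

#' Monte-Carlo significance of a two-way split
#'
#' SigClust-style test of the null that the cells form a single Gaussian
#' cluster. The observed statistic is the two-cluster index (within-split
#' sum of squares over total sum of squares; small means a strong split).
#' The null is a single multivariate Gaussian whose diagonal covariance
#' holds the per-coordinate variances in the sample's principal-component
#' basis (the eigenvalues of the cell-by-cell sample covariance), with a
#' soft floor at the background noise variance estimated robustly (squared
#' MAD of the centred entries) so degenerate low-variance directions do
#' not collapse the null. The cluster index is rotation invariant, so
#' simulating in the eigenbasis is equivalent to simulating from the full
#' sample covariance. Each simulated dataset is re-split by [splitOnce()]
#' and the p-value is
#' \eqn{(1 + \#\{CI_{null} \le CI_{obs}\}) / (1 + n_{mc})}.
#'
#' @param D a [DepartureMatrix-class] or dense matrix, cells in columns.
#' @param labels binary partition from [splitOnce()]; both groups
#'   non-empty.
#' @param nMc Monte-Carlo replicates, at least 19 (p resolution must
#'   support a 0.05 level).
#' @param seed optional seed; leave \code{NULL} to consume the ambient RNG
#'   stream (as [hclustDeparture()] does).
#' @return the Monte-Carlo p-value.
#' @export
splitSignificance <- function(D, labels, nMc = 100L, seed = NULL) {
    V <- if (is(D, "DepartureMatrix")) D@values else as.matrix(D)
    if (nMc < 19L) stop("nMc < 19 gives too coarse a p-value resolution")
    if (length(unique(labels)) != 2L) stop("labels must form two non-empty groups")
    if (!is.null(seed)) set.seed(seed)
    n <- ncol(V)
    ciObs <- .clusterIndex(V, labels)
    Vc <- V - rowMeans(V)
    ev <- svd(Vc, nu = 0, nv = 0)$d^2 / max(1L, n - 1L)
    sigb <- stats::mad(Vc)^2
    if (sigb == 0) sigb <- max(mean(ev), .Machine$double.eps)
    ev <- pmax(ev, sigb)
    k <- length(ev)
    sdv <- sqrt(ev)
    hits <- 0L
    for (b in seq_len(nMc)) {
        Vb <- sdv * matrix(stats::rnorm(k * n), k, n)
        sp <- splitOnce(Vb)
        if (.clusterIndex(Vb, sp$labels) <= ciObs) hits <- hits + 1L
    }
    (1 + hits) / (1 + nMc)
}

#' Recursive significance-gated clustering on the departure representation
#'
#' Top-down bisection of cells. At each node the two-way approximation is
#' re-fitted on that node's cells alone (genes all-zero within the node
#' are dropped for that node's fit and distance computation), the
#' departure matrix recomputed, the cells Ward-bisected, and the split
#' tested by the Monte-Carlo cluster-index test. Recursion continues into
#' a child only while the split is significant at \code{alpha}, the depth
#' is below \code{J} and both children have at least \code{S} cells; a
#' node with fewer than \code{2 S} cells is not split at all (neither
#' child could reach \code{S}). With the default \code{J = 10} the tree
#' has at most \eqn{2^{10} = 1024} leaves. No multiplicity correction is
#' applied across the tree's split tests. Deterministic given \code{seed}.
#'
#' @param m a filtered [CountMatrix-class].
#' @param alpha significance level gating each split (the one tunable).
#' @param J maximum depth.
#' @param S minimum cluster size eligible for splitting.
#' @param nMc Monte-Carlo replicates per split test.
#' @param seed RNG seed for the whole recursion.
#' @return a [ClusterTree-class].
#' @export
hclustDeparture <- function(m, alpha = 0.05, J = 10L, S = 10L,
                            nMc = 100L, seed = 1L) {
    stopifnot(is(m, "CountMatrix"))
    x <- as.matrix(m@values)
    if (any(rowSums(x) == 0) || any(colSums(x) == 0))
        stop("zero margins present; apply filterCounts() first")
    set.seed(seed)
    root <- .splitNode(x, seq_len(ncol(x)), path = "0", depth = 0L,
                       alpha = alpha, J = as.integer(J), S = as.integer(S),
                       nMc = as.integer(nMc))
    new("ClusterTree", root = root, alpha = alpha, J = as.integer(J),
        S = as.integer(S), nMc = as.integer(nMc), seed = as.integer(seed),
        cellIds = m@cellIds)
}

.splitNode <- function(x, cells, path, depth, alpha, J, S, nMc) {
    node <- list(path = path, cells = cells, n = length(cells),
                 depth = depth, pValue = NULL, height = NULL,
                 stopReason = NULL, children = NULL)
    if (length(cells) < 2L * S) {
        node$stopReason <- "min_size"
        return(node)
    }
    if (depth >= J) {
        node$stopReason <- "max_depth"
        return(node)
    }
    xs <- x[, cells, drop = FALSE]
    keep <- rowSums(xs) > 0
    xs <- xs[keep, , drop = FALSE]
    sub <- CountMatrix(xs, sprintf("g%d", which(keep)),
                       sprintf("c%d", cells))
    fit <- fitTwoWay(sub)
    D <- dipd(sub, fit)
    sp <- splitOnce(D)
    p <- splitSignificance(D, sp$labels, nMc = nMc)
    node$pValue <- p
    node$height <- sp$height
    if (p >= alpha) {
        node$stopReason <- "not_significant"
        return(node)
    }
    sizes <- tabulate(sp$labels, 2L)
    if (min(sizes) < S) {
        node$stopReason <- "min_size"
        return(node)
    }
    node$stopReason <- "significant_split"
    node$children <- list(
        .splitNode(x, cells[sp$labels == 1L], paste0(path, "0"), depth + 1L,
                   alpha, J, S, nMc),
        .splitNode(x, cells[sp$labels == 2L], paste0(path, "1"), depth + 1L,
                   alpha, J, S, nMc))
    node
}

.collectLeaves <- function(node) {
    if (is.null(node$children)) return(list(node))
    c(.collectLeaves(node$children[[1L]]), .collectLeaves(node$children[[2L]]))
}

#' ClusterTree accessors
#'
#' \code{leafLabels()} returns a character vector of leaf path labels named
#' by cell id (in input cell order); \code{nLeaves()} the number of leaves.
#'
#' @param object a [ClusterTree-class].
#' @name clusterTree-accessors
NULL

#' @rdname clusterTree-accessors
#' @export
setMethod("leafLabels", "ClusterTree", function(object) {
    lab <- character(length(object@cellIds))
    for (leaf in .collectLeaves(object@root)) lab[leaf$cells] <- leaf$path
    stats::setNames(lab, object@cellIds)
})

#' @rdname clusterTree-accessors
#' @export
setMethod("nLeaves", "ClusterTree", function(object) {
    length(.collectLeaves(object@root))
})

setMethod("show", "ClusterTree", function(object) {
    leaves <- .collectLeaves(object@root)
    cat(sprintf("ClusterTree: %d cells, %d leaves (alpha = %g, J = %d, S = %d)\n",
                length(object@cellIds), length(leaves), object@alpha,
                object@J, object@S))
    for (leaf in leaves)
        cat(sprintf("  leaf %-12s %4d cells  [%s]\n", leaf$path, leaf$n,
                    leaf$stopReason))
})

.nodeToList <- function(node) {
    out <- list(path = node$path, n = node$n, depth = node$depth,
                stop_reason = node$stopReason)
    if (!is.null(node$pValue)) out$p_value <- node$pValue
    if (!is.null(node$height)) out$height <- node$height
    if (is.null(node$children)) {
        out$cells <- node$cells
    } else {
        out$children <- list(.nodeToList(node$children[[1L]]),
                             .nodeToList(node$children[[2L]]))
    }
    out
}

#' Serialize a ClusterTree to JSON
#'
#' Byte-identical for identical inputs and seed.
#'
#' @param tree a [ClusterTree-class].
#' @param path optional file; when omitted the JSON string is returned.
#' @export
clusterTreeJSON <- function(tree, path = NULL) {
    stopifnot(is(tree, "ClusterTree"))
    obj <- list(alpha = tree@alpha, J = tree@J, S = tree@S, nMc = tree@nMc,
                seed = tree@seed, cell_ids = tree@cellIds,
                tree = .nodeToList(tree@root))
    js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}

#' Departure-based marker genes between two cell groups
#'
#' Per gene, a two-sample test on the departure values: Welch t-test when
#' both groups have at least 30 cells, Wilcoxon rank-sum otherwise, with
#' Benjamini-Hochberg adjustment across genes. Genes are categorized as
#' \code{red} (adjusted p < 0.05 and absolute mean departure difference
#' > 4, the marker calls), \code{orange} (significant but small
#' difference) or \code{black}. A gene with zero variance in both groups
#' under the t-test gets p = 1 and is flagged.
#'
#' @param D a [DepartureMatrix-class].
#' @param groupA,groupB disjoint cell sets (ids or column indices), each of
#'   size at least 2.
#' @return data.frame with geneId, meanDiff, pValue, pAdj, category, test
#'   and degenerate columns, in input gene order.
#' @export
departureMarkers <- function(D, groupA, groupB) {
    stopifnot(is(D, "DepartureMatrix"))
    ia <- .resolveCells(D, groupA)
    ib <- .resolveCells(D, groupB)
    if (length(intersect(ia, ib))) stop("groups must be disjoint")
    if (length(ia) < 2L || length(ib) < 2L)
        stop("each group needs at least 2 cells")
    useT <- min(length(ia), length(ib)) >= 30L
    A <- D@values[, ia, drop = FALSE]
    B <- D@values[, ib, drop = FALSE]
    G <- nrow(A)
    p <- numeric(G); degen <- logical(G)
    for (g in seq_len(G)) {
        if (useT) {
            if (stats::var(A[g, ]) == 0 && stats::var(B[g, ]) == 0) {
                p[g] <- 1; degen[g] <- TRUE
            } else {
                p[g] <- stats::t.test(A[g, ], B[g, ])$p.value
            }
        } else {
            p[g] <- stats::wilcox.test(A[g, ], B[g, ], exact = FALSE)$p.value
        }
    }
    diff <- rowMeans(A) - rowMeans(B)
    padj <- stats::p.adjust(p, method = "BH")
    cat_ <- ifelse(padj < 0.05 & abs(diff) > 4, "red",
                   ifelse(padj < 0.05, "orange", "black"))
    data.frame(geneId = D@geneIds, meanDiff = unname(diff), pValue = p,
               pAdj = padj, category = cat_,
               test = if (useT) "t" else "wilcoxon",
               degenerate = degen, stringsAsFactors = FALSE)
}

.resolveCells <- function(D, g) {
    if (is.character(g)) {
        i <- match(g, D@cellIds)
        if (anyNA(i)) stop("unknown cell id(s): ",
                           paste(g[is.na(i)], collapse = ", "))
        i
    } else {
        as.integer(g)
    }
}
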
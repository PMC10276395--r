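#' Construct a CountMatrix
#'
#' @param values a base matrix or sparse Matrix of non-negative integer
#'   counts, genes in rows and cells in columns.
#' @param geneIds,cellIds identifiers; defaults to the dimnames of
#'   \code{values}, or \code{g1..gG} / \code{c1..cC} when absent.
#' @return a validated [CountMatrix-class].
#' @examples
#' m <- CountMatrix(matrix(c(1, 3, 2, 4), 2, 2))
#' counts(m)
#' @export
CountMatrix <- function(values, geneIds = NULL, cellIds = NULL) {
    if (is.null(geneIds))
        geneIds <- if (!is.null(rownames(values))) rownames(values)
                   else sprintf("g%d", seq_len(nrow(values)))
    if (is.null(cellIds))
        cellIds <- if (!is.null(colnames(values))) colnames(values)
                   else sprintf("c%d", seq_len(ncol(values)))
    v <- .asDgc(values)
    dimnames(v) <- NULL
    new("CountMatrix", values = v,
        geneIds = as.character(geneIds), cellIds = as.character(cellIds))
}

.asDgc <- function(values) {
    if (is(values, "dgCMatrix")) return(values)
    v <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
    as(as(as(v, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' @rdname accessors
#' @export
setMethod("counts", "CountMatrix", function(object) {
    x <- as.matrix(object@values)
    dimnames(x) <- list(object@geneIds, object@cellIds)
    x
})

#' @rdname accessors
#' @export
setMethod("geneIds", "CountMatrix", function(object) object@geneIds)

#' @rdname accessors
#' @export
setMethod("cellIds", "CountMatrix", function(object) object@cellIds)

#' @rdname accessors
#' @export
setMethod("cellTotals", "CountMatrix", function(object) {
    stats::setNames(Matrix::colSums(object@values), object@cellIds)
})

#' @rdname accessors
#' @export
setMethod("geneTotals", "CountMatrix", function(object) {
    stats::setNames(Matrix::rowSums(object@values), object@geneIds)
})

#' @export
setMethod("dim", "CountMatrix", function(x) dim(x@values))

setMethod("show", "CountMatrix", function(object) {
    v <- object@values
    cat(sprintf("CountMatrix: %d genes x %d cells\n", nrow(v), ncol(v)))
    cat(sprintf("  nonzero entries: %d (%.1f%% zeros)\n", length(v@x),
                100 * (1 - length(v@x) / max(1, prod(dim(v))))))
    cat(sprintf("  total UMI count: %.0f\n", sum(v@x)))
})

#' Read a count matrix
#'
#' Reads either a 10x-style Matrix-Market directory (\code{matrix.mtx} plus
#' \code{features.tsv}/\code{genes.tsv} and \code{barcodes.tsv}, plain or
#' gzipped) or a dense CSV with gene ids in the first column and cell ids in
#' the header. Matrices are oriented genes x cells internally; if the
#' sidecar files indicate the transposed orientation the matrix is
#' transposed with a message.
#'
#' @param path directory (mtx10x) or file (csv).
#' @param format "mtx10x" or "csv".
#' @return a validated [CountMatrix-class]; sparse zeros are logical zeros.
#' @export
readCounts <- function(path, format = c("mtx10x", "csv")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("input not found: ", path)
    if (format == "mtx10x") {
        mtx <- .sidecar(path, c("matrix.mtx", "matrix.mtx.gz"))
        feat <- .sidecar(path, c("features.tsv", "features.tsv.gz",
                                 "genes.tsv", "genes.tsv.gz"))
        bar <- .sidecar(path, c("barcodes.tsv", "barcodes.tsv.gz"))
        v <- Matrix::readMM(mtx)
        genes <- utils::read.table(feat, sep = "\t",
                                   stringsAsFactors = FALSE)[[1L]]
        cells <- utils::read.table(bar, sep = "\t",
                                   stringsAsFactors = FALSE)[[1L]]
        if (nrow(v) != length(genes) && nrow(v) == length(cells) &&
            ncol(v) == length(genes)) {
            message("matrix stored cells x genes; transposing to genes x cells")
            v <- Matrix::t(v)
        }
        if (nrow(v) != length(genes) || ncol(v) != length(cells))
            stop("matrix dimensions do not match features/barcodes files")
        CountMatrix(v, genes, cells)
    } else {
        df <- utils::read.csv(path, check.names = FALSE,
                              stringsAsFactors = FALSE)
        genes <- as.character(df[[1L]])
        v <- as.matrix(df[, -1L, drop = FALSE])
        CountMatrix(v, genes, colnames(v))
    }
}

.sidecar <- function(dir, names) {
    for (nm in names) {
        p <- file.path(dir, nm)
        if (file.exists(p)) return(p)
    }
    stop("missing file in ", dir, ": expected one of ",
         paste(names, collapse = ", "))
}

#' Write a count matrix
#'
#' Inverse of [readCounts()]: \code{readCounts(path, format)} after
#' \code{writeCounts(m, path, format)} reproduces \code{m} exactly.
#' Degenerate matrices (no genes or no cells) are refused.
#'
#' @param m a [CountMatrix-class].
#' @param path target directory (mtx10x) or file (csv).
#' @param format "mtx10x" or "csv".
#' @export
writeCounts <- function(m, path, format = c("mtx10x", "csv")) {
    format <- match.arg(format)
    stopifnot(is(m, "CountMatrix"))
    if (any(dim(m) == 0L))
        stop("refusing to write a degenerate (empty) matrix")
    if (format == "mtx10x") {
        dir.create(path, showWarnings = FALSE, recursive = TRUE)
        Matrix::writeMM(m@values, file.path(path, "matrix.mtx"))
        writeLines(m@geneIds, file.path(path, "features.tsv"))
        writeLines(m@cellIds, file.path(path, "barcodes.tsv"))
    } else {
        df <- data.frame(gene = m@geneIds, as.matrix(m@values),
                         check.names = FALSE)
        colnames(df) <- c("gene", m@cellIds)
        utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
    invisible(NULL)
}

#' Drop empty genes and cells
#'
#' Removes genes with zero total count and cells with zero total count, in
#' that order, preserving the order of survivors. Required before
#' [fitTwoWay()], whose gene and cell effects are undefined at zero margins.
#' Idempotent.
#'
#' @param m a [CountMatrix-class].
#' @return the filtered [CountMatrix-class].
#' @export
filterCounts <- function(m) {
    stopifnot(is(m, "CountMatrix"))
    keepG <- Matrix::rowSums(m@values) > 0
    keepC <- Matrix::colSums(m@values) > 0
    if (!any(keepG) || !any(keepC))
        stop("no informative entries: all counts are zero")
    if (all(keepG) && all(keepC)) return(m)
    new("CountMatrix", values = m@values[keepG, keepC, drop = FALSE],
        geneIds = m@geneIds[keepG], cellIds = m@cellIds[keepC])
}

#' Write cell-to-cluster assignments
#'
#' Two-column tab-separated table (cell_id, cluster), the conventional
#' exchange format for downstream tools.
#'
#' @param labels named vector of cluster labels, names are cell ids.
#' @param path output file.
#' @export
writeAssignments <- function(labels, path) {
    utils::write.table(
        data.frame(cell_id = names(labels), cluster = as.character(labels)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}
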
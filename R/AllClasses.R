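#' @import methods
#' @importFrom stats p.adjust pnorm rnbinom rlnorm setNames
NULL

#' CSSMatrix: pairwise cluster similarity scores between two datasets
#'
#' An m x n matrix of enhanced cluster similarity scores (CSS) between the
#' m clusters of dataset A (rows) and the n clusters of dataset B (columns),
#' together with the clustering parameters the scores were computed under.
#' Every entry lies in [0, 1]: 1 means the two clusters share all their
#' (weighted) positive marker genes, 0 means they share none.
#'
#' @slot values numeric matrix with cluster labels as dimnames; entries in
#'   [0, 1].
#' @slot res numeric(1), community-detection resolution the clusterings were
#'   obtained at (NA when the matrix was built from external marker tables).
#' @slot nPCs integer(1), number of principal components (NA likewise).
#'
#' @seealso [buildCSSMatrix()], [rowColDistinction()]
#' @export
setClass("CSSMatrix",
    representation(values = "matrix", res = "numeric", nPCs = "integer"),
    prototype(values = matrix(numeric(0), 0, 0),
              res = NA_real_, nPCs = NA_integer_))

setValidity("CSSMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("'values' must be a numeric matrix")
    if (nrow(v) < 1L || ncol(v) < 1L)
        return("CSS matrix must have at least one row and one column")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("'values' must carry cluster labels as dimnames")
    if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
        return("cluster labels must be unique")
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1 + 1e-12))
        return("all CSS values must be finite and lie in [0, 1]")
    if (length(object@res) != 1L || length(object@nPCs) != 1L)
        return("'res' and 'nPCs' must be scalars")
    TRUE
})

#' Construct a CSSMatrix
#'
#' @param values numeric matrix of CSS values with cluster-label dimnames.
#' @param res,nPCs clustering parameters the matrix belongs to (optional).
#' @return A [CSSMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("a1", "a2"), c("b1", "b2")))
#' CSSMatrix(m)
#' @export
CSSMatrix <- function(values, res = NA_real_, nPCs = NA_integer_) {
    new("CSSMatrix", values = as.matrix(values), res = as.numeric(res),
        nPCs = as.integer(nPCs))
}

#' @describeIn CSSMatrix-class the underlying numeric matrix.
#' @param x,object a \code{CSSMatrix}.
#' @export
cssValues <- function(x) {
    stopifnot(is(x, "CSSMatrix"))
    x@values
}

#' @describeIn CSSMatrix-class clustering parameters as a named list.
#' @export
cssParams <- function(x) {
    stopifnot(is(x, "CSSMatrix"))
    list(res = x@res, npcs = x@nPCs)
}

#' @export
setMethod("dim", "CSSMatrix", function(x) dim(x@values))

#' @export
setMethod("dimnames", "CSSMatrix", function(x) dimnames(x@values))

setMethod("show", "CSSMatrix", function(object) {
    d <- dim(object@values)
    cat(sprintf("CSSMatrix: %d x %d clusters", d[1L], d[2L]))
    if (!is.na(object@res))
        cat(sprintf(" (res = %g, nPCs = %d)", object@res, object@nPCs))
    cat("\n")
    print(round(object@values, 3))
    invisible(NULL)
})

#' DIDecomposition: row, column and matrix-level distinction indices
#'
#' For a CSS matrix, the distinction index (DI) of a row (or column) is its
#' maximum entry minus the mean of the remaining entries of that row (or
#' column); it is large when one cluster of the other dataset matches far
#' better than all others. The matrix-level DI summarizes the m row and n
#' column DIs by a single mean, under one of two normalizations.
#'
#' @slot rowDI,colDI named numeric vectors of per-row / per-column DIs.
#' @slot matrixDI numeric(1), the matrix-level distinction index.
#' @slot normalization either \code{"mean_over_m_plus_n"} (sum of the m + n
#'   DIs divided by m + n, the default) or \code{"mean_over_mn"} (same sum
#'   divided by m * n).
#'
#' @seealso [rowColDistinction()], [matrixDistinctionIndex()]
#' @export
setClass("DIDecomposition",
    representation(rowDI = "numeric", colDI = "numeric",
                   matrixDI = "numeric", normalization = "character"),
    prototype(matrixDI = NA_real_,
              normalization = "mean_over_m_plus_n"))

setValidity("DIDecomposition", function(object) {
    if (length(object@rowDI) < 1L || length(object@colDI) < 1L)
        return("row and column DI vectors must be non-empty")
    if (is.null(names(object@rowDI)) || is.null(names(object@colDI)))
        return("DI vectors must be named by cluster label")
    if (!object@normalization %in% c("mean_over_m_plus_n", "mean_over_mn"))
        return("unknown normalization")
    TRUE
})

#' @describeIn DIDecomposition-class per-row distinction indices.
#' @param x,object a \code{DIDecomposition}.
#' @export
rowDI <- function(x) {
    stopifnot(is(x, "DIDecomposition"))
    x@rowDI
}

#' @describeIn DIDecomposition-class per-column distinction indices.
#' @export
colDI <- function(x) {
    stopifnot(is(x, "DIDecomposition"))
    x@colDI
}

#' @describeIn DIDecomposition-class the matrix-level DI (NA until set by
#'   [matrixDistinctionIndex()]).
#' @export
matrixDI <- function(x) {
    stopifnot(is(x, "DIDecomposition"))
    x@matrixDI
}

setMethod("show", "DIDecomposition", function(object) {
    cat(sprintf("DIDecomposition: %d row + %d column indices\n",
                length(object@rowDI), length(object@colDI)))
    cat("  row DI: ", paste(sprintf("%s=%.3f", names(object@rowDI),
                                    object@rowDI), collapse = " "), "\n")
    cat("  col DI: ", paste(sprintf("%s=%.3f", names(object@colDI),
                                    object@colDI), collapse = " "), "\n")
    if (!is.na(object@matrixDI))
        cat(sprintf("  matrix DI = %.6g (%s)\n", object@matrixDI,
                    object@normalization))
    invisible(NULL)
})

#' NebulaSpec: data layer of a Nebula plot
#'
#' Holds everything needed to draw a Nebula plot -- for each selected gene
#' the four expression samples (cluster A, cluster B, and their respective
#' background populations), the average-expression "diamond" levels, the
#' expressing fractions, the specific/shared/specific group assignment and
#' the final left-to-right display position.
#'
#' @slot genes data.frame with one row per gene: \code{gene}, \code{group}
#'   (one of \code{"specific_a"}, \code{"shared"}, \code{"specific_b"}),
#'   \code{diamond_a}, \code{diamond_b}, \code{frac_a}, \code{frac_b},
#'   \code{position} (1-based display order).
#' @slot expr long data.frame of expression samples: \code{gene},
#'   \code{violin} (one of \code{"bg_a"}, \code{"a"}, \code{"b"},
#'   \code{"bg_b"}), \code{value}.
#' @slot clusterA,clusterB focal cluster labels.
#'
#' @seealso [prepareNebulaData()], [renderNebula()]
#' @export
setClass("NebulaSpec",
    representation(genes = "data.frame", expr = "data.frame",
                   clusterA = "character", clusterB = "character"))

setValidity("NebulaSpec", function(object) {
    g <- object@genes
    need <- c("gene", "group", "diamond_a", "diamond_b",
              "frac_a", "frac_b", "position")
    if (!all(need %in% names(g)))
        return("'genes' is missing required columns")
    if (anyDuplicated(g$gene))
        return("duplicate genes in spec")
    if (any(g$frac_a < 0 | g$frac_a > 1 | g$frac_b < 0 | g$frac_b > 1))
        return("expressing fractions must lie in [0, 1]")
    if (!all(sort(g$position) == seq_len(nrow(g))))
        return("'position' must be a permutation of 1..n")
    if (!all(g$group %in% c("specific_a", "shared", "specific_b")))
        return("unknown gene group")
    TRUE
})

setMethod("show", "NebulaSpec", function(object) {
    tab <- table(factor(object@genes$group,
                        c("specific_a", "shared", "specific_b")))
    cat(sprintf(
        "NebulaSpec: %s vs %s; %d specific-A + %d shared + %d specific-B genes\n",
        object@clusterA, object@clusterB,
        tab[["specific_a"]], tab[["shared"]], tab[["specific_b"]]))
    invisible(NULL)
})

#' @describeIn NebulaSpec-class per-gene table in display order.
#' @param x,object a \code{NebulaSpec}.
#' @export
nebulaGenes <- function(x) {
    stopifnot(is(x, "NebulaSpec"))
    x@genes[order(x@genes$position), , drop = FALSE]
}
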
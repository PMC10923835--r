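## max minus mean-of-the-rest for one vector; a length-1 vector has no
## "rest", whose mean is defined as 0, so the DI is the value itself.
.di1 <- function(v) {
    if (length(v) == 1L) return(v)
    i <- which.max(v)
    v[i] - mean(v[-i])
}

#' Row- and column-wise distinction indices of a CSS matrix
#'
#' For every row (and column): the maximum entry minus the mean of the
#' remaining entries of that row (column). A high row DI means one cluster
#' of the other dataset matches this cluster far better than all
#' alternatives; a row whose entries are all alike scores 0.
#'
#' @param css a [CSSMatrix-class] or plain numeric matrix.
#' @return A [DIDecomposition-class] with \code{rowDI} and \code{colDI}
#'   filled in and \code{matrixDI} still \code{NA}; pass it to
#'   [matrixDistinctionIndex()].
#' @examples
#' m <- matrix(c(0.9, 0.1, 0.1, 0.8, 0.2, 0.1), 2, 3,
#'             dimnames = list(c("a1", "a2"), c("b1", "b2", "b3")))
#' rowColDistinction(m)
#' @export
rowColDistinction <- function(css) {
    v <- if (is(css, "CSSMatrix")) cssValues(css) else as.matrix(css)
    if (length(v) == 0L)
        stop("value error: empty matrix", call. = FALSE)
    if (is.null(rownames(v)))
        rownames(v) <- paste0("r", seq_len(nrow(v)))
    if (is.null(colnames(v)))
        colnames(v) <- paste0("c", seq_len(ncol(v)))
    if (ncol(v) == 1L)
        message("single-column matrix: row DIs equal the entries themselves")
    if (nrow(v) == 1L)
        message("single-row matrix: column DIs equal the entries themselves")
    new("DIDecomposition",
        rowDI = setNames(apply(v, 1L, .di1), rownames(v)),
        colDI = setNames(apply(v, 2L, .di1), colnames(v)))
}

#' Matrix-level distinction index
#'
#' Summarizes the m row and n column DIs of a decomposition into a single
#' score for the parameter pair. Two normalizations of the same sum are
#' supported: dividing by \code{m + n} (the default; the mean of the m + n
#' indices) or by \code{m * n}. They disagree whenever \code{m + n != m *
#' n} and may order parameter pairs differently, so the choice is explicit.
#'
#' @param decomp a [DIDecomposition-class] from [rowColDistinction()], or a
#'   CSS matrix / plain matrix (decomposed on the fly).
#' @param normalization \code{"mean_over_m_plus_n"} or
#'   \code{"mean_over_mn"}.
#' @return the decomposition with \code{matrixDI} set; use [matrixDI()] to
#'   extract the number.
#' @export
matrixDistinctionIndex <- function(decomp,
                                   normalization = c("mean_over_m_plus_n",
                                                     "mean_over_mn")) {
    normalization <- match.arg(normalization)
    if (!is(decomp, "DIDecomposition")) decomp <- rowColDistinction(decomp)
    m <- length(decomp@rowDI)
    n <- length(decomp@colDI)
    s <- sum(decomp@rowDI) + sum(decomp@colDI)
    decomp@matrixDI <- s / switch(normalization,
                                  mean_over_m_plus_n = m + n,
                                  mean_over_mn = m * n)
    decomp@normalization <- normalization
    decomp
}

## Parse one grid axis: "start:stop:step" or numeric c(start, stop, step)
## or an explicit value vector (length != 3 or attr(explicit)).
.axisValues <- function(spec, integer = FALSE) {
    if (is.character(spec)) {
        parts <- as.numeric(strsplit(spec, ":", fixed = TRUE)[[1L]])
        if (length(parts) != 3L || any(is.na(parts)))
            stop("parameter error: axis spec must be 'start:stop:step'",
                 call. = FALSE)
        spec <- parts
    } else {
        spec <- as.numeric(spec)
        if (length(spec) != 3L) {   # explicit values
            if (any(duplicated(spec)) || is.unsorted(spec))
                stop("parameter error: axis values must be unique and ",
                     "ascending", call. = FALSE)
            return(if (integer) as.integer(spec) else spec)
        }
    }
    start <- spec[1L]; stop_ <- spec[2L]; step <- spec[3L]
    if (step <= 0)
        stop("parameter error: axis step must be positive", call. = FALSE)
    if (start > stop_)
        stop("parameter error: axis start exceeds stop", call. = FALSE)
    ## integer index arithmetic with an inclusive end tolerance, so that
    ## e.g. 2.0 is not dropped from 0.4:2.0:0.2 by floating-point drift
    k <- 0:floor((stop_ - start) / step + 1e-9)
    vals <- start + k * step
    if (integer) as.integer(round(vals)) else vals
}

#' Build a clustering-parameter grid
#'
#' Generates the Cartesian product of a resolution axis, a
#' number-of-principal-components axis, and optional extra axes. Each axis
#' is given as \code{"start:stop:step"} (inclusive of the endpoint, with a
#' 1e-9 tolerance on real axes), as \code{c(start, stop, step)}, or as an
#' explicit vector of values (any length other than 3).
#'
#' @param res resolution axis; default \code{"0.4:2.0:0.2"} (9 values).
#' @param npcs principal-component axis; default \code{"10:75:5"}
#'   (14 values).
#' @param extra_axes named list of extra axes (explicit value vectors or
#'   \code{"start:stop:step"} specs).
#' @return data.frame with one row per grid cell, columns \code{res},
#'   \code{npcs} and any extra axes; the number of rows is the product of
#'   the axis lengths (126 for the defaults).
#' @examples
#' nrow(buildParameterGrid())  # 126
#' @export
buildParameterGrid <- function(res = "0.4:2.0:0.2", npcs = "10:75:5",
                               extra_axes = list()) {
    axes <- c(list(res = .axisValues(res),
                   npcs = .axisValues(npcs, integer = TRUE)),
              lapply(extra_axes, .axisValues))
    grid <- do.call(expand.grid,
                    c(axes, list(KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE)))
    attr(grid, "axes") <- axes
    grid
}

#' Sweep a parameter grid and rank parameter pairs
#'
#' For every grid cell, clusters the two datasets separately
#' ([runGridCell()]), assembles the CSS matrix ([buildCSSMatrix()]) and
#' reduces it to a matrix-level distinction index. Parameter pairs are then
#' ranked by decreasing DI; ties are broken in favour of fewer total
#' clusters (penalizing over-clustering), then lower resolution, then fewer
#' principal components. A failing cell is recorded with status
#' \code{"failed"} and does not abort the sweep.
#'
#' @param counts_a,counts_b the two count matrices.
#' @param grid data.frame from [buildParameterGrid()] (columns \code{res},
#'   \code{npcs}).
#' @param seed base seed; every cell derives its own seed from
#'   \code{(seed, res, npcs)}.
#' @param normalization matrix-DI normalization, see
#'   [matrixDistinctionIndex()].
#' @param pct_floor background-fraction floor for the CSS weights.
#' @param verbose print one line per cell.
#' @param ... passed to [runGridCell()].
#' @return list with \code{ranked} (data.frame: \code{rank}, \code{res},
#'   \code{npcs}, \code{di}, \code{m_clusters}, \code{n_clusters},
#'   \code{status}), \code{css} (named list of [CSSMatrix-class], one per
#'   successful cell, names \code{"res<r>_npcs<p>"}) and \code{runs} (the
#'   per-cell clustering runs).
#' @export
sweepAndRank <- function(counts_a, counts_b, grid = buildParameterGrid(),
                         seed = 0L,
                         normalization = c("mean_over_m_plus_n",
                                           "mean_over_mn"),
                         pct_floor = 0.001, verbose = FALSE, ...) {
    normalization <- match.arg(normalization)
    if (!all(c("res", "npcs") %in% names(grid)))
        stop("parameter error: grid must have 'res' and 'npcs' columns",
             call. = FALSE)
    cells <- vector("list", nrow(grid))
    css_list <- list()
    runs <- list()
    for (g in seq_len(nrow(grid))) {
        res <- grid$res[g]; npcs <- grid$npcs[g]
        key <- sprintf("res%g_npcs%d", res, npcs)
        cell <- tryCatch({
            run <- runGridCell(counts_a, counts_b, res = res, npcs = npcs,
                               seed = seed, ...)
            css <- buildCSSMatrix(run$a$markers, run$b$markers,
                                  clusters_a = unique(run$a$labels),
                                  clusters_b = unique(run$b$labels),
                                  res = res, npcs = npcs,
                                  pct_floor = pct_floor)
            di <- matrixDI(matrixDistinctionIndex(css, normalization))
            css_list[[key]] <- css
            runs[[key]] <- run
            data.frame(res = res, npcs = npcs, di = di,
                       m_clusters = nrow(cssValues(css)),
                       n_clusters = ncol(cssValues(css)),
                       status = "ok", stringsAsFactors = FALSE)
        }, error = function(e) {
            data.frame(res = res, npcs = npcs, di = NA_real_,
                       m_clusters = NA_integer_, n_clusters = NA_integer_,
                       status = paste0("failed: ", conditionMessage(e)),
                       stringsAsFactors = FALSE)
        })
        if (verbose)
            message(sprintf("[%d/%d] %s di=%s", g, nrow(grid), key,
                            format(cell$di, digits = 4)))
        cells[[g]] <- cell
    }
    tab <- do.call(rbind, cells)
    ord <- order(-tab$di, tab$m_clusters + tab$n_clusters, tab$res,
                 tab$npcs, na.last = TRUE)
    tab <- tab[ord, , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    list(ranked = tab[, c("rank", "res", "npcs", "di", "m_clusters",
                          "n_clusters", "status")],
         css = css_list, runs = runs)
}

#' Cross-tabulate two labelings of the same cells
#'
#' Contingency table of cell counts between two per-cell cluster
#' assignments over the same cell universe -- e.g. a combined clustering
#' versus a separate (per-genotype) clustering, the table behind an
#' alluvial diagram. Row sums equal the x-cluster sizes.
#'
#' @param labels_x,labels_y named per-cell label vectors over the same
#'   cells (matched by name; unnamed vectors are matched by position and
#'   must have equal length).
#' @return integer matrix, x clusters in rows, y clusters in columns.
#' @export
crossTabulateLabelings <- function(labels_x, labels_y) {
    x <- setNames(as.character(labels_x), names(labels_x))
    y <- setNames(as.character(labels_y), names(labels_y))
    if (!is.null(names(x)) && !is.null(names(y))) {
        if (!setequal(names(x), names(y)))
            stop("consistency error: the two labelings cover different ",
                 "cells", call. = FALSE)
        y <- y[names(x)]
    } else if (length(x) != length(y)) {
        stop("consistency error: labelings differ in length", call. = FALSE)
    }
    unclass(table(x, y, dnn = NULL))
}
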
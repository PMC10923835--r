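#' @importFrom withr with_seed
NULL

## Library-size normalize to a fixed total and log1p; returns sparse
## genes x cells log-normalized matrix.
.logNormalize <- function(m, target_sum = 1e4) {
    libs <- Matrix::colSums(m)
    ln <- m %*% Matrix::Diagonal(x = target_sum / libs)
    ln@x <- log1p(ln@x)
    dimnames(ln) <- dimnames(m)
    ln
}

## Highly-variable-gene selection on the log scale; falls back to a plain
## variance ranking if the mean-variance trend cannot be fit.
.selectHVGs <- function(lognorm, n_hvgs, minimum) {
    hv <- tryCatch({
        fit <- scran::modelGeneVar(lognorm)
        scran::getTopHVGs(fit, n = n_hvgs)
    }, error = function(e) character(0))
    if (length(hv) < minimum) {
        v <- apply(as.matrix(lognorm), 1L, stats::var)
        hv <- names(sort(v, decreasing = TRUE))[seq_len(min(n_hvgs, nrow(lognorm)))]
        hv <- hv[v[hv] > 0]
    }
    hv
}

## Per-gene z-scaling with an upper cap, genes x cells dense.
.scaleCapped <- function(x, cap = 10) {
    x <- as.matrix(x)
    mu <- rowMeans(x)
    sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
    sdv[sdv == 0] <- 1
    pmin((x - mu) / sdv, cap)
}

## PCA scores (cells x npcs) of a scaled genes x cells matrix. Exact SVD
## for small problems, truncated (irlba) otherwise; sign-fixed so results
## do not depend on the SVD backend's sign convention.
.pcaScores <- function(scaled, npcs) {
    xc <- t(scaled)
    if (npcs > 0.25 * min(dim(xc))) {
        sv <- svd(xc, nu = npcs, nv = 0)
        scores <- sv$u %*% diag(sv$d[seq_len(npcs)], npcs)
    } else {
        sv <- irlba::irlba(xc, nv = npcs)
        scores <- sv$u %*% diag(sv$d, npcs)
    }
    ## fix component signs: largest-magnitude loading per component positive
    for (j in seq_len(ncol(scores))) {
        i <- which.max(abs(scores[, j]))
        if (scores[i, j] < 0) scores[, j] <- -scores[, j]
    }
    rownames(scores) <- colnames(scaled)
    scores
}

#' Preprocess and cluster a count matrix
#'
#' Runs the standard single-dataset pipeline: per-cell library-size
#' normalization to \code{target_sum}, \code{log1p}, highly-variable-gene
#' selection, per-gene z-scaling with an upper cap, PCA to \code{npcs}
#' components, a shared-nearest-neighbor graph, and modularity-based
#' (Louvain) community detection at resolution \code{res}. The result is
#' deterministic for a fixed (input, parameters, seed).
#'
#' @param counts a \code{SingleCellExperiment} with a \code{"counts"} assay
#'   or a sparse/dense integer matrix (genes x cells, with dimnames).
#' @param res community-detection resolution (> 0); larger values yield
#'   more clusters.
#' @param npcs number of principal components (>= 2 and smaller than either
#'   matrix dimension).
#' @param seed integer seed governing all stochastic steps.
#' @param n_hvgs number of highly variable genes retained.
#' @param scale_cap upper cap applied to z-scores.
#' @param k neighbors for the SNN graph.
#' @param target_sum per-cell normalization total.
#' @return named character vector of cluster labels ("0", "1", ... in
#'   decreasing cluster-size order), one per cell.
#' @examples
#' sim <- simulatePairedDatasets(syntheticConfig(
#'     k_shared = 2, k_unique_b = 0, cells_per_cluster = 100,
#'     n_genes = 300, seed = 1))
#' labels <- preprocessAndCluster(sim$a, res = 0.8, npcs = 10, seed = 1)
#' table(labels)
#' @export
preprocessAndCluster <- function(counts, res, npcs, seed = 0L,
                                 n_hvgs = 2000, scale_cap = 10, k = 20,
                                 target_sum = 1e4) {
    m <- .countsOf(counts)
    if (res <= 0)
        stop("parameter error: 'res' must be > 0", call. = FALSE)
    npcs <- as.integer(npcs)
    if (npcs < 2L)
        stop("parameter error: 'npcs' must be >= 2", call. = FALSE)
    zero <- Matrix::colSums(m) == 0
    if (any(zero)) {
        warning(sum(zero), " all-zero cell(s) dropped")
        m <- m[, !zero, drop = FALSE]
    }
    if (ncol(m) < 50L)
        stop("parameter error: need at least 50 cells, got ", ncol(m),
             call. = FALSE)
    if (npcs >= min(dim(m)))
        stop("parameter error: 'npcs' (", npcs, ") must be smaller than ",
             "both matrix dimensions", call. = FALSE)

    withr::with_seed(as.integer(seed), {
        ln <- .logNormalize(m, target_sum)
        hv <- .selectHVGs(ln, n_hvgs, minimum = npcs + 1L)
        scaled <- .scaleCapped(ln[hv, , drop = FALSE], scale_cap)
        scores <- .pcaScores(scaled, min(npcs, length(hv) - 1L))
        g <- scran::buildSNNGraph(scores, k = k, transposed = TRUE,
                                  type = "jaccard")
        comm <- igraph::cluster_louvain(g, resolution = res)
        memb <- igraph::membership(comm)
        ## relabel clusters 0,1,... by decreasing size (ties by first
        ## occurrence) for stable, backend-independent labels
        sizes <- sort(table(memb), decreasing = TRUE)
        relab <- setNames(as.character(seq_along(sizes) - 1L), names(sizes))
        setNames(unname(relab[as.character(memb)]), colnames(m))
    })
}

## Dense log-normalized expression plus per-gene rank machinery shared by
## every cluster-vs-rest test on the same dataset.
.markerContext <- function(m, target_sum = 1e4) {
    ln <- as.matrix(.logNormalize(m, target_sum))
    n <- ncol(ln)
    ranks <- t(apply(ln, 1L, rank))
    ## tie adjustment sum(t^3 - t) per gene
    tieadj <- apply(ln, 1L, function(v) {
        t <- tabulate(match(v, unique(v)))
        sum(t^3 - t)
    })
    list(expr = ln, expm1 = expm1(ln), nonzero = m > 0, ranks = ranks,
         tieadj = tieadj, n = n)
}

## Vectorized two-sided Wilcoxon rank-sum (normal approximation with tie
## and continuity correction, matching stats::wilcox.test(exact = FALSE)),
## cluster cells vs all remaining cells, one p-value per gene row.
.wilcoxVsRest <- function(ctx, in_cluster, genes) {
    n1 <- sum(in_cluster)
    n <- ctx$n
    n2 <- n - n1
    r1 <- rowSums(ctx$ranks[genes, in_cluster, drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    z <- u - n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) *
                  ((n + 1) - ctx$tieadj[genes] / (n * (n - 1))))
    z <- (z - sign(z) * 0.5) / sigma
    p <- 2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE))
    p[!is.finite(p)] <- 1
    pmin(p, 1)
}

#' Identify positive marker genes of clusters
#'
#' For each requested cluster, compares its cells with all remaining cells
#' of the same dataset: the expressing fractions \code{pct.1} / \code{pct.2}
#' (fraction of cells with a nonzero count), the natural-log fold change of
#' average de-logged normalized expression (pseudocount 1 on both sides),
#' and a two-sided Wilcoxon rank-sum p-value per gene with
#' Benjamini-Hochberg adjustment across the genes actually tested. Only
#' genes with \code{max(pct.1, pct.2) >= min_pct} and
#' \code{avg_logFC >= min_logfc} are tested.
#'
#' @param counts count matrix or \code{SingleCellExperiment} (genes x cells).
#' @param labels per-cell cluster labels (named by cell id, or in column
#'   order).
#' @param clusters cluster label(s) to test; default all.
#' @param min_pct minimum expressing fraction (in cluster or background)
#'   for a gene to be tested.
#' @param min_logfc minimum natural-log fold change for a gene to be tested.
#' @param target_sum per-cell normalization total (must match the value
#'   used for clustering).
#' @return data.frame with columns \code{gene}, \code{cluster},
#'   \code{avg_logFC}, \code{pct.1}, \code{pct.2}, \code{p_val},
#'   \code{p_val_adj}, ordered by cluster then increasing p-value. No
#'   significance filter is applied here; see [filterMarkers()].
#' @seealso [filterMarkers()], [preprocessAndCluster()]
#' @export
findClusterMarkers <- function(counts, labels, clusters = NULL,
                               min_pct = 0.1, min_logfc = 0.25,
                               target_sum = 1e4) {
    m <- .countsOf(counts)
    labels <- .alignLabels(labels, colnames(m))
    if (is.null(clusters)) clusters <- sort(unique(labels))
    absent <- setdiff(clusters, unique(labels))
    if (length(absent))
        stop("key error: cluster label(s) not present: ",
             paste(absent, collapse = ", "), call. = FALSE)
    ctx <- .markerContext(m, target_sum)
    out <- lapply(clusters, function(cl) {
        inc <- labels == cl
        if (sum(inc) < 3L)
            stop("parameter error: cluster '", cl, "' has fewer than 3 cells",
                 call. = FALSE)
        if (sum(!inc) < 1L)
            stop("parameter error: empty background for cluster '", cl, "'",
                 call. = FALSE)
        pct1 <- Matrix::rowMeans(ctx$nonzero[, inc, drop = FALSE])
        pct2 <- Matrix::rowMeans(ctx$nonzero[, !inc, drop = FALSE])
        lfc <- log((rowMeans(ctx$expm1[, inc, drop = FALSE]) + 1) /
                   (rowMeans(ctx$expm1[, !inc, drop = FALSE]) + 1))
        test <- which(pmax(pct1, pct2) >= min_pct & lfc >= min_logfc)
        if (!length(test)) return(NULL)
        p <- .wilcoxVsRest(ctx, inc, test)
        df <- data.frame(gene = rownames(m)[test], cluster = cl,
                         avg_logFC = lfc[test], pct.1 = pct1[test],
                         pct.2 = pct2[test], p_val = p,
                         p_val_adj = p.adjust(p, "BH"),
                         stringsAsFactors = FALSE)
        df[order(df$p_val, -df$avg_logFC, df$gene), , drop = FALSE]
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(gene = character(0), cluster = character(0),
                          avg_logFC = numeric(0), pct.1 = numeric(0),
                          pct.2 = numeric(0), p_val = numeric(0),
                          p_val_adj = numeric(0))
    rownames(out) <- NULL
    out
}

.alignLabels <- function(labels, cell_ids) {
    labels <- setNames(as.character(labels), names(labels))
    if (!is.null(names(labels))) {
        if (!setequal(names(labels), cell_ids))
            stop("consistency error: label names do not match cell ids",
                 call. = FALSE)
        labels <- labels[cell_ids]
    } else if (length(labels) != length(cell_ids)) {
        stop("consistency error: ", length(labels), " labels for ",
             length(cell_ids), " cells", call. = FALSE)
    } else {
        names(labels) <- cell_ids
    }
    labels
}

#' Retain significant positive markers
#'
#' Applies the global marker-retention rule: keep records with adjusted
#' p-value at or below \code{p_threshold} and (by default) a positive
#' natural-log fold change. Idempotent.
#'
#' @param markers marker data.frame.
#' @param p_threshold adjusted-p cutoff.
#' @param positive_only drop non-positive fold changes.
#' @return filtered data.frame with attribute \code{retained_only}.
#' @export
filterMarkers <- function(markers, p_threshold = 0.05, positive_only = TRUE) {
    keep <- markers$p_val_adj <= p_threshold
    if (positive_only) keep <- keep & markers$avg_logFC > 0
    out <- markers[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "retained_only") <- (p_threshold <= 0.05) && positive_only
    out
}

## Deterministic per-grid-cell seed below 2^31.
.deriveSeed <- function(seed, res, npcs) {
    (as.integer(seed) %% 100003L) * 20011L +
        (as.integer(round(res * 1000)) %% 4001L) * 211L +
        as.integer(npcs) %% 1009L
}

#' Cluster two datasets separately under one parameter pair
#'
#' Runs [preprocessAndCluster()] and marker identification independently on
#' the two datasets -- they are never merged and no batch correction is
#' applied -- and retains significant positive markers for each. The cell's
#' seed is derived deterministically from \code{(seed, res, npcs)} so that
#' grid cells are reproducible and independent.
#'
#' @param counts_a,counts_b the two count matrices (genes x cells).
#' @param res,npcs clustering parameters.
#' @param seed base integer seed.
#' @param ... further arguments passed to [preprocessAndCluster()] and the
#'   marker test (\code{min_pct}, \code{min_logfc}, ...).
#' @return list with elements \code{a} and \code{b}, each a "clustering
#'   run": \code{dataset_id}, \code{res}, \code{npcs}, \code{seed},
#'   \code{labels} (named character) and \code{markers} (retained-only
#'   data.frame).
#' @export
runGridCell <- function(counts_a, counts_b, res, npcs, seed = 0L, ...) {
    cellseed <- .deriveSeed(seed, res, npcs)
    run1 <- .oneRun(counts_a, res, npcs, cellseed, "a", ...)
    run2 <- .oneRun(counts_b, res, npcs, cellseed, "b", ...)
    list(a = run1, b = run2)
}

.oneRun <- function(counts, res, npcs, seed, default_id,
                    min_pct = 0.1, min_logfc = 0.25, ...) {
    labels <- preprocessAndCluster(counts, res = res, npcs = npcs,
                                   seed = seed, ...)
    ## all-zero cells may have been dropped during preprocessing
    m <- .countsOf(counts)[, names(labels), drop = FALSE]
    markers <- findClusterMarkers(m, labels, min_pct = min_pct,
                                  min_logfc = min_logfc)
    list(dataset_id = .datasetIdOf(counts, default_id),
         res = res, npcs = as.integer(npcs), seed = seed,
         labels = labels, markers = filterMarkers(markers))
}
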
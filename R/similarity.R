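#' Marker uniqueness score
#'
#' Quantifies how exclusively a gene marks clusters: \code{1 - sqrt(L_i /
#' L_n)}, where \code{L_i} is the number of clusters (across both datasets
#' combined) for which the gene is a retained marker and \code{L_n} is the
#' total number of clusters in the two cluster sets. A gene marking a
#' single cluster out of many scores close to 1; a gene marking every
#' cluster scores 0.
#'
#' @param L_i integer vector, clusters marked per gene (1 <= L_i <= L_n).
#' @param L_n total number of clusters across both datasets (>= 2).
#' @return numeric vector of uniqueness scores in [0, 1).
#' @examples
#' uniquenessScore(1, 4)  # 0.5
#' uniquenessScore(4, 4)  # 0
#' @export
uniquenessScore <- function(L_i, L_n) {
    if (any(L_n < 2))
        stop("value error: total cluster count must be >= 2", call. = FALSE)
    if (any(L_i < 1) || any(L_i > L_n))
        stop("value error: L_i must lie in [1, L_n]", call. = FALSE)
    1 - sqrt(L_i / L_n)
}

#' Marker weight
#'
#' The contribution weight of a positive marker gene in one cluster:
#' \code{avg_log_fc * pct_in^2 / pct_bg}, rewarding genes that are strongly
#' (high fold change), widely (high expressing fraction in the cluster) and
#' specifically (low expressing fraction in the background) expressed. The
#' background fraction is floored at \code{pct_floor} so that markers absent
#' from the background keep a finite weight.
#'
#' @param avg_log_fc natural-log fold change, must be positive (non-positive
#'   markers are filtered upstream).
#' @param pct_in,pct_bg expressing fractions in cluster / background.
#' @param pct_floor lower floor applied to \code{pct_bg}.
#' @return non-negative numeric vector of weights.
#' @examples
#' markerWeight(0.5, 0.8, 0.2)  # 1.6
#' @export
markerWeight <- function(avg_log_fc, pct_in, pct_bg, pct_floor = 0.001) {
    if (any(avg_log_fc <= 0))
        stop("value error: marker weights are defined for positive ",
             "fold changes only", call. = FALSE)
    if (any(pct_in < 0 | pct_in > 1 | pct_bg < 0 | pct_bg > 1))
        stop("value error: expressing fractions must lie in [0, 1]",
             call. = FALSE)
    avg_log_fc * pct_in^2 / pmax(pct_bg, pct_floor)
}

#' Basic cluster similarity score (Jaccard)
#'
#' The plain Jaccard index of two marker-gene sets:
#' \code{C12 / (C12 + U1 + U2)} with \code{C12} shared markers and
#' \code{U1}, \code{U2} markers unique to either cluster. Two empty sets
#' score 0 (most dissimilar) by convention.
#'
#' @param markers_a,markers_b character vectors of marker gene names.
#' @return similarity in [0, 1].
#' @export
cssBasic <- function(markers_a, markers_b) {
    a <- unique(as.character(markers_a))
    b <- unique(as.character(markers_b))
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
}

#' Uniqueness context over two cluster sets
#'
#' Counts, for every retained marker gene, the number of clusters (across
#' both marker tables combined) it marks, and records the total cluster
#' count \code{L_n = m + n}. Cluster membership is taken from the tables'
#' \code{cluster} column; every cluster present in either clustering should
#' appear, which is why the total is supplied explicitly when clusters with
#' zero retained markers exist.
#'
#' @param markers_a,markers_b retained marker data.frames.
#' @param total_clusters total cluster count m + n; defaults to the number
#'   of distinct cluster labels seen in the two tables.
#' @return list with \code{counts} (named integer, gene -> L_i) and
#'   \code{total} (L_n).
#' @seealso [cssEnhanced()], [buildCSSMatrix()]
#' @export
uniquenessContext <- function(markers_a, markers_b, total_clusters = NULL) {
    if (is.null(total_clusters))
        total_clusters <- length(unique(markers_a$cluster)) +
            length(unique(markers_b$cluster))
    pairs <- rbind(
        unique(data.frame(gene = markers_a$gene, cluster = paste0("a.", markers_a$cluster))),
        unique(data.frame(gene = markers_b$gene, cluster = paste0("b.", markers_b$cluster))))
    counts <- table(pairs$gene)
    list(counts = setNames(as.integer(counts), names(counts)),
         total = as.integer(total_clusters))
}

## Per-gene uniqueness under a context; errors on unknown genes.
.ctxUniqueness <- function(genes, ctx) {
    li <- ctx$counts[genes]
    if (any(is.na(li)))
        stop("consistency error: gene(s) absent from uniqueness context: ",
             paste(genes[is.na(li)], collapse = ", "), call. = FALSE)
    uniquenessScore(li, ctx$total)
}

#' Enhanced cluster similarity score
#'
#' The weighted, uniqueness-aware generalization of [cssBasic()]. With
#' shared markers \code{i} (in both clusters), markers \code{j} unique to
#' cluster A and markers \code{k} unique to cluster B,
#' \deqn{CSS_{enh} = \frac{\sum_i (w_{i1} + w_{i2})\,u_i}
#'   {\sum_i (w_{i1} + w_{i2})\,u_i + \sum_j w_{j1} u_j + \sum_k w_{k2} u_k}}
#' where \code{w} are marker weights ([markerWeight()]) in the respective
#' cluster and \code{u} the uniqueness scores from the shared context. A
#' zero denominator (no markers, or all uniqueness zero) yields 0.
#'
#' @param markers_a,markers_b retained marker data.frames for one cluster
#'   each (single-cluster slices).
#' @param ctx uniqueness context from [uniquenessContext()].
#' @param pct_floor background-fraction floor for [markerWeight()].
#' @return similarity in [0, 1]; symmetric in its two cluster arguments.
#' @examples
#' a <- data.frame(gene = c("g1", "g2", "g3"), cluster = "0",
#'                 avg_logFC = 1, pct.1 = 1, pct.2 = 0.5,
#'                 p_val = 0, p_val_adj = 0)
#' b <- data.frame(gene = c("g1", "g2", "g4"), cluster = "0",
#'                 avg_logFC = 1, pct.1 = 1, pct.2 = 0.5,
#'                 p_val = 0, p_val_adj = 0)
#' cssEnhanced(a, b, uniquenessContext(a, b, total_clusters = 4))
#' @export
cssEnhanced <- function(markers_a, markers_b, ctx, pct_floor = 0.001) {
    wa <- setNames(markerWeight(markers_a$avg_logFC, markers_a$pct.1,
                                markers_a$pct.2, pct_floor), markers_a$gene)
    wb <- setNames(markerWeight(markers_b$avg_logFC, markers_b$pct.1,
                                markers_b$pct.2, pct_floor), markers_b$gene)
    shared <- intersect(names(wa), names(wb))
    only_a <- setdiff(names(wa), shared)
    only_b <- setdiff(names(wb), shared)
    u_s <- if (length(shared)) .ctxUniqueness(shared, ctx) else numeric(0)
    u_a <- if (length(only_a)) .ctxUniqueness(only_a, ctx) else numeric(0)
    u_b <- if (length(only_b)) .ctxUniqueness(only_b, ctx) else numeric(0)
    num <- sum((wa[shared] + wb[shared]) * u_s)
    den <- num + sum(wa[only_a] * u_a) + sum(wb[only_b] * u_b)
    if (den == 0) 0 else num / den
}

#' Assemble the CSS matrix for two clusterings
#'
#' Computes [cssEnhanced()] for every (cluster of A, cluster of B) pair
#' under one uniqueness context built across all m + n clusters of the two
#' runs. Clusters with no retained markers contribute a zero row or column
#' (with a warning).
#'
#' @param markers_a,markers_b retained-only marker data.frames covering all
#'   clusters of dataset A / B.
#' @param clusters_a,clusters_b full cluster label sets; defaults to the
#'   labels present in the tables, but should be given when some clusters
#'   retained no markers (they still count towards L_n).
#' @param res,npcs clustering parameters recorded in the result.
#' @param pct_floor background-fraction floor.
#' @return A [CSSMatrix-class] (rows: clusters of A, columns: clusters of
#'   B, lexicographically ordered).
#' @export
buildCSSMatrix <- function(markers_a, markers_b,
                           clusters_a = NULL, clusters_b = NULL,
                           res = NA_real_, npcs = NA_integer_,
                           pct_floor = 0.001) {
    .checkRetained(markers_a, "markers_a")
    .checkRetained(markers_b, "markers_b")
    if (is.null(clusters_a)) clusters_a <- unique(markers_a$cluster)
    if (is.null(clusters_b)) clusters_b <- unique(markers_b$cluster)
    clusters_a <- sort(as.character(clusters_a))
    clusters_b <- sort(as.character(clusters_b))
    if (!length(clusters_a) || !length(clusters_b))
        stop("value error: empty cluster set", call. = FALSE)
    empty <- c(setdiff(clusters_a, markers_a$cluster),
               setdiff(clusters_b, markers_b$cluster))
    if (length(empty))
        warning("cluster(s) with no retained markers yield zero scores: ",
                paste(empty, collapse = ", "))
    ctx <- uniquenessContext(markers_a, markers_b,
                             total_clusters = length(clusters_a) +
                                 length(clusters_b))
    slices_a <- split(markers_a, factor(markers_a$cluster, clusters_a))
    slices_b <- split(markers_b, factor(markers_b$cluster, clusters_b))
    v <- matrix(0, length(clusters_a), length(clusters_b),
                dimnames = list(clusters_a, clusters_b))
    for (i in clusters_a)
        for (j in clusters_b)
            v[i, j] <- cssEnhanced(slices_a[[i]], slices_b[[j]], ctx,
                                   pct_floor)
    CSSMatrix(v, res = res, nPCs = npcs)
}

.checkRetained <- function(markers, what) {
    if (!all(c("gene", "cluster", "avg_logFC", "pct.1", "pct.2",
               "p_val_adj") %in% names(markers)))
        stop("format error: '", what, "' is missing marker-table columns",
             call. = FALSE)
    if (nrow(markers) &&
        (any(markers$avg_logFC <= 0) || any(markers$p_val_adj > 0.05)))
        stop("value error: '", what, "' must contain retained markers only ",
             "(positive avg_logFC, p_val_adj <= 0.05); see filterMarkers()",
             call. = FALSE)
    invisible(TRUE)
}
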
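## Shared fixture builders and independent oracles. Oracles are written as
## plain straight-line code so that they stay independent of the package
## implementation they check.

mkMarkers <- function(genes, cluster = "0", lfc = 1, pct1 = 1, pct2 = 0.5,
                      padj = 0.01) {
    data.frame(gene = genes, cluster = rep_len(cluster, length(genes)),
               avg_logFC = rep_len(lfc, length(genes)),
               pct.1 = rep_len(pct1, length(genes)),
               pct.2 = rep_len(pct2, length(genes)),
               p_val = rep_len(padj, length(genes)),
               p_val_adj = rep_len(padj, length(genes)),
               stringsAsFactors = FALSE)
}

## Brute-force Jaccard on two character sets.
oracleJaccard <- function(a, b) {
    a <- unique(a); b <- unique(b)
    if (length(union(a, b)) == 0) return(0)
    length(intersect(a, b)) / length(union(a, b))
}

## Straight-line evaluation of the enhanced similarity: explicit loops over
## shared and unique genes, weights and uniqueness computed in place.
oracleCssEnh <- function(ma, mb, L, Ln, floor. = 0.001) {
    w <- function(row) row$avg_logFC * row$pct.1^2 / max(row$pct.2, floor.)
    u <- function(g) 1 - sqrt(L[[g]] / Ln)
    num <- 0; den_extra <- 0
    for (i in seq_len(nrow(ma))) {
        g <- ma$gene[i]
        j <- match(g, mb$gene)
        if (!is.na(j)) num <- num + (w(ma[i, ]) + w(mb[j, ])) * u(g)
        else den_extra <- den_extra + w(ma[i, ]) * u(g)
    }
    for (j in seq_len(nrow(mb))) {
        g <- mb$gene[j]
        if (!g %in% ma$gene) den_extra <- den_extra + w(mb[j, ]) * u(g)
    }
    if (num + den_extra == 0) 0 else num / (num + den_extra)
}

## Brute-force row/column distinction indices via explicit loops.
oracleDI <- function(v) {
    rd <- numeric(nrow(v)); cd <- numeric(ncol(v))
    for (i in seq_len(nrow(v))) {
        x <- v[i, ]; k <- which.max(x)
        rd[i] <- if (length(x) == 1) x else x[k] - mean(x[-k])
    }
    for (j in seq_len(ncol(v))) {
        x <- v[, j]; k <- which.max(x)
        cd[j] <- if (length(x) == 1) x else x[k] - mean(x[-k])
    }
    list(row = rd, col = cd)
}

## Random retained marker table pair plus a consistent uniqueness map.
randomCssFixture <- function(pool_size = 12, Ln = 8) {
    pool <- paste0("g", seq_len(pool_size))
    a <- sample(pool, sample(0:6, 1))
    b <- sample(pool, sample(0:6, 1))
    rnd <- function(genes, cl) {
        if (!length(genes)) return(mkMarkers(character(0), cl))
        mkMarkers(genes, cl,
                  lfc = runif(length(genes), 0.1, 3),
                  pct1 = runif(length(genes), 0.05, 1),
                  pct2 = round(runif(length(genes), 0, 0.9), 3))
    }
    L <- setNames(sample.int(Ln, pool_size, replace = TRUE), pool)
    list(a = rnd(a, "0"), b = rnd(b, "1"), L = as.list(L), Ln = Ln)
}

## A small two-population count matrix with strong planted markers.
twoPopulationCounts <- function(cells_per = 100, n_genes = 300,
                                markers_per = 50, fold = 8, seed = 11) {
    simulatePairedDatasets(syntheticConfig(
        n_genes = n_genes, cells_per_cluster = cells_per, k_shared = 2,
        k_unique_a = 0, k_unique_b = 0, markers_per_cluster = markers_per,
        fold_change = fold, seed = seed))
}

ari <- function(x, y) mclust::adjustedRandIndex(x, y)
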
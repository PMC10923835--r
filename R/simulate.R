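#' Configuration for the paired-dataset simulator
#'
#' Defines a pair of genotype-matched single-cell count matrices with
#' planted cluster structure: \code{k_shared} clusters present in both
#' conditions (identical marker sets and expression means on both sides),
#' plus optional condition-exclusive clusters. Counts follow a negative
#' binomial model with a gene-shared dispersion: non-marker genes have mean
#' \code{baseline_mean} everywhere, and each cluster's own marker genes
#' have mean \code{baseline_mean * fold_change} in that cluster's cells
#' only. Marker sets are pairwise disjoint across clusters, so the planted
#' uniqueness scores are analytic (a shared cluster's markers mark exactly
#' two clusters across the pair, an exclusive cluster's mark one).
#' A per-cell log-normal library-size jitter makes normalization
#' non-trivial; set \code{library_jitter_sd = 0} to disable it.
#'
#' @param n_genes total number of genes.
#' @param cells_per_cluster cells per cluster (scalar, recycled).
#' @param k_shared clusters present in both conditions.
#' @param k_unique_a,k_unique_b clusters exclusive to condition A / B.
#' @param markers_per_cluster planted marker genes per cluster.
#' @param fold_change marker-gene mean multiplier (> 1).
#' @param baseline_mean negative-binomial mean of background expression.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param library_jitter_sd sdlog of the per-cell library-size factor.
#' @param seed integer seed; the simulation is fully determined by it.
#' @return named list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(n_genes = 1000, cells_per_cluster = 200,
                            k_shared = 4, k_unique_a = 0, k_unique_b = 1,
                            markers_per_cluster = 25, fold_change = 8,
                            baseline_mean = 0.2, dispersion = 0.5,
                            library_jitter_sd = 0.1, seed = 0L) {
    cfg <- list(n_genes = as.integer(n_genes),
                cells_per_cluster = as.integer(cells_per_cluster),
                k_shared = as.integer(k_shared),
                k_unique_a = as.integer(k_unique_a),
                k_unique_b = as.integer(k_unique_b),
                markers_per_cluster = as.integer(markers_per_cluster),
                fold_change = fold_change,
                baseline_mean = baseline_mean,
                dispersion = dispersion,
                library_jitter_sd = library_jitter_sd,
                seed = as.integer(seed))
    k_total <- cfg$k_shared + cfg$k_unique_a + cfg$k_unique_b
    if (k_total < 1L)
        stop("config error: need at least one cluster", call. = FALSE)
    if (cfg$markers_per_cluster * k_total > cfg$n_genes)
        stop("config error: ", cfg$markers_per_cluster * k_total,
             " marker genes requested but only ", cfg$n_genes,
             " genes available", call. = FALSE)
    if (cfg$fold_change < 1 || cfg$baseline_mean <= 0 || cfg$dispersion <= 0)
        stop("config error: fold_change >= 1, baseline_mean > 0 and ",
             "dispersion > 0 required", call. = FALSE)
    class(cfg) <- "syntheticConfig"
    cfg
}

## NB draws for one condition: clusters = character vector of planted
## cluster names (one entry per cluster), marker_sets = named list.
.simulateCondition <- function(cfg, clusters, marker_sets, genes, prefix) {
    n_cells_per <- rep(cfg$cells_per_cluster, length(clusters))
    n_cells <- sum(n_cells_per)
    labels <- rep(clusters, n_cells_per)
    cell_ids <- sprintf("%s_cell%04d", prefix, seq_len(n_cells))
    mu <- matrix(cfg$baseline_mean, length(genes), n_cells,
                 dimnames = list(genes, cell_ids))
    for (cl in clusters)
        mu[marker_sets[[cl]], labels == cl] <-
            cfg$baseline_mean * cfg$fold_change
    if (cfg$library_jitter_sd > 0) {
        f <- rlnorm(n_cells, 0, cfg$library_jitter_sd)
        mu <- sweep(mu, 2L, f, `*`)
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                     nrow(mu), ncol(mu), dimnames = dimnames(mu))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
        metadata = list(dataset_id = prefix))
    list(sce = sce, labels = setNames(labels, cell_ids))
}

#' Simulate a pair of count matrices with planted clusters
#'
#' @param config a [syntheticConfig()].
#' @return list with \code{a}, \code{b} (two \code{SingleCellExperiment}s,
#'   genes x cells) and \code{truth}, itself a list: \code{labels_a},
#'   \code{labels_b} (planted per-cell cluster labels, named by cell id),
#'   \code{mapping} (data.frame of ground-truth shared-cluster pairs
#'   \code{a}, \code{b}), and \code{marker_assignment} (named character,
#'   gene -> owning cluster).
#' @examples
#' sim <- simulatePairedDatasets(syntheticConfig(seed = 7))
#' dim(SummarizedExperiment::assay(sim$a))
#' sim$truth$mapping
#' @export
simulatePairedDatasets <- function(config = syntheticConfig()) {
    cfg <- if (is(config, "syntheticConfig")) config
           else do.call(syntheticConfig, config)
    shared <- if (cfg$k_shared) paste0("S", seq_len(cfg$k_shared)) else character(0)
    uniq_a <- if (cfg$k_unique_a) paste0("A", seq_len(cfg$k_unique_a)) else character(0)
    uniq_b <- if (cfg$k_unique_b) paste0("B", seq_len(cfg$k_unique_b)) else character(0)
    all_clusters <- c(shared, uniq_a, uniq_b)
    genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
    marker_sets <- setNames(lapply(seq_along(all_clusters), function(i) {
        genes[((i - 1L) * cfg$markers_per_cluster + 1L):
              (i * cfg$markers_per_cluster)]
    }), all_clusters)

    withr::with_seed(cfg$seed, {
        a <- .simulateCondition(cfg, c(shared, uniq_a), marker_sets, genes, "a")
        b <- .simulateCondition(cfg, c(shared, uniq_b), marker_sets, genes, "b")
    })
    assign_vec <- setNames(rep(names(marker_sets),
                               lengths(marker_sets)),
                           unlist(marker_sets))
    list(a = a$sce, b = b$sce,
         truth = list(labels_a = a$labels, labels_b = b$labels,
                      mapping = data.frame(a = shared, b = shared,
                                           stringsAsFactors = FALSE),
                      marker_assignment = assign_vec,
                      config = cfg))
}

## Majority alignment of empirical clusters to planted clusters.
.majorityAlign <- function(empirical, planted) {
    planted <- planted[names(empirical)]
    map <- character(0)
    for (cl in unique(empirical)) {
        tab <- sort(table(planted[empirical == cl]), decreasing = TRUE)
        if (length(tab) > 1L && tab[1L] == tab[2L])
            stop("alignment error: empirical cluster '", cl,
                 "' has no majority planted cluster", call. = FALSE)
        map[cl] <- names(tab)[1L]
    }
    map
}

#' Score a CSS matrix against the planted cluster mapping
#'
#' Aligns the empirical clusters behind a CSS matrix to the planted
#' clusters by majority cell overlap, then checks how many planted shared
#' cluster pairs are recovered by the row-wise argmax of the matrix, and
#' whether each planted condition-exclusive cluster is isolated (its
#' aligned column's best score is the smallest column maximum; analogously
#' for rows of A-exclusive clusters).
#'
#' @param truth the \code{truth} element of [simulatePairedDatasets()].
#' @param css a [CSSMatrix-class] whose row/column labels are clusters of
#'   dataset A / B.
#' @param labels_a,labels_b empirical per-cell labelings the CSS matrix was
#'   built from; omit when the matrix was built directly from the planted
#'   labels.
#' @return list: \code{n_shared}, \code{n_matched}, \code{matched}
#'   (planted pair names recovered), \code{unmatched_unique} (planted
#'   exclusive clusters), \code{unique_isolated} (TRUE when every exclusive
#'   cluster has the smallest best-match score on its side), plus the
#'   row/column alignment maps.
#' @export
expectedMappingScore <- function(truth, css, labels_a = NULL,
                                 labels_b = NULL) {
    v <- cssValues(css)
    row_map <- if (is.null(labels_a)) setNames(rownames(v), rownames(v))
               else .majorityAlign(labels_a, truth$labels_a)
    col_map <- if (is.null(labels_b)) setNames(colnames(v), colnames(v))
               else .majorityAlign(labels_b, truth$labels_b)
    if (!all(rownames(v) %in% names(row_map)) ||
        !all(colnames(v) %in% names(col_map)))
        stop("alignment error: CSS labels not covered by the labelings",
             call. = FALSE)

    matched <- character(0)
    for (i in seq_len(nrow(truth$mapping))) {
        pa <- truth$mapping$a[i]; pb <- truth$mapping$b[i]
        rows <- rownames(v)[row_map[rownames(v)] == pa]
        if (!length(rows)) next
        hits <- vapply(rows, function(r) {
            best <- colnames(v)[which.max(v[r, ])]
            col_map[[best]] == pb
        }, logical(1))
        if (all(hits)) matched <- c(matched, pa)
    }
    uniq_b <- setdiff(unique(truth$labels_b), truth$mapping$b)
    uniq_a <- setdiff(unique(truth$labels_a), truth$mapping$a)
    col_max <- apply(v, 2L, max)
    row_max <- apply(v, 1L, max)
    isolated <- TRUE
    for (u in uniq_b) {
        cols <- colnames(v)[col_map[colnames(v)] == u]
        others <- setdiff(colnames(v), cols)
        if (!length(cols) ||
            max(col_max[cols]) >= min(col_max[others]))
            isolated <- FALSE
    }
    for (u in uniq_a) {
        rows <- rownames(v)[row_map[rownames(v)] == u]
        others <- setdiff(rownames(v), rows)
        if (!length(rows) ||
            max(row_max[rows]) >= min(row_max[others]))
            isolated <- FALSE
    }
    list(n_shared = nrow(truth$mapping), n_matched = length(matched),
         matched = matched, unmatched_unique = c(uniq_a, uniq_b),
         unique_isolated = isolated,
         row_map = row_map, col_map = col_map)
}
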
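#' @import ggplot2
NULL

#' Select genes for a Nebula plot
#'
#' Partitions the retained markers of two clusters into cluster-A-specific,
#' shared, and cluster-B-specific genes and keeps the top \code{k_specific}
#' (resp. \code{k_shared}) of each block. "Top" is ranked by the marker
#' weight ([markerWeight()]) -- the expression strength x breadth x
#' specificity composite the similarity score itself uses; shared genes are
#' ranked by the mean of their two weights.
#'
#' @param markers_a,markers_b single-cluster marker slices (retained
#'   markers of the two focal clusters).
#' @param k_specific genes kept per specific block.
#' @param k_shared genes kept in the shared block.
#' @param pct_floor background-fraction floor for the weights.
#' @return list with character vectors \code{specific_a}, \code{shared},
#'   \code{specific_b}, each in decreasing weight order. Blocks with fewer
#'   candidates than requested return all available, with a warning.
#' @export
selectNebulaGenes <- function(markers_a, markers_b, k_specific = 15,
                              k_shared = 10, pct_floor = 0.001) {
    wa <- setNames(markerWeight(markers_a$avg_logFC, markers_a$pct.1,
                                markers_a$pct.2, pct_floor), markers_a$gene)
    wb <- setNames(markerWeight(markers_b$avg_logFC, markers_b$pct.1,
                                markers_b$pct.2, pct_floor), markers_b$gene)
    shared <- intersect(names(wa), names(wb))
    only_a <- setdiff(names(wa), shared)
    only_b <- setdiff(names(wb), shared)
    topk <- function(w, k, what) {
        if (length(w) < k)
            warning("only ", length(w), " ", what, " gene(s) available (",
                    k, " requested)")
        names(sort(w, decreasing = TRUE))[seq_len(min(k, length(w)))]
    }
    list(specific_a = topk(wa[only_a], k_specific, "cluster-A-specific"),
         shared = topk((wa[shared] + wb[shared]) / 2, k_shared, "shared"),
         specific_b = topk(wb[only_b], k_specific, "cluster-B-specific"))
}

## Center-out slot order for k items ranked best-first: best in the middle,
## then alternating right, left, right, ...
.centerOutSlots <- function(k) {
    if (k == 0L) return(integer(0))
    centre <- as.integer(ceiling(k / 2))
    offs <- c(0L, as.vector(rbind(seq_len(k), -seq_len(k))))
    slots <- centre + offs
    slots[slots >= 1L & slots <= k][seq_len(k)]
}

#' Prepare the data layer of a Nebula plot
#'
#' For every selected gene, extracts the four expression samples (cluster
#' A, cluster B, and their backgrounds -- all cells of the dataset outside
#' the focal cluster, mirroring marker detection), the average-expression
#' "diamond" levels (log1p of the mean de-logged normalized expression,
#' the same averaging convention as the marker fold change), and the
#' fraction of cluster cells expressing the gene. Genes are ordered for
#' display: A-specific genes in decreasing order of the A diamond,
#' B-specific genes in increasing order of the B diamond, and shared genes
#' by the mean of the two diamonds with the highest mean at the center,
#' falling off on either side.
#'
#' @param counts count matrix or \code{SingleCellExperiment}.
#' @param labels per-cell cluster labels.
#' @param cluster_a,cluster_b the two focal cluster labels.
#' @param partition gene partition from [selectNebulaGenes()] (list with
#'   \code{specific_a}, \code{shared}, \code{specific_b}).
#' @param target_sum per-cell normalization total.
#' @return A [NebulaSpec-class].
#' @export
prepareNebulaData <- function(counts, labels, cluster_a, cluster_b,
                              partition, target_sum = 1e4) {
    m <- .countsOf(counts)
    labels <- .alignLabels(labels, colnames(m))
    for (cl in c(cluster_a, cluster_b))
        if (!cl %in% labels)
            stop("key error: cluster '", cl, "' not present", call. = FALSE)
    genes <- unlist(partition, use.names = FALSE)
    miss <- setdiff(genes, rownames(m))
    if (length(miss))
        stop("key error: gene(s) absent from matrix: ",
             paste(miss, collapse = ", "), call. = FALSE)
    groups <- rep(c("specific_a", "shared", "specific_b"),
                  lengths(partition[c("specific_a", "shared", "specific_b")]))
    genes <- unlist(partition[c("specific_a", "shared", "specific_b")],
                    use.names = FALSE)

    ln <- as.matrix(.logNormalize(m[genes, , drop = FALSE], target_sum))
    in_a <- labels == cluster_a
    in_b <- labels == cluster_b
    diamond <- function(x) log1p(mean(expm1(x)))
    ga <- apply(ln[, in_a, drop = FALSE], 1L, diamond)
    gb <- apply(ln[, in_b, drop = FALSE], 1L, diamond)
    fa <- Matrix::rowMeans(m[genes, in_a, drop = FALSE] > 0)
    fb <- Matrix::rowMeans(m[genes, in_b, drop = FALSE] > 0)

    df <- data.frame(gene = genes, group = groups, diamond_a = ga,
                     diamond_b = gb, frac_a = fa, frac_b = fb,
                     stringsAsFactors = FALSE)
    ## display positions per the three ordering rules
    pos <- integer(nrow(df))
    ia <- which(df$group == "specific_a")
    is <- which(df$group == "shared")
    ib <- which(df$group == "specific_b")
    pos[ia[order(-df$diamond_a[ia])]] <- seq_along(ia)
    if (length(is)) {
        ranked <- is[order(-(df$diamond_a[is] + df$diamond_b[is]) / 2)]
        pos[ranked] <- length(ia) + .centerOutSlots(length(is))
    }
    pos[ib[order(df$diamond_b[ib])]] <-
        length(ia) + length(is) + seq_along(ib)
    df$position <- pos
    rownames(df) <- NULL

    expr <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
        g <- df$gene[i]
        rbind(data.frame(gene = g, violin = "bg_a", value = ln[g, !in_a]),
              data.frame(gene = g, violin = "a", value = ln[g, in_a]),
              data.frame(gene = g, violin = "b", value = ln[g, in_b]),
              data.frame(gene = g, violin = "bg_b", value = ln[g, !in_b]))
    }))
    rownames(expr) <- NULL
    new("NebulaSpec", genes = df, expr = expr,
        clusterA = as.character(cluster_a),
        clusterB = as.character(cluster_b))
}

#' Render a Nebula plot
#'
#' Draws four violins per gene (background A, cluster A, cluster B,
#' background B, left to right), black diamonds at the average expression
#' levels, expressing-fraction bars along the top, and gene labels colored
#' by block (A-specific, shared, B-specific). Output is deterministic for
#' a given spec.
#'
#' @param spec a [NebulaSpec-class].
#' @param path output file; the device is chosen from \code{format}.
#' @param format \code{"svg"} or \code{"png"}.
#' @param width,height device size in inches.
#' @param colors length-3 vector: A-specific, shared, B-specific.
#' @return \code{path}, invisibly.
#' @export
renderNebula <- function(spec, path, format = c("svg", "png"),
                         width = NULL, height = 6,
                         colors = c("#2166ac", "#4d4d4d", "#b2182b")) {
    stopifnot(is(spec, "NebulaSpec"))
    format <- match.arg(format)
    g <- spec@genes[order(spec@genes$position), , drop = FALSE]
    ng <- nrow(g)
    if (is.null(width)) width <- max(6, 0.45 * ng)
    off <- c(bg_a = 1, a = 2, b = 3, bg_b = 4)
    expr <- spec@expr
    expr$x <- (match(expr$gene, g$gene) - 1L) * 5L + off[expr$violin]
    expr$violin <- factor(expr$violin, names(off))
    dia <- rbind(
        data.frame(x = (seq_len(ng) - 1L) * 5L + off[["a"]], y = g$diamond_a),
        data.frame(x = (seq_len(ng) - 1L) * 5L + off[["b"]], y = g$diamond_b))
    ymax <- max(expr$value, 1e-6)
    bars <- rbind(
        data.frame(x = (seq_len(ng) - 1L) * 5L + off[["a"]], frac = g$frac_a,
                   side = "a"),
        data.frame(x = (seq_len(ng) - 1L) * 5L + off[["b"]], frac = g$frac_b,
                   side = "b"))
    bars$ymin <- ymax * 1.06
    bars$ymax <- ymax * (1.06 + 0.25 * bars$frac)
    lab_col <- colors[match(g$group, c("specific_a", "shared", "specific_b"))]
    labs_df <- data.frame(x = (seq_len(ng) - 1L) * 5L + 2.5, gene = g$gene,
                          col = lab_col)

    p <- ggplot(expr, aes(x = .data$x, y = .data$value,
                          group = .data$x, fill = .data$violin)) +
        geom_violin(scale = "width", width = 0.9, linewidth = 0.15,
                    adjust = 1.5, na.rm = TRUE) +
        geom_point(data = dia, aes(x = .data$x, y = .data$y),
                   inherit.aes = FALSE, shape = 18, size = 2) +
        geom_rect(data = bars,
                  aes(xmin = .data$x - 0.45, xmax = .data$x + 0.45,
                      ymin = .data$ymin, ymax = .data$ymax,
                      fill = .data$side),
                  inherit.aes = FALSE, show.legend = FALSE) +
        geom_text(data = labs_df,
                  aes(x = .data$x, y = -0.06 * ymax, label = .data$gene),
                  inherit.aes = FALSE, angle = 90, hjust = 1, size = 2.6,
                  colour = labs_df$col) +
        scale_fill_manual(values = c(bg_a = "#c6dbef", a = colors[1],
                                     b = colors[3], bg_b = "#fdd0a2"),
                          breaks = c("bg_a", "a", "b", "bg_b"),
                          labels = c(paste0(spec@clusterA, " background"),
                                     spec@clusterA, spec@clusterB,
                                     paste0(spec@clusterB, " background")),
                          name = NULL) +
        coord_cartesian(ylim = c(-0.45 * ymax, ymax * 1.35), clip = "off") +
        labs(x = NULL, y = "log-normalized expression",
             title = sprintf("%s vs %s", spec@clusterA, spec@clusterB)) +
        theme_classic(base_size = 9) +
        theme(axis.text.x = element_blank(),
              axis.ticks.x = element_blank(),
              legend.position = "bottom")

    dev <- switch(format,
        svg = function(f) grDevices::svg(f, width = width, height = height),
        png = function(f) grDevices::png(f, width = width, height = height,
                                         units = "in", res = 150))
    dev(path)
    on.exit(grDevices::dev.off())
    print(p)
    invisible(path)
}
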
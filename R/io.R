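#' @importFrom Matrix readMM writeMM colSums rowSums rowMeans t sparseMatrix
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

## Locate a triplet member, accepting plain and gzipped variants.
.tripletMember <- function(dir, base) {
    for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz"))))
        if (file.exists(f)) return(f)
    stop("format error: missing 10x triplet member '", base,
         "' (plain or .gz) in ", dir, call. = FALSE)
}

.readLinesMaybeGz <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    readLines(con)
}

#' Read a 10x-style count-matrix triplet
#'
#' Reads a directory holding \code{matrix.mtx}, \code{features.tsv} and
#' \code{barcodes.tsv} (each optionally gzipped; MatrixMarket coordinate
#' format, genes x cells) into a [SingleCellExperiment::SingleCellExperiment]
#' with a single \code{"counts"} assay of non-negative integers.
#'
#' @param path directory containing the triplet.
#' @param dataset_id identifier stored in the object metadata; defaults to
#'   the directory name.
#' @return A \code{SingleCellExperiment}; gene ids are rownames, cell
#'   barcodes colnames.
#' @details Duplicate gene ids are deduplicated by suffixing (\code{.1},
#'   \code{.2}, ...) with a warning. Non-integer or negative matrix entries
#'   are a format error.
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(path, dataset_id = basename(normalizePath(path))) {
    if (!dir.exists(path))
        stop("format error: '", path, "' is not a directory", call. = FALSE)
    fm <- .tripletMember(path, "matrix.mtx")
    ff <- .tripletMember(path, "features.tsv")
    fb <- .tripletMember(path, "barcodes.tsv")

    m <- if (grepl("\\.gz$", fm)) {
        con <- gzfile(fm, "rt")
        on.exit(close(con), add = TRUE)
        Matrix::readMM(con)
    } else Matrix::readMM(fm)
    m <- as(m, "CsparseMatrix")
    if (any(m@x < 0) || any(m@x != round(m@x)))
        stop("format error: count matrix contains negative or non-integer ",
             "values", call. = FALSE)

    feat <- .readLinesMaybeGz(ff)
    genes <- vapply(strsplit(feat, "\t", fixed = TRUE), `[[`, "", 1L)
    cells <- .readLinesMaybeGz(fb)
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
        stop("format error: matrix dimensions (", nrow(m), " x ", ncol(m),
             ") do not match features/barcodes (", length(genes), " / ",
             length(cells), ")", call. = FALSE)
    if (anyDuplicated(genes)) {
        warning("duplicate gene ids deduplicated by suffixing")
        genes <- make.unique(genes, sep = ".")
    }
    if (anyDuplicated(cells))
        stop("format error: duplicate cell barcodes", call. = FALSE)
    dimnames(m) <- list(genes, cells)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        metadata = list(dataset_id = dataset_id))
}

#' Write a count matrix as a 10x-style triplet
#'
#' @param counts a \code{SingleCellExperiment} with a \code{"counts"} assay,
#'   or a (sparse) integer matrix with gene/cell dimnames.
#' @param path output directory (created if needed).
#' @param gzip write gzipped members.
#' @return \code{path}, invisibly.
#' @export
writeCountMatrix <- function(counts, path, gzip = FALSE) {
    m <- .countsOf(counts)
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    ext <- if (gzip) ".gz" else ""
    mf <- file.path(path, "matrix.mtx")
    Matrix::writeMM(m, mf)
    if (gzip) {
        con <- gzfile(paste0(mf, ".gz"), "wt")
        writeLines(readLines(mf), con)
        close(con)
        unlink(mf)
    }
    .writeLinesMaybeGz(rownames(m), file.path(path, paste0("features.tsv", ext)))
    .writeLinesMaybeGz(colnames(m), file.path(path, paste0("barcodes.tsv", ext)))
    invisible(path)
}

.writeLinesMaybeGz <- function(x, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(x, con)
}

## Extract the counts matrix from any accepted container.
.countsOf <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "counts")
    if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
    x <- as(x, "CsparseMatrix")
    if (is.null(rownames(x)) || is.null(colnames(x)))
        stop("count matrix must carry gene and cell ids as dimnames",
             call. = FALSE)
    x
}

.datasetIdOf <- function(x, default = "dataset") {
    if (is(x, "SummarizedExperiment")) {
        id <- S4Vectors::metadata(x)$dataset_id
        if (!is.null(id)) return(id)
    }
    default
}

.MARKER_COLS <- c("gene", "cluster", "avg_logFC", "pct.1", "pct.2",
                  "p_val", "p_val_adj")

#' Read a marker table
#'
#' Reads a TSV of per-cluster marker genes in the classic export dialect:
#' columns \code{gene}, \code{cluster}, \code{avg_logFC} (natural-log fold
#' change of average expression, cluster vs background), \code{pct.1} /
#' \code{pct.2} (expressing fractions in cluster / background), \code{p_val},
#' \code{p_val_adj} (Benjamini-Hochberg). Rows failing the adjusted-p
#' threshold, and (by default) non-positive markers, are dropped on read.
#'
#' A table with an \code{avg_log2FC} column is rejected outright: the
#' similarity weights assume the natural-log dialect, and silently accepting
#' log2 fold changes would distort every downstream score.
#'
#' @param path TSV file.
#' @param p_threshold keep rows with \code{p_val_adj <=} this value.
#' @param positive_only drop rows with \code{avg_logFC <= 0}.
#' @return data.frame of retained markers with attribute
#'   \code{retained_only} recording whether the default retention filter
#'   (p <= 0.05, positive) is guaranteed.
#' @export
readMarkerTable <- function(path, p_threshold = 0.05, positive_only = TRUE) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if ("avg_log2FC" %in% names(df))
        stop("format error: column 'avg_log2FC' found; marker tables must ",
             "use the natural-log 'avg_logFC' dialect", call. = FALSE)
    need <- setdiff(.MARKER_COLS, c("p_val"))
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("format error: missing marker-table column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (!"p_val" %in% names(df)) df$p_val <- df$p_val_adj
    if (any(df$pct.1 < 0 | df$pct.1 > 1 | df$pct.2 < 0 | df$pct.2 > 1))
        stop("value error: pct.1/pct.2 outside [0, 1]", call. = FALSE)
    if (any(df$p_val_adj < 0 | df$p_val_adj > 1))
        stop("value error: p_val_adj outside [0, 1]", call. = FALSE)
    df$cluster <- as.character(df$cluster)
    df <- df[df$p_val_adj <= p_threshold, , drop = FALSE]
    if (positive_only) df <- df[df$avg_logFC > 0, , drop = FALSE]
    rownames(df) <- NULL
    df <- df[, .MARKER_COLS, drop = FALSE]
    attr(df, "retained_only") <- (p_threshold <= 0.05) && positive_only
    df
}

#' Write a marker table as TSV
#'
#' @param markers marker data.frame (as from [findClusterMarkers()]).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMarkerTable <- function(markers, path) {
    write.table(markers[, intersect(.MARKER_COLS, names(markers))], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## Zero-pad purely numeric cluster labels for deterministic lexicographic
## ordering on disk.
.padLabels <- function(x) {
    if (all(grepl("^[0-9]+$", x)))
        paste0(strrep("0", max(nchar(x)) - nchar(x)), x)
    else x
}

#' Write / read a CSS matrix as CSV
#'
#' The CSV carries column cluster labels in the header and row cluster
#' labels in the first column; values survive a round trip to at least
#' twelve significant decimal digits.
#'
#' @param css a [CSSMatrix-class].
#' @param path CSV file.
#' @return For the writer, \code{path} invisibly; for the reader, a
#'   \code{CSSMatrix}.
#' @export
writeCSSMatrix <- function(css, path) {
    v <- cssValues(css)
    rownames(v) <- .padLabels(rownames(v))
    colnames(v) <- .padLabels(colnames(v))
    df <- data.frame(cluster = rownames(v),
                     signif(v, 15), check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCSSMatrix
#' @export
readCSSMatrix <- function(path) {
    nm <- names(read.csv(path, check.names = FALSE, nrows = 1))
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = c("character",
                                  rep("numeric", length(nm) - 1L)))
    v <- as.matrix(df[, -1L, drop = FALSE])
    rownames(v) <- as.character(df[[1L]])
    CSSMatrix(v)
}

#' Write / read a ranked parameter table as CSV
#'
#' Columns: \code{rank}, \code{res}, \code{npcs}, \code{di},
#' \code{m_clusters}, \code{n_clusters}.
#'
#' @param ranked data.frame as returned in \code{$ranked} by
#'   [sweepAndRank()].
#' @param path CSV file.
#' @export
writeRankedTable <- function(ranked, path) {
    cols <- c("rank", "res", "npcs", "di", "m_clusters", "n_clusters")
    miss <- setdiff(cols, names(ranked))
    if (length(miss))
        stop("format error: ranked table missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    out <- ranked[, cols, drop = FALSE]
    out$di <- signif(out$di, 15)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeRankedTable
#' @export
readRankedTable <- function(path) {
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
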
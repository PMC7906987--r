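#' Log2-transform an expression matrix
#'
#' Applies \code{log2(x + pseudocount)} cell-wise. The transform is not
#' assumed idempotent: the caller is responsible for flagging whether a
#' matrix is already on the log scale.
#'
#' @param x numeric matrix, all values >= 0.
#' @param pseudocount non-negative offset; must be > 0 if any value is 0.
#' @return matrix of the same shape.
#' @examples
#' log2Transform(matrix(c(0, 3, 7), 3, 1,
#'                      dimnames = list(c("a","b","c"), "s1")), 1)
#' @export
log2Transform <- function(x, pseudocount = 0) {
    x <- as.matrix(x)
    bad <- which(x < 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop(sprintf("negative expression value at row %d, column %d",
                     bad[1, 1], bad[1, 2]))
    if (pseudocount < 0) stop("pseudocount must be non-negative")
    if (pseudocount == 0 && any(x == 0))
        stop("pseudocount must be > 0 when the matrix contains zeros")
    log2(x + pseudocount)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile-normalize the columns of a matrix
#'
#' Forces every column (sample) onto the same empirical distribution: the
#' reference is the vector of row means of the column-wise sorted matrix, and
#' each column's values are replaced by the reference value at their rank.
#' Ties within a column receive the mean of the reference values their rank
#' range spans, so the result is deterministic.
#'
#' @param x numeric matrix with >= 2 columns and no missing values.
#' @return matrix of the same shape; every column has an identical sorted
#'   value vector.
#' @examples
#' quantileNormalize(cbind(a = c(5, 2, 3), b = c(4, 1, 6)))
#' @export
quantileNormalize <- function(x) {
    x <- as.matrix(x)
    if (anyNA(x)) stop("missing values are not allowed; drop those genes first")
    if (ncol(x) < 2) {
        warning("single-column matrix returned unchanged")
        return(x)
    }
    ref <- rowMeans(apply(x, 2, sort))
    out <- x
    for (j in seq_len(ncol(x))) {
        col <- x[, j]
        v <- ref[order(order(col))]       # reference value at each rank
        # tie groups share the mean of the reference values they span
        out[, j] <- stats::ave(v, match(col, col), FUN = mean)
    }
    out
}

#' Read a probe-to-gene mapping table
#'
#' Two-column tab-separated file (probe_id, gene_id), many probes to one
#' gene. A probe mapped to more than one gene is an error.
#'
#' @param path file path.
#' @return named character vector: names are probe ids, values gene ids.
#' @export
readProbeGeneMap <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
    if (ncol(tab) < 2) stop("probe map must have two columns: probe_id, gene_id")
    probes <- trimws(tab[[1]]); genes <- trimws(tab[[2]])
    dup <- unique(probes[duplicated(probes)])
    conflict <- dup[vapply(dup, function(p)
        length(unique(genes[probes == p])) > 1L, logical(1))]
    if (length(conflict))
        stop("probe(s) mapped to more than one gene: ",
             paste(utils::head(conflict, 5), collapse = ", "))
    keep <- !duplicated(probes)
    stats::setNames(genes[keep], probes[keep])
}

#' Collapse probe-level rows to gene level
#'
#' @param x probe-level matrix (rownames are probe ids).
#' @param map named character vector probe_id -> gene_id (see
#'   \code{\link{readProbeGeneMap}}).
#' @param rule \code{"max_mean_probe"} (default: keep the probe with the
#'   highest mean across samples) or \code{"median_of_probes"} (per-sample
#'   median over a gene's probes).
#' @return gene-level matrix. Attribute \code{"provenance"} records, per
#'   gene, the chosen probe (max_mean_probe) or the probe count
#'   (median_of_probes); attribute \code{"unmapped"} lists probes absent from
#'   the map (excluded, with a message).
#' @export
collapseProbes <- function(x, map, rule = c("max_mean_probe",
                                            "median_of_probes")) {
    rule <- match.arg(rule)
    x <- as.matrix(x)
    probes <- rownames(x)
    unmapped <- probes[!probes %in% names(map)]
    if (length(unmapped))
        message(length(unmapped), " probe(s) absent from the map were excluded")
    keep <- probes %in% names(map)
    x <- x[keep, , drop = FALSE]
    gene <- unname(map[rownames(x)])
    genes <- unique(gene)
    out <- matrix(NA_real_, length(genes), ncol(x),
                  dimnames = list(genes, colnames(x)))
    prov <- character(length(genes)); names(prov) <- genes
    for (g in genes) {
        rows <- which(gene == g)
        if (rule == "max_mean_probe") {
            best <- rows[which.max(rowMeans(x[rows, , drop = FALSE]))]
            out[g, ] <- x[best, ]
            prov[g] <- rownames(x)[best]
        } else {
            out[g, ] <- apply(x[rows, , drop = FALSE], 2, stats::median)
            prov[g] <- as.character(length(rows))
        }
    }
    structure(out, provenance = prov, unmapped = unmapped)
}

#' Preprocess one dataset: drop incomplete genes, quantile-normalize
#'
#' Genes with any missing value are dropped (no imputation) and reported via
#' a message; the matrix is then quantile-normalized within the dataset.
#' Input is assumed to be on the log2 scale already (use
#' \code{\link{log2Transform}} upstream if not).
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @return the dataset with its expression assay normalized.
#' @export
preprocessDataset <- function(dataset) {
    x <- exprs(dataset)
    bad <- rowSums(!is.finite(x)) > 0
    if (any(bad)) {
        message(datasetId(dataset), ": dropped ", sum(bad),
                " gene(s) with missing values")
        dataset <- dataset[!bad, ]
        x <- exprs(dataset)
    }
    SummarizedExperiment::assay(dataset, "exprs") <- quantileNormalize(x)
    dataset
}
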